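#' Birefringent retarder
#'
#' @param retardance_nm optical path difference between extraordinary and
#'   ordinary axes, `lambda0 = delta_n * d` in nm; > 0.
#' @param axis_deg orientation of the extraordinary axis in degrees.
#' @return object of class `retarder`.
#' @export
retarder <- function(retardance_nm, axis_deg = 0) {
  if (!is.finite(retardance_nm) || retardance_nm <= 0) {
    stop_config("retardance_nm must be > 0")
  }
  structure(list(retardance_nm = retardance_nm, axis_deg = axis_deg),
            class = "retarder")
}

#' Instrument configuration for the single-shot modulation module
#'
#' Describes one of the two single-shot configurations:
#' `"polarsens_single_shot"` -- input linear polariser, two identical
#' retarders (extraordinary axes at 45 and 0 degrees) and a
#' division-of-focal-plane camera whose 2x2 pixel mosaic analyses at 0, 45,
#' 90 and 135 degrees; or `"four_detector"` -- a polarising beamsplitter
#' feeding two parallel Lyot stages with retardances `lambda0` and
#' `2*lambda0`, each read out by a complementary detector pair.
#'
#' The default retardance of 335 nm corresponds to half-wave plates designed
#' for 670 nm.
#'
#' @param config_kind `"polarsens_single_shot"` or `"four_detector"`.
#' @param retardance_nm base retardance `lambda0` (nm), > 0.
#' @param extinction_ratio analyser contrast; `Inf` (default) is an ideal
#'   analyser.  A finite scalar is applied as channel mixing by
#'   [mosaic_and_noise()]; a `function(lambda_nm)` models a
#'   wavelength-dependent roll-off and is applied inside the channel
#'   integrals by [polarsens_channels()].
#' @param mosaic_layout 2x2 integer matrix giving the analyser angle of each
#'   pixel in a superpixel; must be a permutation of 0, 45, 90, 135.
#' @return object of class `instrument_config`.
#' @examples
#' cfg <- instrument_config()
#' cfg$retardance_nm
#' @export
instrument_config <- function(config_kind = c("polarsens_single_shot",
                                              "four_detector"),
                              retardance_nm = 335,
                              extinction_ratio = Inf,
                              mosaic_layout = matrix(c(90, 135, 45, 0), 2, 2)) {
  config_kind <- match.arg(config_kind)
  if (!is.finite(retardance_nm) || retardance_nm <= 0) {
    stop_config("retardance_nm must be > 0")
  }
  if (!is.function(extinction_ratio)) {
    if (!is.numeric(extinction_ratio) || length(extinction_ratio) != 1L ||
        extinction_ratio <= 1) {
      stop_config("extinction_ratio must be > 1 (Inf = ideal) or a function of wavelength")
    }
  }
  mosaic_layout <- as.matrix(mosaic_layout)
  if (!all(dim(mosaic_layout) == c(2L, 2L)) ||
      !setequal(as.vector(mosaic_layout), c(0, 45, 90, 135))) {
    stop_config("mosaic_layout must be a 2x2 permutation of 0, 45, 90, 135 degrees")
  }
  structure(list(config_kind = config_kind, retardance_nm = retardance_nm,
                 extinction_ratio = extinction_ratio,
                 mosaic_layout = mosaic_layout),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  er <- if (is.function(x$extinction_ratio)) "wavelength-dependent"
        else format(x$extinction_ratio)
  cat(sprintf("<instrument_config> %s, lambda0 = %g nm, extinction ratio %s\n",
              x$config_kind, x$retardance_nm, er))
  invisible(x)
}

#' Lyot filter spectral transmission
#'
#' Transmission of a retarder of retardance `lambda0` between parallel linear
#' polarisers, for normally incident light:
#' `T(lambda) = cos^2(pi * lambda0 / lambda)`, i.e. a raised cosine in
#' optical frequency.
#'
#' @param retardance_nm retardance `lambda0` in nm, > 0.
#' @param wavelength_nm wavelength(s) in nm, > 0.
#' @return transmission fraction(s) in \[0, 1\].
#' @examples
#' lyot_transmission(335, c(335, 670))
#' @export
lyot_transmission <- function(retardance_nm, wavelength_nm) {
  if (any(!is.finite(retardance_nm)) || any(retardance_nm <= 0)) {
    stop_data("retardance_nm must be > 0")
  }
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    stop_data("wavelength_nm must be > 0")
  }
  cos(pi * retardance_nm / wavelength_nm)^2
}

# frequency-domain quadrature: weights aligned with the grid's stored
# wavelength order such that sum(w * I_lambda * lambda^2) = int I(u) du
freq_quadrature <- function(grid) {
  wl <- grid$wavelengths_nm
  u <- wavelength_to_freq(wl)              # decreasing
  w <- rev(trapz_weights(rev(u)))
  list(u = u, w = w, jac = wl^2)
}

# L x 4 kernel matrix for the mosaic-analyser channels (I0, I45, I90, I135);
# er is Inf, or a vector of per-wavelength extinction ratios
polarsens_kernels <- function(u, lambda0, er = Inf) {
  phi <- 2 * pi * lambda0 * u
  k <- cbind(I0   = (1 + cos(phi)) / 2,
             I45  = (3 - cos(2 * phi)) / 4,
             I90  = (1 - cos(phi)) / 2,
             I135 = (1 + cos(2 * phi)) / 4)
  if (any(is.finite(er))) {
    mix <- function(par, perp) (er * par + perp) / (er + 1)
    k <- cbind(I0   = mix(k[, "I0"], k[, "I90"]),
               I45  = mix(k[, "I45"], k[, "I135"]),
               I90  = mix(k[, "I90"], k[, "I0"]),
               I135 = mix(k[, "I135"], k[, "I45"]))
  }
  k
}

#' Single-shot mosaic-camera channel integrals for one spectrum
#'
#' Forward model of the polarisation-mosaic configuration: for polarised
#' input flux `Ii(nu)` entering the retarder pair, the four analyser channels
#' are
#' \deqn{I_0 = \int \frac{I_i}{2}(1+\cos\Lambda\nu)\,d\nu,\quad
#'       I_{90} = \int \frac{I_i}{2}(1-\cos\Lambda\nu)\,d\nu,}
#' \deqn{I_{45} = \int \frac{I_i}{4}(3-\cos 2\Lambda\nu)\,d\nu,\quad
#'       I_{135} = \int \frac{I_i}{4}(1+\cos 2\Lambda\nu)\,d\nu,}
#' with \eqn{\Lambda\nu = 2\pi\lambda_0/\lambda}.  Each complementary pair
#' sums to the input power: `I0 + I90 = I45 + I135 = total`.
#'
#' The input spectrum is taken *after* the input polariser; see
#' [render_scene()] for the unpolarised-input loss factor.
#'
#' @param spectrum a `light_spectrum` (polarised flux entering the retarders).
#' @param config an `instrument_config` with
#'   `config_kind = "polarsens_single_shot"`.
#' @return named numeric vector `c(I0, I45, I90, I135)`.
#' @export
polarsens_channels <- function(spectrum, config = instrument_config()) {
  stopifnot(inherits(spectrum, "light_spectrum"),
            inherits(config, "instrument_config"))
  if (config$config_kind != "polarsens_single_shot") {
    stop_config("polarsens_channels requires a polarsens_single_shot config")
  }
  q <- freq_quadrature(spectrum$grid)
  er <- if (is.function(config$extinction_ratio)) {
    config$extinction_ratio(spectrum$grid$wavelengths_nm)
  } else Inf
  k <- polarsens_kernels(q$u, config$retardance_nm, er)
  drop((spectrum$intensity * q$jac * q$w) %*% k)
}

#' Four-detector dual-Lyot channel integrals
#'
#' Forward model of the lossless four-detector configuration: the input is
#' split into orthogonal polarisation components `Ii0` and `Ii90`, modulated
#' by parallel Lyot stages of retardance `lambda0` and `2*lambda0`
#' respectively, and each stage's transmitted and reflected outputs are both
#' detected:
#' \deqn{I_{0,0} = \int \frac{I_i^0}{2}(1+\cos\Lambda\nu)\,d\nu,\quad
#'       I_{0,90} = \int \frac{I_i^0}{2}(1-\cos\Lambda\nu)\,d\nu,}
#' \deqn{I_{90,0} = \int \frac{I_i^{90}}{2}(1-\cos 2\Lambda\nu)\,d\nu,\quad
#'       I_{90,90} = \int \frac{I_i^{90}}{2}(1+\cos 2\Lambda\nu)\,d\nu.}
#' Total detected power equals total input power (in principle lossless).
#'
#' @param spectrum_0deg,spectrum_90deg the two polarisation components as
#'   `light_spectrum` objects on the same grid.
#' @param config an `instrument_config` with `config_kind = "four_detector"`.
#' @return named numeric `c(I00, I090, I900, I9090)`.
#' @export
four_detector_channels <- function(spectrum_0deg, spectrum_90deg,
                                   config = instrument_config("four_detector")) {
  stopifnot(inherits(spectrum_0deg, "light_spectrum"),
            inherits(spectrum_90deg, "light_spectrum"),
            inherits(config, "instrument_config"))
  if (config$config_kind != "four_detector") {
    stop_config("four_detector_channels requires a four_detector config")
  }
  if (!identical(spectrum_0deg$grid$wavelengths_nm,
                 spectrum_90deg$grid$wavelengths_nm)) {
    stop_data("the two polarisation components must share one grid")
  }
  q <- freq_quadrature(spectrum_0deg$grid)
  phi <- 2 * pi * config$retardance_nm * q$u
  i0 <- spectrum_0deg$intensity * q$jac * q$w
  i90 <- spectrum_90deg$intensity * q$jac * q$w
  c(I00   = sum(i0 * (1 + cos(phi)) / 2),
    I090  = sum(i0 * (1 - cos(phi)) / 2),
    I900  = sum(i90 * (1 - cos(2 * phi)) / 2),
    I9090 = sum(i90 * (1 + cos(2 * phi)) / 2))
}

#' Per-pixel analysed channel images
#'
#' Container for the four polarisation-analysed intensity images produced by
#' an acquisition (or forward model), keyed by analyser label.
#'
#' @param channels named list of non-negative matrices of equal dimension;
#'   names `I0, I45, I90, I135` (mosaic camera) or `I00, I090, I900, I9090`
#'   (four-detector).
#' @param config the `instrument_config` used.
#' @param meta optional provenance list.
#' @return object of class `channel_images`.
#' @export
channel_images <- function(channels, config, meta = list()) {
  nm <- names(channels)
  ok <- identical(sort(nm), sort(c("I0", "I45", "I90", "I135"))) ||
    identical(sort(nm), sort(c("I00", "I090", "I900", "I9090")))
  if (!ok) stop_data("channel names must be the mosaic or four-detector quartet")
  d <- dim(channels[[1L]])
  for (ch in channels) {
    if (!is.matrix(ch) || !all(dim(ch) == d)) {
      stop_data("all channel images must be matrices of equal dimension")
    }
    if (any(ch < 0)) stop_data("channel intensities must be non-negative")
  }
  structure(list(channels = channels, config = config, meta = meta),
            class = "channel_images")
}

#' @export
print.channel_images <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<channel_images> %s: %d x %d pixels\n",
              paste(names(x$channels), collapse = ", "), d[1L], d[2L]))
  invisible(x)
}

#' Render a hyperspectral scene through the single-shot forward model
#'
#' Applies the input-polariser transmission factor (0.5 for unpolarised
#' incident light such as fluorescence, 1.0 for light already polarised along
#' the polariser axis) and then [polarsens_channels()] at every pixel.
#' Noiseless; see [mosaic_and_noise()] for the sensor model.
#'
#' @param scene a `hyperspectral_scene`.
#' @param config a polarsens `instrument_config`.
#' @param input_polarisation `"unpolarised"` or `"polarised_0deg"`.
#' @return a `channel_images` object with full-resolution `I0, I45, I90, I135`.
#' @export
render_scene <- function(scene, config = instrument_config(),
                         input_polarisation = c("unpolarised",
                                                "polarised_0deg")) {
  stopifnot(inherits(scene, "hyperspectral_scene"),
            inherits(config, "instrument_config"))
  input_polarisation <- match.arg(input_polarisation)
  if (config$config_kind != "polarsens_single_shot") {
    stop_config("render_scene models the polarsens_single_shot configuration")
  }
  factor <- if (input_polarisation == "unpolarised") 0.5 else 1.0
  q <- freq_quadrature(scene$grid)
  er <- if (is.function(config$extinction_ratio)) {
    config$extinction_ratio(scene$grid$wavelengths_nm)
  } else Inf
  k <- polarsens_kernels(q$u, config$retardance_nm, er)
  d <- dim(scene$cube)
  flat <- matrix(scene$cube, d[1L] * d[2L], d[3L])
  out <- factor * (flat %*% (q$jac * q$w * k))
  chans <- lapply(setNames(1:4, colnames(k)), function(j) {
    m <- matrix(out[, j], d[1L], d[2L])
    m[m < 0] <- 0     # guard against quadrature round-off at zero pixels
    m
  })
  channel_images(chans, config,
                 meta = list(input_polarisation = input_polarisation,
                             polariser_factor = factor))
}

#' Intensity behind a linear analyser for a given polarisation state
#'
#' Stokes description of one mosaic pixel: for incident state
#' `(S0, S1, S2, S3)` an ideal analyser at angle theta transmits
#' `(S0 + S1 cos 2theta + S2 sin 2theta) / 2`; a finite extinction ratio
#' mixes in the crossed channel as `(ER * Ipar + Iperp) / (ER + 1)`.
#'
#' @param stokes numeric length-4 vector or n x 4 matrix of Stokes vectors.
#' @param angle_deg analyser angle(s) in degrees.
#' @param extinction_ratio scalar analyser contrast, `Inf` for ideal.
#' @return numeric vector (or matrix over angles) of transmitted intensities.
#' @export
analyser_intensity <- function(stokes, angle_deg, extinction_ratio = Inf) {
  s <- if (is.matrix(stokes)) stokes else matrix(stokes, 1L)
  stopifnot(ncol(s) == 4L)
  ideal <- function(th) {
    (s[, 1L] + s[, 2L] * cos(2 * th * pi / 180) +
       s[, 3L] * sin(2 * th * pi / 180)) / 2
  }
  out <- sapply(angle_deg, function(th) {
    if (is.finite(extinction_ratio)) {
      (extinction_ratio * ideal(th) + ideal(th + 90)) / (extinction_ratio + 1)
    } else ideal(th)
  })
  if (is.matrix(stokes)) out else drop(out)
}

#' Photon efficiency of a 2x2 analyser-mosaic superpixel
#'
#' Fraction of sensor-incident light detected when each of the four pixels of
#' a superpixel analyses one of 0, 45, 90, 135 degrees.  For an ideal mask
#' this is exactly 1/2 for *any* incident polarisation state, because the
#' Malus factors of the four orientations average to 1/2.
#'
#' @param stokes length-4 Stokes vector or n x 4 matrix.
#' @param extinction_ratio scalar analyser contrast.
#' @return detected fraction(s) of incident power.
#' @examples
#' mask_efficiency(c(1, 1, 0, 0))   # horizontally polarised: 0.5
#' @export
mask_efficiency <- function(stokes, extinction_ratio = Inf) {
  s <- if (is.matrix(stokes)) stokes else matrix(stokes, 1L)
  det <- analyser_intensity(s, c(0, 45, 90, 135), extinction_ratio)
  det <- if (is.matrix(det)) rowSums(det) else sum(det)
  drop(det / (4 * s[, 1L]))
}
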