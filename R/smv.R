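#' Family of spectral modulation functions
#'
#' A set of N bounded functions \eqn{P_k(\nu)} onto which spectra are
#' projected to form spectral modulation vectors (SMVs).  Three named
#' families are provided, all with base phase
#' \eqn{\Lambda\nu = 2\pi\lambda_0/\lambda}:
#'
#' * `"polarsens_pair"`: \eqn{\{\cos\Lambda\nu,\ \sin^2\Lambda\nu\}} -- what
#'   the single-shot mosaic-camera configuration measures;
#' * `"cos_harmonics"`: \eqn{\{\cos k\Lambda\nu\}_{k=1..N}} -- the harmonic
#'   family of cascaded Lyot stages (the four-detector configuration
#'   measures k = 1, 2);
#' * `"phasor_pair"`: \eqn{\{\cos\Lambda\nu,\ \sin\Lambda\nu\}} -- the
#'   classical spectral-phasor pair.
#'
#' @param family one of `"polarsens_pair"`, `"cos_harmonics"`,
#'   `"phasor_pair"`.
#' @param retardance_nm base retardance `lambda0` (nm) setting the
#'   modulation frequency.
#' @param n number of harmonics for `"cos_harmonics"` (the pairs are fixed
#'   at N = 2).
#' @return object of class `modulation_set`.
#' @examples
#' mods <- modulation_set("polarsens_pair", 335)
#' compute_smv(make_narrowband(550, 3), mods)
#' @export
modulation_set <- function(family = c("polarsens_pair", "cos_harmonics",
                                      "phasor_pair"),
                           retardance_nm = 335, n = 2L) {
  family <- match.arg(family)
  if (!is.finite(retardance_nm) || retardance_nm <= 0) {
    stop_config("retardance_nm must be > 0")
  }
  n <- if (family == "cos_harmonics") as.integer(n) else 2L
  if (n < 1L) stop_config("n must be >= 1")
  structure(list(family = family, retardance_nm = retardance_nm, n = n),
            class = "modulation_set")
}

#' @export
print.modulation_set <- function(x, ...) {
  cat(sprintf("<modulation_set> %s, N = %d, lambda0 = %g nm\n",
              x$family, x$n, x$retardance_nm))
  invisible(x)
}

#' Evaluate the modulation functions at given wavelengths
#'
#' @param mods a `modulation_set`.
#' @param wavelength_nm wavelengths (nm).
#' @return matrix (length(wavelength_nm) x N) of \eqn{P_k} values in
#'   \[-1, 1\].
#' @export
eval_modulation <- function(mods, wavelength_nm) {
  stopifnot(inherits(mods, "modulation_set"))
  phi <- 2 * pi * mods$retardance_nm / wavelength_nm
  switch(mods$family,
    polarsens_pair = cbind(V1 = cos(phi), V2 = sin(phi)^2),
    phasor_pair    = cbind(V1 = cos(phi), V2 = sin(phi)),
    cos_harmonics  = {
      m <- sapply(seq_len(mods$n), function(k) cos(k * phi))
      m <- matrix(m, nrow = length(wavelength_nm))
      colnames(m) <- paste0("V", seq_len(mods$n))
      m
    })
}

#' Spectral modulation vector of a spectrum
#'
#' The normalised projection integrals, evaluated in optical frequency:
#' \deqn{V_k = \frac{\int I_i(\nu) P_k(\nu)\, d\nu}{\int I_i(\nu)\, d\nu}.}
#' Each component is bounded in \[-1, 1\] for any non-negative spectrum, and
#' the SMV of a weighted sum of spectra is the power-weighted mean of their
#' SMVs (the linearity that underpins unmixing).
#'
#' @param spectrum a `light_spectrum` with positive total power.
#' @param mods a `modulation_set`.
#' @return named numeric N-vector.
#' @export
compute_smv <- function(spectrum, mods) {
  stopifnot(inherits(spectrum, "light_spectrum"),
            inherits(mods, "modulation_set"))
  q <- freq_quadrature(spectrum$grid)
  iu <- spectrum$intensity * q$jac * q$w
  tot <- sum(iu)
  if (tot <= 0) stop_data("SMV undefined for a zero-power spectrum")
  p <- eval_modulation(mods, spectrum$grid$wavelengths_nm)
  drop(iu %*% p) / tot
}

#' Pairwise orthogonality integrals of a modulation family
#'
#' Computes the Gram matrix \eqn{\int P_l(\nu) P_m(\nu)\, d\nu} over a
#' frequency window.  The families are exactly orthogonal over an integer
#' number of base periods \eqn{2\pi/\Lambda} (period `1/lambda0` in reduced
#' frequency); over an arbitrary finite band -- such as a real instrument's
#' 450-650 nm span -- orthogonality is only approximate, so the matrix is
#' returned for inspection rather than asserted to vanish, and a warning
#' status flags non-integer-period windows.
#'
#' @param mods a `modulation_set`.
#' @param freq_window length-2 reduced-frequency interval (1/nm); default is
#'   one full period starting at `1/650`.
#' @param n_quad quadrature samples (uniform trapezoid; exact for
#'   trigonometric polynomials over full periods).
#' @return N x N matrix with attribute `"status"` (`"ok"` or
#'   `"non_integer_period"`).
#' @export
check_orthogonality <- function(mods, freq_window = NULL, n_quad = 4096L) {
  stopifnot(inherits(mods, "modulation_set"))
  period <- 1 / mods$retardance_nm
  if (is.null(freq_window)) freq_window <- 1 / 650 + c(0, period)
  stopifnot(length(freq_window) == 2L, freq_window[2L] > freq_window[1L])
  n_periods <- diff(freq_window) / period
  status <- "ok"
  if (abs(n_periods - round(n_periods)) > 1e-9) {
    status <- "non_integer_period"
    warning("window does not span an integer number of modulation periods; ",
            "orthogonality is only approximate")
  }
  u <- seq(freq_window[1L], freq_window[2L], length.out = n_quad)
  p <- eval_modulation(mods, 1 / u)
  w <- trapz_weights(u)
  gram <- t(p) %*% (w * p)
  attr(gram, "status") <- status
  gram
}

#' Per-pixel SMV image
#'
#' @param v array (height, width, N) of SMV components.
#' @param total matrix of per-pixel total intensity.
#' @param mask logical matrix; `TRUE` where the SMV is defined (intensity
#'   above threshold).  Components are `NA` where masked.
#' @param meta provenance list.
#' @return object of class `smv_image`.
#' @export
smv_image <- function(v, total, mask, meta = list()) {
  stopifnot(is.array(v), length(dim(v)) == 3L, is.matrix(total),
            is.matrix(mask), all(dim(total) == dim(v)[1:2]),
            all(dim(mask) == dim(total)))
  structure(list(v = v, total = total, mask = mask, meta = meta),
            class = "smv_image")
}

#' @export
print.smv_image <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<smv_image> %d x %d pixels, N = %d, %.1f%% valid\n",
              d[1L], d[2L], d[3L], 100 * mean(x$mask)))
  invisible(x)
}

# shared ratio machinery: numerators/denominators per component
smv_ratio_image <- function(num1, den1, num2, den2, total,
                            min_frac, min_abs, meta) {
  mask <- total > pmax(min_abs, min_frac * max(total)) & den1 > 0 & den2 > 0
  v1 <- ifelse(mask, num1 / den1, NA_real_)
  v2 <- ifelse(mask, num2 / den2, NA_real_)
  v <- array(c(v1, v2), dim = c(dim(total), 2L),
             dimnames = list(NULL, NULL, c("V1", "V2")))
  smv_image(v, total, mask, meta)
}

#' SMV image from mosaic-camera channel images
#'
#' Channel-ratio estimator of the \eqn{(\cos\Lambda\nu, \sin^2\Lambda\nu)}
#' SMV:
#' \deqn{V_1 = \frac{I_0 - I_{90}}{I_0 + I_{90}},\qquad
#'       V_2 = \frac{I_{45} - I_{135}}{I_{45} + I_{135}},}
#' with total intensity \eqn{I_0 + I_{90}}.  Pixels whose total intensity
#' falls at or below `max(min_abs, min_frac * max(total))` are masked (the
#' SMV is undefined at zero power), as are any 0/0 ratios, so no non-finite
#' values propagate.
#'
#' @param channels a mosaic-camera `channel_images` (full or half
#'   resolution).
#' @param min_frac relative intensity threshold (fraction of the image
#'   maximum).
#' @param min_abs absolute intensity threshold.
#' @return an `smv_image`.
#' @export
smv_from_polarsens <- function(channels, min_frac = 1e-3, min_abs = 0) {
  stopifnot(inherits(channels, "channel_images"))
  ch <- channels$channels
  if (!all(c("I0", "I45", "I90", "I135") %in% names(ch))) {
    stop_data("expected the I0/I45/I90/I135 channel set")
  }
  total <- ch$I0 + ch$I90
  smv_ratio_image(ch$I0 - ch$I90, total, ch$I45 - ch$I135, ch$I45 + ch$I135,
                  total, min_frac, min_abs,
                  meta = list(family = "polarsens_pair",
                              retardance_nm = channels$config$retardance_nm))
}

#' SMV image from four-detector channel quartets
#'
#' Channel-ratio estimator of the \eqn{(\cos\Lambda\nu, \cos 2\Lambda\nu)}
#' SMV from the dual-Lyot configuration:
#' \deqn{V_1 = \frac{I_{0,0} - I_{0,90}}{I_{0,0} + I_{0,90}},\qquad
#'       V_2 = \frac{I_{90,90} - I_{90,0}}{I_{90,90} + I_{90,0}},}
#' each computed on its own polarisation arm.  Pixels where either arm has
#' no power are masked.
#'
#' @inheritParams smv_from_polarsens
#' @return an `smv_image`.
#' @export
smv_from_four_detector <- function(channels, min_frac = 1e-3, min_abs = 0) {
  stopifnot(inherits(channels, "channel_images"))
  ch <- channels$channels
  if (!all(c("I00", "I090", "I900", "I9090") %in% names(ch))) {
    stop_data("expected the I00/I090/I900/I9090 channel set")
  }
  total <- ch$I00 + ch$I090 + ch$I900 + ch$I9090
  smv_ratio_image(ch$I00 - ch$I090, ch$I00 + ch$I090,
                  ch$I9090 - ch$I900, ch$I9090 + ch$I900,
                  total, min_frac, min_abs,
                  meta = list(family = "cos_harmonics",
                              retardance_nm = channels$config$retardance_nm))
}

# valid SMV points of an smv_image as a matrix (n x N)
smv_points <- function(smv) {
  stopifnot(inherits(smv, "smv_image"))
  n <- dim(smv$v)[3L]
  pts <- sapply(seq_len(n), function(k) smv$v[, , k][smv$mask])
  matrix(pts, ncol = n, dimnames = list(NULL, dimnames(smv$v)[[3L]]))
}
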