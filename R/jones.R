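# Jones-calculus oracle for the mosaic-camera forward model.
#
# Propagates a fully polarised field sample-by-sample through the optical
# train (linear polariser at 0 deg -> retarder at 45 deg -> retarder at
# 0 deg -> pixel analysers at 0/45/90/135 deg) using explicit 2x2 complex
# transfer matrices, then integrates over the spectrum.  Entirely independent
# of the closed-form channel integrals in polarsens_channels(), which it is
# used to verify.

# rotation matrix R(theta)
jones_rotation <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# retarder with extraordinary axis at theta_deg and phase delay delta
# (symmetric convention: diag(exp(-i delta/2), exp(+i delta/2)) in its
# eigenbasis; the global phase is irrelevant for intensities)
jones_retarder <- function(theta_deg, delta) {
  r <- jones_rotation(theta_deg)
  r %*% diag(c(exp(-1i * delta / 2), exp(1i * delta / 2))) %*% t(r)
}

# unit transmission axis of an analyser at angle theta_deg
analyser_axis <- function(theta_deg) {
  th <- theta_deg * pi / 180
  c(cos(th), sin(th))
}

#' Jones-calculus oracle for the single-shot mosaic channels
#'
#' Brute-force reference computation of the four channel intensities: the
#' polarised input field at each wavelength sample is propagated through the
#' retarder cascade (axes 45 and 0 degrees, both with phase
#' `delta = 2*pi*lambda0/lambda`) by explicit complex 2x2 matrix products,
#' projected on each analyser axis, and the resulting per-wavelength
#' intensities are integrated over frequency.  Agrees with
#' [polarsens_channels()] to numerical precision and serves as its
#' independent check.
#'
#' @param spectrum a `light_spectrum` (polarised flux entering the retarders).
#' @param config a polarsens `instrument_config` (ideal analysers assumed).
#' @return named numeric `c(I0, I45, I90, I135)`.
#' @export
jones_oracle_channels <- function(spectrum, config = instrument_config()) {
  stopifnot(inherits(spectrum, "light_spectrum"),
            inherits(config, "instrument_config"))
  if (config$config_kind != "polarsens_single_shot") {
    stop_config("jones_oracle_channels requires a polarsens_single_shot config")
  }
  q <- freq_quadrature(spectrum$grid)
  iu <- spectrum$intensity * q$jac            # flux density in frequency
  angles <- c(I0 = 0, I45 = 45, I90 = 90, I135 = 135)
  axes <- lapply(angles, analyser_axis)
  per_sample <- matrix(0, length(q$u), 4L, dimnames = list(NULL, names(angles)))
  for (j in seq_along(q$u)) {
    delta <- 2 * pi * config$retardance_nm * q$u[j]
    m <- jones_retarder(0, delta) %*% jones_retarder(45, delta)
    e <- m %*% c(sqrt(iu[j]), 0)              # field polarised at 0 deg
    for (a in seq_along(axes)) {
      amp <- sum(axes[[a]] * e)
      per_sample[j, a] <- Re(amp * Conj(amp))
    }
  }
  drop(q$w %*% per_sample)
}
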