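#' Instrument response curve (SMV vs wavelength)
#'
#' The "rainbow response curve": the instrument's SMV as a function of input
#' wavelength, mapped by sweeping a narrowband source (or evaluated
#' analytically).  For the ideal mosaic-camera pair
#' \eqn{(\cos\Lambda\nu, \sin^2\Lambda\nu)} every monochromatic point lies
#' on the parabola \eqn{V_2 = 1 - V_1^2}.
#'
#' @param wavelengths_nm sweep wavelengths.
#' @param smv matrix (length(wavelengths_nm) x N) of SMVs.
#' @param retardance_nm retardance used.
#' @param family modulation family name.
#' @return object of class `response_curve`.
#' @export
response_curve <- function(wavelengths_nm, smv, retardance_nm,
                           family = "polarsens_pair") {
  smv <- as.matrix(smv)
  stopifnot(nrow(smv) == length(wavelengths_nm))
  structure(list(wavelengths_nm = as.numeric(wavelengths_nm), smv = smv,
                 retardance_nm = retardance_nm, family = family),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %d sweep points, %.6g-%.6g nm, lambda0 = %g nm (%s)\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$retardance_nm, x$family))
  invisible(x)
}

#' Theoretical (monochromatic-limit) response curve
#'
#' Evaluates each modulation function at each sweep wavelength -- the SMV a
#' delta-function input would produce.  For the `"polarsens_pair"` family the
#' points satisfy \eqn{V_2 = 1 - V_1^2} identically; for two cosine
#' harmonics they satisfy the Chebyshev relation \eqn{V_2 = 2V_1^2 - 1}.
#'
#' @param mods a `modulation_set`.
#' @param wavelengths_nm sweep wavelengths.
#' @return a `response_curve`.
#' @examples
#' irf <- theoretical_irf(modulation_set(), seq(450, 650, 5))
#' max(abs(irf$smv[, 2] - (1 - irf$smv[, 1]^2)))
#' @export
theoretical_irf <- function(mods, wavelengths_nm = seq(450, 650, by = 1)) {
  stopifnot(inherits(mods, "modulation_set"))
  response_curve(wavelengths_nm, eval_modulation(mods, wavelengths_nm),
                 mods$retardance_nm, mods$family)
}

#' Measure the response curve from a narrowband sweep
#'
#' Given frames acquired (or simulated) at a sequence of narrowband centre
#' wavelengths, computes the mean SMV over valid pixels at each wavelength.
#' Raw mosaic frames are demosaiced first; the curve is stored at sweep
#' resolution with no smoothing.
#'
#' @param sweep list of entries, each a list with elements `wavelength_nm`
#'   and `frames` (a `channel_images` or `raw_mosaic`).
#' @param min_frac,min_abs validity thresholds passed to
#'   [smv_from_polarsens()].
#' @return a `response_curve`.
#' @export
measure_irf <- function(sweep, min_frac = 1e-3, min_abs = 0) {
  if (length(sweep) < 1L) stop_data("empty sweep")
  wl <- vapply(sweep, function(s) as.numeric(s$wavelength_nm), numeric(1))
  lam0 <- NA_real_
  smv <- t(vapply(sweep, function(s) {
    fr <- s$frames
    if (inherits(fr, "raw_mosaic")) fr <- demosaic(fr)
    if (!inherits(fr, "channel_images")) {
      stop_data("sweep frames must be channel_images or raw_mosaic")
    }
    lam0 <<- fr$config$retardance_nm
    img <- smv_from_polarsens(fr, min_frac = min_frac, min_abs = min_abs)
    colMeans(smv_points(img))
  }, numeric(2)))
  response_curve(wl, smv, lam0, "polarsens_pair")
}

#' Fit the retardance from a measured response curve
#'
#' Least-squares fit of the first SMV component to the Lyot model
#' \eqn{V_1(\lambda) = \cos(2\pi\lambda_0/\lambda)} over the sweep.  The
#' cosine makes the objective multimodal, so a dense grid search over the
#' search interval seeds a local golden-section refinement.
#'
#' @param curve a `response_curve` with at least 5 sweep points spanning
#'   more than one wavelength.
#' @param search length-2 interval of candidate retardances (nm).
#' @return object of class `retardance_fit` with components
#'   `retardance_nm`, `residual_norm`, `fitted`, `curve`; supports `print`,
#'   `coef`, `predict` and `residuals`.
#' @examples
#' irf <- theoretical_irf(modulation_set(), seq(450, 650, 5))
#' coef(fit_retardance(irf))
#' @export
fit_retardance <- function(curve, search = c(50, 1500)) {
  stopifnot(inherits(curve, "response_curve"))
  wl <- curve$wavelengths_nm
  if (length(wl) < 5L) stop_data("need at least 5 sweep points")
  if (diff(range(wl)) <= 0) stop_data("degenerate sweep: a single wavelength")
  v1 <- curve$smv[, 1L]
  ssr <- function(l0) sum((v1 - cos(2 * pi * l0 / wl))^2)
  grid <- seq(search[1L], search[2L], by = 0.25)
  best <- grid[which.min(vapply(grid, ssr, numeric(1)))]
  opt <- optimize(ssr, interval = best + c(-0.5, 0.5), tol = 1e-10)
  fitted <- cos(2 * pi * opt$minimum / wl)
  structure(list(retardance_nm = opt$minimum,
                 residual_norm = sqrt(opt$objective),
                 fitted = fitted, curve = curve, search = search),
            class = "retardance_fit")
}

#' @export
print.retardance_fit <- function(x, ...) {
  cat(sprintf("Retardance fit: lambda0 = %.4f nm (residual norm %.3g, %d sweep points)\n",
              x$retardance_nm, x$residual_norm,
              length(x$curve$wavelengths_nm)))
  invisible(x)
}

#' @export
coef.retardance_fit <- function(object, ...) {
  c(retardance_nm = object$retardance_nm)
}

#' @export
residuals.retardance_fit <- function(object, ...) {
  object$curve$smv[, 1L] - object$fitted
}

#' @rdname fit_retardance
#' @param object a `retardance_fit`.
#' @param wavelength_nm wavelengths at which to evaluate the fitted
#'   \eqn{V_1(\lambda)} model (defaults to the sweep wavelengths).
#' @param ... unused.
#' @export
predict.retardance_fit <- function(object,
                                   wavelength_nm = object$curve$wavelengths_nm,
                                   ...) {
  cos(2 * pi * object$retardance_nm / wavelength_nm)
}
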