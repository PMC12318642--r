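#' Plot an SMV image as a 2-D modulation-plane scatter
#'
#' Scatter of valid pixel SMVs in the (V1, V2) plane with the theoretical
#' monochromatic response curve overlaid, the standard visualisation for
#' spotting spectral clusters before gating.
#'
#' @param x an `smv_image`.
#' @param mods optional `modulation_set` for the overlay curve (defaults to
#'   the family recorded in the image metadata).
#' @param max_points subsample cap for large images.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted point matrix.
#' @export
plot.smv_image <- function(x, mods = NULL, max_points = 20000L, ...) {
  pts <- smv_points(x)
  if (nrow(pts) > max_points) {
    pts <- pts[seq(1L, nrow(pts), length.out = max_points), , drop = FALSE]
  }
  plot(pts[, 1L], pts[, 2L], pch = ".", col = "#00000040",
       xlab = "V1", ylab = "V2", xlim = c(-1, 1), ylim = c(-1, 1), ...)
  if (is.null(mods) && !is.null(x$meta$family)) {
    mods <- modulation_set(x$meta$family, x$meta$retardance_nm %||% 335)
  }
  if (!is.null(mods)) {
    irf <- theoretical_irf(mods, seq(430, 700, by = 0.5))
    lines(irf$smv[, 1L], irf$smv[, 2L], col = "orange", lty = 2)
  }
  invisible(pts)
}

#' Plot a response curve coloured by wavelength
#'
#' The "rainbow" rendering of the instrument response: sweep SMVs in the
#' modulation plane, coloured from short to long wavelength, with the
#' theoretical curve dashed underneath.
#'
#' @param x a `response_curve`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly `x`.
#' @export
plot.response_curve <- function(x, ...) {
  cols <- hcl.colors(length(x$wavelengths_nm), "Spectral", rev = TRUE)
  plot(x$smv[, 1L], x$smv[, 2L], col = cols, pch = 16,
       xlab = "V1", ylab = "V2", xlim = c(-1, 1), ylim = c(-1, 1), ...)
  th <- theoretical_irf(modulation_set(x$family, x$retardance_nm),
                        seq(min(x$wavelengths_nm), max(x$wavelengths_nm),
                            length.out = 400))
  lines(th$smv[, 1L], th$smv[, 2L], lty = 2)
  invisible(x)
}

#' @export
plot.retardance_fit <- function(x, ...) {
  wl <- x$curve$wavelengths_nm
  plot(wl, x$curve$smv[, 1L], pch = 16, cex = 0.6,
       xlab = "wavelength (nm)", ylab = "V1", ...)
  ws <- seq(min(wl), max(wl), length.out = 400)
  lines(ws, predict(x, ws), col = "red")
  legend("topright", bty = "n",
         legend = sprintf("lambda0 = %.2f nm", x$retardance_nm))
  invisible(x)
}
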