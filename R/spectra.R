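#' Wavelength sampling grid
#'
#' A strictly increasing set of wavelength sample points (nm) on which spectra
#' and hyperspectral scenes are sampled.  The grid carries its reduced-
#' frequency representation u = nu/c = 1/lambda (1/nm): every modulation
#' integral in the package is evaluated in optical frequency, and the constant
#' speed of light cancels in all normalised quantities, so only 1/lambda is
#' ever needed.
#'
#' @param wavelengths_nm numeric vector of sample wavelengths in nm; at least
#'   8 samples, all positive, strictly increasing.
#' @return An object of class `spectral_grid`.
#' @examples
#' g <- spectral_grid(seq(450, 650, by = 0.5))
#' range(g$wavelengths_nm)
#' @export
spectral_grid <- function(wavelengths_nm) {
  wl <- as.numeric(wavelengths_nm)
  if (length(wl) < 8L) stop_data("a spectral grid needs at least 8 samples")
  if (any(!is.finite(wl)) || any(wl <= 0)) {
    stop_data("wavelengths must be finite and positive")
  }
  if (any(diff(wl) <= 0)) stop_data("wavelengths must be strictly increasing")
  structure(list(wavelengths_nm = wl), class = "spectral_grid")
}

#' Default instrument wavelength grid (450-650 nm at 0.5 nm)
#'
#' The visible band swept by the tuneable narrowband source used for
#' instrument-response calibration, sampled finely enough that 3 nm lines are
#' well resolved.
#' @return A `spectral_grid`.
#' @export
default_grid <- function() spectral_grid(seq(450, 650, by = 0.5))

#' Convert between wavelength (nm) and reduced optical frequency (1/nm)
#'
#' Reduced frequency is u = nu/c = 1/lambda.  The two functions are exact
#' inverses of one another.
#' @param wavelength_nm,u numeric vectors.
#' @return numeric vector of the converted values.
#' @export
wavelength_to_freq <- function(wavelength_nm) 1 / wavelength_nm

#' @rdname wavelength_to_freq
#' @export
freq_to_wavelength <- function(u) 1 / u

#' @export
print.spectral_grid <- function(x, ...) {
  wl <- x$wavelengths_nm
  cat(sprintf("<spectral_grid> %d samples, %.6g-%.6g nm\n",
              length(wl), wl[1L], wl[length(wl)]))
  invisible(x)
}

#' Sampled emission/transmission spectrum
#'
#' Non-negative spectral photon flux per wavelength sample (arbitrary units
#' per nm) on a [spectral_grid()].
#'
#' @param grid a `spectral_grid`.
#' @param intensity numeric vector, same length as the grid, all entries
#'   finite and non-negative.
#' @return An object of class `light_spectrum`.
#' @export
light_spectrum <- function(grid, intensity) {
  stopifnot(inherits(grid, "spectral_grid"))
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(grid$wavelengths_nm)) {
    stop_data("intensity length must match the grid")
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_data("spectral intensity must be finite and non-negative")
  }
  structure(list(grid = grid, intensity = intensity),
            class = "light_spectrum")
}

#' Total power of a spectrum
#'
#' Trapezoidal integral of the sampled intensity.  `domain = "wavelength"`
#' integrates over lambda in nm (the natural normalisation for generators);
#' `domain = "frequency"` integrates the same flux over reduced frequency,
#' which is the quadrature used by the channel forward models, so conservation
#' identities against channel sums hold to machine precision in that domain.
#'
#' @param spectrum a `light_spectrum`.
#' @param domain `"wavelength"` or `"frequency"`.
#' @return scalar total power.
#' @export
spectrum_power <- function(spectrum, domain = c("wavelength", "frequency")) {
  domain <- match.arg(domain)
  wl <- spectrum$grid$wavelengths_nm
  if (domain == "wavelength") {
    pracma::trapz(wl, spectrum$intensity)
  } else {
    u <- rev(wavelength_to_freq(wl))
    pracma::trapz(u, rev(spectrum$intensity * wl^2))
  }
}

#' @export
print.light_spectrum <- function(x, ...) {
  wl <- x$grid$wavelengths_nm
  cat(sprintf("<light_spectrum> %d samples, %.6g-%.6g nm, power %.4g, peak at %.6g nm\n",
              length(wl), wl[1L], wl[length(wl)],
              spectrum_power(x), wl[which.max(x$intensity)]))
  invisible(x)
}

#' Narrowband (quasi-monochromatic) source line
#'
#' Gaussian line profile of given full width at half maximum, normalised to
#' unit total power on the grid, emulating a tuneable filtered supercontinuum
#' line (bandwidth below 3 nm, tuneable across the instrument band).  When the
#' requested FWHM does not exceed the local grid step the line degenerates to
#' a single-sample spike at the nearest grid point (a sampled delta function).
#'
#' @param center_nm line centre wavelength; must lie within the grid span.
#' @param fwhm_nm full width at half maximum in nm, > 0.
#' @param grid a `spectral_grid`.
#' @return A unit-power `light_spectrum`.
#' @examples
#' sp <- make_narrowband(550, 3, default_grid())
#' spectrum_power(sp)
#' @export
make_narrowband <- function(center_nm, fwhm_nm, grid = default_grid()) {
  stopifnot(inherits(grid, "spectral_grid"))
  wl <- grid$wavelengths_nm
  if (!is.finite(fwhm_nm) || fwhm_nm <= 0) stop_data("fwhm_nm must be > 0")
  if (center_nm < wl[1L] || center_nm > wl[length(wl)]) {
    stop_data(sprintf(
      "narrowband centre %.6g nm is outside the grid span %.6g-%.6g nm",
      center_nm, wl[1L], wl[length(wl)]))
  }
  step <- min(diff(wl))
  if (fwhm_nm <= step) {
    intensity <- numeric(length(wl))
    intensity[which.min(abs(wl - center_nm))] <- 1
  } else {
    sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
    intensity <- exp(-0.5 * ((wl - center_nm) / sigma)^2)
  }
  intensity <- intensity / pracma::trapz(wl, intensity)
  light_spectrum(grid, intensity)
}

#' Broadband Gaussian fluorophore emission spectrum
#'
#' Stand-in for a fluorophore emission profile: a Gaussian in wavelength with
#' unit total power.
#'
#' @param mean_nm emission peak wavelength (nm).
#' @param sigma_nm Gaussian width (nm), > 0.
#' @param grid a `spectral_grid`.
#' @return A unit-power `light_spectrum`.
#' @export
make_gaussian_emitter <- function(mean_nm, sigma_nm, grid = default_grid()) {
  stopifnot(inherits(grid, "spectral_grid"))
  if (!is.finite(sigma_nm) || sigma_nm <= 0) stop_data("sigma_nm must be > 0")
  wl <- grid$wavelengths_nm
  intensity <- exp(-0.5 * ((wl - mean_nm) / sigma_nm)^2)
  tot <- pracma::trapz(wl, intensity)
  if (tot <= 0) stop_data("emission spectrum has no power on this grid")
  light_spectrum(grid, intensity / tot)
}

#' Flat (spectrally uniform) illuminant
#'
#' @param grid a `spectral_grid`.
#' @param total_power total integrated power (photons per pixel, say); the
#'   per-nm level is constant.
#' @return A `light_spectrum`.
#' @export
make_flat_spectrum <- function(grid = default_grid(), total_power = 1) {
  wl <- grid$wavelengths_nm
  span <- wl[length(wl)] - wl[1L]
  light_spectrum(grid, rep(total_power / span, length(wl)))
}
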