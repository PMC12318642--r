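#' Hyperspectral scene container
#'
#' A (y, x, lambda) cube of per-pixel spectral photon flux on a common
#' [spectral_grid()], with optional ground truth: an integer label map
#' (0 = background / unstained) and per-pixel component abundance fractions
#' that sum to 1.
#'
#' @param cube numeric array (height, width, n_wavelengths), non-negative.
#' @param grid a `spectral_grid` whose length matches `dim(cube)[3]`.
#' @param labels optional integer matrix (height, width).
#' @param abundances optional array (height, width, K) of non-negative
#'   fractions summing to 1 per pixel.
#' @param components optional named list of unit-power `light_spectrum`
#'   objects, one per abundance channel.
#' @param meta optional list of provenance (seed, generator parameters).
#' @return An object of class `hyperspectral_scene`.
#' @export
hyperspectral_scene <- function(cube, grid, labels = NULL, abundances = NULL,
                                components = NULL, meta = list()) {
  stopifnot(inherits(grid, "spectral_grid"), is.array(cube),
            length(dim(cube)) == 3L)
  d <- dim(cube)
  if (d[3L] != length(grid$wavelengths_nm)) {
    stop_data("cube spectral dimension does not match the grid")
  }
  if (any(cube < 0) || any(!is.finite(cube))) {
    stop_data("scene cube must be finite and non-negative")
  }
  if (!is.null(labels)) {
    stopifnot(is.matrix(labels), all(dim(labels) == d[1:2]))
  }
  if (!is.null(abundances)) {
    stopifnot(is.array(abundances), all(dim(abundances)[1:2] == d[1:2]))
    if (any(abundances < -1e-12)) stop_data("abundances must be non-negative")
    s <- apply(abundances, c(1, 2), sum)
    if (max(abs(s - 1)) > 1e-9) stop_data("abundances must sum to 1 per pixel")
  }
  structure(list(height = d[1L], width = d[2L], grid = grid, cube = cube,
                 labels = labels, abundances = abundances,
                 components = components, meta = meta),
            class = "hyperspectral_scene")
}

#' @export
print.hyperspectral_scene <- function(x, ...) {
  cat(sprintf("<hyperspectral_scene> %d x %d pixels, %d wavelengths (%.6g-%.6g nm)\n",
              x$height, x$width, length(x$grid$wavelengths_nm),
              min(x$grid$wavelengths_nm), max(x$grid$wavelengths_nm)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(sort(unique(as.vector(x$labels))), collapse = ", "), "\n")
  }
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}

#' Per-pixel total power image of a scene
#'
#' @param scene a `hyperspectral_scene`.
#' @param domain quadrature domain as in [spectrum_power()].
#' @return matrix (height, width).
#' @export
scene_total_power <- function(scene, domain = c("wavelength", "frequency")) {
  domain <- match.arg(domain)
  wl <- scene$grid$wavelengths_nm
  if (domain == "wavelength") {
    w <- trapz_weights(wl)
  } else {
    w <- rev(trapz_weights(rev(wavelength_to_freq(wl)))) * wl^2
  }
  d <- dim(scene$cube)
  matrix(matrix(scene$cube, d[1L] * d[2L], d[3L]) %*% w, d[1L], d[2L])
}

# stamp filled ellipses into a label matrix; returns updated labels
stamp_ellipses <- function(labels, n, value, rx_range, ry_range) {
  h <- nrow(labels); w <- ncol(labels)
  if (n < 1L) return(labels)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n)) {
    cy <- runif(1, 0.1 * h, 0.9 * h)
    cx <- runif(1, 0.1 * w, 0.9 * w)
    ry <- runif(1, ry_range[1L], ry_range[2L])
    rx <- runif(1, rx_range[1L], rx_range[2L])
    th <- runif(1, 0, pi)
    dy <- yy - cy; dx <- xx - cx
    ur <- cos(th) * dx + sin(th) * dy
    vr <- -sin(th) * dx + cos(th) * dy
    labels[(ur / rx)^2 + (vr / ry)^2 <= 1] <- value
  }
  labels
}

#' Synthetic two-fluorophore scene with dim background
#'
#' Emulates a fluorescence field of view containing two populations of
#' blob-like objects (e.g. two types of pollen grains) whose emission spectra
#' differ, over a spatially uniform dim background (e.g. mounting-medium
#' autofluorescence).  Class A emits around 545 nm, class B around 605 nm,
#' and the background is a broad short-wavelength component; all three are
#' stand-ins, since no reference emission spectra are prescribed for such
#' samples.  The scene is a pure function of `(seed, parameters)`.
#'
#' Ground truth: `labels` is 0 (background), 1 (class A), 2 (class B);
#' `abundances` holds the per-pixel power fractions of the three components.
#'
#' @param seed integer RNG seed.
#' @param n_blobs_per_class blobs drawn per class.
#' @param photon_budget expected total photons per pixel inside a blob
#'   (background sits at 5% of this); must be > 0.
#' @param grid a `spectral_grid`.
#' @param size image side length in pixels (square scene).
#' @return A `hyperspectral_scene` with ground truth populated.
#' @examples
#' sc <- make_two_fluorophore_scene(seed = 1, n_blobs_per_class = 3,
#'                                  photon_budget = 1e4, size = 32)
#' table(sc$labels)
#' @export
make_two_fluorophore_scene <- function(seed, n_blobs_per_class = 5,
                                       photon_budget = 1e4,
                                       grid = default_grid(), size = 128L) {
  if (!is.finite(photon_budget) || photon_budget <= 0) {
    stop_data("photon_budget must be > 0")
  }
  size <- as.integer(size)
  comps <- list(
    background = make_gaussian_emitter(500, 45, grid),
    classA     = make_gaussian_emitter(545, 18, grid),
    classB     = make_gaussian_emitter(605, 20, grid)
  )
  bg_level <- 0.05 * photon_budget
  labels <- with_seed(seed, {
    lab <- matrix(0L, size, size)
    r <- c(size / 16, size / 6)
    lab <- stamp_ellipses(lab, n_blobs_per_class, 1L, r, r)
    stamp_ellipses(lab, n_blobs_per_class, 2L, r, r)
  })
  nl <- length(grid$wavelengths_nm)
  amp <- matrix(0, size * size, 3L)   # photons per component per pixel
  amp[, 1L] <- bg_level
  amp[labels == 1L, 2L] <- photon_budget
  amp[labels == 2L, 3L] <- photon_budget
  smat <- rbind(comps$background$intensity, comps$classA$intensity,
                comps$classB$intensity)
  cube <- array(amp %*% smat, dim = c(size, size, nl))
  ab <- array(amp / rowSums(amp), dim = c(size, size, 3L),
              dimnames = list(NULL, NULL, names(comps)))
  hyperspectral_scene(cube, grid, labels = labels, abundances = ab,
                      components = comps,
                      meta = list(seed = seed, generator = "two_fluorophore",
                                  photon_budget = photon_budget,
                                  n_blobs_per_class = n_blobs_per_class))
}

#' Synthetic transmitted-light absorption scene
#'
#' Emulates a stained histological section transilluminated with white light:
#' a flat illuminant attenuated per pixel by Beer-Lambert absorption from
#' three synthetic chromophores with Gaussian absorbance bands (peaks near
#' 460, 530 and 600 nm), whose optical densities vary spatially over
#' blob-like regions.  The left-most eighth of the field is left unstained
#' (illuminant only) as a white-balance reference.  Deterministic given the
#' seed.
#'
#' Ground truth: `meta$od` holds the (height, width, 3) optical-density maps;
#' `labels` is 0 where effectively unstained and otherwise the index of the
#' dominant chromophore.
#'
#' @param seed integer RNG seed.
#' @param grid a `spectral_grid`.
#' @param size image side length in pixels.
#' @param illuminant_photons total illuminant photons per pixel.
#' @param n_blobs stained regions drawn per chromophore.
#' @return A `hyperspectral_scene`.
#' @export
make_absorption_scene <- function(seed, grid = default_grid(), size = 96L,
                                  illuminant_photons = 1e4, n_blobs = 4) {
  size <- as.integer(size)
  wl <- grid$wavelengths_nm
  peaks <- c(460, 530, 600)
  widths <- c(30, 35, 40)
  eps <- sapply(seq_along(peaks), function(k) {
    exp(-0.5 * ((wl - peaks[k]) / widths[k])^2)
  })                                   # L x 3, unit peak absorbance
  od <- with_seed(seed, {
    od <- array(0, dim = c(size, size, 3L))
    for (k in 1:3) {
      m <- matrix(0L, size, size)
      m <- stamp_ellipses(m, n_blobs, 1L, c(size / 12, size / 5),
                          c(size / 12, size / 5))
      od[, , k] <- m * runif(1, 0.4, 1.2)
    }
    od
  })
  clear <- max(2L, size %/% 8L)        # unstained reference strip
  od[, seq_len(clear), ] <- 0
  illum <- make_flat_spectrum(grid, illuminant_photons)
  npix <- size * size
  odm <- matrix(od, npix, 3L)
  # transmission 10^(-sum_k OD_k * eps_k(lambda)) per pixel
  att <- 10^(-(odm %*% t(eps)))
  cube <- array(sweep(att, 2L, illum$intensity, `*`),
                dim = c(size, size, length(wl)))
  odsum <- apply(od, c(1, 2), sum)
  labels <- matrix(0L, size, size)
  dom <- apply(od, c(1, 2), which.max)
  labels[odsum > 0.05] <- dom[odsum > 0.05]
  hyperspectral_scene(cube, grid, labels = labels,
                      meta = list(seed = seed, generator = "absorption",
                                  od = od, chromophore_peaks_nm = peaks,
                                  illuminant_photons = illuminant_photons,
                                  clear_columns = seq_len(clear)))
}
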