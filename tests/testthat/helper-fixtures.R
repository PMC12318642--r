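# shared fixtures, all built in code

# spectrum Gaussian in reduced frequency u = 1/lambda (mean u0, sd su),
# sampled on a wavelength grid with the frequency->wavelength Jacobian
freq_gaussian_spectrum <- function(grid, u0, su) {
  wl <- grid$wavelengths_nm
  light_spectrum(grid, exp(-0.5 * ((1 / wl - u0) / su)^2) / wl^2)
}

# characteristic-function closed form for the SMV of a frequency-domain
# Gaussian under the (cos, sin^2) pair -- independent of the package's
# quadrature path
smv_gaussian_closed_form <- function(lambda0, u0, su) {
  L <- 2 * pi * lambda0
  c(V1 = cos(L * u0) * exp(-L^2 * su^2 / 2),
    V2 = 0.5 * (1 - cos(2 * L * u0) * exp(-2 * L^2 * su^2)))
}

# delta-like monochromatic spectrum: a fine 9-sample grid centred exactly on
# the requested wavelength, so the single-sample spike sits at wl itself
mono_delta <- function(wl) {
  g <- spectral_grid(wl + seq(-4, 4) * 0.25)
  make_narrowband(wl, 0.1, g)
}

# smooth random non-negative spectrum on a grid (mixture of 3 Gaussians)
random_spectrum <- function(grid) {
  wl <- grid$wavelengths_nm
  span <- range(wl)
  i <- rep(1e-3, length(wl))
  for (k in 1:3) {
    i <- i + runif(1, 0.2, 1) *
      exp(-0.5 * ((wl - runif(1, span[1], span[2])) / runif(1, 5, 60))^2)
  }
  light_spectrum(grid, i)
}

# random physical Stokes vectors (degree of polarisation in [0, 1])
random_stokes <- function(n, fully_polarised = FALSE) {
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  p <- if (fully_polarised) rep(1, n) else runif(n)
  s0 <- runif(n, 0.5, 2)
  cbind(s0, s0 * p * v)
}

# majority ground-truth label over each 2x2 superpixel
halfres_majority_labels <- function(labels) {
  h <- nrow(labels) %/% 2L
  w <- ncol(labels) %/% 2L
  blocks <- array(c(labels[seq(1, 2 * h, 2), seq(1, 2 * w, 2)],
                    labels[seq(2, 2 * h, 2), seq(1, 2 * w, 2)],
                    labels[seq(1, 2 * h, 2), seq(2, 2 * w, 2)],
                    labels[seq(2, 2 * h, 2), seq(2, 2 * w, 2)]),
                  c(h, w, 4L))
  apply(blocks, c(1, 2), function(v) as.integer(names(which.max(table(v)))))
}

# run the full seeded single-shot pipeline on a two-fluorophore scene and
# gate with Voronoi cells of the ground-truth cluster centroids
run_pollen_pipeline <- function(scene_seed, noise_seed, size = 128L,
                                photon_budget = 1e4, read_noise_sd = 2) {
  scene <- make_two_fluorophore_scene(seed = scene_seed,
                                      n_blobs_per_class = 5,
                                      photon_budget = photon_budget,
                                      size = size)
  channels <- render_scene(scene)
  raw <- mosaic_and_noise(channels, photon_scale = 1,
                          read_noise_sd = read_noise_sd, seed = noise_seed)
  smv <- smv_from_polarsens(demosaic(raw))
  truth <- halfres_majority_labels(scene$labels)
  pts <- cbind(smv$v[, , 1][smv$mask], smv$v[, , 2][smv$mask])
  cls <- truth[smv$mask]
  centroids <- t(sapply(0:2, function(k) colMeans(pts[cls == k, , drop = FALSE])))
  gates <- nearest_reference_gates(centroids, labels = 1:3)
  predicted <- classify_smv(smv, gates) - 1L   # gate k+1 <-> class k
  list(scene = scene, smv = smv, truth = truth, points = pts, cls = cls,
       centroids = centroids, predicted = predicted,
       agreement = mean(predicted[smv$mask] == cls))
}
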