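test_that("SMV of a flat spectrum over one full modulation period vanishes", {
  lam0 <- 335
  u0 <- 1 / 650
  u <- seq(u0, u0 + 1 / lam0, length.out = 512)   # one period in frequency
  g <- spectral_grid(rev(1 / u))
  flat_in_freq <- light_spectrum(g, 1 / g$wavelengths_nm^2)
  v <- compute_smv(flat_in_freq, modulation_set("cos_harmonics", lam0, n = 1))
  expect_equal(unname(v), 0, tolerance = 1e-10)
})

test_that("Gaussian-spectrum SMVs match the characteristic-function closed form", {
  g <- spectral_grid(seq(450, 650, by = 0.1))
  mods <- modulation_set("polarsens_pair", 335)
  # keep the line >= 6 sigma inside the band so the infinite-support
  # closed form applies without truncation error
  for (u0 in 1 / c(500, 545, 590)) {
    for (su in c(8e-6, 1.5e-5, 2e-5)) {
      sp <- freq_gaussian_spectrum(g, u0, su)
      expect_equal(unname(compute_smv(sp, mods)),
                   unname(smv_gaussian_closed_form(335, u0, su)),
                   tolerance = 1e-8)
    }
  }
})

test_that("delta-like inputs give SMV = (cos, sin^2) of the retarder phase", {
  mods <- modulation_set("polarsens_pair", 335)
  for (wl in c(460, 500, 550, 600, 640)) {
    phi <- 2 * pi * 335 / wl
    v <- compute_smv(mono_delta(wl), modulation_set("polarsens_pair", 335))
    expect_equal(unname(v), c(cos(phi), sin(phi)^2), tolerance = 1e-12)
  }
  zero <- light_spectrum(default_grid(), rep(0, 401))
  expect_error(compute_smv(zero, mods), "zero-power")
})

test_that("SMV components are bounded and mix linearly by power fractions", {
  set.seed(41)
  g <- default_grid()
  mods <- modulation_set("polarsens_pair", 335)
  for (rep in 1:25) {
    a <- random_spectrum(g)
    b <- random_spectrum(g)
    va <- compute_smv(a, mods)
    vb <- compute_smv(b, mods)
    expect_true(all(abs(va) <= 1 + 1e-12))
    wa <- runif(1, 0.1, 5)
    wb <- runif(1, 0.1, 5)
    mix <- light_spectrum(g, wa * a$intensity + wb * b$intensity)
    pa <- wa * spectrum_power(a, "frequency")
    pb <- wb * spectrum_power(b, "frequency")
    expect_equal(compute_smv(mix, mods),
                 (pa * va + pb * vb) / (pa + pb), tolerance = 1e-12)
  }
})

test_that("modulation families are orthogonal over integer-period windows", {
  h <- check_orthogonality(modulation_set("cos_harmonics", 335, n = 2))
  expect_lt(abs(h[1, 2]), 1e-10)
  expect_gt(h[1, 1], 0)
  p <- check_orthogonality(modulation_set("polarsens_pair", 335))
  expect_lt(abs(p[1, 2]), 1e-10)
  expect_identical(attr(p, "status"), "ok")
  # a non-integer-period window only approximates orthogonality
  expect_warning(
    w <- check_orthogonality(modulation_set("polarsens_pair", 335),
                             freq_window = c(1 / 650, 1 / 450)),
    "integer")
  expect_identical(attr(w, "status"), "non_integer_period")
})

test_that("channel-ratio SMV images implement the quartet algebra with masking", {
  cfg <- instrument_config()
  mk <- function(i0, i45, i90, i135) {
    channel_images(list(I0 = matrix(i0, 2, 2), I45 = matrix(i45, 2, 2),
                        I90 = matrix(i90, 2, 2), I135 = matrix(i135, 2, 2)),
                   cfg)
  }
  v <- smv_from_polarsens(mk(0.5, 1.0, 0.5, 0.0))
  expect_equal(unname(v$v[1, 1, ]), c(0, 1))
  v2 <- smv_from_polarsens(mk(1, 0.5, 0, 0.5))
  expect_equal(unname(v2$v[1, 1, ]), c(1, 0))
  # an all-zero pixel is masked, not NaN-propagated
  ch <- mk(1, 0.5, 0, 0.5)
  for (k in names(ch$channels)) ch$channels[[k]][2, 2] <- 0
  vm <- smv_from_polarsens(ch)
  expect_false(vm$mask[2, 2])
  expect_true(is.na(vm$v[2, 2, 1]))
  expect_true(all(is.finite(vm$v[, , 1][vm$mask])))
})

test_that("four-detector SMVs are computed per polarisation arm", {
  cfg <- instrument_config("four_detector")
  mk4 <- function(i00, i090, i900, i9090) {
    channel_images(list(I00 = matrix(i00, 2, 2), I090 = matrix(i090, 2, 2),
                        I900 = matrix(i900, 2, 2), I9090 = matrix(i9090, 2, 2)),
                   cfg)
  }
  # monochromatic at cos(phase) = 1, equal-power arms -> V = (1, 1)
  v <- smv_from_four_detector(mk4(1, 0, 0, 1))
  expect_equal(unname(v$v[1, 1, ]), c(1, 1))
  # cosine means vanish for a full-period flat spectrum -> V = (0, 0)
  v0 <- smv_from_four_detector(mk4(0.5, 0.5, 0.5, 0.5))
  expect_equal(unname(v0$v[1, 1, ]), c(0, 0))
  # a dead 90-deg arm masks the pixel (V2 undefined there)
  vz <- smv_from_four_detector(mk4(1, 0.2, 0, 0))
  expect_false(vz$mask[1, 1])
})

test_that("noiseless pipeline SMVs equal direct projection per pixel", {
  sc <- make_two_fluorophore_scene(seed = 3, size = 12)
  smv <- smv_from_polarsens(render_scene(sc))
  mods <- modulation_set("polarsens_pair", 335)
  for (ij in list(c(1, 1), c(6, 7), c(12, 12))) {
    ref <- compute_smv(light_spectrum(sc$grid, sc$cube[ij[1], ij[2], ]), mods)
    expect_equal(unname(smv$v[ij[1], ij[2], ]), unname(ref),
                 tolerance = 1e-10)
  }
})
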