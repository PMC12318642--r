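test_that("Lyot transmission follows cos^2(pi lambda0 / lambda)", {
  expect_equal(lyot_transmission(335, 335), 1)
  expect_equal(lyot_transmission(335, 670), 0, tolerance = 1e-15)
  # quarter-period point: cos^2(0.75 pi) = 1/2
  expect_equal(lyot_transmission(335, 335 / 0.75), 0.5, tolerance = 1e-12)
  expect_true(all(lyot_transmission(500, seq(400, 700, 10)) >= 0))
  expect_true(all(lyot_transmission(500, seq(400, 700, 10)) <= 1))
  expect_error(lyot_transmission(-1, 500))
  expect_error(lyot_transmission(335, 0))
})

test_that("monochromatic channel quartets match the quadrature-point algebra", {
  cfg <- instrument_config()
  # cos(phase) = 0 at lambda = lambda0 / 0.75: channels (I0,I90,I45,I135)
  # = (1/2, 1/2, 1, 0) for unit power
  sp0 <- mono_delta(335 / 0.75)
  ch0 <- polarsens_channels(sp0, cfg)
  ch0 <- ch0 / (ch0[["I0"]] + ch0[["I90"]])   # per unit input power
  expect_equal(unname(ch0[c("I0", "I90", "I45", "I135")]),
               c(0.5, 0.5, 1, 0), tolerance = 1e-12)
  # cos(phase) = 1 at lambda = lambda0 (full-wave point): channels
  # (1, 0, 1/2, 1/2)
  sp1 <- mono_delta(335)
  ch1 <- polarsens_channels(sp1, cfg)
  ch1 <- ch1 / (ch1[["I0"]] + ch1[["I90"]])
  expect_equal(unname(ch1[c("I0", "I90", "I45", "I135")]),
               c(1, 0, 0.5, 0.5), tolerance = 1e-12)
  expect_error(polarsens_channels(sp1, instrument_config("four_detector")),
               "polarsens_single_shot")
})

test_that("channel sums conserve input power for arbitrary spectra", {
  set.seed(11)
  g <- default_grid()
  cfg <- instrument_config()
  for (rep in 1:10) {
    sp <- random_spectrum(g)
    tot <- spectrum_power(sp, "frequency")
    ch <- polarsens_channels(sp, cfg)
    expect_equal(unname(ch["I0"] + ch["I90"]), tot, tolerance = 1e-10)
    expect_equal(unname(ch["I45"] + ch["I135"]), tot, tolerance = 1e-10)
  }
})

test_that("the four-detector configuration is lossless per arm", {
  cfg <- instrument_config("four_detector")
  g <- default_grid()
  # monochromatic at cos(phase) = 1: all 0-deg power lands in I00
  sp <- mono_delta(335)
  z <- light_spectrum(sp$grid, rep(0, length(sp$intensity)))
  ch <- four_detector_channels(sp, z, cfg)
  ch <- ch / sum(ch)                          # per unit input power
  expect_equal(unname(ch["I00"]), 1, tolerance = 1e-12)
  expect_equal(unname(ch["I090"]), 0, tolerance = 1e-12)
  # zero 90-deg arm contributes nothing
  expect_equal(unname(ch["I900"] + ch["I9090"]), 0)
  # conservation: total out = total in, both arms populated
  set.seed(4)
  a <- random_spectrum(g)
  b <- random_spectrum(g)
  chab <- four_detector_channels(a, b, cfg)
  expect_equal(sum(chab),
               spectrum_power(a, "frequency") + spectrum_power(b, "frequency"),
               tolerance = 1e-10)
  expect_error(four_detector_channels(a, b, instrument_config()),
               "four_detector")
})

test_that("the Jones oracle reproduces the channel integrals", {
  cfg <- instrument_config()
  g <- default_grid()
  # monochromatic agreement at machine precision
  sp <- mono_delta(550)
  expect_equal(jones_oracle_channels(sp, cfg), polarsens_channels(sp, cfg),
               tolerance = 1e-12)
  # vanishing retarder phase: pure Malus factors on 0-deg polarised light
  tiny <- instrument_config(retardance_nm = 1e-8)
  ch <- jones_oracle_channels(sp, tiny)
  expect_equal(unname(ch[c("I0", "I45", "I90", "I135")]), c(1, 0.5, 0, 0.5),
               tolerance = 1e-6)
  # broadband property check
  set.seed(21)
  for (rep in 1:20) {
    spr <- random_spectrum(g)
    a <- polarsens_channels(spr, cfg)
    b <- jones_oracle_channels(spr, cfg)
    expect_lt(max(abs(a - b)) / sum(a[c("I0", "I90")]), 1e-10)
  }
})

test_that("rendering applies the input-polariser loss factor", {
  sc <- make_two_fluorophore_scene(seed = 2, size = 16)
  tot <- scene_total_power(sc, "frequency")
  un <- render_scene(sc, input_polarisation = "unpolarised")
  expect_equal(un$channels$I0 + un$channels$I90, 0.5 * tot, tolerance = 1e-12)
  pol <- render_scene(sc, input_polarisation = "polarised_0deg")
  expect_equal(pol$channels$I0 + pol$channels$I90, tot, tolerance = 1e-12)
  # all-zero scene renders to all-zero channels
  z <- hyperspectral_scene(array(0, c(8, 8, length(sc$grid$wavelengths_nm))),
                           sc$grid)
  chz <- render_scene(z)
  expect_true(all(chz$channels$I0 == 0) && all(chz$channels$I135 == 0))
})

test_that("the analyser mosaic detects half the light for any polarisation state", {
  set.seed(31)
  eff <- mask_efficiency(random_stokes(200))
  expect_equal(eff, rep(0.5, 200), tolerance = 1e-12)
  # finite extinction ratio preserves the superpixel sum (leak is
  # complementary between crossed channels)
  eff_er <- mask_efficiency(random_stokes(50), extinction_ratio = 100)
  expect_equal(eff_er, rep(0.5, 50), tolerance = 1e-12)
})

test_that("mosaic sampling interleaves, degrades gracefully and is seeded", {
  sc <- make_two_fluorophore_scene(seed = 7, size = 16)
  ch <- render_scene(sc)
  # noiseless, ideal ER: demosaic recovers the channel values at their sites
  raw <- mosaic_and_noise(ch, poisson = FALSE)
  sub <- demosaic(raw)
  for (a in 1:2) for (b in 1:2) {
    key <- paste0("I", raw$layout[a, b])
    expect_identical(sub$channels[[key]],
                     ch$channels[[key]][seq(a, 16, 2), seq(b, 16, 2)])
  }
  # remosaic inverts demosaic bit for bit
  expect_identical(remosaic(demosaic(raw))$values, raw$values)
  # same seed, same frame; different seed differs
  n1 <- mosaic_and_noise(ch, seed = 5)
  n2 <- mosaic_and_noise(ch, seed = 5)
  n3 <- mosaic_and_noise(ch, seed = 6)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  expect_error(mosaic_and_noise(ch, seed = NULL), "seed")
  # finite extinction ratio mixes complementary channels
  cfg_er <- instrument_config(extinction_ratio = 10)
  ch_er <- render_scene(sc, cfg_er)
  raw_er <- mosaic_and_noise(ch_er, cfg_er, poisson = FALSE)
  sub_er <- demosaic(raw_er)
  mixed <- (10 * ch_er$channels$I0 + ch_er$channels$I90) / 11
  expect_equal(sub_er$channels$I0, mixed[seq(2, 16, 2), seq(2, 16, 2)],
               tolerance = 1e-12)
  # odd dimensions are rejected
  odd <- channel_images(lapply(ch$channels, function(m) m[1:15, ]),
                        ch$config)
  expect_error(mosaic_and_noise(odd, poisson = FALSE), "even")
})

test_that("SMV error decreases monotonically with photon budget", {
  g <- default_grid()
  sp <- make_gaussian_emitter(560, 25, g)
  truth <- compute_smv(sp, modulation_set("polarsens_pair", 335))
  err <- sapply(c(1e2, 1e3, 1e4), function(budget) {
    cube <- array(rep(budget * sp$intensity, each = 256),
                  c(16, 16, length(sp$intensity)))
    ch <- render_scene(hyperspectral_scene(cube, g))
    raw <- mosaic_and_noise(ch, seed = 123)
    img <- smv_from_polarsens(demosaic(raw))
    pts <- colMeans(cbind(img$v[, , 1][img$mask], img$v[, , 2][img$mask]))
    sqrt(sum((pts - truth)^2))
  })
  expect_true(all(diff(err) <= 0))
})
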