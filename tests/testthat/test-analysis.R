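make_smv_from_points <- function(pts, total = rep(1, nrow(pts))) {
  n <- nrow(pts)
  v <- array(c(pts[, 1], pts[, 2]), c(n, 1, 2))
  smv_image(v, matrix(total, n, 1), matrix(TRUE, n, 1),
            meta = list(family = "polarsens_pair", retardance_nm = 335))
}

test_that("gate construction validates its polygon", {
  expect_error(smv_gate(1, cbind(c(0, 1), c(0, 1))), "3")
  expect_error(smv_gate(0, cbind(c(0, 1, 1), c(0, 0, 1))), "positive")
  # bow-tie self-intersection
  expect_error(smv_gate(1, cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))),
               "self-intersecting")
  g <- smv_gate(2, cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), name = "cells")
  expect_identical(g$name, "cells")
})

test_that("classification respects boundaries, priority and masks", {
  sq <- function(cx, cy, h) cbind(cx + h * c(-1, 1, 1, -1),
                                  cy + h * c(-1, -1, 1, 1))
  pts <- rbind(c(0.1, 0.05),  # inside gate 1 only
               c(0.25, 0),    # exactly on gate 1's edge: closed boundary
               c(0.5, 0.5),   # ungated
               c(-0.2, 0))    # overlap of gates 1 and 2
  smv <- make_smv_from_points(pts)
  smv$mask[4, 1] <- FALSE     # mask the overlap point
  gates <- list(smv_gate(1, sq(0, 0, 0.25), priority = 1),
                smv_gate(2, sq(-0.25, 0, 0.25), priority = 2))
  lab <- classify_smv(smv, gates)
  expect_identical(as.vector(lab), c(1L, 1L, 0L, 0L))
  # unmask the overlap point: higher priority wins
  smv$mask[4, 1] <- TRUE
  expect_identical(classify_smv(smv, gates)[4, 1], 2L)
  # empty gate list labels everything background
  expect_true(all(classify_smv(smv, list()) == 0L))
})

test_that("classification is invariant to uniform intensity rescaling", {
  sc <- make_two_fluorophore_scene(seed = 9, size = 32)
  smv1 <- smv_from_polarsens(render_scene(sc))
  sc2 <- sc
  sc2$cube <- sc$cube * 7.3
  smv2 <- smv_from_polarsens(render_scene(sc2))
  cents <- rbind(c(-0.5, 0.66), c(-0.72, 0.44), c(-0.9, 0.15))
  gates <- nearest_reference_gates(cents)
  expect_identical(classify_smv(smv1, gates), classify_smv(smv2, gates))
})

test_that("exact unmixing solves the simplex-constrained linear system", {
  refs <- reference_set(rbind(c(1, 0), c(-1, 0), c(0, 1)),
                        labels = c("a", "b", "c"))
  # V = (0, 0.5): f1 - f2 = 0, f3 = 0.5, sum = 1 => (0.25, 0.25, 0.5)
  smv <- make_smv_from_points(rbind(c(0, 0.5), c(-1, 0)))
  um <- unmix(smv, refs)
  expect_equal(unname(um$fractions[1, 1, ]), c(0.25, 0.25, 0.5),
               tolerance = 1e-12)
  # a vertex point is a pure component
  expect_equal(unname(um$fractions[2, 1, ]), c(0, 1, 0), tolerance = 1e-12)
  # component intensities are fraction * total
  expect_equal(um$intensity[1, 1, "c"], 0.5, ignore_attr = TRUE)
  # degenerate references are refused by name
  expect_error(reference_set(rbind(c(0, 0.2), c(0, 0.5), c(0, 0.9)),
                             labels = c("x", "y", "z")),
               "x, y, z")
  expect_error(reference_set(rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(1, 1))),
               "exceed")
})

test_that("unmixing inverts mixing on the reference simplex", {
  set.seed(51)
  refs <- reference_set(rbind(c(0.8, 0.1), c(-0.6, 0.4), c(0.1, 0.9)))
  for (rep in 1:200) {
    f <- runif(3)
    f <- f / sum(f)
    v <- drop(f %*% refs$refs)
    um <- unmix(make_smv_from_points(rbind(v)), refs)
    expect_lt(max(abs(um$fractions[1, 1, ] - f)), 1e-10)
  }
})

test_that("noiseless emitter mixtures unmix to their generating fractions", {
  g <- default_grid()
  mods <- modulation_set("polarsens_pair", 335)
  comps <- list(a = make_gaussian_emitter(545, 18, g),
                b = make_gaussian_emitter(605, 20, g),
                bg = make_gaussian_emitter(500, 45, g))
  refs <- refs_from_spectra(comps, mods)
  f_true <- c(0.2, 0.5, 0.3)
  mixed <- light_spectrum(g, f_true[1] * comps$a$intensity +
                               f_true[2] * comps$b$intensity +
                               f_true[3] * comps$bg$intensity)
  # SMVs mix by frequency-domain power fractions; the components are
  # unit-power in wavelength, so correct for the (tiny) quadrature
  # difference between the two domains before comparing
  pf <- f_true * vapply(comps, spectrum_power, numeric(1),
                        domain = "frequency")
  v <- compute_smv(mixed, mods)
  um <- unmix(make_smv_from_points(rbind(v)), refs)
  expect_lt(max(abs(um$fractions[1, 1, ] - pf / sum(pf))), 1e-10)
  expect_lt(max(abs(um$fractions[1, 1, ] - f_true)), 1e-4)
})

test_that("constrained variants keep fractions on the simplex", {
  refs <- reference_set(rbind(c(1, 0), c(-1, 0), c(0, 1)))
  out <- make_smv_from_points(rbind(c(0.9, 0.4)))   # outside the simplex
  raw <- unmix(out, refs, nonneg = "none")
  expect_lt(min(raw$fractions[1, 1, ]), 0)
  for (method in c("clip", "nnls")) {
    um <- unmix(out, refs, nonneg = method)
    f <- um$fractions[1, 1, ]
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})

test_that("pseudocolour balances to grey on the white reference", {
  ab <- array(0, c(4, 4, 3))
  ab[, , 1] <- 0.5; ab[, , 2] <- 0.3; ab[, , 3] <- 0.2
  ab[1, 1, ] <- c(1, 0, 0)                       # one pure-red pixel
  total <- matrix(100, 4, 4)
  white <- matrix(FALSE, 4, 4)
  white[4, ] <- TRUE                             # bottom row is reference
  rgb <- pseudocolour(ab, total, white)
  # reference pixels come out grey
  expect_equal(rgb[4, 2, 1], rgb[4, 2, 2], tolerance = 1e-12)
  expect_equal(rgb[4, 2, 2], rgb[4, 2, 3], tolerance = 1e-12)
  # the pure component renders as a pure primary
  expect_gt(rgb[1, 1, 1], 0)
  expect_equal(rgb[1, 1, 2], 0)
  expect_equal(rgb[1, 1, 3], 0)
  expect_true(max(rgb) <= 1 && min(rgb) >= 0)
  expect_error(pseudocolour(ab * 0, total, white), "zero mean")
})

test_that("absorption scenes pseudocolour to region-consistent hues", {
  sc <- make_absorption_scene(seed = 8, size = 48)
  smv <- smv_from_polarsens(render_scene(sc, input_polarisation = "polarised_0deg"))
  mods <- modulation_set("polarsens_pair", 335)
  # references: the transmitted spectrum of each pure chromophore at OD 1
  wl <- sc$grid$wavelengths_nm
  peaks <- sc$meta$chromophore_peaks_nm
  widths <- c(30, 35, 40)
  refs <- refs_from_spectra(setNames(lapply(1:3, function(k) {
    light_spectrum(sc$grid, 10^(-exp(-0.5 * ((wl - peaks[k]) / widths[k])^2)))
  }), paste0("chrom", 1:3)), mods)
  um <- unmix(smv, refs)
  white <- matrix(FALSE, 48, 48)
  white[, sc$meta$clear_columns] <- TRUE
  rgb <- pseudocolour(um$fractions, smv$total, white)
  # each stained region's dominant channel matches its dominant chromophore
  for (k in 1:3) {
    sel <- sc$labels == k
    if (!any(sel)) next
    chan_means <- sapply(1:3, function(j) mean(rgb[, , j][sel]))
    expect_identical(which.max(chan_means), as.integer(k))
  }
})
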