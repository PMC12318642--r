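#' Polygonal gate in the SMV plane
#'
#' A closed polygonal region of the (V1, V2) plane used to classify pixels by
#' spectral similarity.  Boundaries are inclusive: a point exactly on an edge
#' belongs to the gate.  Overlapping gates are resolved by priority (higher
#' wins).
#'
#' @param label positive integer class label.
#' @param polygon matrix or data.frame with >= 3 rows of (V1, V2) vertices;
#'   must be a simple (non-self-intersecting) polygon.
#' @param priority ordering integer; higher priority wins on overlap.
#' @param name optional class name.
#' @return object of class `smv_gate`.
#' @export
smv_gate <- function(label, polygon, priority = label, name = NULL) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop_config("a gate polygon needs >= 3 (V1, V2) vertices")
  }
  if (!is.numeric(label) || label < 1) {
    stop_config("gate labels are positive integers (0 is background)")
  }
  if (polygon_self_intersects(polygon)) {
    stop_config("gate polygon is self-intersecting")
  }
  structure(list(label = as.integer(label), polygon = polygon,
                 priority = priority, name = name %||% paste0("class", label)),
            class = "smv_gate")
}

# segment-intersection test over non-adjacent edges
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1L), ])
  inter <- function(a, b) {
    d1 <- sign((b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1]))
    d2 <- sign((b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1]))
    d3 <- sign((a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1]))
    d4 <- sign((a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1]))
    d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adjacent <- abs(i - j) <= 1L || abs(i - j) == n - 1L
      if (!adjacent && inter(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Classify SMV pixels with polygonal gates
#'
#' Every valid pixel whose SMV point falls inside a gate polygon (boundary
#' inclusive) is assigned that gate's label; where gates overlap the highest
#' priority wins.  Masked or ungated pixels get label 0
#' (background/unclassified).  Because SMVs are intensity-normalised, the
#' classification is invariant to uniform rescaling of the scene.
#'
#' @param smv an `smv_image` with N >= 2 (the first two components are
#'   gated).
#' @param gates list of [smv_gate()] objects (possibly empty).
#' @return integer label matrix with attribute `"gate_names"`.
#' @export
classify_smv <- function(smv, gates) {
  stopifnot(inherits(smv, "smv_image"))
  labels <- matrix(0L, nrow(smv$total), ncol(smv$total))
  if (length(gates) == 0L) return(labels)
  ok <- vapply(gates, inherits, logical(1), "smv_gate")
  if (!all(ok)) stop_config("gates must be smv_gate objects")
  idx <- which(smv$mask)
  if (length(idx) == 0L) return(labels)
  px <- smv$v[, , 1L][idx]
  py <- smv$v[, , 2L][idx]
  ord <- order(vapply(gates, function(g) g$priority, numeric(1)))
  for (g in gates[ord]) {   # ascending priority: later (higher) overwrites
    inside <- points_in_polygon(px, py, g$polygon[, 1L], g$polygon[, 2L])
    labels[idx[inside]] <- g$label
  }
  attr(labels, "gate_names") <-
    setNames(vapply(gates, function(g) g$name, character(1)),
             vapply(gates, function(g) g$label, integer(1)))
  labels
}

# Sutherland-Hodgman: clip polygon to the half-plane a*x + b*y <= c0
clip_halfplane <- function(poly, a, b, c0) {
  n <- nrow(poly)
  out <- NULL
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1L else i + 1L, ]
    fp <- a * p[1L] + b * p[2L] - c0
    fq <- a * q[1L] + b * q[2L] - c0
    if (fp <= 0) out <- rbind(out, p)
    if (fp * fq < 0) out <- rbind(out, p + (q - p) * fp / (fp - fq))
  }
  out
}

#' Polygonal gates partitioning the SMV plane around reference points
#'
#' Builds one convex polygonal gate per reference SMV: the Voronoi cell of
#' that reference (clipped to a bounding box), so that gating assigns every
#' valid pixel to its nearest reference point.  A convenient way to turn
#' reference SMVs -- supplied numerically or picked from an SMV plot -- into
#' an exhaustive, non-overlapping set of gates.
#'
#' @param centers K x 2 matrix of reference points in the (V1, V2) plane,
#'   or a `reference_set` with 2 SMV dimensions.
#' @param box half-width of the clipping box (SMV components live in
#'   \[-1, 1\], so the default covers the whole attainable plane).
#' @param labels gate labels (default `1:K`).
#' @return list of [smv_gate()] objects.
#' @export
nearest_reference_gates <- function(centers, box = 1.5, labels = NULL) {
  if (inherits(centers, "reference_set")) centers <- centers$refs
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2L, nrow(centers) >= 2L)
  k <- nrow(centers)
  labels <- labels %||% seq_len(k)
  lapply(seq_len(k), function(i) {
    poly <- cbind(c(-box, box, box, -box), c(-box, -box, box, box))
    for (j in seq_len(k)) {
      if (j == i) next
      d <- centers[j, ] - centers[i, ]
      m <- (centers[i, ] + centers[j, ]) / 2
      poly <- clip_halfplane(poly, d[1L], d[2L], sum(d * m))
    }
    smv_gate(labels[i], poly)
  })
}

#' Reference SMVs of pure spectral components
#'
#' @param refs K x N matrix of reference SMVs, one row per pure component.
#'   For exact unmixing of an N-dimensional SMV, K <= N + 1 and the
#'   augmented matrix `rbind(t(refs), 1)` must have full rank.
#' @param labels component names (default `ref1..refK`).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(refs, labels = NULL) {
  refs <- as.matrix(refs)
  k <- nrow(refs); n <- ncol(refs)
  if (k < 2L) stop_config("need at least 2 references")
  if (k > n + 1L) {
    stop_config(sprintf("K = %d references exceed N + 1 = %d for N = %d SMV components",
                        k, n + 1L, n))
  }
  labels <- labels %||% paste0("ref", seq_len(k))
  m <- rbind(t(refs), rep(1, k))
  if (qr(m)$rank < k) {
    stop_config("degenerate reference set (collinear SMVs): ",
                paste(labels, collapse = ", "))
  }
  structure(list(refs = refs, labels = labels, augmented = m),
            class = "reference_set")
}

#' Reference SMVs computed from pure component spectra
#'
#' @param spectra named list of `light_spectrum` objects.
#' @param mods a `modulation_set`.
#' @return a `reference_set`.
#' @export
refs_from_spectra <- function(spectra, mods) {
  refs <- t(vapply(spectra, compute_smv, numeric(mods$n), mods = mods))
  reference_set(refs, labels = names(spectra) %||% NULL)
}

#' Linear unmixing of an SMV image onto reference SMVs
#'
#' Solves, per valid pixel, for fractions f with
#' \eqn{\sum_k f_k R_k = V} and \eqn{\sum_k f_k = 1}: mixtures of components
#' combine linearly in SMV space with power-fraction weights, so the
#' fractions recover the per-pixel proportions of each component.  With
#' K = N + 1 references this is an exact square solve; with K < N + 1 an
#' equality-constrained least-squares solve.  Component intensity images are
#' `f_k * total_intensity`.
#'
#' Negative fractions (noise, or points outside the reference simplex) are
#' handled by `nonneg`:
#' * `"clip"` (default): clip at zero and renormalise to sum 1;
#' * `"none"`: return the exact signed solution;
#' * `"nnls"`: non-negative least squares on the constraint-augmented
#'   system (slower; per-pixel active-set solve).
#'
#' @param smv an `smv_image`.
#' @param refs a `reference_set` with as many SMV dimensions as `smv`.
#' @param nonneg `"clip"`, `"none"` or `"nnls"`.
#' @return list with `fractions` (height x width x K array, NA where
#'   masked), `intensity` (fractions times total intensity) and `labels`.
#' @export
unmix <- function(smv, refs, nonneg = c("clip", "none", "nnls")) {
  stopifnot(inherits(smv, "smv_image"), inherits(refs, "reference_set"))
  nonneg <- match.arg(nonneg)
  n <- dim(smv$v)[3L]
  if (ncol(refs$refs) != n) {
    stop_data("reference SMV dimension does not match the image")
  }
  k <- nrow(refs$refs)
  idx <- which(smv$mask)
  vmat <- rbind(t(smv_points(smv)), rep(1, length(idx)))   # (N+1) x n_valid
  m <- refs$augmented                                      # (N+1) x K
  if (k == n + 1L) {
    f <- solve(m, vmat)                                    # K x n_valid
  } else {
    # equality-constrained LS via KKT system
    a <- t(refs$refs)                                      # N x K
    kkt <- rbind(cbind(2 * crossprod(a), rep(1, k)), c(rep(1, k), 0))
    rhs <- rbind(2 * crossprod(a, vmat[seq_len(n), , drop = FALSE]),
                 rep(1, ncol(vmat)))
    f <- solve(kkt, rhs)[seq_len(k), , drop = FALSE]
  }
  if (nonneg == "clip") {
    f[f < 0] <- 0
    cs <- colSums(f)
    cs[cs == 0] <- NA_real_
    f <- sweep(f, 2L, cs, `/`)
  } else if (nonneg == "nnls") {
    aug <- rbind(t(refs$refs), rep(1, k))
    for (j in seq_len(ncol(f))) {
      f[, j] <- pracma::lsqnonneg(aug, vmat[, j])$x
    }
    cs <- colSums(f)
    cs[cs == 0] <- NA_real_
    f <- sweep(f, 2L, cs, `/`)
  }
  d <- dim(smv$total)
  fractions <- array(NA_real_, c(d, k),
                     dimnames = list(NULL, NULL, refs$labels))
  intensity <- array(NA_real_, c(d, k),
                     dimnames = list(NULL, NULL, refs$labels))
  for (j in seq_len(k)) {
    fr <- matrix(NA_real_, d[1L], d[2L])
    fr[idx] <- f[j, ]
    fractions[, , j] <- fr
    intensity[, , j] <- fr * smv$total
  }
  list(fractions = fractions, intensity = intensity, labels = refs$labels)
}

#' Pseudocolour synthesis with white balance
#'
#' Builds an RGB rendering from three component abundance maps: each channel
#' is the component's intensity contribution (abundance times total
#' intensity), divided by the mean of that product over a designated
#' white-reference region (e.g. an unstained area seeing only the
#' illuminant), then all three channels are jointly rescaled to \[0, 1\].
#' Pixels in the reference region therefore come out grey, and saturated
#' pure components map to pure primaries.  The balancing convention
#' (division by white-region channel means) is this package's own.
#'
#' @param abundances height x width x 3 array of component fractions
#'   (ordered R, G, B).
#' @param total_intensity matrix of per-pixel total intensity.
#' @param white_region logical matrix marking the reference pixels, or a
#'   two-column index matrix; must select at least one pixel with non-zero
#'   mean channel products.
#' @return height x width x 3 RGB array in \[0, 1\] (NA pixels render
#'   black).
#' @export
pseudocolour <- function(abundances, total_intensity, white_region) {
  stopifnot(is.array(abundances), length(dim(abundances)) == 3L,
            dim(abundances)[3L] == 3L, is.matrix(total_intensity))
  if (is.logical(white_region)) {
    stopifnot(all(dim(white_region) == dim(total_intensity)))
    sel <- which(white_region)
  } else {
    sel <- white_region
  }
  if (length(sel) == 0L) stop_data("empty white-reference region")
  rgb <- array(0, dim(abundances))
  means <- numeric(3L)
  for (j in 1:3) {
    prod <- abundances[, , j] * total_intensity
    means[j] <- mean(prod[sel], na.rm = TRUE)
    if (!is.finite(means[j]) || means[j] <= 0) {
      stop_data("white-reference region has zero mean in channel ", j)
    }
    rgb[, , j] <- prod / means[j]
  }
  rgb[!is.finite(rgb)] <- 0
  top <- max(rgb)
  if (top > 0) rgb <- rgb / top
  rgb
}
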