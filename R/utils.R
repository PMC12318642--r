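# internal helpers: quadrature, seeding, geometry

# Trapezoid weights for sample points x (strictly monotone increasing).
# sum(w * f(x)) == pracma::trapz(x, f(x)) for any f.
trapz_weights <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L)
  w <- numeric(n)
  dx <- diff(x)
  w[1L] <- dx[1L] / 2
  w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2L:(n - 1L)] <- (dx[-(n - 1L)] + dx[-1L]) / 2
  w
}

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards
# so that generators are pure functions of (seed, arguments).
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Point-in-polygon with closed-boundary semantics: points exactly on an edge
# or vertex count as inside.  Even-odd (ray casting) rule plus an explicit
# on-segment test; vectorised over query points.
points_in_polygon <- function(px, py, vx, vy, tol = 1e-12) {
  n <- length(vx)
  stopifnot(n >= 3L, length(vy) == n, length(px) == length(py))
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    seg2 <- (x2 - x1)^2 + (y2 - y1)^2
    onb <- abs(cross) <= tol * max(1, sqrt(seg2)) &
      px >= pmin(x1, x2) - tol & px <= pmax(x1, x2) + tol &
      py >= pmin(y1, y2) - tol & py <= pmax(y1, y2) + tol
    on_edge <- on_edge | onb
    # even-odd crossing test
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(structure(class = c("polsmv_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("polsmv_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
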