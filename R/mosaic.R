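#' Raw division-of-focal-plane mosaic frame
#'
#' A single sensor frame in which each 2x2 superpixel interleaves the four
#' analyser channels according to the mosaic layout.  Constructed by
#' [mosaic_and_noise()] (or [remosaic()]); inverted by [demosaic()].
#'
#' @param values numeric matrix with even dimensions, non-negative.
#' @param layout 2x2 analyser-angle matrix.
#' @param meta provenance (seed, noise parameters, config).
#' @return object of class `raw_mosaic`.
#' @export
raw_mosaic <- function(values, layout, meta = list()) {
  stopifnot(is.matrix(values))
  d <- dim(values)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop_data("mosaic frames need even height and width")
  }
  if (any(values < 0)) stop_data("mosaic values must be non-negative")
  structure(list(values = values, layout = as.matrix(layout), meta = meta),
            class = "raw_mosaic")
}

#' @export
print.raw_mosaic <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raw_mosaic> %d x %d, layout [%s; %s]\n", d[1L], d[2L],
              paste(x$layout[1L, ], collapse = " "),
              paste(x$layout[2L, ], collapse = " ")))
  invisible(x)
}

# apply finite extinction-ratio mixing between complementary channel pairs
apply_extinction <- function(ch, er) {
  if (!is.finite(er)) return(ch)
  mix <- function(par, perp) (er * par + perp) / (er + 1)
  list(I0   = mix(ch$I0, ch$I90),   I45  = mix(ch$I45, ch$I135),
       I90  = mix(ch$I90, ch$I0),   I135 = mix(ch$I135, ch$I45))
}

#' Sample channel images onto the sensor mosaic, with noise
#'
#' Interleaves the four full-resolution analyser channels into one raw frame:
#' each pixel of a 2x2 superpixel detects the channel its mask orientation
#' selects, so each channel is sampled at one of the four sites.  Averaged
#' over a superpixel the mask therefore detects half of the sensor-incident
#' light (the four Malus factors average to 1/2).  Optionally applies finite
#' extinction-ratio mixing `I_meas = (ER * Ipar + Iperp) / (ER + 1)` between
#' complementary channels, then Poisson photon noise on
#' `photon_scale * intensity` and additive Gaussian read noise.
#'
#' With `poisson = FALSE`, `read_noise_sd = 0` and an ideal extinction ratio
#' the frame is an exact interleaving and [demosaic()] recovers the channel
#' values bit for bit.
#'
#' @param channels a full-resolution mosaic-camera `channel_images`.
#' @param config the `instrument_config` (supplies layout and a finite scalar
#'   extinction ratio, if any).
#' @param photon_scale gain converting channel intensity to expected photon
#'   counts (counts are Poisson distributed around `photon_scale * I`).
#' @param read_noise_sd Gaussian read noise standard deviation, in counts.
#' @param seed RNG seed for the noise draws (required if any noise enabled).
#' @param poisson logical; draw Poisson photon noise.
#' @return a `raw_mosaic` frame in count units (negative read-noise
#'   excursions are clipped at zero).
#' @export
mosaic_and_noise <- function(channels, config = channels$config,
                             photon_scale = 1, read_noise_sd = 0,
                             seed = NULL, poisson = TRUE) {
  stopifnot(inherits(channels, "channel_images"))
  ch <- channels$channels
  if (!all(c("I0", "I45", "I90", "I135") %in% names(ch))) {
    stop_data("mosaic sampling needs the I0/I45/I90/I135 channel set")
  }
  d <- dim(ch$I0)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop_data("channel images must have even dimensions for 2x2 tiling")
  }
  er <- config$extinction_ratio
  if (is.numeric(er) && is.finite(er)) ch <- apply_extinction(ch, er)
  layout <- config$mosaic_layout
  frame <- matrix(0, d[1L], d[2L])
  for (a in 1:2) for (b in 1:2) {
    key <- paste0("I", layout[a, b])
    rows <- seq.int(a, d[1L], by = 2L)
    cols <- seq.int(b, d[2L], by = 2L)
    frame[rows, cols] <- photon_scale * ch[[key]][rows, cols]
  }
  noisy <- poisson || read_noise_sd > 0
  if (noisy) {
    if (is.null(seed)) stop_config("a seed is required when noise is enabled")
    frame <- with_seed(seed, {
      f <- frame
      if (poisson) f[] <- rpois(length(f), lambda = f)
      if (read_noise_sd > 0) f <- f + rnorm(length(f), sd = read_noise_sd)
      f
    })
    frame[frame < 0] <- 0
  }
  raw_mosaic(frame, layout,
             meta = list(photon_scale = photon_scale,
                         read_noise_sd = read_noise_sd, seed = seed,
                         poisson = poisson,
                         extinction_ratio = if (is.function(er)) NA else er,
                         config_kind = config$config_kind))
}

#' Split a raw mosaic frame into the four analyser sub-images
#'
#' Exact superpixel extraction (no interpolation): each analyser channel is
#' returned at half the sensor resolution, taken from its site in every 2x2
#' superpixel.  This keeps the channel algebra bit-faithful; an interpolating
#' demosaic would be lossy and is deliberately not applied.
#'
#' @param raw a `raw_mosaic` with layout metadata.
#' @return a `channel_images` with half-resolution `I0, I45, I90, I135`.
#' @export
demosaic <- function(raw) {
  stopifnot(inherits(raw, "raw_mosaic"))
  layout <- raw$layout
  if (is.null(layout)) stop_data("raw frame is missing its mosaic layout")
  d <- dim(raw$values)
  chans <- list()
  for (a in 1:2) for (b in 1:2) {
    key <- paste0("I", layout[a, b])
    chans[[key]] <- raw$values[seq.int(a, d[1L], 2L), seq.int(b, d[2L], 2L)]
  }
  cfg <- instrument_config(mosaic_layout = layout)
  channel_images(chans[c("I0", "I45", "I90", "I135")], cfg,
                 meta = c(raw$meta, list(demosaiced = TRUE)))
}

#' Re-interleave half-resolution channels into a mosaic frame
#'
#' Inverse of [demosaic()]: `remosaic(demosaic(raw))` reproduces `raw`
#' exactly.
#'
#' @param channels half-resolution `channel_images`.
#' @param layout 2x2 analyser-angle matrix (defaults to the config's layout).
#' @return a `raw_mosaic`.
#' @export
remosaic <- function(channels, layout = channels$config$mosaic_layout) {
  stopifnot(inherits(channels, "channel_images"))
  d <- dim(channels$channels[[1L]])
  frame <- matrix(0, 2L * d[1L], 2L * d[2L])
  for (a in 1:2) for (b in 1:2) {
    key <- paste0("I", layout[a, b])
    frame[seq.int(a, 2L * d[1L], 2L), seq.int(b, 2L * d[2L], 2L)] <-
      channels$channels[[key]]
  }
  raw_mosaic(frame, layout, meta = channels$meta)
}
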