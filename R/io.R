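# File interchange: rasters as 32-bit float TIFF (multi-page where needed)
# with a JSON sidecar carrying metadata and the intensity scale (float TIFF
# storage is defined on [0, 1], so arrays are stored divided by their
# recorded maximum), curves and tables as CSV, gates/references as JSON.

sidecar_path <- function(path) paste0(path, ".json")

write_pages_tiff <- function(pages, path, meta = list()) {
  vals <- unlist(lapply(pages, as.vector))
  scale <- max(vals, 0)
  if (scale == 0) scale <- 1
  scaled <- lapply(pages, function(p) {
    m <- as.matrix(p) / scale
    m[m < 0] <- 0
    m
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  meta$intensity_scale <- scale
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

read_pages_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  scale <- meta$intensity_scale %||% 1
  list(pages = lapply(pages, function(p) p * scale), meta = meta)
}

#' Write / read a hyperspectral scene
#'
#' One TIFF page per wavelength plus a JSON sidecar holding the grid, the
#' generator seed and (when present) the label map file name.  Labels are
#' written to `<path>.labels.tif` as a single-page integer-valued image.
#'
#' @param scene a `hyperspectral_scene`.
#' @param path TIFF output path.
#' @return `write_scene` returns the path invisibly; `read_scene` returns a
#'   `hyperspectral_scene` (without abundances, which are not serialised).
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "hyperspectral_scene"))
  pages <- lapply(seq_len(dim(scene$cube)[3L]),
                  function(j) scene$cube[, , j])
  meta <- list(kind = "hyperspectral_scene",
               wavelengths_nm = scene$grid$wavelengths_nm,
               seed = scene$meta$seed %||% NULL,
               generator = scene$meta$generator %||% NULL)
  if (!is.null(scene$labels)) {
    lp <- paste0(path, ".labels.tif")
    tiff::writeTIFF(scene$labels / max(1, max(scene$labels)), lp,
                    bits.per.sample = 16L)
    meta$labels_file <- basename(lp)
    meta$labels_max <- max(1, max(scene$labels))
  }
  write_pages_tiff(pages, path, meta)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  r <- read_pages_tiff(path)
  grid <- spectral_grid(r$meta$wavelengths_nm)
  d <- dim(r$pages[[1L]])
  cube <- array(unlist(r$pages), dim = c(d, length(r$pages)))
  labels <- NULL
  if (!is.null(r$meta$labels_file)) {
    lp <- file.path(dirname(path), r$meta$labels_file)
    labels <- matrix(as.integer(round(tiff::readTIFF(lp) * r$meta$labels_max)),
                     d[1L], d[2L])
  }
  hyperspectral_scene(cube, grid, labels = labels,
                      meta = list(seed = r$meta$seed,
                                  generator = r$meta$generator))
}

#' Write / read channel images
#'
#' Four TIFF pages in a fixed order (`I0, I45, I90, I135`, or the
#' four-detector quartet `I00, I090, I900, I9090`) plus a JSON sidecar with
#' the instrument parameters.
#'
#' @param channels a `channel_images`.
#' @param path TIFF output path.
#' @return the path invisibly / a `channel_images`.
#' @export
write_channels <- function(channels, path) {
  stopifnot(inherits(channels, "channel_images"))
  ord <- if ("I0" %in% names(channels$channels)) {
    c("I0", "I45", "I90", "I135")
  } else c("I00", "I090", "I900", "I9090")
  cfg <- channels$config
  write_pages_tiff(channels$channels[ord], path,
                   list(kind = "channel_images", channel_order = ord,
                        config_kind = cfg$config_kind,
                        retardance_nm = cfg$retardance_nm,
                        mosaic_layout = cfg$mosaic_layout,
                        extinction_ratio =
                          if (is.function(cfg$extinction_ratio)) "custom"
                          else unname(cfg$extinction_ratio)))
}

#' @rdname write_channels
#' @export
read_channels <- function(path) {
  r <- read_pages_tiff(path)
  ord <- r$meta$channel_order
  chans <- setNames(r$pages, ord)
  er <- r$meta$extinction_ratio
  if (is.character(er) || is.null(er)) er <- Inf
  cfg <- instrument_config(r$meta$config_kind,
                           retardance_nm = r$meta$retardance_nm,
                           extinction_ratio = er,
                           mosaic_layout = matrix(as.numeric(unlist(r$meta$mosaic_layout)),
                                                  2, 2))
  channel_images(chans, cfg)
}

#' Write / read a raw mosaic frame
#'
#' Single-page TIFF plus a JSON sidecar recording the 2x2 layout, seed and
#' noise parameters.
#'
#' @param raw a `raw_mosaic`.
#' @param path TIFF output path.
#' @return the path invisibly / a `raw_mosaic`.
#' @export
write_mosaic <- function(raw, path) {
  stopifnot(inherits(raw, "raw_mosaic"))
  write_pages_tiff(list(raw$values), path,
                   list(kind = "raw_mosaic", mosaic_layout = raw$layout,
                        noise = raw$meta[intersect(names(raw$meta),
                          c("photon_scale", "read_noise_sd", "seed",
                            "poisson", "extinction_ratio"))]))
}

#' @rdname write_mosaic
#' @export
read_mosaic <- function(path) {
  r <- read_pages_tiff(path)
  raw_mosaic(r$pages[[1L]],
             matrix(as.numeric(unlist(r$meta$mosaic_layout)), 2, 2),
             meta = r$meta$noise %||% list())
}

#' Write / read an SMV image
#'
#' Pages V1, V2, ..., total intensity; the validity mask goes to
#' `<path>.mask.tif`.
#'
#' @param smv an `smv_image`.
#' @param path TIFF output path.
#' @return the path invisibly / an `smv_image`.
#' @export
write_smv <- function(smv, path) {
  stopifnot(inherits(smv, "smv_image"))
  n <- dim(smv$v)[3L]
  # components are in [-1, 1]: store (v + 1) / 2 and invert on read
  pages <- c(lapply(seq_len(n), function(k) {
    m <- (smv$v[, , k] + 1) / 2
    m[!smv$mask] <- 0
    m
  }), list(smv$total))
  mp <- paste0(path, ".mask.tif")
  tiff::writeTIFF(smv$mask * 1, mp, bits.per.sample = 8L)
  write_pages_tiff(pages, path,
                   list(kind = "smv_image", n_components = n,
                        component_encoding = "half_shifted",
                        mask_file = basename(mp),
                        family = smv$meta$family %||% NULL,
                        retardance_nm = smv$meta$retardance_nm %||% NULL))
}

#' @rdname write_smv
#' @export
read_smv <- function(path) {
  r <- read_pages_tiff(path)
  n <- r$meta$n_components
  mask <- tiff::readTIFF(file.path(dirname(path), r$meta$mask_file)) > 0.5
  d <- dim(r$pages[[1L]])
  v <- array(NA_real_, c(d, n), dimnames = list(NULL, NULL, paste0("V", 1:n)))
  for (k in seq_len(n)) {
    comp <- r$pages[[k]] * 2 - 1             # undo the half shift
    comp[!mask] <- NA_real_
    v[, , k] <- comp
  }
  smv_image(v, r$pages[[n + 1L]], mask,
            meta = list(family = r$meta$family,
                        retardance_nm = r$meta$retardance_nm))
}

#' Write / read a response curve as CSV
#'
#' Columns `wavelength_nm, V1, V2, ...`; retardance and family ride along in
#' a JSON sidecar.
#'
#' @param curve a `response_curve`.
#' @param path CSV output path.
#' @return the path invisibly / a `response_curve`.
#' @export
write_response_csv <- function(curve, path) {
  stopifnot(inherits(curve, "response_curve"))
  df <- data.frame(wavelength_nm = curve$wavelengths_nm, curve$smv)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(kind = "response_curve",
                            retardance_nm = curve$retardance_nm,
                            family = curve$family),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  response_curve(df$wavelength_nm, as.matrix(df[, -1L, drop = FALSE]),
                 meta$retardance_nm, meta$family)
}

#' Write / read gates as JSON
#'
#' @param gates list of `smv_gate` objects.
#' @param path JSON path.
#' @return the path invisibly / a list of gates.
#' @export
write_gates <- function(gates, path) {
  jsonlite::write_json(lapply(gates, function(g) {
    list(label = g$label, name = g$name, priority = g$priority,
         polygon = unname(as.matrix(g$polygon)))
  }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(g) {
    smv_gate(g$label, matrix(unlist(g$polygon), ncol = 2),
             priority = g$priority, name = g$name)
  })
}

#' Write / read a reference set as JSON
#'
#' @param refs a `reference_set`.
#' @param path JSON path.
#' @return the path invisibly / a `reference_set`.
#' @export
write_refs <- function(refs, path) {
  jsonlite::write_json(list(labels = refs$labels,
                            refs = unname(as.matrix(refs$refs))),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_refs
#' @export
read_refs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_set(matrix(unlist(raw$refs), nrow = length(raw$labels)),
                labels = raw$labels)
}

#' Write an RGB array as 8-bit PNG
#'
#' @param rgb height x width x 3 array in \[0, 1\].
#' @param path PNG path.
#' @return the path invisibly.
#' @export
write_rgb_png <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  rgb[!is.finite(rgb)] <- 0
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  png::writePNG(rgb, path)
  invisible(path)
}
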