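#' Read a channel stack from TIFF
#'
#' Accepts a multi-page grayscale TIFF or a directory of per-slice TIFFs
#' (slices ordered by the trailing integer in each file name; a gap in the
#' index sequence is a format error). Integer intensities are preserved
#' bit-exactly.
#'
#' @param path TIFF file or directory of per-slice TIFFs.
#' @param name marker name for the resulting channel.
#' @param geometry optional [at_geometry()]; pixel calibration is taken from
#'   it (TIFF files carry no reliable physical calibration here). Defaults
#'   inferred with 0.1 um/px and 0.07 um/slice.
#' @return A [channel_volume()].
#' @export
read_channel_stack <- function(path, name, geometry = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) stop("no TIFF files in directory: ", path)
    idx <- suppressWarnings(as.integer(sub(".*?([0-9]+)\\.[Tt][Ii][Ff][Ff]?$",
                                           "\\1", basename(files))))
    if (any(is.na(idx))) stop("per-slice TIFF names must end in an integer index")
    files <- files[order(idx)]
    idx <- sort(idx)
    if (any(diff(idx) != 1L)) {
      stop("missing slices in ", path, ": indices ", paste(idx, collapse = ","))
    }
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      if (dim(p)[3] == 1) p <- p[, , 1] else stop("not a grayscale TIFF: ", path)
    }
    p
  })
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), TRUE))) {
    stop("mismatched slice shapes in ", path)
  }
  a <- array(0, c(d1[1], d1[2], length(pages)))
  for (z in seq_along(pages)) a[, , z] <- pages[[z]]
  if (is.null(geometry)) {
    geometry <- at_geometry(d1[1], d1[2], length(pages))
  } else {
    geometry <- at_geometry(d1[1], d1[2], length(pages),
                            geometry$pixel_size_xy, geometry$slice_thickness)
  }
  channel_volume(a, name, geometry)
}

#' Write a channel stack as a multi-page TIFF
#'
#' Integer data are stored at 16 bits per sample (bit-exact round trip for
#' intensities in 0..65535); `bits = 32` stores floating point (used for
#' probability maps).
#'
#' @param channel a [channel_volume()] or `probability_volume`.
#' @param path output TIFF path.
#' @param bits 8, 16 (integer) or 32 (float).
#' @export
write_channel_stack <- function(channel, path, bits = 16L) {
  a <- if (inherits(channel, c("channel_volume", "probability_volume")))
    channel$data else channel
  stopifnot(bits %in% c(8L, 16L, 32L))
  scale <- c(`8` = 255, `16` = 65535, `32` = 1)[[as.character(bits)]]
  if (bits < 32 && max(a) > scale) {
    stop("intensities exceed ", bits, "-bit range")
  }
  pages <- lapply(seq_len(dim(a)[3]), function(z) {
    if (bits < 32) round(a[, , z]) / scale else a[, , z]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Write / read a detection table
#'
#' One CSV row per detection with id, query, centroid in px and um, voxel
#' count, any per-marker slice-span columns, layer and astrocyte flag, in
#' deterministic (slice, row, col) order. Component voxel sets are not
#' serialized.
#'
#' @param detections a `synapse_detections` data.frame.
#' @param path CSV path.
#' @export
write_detection_table <- function(detections, path) {
  utils::write.csv(as.data.frame(detections), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_table
#' @export
read_detection_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a density table
#' @param table data.frame from [size_binned_densities()] and relatives.
#' @param path CSV path.
#' @export
write_density_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline configuration
#'
#' Reads a YAML file declaring channels (marker name to TIFF path), voxel
#' calibration, queries, optional layer boundaries, thresholds and statistics
#' options. Missing thresholds receive the standard defaults (probability
#' threshold 0.9, DAPI threshold 0.6, minimum punctum footprint 2 x 2 px),
#' which are echoed via `message()`. Every query marker must name a declared
#' channel.
#'
#' @param path YAML configuration file.
#' @return A list: `geometry` (pixel calibration), `channels` (name -> path),
#'   `queries` (list of [synapse_query()]), `layers` ([layer_partition()] or
#'   `NULL`), `thresholds` (`probability`, `dapi`), `params`
#'   ([query_params()]), `stats` (`var_equal`).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$channels) || length(cfg$channels) == 0) {
    stop("config must declare at least one channel")
  }
  channels <- vapply(cfg$channels, as.character, "")
  geom <- list(
    pixel_size_xy = cfg$geometry$pixel_size_xy %||% 0.1,
    slice_thickness = cfg$geometry$slice_thickness %||% 0.07
  )
  thresholds <- list(
    probability = cfg$thresholds$probability %||% 0.9,
    dapi = cfg$thresholds$dapi %||% 0.6
  )
  min_xy <- cfg$params$min_xy_px %||% 2L
  params <- query_params(
    r_coloc = cfg$params$r_coloc %||% 1L,
    adjacency_xy = cfg$params$adjacency_xy %||% 2L,
    adjacency_z = cfg$params$adjacency_z %||% 1L
  )
  queries <- lapply(cfg$queries, function(q) {
    mk <- function(ch) {
      ms <- q$min_slices[[ch]]
      marker_spec(ch, min_xy_px = min_xy,
                  min_slices = if (is.null(ms)) NULL else as.integer(ms))
    }
    for (ch in unlist(c(q$presynaptic, q$postsynaptic, q$astrocyte))) {
      if (!ch %in% names(channels)) {
        stop("query '", q$name, "' references undeclared channel '", ch, "'")
      }
    }
    synapse_query(q$name,
                  presynaptic = lapply(unlist(q$presynaptic), mk),
                  postsynaptic = lapply(unlist(q$postsynaptic), mk),
                  astrocyte = if (is.null(q$astrocyte)) NULL
                              else mk(q$astrocyte),
                  required_span = q$required_span %||% 1L)
  })
  names(queries) <- vapply(queries, function(q) q$name, "")
  layers <- NULL
  if (!is.null(cfg$layers)) {
    stopifnot(!is.null(cfg$layers$height_px))
    layers <- layer_partition(cfg$layers$boundaries,
                              unlist(cfg$layers$names),
                              cfg$layers$height_px)
  }
  message(sprintf(
    "config: %d channels, %d queries; probability threshold %.2f, DAPI threshold %.2f, min punctum %d x %d px",
    length(channels), length(queries), thresholds$probability,
    thresholds$dapi, min_xy, min_xy))
  list(geometry = geom, channels = channels, queries = queries,
       layers = layers, thresholds = thresholds, params = params,
       stats = list(var_equal = cfg$stats$var_equal %||% TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
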