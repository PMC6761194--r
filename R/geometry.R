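#' Acquisition geometry of a serial-section volume
#'
#' Physical calibration tying voxels to micrometres. Array tomography images
#' ribbons of ultrathin resin sections, so the axial step (section thickness,
#' default 70 nm) differs from the lateral pixel pitch (default 0.1 um).
#'
#' @param height_px,width_px lateral image size in pixels (rows, columns).
#' @param n_slices number of serial sections in the stack.
#' @param pixel_size_xy lateral pixel size in um (default 0.1).
#' @param slice_thickness section thickness in um (default 0.07).
#'
#' @return An object of class `at_geometry`.
#' @examples
#' g <- at_geometry(100, 100, 30)
#' volume_um3(g)  # 100*100*30 * 0.1^2 * 0.07 = 210 um^3
#' @export
at_geometry <- function(height_px, width_px, n_slices,
                        pixel_size_xy = 0.1, slice_thickness = 0.07) {
  stopifnot(pixel_size_xy > 0, slice_thickness > 0,
            height_px >= 1, width_px >= 1, n_slices >= 1)
  structure(list(
    height_px = as.integer(height_px),
    width_px = as.integer(width_px),
    n_slices = as.integer(n_slices),
    pixel_size_xy = pixel_size_xy,
    slice_thickness = slice_thickness
  ), class = "at_geometry")
}

#' Physical volume of an imaged stack
#'
#' @param geometry an [at_geometry()].
#' @return Volume in cubic micrometres.
#' @export
volume_um3 <- function(geometry) {
  stopifnot(inherits(geometry, "at_geometry"))
  with(geometry,
       as.numeric(height_px) * width_px * n_slices *
         pixel_size_xy^2 * slice_thickness)
}

#' Volume of a single voxel in um^3
#' @param geometry an [at_geometry()].
#' @export
voxel_um3 <- function(geometry) {
  geometry$pixel_size_xy^2 * geometry$slice_thickness
}

#' @export
print.at_geometry <- function(x, ...) {
  cat(sprintf("<at_geometry> %d x %d px x %d slices (%.3g um/px, %.3g um/slice), %.4g um^3\n",
              x$height_px, x$width_px, x$n_slices,
              x$pixel_size_xy, x$slice_thickness, volume_um3(x)))
  invisible(x)
}

#' A single calibrated immunofluorescence channel
#'
#' Wraps a 3-D intensity array indexed `[row, col, slice]` together with its
#' marker name and acquisition geometry. Intensities must be finite and
#' nonnegative; dimensions must match the geometry.
#'
#' @param data numeric 3-D array `[row, col, slice]`.
#' @param name marker identifier, e.g. `"synapsin"`, `"PSD95"`, `"DAPI"`.
#' @param geometry an [at_geometry()]; inferred from `data` if `NULL`.
#' @return An object of class `channel_volume`.
#' @export
channel_volume <- function(data, name, geometry = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(geometry)) {
    d <- dim(data)
    geometry <- at_geometry(d[1], d[2], d[3])
  }
  stopifnot(inherits(geometry, "at_geometry"))
  d <- dim(data)
  if (d[1] != geometry$height_px || d[2] != geometry$width_px ||
      d[3] != geometry$n_slices) {
    stop("channel '", name, "': data dimensions do not match geometry")
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    stop("channel '", name, "': intensities must be finite and >= 0")
  }
  structure(list(data = data, name = name, geometry = geometry),
            class = "channel_volume")
}

#' @export
print.channel_volume <- function(x, ...) {
  cat(sprintf("<channel_volume> '%s' %d x %d x %d, range [%.4g, %.4g]\n",
              x$name, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Cortical layer partition by image rows
#'
#' The imaged column spans several cortical layers; the analysis
#' subdivides the volume into layer subvolumes along the cortical depth axis
#' (image rows). Boundaries are user-supplied row offsets; intervals are
#' half-open `[start, next_start)` and exhaustive.
#'
#' @param boundaries strictly increasing integer row offsets (1-based, the
#'   first row of each layer after the first); must lie within `(1, height_px]`.
#' @param names layer labels, one more than `length(boundaries)`.
#' @param height_px image height the partition applies to.
#' @return An object of class `layer_partition`.
#' @examples
#' layer_partition(c(40, 80), c("L1", "L2/3", "L4"), height_px = 120)
#' @export
layer_partition <- function(boundaries, names, height_px) {
  boundaries <- as.integer(boundaries)
  stopifnot(length(names) == length(boundaries) + 1,
            all(diff(c(1L, boundaries, height_px + 1L)) > 0))
  structure(list(boundaries = boundaries, names = names,
                 height_px = as.integer(height_px)),
            class = "layer_partition")
}

#' Layer label for centroid rows
#' @param rows numeric centroid row coordinates (px).
#' @param partition a [layer_partition()].
#' @return Character vector of layer labels.
#' @export
layer_of_row <- function(rows, partition) {
  stopifnot(inherits(partition, "layer_partition"))
  idx <- findInterval(rows, c(1, partition$boundaries))
  idx[idx < 1L] <- 1L
  idx[idx > length(partition$names)] <- length(partition$names)
  partition$names[idx]
}
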