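# 3-D 26-connected component labeling over a logical array. Returns an
# integer array of labels (0 = background). Hand-rolled breadth-first fill:
# supra-threshold voxels are sparse in probability maps, so a frontier-based
# vectorized BFS is fast enough without compiled code.
label_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- d[1]; nc <- d[2]; nz <- d[3]
  off <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0 & off$dz == 0), ]
  cur <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      z <- (frontier - 1L) %/% (nr * nc)
      rem <- (frontier - 1L) %% (nr * nc)
      c0 <- rem %/% nr
      r0 <- rem %% nr
      nbr <- integer(0)
      for (k in seq_len(nrow(off))) {
        r1 <- r0 + off$dr[k]; c1 <- c0 + off$dc[k]; z1 <- z + off$dz[k]
        ok <- r1 >= 0L & r1 < nr & c1 >= 0L & c1 < nc & z1 >= 0L & z1 < nz
        if (any(ok)) nbr <- c(nbr, r1[ok] + nr * (c1[ok] + nc * z1[ok]) + 1L)
      }
      nbr <- unique(nbr)
      nbr <- nbr[mask[nbr] & lab[nbr] == 0L]
      lab[nbr] <- cur
      frontier <- nbr
    }
  }
  lab
}

#' Threshold a probability map into discrete synapse detections
#'
#' Voxels at or above the threshold are grouped into 26-connected 3-D
#' components; each component becomes one detection. The default threshold of
#' 0.9 is the empirically optimal value for probabilistic synapse maps.
#'
#' @param prob_map a `probability_volume` (e.g. from [evaluate_query()]) or
#'   probability array.
#' @param threshold detection threshold in (0, 1), default 0.9.
#' @param geometry an [at_geometry()]; taken from `prob_map` if available.
#' @param query_name label recorded on each detection.
#' @return A data.frame of class `synapse_detections`, ordered by centroid
#'   (slice, row, col), with columns `id`, `query`, `row`, `col`, `slice`
#'   (centroid, px, 1-based), `x_um`, `y_um`, `z_um` (voxel-center um),
#'   `n_voxels`, `astro_associated`; the component voxel index sets are kept
#'   in `attr(, "voxels")`.
#' @export
threshold_and_label <- function(prob_map, threshold = 0.9, geometry = NULL,
                                query_name = NULL) {
  p <- prob_data(prob_map)
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(geometry) && inherits(prob_map, "probability_volume"))
    geometry <- prob_map$geometry
  if (is.null(geometry)) {
    d <- dim(p); geometry <- at_geometry(d[1], d[2], d[3])
  }
  if (is.null(query_name)) {
    query_name <- if (inherits(prob_map, "probability_volume"))
      prob_map$channel else NA_character_
  }
  lab <- label_components_3d(p >= threshold)
  n <- max(lab)
  d <- dim(p)
  if (n == 0L) {
    det <- data.frame(id = integer(0), query = character(0),
                      row = numeric(0), col = numeric(0), slice = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      n_voxels = integer(0), astro_associated = logical(0))
    attr(det, "voxels") <- list()
    attr(det, "geometry") <- geometry
    class(det) <- c("synapse_detections", "data.frame")
    return(det)
  }
  idx <- which(lab > 0L)
  comp <- lab[idx]
  ai <- arrayInd(idx, d)
  rowm <- tapply(ai[, 1], comp, mean)
  colm <- tapply(ai[, 2], comp, mean)
  slim <- tapply(ai[, 3], comp, mean)
  cnt <- tapply(idx, comp, length)
  vox <- split(idx, comp)
  ord <- order(round(slim, 9), round(rowm, 9), round(colm, 9))
  det <- data.frame(
    id = seq_len(n),
    query = query_name,
    row = as.numeric(rowm[ord]), col = as.numeric(colm[ord]),
    slice = as.numeric(slim[ord]),
    x_um = (as.numeric(colm[ord]) - 0.5) * geometry$pixel_size_xy,
    y_um = (as.numeric(rowm[ord]) - 0.5) * geometry$pixel_size_xy,
    z_um = (as.numeric(slim[ord]) - 0.5) * geometry$slice_thickness,
    n_voxels = as.integer(cnt[ord]),
    astro_associated = NA,
    stringsAsFactors = FALSE
  )
  attr(det, "voxels") <- vox[ord]
  attr(det, "geometry") <- geometry
  class(det) <- c("synapse_detections", "data.frame")
  det
}

#' Detect synapses matching a query
#'
#' Convenience composition of [evaluate_query()] and [threshold_and_label()].
#' Detections from tripartite queries are flagged astrocyte-associated.
#'
#' @inheritParams evaluate_query
#' @param threshold detection threshold (default 0.9).
#' @return A `synapse_detections` data.frame.
#' @export
detect_synapses <- function(prob_channels, query, threshold = 0.9,
                            params = query_params(), required_span = NULL) {
  pm <- evaluate_query(prob_channels, query, params, required_span)
  det <- threshold_and_label(pm, threshold, query_name = query$name)
  det$astro_associated <- rep(!is.null(query$astrocyte), nrow(det))
  det
}

#' Assign cortical layer labels to detections
#'
#' Labels each detection by the layer interval containing its centroid row;
#' intervals are half-open so every centroid receives exactly one label.
#'
#' @param detections a `synapse_detections` data.frame.
#' @param partition a [layer_partition()].
#' @return The detections with a `layer` column.
#' @export
assign_layers <- function(detections, partition) {
  detections$layer <- if (nrow(detections) == 0) character(0)
                      else layer_of_row(detections$row, partition)
  detections
}

#' Per-marker slice spans at detection sites
#'
#' For each detection, counts the longest run of consecutive slices on which
#' each marker's single-slice punctum probability is supra-threshold within
#' the detection's laterally dilated footprint.
#'
#' @param detections a `synapse_detections` data.frame.
#' @param prob_channels named list of foreground probability volumes.
#' @param query the [synapse_query()] the detections came from.
#' @param threshold punctum presence threshold (default 0.9).
#' @param params a [query_params()] (adjacency radius sets the footprint
#'   dilation).
#' @return The detections with one `span_<channel>` column per marker.
#' @export
marker_slice_spans <- function(detections, prob_channels, query,
                               threshold = 0.9, params = query_params()) {
  specs <- c(query$presynaptic, query$postsynaptic,
             if (!is.null(query$astrocyte)) list(query$astrocyte))
  if (nrow(detections) == 0) {
    for (m in specs) detections[[paste0("span_", m$channel)]] <- integer(0)
    return(detections)
  }
  d <- dim(prob_data(prob_channels[[specs[[1]]$channel]]))
  vox <- attr(detections, "voxels")
  bmaps <- lapply(specs, function(m)
    prob_data(punctum_probability(prob_channels[[m$channel]], m,
                                  required_span = 1L)))
  a <- params$adjacency_xy
  for (j in seq_along(specs)) {
    spans <- integer(nrow(detections))
    for (i in seq_len(nrow(detections))) {
      ai <- arrayInd(vox[[i]], d)
      rr <- max(1L, min(ai[, 1]) - a):min(d[1], max(ai[, 1]) + a)
      cc <- max(1L, min(ai[, 2]) - a):min(d[2], max(ai[, 2]) + a)
      zz <- max(1L, min(ai[, 3]) - params$adjacency_z):
            min(d[3], max(ai[, 3]) + params$adjacency_z)
      present <- vapply(zz, function(z)
        max(bmaps[[j]][rr, cc, z]) >= threshold, TRUE)
      spans[i] <- if (!any(present)) 0L else {
        r <- rle(present)
        max(r$lengths[r$values])
      }
    }
    detections[[paste0("span_", specs[[j]]$channel)]] <- spans
  }
  detections
}

#' Size-binned synapse densities by query subtraction
#'
#' Runs the query at slice-span requirements 1, 2 and 3 and converts the
#' counts `N1 >= N2 >= N3` into densities per um^3 of neuropil:
#' all = N1/V, small = (N1-N2)/V, medium = (N2-N3)/V, large = N3/V.
#' A small synapse thus has at least one marker on only one slice; a large
#' synapse has all markers on three or more slices.
#'
#' @inheritParams detect_synapses
#' @param neuropil_um3 neuropil volume in um^3 (denominator), > 0.
#' @return A data.frame with columns `query`, `size_class`
#'   (small/medium/large/all), `n`, `density`.
#' @export
size_binned_densities <- function(prob_channels, query, neuropil_um3,
                                  threshold = 0.9, params = query_params()) {
  stopifnot(neuropil_um3 > 0)
  n <- vapply(1:3, function(s)
    nrow(detect_synapses(prob_channels, query, threshold, params,
                         required_span = s)), 0L)
  if (n[1] < n[2] || n[2] < n[3]) {
    stop("span anti-monotonicity violated: counts ", paste(n, collapse = ", "))
  }
  data.frame(
    query = query$name,
    size_class = c("small", "medium", "large", "all"),
    n = c(n[1] - n[2], n[2] - n[3], n[3], n[1]),
    density = c(n[1] - n[2], n[2] - n[3], n[3], n[1]) / neuropil_um3,
    stringsAsFactors = FALSE
  )
}

#' Size-binned puncta densities for a single marker
#'
#' The degenerate single-channel analysis: the same span-subtraction scheme
#' applied to one marker's punctum probability map, with no colocalization or
#' adjacency requirement.
#'
#' @param prob a foreground `probability_volume` for the channel.
#' @param spec a [marker_spec()] (its `min_slices` override, if any, is
#'   ignored in favour of the scanned span requirement).
#' @inheritParams size_binned_densities
#' @return A data.frame as in [size_binned_densities()].
#' @export
single_marker_puncta_density <- function(prob, spec, neuropil_um3,
                                         threshold = 0.9) {
  stopifnot(neuropil_um3 > 0)
  spec$min_slices <- NULL
  n <- vapply(1:3, function(s) {
    pm <- punctum_probability(prob, spec, required_span = s)
    nrow(threshold_and_label(pm, threshold, query_name = spec$channel))
  }, 0L)
  if (n[1] < n[2] || n[2] < n[3]) {
    stop("span anti-monotonicity violated: counts ", paste(n, collapse = ", "))
  }
  data.frame(
    query = spec$channel,
    size_class = c("small", "medium", "large", "all"),
    n = c(n[1] - n[2], n[2] - n[3], n[3], n[1]),
    density = c(n[1] - n[2], n[2] - n[3], n[3], n[1]) / neuropil_um3,
    stringsAsFactors = FALSE
  )
}

#' Distribution of the postsynaptic punctum span among detected synapses
#'
#' Re-runs the query varying only the postsynaptic markers' minimum slice
#' span over `span_values`; successive differences of the (nonincreasing)
#' counts give the number of detected synapses whose postsynaptic punctum
#' spans exactly k slices, with the last class open-ended (>= max span).
#'
#' @inheritParams detect_synapses
#' @param span_values increasing integer spans, e.g. `1:6`.
#' @return A data.frame with `span` (labels, last one `">=k"`), `n`.
#' @export
postsynaptic_span_distribution <- function(prob_channels, query,
                                           span_values = 1:6,
                                           threshold = 0.9,
                                           params = query_params()) {
  span_values <- sort(as.integer(span_values))
  counts <- vapply(span_values, function(s) {
    q <- query
    q$postsynaptic <- lapply(q$postsynaptic, function(m) {
      m$min_slices <- s
      m
    })
    nrow(detect_synapses(prob_channels, q, threshold, params))
  }, 0L)
  if (any(diff(counts) > 0)) {
    stop("span anti-monotonicity violated: counts ",
         paste(counts, collapse = ", "))
  }
  k <- length(span_values)
  data.frame(
    span = c(paste0(span_values[-k]), paste0(">=", span_values[k])),
    n = c(-diff(counts), counts[k]),
    stringsAsFactors = FALSE
  )
}

#' Match detections to ground truth
#'
#' Greedy one-to-one assignment by anisotropic centroid distance: candidate
#' pairs within `radius_um` are matched closest-first, each detection and
#' truth record used at most once.
#'
#' @param detections a `synapse_detections` data.frame (needs `x_um`, `y_um`,
#'   `z_um`).
#' @param truth a data.frame with `x_um`, `y_um`, `z_um` (e.g. simulator
#'   ground truth).
#' @param radius_um matching radius in um (default 0.3, about one synapse).
#' @return A list with `matches` (data.frame det/truth index pairs and
#'   distance), `recall`, `precision`.
#' @export
match_ground_truth <- function(detections, truth, radius_um = 0.3) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(matches = data.frame(det = integer(0), truth = integer(0),
                                     dist_um = numeric(0)),
                recall = if (nt == 0) NA_real_ else 0,
                precision = if (nd == 0) NA_real_ else 0))
  }
  dx <- outer(detections$x_um, truth$x_um, "-")
  dy <- outer(detections$y_um, truth$y_um, "-")
  dz <- outer(detections$z_um, truth$z_um, "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  cand <- which(dist <= radius_um, arr.ind = TRUE)
  ord <- order(dist[cand])
  cand <- cand[ord, , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    di <- cand[i, 1]; ti <- cand[i, 2]
    if (!used_d[di] && !used_t[ti]) {
      used_d[di] <- TRUE; used_t[ti] <- TRUE; keep[i] <- TRUE
    }
  }
  m <- cand[keep, , drop = FALSE]
  list(matches = data.frame(det = m[, 1], truth = m[, 2],
                            dist_um = dist[m]),
       recall = sum(keep) / nt,
       precision = sum(keep) / nd)
}
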