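#' Marker requirement within a synapse query
#'
#' @param channel marker channel name.
#' @param min_xy_px minimum lateral punctum footprint in pixels per side
#'   (default 2, i.e. 2 x 2 px = 0.2 um x 0.2 um at 0.1 um/px).
#' @param min_slices required slice span; `NULL` means "use the query-level
#'   span requirement". A per-marker override expresses rules such as the
#'   VGluT2 channel's two-or-more-slice requirement, adopted because that
#'   antibody also produces scattered single-slice background speckle.
#' @return An object of class `marker_spec`.
#' @export
marker_spec <- function(channel, min_xy_px = 2L, min_slices = NULL) {
  stopifnot(is.character(channel), length(channel) == 1, min_xy_px >= 1)
  if (!is.null(min_slices)) stopifnot(min_slices >= 1)
  structure(list(channel = channel, min_xy_px = as.integer(min_xy_px),
                 min_slices = if (is.null(min_slices)) NULL
                              else as.integer(min_slices)),
            class = "marker_spec")
}

#' Declarative synapse-type query
#'
#' A query states what a synapse of interest looks like: which markers must be
#' present, which markers colocalize (same subclass: presynaptic with
#' presynaptic), which lie adjacent (presynaptic vs postsynaptic vs astrocytic
#' subclasses), and how large each punctum must be. A query with an astrocyte
#' marker detects tripartite synapses (those immediately adjacent to an
#' astrocytic process).
#'
#' @param name query label.
#' @param presynaptic,postsynaptic lists of [marker_spec()] (bare channel-name
#'   character vectors are promoted); at least one of each.
#' @param astrocyte optional single [marker_spec()] or channel name.
#' @param required_span query-level slice-span requirement applied to every
#'   marker without its own `min_slices` override (default 1).
#' @return An object of class `synapse_query`.
#' @export
synapse_query <- function(name, presynaptic, postsynaptic, astrocyte = NULL,
                          required_span = 1L) {
  promote <- function(x) {
    if (inherits(x, "marker_spec")) return(list(x))
    if (is.character(x)) return(lapply(x, marker_spec))
    stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "marker_spec")))
    x
  }
  presynaptic <- promote(presynaptic)
  postsynaptic <- promote(postsynaptic)
  if (!is.null(astrocyte)) astrocyte <- promote(astrocyte)[[1]]
  stopifnot(length(presynaptic) >= 1, length(postsynaptic) >= 1,
            required_span >= 1)
  structure(list(name = name, presynaptic = presynaptic,
                 postsynaptic = postsynaptic, astrocyte = astrocyte,
                 required_span = as.integer(required_span)),
            class = "synapse_query")
}

#' @export
print.synapse_query <- function(x, ...) {
  fmt <- function(ms) paste(vapply(ms, function(m) m$channel, ""), collapse = "+")
  cat(sprintf("<synapse_query> '%s': pre=%s post=%s astro=%s span>=%d\n",
              x$name, fmt(x$presynaptic), fmt(x$postsynaptic),
              if (is.null(x$astrocyte)) "none" else x$astrocyte$channel,
              x$required_span))
  invisible(x)
}

#' The standard ten-query catalog
#'
#' The bipartite and tripartite queries used for cortical synapse typing:
#' glutamatergic (synapsin/PSD95) overall and split by vesicular glutamate
#' transporter (VGluT1, VGluT2, both), GABAergic (synapsin+GAD/gephyrin), and
#' each of those five with a glutamine synthetase (GS) astrocyte marker. The
#' VGluT2 marker always carries a two-slice minimum span.
#'
#' @param vglut2_min_slices minimum slice span for the VGluT2 channel
#'   (default 2).
#' @return Named list of ten [synapse_query()] objects.
#' @export
default_queries <- function(vglut2_min_slices = 2L) {
  v2 <- function() marker_spec("VGluT2", min_slices = vglut2_min_slices)
  q <- list(
    synapse_query("Glutamatergic", "synapsin", "PSD95"),
    synapse_query("Glutamatergic VGluT1", c("synapsin", "VGluT1"), "PSD95"),
    synapse_query("Glutamatergic VGluT2",
                  list(marker_spec("synapsin"), v2()), "PSD95"),
    synapse_query("Glutamatergic VGluT1/VGluT2",
                  list(marker_spec("synapsin"), marker_spec("VGluT1"), v2()),
                  "PSD95"),
    synapse_query("GABAergic", c("synapsin", "GAD"), "gephyrin")
  )
  qa <- lapply(q, function(x) {
    x$name <- paste(x$name, "adjacent to astrocyte")
    x$astrocyte <- marker_spec("GS")
    x
  })
  out <- c(q, qa)
  names(out) <- vapply(out, function(x) x$name, "")
  out
}

#' Spatial tolerances of the query operators
#'
#' @param r_coloc lateral dilation radius (px) allowed between colocalizing
#'   markers of the same subclass, which may share only part of their pixels.
#' @param adjacency_xy,adjacency_z half-width (px) and half-depth (slices) of
#'   the adjacency neighborhood searched between subclasses. Lateral and axial
#'   extents are parameterized separately because voxels are anisotropic
#'   (0.1 um laterally vs 0.07 um axially by default).
#' @return A list of class `query_params`.
#' @export
query_params <- function(r_coloc = 1L, adjacency_xy = 2L, adjacency_z = 1L) {
  stopifnot(r_coloc >= 0, adjacency_xy >= 0, adjacency_z >= 0)
  structure(list(r_coloc = as.integer(r_coloc),
                 adjacency_xy = as.integer(adjacency_xy),
                 adjacency_z = as.integer(adjacency_z)),
            class = "query_params")
}

#' Per-voxel punctum probability for one marker
#'
#' The probability that a punctum meeting the marker's minimum size is present
#' at each voxel: the lateral evidence is the product of foreground
#' probabilities over the `min_xy_px` window on each slice (every pixel of
#' the minimum footprint must be foreground), and the axial
#' requirement takes, at each voxel, the maximum over all windows of
#' `min_slices` consecutive slices containing it of the product of the
#' windowed per-slice values. Windows are clipped at volume borders, so
#' probabilities near edges are naturally attenuated.
#'
#' @param prob a [foreground_probability()] result or probability array.
#' @param spec a [marker_spec()]; `min_slices` must be resolved (non-`NULL`)
#'   or supplied via `required_span`.
#' @param required_span fallback span when `spec$min_slices` is `NULL`.
#' @return A `probability_volume`.
#' @export
punctum_probability <- function(prob, spec, required_span = 1L) {
  p <- prob_data(prob)
  stopifnot(all(p >= 0 & p <= 1))
  s <- if (is.null(spec$min_slices)) as.integer(required_span) else spec$min_slices
  nz <- dim(p)[3]
  geom <- if (inherits(prob, "probability_volume")) prob$geometry else
    at_geometry(dim(p)[1], dim(p)[2], nz)
  if (s > nz) {
    warning("min_slices (", s, ") exceeds stack depth (", nz, "); empty result")
    return(structure(list(data = array(0, dim(p)), channel = spec$channel,
                          geometry = geom), class = "probability_volume"))
  }
  b <- box_prod_xy(p, spec$min_xy_px)
  # product over s consecutive slices, anchored at window start z0
  w <- b
  if (s > 1L) {
    for (k in 1:(s - 1L)) {
      w <- w * shift3(b, 0L, 0L, -k, fill = 0)
    }
    # w[,,z0] now = prod over z0..z0+s-1 (zero where window exits the stack);
    # each voxel z takes the best window containing it: z0 in [z-s+1, z]
    out <- w
    for (k in 1:(s - 1L)) out <- pmax(out, shift3(w, 0L, 0L, k, fill = 0))
    w <- out
  }
  structure(list(data = w, channel = spec$channel, geometry = geom),
            class = "probability_volume")
}

#' Combine colocalizing markers of one subclass
#'
#' Markers of the same subclass (e.g. synapsin and VGluT1, both presynaptic)
#' occupy the same 3-D space up to a small misregistration, so each punctum
#' probability map is laterally max-dilated by `r_coloc` pixels and the maps
#' are multiplied voxelwise. The dilation is applied uniformly, including to
#' a single-marker subclass: this keeps the query algebra anti-monotone
#' (adding a marker multiplies by one more factor in `[0, 1]` and can never
#' raise the probability anywhere) and invariant to marker order.
#'
#' @param punctum_probs nonempty list of `probability_volume`s / arrays on the
#'   same grid.
#' @param r_coloc lateral dilation radius in px (default from [query_params()]).
#' @return A probability array.
#' @export
combine_colocalized <- function(punctum_probs, r_coloc = 1L) {
  if (length(punctum_probs) == 0) stop("empty marker list")
  mats <- lapply(punctum_probs, prob_data)
  d <- dim(mats[[1]])
  stopifnot(all(vapply(mats, function(m) identical(dim(m), d), TRUE)))
  out <- max_filter(mats[[1]], r_coloc, r_coloc, 0L)
  for (m in mats[-1]) out <- out * max_filter(m, r_coloc, r_coloc, 0L)
  out
}

#' Combine subclasses by adjacency
#'
#' Presynaptic, postsynaptic and (optionally) astrocytic evidence do not
#' overlap but are juxtaposed. The synapse probability anchored at the
#' presynaptic side is `pre * maxN(post) * maxN(astro)`, where `maxN` is the
#' maximum over the adjacency neighborhood (+/- `adjacency_xy` px laterally,
#' +/- `adjacency_z` slices).
#'
#' @param pre,post,astro probability arrays (astro may be `NULL`).
#' @param params a [query_params()].
#' @return A probability array.
#' @export
combine_adjacent <- function(pre, post, astro = NULL, params = query_params()) {
  pre <- prob_data(pre); post <- prob_data(post)
  q <- pre * max_filter(post, params$adjacency_xy, params$adjacency_xy,
                        params$adjacency_z)
  if (!is.null(astro)) {
    q <- q * max_filter(prob_data(astro), params$adjacency_xy,
                        params$adjacency_xy, params$adjacency_z)
  }
  q
}

#' Evaluate a synapse query into a probability map
#'
#' Composes [punctum_probability()] per marker, [combine_colocalized()] within
#' each subclass, and [combine_adjacent()] across subclasses. The result is a
#' per-voxel probability that a synapse matching the query is centered there.
#'
#' @param prob_channels named list of foreground `probability_volume`s (or
#'   arrays), one per marker channel.
#' @param query a [synapse_query()].
#' @param params a [query_params()].
#' @param required_span optional override of `query$required_span` (used for
#'   size binning by query subtraction).
#' @return A `probability_volume` named after the query.
#' @export
evaluate_query <- function(prob_channels, query, params = query_params(),
                           required_span = NULL) {
  span <- if (is.null(required_span)) query$required_span
          else as.integer(required_span)
  get_chan <- function(nm) {
    if (!nm %in% names(prob_channels)) {
      stop("query '", query$name, "' references missing channel '", nm, "'")
    }
    prob_channels[[nm]]
  }
  sub <- function(specs) {
    pp <- lapply(specs, function(m)
      punctum_probability(get_chan(m$channel), m, required_span = span))
    combine_colocalized(pp, params$r_coloc)
  }
  pre <- sub(query$presynaptic)
  post <- sub(query$postsynaptic)
  astro <- if (is.null(query$astrocyte)) NULL else sub(list(query$astrocyte))
  q <- combine_adjacent(pre, post, astro, params)
  d <- dim(q)
  geom <- {
    g1 <- prob_channels[[query$presynaptic[[1]]$channel]]
    if (inherits(g1, "probability_volume")) g1$geometry
    else at_geometry(d[1], d[2], d[3])
  }
  structure(list(data = q, channel = query$name, geometry = geom),
            class = "probability_volume")
}
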