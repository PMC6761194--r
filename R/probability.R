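#' Estimate the Gaussian background model of a channel
#'
#' Immunofluorescent array tomography channels are dominated by background:
#' puncta occupy a small fraction of voxels. The background noise is modeled
#' as a Gaussian whose location and scale are estimated from the data itself.
#' By default a robust estimate (median and scaled MAD) is used so sparse
#' bright puncta do not inflate the scale; plain sample moments are available
#' via `method = "moments"`. Staining intensity varies section to section, so
#' the default scope fits one model per slice.
#'
#' @param channel a [channel_volume()] or numeric 3-D array.
#' @param scope `"slice"` (one model per section, default) or `"volume"`.
#' @param method `"robust"` (median/MAD, default) or `"moments"` (mean/sd).
#' @return An object of class `background_model`: a data.frame with columns
#'   `slice` (NA for volume scope), `mean`, `sd`.
#' @export
estimate_background <- function(channel,
                                scope = c("slice", "volume"),
                                method = c("robust", "moments")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  a <- if (inherits(channel, "channel_volume")) channel$data else channel
  stopifnot(is.array(a), length(dim(a)) == 3, length(a) > 0)
  est <- function(v) {
    if (method == "robust") c(stats::median(v), stats::mad(v))
    else c(mean(v), stats::sd(v))
  }
  if (scope == "volume") {
    e <- est(as.vector(a))
    df <- data.frame(slice = NA_integer_, mean = e[1], sd = e[2])
  } else {
    nz <- dim(a)[3]
    m <- vapply(seq_len(nz), function(z) est(as.vector(a[, , z])),
                numeric(2))
    df <- data.frame(slice = seq_len(nz), mean = m[1, ], sd = m[2, ])
  }
  df$sd[is.na(df$sd)] <- 0
  structure(df, class = c("background_model", "data.frame"),
            scope = scope, method = method)
}

#' Per-voxel foreground probability under the background model
#'
#' The foreground probability is one minus the probability that the voxel's
#' intensity arose from the Gaussian background: `p(x) = pnorm((I(x) - mu)/sd)`,
#' the upper-tail rule. It is monotone nondecreasing in intensity and lies in
#' `[0, 1]`. A degenerate background (`sd = 0`) maps intensities above the mean
#' to 1 and all others to 0.
#'
#' @param channel a [channel_volume()] or numeric 3-D array.
#' @param background a `background_model` from [estimate_background()]; if
#'   `NULL` it is estimated with defaults.
#' @return An object of class `probability_volume`: list with `data` (array of
#'   probabilities), `channel` (source name), `geometry`.
#' @export
foreground_probability <- function(channel, background = NULL) {
  a <- if (inherits(channel, "channel_volume")) channel$data else channel
  nm <- if (inherits(channel, "channel_volume")) channel$name else NA_character_
  geom <- if (inherits(channel, "channel_volume")) channel$geometry else {
    d <- dim(a); at_geometry(d[1], d[2], d[3])
  }
  if (is.null(background)) background <- estimate_background(a)
  stopifnot(inherits(background, "background_model"))
  p <- array(0, dim(a))
  apply_one <- function(x, mu, sd) {
    if (sd > 0) stats::pnorm((x - mu) / sd) else as.numeric(x > mu)
  }
  if (attr(background, "scope") == "volume") {
    p[] <- apply_one(a, background$mean[1], background$sd[1])
  } else {
    stopifnot(nrow(background) == dim(a)[3])
    for (z in seq_len(dim(a)[3])) {
      p[, , z] <- apply_one(a[, , z], background$mean[z], background$sd[z])
    }
  }
  structure(list(data = p, channel = nm, geometry = geom),
            class = "probability_volume")
}

#' @export
print.probability_volume <- function(x, ...) {
  cat(sprintf("<probability_volume> '%s' %s, mean %.3f\n",
              x$channel, paste(dim(x$data), collapse = " x "),
              mean(x$data)))
  invisible(x)
}

# Accept either a probability_volume or a bare array in internal code.
prob_data <- function(x) {
  if (inherits(x, "probability_volume")) x$data else x
}
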