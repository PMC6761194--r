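#' Fraction of synapses adjacent to astrocytic processes
#'
#' The ratio of the tripartite (astrocyte-requiring) density to the matching
#' bipartite density for the same sample, layer and synapse type. Values
#' slightly above 1 can arise from detection noise and are clipped with a
#' warning.
#'
#' @param density_tripartite,density_bipartite densities per um^3.
#' @return Fraction in `[0, 1]`, or `NA` when the bipartite density is 0.
#' @export
astro_association_fraction <- function(density_tripartite, density_bipartite) {
  if (length(density_bipartite) == 1 && (is.na(density_bipartite) ||
                                         density_bipartite == 0)) {
    return(NA_real_)
  }
  f <- density_tripartite / density_bipartite
  f[density_bipartite == 0] <- NA_real_
  if (any(f > 1, na.rm = TRUE)) {
    warning("association fraction > 1 clipped (detection noise)")
    f <- pmin(f, 1)
  }
  f
}

#' Excitation/inhibition ratio
#'
#' Excitation is the density of synapsin+PSD95 synapses; inhibition the
#' density of synapsin+GAD/gephyrin synapses.
#'
#' @param excitatory,inhibitory densities per um^3 (vectors allowed, e.g. one
#'   entry per layer).
#' @return Elementwise ratio; `NA` where the inhibitory density is 0.
#' @export
excitation_inhibition_ratio <- function(excitatory, inhibitory) {
  r <- excitatory / inhibitory
  r[inhibitory == 0] <- NA_real_
  r
}

#' Linear to volumetric shrinkage
#'
#' Tissue dehydration and resin embedding shrink each linear dimension by a
#' fraction `l`; the volumetric shrinkage is `1 - (1 - l)^3` (23% linear
#' corresponds to about 54% volumetric).
#'
#' @param linear_fraction linear shrinkage in `[0, 1)`.
#' @return Volumetric shrinkage fraction.
#' @export
shrinkage_volumetric <- function(linear_fraction) {
  stopifnot(all(linear_fraction >= 0), all(linear_fraction < 1))
  1 - (1 - linear_fraction)^3
}

#' Convert embedded-tissue density to unprocessed-tissue density
#'
#' Densities are measured per um^3 of embedded (shrunken) tissue; the same
#' synapses occupy a larger unprocessed volume, so the density deflates by
#' the volume ratio `(1 - l)^3`.
#'
#' @param density_embedded synapses per um^3 of embedded tissue.
#' @param linear_fraction linear shrinkage in `[0, 1)`.
#' @return Synapses per um^3 of unprocessed tissue.
#' @export
density_to_unprocessed <- function(density_embedded, linear_fraction) {
  stopifnot(all(density_embedded >= 0),
            all(linear_fraction >= 0), all(linear_fraction < 1))
  density_embedded * (1 - linear_fraction)^3
}

#' Two-tailed unpaired t-test
#'
#' Student's pooled-variance t-test (Welch's available via `var_equal =
#' FALSE`), the small-sample test used for WT/KO comparisons. Degenerate
#' zero-variance inputs are resolved deterministically: equal means give
#' p = 1, unequal means p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool variances (default `TRUE`).
#' @return List with `t` and two-tailed `p`.
#' @export
unpaired_ttest <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Percent difference of a knockout mean relative to wild type
#'
#' @param wt_mean,ko_mean group means; `wt_mean` must be nonzero.
#' @return `100 * (ko_mean - wt_mean) / wt_mean`, `NA` when `wt_mean` is 0.
#' @export
percent_difference <- function(wt_mean, ko_mean) {
  out <- 100 * (ko_mean - wt_mean) / wt_mean
  out[wt_mean == 0] <- NA_real_
  out
}

#' Compare WT and KO cohorts cell by cell
#'
#' For every (layer, query, size class) cell present in the per-sample
#' density tables: group means and sds, percent difference, and the two-tailed
#' unpaired t-test p-value. Cells missing from some samples are reported with
#' `NA` statistics rather than imputed. Per-sample values are retained in the
#' `samples` attribute.
#'
#' @param per_sample_tables named list of per-sample density data.frames with
#'   columns `query`, `size_class`, `density` and optionally `layer`.
#' @param groups character vector (`"WT"`/`"KO"`) parallel to the tables; at
#'   least two samples per group.
#' @param var_equal pool variances in the t-test (default `TRUE`).
#' @return A data.frame with one row per cell: `layer`, `query`, `size_class`,
#'   `mean_wt`, `sd_wt`, `n_wt`, `mean_ko`, `sd_ko`, `n_ko`, `percent_diff`,
#'   `t`, `p`.
#' @export
compare_cohorts <- function(per_sample_tables, groups, var_equal = TRUE) {
  stopifnot(length(per_sample_tables) == length(groups),
            all(groups %in% c("WT", "KO")))
  if (sum(groups == "WT") < 2 || sum(groups == "KO") < 2) {
    stop("need at least two samples per group")
  }
  long <- do.call(rbind, lapply(seq_along(per_sample_tables), function(i) {
    t <- per_sample_tables[[i]]
    if (is.null(t$layer)) t$layer <- "all"
    nm <- names(per_sample_tables)[i]
    data.frame(sample = if (is.null(nm) || nm == "") paste0("s", i) else nm,
               group = groups[i], layer = t$layer, query = t$query,
               size_class = t$size_class, density = t$density,
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$layer, long$query, long$size_class, long$group,
                     long$sample), ]
  cells <- unique(long[, c("layer", "query", "size_class")])
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sub <- long[long$layer == cl$layer & long$query == cl$query &
                long$size_class == cl$size_class, ]
    wt <- sub$density[sub$group == "WT"]
    ko <- sub$density[sub$group == "KO"]
    ok <- length(wt) >= 2 && length(ko) >= 2
    tt <- if (ok) unpaired_ttest(wt, ko, var_equal) else list(t = NA, p = NA)
    data.frame(cl,
               mean_wt = mean(wt), sd_wt = stats::sd(wt), n_wt = length(wt),
               mean_ko = mean(ko), sd_ko = stats::sd(ko), n_ko = length(ko),
               percent_diff = percent_difference(mean(wt), mean(ko)),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "samples") <- long
  res
}
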