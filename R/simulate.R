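SYNAPSE_TYPES <- c("VGluT1", "VGluT2", "VGluT1/2", "GABAergic")
ALL_CHANNELS <- c("synapsin", "PSD95", "VGluT1", "VGluT2", "GAD",
                  "gephyrin", "GS", "DAPI")

#' Configuration of the synthetic array-tomography scene
#'
#' Declares the generative model for a calibrated multi-channel volume:
#' synapses of four molecular types are placed uniformly in the neuropil at
#' the given per-type densities, each rendered as co-centered presynaptic
#' Gaussian puncta, a postsynaptic punctum displaced by a synaptic-cleft
#' offset in a random lateral direction, and (with the per-type association
#' probability) a glutamine synthetase punctum apposed to the cleft. Punctum
#' slice spans follow a log-normal law rounded to whole sections; the VGluT2
#' channel of a true VGluT2 synapse always spans at least two sections,
#' mirroring that antibody's robust labeling, while the channel also carries
#' randomly scattered single-slice speckle. DAPI nuclei are ellipsoids scaled
#' to a target volume fraction; synapses are never placed inside nuclei.
#'
#' Default densities are calibrated to reported wild-type cortical values:
#' glutamatergic 1.63/um^3 (VGluT1 1.24, VGluT2 0.265, dual 0.12) plus
#' GABAergic 0.311/um^3, totalling 1.94 synapses/um^3 of embedded tissue with
#' an excitation/inhibition ratio of 5.2, and astrocytic association 0.61
#' (VGluT1), 0.46 (VGluT2), 0.29 (GABAergic).
#'
#' @param geometry an [at_geometry()] (default 100 x 100 px x 30 slices).
#' @param densities named per-type synapse densities per um^3 of neuropil.
#' @param astro_prob named per-type astrocyte-association probabilities.
#' @param span_meanlog,span_sdlog log-normal parameters of the punctum slice
#'   span before rounding (defaults 0.5, 0.6: median about 1.6 sections).
#' @param cleft_offset_um range of the pre/post separation (default
#'   0.15-0.25 um).
#' @param astro_offset_um range of the GS punctum distance from the cleft
#'   midpoint, placed perpendicular to the pre/post axis (default 0.1-0.25 um).
#' @param punctum_radius_um range of the synaptic punctum lateral radius
#'   (visible half-width, about twice the Gaussian sigma) in um.
#' @param gs_radius_um radius range of glutamine synthetase puncta (default
#'   0.08-0.18 um, smaller than synaptic puncta: GS labels thin peripheral
#'   astrocytic processes, consistent with GS punctum size skewing small).
#' @param psf_sigma_um lateral point-spread sigma (default 0.1 um).
#' @param background list with `mean` and `sd` of the per-channel Gaussian
#'   background (default 100, 15).
#' @param amplitude_nsigma punctum peak amplitude above background, in
#'   background-sd units (default 8).
#' @param vglut2_speckle_per_um3 rate of single-slice VGluT2 false puncta.
#' @param gs_background_per_um3 rate of GS puncta not associated with any
#'   synapse (default 0.05: sparse enough that chance adjacency to a synapse
#'   stays below a few percent, the regime in which astrocytic-association
#'   fractions are interpretable).
#' @param nuclei list: `fraction` (target nuclear volume fraction), `n`
#'   (ellipsoid count), `axes_um` (semi-axes, row/col/slice).
#' @param size_multipliers optional named list `type -> c(small=, medium=,
#'   large=)` scaling the expected count of that type and size class;
#'   used to encode knockout effects (e.g. `list(GABAergic = c(large = 0.85))`
#'   for a 15% deficit of large inhibitory synapses).
#' @param layers optional [layer_partition()]; recorded on ground truth.
#' @param channels channels to render (default all eight).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(geometry = at_geometry(100, 100, 30),
                              densities = c("VGluT1" = 1.24,
                                            "VGluT2" = 0.265,
                                            "VGluT1/2" = 0.12,
                                            "GABAergic" = 0.311),
                              astro_prob = c("VGluT1" = 0.61, "VGluT2" = 0.46,
                                             "VGluT1/2" = 0.61,
                                             "GABAergic" = 0.29),
                              span_meanlog = 0.5, span_sdlog = 0.6,
                              cleft_offset_um = c(0.15, 0.25),
                              astro_offset_um = c(0.10, 0.25),
                              punctum_radius_um = c(0.10, 0.30),
                              gs_radius_um = c(0.08, 0.18),
                              psf_sigma_um = 0.1,
                              background = list(mean = 100, sd = 15),
                              amplitude_nsigma = 8,
                              vglut2_speckle_per_um3 = 2,
                              gs_background_per_um3 = 0.05,
                              nuclei = list(fraction = 0.1, n = 2,
                                            axes_um = c(3, 3, 2.5)),
                              size_multipliers = NULL,
                              layers = NULL,
                              channels = ALL_CHANNELS) {
  dens <- rep(0, length(SYNAPSE_TYPES)); names(dens) <- SYNAPSE_TYPES
  dens[names(densities)] <- densities
  ap <- rep(0, length(SYNAPSE_TYPES)); names(ap) <- SYNAPSE_TYPES
  ap[names(astro_prob)] <- astro_prob
  stopifnot(all(dens >= 0), all(ap >= 0 & ap <= 1), span_sdlog > 0,
            nuclei$fraction >= 0, nuclei$fraction < 1)
  structure(list(geometry = geometry, densities = dens, astro_prob = ap,
                 span_meanlog = span_meanlog, span_sdlog = span_sdlog,
                 cleft_offset_um = cleft_offset_um,
                 astro_offset_um = astro_offset_um,
                 punctum_radius_um = punctum_radius_um,
                 gs_radius_um = gs_radius_um,
                 psf_sigma_um = psf_sigma_um, background = background,
                 amplitude_nsigma = amplitude_nsigma,
                 vglut2_speckle_per_um3 = vglut2_speckle_per_um3,
                 gs_background_per_um3 = gs_background_per_um3,
                 nuclei = nuclei, size_multipliers = size_multipliers,
                 layers = layers, channels = channels),
            class = "simulation_config")
}

# Slice-span size classes: span = max(1, round(L)), L ~ lognormal.
# small: L < 1.5 (span 1); medium: 1.5 <= L < 2.5 (span 2); large: L >= 2.5.
span_class_probs <- function(meanlog, sdlog) {
  p1 <- stats::plnorm(1.5, meanlog, sdlog)
  p2 <- stats::plnorm(2.5, meanlog, sdlog) - p1
  c(small = p1, medium = p2, large = 1 - p1 - p2)
}

# Inverse-CDF draw of L ~ lognormal truncated to a size class.
draw_span_in_class <- function(n, class, meanlog, sdlog) {
  lo <- c(small = 0, medium = 1.5, large = 2.5)[[class]]
  hi <- c(small = 1.5, medium = 2.5, large = Inf)[[class]]
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

# Ellipsoid nuclei mask hitting a target volume fraction: random centers,
# global scale found by bisection on the lateral/axial semi-axes.
make_nuclei <- function(geom, nuclei) {
  d <- c(geom$height_px, geom$width_px, geom$n_slices)
  if (nuclei$fraction <= 0 || nuclei$n < 1) {
    return(array(FALSE, d))
  }
  centers <- cbind(stats::runif(nuclei$n, 1, d[1]),
                   stats::runif(nuclei$n, 1, d[2]),
                   stats::runif(nuclei$n, 1, d[3]))
  ax_px <- nuclei$axes_um / c(geom$pixel_size_xy, geom$pixel_size_xy,
                              geom$slice_thickness)
  rr <- seq_len(d[1]); cc <- seq_len(d[2]); zz <- seq_len(d[3])
  mask_at <- function(s) {
    m <- array(FALSE, d)
    for (i in seq_len(nuclei$n)) {
      q <- outer(outer((rr - centers[i, 1])^2 / (s * ax_px[1])^2,
                       (cc - centers[i, 2])^2 / (s * ax_px[2])^2, "+"),
                 (zz - centers[i, 3])^2 / (s * ax_px[3])^2, "+")
      m <- m | (q <= 1)
    }
    m
  }
  lo <- 0.2; hi <- 4
  for (it in 1:14) {
    mid <- (lo + hi) / 2
    f <- mean(mask_at(mid))
    if (f < nuclei$fraction) lo <- mid else hi <- mid
  }
  mask_at((lo + hi) / 2)
}

#' Generate a synthetic multi-channel array-tomography volume
#'
#' Draws a scene from the generative model in [simulation_config()] and
#' renders the immunofluorescence channels: per-type synapse counts are
#' Poisson in the neuropil volume, puncta are Gaussian blobs constant across
#' their slice span, channels are blurred laterally by the PSF (sections are
#' imaged independently, so there is no axial blur) and Gaussian background
#' noise is added. Deterministic under a fixed seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer RNG seed.
#' @return A list of class `at_simulation`: `channels` (named list of
#'   [channel_volume()]), `truth` (ground-truth data.frame: one row per
#'   synapse with type, centroid in px and um, slice span, size class,
#'   astrocyte flag, layer), `nuclei` (logical truth mask), `neuropil_um3`,
#'   `config`, `seed`.
#' @export
generate_volume <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  geom <- config$geometry
  d <- c(geom$height_px, geom$width_px, geom$n_slices)
  px <- geom$pixel_size_xy
  nuc <- make_nuclei(geom, config$nuclei)
  neuropil_um3 <- volume_um3(geom) * (1 - mean(nuc))

  pcls <- span_class_probs(config$span_meanlog, config$span_sdlog)
  classes <- names(pcls)

  # --- draw ground truth ------------------------------------------------
  margin <- 3L
  truth <- list()
  for (type in SYNAPSE_TYPES) {
    for (cl in classes) {
      mult <- 1
      sm <- config$size_multipliers
      if (!is.null(sm) && type %in% names(sm) && cl %in% names(sm[[type]])) {
        mult <- sm[[type]][[cl]]
      }
      lambda <- config$densities[[type]] * pcls[[cl]] * mult * neuropil_um3
      n <- stats::rpois(1, lambda)
      if (n == 0) next
      L <- draw_span_in_class(n, cl, config$span_meanlog, config$span_sdlog)
      span <- pmin(pmax(1L, as.integer(round(L))), d[3])
      zmin <- floor((span - 1) / 2) + 1L
      zmax <- pmax(d[3] - ceiling((span - 1) / 2), zmin)
      # vectorized rejection sampling of neuropil locations
      r0 <- c0 <- numeric(n); z0 <- integer(n)
      todo <- seq_len(n)
      for (it in 1:200) {
        m <- length(todo)
        if (m == 0) break
        r0[todo] <- stats::runif(m, margin + 1, d[1] - margin)
        c0[todo] <- stats::runif(m, margin + 1, d[2] - margin)
        z0[todo] <- zmin[todo] +
          as.integer(floor(stats::runif(m) * (zmax[todo] - zmin[todo] + 1L)))
        todo <- todo[nuc[cbind(round(r0[todo]), round(c0[todo]), z0[todo])]]
      }
      truth[[length(truth) + 1L]] <- data.frame(
        type = type, row = r0, col = c0, slice = z0,
        span = span, span_raw = L, size_class = cl,
        radius_um = stats::runif(n, config$punctum_radius_um[1],
                                 config$punctum_radius_um[2]),
        astro_associated = stats::runif(n) < config$astro_prob[[type]],
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), row = numeric(0),
               col = numeric(0), slice = integer(0), span = integer(0),
               span_raw = numeric(0), size_class = character(0),
               radius_um = numeric(0), astro_associated = logical(0))
  truth <- cbind(id = seq_len(nrow(truth)), truth)
  if (nrow(truth) > 0) {
    truth$x_um <- (truth$col - 0.5) * px
    truth$y_um <- (truth$row - 0.5) * px
    truth$z_um <- (truth$slice - 0.5) * geom$slice_thickness
    truth$layer <- if (is.null(config$layers)) "all" else
      layer_of_row(truth$row, config$layers)
  } else {
    truth$x_um <- numeric(0); truth$y_um <- numeric(0)
    truth$z_um <- numeric(0); truth$layer <- character(0)
  }

  # --- puncta list ------------------------------------------------------
  pre_markers <- list("VGluT1" = c("synapsin", "VGluT1"),
                      "VGluT2" = c("synapsin", "VGluT2"),
                      "VGluT1/2" = c("synapsin", "VGluT1", "VGluT2"),
                      "GABAergic" = c("synapsin", "GAD"))
  post_marker <- c("VGluT1" = "PSD95", "VGluT2" = "PSD95",
                   "VGluT1/2" = "PSD95", "GABAergic" = "gephyrin")
  pn <- list()  # vectorized chunks: channel, row, col, z0, z1, sigma_px
  amp <- config$amplitude_nsigma * config$background$sd
  add_puncta <- function(channel, r, c, zc, span, sigma_px) {
    if (length(r) == 0) return(invisible())
    z0 <- pmax(1L, as.integer(zc) - as.integer(floor((span - 1) / 2)))
    z1 <- pmin(d[3], z0 + as.integer(span) - 1L)
    pn[[length(pn) + 1L]] <<- list(
      channel = rep_len(channel, length(r)), row = r, col = c,
      z0 = z0, z1 = z1, sigma_px = rep_len(sigma_px, length(r)))
    invisible()
  }
  rad_sigma <- function(n) {
    # punctum lateral radius ~ visible half-width ~ 2 sigma
    stats::runif(n, config$punctum_radius_um[1],
                 config$punctum_radius_um[2]) / (2 * px)
  }
  gs_sigma <- function(n) {
    stats::runif(n, config$gs_radius_um[1], config$gs_radius_um[2]) / (2 * px)
  }
  for (ty in SYNAPSE_TYPES) {
    i <- which(truth$type == ty)
    if (length(i) == 0) next
    n <- length(i)
    s <- truth$span[i]
    sg <- truth$radius_um[i] / (2 * px)
    for (m in pre_markers[[ty]]) {
      add_puncta(m, truth$row[i], truth$col[i], truth$slice[i],
                 if (m == "VGluT2") pmax(2L, s) else s, sg)
    }
    # postsynaptic punctum across the cleft, random lateral direction
    off <- stats::runif(n, config$cleft_offset_um[1],
                        config$cleft_offset_um[2]) / px
    th <- stats::runif(n, 0, 2 * pi)
    rp <- truth$row[i] + off * sin(th); cp <- truth$col[i] + off * cos(th)
    add_puncta(post_marker[[ty]], rp, cp, truth$slice[i], s, rad_sigma(n))
    a <- which(truth$astro_associated[i])
    if (length(a)) {
      # GS punctum apposed to the cleft: perpendicular to the pre/post axis
      na <- length(a)
      aoff <- stats::runif(na, config$astro_offset_um[1],
                           config$astro_offset_um[2]) / px
      sgn <- sample(c(-1, 1), na, replace = TRUE)
      rm <- (truth$row[i][a] + rp[a]) / 2 + sgn * aoff * cos(th[a])
      cm <- (truth$col[i][a] + cp[a]) / 2 - sgn * aoff * sin(th[a])
      aspan <- pmax(1L, pmin(d[3], as.integer(round(stats::rlnorm(
        na, config$span_meanlog, config$span_sdlog)))))
      add_puncta("GS", rm, cm, truth$slice[i][a], aspan, gs_sigma(na))
    }
  }
  # VGluT2 single-slice speckle
  nspeck <- stats::rpois(1, config$vglut2_speckle_per_um3 * volume_um3(geom))
  if (nspeck > 0) {
    add_puncta("VGluT2", stats::runif(nspeck, 1, d[1]),
               stats::runif(nspeck, 1, d[2]),
               sample.int(d[3], nspeck, replace = TRUE), 1L,
               stats::runif(nspeck, 0.08, 0.15) / (2 * px))
  }
  # unassociated GS puncta
  ngs <- stats::rpois(1, config$gs_background_per_um3 * volume_um3(geom))
  if (ngs > 0) {
    add_puncta("GS", stats::runif(ngs, 1, d[1]), stats::runif(ngs, 1, d[2]),
               sample.int(d[3], ngs, replace = TRUE),
               pmax(1L, pmin(d[3], as.integer(round(stats::rlnorm(
                 ngs, config$span_meanlog, config$span_sdlog))))),
               gs_sigma(ngs))
  }
  puncta <- if (length(pn)) {
    data.frame(channel = unlist(lapply(pn, `[[`, "channel")),
               row = unlist(lapply(pn, `[[`, "row")),
               col = unlist(lapply(pn, `[[`, "col")),
               z0 = unlist(lapply(pn, `[[`, "z0")),
               z1 = unlist(lapply(pn, `[[`, "z1")),
               sigma_px = unlist(lapply(pn, `[[`, "sigma_px")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(channel = character(0), row = numeric(0), col = numeric(0),
               z0 = integer(0), z1 = integer(0), sigma_px = numeric(0))
  }

  # --- render -----------------------------------------------------------
  channels <- list()
  for (nm in config$channels) {
    a <- array(0, d)
    if (nm == "DAPI") {
      a[nuc] <- amp
    } else {
      sub <- puncta[puncta$channel == nm, , drop = FALSE]
      sp <- config$psf_sigma_um / px
      for (i in seq_len(nrow(sub))) {
        sg <- sub$sigma_px[i]
        rad <- ceiling(3 * sg)
        rr <- max(1L, floor(sub$row[i] - rad)):min(d[1], ceiling(sub$row[i] + rad))
        cc <- max(1L, floor(sub$col[i] - rad)):min(d[2], ceiling(sub$col[i] + rad))
        # amplitude is specified as the observed (post-PSF) peak: pre-blur
        # amplitude is inflated by the 2-D Gaussian convolution peak loss
        a_eff <- amp * (sg^2 + sp^2) / sg^2
        g <- a_eff * outer(exp(-(rr - sub$row[i])^2 / (2 * sg^2)),
                           exp(-(cc - sub$col[i])^2 / (2 * sg^2)))
        for (z in sub$z0[i]:sub$z1[i]) a[rr, cc, z] <- a[rr, cc, z] + g
      }
    }
    a <- gaussian_blur_xy(a, config$psf_sigma_um / px)
    a <- a + stats::rnorm(length(a), config$background$mean,
                          config$background$sd)
    a[a < 0] <- 0
    channels[[nm]] <- channel_volume(a, nm, geom)
  }

  structure(list(channels = channels, truth = truth, nuclei = nuc,
                 neuropil_um3 = neuropil_um3, config = config, seed = seed),
            class = "at_simulation")
}

#' @export
print.at_simulation <- function(x, ...) {
  cat(sprintf("<at_simulation> seed %d: %d synapses, %d channels, neuropil %.4g um^3\n",
              x$seed, nrow(x$truth), length(x$channels), x$neuropil_um3))
  invisible(x)
}

#' Generate a WT/KO cohort of synthetic samples
#'
#' Independent samples from two configurations, with per-sample seeds derived
#' from a single cohort seed. Knockout effect sizes are encoded in
#' `config_ko` (typically via `size_multipliers` or altered densities).
#'
#' @param config_wt,config_ko [simulation_config()]s for the two genotypes.
#' @param n_wt,n_ko samples per group (defaults 3 WT, 4 KO).
#' @param seed cohort seed; per-sample seeds are drawn from it.
#' @return A list with `samples` (list of [generate_volume()] results),
#'   `groups` (character vector "WT"/"KO"), `seeds`.
#' @export
generate_cohort <- function(config_wt, config_ko, n_wt = 3L, n_ko = 4L,
                            seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_wt + n_ko)
  groups <- c(rep("WT", n_wt), rep("KO", n_ko))
  samples <- vector("list", n_wt + n_ko)
  for (i in seq_along(samples)) {
    cfg <- if (groups[i] == "WT") config_wt else config_ko
    samples[[i]] <- generate_volume(cfg, seeds[i])
  }
  names(samples) <- paste0(tolower(groups), c(seq_len(n_wt), seq_len(n_ko)))
  list(samples = samples, groups = groups, seeds = seeds)
}

#' Two-channel adjacency calibration scene
#'
#' Renders two channels, "A" and "B", as point-pair puncta in which each B
#' punctum is displaced from its A partner by a distance drawn from
#' `offset_um` in a random lateral direction. Used to calibrate the van
#' Steensel shift-correlation signature of adjacent-but-not-overlapping
#' markers.
#'
#' @param n number of pairs.
#' @param offset_um displacement range in um.
#' @param geometry an [at_geometry()].
#' @param sigma_um punctum Gaussian sigma.
#' @param background,amplitude_nsigma,psf_sigma_um as in
#'   [simulation_config()].
#' @param seed RNG seed.
#' @return Named list of two [channel_volume()]s `A` and `B`.
#' @export
generate_pair_volume <- function(n, offset_um = c(0.35, 0.45),
                                 geometry = at_geometry(256, 256, 10),
                                 sigma_um = 0.12,
                                 background = list(mean = 100, sd = 15),
                                 amplitude_nsigma = 8, psf_sigma_um = 0.1,
                                 seed = 1L) {
  set.seed(seed)
  d <- c(geometry$height_px, geometry$width_px, geometry$n_slices)
  px <- geometry$pixel_size_xy
  amp <- amplitude_nsigma * background$sd
  sg <- sigma_um / px
  a <- array(0, d); b <- array(0, d)
  render <- function(arr, r0, c0, z) {
    rad <- ceiling(3 * sg)
    rr <- max(1L, floor(r0 - rad)):min(d[1], ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(d[2], ceiling(c0 + rad))
    g <- amp * outer(exp(-(rr - r0)^2 / (2 * sg^2)),
                     exp(-(cc - c0)^2 / (2 * sg^2)))
    arr[rr, cc, z] <- arr[rr, cc, z] + g
    arr
  }
  for (i in seq_len(n)) {
    r0 <- stats::runif(1, 5, d[1] - 4)
    c0 <- stats::runif(1, 5, d[2] - 4)
    z <- sample(d[3], 1)
    off <- stats::runif(1, offset_um[1], offset_um[2]) / px
    th <- stats::runif(1, 0, 2 * pi)
    a <- render(a, r0, c0, z)
    b <- render(b, r0 + off * sin(th), c0 + off * cos(th), z)
  }
  a <- gaussian_blur_xy(a, psf_sigma_um / px)
  b <- gaussian_blur_xy(b, psf_sigma_um / px)
  a <- a + stats::rnorm(length(a), background$mean, background$sd)
  b <- b + stats::rnorm(length(b), background$mean, background$sd)
  a[a < 0] <- 0; b[b < 0] <- 0
  list(A = channel_volume(a, "A", geometry),
       B = channel_volume(b, "B", geometry))
}

#' Write / read simulator ground truth
#'
#' One CSV row per synapse with all ground-truth fields; round-trips
#' losslessly up to numeric print precision.
#'
#' @param truth ground-truth data.frame from [generate_volume()].
#' @param path CSV file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
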