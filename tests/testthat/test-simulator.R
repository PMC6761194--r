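test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(geometry = at_geometry(50, 50, 8),
                           channels = c("synapsin", "DAPI"))
  s1 <- generate_volume(cfg, seed = 14)
  s2 <- generate_volume(cfg, seed = 14)
  expect_identical(s1$channels$synapsin$data, s2$channels$synapsin$data)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_volume(cfg, seed = 15)
  expect_false(identical(s1$channels$synapsin$data, s3$channels$synapsin$data))
})

test_that("zero densities give pure background and empty ground truth", {
  cfg <- simulation_config(geometry = at_geometry(50, 50, 6),
                           densities = c("VGluT1" = 0),
                           vglut2_speckle_per_um3 = 0,
                           gs_background_per_um3 = 0,
                           nuclei = list(fraction = 0, n = 0, axes_um = c(1, 1, 1)),
                           channels = c("synapsin", "VGluT2", "GS"))
  sim <- generate_volume(cfg, seed = 16)
  expect_identical(nrow(sim$truth), 0L)
  for (ch in sim$channels) {
    expect_lt(max(ch$data), 100 + 6 * 15)  # noise only, no 8-sigma peaks
  }
})

test_that("synapse counts are Poisson in the neuropil volume", {
  cfg <- simulation_config(densities = c("VGluT1" = 1.9), channels = "DAPI",
                           astro_prob = c("VGluT1" = 0))
  sim <- generate_volume(cfg, seed = 17)
  lambda <- 1.9 * sim$neuropil_um3
  expect_lt(abs(nrow(sim$truth) - lambda), 3 * sqrt(lambda))
})

test_that("marker co-occurrence respects the type definitions", {
  # a purely GABAergic scene must not light up the PSD-95 channel
  cfg <- simulation_config(geometry = at_geometry(60, 60, 10),
                           densities = c("GABAergic" = 0.4),
                           vglut2_speckle_per_um3 = 0,
                           gs_background_per_um3 = 0,
                           channels = c("PSD95", "gephyrin", "GAD"))
  sim <- generate_volume(cfg, seed = 18)
  expect_gt(nrow(sim$truth), 0)
  expect_lt(max(sim$channels$PSD95$data), 185)   # background stays below ~5.7 sigma
  expect_gt(max(sim$channels$gephyrin$data), 185)  # puncta reach the 8-sigma peak
  expect_gt(max(sim$channels$GAD$data), 185)
})

test_that("rendered spans follow the configured log-normal law", {
  cfg <- simulation_config(geometry = at_geometry(120, 120, 50),
                           channels = character(0))
  sim <- generate_volume(cfg, seed = 19)
  expect_gt(nrow(sim$truth), 600)
  ks <- suppressWarnings(stats::ks.test(sim$truth$span_raw, stats::plnorm,
                                        meanlog = 0.5, sdlog = 0.6))
  expect_lt(unname(ks$statistic), 0.1)
  # integer spans are the rounded draws, floored at one slice
  expect_identical(sim$truth$span,
                   pmin(pmax(1L, as.integer(round(sim$truth$span_raw))), 50L))
})

test_that("astrocyte association in truth matches the configured probability", {
  cfg <- simulation_config(geometry = at_geometry(100, 100, 30),
                           densities = c("VGluT1" = 1.5),
                           astro_prob = c("VGluT1" = 0.72),
                           channels = character(0))
  sim <- generate_volume(cfg, seed = 20)
  n <- nrow(sim$truth)
  frac <- mean(sim$truth$astro_associated)
  expect_lt(abs(frac - 0.72), 3 * sqrt(0.72 * 0.28 / n))
})

test_that("synapses avoid nuclei and the nuclear fraction hits its target", {
  cfg <- simulation_config(geometry = at_geometry(80, 80, 20),
                           channels = character(0))
  sim <- generate_volume(cfg, seed = 21)
  expect_equal(mean(sim$nuclei), 0.1, tolerance = 0.01)
  inside <- sim$nuclei[cbind(round(sim$truth$row), round(sim$truth$col),
                             sim$truth$slice)]
  expect_false(any(inside))
})

test_that("cohorts carry group labels and encode knockout effect sizes", {
  g <- at_geometry(100, 100, 30)
  wt <- simulation_config(geometry = g, channels = character(0))
  ko <- simulation_config(geometry = g, channels = character(0),
                          densities = c("VGluT1" = 1.22, "VGluT2" = 0.26 * 0.75,
                                        "VGluT1/2" = 0.12, "GABAergic" = 0.34))
  coh <- generate_cohort(wt, ko, n_wt = 3, n_ko = 4, seed = 1)
  expect_identical(coh$groups, c(rep("WT", 3), rep("KO", 4)))
  expect_length(coh$samples, 7)
  expect_identical(anyDuplicated(coh$seeds), 0L)
  # -25% VGluT2 density shows up in mean ground-truth counts over replicates
  counts <- function(sim) sum(sim$truth$type == "VGluT2")
  wt_n <- ko_n <- 0
  for (s in 1:10) {
    coh <- generate_cohort(wt, ko, 3, 4, seed = s)
    n <- vapply(coh$samples, counts, 0)
    wt_n <- wt_n + mean(n[coh$groups == "WT"])
    ko_n <- ko_n + mean(n[coh$groups == "KO"])
  }
  rel <- (ko_n - wt_n) / wt_n
  expect_lt(abs(rel - (-0.25)), 0.10)
})

test_that("size multipliers thin exactly the targeted size class", {
  g <- at_geometry(80, 80, 16)
  base <- simulation_config(geometry = g, channels = character(0))
  thin <- simulation_config(geometry = g, channels = character(0),
                            size_multipliers = list(GABAergic = c(large = 0.5)))
  n_base <- n_thin <- c(large = 0, other = 0)
  for (s in 1:6) {
    tb <- generate_volume(base, seed = 100 + s)$truth
    tt <- generate_volume(thin, seed = 100 + s)$truth
    gb <- tb[tb$type == "GABAergic", ]; gt <- tt[tt$type == "GABAergic", ]
    n_base <- n_base + c(sum(gb$size_class == "large"), sum(gb$size_class != "large"))
    n_thin <- n_thin + c(sum(gt$size_class == "large"), sum(gt$size_class != "large"))
  }
  expect_lt(n_thin[["large"]] / n_base[["large"]], 0.75)
  expect_equal(n_thin[["other"]] / n_base[["other"]], 1, tolerance = 0.25)
})
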