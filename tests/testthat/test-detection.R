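test_that("3-D component labeling matches a brute-force transitive closure", {
  set.seed(41)
  for (i in 1:6) {
    mask <- array(runif(8 * 7 * 4) < 0.25, c(8, 7, 4))
    lab <- synquery:::label_components_3d(mask)
    got <- unname(lapply(split(which(lab > 0), lab[lab > 0]), sort))
    want <- brute_label_sets(mask)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("thresholding yields one ordered record per supra-threshold component", {
  expect_identical(nrow(threshold_and_label(array(0, c(6, 6, 3)))), 0L)
  p <- array(0, c(20, 20, 5))
  p[3:4, 3:4, 2] <- 0.95
  p[15:16, 10:11, 4] <- 0.99
  det <- threshold_and_label(p, 0.9, at_geometry(20, 20, 5))
  expect_identical(nrow(det), 2L)
  expect_true(all(diff(det$slice) >= 0))  # deterministic (slice,row,col) order
  expect_equal(det$n_voxels, c(4L, 4L))
  # centroid physical coordinates are voxel-center um
  expect_equal(det$x_um[1], (3.5 - 0.5) * 0.1)
  expect_equal(det$z_um[1], (2 - 0.5) * 0.07)
})

test_that("raising the threshold nests detections inside lower-threshold ones", {
  # the supra-threshold voxel set shrinks monotonically, and every component
  # at a higher threshold lies within exactly one component at a lower
  # threshold (counts themselves may rise when merged synapses separate)
  cfg <- simulation_config(geometry = at_geometry(80, 80, 14),
                           densities = c("VGluT1" = 0.4),
                           channels = c("synapsin", "PSD95"))
  sim <- generate_volume(cfg, seed = 44)
  pc <- lapply(sim$channels, foreground_probability)
  pm <- evaluate_query(pc, synapse_query("g", "synapsin", "PSD95"))
  th <- c(0.5, 0.7, 0.9, 0.97)
  dets <- lapply(th, function(t) threshold_and_label(pm, t))
  nv <- vapply(dets, function(d) sum(d$n_voxels), 0L)
  expect_true(all(diff(nv) <= 0))
  for (k in 2:length(th)) {
    lo <- unlist(attr(dets[[k - 1]], "voxels"))
    hi_comps <- attr(dets[[k]], "voxels")
    lo_id <- rep(seq_along(attr(dets[[k - 1]], "voxels")),
                 lengths(attr(dets[[k - 1]], "voxels")))
    for (comp in hi_comps) {
      parents <- unique(lo_id[match(comp, lo)])
      expect_false(anyNA(parents))
      expect_length(parents, 1)
    }
  }
})

test_that("size classes partition the detections and sum exactly to 'all'", {
  cfg <- simulation_config(
    geometry = at_geometry(80, 80, 16),
    densities = c("VGluT1" = 0.3, "GABAergic" = 0.1),
    nuclei = list(fraction = 0, n = 0, axes_um = c(1, 1, 1)),
    channels = c("synapsin", "PSD95", "VGluT1"))
  sim <- generate_volume(cfg, seed = 8)
  pc <- lapply(sim$channels, foreground_probability)
  q <- synapse_query("Glutamatergic", "synapsin", "PSD95")
  tab <- size_binned_densities(pc, q, sim$neuropil_um3)
  expect_identical(tab$size_class, c("small", "medium", "large", "all"))
  expect_identical(sum(tab$n[1:3]), tab$n[4])
  expect_equal(sum(tab$density[1:3]), tab$density[4])
  expect_true(all(tab$density >= 0))
})

test_that("a scene of single-slice synapses has zero medium and large density", {
  cfg <- simulation_config(
    geometry = at_geometry(80, 80, 10),
    densities = c("VGluT1" = 0.3),
    span_meanlog = 0, span_sdlog = 0.01,    # all spans round to 1
    nuclei = list(fraction = 0, n = 0, axes_um = c(1, 1, 1)),
    vglut2_speckle_per_um3 = 0, gs_background_per_um3 = 0,
    channels = c("synapsin", "PSD95"))
  sim <- generate_volume(cfg, seed = 9)
  expect_true(all(sim$truth$span == 1L))
  pc <- lapply(sim$channels, foreground_probability)
  q <- synapse_query("Glutamatergic", "synapsin", "PSD95")
  tab <- size_binned_densities(pc, q, sim$neuropil_um3)
  expect_equal(tab$n[tab$size_class == "medium"], 0L)
  expect_equal(tab$n[tab$size_class == "large"], 0L)
  expect_gt(tab$n[tab$size_class == "all"], 0L)
})

test_that("single-marker puncta densities follow the same subtraction scheme", {
  # empty channel
  empty <- foreground_probability(array(0, c(30, 30, 6)))
  t0 <- single_marker_puncta_density(empty, marker_spec("GS"), 100)
  expect_true(all(t0$density == 0))
  # ten clean single-slice puncta, no noise
  a <- array(0, c(40, 40, 6))
  centers <- cbind(seq(4, 36, length.out = 10), seq(4, 36, length.out = 10),
                   rep(2:4, length.out = 10))
  for (i in 1:10) a[centers[i, 1] + 0:1, centers[i, 2] + 0:1, centers[i, 3]] <- 1000
  p <- foreground_probability(a)
  tab <- single_marker_puncta_density(p, marker_spec("GS"), 100)
  expect_equal(tab$n[tab$size_class == "small"], 10L)
  expect_equal(tab$n[tab$size_class == "medium"], 0L)
  expect_equal(tab$n[tab$size_class == "large"], 0L)
  expect_equal(tab$density[tab$size_class == "all"], 0.1)
})

test_that("layer assignment and span distributions are conserved", {
  p <- array(0, c(30, 20, 4))
  p[2:3, 4:5, 2] <- 1; p[12, 8, 3] <- 0.95; p[25:26, 15:16, 1] <- 0.92
  det <- threshold_and_label(p, 0.9)
  lp <- layer_partition(c(10, 20), c("L1", "L2/3", "L4"), 30)
  det <- assign_layers(det, lp)
  expect_identical(sort(det$layer), c("L1", "L2/3", "L4"))
  expect_identical(sum(table(det$layer)), nrow(det))

  # postsynaptic span distribution concentrates where the generator puts it
  cfg <- simulation_config(
    geometry = at_geometry(70, 70, 12),
    densities = c("VGluT1" = 0.3),
    span_meanlog = log(2), span_sdlog = 0.01,  # all spans exactly 2
    nuclei = list(fraction = 0, n = 0, axes_um = c(1, 1, 1)),
    vglut2_speckle_per_um3 = 0, gs_background_per_um3 = 0,
    channels = c("synapsin", "PSD95"))
  sim <- generate_volume(cfg, seed = 10)
  pc <- lapply(sim$channels, foreground_probability)
  q <- synapse_query("Glutamatergic", "synapsin", "PSD95")
  dist <- postsynaptic_span_distribution(pc, q, span_values = 1:4)
  expect_gt(dist$n[dist$span == "2"], 0)
  expect_equal(sum(dist$n[dist$span %in% c("1", "3", ">=4")]), 0)
})

test_that("tripartite detections never exceed their bipartite counterparts", {
  cfg <- simulation_config(geometry = at_geometry(80, 80, 14),
                           densities = c("VGluT1" = 0.4, "GABAergic" = 0.15),
                           channels = c("synapsin", "PSD95", "GAD",
                                        "gephyrin", "GS"))
  sim <- generate_volume(cfg, seed = 12)
  pc <- lapply(sim$channels, foreground_probability)
  qs <- default_queries()
  for (base in c("Glutamatergic", "GABAergic")) {
    nb <- nrow(detect_synapses(pc, qs[[base]]))
    nt <- nrow(detect_synapses(pc, qs[[paste(base, "adjacent to astrocyte")]]))
    expect_lte(nt, nb)
  }
})

test_that("ground-truth matching is greedy, one-to-one and symmetric in rates", {
  det <- data.frame(x_um = c(0, 1, 5), y_um = 0, z_um = 0)
  truth <- data.frame(x_um = c(0.1, 1.05), y_um = 0, z_um = 0)
  m <- match_ground_truth(det, truth, radius_um = 0.3)
  expect_identical(nrow(m$matches), 2L)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 2 / 3)
  # each truth/detection used at most once even when both are in range
  det2 <- data.frame(x_um = c(0, 0.05), y_um = 0, z_um = 0)
  truth2 <- data.frame(x_um = 0.02, y_um = 0, z_um = 0)
  m2 <- match_ground_truth(det2, truth2, radius_um = 0.3)
  expect_identical(nrow(m2$matches), 1L)
})

test_that("per-marker slice spans at detections reflect the rendered spans", {
  ch <- toy_synapse_channels(dims = c(40, 40, 8), center = c(20, 20, 4),
                             span = 3)
  q <- synapse_query("Glutamatergic", "synapsin", "PSD95")
  det <- detect_synapses(ch, q)
  expect_gte(nrow(det), 1)
  det <- marker_slice_spans(det, ch, q)
  expect_true(all(det$span_synapsin == 3L))
  expect_true(all(det$span_PSD95 == 3L))
  # empty detections still gain the span columns
  none <- threshold_and_label(array(0, c(40, 40, 8)))
  none <- marker_slice_spans(none, ch, q)
  expect_true(all(c("span_synapsin", "span_PSD95") %in% names(none)))
})
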