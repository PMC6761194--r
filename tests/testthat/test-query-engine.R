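test_that("punctum probability matches direct evaluation of its definition", {
  set.seed(31)
  for (i in 1:4) {
    p <- array(runif(7 * 6 * 5)^0.5, c(7, 6, 5))
    for (s in 1:3) {
      got <- punctum_probability(p, marker_spec("m"), required_span = s)$data
      expect_equal(got, naive_punctum(p, 2, s), tolerance = 1e-12)
    }
    got3 <- punctum_probability(p, marker_spec("m", min_xy_px = 3),
                                required_span = 2)$data
    expect_equal(got3, naive_punctum(p, 3, 2), tolerance = 1e-12)
  }
})

test_that("punctum probability behaves on canonical hand cases", {
  # isolated 2x2 block on one slice
  p <- array(0, c(9, 9, 1)); p[4:5, 4:5, 1] <- 1
  out <- punctum_probability(p, marker_spec("m"), required_span = 1)$data
  expect_equal(out[4, 4, 1], 1)
  expect_true(all(out[-4, , 1] < 1) && all(out[, -4, 1] < 1))
  # block spanning slices 4 and 5 of 8
  p2 <- array(0, c(9, 9, 8)); p2[4:5, 4:5, 4:5] <- 1
  s2 <- punctum_probability(p2, marker_spec("m"), required_span = 2)$data
  expect_equal(s2[4, 4, 4], 1); expect_equal(s2[4, 4, 5], 1)
  expect_equal(max(s2[, , c(1:3, 6:8)]), 0)
  s3 <- punctum_probability(p2, marker_spec("m"), required_span = 3)$data
  expect_lt(max(s3), 1)
  # interior closure under certainty
  ones <- array(1, c(6, 6, 4))
  o <- punctum_probability(ones, marker_spec("m"), required_span = 2)$data
  expect_true(all(o[1:5, 1:5, ] == 1))
  # impossible span: warning and empty map
  expect_warning(z <- punctum_probability(p, marker_spec("m"), required_span = 5),
                 "exceeds")
  expect_equal(max(z$data), 0)
})

test_that("colocalization combines dilated maps multiplicatively", {
  a <- array(0, c(11, 11, 1)); a[6, 6, 1] <- 1
  b <- array(0, c(11, 11, 1)); b[6, 7, 1] <- 1   # 1 px offset
  expect_equal(max(combine_colocalized(list(a, b), r_coloc = 1)), 1)
  b5 <- array(0, c(11, 11, 1)); b5[6, 11, 1] <- 1  # 5 px offset
  expect_equal(max(combine_colocalized(list(a, b5), r_coloc = 1)), 0)
  ones <- array(1, c(5, 5, 2))
  expect_equal(combine_colocalized(list(ones, ones), 1), ones)
  expect_error(combine_colocalized(list()), "empty")
})

test_that("adjacency combines subclasses over the search neighborhood", {
  pre <- array(0, c(11, 11, 3)); pre[6, 4, 2] <- 1
  post0 <- pre  # same voxel
  expect_equal(combine_adjacent(pre, post0)[6, 4, 2], 1)
  post2 <- array(0, c(11, 11, 3)); post2[6, 6, 2] <- 1  # 2 px away
  expect_equal(combine_adjacent(pre, post2)[6, 4, 2], 1)
  post5 <- array(0, c(11, 11, 3)); post5[6, 9, 2] <- 1  # 5 px away
  expect_equal(combine_adjacent(pre, post5)[6, 4, 2], 0)
  # an identically-zero astrocyte channel annihilates a tripartite query
  expect_equal(max(combine_adjacent(pre, post2, array(0, c(11, 11, 3)))), 0)
})

test_that("query evaluation detects an ideal synapse and respects tripartite requirements", {
  ch <- toy_synapse_channels()
  ch$GS <- foreground_probability(array(0, c(40, 40, 8)))
  q <- synapse_query("Glutamatergic", "synapsin", "PSD95")
  m <- evaluate_query(ch, q)$data
  expect_gte(max(m[15:25, 15:25, ]), 0.9)
  expect_lt(max(m[1:10, , ]), 0.1)     # far from the synapse
  # the same site fails a tripartite query when no GS punctum exists
  qt <- synapse_query("tri", "synapsin", "PSD95", astrocyte = "GS")
  expect_lt(max(evaluate_query(ch, qt)$data), 0.9)
  # missing channel is reported by name
  expect_error(evaluate_query(ch["synapsin"], q), "PSD95")
  # all-zero channels give an all-zero map
  z <- list(synapsin = array(0, c(8, 8, 3)), PSD95 = array(0, c(8, 8, 3)))
  expect_equal(max(evaluate_query(z, q)$data), 0)
})

test_that("query algebra is anti-monotone and order invariant", {
  set.seed(33)
  for (i in 1:8) {
    dims <- c(20, 20, 6)
    ch <- list(synapsin = rand_prob(dims, 100 + i),
               VGluT1 = rand_prob(dims, 200 + i),
               PSD95 = rand_prob(dims, 300 + i),
               GS = rand_prob(dims, 400 + i))
    q1 <- synapse_query("q1", "synapsin", "PSD95")
    q2 <- synapse_query("q2", c("synapsin", "VGluT1"), "PSD95")
    q3 <- synapse_query("q3", "synapsin", "PSD95", astrocyte = "GS")
    m1 <- evaluate_query(ch, q1)$data
    # adding a presynaptic or astrocytic marker never raises any voxel
    expect_true(all(evaluate_query(ch, q2)$data <= m1 + 1e-12))
    expect_true(all(evaluate_query(ch, q3)$data <= m1 + 1e-12))
    # raising the span requirement never raises any voxel
    expect_true(all(evaluate_query(ch, q1, required_span = 2)$data <= m1 + 1e-12))
    # marker order within a subclass is irrelevant
    q2r <- synapse_query("q2r", c("VGluT1", "synapsin"), "PSD95")
    expect_equal(evaluate_query(ch, q2r)$data, evaluate_query(ch, q2)$data)
    expect_true(all(m1 >= 0 & m1 <= 1))
  }
})
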