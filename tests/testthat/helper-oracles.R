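# Independent oracles and small fixture builders used across the suite.

# Brute-force 26-connected 3-D labeling by transitive closure over all voxel
# pairs (Chebyshev distance 1). Only for tiny arrays.
brute_label_sets <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  ai <- arrayInd(idx, dim(mask))
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && all(abs(ai[i, ] - ai[j, ]) <= 1)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(lapply(split(idx, roots), sort))
}

# Textbook pooled-variance two-sample t statistic and two-tailed p.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# Pearson correlation from raw sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Random probability field with high-probability patches (runif alone almost
# never crosses the detection threshold after windowing).
rand_prob <- function(dims, seed, sharp = 0.25) {
  set.seed(seed)
  array(runif(prod(dims))^sharp, dims)
}

# Noise-free two-marker scene: one synapsin/PSD95 synapse as flat blocks.
# Returns foreground probability volumes (degenerate background: sd 0).
toy_synapse_channels <- function(dims = c(40, 40, 8), center = c(20, 20, 4),
                                 span = 2, offset_px = 2) {
  syn <- array(0, dims); psd <- array(0, dims)
  r <- center[1]; c <- center[2]; z <- center[3]
  zz <- z:(z + span - 1)
  syn[r:(r + 2), c:(c + 2), zz] <- 1000
  psd[r:(r + 2), (c + offset_px):(c + offset_px + 2), zz] <- 1000
  list(synapsin = foreground_probability(syn),
       PSD95 = foreground_probability(psd))
}

# Direct (loop-based) evaluation of the punctum-probability definition:
# lateral product over the w x w window anchored at the voxel (zero outside
# the image), then the max over all fully-contained s-slice windows
# containing z of the product of the windowed slice values.
naive_punctum <- function(p, w, s) {
  d <- dim(p)
  lat <- array(0, d)
  for (z in seq_len(d[3])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    v <- 1
    for (dr in 0:(w - 1)) for (dc in 0:(w - 1)) {
      rr <- r + dr; cc <- c + dc
      v <- v * if (rr <= d[1] && cc <= d[2]) p[rr, cc, z] else 0
    }
    lat[r, c, z] <- v
  }
  out <- array(0, d)
  for (z in seq_len(d[3])) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    best <- 0
    for (z0 in max(1, z - s + 1):z) {
      if (z0 + s - 1 > d[3]) next
      best <- max(best, prod(lat[r, c, z0:(z0 + s - 1)]))
    }
    out[r, c, z] <- best
  }
  out
}
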