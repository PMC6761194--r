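# Internal vectorized 3-D array filters. All operate on plain numeric arrays
# [row, col, slice]; out-of-volume pixels pad with `fill` so border windows are
# clipped (partial windows see zeros / -Inf, never wrap).

shift3 <- function(a, dr = 0L, dc = 0L, dz = 0L, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sr <- max(1L, 1L + dr):min(d[1], d[1] + dr)
  sc <- max(1L, 1L + dc):min(d[2], d[2] + dc)
  sz <- max(1L, 1L + dz):min(d[3], d[3] + dz)
  if (dr > d[1] || -dr > d[1] || dc > d[2] || -dc > d[2] ||
      dz > d[3] || -dz > d[3]) return(out)
  out[sr, sc, sz] <- a[sr - dr, sc - dc, sz - dz]
  out
}

# Lateral footprint evidence over a w x w window anchored so the voxel is the
# window's top-left corner (the window covers the candidate punctum extent):
# the product of the per-pixel foreground probabilities, i.e. every pixel of
# the minimum footprint must be foreground. Border windows are zero-padded,
# so clipped windows score 0. A box mean is too permissive here: background
# probabilities are uniform on [0,1], and the mean of a few uniforms has a
# heavy upper tail that sprays satellite detections around real puncta.
box_prod_xy <- function(a, w) {
  if (w == 1L) return(a)
  acc <- a
  for (dr in 0:(w - 1L)) for (dc in 0:(w - 1L)) {
    if (dr == 0L && dc == 0L) next
    acc <- acc * shift3(a, -dr, -dc, 0L, fill = 0)
  }
  acc
}

# Separable max filter over [-rr, rr] x [-rc, rc] x [-rz, rz].
max_filter <- function(a, rr, rc = rr, rz = 0L) {
  out <- a
  if (rr > 0L) {
    m <- out
    for (k in seq_len(rr)) m <- pmax(m, shift3(out, k, 0L, 0L, -Inf),
                                     shift3(out, -k, 0L, 0L, -Inf))
    out <- m
  }
  if (rc > 0L) {
    m <- out
    for (k in seq_len(rc)) m <- pmax(m, shift3(out, 0L, k, 0L, -Inf),
                                     shift3(out, 0L, -k, 0L, -Inf))
    out <- m
  }
  if (rz > 0L) {
    m <- out
    for (k in seq_len(rz)) m <- pmax(m, shift3(out, 0L, 0L, k, -Inf),
                                     shift3(out, 0L, 0L, -k, -Inf))
    out <- m
  }
  out[!is.finite(out)] <- 0
  out
}

# Lateral Gaussian blur (separable, truncated at 3 sigma), applied slice-wise.
# No axial blur: serial sections are imaged independently, so there is no
# optical crosstalk between slices.
gaussian_blur_xy <- function(a, sigma_px) {
  if (sigma_px <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  out <- array(0, dim(a))
  for (i in seq_along(k)) out <- out + k[i] * shift3(a, i - r - 1L, 0L, 0L)
  a2 <- out
  out <- array(0, dim(a))
  for (i in seq_along(k)) out <- out + k[i] * shift3(a2, 0L, i - r - 1L, 0L)
  out
}
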