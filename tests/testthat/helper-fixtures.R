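# Shared small fixtures. Tests run on reduced grids; the acceptance suite
# uses the standard 96 x 96 x 40 phantom.

small_spec <- function(seed = 3, ...) {
  phantom_spec(shape = c(48, 48, 24), spacing = c(2, 2, 3),
               head_radii = c(40, 40, 45), head_center = c(0, 0, -8),
               tumor_center = c(8, 5, -5), tumor_radius_mm = 9,
               couch_y = c(42, 47), seed = seed, ...)
}

# ramp volume: value = a + 2 * x_mm along x
ramp_volume <- function(d = c(8, 6, 5), spacing = c(1.5, 1, 2), a = 0) {
  x <- (seq_len(d[1]) - 1) * spacing[1]
  volume_image(array(rep(a + 2 * x, times = d[2] * d[3]), d), spacing)
}

random_volume <- function(d = c(9, 8, 7), spacing = c(2, 2, 3), seed = 42,
                          lo = -200, hi = 200) {
  set.seed(seed)
  volume_image(array(runif(prod(d), lo, hi), d), spacing)
}

# Independent loop-based trilinear interpolation at 0-based voxel coords.
oracle_trilinear <- function(values, q, fill = -1000) {
  d <- dim(values)
  out <- numeric(nrow(q))
  for (p in seq_len(nrow(q))) {
    x <- q[p, 1]; y <- q[p, 2]; z <- q[p, 3]
    if (x < 0 || y < 0 || z < 0 || x > d[1] - 1 || y > d[2] - 1 || z > d[3] - 1) {
      out[p] <- fill
      next
    }
    i0 <- min(floor(x), d[1] - 2); j0 <- min(floor(y), d[2] - 2)
    k0 <- min(floor(z), d[3] - 2)
    fx <- x - i0; fy <- y - j0; fz <- z - k0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      wgt <- (if (di == 1) fx else 1 - fx) *
        (if (dj == 1) fy else 1 - fy) *
        (if (dk == 1) fz else 1 - fz)
      acc <- acc + wgt * values[i0 + di + 1, j0 + dj + 1, k0 + dk + 1]
    }
    out[p] <- acc
  }
  out
}

# Independent loop-based nearest-neighbor lookup at 0-based voxel coords
# (ties round away from zero, matching the implementation's convention).
oracle_nearest <- function(values, q, fill = -1000) {
  d <- dim(values)
  out <- numeric(nrow(q))
  for (p in seq_len(nrow(q))) {
    ijk <- floor(q[p, ] + 0.5) + 1
    out[p] <- if (any(ijk < 1) || any(ijk > d)) fill
    else values[ijk[1], ijk[2], ijk[3]]
  }
  out
}

# Independent central/one-sided finite differences (HU/mm).
oracle_gradient <- function(values, spacing) {
  d <- dim(values)
  g <- array(0, c(d, 3))
  idx <- function(i, n) max(1, min(n, i))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (d[1] > 1) {
      ip <- idx(i + 1, d[1]); im <- idx(i - 1, d[1])
      g[i, j, k, 1] <- (values[ip, j, k] - values[im, j, k]) / ((ip - im) * spacing[1])
    }
    if (d[2] > 1) {
      jp <- idx(j + 1, d[2]); jm <- idx(j - 1, d[2])
      g[i, j, k, 2] <- (values[i, jp, k] - values[i, jm, k]) / ((jp - jm) * spacing[2])
    }
    if (d[3] > 1) {
      kp <- idx(k + 1, d[3]); km <- idx(k - 1, d[3])
      g[i, j, k, 3] <- (values[i, j, kp] - values[i, j, km]) / ((kp - km) * spacing[3])
    }
  }
  g
}
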