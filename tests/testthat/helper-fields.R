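# Shared fixture builders and naive reference implementations used as
# independent oracles. Everything is generated in code; no stored data.

# A flow_dataset holding an arbitrary velocity array (t, z, y, x, 3) with unit
# magnitude.
make_ds <- function(vel, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    cycle_duration = 1) {
  flow_dataset(vel, array(1, dim(vel)[1:4]), spacing, origin,
               cycle_duration = cycle_duration)
}

full_mask <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  mask3d(array(1L, shape), c(LA = 1L), spacing, origin)
}

# Digitized ball: voxels with center within radius R of the grid center.
ball_mask <- function(n, R, spacing = 1) {
  sp <- rep(spacing, 3)
  origin <- -(c(n, n, n) - 1) / 2 * sp
  co <- laflow:::grid_coords(c(n, n, n), sp, origin)
  lab <- array(0L, c(n, n, n))
  lab[co$x^2 + co$y^2 + co$z^2 <= R^2] <- 1L
  mask3d(lab, c(LA = 1L), sp, origin)
}

# Naive per-voxel PC-MRA (direct transcription of the formula).
naive_pcmra <- function(vel, mag, gamma, scale) {
  d <- dim(vel)
  out <- array(0, d[2:4])
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (y in seq_len(d[3]))
    for (x in seq_len(d[4])) {
      s2 <- sum((scale * vel[t, z, y, x, ])^2)
      out[z, y, x] <- out[z, y, x] + mag[t, z, y, x] * s2^gamma
    }
  out / d[1]
}

# Naive loop-based mask-aware velocity gradient (same stencil contract as
# velocity_gradient: central/one-sided/zero).
naive_gradient <- function(vel_t, inmask, spacing_mm) {
  d <- dim(inmask)
  h <- spacing_mm * 1e-3
  G <- array(0, c(d, 3, 3))
  ax_of <- c(3L, 2L, 1L)  # world axis x,y,z -> array dim
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    if (!inmask[z, y, x]) next
    idx <- c(z, y, x)
    for (i in 1:3) for (j in 1:3) {
      dm <- ax_of[j]
      ip <- idx; ip[dm] <- ip[dm] + 1L
      im <- idx; im[dm] <- im[dm] - 1L
      has_p <- ip[dm] <= d[dm] && inmask[ip[1], ip[2], ip[3]]
      has_m <- im[dm] >= 1L && inmask[im[1], im[2], im[3]]
      v0 <- vel_t[z, y, x, i]
      if (has_p && has_m) {
        G[z, y, x, i, j] <- (vel_t[ip[1], ip[2], ip[3], i] -
                               vel_t[im[1], im[2], im[3], i]) / (2 * h[j])
      } else if (has_p) {
        G[z, y, x, i, j] <- (vel_t[ip[1], ip[2], ip[3], i] - v0) / h[j]
      } else if (has_m) {
        G[z, y, x, i, j] <- (v0 - vel_t[im[1], im[2], im[3], i]) / h[j]
      }
    }
  }
  G
}

# Brute-force 27-neighborhood median with edge replication.
naive_median3 <- function(f) {
  d <- dim(f)
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zs <- pmin(pmax(z + (-1:1), 1), d[1])
    ys <- pmin(pmax(y + (-1:1), 1), d[2])
    xs <- pmin(pmax(x + (-1:1), 1), d[3])
    out[z, y, x] <- median(f[zs, ys, xs])
  }
  out
}

# Brute-force pooled symmetric surface-distance 95th percentile.
naive_hd95 <- function(maskA, maskB, label = "LA") {
  surf <- function(m) {
    inm <- m$labels == m$label_map[[label]]
    d <- dim(inm)
    pts <- NULL
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      if (!inm[z, y, x]) next
      nb6 <- 0L
      for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        p <- c(z, y, x) + s
        if (all(p >= 1) && all(p <= d) && inm[p[1], p[2], p[3]]) nb6 <- nb6 + 1L
      }
      if (nb6 < 6L)
        pts <- rbind(pts, m$origin + (c(x, y, z) - 1) * m$spacing)
    }
    pts
  }
  SA <- surf(maskA); SB <- surf(maskB)
  dAB <- apply(SA, 1, function(p) min(sqrt(colSums((t(SB) - p)^2))))
  dBA <- apply(SB, 1, function(p) min(sqrt(colSums((t(SA) - p)^2))))
  unname(quantile(c(dAB, dBA), 0.95, type = 7))
}

# Random masked velocity field on a small grid, reproducible.
random_masked_field <- function(n = 10, n_phases = 2, seed = 7) {
  set.seed(seed)
  vel <- array(rnorm(n_phases * n^3 * 3, 0, 0.3), c(n_phases, n, n, n, 3))
  lab <- array(0L, c(n, n, n))
  lab[array(runif(n^3), c(n, n, n)) > 0.35] <- 1L
  mask <- mask3d(lab, c(LA = 1L), c(1.4, 1.2, 1.6))
  ds <- make_ds(vel, spacing = mask$spacing)
  list(ds = apply_mask(ds, mask), mask = mask)
}
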