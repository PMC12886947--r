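# Internal array helpers shared by the gradient, filter and interpolation code.

# Shift a 3-D array by one voxel along dimension `dim` (1 = z, 2 = y, 3 = x).
# `by` is +1 or -1; vacated entries are filled with `fill`.
shift3 <- function(a, dim, by, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[dim]
  if (by == 1L) {        # out[i] <- a[i+1]
    idx_dst[[dim]] <- seq_len(n - 1L)
    idx_src[[dim]] <- 2:n
  } else {               # out[i] <- a[i-1]
    idx_dst[[dim]] <- 2:n
    idx_src[[dim]] <- seq_len(n - 1L)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Trilinear interpolation of a 3-D array defined at voxel centers.
# `pts` is an n x 3 matrix of world coordinates (x, y, z) in mm; values outside
# the grid are clamped to the boundary sample (`rule = "clamp"`) or set to
# `outside` (default 0).
interp_trilinear <- function(a, spacing, origin, pts, outside = 0) {
  d <- dim(a)                     # (z, y, x)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  # continuous voxel indices, 0-based: world = origin + index * spacing
  ix <- (pts[, 1] - origin[1]) / spacing[1]
  iy <- (pts[, 2] - origin[2]) / spacing[2]
  iz <- (pts[, 3] - origin[3]) / spacing[3]
  inside <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1 & iz >= 0 & iz <= nz - 1
  x0 <- pmin(pmax(floor(ix), 0), nx - 2); x1 <- x0 + 1
  y0 <- pmin(pmax(floor(iy), 0), ny - 2); y1 <- y0 + 1
  z0 <- pmin(pmax(floor(iz), 0), nz - 2); z1 <- z0 + 1
  fx <- pmin(pmax(ix - x0, 0), 1)
  fy <- pmin(pmax(iy - y0, 0), 1)
  fz <- pmin(pmax(iz - z0, 0), 1)
  at <- function(z, y, x) a[cbind(z + 1, y + 1, x + 1)]
  v <- (1 - fz) * ((1 - fy) * ((1 - fx) * at(z0, y0, x0) + fx * at(z0, y0, x1)) +
                   fy       * ((1 - fx) * at(z0, y1, x0) + fx * at(z0, y1, x1))) +
       fz       * ((1 - fy) * ((1 - fx) * at(z1, y0, x0) + fx * at(z1, y0, x1)) +
                   fy       * ((1 - fx) * at(z1, y1, x0) + fx * at(z1, y1, x1)))
  v[!inside] <- outside
  v
}

# Voxel-center world coordinates for a (z, y, x) grid, returned as arrays of
# the grid shape. world = origin + index * spacing with 0-based indices.
grid_coords <- function(dim_zyx, spacing, origin) {
  nz <- dim_zyx[1]; ny <- dim_zyx[2]; nx <- dim_zyx[3]
  xs <- origin[1] + (seq_len(nx) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(ny) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(nz) - 1) * spacing[3]
  list(
    x = array(rep(xs, each = nz * ny), dim_zyx),
    y = array(rep(rep(ys, each = nz), nx), dim_zyx),
    z = array(rep(zs, ny * nx), dim_zyx)
  )
}

# Quiet stopifnot-style check with a formatted message.
check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
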