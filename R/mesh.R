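# Surface and volume meshing of voxel label masks.
#
# The surface is the 0.5 iso-level of the label indicator, extracted by
# marching tetrahedra on a Kuhn (6-tet) decomposition of the dual cube
# lattice. Extracting straight from the binary indicator puts every crossing
# at an edge midpoint, which stair-cases the surface and overestimates the
# area of smooth shapes by >20%; a light Gaussian pre-filter of the indicator
# (default sigma 1 voxel) plus a few Taubin passes restores the area and
# enclosed volume of resolved blobs to within ~1-2%. Regions too small to
# survive the filter (e.g. a single voxel) automatically fall back to the
# unfiltered indicator.

# Kuhn decomposition of the unit cube into 6 tetrahedra sharing diagonal 0-7.
# Corner numbering: c = x + 2y + 4z (bits of the corner offset).
.kuhn_tets <- rbind(
  c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L)) + 1L

.corner_offsets <- cbind(x = bitwAnd(0:7, 1L),
                         y = bitwShiftR(bitwAnd(0:7, 2L), 1L),
                         z = bitwShiftR(bitwAnd(0:7, 4L), 2L))

# Separable Gaussian filter of a 3-D array, zero-padded boundaries.
gaussian3 <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    for (s in -r:r) {
      shifted <- if (s == 0) a else shiftn(a, ax, s)
      out <- out + w[s + r + 1] * shifted
    }
    a <- out
  }
  a
}

# Shift a 3-D array by `by` voxels along `dim`, zero fill.
shiftn <- function(a, dim, by) {
  d <- dim(a)
  out <- array(0, d)
  n <- d[dim]
  if (abs(by) >= n) return(out)
  src <- lapply(d, seq_len); dst <- src
  if (by > 0) { dst[[dim]] <- seq_len(n - by); src[[dim]] <- (by + 1):n }
  else { dst[[dim]] <- (1 - by):n; src[[dim]] <- seq_len(n + by) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Extract a triangular surface mesh from a labeled mask
#'
#' Extracts the 0.5 iso-surface of the (optionally Gaussian pre-filtered)
#' binary label indicator by marching tetrahedra with linear edge
#' interpolation, welds shared vertices, and applies Taubin smoothing. The
#' result is a closed, consistently outward-oriented triangle mesh with
#' vertices in world mm.
#'
#' @param mask a `mask3d`.
#' @param label structure name, default `"LA"`.
#' @param presmooth_sigma Gaussian pre-filter width in voxels applied to the
#'   indicator before extraction (default 0.6; 0 disables). If the filtered
#'   field no longer crosses the 0.5 level (tiny regions) the raw indicator is
#'   used instead.
#' @param smooth_iterations Taubin smoothing passes on the extracted mesh
#'   (default 10; 0 disables).
#' @param lambda,mu Taubin shrink/inflate factors.
#' @return a `surface_mesh`: list with `vertices` (n x 3 mm) and `faces`
#'   (m x 3, 1-based, outward-oriented).
#' @export
mask_to_surface_mesh <- function(mask, label = "LA", presmooth_sigma = 0.6,
                                 smooth_iterations = 10L,
                                 lambda = 0.5, mu = -0.53) {
  inmask <- label_array(mask, label)
  check(any(inmask), "label '%s' region is empty", label)
  d <- dim(inmask)
  f <- array(0, d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- inmask * 1
  if (presmooth_sigma > 0) {
    fs <- gaussian3(f, presmooth_sigma)
    if (max(fs) > 0.5) f <- fs   # otherwise region too small: keep binary
  }
  mesh <- marching_tets(f, level = 0.5, spacing = mask$spacing,
                        origin = mask$origin - 2 * mask$spacing)
  if (smooth_iterations > 0)
    mesh <- taubin_smooth(mesh, iterations = smooth_iterations,
                          lambda = lambda, mu = mu)
  mesh
}

# Marching tetrahedra on a scalar field sampled at lattice points.
# `origin` is the world position of lattice point (0,0,0) for the (z,y,x)
# array `f`; crossings are linearly interpolated on lattice edges and welded
# by edge identity.
marching_tets <- function(f, level, spacing, origin) {
  pd <- dim(f)
  ncz <- pd[1] - 1L; ncy <- pd[2] - 1L; ncx <- pd[3] - 1L
  cz <- rep(seq_len(ncz), times = ncy * ncx)
  cy <- rep(rep(seq_len(ncy), each = ncz), times = ncx)
  cx <- rep(seq_len(ncx), each = ncz * ncy)
  vals <- matrix(0, length(cz), 8L)
  lin <- matrix(0L, length(cz), 8L)   # lattice-point linear ids, for welding
  for (c in 1:8) {
    off <- .corner_offsets[c, ]
    zz <- cz + off["z"]; yy <- cy + off["y"]; xx <- cx + off["x"]
    vals[, c] <- f[cbind(zz, yy, xx)]
    lin[, c] <- zz + (yy - 1L) * pd[1] + (xx - 1L) * pd[1] * pd[2]
  }
  ins <- vals >= level
  s <- rowSums(ins)
  mixed <- which(s > 0 & s < 8)
  check(length(mixed) > 0, "no iso-surface found")
  vals <- vals[mixed, , drop = FALSE]
  ins <- ins[mixed, , drop = FALSE]
  lin <- lin[mixed, , drop = FALSE]
  cz <- cz[mixed]; cy <- cy[mixed]; cx <- cx[mixed]
  pos <- lapply(1:8, function(c) {
    off <- .corner_offsets[c, ]
    cbind(origin[1] + (cx + off["x"] - 1) * spacing[1],
          origin[2] + (cy + off["y"] - 1) * spacing[2],
          origin[3] + (cz + off["z"] - 1) * spacing[3])
  })

  # accumulators: triangle vertices plus weld keys (sorted lattice-edge ids)
  va <- list(); vb <- list(); vc <- list()
  ka <- list(); kb <- list(); kc <- list()
  k <- 0L
  gather <- function(P, which_corner, rows) {
    out <- matrix(0, length(rows), 3)
    for (ci in 1:4) {
      sel <- which_corner == ci
      if (any(sel)) out[sel, ] <- P[[ci]][rows[sel], , drop = FALSE]
    }
    out
  }
  gather_v <- function(V, which_corner, rows) {
    out <- numeric(length(rows))
    for (ci in 1:4) {
      sel <- which_corner == ci
      if (any(sel)) out[sel] <- V[cbind(rows[sel], ci)]
    }
    out
  }
  edge_pt <- function(p1, f1, p2, f2) {
    a <- (level - f1) / (f2 - f1)
    p1 + a * (p2 - p1)
  }
  edge_key <- function(l1, l2) paste(pmin(l1, l2), pmax(l1, l2))

  for (t in seq_len(nrow(.kuhn_tets))) {
    tc <- .kuhn_tets[t, ]
    ti <- ins[, tc, drop = FALSE]
    tvals <- vals[, tc, drop = FALSE]
    tlin <- lin[, tc, drop = FALSE]
    ts <- rowSums(ti)
    P <- lapply(1:4, function(i) pos[[tc[i]]])

    for (case_in in c(1L, 3L)) {
      rows <- which(ts == case_in)
      if (!length(rows)) next
      lone_inside <- case_in == 1L
      lm <- if (lone_inside) ti[rows, , drop = FALSE] else !ti[rows, , drop = FALSE]
      lone <- max.col(lm, ties.method = "first")
      oth <- matrix(0L, length(rows), 3)
      for (r in seq_along(rows)) oth[r, ] <- setdiff(1:4, lone[r])
      pl <- gather(P, lone, rows); fl <- gather_v(tvals, lone, rows)
      ll <- gather_v(tlin, lone, rows)
      pts <- keys <- vector("list", 3)
      for (j in 1:3) {
        pj <- gather(P, oth[, j], rows); fj <- gather_v(tvals, oth[, j], rows)
        lj <- gather_v(tlin, oth[, j], rows)
        pts[[j]] <- edge_pt(pl, fl, pj, fj)
        keys[[j]] <- edge_key(ll, lj)
      }
      po <- (gather(P, oth[, 1], rows) + gather(P, oth[, 2], rows) +
             gather(P, oth[, 3], rows)) / 3
      outward <- if (lone_inside) po - pl else pl - po
      nrm <- cross3(pts[[2]] - pts[[1]], pts[[3]] - pts[[1]])
      flip <- rowSums(nrm * outward) < 0
      b <- pts[[2]]; cc <- pts[[3]]; bk <- keys[[2]]; ck <- keys[[3]]
      b[flip, ] <- pts[[3]][flip, ]; cc[flip, ] <- pts[[2]][flip, ]
      bk[flip] <- keys[[3]][flip]; ck[flip] <- keys[[2]][flip]
      k <- k + 1L
      va[[k]] <- pts[[1]]; vb[[k]] <- b; vc[[k]] <- cc
      ka[[k]] <- keys[[1]]; kb[[k]] <- bk; kc[[k]] <- ck
    }

    rows <- which(ts == 2L)
    if (length(rows)) {
      im <- ti[rows, , drop = FALSE]
      i1 <- max.col(im, ties.method = "first")
      i2 <- max.col(im, ties.method = "last")
      o1 <- max.col(!im, ties.method = "first")
      o2 <- max.col(!im, ties.method = "last")
      pA <- gather(P, i1, rows); fA <- gather_v(tvals, i1, rows); lA <- gather_v(tlin, i1, rows)
      pB <- gather(P, i2, rows); fB <- gather_v(tvals, i2, rows); lB <- gather_v(tlin, i2, rows)
      pC <- gather(P, o1, rows); fC <- gather_v(tvals, o1, rows); lC <- gather_v(tlin, o1, rows)
      pD <- gather(P, o2, rows); fD <- gather_v(tvals, o2, rows); lD <- gather_v(tlin, o2, rows)
      mac <- edge_pt(pA, fA, pC, fC); kac <- edge_key(lA, lC)
      mad <- edge_pt(pA, fA, pD, fD); kad <- edge_key(lA, lD)
      mbd <- edge_pt(pB, fB, pD, fD); kbd <- edge_key(lB, lD)
      mbc <- edge_pt(pB, fB, pC, fC); kbc <- edge_key(lB, lC)
      outward <- (pC + pD) / 2 - (pA + pB) / 2
      emit <- function(p1, k1, p2, k2, p3, k3) {
        nrm <- cross3(p2 - p1, p3 - p1)
        flip <- rowSums(nrm * outward) < 0
        q <- p2; r <- p3; qk <- k2; rk <- k3
        q[flip, ] <- p3[flip, ]; r[flip, ] <- p2[flip, ]
        qk[flip] <- k3[flip]; rk[flip] <- k2[flip]
        k <<- k + 1L
        va[[k]] <<- p1; vb[[k]] <<- q; vc[[k]] <<- r
        ka[[k]] <<- k1; kb[[k]] <<- qk; kc[[k]] <<- rk
      }
      emit(mac, kac, mad, kad, mbd, kbd)
      emit(mac, kac, mbd, kbd, mbc, kbc)
    }
  }
  allpts <- rbind(do.call(rbind, va), do.call(rbind, vb), do.call(rbind, vc))
  allkey <- c(unlist(ka), unlist(kb), unlist(kc))
  ntri <- nrow(allpts) / 3L
  uk <- !duplicated(allkey)
  vid <- match(allkey, allkey[uk])
  vertices <- allpts[uk, , drop = FALSE]
  faces <- cbind(vid[seq_len(ntri)],
                 vid[ntri + seq_len(ntri)],
                 vid[2L * ntri + seq_len(ntri)])
  # drop degenerate triangles (duplicated vertex ids within a face)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  structure(list(vertices = vertices, faces = faces[ok, , drop = FALSE]),
            class = "surface_mesh")
}

#' Taubin smoothing of a triangle mesh
#'
#' Alternating shrink (`lambda`) and inflate (`mu`) Laplacian passes with
#' uniform neighbor weights; smooths stair-casing without net shrinkage.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations number of lambda/mu pass pairs.
#' @param lambda,mu positive shrink and negative inflate factors (|mu| >
#'   lambda).
#' @return the smoothed `surface_mesh`.
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  n <- nrow(v)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  W <- A / deg
  for (it in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(W %*% v) - v)
    v <- v + mu * (as.matrix(W %*% v) - v)
  }
  mesh$vertices <- v
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, area %.4g mm^2, enclosed volume %.4g mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x), mesh_volume(x)))
  invisible(x)
}

#' Surface area of a triangle mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
              v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  sum(sqrt(rowSums(n^2))) / 2
}

#' Volume enclosed by a closed triangle mesh (mm^3)
#'
#' Divergence theorem over signed tetrahedra to the origin; the orientation-
#' independent absolute value is returned.
#'
#' @param mesh a `surface_mesh`.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  abs(sum(rowSums(p0 * cross3(p1, p2)))) / 6
}

#' Tetrahedralize the voxels of a labeled region
#'
#' Each labeled voxel (a spacing-sized box around its center) is split into 6
#' tetrahedra (Kuhn decomposition); the summed tet volume equals voxel count
#' times voxel volume exactly.
#'
#' @param mask a `mask3d`.
#' @param label structure name, default `"LA"`.
#' @return a `tet_mesh`: list with `nodes` (n x 3 mm) and `tets` (m x 4,
#'   1-based).
#' @export
mask_to_volume_mesh <- function(mask, label = "LA") {
  inmask <- label_array(mask, label)
  check(any(inmask), "label '%s' region is empty", label)
  idx <- which(inmask, arr.ind = TRUE)  # (z, y, x), 1-based
  sp <- mask$spacing
  corner_idx <- matrix(0L, nrow(idx), 8L)
  all_corners <- NULL
  for (c in 1:8) {
    off <- .corner_offsets[c, ]
    all_corners <- rbind(all_corners,
                         cbind(idx[, 3] - 1L + off["x"],
                               idx[, 2] - 1L + off["y"],
                               idx[, 1] - 1L + off["z"]))
  }
  key <- paste(all_corners[, 1], all_corners[, 2], all_corners[, 3])
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  nvox <- nrow(idx)
  for (c in 1:8) corner_idx[, c] <- ids[(c - 1L) * nvox + seq_len(nvox)]
  uc <- all_corners[uk, , drop = FALSE]
  nodes <- cbind(mask$origin[1] + (uc[, 1] - 0.5) * sp[1],
                 mask$origin[2] + (uc[, 2] - 0.5) * sp[2],
                 mask$origin[3] + (uc[, 3] - 0.5) * sp[3])
  tets <- do.call(rbind, lapply(seq_len(nrow(.kuhn_tets)), function(t)
    corner_idx[, .kuhn_tets[t, ], drop = FALSE]))
  structure(list(nodes = nodes, tets = tets), class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tetrahedra, volume %.6g mm^3\n",
              nrow(x$nodes), nrow(x$tets), tet_volume(x)))
  invisible(x)
}

#' Total volume of a tetrahedral mesh (mm^3)
#' @param mesh a `tet_mesh`.
#' @export
tet_volume <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  c <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  sum(abs(rowSums(a * cross3(b, c)))) / 6
}
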