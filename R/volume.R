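# Left-atrial volumetrics, the 2D biplane comparator, method-agreement
# statistics and segmentation-overlap metrics.

#' Volume of a labeled region (ml)
#'
#' Voxel count times voxel volume.
#'
#' @param mask a `mask3d`.
#' @param label structure name.
#' @export
mask_volume <- function(mask, label = "LA") {
  check(label %in% names(mask$label_map), "unknown label '%s'", label)
  n <- sum(mask$labels == mask$label_map[[label]])
  if (n == 0L) warning(sprintf("label '%s' region is empty; volume 0", label))
  n * prod(mask$spacing) * 1e-3   # mm^3 -> ml
}

#' Body surface area (DuBois)
#'
#' BSA = 0.007184 * W^0.425 * H^0.725 with weight in kg and height in cm.
#'
#' @param weight_kg,height_cm positive body metrics.
#' @return BSA in m^2.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  check(all(weight_kg > 0) && all(height_cm > 0), "weight and height must be positive")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Indexed left-atrial volume (LAVi)
#'
#' @param volume_ml LA volume in ml.
#' @param weight_kg,height_cm body metrics for the DuBois BSA.
#' @return LAVi in ml/m^2.
#' @export
lav_indexed <- function(volume_ml, weight_kg, height_cm) {
  volume_ml / bsa_dubois(weight_kg, height_cm)
}

#' Biplane disk-summation volume from 2D cine diameters
#'
#' Stacks `N` elliptical disks with diameters measured at disk centers in the
#' two- and four-chamber views: \eqn{V = (\pi/4) \sum_i a_i b_i (L/N)}.
#'
#' @param diam_2ch,diam_4ch per-disk diameters (mm), same length.
#' @param long_axis_mm long-axis length L (mm).
#' @return volume in ml.
#' @export
biplane_disk_volume <- function(diam_2ch, diam_4ch, long_axis_mm) {
  check(length(diam_2ch) == length(diam_4ch),
        "diameter lists differ in length (%d vs %d)", length(diam_2ch), length(diam_4ch))
  check(length(diam_2ch) >= 1L, "need at least one disk")
  n <- length(diam_2ch)
  (pi / 4) * sum(diam_2ch * diam_4ch) * (long_axis_mm / n) * 1e-3   # mm^3 -> ml
}

#' Agreement between two measurement methods
#'
#' Pearson correlation with Fisher-z 95% CI plus Bland-Altman bias and 95%
#' limits of agreement (bias +- 1.96 sd of the differences, sample SD).
#'
#' @param x,y paired measurements (e.g. biplane and PC-MRA LAVi), length >= 3.
#' @return an `agreement_result`: list with `n`, `pearson_r`, `r_ci` (length
#'   2), `bias`, `loa_low`, `loa_high`, `differences`, and `r_defined`.
#' @export
agreement <- function(x, y) {
  check(length(x) == length(y), "x and y lengths differ")
  check(length(x) >= 3L, "need at least 3 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  r_defined <- sd(x) > 0 && sd(y) > 0
  if (r_defined) {
    ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
    r <- unname(ct$estimate)
    ci <- as.numeric(ct$conf.int)
  } else {
    warning("zero variance in x or y: correlation undefined")
    r <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  structure(list(n = length(x), pearson_r = r, r_ci = ci,
                 bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 differences = d, r_defined = r_defined),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement (n=%d): r = %.3f (95%% CI %.3f-%.3f), bias = %.3g, LoA (%.3g, %.3g)\n",
              x$n, x$pearson_r, x$r_ci[1], x$r_ci[2], x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Dice overlap coefficient between two masks
#'
#' 2|A intersect B| / (|A| + |B|); two empty masks are defined as Dice 1 with
#' a warning.
#'
#' @param maskA,maskB `mask3d` objects on congruent grids.
#' @param label structure name present in both.
#' @export
dice <- function(maskA, maskB, label = "LA") {
  a <- label_array(maskA, label)
  b <- label_array(maskB, label)
  check(all(dim(a) == dim(b)), "mask grids differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    warning("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

# Boundary voxels of a logical mask: in-mask voxels with a 6-neighbor outside
# (or on the array border).
surface_voxels <- function(inmask, spacing, origin) {
  d <- dim(inmask)
  m <- inmask * 1
  nb <- shift3(m, 1, 1) + shift3(m, 1, -1) + shift3(m, 2, 1) + shift3(m, 2, -1) +
    shift3(m, 3, 1) + shift3(m, 3, -1)
  surf <- inmask & nb < 6
  idx <- which(surf, arr.ind = TRUE)   # (z, y, x)
  cbind(origin[1] + (idx[, 3] - 1) * spacing[1],
        origin[2] + (idx[, 2] - 1) * spacing[2],
        origin[3] + (idx[, 1] - 1) * spacing[3])
}

# Directed nearest-surface distances from points in A to the point set B,
# chunked to bound memory.
directed_dists <- function(A, B, chunk = 2000L) {
  out <- numeric(nrow(A))
  b2 <- rowSums(B^2)
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), b2, "+") - 2 * Ab %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' 95th-percentile Hausdorff distance between two masks (mm)
#'
#' Pooled symmetric surface-to-surface distances between the boundary-voxel
#' centers of the two labeled regions; the 95th percentile is taken by linear
#' interpolation over the pooled distances.
#'
#' @param maskA,maskB `mask3d` objects on congruent grids.
#' @param label structure name present in both.
#' @export
hd95 <- function(maskA, maskB, label = "LA") {
  a <- label_array(maskA, label)
  b <- label_array(maskB, label)
  check(all(dim(a) == dim(b)), "mask grids differ")
  check(any(a) && any(b), "hd95 undefined for an empty mask")
  SA <- surface_voxels(a, maskA$spacing, maskA$origin)
  SB <- surface_voxels(b, maskB$spacing, maskB$origin)
  pooled <- c(directed_dists(SA, SB), directed_dists(SB, SA))
  unname(quantile(pooled, 0.95, type = 7))
}
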