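# Sphere-seeded vessel cross-sections, flow-rate curves and clinical wave
# features (pulmonary-vein S/D/Ar, mitral E/A) extracted from them.

#' Dominant flow direction through a sample sphere
#'
#' For each cardiac phase the velocity is averaged over voxels whose centers
#' lie inside the sphere; phases are ranked by the magnitude of that mean, and
#' the unit normal is the normalized sum of the top `min(5, N)` phase-mean
#' vectors.
#'
#' @param ds a masked `flow_dataset`.
#' @param seed a `sphere_seed`.
#' @param top number of highest-velocity phases averaged (default 5).
#' @return unit 3-vector in world axes.
#' @export
plane_normal_from_flow <- function(ds, seed, top = 5L) {
  d <- dim(ds$velocity)[2:4]
  co <- grid_coords(d, ds$spacing, ds$origin)
  insph <- (co$x - seed$center[1])^2 + (co$y - seed$center[2])^2 +
    (co$z - seed$center[3])^2 <= seed$radius^2
  check(any(insph), "sphere '%s' does not intersect the grid", seed$name)
  means <- t(vapply(seq_len(ds$n_phases), function(t)
    c(mean(ds$velocity[t, , , , 1][insph]),
      mean(ds$velocity[t, , , , 2][insph]),
      mean(ds$velocity[t, , , , 3][insph])), numeric(3)))
  mag <- sqrt(rowSums(means^2))
  check(any(mag > 0), "sphere '%s' contains no nonzero-velocity voxel", seed$name)
  k <- min(top, ds$n_phases)
  sel <- order(mag, decreasing = TRUE)[seq_len(k)]
  n <- colSums(means[sel, , drop = FALSE])
  len <- sqrt(sum(n^2))
  check(len > 0, "top-phase mean velocities cancel; cannot orient plane for '%s'", seed$name)
  n / len
}

#' Extract a vessel cross-section at a sample sphere
#'
#' Samples the plane through the sphere center with the given normal on a
#' uniform in-plane grid (step = half the smallest voxel spacing, extent 3x
#' the seed radius). A sample is lumen if the trilinearly interpolated binary
#' label is >= 0.5; the lumen is restricted to the connected component
#' containing the center.
#'
#' @param mask a `mask3d`.
#' @param label structure name.
#' @param seed a `sphere_seed` giving the plane origin.
#' @param normal unit plane normal (world axes).
#' @return a `cross_section`: list with `name`, `origin`, `normal`, `points`
#'   (k x 3 mm, lumen sample points), `dA` (per-sample area, mm^2).
#' @export
extract_cross_section <- function(mask, label = "LA", seed, normal) {
  normal <- normal / sqrt(sum(normal^2))
  step <- min(mask$spacing) / 2
  extent <- 3 * seed$radius
  # orthonormal in-plane basis
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  s <- seq(-extent, extent, by = step)
  ns <- length(s)
  g1 <- rep(s, times = ns); g2 <- rep(s, each = ns)
  pts <- cbind(seed$center[1] + g1 * e1[1] + g2 * e2[1],
               seed$center[2] + g1 * e1[2] + g2 * e2[2],
               seed$center[3] + g1 * e1[3] + g2 * e2[3])
  lab <- label_array(mask, label) * 1
  vals <- interp_trilinear(lab, mask$spacing, mask$origin, pts, outside = 0)
  lumen <- matrix(vals >= 0.5, ns, ns)
  ci <- (ns + 1L) %/% 2L
  check(lumen[ci, ci], "no lumen at the cross-section center for seed '%s'; reposition the sphere",
        seed$name)
  comp <- flood_fill2(lumen, ci, ci)
  structure(list(name = seed$name, origin = seed$center, normal = normal,
                 points = pts[as.vector(comp), , drop = FALSE],
                 dA = step^2),
            class = "cross_section")
}

# 4-connected flood fill on a logical matrix from (i0, j0); returns the
# connected component as a logical matrix.
flood_fill2 <- function(m, i0, j0) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  stack <- matrix(c(i0, j0), 1L, 2L)
  out[i0, j0] <- TRUE
  while (nrow(stack)) {
    cur <- stack
    stack <- matrix(0L, 0L, 2L)
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      ni <- cur[, 1] + d[1]; nj <- cur[, 2] + d[2]
      ok <- ni >= 1L & ni <= nrow(m) & nj >= 1L & nj <= ncol(m)
      ni <- ni[ok]; nj <- nj[ok]
      idx <- cbind(ni, nj)
      add <- m[idx] & !out[idx]
      if (any(add)) {
        out[idx[add, , drop = FALSE]] <- TRUE
        stack <- rbind(stack, idx[add, , drop = FALSE])
      }
    }
    stack <- unique(stack)
  }
  out
}

#' Lumen area of a cross-section (mm^2)
#' @param cs a `cross_section`.
#' @export
cross_section_area <- function(cs) nrow(cs$points) * cs$dA

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section '%s': normal (%.3f, %.3f, %.3f), lumen area %.4g mm^2\n",
              x$name, x$normal[1], x$normal[2], x$normal[3], cross_section_area(x)))
  invisible(x)
}

#' Flow rate through a cross-section
#'
#' \eqn{Q(t) = \sum_{lumen} v(p, t) \cdot \hat n \, \Delta A} with trilinear
#' velocity interpolation, in ml/s. The sign is oriented so the
#' cycle-integrated flow is positive (inflow into the atrium for pulmonary
#' veins, forward transmitral flow for the mitral valve, matching how the
#' curves are conventionally plotted).
#'
#' @param ds a masked `flow_dataset` (velocities m/s).
#' @param cs a `cross_section`.
#' @param orient_positive flip the sign so the cycle integral is positive
#'   (default TRUE).
#' @return a `flow_ts` named `"flow_<seed>"`, units ml/s.
#' @export
flow_rate <- function(ds, cs, orient_positive = TRUE) {
  q <- vapply(seq_len(ds$n_phases), function(t) {
    vn <- numeric(nrow(cs$points))
    for (c in 1:3)
      vn <- vn + cs$normal[c] * interp_trilinear(ds$velocity[t, , , , c],
                                                 ds$spacing, ds$origin, cs$points)
    sum(vn) * cs$dA                       # (m/s) * mm^2 == ml/s
  }, 0)
  if (orient_positive && sum(q) < 0) q <- -q
  flow_ts(paste0("flow_", cs$name), phase_times(ds), q, units = "ml/s")
}

#' Pulmonary-vein wave features (S, D, Ar)
#'
#' The systolic window runs from cycle start until the mitral flow first
#' exceeds `mv_onset_frac` of its maximum. S is the PV flow maximum inside
#' that window, D the maximum after it, and Ar the minimum over the last
#' `ar_window_frac` of the cycle (atrial-contraction reversal, expected
#' negative).
#'
#' @param q pulmonary-vein `flow_ts` (ml/s).
#' @param mv the same subject's mitral `flow_ts`, same time base.
#' @param mv_onset_frac fraction of the mitral maximum defining E-wave onset
#'   (default 0.10).
#' @param ar_window_frac final fraction of the cycle searched for Ar
#'   (default 0.30).
#' @return list with `S_peak`, `S_time`, `D_peak`, `D_time`, `Ar_peak`,
#'   `Ar_time` (ml/s, s), `SD_ratio`, and `no_reversal` flag.
#' @export
detect_pv_waves <- function(q, mv, mv_onset_frac = 0.10, ar_window_frac = 0.30) {
  check(length(q$times) == length(mv$times) && all(abs(q$times - mv$times) < 1e-9),
        "PV and MV curves are on different time bases")
  check(any(mv$values != 0), "mitral curve is identically zero; cannot phase the cycle")
  onset <- which(mv$values > mv_onset_frac * max(mv$values))[1]
  check(!is.na(onset), "mitral onset not found")
  n <- length(q$times)
  sys_idx <- seq_len(max(onset - 1L, 1L))
  dia_idx <- if (onset <= n) onset:n else integer(0)
  i_s <- sys_idx[which.max(q$values[sys_idx])]
  i_d <- dia_idx[which.max(q$values[dia_idx])]
  cycle <- max(q$times) + diff(q$times)[1]   # nominal cycle duration
  ar_idx <- which(q$times >= (1 - ar_window_frac) * cycle)
  i_ar <- ar_idx[which.min(q$values[ar_idx])]
  ar <- q$values[i_ar]
  list(S_peak = q$values[i_s], S_time = q$times[i_s],
       D_peak = q$values[i_d], D_time = q$times[i_d],
       Ar_peak = ar, Ar_time = q$times[i_ar],
       SD_ratio = q$values[i_s] / q$values[i_d],
       no_reversal = ar >= 0)
}

#' Mitral wave features (E, A, volumes)
#'
#' E is the first prominent flow peak (early passive filling) and A the last
#' (atrial contraction); prominent means a local maximum of at least
#' `min_peak_frac` of the global maximum, so the detection also handles the
#' reversed E < A pattern of impaired relaxation. The split point is the flow
#' minimum between the peaks (the E-A trough). Passive volume integrates from
#' E onset (start of E's contiguous run above `onset_frac` x E) to the split,
#' active volume from the split to cycle end (cycle closed by wrapping the
#' first sample), both trapezoidal with negative lobes clipped at zero. The
#' fusion flag is set when the trough exceeds `fusion_frac` of the E peak.
#'
#' @param q mitral `flow_ts` (ml/s) with at least one positive excursion.
#' @param onset_frac E-onset threshold as a fraction of E peak (default 0.10).
#' @param fusion_frac trough fraction of E flagging E/A fusion (default 0.20).
#' @param min_peak_frac prominence threshold for candidate peaks as a fraction
#'   of the global maximum (default 0.20).
#' @return list with `E_peak`, `E_time`, `A_peak`, `A_time`, `EA_peak`,
#'   `passive_volume_ml`, `active_volume_ml`, `EA_volume`, `fusion`,
#'   `a_absent` flags.
#' @export
detect_mv_waves <- function(q, onset_frac = 0.10, fusion_frac = 0.20,
                            min_peak_frac = 0.20) {
  check(any(q$values > 0), "mitral curve has no positive excursion")
  v <- q$values; tt <- q$times; n <- length(v)
  # local maxima (endpoints count when they dominate their one neighbor)
  is_max <- c(v[1] > v[2],
              v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
              v[n] > v[n - 1]) & v > 0
  cand <- which(is_max & v >= min_peak_frac * max(v))
  if (!length(cand)) cand <- which.max(v)
  i_e <- cand[1]
  i_a <- cand[length(cand)]
  if (i_a == i_e) {
    return(list(E_peak = v[i_e], E_time = tt[i_e],
                A_peak = NA_real_, A_time = NA_real_, EA_peak = NA_real_,
                passive_volume_ml = NA_real_, active_volume_ml = NA_real_,
                EA_volume = NA_real_, fusion = TRUE, a_absent = TRUE))
  }
  between <- i_e:i_a
  i_split <- between[which.min(v[between])]
  onset_candidates <- which(v > onset_frac * v[i_e])
  onset_candidates <- onset_candidates[onset_candidates <= i_e]
  i_on <- if (length(onset_candidates)) {
    # walk back from E to the start of its contiguous above-threshold run
    run <- i_e
    while (run > 1L && v[run - 1L] > onset_frac * v[i_e]) run <- run - 1L
    run
  } else 1L
  # close the cardiac cycle: the sample after the last phase is phase 1 again
  vw <- c(v, v[1]); tw <- c(tt, tt[n] + diff(tt)[1])
  trapz <- function(idx) {
    vv <- pmax(vw[idx], 0)
    sum(diff(tw[idx]) * (head(vv, -1) + tail(vv, -1)) / 2)
  }
  passive <- trapz(i_on:i_split)
  active <- trapz(i_split:(n + 1L))
  list(E_peak = v[i_e], E_time = tt[i_e],
       A_peak = v[i_a], A_time = tt[i_a],
       EA_peak = v[i_e] / v[i_a],
       passive_volume_ml = passive, active_volume_ml = active,
       EA_volume = passive / active,
       fusion = v[i_split] > fusion_frac * v[i_e],
       a_absent = FALSE)
}

#' Cycle-integrated volume of a flow curve (ml)
#'
#' Trapezoidal integral of a ml/s curve over the cycle, closing the cycle by
#' wrapping the last sample to the first.
#'
#' @param q a `flow_ts` in ml/s.
#' @export
stroke_volume <- function(q) {
  dt <- diff(q$times)[1]
  v <- c(q$values, q$values[1])
  tt <- c(q$times, q$times[length(q$times)] + dt)
  sum(diff(tt) * (head(v, -1) + tail(v, -1)) / 2)
}
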