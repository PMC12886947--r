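# Velocity-gradient-tensor machinery and the energy/vorticity indices over the
# masked left atrium. All gradients are in SI (s^-1): velocities m/s, voxel
# spacing converted from mm to m.

#' Physical parameters for hemodynamic indices
#'
#' @param rho blood density, kg/m^3.
#' @param mu dynamic viscosity of blood, Pa.s.
#' @param q_threshold Q-criterion vortex-core threshold, s^-2.
#' @return list of validated parameters.
#' @export
hemo_params <- function(rho = 1060, mu = 0.0035, q_threshold = 500) {
  check(rho > 0 && mu > 0 && q_threshold > 0, "all physical parameters must be positive")
  list(rho = rho, mu = mu, q_threshold = q_threshold)
}

#' Velocity-gradient tensor at one cardiac phase
#'
#' Mask-aware finite differences: central where both axis neighbors are inside
#' the labeled region, one-sided where only one is, zero (and flagged reduced
#' accuracy) where neither is. Exact for affine velocity fields.
#'
#' @param ds a `flow_dataset` (assumed masked; only in-mask values are used).
#' @param mask a `mask3d` on the same grid.
#' @param label structure name.
#' @param phase 1-based phase index.
#' @return list with `tensor` (array `(z, y, x, i, j)` of d v_i / d x_j, s^-1,
#'   components/axes ordered x, y, z), `inmask` (logical array), and `flagged`
#'   (logical array: in-mask voxels missing both neighbors along some axis).
#' @export
velocity_gradient <- function(ds, mask, label = "LA", phase = 1L) {
  check_congruent(ds, mask)
  inmask <- label_array(mask, label)
  check(any(inmask), "label '%s' region is empty", label)
  d <- dim(inmask)
  h <- ds$spacing * 1e-3                 # m
  tensor <- array(0, c(d, 3L, 3L))
  flagged <- array(FALSE, d)
  # array dims: 1 = z, 2 = y, 3 = x; world axis j: x -> dim 3, y -> dim 2, z -> dim 1
  axdim <- c(x = 3L, y = 2L, z = 1L)
  m <- inmask * 1
  for (i in 1:3) {                        # velocity component
    v <- ds$velocity[phase, , , , i]
    for (j in 1:3) {                      # world axis
      dm <- axdim[j]
      vp <- shift3(v, dm, +1L); mp <- shift3(m, dm, +1L) > 0
      vm <- shift3(v, dm, -1L); mm <- shift3(m, dm, -1L) > 0
      g <- array(0, d)
      both <- mp & mm
      g[both] <- (vp[both] - vm[both]) / (2 * h[j])
      fwd <- mp & !mm
      g[fwd] <- (vp[fwd] - v[fwd]) / h[j]
      bwd <- !mp & mm
      g[bwd] <- (v[bwd] - vm[bwd]) / h[j]
      none <- inmask & !mp & !mm
      flagged <- flagged | none
      g[!inmask] <- 0
      tensor[, , , i, j] <- g
    }
  }
  list(tensor = tensor, inmask = inmask, flagged = flagged & inmask)
}

#' Vorticity field and volume-averaged vorticity magnitude
#'
#' Computes the curl of the velocity field per phase and the scalar summary
#' \eqn{|\omega_{LA}|(t) = \sum_i |\omega_i| Vol_i / V_{LA}} (the
#' volume-averaged vorticity magnitude, s^-1), which normalizes out chamber
#' dilation.
#'
#' @inheritParams velocity_gradient
#' @return list with `field` (array `(phase, z, y, x, 3)`, s^-1) and `series`
#'   (a `flow_ts` named `"omega_LA"`, units 1/s).
#' @export
vorticity <- function(ds, mask, label = "LA") {
  inmask <- label_array(mask, label)
  d <- dim(ds$velocity)
  field <- array(0, c(d[1], d[2:4], 3L))
  avg <- numeric(d[1])
  nv <- sum(inmask)
  for (t in seq_len(d[1])) {
    G <- velocity_gradient(ds, mask, label, t)$tensor
    # omega = curl v: (dvz/dy - dvy/dz, dvx/dz - dvz/dx, dvy/dx - dvx/dy)
    field[t, , , , 1] <- G[, , , 3, 2] - G[, , , 2, 3]
    field[t, , , , 2] <- G[, , , 1, 3] - G[, , , 3, 1]
    field[t, , , , 3] <- G[, , , 2, 1] - G[, , , 1, 2]
    mag <- sqrt(field[t, , , , 1]^2 + field[t, , , , 2]^2 + field[t, , , , 3]^2)
    avg[t] <- sum(mag[inmask]) / nv      # uniform voxel volume cancels
  }
  list(field = field,
       series = flow_ts("omega_LA", phase_times(ds), avg, units = "1/s"))
}

#' Q-criterion field and vortex-core volume ratio
#'
#' Q = (||Omega||_F^2 - ||S||_F^2) / 2 with Omega and S the antisymmetric and
#' symmetric parts of the velocity-gradient tensor; positive where rotation
#' dominates strain. The summary curve is the fraction of in-mask voxels with
#' Q above `q_threshold` (dimensionless, in [0, 1]).
#'
#' @inheritParams velocity_gradient
#' @param params a [hemo_params()] list (uses `q_threshold`).
#' @return list with `field` (array `(phase, z, y, x)`, s^-2) and `series`
#'   (`flow_ts` named `"qcrit_ratio"`).
#' @export
q_criterion <- function(ds, mask, label = "LA", params = hemo_params()) {
  inmask <- label_array(mask, label)
  d <- dim(ds$velocity)
  field <- array(0, c(d[1], d[2:4]))
  ratio <- numeric(d[1])
  nv <- sum(inmask)
  for (t in seq_len(d[1])) {
    G <- velocity_gradient(ds, mask, label, t)$tensor
    q <- array(0, d[2:4])
    for (i in 1:3) for (j in 1:3) {
      om <- (G[, , , i, j] - G[, , , j, i]) / 2
      s  <- (G[, , , i, j] + G[, , , j, i]) / 2
      q <- q + om^2 - s^2
    }
    q <- q / 2
    q[!inmask] <- 0
    field[t, , , ] <- q
    ratio[t] <- sum(q[inmask] > params$q_threshold) / nv
  }
  list(field = field,
       series = flow_ts("qcrit_ratio", phase_times(ds), ratio, units = ""))
}

#' Kinetic energy of the masked region
#'
#' \eqn{KE(t) = (1/2) \rho \sum_i v_i^2 Vol_i} over the labeled voxels,
#' reported in mJ, plus the volume-normalized curve KE / V_LA (mJ/ml).
#'
#' @inheritParams q_criterion
#' @return list of two `flow_ts`: `ke` (mJ) and `ke_per_volume` (mJ/ml).
#' @export
kinetic_energy <- function(ds, mask, label = "LA", params = hemo_params()) {
  check_congruent(ds, mask)
  inmask <- label_array(mask, label)
  vol_m3 <- prod(ds$spacing) * 1e-9      # voxel volume, m^3
  v_la_ml <- sum(inmask) * prod(ds$spacing) * 1e-3
  times <- phase_times(ds)
  ke <- vapply(seq_len(ds$n_phases), function(t) {
    v2 <- ds$velocity[t, , , , 1]^2 + ds$velocity[t, , , , 2]^2 + ds$velocity[t, , , , 3]^2
    0.5 * params$rho * sum(v2[inmask]) * vol_m3 * 1e3   # J -> mJ
  }, 0)
  list(ke = flow_ts("KE", times, ke, units = "mJ"),
       ke_per_volume = flow_ts("KE_per_volume", times, ke / v_la_ml, units = "mJ/ml"))
}

#' Viscous energy loss of the masked region
#'
#' Rate of kinetic-energy dissipation by internal friction, from the
#' Navier-Stokes dissipation function:
#' \deqn{\Phi_v = (1/2) \sum_{ij} [ (dv_i/dx_j + dv_j/dx_i)
#'   - (2/3)(\nabla \cdot v)\delta_{ij} ]^2}
#' \deqn{EL(t) = \mu \sum_i \Phi_{v,i} Vol_i}
#' reported in mW, plus the volume-normalized curve (mW/ml). The divergence
#' term is retained because measured MRI fields are not discretely
#' divergence-free. Non-negative for every field.
#'
#' @inheritParams q_criterion
#' @return list of two `flow_ts`: `vel` (mW) and `vel_per_volume` (mW/ml).
#' @export
viscous_energy_loss <- function(ds, mask, label = "LA", params = hemo_params()) {
  inmask <- label_array(mask, label)
  vol_m3 <- prod(ds$spacing) * 1e-9
  v_la_ml <- sum(inmask) * prod(ds$spacing) * 1e-3
  times <- phase_times(ds)
  el <- vapply(seq_len(ds$n_phases), function(t) {
    G <- velocity_gradient(ds, mask, label, t)$tensor
    div <- G[, , , 1, 1] + G[, , , 2, 2] + G[, , , 3, 3]
    phi <- array(0, dim(inmask))
    for (i in 1:3) for (j in 1:3) {
      term <- G[, , , i, j] + G[, , , j, i] - (if (i == j) (2 / 3) * div else 0)
      phi <- phi + term^2
    }
    phi <- phi / 2
    params$mu * sum(phi[inmask]) * vol_m3 * 1e3         # W -> mW
  }, 0)
  list(vel = flow_ts("VEL", times, el, units = "mW"),
       vel_per_volume = flow_ts("VEL_per_volume", times, el / v_la_ml, units = "mW/ml"))
}

#' Ratio of kinetic energy to viscous energy loss
#'
#' Elementwise KE/VEL over a shared time base; a flow-efficiency index
#' (invariant to uniform velocity scaling since both terms are quadratic).
#' Entries where VEL <= `eps` are undefined and returned as `NA`.
#'
#' @param ke,vel `flow_ts` objects on the same time base.
#' @param eps smallest VEL treated as nonzero (units of `vel`).
#' @return a `flow_ts` named `"KE_VEL_ratio"` with attribute `"undefined"`
#'   (logical vector).
#' @export
ke_vel_ratio <- function(ke, vel, eps = 1e-12) {
  check(length(ke$times) == length(vel$times) &&
          all(abs(ke$times - vel$times) < 1e-9),
        "KE and VEL series are on different time bases")
  undef <- vel$values <= eps
  vals <- ifelse(undef, NA_real_, ke$values / vel$values)
  out <- flow_ts("KE_VEL_ratio", ke$times, vals, units = "")
  attr(out, "undefined") <- undef
  out
}

#' 3x3x3 median filter of a scalar field
#'
#' Isotropic 3-voxel-kernel median, used to suppress noise in Q-criterion
#' renderings; borders handled by nearest-edge replication.
#'
#' @param field 3-D scalar array.
#' @return filtered array of the same shape.
#' @export
median_filter3 <- function(field) {
  d <- dim(field)
  check(length(d) == 3L, "field must be a 3-D array")
  # pad by edge replication
  pz <- c(1, seq_len(d[1]), d[1])
  py <- c(1, seq_len(d[2]), d[2])
  px <- c(1, seq_len(d[3]), d[3])
  p <- field[pz, py, px]
  n <- prod(d)
  stack <- matrix(0, n, 27L)
  k <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    stack[, k] <- as.vector(p[dz + seq_len(d[1]), dy + seq_len(d[2]), dx + seq_len(d[3])])
  }
  array(row_median27(stack), d)
}

# Row medians of an n x 27 matrix: median = 14th order statistic; computed by
# column-sorting a rank-ordered representation via repeated pmin/pmax would be
# slow in R, so sort rowwise through matrixStats-free apply on moderate n.
row_median27 <- function(m) {
  s <- apply(m, 1L, sort.int, method = "quick")
  s[14L, ]
}
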