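# Deterministic generators of analytic flow fields and a left-atrial phantom.
# The analytic fields (rigid rotation, Poiseuille tube, Lamb-Oseen vortex) have
# closed-form gradients, energies and fluxes and serve as oracles for the
# hemodynamic indices; the phantom exercises the full geometry/flux/waveform
# plumbing of a subject analysis without any acquisition data.

replicate_phases <- function(vx, vy, vz, n_phases) {
  d <- dim(vx)
  v <- array(0, c(n_phases, d, 3L))
  for (t in seq_len(n_phases)) {
    v[t, , , , 1] <- vx; v[t, , , , 2] <- vy; v[t, , , , 3] <- vz
  }
  v
}

centered_origin <- function(shape, spacing) -(shape[3:1] - 1) / 2 * spacing

#' Rigid-rotation velocity field
#'
#' Solid-body rotation about the z axis through the grid center:
#' v = Omega_z x r. The vorticity magnitude is exactly 2 Omega_z and the
#' Q-criterion exactly Omega_z^2 everywhere.
#'
#' @param omega_z rotation rate, s^-1 (rad/s).
#' @param shape grid shape `(nz, ny, nx)`.
#' @param spacing voxel spacing mm (scalar or length 3).
#' @param n_phases phases to replicate the steady field over.
#' @param cycle_duration RR interval, s.
#' @return list with `ds` (`flow_dataset`) and `mask` (`mask3d`, full grid).
#' @export
solid_body_rotation <- function(omega_z, shape = c(40, 40, 40), spacing = 1,
                                n_phases = 1L, cycle_duration = 1) {
  spacing <- rep(spacing, length.out = 3)
  origin <- centered_origin(shape, spacing)
  co <- grid_coords(shape, spacing, origin)
  x_m <- co$x * 1e-3; y_m <- co$y * 1e-3
  vx <- -omega_z * y_m
  vy <- omega_z * x_m
  vz <- array(0, shape)
  ds <- flow_dataset(replicate_phases(vx, vy, vz, n_phases),
                     array(1, c(n_phases, shape)), spacing, origin,
                     cycle_duration = cycle_duration)
  mask <- mask3d(array(1L, shape), c(LA = 1L), spacing, origin)
  list(ds = ds, mask = mask)
}

#' Poiseuille tube flow
#'
#' Axis-aligned cylindrical tube with the parabolic profile
#' v = v0 (1 - r^2/R^2). Closed forms: flow rate pi R^2 v0 / 2 and viscous
#' dissipation 2 pi mu L v0^2.
#'
#' @param radius_mm tube radius R.
#' @param v0 centerline speed, m/s.
#' @param length_mm tube length L.
#' @param axis flow axis, `"x"`, `"y"` or `"z"`.
#' @param spacing voxel spacing mm.
#' @param margin_mm empty margin around the tube.
#' @param n_phases,cycle_duration timing, as in [solid_body_rotation()].
#' @return list with `ds` and `mask` (tube support labeled `LA = 1`).
#' @export
poiseuille_tube <- function(radius_mm, v0, length_mm, axis = "z", spacing = 1,
                            margin_mm = 3, n_phases = 1L, cycle_duration = 1) {
  spacing <- rep(spacing, length.out = 3)
  if (2 * radius_mm / max(spacing) < 4)
    warning("tube diameter resolved by fewer than 4 voxels")
  cross_mm <- 2 * (radius_mm + margin_mm)
  ext <- switch(axis, x = c(length_mm, cross_mm, cross_mm),
                y = c(cross_mm, length_mm, cross_mm),
                z = c(cross_mm, cross_mm, length_mm))
  shape <- rev(ceiling(ext / spacing[c(1, 2, 3)]) + 1L)   # (nz, ny, nx)
  origin <- centered_origin(shape, spacing)
  co <- grid_coords(shape, spacing, origin)
  r2 <- switch(axis,
               x = co$y^2 + co$z^2, y = co$x^2 + co$z^2, z = co$x^2 + co$y^2)
  axpos <- switch(axis, x = co$x, y = co$y, z = co$z)
  inside <- r2 <= radius_mm^2 & abs(axpos) <= length_mm / 2
  prof <- v0 * (1 - r2 / radius_mm^2) * inside
  zero <- array(0, shape)
  v <- switch(axis,
              x = replicate_phases(prof, zero, zero, n_phases),
              y = replicate_phases(zero, prof, zero, n_phases),
              z = replicate_phases(zero, zero, prof, n_phases))
  ds <- flow_dataset(v, array(1, c(n_phases, shape)), spacing, origin,
                     cycle_duration = cycle_duration)
  mask <- mask3d(array(as.integer(inside), shape), c(LA = 1L), spacing, origin)
  list(ds = ds, mask = mask)
}

#' Lamb-Oseen vortex
#'
#' Planar vortex about the z axis: tangential speed
#' \eqn{v_\theta(r) = \Gamma / (2 \pi r) (1 - exp(-r^2 / r_c^2))}; peak axial
#' vorticity \eqn{\Gamma / (\pi r_c^2)}, far-field circulation-dominated decay
#' \eqn{\Gamma / (2 \pi r)}.
#'
#' @param gamma_m2s circulation Gamma, m^2/s.
#' @param r_c_mm core radius, mm.
#' @param shape,spacing,n_phases,cycle_duration grid and timing.
#' @return list with `ds` and `mask` (full grid).
#' @export
lamb_oseen <- function(gamma_m2s, r_c_mm, shape = c(24, 48, 48), spacing = 1,
                       n_phases = 1L, cycle_duration = 1) {
  spacing <- rep(spacing, length.out = 3)
  if (2 * r_c_mm / max(spacing) < 4)
    warning("vortex core resolved by fewer than 4 voxels")
  origin <- centered_origin(shape, spacing)
  co <- grid_coords(shape, spacing, origin)
  r_mm <- sqrt(co$x^2 + co$y^2)
  r_m <- r_mm * 1e-3
  vt <- ifelse(r_m > 0,
               gamma_m2s / (2 * pi * r_m) * (1 - exp(-(r_mm / r_c_mm)^2)), 0)
  vx <- ifelse(r_mm > 0, -vt * co$y / r_mm, 0)
  vy <- ifelse(r_mm > 0, vt * co$x / r_mm, 0)
  ds <- flow_dataset(replicate_phases(vx, vy, array(0, shape), n_phases),
                     array(1, c(n_phases, shape)), spacing, origin,
                     cycle_duration = cycle_duration)
  mask <- mask3d(array(1L, shape), c(LA = 1L), spacing, origin)
  list(ds = ds, mask = mask)
}

#' Sum-of-Gaussian-pulses waveform
#'
#' @param t times, s.
#' @param amplitudes,centers,widths per-pulse amplitude (ml/s), center (s) and
#'   Gaussian sigma (s).
#' @return waveform values at `t`.
#' @export
gaussian_pulse_waveform <- function(t, amplitudes, centers, widths) {
  out <- numeric(length(t))
  for (k in seq_along(amplitudes))
    out <- out + amplitudes[k] * exp(-((t - centers[k])^2) / (2 * widths[k]^2))
  out
}

#' Specification of the left-atrial phantom
#'
#' Defaults emulate a clinical acquisition: 1.5 mm isotropic grid, 20 phases
#' over a 1 s cycle, all speeds below a 150 cm/s VENC. Geometry: an LA
#' ellipsoid (semi-axes 25, 25, 30 mm) with four pulmonary-vein tubes (radius
#' 7 mm, right pair entering along -x, left pair along +x) carrying Poiseuille
#' profiles scaled by triphasic S/D/Ar Gaussian-pulse waveforms, a mitral tube
#' (radius 13 mm, flow along -z) carrying a biphasic E/A waveform rescaled so
#' the cycle-integrated mitral volume equals the summed pulmonary-vein
#' volumes, and a decaying Lamb-Oseen vortex inside the chamber during the S
#' and D windows.
#'
#' @param spacing_mm isotropic voxel spacing.
#' @param n_phases cardiac phases.
#' @param cycle_duration RR interval, s.
#' @param la_semiaxes_mm LA ellipsoid semi-axes (x, y, z).
#' @param pv_radius_mm,mv_radius_mm tube radii.
#' @param pv_amplitudes S, D, Ar pulse amplitudes per vein, ml/s (Ar < 0).
#' @param pv_centers_frac,pv_widths_frac pulse centers/sigmas as cycle
#'   fractions.
#' @param mv_shape_amplitudes E, A pulse shape amplitudes (rescaled for mass
#'   balance), ml/s.
#' @param mv_centers_frac,mv_widths_frac mitral pulse centers/sigmas, cycle
#'   fractions.
#' @param vortex_gamma,vortex_rc_mm Lamb-Oseen circulation (m^2/s) and core
#'   radius.
#' @param noise_sigma i.i.d. Gaussian velocity noise SD, m/s.
#' @param seed RNG seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(spacing_mm = 1.5, n_phases = 20L, cycle_duration = 1.0,
                         la_semiaxes_mm = c(25, 25, 30),
                         pv_radius_mm = 7, mv_radius_mm = 13,
                         pv_amplitudes = c(80, 64, -24),
                         pv_centers_frac = c(0.15, 0.55, 0.90),
                         pv_widths_frac = c(0.07, 0.08, 0.05),
                         mv_shape_amplitudes = c(220, 110),
                         mv_centers_frac = c(0.60, 0.90),
                         mv_widths_frac = c(0.08, 0.05),
                         vortex_gamma = 0.02, vortex_rc_mm = 8,
                         noise_sigma = 0, seed = 1L) {
  check(noise_sigma >= 0, "noise_sigma must be >= 0")
  check(pv_amplitudes[3] <= 0, "Ar amplitude must be <= 0")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate the left-atrial phantom
#'
#' Builds the voxel dataset, the LA mask (ellipsoid plus tubes), the five
#' sample spheres, and a ground-truth record (per-vein S/D/Ar and mitral E/A
#' peak amplitudes on the sampled time grid, per-vessel cycle volumes, and the
#' mitral passive/active volume split computed from the analytic waveform with
#' the same trough-split rule the detector uses). Deterministic for a fixed
#' spec.
#'
#' @param spec a [phantom_spec()].
#' @return list with `ds`, `mask`, `seeds` (named `sphere_seed` list),
#'   `truth` (list), and `spec`.
#' @export
la_phantom <- function(spec = phantom_spec()) {
  sp <- rep(spec$spacing_mm, 3)
  ax <- spec$la_semiaxes_mm
  Rpv <- spec$pv_radius_mm; Rmv <- spec$mv_radius_mm
  # domain sized to the geometry
  ext <- c(2 * 46 + 7, 2 * max(ax[2] + 2, 11 + Rpv + 2), (46 + 2) + (ax[3] + 3))
  shape <- rev(ceiling(ext / sp) + 1L)
  origin <- c(-(shape[3] - 1) / 2 * sp[1],
              -(shape[2] - 1) / 2 * sp[2],
              -(46 + 2))
  co <- grid_coords(shape, sp, origin)
  T <- spec$cycle_duration
  N <- spec$n_phases
  times <- (seq_len(N) - 1) * T / N

  ellip <- (co$x / ax[1])^2 + (co$y / ax[2])^2 + (co$z / ax[3])^2 <= 1
  tube_pv <- function(side, ysign) {
    d2 <- (co$y - ysign * 11)^2 + (co$z - 10)^2
    if (side > 0) d2 <= Rpv^2 & co$x >= 18 & co$x <= 46
    else d2 <= Rpv^2 & co$x <= -18 & co$x >= -46
  }
  tubes <- list(RS = tube_pv(+1, +1), RI = tube_pv(+1, -1),
                LS = tube_pv(-1, +1), LI = tube_pv(-1, -1))
  mv_tube <- co$x^2 + co$y^2 <= Rmv^2 & co$z <= -24 & co$z >= -46
  for (a in tubes) check(!any(a & mv_tube), "phantom tubes overlap")
  lab <- array(0L, shape)
  lab[ellip | Reduce(`|`, tubes) | mv_tube] <- 1L
  mask <- mask3d(lab, c(LA = 1L), sp, origin)

  # waveforms (ml/s)
  q_pv <- function(t) gaussian_pulse_waveform(
    t, spec$pv_amplitudes, spec$pv_centers_frac * T, spec$pv_widths_frac * T)
  pv_int <- sum(spec$pv_amplitudes * spec$pv_widths_frac * T * sqrt(2 * pi))
  mv_shape_int <- sum(spec$mv_shape_amplitudes * spec$mv_widths_frac * T * sqrt(2 * pi))
  lambda <- 4 * pv_int / mv_shape_int
  mv_amp <- lambda * spec$mv_shape_amplitudes
  q_mv <- function(t) gaussian_pulse_waveform(
    t, mv_amp, spec$mv_centers_frac * T, spec$mv_widths_frac * T)

  # per-voxel parabolic profile weights (dimensionless in [0, 1])
  prof_pv <- list(
    RS = (1 - ((co$y - 11)^2 + (co$z - 10)^2) / Rpv^2) * tubes$RS,
    RI = (1 - ((co$y + 11)^2 + (co$z - 10)^2) / Rpv^2) * tubes$RI,
    LS = (1 - ((co$y - 11)^2 + (co$z - 10)^2) / Rpv^2) * tubes$LS,
    LI = (1 - ((co$y + 11)^2 + (co$z - 10)^2) / Rpv^2) * tubes$LI)
  dir_pv <- c(RS = -1, RI = -1, LS = +1, LI = +1)     # x direction into the LA
  prof_mv <- (1 - (co$x^2 + co$y^2) / Rmv^2) * mv_tube

  # chamber vortex (Lamb-Oseen about z, tapered to zero at the wall)
  chamber <- ellip & !Reduce(`|`, tubes) & !mv_tube
  r_mm <- sqrt(co$x^2 + co$y^2)
  vt <- ifelse(r_mm > 0, spec$vortex_gamma / (2 * pi * (r_mm * 1e-3)) *
                 (1 - exp(-(r_mm / spec$vortex_rc_mm)^2)), 0)
  rho2 <- (co$x / ax[1])^2 + (co$y / ax[2])^2 + (co$z / ax[3])^2
  taper <- pmax(1 - rho2, 0)
  vvx <- ifelse(r_mm > 0, -vt * co$y / r_mm, 0) * taper * chamber
  vvy <- ifelse(r_mm > 0, vt * co$x / r_mm, 0) * taper * chamber
  vortex_env <- gaussian_pulse_waveform(times, c(1, 0.8), c(0.2, 0.6) * T,
                                        c(0.1, 0.1) * T)

  vel <- array(0, c(N, shape, 3L))
  for (t in seq_len(N)) {
    tk <- times[t]
    qp <- q_pv(tk)
    vx <- array(0, shape); vy <- array(0, shape); vz <- array(0, shape)
    for (nm in names(tubes)) {
      v0 <- 2 * qp / (pi * Rpv^2)          # ml/s over mm^2 -> m/s
      vx <- vx + dir_pv[[nm]] * v0 * prof_pv[[nm]]
    }
    v0m <- 2 * q_mv(tk) / (pi * Rmv^2)
    vz <- vz - v0m * prof_mv
    vx <- vx + vvx * vortex_env[t]
    vy <- vy + vvy * vortex_env[t]
    vel[t, , , , 1] <- vx; vel[t, , , , 2] <- vy; vel[t, , , , 3] <- vz
  }
  mag <- array(20, c(N, shape))
  inm <- aperm(array(lab == 1L, c(shape, N)), c(4, 1, 2, 3))
  mag[inm] <- 100
  ds <- flow_dataset(vel, mag, sp, origin, cycle_duration = T, venc = 150)
  if (spec$noise_sigma > 0) ds <- add_noise(ds, spec$noise_sigma, spec$seed)

  seeds <- list(
    RS = sphere_seed("RS", c(33, 11, 10), 6),
    RI = sphere_seed("RI", c(33, -11, 10), 6),
    LS = sphere_seed("LS", c(-33, 11, 10), 6),
    LI = sphere_seed("LI", c(-33, -11, 10), 6),
    MV = sphere_seed("MV", c(0, 0, -36), 8))

  truth <- phantom_truth(spec, times, q_pv, q_mv, mv_amp, lambda)
  list(ds = ds, mask = mask, seeds = seeds, truth = truth, spec = spec)
}

# Ground truth of the phantom waveforms. The phantom's velocity field exists
# only at the N sampled phases, so ground truth is the prescribed waveform on
# that same phase grid: peak amplitudes are grid maxima and the mitral
# passive/active split applies the detector's trough rule to the exact
# waveform samples (so downstream comparisons isolate spatial-flux fidelity,
# not time-discretization of the waveform). Analytic Gaussian-pulse integrals
# are recorded alongside.
phantom_truth <- function(spec, times, q_pv, q_mv, mv_amp, lambda) {
  T <- spec$cycle_duration
  qp <- q_pv(times); qm <- q_mv(times)
  mv_feats <- detect_mv_waves(flow_ts("mv_truth", times, qm, "ml/s"))
  pv_cycle_volume <- sum(spec$pv_amplitudes * spec$pv_widths_frac * T * sqrt(2 * pi))
  ar_win <- qp[times >= 0.7 * T]
  list(
    pv = list(S_peak = max(qp[times < 0.35 * T]),
              D_peak = max(qp[times >= 0.35 * T]),
              Ar_peak = if (length(ar_win)) min(ar_win) else NA_real_,
              SD_ratio = max(qp[times < 0.35 * T]) / max(qp[times >= 0.35 * T]),
              cycle_volume_ml = sum(qp) * T / length(times),
              cycle_volume_ml_analytic = pv_cycle_volume),
    mv = list(E_peak = mv_feats$E_peak, A_peak = mv_feats$A_peak,
              EA_peak = mv_feats$EA_peak,
              passive_volume_ml = mv_feats$passive_volume_ml,
              active_volume_ml = mv_feats$active_volume_ml,
              EA_volume = mv_feats$EA_volume,
              cycle_volume_ml = sum(qm) * T / length(times),
              cycle_volume_ml_analytic = 4 * pv_cycle_volume,
              mass_balance_scale = lambda),
    vortex = list(gamma_m2s = spec$vortex_gamma, r_c_mm = spec$vortex_rc_mm))
}

#' Write a phantom to disk
#'
#' Saves the NIfTI dataset, the mask (NIfTI), the seeds JSON and the truth
#' JSON into `dir`.
#'
#' @param phantom result of [la_phantom()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  save_flowdataset(phantom$ds, dir, "flow")
  m <- aperm(phantom$mask$labels, c(3, 2, 1))
  RNifti::writeNifti(RNifti::asNifti(m, pixdim = phantom$mask$spacing),
                     file.path(dir, "mask.nii.gz"))
  write_seeds(phantom$seeds, file.path(dir, "seeds.json"))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Add i.i.d. Gaussian noise to the velocity field
#'
#' Zero-mean noise of SD `sigma` (m/s) added independently to each velocity
#' component at every voxel and phase; the magnitude image is untouched.
#' Reproducible for a fixed seed.
#'
#' @param ds a `flow_dataset`.
#' @param sigma noise SD, m/s.
#' @param seed RNG seed.
#' @return the noisy `flow_dataset`.
#' @export
add_noise <- function(ds, sigma, seed = 1L) {
  check(sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(ds)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ds$velocity <- ds$velocity + array(rnorm(length(ds$velocity), 0, sigma),
                                     dim(ds$velocity))
  ds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
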