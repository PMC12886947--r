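# Gradient-tensor machinery and the energy/vorticity indices against analytic
# oracles and a naive loop-based reference.

test_that("gradients are exact for affine fields, including mask boundaries", {
  n <- 10
  co <- laflow:::grid_coords(c(n, n, n), c(1.5, 1.5, 1.5), c(0, 0, 0))
  a <- 2.4
  vel <- array(0, c(1, n, n, n, 3))
  vel[1, , , , 1] <- a * co$x * 1e-3       # v_x = a x, a in s^-1
  ds <- make_ds(vel, spacing = c(1.5, 1.5, 1.5))
  g <- velocity_gradient(ds, full_mask(c(n, n, n), c(1.5, 1.5, 1.5)))
  expect_lt(max(abs(g$tensor[, , , 1, 1] - a)), 1e-10)
  expect_lt(max(abs(g$tensor[, , , 2, ])), 1e-12)
  expect_false(any(g$flagged))
})

test_that("solid-body rotation gives an antisymmetric tensor with vanishing strain", {
  rot <- solid_body_rotation(1, shape = c(12, 12, 12), spacing = 2)
  g <- velocity_gradient(rot$ds, rot$mask)$tensor
  S_norm <- 0
  for (i in 1:3) for (j in 1:3)
    S_norm <- max(S_norm, max(abs((g[, , , i, j] + g[, , , j, i]) / 2)))
  expect_lt(S_norm, 1e-8)
  expect_equal(max(abs(g[, , , 2, 1] - 1)), 0, tolerance = 1e-10)
  expect_equal(max(abs(g[, , , 1, 2] + 1)), 0, tolerance = 1e-10)
})

test_that("a single-voxel mask yields a zero, flagged tensor", {
  lab <- array(0L, c(5, 5, 5)); lab[3, 3, 3] <- 1L
  mask <- mask3d(lab, c(LA = 1L), c(1, 1, 1))
  vel <- array(rnorm(5^3 * 3), c(1, 5, 5, 5, 3))
  g <- velocity_gradient(apply_mask(make_ds(vel), mask), mask)
  expect_true(all(g$tensor[3, 3, 3, , ] == 0))
  expect_true(g$flagged[3, 3, 3])
})

test_that("vectorized gradient, vorticity, Q and dissipation match the naive loop reference", {
  rf <- random_masked_field(n = 10, n_phases = 1, seed = 7)
  inmask <- rf$mask$labels == 1L
  G_fast <- velocity_gradient(rf$ds, rf$mask)$tensor
  G_ref <- naive_gradient(rf$ds$velocity[1, , , , ], inmask, rf$mask$spacing)
  expect_lt(max(abs(G_fast - G_ref)), 1e-10)
  # vorticity from the reference tensor
  vo <- vorticity(rf$ds, rf$mask)
  w_ref <- array(0, c(dim(inmask), 3))
  w_ref[, , , 1] <- G_ref[, , , 3, 2] - G_ref[, , , 2, 3]
  w_ref[, , , 2] <- G_ref[, , , 1, 3] - G_ref[, , , 3, 1]
  w_ref[, , , 3] <- G_ref[, , , 2, 1] - G_ref[, , , 1, 2]
  expect_lt(max(abs(vo$field[1, , , , ] - w_ref)), 1e-10)
  # Q from the reference tensor
  qc <- q_criterion(rf$ds, rf$mask)
  q_ref <- array(0, dim(inmask))
  for (i in 1:3) for (j in 1:3)
    q_ref <- q_ref + ((G_ref[, , , i, j] - G_ref[, , , j, i]) / 2)^2 -
      ((G_ref[, , , i, j] + G_ref[, , , j, i]) / 2)^2
  q_ref <- q_ref / 2; q_ref[!inmask] <- 0
  expect_lt(max(abs(qc$field[1, , , ] - q_ref)), 1e-10)
  # dissipation from the reference tensor
  vel_ts <- viscous_energy_loss(rf$ds, rf$mask)
  div <- G_ref[, , , 1, 1] + G_ref[, , , 2, 2] + G_ref[, , , 3, 3]
  phi <- array(0, dim(inmask))
  for (i in 1:3) for (j in 1:3)
    phi <- phi + (G_ref[, , , i, j] + G_ref[, , , j, i] -
                    (if (i == j) 2 / 3 * div else 0))^2
  el_ref <- 0.0035 * sum((phi / 2)[inmask]) * prod(rf$mask$spacing) * 1e-9 * 1e3
  expect_equal(vel_ts$vel$values[1], el_ref, tolerance = 1e-10)
})

test_that("rigid rotation: |omega| = 2 Omega_z, Q = Omega_z^2, zero dissipation", {
  rot <- solid_body_rotation(1, shape = c(40, 40, 40), spacing = 1)
  vo <- vorticity(rot$ds, rot$mask)
  expect_lt(abs(vo$series$values[1] - 2) / 2, 0.02)
  mag <- sqrt(rowSums(matrix(vo$field[1, , , , ], ncol = 3)^2))
  expect_lt(max(abs(mag - 2)), 1e-8)
  qc <- q_criterion(rot$ds, rot$mask, params = hemo_params(q_threshold = 0.5))
  expect_lt(max(abs(qc$field[1, , , ] - 1)), 1e-8)
  vel_ts <- viscous_energy_loss(rot$ds, rot$mask)
  expect_lt(vel_ts$vel$values[1], 1e-12)
})

test_that("uniform flow has zero vorticity and zero Q-ratio", {
  vel <- array(0, c(2, 8, 8, 8, 3)); vel[, , , , 2] <- 0.7
  ds <- make_ds(vel)
  mask <- full_mask(c(8, 8, 8))
  expect_equal(max(abs(vorticity(ds, mask)$series$values)), 0)
  qc <- q_criterion(ds, mask)
  expect_equal(max(abs(qc$field)), 0)
  expect_equal(qc$series$values, c(0, 0))
})

test_that("Lamb-Oseen peak vorticity matches Gamma / (pi r_c^2)", {
  lo <- lamb_oseen(0.02, 8, shape = c(16, 48, 48), spacing = 1)
  vo <- vorticity(lo$ds, lo$mask)
  peak <- max(abs(vo$field[1, , , , 3]))
  expect_lt(abs(peak - 0.02 / (pi * 0.008^2)) / (0.02 / (pi * 0.008^2)), 0.03)
})

test_that("simple shear: Q = 0 and dissipation mu k^2 V; Q integrates to ~0", {
  n <- 16
  co <- laflow:::grid_coords(c(n, n, n), c(1, 1, 1), c(0, 0, 0))
  k <- 12
  vel <- array(0, c(1, n, n, n, 3))
  vel[1, , , , 1] <- k * co$y * 1e-3
  ds <- make_ds(vel)
  mask <- full_mask(c(n, n, n))
  qc <- q_criterion(ds, mask)
  expect_lt(max(abs(qc$field)), 1e-8)
  expect_lt(abs(sum(qc$field)), 1e-8)
  el <- viscous_energy_loss(ds, mask)$vel$values[1]
  expected <- 0.0035 * k^2 * n^3 * 1e-9 * 1e3
  expect_lt(abs(el - expected) / expected, 0.02)
})

test_that("Poiseuille dissipation matches 2 pi mu L v0^2 and converges under refinement", {
  mu <- 0.0035; v0 <- 0.4; L_m <- 0.04
  expected <- 2 * pi * mu * L_m * v0^2 * 1e3   # mW
  errs <- vapply(c(2.4, 1.2, 0.6), function(h) {
    pt <- suppressWarnings(poiseuille_tube(5, v0, 40, axis = "z", spacing = h))
    el <- viscous_energy_loss(pt$ds, pt$mask)$vel$values[1]
    abs(el - expected) / expected
  }, 0)
  expect_true(all(diff(errs) < 0))
  # at a well-resolved wall (20 voxels per diameter) the closed form is met
  pt <- poiseuille_tube(5, v0, 40, axis = "z", spacing = 0.5)
  el <- viscous_energy_loss(pt$ds, pt$mask)$vel$values[1]
  expect_lt(abs(el - expected) / expected, 0.05)
})

test_that("KE matches the closed form and scales quadratically", {
  # uniform 0.5 m/s over 10^-4 m^3 at rho = 1060 -> 13.25 mJ
  n <- 10                                  # 1000 voxels of 10^-7 m^3 each
  vel <- array(0, c(1, n, n, n, 3)); vel[, , , , 3] <- 0.5
  spacing <- rep((1e-4 / 1000)^(1 / 3) * 1e3, 3)   # 1000 voxels totalling 1e-4 m^3
  ds <- make_ds(vel, spacing = spacing)
  mask <- full_mask(c(n, n, n), spacing)
  ke <- kinetic_energy(ds, mask)
  expect_equal(ke$ke$values[1], 13.25, tolerance = 1e-9)
  expect_equal(ke$ke_per_volume$values[1], 13.25 / 100, tolerance = 1e-9) # 100 ml
  # zero field and quadratic scaling
  expect_equal(kinetic_energy(make_ds(array(0, c(1, n, n, n, 3)), spacing),
                              mask)$ke$values, 0)
  ds2 <- make_ds(2 * vel, spacing = spacing)
  expect_equal(kinetic_energy(ds2, mask)$ke$values, 4 * ke$ke$values)
})

test_that("KE/VEL ratio divides elementwise and flags undefined entries", {
  ke <- flow_ts("KE", c(0, 0.5), c(2, 4), "mJ")
  vel <- flow_ts("VEL", c(0, 0.5), c(1, 2), "mW")
  r <- ke_vel_ratio(ke, vel)
  expect_equal(r$values, c(2, 2))
  vel0 <- flow_ts("VEL", c(0, 0.5), c(0, 0), "mW")
  r0 <- ke_vel_ratio(ke, vel0)
  expect_true(all(is.na(r0$values)))
  expect_true(all(attr(r0, "undefined")))
  expect_error(ke_vel_ratio(ke, flow_ts("VEL", c(0, 0.4), c(1, 2), "mW")),
               "time base")
})

test_that("velocity scaling laws: omega ~ a, Q/KE/VEL ~ a^2, KE/VEL invariant", {
  lo <- lamb_oseen(0.01, 6, shape = c(12, 32, 32), spacing = 1.2)
  base <- list(w = vorticity(lo$ds, lo$mask)$series$values[1],
               q = q_criterion(lo$ds, lo$mask)$field[1, 6, 16, 16],
               ke = kinetic_energy(lo$ds, lo$mask)$ke$values[1],
               el = viscous_energy_loss(lo$ds, lo$mask)$vel$values[1])
  for (a in c(0.5, 2)) {
    ds_a <- lo$ds; ds_a$velocity <- a * ds_a$velocity
    expect_equal(vorticity(ds_a, lo$mask)$series$values[1], a * base$w,
                 tolerance = 1e-10)
    expect_equal(q_criterion(ds_a, lo$mask)$field[1, 6, 16, 16], a^2 * base$q,
                 tolerance = 1e-10)
    ke_a <- kinetic_energy(ds_a, lo$mask)$ke$values[1]
    el_a <- viscous_energy_loss(ds_a, lo$mask)$vel$values[1]
    expect_equal(ke_a, a^2 * base$ke, tolerance = 1e-10)
    expect_equal(el_a, a^2 * base$el, tolerance = 1e-10)
    expect_equal(ke_a / el_a, base$ke / base$el, tolerance = 1e-10)
  }
})

test_that("median filter: constants unchanged, impulses removed, ramps preserved, matches brute force", {
  cf <- array(2.5, c(5, 5, 5))
  expect_equal(median_filter3(cf), cf)
  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 10
  expect_true(all(median_filter3(imp) == 0))
  co <- laflow:::grid_coords(c(6, 6, 6), c(1, 1, 1), c(0, 0, 0))
  ramp <- co$x + 2 * co$y + 3 * co$z
  filt <- median_filter3(ramp)
  expect_equal(filt[2:5, 2:5, 2:5], ramp[2:5, 2:5, 2:5])
  set.seed(9)
  f <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(median_filter3(f), naive_median3(f))
})
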