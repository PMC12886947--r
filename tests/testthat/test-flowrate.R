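# Cross-section geometry, flux fidelity and wave-feature detection.

test_that("plane normal follows the dominant flow direction", {
  pt <- poiseuille_tube(5, 0.4, 40, axis = "z", spacing = 0.8, n_phases = 10)
  seed <- sphere_seed("RS", c(0, 0, 0), 4)
  expect_equal(plane_normal_from_flow(pt$ds, seed), c(0, 0, 1), tolerance = 1e-6)
  # top-5 ranking: strong +z at phases 1-5, weak -z at phases 6-10
  ds <- pt$ds
  for (t in 6:10) ds$velocity[t, , , , 3] <- -0.1 * ds$velocity[t, , , , 3]
  expect_equal(plane_normal_from_flow(ds, seed), c(0, 0, 1), tolerance = 1e-6)
  # with N = 3 phases all are averaged
  pt3 <- poiseuille_tube(5, 0.4, 40, axis = "z", spacing = 0.8, n_phases = 3)
  expect_equal(plane_normal_from_flow(pt3$ds, seed), c(0, 0, 1), tolerance = 1e-6)
  # all-zero sphere region errors
  far <- sphere_seed("LS", c(7.5, 7.5, 15), 1.5)
  expect_error(plane_normal_from_flow(pt$ds, far), "nonzero")
})

test_that("cross-section lumen area matches disc and oblique-ellipse oracles", {
  pt <- poiseuille_tube(5, 0.4, 60, axis = "z", spacing = 0.8)
  seed <- sphere_seed("RS", c(0, 0, 0), 4)
  cs <- extract_cross_section(pt$mask, "LA", seed, c(0, 0, 1))
  expect_lt(abs(cross_section_area(cs) - pi * 25) / (pi * 25), 0.03)
  th <- 60 * pi / 180
  cs60 <- extract_cross_section(pt$mask, "LA", seed, c(sin(th), 0, cos(th)))
  expect_lt(abs(cross_section_area(cs60) - pi * 25 / cos(th)) / (pi * 25 / cos(th)),
            0.03)
})

test_that("the lumen is restricted to the seed's connected component", {
  # two parallel tubes along z, 20 mm apart
  n <- c(20, 20, 41)                       # (z, y, x) at 1 mm
  co <- laflow:::grid_coords(n, c(1, 1, 1), c(-20, -10, -10))
  lab <- array(0L, n)
  lab[(co$x + 10)^2 + co$y^2 <= 16 | (co$x - 10)^2 + co$y^2 <= 16] <- 1L
  mask <- mask3d(lab, c(LA = 1L), c(1, 1, 1), c(-20, -10, -10))
  seed <- sphere_seed("RS", c(-10, 0, 0), 8)   # extent 24 mm reaches both tubes
  cs <- extract_cross_section(mask, "LA", seed, c(0, 0, 1))
  expect_true(all(cs$points[, 1] < 0))     # only the seeded tube
  expect_lt(abs(cross_section_area(cs) - pi * 16) / (pi * 16), 0.1)
  bad <- sphere_seed("LS", c(0, 0, 0), 8)  # centered between the tubes
  expect_error(extract_cross_section(mask, "LA", bad, c(0, 0, 1)), "reposition")
})

test_that("flow rate recovers the Poiseuille mean-velocity closed form", {
  pt <- poiseuille_tube(5, 0.4, 40, axis = "z", spacing = 0.8)
  seed <- sphere_seed("RS", c(0, 0, 0), 4)
  cs <- extract_cross_section(pt$mask, "LA", seed, c(0, 0, 1))
  q <- flow_rate(pt$ds, cs)
  expect_lt(abs(q$values[1] - pi * 25 * 0.4 / 2) / (pi * 25 * 0.4 / 2), 0.03)
  expect_equal(q$units, "ml/s")
  # zero field -> zero series
  ds0 <- make_ds(array(0, dim(pt$ds$velocity)), spacing = pt$ds$spacing,
                 origin = pt$ds$origin)
  expect_equal(flow_rate(ds0, cs)$values, rep(0, 1))
})

test_that("flux is invariant to plane obliquity and position along the tube", {
  pt <- poiseuille_tube(5, 0.4, 60, axis = "z", spacing = 0.8)
  # uniform axial plug flow in the same lumen
  plug <- pt$ds
  plug$velocity[1, , , , 3] <- 0.3 * (pt$mask$labels == 1L)
  seed <- sphere_seed("RS", c(0, 0, 0), 4)
  th <- 60 * pi / 180
  cs0 <- extract_cross_section(pt$mask, "LA", seed, c(0, 0, 1))
  cs60 <- extract_cross_section(pt$mask, "LA", seed, c(sin(th), 0, cos(th)))
  q0 <- flow_rate(plug, cs0)$values[1]
  q60 <- flow_rate(plug, cs60)$values[1]
  expect_lt(abs(q60 - q0) / q0, 0.03)
  # parabolic flow through two parallel planes 14 mm apart
  s2 <- sphere_seed("RI", c(0, 0, 14), 4)
  cs2 <- extract_cross_section(pt$mask, "LA", s2, c(0, 0, 1))
  qa <- flow_rate(pt$ds, cs0)$values[1]
  qb <- flow_rate(pt$ds, cs2)$values[1]
  expect_lt(abs(qa - qb) / qa, 0.02)
})

test_that("PV wave detection finds the generator peaks and scales correctly", {
  tt <- seq(0, 0.95, by = 0.05)
  pv <- flow_ts("pv", tt, gaussian_pulse_waveform(
    tt, c(100, 80, -30), c(0.15, 0.55, 0.90), c(0.05, 0.06, 0.04)), "ml/s")
  mv <- flow_ts("mv", tt, gaussian_pulse_waveform(
    tt, c(300, 150), c(0.60, 0.90), c(0.06, 0.04)), "ml/s")
  w <- detect_pv_waves(pv, mv)
  expect_equal(w$S_peak, 100, tolerance = 0.01)
  expect_equal(w$D_peak, 80, tolerance = 0.01)
  expect_equal(w$Ar_peak, -30, tolerance = 0.01)
  expect_equal(w$SD_ratio, 1.25, tolerance = 0.01)
  expect_false(w$no_reversal)
  # scale equivariance
  pv2 <- flow_ts("pv", tt, 2 * pv$values, "ml/s")
  w2 <- detect_pv_waves(pv2, mv)
  expect_equal(w2$S_peak, 2 * w$S_peak)
  expect_equal(w2$SD_ratio, w$SD_ratio)
  # no negative excursion -> flagged, Ar is the window minimum
  pv3 <- flow_ts("pv", tt, pmax(pv$values, 0), "ml/s")
  w3 <- detect_pv_waves(pv3, mv)
  expect_true(w3$no_reversal)
  expect_gte(w3$Ar_peak, 0)
  # a dead MV curve cannot phase the cycle
  expect_error(detect_pv_waves(pv, flow_ts("mv", tt, rep(0, length(tt)), "ml/s")),
               "zero")
})

test_that("MV wave detection recovers peaks and volumes of separated triangles", {
  dt <- 0.005
  tt <- seq(0, 1 - dt, by = dt)
  tri <- function(t, center, half, peak) {
    pmax(0, peak * (1 - abs(t - center) / half))
  }
  # areas: 200 * 0.2 = 40 ml and 120 * 1/6 = 20 ml
  v <- tri(tt, 0.45, 0.2, 200) + tri(tt, 0.85, 1 / 6, 120)
  q <- flow_ts("mv", tt, v, "ml/s")
  w <- detect_mv_waves(q)
  expect_equal(w$E_peak, 200, tolerance = 0.01)
  expect_equal(w$A_peak, 120, tolerance = 0.01)
  expect_equal(w$EA_peak, 5 / 3, tolerance = 0.01)
  expect_equal(w$passive_volume_ml, 40, tolerance = 0.02)
  expect_equal(w$active_volume_ml, 20, tolerance = 0.02)
  expect_equal(w$EA_volume, 2.0, tolerance = 0.03)
  expect_false(w$fusion)
  # mirrored amplitudes invert the peak ratio
  v_m <- tri(tt, 0.45, 0.2, 120) + tri(tt, 0.85, 1 / 6, 200)
  w_m <- detect_mv_waves(flow_ts("mv", tt, v_m, "ml/s"))
  expect_equal(w_m$EA_peak, 1 / (200 / 120), tolerance = 0.01)
  # single pulse -> absent A flagged
  w1 <- detect_mv_waves(flow_ts("mv", tt, tri(tt, 0.5, 0.2, 200), "ml/s"))
  expect_true(w1$a_absent)
  expect_true(is.na(w1$EA_peak))
  expect_error(detect_mv_waves(flow_ts("mv", tt, rep(-1, length(tt)), "ml/s")),
               "positive")
})

test_that("peak detection is invariant to cyclic time shifts of the curve set", {
  tt <- seq(0, 0.95, by = 0.05)
  pvv <- gaussian_pulse_waveform(tt, c(100, 80, -30), c(0.15, 0.55, 0.90),
                                 c(0.05, 0.06, 0.04))
  mvv <- gaussian_pulse_waveform(tt, c(300, 150), c(0.60, 0.90), c(0.06, 0.04))
  base <- detect_pv_waves(flow_ts("pv", tt, pvv, "ml/s"),
                          flow_ts("mv", tt, mvv, "ml/s"))
  sh <- 3   # shift by 3 samples, cyclically
  rot <- function(x) c(x[-(seq_len(sh))], x[seq_len(sh)])
  shifted <- detect_pv_waves(flow_ts("pv", tt, rot(pvv), "ml/s"),
                             flow_ts("mv", tt, rot(mvv), "ml/s"))
  expect_equal(shifted$S_peak, base$S_peak)
  expect_equal(shifted$D_peak, base$D_peak)
  expect_equal(shifted$SD_ratio, base$SD_ratio)
})
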