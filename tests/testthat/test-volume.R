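# Volumetrics, biplane comparator, agreement and overlap metrics.

test_that("mask volume: exact cube, digitized ellipsoid, empty warning", {
  lab <- array(0L, c(12, 12, 12)); lab[2:11, 2:11, 2:11] <- 1L
  m <- mask3d(lab, c(LA = 1L), c(1, 1, 1))
  expect_equal(mask_volume(m), 1.0)
  co <- laflow:::grid_coords(c(61, 51, 51), c(1, 1, 1), c(-25, -25, -30))
  lab2 <- array(0L, c(61, 51, 51))
  lab2[(co$x / 25)^2 + (co$y / 25)^2 + (co$z / 30)^2 <= 1] <- 1L
  m2 <- mask3d(lab2, c(LA = 1L), c(1, 1, 1), c(-25, -25, -30))
  vol_true <- 4 * pi * 30 * 25 * 25 / 3 * 1e-3
  expect_lt(abs(mask_volume(m2) - vol_true) / vol_true, 0.01)
  empty <- suppressWarnings(mask3d(array(0L, c(4, 4, 4)), c(LA = 1L), c(1, 1, 1)))
  expect_warning(v0 <- mask_volume(empty), "empty")
  expect_equal(v0, 0)
})

test_that("DuBois BSA and LAVi match direct formula evaluation", {
  expect_equal(bsa_dubois(70, 170), 0.007184 * 70^0.425 * 170^0.725,
               tolerance = 1e-15)
  lavi <- lav_indexed(90.5, 70, 170)
  expect_equal(lavi, 90.5 / bsa_dubois(70, 170), tolerance = 1e-12)
  expect_equal(lav_indexed(181, 70, 170), 2 * lavi)
  expect_error(lav_indexed(90, -1, 170), "positive")
  expect_error(lav_indexed(90, 70, 0), "positive")
})

test_that("biplane disk summation recovers sphere and cylinder volumes", {
  R <- 30; nd <- 20
  centers <- -R + (seq_len(nd) - 0.5) * (2 * R / nd)
  d <- 2 * sqrt(R^2 - centers^2)
  vol_true <- 4 / 3 * pi * R^3 * 1e-3
  expect_lt(abs(biplane_disk_volume(d, d, 2 * R) - vol_true) / vol_true, 0.01)
  # single disk of constant diameter = cylinder
  expect_equal(biplane_disk_volume(20, 20, 50), pi / 4 * 20 * 20 * 50 * 1e-3)
  expect_error(biplane_disk_volume(c(1, 2), c(1, 2, 3), 10), "length")
})

test_that("agreement handles identity, hand-computed LoA and anti-identity", {
  x <- c(10, 20, 30, 40, 50)
  a <- agreement(x, x)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$bias, 0)
  expect_equal(c(a$loa_low, a$loa_high), c(0, 0))
  # differences {1,-1,0,2,-2}: sd = 1.5811, LoA = +-3.099
  y <- x + c(1, -1, 0, 2, -2)
  a2 <- agreement(x, y)
  expect_equal(a2$bias, 0)
  expect_equal(a2$loa_high, 1.96 * sd(c(1, -1, 0, 2, -2)), tolerance = 1e-12)
  expect_equal(a2$loa_high, 3.099, tolerance = 1e-3)
  a3 <- agreement(x, -x)
  expect_equal(a3$pearson_r, -1)
  expect_warning(a4 <- agreement(rep(1, 5), c(1, 2, 3, 4, 5)), "variance")
  expect_false(a4$r_defined)
})

test_that("agreement recovers injected bias and noise on simulated pairs", {
  set.seed(42)
  b <- 5; sigma <- 3
  x <- rnorm(200, 60, 15)
  y <- x + b + rnorm(200, 0, sigma)
  a <- agreement(x, y)
  expect_lt(abs(a$bias - b), 0.2 * sigma)
  half <- (a$loa_high - a$loa_low) / 2
  expect_lt(abs(half - 1.96 * sigma) / (1.96 * sigma), 0.10)
})

test_that("Dice matches brute-force counts and its boundary conventions", {
  la <- array(0L, c(8, 8, 8)); la[2:3, 2:3, 2:3] <- 1L   # 8 voxels
  lb <- array(0L, c(8, 8, 8)); lb[2:3, 2:3, 3:4] <- 1L   # overlap 4
  ma <- mask3d(la, c(LA = 1L), c(1, 1, 1))
  mb <- mask3d(lb, c(LA = 1L), c(1, 1, 1))
  expect_equal(dice(ma, mb), 2 * 4 / 16)
  expect_equal(dice(ma, mb), dice(mb, ma))
  expect_equal(dice(ma, ma), 1.0)
  lc <- array(0L, c(8, 8, 8)); lc[6:7, 6:7, 6:7] <- 1L
  expect_equal(dice(ma, mask3d(lc, c(LA = 1L), c(1, 1, 1))), 0.0)
  e <- suppressWarnings(mask3d(array(0L, c(8, 8, 8)), c(LA = 1L), c(1, 1, 1)))
  expect_warning(d1 <- dice(e, e), "empty")
  expect_equal(d1, 1)
})

test_that("HD95 matches the brute-force oracle and known shifts", {
  la <- array(0L, c(10, 10, 10)); la[3:6, 3:6, 3:6] <- 1L
  lb <- array(0L, c(10, 10, 10)); lb[3:6, 3:6, 4:7] <- 1L
  ma <- mask3d(la, c(LA = 1L), c(1, 1, 1))
  mb <- mask3d(lb, c(LA = 1L), c(1, 1, 1))
  expect_equal(hd95(ma, ma), 0)
  expect_equal(hd95(ma, mb), 1.0)
  expect_equal(hd95(ma, mb), naive_hd95(ma, mb))
  expect_equal(hd95(ma, mb), hd95(mb, ma))
  # random blobs vs oracle on a small grid
  set.seed(5)
  lr <- array(as.integer(runif(6^3) > 0.5), c(6, 6, 6))
  ls <- array(as.integer(runif(6^3) > 0.5), c(6, 6, 6))
  mr <- mask3d(lr, c(LA = 1L), c(1.2, 1.1, 0.9))
  ms <- mask3d(ls, c(LA = 1L), c(1.2, 1.1, 0.9))
  expect_equal(hd95(mr, ms), naive_hd95(mr, ms))
  # shrinking one cube by shells increases HD95 monotonically
  shells <- vapply(0:2, function(s) {
    lk <- array(0L, c(12, 12, 12))
    lk[(3 + s):(10 - s), (3 + s):(10 - s), (3 + s):(10 - s)] <- 1L
    big <- array(0L, c(12, 12, 12)); big[3:10, 3:10, 3:10] <- 1L
    hd95(mask3d(big, c(LA = 1L), c(1, 1, 1)), mask3d(lk, c(LA = 1L), c(1, 1, 1)))
  }, 0)
  expect_true(all(diff(shells) > 0))
  e <- suppressWarnings(mask3d(array(0L, c(10, 10, 10)), c(LA = 1L), c(1, 1, 1)))
  expect_error(hd95(ma, e), "empty")
})
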