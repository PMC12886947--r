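# Cohort statistics: ANCOVA, Tukey/Cohen post hoc, BH correction.

make_table <- function(values, groups, ages) {
  cohort_table(seq_along(values), groups, ages, "f", values)
}

test_that("ANCOVA agrees with car type-II and reduces to one-way ANOVA", {
  set.seed(21)
  g <- rep(c("A", "B", "C"), each = 8)
  age <- runif(24, 35, 75)
  val <- rnorm(24) + 0.8 * (g == "C")
  tb <- make_table(val, g, age)
  res <- ancova(tb, "f")
  fit <- lm(value ~ age + group, data = data.frame(value = val, age = age,
                                                   group = factor(g)))
  ca <- car::Anova(fit, type = 2)
  expect_equal(res$F, ca["group", "F value"], tolerance = 1e-12)
  expect_equal(res$p, ca["group", "Pr(>F)"], tolerance = 1e-12)
  # a covariate orthogonal to group and value has an exactly-zero fitted
  # effect, so the ANCOVA F equals the one-way ANOVA F up to the residual-df
  # correction
  M <- cbind(model.matrix(~ factor(g)), val)
  age0 <- residuals(lm(runif(24, 35, 75) ~ M - 1))
  a0 <- ancova(make_table(val, g, 50 + age0), "f")
  f_anova <- anova(lm(val ~ factor(g)))["factor(g)", "F value"]
  n <- 24; k <- 3
  expect_equal(a0$F, f_anova * (n - k - 1) / (n - k), tolerance = 1e-8)
})

test_that("the covariate absorbs a feature that tracks age", {
  # feature = age (plus a deterministic ripple): the group term explains
  # nothing beyond the covariate under equal group-age distributions
  age <- rep(c(38, 42, 47, 53, 58, 64), 2)   # identical ages per group
  g <- rep(c("A", "B"), each = 6)
  val <- age + 0.01 * sin(seq_len(12))
  res <- ancova(make_table(val, g, age), "f")
  ref <- car::Anova(lm(val ~ age + group,
                       data = data.frame(val, age, group = factor(g))), type = 2)
  expect_equal(res$p, ref["group", "Pr(>F)"], tolerance = 1e-10)
  expect_gt(res$p, 0.1)
  expect_lt(res$eta2_partial, 0.25)
})

test_that("type-I error and power are calibrated", {
  set.seed(23)
  rej <- replicate(400, {
    g <- rep(c("A", "B"), each = 20)
    age <- runif(40, 30, 70)
    ancova(make_table(rnorm(40), g, age), "f")$p < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
  set.seed(24)
  pow <- replicate(100, {
    g <- rep(c("A", "B"), each = 20)
    age <- runif(40, 30, 70)
    ancova(make_table(rnorm(40) + 3 * (g == "B"), g, age), "f")$p < 0.05
  })
  expect_gt(mean(pow), 0.99)
})

test_that("Tukey on adjusted means matches multcomp and gates on significance", {
  set.seed(25)
  g <- rep(c("A", "B", "C"), each = 10)
  age <- runif(30, 40, 60)
  val <- rnorm(30) + 2.5 * (g == "B")
  d <- data.frame(value = val, age = age, group = factor(g))
  mine <- tukey_cohen(d)
  fit <- lm(value ~ age + group, data = d)
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey")))
  expect_equal(as.numeric(mine$diff_adjusted), as.numeric(gl$test$coefficients),
               tolerance = 1e-10)
  expect_equal(as.numeric(mine$p_tukey), as.numeric(gl$test$pvalues),
               tolerance = 2e-3)
  # only the shifted group's pairs flagged
  expect_true(all((mine$p_tukey < 0.05) == grepl("B", mine$pair)))
  # gate: identical groups produce no post hoc
  tb_null <- make_table(rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 2),
                        rep(c("A", "B"), each = 5), rep(50, 10) + rnorm(10, 0, 5))
  res_null <- ancova(tb_null, "f")
  expect_false(res_null$gate_passed && !is.null(res_null$posthoc))
})

test_that("Cohen's d uses the pooled SD convention", {
  expect_equal(cohen_d(c(1, 2, 3), c(3, 4, 5)), 2.0)
  expect_equal(cohen_d(c(1, 2, 3), c(1, 2, 3)), 0)
  d <- tukey_cohen(data.frame(value = c(1, 2, 3, 3, 4, 5), age = rep(50, 6) + (1:6) / 10,
                              group = factor(rep(c("A", "B"), each = 3))))
  expect_equal(d$cohen_d_raw, 2.0)
})

test_that("BH adjustment reproduces the hand-computed step-up and its invariances", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  set.seed(26)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))           # monotone in sorted order
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), adj[perm])               # permutation-equivariant
})

test_that("cohort_table and ancova enforce their contracts", {
  expect_error(ancova(make_table(1:6, rep("A", 6), runif(6)), "f"), "2 groups")
  expect_error(ancova(make_table(1:5, c("A", "A", "A", "B", "B"), runif(5)), "f"),
               "subjects")
  expect_error(ancova(make_table(1:6, rep(c("A", "B"), 3), runif(6)), "g"),
               "no rows")
})
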