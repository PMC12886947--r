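# Cohort comparison layer: age-adjusted ANCOVA with partial eta^2, gated
# Tukey post hoc on adjusted means, Cohen's d on raw values and
# Benjamini-Hochberg correction.

#' Assemble a cohort feature table
#'
#' @param subject,group,age,feature,value equal-length vectors: subject id,
#'   group label, age in years, feature name, feature value.
#' @return a `data.frame` with those columns (class `cohort_table`).
#' @export
cohort_table <- function(subject, group, age, feature, value) {
  check(all(is.finite(age)), "ages must be finite")
  out <- data.frame(subject = as.character(subject), group = as.character(group),
                    age = as.numeric(age), feature = as.character(feature),
                    value = as.numeric(value), stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Age-adjusted group comparison (ANCOVA)
#'
#' Fits `value ~ age + group` (homogeneous slopes), tests the group factor
#' with the covariate partialled out, and reports partial
#' eta^2 = SS_group / (SS_group + SS_residual). When the group effect is
#' significant at `alpha`, a pairwise Tukey post hoc on the covariate-adjusted
#' means is run with Cohen's d effect sizes and Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param table a [cohort_table()].
#' @param feature feature name to test.
#' @param alpha significance gate for the post hoc (default 0.05).
#' @param min_per_group minimum subjects per group (default 3).
#' @return an `ancova_result`: list with `feature`, `F`, `p`, `eta2_partial`,
#'   `df`, `gate_passed`, and `posthoc` (data frame or NULL).
#' @export
ancova <- function(table, feature, alpha = 0.05, min_per_group = 3L) {
  d <- table[table$feature == feature & is.finite(table$value), , drop = FALSE]
  check(nrow(d) > 0, "no rows for feature '%s'", feature)
  d$group <- factor(d$group)
  sizes <- table(d$group)
  check(length(sizes) >= 2L, "need at least 2 groups (feature '%s')", feature)
  check(all(sizes >= min_per_group),
        "every group needs >= %d subjects (feature '%s')", min_per_group, feature)
  fit <- lm(value ~ age + group, data = d)
  check(all(is.finite(coef(fit))), "singular design for feature '%s'", feature)
  an <- anova(fit)                       # sequential; group entered last
  ss_g <- an["group", "Sum Sq"]
  ss_r <- an["Residuals", "Sum Sq"]
  Fv <- an["group", "F value"]
  p <- an["group", "Pr(>F)"]
  res <- list(feature = feature, F = Fv, p = p,
              eta2_partial = ss_g / (ss_g + ss_r),
              df = c(an["group", "Df"], an["Residuals", "Df"]),
              gate_passed = is.finite(p) && p < alpha,
              posthoc = NULL)
  if (res$gate_passed) res$posthoc <- tukey_cohen(d, fit)
  class(res) <- "ancova_result"
  res
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA '%s': F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$feature, x$df[1], x$df[2], x$F, x$p, x$eta2_partial))
  if (!is.null(x$posthoc)) print(x$posthoc)
  else cat("  (group effect not significant; no post hoc)\n")
  invisible(x)
}

#' Tukey post hoc on covariate-adjusted means with Cohen's d
#'
#' Pairwise comparisons of the ANCOVA-adjusted group means (the group
#' coefficients of `value ~ age + group`), with p-values from the studentized
#' range distribution on the model residual df. Cohen's d uses the raw group
#' values and the pooled SD (unadjusted convention, labeled as such).
#' Benjamini-Hochberg adjusted p-values are appended over the pairwise family.
#'
#' @param d data frame with `value`, `age`, `group` (factor) columns.
#' @param fit optional pre-fitted `lm(value ~ age + group)` on `d`.
#' @return data frame: `pair`, `diff_adjusted`, `se`, `p_tukey`, `p_bh`,
#'   `cohen_d_raw`.
#' @export
tukey_cohen <- function(d, fit = NULL) {
  d$group <- factor(d$group)
  lev <- levels(d$group)
  check(length(lev) >= 2L, "need at least 2 groups")
  if (is.null(fit)) fit <- lm(value ~ age + group, data = d)
  cf <- coef(fit)
  V <- vcov(fit)
  df_res <- fit$df.residual
  k <- length(lev)
  # adjusted mean offset of each level relative to the reference level
  coef_of <- function(g) if (g == lev[1]) 0 else cf[[paste0("group", g)]]
  var_of <- function(g1, g2) {
    # Var(adjusted difference g2 - g1) from the coefficient covariance
    n1 <- paste0("group", g1); n2 <- paste0("group", g2)
    if (g1 == lev[1]) V[n2, n2]
    else if (g2 == lev[1]) V[n1, n1]
    else V[n1, n1] + V[n2, n2] - 2 * V[n1, n2]
  }
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    g1 <- lev[i]; g2 <- lev[j]
    diff <- coef_of(g2) - coef_of(g1)
    se <- sqrt(var_of(g1, g2))
    q <- sqrt(2) * abs(diff) / se
    p <- ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
    v1 <- d$value[d$group == g1]; v2 <- d$value[d$group == g2]
    sp <- sqrt(((length(v1) - 1) * var(v1) + (length(v2) - 1) * var(v2)) /
                 (length(v1) + length(v2) - 2))
    dd <- if (sp > 0) (mean(v2) - mean(v1)) / sp else 0
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(g1, "vs", g2), diff_adjusted = diff, se = se,
      p_tukey = p, cohen_d_raw = dd, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p_tukey)
  out[, c("pair", "diff_adjusted", "se", "p_tukey", "p_bh", "cohen_d_raw")]
}

#' Cohen's d with pooled SD
#'
#' @param x,y raw values of the two groups.
#' @return (mean(y) - mean(x)) / pooled SD.
#' @export
cohen_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(y) - mean(x)) / sp
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving, outputs capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")
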