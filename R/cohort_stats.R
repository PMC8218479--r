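#' Two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t-test (default) or the pooled-variance Student
#' test, computed from per-group mean, SD and n — the form needed when only
#' a cohort table's summaries are available.
#'
#' @param mean_a,sd_a,n_a summary of group A.
#' @param mean_b,sd_b,n_b summary of group B.
#' @param pooled use the pooled-variance test instead of Welch.
#' @return list with `t`, `df`, `p` (two-sided). Zero variance in both
#'   groups with equal means yields `NA` flagged `undefined = TRUE`.
#' @export
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, pooled = FALSE) {
  if (sd_a < 0 || sd_b < 0) stop("SDs must be >= 0")
  if (n_a <= 1 || n_b <= 1) stop("need n > 1 per group")
  if (sd_a == 0 && sd_b == 0 && mean_a == mean_b)
    return(structure(list(t = NA_real_, df = NA_real_, p = NA_real_),
                     undefined = TRUE))
  if (pooled) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    t <- (mean_a - mean_b) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Chi-squared test for two proportions
#'
#' 2x2 Pearson chi-squared on count/non-count, 1 df, no continuity
#' correction; two-sided p.
#'
#' @param count_a,n_a successes and total in group A.
#' @param count_b,n_b successes and total in group B.
#' @return list with `statistic` and `p`; degenerate margins give `NA`
#'   flagged `undefined = TRUE`.
#' @export
chi2_proportions <- function(count_a, n_a, count_b, n_b) {
  if (count_a > n_a || count_b > n_b || min(count_a, count_b) < 0)
    stop("counts must lie in [0, n]")
  compare_accuracy_chi2(count_a, n_a, count_b, n_b)
}

#' Covariate-adjusted group comparison of a feature
#'
#' Least-squares linear model `feature ~ group + covariates`; reports the
#' partial (type III for this single term) F-test of the group indicator
#' given the covariates and the adjusted group effect (the group
#' coefficient, i.e. the covariate-adjusted mean difference).
#'
#' @param feature numeric response (e.g. gp_norm).
#' @param group two-level grouping vector; the effect is reported for the
#'   second level relative to the first (levels sorted unless a factor).
#' @param covariates optional data frame or matrix of numeric covariates
#'   (e.g. age, sex indicator, gestational age, PMA).
#' @return list with `F`, `df` (c(1, residual df)), `p`, and
#'   `adjusted_effect`.
#' @export
adjusted_group_test <- function(feature, group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  df <- data.frame(.y = as.numeric(feature), .g = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  full <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(full))))
    stop("collinearity error: design matrix is rank deficient")
  reduced <- stats::lm(.y ~ . - .g, data = df)
  an <- stats::anova(reduced, full)
  list(F = an$F[2], df = c(an$Df[2], an$Res.Df[2]), p = an$`Pr(>F)`[2],
       adjusted_effect = unname(stats::coef(full)[paste0(".g",
                                                         levels(group)[2])]))
}

#' Cohort-table group comparisons
#'
#' Reproduces the clinical Table-1 analysis on a cohort data frame: group
#' means +/- SD per continuous covariate with a two-sample t-test, and the
#' sex distribution with a 2x2 chi-squared test.
#'
#' @param records cohort data frame from [sample_cohort()] (needs `group`,
#'   `sex`, and the continuous covariate columns).
#' @param covariates character vector of continuous covariate columns.
#' @param pooled passed to [welch_t()].
#' @return data frame: one row per covariate (plus `sex_male`) with group
#'   summaries and the p-value.
#' @export
cohort_table_tests <- function(records,
                               covariates = c("age_days", "weight_kg",
                                              "gestational_age_weeks",
                                              "tsb_umol_per_l",
                                              "albumin_g_per_l"),
                               pooled = FALSE) {
  g <- records$group == "ABE"
  rows <- lapply(covariates, function(v) {
    x <- records[[v]]
    tt <- welch_t(mean(x[g]), stats::sd(x[g]), sum(g),
                  mean(x[!g]), stats::sd(x[!g]), sum(!g), pooled = pooled)
    data.frame(feature = v,
               abe = sprintf("%.2f ± %.2f", mean(x[g]), stats::sd(x[g])),
               non_abe = sprintf("%.2f ± %.2f", mean(x[!g]),
                                 stats::sd(x[!g])),
               p = tt$p)
  })
  male <- chi2_proportions(sum(records$sex[g] == "M"), sum(g),
                           sum(records$sex[!g] == "M"), sum(!g))
  rows <- c(rows, list(data.frame(
    feature = "sex_male",
    abe = sprintf("%d/%d", sum(records$sex[g] == "M"), sum(g)),
    non_abe = sprintf("%d/%d", sum(records$sex[!g] == "M"), sum(!g)),
    p = male$p)))
  do.call(rbind, rows)
}
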