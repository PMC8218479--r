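#' Confusion matrix for a two-class diagnostic problem
#'
#' Counts true/false positives and negatives with ABE as the positive class.
#'
#' @param predicted,truth equal-length label vectors over the two-level set
#'   `{positive, negative}`.
#' @param positive,negative the two admissible labels.
#' @return Object of class `confusion_matrix`: list with integer `tp`, `fp`,
#'   `fn`, `tn` and the `positive` label.
#' @export
confusion <- function(predicted, truth, positive = "ABE",
                      negative = "non-ABE") {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  ok <- c(positive, negative)
  bad <- setdiff(unique(c(predicted, truth)), ok)
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  structure(list(
    tp = sum(predicted == positive & truth == positive),
    fp = sum(predicted == positive & truth == negative),
    fn = sum(predicted == negative & truth == positive),
    tn = sum(predicted == negative & truth == negative),
    positive = positive), class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts (positive class = ABE).
#' @param positive positive-class label.
#' @return `confusion_matrix` object.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, positive = "ABE") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  structure(c(as.list(counts), list(positive = positive)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c(x$positive, "other"),
                              truth = c(x$positive, "other")))
  print(m)
  invisible(x)
}

#' Diagnostic performance metrics
#'
#' Derives sensitivity, specificity, precision, F1, and accuracy from a 2x2
#' confusion matrix. Raw fractions are retained at full precision; the
#' `display` element carries the percentages under the clinical-table
#' convention: sensitivity and specificity rounded to one decimal in percent
#' (padded to two), precision/F1/accuracy to two decimals. Metrics with a
#' zero denominator are flagged as undefined (`NA` value, name recorded in
#' `undefined`) rather than silently zeroed.
#'
#' @param cm a `confusion_matrix`.
#' @return Object of class `metric_set`: list with `fractions` (named numeric,
#'   possibly `NA`), `display` (named character, percent strings), `undefined`
#'   (character vector of flagged metric names), and the source counts.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  fr <- c(sensitivity = safe(tp, tp + fn),
          specificity = safe(tn, tn + fp),
          precision   = safe(tp, tp + fp))
  f1 <- if (!is.na(fr["precision"]) && !is.na(fr["sensitivity"]) &&
            (fr["precision"] + fr["sensitivity"]) > 0)
    2 * fr[["precision"]] * fr[["sensitivity"]] /
      (fr[["precision"]] + fr[["sensitivity"]]) else NA_real_
  fr <- c(fr, f1 = f1, accuracy = safe(tp + tn, total))
  structure(list(fractions = fr,
                 display = format_metric_percent(fr),
                 undefined = names(fr)[is.na(fr)],
                 counts = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "metric_set")
}

#' Format metric fractions as display percentages
#'
#' Clinical-table convention: sensitivity and specificity are shown at
#' one-decimal precision in percent, padded to two decimals (68.085\% prints
#' as "68.10\%"); precision, F1, accuracy and AUC at two decimals.
#'
#' @param fractions named numeric vector of metric fractions in \[0, 1\].
#' @return named character vector of percent strings ("NA" where undefined).
#' @export
format_metric_percent <- function(fractions) {
  one_dp <- c("sensitivity", "specificity")
  out <- vapply(seq_along(fractions), function(i) {
    v <- fractions[[i]]
    if (is.na(v)) return(NA_character_)
    nm <- names(fractions)[i]
    if (!is.null(nm) && nm %in% one_dp)
      sprintf("%.2f%%", round(100 * v, 1))
    else
      sprintf("%.2f%%", round(100 * v, 2))
  }, character(1))
  names(out) <- names(fractions)
  out
}

#' @export
print.metric_set <- function(x, ...) {
  shown <- ifelse(is.na(x$display), "undefined", x$display)
  cat(paste(sprintf("%-12s %s", names(x$fractions), shown), collapse = "\n"),
      "\n")
  if (length(x$undefined))
    cat("flagged undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate metric sets across raters or cross-validation folds
#'
#' @param sets list of at least two `metric_set` objects (or named numeric
#'   vectors of fractions) with identical metric availability.
#' @return data frame with one row per metric: `mean` and `sd` (sample SD,
#'   n-1 denominator) of the fractions.
#' @export
aggregate_metrics <- function(sets) {
  if (length(sets) < 2) stop("need at least two metric sets")
  rows <- lapply(sets, function(s) {
    if (inherits(s, "metric_set")) s$fractions else s
  })
  nm <- names(rows[[1]])
  if (!all(vapply(rows, function(r) identical(names(r), nm), TRUE)))
    stop("metric sets have mismatched metrics")
  av <- vapply(rows, function(r) is.na(r), logical(length(nm)))
  if (is.null(dim(av))) av <- matrix(av, nrow = length(nm))
  if (any(apply(av, 1, function(z) any(z) && !all(z))))
    stop("mismatched metric availability across sets")
  m <- do.call(rbind, rows)
  data.frame(metric = nm, mean = colMeans(m),
             sd = apply(m, 2, stats::sd), row.names = NULL)
}

#' Fleiss' kappa for inter-rater agreement
#'
#' Standard Fleiss formulation for a complete subjects x raters grid of
#' categorical ratings: per-subject agreement
#' `P_i = (sum_j n_ij^2 - r) / (r (r - 1))` for `r` raters, chance agreement
#' from the pooled category proportions, `kappa = (Pbar - Pe) / (1 - Pe)`.
#'
#' @param ratings matrix or data frame, rows = subjects, columns = raters,
#'   cells categorical (e.g. "ABE" / "non-ABE"). No missing cells; >= 2
#'   raters.
#' @return kappa in \[-1, 1\], or `NA` with attribute `undefined = TRUE`
#'   when every rating falls in one category (chance agreement = 1).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (ncol(ratings) < 2) stop("need at least 2 raters")
  if (any(is.na(ratings))) stop("ratings must be complete")
  cats <- sort(unique(as.vector(ratings)))
  r <- ncol(ratings)
  n <- nrow(ratings)
  counts <- t(apply(ratings, 1, function(row)
    vapply(cats, function(k) sum(row == k), 0)))
  if (length(cats) == 1) counts <- matrix(counts, ncol = 1)
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * r)
  p_e <- sum(p_j^2)
  if (1 - p_e == 0)
    return(structure(NA_real_, undefined = TRUE))
  (p_bar - p_e) / (1 - p_e)
}

#' Compare two classification accuracies by chi-squared test
#'
#' 2x2 Pearson chi-squared (no continuity correction, 1 df) on
#' correct/incorrect counts of two methods; two-sided p-value.
#'
#' @param correct_a,n_a correct count and total for method A.
#' @param correct_b,n_b correct count and total for method B.
#' @return list with `statistic` and `p`. Degenerate margins (all correct or
#'   all incorrect under both methods) give `NA` flagged with
#'   `undefined = TRUE`.
#' @export
compare_accuracy_chi2 <- function(correct_a, n_a, correct_b, n_b) {
  if (correct_a < 0 || correct_a > n_a || correct_b < 0 || correct_b > n_b)
    stop("correct counts must lie in [0, n]")
  tab <- matrix(c(correct_a, n_a - correct_a,
                  correct_b, n_b - correct_b), 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    return(structure(list(statistic = NA_real_, p = NA_real_),
                     undefined = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}
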