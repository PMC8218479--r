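#' Empirical ROC curve
#'
#' Builds the full receiver operating characteristic of a continuous score
#' against a two-level truth. Operating points are placed at every threshold
#' that can change the confusion matrix: the midpoints of adjacent distinct
#' sorted scores, plus sentinel thresholds below the minimum and above the
#' maximum score, so the curve always contains the (0,0) and (1,1) corners.
#' The decision rule is `score >= threshold` => positive; higher scores are
#' assumed to indicate disease (T1 hyperintensity).
#'
#' @param scores numeric vector of finite scores (e.g. GP_norm).
#' @param labels vector coercible to character with exactly two observed
#'   levels, one of which is `positive`.
#' @param positive label of the positive (diseased) class. Default `"ABE"`.
#' @return An object of class `roc_curve`: a data frame with columns
#'   `threshold` (descending), `sensitivity`, `specificity`, plus attributes
#'   `positive` and `n_pos`/`n_neg`.
#' @seealso [auc()], [youden_cutoff()], [classify_scores()]
#' @export
roc_curve <- function(scores, labels, positive = "ABE") {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  truth <- labels == positive
  if (!any(truth) || all(truth))
    stop("degenerate input: both classes must be present")

  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  # sentinels guarantee the all-positive and all-negative operating points
  thr <- sort(c(s[1] - 1, mids, s[length(s)] + 1), decreasing = TRUE)

  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  sens <- vapply(thr, function(t) sum(scores[truth] >= t) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores[!truth] < t) / n_neg, 0)

  out <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  structure(out, class = c("roc_curve", "data.frame"),
            positive = positive, n_pos = n_pos, n_neg = n_neg)
}

#' Area under an ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). For a curve built by
#' [roc_curve()] this equals the rank statistic
#' P(score_pos > score_neg) + 0.5 P(tie) computed by [auc_rank()].
#'
#' @param curve an object returned by [roc_curve()].
#' @return AUC as a fraction in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
}

#' Rank-based AUC (Mann-Whitney oracle)
#'
#' Brute force over every positive x negative score pair: a win scores 1, a
#' tie 0.5. Independent of the curve construction; used as an oracle against
#' the trapezoidal [auc()].
#'
#' @inheritParams roc_curve
#' @return AUC as a fraction in \[0, 1\].
#' @export
auc_rank <- function(scores, labels, positive = "ABE") {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (!length(pos) || !length(neg))
    stop("degenerate input: both classes must be present")
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

#' Youden-index optimal cutoff
#'
#' Finds the operating point maximizing J = sensitivity + specificity - 1.
#' Ties on J are broken by the smallest threshold, favoring sensitivity.
#'
#' @param curve an object returned by [roc_curve()].
#' @return An object of class `cutoff_result`: list with `cutoff`, `j`,
#'   `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.min(curve$threshold[best])]
  structure(list(cutoff = curve$threshold[pick], j = j[pick],
                 sensitivity = curve$sensitivity[pick],
                 specificity = curve$specificity[pick]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden-optimal cutoff: %.4f (J = %.4f; sens %.3f, spec %.3f)\n",
              x$cutoff, x$j, x$sensitivity, x$specificity))
  invisible(x)
}

#' Closed-form AUC for two normal score distributions
#'
#' For scores Normal(mu_pos, sd_pos) in the diseased group and
#' Normal(mu_neg, sd_neg) in the non-diseased group, the population AUC is
#' `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`. Serves as the
#' analytic oracle for Monte Carlo ROC experiments.
#'
#' @param mu_pos,sd_pos mean and SD of the positive-group scores.
#' @param mu_neg,sd_neg mean and SD of the negative-group scores.
#' @return AUC as a fraction.
#' @export
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (!is.finite(sd_pos) || !is.finite(sd_neg) || sd_pos <= 0 || sd_neg <= 0)
    stop("standard deviations must be positive")
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' Threshold classifier
#'
#' Applies the decision rule `score >= cutoff` => positive.
#'
#' @param scores numeric scores.
#' @param cutoff finite decision threshold.
#' @param positive,negative labels to emit.
#' @return character vector of predicted labels.
#' @export
classify_scores <- function(scores, cutoff, positive = "ABE",
                            negative = "non-ABE") {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  ifelse(as.numeric(scores) >= cutoff, positive, negative)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, ...) {
  fpr <- 1 - x$specificity
  if (!add) {
    plot(fpr, x$sensitivity, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "sensitivity", ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else {
    graphics::lines(fpr, x$sensitivity, ...)
  }
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d operating points, %d positive / %d negative (positive = %s)\n",
              nrow(x), attr(x, "n_pos"), attr(x, "n_neg"), attr(x, "positive")))
  cat(sprintf("AUC = %.4f\n", auc(x)))
  invisible(x)
}
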