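#' Fit a semi-quantitative threshold diagnostic model
#'
#' The core estimator of the package: given a per-subject normalized-intensity
#' score (such as GP_norm, the mean globus-pallidus T1 intensity divided by
#' the mean anterior subcortical white-matter intensity) and a two-level
#' diagnosis, it builds the empirical ROC curve, computes the trapezoidal
#' AUC, selects the Youden-index optimal cutoff, and evaluates the resulting
#' threshold classifier on the training cohort.
#'
#' @param formula a two-sided formula `label ~ score` naming one response
#'   (the diagnosis) and exactly one numeric score column.
#' @param data data frame containing the variables, e.g. a feature table from
#'   [build_feature_table()].
#' @param positive label of the diseased class. Default `"ABE"`.
#' @return An object of class `semiquant`: list with the fitted `cutoff`
#'   (a `cutoff_result`), `roc` (`roc_curve`), `auc`, apparent `confusion`
#'   and `metrics`, the group score summaries (`group_stats`), and the call.
#' @examples
#' set.seed(1)
#' d <- data.frame(
#'   gp_norm = c(rnorm(47, 1.39, 0.06), rnorm(32, 1.33, 0.06)),
#'   label = rep(c("ABE", "non-ABE"), c(47, 32)))
#' fit <- semiquant(label ~ gp_norm, d)
#' fit
#' predict(fit, newdata = data.frame(gp_norm = c(1.30, 1.40)))
#' @export
semiquant <- function(formula, data, positive = "ABE") {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2)
    stop("formula must be of the form label ~ score with a single score")
  labels <- as.character(mf[[1]])
  scores <- mf[[2]]
  if (!is.numeric(scores)) stop("score variable must be numeric")
  score_name <- names(mf)[2]
  negative <- setdiff(unique(labels), positive)
  if (length(negative) != 1)
    stop("labels must have exactly two levels, one of them '", positive, "'")

  roc <- roc_curve(scores, labels, positive = positive)
  cut <- youden_cutoff(roc)
  pred <- classify_scores(scores, cut$cutoff, positive = positive,
                          negative = negative)
  cm <- confusion(pred, labels, positive = positive, negative = negative)
  grp <- function(keep) c(n = sum(keep), mean = mean(scores[keep]),
                          sd = stats::sd(scores[keep]))
  structure(list(
    cutoff = cut, roc = roc, auc = auc(roc),
    confusion = cm, metrics = classification_metrics(cm),
    group_stats = rbind(positive = grp(labels == positive),
                        negative = grp(labels != positive)),
    score = score_name, positive = positive, negative = negative,
    training = data.frame(score = scores, label = labels),
    call = match.call()), class = "semiquant")
}

#' @export
print.semiquant <- function(x, ...) {
  cat("Semi-quantitative threshold diagnostic model\n")
  cat("  score:", x$score, "  positive class:", x$positive, "\n")
  cat(sprintf("  AUC = %.4f; Youden cutoff = %.4f (J = %.4f)\n",
              x$auc, x$cutoff$cutoff, x$cutoff$j))
  invisible(x)
}

#' @export
summary.semiquant <- function(object, ...) {
  structure(list(fit = object), class = "summary.semiquant")
}

#' @export
print.summary.semiquant <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nGroup score summaries:\n")
  print(round(f$group_stats, 4))
  cat("\nApparent performance at the fitted cutoff:\n")
  print(f$metrics)
  invisible(x)
}

#' @export
coef.semiquant <- function(object, ...) {
  c(cutoff = object$cutoff$cutoff, j = object$cutoff$j,
    auc = object$auc,
    sensitivity = object$cutoff$sensitivity,
    specificity = object$cutoff$specificity)
}

#' Predict diagnoses from a fitted semi-quantitative model
#'
#' @param object a `semiquant` fit.
#' @param newdata data frame containing the score column used in the fit;
#'   omitted => training data predictions.
#' @param type `"label"` for predicted classes, `"score"` to pass the scores
#'   through.
#' @param ... unused.
#' @export
predict.semiquant <- function(object, newdata = NULL, type = c("label", "score"),
                              ...) {
  type <- match.arg(type)
  scores <- if (is.null(newdata)) {
    object$training$score
  } else {
    if (!object$score %in% names(newdata))
      stop("newdata lacks score column '", object$score, "'")
    as.numeric(newdata[[object$score]])
  }
  if (type == "score") return(scores)
  classify_scores(scores, object$cutoff$cutoff,
                  positive = object$positive, negative = object$negative)
}

#' @export
plot.semiquant <- function(x, ...) {
  plot(x$roc, main = sprintf("%s: AUC = %.3f, cutoff = %.4f",
                             x$score, x$auc, x$cutoff$cutoff), ...)
  idx <- which.min(abs(x$roc$threshold - x$cutoff$cutoff))
  graphics::points(1 - x$roc$specificity[idx], x$roc$sensitivity[idx],
                   pch = 19, col = "red")
  invisible(x)
}

#' Simulate score cohorts from the fitted group distributions
#'
#' Draws new cohorts from normal distributions with the fitted per-group
#' means and SDs at the fitted group sizes — the binormal view of the score
#' underlying the ROC analysis.
#'
#' @param object a `semiquant` fit.
#' @param nsim number of replicate cohorts.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` data frames with the score column and `label`.
#' @export
simulate.semiquant <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  gs <- object$group_stats
  replicate(nsim, simplify = FALSE, {
    sc <- c(stats::rnorm(gs["positive", "n"], gs["positive", "mean"],
                         gs["positive", "sd"]),
            stats::rnorm(gs["negative", "n"], gs["negative", "mean"],
                         gs["negative", "sd"]))
    d <- data.frame(score = sc,
                    label = rep(c(object$positive, object$negative),
                                c(gs["positive", "n"], gs["negative", "n"])))
    names(d)[1] <- object$score
    d
  })
}
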