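# Agreement and validation statistics: Top-1 accuracy, Cohen's kappa
# with under/over-estimation rates, score-distribution means, group
# comparison, and ROC analysis with Youden cut-off selection.

#' Confusion matrix of reference vs predicted cleansing scores
#'
#' Rows are the reference (clinician) scores, columns the predicted
#' (algorithm) scores.
#'
#' @param reference,predicted Integer score vectors in 1..5, paired by
#'   frame.
#' @return A 5 x 5 integer matrix of counts.
#' @export
confusion_matrix <- function(reference, predicted) {
  reference <- validate_scores(reference)
  predicted <- validate_scores(predicted)
  if (length(reference) != length(predicted)) {
    stop_validation("reference and predicted must be the same length")
  }
  cm <- matrix(0L, 5L, 5L,
               dimnames = list(reference = paste0("S", 1:5),
                               predicted = paste0("S", 1:5)))
  for (i in seq_along(reference)) {
    cm[reference[i], predicted[i]] <- cm[reference[i], predicted[i]] + 1L
  }
  cm
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0) ||
      any(cm != round(cm))) {
    stop_validation("confusion matrix must be square with non-negative counts")
  }
  if (sum(cm) == 0) stop_validation("confusion matrix is empty")
  cm
}

#' Mean cleansing score of a frame-count distribution
#'
#' Given the number of frames per score 1..5, returns the frame-weighted
#' mean score `sum(i * n_i) / sum(n_i)`.
#'
#' @param counts 5 non-negative frame counts, one per score.
#' @return The mean score.
#' @examples
#' mean_score_from_distribution(c(10, 10, 10, 10, 10))   # 3
#' @export
mean_score_from_distribution <- function(counts) {
  if (!is.numeric(counts) || length(counts) != 5L || any(counts < 0) ||
      any(counts != round(counts))) {
    stop_validation("counts must be 5 non-negative integers")
  }
  if (sum(counts) == 0) stop_validation("counts are all zero")
  sum((1:5) * counts) / sum(counts)
}

#' Top-1 accuracy
#'
#' Fraction of concordant pairs: trace over total of the confusion
#' matrix.
#'
#' @param cm Confusion matrix (reference rows, predicted columns).
#' @return Accuracy in `[0, 1]`.
#' @export
top1_accuracy <- function(cm) {
  cm <- check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa and agreement rates
#'
#' Chance-corrected agreement `K = (Po - Pe) / (1 - Pe)`, where `Po` is
#' the observed agreement (trace / total) and `Pe` the chance agreement
#' from the row and column marginals. Underestimation is the mass where
#' the algorithm scored below the reference (predicted < reference),
#' overestimation the mass above; the two sum to the misclassification
#' rate `1 - Po`.
#'
#' @param cm Confusion matrix: rows reference, columns predicted.
#' @return An `agreement_result`: list with `top1`, `po`, `pe`, `kappa`,
#'   `misclassification`, `underestimation`, `overestimation`, `n`.
#' @examples
#' cm <- matrix(0, 5, 5); cm[1:2, 1:2] <- c(20, 10, 5, 15)
#' cohen_kappa(cm)$kappa   # 0.4
#' @export
cohen_kappa <- function(cm) {
  cm <- check_cm(cm)
  total <- sum(cm)
  po <- sum(diag(cm)) / total
  pe <- sum((rowSums(cm) / total) * (colSums(cm) / total))
  if (abs(1 - pe) < 1e-12) {
    stop_validation("kappa undefined: chance agreement Pe = 1 ",
                    "(degenerate single-cell marginals)")
  }
  # predicted < reference: column index < row index (lower triangle)
  under <- sum(cm[lower.tri(cm)]) / total
  over <- sum(cm[upper.tri(cm)]) / total
  structure(
    list(top1 = po, po = po, pe = pe, kappa = (po - pe) / (1 - pe),
         misclassification = 1 - po, underestimation = under,
         overestimation = over, n = total),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs\n", x$n))
  cat(sprintf("  Top-1 accuracy (Po): %.3f\n", x$top1))
  cat(sprintf("  Cohen's kappa:       %.3f  (Pe = %.3f)\n", x$kappa, x$pe))
  cat(sprintf("  Misclassification:   %.3f  (under %.3f, over %.3f)\n",
              x$misclassification, x$underestimation, x$overestimation))
  invisible(x)
}

format_p <- function(p) if (p < 0.001) "<0.001" else sprintf("%.3f", p)

#' Compare average cleansing scores across grading groups
#'
#' Per-group mean, SD and 95% confidence interval of the mean, with a
#' one-way analysis-of-variance F test across groups.
#'
#' @param scores_by_grade Named list mapping each grade (e.g. `"A"`,
#'   `"B"`, `"C"`) to the vector of case-level average scores in that
#'   group; at least two non-empty groups.
#' @return A list with `groups` (data frame: `grade`, `n`, `mean`, `sd`,
#'   `ci_lower`, `ci_upper`), `f_statistic`, `df`, `p_value`,
#'   `p_display`.
#' @export
compare_groups <- function(scores_by_grade) {
  scores_by_grade <- scores_by_grade[lengths(scores_by_grade) > 0L]
  if (length(scores_by_grade) < 2L) {
    stop_validation("need at least 2 non-empty groups")
  }
  groups <- do.call(rbind, lapply(names(scores_by_grade), function(g) {
    v <- scores_by_grade[[g]]
    n <- length(v)
    m <- mean(v)
    s <- if (n >= 2L) stats::sd(v) else NA_real_
    half <- if (n >= 2L) stats::qt(0.975, n - 1L) * s / sqrt(n) else NA_real_
    data.frame(grade = g, n = n, mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half)
  }))
  df <- data.frame(
    score = unlist(scores_by_grade, use.names = FALSE),
    grade = factor(rep(names(scores_by_grade), lengths(scores_by_grade)))
  )
  fit <- stats::anova(stats::lm(score ~ grade, data = df))
  list(
    groups = groups,
    f_statistic = fit$`F value`[1L],
    df = c(fit$Df[1L], fit$Df[2L]),
    p_value = fit$`Pr(>F)`[1L],
    p_display = format_p(fit$`Pr(>F)`[1L])
  )
}

#' ROC analysis of the final cleansing score against adequacy
#'
#' Builds the empirical ROC of the rule "call preparation adequate when
#' the final score is at least t" over all distinct observed scores,
#' integrates the AUC by the trapezoidal rule, and selects the cut-off
#' maximising Youden's J (sensitivity + specificity - 1), breaking ties
#' toward the lower threshold. The reported cut-off is the midpoint
#' between the selected threshold and the next lower distinct score, the
#' form in which such cut-offs are conventionally quoted.
#'
#' @param final_scores Case-level average cleansing scores.
#' @param adequate Logical (or 0/1) reference labels: was the
#'   preparation clinically adequate?
#' @return A `roc_result`: list with `thresholds` (descending),
#'   `sensitivity`, `specificity`, `auc`, `cutoff`,
#'   `cutoff_sensitivity`, `cutoff_specificity`, `n_positive`,
#'   `n_negative`.
#' @examples
#' roc_analysis(c(3.4, 3.8, 3.1, 2.4, 2.8),
#'              c(TRUE, TRUE, TRUE, FALSE, FALSE))$cutoff   # 2.95
#' @export
roc_analysis <- function(final_scores, adequate) {
  if (length(final_scores) != length(adequate)) {
    stop_validation("final_scores and adequate must be the same length")
  }
  adequate <- as.logical(adequate)
  if (any(is.na(adequate)) || any(!is.finite(final_scores))) {
    stop_validation("inputs must be finite and non-missing")
  }
  pos <- final_scores[adequate]
  neg <- final_scores[!adequate]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_validation("both adequate and inadequate labels must be present")
  }
  thr <- sort(unique(final_scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(pos >= t), 0)
  spec <- vapply(thr, function(t) mean(neg < t), 0)
  fpr <- c(0, 1 - spec)            # prepend the all-negative operating point
  tpr <- c(0, sens)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[length(best)]       # descending order: last max = lowest threshold
  t_star <- thr[best]
  lower <- thr[thr < t_star]
  cutoff <- if (length(lower)) (t_star + max(lower)) / 2 else t_star
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, cutoff = cutoff,
         cutoff_sensitivity = sens[best], cutoff_specificity = spec[best],
         n_positive = length(pos), n_negative = length(neg)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d adequate / %d inadequate cases\n",
              x$n_positive, x$n_negative))
  cat(sprintf("  AUC: %.3f\n", x$auc))
  cat(sprintf("  Cut-off: %.2f (sensitivity %.2f, specificity %.2f)\n",
              x$cutoff, x$cutoff_sensitivity, x$cutoff_specificity))
  invisible(x)
}
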