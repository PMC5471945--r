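#' Label all drug-enzyme relations for threshold calibration
#'
#' The calibration universe folds drug-metabolite similarities to
#' drug-enzyme scores: for every drug in the matrix and every enzyme that
#' appears in the gold-standard set, the score is the drug's maximum
#' similarity over that enzyme's GSP substrates, and the label is whether
#' the (drug, enzyme) pair is itself a GSP relation. Rows are sorted by
#' descending score with ascending drug id as the deterministic tie-break.
#'
#' @param m a `sim_matrix`.
#' @param gsp a `gsp_set` from [select_gsp()] (or any data frame with
#'   columns `enzyme_label`, `substrate_id`, `drug_id`).
#' @return data frame of class `labeled_scores` with columns `drug_id`,
#'   `enzyme_label`, `score`, `label`.
#' @export
label_relations <- function(m, gsp) {
  labels <- unique(gsp$enzyme_label)
  out <- do.call(rbind, lapply(labels, function(lab) {
    subs <- unique(gsp$substrate_id[gsp$enzyme_label == lab])
    missing <- setdiff(subs, colnames(m))
    if (length(missing))
      mlk_error(sprintf("GSP substrates of '%s' not in matrix: %s", lab,
                        paste(missing, collapse = ", ")),
                "metalike_unknown_id")
    data.frame(drug_id = rownames(m), enzyme_label = lab,
               score = apply(m[, subs, drop = FALSE], 1, max),
               label = rownames(m) %in% gsp$drug_id[gsp$enzyme_label == lab],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$score, out$drug_id, out$enzyme_label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("labeled_scores", "data.frame")
  out
}

#' ROC curve of a score-threshold classifier
#'
#' Sweeps the decision threshold over every distinct observed score plus a
#' sentinel above the maximum (exact step-function ROC, no binning); a
#' relation is called positive when its score is at or above the threshold.
#' The area under the curve is computed by trapezoidal integration, which
#' on a step ROC equals the Mann-Whitney concordance statistic.
#'
#' @param x a `labeled_scores` data frame, or a numeric score vector.
#' @param labels logical vector of true labels (when `x` is numeric).
#' @return object of class `mlk_roc`: `thresholds` (descending, first
#'   element `Inf`), `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(x, labels = NULL) {
  if (is.data.frame(x)) {
    labels <- x$label
    scores <- x$score
  } else scores <- x
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    mlk_error("ROC needs at least one positive and one negative label",
              "metalike_single_class")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  last <- !duplicated(scores, fromLast = TRUE)   # block ends per distinct score
  tp <- cumsum(labels)[last]
  fp <- cumsum(!labels)[last]
  structure(list(thresholds = c(Inf, scores[last]),
                 fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                 auc = trapezoid_auc(c(0, fp / n_neg), c(0, tp / n_pos)),
                 n_pos = n_pos, n_neg = n_neg),
            class = "mlk_roc")
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Youden's J statistic
#'
#' `J(x) = Sp(x) + Se(x) - 1`, giving equal weight to sensitivity and
#' specificity; equivalently `tpr - fpr` at the operating point.
#'
#' @param sensitivity true-positive rate Se(x).
#' @param specificity true-negative rate Sp(x).
#' @return J in \[-1, 1\].
#' @export
youden_j <- function(sensitivity, specificity) {
  sensitivity + specificity - 1
}

#' Youden-optimal threshold of an ROC curve
#'
#' Computes J at every threshold of the curve and returns the threshold at
#' the maximum. A tie on J is resolved toward the higher (more specific)
#' threshold; the infinite sentinel, at which nothing is called positive,
#' is never selected while a finite threshold ties it.
#'
#' @param roc an `mlk_roc`.
#' @return object of class `youden_profile`: `thresholds`, `j`,
#'   `optimal_threshold`, `j_max`, and the `se`/`sp` at the optimum.
#' @export
youden_optimal <- function(roc) {
  j <- youden_j(roc$tpr, 1 - roc$fpr)
  cand <- which(j == max(j) & is.finite(roc$thresholds))
  if (length(cand) == 0L) cand <- which.max(j)
  best <- cand[1L]   # thresholds descend, so the first tie is the highest
  structure(list(thresholds = roc$thresholds, j = j,
                 optimal_threshold = roc$thresholds[best], j_max = j[best],
                 se = roc$tpr[best], sp = 1 - roc$fpr[best]),
            class = "youden_profile")
}

#' @export
print.mlk_roc <- function(x, ...) {
  cat(sprintf("<mlk_roc> %d positives, %d negatives, %d thresholds; AUC = %.3f\n",
              x$n_pos, x$n_neg, length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
print.youden_profile <- function(x, ...) {
  cat(sprintf("<youden_profile> J max = %.3f at threshold %.3f (Se %.3f, Sp %.3f)\n",
              x$j_max, x$optimal_threshold, x$se, x$sp))
  invisible(x)
}

#' @export
plot.mlk_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlab = "False positive rate",
                 ylab = "True positive rate (Se)",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
plot.youden_profile <- function(x, ...) {
  fin <- is.finite(x$thresholds)
  graphics::plot(x$thresholds[fin], x$j[fin], type = "l",
                 xlab = "Similarity threshold", ylab = "Youden's J", ...)
  graphics::points(x$optimal_threshold, x$j_max, pch = 19, col = "red")
  invisible(x)
}

#' Export an ROC / Youden profile as a delimited table
#'
#' @param roc an `mlk_roc`.
#' @param path output file (tab-separated columns threshold, fpr, tpr, j).
#' @export
write_roc <- function(roc, path) {
  utils::write.table(
    data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr,
               j = youden_j(roc$tpr, 1 - roc$fpr)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
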