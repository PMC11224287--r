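#' Area under the ROC curve
#'
#' Computes AUC-ROC as the Mann-Whitney probability that a random positive
#' scores above a random negative, with half credit for ties:
#' `(#\{score_pos > score_neg\} + 0.5 * #ties) / (P * N)`.  This tie
#' convention is equivalent to trapezoidal integration of the ROC curve.
#' Implemented via midranks, so it runs in O(n log n).
#'
#' @param y_true Binary 0/1 labels; both classes must be present.
#' @param y_score Real-valued scores, higher meaning more positive.
#' @return A number in `[0, 1]`.
#' @examples
#' auc_roc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
#' @export
auc_roc <- function(y_true, y_score) {
  if (length(y_true) != length(y_score)) {
    stop("`y_true` and `y_score` must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1))) {
    stop("`y_true` must be binary 0/1", call. = FALSE)
  }
  P <- sum(y_true == 1)
  N <- sum(y_true == 0)
  if (P == 0L || N == 0L) {
    stop("AUC is undefined for single-class input (need at least one ",
         "positive and one negative label)", call. = FALSE)
  }
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - P * (P + 1) / 2) / (P * N)
}

#' ROC curve points
#'
#' (FPR, TPR) pairs at every distinct score threshold, for plotting.
#'
#' @inheritParams auc_roc
#' @return A data.frame with columns `fpr` and `tpr`, starting at (0, 0)
#'   and ending at (1, 1).
#' @export
roc_points <- function(y_true, y_score) {
  if (!all(y_true %in% c(0, 1)) || length(y_true) != length(y_score)) {
    stop("labels must be 0/1 and match scores in length", call. = FALSE)
  }
  P <- sum(y_true == 1)
  N <- sum(y_true == 0)
  if (P == 0L || N == 0L) stop("need both classes", call. = FALSE)
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]
  s <- y_score[ord]
  keep <- c(diff(s) != 0, TRUE)  # last point of each tie group
  tpr <- cumsum(y)[keep] / P
  fpr <- cumsum(1 - y)[keep] / N
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Aggregate per-fold AUCs into an evaluation report
#'
#' @param fold_aucs Numeric vector of per-fold AUC values.
#' @param model_name Model variant label.
#' @param epoch_budget Maximum epochs the folds were trained for.
#' @param seed Seed used for the run.
#' @return An `evaluation_report`: list with `model_name`, `epoch_budget`,
#'   `fold_aucs`, `mean_auc` and `seed`.
#' @export
summarize_folds <- function(fold_aucs, model_name = "dsc",
                            epoch_budget = NA_integer_, seed = NA_integer_) {
  if (length(fold_aucs) == 0L) {
    stop("`fold_aucs` must be non-empty", call. = FALSE)
  }
  if (any(fold_aucs < 0 | fold_aucs > 1)) {
    stop("AUC values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(model_name = model_name,
                 epoch_budget = epoch_budget,
                 fold_aucs = as.numeric(fold_aucs),
                 mean_auc = mean(fold_aucs),
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %s, %s epochs, seed %s>\n",
              x$model_name, x$epoch_budget, x$seed))
  cat(sprintf("  fold AUCs: %s\n",
              paste(sprintf("%.3f", x$fold_aucs), collapse = " ")))
  cat(sprintf("  mean AUC : %.4f\n", x$mean_auc))
  invisible(x)
}

#' Write an evaluation report to TSV and JSON
#'
#' @param report An `evaluation_report`.
#' @param path_tsv,path_json Output paths; either may be `NULL` to skip.
#' @return Invisibly, the report.
#' @export
write_report <- function(report, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(path_tsv)) {
    df <- data.frame(rotation = seq_along(report$fold_aucs) - 1L,
                     test_fold_auc = report$fold_aucs)
    df <- rbind(df, data.frame(rotation = NA_integer_,
                               test_fold_auc = report$mean_auc))
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(report)
}
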