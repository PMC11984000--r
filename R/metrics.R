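# Classification and ranking evaluation: per-class and support-weighted
# precision/recall/F1, rank-based AUC (ties count one half), and precision
# at K for ranked retrieval.

#' Classification metrics
#'
#' Per-class precision, recall and F1 for the two classes, their
#' support-weighted aggregates, and (when scores are supplied) the AUC,
#' defined as the probability that a uniformly drawn positive outranks a
#' uniformly drawn negative, ties counting one half. A class never predicted
#' has precision 0 by convention. With single-class truth the AUC is
#' undefined and returned as `NA` with a warning; the other metrics are
#' still computed.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred 0/1 vector of predicted labels (same length).
#' @param y_score Optional numeric scores for the positive class.
#' @return An object of class `eval_metrics`: list with `per_class` (data
#'   frame of precision/recall/f1/support for classes 0 and 1),
#'   `weighted_precision`, `weighted_recall`, `weighted_f1`, `accuracy` and
#'   `auc`.
#' @export
evaluate <- function(y_true, y_pred, y_score = NULL) {
  if (length(y_true) != length(y_pred)) vu_stop("y_true and y_pred lengths differ")
  if (!is.null(y_score) && length(y_score) != length(y_true)) {
    vu_stop("y_score length differs from y_true")
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(!y_true %in% 0:1) || any(!y_pred %in% 0:1)) {
    vu_stop("labels must be 0/1")
  }
  per <- lapply(c(0L, 1L), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(y_true == cl))
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  auc <- NA_real_
  if (!is.null(y_score)) {
    if (length(unique(y_true)) < 2) {
      warning("AUC undefined: y_true contains a single class")
    } else {
      r <- rank(y_score)  # average ranks: ties contribute 1/2 pairs
      n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
      auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  structure(list(
    per_class = per,
    weighted_precision = sum(w * per$precision),
    weighted_recall = sum(w * per$recall),
    weighted_f1 = sum(w * per$f1),
    accuracy = mean(y_true == y_pred),
    auc = auc
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat("Classification metrics\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("weighted: precision %.4f, recall %.4f, F1 %.4f; accuracy %.4f",
              x$weighted_precision, x$weighted_recall, x$weighted_f1, x$accuracy))
  if (!is.na(x$auc)) cat(sprintf("; AUC %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' Precision at K
#'
#' For each query's ordered 0/1 relevance list, the fraction of the top K
#' slots that are relevant; pooled across queries, the total number of
#' relevant top-K slots over `K * #queries`.
#'
#' @param relevance_lists A list of ordered 0/1 relevance vectors (one per
#'   query), or a single vector for one query. Each must have length >= `k`.
#' @param k Cutoff rank K (positive integer).
#' @return List with `per_query` (numeric vector of P@K values) and
#'   `pooled` (single number).
#' @examples
#' precision_at_k(list(c(1, 0, 1, 0)), k = 2)
#' @export
precision_at_k <- function(relevance_lists, k) {
  if (!is_count(k) || k < 1) vu_stop("k must be a positive integer")
  if (!is.list(relevance_lists)) relevance_lists <- list(relevance_lists)
  if (!length(relevance_lists)) vu_stop("need at least one relevance list")
  short <- which(lengths(relevance_lists) < k)
  if (length(short)) {
    vu_stop("relevance list(s) shorter than K: ", paste(short, collapse = ", "))
  }
  per <- vapply(relevance_lists, function(r) {
    r <- as.numeric(r)
    if (any(!r %in% c(0, 1))) vu_stop("relevance values must be 0/1")
    sum(r[seq_len(k)]) / k
  }, numeric(1))
  list(per_query = per,
       pooled = sum(vapply(relevance_lists, function(r) sum(as.numeric(r)[seq_len(k)]),
                           numeric(1))) / (k * length(relevance_lists)))
}
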