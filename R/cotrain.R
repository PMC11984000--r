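# Human-in-the-loop co-training over the metadata and content feature views.
#
# Each iteration trains one classifier per view on the current labeled set,
# scores the unlabeled pool, selects confident predictions per view
# (probability >= threshold, inclusive), and moves videos to the labeled set
# when the views agree; confident but conflicting predictions are arbitrated
# by the oracle (the human expert, or a simulation of one). Videos selected
# confidently by a single view only remain unlabeled. The loop halts when the
# pool is empty, no additions were made, or the iteration cap is reached.

#' Co-training configuration
#'
#' @param confidence_threshold Minimum predicted class probability for an
#'   unlabeled video to be selected, in `(0.5, 1]` (a threshold at or below
#'   0.5 would let the positive and negative selections overlap). Default
#'   0.65.
#' @param max_iterations Iteration cap K (safety stop). Default 50.
#' @param l2_strength Ridge penalty of the default logistic base learner.
#' @param leftover_policy How to label videos still unlabeled at halt:
#'   `"mean_probability_vote"` (default; label 1 iff the mean of the two
#'   views' positive-class probabilities is at least 0.5) or `"label_low"`
#'   (assign all leftovers the low label, the handling used for
#'   foreign-language narratives whose views cannot agree).
#' @param seed Integer seed; the full run (audit log included) is
#'   deterministic given the seed.
#' @param base_learner A learner contract (see [ridge_logistic_learner()]);
#'   default is L2-regularized logistic regression with `l2_strength`.
#' @return An object of class `cotrain_config`.
#' @export
cotrain_config <- function(confidence_threshold = 0.65, max_iterations = 50,
                           l2_strength = 0.01,
                           leftover_policy = c("mean_probability_vote", "label_low"),
                           seed = 1, base_learner = NULL) {
  if (!is.numeric(confidence_threshold) || confidence_threshold <= 0.5 ||
      confidence_threshold > 1) {
    vu_stop("confidence_threshold must lie in (0.5, 1]")
  }
  if (!is_count(max_iterations) || max_iterations < 1) {
    vu_stop("max_iterations must be a positive integer")
  }
  if (!is.numeric(l2_strength) || l2_strength <= 0) {
    vu_stop("l2_strength must be positive")
  }
  leftover_policy <- match.arg(leftover_policy)
  structure(list(
    confidence_threshold = confidence_threshold,
    max_iterations = as.integer(max_iterations),
    l2_strength = l2_strength, leftover_policy = leftover_policy,
    seed = as.integer(seed),
    base_learner = base_learner %||% ridge_logistic_learner(l2_strength)
  ), class = "cotrain_config")
}

## ---- base learner contract -------------------------------------------------

# Standardization/imputation fitted on training data: z-score per column
# (constant columns get unit scale), NA imputed to the training mean with an
# accompanying 0/1 missingness indicator for columns that were incomplete in
# training.
fit_prep <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd, na_cols = colnames(x)[colSums(is.na(x)) > 0])
}

apply_prep <- function(prep, x) {
  z <- sweep(sweep(x, 2, prep$mu, "-"), 2, prep$sd, "/")
  ind <- NULL
  if (length(prep$na_cols)) {
    ind <- 1 * is.na(x[, prep$na_cols, drop = FALSE])
    colnames(ind) <- paste0("miss_", prep$na_cols)
  }
  z[is.na(z)] <- 0
  if (!is.null(ind)) z <- cbind(z, ind)
  z
}

#' L2-regularized logistic base learner
#'
#' The default base learner of the co-training loop: ridge-penalized
#' logistic regression (fitted with \pkg{glmnet} at a fixed penalty), on
#' per-view standardized features with mean-imputation plus missingness
#' indicators. Any object honouring the same contract — a list with
#' `fit(x, y)` returning a handle and `predict_prob(handle, x)` returning
#' positive-class probabilities — can replace it.
#'
#' @param lambda Ridge penalty (positive).
#' @return A learner contract of class `vu_learner`.
#' @export
ridge_logistic_learner <- function(lambda = 0.01) {
  structure(list(
    id = sprintf("ridge_logistic(lambda=%g)", lambda),
    fit = function(x, y) {
      prep <- fit_prep(x)
      z <- apply_prep(prep, x)
      fit <- glmnet::glmnet(z, factor(y, levels = c(0, 1)), family = "binomial",
                            alpha = 0, lambda = c(10 * lambda, lambda),
                            standardize = FALSE)
      list(prep = prep, fit = fit, lambda = lambda)
    },
    predict_prob = function(handle, x) {
      z <- apply_prep(handle$prep, x)
      p <- stats::predict(handle$fit, newx = z, s = handle$lambda,
                          type = "response")[, 1]
      stats::setNames(as.numeric(p), rownames(x))
    }
  ), class = "vu_learner")
}

## ---- oracles ---------------------------------------------------------------

#' Simulated oracle backed by a ground-truth table
#'
#' Answers conflict queries from a known label table, flipping each video's
#' answer independently with probability `error_rate`. Flips are drawn once
#' at construction from `seed`, so the oracle is deterministic regardless of
#' query order.
#'
#' @param truth Named 0/1 vector of true labels, named by `video_id`.
#' @param error_rate Probability of answering incorrectly (default 0: a
#'   perfect expert).
#' @param seed Integer seed for the flip draws.
#' @return An oracle: `function(video_id, features, predictions)` returning
#'   a 0/1 label.
#' @export
oracle_simulated <- function(truth, error_rate = 0, seed = 1) {
  if (is.null(names(truth)) || any(!nzchar(names(truth)))) {
    vu_stop("truth must be a named 0/1 vector")
  }
  truth <- truth[order(names(truth))]
  flips <- with_local_seed(seed, stats::runif(length(truth)) < error_rate)
  names(flips) <- names(truth)
  function(video_id, features = NULL, predictions = NULL) {
    if (!video_id %in% names(truth)) vu_stop("oracle has no label for ", video_id)
    t <- truth[[video_id]]
    if (flips[[video_id]]) 1 - t else t
  }
}

#' File-queue oracle
#'
#' A non-interactive human protocol: unanswered queries are appended to
#' `pending.csv` in `dir` and raise an error that aborts the iteration with
#' state preserved; a human fills `answers.csv` (columns `video_id,label`)
#' and the run is repeated.
#'
#' @param dir Directory holding `pending.csv` / `answers.csv`.
#' @return An oracle function.
#' @export
oracle_file_queue <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  function(video_id, features = NULL, predictions = NULL) {
    ans_path <- file.path(dir, "answers.csv")
    if (file.exists(ans_path)) {
      ans <- utils::read.csv(ans_path, stringsAsFactors = FALSE)
      hit <- ans$label[ans$video_id == video_id]
      if (length(hit)) return(as.integer(hit[1]))
    }
    pend_path <- file.path(dir, "pending.csv")
    if (!file.exists(pend_path)) writeLines("video_id", pend_path)
    cat(video_id, "\n", file = pend_path, append = TRUE, sep = "")
    vu_stop("oracle answer missing for ", video_id,
            "; query appended to ", pend_path)
  }
}

#' Interactive console oracle
#'
#' Prompts on the console for a 0/1 label for each conflicting video.
#'
#' @return An oracle function.
#' @export
oracle_interactive <- function() {
  function(video_id, features = NULL, predictions = NULL) {
    repeat {
      ans <- trimws(readline(sprintf("Label for %s (0 = low, 1 = high): ", video_id)))
      if (ans %in% c("0", "1")) return(as.integer(ans))
      cat("Please answer 0 or 1.\n")
    }
  }
}

## ---- algorithm steps -------------------------------------------------------

#' Select confident predictions
#'
#' Splits a set of predicted positive-class probabilities into the confident
#' positives (`p >= threshold`) and confident negatives (`1 - p >= threshold`);
#' the comparison is inclusive at the boundary. With `threshold > 0.5` the
#' two sets are disjoint.
#'
#' @param prob_positive Named vector of probabilities in `[0, 1]`.
#' @param threshold Confidence threshold in `(0.5, 1]`.
#' @return List with sorted id sets `positives` and `negatives`.
#' @export
select_confident <- function(prob_positive, threshold) {
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    vu_stop("threshold must lie in (0.5, 1]")
  }
  ids <- names(prob_positive)
  list(positives = sort(ids[prob_positive >= threshold]),
       negatives = sort(ids[1 - prob_positive >= threshold]))
}

#' Resolve per-view selections into labels
#'
#' Videos selected positive (or negative) by both views get that label with
#' provenance `view-agreement`; videos selected with conflicting signs are
#' referred to the oracle (provenance `oracle`). Videos selected by one view
#' only are not labeled this iteration and remain in the unlabeled pool.
#'
#' @param p1,n1 Confident positive/negative id sets from the metadata view.
#' @param p2,n2 Confident positive/negative id sets from the content view.
#' @param oracle Oracle function for conflicts.
#' @param features Optional per-id feature payload passed through to the
#'   oracle.
#' @param predictions Optional per-id predictions passed through to the
#'   oracle.
#' @return List with `new_labels` (data frame `video_id`, `label`,
#'   `provenance`) and `oracle_calls` (data frame `video_id`, `label`).
#' @export
resolve_labels <- function(p1, n1, p2, n2, oracle = NULL, features = NULL,
                           predictions = NULL) {
  if (length(intersect(p1, n1)) || length(intersect(p2, n2))) {
    vu_stop("a view's positive and negative selections overlap")
  }
  agree_pos <- sort(intersect(p1, p2))
  agree_neg <- sort(intersect(n1, n2))
  conflicts <- sort(union(intersect(p1, n2), intersect(p2, n1)))
  oracle_labels <- integer(0)
  if (length(conflicts)) {
    if (is.null(oracle)) vu_stop("cross-view conflicts require an oracle")
    oracle_labels <- vapply(conflicts, function(id) {
      as.integer(oracle(id, features = features[[id]],
                        predictions = predictions[[id]]))
    }, integer(1))
  }
  new_labels <- data.frame(
    video_id = c(agree_pos, agree_neg, conflicts),
    label = c(rep(1L, length(agree_pos)), rep(0L, length(agree_neg)),
              oracle_labels),
    provenance = c(rep("view-agreement", length(agree_pos) + length(agree_neg)),
                   rep("oracle", length(conflicts))),
    stringsAsFactors = FALSE
  )
  new_labels <- new_labels[order(new_labels$video_id), , drop = FALSE]
  rownames(new_labels) <- NULL
  list(new_labels = new_labels,
       oracle_calls = data.frame(video_id = conflicts,
                                 label = unname(oracle_labels),
                                 stringsAsFactors = FALSE))
}

## ---- the fitting function --------------------------------------------------

#' Fit a human-in-the-loop co-training classifier
#'
#' Trains one classifier per feature view (video metadata; video content) on
#' the labeled set, iteratively enlarging it with confidently and
#' consistently predicted unlabeled videos, arbitrating cross-view conflicts
#' through the oracle. Returns the fitted pair, the enlarged labeled set
#' with per-video provenance, and a per-iteration audit log.
#'
#' @param labeled List with matrices `meta` and `content` (rows named by
#'   `video_id`) and a named 0/1 vector `labels`; both classes must be
#'   present.
#' @param unlabeled Optional list with matrices `meta` and `content` for the
#'   unlabeled pool.
#' @param config A [cotrain_config()].
#' @param oracle Oracle function for cross-view conflicts (required when
#'   conflicts occur).
#' @param holdout Optional list (`meta`, `content`, `labels`); when given,
#'   the combined-model misclassification error on it is recorded at every
#'   iteration in the audit log.
#' @return An object of class `cotrain` with components
#'   `classifier_meta`, `classifier_content` (fitted learner handles),
#'   `labeled_prime` (data frame `video_id`, `label`, `provenance`),
#'   `audit` (list of per-iteration records plus `halt_reason`),
#'   `oracle_call_count`, `holdout_errors` and `config`. Methods:
#'   [predict.cotrain()], `print`, `summary`.
#' @export
cotrain <- function(labeled, unlabeled = NULL, config = cotrain_config(),
                    oracle = NULL, holdout = NULL) {
  if (!inherits(config, "cotrain_config")) vu_stop("config must be a cotrain_config")
  L_meta <- labeled$meta; L_content <- labeled$content
  y <- labeled$labels
  if (is.null(rownames(L_meta)) || is.null(rownames(L_content))) {
    vu_stop("labeled view matrices must have video_id row names")
  }
  if (is.null(names(y))) names(y) <- rownames(L_meta)
  if (!setequal(rownames(L_meta), rownames(L_content)) ||
      !setequal(rownames(L_meta), names(y))) {
    vu_stop("labeled ids must agree across both views and labels")
  }
  if (length(unique(y)) < 2) vu_stop("labeled set must contain both classes")
  ord <- order(names(y))
  y <- y[ord]
  L_meta <- L_meta[names(y), , drop = FALSE]
  L_content <- L_content[names(y), , drop = FALSE]
  prov <- stats::setNames(rep("seed", length(y)), names(y))

  U_meta <- unlabeled$meta
  U_content <- unlabeled$content
  u_ids <- if (is.null(U_meta)) character() else sort(rownames(U_meta))
  if (length(u_ids)) {
    if (is.null(U_content) || !setequal(rownames(U_meta), rownames(U_content))) {
      vu_stop("every unlabeled unit needs both feature views")
    }
    U_meta <- U_meta[u_ids, , drop = FALSE]
    U_content <- U_content[u_ids, , drop = FALSE]
  }

  learner <- config$base_learner
  set.seed(config$seed)
  audit <- list()
  oracle_call_count <- 0L
  holdout_errors <- numeric()
  halt_reason <- NULL
  f1 <- f2 <- NULL

  record_holdout <- function(f1, f2) {
    if (is.null(holdout)) return(NA_real_)
    p <- (learner$predict_prob(f1, holdout$meta) +
            learner$predict_prob(f2, holdout$content)) / 2
    mean(as.integer(p >= 0.5) != holdout$labels)
  }

  iter <- 0L
  repeat {
    f1 <- learner$fit(L_meta, y)
    f2 <- learner$fit(L_content, y)
    err <- record_holdout(f1, f2)
    if (!is.na(err)) holdout_errors <- c(holdout_errors, err)

    if (!length(u_ids)) {
      halt_reason <- "U empty"
      break
    }
    if (iter >= config$max_iterations) {
      halt_reason <- "max iterations"
      break
    }
    iter <- iter + 1L

    prob1 <- learner$predict_prob(f1, U_meta[u_ids, , drop = FALSE])
    prob2 <- learner$predict_prob(f2, U_content[u_ids, , drop = FALSE])
    sel1 <- select_confident(prob1, config$confidence_threshold)
    sel2 <- select_confident(prob2, config$confidence_threshold)
    feats <- stats::setNames(lapply(u_ids, function(id)
      list(meta = U_meta[id, ], content = U_content[id, ])), u_ids)
    preds <- stats::setNames(lapply(u_ids, function(id)
      c(meta = unname(prob1[id]), content = unname(prob2[id]))), u_ids)
    res <- resolve_labels(sel1$positives, sel1$negatives,
                          sel2$positives, sel2$negatives,
                          oracle = oracle, features = feats, predictions = preds)
    added <- res$new_labels
    oracle_call_count <- oracle_call_count + nrow(res$oracle_calls)
    audit[[iter]] <- list(
      iteration = iter,
      pool_size = length(u_ids),
      n_p1 = length(sel1$positives), n_n1 = length(sel1$negatives),
      n_p2 = length(sel2$positives), n_n2 = length(sel2$negatives),
      n_agree_pos = sum(added$provenance == "view-agreement" & added$label == 1L),
      n_agree_neg = sum(added$provenance == "view-agreement" & added$label == 0L),
      conflict_ids = res$oracle_calls$video_id,
      n_oracle_calls = nrow(res$oracle_calls),
      n_added = nrow(added),
      holdout_error = err
    )
    if (!nrow(added)) {
      halt_reason <- "no new videos"
      break
    }
    ids <- added$video_id
    L_meta <- rbind(L_meta, U_meta[ids, , drop = FALSE])
    L_content <- rbind(L_content, U_content[ids, , drop = FALSE])
    y <- c(y, stats::setNames(added$label, ids))
    prov <- c(prov, stats::setNames(added$provenance, ids))
    u_ids <- setdiff(u_ids, ids)
    if (!length(u_ids)) {
      # refit on the enlarged set before halting so the returned pair
      # reflects all additions
      f1 <- learner$fit(L_meta, y)
      f2 <- learner$fit(L_content, y)
      err <- record_holdout(f1, f2)
      if (!is.na(err)) holdout_errors <- c(holdout_errors, err)
      halt_reason <- "U empty"
      break
    }
  }

  labeled_prime <- data.frame(video_id = names(y), label = as.integer(y),
                              provenance = unname(prov), stringsAsFactors = FALSE)
  if (length(u_ids)) {
    p <- (learner$predict_prob(f1, U_meta[u_ids, , drop = FALSE]) +
            learner$predict_prob(f2, U_content[u_ids, , drop = FALSE])) / 2
    leftover_label <- switch(config$leftover_policy,
      mean_probability_vote = as.integer(p >= 0.5),
      label_low = rep(0L, length(u_ids)))
    labeled_prime <- rbind(labeled_prime, data.frame(
      video_id = u_ids, label = leftover_label,
      provenance = "fallback", stringsAsFactors = FALSE))
  }
  rownames(labeled_prime) <- NULL

  structure(list(
    classifier_meta = f1, classifier_content = f2, learner = learner,
    labeled_prime = labeled_prime,
    audit = list(iterations = audit, halt_reason = halt_reason),
    oracle_call_count = oracle_call_count,
    holdout_errors = holdout_errors,
    n_seed = sum(labeled_prime$provenance == "seed"),
    config = config, call = match.call()
  ), class = "cotrain")
}

#' Predict from a fitted co-training classifier
#'
#' The combined positive-class probability is the mean of the two views'
#' probabilities; the label is 1 exactly when the combined probability is at
#' least 0.5 (inclusive at the boundary).
#'
#' @param object A fitted [cotrain] object.
#' @param newdata List with matrices `meta` and `content` (rows named by
#'   `video_id`); both views are required.
#' @param type `"both"` (default; data frame of label and probability),
#'   `"prob"` or `"label"`.
#' @param ... Unused.
#' @return Per `type`: a named vector of probabilities or labels, or a data
#'   frame with `video_id`, `label`, `prob`.
#' @export
predict.cotrain <- function(object, newdata, type = c("both", "prob", "label"), ...) {
  type <- match.arg(type)
  if (is.null(newdata$meta) || is.null(newdata$content)) {
    vu_stop("newdata needs both feature views (meta and content)")
  }
  p1 <- object$learner$predict_prob(object$classifier_meta, newdata$meta)
  p2 <- object$learner$predict_prob(object$classifier_content, newdata$content)
  p <- (p1 + p2) / 2
  lab <- as.integer(p >= 0.5)
  switch(type,
    prob = p,
    label = stats::setNames(lab, names(p)),
    both = data.frame(video_id = names(p), label = lab, prob = unname(p),
                      stringsAsFactors = FALSE))
}

#' @export
print.cotrain <- function(x, ...) {
  cat("Co-trained two-view understandability classifier\n")
  cat("  labeled set: ", nrow(x$labeled_prime), " videos (",
      x$n_seed, " seed)\n", sep = "")
  cat("  iterations: ", length(x$audit$iterations),
      "; halt: ", x$audit$halt_reason, "\n", sep = "")
  cat("  oracle calls: ", x$oracle_call_count, "\n", sep = "")
  invisible(x)
}

#' @export
summary.cotrain <- function(object, ...) {
  prov <- table(object$labeled_prime$provenance)
  out <- list(
    n_labeled_prime = nrow(object$labeled_prime),
    provenance = prov,
    iterations = length(object$audit$iterations),
    halt_reason = object$audit$halt_reason,
    oracle_call_count = object$oracle_call_count,
    holdout_errors = object$holdout_errors
  )
  class(out) <- "summary.cotrain"
  out
}

#' @export
print.summary.cotrain <- function(x, ...) {
  cat("Co-training summary\n")
  cat("  labeled set L': ", x$n_labeled_prime, " videos\n", sep = "")
  cat("  provenance:", paste(names(x$provenance), as.integer(x$provenance),
                             sep = "=", collapse = ", "), "\n")
  cat("  iterations: ", x$iterations, " (halt: ", x$halt_reason, ")\n", sep = "")
  cat("  oracle calls: ", x$oracle_call_count, "\n", sep = "")
  if (length(x$holdout_errors)) {
    cat("  holdout error by iteration:",
        paste(sprintf("%.3f", x$holdout_errors), collapse = " "), "\n")
  }
  invisible(x)
}

#' Write the per-iteration audit log as JSON Lines
#'
#' @param fit A fitted [cotrain] object.
#' @param path Output path (one iteration per line).
#' @return Invisibly, `path`.
#' @export
write_audit_jsonl <- function(fit, path) {
  lines <- vapply(fit$audit$iterations, function(it) {
    as.character(jsonlite::toJSON(it, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  writeLines(c(lines, as.character(jsonlite::toJSON(
    list(halt_reason = fit$audit$halt_reason,
         oracle_call_count = fit$oracle_call_count), auto_unbox = TRUE))), path)
  invisible(path)
}
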