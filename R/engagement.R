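# Matched-sample causal analysis of the effect of high understandability
# (treatment) on viewer engagement. Covariates are heuristic video/channel
# quality measures; outcomes are log(count + 1) engagement counts. Two
# matching methods are provided: coarsened exact matching (CEM; default,
# variable-ratio with stratum weights) and 1:1 propensity-score matching
# (PSM) on the logit propensity with a caliper.

CAUSAL_COVARIATES <- c(
  "log_channel_views", "log_channel_subs", "log_channel_videos",
  "content_definition_sd", "duration_s", "description_word_count",
  "description_unique_words", "log_published_days"
)

CAUSAL_OUTCOMES <- c("log_view_count", "log_like_count", "log_comment_count")

#' Build causal analysis units from video records
#'
#' Applies the documented transforms: natural log of count + 1 for channel
#' views, channel subscribers, published days and the three engagement
#' outcomes; `log(channel_video_count)` without the +1 (with a +1 fallback
#' and a warning when zeros occur); an SD-definition indicator (HD is the
#' reference); raw duration in seconds; and description word/unique-word
#' counts from the package tokenizer.
#'
#' @param corpus A `video_corpus` (or list of units with `$record`).
#' @param treatment Named 0/1 vector (by `video_id`): 1 = high
#'   understandability.
#' @return A data frame of class `causal_units` with `video_id`,
#'   `treatment`, the eight covariates and the three log outcomes.
#' @export
causal_units <- function(corpus, treatment) {
  recs <- lapply(corpus, function(u) if (is.list(u) && !is.null(u$record)) u$record else u)
  ids <- vapply(recs, function(r) r$video_id, character(1))
  if (is.null(names(treatment))) vu_stop("treatment must be named by video_id")
  missing <- setdiff(ids, names(treatment))
  if (length(missing)) {
    vu_stop("treatment missing for ", length(missing), " video(s), e.g. ", missing[1])
  }
  cvc <- vapply(recs, function(r) r$channel_video_count, numeric(1))
  if (any(cvc == 0)) {
    warning("channel_video_count contains zeros; using log(count + 1) for those units")
  }
  desc_words <- lapply(recs, function(r) tokenize_words(r$description, lower = TRUE))
  df <- data.frame(
    video_id = ids,
    treatment = as.integer(treatment[ids]),
    log_channel_views = log1p(vapply(recs, function(r) r$channel_view_count, numeric(1))),
    log_channel_subs = log1p(vapply(recs, function(r) r$channel_subscriber_count, numeric(1))),
    log_channel_videos = ifelse(cvc == 0, log1p(cvc), log(cvc)),
    content_definition_sd = vapply(recs, function(r) as.numeric(r$content_definition == "SD"), numeric(1)),
    duration_s = vapply(recs, function(r) r$duration_s, numeric(1)),
    description_word_count = lengths(desc_words),
    description_unique_words = vapply(desc_words, function(w) length(unique(w)), numeric(1)),
    log_published_days = log1p(vapply(recs, function(r) r$published_days, numeric(1))),
    log_view_count = log1p(vapply(recs, function(r) r$view_count, numeric(1))),
    log_like_count = log1p(vapply(recs, function(r) r$like_count, numeric(1))),
    log_comment_count = log1p(vapply(recs, function(r) r$comment_count, numeric(1))),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  class(df) <- c("causal_units", "data.frame")
  df
}

#' Fit the treatment propensity model
#'
#' Logistic regression of treatment on the eight covariates; returns fitted
#' propensities. Perfect separation is an error naming the offending
#' covariate(s).
#'
#' @param units A [causal_units] data frame.
#' @return Named vector of propensities in `(0, 1)`, with the fitted `glm`
#'   as attribute `model`.
#' @export
fit_propensity <- function(units) {
  if (length(unique(units$treatment)) < 2) vu_stop("both treatment groups must be nonempty")
  fml <- stats::as.formula(paste("treatment ~", paste(CAUSAL_COVARIATES, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = units, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep_warn) {
    # identify covariates whose treated/control supports do not overlap
    bad <- Filter(function(cv) {
      t1 <- units[[cv]][units$treatment == 1]
      t0 <- units[[cv]][units$treatment == 0]
      min(t1) > max(t0) || min(t0) > max(t1)
    }, CAUSAL_COVARIATES)
    if (length(bad)) {
      vu_stop("perfect separation in propensity model on covariate(s): ",
              paste(bad, collapse = ", "))
    }
    warning("propensity model shows quasi-separation ",
            "(some fitted probabilities numerically 0 or 1)")
  }
  p <- stats::fitted(fit)
  structure(stats::setNames(as.numeric(p), units$video_id), model = fit)
}

#' Match treated and control videos
#'
#' CEM (default): each non-binary covariate is coarsened into equal-width
#' bins over its observed range (bin count per Sturges' rule unless
#' overridden), units are stratified by their joint bin signature, strata
#' lacking either group are dropped, and retained controls are weighted to
#' balance strata (treated weight 1; control weight
#' `(treated_s / controls_s) * (matched controls / matched treated)`), giving
#' a variable-ratio match. PSM: greedy 1:1 nearest-neighbour matching on the
#' logit propensity without replacement, within a caliper of `caliper` SDs
#' of the logit, processing treated units in decreasing propensity order.
#'
#' @param units A [causal_units] data frame.
#' @param method `"cem"` (default) or `"psm"`.
#' @param propensity Named propensity vector for PSM (computed via
#'   [fit_propensity()] when absent).
#' @param breaks CEM bin count: a single number, or a named vector/list per
#'   covariate; default Sturges.
#' @param caliper PSM caliper in SDs of the logit propensity (default 0.2).
#' @return An object of class `matched_sample`: data frame rows for every
#'   unit with `video_id`, `treatment`, `weight` (0 = dropped), `stratum`,
#'   plus attributes `method` and `params`.
#' @export
match_units <- function(units, method = c("cem", "psm"), propensity = NULL,
                        breaks = NULL, caliper = 0.2) {
  method <- match.arg(method)
  t_idx <- units$treatment == 1
  if (!any(t_idx) || all(t_idx)) vu_stop("both treatment groups must be nonempty")
  weight <- numeric(nrow(units))
  stratum <- rep(NA_character_, nrow(units))

  if (method == "cem") {
    sig <- rep("", nrow(units))
    for (cv in CAUSAL_COVARIATES) {
      x <- units[[cv]]
      if (all(x %in% c(0, 1))) {
        b <- as.character(x)
      } else if (diff(range(x)) == 0) {
        b <- rep("all", length(x))
      } else {
        k <- if (is.null(breaks)) grDevices::nclass.Sturges(x)
             else if (length(breaks) == 1L && is.null(names(breaks))) as.integer(breaks)
             else as.integer(breaks[[cv]] %||% grDevices::nclass.Sturges(x))
        edges <- seq(min(x), max(x), length.out = k + 1L)
        edges[1] <- edges[1] - 1e-9; edges[length(edges)] <- edges[length(edges)] + 1e-9
        b <- as.character(cut(x, edges, labels = FALSE))
      }
      sig <- paste(sig, b, sep = "|")
    }
    stratum <- sig
    tab_t <- table(sig[t_idx])
    tab_c <- table(sig[!t_idx])
    common <- intersect(names(tab_t), names(tab_c))
    if (!length(common)) vu_stop("no common support: every stratum lacks one group")
    in_common <- sig %in% common
    m_t <- sum(in_common & t_idx)
    m_c <- sum(in_common & !t_idx)
    weight[in_common & t_idx] <- 1
    ctrl <- which(in_common & !t_idx)
    weight[ctrl] <- (as.numeric(tab_t[sig[ctrl]]) / as.numeric(tab_c[sig[ctrl]])) *
      (m_c / m_t)
    params <- list(breaks = breaks %||% "Sturges")
  } else {
    if (is.null(propensity)) propensity <- fit_propensity(units)
    p <- propensity[units$video_id]
    if (any(is.na(p))) vu_stop("propensity missing for some units")
    lp <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
    cal <- caliper * stats::sd(lp)
    treated <- which(t_idx)
    controls <- which(!t_idx)
    # deterministic greedy order: decreasing logit, ties by video_id
    treated <- treated[order(-lp[treated], units$video_id[treated])]
    avail <- rep(TRUE, length(controls))
    pair <- 0L
    for (ti in treated) {
      d <- abs(lp[controls] - lp[ti])
      d[!avail] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= cal) {
        pair <- pair + 1L
        ci <- controls[j]
        avail[j] <- FALSE
        weight[c(ti, ci)] <- 1
        stratum[c(ti, ci)] <- sprintf("pair_%04d", pair)
      }
    }
    if (pair == 0L) vu_stop("no common support: no pairs within the caliper")
    params <- list(caliper = caliper, ratio = 1)
  }

  out <- data.frame(video_id = units$video_id, treatment = units$treatment,
                    weight = weight, stratum = stratum, stringsAsFactors = FALSE)
  structure(out, class = c("matched_sample", "data.frame"),
            method = method, params = params)
}

#' @export
print.matched_sample <- function(x, ...) {
  kept <- x$weight > 0
  cat("<matched_sample> method ", attr(x, "method"),
      ": treated ", sum(kept & x$treatment == 1),
      ", control ", sum(kept & x$treatment == 0),
      " retained (of ", sum(x$treatment == 1), "/", sum(x$treatment == 0), ")\n",
      sep = "")
  invisible(x)
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

#' Covariate balance report
#'
#' Standardized mean differences per covariate:
#' `SMD = (weighted mean treated - weighted mean control) / SD_treated`,
#' where the denominator is the unweighted sample SD of the full treated
#' group (a common scale for the before/after contrast). A zero treated SD
#' with unequal means yields a `+/-Inf` sentinel and a flag.
#'
#' @param units A [causal_units] data frame.
#' @param matched Optional [match_units()] result; adds post-matching rows.
#' @return An object of class `balance_report`: data frame with `covariate`,
#'   `phase` (`"all"` / `"matched"`), `mean_treated`, `mean_control`, `smd`,
#'   `degenerate`.
#' @export
balance <- function(units, matched = NULL) {
  if (sum(units$treatment == 1) < 2 || sum(units$treatment == 0) < 2) {
    vu_stop("need at least 2 units per group")
  }
  sd_t <- vapply(CAUSAL_COVARIATES, function(cv)
    stats::sd(units[[cv]][units$treatment == 1]), numeric(1))
  one_phase <- function(w, phase) {
    rows <- lapply(seq_along(CAUSAL_COVARIATES), function(i) {
      cv <- CAUSAL_COVARIATES[i]
      x <- units[[cv]]
      mt <- weighted_mean(x[units$treatment == 1], w[units$treatment == 1])
      mc <- weighted_mean(x[units$treatment == 0], w[units$treatment == 0])
      degen <- sd_t[i] == 0 && mt != mc
      smd <- if (mt == mc) 0
             else if (sd_t[i] == 0) sign(mt - mc) * Inf
             else (mt - mc) / sd_t[i]
      data.frame(covariate = cv, phase = phase, mean_treated = mt,
                 mean_control = mc, smd = smd, degenerate = degen,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- one_phase(rep(1, nrow(units)), "all")
  if (!is.null(matched)) {
    w <- matched$weight[match(units$video_id, matched$video_id)]
    if (sum(w[units$treatment == 1] > 0) < 1 || sum(w[units$treatment == 0] > 0) < 1) {
      vu_stop("matched sample is empty in one group")
    }
    out <- rbind(out, one_phase(w, "matched"))
  }
  rownames(out) <- NULL
  structure(out, class = c("balance_report", "data.frame"))
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Covariate balance (SMD = standardized mean difference)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  for (ph in unique(x$phase)) {
    cat(sprintf("mean |SMD| (%s): %.4f\n", ph,
                mean(abs(x$smd[x$phase == ph & is.finite(x$smd)]))))
  }
  invisible(x)
}

#' Mean absolute standardized mean difference
#'
#' @param report A [balance()] report.
#' @param phase `"all"` or `"matched"`.
#' @return Mean of `|SMD|` over covariates with finite SMD.
#' @export
mean_abs_smd <- function(report, phase = c("all", "matched")) {
  phase <- match.arg(phase)
  s <- report$smd[report$phase == phase]
  mean(abs(s[is.finite(s)]))
}

#' Estimate the average treatment effect on a log engagement outcome
#'
#' Weighted least squares of the log outcome on intercept + treatment over
#' the matched (weighted) sample; with `matched = NULL` the unmatched
#' (naive) contrast is estimated with unit weights. The regression contains
#' no further covariates by design.
#'
#' @param units A [causal_units] data frame.
#' @param matched A [match_units()] result, or `NULL` for the naive
#'   unmatched estimate.
#' @param outcome One of `"log_view_count"`, `"log_like_count"`,
#'   `"log_comment_count"`.
#' @return An object of class `ate_estimate`: list with `outcome`,
#'   `intercept`, `ate`, `se`, `p_value`, `conf_low`, `conf_high`,
#'   `n_treated`, `n_control`, `method`.
#' @export
estimate_ate <- function(units, matched = NULL,
                         outcome = c("log_view_count", "log_like_count",
                                     "log_comment_count")) {
  outcome <- match.arg(outcome)
  if (is.null(matched)) {
    w <- rep(1, nrow(units))
    method <- "none"
  } else {
    w <- matched$weight[match(units$video_id, matched$video_id)]
    method <- attr(matched, "method")
  }
  keep <- w > 0
  if (!any(keep & units$treatment == 1) || !any(keep & units$treatment == 0)) {
    vu_stop("matched sample is empty in one group")
  }
  dat <- units[keep, , drop = FALSE]
  fit <- stats::lm(stats::reformulate("treatment", response = outcome),
                   data = dat, weights = w[keep])
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "treatment", level = 0.95)
  structure(list(
    outcome = outcome,
    intercept = unname(sm["(Intercept)", "Estimate"]),
    ate = unname(sm["treatment", "Estimate"]),
    se = unname(sm["treatment", "Std. Error"]),
    p_value = unname(sm["treatment", "Pr(>|t|)"]),
    conf_low = ci[1], conf_high = ci[2],
    n_treated = sum(dat$treatment == 1), n_control = sum(dat$treatment == 0),
    method = method
  ), class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("ATE on %s (%s matching): %.4f (SE %.4f, p %s; 95%% CI %.4f..%.4f)\n",
              x$outcome, x$method, x$ate, x$se, format.pval(x$p_value, digits = 3),
              x$conf_low, x$conf_high))
  cat(sprintf("  intercept %.4f; treated %d, control %d\n",
              x$intercept, x$n_treated, x$n_control))
  invisible(x)
}

#' Write a Table-style ATE report as CSV
#'
#' One block per outcome with intercept and ATE rows.
#'
#' @param estimates List of [estimate_ate()] results.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_ate_csv <- function(estimates, path) {
  rows <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(measure = e$outcome, term = c("Intercept", "ATE"),
               estimate = c(e$intercept, e$ate),
               se = c(NA_real_, e$se), p_value = c(NA_real_, e$p_value),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
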