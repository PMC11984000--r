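# Shared fixtures. Simulated corpora are cached for the duration of the test
# run so several test files can reuse the same generated data.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# Separable two-view corpus: 60 seed-labeled, 600 unlabeled, 200 held out.
separable_sim <- function() {
  cached("separable", {
    cfg <- synthetic_config(n_videos = 860, seed = 7, confounding = FALSE)
    sim <- generate_corpus(cfg)
    vm <- view_matrices(sim$corpus)
    truth <- stats::setNames(sim$truth$label, sim$truth$video_id)
    ids <- vm$ids
    list(cfg = cfg, sim = sim, vm = vm, truth = truth,
         lab_ids = ids[1:60], unlab_ids = ids[61:660], hold_ids = ids[661:860])
  })
}

separable_fit <- function() {
  cached("separable_fit", {
    fx <- separable_sim()
    labeled <- list(meta = fx$vm$meta[fx$lab_ids, ],
                    content = fx$vm$content[fx$lab_ids, ],
                    labels = fx$truth[fx$lab_ids])
    unlabeled <- list(meta = fx$vm$meta[fx$unlab_ids, ],
                      content = fx$vm$content[fx$unlab_ids, ])
    holdout <- list(meta = fx$vm$meta[fx$hold_ids, ],
                    content = fx$vm$content[fx$hold_ids, ],
                    labels = fx$truth[fx$hold_ids])
    fit <- cotrain(labeled, unlabeled, cotrain_config(seed = 7),
                   oracle = oracle_simulated(fx$truth, 0, seed = 7),
                   holdout = holdout)
    list(fit = fit, labeled = labeled, unlabeled = unlabeled, holdout = holdout)
  })
}

# Confounded causal corpus with planted treatment effect 2.5.
confounded_sim <- function() {
  cached("confounded", {
    cfg <- synthetic_config(n_videos = 2000, seed = 17)
    sim <- generate_corpus(cfg)
    eng <- generate_engagement(sim$corpus, sim$truth, cfg)
    tr <- stats::setNames(eng$truth$label, eng$truth$video_id)
    list(cfg = cfg, corpus = eng$corpus, truth = eng$truth,
         units = causal_units(eng$corpus, tr))
  })
}

# Unconfounded corpus: treatment independent of covariates.
unconfounded_sim <- function() {
  cached("unconfounded", {
    cfg <- synthetic_config(n_videos = 1000, seed = 11, confounding = FALSE)
    sim <- generate_corpus(cfg)
    eng <- generate_engagement(sim$corpus, sim$truth, cfg)
    tr <- stats::setNames(eng$truth$label, eng$truth$video_id)
    list(cfg = cfg, corpus = eng$corpus, truth = eng$truth,
         units = causal_units(eng$corpus, tr))
  })
}

# Causal-units table with covariates drawn directly (no corpus, no texts) and
# treatment from a stated logistic model: the oracle for propensity-recovery
# checks, where covariates must be genuinely pre-treatment.
logistic_units_df <- function(n, seed, beta = c(log_channel_views = 0,
                                                log_channel_subs = 0),
                              intercept = 0) {
  set.seed(seed)
  df <- data.frame(
    video_id = sprintf("s%05d", seq_len(n)),
    log_channel_views = stats::rnorm(n, 12, 1.5),
    log_channel_subs = stats::rnorm(n, 8, 1.2),
    log_channel_videos = stats::rnorm(n, 4, 0.5),
    content_definition_sd = stats::rbinom(n, 1, 0.35),
    duration_s = exp(stats::rnorm(n, log(500), 0.5)),
    description_word_count = stats::rpois(n, 80),
    description_unique_words = stats::rpois(n, 60),
    log_published_days = stats::rnorm(n, 6.8, 0.8),
    stringsAsFactors = FALSE
  )
  eta <- rep(intercept, n)
  for (cv in names(beta)) eta <- eta + beta[[cv]] * (df[[cv]] - mean(df[[cv]]))
  df$treatment <- stats::rbinom(n, 1, stats::plogis(eta))
  df$log_view_count <- stats::rnorm(n, 9, 2)
  df$log_like_count <- stats::rnorm(n, 3, 1)
  df$log_comment_count <- stats::rnorm(n, 2, 1)
  class(df) <- c("causal_units", "data.frame")
  df
}

# Minimal hand-built causal units table: one varying covariate, the rest
# constant, so balance/matching arithmetic can be checked by hand.
tiny_causal_units <- function(lv_treated, lv_control, y_treated = NULL,
                              y_control = NULL) {
  nt <- length(lv_treated); nc <- length(lv_control)
  df <- data.frame(
    video_id = sprintf("u%02d", seq_len(nt + nc)),
    treatment = c(rep(1L, nt), rep(0L, nc)),
    log_channel_views = c(lv_treated, lv_control),
    log_channel_subs = 1, log_channel_videos = 1, content_definition_sd = 0,
    duration_s = 100, description_word_count = 10, description_unique_words = 8,
    log_published_days = 2,
    log_view_count = c(y_treated %||% rep(1, nt), y_control %||% rep(1, nc)),
    log_like_count = 1, log_comment_count = 1,
    stringsAsFactors = FALSE
  )
  class(df) <- c("causal_units", "data.frame")
  df
}

make_record <- function(id = "v1", ...) {
  args <- list(...)
  do.call(video_record, c(list(video_id = id), args))
}
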