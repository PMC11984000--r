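# Seeded synthetic corpora with known ground truth. The generator realizes
# the two-view co-training setting: a latent understandability label drives
# class-conditional feature distributions in both views, conditionally
# independent across views given the label, and texts are assembled so that
# the package's own counters recover the planted counts exactly. Channel
# covariates optionally confound both the label and engagement, giving the
# matching analyses a known biased/unbiased contrast.

#' Synthetic corpus configuration
#'
#' Defaults encode the study conditions the package is tested under: a 55%
#' prevalence of high understandability, a separable two-view setting with a
#' class-mean separation of 2 SDs on the informative features of each view,
#' and a log-linear engagement model on the scale of real view/like/comment
#' counts (`alpha` of roughly 8.9/3.2/1.6, treatment effect 2.5, noise SD
#' 1.5), confounded through the channel-popularity covariates.
#'
#' @param n_videos Number of videos.
#' @param prevalence Marginal probability of the high label, in `(0, 1)`.
#' @param separation Class-mean separation in SD units applied to every
#'   informative feature of both views (2 = the default separable setting).
#' @param oracle_error_rate Error rate of the simulated oracle built from
#'   this corpus's ground truth.
#' @param confounding Route channel covariates into the label probability
#'   (and, via `beta`, the outcome), confounding the engagement contrast.
#' @param conf_strength Named coefficients (`views`, `subs`) of the centered
#'   log channel covariates in the label model (used when
#'   `confounding = TRUE`).
#' @param engagement List: `alpha` (named intercepts `view`, `like`,
#'   `comment` of the log-outcome model), `tau` (treatment effect on every
#'   log outcome), `beta` (named coefficients `views`, `subs` of the
#'   centered log channel covariates), `sigma` (noise SD).
#' @param seed Integer seed; the corpus is byte-identical given the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_videos = 700, prevalence = 0.55, separation = 2,
                             oracle_error_rate = 0, confounding = TRUE,
                             conf_strength = c(views = 0.6, subs = 0.3),
                             engagement = list(),
                             seed = 1) {
  engagement <- utils::modifyList(
    list(alpha = c(view = 8.9, like = 3.2, comment = 1.6),
         tau = 2.5, beta = c(views = 0.4, subs = 0.2), sigma = 1.5),
    engagement)
  if (!is_count(n_videos) || n_videos < 1) vu_stop("n_videos must be a positive integer")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence > 1) {
    vu_stop("prevalence must lie in (0, 1]")
  }
  if (!is.numeric(separation) || separation < 0) vu_stop("separation must be nonnegative")
  if (!is.numeric(oracle_error_rate) || oracle_error_rate < 0 || oracle_error_rate > 1) {
    vu_stop("oracle_error_rate must lie in [0, 1]")
  }
  structure(list(
    n_videos = as.integer(n_videos), prevalence = prevalence,
    separation = separation, oracle_error_rate = oracle_error_rate,
    confounding = isTRUE(confounding), conf_strength = conf_strength,
    engagement = engagement, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Class-conditional settings: midpoint, SD, and the direction in which the
# high-understandability class moves. Counts are rounded and clamped at 0;
# `logit` rows are mapped through plogis; `log` rows are exponentiated.
.META_SETTINGS <- data.frame(
  feature = c("active", "summary", "transition", "medical", "log_duration", "words"),
  base = c(4.5, 1.5, 2.5, 5, log(500), 70),
  sd = c(1.5, 1, 1.2, 1.5, 0.35, 15),
  dir = c(1, 1, 1, -1, -1, -1),
  stringsAsFactors = FALSE
)

.CONTENT_SETTINGS <- data.frame(
  feature = c("active", "summary", "transition", "medical", "logit_trans_conf",
              "logit_text_conf", "scenes", "words", "objects"),
  base = c(9, 1.5, 4, 8, 1.4, 1.2, 8, 250, 10),
  sd = c(2, 1, 1.5, 2, 0.45, 0.45, 2.5, 50, 3),
  dir = c(1, 1, 1, -1, 1, 1, 1, -1, -1),
  stringsAsFactors = FALSE
)

draw_view_settings <- function(settings, label, separation) {
  n <- length(label)
  out <- matrix(0, nrow = n, ncol = nrow(settings),
                dimnames = list(NULL, settings$feature))
  for (i in seq_len(nrow(settings))) {
    mu <- settings$base[i] +
      ifelse(label == 1, 1, -1) * settings$dir[i] * separation * settings$sd[i] / 2
    out[, i] <- stats::rnorm(n, mu, settings$sd[i])
  }
  out
}

# Neutral filler vocabulary: nouns under the fallback tagger, absent from
# every packaged lexicon.
.FILLER_WORDS <- c("garden", "window", "music", "river", "mountain", "village",
                   "candle", "mirror", "stone", "meadow", "lantern", "harbor")

.ACTIVE_VERB_POOL <- c("explains", "shows", "helps")

plantable_pool <- function(lex, other_lex) {
  pool <- setdiff(lex$phrases, other_lex$phrases)
  ok <- vapply(pool, function(p) {
    count_active_verbs(default_pos_tagger(p)) == 0 &&
      count_medical_terms(p)$total == 0 &&
      count_lexicon_phrases(p, other_lex) == 0
  }, logical(1))
  sort(pool[ok])
}

.plant_cache <- new.env(parent = emptyenv())

plant_pools <- function() {
  if (is.null(.plant_cache$pools)) {
    s <- lexicon_summary(); t <- lexicon_transition()
    summary_pool <- plantable_pool(s, t)
    transition_pool <- plantable_pool(t, s)
    med <- lexicon_medical()
    medical_pool <- sort(unlist(lapply(med, function(l) l$phrases), use.names = FALSE))
    .plant_cache$pools <- list(summary = summary_pool, transition = transition_pool,
                               medical = medical_pool)
  }
  .plant_cache$pools
}

#' Assemble text with exactly the requested feature counts
#'
#' Builds a text from neutral filler sentences (guaranteed free of lexicon
#' phrases and active-voice verbs) into which summary phrases, transition
#' phrases, active-voice verb sentences and medical terms are planted as
#' standalone sentences, so that [count_lexicon_phrases()],
#' [count_active_verbs()] (on the included tagging or the default tagger)
#' and [count_medical_terms()] recover the planted counts exactly. Planted
#' summary/transition phrases are drawn from the portions of the two
#' lexicons that do not overlap; phrases on both lists can be planted
#' explicitly via `overlap_phrases` and then count toward each lexicon.
#'
#' @param summary,transition,active,medical Requested counts (>= 0).
#' @param target_words Optional total word count to pad to with filler
#'   sentences (overshoot from planted material is kept).
#' @param overlap_phrases Character vector of phrases (e.g. `"finally"`)
#'   planted verbatim in their own sentences, in addition to the counts
#'   above.
#' @return A list with `text`, `tags` (a [tagged_tokens] hand-tag map of the
#'   whole text) and `counts` (the planted counts).
#' @export
plant_text <- function(summary = 0, transition = 0, active = 0, medical = 0,
                       target_words = NULL, overlap_phrases = character()) {
  for (v in c(summary, transition, active, medical)) {
    if (!is_count(v)) vu_stop("planted counts must be nonnegative integers")
  }
  pools <- plant_pools()
  cycle <- function(pool, k) if (k == 0) character() else
    pool[((seq_len(k) - 1L) %% length(pool)) + 1L]
  sentences <- c(
    vapply(cycle(pools$summary, summary), function(p)
      paste0(toupper_first(p), "."), character(1)),
    vapply(cycle(pools$transition, transition), function(p)
      paste0(toupper_first(p), "."), character(1)),
    vapply(cycle(.ACTIVE_VERB_POOL, active), function(v)
      paste0("Narrator ", v, " details."), character(1)),
    vapply(cycle(pools$medical, medical), function(m)
      paste0(toupper_first(m), "."), character(1)),
    vapply(overlap_phrases, function(p) paste0(toupper_first(p), "."), character(1))
  )
  n_words <- sum(lengths(lapply(sentences, tokenize_words)))
  if (!is.null(target_words) && target_words > n_words) {
    pad <- target_words - n_words
    filler <- cycle(.FILLER_WORDS, pad)
    chunks <- split(filler, ceiling(seq_along(filler) / 6))
    sentences <- c(sentences, vapply(chunks, function(ch)
      paste0(toupper_first(paste(ch, collapse = " ")), "."), character(1)))
  }
  text <- paste(sentences, collapse = " ")
  toks <- tokenize_words(text)
  tags <- default_pos_tagger(text)
  list(text = text, tags = tags,
       counts = list(summary = summary, transition = transition,
                     active = active, medical = medical))
}

toupper_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Generate a synthetic two-view video corpus with known ground truth
#'
#' Draws a latent understandability label per video (optionally confounded
#' by channel popularity), class-conditional feature values for both views,
#' and assembles descriptions and transcripts containing the planted counts,
#' plus content signals (confidences, scene and object counts). Engagement
#' counts are zero until [generate_engagement()] is applied.
#'
#' @param config A [synthetic_config()].
#' @return A list with `corpus` (a `video_corpus` of records + signals),
#'   `truth` (data frame with the latent label and planted counts per
#'   video) and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) vu_stop("config must be a synthetic_config")
  set.seed(config$seed)
  n <- config$n_videos
  ids <- sprintf("vid_%05d", seq_len(n))

  q <- stats::rnorm(n)
  lv <- 12 + 1.5 * q + stats::rnorm(n, 0, 0.5)
  ls <- 8 + 1.2 * q + stats::rnorm(n, 0, 0.5)
  channel_views <- pmax(round(expm1(lv)), 0)
  channel_subs <- pmax(round(expm1(ls)), 0)
  channel_videos <- pmax(round(exp(stats::rnorm(n, 4, 0.5))), 1)
  content_def <- ifelse(stats::runif(n) < 0.35, "SD", "HD")
  published_days <- pmax(round(exp(stats::rnorm(n, log(900), 0.8))), 1)

  if (config$confounding) {
    eta <- stats::qlogis(config$prevalence) +
      config$conf_strength[["views"]] * (log1p(channel_views) - 12) +
      config$conf_strength[["subs"]] * (log1p(channel_subs) - 8)
    label <- stats::rbinom(n, 1, stats::plogis(eta))
  } else {
    label <- stats::rbinom(n, 1, config$prevalence)
  }

  meta_draw <- draw_view_settings(.META_SETTINGS, label, config$separation)
  content_draw <- draw_view_settings(.CONTENT_SETTINGS, label, config$separation)
  cnt <- function(x) pmax(round(x), 0)
  has_title <- stats::rbinom(n, 1, ifelse(label == 1, 0.95, 0.75))
  has_tags <- stats::rbinom(n, 1, ifelse(label == 1, 0.9, 0.6))

  truth <- data.frame(
    video_id = ids, label = label, channel_quality = q,
    desc_summary = cnt(meta_draw[, "summary"]),
    desc_transition = cnt(meta_draw[, "transition"]),
    desc_active = cnt(meta_draw[, "active"]),
    desc_medical = cnt(meta_draw[, "medical"]),
    desc_words = cnt(meta_draw[, "words"]),
    tr_summary = cnt(content_draw[, "summary"]),
    tr_transition = cnt(content_draw[, "transition"]),
    tr_active = cnt(content_draw[, "active"]),
    tr_medical = cnt(content_draw[, "medical"]),
    tr_words = cnt(content_draw[, "words"]),
    stringsAsFactors = FALSE
  )

  units <- vector("list", n)
  for (i in seq_len(n)) {
    desc <- plant_text(summary = truth$desc_summary[i],
                       transition = truth$desc_transition[i],
                       active = truth$desc_active[i],
                       medical = truth$desc_medical[i],
                       target_words = truth$desc_words[i])
    trans <- plant_text(summary = truth$tr_summary[i],
                        transition = truth$tr_transition[i],
                        active = truth$tr_active[i],
                        medical = truth$tr_medical[i],
                        target_words = truth$tr_words[i])
    tconf <- unname(stats::plogis(content_draw[i, "logit_trans_conf"]))
    oconf <- unname(stats::plogis(content_draw[i, "logit_text_conf"]))
    rec <- video_record(
      video_id = ids[i],
      title = if (has_title[i] == 1) paste("Managing your condition", i) else "",
      description = desc$text,
      tags = if (has_tags[i] == 1) c("health", "education") else character(),
      duration_s = unname(round(exp(meta_draw[i, "log_duration"]))),
      published_days = published_days[i],
      view_count = 0, like_count = 0, comment_count = 0,
      channel_view_count = channel_views[i],
      channel_subscriber_count = channel_subs[i],
      channel_video_count = channel_videos[i],
      content_definition = content_def[i]
    )
    sig <- video_signals(
      video_id = ids[i], transcript = trans$text,
      transcription_confidence = tconf,
      screen_texts = data.frame(text = c("on screen note", "caption line"),
                                confidence = c(oconf, oconf),
                                stringsAsFactors = FALSE),
      scene_count = unname(cnt(content_draw[i, "scenes"])),
      object_count = unname(cnt(content_draw[i, "objects"]))
    )
    units[[i]] <- list(record = rec, signals = sig)
  }
  names(units) <- ids
  list(corpus = structure(units, class = "video_corpus"), truth = truth,
       config = config)
}

#' Generate engagement counts from the planted causal model
#'
#' For each outcome o in (view, like, comment):
#' `log(count_o + 1) = alpha_o + tau * label + beta_views * (log channel
#' views - 12) + beta_subs * (log channel subs - 8) + Normal(0, sigma)`,
#' exponentiated and rounded to a nonnegative integer. The latent (pre-
#' rounding) log outcomes are appended to the truth table as `y_view`,
#' `y_like`, `y_comment`.
#'
#' @param corpus A `video_corpus` from [generate_corpus()].
#' @param truth The matching ground-truth data frame.
#' @param config The matching [synthetic_config()].
#' @return A list with the updated `corpus` and `truth`.
#' @export
generate_engagement <- function(corpus, truth, config) {
  set.seed(config$seed + 7919L)
  eng <- config$engagement
  n <- length(corpus)
  lvx <- vapply(corpus, function(u) log1p(u$record$channel_view_count), numeric(1))
  lsx <- vapply(corpus, function(u) log1p(u$record$channel_subscriber_count), numeric(1))
  lin <- eng$tau * truth$label +
    eng$beta[["views"]] * (lvx - 12) + eng$beta[["subs"]] * (lsx - 8)
  for (o in c("view", "like", "comment")) {
    y <- eng$alpha[[o]] + lin + stats::rnorm(n, 0, eng$sigma)
    counts <- pmax(round(expm1(y)), 0)
    field <- paste0(o, "_count")
    for (i in seq_len(n)) corpus[[i]]$record[[field]] <- counts[i]
    truth[[paste0("y_", o)]] <- y
  }
  list(corpus = corpus, truth = truth)
}

#' Write a generated corpus and its ground truth to disk
#'
#' Standard corpus JSONL files plus a ground-truth CSV.
#'
#' @param sim Result of [generate_corpus()] (optionally after
#'   [generate_engagement()] — pass the updated pieces).
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(sim$corpus, file.path(dir, "records.jsonl"),
               file.path(dir, "signals.jsonl"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
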