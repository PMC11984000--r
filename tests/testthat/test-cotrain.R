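test_that("confident selection is inclusive at the boundary and disjoint", {
  probs <- c(a = 0.9, b = 0.6, c = 0.2)
  sel <- select_confident(probs, 0.65)
  expect_identical(sel$positives, "a")
  expect_identical(sel$negatives, "c")
  sel1 <- select_confident(c(a = 0.8, b = 0.99), 1.0)
  expect_length(sel1$positives, 0L)
  expect_length(sel1$negatives, 0L)
  # probability exactly at the threshold is selected
  expect_identical(select_confident(c(x = 0.65), 0.65)$positives, "x")
  expect_identical(select_confident(c(x = 0.35), 0.65)$negatives, "x")
  expect_error(select_confident(probs, 0.5), "\\(0.5, 1\\]")
})

test_that("raising the threshold never enlarges either selected set", {
  set.seed(12)
  for (i in 1:20) {
    p <- stats::setNames(stats::runif(30), sprintf("v%02d", 1:30))
    thr <- sort(stats::runif(2, 0.51, 1))
    lo <- select_confident(p, thr[1]); hi <- select_confident(p, thr[2])
    expect_true(all(hi$positives %in% lo$positives))
    expect_true(all(hi$negatives %in% lo$negatives))
  }
})

test_that("label resolution separates agreement, conflict and single-view cases", {
  agree <- resolve_labels("a", character(), "a", character())
  expect_equal(agree$new_labels$label, 1L)
  expect_equal(agree$new_labels$provenance, "view-agreement")
  expect_equal(nrow(agree$oracle_calls), 0L)

  calls <- 0L
  oracle <- function(id, features = NULL, predictions = NULL) { calls <<- calls + 1L; 1L }
  conf <- resolve_labels("a", character(), character(), "a", oracle)
  expect_equal(calls, 1L)
  expect_equal(conf$new_labels$label, 1L)
  expect_equal(conf$new_labels$provenance, "oracle")

  single <- resolve_labels("a", character(), character(), character())
  expect_equal(nrow(single$new_labels), 0L)

  expect_error(resolve_labels(c("a"), c("a"), character(), character()), "overlap")
  expect_error(resolve_labels("a", character(), character(), "a"), "require an oracle")
})

test_that("prediction combines views by mean probability with an inclusive 0.5 boundary", {
  stub_learner <- function(tbl) {
    structure(list(
      id = "stub",
      fit = function(x, y) NULL,
      predict_prob = function(handle, x) tbl[rownames(x), handle]
    ), class = "vu_learner")
  }
  tbl <- cbind(meta = c(a = 0.8, b = 0.5, c = 0.2),
               content = c(a = 0.6, b = 0.5, c = 0.3))
  obj <- structure(list(classifier_meta = "meta", classifier_content = "content",
                        learner = stub_learner(tbl)), class = "cotrain")
  nd <- list(meta = matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "f")),
             content = matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "f")))
  pr <- predict(obj, nd)
  expect_equal(pr$prob, c(0.7, 0.5, 0.25))
  expect_equal(pr$label, c(1L, 1L, 0L))
  expect_error(predict(obj, list(meta = nd$meta)), "both feature views")
})

test_that("degenerate runs halt correctly", {
  fx <- separable_sim()
  labeled <- list(meta = fx$vm$meta[fx$lab_ids, ],
                  content = fx$vm$content[fx$lab_ids, ],
                  labels = fx$truth[fx$lab_ids])
  # empty unlabeled pool: train on L alone, no labeling iterations
  fit0 <- cotrain(labeled, NULL, cotrain_config(seed = 1))
  expect_identical(fit0$audit$halt_reason, "U empty")
  expect_length(fit0$audit$iterations, 0L)
  expect_equal(fit0$oracle_call_count, 0L)
  expect_equal(nrow(fit0$labeled_prime), 60L)

  # threshold 1.0 with interior probabilities: halt with no additions,
  # leftovers labeled by policy
  un <- list(meta = fx$vm$meta[fx$unlab_ids[1:40], ],
             content = fx$vm$content[fx$unlab_ids[1:40], ])
  fit1 <- cotrain(labeled, un, cotrain_config(confidence_threshold = 1, seed = 1))
  expect_identical(fit1$audit$halt_reason, "no new videos")
  expect_equal(fit1$oracle_call_count, 0L)
  fb <- fit1$labeled_prime[fit1$labeled_prime$provenance == "fallback", ]
  expect_equal(nrow(fb), 40L)

  fit2 <- cotrain(labeled, un, cotrain_config(confidence_threshold = 1, seed = 1,
                                              leftover_policy = "label_low"))
  fb2 <- fit2$labeled_prime[fit2$labeled_prime$provenance == "fallback", ]
  expect_true(all(fb2$label == 0L))

  # single-class seed set is rejected
  pos <- names(fx$truth[fx$lab_ids])[fx$truth[fx$lab_ids] == 1]
  expect_error(
    cotrain(list(meta = fx$vm$meta[pos, ], content = fx$vm$content[pos, ],
                 labels = fx$truth[pos]), NULL, cotrain_config()),
    "both classes")
})

test_that("the enlarged labeled set contains the seed set with unchanged labels", {
  fx <- separable_sim()
  run <- separable_fit()
  lp <- run$fit$labeled_prime
  expect_true(all(fx$lab_ids %in% lp$video_id))
  seed_rows <- lp[match(fx$lab_ids, lp$video_id), ]
  expect_true(all(seed_rows$provenance == "seed"))
  expect_equal(seed_rows$label, unname(fx$truth[fx$lab_ids]))
  expect_lte(run$fit$oracle_call_count, length(fx$unlab_ids))
  # every oracle call corresponds to an audited cross-view conflict
  audited <- unlist(lapply(run$fit$audit$iterations, `[[`, "conflict_ids"))
  expect_equal(run$fit$oracle_call_count, length(audited))
})

test_that("identical seeds reproduce the audit log and labels exactly", {
  fx <- separable_sim()
  run <- separable_fit()
  args <- list(run$labeled, run$unlabeled, cotrain_config(seed = 7),
               oracle = oracle_simulated(fx$truth, 0, seed = 7),
               holdout = run$holdout)
  refit <- do.call(cotrain, args)
  expect_identical(refit$audit, run$fit$audit)
  expect_identical(refit$labeled_prime, run$fit$labeled_prime)
  expect_identical(refit$holdout_errors, run$fit$holdout_errors)
})

test_that("a noisy simulated oracle is deterministic and flips at the set rate", {
  truth <- stats::setNames(rep(c(0, 1), 500), sprintf("v%04d", 1:1000))
  o1 <- oracle_simulated(truth, error_rate = 0.2, seed = 5)
  o2 <- oracle_simulated(truth, error_rate = 0.2, seed = 5)
  ans1 <- vapply(names(truth), o1, numeric(1))
  ans2 <- vapply(names(truth), o2, numeric(1))
  expect_identical(ans1, ans2)
  rate <- mean(ans1 != truth)
  expect_gt(rate, 0.15); expect_lt(rate, 0.25)
  expect_error(o1("nonexistent"), "no label")
})
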