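test_that("causal units apply the documented log transforms", {
  rec <- make_record("v1", channel_view_count = 99, channel_subscriber_count = 9,
                     channel_video_count = 10, published_days = 19,
                     view_count = 49, like_count = 0, comment_count = 1,
                     content_definition = "SD", duration_s = 120,
                     description = "Garden window music. River mountain.")
  cu <- causal_units(list(list(record = rec)), c(v1 = 1))
  expect_equal(cu$log_channel_views, log(100))
  expect_equal(cu$log_channel_subs, log(10))
  expect_equal(cu$log_channel_videos, log(10))  # no +1
  expect_equal(cu$log_published_days, log(20))
  expect_equal(cu$log_view_count, log(50))
  expect_equal(cu$log_like_count, 0)
  expect_equal(cu$content_definition_sd, 1)
  expect_equal(cu$description_word_count, 5)
  expect_equal(cu$description_unique_words, 5)

  rec0 <- make_record("v2", channel_video_count = 0)
  expect_warning(cu0 <- causal_units(list(list(record = rec0)), c(v2 = 0)),
                 "zeros")
  expect_equal(cu0$log_channel_videos, 0)
})

test_that("propensity reduces to the treated fraction when covariates are constant", {
  df <- tiny_causal_units(rep(1, 3), rep(1, 7))
  p <- fit_propensity(df)
  expect_equal(as.numeric(p), rep(0.3, 10))
})

test_that("propensity coefficients recover a known treatment model", {
  # treatment from a stated logistic model: coefficients recovered within 3 SE
  beta <- c(log_channel_views = 0.5, log_channel_subs = -0.3)
  df <- logistic_units_df(5000, seed = 11, beta = beta)
  cf <- summary(attr(fit_propensity(df), "model"))$coefficients
  for (cv in names(beta)) {
    expect_lt(abs(cf[cv, "Estimate"] - beta[[cv]]), 3 * cf[cv, "Std. Error"])
  }
  # under treatment independent of covariates, all slopes are near 0
  df0 <- logistic_units_df(2000, seed = 12)
  cf0 <- summary(attr(fit_propensity(df0), "model"))$coefficients
  slopes <- cf0[rownames(cf0) != "(Intercept)", , drop = FALSE]
  expect_true(all(abs(slopes[, "Estimate"]) < 3 * slopes[, "Std. Error"]))
})

test_that("propensity errors on perfect separation, naming the covariate", {
  df <- tiny_causal_units(c(5, 6, 7), c(1, 2, 3))
  expect_error(fit_propensity(df), "separation.*log_channel_views")
})

test_that("CEM retains identical rows with unit weights and drops unique strata", {
  df <- tiny_causal_units(c(1, 2), c(1, 2))
  m <- match_units(df, "cem")
  expect_true(all(m$weight == 1))
  # a treated unit in a bin with no controls is dropped
  df2 <- tiny_causal_units(c(1, 100), c(1, 2))
  m2 <- match_units(df2, "cem", breaks = 5)
  expect_equal(m2$weight[m2$video_id == "u02"], 0)
  # weights conserve group totals: control weights sum to matched control count
  fx <- confounded_sim()
  m3 <- match_units(fx$units, "cem", breaks = 4)
  kept_c <- m3$treatment == 0 & m3$weight > 0
  expect_equal(sum(m3$weight[kept_c]), sum(kept_c))
  expect_true(all(m3$weight[m3$treatment == 1 & m3$weight > 0] == 1))
  # within retained strata both groups share the coarsened signature
  strata <- split(m3$treatment[m3$weight > 0], m3$stratum[m3$weight > 0])
  expect_true(all(vapply(strata, function(tr) any(tr == 1) && any(tr == 0),
                         logical(1))))
})

test_that("matching errors when there is no common support", {
  df <- tiny_causal_units(c(100, 101), c(1, 2))
  expect_error(match_units(df, "cem", breaks = 50), "no common support")
})

test_that("balance SMDs match hand arithmetic and flag degenerate denominators", {
  same <- tiny_causal_units(c(1, 2, 3), c(1, 2, 3))
  b <- balance(same)
  expect_true(all(b$smd == 0))
  # treated {2,4}, control {1,3}: SMD = 1 / sd({2,4}) = 1/sqrt(2)
  b2 <- balance(tiny_causal_units(c(2, 4), c(1, 3)))
  expect_equal(b2$smd[b2$covariate == "log_channel_views"], 1 / sqrt(2))
  # control shifted up by exactly SD_treated gives SMD -1
  sdt <- sd(c(2, 4))
  b3 <- balance(tiny_causal_units(c(2, 4), c(2, 4) + sdt))
  expect_equal(b3$smd[b3$covariate == "log_channel_views"], -1)
  # zero treated SD with unequal means -> infinite sentinel, flagged
  b4 <- balance(tiny_causal_units(c(2, 2), c(3, 3)))
  row <- b4[b4$covariate == "log_channel_views", ]
  expect_true(is.infinite(row$smd) && row$smd < 0)
  expect_true(row$degenerate)
})

test_that("ATE on a constant outcome is exactly zero", {
  df <- tiny_causal_units(c(1, 2), c(1, 2),
                          y_treated = c(5, 5), y_control = c(5, 5))
  m <- match_units(df, "cem")
  # zero residual variance makes lm's summary warn about a perfect fit
  est <- suppressWarnings(estimate_ate(df, m, "log_view_count"))
  expect_equal(est$ate, 0)
  expect_equal(est$intercept, 5)
})

test_that("the planted effect is recovered without confounding", {
  fx <- unconfounded_sim()
  naive <- estimate_ate(fx$units, NULL, "log_view_count")
  expect_lt(abs(naive$ate - 2.5), 3 * naive$se)
})

test_that("matching reduces confounding bias and covariate imbalance", {
  fx <- confounded_sim()
  p <- fit_propensity(fx$units)
  m <- match_units(fx$units, "psm", propensity = p)
  b <- balance(fx$units, m)
  expect_lt(mean_abs_smd(b, "matched"), mean_abs_smd(b, "all"))
  naive <- estimate_ate(fx$units, NULL, "log_view_count")
  matched <- estimate_ate(fx$units, m, "log_view_count")
  expect_lt(abs(matched$ate - 2.5), abs(naive$ate - 2.5))
  # CEM at coarse bins also improves balance on the confounded design
  m2 <- match_units(fx$units, "cem", breaks = 4)
  b2 <- balance(fx$units, m2)
  expect_lt(mean_abs_smd(b2, "matched"), mean_abs_smd(b2, "all"))
})
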