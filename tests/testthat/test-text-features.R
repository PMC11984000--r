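test_that("readability formulas match hand arithmetic", {
  expect_equal(readability("The cat sat on the mat.", "ARI"),
               4.71 * (17 / 6) + 0.5 * (6 / 1) - 21.43)
  expect_equal(readability("The cat sat on the mat.", "FK_grade"),
               0.39 * 6 + 11.8 * 1 - 15.59)
  expect_error(readability("", "ARI"), "no words")
  expect_error(readability("  ...  ", "FK_grade"), "no words")
  # two sentences halve the words-per-sentence term
  expect_lt(readability("The cat sat. The dog ran.", "ARI"),
            readability("The cat sat the dog ran.", "ARI"))
})

test_that("active-voice counting follows the verb tag set and excludes participles", {
  expect_equal(count_active_verbs(
    hand_tagged("The/DT doctor/NN explains/VBZ the/DT treatment/NN")), 1)
  expect_equal(count_active_verbs(tagged_tokens(character(), character())), 0)
  # auxiliary past tense counts, past participle does not
  expect_equal(count_active_verbs(
    hand_tagged("The/DT test/NN was/VBD performed/VBN")), 1)
  expect_equal(count_active_verbs(
    hand_tagged("She/PRP is/VBZ testing/VBG and/CC explains/VBZ")), 3)
  expect_error(tagged_tokens("x", "XYZ"), "unknown POS tag")
})

test_that("lexicon phrase counting is case-insensitive, longest-first, non-overlapping", {
  lex_s <- lexicon_summary()
  expect_equal(count_lexicon_phrases("In conclusion, check your blood sugar daily.", lex_s), 1)
  expect_equal(count_lexicon_phrases("", lex_s), 0)
  expect_equal(count_lexicon_phrases("Finally, to sum up, thus we end.", lex_s), 3)
  expect_equal(count_lexicon_phrases("IN CONCLUSION we stop.", lex_s), 1)
  # "to sum up" must match as one phrase, not leave "sum" free for others
  lex <- lexicon("toy", c("to sum up", "sum"))
  expect_equal(count_lexicon_phrases("We need to sum up now.", lex), 1)
  expect_equal(count_lexicon_phrases("The sum is odd.", lex), 1)
  # matches stay within word boundaries
  expect_equal(count_lexicon_phrases("thusly we continue", lex_s), 0)
})

test_that("lexicon counting is additive over sentence-boundary concatenation", {
  set.seed(77)
  for (i in 1:10) {
    a <- plant_text(summary = sample(0:3, 1), transition = sample(0:3, 1))$text
    b <- plant_text(summary = sample(0:3, 1), transition = sample(0:3, 1))$text
    for (lex in list(lexicon_summary(), lexicon_transition())) {
      expect_equal(count_lexicon_phrases(paste(a, b, sep = ". "), lex),
                   count_lexicon_phrases(a, lex) + count_lexicon_phrases(b, lex))
    }
  }
})

test_that("medical term matching counts per category and accepts a plug-in recognizer", {
  m <- count_medical_terms("Insulin and metformin lower HbA1c.")
  expect_equal(m$total, 3)
  expect_equal(unname(m$per_category[c("chemicals_drugs", "medical_procedures")]),
               c(2L, 1L))
  expect_equal(sum(m$per_category), m$total)
  expect_equal(count_medical_terms("")$total, 0)
  expect_equal(count_medical_terms("quantum flux capacitors")$total, 0)
  # longest-first: "insulin pen" is a device, not the drug plus a noun
  m2 <- count_medical_terms("Use an insulin pen daily.")
  expect_equal(unname(m2$per_category["medical_devices"]), 1L)
  expect_equal(unname(m2$per_category["chemicals_drugs"]), 0L)
  # pluggable recognizer replaces the dictionary
  rec <- function(text) data.frame(term = "x", category = "body_part")
  expect_equal(count_medical_terms("anything", recognizer = rec)$total, 1)
})

test_that("metadata features compose the per-feature operations", {
  rec <- make_record("v1", title = "", tags = character(),
                     description = "In conclusion, take insulin daily.")
  f <- build_metadata_features(rec)
  expect_named(f, c("has_title", "has_description", "has_tags",
                    "description_readability", "active_word_count",
                    "summary_word_count", "transition_word_count",
                    "video_duration", "description_word_count", "sentence_count",
                    "description_unique_words",
                    "description_medical_term_count"))
  expect_equal(unname(f["has_title"]), 0)
  expect_equal(unname(f["has_description"]), 1)
  expect_equal(unname(f["has_tags"]), 0)
  expect_equal(unname(f["summary_word_count"]), 1)
  expect_equal(unname(f["description_medical_term_count"]), 1)

  empty <- build_metadata_features(make_record("v2"))
  expect_true(is.na(empty["description_readability"]))
  expect_true(all(empty[c("has_title", "has_description", "has_tags",
                          "active_word_count", "summary_word_count",
                          "description_word_count")] == 0))
  expect_equal(unname(build_metadata_features(
    make_record("v3", tags = c("a", "b", "c")))["has_tags"]), 1)
})

test_that("content features read signals and average screen-text confidences", {
  rec <- make_record("v1")
  sig <- video_signals("v1", transcript = "Finally, check glucose.",
                       transcription_confidence = 0.9, scene_count = 4)
  f <- build_content_features(rec, sig)
  expect_length(f, 12L)
  expect_equal(unname(f["summary_word_count"]), 1)
  expect_equal(unname(f["video_transcription_confidence"]), 0.9)
  expect_equal(unname(f["scene_count"]), 4)
  expect_true(is.na(f["text_detection_confidence"]))

  sig2 <- video_signals("v1", screen_texts = data.frame(
    text = c("a", "b"), confidence = c(0.8, 0.6)))
  f2 <- build_content_features(rec, sig2)
  expect_equal(unname(f2["text_detection_confidence"]), 0.7)
  expect_true(is.na(f2["narrative_readability"]))
  expect_equal(unname(f2["transcript_word_count"]), 0)

  expect_error(build_content_features(rec, NULL), "exclude")
})

test_that("count invariants hold over randomly planted texts", {
  set.seed(88)
  for (i in 1:12) {
    pt <- plant_text(summary = sample(0:4, 1), transition = sample(0:4, 1),
                     active = sample(0:4, 1), medical = sample(0:4, 1),
                     target_words = sample(30:80, 1))
    words <- tokenize_words(pt$text, lower = TRUE)
    expect_lte(length(unique(words)), length(words))
    rec <- make_record("v", description = pt$text)
    f <- build_metadata_features(rec)
    expect_true(all(f[-4] >= 0, na.rm = TRUE))
    expect_lte(unname(f["description_unique_words"]),
               unname(f["description_word_count"]))
  }
})
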