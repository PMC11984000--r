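test_that("reading handles empty files, minimal records, and absent signals", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), p)
  expect_length(read_corpus(p), 0L)

  writeLines(paste0('{"video_id":"a1","duration_s":10,"published_days":5,',
                    '"view_count":3,"like_count":0,"comment_count":0,',
                    '"channel_view_count":100,"channel_subscriber_count":10,',
                    '"channel_video_count":2,"content_definition":"HD"}'), p)
  corpus <- read_corpus(p)
  expect_length(corpus, 1L)
  expect_s3_class(corpus[[1]]$record, "video_record")
  expect_null(corpus[[1]]$signals)
  expect_identical(corpus[[1]]$record$description, "")
  expect_identical(corpus[[1]]$record$tags, character())
})

test_that("validation errors name the line and offending field", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"video_id":"a1","duration_s":10,"published_days":5,',
                    '"view_count":-3,"like_count":0,"comment_count":0,',
                    '"channel_view_count":100,"channel_subscriber_count":10,',
                    '"channel_video_count":2,"content_definition":"HD"}'), p)
  expect_error(read_corpus(p), "line 1.*view_count")

  writeLines(paste0('{"duration_s":10,"published_days":5,"view_count":1,',
                    '"like_count":0,"comment_count":0,"channel_view_count":1,',
                    '"channel_subscriber_count":1,"channel_video_count":1,',
                    '"content_definition":"HD"}'), p)
  expect_error(read_corpus(p), "video_id")
})

test_that("duplicate video ids are rejected on read and before write", {
  rec <- make_record("dup")
  expect_error(
    write_corpus(list(list(record = rec, signals = NULL),
                      list(record = rec, signals = NULL)),
                 withr::local_tempfile()),
    "duplicate video_id")
  p <- withr::local_tempfile(fileext = ".jsonl")
  line <- paste0('{"video_id":"dup","duration_s":1,"published_days":1,',
                 '"view_count":0,"like_count":0,"comment_count":0,',
                 '"channel_view_count":0,"channel_subscriber_count":0,',
                 '"channel_video_count":0,"content_definition":"SD"}')
  writeLines(c(line, line), p)
  expect_error(read_corpus(p), "duplicate video_id")
})

test_that("write/read round-trips preserve every field, including degenerate ones", {
  units <- list(
    list(record = make_record("v1", title = "T", description = "A desc.",
                              tags = c("x", "y"), duration_s = 12.5,
                              published_days = 3, view_count = 9,
                              channel_view_count = 50, content_definition = "SD"),
         signals = video_signals("v1", transcript = "Finally, done.",
                                 transcription_confidence = 0.91,
                                 screen_texts = data.frame(text = c("a", "b"),
                                                           confidence = c(0.5, 0.75)),
                                 scene_count = 4, object_count = 2)),
    list(record = make_record("v2", description = "", tags = character()),
         signals = NULL),
    list(record = make_record("v3", tags = "one"),
         signals = video_signals("v3"))
  )
  rp <- withr::local_tempfile(fileext = ".jsonl")
  sp <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(units, rp, sp)
  back <- read_corpus(rp, sp)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(unclass(back[[i]]$record), unclass(units[[i]]$record))
  }
  expect_null(back[["v2"]]$signals)
  expect_equal(back[["v1"]]$signals$screen_texts$confidence, c(0.5, 0.75))
  expect_equal(back[["v1"]]$signals$transcription_confidence, 0.91)
  expect_true(is.na(back[["v3"]]$signals$transcription_confidence))
})

test_that("reading is insensitive to JSON key order", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"content_definition":"HD","view_count":7,"video_id":"z9",',
                    '"channel_video_count":2,"duration_s":10,"published_days":5,',
                    '"like_count":1,"comment_count":0,"channel_view_count":100,',
                    '"channel_subscriber_count":10}'), p)
  expect_identical(read_corpus(p)[[1]]$record$view_count, 7L)
})

test_that("generated synthetic corpora round-trip identically across seeds", {
  for (seed in c(2, 9)) {
    sim <- generate_corpus(synthetic_config(n_videos = 15, seed = seed))
    rp <- withr::local_tempfile(fileext = ".jsonl")
    sp <- withr::local_tempfile(fileext = ".jsonl")
    write_corpus(sim$corpus, rp, sp)
    back <- read_corpus(rp, sp)
    for (i in seq_along(sim$corpus)) {
      expect_equal(unclass(back[[i]]$record), unclass(sim$corpus[[i]]$record))
      expect_equal(unclass(back[[i]]$signals), unclass(sim$corpus[[i]]$signals))
    }
  }
})

test_that("annotation CSV round-trips 0/1/NA item scores", {
  fx <- list(pemat_assessment("a", c(1, 0, 1, 0, NA, 1, 0, NA, 1, 0, 1, NA)),
             pemat_assessment("b", rep(1, 12)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_annotations(fx, p)
  back <- read_annotations(p)
  expect_equal(back[[1]]$item_scores, fx[[1]]$item_scores)
  expect_equal(back[[2]]$item_scores, fx[[2]]$item_scores)
})
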