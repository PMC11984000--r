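# Corpus I/O: JSON Lines readers/writers for video records and content
# signals, plus the CSV annotation format. One JSON object per line keeps
# the artifacts append- and diff-friendly.

RECORD_NUMERIC_FIELDS <- c(
  "duration_s", "published_days", "view_count", "like_count", "comment_count",
  "channel_view_count", "channel_subscriber_count", "channel_video_count"
)

#' Construct a video record
#'
#' One video's metadata, channel statistics, and engagement counts: the raw
#' material of the metadata feature view. Missing optional text fields are
#' stored as empty (`""` / empty tag vector); the derived purpose-evident
#' flags treat empty as absent.
#'
#' @param video_id Nonempty unique string key.
#' @param title,description Free text; may be empty.
#' @param tags Character vector of tags; may be empty.
#' @param duration_s Video length in seconds (>= 0).
#' @param published_days Days since publication at collection time (>= 0).
#' @param view_count,like_count,comment_count Engagement counts (>= 0).
#' @param channel_view_count,channel_subscriber_count,channel_video_count
#'   Channel statistics snapshotted at collection (>= 0).
#' @param content_definition `"SD"` or `"HD"`.
#' @return An object of class `video_record`.
#' @export
video_record <- function(video_id, title = "", description = "",
                         tags = character(), duration_s = 0,
                         published_days = 0, view_count = 0, like_count = 0,
                         comment_count = 0, channel_view_count = 0,
                         channel_subscriber_count = 0, channel_video_count = 0,
                         content_definition = "HD") {
  rec <- list(
    video_id = video_id, title = title %||% "", description = description %||% "",
    tags = as.character(tags %||% character()), duration_s = duration_s,
    published_days = published_days, view_count = view_count,
    like_count = like_count, comment_count = comment_count,
    channel_view_count = channel_view_count,
    channel_subscriber_count = channel_subscriber_count,
    channel_video_count = channel_video_count,
    content_definition = content_definition
  )
  validate_video_record(rec)
  structure(rec, class = "video_record")
}

validate_video_record <- function(rec, where = "") {
  ctx <- if (nzchar(where)) paste0(" (", where, ")") else ""
  if (!is_string(rec$video_id) || !nzchar(rec$video_id)) {
    vu_stop("invalid field 'video_id': must be a nonempty string", ctx)
  }
  for (f in c("title", "description")) {
    if (!is_string(rec[[f]])) vu_stop("invalid field '", f, "': must be text", ctx)
  }
  if (!is.character(rec$tags)) vu_stop("invalid field 'tags': must be a character vector", ctx)
  if (!is.numeric(rec$duration_s) || length(rec$duration_s) != 1L ||
      !is.finite(rec$duration_s) || rec$duration_s < 0) {
    vu_stop("invalid field 'duration_s': must be a nonnegative number", ctx)
  }
  if (!is.numeric(rec$published_days) || rec$published_days < 0) {
    vu_stop("invalid field 'published_days': must be a nonnegative number", ctx)
  }
  for (f in setdiff(RECORD_NUMERIC_FIELDS, c("duration_s", "published_days"))) {
    if (!is_count(rec[[f]])) {
      vu_stop("invalid field '", f, "': must be a nonnegative integer", ctx)
    }
  }
  if (!is_string(rec$content_definition) ||
      !rec$content_definition %in% c("SD", "HD")) {
    vu_stop("invalid field 'content_definition': must be \"SD\" or \"HD\"", ctx)
  }
  invisible(rec)
}

#' Construct a video signals object
#'
#' Precomputed content-analysis outputs for one video: the transcript and its
#' transcription confidence, on-screen texts with OCR confidences, and scene
#' and object counts. These stand in for the outputs of an upstream video
#' intelligence service; the package never runs ASR/OCR itself.
#'
#' @param video_id String key matching a video record.
#' @param transcript Transcript text; may be empty.
#' @param transcription_confidence Number in `[0, 1]`, or `NA` when absent.
#' @param screen_texts Data frame with columns `text` and `confidence`
#'   (each confidence in `[0, 1]`); may have zero rows.
#' @param scene_count,object_count Nonnegative integers.
#' @return An object of class `video_signals`.
#' @export
video_signals <- function(video_id, transcript = "",
                          transcription_confidence = NA_real_,
                          screen_texts = NULL,
                          scene_count = 0, object_count = 0) {
  if (is.null(screen_texts) || (is.list(screen_texts) && length(screen_texts) == 0L)) {
    screen_texts <- data.frame(text = character(), confidence = numeric(),
                               stringsAsFactors = FALSE)
  }
  sig <- list(
    video_id = video_id, transcript = transcript %||% "",
    transcription_confidence = transcription_confidence,
    screen_texts = screen_texts,
    scene_count = scene_count, object_count = object_count
  )
  validate_video_signals(sig)
  structure(sig, class = "video_signals")
}

validate_video_signals <- function(sig, where = "") {
  ctx <- if (nzchar(where)) paste0(" (", where, ")") else ""
  if (!is_string(sig$video_id) || !nzchar(sig$video_id)) {
    vu_stop("invalid field 'video_id': must be a nonempty string", ctx)
  }
  if (!is_string(sig$transcript)) vu_stop("invalid field 'transcript': must be text", ctx)
  tc <- sig$transcription_confidence
  if (!(length(tc) == 1L && (is.na(tc) || (is.numeric(tc) && tc >= 0 && tc <= 1)))) {
    vu_stop("invalid field 'transcription_confidence': must be in [0,1] or NA", ctx)
  }
  st <- sig$screen_texts
  if (!is.data.frame(st) || !all(c("text", "confidence") %in% names(st))) {
    vu_stop("invalid field 'screen_texts': need columns text, confidence", ctx)
  }
  if (nrow(st) && (any(!is.finite(st$confidence)) ||
                   any(st$confidence < 0) || any(st$confidence > 1))) {
    vu_stop("invalid field 'screen_texts': confidences must lie in [0,1]", ctx)
  }
  for (f in c("scene_count", "object_count")) {
    if (!is_count(sig[[f]])) vu_stop("invalid field '", f, "': must be a nonnegative integer", ctx)
  }
  invisible(sig)
}

#' Read a corpus from JSON Lines files
#'
#' Reads one video record per line, optionally joining precomputed content
#' signals by `video_id`. Input order is preserved; units without signals
#' carry `signals = NULL`.
#'
#' @param records_path Path to the records JSONL file.
#' @param signals_path Optional path to the signals JSONL file.
#' @return An object of class `video_corpus`: a list of units, each a list
#'   with elements `record` (a [video_record]) and `signals`
#'   (a [video_signals] or `NULL`).
#' @export
read_corpus <- function(records_path, signals_path = NULL) {
  if (!file.exists(records_path)) vu_stop("records file not found: ", records_path)
  lines <- readLines(records_path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  units <- vector("list", sum(keep))
  ids <- character(sum(keep))
  k <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    k <- k + 1L
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) vu_stop("line ", i, ": malformed JSON: ",
                                                conditionMessage(e)))
    rec <- tryCatch(
      video_record(
        video_id = obj$video_id %||% vu_stop("line ", i, ": missing field 'video_id'"),
        title = obj$title %||% "", description = obj$description %||% "",
        tags = unlist(obj$tags) %||% character(),
        duration_s = obj$duration_s %||% vu_stop("line ", i, ": missing field 'duration_s'"),
        published_days = obj$published_days %||% vu_stop("line ", i, ": missing field 'published_days'"),
        view_count = obj$view_count %||% vu_stop("line ", i, ": missing field 'view_count'"),
        like_count = obj$like_count %||% vu_stop("line ", i, ": missing field 'like_count'"),
        comment_count = obj$comment_count %||% vu_stop("line ", i, ": missing field 'comment_count'"),
        channel_view_count = obj$channel_view_count %||% vu_stop("line ", i, ": missing field 'channel_view_count'"),
        channel_subscriber_count = obj$channel_subscriber_count %||% vu_stop("line ", i, ": missing field 'channel_subscriber_count'"),
        channel_video_count = obj$channel_video_count %||% vu_stop("line ", i, ": missing field 'channel_video_count'"),
        content_definition = obj$content_definition %||% vu_stop("line ", i, ": missing field 'content_definition'")
      ),
      error = function(e) vu_stop("line ", i, ": ", conditionMessage(e))
    )
    ids[k] <- rec$video_id
    units[[k]] <- list(record = rec, signals = NULL)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) vu_stop("duplicate video_id in records: ", paste(unique(dup), collapse = ", "))
  names(units) <- ids

  if (!is.null(signals_path)) {
    if (!file.exists(signals_path)) vu_stop("signals file not found: ", signals_path)
    slines <- readLines(signals_path, warn = FALSE)
    for (i in seq_along(slines)) {
      if (!nzchar(trimws(slines[i]))) next
      obj <- tryCatch(jsonlite::fromJSON(slines[i], simplifyVector = TRUE),
                      error = function(e) vu_stop("signals line ", i, ": malformed JSON: ",
                                                  conditionMessage(e)))
      st <- obj$screen_texts
      if (is.null(st) || (is.list(st) && !is.data.frame(st) && length(st) == 0L)) {
        st <- NULL
      }
      sig <- tryCatch(
        video_signals(
          video_id = obj$video_id %||% vu_stop("signals line ", i, ": missing field 'video_id'"),
          transcript = obj$transcript %||% "",
          transcription_confidence = obj$transcription_confidence %||% NA_real_,
          screen_texts = st,
          scene_count = obj$scene_count %||% 0,
          object_count = obj$object_count %||% 0
        ),
        error = function(e) vu_stop("signals line ", i, ": ", conditionMessage(e))
      )
      if (sig$video_id %in% names(units)) {
        units[[sig$video_id]]$signals <- sig
      }
    }
  }
  structure(units, class = "video_corpus")
}

#' Write a corpus to JSON Lines files
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x))` reproduces the
#' units field-for-field, including the distinction between empty and
#' populated optional fields.
#'
#' @param corpus A `video_corpus` (or plain list of units).
#' @param records_path Output path for the records JSONL.
#' @param signals_path Optional output path for the signals JSONL; units
#'   without signals are skipped there.
#' @return Invisibly, `corpus`.
#' @export
write_corpus <- function(corpus, records_path, signals_path = NULL) {
  ids <- vapply(corpus, function(u) u$record$video_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) vu_stop("duplicate video_id in corpus: ", paste(unique(dup), collapse = ", "))
  rec_lines <- vapply(corpus, function(u) {
    rec <- unclass(u$record)
    rec$tags <- I(rec$tags)  # keep tags a JSON array even when length <= 1
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"))
  }, character(1))
  writeLines(rec_lines, records_path)
  if (!is.null(signals_path)) {
    has_sig <- !vapply(corpus, function(u) is.null(u$signals), logical(1))
    sig_lines <- vapply(corpus[has_sig], function(u) {
      sig <- unclass(u$signals)
      if (is.na(sig$transcription_confidence)) sig$transcription_confidence <- NULL
      as.character(jsonlite::toJSON(sig, auto_unbox = TRUE, digits = NA,
                                    null = "null", dataframe = "rows"))
    }, character(1))
    writeLines(sig_lines, signals_path)
  }
  invisible(corpus)
}

#' @export
print.video_corpus <- function(x, ...) {
  n_sig <- sum(!vapply(x, function(u) is.null(u$signals), logical(1)))
  cat("<video_corpus> ", length(x), " units (", n_sig, " with content signals)\n", sep = "")
  invisible(x)
}

#' Read PEMAT annotations from CSV
#'
#' Expects a header `video_id,item_01,...,item_12` with cell tokens `0`, `1`
#' or `NA`.
#'
#' @param path CSV path.
#' @return A list of [pemat_assessment] objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) vu_stop("annotations file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  item_cols <- sprintf("item_%02d", 1:12)
  if (!all(c("video_id", item_cols) %in% names(df))) {
    vu_stop("annotations CSV must have columns video_id, item_01..item_12")
  }
  lapply(seq_len(nrow(df)), function(i) {
    raw <- unlist(df[i, item_cols], use.names = FALSE)
    scores <- suppressWarnings(as.integer(raw))
    scores[raw %in% c("NA", "N/A", "na", "")] <- NA_integer_
    pemat_assessment(df$video_id[i], scores)
  })
}

#' Write PEMAT annotations to CSV
#'
#' @param assessments List of [pemat_assessment] objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(assessments, path) {
  rows <- vapply(assessments, function(a) {
    toks <- ifelse(is.na(a$item_scores), "NA", as.character(a$item_scores))
    paste(c(a$video_id, toks), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("video_id", sprintf("item_%02d", 1:12)), collapse = ","), rows), path)
  invisible(path)
}
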