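# PEMAT (Patient Education Materials Assessment Tool, audio/visual form)
# understandability scoring. Twelve items are scored agree (1) / disagree (0);
# seven of them additionally admit "not applicable". The understandability
# score is the percentage of applicable items scored agree, and a video is
# called highly understandable when that score strictly exceeds 50%.

#' The PEMAT audio/visual understandability item schema
#'
#' @return A data frame with columns `item_id`, `item_label`, `aspect` and
#'   `na_allowed`. Seven items (chunking, headers, summary, on-screen text,
#'   audibility, illustrations, tables) admit an N/A score; the remaining
#'   five admit only 0/1.
#' @export
pemat_items <- function() {
  data.frame(
    item_id = sprintf("item_%02d", 1:12),
    item_label = c(
      "Purpose completely evident",
      "Common, everyday language",
      "Medical terms defined",
      "Active voice",
      "Chunks information into short sections",
      "Informative headers",
      "Logical sequence",
      "Provides a summary",
      "Text on screen easy to read",
      "Words heard clearly",
      "Clear illustrations and photographs",
      "Simple tables with clear headings"
    ),
    aspect = c("content", rep("word choice and style", 3),
               rep("organization", 4), rep("layout and design", 4)),
    na_allowed = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
                   TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Construct a PEMAT assessment
#'
#' @param video_id String key.
#' @param item_scores Length-12 vector over the [pemat_items()] schema, each
#'   element 0, 1 or `NA`. `NA` is rejected on the five items that do not
#'   admit it, as is an all-`NA` assessment (the score would have an empty
#'   denominator).
#' @return An object of class `pemat_assessment`.
#' @export
pemat_assessment <- function(video_id, item_scores) {
  if (!is_string(video_id) || !nzchar(video_id)) vu_stop("video_id must be a nonempty string")
  s <- as.integer(item_scores)
  if (length(s) != 12L) vu_stop("item_scores must have exactly 12 slots")
  if (any(!is.na(s) & !s %in% c(0L, 1L))) vu_stop("item scores must be 0, 1 or NA")
  items <- pemat_items()
  bad <- which(is.na(s) & !items$na_allowed)
  if (length(bad)) {
    vu_stop("NA not permitted on item(s): ", paste(items$item_id[bad], collapse = ", "))
  }
  if (all(is.na(s))) vu_stop("all-NA assessment: at least one item must be applicable")
  structure(list(video_id = video_id, item_scores = s), class = "pemat_assessment")
}

#' PEMAT understandability score and binary label
#'
#' The score is `100 * agreed / applicable`, where applicable items are those
#' not scored N/A. The binary label is `"high"` exactly when the score
#' strictly exceeds 50 (a score of exactly 50 is `"low"`).
#'
#' @param assessment A [pemat_assessment].
#' @return An object of class `understandability_result`: a list with
#'   `score_pct` (in `[0, 100]`), `label` (`"low"` or `"high"`) and
#'   `n_applicable`.
#' @export
understandability_score <- function(assessment) {
  if (!inherits(assessment, "pemat_assessment")) {
    vu_stop("understandability_score() expects a pemat_assessment")
  }
  s <- assessment$item_scores
  n_app <- sum(!is.na(s))
  score <- 100 * sum(s, na.rm = TRUE) / n_app
  structure(
    list(video_id = assessment$video_id, score_pct = score,
         label = if (score > 50) "high" else "low", n_applicable = n_app),
    class = "understandability_result"
  )
}

#' @export
print.understandability_result <- function(x, ...) {
  cat(sprintf("PEMAT understandability: %.1f%% (%s; %d applicable items)\n",
              x$score_pct, x$label, x$n_applicable))
  invisible(x)
}

#' Summarize a set of PEMAT annotations
#'
#' Counts 0/1/N/A per item and the derived low/high understandability split,
#' with percentages of N rounded half-up to one decimal for reporting
#' (internal comparisons use the exact counts).
#'
#' @param assessments Nonempty list of [pemat_assessment] objects.
#' @return An object of class `annotation_summary`: a list with `n`, a
#'   per-item data frame `items` (counts and percentages), and `overall`
#'   (low/high counts and percentages).
#' @export
summarize_annotations <- function(assessments) {
  if (!length(assessments)) vu_stop("summarize_annotations() needs a nonempty list")
  ok <- vapply(assessments, inherits, logical(1), what = "pemat_assessment")
  if (!all(ok)) vu_stop("all elements must be pemat_assessment objects")
  n <- length(assessments)
  mat <- t(vapply(assessments, function(a) a$item_scores, integer(12)))
  items <- pemat_items()
  count0 <- colSums(mat == 0L, na.rm = TRUE)
  count1 <- colSums(mat == 1L, na.rm = TRUE)
  countNA <- colSums(is.na(mat))
  labels <- vapply(assessments, function(a) understandability_score(a)$label, character(1))
  n_high <- sum(labels == "high")
  structure(list(
    n = n,
    items = data.frame(
      item_id = items$item_id, item_label = items$item_label,
      count0 = count0, count1 = count1, countNA = countNA,
      pct0 = round_half_up(100 * count0 / n, 1),
      pct1 = round_half_up(100 * count1 / n, 1),
      pctNA = round_half_up(100 * countNA / n, 1),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    overall = list(
      count_low = n - n_high, count_high = n_high,
      pct_low = round_half_up(100 * (n - n_high) / n, 1),
      pct_high = round_half_up(100 * n_high / n, 1)
    )
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("PEMAT annotation summary (N = ", x$n, ")\n", sep = "")
  df <- x$items
  df$`0 (no)` <- sprintf("%d (%.1f)", df$count0, df$pct0)
  df$`1 (yes)` <- sprintf("%d (%.1f)", df$count1, df$pct1)
  df$`N/A` <- sprintf("%d (%.1f)", df$countNA, df$pctNA)
  print(df[, c("item_id", "0 (no)", "1 (yes)", "N/A")], row.names = FALSE)
  cat(sprintf("Understandability: low %d (%.1f), high %d (%.1f)\n",
              x$overall$count_low, x$overall$pct_low,
              x$overall$count_high, x$overall$pct_high))
  invisible(x)
}

#' Write an annotation summary as CSV
#'
#' Emits the per-item rows plus an `overall` row (count0 = low, count1 = high).
#'
#' @param summary An `annotation_summary`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_annotation_summary <- function(summary, path) {
  df <- summary$items
  overall <- data.frame(
    item_id = "overall", item_label = "Understandability",
    count0 = summary$overall$count_low, count1 = summary$overall$count_high,
    countNA = 0L, pct0 = summary$overall$pct_low, pct1 = summary$overall$pct_high,
    pctNA = 0, stringsAsFactors = FALSE
  )
  utils::write.csv(rbind(df, overall), path, row.names = FALSE)
  invisible(path)
}

#' Packaged reference annotation marginals
#'
#' Per-item 0/1/N/A counts, and the overall low/high split, from a reference
#' 700-video expert annotation exercise on diabetes education videos. Used to
#' build fixture assessment sets with [build_marginal_assessments()].
#'
#' @return A data frame with columns `item_id`, `item_label`, `count0`,
#'   `count1`, `countNA`; the final row (`item_id == "overall"`) carries the
#'   low/high label split.
#' @export
reference_annotation_marginals <- function() {
  path <- system.file("extdata", "annotation_marginals_700.csv", package = "vidunder")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a fixture assessment set matching item-wise marginal counts
#'
#' Constructs `N` assessments whose per-item 0/1/N/A counts equal the given
#' marginals and whose derived low/high understandability split equals the
#' given target. Items are filled independently per row (only marginals are
#' constrained): designated high rows receive each item's agree scores first
#' and its N/As next, while the leftover agree scores spill into the first
#' low rows and leftover N/As fill low rows from the bottom up, keeping every
#' designated low row at or below the 50% threshold. The construction is
#' verified before returning; unrealizable marginals are an error.
#'
#' @param marginals Data frame with columns `item_id`, `count0`, `count1`,
#'   `countNA` for the 12 items, plus optionally a row `item_id == "overall"`
#'   whose `count1` is the target number of high-label rows (required if
#'   `n_high` is not given).
#' @param n_high Target number of rows with the high label; defaults to the
#'   `overall` row of `marginals`.
#' @return A list of `N` [pemat_assessment] objects (ids `fx_0001`, ...).
#' @export
build_marginal_assessments <- function(marginals, n_high = NULL) {
  ov <- marginals$item_id == "overall"
  if (is.null(n_high)) {
    if (!any(ov)) vu_stop("n_high not given and no 'overall' row in marginals")
    n_high <- marginals$count1[ov]
  }
  m <- marginals[!ov, , drop = FALSE]
  m <- m[match(sprintf("item_%02d", 1:12), m$item_id), ]
  if (any(is.na(m$item_id))) vu_stop("marginals must cover item_01..item_12")
  n_total <- unique(m$count0 + m$count1 + m$countNA)
  if (length(n_total) != 1L) vu_stop("item marginals must sum to a common N")
  N <- n_total
  H <- n_high
  items <- pemat_items()

  mat <- matrix(0L, nrow = N, ncol = 12)
  for (j in 1:12) {
    n1 <- m$count1[j]; nNA <- m$countNA[j]
    if (nNA > 0 && !items$na_allowed[j]) {
      vu_stop("marginals assign N/A to item ", m$item_id[j], ", which does not admit it")
    }
    ones <- seq_len(min(n1, N))
    if (n1 > N) vu_stop("count1 exceeds N for ", m$item_id[j])
    na_rows <- integer()
    if (nNA > 0) {
      # N/As go to high rows not already holding a 1, then to the last low rows
      gap <- if (n1 < H) seq.int(n1 + 1L, H) else integer()
      take <- min(nNA, length(gap))
      na_rows <- gap[seq_len(take)]
      rest <- nNA - take
      if (rest > 0) {
        bottom <- seq.int(N - rest + 1L, N)
        if (any(bottom %in% ones)) {
          vu_stop("marginals not realizable: N/A block overlaps agree block on ",
                  m$item_id[j])
        }
        na_rows <- c(na_rows, bottom)
      }
    }
    mat[ones, j] <- 1L
    mat[na_rows, j] <- NA_integer_
  }
  ids <- sprintf("fx_%04d", seq_len(N))
  out <- lapply(seq_len(N), function(i) pemat_assessment(ids[i], mat[i, ]))
  labels <- vapply(out, function(a) understandability_score(a)$label, character(1))
  got_high <- sum(labels == "high")
  if (got_high != H || !all(labels[seq_len(H)] == "high")) {
    vu_stop("marginals not realizable by this construction: got ", got_high,
            " high rows, wanted ", H)
  }
  out
}
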