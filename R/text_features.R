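# Text and signal features mapped to the PEMAT criteria, and the assembly of
# the two 12-slot per-view feature vectors (metadata view and content view).
#
# Tokenization contract (deterministic, documented):
#   * words are maximal runs of alphanumerics plus apostrophe/hyphen;
#   * sentences split on . ! ? followed by whitespace or end of text;
#   * ARI uses a letters-only character count;
#   * FK syllables use a vowel-group heuristic (consecutive vowels = one
#     group, silent final "e" dropped unless the word ends in "le",
#     minimum one syllable per word).

#' Tokenize text into words
#'
#' Words are maximal runs of letters, digits, apostrophes and hyphens.
#'
#' @param text A single string.
#' @param lower Lowercase the tokens (default `FALSE`).
#' @return Character vector of word tokens (possibly empty).
#' @export
tokenize_words <- function(text, lower = FALSE) {
  if (!is_string(text)) vu_stop("text must be a single string")
  if (lower) text <- tolower(text)
  toks <- regmatches(text, gregexpr("[A-Za-z0-9][A-Za-z0-9'-]*", text))[[1]]
  toks[nzchar(toks)]
}

#' Split text into sentences
#'
#' Sentences end at `.`, `!` or `?` followed by whitespace or end of text;
#' text without a terminator is a single sentence. Fragments with no word
#' tokens are dropped.
#'
#' @param text A single string.
#' @return Character vector of sentences (possibly empty).
#' @export
split_sentences <- function(text) {
  if (!is_string(text)) vu_stop("text must be a single string")
  parts <- strsplit(text, "(?<=[.!?])\\s+|(?<=[.!?])$", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[vapply(parts, function(p) length(tokenize_words(p)) > 0, logical(1))]
}

count_letters <- function(text) {
  sum(nchar(gsub("[^A-Za-z]", "", text)))
}

count_syllables_word <- function(word) {
  w <- tolower(gsub("[^a-z]", "", tolower(word)))
  if (!nzchar(w)) return(0L)
  groups <- length(regmatches(w, gregexpr("[aeiouy]+", w))[[1]])
  if (groups > 1 && grepl("e$", w) && !grepl("le$", w)) groups <- groups - 1L
  max(groups, 1L)
}

#' Readability indices
#'
#' Computes the Automated Readability Index (ARI) or the Flesch-Kincaid
#' grade level on one text:
#' \deqn{ARI = 4.71 (letters/words) + 0.5 (words/sentences) - 21.43}
#' \deqn{FK  = 0.39 (words/sentences) + 11.8 (syllables/words) - 15.59}
#'
#' @param text A single string with at least one word.
#' @param index `"ARI"` (default) or `"FK_grade"`.
#' @return The index score (a grade-level style number; can be negative for
#'   very simple text).
#' @examples
#' readability("The cat sat on the mat.", "ARI")
#' @export
readability <- function(text, index = c("ARI", "FK_grade")) {
  index <- match.arg(index)
  words <- tokenize_words(text)
  if (!length(words)) vu_stop("readability is undefined for text with no words")
  n_w <- length(words)
  n_s <- max(length(split_sentences(text)), 1L)
  if (index == "ARI") {
    4.71 * (count_letters(text) / n_w) + 0.5 * (n_w / n_s) - 21.43
  } else {
    n_syl <- sum(vapply(words, count_syllables_word, integer(1)))
    0.39 * (n_w / n_s) + 11.8 * (n_syl / n_w) - 15.59
  }
}

## ---- lexicons --------------------------------------------------------------

#' Construct a phrase lexicon
#'
#' @param name Lexicon name.
#' @param phrases Character vector of phrases (1+ tokens each); lowercased
#'   and deduplicated. Empty phrases are an error.
#' @param category Optional category label (used by the medical lexicons).
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(name, phrases, category = NULL) {
  phrases <- tolower(trimws(phrases))
  if (any(!nzchar(phrases))) vu_stop("lexicon phrases must be nonempty")
  phrases <- unique(phrases)
  toks <- lapply(phrases, function(p) tokenize_words(p, lower = TRUE))
  if (any(lengths(toks) == 0L)) vu_stop("lexicon phrases must contain at least one word")
  structure(list(name = name, category = category, phrases = phrases,
                 phrase_tokens = toks), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", x$name,
      if (!is.null(x$category)) paste0(" [", x$category, "]"),
      ": ", length(x$phrases), " phrases\n", sep = "")
  invisible(x)
}

#' Read a lexicon from a plain-text file
#'
#' One phrase per line; header comment lines `# lexicon: <name>` and
#' `# category: <category>` name the lexicon.
#'
#' @param path File path.
#' @return A [lexicon].
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) vu_stop("lexicon file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  name <- sub("^#\\s*lexicon:\\s*", "", grep("^#\\s*lexicon:", hdr, value = TRUE)[1])
  cat_line <- grep("^#\\s*category:", hdr, value = TRUE)
  category <- if (length(cat_line)) sub("^#\\s*category:\\s*", "", cat_line[1]) else NULL
  phrases <- trimws(grep("^#", lines, value = TRUE, invert = TRUE))
  phrases <- phrases[nzchar(phrases)]
  lexicon(if (is.na(name)) basename(path) else name, phrases, category)
}

.lex_cache <- new.env(parent = emptyenv())

packaged_lexicon <- function(file) {
  if (is.null(.lex_cache[[file]])) {
    .lex_cache[[file]] <- read_lexicon(
      system.file("extdata", file, package = "vidunder"))
  }
  .lex_cache[[file]]
}

#' Packaged summary-phrase lexicon
#' @return A [lexicon] of summary/conclusion words and phrases.
#' @export
lexicon_summary <- function() packaged_lexicon("lexicon_summary.txt")

#' Packaged transition-phrase lexicon
#' @return A [lexicon] of transition words and phrases.
#' @export
lexicon_transition <- function() packaged_lexicon("lexicon_transition.txt")

#' Packaged medical term lexicons
#'
#' A starter dictionary seeded with example terms for the six categories of
#' medical terminology found in patient-education materials (body parts,
#' chemicals/drugs, medical devices, medical events, medical professionals,
#' medical procedures). Extend by placing additional phrase files in the
#' same one-phrase-per-line format and passing them to
#' [count_medical_terms()].
#'
#' @return A named list of six [lexicon] objects.
#' @export
lexicon_medical <- function() {
  cats <- c("body_part", "chemicals_drugs", "medical_devices",
            "medical_events", "medical_professionals", "medical_procedures")
  out <- lapply(cats, function(cc) packaged_lexicon(paste0("lexicon_medical_", cc, ".txt")))
  names(out) <- cats
  out
}

# Greedy longest-first, non-overlapping phrase matching at word boundaries,
# within sentences (so counting is additive over sentence concatenation).
# Returns a character vector of matched phrases, in match order.
match_phrases <- function(text, phrase_tokens, phrase_keys) {
  if (!nzchar(trimws(text))) return(character())
  lens <- lengths(phrase_tokens)
  max_len <- max(lens)
  key_set <- new.env(parent = emptyenv())
  for (i in seq_along(phrase_tokens)) {
    assign(paste(phrase_tokens[[i]], collapse = " "), phrase_keys[i], envir = key_set)
  }
  hits <- character()
  for (sent in split_sentences(text)) {
    toks <- tokenize_words(sent, lower = TRUE)
    n <- length(toks)
    i <- 1L
    while (i <= n) {
      matched <- FALSE
      for (len in seq.int(min(max_len, n - i + 1L), 1L)) {
        key <- paste(toks[i:(i + len - 1L)], collapse = " ")
        if (!is.null(key_set[[key]])) {
          hits <- c(hits, key_set[[key]])
          i <- i + len
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  hits
}

#' Count lexicon phrase occurrences in text
#'
#' Case-insensitive count of non-overlapping phrase occurrences at word
#' boundaries, matching longest phrases first. Matches do not cross sentence
#' boundaries, so the count is additive over concatenation with a
#' sentence-boundary separator.
#'
#' @param text A single string (empty text counts 0).
#' @param lex A [lexicon].
#' @return Nonnegative integer count.
#' @examples
#' count_lexicon_phrases("Finally, to sum up, thus we end.", lexicon_summary())
#' @export
count_lexicon_phrases <- function(text, lex) {
  if (!inherits(lex, "lexicon")) vu_stop("lex must be a lexicon")
  if (!length(lex$phrases)) vu_stop("lexicon is empty")
  length(match_phrases(text, lex$phrase_tokens, lex$phrases))
}

#' Count medical terms in text
#'
#' Dictionary matcher over the six medical-term category lexicons, with the
#' same longest-first non-overlapping word-boundary rule as
#' [count_lexicon_phrases()]. The recognizer is pluggable: supply
#' `recognizer` to replace the dictionary with a learned tagger returning a
#' data frame of `term`/`category` mentions.
#'
#' @param text A single string.
#' @param lexicons List of category [lexicon] objects
#'   (default [lexicon_medical()]).
#' @param recognizer Optional `function(text)` returning a data frame with a
#'   `category` column, one row per recognized mention.
#' @return A list with `total` and named `per_category` counts
#'   (`sum(per_category) == total`).
#' @export
count_medical_terms <- function(text, lexicons = lexicon_medical(), recognizer = NULL) {
  cats <- vapply(lexicons, function(l) l$category %||% l$name, character(1))
  if (!is.null(recognizer)) {
    mentions <- recognizer(text)
    per <- table(factor(mentions$category, levels = cats))
  } else {
    all_tokens <- unlist(lapply(lexicons, function(l) l$phrase_tokens), recursive = FALSE)
    all_cats <- rep(cats, vapply(lexicons, function(l) length(l$phrases), integer(1)))
    hits <- match_phrases(text, all_tokens, all_cats)
    per <- table(factor(hits, levels = cats))
  }
  per <- stats::setNames(as.integer(per), cats)
  list(total = sum(per), per_category = per)
}

## ---- part-of-speech tagging ------------------------------------------------

PENN_TAGS <- c("CC", "CD", "DT", "EX", "FW", "IN", "JJ", "JJR", "JJS", "LS",
               "MD", "NN", "NNS", "NNP", "NNPS", "PDT", "POS", "PRP", "PRP$",
               "RB", "RBR", "RBS", "RP", "SYM", "TO", "UH", "VB", "VBD",
               "VBG", "VBN", "VBP", "VBZ", "WDT", "WP", "WP$", "WRB")

ACTIVE_VERB_TAGS <- c("VB", "VBD", "VBG", "VBP", "VBZ")

#' Construct tagged tokens
#'
#' @param token Character vector of tokens.
#' @param pos_tag Penn-Treebank-style tag per token.
#' @return A data frame of class `tagged_tokens`.
#' @export
tagged_tokens <- function(token, pos_tag) {
  if (length(token) != length(pos_tag)) vu_stop("token and pos_tag lengths differ")
  bad <- setdiff(unique(pos_tag), PENN_TAGS)
  if (length(bad)) vu_stop("unknown POS tag(s): ", paste(bad, collapse = ", "))
  structure(data.frame(token = as.character(token), pos_tag = as.character(pos_tag),
                       stringsAsFactors = FALSE),
            class = c("tagged_tokens", "data.frame"))
}

#' Parse a slash-tagged string into tagged tokens
#'
#' Convenience for hand-tagged fixtures, e.g.
#' `hand_tagged("The/DT doctor/NN explains/VBZ")`.
#'
#' @param text Tokens in `token/TAG` form separated by whitespace.
#' @return A [tagged_tokens] data frame.
#' @export
hand_tagged <- function(text) {
  parts <- strsplit(trimws(text), "\\s+")[[1]]
  if (!length(parts)) return(tagged_tokens(character(), character()))
  toks <- sub("/[^/]*$", "", parts)
  tags <- sub("^.*/", "", parts)
  tagged_tokens(toks, tags)
}

# Closed-class dictionary for the built-in fallback tagger.
.TAG_DICT <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", of = "IN", on = "IN", at = "IN", by = "IN", with = "IN",
  from = "IN", into = "IN", about = "IN", over = "IN", under = "IN",
  daily = "RB", very = "RB", i = "PRP", you = "PRP", he = "PRP", she = "PRP",
  it = "PRP", we = "PRP", they = "PRP", your = "PRP$", their = "PRP$",
  be = "VB", is = "VBZ", are = "VBP", was = "VBD", were = "VBD", been = "VBN",
  am = "VBP", has = "VBZ", have = "VBP", had = "VBD", do = "VBP", does = "VBZ",
  did = "VBD", can = "MD", will = "MD", should = "MD", must = "MD",
  check = "VB", take = "VB", eat = "VB", drink = "VB", ask = "VB",
  explain = "VB", explains = "VBZ", explained = "VBD", explaining = "VBG",
  show = "VB", shows = "VBZ", showed = "VBD", showing = "VBG",
  help = "VB", helps = "VBZ", helped = "VBD", helping = "VBG",
  describe = "VB", describes = "VBZ", lower = "VB", lowers = "VBZ",
  measure = "VB", measures = "VBZ", monitor = "VB", monitors = "VBZ"
)

#' Built-in fallback part-of-speech tagger
#'
#' A small deterministic dictionary-and-suffix tagger: closed-class words and
#' common verbs are looked up; `-ing` maps to VBG and unknown tokens to NN.
#' It is intentionally crude — the tagging backend is a pluggable contract
#' (`function(text) -> tagged_tokens`), and correctness of
#' [count_active_verbs()] is established on hand-tagged input.
#'
#' @param text A single string.
#' @return A [tagged_tokens] data frame.
#' @export
default_pos_tagger <- function(text) {
  toks <- tokenize_words(text)
  if (!length(toks)) return(tagged_tokens(character(), character()))
  lw <- tolower(toks)
  tags <- unname(.TAG_DICT[lw])
  unknown <- is.na(tags)
  tags[unknown & grepl("ing$", lw)] <- "VBG"
  tags[unknown & grepl("^[0-9]", lw)] <- "CD"
  tags[is.na(tags)] <- "NN"
  tagged_tokens(toks, tags)
}

#' Count verbs in active voice
#'
#' Counts tokens whose tag is in the active-voice verb tag set: base form
#' (VB), past tense (VBD), gerund/present participle (VBG), non-3rd-person
#' singular present (VBP) and 3rd-person singular present (VBZ). Past
#' participles (VBN) are excluded.
#'
#' @param tagged A [tagged_tokens] data frame.
#' @return Nonnegative integer count (empty input counts 0).
#' @examples
#' count_active_verbs(hand_tagged("The/DT test/NN was/VBD performed/VBN"))
#' @export
count_active_verbs <- function(tagged) {
  if (!inherits(tagged, "tagged_tokens")) vu_stop("expected tagged_tokens")
  sum(tagged$pos_tag %in% ACTIVE_VERB_TAGS)
}

## ---- per-view feature vectors ----------------------------------------------

METADATA_FEATURE_NAMES <- c(
  "has_title", "has_description", "has_tags", "description_readability",
  "active_word_count", "summary_word_count", "transition_word_count",
  "video_duration", "description_word_count", "sentence_count",
  "description_unique_words", "description_medical_term_count"
)

CONTENT_FEATURE_NAMES <- c(
  "narrative_readability", "active_word_count", "summary_word_count",
  "transition_word_count", "video_transcription_confidence",
  "text_detection_confidence", "scene_count", "transcript_word_count",
  "transcript_unique_word", "transcript_sentence_count",
  "transcript_medical_term", "video_object"
)

text_view_counts <- function(text, tagger, medical) {
  words <- tokenize_words(text, lower = TRUE)
  list(
    active = count_active_verbs(tagger(text)),
    summary = count_lexicon_phrases(text, lexicon_summary()),
    transition = count_lexicon_phrases(text, lexicon_transition()),
    words = length(words),
    sentences = length(split_sentences(text)),
    unique_words = length(unique(words)),
    medical = count_medical_terms(text, medical)$total
  )
}

#' Metadata-view feature vector
#'
#' The 12 features of the video metadata view: purpose-evident flags
#' (has title/description/tags, empty counting as absent), description
#' readability, active-voice / summary / transition counts, duration, and
#' description word, sentence, unique-word and medical-term counts. With an
#' empty description the readability slot carries the missing-value code
#' `NA` and all description-derived counts are 0.
#'
#' @param record A [video_record].
#' @param tagger POS tagging backend, `function(text) -> tagged_tokens`.
#' @param readability_index `"ARI"` (default) or `"FK_grade"`.
#' @param medical Medical lexicon list (default [lexicon_medical()]).
#' @return Named numeric vector of length 12 (class `view_features`).
#' @export
build_metadata_features <- function(record, tagger = default_pos_tagger,
                                    readability_index = "ARI",
                                    medical = lexicon_medical()) {
  validate_video_record(unclass(record))
  desc <- record$description
  has_desc <- nzchar(trimws(desc))
  cnt <- if (has_desc) text_view_counts(desc, tagger, medical) else
    list(active = 0, summary = 0, transition = 0, words = 0, sentences = 0,
         unique_words = 0, medical = 0)
  v <- c(
    has_title = as.numeric(nzchar(trimws(record$title))),
    has_description = as.numeric(has_desc),
    has_tags = as.numeric(length(record$tags) > 0 && any(nzchar(trimws(record$tags)))),
    description_readability = if (has_desc) readability(desc, readability_index) else NA_real_,
    active_word_count = cnt$active,
    summary_word_count = cnt$summary,
    transition_word_count = cnt$transition,
    video_duration = record$duration_s,
    description_word_count = cnt$words,
    sentence_count = cnt$sentences,
    description_unique_words = cnt$unique_words,
    description_medical_term_count = cnt$medical
  )
  structure(v[METADATA_FEATURE_NAMES], class = "view_features", view = "metadata")
}

#' Content-view feature vector
#'
#' The 12 features of the video content view: narrative (transcript)
#' readability, active-voice / summary / transition counts, transcription
#' confidence, mean on-screen-text detection confidence, scene count,
#' transcript word / unique-word / sentence / medical-term counts, and
#' object count. Absent confidences and the readability of an empty
#' transcript carry the missing-value code `NA`.
#'
#' @param record A [video_record].
#' @param signals A [video_signals]; `NULL` is an error — the analysis
#'   includes only videos with both a description and a narrative, so units
#'   without signals must be excluded by the caller.
#' @inheritParams build_metadata_features
#' @return Named numeric vector of length 12 (class `view_features`).
#' @export
build_content_features <- function(record, signals, tagger = default_pos_tagger,
                                   readability_index = "ARI",
                                   medical = lexicon_medical()) {
  if (is.null(signals)) {
    vu_stop("unit ", record$video_id, " has no content signals; ",
            "exclude units without signals before building content features")
  }
  validate_video_signals(unclass(signals))
  tr <- signals$transcript
  has_tr <- nzchar(trimws(tr))
  cnt <- if (has_tr) text_view_counts(tr, tagger, medical) else
    list(active = 0, summary = 0, transition = 0, words = 0, sentences = 0,
         unique_words = 0, medical = 0)
  tdc <- if (nrow(signals$screen_texts)) mean(signals$screen_texts$confidence) else NA_real_
  v <- c(
    narrative_readability = if (has_tr) readability(tr, readability_index) else NA_real_,
    active_word_count = cnt$active,
    summary_word_count = cnt$summary,
    transition_word_count = cnt$transition,
    video_transcription_confidence = signals$transcription_confidence,
    text_detection_confidence = tdc,
    scene_count = as.numeric(signals$scene_count),
    transcript_word_count = cnt$words,
    transcript_unique_word = cnt$unique_words,
    transcript_sentence_count = cnt$sentences,
    transcript_medical_term = cnt$medical,
    video_object = as.numeric(signals$object_count)
  )
  structure(v[CONTENT_FEATURE_NAMES], class = "view_features", view = "content")
}

#' Feature matrices for both views of a corpus
#'
#' Builds the metadata-view and content-view feature matrices for all units
#' that carry content signals. Units without signals are an error unless
#' `drop_incomplete = TRUE`, mirroring the inclusion rule that only videos
#' with both a description and a narrative enter the analysis.
#'
#' @param corpus A `video_corpus`.
#' @param drop_incomplete Drop units without signals instead of erroring.
#' @inheritParams build_metadata_features
#' @return A list with matrices `meta` and `content` (rows named by
#'   `video_id`, 12 named columns each) and the `video_id` vector `ids`.
#' @export
view_matrices <- function(corpus, drop_incomplete = FALSE,
                          tagger = default_pos_tagger,
                          readability_index = "ARI",
                          medical = lexicon_medical()) {
  has_sig <- vapply(corpus, function(u) !is.null(u$signals), logical(1))
  if (!all(has_sig)) {
    if (!drop_incomplete) {
      vu_stop(sum(!has_sig), " unit(s) lack content signals; pass ",
              "drop_incomplete = TRUE to exclude them")
    }
    corpus <- corpus[has_sig]
  }
  meta <- t(vapply(corpus, function(u)
    build_metadata_features(u$record, tagger, readability_index, medical),
    numeric(12)))
  content <- t(vapply(corpus, function(u)
    build_content_features(u$record, u$signals, tagger, readability_index, medical),
    numeric(12)))
  ids <- vapply(corpus, function(u) u$record$video_id, character(1))
  rownames(meta) <- rownames(content) <- ids
  colnames(meta) <- METADATA_FEATURE_NAMES
  colnames(content) <- CONTENT_FEATURE_NAMES
  list(meta = meta, content = content, ids = ids)
}

#' Write a per-view feature matrix as CSV
#'
#' @param mat Feature matrix with `video_id` row names.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(mat, path) {
  df <- data.frame(video_id = rownames(mat), mat, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
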