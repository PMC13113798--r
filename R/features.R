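#' Segment a narrative text into sentences
#'
#' Automatic segmentation splits on runs of sentence-final punctuation
#' (`.`, `!`, `?`) followed by whitespace or end-of-text, discarding empty
#' fragments. The splitter is deliberately naive — it does not know about
#' abbreviations ("Mr. Smith") or clause boundaries that punctuation misses —
#' so an explicit `override` count is the sanctioned correction path: when
#' given, the effective sentence count is the override while the automatic
#' fragments are retained (they still drive the complex-sentence flags).
#'
#' @param text A single narrative text.
#' @param override Optional manually verified sentence count (>= 1).
#' @return A list of class `sentence_segmentation` with elements `sentences`
#'   (character vector of automatic fragments), `provenance` (`"auto"` or
#'   `"override"`), and `effective_count`.
#' @examples
#' segment_sentences("He ran. She walked! Done?")$effective_count  # 3
#' segment_sentences("Mr. Smith left.", override = 1)$effective_count  # 1
#' @export
segment_sentences <- function(text, override = NULL) {
  stopifnot_scalar_string(text, "text")
  marked <- stringr::str_replace_all(text, "([.!?]+)(\\s+|$)", "\\1\u0001")
  parts <- stringr::str_split(marked, "\u0001")[[1]]
  parts <- stringr::str_trim(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) {
    abort_validation("segmentation produced zero sentences (text is empty?)")
  }
  if (!is.null(override) && !is.na(override)) {
    override <- as.integer(override)
    if (override < 1L) {
      abort_validation("sentence count override must be >= 1")
    }
    provenance <- "override"
    effective <- override
  } else {
    provenance <- "auto"
    effective <- length(parts)
  }
  structure(
    list(sentences = parts, provenance = provenance,
         effective_count = effective),
    class = "sentence_segmentation"
  )
}

#' Count whitespace-delimited words
#'
#' A word is a maximal run of non-whitespace characters; punctuation stays
#' attached to its token ("ran." is one word). Empty or all-whitespace text
#' counts zero.
#'
#' @param text A character string.
#' @return Non-negative integer word count.
#' @examples
#' count_words("A dog ran.")      # 3
#' count_words("  two   words  ") # 2
#' @export
count_words <- function(text) {
  if (length(text) != 1L || is.na(text)) {
    abort_validation("`text` must be a single string")
  }
  tokens <- stringr::str_split(text, "\\s+")[[1]]
  sum(nzchar(tokens))
}

subordinator_pattern <- function(cfg) {
  stringr::regex(
    paste0("\\b(", paste(cfg$subordinators, collapse = "|"), ")\\b"),
    ignore_case = cfg$case_insensitive
  )
}

#' Complex-sentence ratio
#'
#' Proportion of sentences containing at least one subordinating conjunction.
#' The numerator counts automatic-split sentences with a whole-word,
#' case-insensitive (by default) subordinator match — a sentence with several
#' subordinators counts once. The denominator is the effective sentence count,
#' which honours a manual override.
#'
#' @param seg A [segment_sentences()] result.
#' @param cfg A [feature_config()].
#' @return Ratio in `[0, 1]`.
#' @examples
#' seg <- segment_sentences("He left because it rained. She stayed.")
#' complex_sentence_ratio(seg, feature_config())  # 0.5
#' @export
complex_sentence_ratio <- function(seg, cfg = feature_config()) {
  stopifnot(inherits(seg, "sentence_segmentation"))
  if (seg$effective_count < 1L) {
    abort_validation("complex-sentence ratio is undefined for zero sentences")
  }
  pat <- subordinator_pattern(cfg)
  numerator <- sum(stringr::str_detect(seg$sentences, pat))
  numerator / seg$effective_count
}

#' Estimated information units
#'
#' Surface proxy for the informational density of a written stimulus: the
#' count of ASCII commas plus occurrences of "and" plus occurrences of "but".
#' In the default `word_boundary` mode "band" and "butter" do not match; the
#' `substring` mode reproduces naive substring counting, where they do. Other
#' pause punctuation (semicolons, dashes) is never counted. This proxy is not
#' comparable to produced information units scored from spoken retellings.
#'
#' @param text A character string.
#' @param cfg A [feature_config()].
#' @return Non-negative integer count.
#' @examples
#' estimated_ius("I ran, and he walked, but she stayed.")  # 4
#' @export
estimated_ius <- function(text, cfg = feature_config()) {
  if (length(text) != 1L || is.na(text)) {
    abort_validation("`text` must be a single string")
  }
  commas <- stringr::str_count(text, stringr::fixed(","))
  core <- "and|but"
  pat <- if (cfg$iu_match_mode == "word_boundary") {
    paste0("\\b(", core, ")\\b")
  } else {
    paste0("(", core, ")")
  }
  conj <- stringr::str_count(
    text, stringr::regex(pat, ignore_case = cfg$case_insensitive)
  )
  as.integer(commas + conj)
}

extract_features_one <- function(id, text, override, cfg) {
  seg <- segment_sentences(text, override)
  wc <- count_words(text)
  tibble(
    id = id,
    sentence_count = as.integer(seg$effective_count),
    word_count = as.integer(wc),
    avg_sentence_length = wc / seg$effective_count,
    complex_ratio = complex_sentence_ratio(seg, cfg),
    estimated_ius = estimated_ius(text, cfg)
  )
}

#' Extract the four structural features from a corpus
#'
#' Composes sentence segmentation, word counting, the complex-sentence ratio
#' and the estimated-IU proxy for every stimulus in a corpus. Average sentence
#' length is `word_count / sentence_count` at full precision (display rounding
#' is left to report writers).
#'
#' @param corpus A [stimulus_corpus()].
#' @param cfg A [feature_config()].
#' @return A tibble with columns `id`, `sentence_count`, `word_count`,
#'   `avg_sentence_length`, `complex_ratio`, `estimated_ius`, in corpus order.
#' @export
extract_features <- function(corpus, cfg = feature_config()) {
  corpus <- validate_corpus(corpus)
  purrr::pmap(
    list(corpus$id, corpus$text, corpus$sentence_count_override),
    function(id, text, ov) extract_features_one(id, text, ov, cfg)
  ) |>
    purrr::list_rbind()
}

#' Write a feature table as CSV
#'
#' Full-precision values; column order `id, sentence_count, word_count,
#' avg_sentence_length, complex_ratio, estimated_ius`.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("id", "sentence_count", "word_count", "avg_sentence_length",
            "complex_ratio", "estimated_ius")
  stopifnot(all(cols %in% names(features)))
  readr::write_csv(features[cols], path)
  invisible(path)
}
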