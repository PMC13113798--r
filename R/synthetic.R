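# Filler vocabulary for generated narratives. Chosen so that no word contains
# a subordinating conjunction, "and", or "but" as a substring — the
# word-boundary and substring matching modes therefore agree on every
# generated text, and the only IU/complexity events are the ones the
# generator inserts deliberately.
synth_vocab <- c(
  "the", "old", "man", "walked", "home", "slowly", "a", "small", "dog",
  "ran", "near", "river", "girl", "saw", "bird", "over", "garden", "house",
  "quiet", "morning", "sun", "rose", "they", "talked", "together", "for",
  "hours", "he", "she", "smiled"
)

sample_one <- function(x) x[sample.int(length(x), 1L)]

#' Specification of a synthetic narrative stimulus
#'
#' Describes a narrative text by the exact structural features it must have:
#' number of sentences, whitespace-token word count, number of sentences
#' containing a subordinating conjunction, and number of estimated-IU events
#' (commas + "and" + "but"). A spec is achievable when every sentence can hold
#' at least one word and every complex sentence at least three (a filler word
#' on each side of its subordinator): `word_count >= sentence_count +
#' 2 * complex_numerator`.
#'
#' @param sentence_count Positive integer.
#' @param word_count Positive integer (>= `sentence_count + 2 *
#'   complex_numerator`).
#' @param complex_numerator Integer in `[0, sentence_count]`: how many
#'   sentences contain a subordinator.
#' @param ius Non-negative integer: total comma/"and"/"but" events.
#' @param seed Integer seed making generation deterministic.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(sentence_count, word_count, complex_numerator,
                       ius, seed = 1L) {
  sentence_count <- as.integer(sentence_count)
  word_count <- as.integer(word_count)
  complex_numerator <- as.integer(complex_numerator)
  ius <- as.integer(ius)
  if (sentence_count < 1L) {
    abort_validation("unachievable spec: sentence_count must be >= 1")
  }
  if (complex_numerator < 0L || complex_numerator > sentence_count) {
    abort_validation(
      "unachievable spec: complex_numerator must lie in [0, sentence_count]"
    )
  }
  if (word_count < sentence_count) {
    abort_validation(
      sprintf("unachievable spec: %d words cannot fill %d sentences (each sentence needs >= 1 word)",
              word_count, sentence_count)
    )
  }
  if (word_count < sentence_count + 2L * complex_numerator) {
    abort_validation(
      sprintf("unachievable spec: %d complex sentences need >= 3 words each, so word_count must be >= %d (got %d)",
              complex_numerator, sentence_count + 2L * complex_numerator,
              word_count)
    )
  }
  if (ius < 0L) {
    abort_validation("unachievable spec: ius must be >= 0")
  }
  structure(
    list(sentence_count = sentence_count, word_count = word_count,
         complex_numerator = complex_numerator, ius = ius,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a narrative-like text with exact structural features
#'
#' Builds a text whose extracted features equal the spec's targets by
#' construction, under the default [feature_config()]: the automatic sentence
#' split yields exactly `sentence_count` sentences, the whitespace token count
#' is `word_count`, exactly `complex_numerator` sentences contain a
#' subordinating conjunction (inserted mid-sentence, flanked by filler), and
#' the comma/"and"/"but" events sum to `ius`. Counts are tracked during
#' construction, never patched afterwards, so the round trip through feature
#' extraction is exact. Generation is deterministic given the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @param id Stimulus id for the returned record.
#' @param role `"treated"` or `"evaluation"`.
#' @return A one-row [stimulus_corpus()].
#' @examples
#' rec <- generate_stimulus(synth_spec(2, 12, 1, 3, seed = 42))
#' extract_features(rec)
#' @export
generate_stimulus <- function(spec, id = "synthetic", role = "treated") {
  stopifnot(inherits(spec, "synth_spec"))
  text <- withr::with_seed(spec$seed, build_synth_text(spec))
  rec <- stimulus_corpus(id = id, text = text, role = role)
  feats <- extract_features(rec)
  ok <- feats$sentence_count == spec$sentence_count &&
    feats$word_count == spec$word_count &&
    isTRUE(all.equal(feats$complex_ratio,
                     spec$complex_numerator / spec$sentence_count)) &&
    feats$estimated_ius == spec$ius
  if (!ok) {
    abort("internal error: generated text does not meet its spec targets")
  }
  rec
}

build_synth_text <- function(spec) {
  S <- spec$sentence_count
  lens <- rep(1L, S)
  complex_idx <- if (spec$complex_numerator > 0L) {
    sort(sample.int(S, spec$complex_numerator))
  } else {
    integer()
  }
  lens[complex_idx] <- 3L
  extra <- spec$word_count - sum(lens)
  if (extra > 0L) {
    lens <- lens + tabulate(sample.int(S, extra, replace = TRUE), nbins = S)
  }
  words <- lapply(lens, function(k) {
    synth_vocab[sample.int(length(synth_vocab), k, replace = TRUE)]
  })
  # one subordinator per complex sentence, strictly mid-sentence
  sub_pos <- rep(NA_integer_, S)
  for (i in complex_idx) {
    pos <- sample_one(2L:(lens[i] - 1L))
    words[[i]][pos] <- sample_one(default_subordinators())
    sub_pos[i] <- pos
  }
  # IU events: split between "and"/"but" word substitutions (at most one per
  # free slot) and commas (stackable), then place them
  slot_sentence <- rep(seq_len(S), lens)
  slot_pos <- unlist(lapply(lens, seq_len))
  is_sub_slot <- !is.na(sub_pos[slot_sentence]) &
    slot_pos == sub_pos[slot_sentence]
  free_slots <- which(!is_sub_slot)
  n_ab <- if (spec$ius > 0L && length(free_slots) > 0L) {
    sample.int(min(spec$ius, length(free_slots)) + 1L, 1L) - 1L
  } else {
    0L
  }
  if (n_ab > 0L) {
    chosen <- free_slots[sample.int(length(free_slots), n_ab)]
    for (s in chosen) {
      words[[slot_sentence[s]]][slot_pos[s]] <- sample_one(c("and", "but"))
    }
  }
  n_commas <- spec$ius - n_ab
  if (n_commas > 0L) {
    nonfinal <- which(slot_pos < lens[slot_sentence])
    pool <- if (length(nonfinal)) nonfinal else seq_along(slot_sentence)
    pick <- pool[sample.int(length(pool), n_commas, replace = TRUE)]
    for (s in pick) {
      i <- slot_sentence[s]
      p <- slot_pos[s]
      words[[i]][p] <- paste0(words[[i]][p], ",")
    }
  }
  sentences <- vapply(words, function(w) {
    w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
    paste0(paste(w, collapse = " "), ".")
  }, character(1))
  paste(sentences, collapse = " ")
}

#' Generate a synthetic corpus with known ground-truth features
#'
#' Draws per-stimulus feature targets uniformly from the given ranges and
#' generates one text per stimulus with those exact features. The default
#' ranges emulate a set of short therapy narratives of the scale used in
#' story-retelling work (11-16 sentences, 150-225 words, 10-21 IU events,
#' up to 11 complex sentences). When `n >= 12`, three stimuli are marked as
#' evaluation-only, mirroring a 9-treated / 3-evaluation study layout.
#'
#' @param n Number of stimuli (>= 3, so tertile blocks remain definable
#'   downstream).
#' @param feature_ranges Named list overriding any of `sentence_count`,
#'   `word_count`, `complex_numerator`, `ius`; each a `c(min, max)` pair.
#' @param seed Integer seed; the whole corpus is deterministic given it.
#' @return List with `corpus` (a [stimulus_corpus()]), `features` (the
#'   ground-truth feature tibble, same shape as [extract_features()]), and
#'   `specs` (the per-stimulus [synth_spec()] list).
#' @export
generate_corpus <- function(n, feature_ranges = list(), seed = 1L) {
  n <- as.integer(n)
  if (n < 3L) {
    abort_validation("need at least 3 stimuli to form tertile blocks downstream")
  }
  ranges <- utils::modifyList(
    list(
      sentence_count = c(11L, 16L),
      word_count = c(150L, 225L),
      complex_numerator = c(0L, 11L),
      ius = c(10L, 21L)
    ),
    feature_ranges
  )
  draw <- function(rng) rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  withr::with_seed(seed, {
    specs <- vector("list", n)
    for (i in seq_len(n)) {
      S <- draw(ranges$sentence_count)
      C <- min(draw(ranges$complex_numerator), S)
      W <- max(draw(ranges$word_count), S + 2L * C)
      U <- draw(ranges$ius)
      specs[[i]] <- synth_spec(S, W, C, U, seed = sample.int(.Machine$integer.max, 1L))
    }
    roles <- rep("treated", n)
    if (n >= 12L) roles[sample.int(n, 3L)] <- "evaluation"
  })
  ids <- sprintf("story%02d", seq_len(n))
  records <- purrr::pmap(
    list(specs, ids, roles),
    function(sp, id, role) generate_stimulus(sp, id = id, role = role)
  )
  corpus <- validate_corpus(dplyr::bind_rows(records))
  features <- tibble(
    id = ids,
    sentence_count = vapply(specs, `[[`, integer(1), "sentence_count"),
    word_count = vapply(specs, `[[`, integer(1), "word_count"),
    avg_sentence_length = vapply(specs, function(s) s$word_count / s$sentence_count, numeric(1)),
    complex_ratio = vapply(specs, function(s) s$complex_numerator / s$sentence_count, numeric(1)),
    estimated_ius = vapply(specs, `[[`, integer(1), "ius")
  )
  list(corpus = corpus, features = features, specs = specs)
}

#' Read a list of synthesis specs from YAML or JSON
#'
#' The file holds a list of records with fields `id`, `sentence_count`,
#' `word_count`, `complex_numerator`, `ius`, and optional `seed` and `role`.
#'
#' @param path Spec file path (`.json` for JSON, otherwise YAML).
#' @return List with `specs` (list of [synth_spec()]), `ids`, `roles`.
#' @export
read_synth_specs <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("spec file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(raw)) abort_validation("spec file contains no specs")
  ids <- vapply(raw, function(r) as.character(r$id %||% NA_character_), character(1))
  if (anyNA(ids) || !all(nzchar(ids))) {
    abort_validation("every spec needs a non-empty id")
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort_validation(sprintf("duplicate spec id(s): %s", paste(dup, collapse = ", ")))
  }
  specs <- lapply(seq_along(raw), function(i) {
    r <- raw[[i]]
    tryCatch(
      synth_spec(r$sentence_count, r$word_count, r$complex_numerator, r$ius,
                 seed = r$seed %||% i),
      storyload_validation_error = function(e) {
        abort_validation(sprintf("spec '%s': %s", ids[i], conditionMessage(e)))
      }
    )
  })
  roles <- vapply(raw, function(r) as.character(r$role %||% "treated"), character(1))
  list(specs = specs, ids = ids, roles = roles)
}
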