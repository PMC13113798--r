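#' Construct a stimulus corpus
#'
#' A stimulus corpus is a tibble with one row per narrative stimulus: an `id`,
#' the full `text`, a `role` (`"treated"` or `"evaluation"`), and an optional
#' positive-integer `sentence_count_override` used when the automatic
#' punctuation-based sentence splitter needs manual correction (abbreviations,
#' clause boundaries that punctuation misses). Row order is meaningful and is
#' preserved through every downstream table.
#'
#' @param id Character vector of unique, non-empty stimulus identifiers.
#' @param text Character vector of narrative texts (non-empty after trimming).
#' @param role `"treated"` or `"evaluation"`, recycled if length 1.
#' @param sentence_count_override Optional integer vector (`NA` where the
#'   automatic split is trusted); values must be >= 1.
#' @return A tibble of class `stimulus_corpus`.
#' @examples
#' stimulus_corpus("dog", "A dog ran. It barked.")
#' @export
stimulus_corpus <- function(id, text, role = "treated",
                            sentence_count_override = NA_integer_) {
  n <- length(id)
  role <- rep_len(role, n)
  sentence_count_override <- rep_len(as.integer(sentence_count_override), n)
  corpus <- tibble(
    id = as.character(id),
    text = as.character(text),
    role = as.character(role),
    sentence_count_override = sentence_count_override
  )
  validate_corpus(corpus)
}

validate_corpus <- function(corpus) {
  if (nrow(corpus) == 0L) {
    abort_validation("no stimuli: the corpus is empty")
  }
  if (anyNA(corpus$id) || !all(nzchar(trimws(corpus$id)))) {
    abort_validation("every stimulus id must be a non-empty string")
  }
  dup <- unique(corpus$id[duplicated(corpus$id)])
  if (length(dup)) {
    abort_validation(
      sprintf("duplicate stimulus id(s): %s", paste(dup, collapse = ", "))
    )
  }
  bad_role <- setdiff(unique(corpus$role), c("treated", "evaluation"))
  if (length(bad_role)) {
    abort_validation(
      sprintf("unknown role value(s): %s (expected 'treated' or 'evaluation')",
              paste(bad_role, collapse = ", "))
    )
  }
  if (anyNA(corpus$text) || !all(nzchar(trimws(corpus$text)))) {
    empty <- corpus$id[is.na(corpus$text) | !nzchar(trimws(corpus$text))]
    abort_validation(
      sprintf("empty text for stimulus id(s): %s", paste(empty, collapse = ", "))
    )
  }
  ov <- corpus$sentence_count_override
  if (any(!is.na(ov) & ov < 1L)) {
    abort_validation("sentence_count_override must be >= 1 where present")
  }
  class(corpus) <- unique(c("stimulus_corpus", class(corpus)))
  corpus
}

# Strip a UTF-8 byte-order mark and normalize CRLF/CR line endings to LF, so
# feature counts cannot depend on the platform the texts were written on.
normalize_text <- function(x) {
  x <- sub("^\ufeff", "", x)
  x <- gsub("\r\n", "\n", x, fixed = TRUE)
  gsub("\r", "\n", x, fixed = TRUE)
}

read_stimulus_text <- function(path, id) {
  if (!file.exists(path)) {
    abort_validation(
      sprintf("stimulus '%s': file not found: %s", id, path)
    )
  }
  raw <- readChar(path, file.size(path), useBytes = TRUE)
  Encoding(raw) <- "UTF-8"
  normalize_text(raw)
}

#' Load a stimulus corpus from a manifest
#'
#' Reads a comma-delimited, UTF-8 manifest with required header columns `id`,
#' `file`, `role` and an optional `sentence_count_override` column, then reads
#' each referenced plain-text file. Relative `file` paths are resolved against
#' the manifest's directory. Texts are read as UTF-8 with any byte-order mark
#' stripped and line endings normalized to `"\n"`. Manifest row order is
#' preserved.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A [stimulus_corpus()] tibble with the manifest path attached as the
#'   `source_manifest` attribute.
#' @export
load_corpus <- function(manifest_path) {
  stopifnot_scalar_string(manifest_path, "manifest_path")
  if (!file.exists(manifest_path)) {
    abort_validation(sprintf("manifest not found: %s", manifest_path))
  }
  manifest <- readr::read_csv(manifest_path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  required <- c("id", "file", "role")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) {
    abort_validation(
      sprintf("manifest is missing required column(s): %s",
              paste(missing, collapse = ", "))
    )
  }
  if (nrow(manifest) == 0L) {
    abort_validation("no stimuli: the manifest has no rows")
  }
  base_dir <- dirname(manifest_path)
  paths <- ifelse(
    grepl("^(/|[A-Za-z]:)", manifest$file),
    manifest$file,
    file.path(base_dir, manifest$file)
  )
  texts <- purrr::map2_chr(paths, manifest$id, read_stimulus_text)
  override <- if ("sentence_count_override" %in% names(manifest)) {
    suppressWarnings(as.integer(manifest$sentence_count_override))
  } else {
    NA_integer_
  }
  corpus <- stimulus_corpus(
    id = manifest$id, text = texts, role = manifest$role,
    sentence_count_override = override
  )
  attr(corpus, "source_manifest") <- manifest_path
  corpus
}

#' Write a stimulus corpus to disk
#'
#' Writes one UTF-8 `.txt` file per stimulus plus a `manifest.csv` compatible
#' with [load_corpus()], so a corpus round-trips exactly.
#'
#' @param corpus A [stimulus_corpus()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  corpus <- validate_corpus(corpus)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(gsub("[^A-Za-z0-9_-]+", "_", corpus$id), ".txt")
  for (i in seq_len(nrow(corpus))) {
    con <- file(file.path(dir, files[i]), open = "wb")
    writeChar(corpus$text[i], con, eos = NULL, useBytes = TRUE)
    close(con)
  }
  manifest <- tibble(
    id = corpus$id, file = files, role = corpus$role,
    sentence_count_override = corpus$sentence_count_override
  )
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path, na = "")
  invisible(path)
}

#' Echo a validated corpus as JSON for provenance logging
#'
#' @param corpus A [stimulus_corpus()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
corpus_json <- function(corpus, path = NULL) {
  corpus <- validate_corpus(corpus)
  payload <- list(
    n_stimuli = nrow(corpus),
    source_manifest = attr(corpus, "source_manifest") %||% NA_character_,
    records = as_tibble(corpus)[, c("id", "role", "sentence_count_override")]
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Load a produced-IU outcomes table
#'
#' Reads a CSV with header `id,role,iu_pre,iu_post,iu_post1,iu_post2`. Treated
#' stimuli (retold before and after their single treatment session) must carry
#' `iu_pre` and `iu_post`; evaluation-only stimuli (retold at pre-treatment,
#' immediately post-treatment, and at maintenance follow-up) must carry
#' `iu_pre`, `iu_post1` and `iu_post2`. Blank cells are allowed where the role
#' permits; all counts must be non-negative integers.
#'
#' @param outcomes_path Path to the outcomes CSV.
#' @return A tibble with one validated row per stimulus.
#' @export
load_outcomes <- function(outcomes_path) {
  stopifnot_scalar_string(outcomes_path, "outcomes_path")
  if (!file.exists(outcomes_path)) {
    abort_validation(sprintf("outcomes file not found: %s", outcomes_path))
  }
  raw <- readr::read_csv(outcomes_path, col_types = readr::cols(
    id = readr::col_character(),
    role = readr::col_character(),
    .default = readr::col_integer()
  ))
  required <- c("id", "role", "iu_pre", "iu_post", "iu_post1", "iu_post2")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort_validation(
      sprintf("outcomes table is missing column(s): %s",
              paste(missing, collapse = ", "))
    )
  }
  validate_outcomes(raw[required])
}

validate_outcomes <- function(outcomes) {
  outcomes <- as_tibble(outcomes)
  dup <- unique(outcomes$id[duplicated(outcomes$id)])
  if (length(dup)) {
    abort_validation(
      sprintf("duplicate outcome id(s): %s", paste(dup, collapse = ", "))
    )
  }
  bad_role <- setdiff(unique(outcomes$role), c("treated", "evaluation"))
  if (length(bad_role)) {
    abort_validation(
      sprintf("unknown role value(s): %s", paste(bad_role, collapse = ", "))
    )
  }
  counts <- outcomes[, c("iu_pre", "iu_post", "iu_post1", "iu_post2")]
  if (any(unlist(counts) < 0, na.rm = TRUE)) {
    abort_validation("IU counts must be non-negative")
  }
  treated <- outcomes$role == "treated"
  bad_treated <- outcomes$id[treated &
    (is.na(outcomes$iu_pre) | is.na(outcomes$iu_post))]
  if (length(bad_treated)) {
    abort_validation(
      sprintf("treated stimulus/stimuli missing iu_pre or iu_post: %s",
              paste(bad_treated, collapse = ", "))
    )
  }
  evaln <- outcomes$role == "evaluation"
  bad_eval <- outcomes$id[evaln &
    (is.na(outcomes$iu_pre) | is.na(outcomes$iu_post1) | is.na(outcomes$iu_post2))]
  if (length(bad_eval)) {
    abort_validation(
      sprintf("evaluation stimulus/stimuli missing iu_pre, iu_post1 or iu_post2: %s",
              paste(bad_eval, collapse = ", "))
    )
  }
  outcomes
}

#' Write an outcomes table
#'
#' Inverse of [load_outcomes()]; blank cells encode absent timepoints.
#'
#' @param outcomes Outcomes tibble as returned by [load_outcomes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  outcomes <- validate_outcomes(outcomes)
  readr::write_csv(outcomes, path, na = "")
  invisible(path)
}
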