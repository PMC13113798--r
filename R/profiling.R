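feature_columns <- c("sentence_count", "complex_ratio", "avg_sentence_length",
                     "estimated_ius")
z_columns <- c("z_sentence_count", "z_complex_ratio", "z_avg_length", "z_ius")

# Population (divide-by-n) standard deviation. This convention — not the
# sample n-1 one — is what makes composites comparable across corpora of
# different sizes and is the convention the block-assignment pipeline assumes.
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Z-normalize structural features across a corpus
#'
#' Converts each raw feature column to z = (x - mu) / sigma, where mu and
#' sigma are the mean and the population (divide-by-n) standard deviation of
#' that feature across all stimuli in the corpus. Full precision is kept
#' throughout; no display rounding enters the computation.
#'
#' @param features Feature tibble from [extract_features()] (columns `id`,
#'   `sentence_count`, `complex_ratio`, `avg_sentence_length`,
#'   `estimated_ius`; at least 2 rows).
#' @param sd_type `"population"` (default, divide by n) or `"sample"`
#'   (divide by n-1); the sample option exists only for convention checks.
#' @return A list with `z` (tibble: `id`, `z_sentence_count`,
#'   `z_complex_ratio`, `z_avg_length`, `z_ius`) and `stats` (tibble:
#'   `feature`, `mu`, `sigma`).
#' @export
zscore_features <- function(features, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  missing <- setdiff(c("id", feature_columns), names(features))
  if (length(missing)) {
    abort_validation(
      sprintf("feature table is missing column(s): %s",
              paste(missing, collapse = ", "))
    )
  }
  if (nrow(features) < 2L) {
    abort_validation("z-normalization needs at least 2 stimuli")
  }
  sd_fun <- if (sd_type == "population") pop_sd else stats::sd
  mus <- vapply(features[feature_columns], mean, numeric(1))
  sigmas <- vapply(features[feature_columns], sd_fun, numeric(1))
  degenerate <- feature_columns[sigmas == 0]
  if (length(degenerate)) {
    abort_validation(
      sprintf("degenerate feature column(s) with zero variance: %s",
              paste(degenerate, collapse = ", ")),
      class = "storyload_degenerate_feature"
    )
  }
  z <- tibble(
    id = features$id,
    z_sentence_count = (features$sentence_count - mus["sentence_count"]) /
      sigmas["sentence_count"],
    z_complex_ratio = (features$complex_ratio - mus["complex_ratio"]) /
      sigmas["complex_ratio"],
    z_avg_length = (features$avg_sentence_length - mus["avg_sentence_length"]) /
      sigmas["avg_sentence_length"],
    z_ius = (features$estimated_ius - mus["estimated_ius"]) /
      sigmas["estimated_ius"]
  )
  list(
    z = z,
    stats = tibble(feature = feature_columns, mu = unname(mus),
                   sigma = unname(sigmas))
  )
}

#' Composite structural load scores
#'
#' The composite structural load score of a stimulus is the unweighted mean of
#' its four feature z-scores (sentence count, complex-sentence ratio, average
#' sentence length, estimated IUs).
#'
#' @param ztable Z-score tibble from [zscore_features()] (`$z`).
#' @return Numeric vector of composites, one per row of `ztable`.
#' @export
composite_scores <- function(ztable) {
  missing <- setdiff(z_columns, names(ztable))
  if (length(missing)) {
    abort_validation(
      sprintf("z-score table is missing column(s): %s",
              paste(missing, collapse = ", "))
    )
  }
  rowMeans(as.matrix(ztable[z_columns]))
}

#' Assign tertile load blocks
#'
#' Rank-based equal-frequency binning of composite scores into ascending
#' blocks (default Low, Medium, High: the top third of composites is High
#' load). With n divisible by 3 and distinct composites the blocks have equal
#' size; otherwise sizes differ by at most one. Ties at a block boundary are
#' broken by stable input order with a warning.
#'
#' @param composites Numeric vector of composite scores (length >= number of
#'   blocks).
#' @param labels Ascending block labels; default `c("Low","Medium","High")`.
#' @return Factor of block labels with levels in ascending-load order.
#' @examples
#' assign_blocks(c(-1, 0, 1))  # Low, Medium, High
#' @export
assign_blocks <- function(composites, labels = c("Low", "Medium", "High")) {
  k <- length(labels)
  n <- length(composites)
  if (k < 2L) abort_validation("at least two block labels are required")
  if (n < k) {
    abort_validation(
      sprintf("need at least %d stimuli to form %d blocks (got %d)", k, k, n)
    )
  }
  if (length(unique(composites)) == 1L) {
    abort_validation("all composite scores are equal; blocks are undefined")
  }
  if (anyDuplicated(composites)) {
    warn("tied composite scores: boundary ties broken by stable input order")
  }
  r <- rank(composites, ties.method = "first")
  breaks <- seq(0, n, length.out = k + 1L)
  cut(r, breaks = breaks, labels = labels, include.lowest = TRUE)
}

#' Profile a stimulus corpus
#'
#' Runs the full structural-load pipeline: feature extraction, z-normalization
#' across the corpus (population SD), composite scoring, and tertile block
#' assignment. `profile_features()` starts from an existing feature table
#' instead of raw texts (useful when features come from a published table or a
#' generator's ground truth).
#'
#' @param corpus A [stimulus_corpus()].
#' @param cfg A [feature_config()]; echoed into the profile for provenance.
#' @param features Feature tibble (columns as in [extract_features()]).
#' @return An object of class `stimulus_profile`: a list with `table` (one row
#'   per stimulus: features, the four z-scores, `composite`, `block`),
#'   `feature_stats` (per-feature `mu` and population `sigma`) and `config`.
#' @examples
#' corpus <- stimulus_corpus(
#'   c("a", "b", "c"),
#'   c("He left, because it rained. She stayed. They waited and watched.",
#'     "A dog ran. It barked!",
#'     "When the sun rose, the town woke. Bread was baked. Doors opened, and carts rolled.")
#' )
#' profile_corpus(corpus)
#' @export
profile_corpus <- function(corpus, cfg = feature_config()) {
  corpus <- validate_corpus(corpus)
  features <- extract_features(corpus, cfg)
  prof <- profile_features(features, cfg)
  prof$table$role <- corpus$role[match(prof$table$id, corpus$id)]
  prof
}

#' @rdname profile_corpus
#' @export
profile_features <- function(features, cfg = feature_config()) {
  zres <- zscore_features(features)
  composite <- composite_scores(zres$z)
  block <- assign_blocks(composite)
  keep <- intersect(
    c("id", "sentence_count", "word_count", "avg_sentence_length",
      "complex_ratio", "estimated_ius"),
    names(features)
  )
  table <- dplyr::bind_cols(features[keep], zres$z[z_columns])
  table$composite <- composite
  table$block <- block
  structure(
    list(table = as_tibble(table), feature_stats = zres$stats, config = cfg),
    class = "stimulus_profile"
  )
}

#' @export
print.stimulus_profile <- function(x, digits = 3, ...) {
  cat(sprintf("<stimulus_profile> %d stimuli (iu_match_mode = %s)\n",
              nrow(x$table), x$config$iu_match_mode))
  shown <- x$table
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], round, digits = digits)
  print(as.data.frame(shown), row.names = FALSE)
  invisible(x)
}

#' Write profile artifacts
#'
#' Writes the full-precision profile as CSV and/or JSON (with per-feature
#' mu/sigma and the configuration echo) and/or a display-rounded markdown
#' table mirroring the canonical report layout (two-decimal features, three-
#' decimal composites).
#'
#' @param profile A [profile_corpus()] result.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json", "md")`.
#' @return Character vector of written paths, invisibly.
#' @export
write_profile <- function(profile, dir, formats = c("csv", "json", "md")) {
  stopifnot(inherits(profile, "stimulus_profile"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if ("csv" %in% formats) {
    p <- file.path(dir, "profile.csv")
    readr::write_csv(profile$table, p)
    written <- c(written, p)
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "profile.json")
    payload <- list(
      config = config_echo(profile$config),
      feature_stats = profile$feature_stats,
      profile = profile$table
    )
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, p)
  }
  if ("md" %in% formats) {
    p <- file.path(dir, "profile.md")
    writeLines(profile_markdown(profile), p)
    written <- c(written, p)
  }
  invisible(written)
}

profile_markdown <- function(profile) {
  t <- profile$table
  disp <- tibble(
    Story = t$id,
    `Sentence count` = t$sentence_count,
    `Word count` = if ("word_count" %in% names(t)) t$word_count else NA,
    `Avg sentence length` = sprintf("%.2f", t$avg_sentence_length),
    `Complex sentence ratio` = sprintf("%.2f", t$complex_ratio),
    `Estimated IUs` = t$estimated_ius,
    `Composite score` = sprintf("%.3f", t$composite),
    `Load block` = as.character(t$block)
  )
  markdown_table(disp)
}

markdown_table <- function(df) {
  cells <- vapply(df, function(col) as.character(col), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
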