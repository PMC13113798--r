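#' Per-stimulus produced-IU gains
#'
#' The headline gain of a treated stimulus is its within-session change,
#' `iu_post - iu_pre`. For an evaluation-only stimulus — retold at
#' pre-treatment, immediately post-treatment (Post1) and at maintenance
#' follow-up (Post2) — the headline gain is `iu_post2 - iu_pre`, with all
#' three interval gains (`Post1 - Pre`, `Post2 - Pre`, `Post2 - Post1`)
#' reported alongside. Gains are integers and may be negative.
#'
#' @param outcomes Validated outcomes tibble from [load_outcomes()].
#' @return A tibble with columns `id`, `role`, `gain`, `gain_post1_pre`,
#'   `gain_post2_pre`, `gain_post2_post1` (interval columns are `NA` for
#'   treated stimuli).
#' @examples
#' outcomes <- tibble::tibble(
#'   id = c("lib", "sess1"), role = c("evaluation", "treated"),
#'   iu_pre = c(19L, 20L), iu_post = c(NA, 35L),
#'   iu_post1 = c(44L, NA), iu_post2 = c(57L, NA)
#' )
#' compute_gains(outcomes)
#' @export
compute_gains <- function(outcomes) {
  outcomes <- validate_outcomes(outcomes)
  treated <- outcomes$role == "treated"
  gain <- ifelse(
    treated,
    outcomes$iu_post - outcomes$iu_pre,
    outcomes$iu_post2 - outcomes$iu_pre
  )
  tibble(
    id = outcomes$id,
    role = outcomes$role,
    gain = as.integer(gain),
    gain_post1_pre = ifelse(treated, NA_integer_,
                            outcomes$iu_post1 - outcomes$iu_pre),
    gain_post2_pre = ifelse(treated, NA_integer_,
                            outcomes$iu_post2 - outcomes$iu_pre),
    gain_post2_post1 = ifelse(treated, NA_integer_,
                              outcomes$iu_post2 - outcomes$iu_post1)
  )
}

#' Pearson product-moment correlation
#'
#' Thin validated front end to the standard product-moment coefficient:
#' requires equal lengths of at least 3 and nonzero variance in both
#' arguments, and raises on degenerate input rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient in `[-1, 1]`, full precision.
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1)  # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort_validation("`x` and `y` must have equal length")
  }
  if (length(x) < 3L) {
    abort_validation("correlation needs at least 3 observations")
  }
  if (anyNA(x) || anyNA(y)) {
    abort_validation("missing values are not allowed in correlation input")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort_validation("correlation is undefined when either input has zero variance")
  }
  stats::cor(x, y, method = "pearson")
}

#' Summarize gains against the structural profile
#'
#' Joins per-stimulus gains to a profile by `id` and computes the exploratory
#' descriptives: Pearson correlations between composite load and gain for the
#' full corpus and for the treated and evaluation subsets, mean gain per load
#' block, and mean gain per condition (treated vs evaluation). These are
#' descriptive, directional summaries: with a dozen stimuli from a single
#' participant no significance testing is attempted by default.
#'
#' @param profile A [profile_corpus()] result.
#' @param gains Gains tibble from [compute_gains()] (or any tibble with `id`,
#'   `role`, `gain`).
#' @return An object of class `analysis_summary`: list with `correlations`
#'   (tibble `subset`, `n`, `r`), `block_means`, `condition_means`, and the
#'   joined `data` (id, composite, block, role, gain).
#' @export
summarize_gains <- function(profile, gains) {
  stopifnot(inherits(profile, "stimulus_profile"))
  missing_cols <- setdiff(c("id", "role", "gain"), names(gains))
  if (length(missing_cols)) {
    abort_validation(
      sprintf("gains table is missing column(s): %s",
              paste(missing_cols, collapse = ", "))
    )
  }
  orphans <- setdiff(gains$id, profile$table$id)
  if (length(orphans)) {
    abort_validation(
      sprintf("gain id(s) not present in profile: %s",
              paste(orphans, collapse = ", "))
    )
  }
  data <- dplyr::inner_join(
    profile$table[c("id", "composite", "block")],
    as_tibble(gains)[c("id", "role", "gain")],
    by = "id"
  )
  subsets <- list(
    all = data,
    treated = data[data$role == "treated", ],
    evaluation = data[data$role == "evaluation", ]
  )
  correlations <- purrr::imap(subsets, function(d, label) {
    tibble(subset = label, n = nrow(d),
           r = pearson_r(d$composite, d$gain))
  }) |> purrr::list_rbind()
  block_means <- data |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(mean_gain = mean(.data$gain), n = dplyr::n()) |>
    dplyr::ungroup()
  condition_means <- data |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(mean_gain = mean(.data$gain), n = dplyr::n()) |>
    dplyr::ungroup()
  structure(
    list(correlations = correlations, block_means = block_means,
         condition_means = condition_means, data = data),
    class = "analysis_summary"
  )
}

#' @export
print.analysis_summary <- function(x, ...) {
  cat("<analysis_summary>\n\nCorrelations (composite load vs IU gain):\n")
  c2 <- x$correlations
  c2$r <- sprintf("%+.2f", c2$r)
  print(as.data.frame(c2), row.names = FALSE)
  cat("\nMean IU gain by load block:\n")
  b <- x$block_means
  b$mean_gain <- sprintf("%.2f", b$mean_gain)
  print(as.data.frame(b), row.names = FALSE)
  cat("\nMean IU gain by condition:\n")
  m <- x$condition_means
  m$mean_gain <- sprintf("%.2f", m$mean_gain)
  print(as.data.frame(m), row.names = FALSE)
  invisible(x)
}

#' Write an analysis summary as JSON
#'
#' Full-precision values; correlations as `[{subset, n, r}]`, block and
#' condition means keyed by label, plus the joined scatter data (composite,
#' gain, role) backing a complexity-vs-gain plot.
#'
#' @param summary An [summarize_gains()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  stopifnot(inherits(summary, "analysis_summary"))
  payload <- list(
    correlations = summary$correlations,
    block_means = as.list(stats::setNames(summary$block_means$mean_gain,
                                          as.character(summary$block_means$block))),
    condition_means = as.list(stats::setNames(summary$condition_means$mean_gain,
                                              summary$condition_means$role)),
    scatter = summary$data[c("id", "composite", "gain", "role")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
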