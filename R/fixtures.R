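fixture_path <- function(file) {
  system.file("extdata", file, package = "storyload", mustWork = TRUE)
}

#' Packaged reference fixtures
#'
#' The package ships the published per-stimulus reference values for the
#' twelve-story corpus used in the original story-retelling study: the raw
#' structural features with printed composites and load blocks
#' (`table1_features`), the per-stimulus produced-IU gains with roles
#' (`table2_outcomes`), and the three evaluation-only IU trajectories across
#' Pre/Post1/Post2 (`trajectories`). The original story texts are adaptations
#' of a standardized discourse measure and are not redistributable, so the
#' fixtures carry the published feature values rather than texts.
#'
#' @return A list of three tibbles: `table1_features`, `table2_outcomes`,
#'   `trajectories`. Ids are consistent across tables; Gas, Library and Loan
#'   are the evaluation-only stimuli.
#' @export
load_fixtures <- function() {
  table1 <- readr::read_csv(
    fixture_path("table1_features.csv"),
    col_types = "ciiddidc"
  )
  table2 <- readr::read_csv(
    fixture_path("table2_outcomes.csv"),
    col_types = "cdicc"
  )
  traj <- readr::read_csv(
    fixture_path("trajectories.csv"),
    col_types = "ciii"
  )
  stopifnot(
    setequal(table1$id, table2$id),
    all(traj$id %in% table1$id),
    setequal(table2$id[table2$role == "evaluation"], traj$id)
  )
  list(table1_features = table1, table2_outcomes = table2,
       trajectories = traj)
}

#' Full-precision feature vectors for the reference corpus
#'
#' The published feature table prints average sentence length and the
#' complex-sentence ratio rounded to two decimals. Composites must be computed
#' on full-precision features, so this helper reconstructs the exact values:
#' average sentence length as `word_count / sentence_count`, and the complex
#' ratio as the exact fraction `k / sentence_count` whose value rounds to the
#' printed ratio (k recovered as `round(ratio * sentence_count)`).
#'
#' @return Feature tibble ready for [profile_features()], in published row
#'   order, with a `role` column attached.
#' @export
fixture_features <- function() {
  t1 <- load_fixtures()$table1_features
  t2 <- load_fixtures()$table2_outcomes
  tibble(
    id = t1$id,
    sentence_count = t1$sentence_count,
    word_count = t1$word_count,
    avg_sentence_length = t1$word_count / t1$sentence_count,
    complex_ratio = round(t1$complex_ratio * t1$sentence_count) / t1$sentence_count,
    estimated_ius = t1$estimated_ius,
    role = t2$role[match(t1$id, t2$id)]
  )
}

#' Profile of the reference corpus
#'
#' Runs the full profiling pipeline on the reconstructed full-precision
#' reference features: z-normalization (population SD), composite structural
#' load scores, and tertile block assignment.
#'
#' @param cfg A [feature_config()] (echoed into the profile).
#' @return A `stimulus_profile` with a `role` column in its table.
#' @export
fixture_profile <- function(cfg = feature_config()) {
  feats <- fixture_features()
  prof <- profile_features(feats[setdiff(names(feats), "role")], cfg)
  prof$table$role <- feats$role[match(prof$table$id, feats$id)]
  prof
}

#' Per-stimulus reference gains
#'
#' Produced-IU gains for the reference corpus: the published per-stimulus
#' gains, with the three evaluation-only interval gains (Post1-Pre, Post2-Pre,
#' Post2-Post1) derived from the packaged trajectories.
#'
#' @return Gains tibble in the shape produced by [compute_gains()].
#' @export
fixture_gains <- function() {
  fx <- load_fixtures()
  t2 <- fx$table2_outcomes
  traj <- fx$trajectories
  m <- match(t2$id, traj$id)
  tibble(
    id = t2$id,
    role = t2$role,
    gain = as.integer(t2$iu_gain),
    gain_post1_pre = as.integer(traj$iu_post1[m] - traj$iu_pre[m]),
    gain_post2_pre = as.integer(traj$iu_post2[m] - traj$iu_pre[m]),
    gain_post2_post1 = as.integer(traj$iu_post2[m] - traj$iu_post1[m])
  )
}
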