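#' Default subordinating conjunctions
#'
#' The closed set of subordinating conjunctions used to flag a sentence as
#' syntactically complex: because, although, when, if, since, though, unless,
#' while.
#'
#' @return Character vector of lowercase conjunctions.
#' @export
default_subordinators <- function() {
  c("because", "although", "when", "if", "since", "though", "unless", "while")
}

#' Feature extraction configuration
#'
#' Bundles the tunable choices behind the rule-based feature extractors:
#' which subordinating conjunctions mark a complex sentence, whether the
#' "and"/"but" events in the estimated information-unit (IU) proxy are matched
#' at word boundaries or as raw substrings, and whether matching ignores case.
#'
#' The substring mode reproduces naive `str.count()`-style counting, where
#' "band" contains "and"; the default word-boundary mode does not. Subordinator
#' detection for the complex-sentence ratio is always whole-word.
#'
#' @param subordinators Character vector of lowercase subordinating
#'   conjunctions; must be non-empty. Defaults to [default_subordinators()].
#' @param iu_match_mode `"word_boundary"` (default) or `"substring"`; how
#'   "and"/"but" are matched when estimating IUs.
#' @param case_insensitive Should matching ignore case? Default `TRUE`.
#'
#' @return An object of class `feature_config`.
#' @examples
#' cfg <- feature_config()
#' estimated_ius("The band played.", cfg)                               # 0
#' estimated_ius("The band played.", feature_config(iu_match_mode = "substring")) # 1
#' @export
feature_config <- function(subordinators = default_subordinators(),
                           iu_match_mode = c("word_boundary", "substring"),
                           case_insensitive = TRUE) {
  iu_match_mode <- match.arg(iu_match_mode)
  if (!is.character(subordinators) || length(subordinators) == 0L ||
      anyNA(subordinators) || !all(nzchar(subordinators))) {
    abort_validation("`subordinators` must be a non-empty character vector.")
  }
  if (!is.logical(case_insensitive) || length(case_insensitive) != 1L ||
      is.na(case_insensitive)) {
    abort_validation("`case_insensitive` must be TRUE or FALSE.")
  }
  structure(
    list(
      subordinators = tolower(subordinators),
      iu_match_mode = iu_match_mode,
      case_insensitive = case_insensitive
    ),
    class = "feature_config"
  )
}

#' @export
print.feature_config <- function(x, ...) {
  cat("<feature_config>\n")
  cat("  subordinators:   ", paste(x$subordinators, collapse = ", "), "\n")
  cat("  iu_match_mode:   ", x$iu_match_mode, "\n")
  cat("  case_insensitive:", x$case_insensitive, "\n")
  invisible(x)
}

#' Read or write a feature configuration
#'
#' Configurations serialize to YAML or JSON with keys `subordinators`,
#' `iu_match_mode` and `case_insensitive`, so a run's matching rules can be
#' pinned in version control and echoed into report artifacts.
#'
#' @param path File path; the format is chosen by extension (`.json` for JSON,
#'   anything else is treated as YAML).
#' @param cfg A [feature_config()] object.
#' @return `read_feature_config()` returns a `feature_config`;
#'   `write_feature_config()` returns `path` invisibly.
#' @export
read_feature_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  feature_config(
    subordinators = raw$subordinators %||% default_subordinators(),
    iu_match_mode = raw$iu_match_mode %||% "word_boundary",
    case_insensitive = raw$case_insensitive %||% TRUE
  )
}

#' @rdname read_feature_config
#' @export
write_feature_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "feature_config"))
  lst <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

# Plain-list echo of a config, embedded in artifact headers for provenance.
config_echo <- function(cfg) {
  list(
    subordinators = cfg$subordinators,
    iu_match_mode = cfg$iu_match_mode,
    case_insensitive = cfg$case_insensitive,
    sd_convention = "population"
  )
}
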