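test_that("z-scored columns have mean 0 and population variance 1", {
  feats <- fixture_features()
  zres <- zscore_features(feats)
  pop_var <- function(x) mean((x - mean(x))^2)
  for (col in c("z_sentence_count", "z_complex_ratio", "z_avg_length", "z_ius")) {
    expect_lt(abs(mean(zres$z[[col]])), 1e-9)
    expect_lt(abs(pop_var(zres$z[[col]]) - 1), 1e-9)
  }
  expect_equal(zres$stats$feature,
               c("sentence_count", "complex_ratio", "avg_sentence_length",
                 "estimated_ius"))
})

test_that("z-scores are location-invariant: z(x + c) = z(x)", {
  feats <- fixture_features()
  shifted <- feats
  shifted$estimated_ius <- shifted$estimated_ius + 100L
  expect_equal(zscore_features(shifted)$z$z_ius,
               zscore_features(feats)$z$z_ius, tolerance = 1e-12)
})

test_that("constant feature columns raise a degenerate-feature error", {
  feats <- tibble::tibble(
    id = c("a", "b", "c"),
    sentence_count = c(10L, 10L, 10L),
    complex_ratio = c(0.1, 0.2, 0.3),
    avg_sentence_length = c(10, 11, 12),
    estimated_ius = c(5L, 6L, 7L)
  )
  expect_error(zscore_features(feats), "sentence_count",
               class = "storyload_degenerate_feature")
  expect_error(
    profile_corpus(stimulus_corpus(
      c("a", "b", "c"), rep("A dog ran. It barked.", 3)
    )),
    class = "storyload_degenerate_feature"
  )
})

test_that("composites are the unweighted mean of the four z-scores", {
  z <- tibble::tibble(
    id = c("a", "b"),
    z_sentence_count = c(1, 0),
    z_complex_ratio = c(-1, 0),
    z_avg_length = c(2, 0),
    z_ius = c(0, 0)
  )
  expect_equal(composite_scores(z), c(0.5, 0))
  expect_error(composite_scores(z[-2]), "z_sentence_count",
               class = "storyload_validation_error")
})

test_that("reference composites and blocks are reproduced at full precision", {
  fx <- load_fixtures()
  prof <- fixture_profile()
  m <- match(fx$table1_features$id, prof$table$id)
  expect_true(all(abs(prof$table$composite[m] -
                        fx$table1_features$composite) < 0.005))
  expect_identical(as.character(prof$table$block[m]),
                   fx$table1_features$block)
  expect_equal(as.integer(table(prof$table$block)), c(4L, 4L, 4L))
  expect_setequal(prof$table$id[prof$table$block == "High"],
                  c("Airport", "Gas", "Tickets", "Fire"))
})

test_that("only the population-SD convention reproduces the printed composites", {
  feats <- fixture_features()
  airport <- function(sd_type) {
    z <- zscore_features(feats, sd_type = sd_type)$z
    composite_scores(z)[feats$id == "Airport"]
  }
  expect_lt(abs(airport("population") - 0.698), 0.005)
  expect_gt(abs(airport("sample") - 0.698), 0.02)
})

test_that("composite column mean is 0 for any corpus", {
  set.seed(11)
  for (i in 1:5) {
    n <- sample(4:20, 1)
    feats <- tibble::tibble(
      id = paste0("s", seq_len(n)),
      sentence_count = sample(5:20, n, replace = TRUE),
      complex_ratio = runif(n),
      avg_sentence_length = runif(n, 8, 20),
      estimated_ius = sample(5:25, n, replace = TRUE)
    )
    comp <- composite_scores(zscore_features(feats)$z)
    expect_lt(abs(mean(comp)), 1e-9)
  }
})

test_that("block assignment matches the sort-and-slice oracle", {
  expect_identical(as.character(assign_blocks(c(-1, 0, 1))),
                   c("Low", "Medium", "High"))
  set.seed(7)
  for (n in seq(3, 30, by = 3)) {
    x <- sample(seq_len(1000), n) / 10
    expect_identical(as.character(assign_blocks(x)), sort_slice_blocks(x))
  }
})

test_that("non-multiple-of-three sizes differ by at most one per block", {
  set.seed(3)
  for (n in c(4, 5, 7, 10, 11)) {
    x <- sample(seq_len(500), n)
    sizes <- as.integer(table(assign_blocks(x)))
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

test_that("degenerate block inputs raise and ties warn", {
  expect_error(assign_blocks(c(1, 2)), class = "storyload_validation_error")
  expect_error(assign_blocks(rep(1, 6)), class = "storyload_validation_error")
  expect_warning(assign_blocks(c(1, 1, 2, 3, 4, 5)), "tie")
})

test_that("profiles are invariant under stimulus reordering", {
  feats <- fixture_features()[setdiff(names(fixture_features()), "role")]
  prof1 <- profile_features(feats)
  set.seed(5)
  perm <- sample(nrow(feats))
  prof2 <- profile_features(feats[perm, ])
  m <- match(prof1$table$id, prof2$table$id)
  expect_equal(prof1$table$composite, prof2$table$composite[m],
               tolerance = 1e-12)
  expect_identical(as.character(prof1$table$block),
                   as.character(prof2$table$block[m]))
})

test_that("profile artifacts include config echo and full precision", {
  dir <- withr::local_tempdir()
  prof <- fixture_profile()
  write_profile(prof, dir)
  expect_true(all(file.exists(file.path(
    dir, c("profile.csv", "profile.json", "profile.md")
  ))))
  js <- jsonlite::read_json(file.path(dir, "profile.json"),
                            simplifyVector = TRUE)
  expect_identical(js$config$sd_convention, "population")
  expect_identical(js$config$iu_match_mode, "word_boundary")
  airport <- js$profile$composite[js$profile$id == "Airport"]
  expect_lt(abs(airport - 0.6984), 1e-3)
  md <- readLines(file.path(dir, "profile.md"))
  expect_match(md[1], "^\\| Story \\|")
  expect_true(any(grepl("\\| 0.698 \\| High \\|", md)))
})
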