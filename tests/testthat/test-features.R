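cfg <- feature_config()

test_that("automatic segmentation splits on terminator runs and drops empties", {
  seg <- segment_sentences("He ran. She walked! Done?")
  expect_identical(seg$sentences, c("He ran.", "She walked!", "Done?"))
  expect_equal(seg$effective_count, 3L)
  expect_identical(seg$provenance, "auto")

  expect_equal(segment_sentences("No terminal punctuation")$effective_count, 1L)
  expect_equal(segment_sentences("Wait... what?! Yes.")$effective_count, 3L)
  expect_error(segment_sentences("   "), class = "storyload_validation_error")
})

test_that("a manual override wins over the naive split but keeps fragments", {
  seg <- segment_sentences("Mr. Smith left.", override = 1)
  expect_equal(length(seg$sentences), 2L)
  expect_equal(seg$effective_count, 1L)
  expect_identical(seg$provenance, "override")
  expect_error(segment_sentences("Hi.", override = 0),
               class = "storyload_validation_error")
})

test_that("word counting is whitespace-delimited with punctuation attached", {
  expect_equal(count_words("A dog ran."), 3L)
  expect_equal(count_words("  two   words  "), 2L)
  expect_equal(count_words(""), 0L)
  expect_equal(count_words("well-known isn't one-off"), 3L)
  expect_equal(count_words("line\none\ttab two"), 4L)
})

test_that("complex ratio flags sentences with any subordinator, once each", {
  seg <- segment_sentences("He left because it rained. She stayed.")
  expect_equal(complex_sentence_ratio(seg, cfg), 0.5)

  # multiple subordinators in one sentence still count that sentence once,
  # and "although" must not double-match through its "though" substring
  seg2 <- segment_sentences("Although he thought so when asked, he left. Fine.")
  expect_equal(complex_sentence_ratio(seg2, cfg), 0.5)

  # sentence-initial subordinators count; non-subordinator text does not
  seg3 <- segment_sentences("When he arrived, all clapped. The end came.")
  expect_equal(complex_sentence_ratio(seg3, cfg), 0.5)

  # word-boundary matching: "whenever"/"iffy" are not subordinator hits
  seg4 <- segment_sentences("Whenever is not counted. That iffy plan failed.")
  expect_equal(complex_sentence_ratio(seg4, cfg), 0)
})

test_that("estimated IUs counts commas plus and/but per matching mode", {
  expect_equal(estimated_ius("I ran, and he walked, but she stayed.", cfg), 4L)
  expect_equal(estimated_ius("The band played.", cfg), 0L)
  expect_equal(
    estimated_ius("The band played.", feature_config(iu_match_mode = "substring")),
    1L
  )
  expect_equal(estimated_ius("Butter and jam; a dash - done.", cfg), 1L)
  expect_equal(estimated_ius("", cfg), 0L)
})

test_that("word-boundary IU counts never exceed substring counts", {
  sub_cfg <- feature_config(iu_match_mode = "substring")
  texts <- c(
    "The band played, and butter melted.",
    "Sand and sandwiches abound.",
    "Plain text with no events here.",
    vapply(1:20, function(i) {
      generate_stimulus(synth_spec(3, 20, 1, i %% 7, seed = i))$text
    }, character(1))
  )
  for (t in texts) {
    expect_lte(estimated_ius(t, cfg), estimated_ius(t, sub_cfg))
  }
})

test_that("feature extraction composes the four operators at full precision", {
  corpus <- toy_corpus()
  feats <- extract_features(corpus, cfg)
  expect_identical(feats$id, corpus$id)
  # avg length * sentence count reproduces word count exactly
  expect_equal(feats$avg_sentence_length * feats$sentence_count,
               as.numeric(feats$word_count), tolerance = 1e-12)
  expect_true(all(feats$complex_ratio >= 0 & feats$complex_ratio <= 1))
  # spot-check the first story: 3 sentences, 14 words, 1 complex, 2 IU events
  expect_equal(feats$sentence_count[1], 3L)
  expect_equal(feats$word_count[1], 14L)
  expect_equal(feats$complex_ratio[1], 1 / 3)
  expect_equal(feats$estimated_ius[1], 2L)
})

test_that("extraction is invariant to trailing whitespace and line endings", {
  base <- "He left because it rained. She stayed, and he waved."
  variants <- c(base, paste0(base, "   \n"), gsub(" ", "\n", base))
  ref <- extract_features(stimulus_corpus("x", base), cfg)
  for (v in variants[-3]) {
    got <- extract_features(stimulus_corpus("x", v), cfg)
    expect_equal(got, ref)
  }
  # newlines instead of spaces change nothing either (same token runs)
  got <- extract_features(stimulus_corpus("x", variants[3]), cfg)
  expect_equal(got$word_count, ref$word_count)
  expect_equal(got$estimated_ius, ref$estimated_ius)
})

test_that("feature tables write with the documented column order", {
  dir <- withr::local_tempdir()
  feats <- extract_features(toy_corpus(), cfg)
  path <- write_features(feats, file.path(dir, "features.csv"))
  header <- readLines(path, n = 1)
  expect_identical(
    header,
    "id,sentence_count,word_count,avg_sentence_length,complex_ratio,estimated_ius"
  )
})

test_that("feature configs round-trip through YAML and JSON", {
  dir <- withr::local_tempdir()
  custom <- feature_config(subordinators = c("because", "while"),
                           iu_match_mode = "substring",
                           case_insensitive = FALSE)
  for (ext in c("yaml", "json")) {
    p <- file.path(dir, paste0("cfg.", ext))
    write_feature_config(custom, p)
    expect_equal(read_feature_config(p), custom)
  }
})
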