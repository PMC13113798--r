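---
title: "Structural load profiling of narrative stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural load profiling of narrative stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(storyload)
```

## The problem

Discourse-level aphasia therapies such as story-retelling therapy lean on
narrative stimuli whose structural properties are rarely quantified. Two
stories of similar length can impose very different processing demands —
more clause embedding, denser information, longer sentences — and without a
measurement of that load, stimulus selection and sequencing stay informal.
storyload implements a transparent, rule-based profiling pipeline for such
stimuli: four surface features per story, corpus-wide z-normalization, a
composite structural load score, and tertile load blocks. It also provides
the exploratory outcome side: relating composite load to the number of
information units (IUs) a client produces when retelling each story before
and after treatment.

Everything is deliberately rule-based rather than model-based. The point is
reproducibility: every number a profile contains can be recomputed by hand
from the text.

## The four features

For each stimulus text:

* **Sentence count** — the automatic splitter cuts at runs of `.`, `!`, `?`
  followed by whitespace or end of text. Punctuation splitting is a known
  approximation (it cannot see abbreviations or independent-clause boundaries
  that lack punctuation), so a manually verified count can be supplied per
  stimulus as `sentence_count_override`; the override then becomes the
  effective count while the automatic fragments continue to drive the
  complex-sentence flags.
* **Word count** — maximal whitespace-delimited token runs; punctuation stays
  attached, hyphenated words and contractions are single tokens.
* **Average sentence length** — `word_count / sentence_count`, kept at full
  precision.
* **Complex sentence ratio** — the fraction of sentences containing at least
  one subordinating conjunction from a closed set (*because, although, when,
  if, since, though, unless, while*). A sentence with several subordinators
  counts once; matching is whole-word and case-insensitive, so "although"
  cannot double-match through its "though" substring and "whenever" is not a
  hit. Sentence position is ignored: a sentence-initial "When …" counts.
* **Estimated IUs** — a surface proxy for information density: the count of
  ASCII commas plus occurrences of "and" plus occurrences of "but". Two
  matching modes exist because naive substring counting (the
  `str.count`-style convention common in quick text pipelines) also matches
  "band" and "butter". The default `word_boundary` mode does not; the
  `substring` mode reproduces the naive convention exactly. The mode in force
  is echoed into every artifact so a profile is never ambiguous about its
  counting rule. Only the comma character U+002C counts; semicolons and
  dashes are excluded because the definition names commas only, and curly
  quotation marks are left untouched. Estimated IUs describe the *written*
  stimulus and are not comparable to produced IUs scored from spoken
  retellings.

```{r}
cfg <- feature_config()
corpus <- stimulus_corpus(
  id = c("walk", "storm", "market"),
  text = c(
    "He left early. She stayed home because it rained. They met, and they talked.",
    "The storm came. Trees fell! Roads closed, but crews worked, and power returned. All was calm.",
    "When the market opened, carts rolled in. Bread sold fast. Prices rose. People waited, watched, and smiled. A dog slept. The bell rang."
  )
)
extract_features(corpus, cfg)
```

## Composite structural load and blocks

Each feature x is z-normalized across the corpus, `z = (x - mu) / sigma`,
with sigma the **population** (divide-by-n) standard deviation, and the
composite structural load score of a stimulus is the unweighted mean of its
four z-scores. The population-sigma choice is not cosmetic: on the packaged
reference corpus it reproduces the published composites to three decimals,
while the sample (n−1) convention misses the first of them by about 0.03 —
the package tests pin this contrast down as an explicit convention check.
Composites are always computed on full-precision features (for features
published in rounded form, `fixture_features()` reconstructs exact values:
average length as `word_count / sentence_count`, the complex ratio as the
exact fraction over the sentence count), never on two-decimal display
values.

Load blocks are equal-frequency tertiles of the composite: ranks are cut at
n/3 and 2n/3, the top third is High load. With n divisible by 3 and distinct
composites the split is exact (4/4/4 at n = 12); otherwise block sizes
differ by at most one. Ties at a boundary are broken by stable input order
with a warning — real corpora essentially never tie on a four-feature
composite, but the behaviour is pinned down rather than left to chance. A
constant feature column (sigma = 0) or an all-equal composite vector raises
an error instead of producing silent zeros.

```{r}
prof <- fixture_profile()
prof
```

## Outcome analysis

Per-stimulus produced-IU gains follow the study design the package mirrors:
a treated stimulus is retold before and after its single treatment session
(gain = post − pre); an evaluation-only stimulus is never treated and is
retold at pre-treatment, immediately after the treatment block (Post1), and
at a maintenance follow-up (Post2). Its headline gain is Post2 − Pre, with
all three interval gains reported alongside (they telescope:
`(Post1-Pre) + (Post2-Post1) = (Post2-Pre)`).

`summarize_gains()` joins gains to a profile and reports Pearson
correlations between composite load and gain for the full corpus and for
each condition, mean gain per load block, and mean gain per condition. With
a dozen stimuli from a single participant these are directional descriptives
only, so no p-values are attached by default. Degenerate subsets (fewer than
three stimuli, zero variance) raise rather than returning `NaN`.

```{r}
summary <- summarize_gains(prof, fixture_gains())
summary
```

## The synthetic generator

`generate_stimulus()` inverts the feature definitions: given target sentence
count, word count, number of complex sentences and number of IU events, it
builds a narrative-like text that hits all four targets *by construction*.
Sentences are assembled from a small closed filler vocabulary chosen so that
no filler contains a subordinator, "and" or "but" even as a substring —
therefore the word-boundary and substring counting modes agree on every
generated text, and the only countable events are the ones the generator
inserts deliberately. Subordinators go strictly mid-sentence with filler on
both sides (which is why a complex sentence needs at least three words, and
an infeasible request fails with a constructive message); IU events are
split between "and"/"but" substitutions into free word slots and commas
appended to words. Counts are tracked during construction, never patched
post hoc, so the round trip through `extract_features()` is exact — the test
suite asserts this for a hundred random specifications.

`generate_corpus()` draws feature targets uniformly from ranges calibrated
to short therapy narratives (11–16 sentences, 150–225 words, 10–21 IU
events, up to 11 complex sentences — the scale of the reference corpus), and
returns the ground-truth feature table alongside the texts. From 12 stimuli
on, three are marked evaluation-only, mirroring the 9-treated/3-evaluation
layout. What generated texts do **not** emulate is real narrative language:
they have no semantics, no schema structure, no referential cohesion, no
controlled lexical frequency. Passing round-trip tests therefore validates
the *counting machinery*, not any claim about how real stories distribute
their features.

```{r}
rec <- generate_stimulus(synth_spec(14, 220, 7, 21, seed = 1))
extract_features(rec)
```

## Packaged reference fixtures

The original twelve story texts are adaptations of a standardized discourse
comprehension measure and cannot be redistributed, so the package ships the
published per-stimulus values instead: raw features with printed composites
and blocks, per-stimulus IU gains with condition roles, and the three
evaluation trajectories. `fixture_profile()` recomputes the profile from the
raw features and matches every printed composite within ±0.005 and every
block label exactly; `fixture_gains()` reproduces the published gain column,
including the evaluation gains derived from the trajectories.

## Numerical and design choices

* Population SD in z-scores (see above); the sample convention is available
  only for the convention check.
* `iu_match_mode` governs only the "and"/"but" matching; subordinator
  detection is always whole-word, since a substring rule there would let
  "whenever" or "iffy" flag a sentence as complex.
* Text is normalized at load (BOM stripped, CRLF/CR to LF) and nowhere else;
  feature extraction is invariant to trailing whitespace and line-ending
  style.
* All stored artifacts carry full precision; rounding (two decimals for
  features and means, three for composites) happens only in display
  renderers. JSON artifacts embed a configuration echo (subordinator set,
  matching mode, SD convention) for provenance.
* Everything is deterministic: profiling has no randomness, and generation is
  a pure function of its seed.

The test suite exercises the pipeline at the scale it is meant for — corpora
of three to thirty stimuli and a hundred-spec generator sweep — which keeps
a full run in seconds while still covering every invariant stated above.

## Limitations

Four surface features cannot capture lexical sophistication, imageability,
cohesion, semantic density or schema familiarity, all of which plausibly
influence retelling performance; the composite is a structural index, not a
difficulty oracle. The comma-based IU proxy inherits every inconsistency of
an author's punctuation. And the outcome analysis is descriptive by design:
correlations over a dozen stimuli from one participant support direction
statements, not inference.
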