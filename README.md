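# storyload

Rule-based structural profiling of narrative stimuli for discourse-level
aphasia therapy, plus exploratory analysis of produced information-unit (IU)
gains against stimulus complexity.

Story-retelling therapy presents a client with short narratives; clinicians
usually pick those stories by topic and familiarity, while their *structural*
demands go unmeasured. storyload quantifies them with four transparent
features per story — sentence count, word count–derived average sentence
length, the complex-sentence ratio, and a comma/conjunction proxy for
estimated information units — then z-normalizes each feature across the
corpus, averages the four z-scores into a **composite structural load
score**, and assigns **Low / Medium / High load blocks** by tertile:

    z_f(s)      = (x_f(s) - mu_f) / sigma_f        (sigma_f: population SD)
    composite(s) = mean over the four features of z_f(s)
    block(s)     = tertile of composite(s)  (top third = High)

On the outcome side, the package computes per-stimulus IU gains (post − pre
for treated stories; Post2 − pre, with all interval gains, for
evaluation-only stories), Pearson correlations between composite load and
gain, and mean gains per block and condition. A deterministic generator
builds narrative-like texts whose extracted features hit specified targets
exactly, for calibration and testing, and the published reference values for
a twelve-story corpus ship as fixtures.

## Worked example

```r
library(storyload)

prof <- fixture_profile()        # profile of the packaged reference corpus
prof$table[1, c("id", "composite", "block")]
#> # A tibble: 1 × 3
#>   id      composite block
#>   <chr>       <dbl> <fct>
#> 1 Airport     0.698 High

summarize_gains(prof, fixture_gains())
#> <analysis_summary>
#>
#> Correlations (composite load vs IU gain):
#>      subset  n     r
#>         all 12 +0.05
#>     treated  9 +0.13
#>  evaluation  3 -0.07
#>
#> Mean IU gain by load block:
#>   block mean_gain n
#>     Low     18.25 4
#>  Medium     43.75 4
#>    High     25.00 4
#>
#> Mean IU gain by condition:
#>        role mean_gain n
#>  evaluation      8.33 3
#>     treated     35.89 9
```

The Airport story carries the highest structural load of the corpus
(composite +0.698, High block). Across stimuli, load is essentially
uncorrelated with how many more IUs the client produced after treatment
(r = +0.05 over all 12), while Medium-load stories show the largest average
gain (43.75 IUs) — descriptive patterns, not inference, given n = 12 from a
single participant.

Profiling your own corpus:

```r
profile <- run_profile("stimuli/manifest.csv", "out/")      # csv + json + md
summary <- run_analyze("stimuli/manifest.csv", "outcomes.csv", "out/")
```

or from a shell via the bundled CLI (exit code 2 on validation errors):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "storyload.R", package = "storyload"))')" \
  profile --manifest stimuli/manifest.csv --out out/
```

Synthetic corpora with exact known features:

```r
gen <- generate_corpus(12, seed = 7)
all.equal(extract_features(gen$corpus), gen$features)  # TRUE, exactly
```

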