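# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-pass product-moment formula for Pearson's r.
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Equal-frequency tertiles by sorting and slicing into three contiguous runs.
# Defined for distinct values with n divisible by 3.
sort_slice_blocks <- function(x, labels = c("Low", "Medium", "High")) {
  stopifnot(length(x) %% 3 == 0, !anyDuplicated(x))
  third <- length(x) / 3
  ord <- order(x)
  out <- character(length(x))
  out[ord] <- rep(labels, each = third)
  out
}

# A six-story corpus built in code: three treated and three evaluation
# stimuli, varied enough that no feature column is degenerate and every
# analysis subset supports a correlation.
toy_corpus <- function() {
  stimulus_corpus(
    id = c("walk", "storm", "market", "river", "bakery", "garden"),
    text = c(
      "He left early. She stayed home because it rained. They met, and they talked.",
      "The storm came. Trees fell! Roads closed, but crews worked, and power returned. All was calm.",
      "When the market opened, carts rolled in. Bread sold fast. Prices rose. People waited, watched, and smiled. A dog slept. The bell rang.",
      "The river rose since the rain kept on. Boats waited. A bridge closed, and ferries stopped. Children watched from the hill. Water fell slowly.",
      "Flour arrived at dawn. The ovens warmed. Bread, rolls, and cakes filled the shelves while the town slept. A line formed outside.",
      "She planted seeds. Rain came when clouds gathered. Weeds grew, but flowers won. The fence leaned. Birds sang. Summer ended."
    ),
    role = rep(c("treated", "evaluation"), each = 3)
  )
}

write_toy_corpus_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- toy_corpus()
  write_corpus(corpus, dir)
}
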