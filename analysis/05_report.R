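#!/usr/bin/env Rscript
# Collate the stage outputs into one plain-text summary.

library(utrmotif)

read_stage <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE)
}

ranking <- read_stage("results/kmer_stats.tsv")
inst <- read_stage("results/instances.tsv")
strata <- read_stage("results/cdf_tests.tsv")
truth <- read_stage("results/data/truth_genes.tsv")

lines <- c(
  sprintf("conserved 8-mer scan: %d 8-mers scored; top by signal: %s (signal %.0f)",
          nrow(ranking), ranking$kmer[1], ranking$signal[1]),
  sprintf("planted pattern expansions rank: %s",
          paste(match(c("UAAGUUAU", "UAACUUAU"), ranking$kmer),
                collapse = ", ")),
  sprintf("motif instances: %d in %d UTRs (%d conserved)",
          nrow(inst), length(unique(inst$utr_id)),
          sum(inst$conserved, na.rm = TRUE)),
  sprintf("ground truth: %d planted genes", sum(truth$motif_planted)),
  "position-stratified KS tests:",
  paste(capture.output(print(strata)), collapse = "\n"))

writeLines(lines, "results/summary.txt")
cat(lines, sep = "\n")
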