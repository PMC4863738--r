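#!/usr/bin/env Rscript
# Test whether motif-bearing transcripts respond to the simulated knockdown:
# hypergeometric overlap with the up-regulated set, one-sided KS comparison
# of fold-change CDFs against all other expressed genes, the shuffled-motif
# enrichment spectrum, and position-stratified variants of the CDF test.

library(utrmotif)

seed <- 1L
utrs <- one_utr_per_gene(read_utr_fasta("results/data/utrs.fa"))
expr <- read_expression_table("results/data/expression.tsv",
                              q_threshold = 0.05)
inst <- scan_motif(utrs, "UAASUUAU", window = 300)

universe <- unique(expr$gene_id)
motif_genes <- intersect(unique(inst$gene_id), universe)
up <- expr$gene_id[expr$de_class == "up"]

enr <- hypergeometric_enrichment(motif_genes, up, universe)
cat(sprintf("up-set enrichment: k=%d of n=%d up genes, K=%d motif genes, N=%d, p=%.3g\n",
            enr$overlap_k, enr$de_set_n, enr$motif_set_K, enr$universe_N,
            enr$p_value))

fc <- setNames(expr$log2_fold_change, expr$gene_id)
ks <- cdf_fold_change_comparison(fc[motif_genes],
                                 fc[setdiff(universe, motif_genes)])
cat(sprintf("fold-change CDF shift vs all other genes: D=%.3f, one-sided p=%.3g\n",
            ks$D, ks$p_value))

for (mode in c("mononucleotide", "dinucleotide")) {
  spec <- shuffle_spec(mode = mode, seed = seed)
  spectrum <- shuffled_motif_background(utrs, "UAASUUAU", spec, expr)
  utrmotif:::write_tsv(spectrum,
                       sprintf("results/control_spectrum_%s.tsv", mode),
                       seed)
  ctrl <- spectrum[spectrum$role == "control", ]
  cat(sprintf("%s shuffles: motif p=%.3g vs control p range [%.3g, %.3g] (%d controls)\n",
              mode, spectrum$enrich_p[spectrum$role == "motif"],
              min(ctrl$enrich_p), max(ctrl$enrich_p), nrow(ctrl)))
}

strata <- do.call(rbind, lapply(
  c("terminal", "central", "proximal", "distal"), function(s) {
    r <- position_stratified_cdf(inst, expr, s, window = 300)
    data.frame(stratum = s, n_genes = r$n_genes,
               D = ifelse(r$untestable, NA, r$D),
               p_value = ifelse(r$untestable, NA, r$p_value))
  }))
utrmotif:::write_tsv(strata, "results/cdf_tests.tsv", seed)
print(strata)
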