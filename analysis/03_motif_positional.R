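#!/usr/bin/env Rscript
# Characterize the UAASUUAU motif: instance scan with conservation flags,
# multi-copy statistics, variant co-occurrence, positional profile along the
# UTR, sequence-logo context matrix, and the terminal-vs-central
# conservation bias test.

library(utrmotif)

seed <- 1L
utrs <- one_utr_per_gene(read_utr_fasta("results/data/utrs.fa"))
alignments <- read_alignment_blocks("results/data/alignments.fa")

inst <- scan_motif(utrs, "UAASUUAU", alignments, window = 300)
utrmotif:::write_tsv(inst, "results/instances.tsv", seed)

mc <- multi_copy_stats(inst)
cat(sprintf("motif-bearing UTRs: %d (%.1f%% of %d)\n",
            mc$n_single + mc$n_multi,
            100 * (mc$n_single + mc$n_multi) / nrow(utrs), nrow(utrs)))
cat(sprintf("multi-copy UTRs: %d (%.1f%%), median spacing %s nt\n",
            mc$n_multi, 100 * mc$fraction_multi,
            format(mc$median_spacing)))

# do the two variants co-occur more than chance?
gHit <- function(p) unique(inst$utr_id[inst$matched_seq == p])
co <- cooccurrence_hypergeometric(gHit("UAAGUUAU"), gHit("UAACUUAU"),
                                  nrow(utrs))
cat(sprintf("variant co-occurrence: k=%d of K=%d x n=%d, p=%.3g\n",
            co$k, co$K, co$n, co$p_value))

prof <- positional_profile(inst$relative_position, inst$conserved,
                           n_bins = 20)
utrmotif:::write_tsv(
  data.frame(bin_lo = prof$bin_edges[-21], bin_hi = prof$bin_edges[-1],
             total = prof$total_counts, conserved = prof$conserved_counts,
             uniform_expectation = prof$uniform_expectation),
  "results/profile.tsv", seed)

pfm <- context_matrix(inst, utrs, flank = 10)
utrmotif:::write_tsv(data.frame(base = rownames(pfm), as.data.frame(pfm)),
                     "results/context_pfm.tsv", seed)

bias <- conservation_position_bias(inst, window = 300)
cat(sprintf(paste0("conservation bias: terminal %.3f vs central %.3f ",
                   "conserved (z=%.2f, one-sided p=%.3g)\n"),
            bias$frac_terminal, bias$frac_central, bias$z, bias$p_value))
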