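# utrmotif

Discovery and characterization of conserved 3' UTR decay elements.

Mammalian 3' UTRs carry short cis-regulatory elements that control mRNA
stability, and comparative genomics can find them: a word under purifying
selection is conserved across species more often than shuffled versions of
itself. `utrmotif` implements that discovery scan and the downstream
characterization used to study the degenerate element UAASUUAU
(S = C or G), a prevalent AU-rich motif that destabilizes host transcripts:

1. **Conserved k-mer enrichment.** For each 8-mer *w* observed in a set of
   3' UTRs aligned across human, mouse, rat and dog, count UTRs with at
   least one conserved instance (column-exact presence in all four
   species), and form the signal

   `signal(w) = C(w) / mean_i C(s_i(w))`

   where `C` is the conserved-UTR count and `s_1..s_n` are shuffled
   controls of *w* matched for nucleotide (or dinucleotide) composition,
   UGUA content and abundance, excluding miRNA seed matches, the
   polyadenylation signal, pumilio sites and ARE consensus words.
2. **Motif characterization.** IUPAC scanning with overlapping matches,
   multi-copy statistics and spacing, exact hypergeometric co-occurrence
   (`P(X >= k)`), positional binning along the UTR, sequence-logo context
   matrices, and a one-sided two-proportion z-test for preferential
   conservation in the first/last 300 nt.
3. **Expression enrichment.** Against a CuffDiff-style knockdown table:
   upper-tail hypergeometric overlap of motif-bearing genes with the
   up-regulated set, one-sided two-sample Kolmogorov–Smirnov comparison of
   fold-change CDFs versus all other expressed genes and versus
   shuffled-motif gene sets, and position-stratified variants.

A synthetic-data generator (`generate_utr_set()`,
`generate_expression_table()`) stands in for genome annotations and
deposited RNA-seq: it plants motifs with controlled cross-species retention,
positional bias and knockdown effects, and ships a complete ground-truth
ledger so every stage is testable by parameter recovery.

## Worked example

```r
library(utrmotif)

cfg <- synthetic_config(seed = 1)          # 2000 genes, ~1700-nt UTRs,
sim <- generate_utr_set(cfg)               # UAASUUAU planted in 10%
expr <- generate_expression_table(sim$truth, cfg)

ranking <- rank_kmers(sim$utrs, sim$alignments, shuffle_spec(seed = 1))
head(ranking[, 1:7], 3)
#>        kmer utr_count conserved_utr_count conserved_instance_count
#> 1: UAAGUUAU       230                  77                       78
#> 2: UAACUUAU       221                  66                       66
#> 3: UUAAGUUA       181                  16                       16
#>    n_controls_used shuffle_mean signal
#> 1:              10          0.0    770
#> 2:              10          0.3    220
#> 3:              10          0.0    160
```

Both expansions of the planted pattern top the ranking: ~70 of the ~200
planted UTRs retain a perfectly aligned copy in all four species, while
their composition-matched shuffles are almost never conserved (when the
shuffle mean is 0 the signal falls back to the pseudocount denominator
`1/n_controls` and is flagged `unstable`). The third word is a 1-nt shift
of the planted motif picking up its flanks.

```r
inst <- scan_motif(sim$utrs, "UAASUUAU", sim$alignments)
up <- expr$gene_id[expr$de_class == "up"]
hypergeometric_enrichment(unique(inst$gene_id), up, expr$gene_id)
#> $overlap_k   : int 125      $motif_set_K : int 420
#> $de_set_n    : int 125      $universe_N  : int 2000
#> $p_value     : num 1.11e-92
```

All 125 up-called genes carry the motif — the simulated knockdown
de-represses exactly the motif-bearing transcripts, and the hypergeometric
tail reports the overlap as (vanishingly) unlikely under independence.

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `05_report.R`) that run these stages on the default
profile and write tables under `results/`.

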