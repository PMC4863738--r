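---
title: "Discovering conserved 3' UTR decay elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved 3' UTR decay elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`utrmotif` implements a comparative-genomics workflow for finding short
cis-regulatory elements in mammalian 3' UTRs and characterizing their
regulatory impact. The workflow has three statistical stages:

1. **Conserved k-mer enrichment.** For every 8-nt word observed in a set of
   3' UTRs, count the UTRs that carry at least one *conserved* instance —
   an occurrence present, column-exact, in the aligned orthologous sequence
   of every species in the panel (human, mouse, rat and dog by default) —
   and normalize that count by the mean conserved count of matched
   *shuffled controls* of the same word. Words under purifying selection
   out-conserve their shuffles; neutral words score near 1.
2. **Motif characterization.** Scan a degenerate (IUPAC) motif such as
   UAASUUAU (S = C/G), report all overlapping instances with 0-based
   coordinates, quantify multi-copy UTRs and the spacing between copies,
   test variant co-occurrence by exact hypergeometric tail, bin instances
   by relative UTR position, emit a position-frequency matrix of the
   sequence context, and test whether conserved instances concentrate in
   the terminal (first/last 300 nt) regions of UTRs.
3. **Expression enrichment.** Given a two-condition knockdown
   differential-expression table (CuffDiff-style gene-level TSV), test
   motif-bearing transcripts for over-representation among up-regulated
   genes (exact hypergeometric upper tail, `P(X >= k)`), compare their
   fold-change CDF against all other expressed genes with a one-sided
   two-sample Kolmogorov–Smirnov test, repeat both against
   shuffled-motif gene sets, and stratify by instance position.

Because the genome-scale inputs (UTR annotations, whole-genome alignments,
deposited RNA-seq) are not redistributable at package scale, a first-class
synthetic generator (`generate_utr_set()`, `generate_expression_table()`)
produces all three inputs with a complete ground-truth ledger, and every
stage is validated by parameter recovery against that truth.

# Conventions and numerical choices

* **Coordinates** are 0-based, half-open, on the ungapped reference-species
  UTR, 5'→3' (BED-compatible interval arithmetic).
* **Alphabet** is DNA internally (U→T on input); reports render motifs in
  RNA. `N` never matches a pattern and always breaks conservation.
* **One UTR per gene**: when several transcripts share a gene id, the
  longest UTR is kept, ties broken to the lexicographically smallest UTR
  id — a deterministic rule so that gene- and UTR-level counts are
  interchangeable.
* **Conservation call**: the strict default requires, over the alignment
  columns occupied by the word, every non-reference row to be gap-free and
  identical to the word. The alternative `conservation = list(window = w)`
  call accepts the word anywhere within ±w of the orthologous position in
  each species' ungapped row; strictness is the default because it is the
  most reproducible reading and conservative against alignment noise.
* **Signal** = conserved-UTR count / mean conserved-UTR count of the
  controls. When the control mean is zero the divisor becomes
  `1/n_controls` and the row is flagged `unstable`: ranking is preserved
  without dividing by zero.
* **KS sidedness**: `alternative = "greater"` always means "the sample is
  shifted toward higher fold changes" (its CDF lies below the
  background's); the mapping to `stats::ks.test`'s convention is handled
  internally and pinned by tests.

# Shuffled controls

Controls for a word preserve either its letter multiset (mononucleotide
mode) or its exact dinucleotide multiset (dinucleotide mode; every Eulerian
walk over the word's dinucleotide multigraph is enumerated). Candidates are
then filtered:

* equal overlapping UGUA count (the pumilio core), so that pumilio-driven
  conservation cannot leak into the null;
* no 7-mer from the excluded-site list (miRNA seed matches; the list is an
  input — the package ships none, and tests use small synthetic lists);
* neither containing nor contained in an expansion of the excluded IUPAC
  patterns — by default the polyadenylation signal AAUAAA, the
  pumilio site UGUAHAUA, and the ARE consensus UUAUUUAWW;
* no 7-mer shared with the source word itself. This filter is ours: a 1-nt
  shift of the source co-occurs and co-conserves with the source's own
  instances, so it is not an independent draw from the null and would
  inflate the control mean precisely for the words of interest;
* UTR count within `abundance_tolerance`-fold (default 2) of the source's.

Up to `n_controls` (default 10) survivors are drawn without replacement by
a seeded RNG; the draw is byte-reproducible given seed, spec and data. In
the genome-wide scan (`rank_kmers()`) and in the enrichment spectrum, a
word whose abundance filter removes every candidate — the expected
situation for a word under strong selection, which out-numbers all its
shuffles — falls back to composition-matched controls without the
abundance filter and is flagged `abundance_relaxed`; a word with no
shuffles at all (e.g. a homopolymer) is flagged `no_controls` and left
unscored. The standalone `generate_shuffle_controls()` keeps the strict
contract: warning on shortfall, error when nothing survives.

The number of controls per word is configurable because published analyses
of this kind typically show several control points per motif without
fixing the count; 10 per mode keeps the control-mean noise below the
discreteness of the conserved counts at the package's default problem
sizes.

# The synthetic generator as study conditions

The generator's defaults are the package's study conditions and are frozen:

| parameter | default | why |
|---|---|---|
| `n_genes` | 2000 | large enough for stable enrichment statistics, small enough to iterate on a laptop |
| UTR lengths | log-normal, mean 1700 nt, sdlog 0.6 | mammalian 3' UTRs average ~1.7 kb |
| composition | A .30, C .20, G .20, T .30 | AU-rich, as 3' UTRs are |
| species | human, mouse, rat, dog | the 4-species conservation panel |
| substitution | 0.30/column/species | neutral divergence at which chance 8-mer conservation is rare (~(0.7)^24 per instance) |
| indels | 0.01/column, geometric length (mean 2) | exercises gap handling; placed only in non-reference rows so truth coordinates stay exact, and never inside planted instances so retention is controlled by `retention_prob` alone |
| `plant_fraction` | 0.10 | an order of magnitude consistent with a prevalent regulatory element |
| `multi_copy_prob` | 0.11 | mirrors the ~11% multi-copy fraction among motif-bearing UTRs |
| `retention_prob` | 0.90/species | strong purifying selection on planted copies |
| `effect_log2fc` | +0.5 | a modest de-repression upon knockdown |
| `replicate_sd` | 0.15 (log2) | well-correlated replicates |
| `noise_sd` | 0 | gene-level fold-change noise off by default so the null is a point null and Benjamini–Hochberg calibration is testable |

Expression p-values default to `q_model = "ztest"`: a per-gene z statistic
at the generative replicate standard deviation. This emulates the
dispersion pooling that count-based DE tools achieve by sharing variance
information across genes; a per-gene Welch t on two replicates (also
available as `q_model = "ttest"`) has so few degrees of freedom that even
large true effects cannot clear an FDR threshold, which is a property of
the t test, not of the data. Chance occurrences of the planted pattern are
detected post hoc and recorded in the truth ledger rather than suppressed;
suppression would distort the background composition.

What the generator does *not* emulate: phylogenetic structure (substitutions
are i.i.d. per column and species, with no tree or rate matrix), alternative
polyadenylation isoforms, composition heterogeneity along the UTR, and
count-based measurement noise. Passing recovery tests therefore shows the
statistics behave correctly under their stated model, not that genome-scale
prevalence numbers would be reproduced on real annotations.

# Calibration regimes

Two test regimes deserve explanation because naive choices degenerate:

* **Neutral conservation calibration.** The median shuffle-normalized
  signal over all observed 8-mers is checked on a no-plant simulation of
  200 UTRs at substitution 0.02/column and indels 0.002/column. At
  realistic divergence (0.3/column) per-word conserved counts at this
  sample size are almost all zero and the ratio is undefined; the
  low-divergence regime keeps per-word conserved counts at O(1–10), where
  the ratio is informative and its median should sit near 1.
* **Null enrichment calibration.** Under a global expression null,
  Benjamini–Hochberg leaves the `q < 0.05` up-set empty, so the up-set
  hypergeometric p is identically 1 and cannot be uniform. The uniformity
  calibration therefore uses the raw `p < 0.05` & positive-fold-change
  up-set, which is non-empty under the null; the `q < 0.05` definition
  remains the operative enrichment set for every substantive analysis.

# Degenerate inputs and tie-breaks

* Empty UTR sets, empty instance tables and empty strata return empty
  tables or results flagged `untestable` rather than erroring.
* An instance in a UTR shorter than `2 * window` is terminal by
  construction; `proximal` takes precedence and the instance carries a
  `both_terminal` flag, so regions still partition instances.
* Instance spacing is start-to-start between adjacent copies (stated in
  the output header), the only unambiguous choice for overlapping copies.
* Relative position is the instance midpoint over UTR length, symmetric
  for the 5'-vs-3' comparison.
* Ranking ties are broken by conserved-UTR count, then lexicographic
  word order, so output is deterministic.

# Problem sizes

The test-suite and acceptance runs use the default profile (2000 genes)
for recovery checks (20 seeds), 200 UTRs for the neutral conservation
calibration, and reduced sizes (25–500 genes) for unit-level properties —
sizes at which every check completes quickly while keeping the binomial
noise of each statistic well inside its asserted tolerance.

# Known limitations

* Conservation is a categorical 4-species presence call; no branch-length
  weighting (a deliberate non-goal).
* The genome-wide scan supports words up to k = 8 (the lookup tables are
  4^k); single-word operations accept any length.
* The shuffled-control machinery assumes the excluded-site lists are
  small; very large 7-mer lists would be better served by a trie.
* Absolute prevalence numbers (fractions of UTRs containing a motif,
  overlap counts) depend on the UTR annotation and alignment build and are
  only meaningful relative to the synthetic study conditions.
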