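#' Hypergeometric enrichment of a gene set among differentially expressed genes
#'
#' Exact upper-tail hypergeometric test of the overlap between motif-bearing
#' genes and a differential-expression set within the universe of expressed
#' genes. Genes outside the universe are dropped with a message.
#'
#' @param motif_genes character vector of motif-bearing gene ids.
#' @param de_genes character vector of DE gene ids (e.g. the up-set).
#' @param universe_genes all expressed gene ids.
#' @param direction label recorded in the result (`"up"` or `"down"`).
#' @return list with `overlap_k`, `motif_set_K`, `de_set_n`, `universe_N`,
#'   `p_value`, `direction`.
#' @export
hypergeometric_enrichment <- function(motif_genes, de_genes, universe_genes,
                                      direction = c("up", "down")) {
  direction <- match.arg(direction)
  universe <- unique(universe_genes)
  if (!length(universe)) stop("empty gene universe")
  motif <- unique(motif_genes); de <- unique(de_genes)
  dropped <- sum(!(motif %in% universe)) + sum(!(de %in% universe))
  if (dropped > 0L) {
    message(dropped, " gene(s) outside the expression universe dropped")
  }
  motif <- intersect(motif, universe)
  de <- intersect(de, universe)
  k <- length(intersect(motif, de))
  p <- phyper(k - 1, length(motif), length(universe) - length(motif),
              length(de), lower.tail = FALSE)
  list(overlap_k = k, motif_set_K = length(motif), de_set_n = length(de),
       universe_N = length(universe), p_value = p, direction = direction)
}

#' One-sided KS comparison of fold-change distributions
#'
#' Two-sample Kolmogorov-Smirnov test with the one-sided alternative that
#' the sample distribution is shifted relative to the background.
#' `alternative = "greater"` means the sample tends toward *higher* fold
#' changes (its CDF lies below the background's).
#'
#' @param sample_fc fold changes of the gene set of interest.
#' @param background_fc fold changes of the (disjoint) background set.
#' @param alternative `"greater"` (sample shifted up, default) or `"less"`.
#' @return list with `n_sample`, `n_background`, `D`, `p_value`,
#'   `shift_direction`, `low_power` (TRUE when either n < 3).
#' @export
cdf_fold_change_comparison <- function(sample_fc, background_fc,
                                       alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  sample_fc <- sample_fc[is.finite(sample_fc)]
  background_fc <- background_fc[is.finite(background_fc)]
  if (!length(sample_fc) || !length(background_fc)) {
    stop("both samples must be non-empty")
  }
  # ks.test's "less" puts the CDF of x below that of y, i.e. x stochastically
  # larger -- our "greater"
  ks_alt <- if (alternative == "greater") "less" else "greater"
  res <- suppressWarnings(ks.test(sample_fc, background_fc,
                                  alternative = ks_alt, exact = FALSE))
  list(n_sample = length(sample_fc), n_background = length(background_fc),
       D = unname(res$statistic), p_value = unname(res$p.value),
       shift_direction = alternative,
       low_power = length(sample_fc) < 3L || length(background_fc) < 3L)
}

#' Enrichment spectrum of a motif against its shuffled controls
#'
#' For each concrete expansion of the motif and each of its shuffled
#' controls, forms the gene set whose UTRs contain the sequence, then (a)
#' compares the motif gene set's fold changes against that control set's by
#' one-sided KS and (b) tests the control set's own enrichment in the
#' up-regulated set by hypergeometric test, yielding the motif-vs-shuffles
#' enrichment spectrum. Genes carrying both the motif and a control sequence
#' stay in the motif set and are excluded from that control's set.
#'
#' @param utrs UTR set.
#' @param pattern IUPAC motif pattern.
#' @param spec a [shuffle_spec()].
#' @param expression expression table ([read_expression_table()] shape).
#' @param q_threshold q-value cutoff defining the up-set.
#' @return `data.frame` with one row for the motif and one per control:
#'   `sequence` (RNA), `role` (`motif`/`control`), `source_expansion`,
#'   `n_genes`, `enrich_p` (up-set hypergeometric), `cdf_p` (KS vs the motif
#'   set; NA for the motif row), `cdf_D`.
#' @export
shuffled_motif_background <- function(utrs, pattern, spec, expression,
                                      q_threshold = 0.05) {
  universe <- unique(expression$gene_id)
  fc <- setNames(expression$log2_fold_change, expression$gene_id)
  up <- expression$gene_id[classify_de(expression$log2_fold_change,
                                       expression$q_value,
                                       q_threshold) == "up"]
  genes_with <- function(seq_dna) {
    unique(utrs$gene_id[grepl(seq_dna, utrs$sequence, fixed = TRUE)])
  }
  expansions <- expand_iupac(rna_to_dna(pattern))
  motif_genes <- intersect(
    unique(unlist(lapply(expansions, genes_with))), universe)
  if (!length(motif_genes)) stop("no motif-bearing genes in the universe")
  motif_enrich <- hypergeometric_enrichment(motif_genes, up, universe)
  rows <- list(data.frame(sequence = dna_to_rna(pattern), role = "motif",
                          source_expansion = NA_character_,
                          n_genes = length(motif_genes),
                          enrich_p = motif_enrich$p_value,
                          cdf_p = NA_real_, cdf_D = NA_real_,
                          stringsAsFactors = FALSE))
  for (ex in expansions) {
    # a genuinely selected motif out-numbers all its shuffles, so the
    # abundance filter may empty the candidate set; retry without it (as in
    # rank_kmers) before giving up
    controls <- tryCatch(
      suppressWarnings(generate_shuffle_controls(ex, spec, utrs = utrs)),
      error = function(e) {
        message("abundance filter relaxed for '", dna_to_rna(ex), "'")
        tryCatch(
          suppressWarnings(generate_shuffle_controls(ex, spec)),
          error = function(e2) {
            stop("control set empty after filters for '", dna_to_rna(ex),
                 "'; relax the shuffle spec (", conditionMessage(e2), ")")
          })
      })
    for (ctrl in controls) {
      ctrl_genes <- setdiff(intersect(genes_with(ctrl), universe),
                            motif_genes)
      if (!length(ctrl_genes)) {
        message("control ", dna_to_rna(ctrl), " has no host genes; skipped")
        next
      }
      cdf <- cdf_fold_change_comparison(fc[motif_genes], fc[ctrl_genes])
      enr <- hypergeometric_enrichment(ctrl_genes, up, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = dna_to_rna(ctrl), role = "control",
        source_expansion = dna_to_rna(ex), n_genes = length(ctrl_genes),
        enrich_p = enr$p_value, cdf_p = cdf$p_value, cdf_D = cdf$D,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Position-stratified fold-change comparison
#'
#' Restricts the motif gene set to genes with at least one instance in a
#' positional stratum of the 3' UTR and compares that set's fold changes
#' against all other expressed genes by one-sided KS. A gene enters every
#' stratum in which it has an instance.
#'
#' @param instances a [scan_motif()] table.
#' @param expression expression table.
#' @param stratum one of `"terminal"`, `"central"`, `"proximal"`, `"distal"`.
#' @param window terminal-region width in nt.
#' @return a [cdf_fold_change_comparison()] result with `stratum`,
#'   `n_genes`, and `untestable` added (`untestable = TRUE`, p NA when the
#'   stratum is empty).
#' @export
position_stratified_cdf <- function(instances, expression,
                                    stratum = c("terminal", "central",
                                                "proximal", "distal"),
                                    window = 300L) {
  stratum <- match.arg(stratum)
  reg <- classify_region(instances$start, instances$end,
                         instances$utr_length, window)
  in_stratum <- switch(stratum,
                       terminal = reg$region %in% c("proximal", "distal"),
                       central = reg$region == "central",
                       proximal = reg$region == "proximal" | reg$both,
                       distal = reg$region == "distal" | reg$both)
  genes <- intersect(unique(instances$gene_id[in_stratum]),
                     expression$gene_id)
  if (!length(genes)) {
    return(list(stratum = stratum, n_genes = 0L, n_sample = 0L,
                n_background = 0L, D = NA_real_, p_value = NA_real_,
                untestable = TRUE))
  }
  fc <- setNames(expression$log2_fold_change, expression$gene_id)
  background <- setdiff(expression$gene_id, genes)
  res <- cdf_fold_change_comparison(fc[genes], fc[background])
  c(list(stratum = stratum, n_genes = length(genes)), res,
    list(untestable = FALSE))
}
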