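#' Default pipeline configuration
#'
#' Resolved run configuration for [run_pipeline()]: the synthetic-data
#' profile (or input paths), the motif pattern, shuffle spec, windows/bins,
#' thresholds and the seed. Values supplied in `...` override the defaults;
#' a YAML file may supply the same fields via [read_run_config()].
#'
#' @param ... overrides for any field.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "conserve", "scan", "position", "enrich",
               "report"),
    utrs_fasta = NULL, alignment_fasta = NULL, expression_tsv = NULL,
    species = c("human", "mouse", "rat", "dog"),
    pattern = "UAASUUAU",
    shuffle_mode = "mononucleotide",
    n_controls = 10L,
    abundance_tolerance = 2,
    excluded_7mers = character(0),
    window = 300L,
    n_bins = 20L,
    q_threshold = 0.05,
    seed = 1L,
    synthetic = list())
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with configuration fields.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the discovery pipeline
#'
#' Orchestrates the stages: `simulate` (or load the configured inputs),
#' `conserve` (genome-wide k-mer conservation ranking), `scan` + `position`
#' (motif instances, positional profile, conservation-position bias),
#' `enrich` (hypergeometric and KS enrichment against the expression table,
#' including the shuffled-motif spectrum and position strata), and `report`
#' (a plain-text summary). Outputs are TSVs with a provenance comment; a
#' resolved-config echo (`config.yaml`) and the seed are written so a rerun
#' reproduces all outputs byte-identically.
#'
#' @param config a [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `status` (0 on success), `out_dir` and the
#'   main result objects.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  seed <- config$seed
  yaml::write_yaml(unclass(strip_null(config)), file.path(out_dir,
                                                          "config.yaml"))
  res <- list(status = 0L, out_dir = out_dir)

  if ("simulate" %in% stages) {
    syn_args <- config$synthetic
    syn_args$seed <- seed
    syn_args$planted_pattern <- config$pattern
    syn_args$species <- config$species
    syn_args$q_threshold <- config$q_threshold
    scfg <- do.call(synthetic_config, syn_args)
    sim <- generate_utr_set(scfg)
    utrs <- sim$utrs
    alignments <- sim$alignments
    expression <- generate_expression_table(sim$truth, scfg)
    write_utr_fasta(utrs, file.path(out_dir, "utrs.fa"))
    write_alignment_blocks(alignments, file.path(out_dir, "alignments.fa"))
    write_expression_table(expression, file.path(out_dir, "expression.tsv"),
                           seed = seed)
    write_tsv(sim$truth$plants, file.path(out_dir, "truth_plants.tsv"),
              seed)
    write_tsv(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"), seed)
    res$truth <- sim$truth
  } else {
    if (is.null(config$utrs_fasta)) {
      stop("missing input: utrs_fasta (no simulate stage configured)")
    }
    utrs <- read_utr_fasta(config$utrs_fasta)
    alignments <- if (!is.null(config$alignment_fasta)) {
      read_alignment_blocks(config$alignment_fasta, config$species)
    }
    expression <- if (!is.null(config$expression_tsv)) {
      read_expression_table(config$expression_tsv, config$q_threshold)
    }
  }
  utrs <- one_utr_per_gene(utrs)
  spec <- shuffle_spec(mode = config$shuffle_mode,
                       n_controls = config$n_controls,
                       abundance_tolerance = config$abundance_tolerance,
                       excluded_7mers = config$excluded_7mers,
                       seed = seed)

  if ("conserve" %in% stages) {
    if (is.null(alignments)) stop("missing input: alignment_fasta")
    ranking <- rank_kmers(utrs, alignments, spec)
    write_tsv(as.data.frame(ranking), file.path(out_dir, "kmer_stats.tsv"),
              seed)
    res$ranking <- ranking
  }

  instances <- NULL
  if (any(c("scan", "position") %in% stages)) {
    instances <- scan_motif(utrs, config$pattern, alignments,
                            window = config$window)
    write_tsv(instances, file.path(out_dir, "instances.tsv"), seed)
    res$instances <- instances
    res$multi_copy <- multi_copy_stats(instances)
  }
  if ("position" %in% stages && !is.null(instances)) {
    prof <- positional_profile(instances$relative_position,
                               instances$conserved, config$n_bins)
    write_tsv(data.frame(bin_lo = prof$bin_edges[-(prof$n_bins + 1L)],
                         bin_hi = prof$bin_edges[-1L],
                         total = prof$total_counts,
                         conserved = prof$conserved_counts,
                         uniform_expectation = prof$uniform_expectation),
              file.path(out_dir, "profile.tsv"), seed)
    res$profile <- prof
    if (any(!is.na(instances$conserved))) {
      res$position_bias <- conservation_position_bias(instances,
                                                      config$window)
    }
    pfm <- context_matrix(instances, utrs, flank = 10L)
    write_tsv(data.frame(base = rownames(pfm), as.data.frame(pfm)),
              file.path(out_dir, "context_pfm.tsv"), seed)
  }

  if ("enrich" %in% stages) {
    if (is.null(expression)) stop("missing input: expression_tsv")
    if (is.null(instances)) {
      instances <- scan_motif(utrs, config$pattern, alignments,
                              window = config$window)
    }
    universe <- unique(expression$gene_id)
    motif_genes <- unique(instances$gene_id)
    up <- expression$gene_id[expression$de_class == "up"]
    res$enrichment <- hypergeometric_enrichment(motif_genes, up, universe)
    fc <- setNames(expression$log2_fold_change, expression$gene_id)
    in_universe <- intersect(motif_genes, universe)
    res$cdf <- cdf_fold_change_comparison(fc[in_universe],
                                          fc[setdiff(universe, motif_genes)])
    res$spectrum <- shuffled_motif_background(utrs, config$pattern, spec,
                                              expression,
                                              config$q_threshold)
    write_tsv(res$spectrum, file.path(out_dir, "control_spectrum.tsv"), seed)
    strata <- lapply(c("terminal", "central", "proximal", "distal"),
                     function(s) {
                       r <- position_stratified_cdf(instances, expression, s,
                                                    config$window)
                       data.frame(stratum = s, n_genes = r$n_genes,
                                  D = if (r$untestable) NA_real_ else r$D,
                                  p_value = if (r$untestable) NA_real_ else
                                    r$p_value,
                                  untestable = r$untestable)
                     })
    res$strata <- do.call(rbind, strata)
    write_tsv(data.frame(
      test = c("hypergeometric_up", "ks_vs_other_genes"),
      statistic = c(res$enrichment$overlap_k, res$cdf$D),
      p_value = c(res$enrichment$p_value, res$cdf$p_value)),
      file.path(out_dir, "enrichment.tsv"), seed)
    write_tsv(res$strata, file.path(out_dir, "cdf_tests.tsv"), seed)
  }

  if ("report" %in% stages) {
    lines <- c(provenance_line(seed),
               sprintf("UTRs analyzed: %d", nrow(utrs)))
    if (!is.null(res$ranking)) {
      lines <- c(lines, sprintf(
        "top conserved 8-mer: %s (signal %.1f, conserved in %d UTRs)",
        res$ranking$kmer[1L], res$ranking$signal[1L],
        res$ranking$conserved_utr_count[1L]))
    }
    if (!is.null(res$multi_copy)) {
      lines <- c(lines, sprintf(
        "motif %s: %d single-copy / %d multi-copy UTRs (%.1f%% multi; median spacing %s nt)",
        config$pattern, res$multi_copy$n_single, res$multi_copy$n_multi,
        100 * res$multi_copy$fraction_multi,
        format(res$multi_copy$median_spacing)))
    }
    if (!is.null(res$enrichment)) {
      lines <- c(lines, sprintf(
        "up-set enrichment: k=%d of K=%d motif genes, p=%.3g; KS vs other genes p=%.3g",
        res$enrichment$overlap_k, res$enrichment$motif_set_K,
        res$enrichment$p_value, res$cdf$p_value))
    }
    writeLines(lines, file.path(out_dir, "summary.txt"))
  }
  invisible(res)
}

strip_null <- function(x) x[!vapply(x, is.null, logical(1))]

# TSV writer with the provenance comment line all pipeline outputs carry
write_tsv <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
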