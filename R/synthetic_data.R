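#' Configuration for the synthetic UTR / expression generator
#'
#' The generator emulates the inputs of the discovery pipeline: a set of
#' reference-species 3' UTRs with log-normal lengths averaging ~1700 nt
#' (mammalian 3' UTR scale), orthologous rows for each further species
#' derived by per-column substitution and geometric indels, planted motif
#' instances with elevated cross-species retention and optional terminal
#' positional bias, and a two-condition knockdown expression table in which
#' motif-bearing genes are up-shifted.
#'
#' @param n_genes number of genes (one UTR per gene).
#' @param utr_mean_length target mean UTR length in nt.
#' @param utr_sdlog log-sd of the log-normal length distribution.
#' @param background_composition named A/C/G/T probabilities (AU-rich
#'   default, as in mammalian 3' UTRs).
#' @param species ordered species names; first is the reference.
#' @param per_species_substitution_rate substitutions per column in each
#'   non-reference species.
#' @param indel_rate indel events per column in each non-reference species
#'   (split evenly between insertions and deletions; lengths geometric,
#'   mean 2).
#' @param planted_pattern IUPAC motif planted into a fraction of UTRs.
#' @param plant_fraction fraction of genes receiving >= 1 instance.
#' @param multi_copy_prob probability a planted gene receives a second
#'   instance.
#' @param retention_prob probability a planted instance stays intact in each
#'   non-reference species (an unretained copy receives one random
#'   substitution).
#' @param positional_bias `"uniform"` or `list(type = "terminal", window)`.
#' @param effect_log2fc knockdown log2 fold change added to affected genes.
#' @param effect_scope `"all"` planted genes or only `"terminal"` ones
#'   (>= 1 planted instance within `effect_window` of either UTR end).
#' @param effect_window terminal window (nt) used by `effect_scope`.
#' @param noise_sd sd of gene-level log2 fold-change noise.
#' @param replicate_sd sd of per-replicate log2 measurement noise.
#' @param n_replicates replicates per condition.
#' @param q_model `"ztest"` (z statistic at the generative replicate sd,
#'   emulating dispersion pooling across genes) or `"ttest"` (per-gene
#'   Welch t).
#' @param q_threshold q cutoff for the up/down call.
#' @param seed RNG seed; all randomness in the generator flows from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             utr_mean_length = 1700,
                             utr_sdlog = 0.6,
                             background_composition = c(A = 0.3, C = 0.2,
                                                        G = 0.2, T = 0.3),
                             species = c("human", "mouse", "rat", "dog"),
                             per_species_substitution_rate = 0.3,
                             indel_rate = 0.01,
                             planted_pattern = "UAASUUAU",
                             plant_fraction = 0.1,
                             multi_copy_prob = 0.11,
                             retention_prob = 0.9,
                             positional_bias = "uniform",
                             effect_log2fc = 0.5,
                             effect_scope = c("all", "terminal"),
                             effect_window = 300L,
                             noise_sd = 0,
                             replicate_sd = 0.15,
                             n_replicates = 2L,
                             q_model = c("ztest", "ttest"),
                             q_threshold = 0.05,
                             seed = 1L) {
  effect_scope <- match.arg(effect_scope)
  q_model <- match.arg(q_model)
  stopifnot(n_genes >= 1L, utr_mean_length > 0, utr_sdlog > 0,
            abs(sum(background_composition) - 1) < 1e-8,
            per_species_substitution_rate >= 0,
            per_species_substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            plant_fraction >= 0, plant_fraction <= 1,
            multi_copy_prob >= 0, multi_copy_prob <= 1,
            retention_prob >= 0, retention_prob <= 1,
            length(species) >= 2L, n_replicates >= 2L)
  structure(list(n_genes = as.integer(n_genes),
                 utr_mean_length = utr_mean_length, utr_sdlog = utr_sdlog,
                 background_composition = background_composition[DNA_BASES],
                 species = species,
                 per_species_substitution_rate = per_species_substitution_rate,
                 indel_rate = indel_rate,
                 planted_pattern = planted_pattern,
                 plant_fraction = plant_fraction,
                 multi_copy_prob = multi_copy_prob,
                 retention_prob = retention_prob,
                 positional_bias = positional_bias,
                 effect_log2fc = effect_log2fc, effect_scope = effect_scope,
                 effect_window = as.integer(effect_window),
                 noise_sd = noise_sd, replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 q_model = q_model, q_threshold = q_threshold, seed = seed),
            class = "synthetic_config")
}

# meanlog of a log-normal with the configured mean and sdlog
lnorm_meanlog <- function(mean, sdlog) log(mean) - sdlog^2 / 2

#' Generate a synthetic aligned UTR set with planted motifs
#'
#' Reference sequences are drawn from the background composition;
#' non-reference rows are derived by per-column substitution and geometric
#' indels (indels never fall inside planted instances, so reference
#' coordinates in the truth ledger stay exact). Planted instances are
#' overwritten into every species and then independently broken (one random
#' substitution) with probability `1 - retention_prob` per non-reference
#' species. Fully reproducible from the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `utrs` (UTR set), `alignments` (named list of
#'   `utr_alignment`), and `truth`: `genes` (per-gene ledger with
#'   `motif_planted`, `terminal_plant`), `plants` (per planted instance:
#'   exact 0-based coordinates, per-species retention, `conserved`),
#'   `background` (chance occurrences of the pattern, detected post hoc),
#'   and the config.
#' @export
generate_utr_set <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_utr_set_impl(config))
}

generate_utr_set_impl <- function(config) {
  n <- config$n_genes
  k <- nchar(config$planted_pattern)
  expansions <- expand_iupac(rna_to_dna(config$planted_pattern))
  comp <- config$background_composition
  min_len <- max(50L, k + 2L)
  meanlog <- lnorm_meanlog(config$utr_mean_length, config$utr_sdlog)
  lens <- as.integer(round(rlnorm(n, meanlog, config$utr_sdlog)))
  short <- which(lens < min_len)
  while (length(short)) {                       # redraw too-short UTRs
    lens[short] <- as.integer(round(rlnorm(length(short), meanlog,
                                           config$utr_sdlog)))
    short <- which(lens < min_len)
  }
  gene_id <- sprintf("gene%05d", seq_len(n))
  utr_id <- sprintf("utr%05d", seq_len(n))
  planted <- runif(n) < config$plant_fraction
  others <- config$species[-1L]
  utr_seq <- character(n)
  alignments <- vector("list", n)
  plant_rows <- list()
  for (g in seq_len(n)) {
    L <- lens[g]
    ref <- sample(DNA_BASES, L, replace = TRUE, prob = comp)
    starts <- integer(0); seqs <- character(0)
    if (planted[g]) {
      starts <- draw_plant_position(L, k, config$positional_bias)
      seqs <- sample(expansions, 1L)
      if (runif(1) < config$multi_copy_prob) {
        for (try in 1:20) {
          s2 <- draw_plant_position(L, k, config$positional_bias)
          if (abs(s2 - starts[1L]) >= k) {
            starts <- c(starts, s2)
            seqs <- c(seqs, sample(expansions, 1L))
            break
          }
        }
      }
      for (j in seq_along(starts)) {
        ref[starts[j]:(starts[j] + k - 1L)] <- strsplit(seqs[j], "")[[1]]
      }
    }
    plant_mask <- rep(FALSE, L)
    for (s in starts) plant_mask[s:(s + k - 1L)] <- TRUE
    sp_chars <- list()
    ins_list <- list()
    retained <- matrix(TRUE, nrow = length(starts), ncol = length(others),
                       dimnames = list(NULL, others))
    for (sp in others) {
      row <- ref
      mut <- which(runif(L) < config$per_species_substitution_rate)
      if (length(mut)) {
        cur <- match(row[mut], DNA_BASES)
        row[mut] <- DNA_BASES[((cur - 1L + sample(1:3, length(mut),
                                                  replace = TRUE)) %% 4L) + 1L]
      }
      # planted copies overwritten into the species, then possibly broken
      for (j in seq_along(starts)) {
        span <- starts[j]:(starts[j] + k - 1L)
        row[span] <- strsplit(seqs[j], "")[[1]]
        if (runif(1) >= config$retention_prob) {
          pos <- span[sample.int(k, 1L)]
          cur <- match(row[pos], DNA_BASES)
          row[pos] <- DNA_BASES[((cur - 1L + sample(1:3, 1L)) %% 4L) + 1L]
          retained[j, sp] <- FALSE
        }
      }
      # deletions (never inside planted instances)
      del_start <- which(runif(L) < config$indel_rate / 2 & !plant_mask)
      if (length(del_start)) {
        del_len <- rgeom(length(del_start), 0.5) + 1L
        del_pos <- unique(unlist(mapply(function(s0, l0) {
          seq.int(s0, min(L, s0 + l0 - 1L))
        }, del_start, del_len, SIMPLIFY = FALSE)))
        del_pos <- del_pos[!plant_mask[del_pos]]
        row[del_pos] <- "-"
      }
      sp_chars[[sp]] <- row
      # insertions (columns gapped in all other rows)
      ins_b <- which(runif(L + 1L) < config$indel_rate / 2) - 1L  # 0..L
      ins <- list()
      for (b in ins_b) {
        len0 <- rgeom(1L, 0.5) + 1L
        ins[[as.character(b)]] <- paste(
          sample(DNA_BASES, len0, replace = TRUE, prob = comp),
          collapse = "")
      }
      ins_list[[sp]] <- ins
    }
    rows <- c(setNames(list(ref), config$species[1L]), sp_chars)
    aligned <- assemble_alignment(rows, ins_list, config$species)
    utr_seq[g] <- paste(ref, collapse = "")
    alignments[[g]] <- new_utr_alignment(utr_id[g], aligned,
                                         reference_species = config$species[1L])
    if (length(starts)) {
      df <- data.frame(gene_id = gene_id[g], utr_id = utr_id[g],
                       start = starts - 1L, end = starts - 1L + k,
                       seq = dna_to_rna(seqs), utr_length = L,
                       stringsAsFactors = FALSE)
      for (sp in others) df[[paste0("retained_", sp)]] <- retained[, sp]
      df$conserved <- rowSums(retained) == length(others)
      plant_rows[[length(plant_rows) + 1L]] <- df
    }
  }
  names(alignments) <- utr_id
  utrs <- data.frame(utr_id = utr_id, gene_id = gene_id, sequence = utr_seq,
                     length = lens, stringsAsFactors = FALSE)
  plants <- if (length(plant_rows)) {
    do.call(rbind, plant_rows)
  } else {
    data.frame(gene_id = character(0), utr_id = character(0),
               start = integer(0), end = integer(0), seq = character(0),
               utr_length = integer(0), conserved = logical(0))
  }
  background <- chance_occurrences(utrs, expansions, plants, k)
  w <- config$effect_window
  terminal_plant <- if (nrow(plants)) {
    tp <- plants$start < w | plants$end > plants$utr_length - w
    gene_id %in% unique(plants$gene_id[tp])
  } else {
    rep(FALSE, n)
  }
  genes <- data.frame(gene_id = gene_id, utr_id = utr_id, utr_length = lens,
                      motif_planted = planted,
                      terminal_plant = terminal_plant,
                      stringsAsFactors = FALSE)
  list(utrs = utrs, alignments = alignments,
       truth = list(genes = genes, plants = plants, background = background,
                    config = config))
}

# draw a 1-based plant start under the configured positional bias
draw_plant_position <- function(L, k, bias) {
  last <- L - k + 1L
  if (identical(bias, "uniform")) return(sample.int(last, 1L))
  if (is.list(bias) && identical(bias$type, "terminal")) {
    w <- min(bias$window, last)
    if (runif(1) < 0.5) {
      sample.int(w, 1L)                                   # first w nt
    } else {
      max(1L, L - k + 1L - w + 1L) + sample.int(w, 1L) - 1L  # last w nt
    }
  } else {
    stop("positional_bias must be \"uniform\" or list(type=\"terminal\", window)")
  }
}

# merge per-species insertion blocks into consistent aligned rows
assemble_alignment <- function(rows, ins_list, species) {
  boundaries <- sort(unique(as.integer(unlist(lapply(ins_list, names)))))
  base <- vapply(rows, paste, character(1), collapse = "")
  if (!length(boundaries)) return(base[species])
  L <- length(rows[[1L]])
  out <- setNames(character(length(species)), species)
  for (sp in species) {
    parts <- character(0)
    prev <- 0L
    for (b in boundaries) {
      parts <- c(parts, substr(base[[sp]], prev + 1L, b))
      for (owner in names(ins_list)) {
        blk <- ins_list[[owner]][[as.character(b)]]
        if (is.null(blk)) next
        parts <- c(parts,
                   if (owner == sp) blk else strrep("-", nchar(blk)))
      }
      prev <- b
    }
    parts <- c(parts, substr(base[[sp]], prev + 1L, L))
    out[[sp]] <- paste(parts, collapse = "")
  }
  out
}

# occurrences of the pattern in the reference UTRs that were not planted;
# recorded, not suppressed (suppression would distort composition)
chance_occurrences <- function(utrs, expansions, plants, k) {
  rows <- list()
  for (g in seq_len(nrow(utrs))) {
    hits <- integer(0)
    for (ex in expansions) {
      hits <- c(hits, overlap_starts(utrs$sequence[g], ex))
    }
    hits <- sort(unique(hits)) - 1L
    if (!length(hits)) next
    planted_here <- plants$start[plants$utr_id == utrs$utr_id[g]]
    hits <- setdiff(hits, planted_here)
    if (!length(hits)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = utrs$gene_id[g], utr_id = utrs$utr_id[g], start = hits,
      end = hits + k,
      seq = dna_to_rna(substring(utrs$sequence[g], hits + 1L, hits + k)),
      utr_length = utrs$length[g], stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(gene_id = character(0), utr_id = character(0),
               start = integer(0), end = integer(0), seq = character(0),
               utr_length = integer(0))
  }
}

#' Generate a knockdown differential-expression table with known truth
#'
#' Control abundances are log-normal FPKMs; treated abundances are
#' `control * 2^(effect_log2fc * affected + noise)`, with `n_replicates`
#' noisy replicates per condition. P-values come from a per-gene two-sample
#' test on the replicates (`q_model`), q-values from Benjamini-Hochberg.
#'
#' @param truth truth component of [generate_utr_set()] output.
#' @param config the same [synthetic_config()] (expression uses
#'   `seed + 1` so the UTR and expression draws are independent).
#' @return expression `data.frame` ([read_expression_table()] shape) with a
#'   `"effect_genes"` attribute naming the genes that received the effect.
#' @export
generate_expression_table <- function(truth, config = truth$config) {
  genes <- truth$genes
  n <- nrow(genes)
  affected <- switch(config$effect_scope,
                     all = genes$motif_planted,
                     terminal = genes$terminal_plant)
  with_seed(config$seed + 1L, {
    base_log2 <- log2(rlnorm(n, meanlog = 3, sdlog = 1))
    true_lfc <- config$effect_log2fc * affected +
      rnorm(n, 0, config$noise_sd)
    r <- config$n_replicates
    ctrl <- matrix(base_log2, n, r) +
      matrix(rnorm(n * r, 0, config$replicate_sd), n, r)
    trt <- matrix(base_log2 + true_lfc, n, r) +
      matrix(rnorm(n * r, 0, config$replicate_sd), n, r)
    value_1 <- rowMeans(2^ctrl)
    value_2 <- rowMeans(2^trt)
    delta <- rowMeans(trt) - rowMeans(ctrl)
    p <- if (config$q_model == "ztest") {
      se <- config$replicate_sd * sqrt(2 / r)
      2 * pnorm(-abs(delta) / se)
    } else {
      vapply(seq_len(n), function(i) {
        t.test(trt[i, ], ctrl[i, ])$p.value
      }, numeric(1))
    }
    out <- data.frame(gene_id = genes$gene_id, value_1 = value_1,
                      value_2 = value_2,
                      log2_fold_change = log2(value_2 / value_1),
                      p_value = p, q_value = p.adjust(p, "BH"),
                      stringsAsFactors = FALSE)
    out$de_class <- classify_de(out$log2_fold_change, out$q_value,
                                config$q_threshold)
    attr(out, "effect_genes") <- genes$gene_id[affected]
    attr(out, "q_threshold") <- config$q_threshold
    out
  })
}
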