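IUPAC_CODES <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

#' Expand an IUPAC pattern into its concrete k-mers
#'
#' @param pattern IUPAC string (RNA or DNA alphabet), e.g. `"UAASUUAU"`.
#' @return character vector of all concrete expansions, DNA alphabet.
#' @export
expand_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  unknown <- setdiff(chars, names(IUPAC_CODES))
  if (length(unknown)) {
    stop("unknown IUPAC code(s): ", paste(unique(unknown), collapse = ", "))
  }
  out <- ""
  for (ch in chars) {
    out <- as.vector(outer(out, IUPAC_CODES[[ch]], paste0))
  }
  out
}

# character-class regex for an IUPAC pattern (DNA); used for one-pass scans
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    if (is.null(opts)) stop("unknown IUPAC code: ", ch)
    if (length(opts) == 1L) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan UTRs for a degenerate motif
#'
#' Reports every (possibly overlapping) match of any expansion of the IUPAC
#' pattern, with 0-based half-open coordinates, the relative position of the
#' instance midpoint, the terminal-region class, and — when alignments are
#' supplied — a strict cross-species conservation flag per instance.
#'
#' @param utrs UTR set ([read_utr_fasta()] shape).
#' @param pattern IUPAC pattern (RNA or DNA).
#' @param alignments optional named list of `utr_alignment` objects used to
#'   flag conserved instances (NA where no alignment is available).
#' @param window terminal-region width in nt for the region call.
#' @return `data.frame` ordered by (`utr_id`, `start`) with columns
#'   `utr_id`, `gene_id`, `pattern`, `matched_seq`, `start`, `end`,
#'   `utr_length`, `relative_position`, `region`, `both_terminal`,
#'   `conserved`.
#' @export
scan_motif <- function(utrs, pattern, alignments = NULL, window = 300L) {
  regex <- iupac_regex(rna_to_dna(pattern))
  k <- nchar(pattern)
  pieces <- vector("list", nrow(utrs))
  for (j in seq_len(nrow(utrs))) {
    seqj <- utrs$sequence[j]
    if (nchar(seqj) < k) next
    starts <- overlap_starts(seqj, regex)
    if (!length(starts)) next
    conserved <- rep(NA, length(starts))
    if (!is.null(alignments)) {
      a <- alignments[[utrs$utr_id[j]]]
      if (!is.null(a)) {
        flags <- conservation_flags(a, k)
        conserved <- flags[starts]
      }
    }
    pieces[[j]] <- data.frame(
      utr_id = utrs$utr_id[j], gene_id = utrs$gene_id[j],
      pattern = dna_to_rna(pattern),
      matched_seq = dna_to_rna(substring(seqj, starts, starts + k - 1L)),
      start = starts - 1L, end = starts - 1L + k,
      utr_length = nchar(seqj), stringsAsFactors = FALSE)
    pieces[[j]]$conserved <- as.logical(conserved)
  }
  inst <- do.call(rbind, pieces)
  if (is.null(inst)) {
    inst <- data.frame(utr_id = character(0), gene_id = character(0),
                       pattern = character(0), matched_seq = character(0),
                       start = integer(0), end = integer(0),
                       utr_length = integer(0), conserved = logical(0),
                       stringsAsFactors = FALSE)
  }
  inst$relative_position <- ifelse(inst$utr_length > 0,
                                   (inst$start + k / 2) / inst$utr_length,
                                   NA_real_)
  reg <- classify_region(inst$start, inst$end, inst$utr_length, window)
  inst$region <- reg$region
  inst$both_terminal <- reg$both
  inst <- inst[order(inst$utr_id, inst$start), , drop = FALSE]
  rownames(inst) <- NULL
  cols <- c("utr_id", "gene_id", "pattern", "matched_seq", "start", "end",
            "utr_length", "relative_position", "region", "both_terminal",
            "conserved")
  inst[, cols]
}

#' Terminal-region classification of motif instances
#'
#' An instance is `proximal` when it starts within the first `window` nt,
#' `distal` when it ends within the last `window` nt, and `central`
#' otherwise. In UTRs of at most `2 * window` nt an instance can satisfy
#' both rules; it is then classed `proximal` and flagged in `both`.
#'
#' @param start,end 0-based half-open instance coordinates (vectors).
#' @param utr_length UTR length(s) in nt.
#' @param window terminal-region width in nt.
#' @return list with `region` (character) and `both` (logical).
#' @export
classify_region <- function(start, end, utr_length, window = 300L) {
  prox <- start < window
  dist <- end > utr_length - window
  region <- ifelse(prox, "proximal", ifelse(dist, "distal", "central"))
  list(region = region, both = prox & dist)
}

#' Single- versus multi-copy statistics of a motif scan
#'
#' @param instances a [scan_motif()] table (one pattern).
#' @return list with `n_single`, `n_multi` (UTRs with >= 2 distinct instance
#'   starts), `fraction_multi` of motif-containing UTRs, and
#'   `median_spacing`: the median start-to-start distance between adjacent
#'   instances within multi-copy UTRs (NA when none exist).
#' @export
multi_copy_stats <- function(instances) {
  if (!nrow(instances)) {
    return(list(n_single = 0L, n_multi = 0L, fraction_multi = NA_real_,
                median_spacing = NA_real_))
  }
  per_utr <- split(instances$start, instances$utr_id)
  n_copies <- vapply(per_utr, function(s) length(unique(s)), integer(1))
  n_single <- sum(n_copies == 1L)
  n_multi <- sum(n_copies >= 2L)
  spacings <- unlist(lapply(per_utr[n_copies >= 2L],
                            function(s) diff(sort(unique(s)))))
  list(n_single = n_single, n_multi = n_multi,
       fraction_multi = n_multi / (n_single + n_multi),
       median_spacing = if (length(spacings)) median(spacings) else NA_real_)
}

#' Upper-tail hypergeometric co-occurrence test
#'
#' Tests whether two UTR (or gene) sets overlap more than expected if
#' membership were independent: `P(X >= k)` for the observed intersection
#' `k`, with `K = |A|`, `n = |B|` drawn from a universe of size `N`.
#'
#' @param setA_utrs,setB_utrs character vectors of ids.
#' @param universe_size integer universe size `N`.
#' @return list with `k`, `K`, `n`, `N`, `p_value` (exact upper tail).
#' @export
cooccurrence_hypergeometric <- function(setA_utrs, setB_utrs, universe_size) {
  A <- unique(setA_utrs); B <- unique(setB_utrs)
  K <- length(A); n <- length(B); k <- length(intersect(A, B))
  if (K > universe_size || n > universe_size) {
    stop("set larger than the universe")
  }
  p <- phyper(k - 1, K, universe_size - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = universe_size, p_value = p)
}

#' Positional profile of motif instances along the UTR
#'
#' Bins relative positions (in `[0, 1]`) into `n_bins` equal-width bins
#' (last bin right-closed) for total and conserved instances, together with
#' the per-bin count expected under a uniform positional distribution.
#'
#' @param relative_position numeric vector in `[0, 1]`.
#' @param conserved logical vector (NA treated as not conserved).
#' @param n_bins number of bins (>= 2).
#' @return list with `n_bins`, `bin_edges`, `total_counts`,
#'   `conserved_counts`, `uniform_expectation`
#'   (`length(relative_position) / n_bins`).
#' @export
positional_profile <- function(relative_position, conserved = NULL,
                               n_bins = 20L) {
  stopifnot(n_bins >= 2L)
  if (any(relative_position < 0 | relative_position > 1, na.rm = TRUE)) {
    stop("relative position outside [0, 1]; instance/UTR length mismatch?")
  }
  if (is.null(conserved)) conserved <- rep(FALSE, length(relative_position))
  conserved <- !is.na(conserved) & conserved
  bin <- pmax(1L, ceiling(relative_position * n_bins))
  total <- tabulate(bin, nbins = n_bins)
  cons <- tabulate(bin[conserved], nbins = n_bins)
  list(n_bins = n_bins,
       bin_edges = seq(0, 1, length.out = n_bins + 1L),
       total_counts = total, conserved_counts = cons,
       uniform_expectation = length(relative_position) / n_bins)
}

#' Nucleotide context matrix around motif instances
#'
#' Position-frequency matrix over the instances and `flank` nt of context on
#' each side (sequence-logo input). Instances whose flanks would run past a
#' UTR boundary are dropped with a message.
#'
#' @param instances a [scan_motif()] table.
#' @param utrs the UTR set the instances were scanned from.
#' @param flank context width in nt on each side.
#' @return numeric matrix, 4 rows (A, C, G, U) by `2 * flank + k` columns of
#'   frequencies summing to 1 per column.
#' @export
context_matrix <- function(instances, utrs, flank = 10L) {
  stopifnot(flank >= 0L)
  if (!nrow(instances)) stop("no instances to profile")
  k <- unique(instances$end - instances$start)
  stopifnot(length(k) == 1L)
  seqs <- utrs$sequence[match(instances$utr_id, utrs$utr_id)]
  lo <- instances$start - flank + 1L          # 1-based window bounds
  hi <- instances$end + flank
  usable <- lo >= 1L & hi <= nchar(seqs)
  if (!all(usable)) {
    message(sum(!usable), " instance(s) dropped: flank exceeds UTR boundary")
  }
  if (!any(usable)) stop("no usable instances after boundary clipping")
  win <- substring(seqs[usable], lo[usable], hi[usable])
  width <- 2L * flank + k
  mat <- matrix(0, nrow = 4L, ncol = width,
                dimnames = list(c("A", "C", "G", "U"), NULL))
  chars <- matrix(unlist(strsplit(win, "")), nrow = width)
  for (j in seq_len(width)) {
    tab <- table(factor(chars[j, ], levels = DNA_BASES))
    mat[, j] <- as.numeric(tab) / sum(tab)
  }
  mat
}

#' Conservation bias between terminal and central instances
#'
#' One-sided pooled two-proportion z-test of whether the fraction of
#' conserved instances is higher in the terminal regions (first/last
#' `window` nt) than in the central region.
#'
#' @param instances a [scan_motif()] table with non-NA `conserved` flags.
#' @param window terminal-region width in nt.
#' @return list with per-stratum counts and fractions, `z`, `p_value`, and
#'   `untestable` (TRUE when a stratum is empty).
#' @export
conservation_position_bias <- function(instances, window = 300L) {
  inst <- instances[!is.na(instances$conserved), , drop = FALSE]
  reg <- classify_region(inst$start, inst$end, inst$utr_length, window)
  terminal <- reg$region %in% c("proximal", "distal")
  n_t <- sum(terminal); n_c <- sum(!terminal)
  x_t <- sum(inst$conserved[terminal]); x_c <- sum(inst$conserved[!terminal])
  if (n_t == 0L || n_c == 0L) {
    return(list(n_terminal = n_t, n_central = n_c,
                frac_terminal = NA_real_, frac_central = NA_real_,
                z = NA_real_, p_value = NA_real_, untestable = TRUE))
  }
  p_t <- x_t / n_t; p_c <- x_c / n_c
  pool <- (x_t + x_c) / (n_t + n_c)
  se <- sqrt(pool * (1 - pool) * (1 / n_t + 1 / n_c))
  z <- if (se > 0) (p_t - p_c) / se else 0
  list(n_terminal = n_t, n_central = n_c,
       frac_terminal = p_t, frac_central = p_c,
       z = z, p_value = pnorm(z, lower.tail = FALSE), untestable = FALSE)
}
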