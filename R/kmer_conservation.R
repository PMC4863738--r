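#' Count UTRs containing a k-mer
#'
#' A UTR counts once however many (possibly overlapping) occurrences it
#' contains.
#'
#' @param utrs UTR set ([read_utr_fasta()] shape).
#' @param kmer concrete k-mer over A/C/G/T (RNA accepted, mapped to DNA).
#' @param k expected k-mer length (default 8).
#' @return integer count of distinct UTRs with at least one occurrence.
#' @export
count_utrs_with_kmer <- function(utrs, kmer, k = 8L) {
  kmer <- rna_to_dna(kmer)
  if (nchar(kmer) != k) {
    stop("kmer '", kmer, "' has length ", nchar(kmer), ", expected ", k)
  }
  if (grepl("[^ACGT]", kmer)) stop("kmer must be concrete (A/C/G/T only)")
  sum(grepl(kmer, utrs$sequence, fixed = TRUE))
}

# per-reference-position conservation flags for windows of width k.
# Position i (1-based, on the ungapped reference) is flagged when, at each of
# the k alignment columns carrying reference positions i..i+k-1, every
# non-reference row equals the reference base and no row holds a gap or N.
# Returns logical of length max(L - k + 1, 0).
conservation_flags <- function(alignment, k = 8L) {
  rows <- lapply(alignment$rows, function(s) strsplit(s, "")[[1]])
  ref <- rows[[alignment$reference_species]]
  okcol <- ref %in% DNA_BASES
  for (sp in setdiff(names(rows), alignment$reference_species)) {
    okcol <- okcol & (rows[[sp]] == ref)
  }
  ok <- okcol[ref != "-"]
  L <- length(ok)
  if (L < k) return(logical(0))
  cs <- cumsum(ok)
  (cs[k:L] - c(0, cs[seq_len(L - k)])) == k
}

#' Find occurrences of a k-mer in an alignment, flagged for conservation
#'
#' Occurrences are located on the ungapped reference row. Under the default
#' strict rule an occurrence is conserved when, over the alignment columns it
#' occupies, every non-reference row is gap-free and identical to the k-mer.
#' With `conservation = list(window = w)` the rule relaxes to: each
#' non-reference species' ungapped row contains the k-mer starting within
#' `w` positions of the orthologous location.
#'
#' @param alignment a `utr_alignment`.
#' @param kmer concrete k-mer (RNA accepted).
#' @param conservation `"strict"` (default) or `list(window = w)`.
#' @return `data.frame` with `reference_start` (0-based) and `conserved`.
#' @export
find_conserved_instances <- function(alignment, kmer,
                                     conservation = "strict") {
  kmer <- rna_to_dna(kmer)
  if (grepl("[^ACGT]", kmer)) stop("kmer must be concrete (A/C/G/T only)")
  k <- nchar(kmer)
  ref <- reference_sequence(alignment)
  starts <- overlap_starts(ref, kmer)
  if (!length(starts)) {
    return(data.frame(reference_start = integer(0), conserved = logical(0)))
  }
  if (identical(conservation, "strict")) {
    flags <- conservation_flags(alignment, k)
    conserved <- flags[starts]
  } else if (is.list(conservation) && !is.null(conservation$window)) {
    conserved <- window_conserved(alignment, kmer, starts,
                                  conservation$window)
  } else {
    stop("conservation must be \"strict\" or list(window = w)")
  }
  data.frame(reference_start = starts - 1L, conserved = conserved)
}

# relaxed positional-window conservation call (see find_conserved_instances)
window_conserved <- function(alignment, kmer, starts, w) {
  refrow <- strsplit(alignment$rows[[alignment$reference_species]], "")[[1]]
  refcols <- which(refrow != "-")
  others <- setdiff(names(alignment$rows), alignment$reference_species)
  per_species <- lapply(others, function(sp) {
    row <- strsplit(alignment$rows[[sp]], "")[[1]]
    ung <- cumsum(row != "-")            # column -> ortholog ungapped position
    seq_sp <- paste(row[row != "-"], collapse = "")
    hits <- overlap_starts(seq_sp, kmer)
    vapply(starts, function(i) {
      o <- ung[refcols[i]]               # orthologous ungapped position
      any(abs(hits - o) <= w)
    }, logical(1))
  })
  Reduce(`&`, per_species)
}

# per-instance table over every window of width k in every alignment:
# data.table(utr = integer id, kmer = integer code, pos = 1-based start,
# conserved = logical). Windows containing N are dropped.
kmer_instance_table <- function(alignments, k = 8L) {
  pieces <- vector("list", length(alignments))
  for (j in seq_along(alignments)) {
    a <- alignments[[j]]
    ref <- reference_sequence(a)
    L <- nchar(ref)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km <- substring(ref, starts, starts + k - 1L)
    idx <- kmer_index(km, k)
    flags <- conservation_flags(a, k)
    keep <- !is.na(idx)
    if (!any(keep)) next
    pieces[[j]] <- data.table(utr = j, kmer = idx[keep], pos = starts[keep],
                              conserved = flags[keep])
  }
  rbindlist(pieces)
}

#' Normalized conservation signal of a k-mer
#'
#' The signal is the conserved-UTR count divided by the mean conserved-UTR
#' count of the k-mer's shuffled controls. When the control mean is zero a
#' pseudocount of `1/n_controls` replaces it and the value is flagged
#' `unstable` (ranking is preserved, division by zero avoided).
#'
#' @param conserved_utr_count conserved-UTR count of the source k-mer.
#' @param control_counts conserved-UTR counts of its controls.
#' @param n_controls nominal control-set size for the pseudocount.
#' @return list with `signal` and `flag` (`"ok"` or `"unstable"`).
#' @export
conservation_signal <- function(conserved_utr_count, control_counts,
                                n_controls = length(control_counts)) {
  if (!length(control_counts)) stop("empty control set")
  m <- mean(control_counts)
  if (m > 0) {
    list(signal = conserved_utr_count / m, flag = "ok")
  } else {
    list(signal = conserved_utr_count * n_controls, flag = "unstable")
  }
}

#' Rank all observed k-mers by shuffle-normalized conservation signal
#'
#' Every k-mer occurring in at least one UTR is scored: UTRs containing it,
#' UTRs with at least one strictly conserved instance, total conserved
#' instances, and the conservation signal relative to its matched shuffled
#' controls. Exclusion lists in `spec` apply to controls only; the scan
#' itself covers every observed k-mer. When the abundance-tolerance filter
#' leaves no candidate control (typical for k-mers under strong selection,
#' which out-number all their shuffles), the k-mer's controls are re-drawn
#' without that filter and the row is flagged `abundance_relaxed`.
#'
#' @param utrs UTR set; must be the ungapped reference rows of `alignments`.
#' @param alignments named list of `utr_alignment` objects.
#' @param spec a [shuffle_spec()].
#' @param k word length (<= 8; default 8).
#' @return `data.table` sorted by descending signal with columns `kmer`
#'   (RNA), `utr_count`, `conserved_utr_count`, `conserved_instance_count`,
#'   `n_controls_used`, `shuffle_mean`, `signal`, `flag`, `controls`
#'   (comma-joined, RNA).
#' @export
rank_kmers <- function(utrs, alignments, spec = shuffle_spec(), k = 8L) {
  if (k > 8L) stop("rank_kmers supports k <= 8")
  if (!length(alignments)) {
    return(data.table(kmer = character(), utr_count = integer(),
                      conserved_utr_count = integer(),
                      conserved_instance_count = integer(),
                      n_controls_used = integer(), shuffle_mean = numeric(),
                      signal = numeric(), flag = character(),
                      controls = character()))
  }
  check_alignment_consistency(utrs, alignments)
  inst <- kmer_instance_table(alignments, k)
  stats <- inst[, list(utr_count = uniqueN(utr),
                       conserved_utr_count = uniqueN(utr[conserved]),
                       conserved_instance_count = sum(conserved)),
                by = "kmer"]
  setkey(stats, kmer)
  n_words <- as.integer(4^k)
  uc <- integer(n_words); uc[stats$kmer] <- stats$utr_count
  cc <- integer(n_words); cc[stats$kmer] <- stats$conserved_utr_count
  st <- kmer_static_tables(k, spec)
  observed <- stats$kmer
  n <- length(observed)
  n_used <- integer(n); smean <- numeric(n); sig <- numeric(n)
  flag <- character(n); chosen_list <- vector("list", n)
  words <- all_kmers(k)
  tol <- spec$abundance_tolerance
  with_seed(spec$seed, {
    for (r in seq_len(n)) {
      i <- observed[r]
      cand <- static_candidates(i, spec, st)
      flags_r <- character(0)
      if (length(cand)) {
        src <- uc[i]
        ab <- cand[uc[cand] >= src / tol & uc[cand] <= src * tol]
        if (length(ab)) {
          cand <- ab
        } else {
          flags_r <- "abundance_relaxed"
        }
      }
      if (!length(cand)) {
        n_used[r] <- 0L; smean[r] <- NA_real_; sig[r] <- NA_real_
        flag[r] <- "no_controls"
        next
      }
      chosen <- if (length(cand) > spec$n_controls) {
        sort(sample(cand, spec$n_controls))
      } else {
        if (length(cand) < spec$n_controls) {
          flags_r <- c(flags_r, "fewer_controls")
        }
        cand
      }
      n_used[r] <- length(chosen)
      m <- mean(cc[chosen])
      smean[r] <- m
      if (m > 0) {
        sig[r] <- cc[i] / m
      } else {
        sig[r] <- cc[i] * spec$n_controls
        flags_r <- c(flags_r, "unstable")
      }
      flag[r] <- if (length(flags_r)) paste(flags_r, collapse = ";") else "ok"
      chosen_list[[r]] <- chosen
    }
  })
  ctrl_str <- vapply(chosen_list, function(ix) {
    if (is.null(ix)) "" else paste(st$rna_words[ix], collapse = ",")
  }, character(1))
  out <- data.table(kmer = st$rna_words[observed],
                    utr_count = stats$utr_count,
                    conserved_utr_count = stats$conserved_utr_count,
                    conserved_instance_count = stats$conserved_instance_count,
                    n_controls_used = n_used, shuffle_mean = smean,
                    signal = sig, flag = flag, controls = ctrl_str)
  setorder(out, -signal, -conserved_utr_count, kmer, na.last = TRUE)
  out[]
}

# the ungapped reference rows must equal the UTR sequences of the same ids
check_alignment_consistency <- function(utrs, alignments) {
  common <- intersect(utrs$utr_id, names(alignments))
  probe <- head(common, 25L)
  for (id in probe) {
    if (!identical(utrs$sequence[match(id, utrs$utr_id)],
                   reference_sequence(alignments[[id]]))) {
      stop("ungapped reference row of alignment '", id,
           "' differs from the UTR sequence of the same id")
    }
  }
  invisible(TRUE)
}
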