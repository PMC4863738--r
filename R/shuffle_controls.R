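#' Specification of a shuffled-control set
#'
#' Controls for a source k-mer are shuffles preserving its mononucleotide
#' composition (anagrams) or its exact dinucleotide multiset. Candidates are
#' additionally filtered to: carry the same number of (overlapping) UGUA
#' cores as the source when `require_equal_ugua`; contain no excluded 7-mer
#' (miRNA seed matches); neither contain nor be contained in an expansion of
#' any excluded IUPAC pattern (polyadenylation signal, pumilio site, ARE by
#' default); share no 7-mer with the source itself when
#' `exclude_self_overlap` (a 1-nt shift of the source co-occurs with the
#' source's own instances and is not an independent null draw); and occur in
#' a number of UTRs within `abundance_tolerance`-fold of the source's count.
#'
#' @param mode `"mononucleotide"` or `"dinucleotide"`.
#' @param n_controls controls drawn per source k-mer.
#' @param abundance_tolerance allowed fold difference in UTR counts.
#' @param require_equal_ugua require equal overlapping UGUA counts.
#' @param excluded_7mers 7-nt site sequences banned from controls (RNA or
#'   DNA alphabet).
#' @param excluded_patterns IUPAC patterns banned from controls.
#' @param exclude_self_overlap drop candidates sharing a 7-mer with the
#'   source.
#' @param seed RNG seed for the (deterministic) control draw.
#' @return an object of class `shuffle_spec`.
#' @export
shuffle_spec <- function(mode = c("mononucleotide", "dinucleotide"),
                         n_controls = 10L,
                         abundance_tolerance = 2,
                         require_equal_ugua = TRUE,
                         excluded_7mers = character(0),
                         excluded_patterns = c("AAUAAA", "UGUAHAUA",
                                               "UUAUUUAWW"),
                         exclude_self_overlap = TRUE,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_controls >= 1L, abundance_tolerance >= 1)
  structure(list(mode = mode, n_controls = as.integer(n_controls),
                 abundance_tolerance = abundance_tolerance,
                 require_equal_ugua = isTRUE(require_equal_ugua),
                 excluded_7mers = rna_to_dna(excluded_7mers),
                 excluded_patterns = excluded_patterns,
                 exclude_self_overlap = isTRUE(exclude_self_overlap),
                 seed = seed),
            class = "shuffle_spec")
}

# evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' All distinct anagrams of a k-mer
#'
#' @param kmer concrete k-mer (RNA accepted).
#' @return character vector of every distinct letter permutation (DNA),
#'   including the k-mer itself.
#' @export
mono_variants <- function(kmer) {
  kmer <- rna_to_dna(kmer)
  ltr <- sort(strsplit(kmer, "")[[1]])
  rec <- function(rem) {
    if (length(rem) == 1L) return(rem)
    out <- character(0)
    for (u in unique(rem)) {
      out <- c(out, paste0(u, rec(rem[-match(u, rem)])))
    }
    out
  }
  rec(ltr)
}

#' All sequences with the same dinucleotide multiset as a k-mer
#'
#' Enumerates every Eulerian walk over the k-mer's dinucleotide multigraph,
#' i.e. every string of the same length whose multiset of adjacent pairs is
#' identical to the source's.
#'
#' @param kmer concrete k-mer (RNA accepted).
#' @return character vector of variants (DNA), including the k-mer itself.
#' @export
dinuc_variants <- function(kmer) {
  kmer <- rna_to_dna(kmer)
  k <- nchar(kmer)
  if (k < 2L) return(kmer)
  ltr <- strsplit(kmer, "")[[1]]
  tab <- table(paste0(ltr[-k], ltr[-1L]))
  edges <- names(tab)
  from <- substr(edges, 1L, 1L)
  to <- substr(edges, 2L, 2L)
  acc <- new.env(parent = emptyenv()); acc$res <- character(0)
  walk <- function(last, cnt, path) {
    if (all(cnt == 0L)) {
      acc$res <- c(acc$res, path)
      return(invisible(NULL))
    }
    for (i in seq_along(edges)) {
      if (cnt[i] > 0L && from[i] == last) {
        cnt2 <- cnt; cnt2[i] <- cnt2[i] - 1L
        walk(to[i], cnt2, paste0(path, to[i]))
      }
    }
  }
  for (s in unique(from)) walk(s, as.integer(tab), s)
  unique(acc$res)
}

# candidate controls passing every filter that does not need UTR data;
# returns DNA strings, never including the source
control_candidates_chr <- function(kmer, spec) {
  cands <- switch(spec$mode,
                  mononucleotide = mono_variants(kmer),
                  dinucleotide = dinuc_variants(kmer))
  cands <- setdiff(cands, kmer)
  if (!length(cands)) return(character(0))
  k <- nchar(kmer)
  if (spec$require_equal_ugua) {
    cands <- cands[count_overlapping(cands, "TGTA") ==
                     count_overlapping(kmer, "TGTA")]
  }
  if (length(spec$excluded_7mers) && length(cands)) {
    hit <- rep(FALSE, length(cands))
    for (s in spec$excluded_7mers) hit <- hit | grepl(s, cands, fixed = TRUE)
    cands <- cands[!hit]
  }
  if (length(spec$excluded_patterns) && length(cands)) {
    expz <- rna_to_dna(unlist(lapply(spec$excluded_patterns, expand_iupac)))
    hit <- rep(FALSE, length(cands))
    for (e in expz) {
      hit <- hit | if (nchar(e) <= k) {
        grepl(e, cands, fixed = TRUE)
      } else {
        vapply(cands, function(cc) grepl(cc, e, fixed = TRUE), logical(1))
      }
    }
    cands <- cands[!hit]
  }
  if (spec$exclude_self_overlap && k > 6L && length(cands)) {
    src7 <- substring(kmer, seq_len(k - 6L), 7:k)
    shares <- vapply(cands, function(cc) {
      any(substring(cc, seq_len(k - 6L), 7:k) %in% src7)
    }, logical(1))
    cands <- cands[!shares]
  }
  sort(cands)
}

#' Generate shuffled-control k-mers for a source k-mer
#'
#' Enumerates all composition-preserving shuffles, applies the filters of
#' [shuffle_spec()], and draws up to `n_controls` deterministically under the
#' spec's seed. A shortfall produces a warning; zero survivors an error.
#'
#' @param kmer concrete source k-mer (RNA accepted).
#' @param spec a [shuffle_spec()].
#' @param utrs UTR set for the abundance filter; with `utrs = NULL` (and no
#'   `utr_counts`) the abundance filter is skipped.
#' @param utr_counts optional precomputed UTR counts, a named integer vector
#'   over candidate k-mers (overrides `utrs`).
#' @return character vector of control k-mers (DNA alphabet).
#' @export
generate_shuffle_controls <- function(kmer, spec = shuffle_spec(),
                                      utrs = NULL, utr_counts = NULL) {
  kmer <- rna_to_dna(kmer)
  if (grepl("[^ACGT]", kmer)) stop("source kmer must be concrete")
  cands <- control_candidates_chr(kmer, spec)
  if (length(cands) && (!is.null(utrs) || !is.null(utr_counts))) {
    lookup <- function(x) {
      if (!is.null(utr_counts)) {
        n <- utr_counts[x]
        n[is.na(n)] <- 0L
        as.integer(n)
      } else {
        vapply(x, function(cc) sum(grepl(cc, utrs$sequence, fixed = TRUE)),
               integer(1))
      }
    }
    src <- lookup(kmer)
    cnt <- lookup(cands)
    tol <- spec$abundance_tolerance
    cands <- cands[cnt >= src / tol & cnt <= src * tol]
  }
  if (!length(cands)) {
    stop("no shuffle controls for '", dna_to_rna(kmer),
         "' survive the filters; relax abundance_tolerance or the ",
         "exclusion lists")
  }
  if (length(cands) <= spec$n_controls) {
    if (length(cands) < spec$n_controls) {
      warning("only ", length(cands), " of ", spec$n_controls,
              " requested controls available for '", dna_to_rna(kmer), "'")
    }
    return(cands)
  }
  with_seed(spec$seed, sort(sample(cands, spec$n_controls)))
}

# ---- cached lookup tables for the genome-wide scan ------------------------

# static per-word tables for rank_kmers: composition classes, UGUA counts,
# 7-mer prefixes/suffixes, and the exclusion mask implied by the spec
kmer_static_tables <- function(k, spec) {
  key <- paste0("static_", k, "_",
                paste(sort(spec$excluded_patterns), collapse = "+"), "_",
                paste(sort(spec$excluded_7mers), collapse = "+"))
  cached <- .utrmotif_cache[[key]]
  if (!is.null(cached)) return(cached)
  words <- all_kmers(k)
  ugua <- integer(length(words))
  if (k >= 4L) {
    for (p in seq_len(k - 3L)) {
      ugua <- ugua + (substring(words, p, p + 3L) == "TGTA")
    }
  }
  left7 <- if (k >= 7L) substring(words, 1L, 7L) else rep("", length(words))
  right7 <- if (k >= 7L) substring(words, k - 6L, k) else rep("", length(words))
  excluded <- rep(FALSE, length(words))
  if (length(spec$excluded_patterns)) {
    expz <- rna_to_dna(unlist(lapply(spec$excluded_patterns, expand_iupac)))
    for (e in expz) {
      if (nchar(e) <= k) {
        excluded <- excluded | grepl(e, words, fixed = TRUE)
      } else {
        subs <- unique(substring(e, seq_len(nchar(e) - k + 1L),
                                 k:nchar(e)))
        excluded[kmer_index(subs, k)] <- TRUE
      }
    }
  }
  if (length(spec$excluded_7mers) && k >= 7L) {
    for (s in spec$excluded_7mers) excluded <- excluded | grepl(s, words,
                                                                fixed = TRUE)
  }
  counts <- matrix(0L, length(words), 4L, dimnames = list(NULL, DNA_BASES))
  idx <- 0:(length(words) - 1L)
  for (j in seq_len(k)) {
    b <- (idx %/% 4^(k - j)) %% 4 + 1
    for (bb in 1:4) counts[, bb] <- counts[, bb] + (b == bb)
  }
  comp_key <- paste(counts[, 1], counts[, 2], counts[, 3], counts[, 4])
  comp_groups <- split(seq_along(words), comp_key)
  # integer codes of the flanking 7-mers make the self-overlap filter a
  # plain integer comparison in the hot loop
  left7i <- if (k >= 7L) kmer_index(left7, 7L) else rep(NA_integer_,
                                                        length(words))
  right7i <- if (k >= 7L) kmer_index(right7, 7L) else rep(NA_integer_,
                                                          length(words))
  st <- list(words = words, rna_words = dna_to_rna(words), ugua = ugua,
             left7i = left7i, right7i = right7i,
             excluded = excluded, comp_key = comp_key,
             comp_groups = comp_groups,
             dinuc_memo = new.env(parent = emptyenv()))
  .utrmotif_cache[[key]] <- st
  st
}

# integer-index candidates for word index i under the static filters
static_candidates <- function(i, spec, st) {
  if (spec$mode == "mononucleotide") {
    cand <- st$comp_groups[[st$comp_key[i]]]
  } else {
    w <- st$words[i]
    dkey <- paste(sort(substring(w, seq_len(nchar(w) - 1L), 2:nchar(w))),
                  collapse = "")
    cand <- st$dinuc_memo[[dkey]]
    if (is.null(cand)) {
      cand <- sort(kmer_index(dinuc_variants(w), nchar(w)))
      st$dinuc_memo[[dkey]] <- cand
    }
  }
  cand <- cand[cand != i & !st$excluded[cand] & st$ugua[cand] == st$ugua[i]]
  if (spec$exclude_self_overlap && length(cand) && !is.na(st$left7i[i])) {
    a <- st$left7i[i]; b <- st$right7i[i]
    l <- st$left7i[cand]; r <- st$right7i[cand]
    cand <- cand[!(l == a | l == b | r == a | r == b)]
  }
  cand
}
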