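# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

make_utrs <- function(seqs, ids = sprintf("u%03d", seq_along(seqs)),
                      genes = ids) {
  data.frame(utr_id = ids, gene_id = genes, sequence = toupper(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

make_alignment <- function(rows, utr_id = "u001",
                           species = names(rows)) {
  utrmotif:::new_utr_alignment(utr_id, setNames(unlist(rows), species),
                               reference_species = species[1L])
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

random_utrs <- function(n, len, seed,
                        prob = c(A = .3, C = .2, G = .2, T = .3)) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = prob),
          collapse = "")
  }, character(1))
  make_utrs(seqs)
}

# independent oracle: all (overlapping) start positions, 1-based, where any
# of the concrete expansions matches, by per-position substring comparison
naive_scan_starts <- function(seq, expansions) {
  k <- nchar(expansions[1L])
  L <- nchar(seq)
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1L)
  starts[substring(seq, starts, starts + k - 1L) %in% expansions]
}

# independent conservation oracle: re-derives alignment columns by
# cumulative gap counting on the reference row, then compares the substring
# of each non-reference row over exactly those columns to the k-mer
oracle_conserved <- function(alignment, kmer) {
  ref_gapped <- strsplit(alignment$rows[[alignment$reference_species]],
                         "")[[1]]
  cols_of_refpos <- which(ref_gapped != "-")
  ref <- paste(ref_gapped[ref_gapped != "-"], collapse = "")
  k <- nchar(kmer)
  starts <- naive_scan_starts(ref, kmer)
  others <- setdiff(names(alignment$rows), alignment$reference_species)
  flags <- vapply(starts, function(i) {
    cols <- cols_of_refpos[i:(i + k - 1L)]
    all(vapply(others, function(sp) {
      chars <- strsplit(alignment$rows[[sp]], "")[[1]][cols]
      paste(chars, collapse = "") == kmer
    }, logical(1)))
  }, logical(1))
  data.frame(reference_start = starts - 1L, conserved = flags)
}

# dinucleotide multiset of a sequence, as a sorted character vector
dinuc_multiset <- function(x) {
  ltr <- strsplit(x, "")[[1]]
  sort(paste0(ltr[-length(ltr)], ltr[-1L]))
}
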