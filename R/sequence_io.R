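#' Read a 3' UTR sequence set from FASTA
#'
#' Reads one UTR per FASTA entry and normalizes the alphabet: sequences are
#' upper-cased, U is mapped to T, and alignment gap characters (`-`) are
#' stripped, so the stored sequence is the ungapped DNA-alphabet UTR. Headers
#' are split on `|` or whitespace; the first token is the UTR id and the
#' second, when present, the gene id (defaults to the UTR id).
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `utr_id`, `gene_id`, `sequence`
#'   (over A/C/G/T/N) and `length` (non-gap nucleotides).
#' @export
read_utr_fasta <- function(path) {
  check_fasta_preamble(path)
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  if (length(seqs) == 0L) {
    return(data.frame(utr_id = character(), gene_id = character(),
                      sequence = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(headers, "[|[:space:]]+")
  utr_id <- vapply(toks, `[[`, "", 1L)
  gene_id <- vapply(toks, function(t) if (length(t) >= 2L) t[[2L]] else t[[1L]], "")
  if (anyDuplicated(utr_id)) {
    stop("duplicate utr_id in FASTA: ",
         paste(unique(utr_id[duplicated(utr_id)]), collapse = ", "))
  }
  sequence <- unname(normalize_sequence(as.character(seqs), utr_id))
  out <- data.frame(utr_id = unname(utr_id), gene_id = unname(gene_id),
                    sequence = sequence, length = nchar(sequence),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# reject anything outside the tolerated input alphabet, map U->T, upcase,
# strip gaps
normalize_sequence <- function(x, ids, keep_gaps = FALSE) {
  x <- toupper(x)
  bad <- grepl("[^ACGTUN-]", x)
  if (any(bad)) {
    stop("disallowed characters in sequence(s): ",
         paste(head(ids[bad], 5L), collapse = ", "))
  }
  x <- chartr("U", "T", x)
  if (!keep_gaps) x <- gsub("-", "", x, fixed = TRUE)
  x
}

check_fasta_preamble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1], " of ", path,
         " does not start a record")
  }
  invisible(TRUE)
}

#' Read per-UTR multi-species alignment blocks
#'
#' The file is multi-FASTA with `|species|`-suffixed headers
#' (`utr_id|species`), grouped in consecutive blocks of `length(species)`
#' entries per UTR. All rows of a block must have equal (gapped) length and
#' cover exactly the configured species set. The first species is the
#' reference.
#'
#' @param path path to the alignment-block FASTA.
#' @param species ordered species names; the first is the reference.
#' @return a named list of `utr_alignment` objects (names are UTR ids), each
#'   a list with `utr_id`, `rows` (named aligned strings), `n_columns`,
#'   `reference_species`.
#' @export
read_alignment_blocks <- function(path,
                                  species = c("human", "mouse", "rat", "dog")) {
  check_fasta_preamble(path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) return(structure(list(), names = character()))
  if (length(seqs) %% length(species) != 0L) {
    stop("number of FASTA entries (", length(seqs),
         ") is not a multiple of the species count (", length(species), ")")
  }
  toks <- strsplit(names(seqs), "|", fixed = TRUE)
  ok <- lengths(toks) == 2L
  if (!all(ok)) stop("alignment header without 'utr_id|species': ",
                     names(seqs)[!ok][1])
  ids <- vapply(toks, `[[`, "", 1L)
  sps <- vapply(toks, `[[`, "", 2L)
  unknown <- setdiff(unique(sps), species)
  if (length(unknown)) stop("unknown species label(s): ",
                            paste(unknown, collapse = ", "))
  blocks <- split(seq_along(seqs),
                  rep(seq_len(length(seqs) / length(species)),
                      each = length(species)))
  out <- lapply(blocks, function(i) {
    uid <- unique(ids[i])
    if (length(uid) != 1L) {
      stop("alignment block mixes UTR ids: ", paste(uid, collapse = ", "))
    }
    if (!setequal(sps[i], species) || anyDuplicated(sps[i])) {
      stop("block for '", uid, "' must contain each of: ",
           paste(species, collapse = ", "))
    }
    rows <- as.character(seqs[i])
    names(rows) <- sps[i]
    rows <- rows[species]
    widths <- nchar(rows)
    if (length(unique(widths)) != 1L) {
      stop("ragged alignment block for '", uid, "': row lengths ",
           paste(widths, collapse = ", "))
    }
    rows <- normalize_sequence(rows, paste0(uid, "|", species),
                               keep_gaps = TRUE)
    names(rows) <- species
    new_utr_alignment(uid, rows, reference_species = species[1L])
  })
  names(out) <- vapply(out, `[[`, "", "utr_id")
  if (anyDuplicated(names(out))) {
    stop("duplicate alignment blocks for: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  }
  out
}

new_utr_alignment <- function(utr_id, rows, reference_species) {
  structure(list(utr_id = utr_id, rows = rows,
                 n_columns = nchar(rows[[1L]]),
                 reference_species = reference_species),
            class = "utr_alignment")
}

#' @export
print.utr_alignment <- function(x, ...) {
  cat("utr_alignment '", x$utr_id, "': ", length(x$rows), " species x ",
      x$n_columns, " columns (reference: ", x$reference_species, ")\n",
      sep = "")
  invisible(x)
}

#' Ungapped reference-species sequence of an alignment
#'
#' @param alignment a `utr_alignment`.
#' @return the reference row with gap characters removed.
#' @export
reference_sequence <- function(alignment) {
  gsub("-", "", alignment$rows[[alignment$reference_species]], fixed = TRUE)
}

#' Read a differential-expression table
#'
#' Reads a CuffDiff-style gene-level TSV (header required, `#` comment lines
#' skipped) and classifies each gene as up/down/unchanged at the given
#' q-value threshold. Rows with a non-finite log2 fold change are excluded
#' (with a message); the number excluded is recorded in the `"excluded"`
#' attribute.
#'
#' @param path path to the TSV.
#' @param q_threshold q-value threshold for the up/down call.
#' @param column_map named character vector mapping required names
#'   (`gene_id`, `value_1`, `value_2`, `log2_fold_change`, `p_value`,
#'   `q_value`) to the file's column names; defaults to identity.
#' @return `data.frame` with the six required columns plus `de_class`.
#' @export
read_expression_table <- function(path, q_threshold = 0.05,
                                  column_map = NULL) {
  required <- c("gene_id", "value_1", "value_2", "log2_fold_change",
                "p_value", "q_value")
  map <- setNames(required, required)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols)) {
    stop("expression table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(gene_id = raw[[map[["gene_id"]]]],
                    stringsAsFactors = FALSE)
  for (col in setdiff(required, "gene_id")) {
    v <- raw[[map[[col]]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !(toupper(v) %in% c("INF", "-INF", "NAN")))
    # 'inf'/'nan' strings are numeric in CuffDiff output; anything else is not
    num[toupper(v) == "INF"] <- Inf
    num[toupper(v) == "-INF"] <- -Inf
    num[toupper(v) == "NAN"] <- NaN
    if (length(bad)) {
      stop("non-numeric value '", v[bad[1]], "' in column '", map[[col]],
           "', row ", bad[1])
    }
    out[[col]] <- num
  }
  nonfinite <- !is.finite(out$log2_fold_change)
  if (any(nonfinite)) {
    message(sum(nonfinite),
            " gene(s) with non-finite log2 fold change excluded")
  }
  out <- out[!nonfinite, , drop = FALSE]
  rownames(out) <- NULL
  out$de_class <- classify_de(out$log2_fold_change, out$q_value, q_threshold)
  attr(out, "excluded") <- sum(nonfinite)
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Up/down/unchanged call from fold change and q-value
#'
#' @param log2_fold_change,q_value numeric vectors.
#' @param q_threshold significance threshold on the q-value.
#' @return character vector over `up`, `down`, `unchanged`.
#' @export
classify_de <- function(log2_fold_change, q_value, q_threshold = 0.05) {
  ifelse(q_value < q_threshold & log2_fold_change > 0, "up",
         ifelse(q_value < q_threshold & log2_fold_change < 0, "down",
                "unchanged"))
}

#' Keep one UTR per gene
#'
#' When several transcripts map to one gene id, the longest UTR is kept;
#' ties break to the lexicographically smallest UTR id.
#'
#' @param utrs UTR set from [read_utr_fasta()].
#' @return the filtered UTR set.
#' @export
one_utr_per_gene <- function(utrs) {
  ord <- order(utrs$gene_id, -utrs$length, utrs$utr_id)
  utrs <- utrs[ord, , drop = FALSE]
  utrs <- utrs[!duplicated(utrs$gene_id), , drop = FALSE]
  utrs[order(utrs$utr_id), , drop = FALSE]
}

# ---- writers (round-trip partners of the readers) -------------------------

provenance_line <- function(seed = NA, extra = NULL) {
  paste0("# utrmotif ",
         as.character(utils::packageVersion("utrmotif")),
         " | seed=", seed,
         if (!is.null(extra)) paste0(" | ", extra) else "")
}

#' Write a UTR set, alignment collection, or expression table
#'
#' Writers emit the same formats the readers consume, so that
#' write-then-read is the identity on all fields.
#'
#' @param utrs,alignments,expression objects as returned by the readers.
#' @param path output path.
#' @param seed seed recorded in the provenance comment of TSV outputs.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  header <- paste0(">", utrs$utr_id,
                   ifelse(utrs$gene_id == utrs$utr_id, "",
                          paste0("|", utrs$gene_id)))
  writeLines(as.vector(rbind(header, utrs$sequence)), path)
  invisible(path)
}

#' @rdname write_utr_fasta
#' @export
write_alignment_blocks <- function(alignments, path) {
  lines <- unlist(lapply(alignments, function(a) {
    as.vector(rbind(paste0(">", a$utr_id, "|", names(a$rows)),
                    unname(a$rows)))
  }), use.names = FALSE)
  writeLines(if (is.null(lines)) character() else lines, path)
  invisible(path)
}

#' @rdname write_utr_fasta
#' @export
write_expression_table <- function(expression, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(seed), con)
  cols <- c("gene_id", "value_1", "value_2", "log2_fold_change",
            "p_value", "q_value")
  write.table(expression[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
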