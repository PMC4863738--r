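test_that("FASTA reading normalizes the alphabet and validates ids", {
  p <- write_tmp(c(">x", "uaaguuau"), ".fa")
  utrs <- read_utr_fasta(p)
  expect_equal(utrs$sequence, "TAAGTTAT")
  expect_equal(utrs$length, 8L)
  expect_equal(utrs$gene_id, "x")

  expect_equal(nrow(read_utr_fasta(write_tmp(character(0), ".fa"))), 0L)
  expect_error(read_utr_fasta(write_tmp(c(">x", "ACGT", ">x", "ACGT"),
                                        ".fa")),
               "duplicate utr_id")
  expect_error(read_utr_fasta(write_tmp(c(">x", "ACXT"), ".fa")),
               "disallowed")
  expect_error(read_utr_fasta(write_tmp(c("ACGT"), ".fa")), "line 1")

  p2 <- write_tmp(c(">utr1|geneA", "ACGUN"), ".fa")
  u2 <- read_utr_fasta(p2)
  expect_equal(u2$gene_id, "geneA")
  expect_equal(u2$sequence, "ACGTN")
})

test_that("alignment blocks are validated and parsed", {
  sp <- c("human", "mouse", "rat", "dog")
  row <- strrep("ACGT-", 4)  # 20 columns
  p <- write_tmp(as.vector(rbind(paste0(">u1|", sp), row)), ".fa")
  aln <- read_alignment_blocks(p, sp)
  expect_length(aln, 1L)
  expect_equal(aln$u1$n_columns, 20L)
  expect_equal(aln$u1$reference_species, "human")
  expect_equal(reference_sequence(aln$u1), strrep("ACGT", 4))

  expect_error(read_alignment_blocks(
    write_tmp(as.vector(rbind(paste0(">u1|", sp[1:3]), "ACGT")), ".fa"), sp),
    "not a multiple")
  expect_error(read_alignment_blocks(
    write_tmp(as.vector(rbind(paste0(">u1|", sp[c(1, 2, 3, 3)]), "ACGT")),
              ".fa"), sp),
    "must contain each")
  expect_error(read_alignment_blocks(
    write_tmp(c(">u1|human", "ACGTA", ">u1|mouse", "ACGTA", ">u1|rat",
                "ACGTA", ">u1|dog", "ACGT"), ".fa"), sp),
    "ragged")
  expect_error(read_alignment_blocks(
    write_tmp(c(">u1|human", "ACGT", ">u1|mouse", "ACGT", ">u1|rat", "ACGT",
                ">u1|horse", "ACGT"), ".fa"), sp),
    "unknown species")
})

test_that("expression tables parse, classify, and reject bad fields", {
  tsv <- c("gene_id\tvalue_1\tvalue_2\tlog2_fold_change\tp_value\tq_value",
           "g1\t10\t40\t2.0\t1e-5\t1e-3",
           "g2\t10\t10\t0.0\t0.9\t0.95",
           "g3\t10\t2\t-2.3\t1e-4\t1e-2",
           "g4\t0\t5\tinf\t1e-4\t1e-2")
  expect_message(expr <- read_expression_table(write_tmp(tsv, ".tsv"),
                                               q_threshold = 0.05),
                 "non-finite")
  expect_equal(expr$de_class, c("up", "unchanged", "down"))
  expect_equal(attr(expr, "excluded"), 1L)

  bad <- c(tsv[1], "g1\t10\t40\t2.0\t1e-5\tNA")
  expect_error(read_expression_table(write_tmp(bad, ".tsv")),
               "non-numeric.*row 1")
  expect_error(read_expression_table(write_tmp(tsv[2:3], ".tsv")),
               "required column")

  # CuffDiff-style headers via the column map
  cuff <- sub("gene_id", "gene", tsv[1])
  cuff <- sub("log2_fold_change", "log2(fold_change)", cuff, fixed = TRUE)
  expr2 <- read_expression_table(write_tmp(c(cuff, tsv[2]), ".tsv"),
                                 column_map = c(
                                   gene_id = "gene",
                                   log2_fold_change = "log2(fold_change)"))
  expect_equal(expr2$de_class, "up")
})

test_that("write-then-read is the identity for all three formats", {
  cfg <- synthetic_config(n_genes = 25, utr_mean_length = 300, seed = 42)
  sim <- generate_utr_set(cfg)
  expr <- generate_expression_table(sim$truth, cfg)

  fa <- tempfile(fileext = ".fa")
  write_utr_fasta(sim$utrs, fa)
  expect_equal(read_utr_fasta(fa), sim$utrs)

  alnfile <- tempfile(fileext = ".fa")
  write_alignment_blocks(sim$alignments, alnfile)
  back <- read_alignment_blocks(alnfile, cfg$species)
  expect_equal(back, sim$alignments)

  tsv <- tempfile(fileext = ".tsv")
  write_expression_table(expr, tsv, seed = 42)
  back2 <- read_expression_table(tsv, q_threshold = cfg$q_threshold)
  for (col in c("value_1", "value_2", "log2_fold_change", "p_value",
                "q_value")) {
    expect_equal(back2[[col]], expr[[col]], tolerance = 1e-12)
  }
  expect_equal(back2$de_class, expr$de_class)
})

test_that("ungapped reference rows equal the UTR sequences (gap strip)", {
  sim <- generate_utr_set(synthetic_config(n_genes = 30,
                                           utr_mean_length = 300,
                                           indel_rate = 0.05, seed = 5))
  refs <- vapply(sim$alignments, reference_sequence, character(1))
  expect_equal(unname(refs[sim$utrs$utr_id]), sim$utrs$sequence)
})

test_that("one UTR per gene keeps the longest, ties to smallest id", {
  utrs <- make_utrs(c("ACGTACGT", "ACGTACGTACGT", "ACGT", "TTTT"),
                    ids = c("u2", "u1", "u3", "u4"),
                    genes = c("gA", "gA", "gB", "gB"))
  kept <- one_utr_per_gene(utrs)
  expect_equal(sort(kept$utr_id), c("u1", "u3"))
  # tie on length -> lexicographically smallest utr_id
  tie <- make_utrs(c("AAAA", "CCCC"), ids = c("ub", "ua"),
                   genes = c("g", "g"))
  expect_equal(one_utr_per_gene(tie)$utr_id, "ua")
})
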