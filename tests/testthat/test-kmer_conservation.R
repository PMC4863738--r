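test_that("UTR counting matches a naive substring oracle", {
  utrs <- make_utrs("TAAGTTATTAAGTTAT")
  expect_equal(count_utrs_with_kmer(utrs, "TAAGTTAT"), 1L)  # once per UTR
  expect_equal(count_utrs_with_kmer(utrs, "GGGGGGGG"), 0L)
  expect_error(count_utrs_with_kmer(utrs, "ACGT"), "length")

  rnd <- random_utrs(50, 1000, seed = 31)
  set.seed(32)
  for (kmer in replicate(5, paste(sample(c("A", "C", "G", "T"), 8, TRUE),
                                  collapse = ""))) {
    oracle <- sum(vapply(rnd$sequence, function(s) {
      length(naive_scan_starts(s, kmer)) > 0
    }, logical(1)))
    expect_equal(count_utrs_with_kmer(rnd, kmer), oracle)
  }
})

test_that("strict conservation calls match an independent column-mapping oracle", {
  # perfect identity -> conserved
  rows <- rep(list(paste0("GG", "TAAGTTAT", "CC")), 4)
  names(rows) <- c("human", "mouse", "rat", "dog")
  a <- make_alignment(rows)
  res <- find_conserved_instances(a, "TAAGTTAT")
  expect_equal(res$reference_start, 2L)
  expect_true(res$conserved)

  # gap inside the window breaks conservation
  rows$mouse <- paste0("GG", "TAAG-TAT", "CC")
  expect_false(find_conserved_instances(make_alignment(rows),
                                        "TAAGTTAT")$conserved)
  # N breaks conservation
  rows$mouse <- paste0("GG", "TAAGNTAT", "CC")
  expect_false(find_conserved_instances(make_alignment(rows),
                                        "TAAGTTAT")$conserved)

  # simulated alignments vs the oracle, across divergence levels
  for (rate in c(0.05, 0.3)) {
    sim <- generate_utr_set(synthetic_config(
      n_genes = 20, utr_mean_length = 250,
      per_species_substitution_rate = rate, indel_rate = 0.03,
      plant_fraction = 0.5, retention_prob = 0.7, seed = 100 + rate * 100))
    for (i in seq_len(nrow(sim$truth$plants))) {
      aln <- sim$alignments[[sim$truth$plants$utr_id[i]]]
      kmer <- rna_to_dna(sim$truth$plants$seq[i])
      expect_equal(find_conserved_instances(aln, kmer),
                   oracle_conserved(aln, kmer))
    }
  }
})

test_that("windowed conservation relaxes the column-exact rule", {
  rows <- list(human = "CCTAAGTTATGGGGG",
               mouse = "TAAGTTATCCGGGGG",  # same kmer, shifted by 2
               rat   = "CCTAAGTTATGGGGG",
               dog   = "CCTAAGTTATGGGGG")
  a <- make_alignment(rows)
  expect_false(find_conserved_instances(a, "TAAGTTAT")$conserved)
  expect_true(find_conserved_instances(a, "TAAGTTAT",
                                       conservation = list(window = 2))$conserved)
  expect_false(find_conserved_instances(a, "TAAGTTAT",
                                        conservation = list(window = 1))$conserved)
})

test_that("conservation signal arithmetic and pseudocount policy", {
  expect_equal(conservation_signal(40, c(20, 20, 20))$signal, 2)
  expect_equal(conservation_signal(20, c(20, 20, 20))$signal, 1)
  expect_error(conservation_signal(5, numeric(0)), "empty control")
  ps <- conservation_signal(4, c(0, 0, 0, 0, 0), n_controls = 5)
  expect_equal(ps$signal, 4 / (1 / 5))
  expect_equal(ps$flag, "unstable")
})

test_that("mononucleotide controls are anagrams; dinucleotide controls share the dinucleotide multiset", {
  utrs <- random_utrs(80, 500, seed = 77)
  sortchr <- function(x) {
    vapply(strsplit(x, ""), function(ch) paste(sort(ch), collapse = ""), "")
  }
  mono <- generate_shuffle_controls("TAAGTTAT", shuffle_spec(seed = 2),
                                    utrs = utrs)
  expect_true(all(sortchr(mono) == sortchr("TAAGTTAT")))
  expect_false("TAAGTTAT" %in% mono)

  di <- generate_shuffle_controls("TAAGTTAT",
                                  shuffle_spec(mode = "dinucleotide",
                                               seed = 2),
                                  utrs = utrs)
  src_ms <- dinuc_multiset("TAAGTTAT")
  for (ctrl in di) expect_equal(dinuc_multiset(ctrl), src_ms)
})

test_that("controls preserve UGUA count and honor exclusion lists", {
  utrs <- random_utrs(80, 500, seed = 78)
  # source with exactly one UGUA core
  src <- "TGTACTAA"
  ctrls <- generate_shuffle_controls(src, shuffle_spec(seed = 4),
                                     utrs = utrs)
  cnt <- function(x) {
    lengths(regmatches(x, gregexpr("(?=TGTA)", x, perl = TRUE)))
  }
  expect_true(all(cnt(ctrls) == 1L))

  ex7 <- c("ACTAAGT", "TTAGTCA")
  ctrls2 <- suppressWarnings(generate_shuffle_controls(
    src, shuffle_spec(seed = 4, excluded_7mers = ex7), utrs = utrs))
  for (s in rna_to_dna(ex7)) expect_false(any(grepl(s, ctrls2, fixed = TRUE)))

  # excluded IUPAC patterns are banned as substring or containing-string
  expz <- rna_to_dna(unlist(lapply(c("AAUAAA", "UGUAHAUA", "UUAUUUAWW"),
                                   expand_iupac)))
  for (ctrl in ctrls) {
    for (e in expz) {
      if (nchar(e) <= 8) expect_false(grepl(e, ctrl, fixed = TRUE))
      else expect_false(grepl(ctrl, e, fixed = TRUE))
    }
  }
})

test_that("control generation is deterministic and errors when nothing survives", {
  utrs <- random_utrs(50, 400, seed = 79)
  a <- generate_shuffle_controls("TAAGTTAT", shuffle_spec(seed = 9),
                                 utrs = utrs)
  b <- generate_shuffle_controls("TAAGTTAT", shuffle_spec(seed = 9),
                                 utrs = utrs)
  expect_identical(a, b)
  # homopolymer has no distinct shuffles at all
  expect_error(generate_shuffle_controls("AAAAAAAA", shuffle_spec(seed = 9)),
               "no shuffle controls")
})

test_that("k-mer ranking recovers a planted motif and is reproducible", {
  cfg <- synthetic_config(n_genes = 120, utr_mean_length = 500, seed = 21)
  sim <- generate_utr_set(cfg)
  spec <- shuffle_spec(seed = 21)
  rk <- rank_kmers(sim$utrs, sim$alignments, spec)
  expect_true(rk$kmer[1] %in% c("UAAGUUAU", "UAACUUAU"))
  expect_true(all(rk$conserved_utr_count <= rk$utr_count))
  expect_true(all(rk$utr_count <= nrow(sim$utrs)))
  # identical rerun under the same seed/spec/data
  expect_equal(rk, rank_kmers(sim$utrs, sim$alignments, spec))
  # empty input -> empty table
  expect_equal(nrow(rank_kmers(sim$utrs[0, ], list(), spec)), 0L)
})

test_that("conserved counts decrease with substitution rate", {
  totals <- vapply(c(0.05, 0.2, 0.5), function(rate) {
    sim <- generate_utr_set(synthetic_config(
      n_genes = 40, utr_mean_length = 300, plant_fraction = 0,
      per_species_substitution_rate = rate, indel_rate = 0, seed = 55))
    sum(utrmotif:::kmer_instance_table(sim$alignments)$conserved)
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})
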