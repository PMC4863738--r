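test_that("IUPAC expansion covers the degenerate codes", {
  expect_setequal(expand_iupac("UAASUUAU"), c("TAAGTTAT", "TAACTTAT"))
  expect_length(expand_iupac("UGUAHAUA"), 3L)
  expect_length(expand_iupac("UUAUUUAWW"), 4L)
  expect_setequal(expand_iupac("ANT"),
                  c("AAT", "ACT", "AGT", "ATT"))
  expect_error(expand_iupac("UAAZ"), "unknown IUPAC")
})

test_that("motif scanning reports all overlapping matches with coordinates", {
  utrs <- make_utrs("GGTAAGTTATGG")
  inst <- scan_motif(utrs, "UAASUUAU")
  expect_equal(nrow(inst), 1L)
  expect_equal(inst$start, 2L)
  expect_equal(inst$end, 10L)
  expect_equal(inst$matched_seq, "UAAGUUAU")
  expect_equal(inst$relative_position, (2 + 4) / 12)

  both <- scan_motif(make_utrs("TAAGTTATAACTTAT"), "UAASUUAU")
  expect_equal(both$start, c(0L, 7L))
  expect_equal(both$matched_seq, c("UAAGUUAU", "UAACUUAU"))

  expect_equal(nrow(scan_motif(make_utrs("ACG"), "UAASUUAU")), 0L)
  expect_equal(nrow(scan_motif(make_utrs(character(0)), "UAASUUAU")), 0L)

  # equivalence with the union of naive per-expansion scans
  rnd <- random_utrs(25, 1000, seed = 41)
  for (pat in c("UAASUUAU", "UUAUUUAWW", "UGUAHAUA")) {
    inst <- scan_motif(rnd, pat)
    expz <- expand_iupac(pat)
    for (i in seq_len(nrow(rnd))) {
      expect_equal(inst$start[inst$utr_id == rnd$utr_id[i]],
                   naive_scan_starts(rnd$sequence[i], expz) - 1L)
    }
  }
})

test_that("region classification uses the 300-nt terminal windows", {
  expect_equal(classify_region(10, 18, 2000)$region, "proximal")
  expect_equal(classify_region(1800, 1808, 2000)$region, "distal")
  expect_equal(classify_region(900, 908, 2000)$region, "central")
  short <- classify_region(100, 108, 400)
  expect_equal(short$region, "proximal")   # proximal takes precedence
  expect_true(short$both)
})

test_that("multi-copy statistics and spacing", {
  one <- data.frame(utr_id = "u1", start = c(0L, 780L))
  mc <- multi_copy_stats(one)
  expect_equal(mc$n_multi, 1L)
  expect_equal(mc$median_spacing, 780)

  none <- data.frame(utr_id = c("u1", "u2"), start = c(5L, 9L))
  mc2 <- multi_copy_stats(none)
  expect_equal(mc2$n_single, 2L)
  expect_true(is.na(mc2$median_spacing))
  expect_equal(mc2$fraction_multi, 0)
})

test_that("co-occurrence hypergeometric matches subset enumeration", {
  # N=10, K=4, n=5, k=4 -> C(4,4) C(6,1) / C(10,5) = 6/252
  res <- cooccurrence_hypergeometric(paste0("a", 1:4),
                                     c(paste0("a", 1:4), "b1"), 10)
  expect_equal(res$p_value, 6 / 252)
  subs <- combn(10, 5)
  expect_equal(res$p_value, mean(colSums(subs <= 4) >= 4))

  expect_equal(cooccurrence_hypergeometric(paste0("a", 1:3),
                                           paste0("b", 1:3), 10)$p_value, 1)
  expect_equal(cooccurrence_hypergeometric(paste0("a", 1:10),
                                           paste0("a", 1:4), 10)$p_value, 1)
  expect_error(cooccurrence_hypergeometric(paste0("a", 1:11), "a1", 10),
               "larger than the universe")
})

test_that("positional profile bins counts against uniform expectation", {
  set.seed(91)
  pos <- runif(100)
  prof <- positional_profile(pos, n_bins = 10)
  expect_equal(sum(prof$total_counts), 100L)
  expect_equal(prof$uniform_expectation, 10)
  sigma <- sqrt(100 * 0.1 * 0.9)
  expect_true(all(abs(prof$total_counts - 10) <= 3 * sigma))

  edge <- positional_profile(rep(0.95, 7), n_bins = 10)
  expect_equal(edge$total_counts, c(rep(0L, 9), 7L))
  expect_error(positional_profile(c(0.5, 1.2)), "outside")

  cons <- positional_profile(c(0.1, 0.1, 0.9), c(TRUE, FALSE, TRUE),
                             n_bins = 2)
  expect_equal(cons$conserved_counts, c(1L, 1L))
})

test_that("context matrix reflects instance letters and background flanks", {
  utrs <- make_utrs(c("GGTAAGTTATGG", "CCTAACTTATCC"))
  inst <- scan_motif(utrs, "UAASUUAU")
  pfm <- context_matrix(inst, utrs, flank = 0)
  expect_equal(dim(pfm), c(4L, 8L))
  expect_true(all(abs(colSums(pfm) - 1) < 1e-12))
  expect_equal(unname(pfm["U", 1]), 1)              # U at position 1
  expect_equal(unname(pfm["C", 4] + pfm["G", 4]), 1)  # S position
  expect_equal(unname(pfm["C", 4]), 0.5)

  # flanks exceeding a UTR boundary drop that instance with a message
  utrs3 <- make_utrs(c("GGTAAGTTATGG", "CCTAACTTATCC", "TAAGTTAT"))
  inst3 <- scan_motif(utrs3, "UAASUUAU")
  expect_message(pfm3 <- context_matrix(inst3, utrs3, flank = 2), "dropped")
  expect_equal(dim(pfm3), c(4L, 12L))
  expect_error(context_matrix(inst[0, ], utrs, flank = 0), "no instances")

  # flank columns approach the background composition
  rnd <- random_utrs(300, 200, seed = 71,
                     prob = c(A = .25, C = .25, G = .25, T = .25))
  inst2 <- scan_motif(rnd, "AUAU")
  pfm2 <- suppressMessages(context_matrix(inst2, rnd, flank = 3))
  flank_cols <- c(1:3, 8:10)
  expect_true(all(abs(pfm2[, flank_cols] - 0.25) < 0.1))
})

test_that("conservation-position bias test is a one-sided pooled z", {
  inst <- function(n_t, x_t, n_c, x_c) {
    data.frame(start = c(rep(0L, n_t), rep(900L, n_c)),
               end = c(rep(8L, n_t), rep(908L, n_c)),
               utr_length = 2000L,
               conserved = c(rep(c(TRUE, FALSE), c(x_t, n_t - x_t)),
                             rep(c(TRUE, FALSE), c(x_c, n_c - x_c))))
  }
  flat <- conservation_position_bias(inst(100, 30, 100, 30))
  expect_equal(flat$p_value, 0.5)

  biased <- conservation_position_bias(inst(100, 50, 100, 10))
  pool <- 60 / 200
  z <- (0.5 - 0.1) / sqrt(pool * (1 - pool) * (2 / 100))
  expect_equal(biased$z, z)
  expect_equal(biased$p_value, pnorm(z, lower.tail = FALSE))
  expect_lt(biased$p_value, 1e-3)

  empty <- conservation_position_bias(inst(100, 30, 100, 30)[1:100, ])
  expect_true(empty$untestable)

  # parameter recovery: conservation concentrated in terminal plants
  cfg <- synthetic_config(n_genes = 250, utr_mean_length = 1000,
                          plant_fraction = 0.6, retention_prob = 0.95,
                          positional_bias = list(type = "terminal",
                                                 window = 300),
                          per_species_substitution_rate = 0.3, seed = 61)
  sim <- generate_utr_set(cfg)
  inst_s <- scan_motif(sim$utrs, "UAASUUAU", sim$alignments)
  bias <- conservation_position_bias(inst_s)
  expect_lt(bias$p_value, 0.05)
  expect_gt(bias$frac_terminal, bias$frac_central)
})
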