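test_that("expand_motif enumerates concrete k-mers", {
  expect_equal(expand_motif("WACTRTGAC"),
               c("AACTATGAC", "AACTGTGAC", "TACTATGAC", "TACTGTGAC"))
  expect_equal(expand_motif("ACGT"), "ACGT")
  expect_length(expand_motif("NN"), 16L)
  expect_equal(iupac_motif("WACTRTGAC")$n_concrete, 4L)
  expect_error(iupac_motif("ACZT"), "position 3")
})

test_that("reverse_complement_motif is IUPAC-aware and involutive", {
  expect_equal(reverse_complement_motif("WACTRTGAC")$pattern, "GTCAYAGTW")
  expect_equal(reverse_complement_motif("ACGT")$pattern, "ACGT")
  for (p in c("WACTRTGAC", "NNBDHV", "GATC", "CCWGG")) {
    expect_equal(
      reverse_complement_motif(reverse_complement_motif(p))$pattern, p)
    expect_equal(reverse_complement_motif(p)$n_concrete,
                 iupac_motif(p)$n_concrete)
  }
})

test_that("scan_genome finds strand-aware hits at exact coordinates", {
  g <- genome("g", "TTTACTATGACTT")
  hits <- scan_genome(g, "WACTRTGAC")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matched, "TACTATGAC")
  # reverse complement of the sequence: same count, minus strand
  g_rc <- genome("g", paste(rev(strsplit(chartr("ACGT", "TGCA", g$seq),
                                         "")[[1]]), collapse = ""))
  hits_rc <- scan_genome(g_rc, "WACTRTGAC")
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, g$length - (2 + 9))
  expect_equal(hits_rc$matched, "TACTATGAC")
  # genome shorter than k: empty result
  expect_equal(nrow(scan_genome(genome("s", "ACGTACG"), "WACTRTGAC")), 0L)
  # N in the genome never matches
  gN <- genome("n", "TTNACTATGACTT")
  expect_equal(nrow(scan_genome(gN, "WACTRTGAC")), 0L)
})

test_that("scan_genome agrees with the brute-force window oracle", {
  set.seed(101)
  for (rep in 1:25) {
    g <- random_genome(sprintf("r%d", rep), 2000, gc = runif(1, 0.3, 0.7))
    for (pat in c("WACTRTGAC", "GATC", "CCWGG")) {
      hits <- scan_genome(g, pat)
      oracle <- brute_scan(g, pat)
      expect_equal(hits$start, oracle$start)
      expect_equal(hits$strand, oracle$strand)
    }
  }
})

test_that("strand symmetry: scanning the reverse complement swaps strands", {
  set.seed(55)
  g0 <- random_genome("g", 3000)
  seq <- g0$seq
  substring(seq, 401, 409) <- "AACTGTGAC"
  substring(seq, 1501, 1509) <- "GTCATAGTT"  # minus-strand occurrence
  substring(seq, 2301, 2309) <- "TACTATGAC"
  g <- genome("g", seq)
  pat <- "WACTRTGAC"
  hits <- scan_genome(g, pat)
  expect_gte(nrow(hits), 3L)
  g_rc <- genome("g", paste(rev(strsplit(chartr("ACGT", "TGCA", g$seq),
                                         "")[[1]]), collapse = ""))
  hits_rc <- scan_genome(g_rc, pat)
  k <- 9L
  reflected <- data.frame(start = g$length - (hits$start + k),
                          strand = ifelse(hits$strand == "+", "-", "+"))
  reflected <- reflected[order(reflected$start, reflected$strand), ]
  expect_equal(hits_rc$start, reflected$start)
  expect_equal(hits_rc$strand, reflected$strand)
})

test_that("expected_count reproduces the analytic model", {
  # uniform composition: exact closed form (L - k + 1) * n_concrete / 4^k
  e <- expected_count("WACTRTGAC", 45228, "uniform")
  expect_equal(e, (45228 - 9 + 1) * 4 / 4^9)
  expect_equal(round(e, 1), 0.7)
  expect_equal(expected_count("ACGT", 4, "uniform"), 1 / 256)
  expect_equal(expected_count("N", 100, c(A = 0.4, C = 0.3, G = 0.2,
                                          T = 0.1),
                              length_convention = "full"), 100)
  # both-strand variant doubles the single-strand expectation
  expect_equal(expected_count("GATC", 1000, "uniform", strands = "both"),
               2 * expected_count("GATC", 1000, "uniform"))
  expect_error(expected_count("GATC", 100, c(A = 0.5, C = 0.5, G = 0.5,
                                             T = 0.5)), "summing")
})

test_that("strand_stats counts per strand with absolute net difference", {
  g <- genome("g", strrep("ACGT", 1000))
  h13 <- data.frame(genome_id = "g", start = seq(0, 1200, 100)[1:13],
                    strand = "+", matched = "AACTATGAC")
  st <- strand_stats(h13, g, "WACTRTGAC")
  expect_equal(st$net, 13L)
  expect_equal(st$n_fwd, 13L)
  h33 <- data.frame(genome_id = "g", start = seq(0, 500, 100)[1:6],
                    strand = rep(c("+", "-"), 3), matched = "AACTATGAC")
  expect_equal(strand_stats(h33, g, "WACTRTGAC")$net, 0L)
  expect_equal(st$expected_per_strand,
               expected_count("WACTRTGAC", g$length, g$base_freqs))
})

test_that("consensus_from_sites recovers a planted degenerate motif", {
  set.seed(9)
  # plant the two W/R variants at 13 sites on a random background
  g0 <- random_genome("c", 8000)
  starts <- seq(300, 7500, length.out = 13)
  variants <- sample(c("TACTATGAC", "TACTGTGAC"), 13, replace = TRUE)
  seq <- g0$seq
  for (i in 1:13)
    substring(seq, starts[i] + 1, starts[i] + 9) <- variants[i]
  g <- genome("c", seq)
  sites <- as.integer(starts + 4)  # motif centres
  cons <- consensus_from_sites(g, sites, flank = 25, k_min = 6, k_max = 12)
  expect_false(is.null(cons))
  # every planted variant must match the recovered pattern
  kmers <- expand_motif(cons$pattern)
  expect_true(all(unique(variants) %in% kmers))

  # identical 9-mer in every window: exact pattern, no degeneracy
  seq2 <- random_genome("d", 6000)$seq
  starts2 <- seq(300, 5500, length.out = 6)
  for (s in starts2) substring(seq2, s + 1, s + 9) <- "AACTGTGAC"
  g2 <- genome("d", seq2)
  cons2 <- consensus_from_sites(g2, as.integer(starts2 + 4), flank = 25,
                                k_min = 6, k_max = 9)
  expect_equal(cons2$pattern, "AACTGTGAC")

  # two windows with nothing in common: explicit no-consensus result
  g3 <- genome("e", paste0(strrep("A", 200), strrep("C", 200)))
  expect_null(consensus_from_sites(g3, c(100L, 300L), flank = 25))
})
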