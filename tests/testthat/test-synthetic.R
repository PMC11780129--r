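test_that("make_genome plants recoverable motifs and is deterministic", {
  spec <- simulation_spec(seed = 1)
  sim <- make_genome(spec)
  expect_equal(sim$genome$length, 45228L)
  expect_equal(nrow(sim$truth$motif_positions), 13L)
  expect_true(all(sim$truth$motif_positions$strand == "-"))
  # self-consistency: the scanner recovers the recorded truth exactly
  hits <- scan_genome(sim$genome, spec$motif)
  expect_equal(hits$start, sim$truth$all_hits$start)
  key_truth <- paste(sim$truth$motif_positions$start,
                     sim$truth$motif_positions$strand)
  key_hits <- paste(hits$start, hits$strand)
  expect_true(all(key_truth %in% key_hits))
  # every nick position lies inside a planted motif occurrence
  inside <- vapply(sim$truth$nick_positions, function(p)
    any(p >= sim$truth$motif_positions$start &
        p < sim$truth$motif_positions$start + spec$motif$k), TRUE)
  expect_true(all(inside))
  # spacing and end clearance respected
  expect_true(all(diff(sort(sim$truth$motif_positions$start)) >= 500))
  expect_true(min(sim$truth$motif_positions$start) >= 500 - spec$motif$k)
  # determinism
  sim2 <- make_genome(simulation_spec(seed = 1))
  expect_identical(sim2$genome$seq, sim$genome$seq)
  # GC close to requested
  expect_equal(sum(sim$genome$base_freqs[c("G", "C")]), 0.525,
               tolerance = 0.01)
  expect_error(simulation_spec(n_nicks = 100L, genome_length = 10000L),
               "spacing infeasible")
})

test_that("simulated read sets have the requested per-strand depth and
           conserve coverage", {
  spec <- simulation_spec(seed = 2, genome_length = 20000L, n_nicks = 5L)
  sim <- make_genome(spec)
  reads <- simulate_reads(sim$genome, sim$truth, spec)
  cov <- coverage_from_reads(reads$control, sim$genome, "wga")
  # per-strand mean depth within 10% of the per-strand target
  expect_equal(mean(cov$depth_fwd), spec$mean_depth, tolerance = 0.1)
  expect_equal(mean(cov$depth_rev), spec$mean_depth, tolerance = 0.1)
  # coverage conservation: total depth equals total emitted read length
  for (rd in reads) {
    cc <- coverage_from_reads(rd, sim$genome, "native")
    for (s in c("+", "-")) {
      d <- if (s == "+") cc$depth_fwd else cc$depth_rev
      expect_equal(sum(d), sum((rd$end - rd$start)[rd$strand == s]))
    }
  }
  # doubling mean_depth doubles the median per-strand depth within 10%
  spec2 <- simulation_spec(seed = 2, genome_length = 20000L, n_nicks = 5L,
                           mean_depth = 100)
  sim2 <- make_genome(spec2)
  reads2 <- simulate_reads(sim2$genome, sim2$truth, spec2)
  cov2 <- coverage_from_reads(reads2$control, sim2$genome, "wga")
  expect_equal(median(cov2$depth_fwd) / median(cov$depth_fwd), 2,
               tolerance = 0.1)
})

test_that("native nicked-strand depth collapses at nicks while the other
           strand and the control stay normal", {
  spec <- simulation_spec(seed = 3)
  sim <- make_genome(spec)
  reads <- simulate_reads(sim$genome, sim$truth, spec)
  covn <- coverage_from_reads(reads$native, sim$genome, "native")
  covc <- coverage_from_reads(reads$control, sim$genome, "wga")
  med_fwd <- median(covn$depth_fwd)
  for (p in sim$truth$nick_positions) {
    expect_lte(covn$depth_rev[p + 1L], 2L)
    expect_gte(covn$depth_fwd[p + 1L], 0.5 * med_fwd)
    expect_gte(covc$depth_rev[p + 1L], 0.5 * median(covc$depth_rev))
  }
})

test_that("with no nicks, native and control are indistinguishable", {
  for (s in 1:3) {
    spec <- simulation_spec(seed = s, n_nicks = 0L,
                            genome_length = 20000L)
    sim <- make_genome(spec)
    reads <- simulate_reads(sim$genome, sim$truth, spec)
    covn <- coverage_from_reads(reads$native, sim$genome, "native")
    covc <- coverage_from_reads(reads$control, sim$genome, "wga")
    expect_equal(nrow(detect_drops(covn, covc)), 0L)
    expect_equal(median(covn$depth_rev), median(covc$depth_rev),
                 tolerance = 0.15)
  }
})

test_that("background occurrence rate in motif-free genomes matches the
           analytic expectation", {
  set.seed(123)
  n_sims <- 60
  counts <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    spec <- simulation_spec(seed = 3000L + i, n_nicks = 0L,
                            genome_length = 20000L, gc = 0.5)
    sim <- make_genome(spec)
    counts[i] <- sum(sim$truth$all_hits$strand == "+")
  }
  e <- expected_count("WACTRTGAC", 20000L, "uniform")
  se <- sd(counts) / sqrt(n_sims)
  expect_lte(abs(mean(counts) - e), 3 * max(se, 1e-3))
})

test_that("make_family plants two clades with calibrated identities and
           byte-identical regeneration", {
  fs <- family_spec(n_in_clade = 3L, n_outgroup = 3L,
                    proteins_per_genome = 4L, protein_length = 60L,
                    genome_length = 8000L, clade_motif_range = c(3L, 5L))
  fam <- make_family(fs, seed = 5)
  expect_length(fam$genomes, 6L)
  expect_equal(unname(fam$truth$clade_assignment),
               rep(c("clade", "outgroup"), each = 3))
  # within-clade pairwise identity near target
  pi <- pairwise_identity(fam$proteomes[[1]]$proteins[[1]],
                          fam$proteomes[[2]]$proteins[[1]])
  expect_equal(pi$identity, 0.9, tolerance = 0.12)
  # clade motifs all on one strand in the canonical frame
  for (id in names(fam$genomes)[1:3])
    expect_true(all(fam$truth$motifs[[id]]$canonical$strand == "+"))
  # raw-frame truth is recoverable by scanning the emitted genome
  for (id in names(fam$genomes)) {
    hits <- scan_genome(fam$genomes[[id]]$genome, "WACTRTGAC")
    tr <- fam$truth$motifs[[id]]$raw
    if (nrow(tr) > 0)
      expect_true(all(paste(tr$start, tr$strand) %in%
                      paste(hits$start, hits$strand)))
  }
  # determinism
  fam2 <- make_family(fs, seed = 5)
  expect_identical(fam2$genomes[[1]]$genome$seq,
                   fam$genomes[[1]]$genome$seq)
  expect_identical(fam2$proteomes[[6]]$proteins,
                   fam$proteomes[[6]]$proteins)
})

test_that("equal within/between identity leaves no two-block structure", {
  fs <- family_spec(n_in_clade = 3L, n_outgroup = 3L,
                    proteins_per_genome = 4L, protein_length = 60L,
                    genome_length = 8000L,
                    within_identity = 0.5, between_identity = 0.5)
  fam <- make_family(fs, seed = 6)
  mat <- wgrr_matrix(fam$proteomes)
  off <- mat[upper.tri(mat)]
  within <- c(mat[1:3, 1:3][upper.tri(diag(3))],
              mat[4:6, 4:6][upper.tri(diag(3))])
  between <- as.vector(mat[1:3, 4:6])
  # no separation between the two planted groups
  expect_lt(abs(mean(within) - mean(between)), 0.1)
})
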