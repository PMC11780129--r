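test_that("pairwise_identity matches the independent DP oracle", {
  al <- gotoh_global("HEAGAWGHEE", "PAWHEAE")
  pi <- pairwise_identity("HEAGAWGHEE", "PAWHEAE")
  expect_equal(pi$score, al$score)
  expect_equal(pi$identity, al$identity)
  # identical sequences
  s <- random_protein(50)
  expect_equal(pairwise_identity(s, s)$identity, 1.0)
  # no common residues
  expect_equal(pairwise_identity(strrep("K", 20), strrep("D", 20))$identity,
               0.0)
  # scores agree with the oracle on random pairs; identities agree on
  # related pairs (unrelated pairs can have co-optimal alignments)
  set.seed(21)
  for (i in 1:10) {
    a <- random_protein(30)
    b <- strsplit(a, "")[[1]]
    mut <- sample(30, 5)
    for (m in mut) b[m] <- sample(setdiff(LETTERS[LETTERS %in%
      c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
        "S","T","W","Y","V")], b[m]), 1)
    b <- paste(b, collapse = "")
    al <- gotoh_global(a, b)
    pi <- pairwise_identity(a, b)
    expect_equal(pi$score, al$score)
    expect_equal(pi$identity, al$identity)
  }
  expect_error(pairwise_identity("ACDE", "AC1E"), "non-amino-acid")
})

test_that("best_bidirectional_hits finds mutual bests with thresholds", {
  set.seed(31)
  seqs <- vapply(1:5, function(i) random_protein(60), "")
  A <- protein_set("gA", setNames(seqs, paste0("a", 1:5)))
  B <- protein_set("gB", setNames(seqs, paste0("b", 1:5)))
  bbh <- best_bidirectional_hits(A, B)
  expect_equal(nrow(bbh), 5L)
  expect_true(all(bbh$identity == 1.0))
  expect_equal(anyDuplicated(bbh$protein_a), 0L)
  # disjoint unrelated sets: no pairs pass the identity threshold
  C <- protein_set("gC", setNames(vapply(1:5, function(i)
    random_protein(60), ""), paste0("c", 1:5)))
  expect_equal(nrow(best_bidirectional_hits(A, C)), 0L)
})

test_that("wgrr endpoints, subset denominator and order invariance", {
  set.seed(41)
  seqs <- vapply(1:5, function(i) random_protein(60), "")
  A <- protein_set("gA", setNames(seqs, paste0("a", 1:5)))
  expect_equal(wgrr(A, A), 1.0)
  C <- protein_set("gC", setNames(vapply(1:5, function(i)
    random_protein(60), ""), paste0("c", 1:5)))
  expect_equal(wgrr(A, C), 0.0)
  # A subset of B: denominator is the smaller repertoire
  B <- protein_set("gB", setNames(c(seqs, vapply(1:5, function(i)
    random_protein(60), "")), paste0("b", 1:10)))
  expect_equal(wgrr(A, B), 1.0)
  # permutation invariance
  perm <- sample(5)
  A2 <- protein_set("gA", A$proteins[perm])
  expect_equal(wgrr(A2, B), wgrr(A, B))
})

test_that("wgrr equals the brute-force all-pairs oracle on small sets", {
  set.seed(51)
  # two related proteomes: mutated copies of shared ancestors
  make_pair <- function(n, len, rate) {
    anc <- vapply(seq_len(n), function(i) random_protein(len), "")
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      idx <- which(runif(length(ch)) < rate)
      for (i in idx) ch[i] <- random_protein(1)
      paste(ch, collapse = "")
    }
    list(A = protein_set("gA", setNames(vapply(anc, mut, "",
                                               USE.NAMES = FALSE),
                                        paste0("a", 1:n))),
         B = protein_set("gB", setNames(vapply(anc, mut, "",
                                               USE.NAMES = FALSE),
                                        paste0("b", 1:n))))
  }
  for (rep in 1:3) {
    pr <- make_pair(n = 4, len = 25, rate = 0.1)
    expect_equal(wgrr(pr$A, pr$B, min_coverage = 0),
                 brute_wgrr(pr$A, pr$B), tolerance = 1e-9)
  }
})

test_that("wGRR matrix is symmetric with unit diagonal in [0,1]", {
  set.seed(61)
  psets <- lapply(1:4, function(i)
    protein_set(paste0("g", i), setNames(vapply(1:3, function(j)
      random_protein(40), ""), paste0("g", i, "_p", 1:3))))
  m <- wgrr_matrix(psets)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("cluster_genomes recovers block structure at the cut", {
  ids <- paste0("g", 1:6)
  m <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.8
  m[4:6, 4:6] <- 0.8
  diag(m) <- 1
  cl <- cluster_genomes(structure(m, class = c("WGRRMatrix", "matrix",
                                               "array")), cut = 0.3)
  expect_equal(length(unique(cl$assignment)), 2L)
  expect_equal(unname(cl$assignment[1:3]), rep(1L, 3))
  expect_equal(unname(cl$assignment[4:6]), rep(2L, 3))
  # all identical: one cluster; cut above max off-diagonal: all singletons
  m1 <- matrix(1, 4, 4, dimnames = list(ids[1:4], ids[1:4]))
  expect_equal(length(unique(cluster_genomes(m1, cut = 0.5)$assignment)),
               1L)
  cl_hi <- cluster_genomes(structure(m, class = c("WGRRMatrix", "matrix",
                                                  "array")), cut = 0.9)
  expect_equal(length(unique(cl_hi$assignment)), 6L)
  # single genome: trivially one cluster
  msolo <- matrix(1, 1, 1, dimnames = list("g1", "g1"))
  expect_equal(unname(cluster_genomes(msolo)$assignment), 1L)
})

test_that("cluster_motif_summary contrasts focal cluster vs the rest", {
  assignment <- setNames(c(1L, 1L, 1L, 2L, 2L), paste0("g", 1:5))
  st <- data.frame(genome_id = paste0("g", 1:5),
                   net = c(10L, 8L, 9L, 1L, 0L))
  cs <- cluster_motif_summary(assignment, st, "g1")
  expect_equal(cs$within_mean, 9)
  expect_equal(cs$outside_mean, 0.5)
  expect_equal(cs$n_within, 3L)
  # single cluster: outside mean not applicable
  one <- setNames(rep(1L, 5), paste0("g", 1:5))
  expect_true(is.na(cluster_motif_summary(one, st, "g1")$outside_mean))
  # all-zero nets
  st0 <- transform(st, net = 0L)
  cs0 <- cluster_motif_summary(assignment, st0, "g1")
  expect_equal(cs0$within_mean, 0)
  expect_equal(cs0$outside_mean, 0)
  expect_error(cluster_motif_summary(assignment, st, "missing"), "focal")
})
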