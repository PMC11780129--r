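# Independent oracles used to cross-check the implementation. These are
# deliberately naive and share no code with the package internals.

random_genome <- function(id, n, gc = 0.5) {
  genome(id, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                          prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                   (1 - gc) / 2)),
                   collapse = ""))
}

rc_string <- function(s) {
  paste(rev(chartr("ACGT", "TGCA",
                   strsplit(s, "")[[1]])), collapse = "")
}

# window-by-window comparison against the expanded k-mer list
brute_scan <- function(g, pattern) {
  kmers <- expand_motif(pattern)
  k <- nchar(kmers[1])
  L <- g$length
  if (L < k)
    return(data.frame(start = integer(0), strand = character(0)))
  subs <- substring(g$seq, 1:(L - k + 1), k:L)
  rc_kmers <- vapply(kmers, rc_string, "", USE.NAMES = FALSE)
  fw <- which(subs %in% kmers) - 1L
  rv <- which(subs %in% rc_kmers) - 1L
  out <- rbind(
    data.frame(start = fw, strand = rep("+", length(fw)),
               stringsAsFactors = FALSE),
    data.frame(start = rv, strand = rep("-", length(rv)),
               stringsAsFactors = FALSE))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# textbook Gotoh affine-gap global alignment with traceback; a gap of
# length len costs open + len * ext (both penalties positive)
gotoh_global <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)  # X: gap in b, Y: gap in a
  M[1, 1] <- 0
  tbM <- tbX <- tbY <- matrix("", n + 1, m + 1)
  for (i in 2:(n + 1)) {
    X[i, 1] <- -open - (i - 1) * ext
    tbX[i, 1] <- if (i == 2) "M" else "X"
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -open - (j - 1) * ext
    tbY[1, j] <- if (j == 2) "M" else "Y"
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[av[i - 1], bv[j - 1]]
      cand <- c(M = M[i - 1, j - 1], X = X[i - 1, j - 1],
                Y = Y[i - 1, j - 1])
      pick <- names(cand)[which.max(cand)]
      M[i, j] <- cand[[pick]] + s
      tbM[i, j] <- pick
      cx <- c(M = M[i - 1, j] - open - ext, X = X[i - 1, j] - ext)
      px <- names(cx)[which.max(cx)]
      X[i, j] <- cx[[px]]; tbX[i, j] <- px
      cy <- c(M = M[i, j - 1] - open - ext, Y = Y[i, j - 1] - ext)
      py <- names(cy)[which.max(cy)]
      Y[i, j] <- cy[[py]]; tbY[i, j] <- py
    }
  }
  fin <- c(M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Y[n + 1, m + 1])
  state <- names(fin)[which.max(fin)]
  i <- n + 1; j <- m + 1
  ident <- 0L; cols <- 0L
  while (i > 1 || j > 1) {
    cols <- cols + 1L
    if (state == "M") {
      if (av[i - 1] == bv[j - 1]) ident <- ident + 1L
      state <- tbM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == "X") {
      state <- tbX[i, j]; i <- i - 1
    } else {
      state <- tbY[i, j]; j <- j - 1
    }
  }
  list(score = unname(max(fin)), identity = ident / cols, columns = cols)
}

# all-pairs BBH + wGRR from the DP oracle, for tiny protein sets; applies
# the identity threshold only (the matching package call sets
# min_coverage = 0)
brute_wgrr <- function(A, B, min_identity = 0.35) {
  nA <- length(A$proteins); nB <- length(B$proteins)
  sc <- id <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    al <- gotoh_global(A$proteins[[i]], B$proteins[[j]])
    sc[i, j] <- al$score
    id[i, j] <- al$identity
  }
  tot <- 0
  for (i in seq_len(nA)) {
    j <- which.max(sc[i, ])
    if (which.max(sc[, j]) == i && id[i, j] >= min_identity)
      tot <- tot + id[i, j]
  }
  tot / min(nA, nB)
}

random_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
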