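# degenerate-motif machinery: expansion, strand-aware scanning, the
# per-strand chance-expectation model and a deterministic consensus finder

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

# reverse lookup: sorted base set -> IUPAC code
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_CODES, function(b) paste(sort(b), collapse = ""), "")
  stats::setNames(names(IUPAC_CODES), keys)
})

#' Construct an IUPAC degenerate motif
#'
#' @param pattern Motif written in IUPAC nucleotide codes, e.g.
#'   `"WACTRTGAC"` (W = A/T, R = A/G).
#' @return An object of class `IUPACMotif` with fields `pattern`, `k`
#'   (length) and `n_concrete` (number of concrete k-mers matched, the
#'   product of per-position degeneracies).
#' @examples
#' iupac_motif("WACTRTGAC")$n_concrete # 4
#' @export
iupac_motif <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad) > 0L)
    stop("invalid IUPAC code '", chars[bad[1]], "' at position ", bad[1],
         " of pattern '", pattern, "'")
  if (length(chars) == 0L) stop("empty motif pattern")
  n_concrete <- prod(vapply(IUPAC_CODES[chars], length, 1L))
  structure(list(pattern = pattern, k = length(chars),
                 n_concrete = as.integer(n_concrete)),
            class = "IUPACMotif")
}

as_motif <- function(x) {
  if (inherits(x, "IUPACMotif")) x else iupac_motif(x)
}

#' @export
print.IUPACMotif <- function(x, ...) {
  cat(sprintf("IUPACMotif %s (k = %d, %d concrete k-mer%s)\n",
              x$pattern, x$k, x$n_concrete,
              if (x$n_concrete == 1L) "" else "s"))
  invisible(x)
}

#' Expand a degenerate motif into its concrete k-mers
#'
#' @param motif An [iupac_motif()] or pattern string.
#' @return Character vector of all concrete A/C/G/T k-mers the motif
#'   matches, lexicographically sorted, without duplicates.
#' @examples
#' expand_motif("WACTRTGAC")
#' @export
expand_motif <- function(motif) {
  motif <- as_motif(motif)
  sets <- IUPAC_CODES[strsplit(motif$pattern, "")[[1]]]
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  kmers <- do.call(paste0, rev(grid))
  sort(unique(kmers))
}

#' Reverse-complement a degenerate motif
#'
#' IUPAC-aware: W stays W, R becomes Y, etc. Applying it twice returns the
#' original pattern, and the number of concrete k-mers is preserved.
#'
#' @param motif An [iupac_motif()] or pattern string.
#' @return An `IUPACMotif` for the reverse complement.
#' @export
reverse_complement_motif <- function(motif) {
  motif <- as_motif(motif)
  chars <- strsplit(motif$pattern, "")[[1]]
  iupac_motif(paste(rev(IUPAC_COMPLEMENT[chars]), collapse = ""))
}

revcomp_seq <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# regex character classes over explicit A/C/G/T only, so that an N (or any
# ambiguity code) in the subject sequence never matches
motif_regex <- function(motif) {
  sets <- IUPAC_CODES[strsplit(motif$pattern, "")[[1]]]
  paste(vapply(sets, function(b)
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]"),
    ""), collapse = "")
}

regex_starts <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a genome for a degenerate motif on both strands
#'
#' Finds every occurrence on both strands of a linear sequence (no origin
#' wrap). Overlapping occurrences are all reported. Positions containing an
#' ambiguous genome base (e.g. N) never match. A minus-strand hit is
#' reported at the 0-based position of its leftmost base on the forward
#' sequence, with `matched` giving the concrete k-mer as read 5'-3' on the
#' hit strand.
#'
#' @param genome A [genome()] object.
#' @param motif An [iupac_motif()] or pattern string.
#' @return data.frame with columns `genome_id`, `start` (0-based), `strand`
#'   (`+`/`-`) and `matched`, ordered by `start` then `+` before `-`.
#' @export
scan_genome <- function(genome, motif) {
  motif <- as_motif(motif)
  empty <- data.frame(genome_id = character(0), start = integer(0),
                      strand = character(0), matched = character(0),
                      stringsAsFactors = FALSE)
  if (genome$length < motif$k) return(empty)
  fwd <- regex_starts(genome$seq, motif_regex(motif))
  rcm <- reverse_complement_motif(motif)
  rev <- regex_starts(genome$seq, motif_regex(rcm))
  hit_text <- function(starts) {
    if (length(starts) == 0L) return(character(0))
    substring(genome$seq, starts, starts + motif$k - 1L)
  }
  hits <- rbind(
    data.frame(genome_id = rep(genome$id, length(fwd)),
               start = fwd - 1L, strand = rep("+", length(fwd)),
               matched = hit_text(fwd), stringsAsFactors = FALSE),
    data.frame(genome_id = rep(genome$id, length(rev)),
               start = rev - 1L, strand = rep("-", length(rev)),
               matched = vapply(hit_text(rev), revcomp_seq, "",
                                USE.NAMES = FALSE),
               stringsAsFactors = FALSE))
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Expected chance occurrences of a motif
#'
#' Analytic per-strand expectation of the number of motif occurrences in an
#' i.i.d. background: `E = W * prod_j sum_{b in code_j} p(b)` where `W` is
#' the number of scan windows (`length - k + 1`, or `length` with
#' `length_convention = "full"`). With uniform composition this reduces to
#' `W * n_concrete / 4^k`. The default reports a single strand; for the
#' degenerate motifs considered here the reverse strand adds the same amount
#' (`strands = "both"` returns `2E`).
#'
#' @param motif An [iupac_motif()] or pattern string.
#' @param length Sequence length in bp (must be at least `k`).
#' @param base_freqs Either `"uniform"` or a named vector of A/C/G/T
#'   frequencies summing to 1 (within 1e-6).
#' @param strands `"single"` (default) or `"both"`.
#' @param length_convention `"windows"` (default; uses `length - k + 1`) or
#'   `"full"` (uses `length`).
#' @return Expected occurrence count (double).
#' @examples
#' expected_count("WACTRTGAC", 45228) # about 0.69
#' @export
expected_count <- function(motif, length, base_freqs = "uniform",
                           strands = c("single", "both"),
                           length_convention = c("windows", "full")) {
  motif <- as_motif(motif)
  strands <- match.arg(strands)
  length_convention <- match.arg(length_convention)
  if (length < motif$k) stop("length must be >= motif length")
  if (identical(base_freqs, "uniform")) {
    p <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else {
    p <- base_freqs[c("A", "C", "G", "T")]
    if (any(is.na(p)) || abs(sum(p) - 1) > 1e-6)
      stop("base_freqs must be named A/C/G/T fractions summing to 1")
  }
  w <- if (length_convention == "windows") length - motif$k + 1 else length
  per_pos <- vapply(IUPAC_CODES[strsplit(motif$pattern, "")[[1]]],
                    function(b) sum(p[b]), 0)
  e <- w * prod(per_pos)
  if (strands == "both") 2 * e else e
}

#' Per-strand motif occurrence statistics for one genome
#'
#' Counts hits by strand, the net (absolute) strand difference, and the
#' analytic per-strand chance expectation under the genome's own base
#' composition. The net difference is absolute because assembly strand
#' orientation is arbitrary across genomes.
#'
#' @param hits data.frame from [scan_genome()] (all for one genome).
#' @param genome The [genome()] the hits came from.
#' @param motif The scanned motif.
#' @return One-row data.frame: `genome_id`, `n_fwd`, `n_rev`, `net`,
#'   `expected_per_strand`, `length`, `gc`.
#' @export
strand_stats <- function(hits, genome, motif) {
  motif <- as_motif(motif)
  if (nrow(hits) > 0L && any(hits$genome_id != genome$id))
    stop("hits are not all from genome '", genome$id, "'")
  n_fwd <- sum(hits$strand == "+")
  n_rev <- sum(hits$strand == "-")
  data.frame(genome_id = genome$id, n_fwd = n_fwd, n_rev = n_rev,
             net = abs(n_fwd - n_rev),
             expected_per_strand = expected_count(motif, genome$length,
                                                  genome$base_freqs),
             length = genome$length,
             gc = sum(genome$base_freqs[c("G", "C")]),
             stringsAsFactors = FALSE)
}

#' Find a degenerate consensus motif shared by site windows
#'
#' A deterministic consensus finder over fixed-width windows centred on
#' candidate sites (e.g. coverage-drop midpoints). Windows
#' `[site - flank, site + flank)` are extracted from the forward strand. For
#' k from `k_max` down to `k_min`, each k-mer of the first window is used as
#' an anchor; every other window is aligned to it at the offset of its
#' best-matching k-mer (most identical bases, ties to the smallest offset),
#' per-column base sets are merged into IUPAC codes, and the motif is
#' accepted if every column has at most two alternative bases and at most a
#' third of the columns are degenerate (otherwise any pair of unrelated
#' windows would yield a vacuous consensus). Ties between
#' accepted candidates are broken by fewer degenerate columns, then
#' lexicographically; longer motifs win over shorter ones.
#'
#' @param genome A [genome()] object.
#' @param sites Integer vector of 0-based site positions (at least 2).
#' @param flank Half-window width in bp (must be at least `k_max`).
#' @param k_min,k_max Motif length search range.
#' @return An [iupac_motif()] matched by every window, or `NULL` if no
#'   consensus exists within the constraints ("no consensus" is a result,
#'   not an error).
#' @export
consensus_from_sites <- function(genome, sites, flank = 25L,
                                 k_min = 6L, k_max = 12L) {
  stopifnot(length(sites) >= 2L, flank >= k_max, k_min <= k_max)
  sites <- sort(as.integer(sites))
  if (any(sites - flank < 0L) || any(sites + flank > genome$length))
    stop("site window extends outside the genome; reduce flank")
  windows <- substring(genome$seq, sites - flank + 1L, sites + flank)
  wlen <- 2L * flank
  wmats <- lapply(windows, function(w) strsplit(w, "")[[1]])
  for (k in seq(k_max, k_min)) {
    n_anchor <- wlen - k + 1L
    candidates <- list()
    for (j in seq_len(n_anchor)) {
      anchor <- wmats[[1]][j:(j + k - 1L)]
      if (any(!anchor %in% c("A", "C", "G", "T"))) next
      cols <- matrix("", nrow = length(windows), ncol = k)
      cols[1, ] <- anchor
      ok <- TRUE
      for (i in seq_along(windows)[-1]) {
        best_o <- 0L; best_m <- -1L
        for (o in seq_len(n_anchor)) {
          m <- sum(wmats[[i]][o:(o + k - 1L)] == anchor)
          if (m > best_m) { best_m <- m; best_o <- o }
        }
        km <- wmats[[i]][best_o:(best_o + k - 1L)]
        if (any(!km %in% c("A", "C", "G", "T"))) { ok <- FALSE; break }
        cols[i, ] <- km
      }
      if (!ok) next
      sets <- apply(cols, 2, function(cc) sort(unique(cc)),
                    simplify = FALSE)
      n_deg <- sum(vapply(sets, length, 1L) > 1L)
      if (any(vapply(sets, length, 1L) > 2L) || n_deg > k %/% 3L) next
      pattern <- paste(vapply(sets, function(s)
        IUPAC_FROM_SET[[paste(s, collapse = "")]], ""), collapse = "")
      candidates[[length(candidates) + 1L]] <-
        list(pattern = pattern, n_deg = n_deg)
    }
    if (length(candidates) > 0L) {
      pats <- vapply(candidates, `[[`, "", "pattern")
      degs <- vapply(candidates, `[[`, 1L, "n_deg")
      ord <- order(degs, pats)
      return(iupac_motif(pats[ord[1]]))
    }
  }
  NULL
}
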