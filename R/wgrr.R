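# weighted gene repertoire relatedness: global protein alignment identity,
# bidirectional best hits, the wGRR statistic, matrix + clustering, and
# cluster-level motif summaries

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a per-genome protein set
#'
#' @param genome_id Genome identifier.
#' @param seqs Named character vector of amino-acid sequences (20 standard
#'   residues plus X). Names are protein ids; unnamed sets get
#'   `<genome_id>_p<i>` ids.
#' @return An object of class `ProteinSet`.
#' @export
protein_set <- function(genome_id, seqs) {
  stopifnot(is.character(seqs), length(seqs) > 0L)
  seqs <- toupper(seqs)
  bad <- gsub(paste0("[", paste(c(AA20, "X"), collapse = ""), "]"), "", seqs)
  if (any(nchar(bad) > 0L))
    stop("protein set '", genome_id, "': non-amino-acid characters in ",
         "sequence ", which(nchar(bad) > 0L)[1])
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("%s_p%03d", genome_id, seq_along(seqs))
  structure(list(genome_id = genome_id, proteins = seqs),
            class = "ProteinSet")
}

#' Read a protein set from FASTA
#'
#' @param path Protein FASTA path.
#' @param genome_id Genome id; defaults to the file name without extension.
#' @return A [protein_set()].
#' @export
read_protein_fasta <- function(path, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(path))
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no records in protein FASTA: ", path)
  seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  protein_set(genome_id, seqs)
}

#' Write a protein set to FASTA
#' @param pset A [protein_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_fasta <- function(pset, path) {
  ss <- Biostrings::AAStringSet(pset$proteins)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# align every sequence of A against every sequence of B once; returns
# score, identity and coverage matrices (rows = A, cols = B)
align_sets <- function(a_seqs, b_seqs,
                       identity_denominator = c("columns", "shorter")) {
  identity_denominator <- match.arg(identity_denominator)
  nA <- length(a_seqs); nB <- length(b_seqs)
  # one elementwise batch: row i, col j at flat index (j-1)*nA + i
  pat <- rep(Biostrings::AAStringSet(a_seqs), times = nB)
  sub <- rep(Biostrings::AAStringSet(b_seqs), each = nA)
  pa <- Biostrings::pairwiseAlignment(
    pat, sub, substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, type = "global")
  same <- Biostrings::nmatch(pa)              # identical aligned pairs
  span <- same + Biostrings::nmismatch(pa)    # columns with two residues
  cols <- Biostrings::nchar(pa)               # alignment columns w/ gaps
  shorter <- pmin(rep(nchar(a_seqs), times = nB),
                  rep(nchar(b_seqs), each = nA))
  denom <- if (identity_denominator == "columns") cols else shorter
  list(score = matrix(Biostrings::score(pa), nA, nB),
       identity = matrix(same / denom, nA, nB),
       coverage = matrix(span / shorter, nA, nB))
}

#' Global alignment identity between two protein sequences
#'
#' Needleman-Wunsch global alignment with BLOSUM62, gap opening 11 and gap
#' extension 1. Identity is the number of identical aligned residue pairs
#' divided by the number of alignment columns (gap columns included), or by
#' the shorter sequence length with
#' `identity_denominator = "shorter"`.
#'
#' @param a,b Amino-acid sequences (character scalars).
#' @param identity_denominator `"columns"` (default) or `"shorter"`.
#' @return List with elements `score` and `identity`.
#' @export
pairwise_identity <- function(a, b,
                              identity_denominator = c("columns", "shorter")) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  protein_set("a", c(p = a)); protein_set("b", c(p = b)) # alphabet check
  al <- align_sets(a, b, identity_denominator)
  list(score = al$score[1, 1], identity = al$identity[1, 1])
}

#' Bidirectional best protein hits between two genomes
#'
#' Every protein of A is aligned against every protein of B; a pair is kept
#' when each member is the other's best-scoring partner (ties broken by
#' lower partner index) and the pair passes the identity and coverage
#' thresholds (coverage = aligned span / shorter sequence).
#'
#' @param A,B [protein_set()] objects.
#' @param min_identity Minimum alignment identity (default 0.35).
#' @param min_coverage Minimum coverage (default 0.5).
#' @param identity_denominator Passed to the identity computation.
#' @return data.frame with columns `protein_a`, `protein_b`, `identity`;
#'   each protein appears in at most one pair.
#' @export
best_bidirectional_hits <- function(A, B, min_identity = 0.35,
                                    min_coverage = 0.5,
                                    identity_denominator = "columns") {
  stopifnot(inherits(A, "ProteinSet"), inherits(B, "ProteinSet"))
  al <- align_sets(A$proteins, B$proteins, identity_denominator)
  best_b <- apply(al$score, 1, which.max)   # for each a, best b
  best_a <- apply(al$score, 2, which.max)   # for each b, best a
  ia <- seq_along(A$proteins)
  mutual <- best_a[best_b[ia]] == ia
  ib <- best_b[ia]
  keep <- mutual &
    al$identity[cbind(ia, ib)] >= min_identity &
    al$coverage[cbind(ia, ib)] >= min_coverage
  data.frame(protein_a = names(A$proteins)[ia[keep]],
             protein_b = names(B$proteins)[ib[keep]],
             identity = al$identity[cbind(ia[keep], ib[keep])],
             stringsAsFactors = FALSE)
}

#' Weighted gene repertoire relatedness between two genomes
#'
#' `wGRR(A, B) = sum of BBH identities / min(|A|, |B|)`: 1 when every
#' protein of the smaller repertoire has an identical partner in the other
#' genome, 0 when no proteins are similar.
#'
#' @inheritParams best_bidirectional_hits
#' @return wGRR value in \[0, 1\].
#' @export
wgrr <- function(A, B, min_identity = 0.35, min_coverage = 0.5,
                 identity_denominator = "columns") {
  bbh <- best_bidirectional_hits(A, B, min_identity, min_coverage,
                                 identity_denominator)
  sum(bbh$identity) / min(length(A$proteins), length(B$proteins))
}

#' All-pairs wGRR matrix
#'
#' @param psets List of [protein_set()] objects.
#' @param ... Passed to [wgrr()].
#' @return A symmetric matrix with unit diagonal, dimnames = genome ids,
#'   of class `WGRRMatrix`.
#' @export
wgrr_matrix <- function(psets, ...) {
  ids <- vapply(psets, `[[`, "", "genome_id")
  if (anyDuplicated(ids)) stop("duplicate genome ids in protein sets")
  n <- length(psets)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- wgrr(psets[[i]], psets[[j]], ...)
      m[i, j] <- m[j, i] <- v
    }
  }
  structure(m, class = c("WGRRMatrix", "matrix", "array"))
}

#' Cluster genomes on a wGRR matrix
#'
#' Agglomerative hierarchical clustering on the distance `1 - wGRR` with
#' average linkage; flat clusters are cut at distance `1 - cut`. Cluster
#' labels are deterministic, numbered by their first member in input order.
#' A leaf ordering for heatmap export is also returned.
#'
#' @param matrix A [wgrr_matrix()].
#' @param cut wGRR threshold: genome pairs with wGRR above `cut` end up in
#'   the same flat cluster under average linkage (default 0.5).
#' @param linkage Agglomeration method (only `"average"` supported).
#' @return List with `assignment` (named integer vector), `order` (genome
#'   ids in dendrogram leaf order) and `hclust` (the tree, or NULL for a
#'   single genome).
#' @export
cluster_genomes <- function(matrix, cut = 0.5, linkage = "average") {
  linkage <- match.arg(linkage, "average")
  ids <- rownames(matrix)
  if (length(ids) < 2L)
    return(list(assignment = stats::setNames(rep(1L, length(ids)), ids),
                order = ids, hclust = NULL))
  d <- stats::as.dist(1 - unclass(matrix))
  h <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(h, h = 1 - cut)
  # renumber clusters by first appearance in input order
  lab <- stats::setNames(seq_along(unique(raw)), unique(raw))
  assignment <- stats::setNames(as.integer(lab[as.character(raw)]), ids)
  list(assignment = assignment, order = ids[h$order], hclust = h)
}

#' Within- versus outside-cluster motif summary
#'
#' Mean net strand difference in motif occurrences for the genomes in the
#' focal genome's cluster versus all other genomes.
#'
#' @param assignment Named cluster vector from [cluster_genomes()].
#' @param stats data.frame of per-genome [strand_stats()] rows (column
#'   `net`), one row per genome in `assignment`.
#' @param focal_genome_id The genome whose cluster is summarised.
#' @return List: `within_mean`, `outside_mean` (NA when no genome is
#'   outside), `n_within`, `n_outside`, `focal_cluster`.
#' @export
cluster_motif_summary <- function(assignment, stats, focal_genome_id) {
  if (!focal_genome_id %in% names(assignment))
    stop("focal genome '", focal_genome_id, "' not in cluster assignment")
  missing <- setdiff(names(assignment), stats$genome_id)
  if (length(missing) > 0L)
    stop("no motif stats for genome(s): ", paste(missing, collapse = ", "))
  net <- stats::setNames(stats$net, stats$genome_id)[names(assignment)]
  focal_cluster <- assignment[[focal_genome_id]]
  inside <- assignment == focal_cluster
  list(within_mean = mean(net[inside]),
       outside_mean = if (any(!inside)) mean(net[!inside]) else NA_real_,
       n_within = sum(inside), n_outside = sum(!inside),
       focal_cluster = focal_cluster)
}
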