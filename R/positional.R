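# terL-based genome reorientation and motif positional statistics relative
# to genome length and coding sequences

#' Reorient a genome to start at the terminase large subunit (terL)
#'
#' If the terL CDS is on the minus strand, the genome is first
#' reverse-complemented (all CDS remapped), then rotated so that the terL
#' start codon sits at position 0 on the plus strand. Rotation treats the
#' sequence as circular for coordinate bookkeeping even though the physical
#' genome is linear; a CDS spanning the new origin keeps `end > length`
#' (unrolled coordinates).
#'
#' @param annotated An `AnnotatedGenome` (see [read_gff_cds()]).
#' @param terl_label Product label to match (case-insensitive substring;
#'   default `"terminase large subunit"`). Exactly one CDS must match.
#' @return A list of class `ReorientedGenome`: `annotated` (the transformed
#'   genome + CDS), `offset` (bp rotation applied after any flip) and
#'   `flipped` (logical).
#' @export
reorient_to_terl <- function(annotated,
                             terl_label = "terminase large subunit") {
  stopifnot(inherits(annotated, "AnnotatedGenome"))
  cds <- annotated$cds
  hit <- grepl(terl_label, cds$product, ignore.case = TRUE, fixed = FALSE)
  if (sum(hit) == 0L)
    stop("no CDS with product matching '", terl_label, "' in genome '",
         annotated$genome$id, "'")
  if (sum(hit) > 1L)
    stop("multiple CDS match '", terl_label, "' in genome '",
         annotated$genome$id, "': ",
         paste(cds$id[hit], collapse = ", "))
  L <- annotated$genome$length
  flipped <- cds$strand[hit] == "-"
  seq <- annotated$genome$seq
  if (flipped) {
    seq <- revcomp_seq(seq)
    cds <- flip_cds(cds, L)
  }
  offset <- cds$start[grepl(terl_label, cds$product, ignore.case = TRUE)][1]
  if (offset > 0L) {
    w <- cds$end - cds$start          # widths survive flip and rotation
    seq <- rotate_seq(seq, offset)
    cds$start <- (cds$start - offset) %% L
    cds$end <- cds$start + w          # may exceed L for origin-spanners
  }
  g2 <- genome(annotated$genome$id, seq)
  cds <- cds[order(cds$start, cds$end), , drop = FALSE]
  rownames(cds) <- NULL
  ann2 <- structure(list(genome = g2, cds = cds), class = "AnnotatedGenome")
  structure(list(annotated = ann2, offset = offset, flipped = flipped),
            class = "ReorientedGenome")
}

rotate_seq <- function(seq, offset) {
  L <- nchar(seq)
  if (offset %% L == 0L) return(seq)
  offset <- offset %% L
  paste0(substring(seq, offset + 1L, L), substring(seq, 1L, offset))
}

flip_cds <- function(cds, L) {
  new <- cds
  new$start <- L - cds$end
  new$end <- L - cds$start
  new$strand <- ifelse(cds$strand == "+", "-", "+")
  new[order(new$start, new$end), , drop = FALSE]
}

#' Map motif hits through a reorientation transform
#'
#' Applies the flip/rotation of a [reorient_to_terl()] result to hit
#' coordinates. Hits whose k-mer would span the rotation junction are
#' dropped (they no longer exist as contiguous matches on the rotated
#' linear sequence).
#'
#' @param hits data.frame from [scan_genome()].
#' @param reoriented A `ReorientedGenome`.
#' @return Transformed hits data.frame, re-sorted.
#' @export
reorient_hits <- function(hits, reoriented) {
  L <- reoriented$annotated$genome$length
  if (nrow(hits) == 0L) return(hits)
  k <- nchar(hits$matched)
  start <- hits$start
  strand <- hits$strand
  if (reoriented$flipped) {
    start <- L - (start + k)
    strand <- ifelse(strand == "+", "-", "+")
  }
  start <- (start - reoriented$offset) %% L
  keep <- start + k <= L
  out <- data.frame(genome_id = hits$genome_id[keep], start = start[keep],
                    strand = strand[keep], matched = hits$matched[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hit_midpoint <- function(hits) {
  hits$start + (nchar(hits$matched) - 1) / 2
}

#' Motif positions relative to genome length
#'
#' @param hits data.frame from [scan_genome()] (normally on terL-reoriented
#'   coordinates).
#' @param genome_length Genome length in bp.
#' @return Numeric vector of hit-midpoint / genome-length fractions in
#'   \[0, 1).
#' @export
relative_genome_positions <- function(hits, genome_length) {
  if (nrow(hits) == 0L) return(numeric(0))
  mid <- hit_midpoint(hits)
  if (any(mid < 0) || any(mid >= genome_length))
    stop("hit midpoints outside the genome")
  mid / genome_length
}

#' Motif positions relative to coding sequences
#'
#' For each hit, finds the CDS it occurs in and reports the position of the
#' hit midpoint along that CDS in its own 5'-3' direction: 0 at the start
#' codon, approaching 1 at the CDS end. `overlap_mode = "any"` (default)
#' assigns a hit to a CDS it overlaps by any amount ("occurs at least partly
#' within"); `"midpoint"` requires the midpoint itself to fall inside.
#' When a hit overlaps several CDS it is assigned to the one containing the
#' larger part of the hit, ties to the smaller start. `rel_cds` is clamped
#' to \[0, 1\] for hits whose midpoint hangs over the CDS edge in `"any"`
#' mode.
#'
#' @param hits data.frame from [scan_genome()].
#' @param annotated An `AnnotatedGenome` on the same coordinates.
#' @param overlap_mode `"any"` or `"midpoint"`.
#' @return data.frame, one row per hit: `genome_id`, `start`, `strand`,
#'   `matched`, `rel_genome`, `cds_id` (NA if outside), `rel_cds` (NA if
#'   outside) and `cds_strand_relation`
#'   (`"coding-strand"`/`"template-strand"`/`"outside"`).
#' @export
cds_relative_position <- function(hits, annotated,
                                  overlap_mode = c("any", "midpoint")) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(inherits(annotated, "AnnotatedGenome"))
  cds <- annotated$cds
  L <- annotated$genome$length
  n <- nrow(hits)
  out <- data.frame(genome_id = hits$genome_id, start = hits$start,
                    strand = hits$strand, matched = hits$matched,
                    rel_genome = relative_genome_positions(hits, L),
                    cds_id = rep(NA_character_, n),
                    rel_cds = rep(NA_real_, n),
                    cds_strand_relation = rep("outside", n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(cds) == 0L) return(out)
  k <- nchar(hits$matched)
  mid <- hit_midpoint(hits)
  for (i in seq_len(n)) {
    hs <- hits$start[i]; he <- hits$start[i] + k[i]
    if (overlap_mode == "midpoint") {
      cand <- which(cds$start <= mid[i] & mid[i] < cds$end)
    } else {
      cand <- which(cds$start < he & hs < cds$end)
    }
    if (length(cand) == 0L) next
    if (length(cand) > 1L) {
      ov <- pmin(cds$end[cand], he) - pmax(cds$start[cand], hs)
      cand <- cand[order(-ov, cds$start[cand])][1]
    }
    w <- cds$end[cand] - cds$start[cand]
    rel <- if (cds$strand[cand] == "+")
      (mid[i] - cds$start[cand]) / w
    else
      (cds$end[cand] - 1 - mid[i]) / w
    out$cds_id[i] <- cds$id[cand]
    out$rel_cds[i] <- min(1, max(0, rel))
    out$cds_strand_relation[i] <-
      if (hits$strand[i] == cds$strand[cand]) "coding-strand"
      else "template-strand"
  }
  out
}

#' Coding density of an annotated genome
#'
#' Fraction of genome bases covered by at least one CDS (union of
#' intervals; overlaps are not double-counted).
#'
#' @param annotated An `AnnotatedGenome`.
#' @return Fraction in \[0, 1\].
#' @export
coding_density <- function(annotated) {
  stopifnot(inherits(annotated, "AnnotatedGenome"))
  cds <- annotated$cds
  if (nrow(cds) == 0L) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = cds$start + 1L,
                                         end = pmin(cds$end,
                                                    annotated$genome$length)))
  sum(IRanges::width(ir)) / annotated$genome$length
}
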