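# nick calling: one-strand coverage-drop detection against a WGA control,
# and association of drop intervals with motif hits

#' Parameters for coverage-drop detection
#'
#' "Near-zero" depth is operationalised as
#' `depth <= max(tau_abs, tau_rel * same-strand median)`, tolerating rare
#' read-through or chimeric molecules. A position is only a candidate when
#' the other strand and the WGA control both retain normal coverage there,
#' so physical genome ends and globally low-coverage regions are not called.
#'
#' @param tau_abs Absolute depth ceiling for "near-zero" (reads; default 2).
#' @param tau_rel Fraction of the same-strand median depth (default 0.05).
#' @param min_other_strand Minimum other-strand depth at the site, as a
#'   fraction of the other-strand median (default 0.5).
#' @param min_control Minimum control same-strand depth at the site, as a
#'   fraction of the control same-strand median (default 0.5).
#' @param merge_gap Low positions closer than this many bp are merged into
#'   one interval (default 5).
#' @param min_callable_median Minimum per-strand native median depth to
#'   attempt calling at all (default 10).
#' @param end_exclusion Intervals touching the first/last this-many bp are
#'   discarded; linear-genome termini produce coverage cliffs that are not
#'   nicks (default 200).
#' @return A list of class `DropParams`.
#' @export
drop_params <- function(tau_abs = 2L, tau_rel = 0.05,
                        min_other_strand = 0.5, min_control = 0.5,
                        merge_gap = 5L, min_callable_median = 10,
                        end_exclusion = 200L) {
  stopifnot(tau_abs >= 0, tau_rel > 0, tau_rel <= 1,
            min_other_strand > 0, min_other_strand <= 1,
            min_control > 0, min_control <= 1,
            merge_gap >= 0, min_callable_median >= 0, end_exclusion >= 0)
  structure(list(tau_abs = tau_abs, tau_rel = tau_rel,
                 min_other_strand = min_other_strand,
                 min_control = min_control, merge_gap = merge_gap,
                 min_callable_median = min_callable_median,
                 end_exclusion = end_exclusion),
            class = "DropParams")
}

empty_drops <- function() {
  data.frame(genome_id = character(0), strand = character(0),
             start = integer(0), end = integer(0),
             min_depth = integer(0), flank_depth = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect single-strand coverage-drop intervals
#'
#' For each strand, marks positions where the native depth on that strand is
#' near-zero while (a) the native depth on the opposite strand and (b) the
#' control depth on the same strand both remain at normal levels. Marked
#' positions within `merge_gap` bp are merged into intervals; intervals
#' touching the genome ends (within `end_exclusion` bp) are discarded. Both
#' strands are tested symmetrically; the reported `strand` is the depleted
#' one.
#'
#' @param native [strand_coverage()] of the native sample.
#' @param control [strand_coverage()] of the WGA control.
#' @param params A [drop_params()] list.
#' @return data.frame with columns `genome_id`, `strand` (depleted strand),
#'   `start`, `end` (0-based half-open), `min_depth` and `flank_depth`
#'   (median same-strand depth over the 100 bp flanks), ordered by `start`
#'   then strand.
#' @export
detect_drops <- function(native, control, params = drop_params()) {
  stopifnot(inherits(native, "StrandCoverage"),
            inherits(control, "StrandCoverage"),
            inherits(params, "DropParams"))
  if (native$genome_id != control$genome_id)
    stop("native and control cover different genomes")
  L <- length(native$depth_fwd)
  if (length(control$depth_fwd) != L)
    stop("native and control depth arrays differ in length")
  med_nf <- stats::median(native$depth_fwd)
  med_nr <- stats::median(native$depth_rev)
  if (min(med_nf, med_nr) < params$min_callable_median)
    stop(sprintf(
      "insufficient coverage: per-strand native median depth %.1f/%.1f below %s",
      med_nf, med_nr, format(params$min_callable_median)))
  one_strand <- function(d, o, cd, strand) {
    med_s <- stats::median(d)
    med_o <- stats::median(o)
    med_c <- stats::median(cd)
    thr <- max(params$tau_abs, params$tau_rel * med_s)
    mask <- (d <= thr) & (o >= params$min_other_strand * med_o) &
      (cd >= params$min_control * med_c)
    idx <- which(mask)
    if (length(idx) == 0L) return(empty_drops())
    ir <- IRanges::reduce(IRanges::IRanges(start = idx, width = 1L),
                          min.gapwidth = params$merge_gap + 1L)
    s0 <- IRanges::start(ir) - 1L
    e0 <- IRanges::end(ir)
    keep <- s0 >= params$end_exclusion & e0 <= L - params$end_exclusion
    if (!any(keep)) return(empty_drops())
    s0 <- s0[keep]; e0 <- e0[keep]
    min_depth <- mapply(function(s, e) min(d[(s + 1L):e]), s0, e0)
    flank_depth <- mapply(function(s, e) {
      left <- d[max(1L, s - 99L):max(1L, s)]
      right <- d[min(L, e + 1L):min(L, e + 100L)]
      stats::median(c(left, right))
    }, s0, e0)
    data.frame(genome_id = native$genome_id, strand = strand,
               start = s0, end = e0,
               min_depth = as.integer(min_depth),
               flank_depth = as.numeric(flank_depth),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_strand(native$depth_fwd, native$depth_rev, control$depth_fwd, "+"),
    one_strand(native$depth_rev, native$depth_fwd, control$depth_rev, "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate coverage-drop intervals with motif hits
#'
#' Greedy one-to-one matching between drop intervals and motif hits: among
#' all (interval, hit) pairs whose midpoints lie within `window` bp of each
#' other, pairs are accepted in order of ascending distance (ties broken by
#' interval, then hit, coordinate), each interval and each hit used at most
#' once. Unmatched intervals are reported with `motif_associated = FALSE`.
#'
#' @param intervals data.frame from [detect_drops()].
#' @param hits data.frame from [scan_genome()] (same genome).
#' @param window Maximum midpoint distance in bp for association
#'   (default 50).
#' @return data.frame of nick calls: the interval columns plus
#'   `motif_start`, `motif_strand`, `distance` (NA when unassociated) and
#'   `motif_associated`.
#' @export
associate_motif_hits <- function(intervals, hits, window = 50) {
  calls <- intervals
  calls$motif_start <- NA_integer_
  calls$motif_strand <- NA_character_
  calls$distance <- NA_real_
  calls$motif_associated <- logical(nrow(calls))
  if (nrow(intervals) == 0L || nrow(hits) == 0L) return(calls)
  if (any(hits$genome_id != intervals$genome_id[1]))
    stop("hits and intervals are from different genomes")
  int_mid <- (intervals$start + intervals$end) / 2
  k <- nchar(hits$matched)
  hit_mid <- hits$start + (k - 1) / 2
  pairs <- expand.grid(i = seq_len(nrow(intervals)),
                       j = seq_len(nrow(hits)))
  pairs$dist <- abs(int_mid[pairs$i] - hit_mid[pairs$j])
  pairs <- pairs[pairs$dist <= window, , drop = FALSE]
  pairs <- pairs[order(pairs$dist, intervals$start[pairs$i],
                       hits$start[pairs$j]), , drop = FALSE]
  used_i <- logical(nrow(intervals))
  used_j <- logical(nrow(hits))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    calls$motif_start[i] <- hits$start[j]
    calls$motif_strand[i] <- hits$strand[j]
    calls$distance[i] <- pairs$dist[r]
    calls$motif_associated[i] <- TRUE
  }
  calls
}

#' Summarise nick calls and motif statistics
#'
#' @param calls data.frame from [associate_motif_hits()].
#' @param stats One-row data.frame from [strand_stats()] for the same
#'   genome, or `NULL`.
#' @return A list: interval counts per strand, fraction of intervals that
#'   are motif-associated, fraction of motif hits with an associated drop,
#'   and the motif strand statistics. Fractions with zero denominator are
#'   `NA` (not applicable).
#' @export
nick_report <- function(calls, stats = NULL) {
  n_int <- nrow(calls)
  n_assoc <- sum(calls$motif_associated)
  n_hits <- if (is.null(stats)) NA_integer_ else stats$n_fwd + stats$n_rev
  list(
    n_intervals = n_int,
    n_intervals_fwd = sum(calls$strand == "+"),
    n_intervals_rev = sum(calls$strand == "-"),
    n_motif_associated = n_assoc,
    frac_intervals_associated = if (n_int > 0L) n_assoc / n_int else NA_real_,
    frac_hits_associated =
      if (!is.na(n_hits) && n_hits > 0L) n_assoc / n_hits else NA_real_,
    motif_stats = stats)
}
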