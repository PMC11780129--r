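# synthetic-data generator: nicked genomes with planted degenerate motifs,
# strand-truncated long-read sets with matched WGA controls, annotations at
# a target coding density, and multi-genome families with planted clades

#' Specification for a synthetic nicked-genome simulation
#'
#' Defaults emulate a ~45 kbp phage genome carrying 13 same-strand
#' WACTRTGAC nick sites sequenced to 50x per-strand long-read depth.
#'
#' @param seed RNG seed.
#' @param genome_length Genome length in bp.
#' @param gc GC fraction of the background sequence.
#' @param n_nicks Number of planted nicks (each inside a planted motif).
#' @param motif Planted degenerate motif (pattern or [iupac_motif()]).
#' @param nick_strand Strand carrying the nicks/motifs (`"+"`/`"-"`).
#' @param mean_depth Target mean per-strand read depth (x coverage).
#' @param read_length_mean,read_length_sd,read_length_min Read-length model:
#'   normal, truncated below at `read_length_min`.
#' @param coding_density_target Coding density for [make_annotation()].
#' @param nick_end_trim Bases lost on each side of a nick when a molecule is
#'   split there (models end losses of nick-terminated reads; this is what
#'   turns a split into a visible one-strand depth trough).
#' @param readthrough_prob Probability that a read crosses a nick intact.
#' @param min_motif_spacing Minimum distance between planted motifs (bp).
#' @param end_clearance No planted motif within this many bp of an end.
#' @param error_rate Optional uniform substitution rate applied to read
#'   sequences when writing SAM (coordinates are unaffected).
#' @return A list of class `SimulationSpec`.
#' @export
simulation_spec <- function(seed = 1L, genome_length = 45228L, gc = 0.525,
                            n_nicks = 13L, motif = "WACTRTGAC",
                            nick_strand = "-", mean_depth = 50,
                            read_length_mean = 4000, read_length_sd = 2000,
                            read_length_min = 200,
                            coding_density_target = 0.89,
                            nick_end_trim = 5L, readthrough_prob = 0,
                            min_motif_spacing = 500L,
                            end_clearance = 500L, error_rate = 0) {
  motif <- as_motif(motif)
  stopifnot(gc > 0, gc < 1, nick_strand %in% c("+", "-"),
            readthrough_prob >= 0, readthrough_prob <= 1,
            coding_density_target > 0, coding_density_target < 1)
  if (n_nicks > 0 &&
      n_nicks * min_motif_spacing + 2 * end_clearance >= genome_length)
    stop("spacing infeasible: ", n_nicks, " motifs at >= ",
         min_motif_spacing, " bp apart do not fit in ", genome_length,
         " bp with ", end_clearance, " bp end clearance")
  structure(as.list(environment()), class = "SimulationSpec")
}

random_seq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a genome with planted motif/nick sites and ground truth
#'
#' Background bases are i.i.d. at the requested GC. Motif occurrences
#' (concrete variants drawn uniformly from [expand_motif()]) are planted at
#' jittered evenly spaced positions, all on `nick_strand`, respecting the
#' minimum spacing and end clearance; one nick position is recorded at the
#' centre of each planted motif. The finished sequence is re-scanned so that
#' accidental background occurrences are also recorded in the truth.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `genome` (a [genome()]) and `truth`: a list
#'   with `motif_positions` (planted; data.frame start/strand/variant),
#'   `nick_positions` (0-based bp), `all_hits` (full re-scan) and
#'   `background_hits` (non-planted occurrences).
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  k <- spec$motif$k
  seq <- random_seq(L, spec$gc)
  n <- spec$n_nicks
  planted <- data.frame(start = integer(0), strand = character(0),
                        variant = character(0), stringsAsFactors = FALSE)
  if (n > 0L) {
    usable <- L - 2L * spec$end_clearance
    slot <- usable / n
    jitter_max <- max(0, (slot - spec$min_motif_spacing) / 2)
    centers <- spec$end_clearance + (seq_len(n) - 0.5) * slot +
      stats::runif(n, -jitter_max, jitter_max)
    starts <- as.integer(round(centers)) - (k - 1L) %/% 2L
    variants <- sample(expand_motif(spec$motif), n, replace = TRUE)
    insert <- if (spec$nick_strand == "+") variants else
      vapply(variants, revcomp_seq, "", USE.NAMES = FALSE)
    for (i in seq_len(n))
      substring(seq, starts[i] + 1L, starts[i] + k) <- insert[i]
    planted <- data.frame(start = starts, strand = spec$nick_strand,
                          variant = variants, stringsAsFactors = FALSE)
  }
  g <- genome(sprintf("sim_seed%d", spec$seed), seq)
  all_hits <- scan_genome(g, spec$motif)
  key <- paste(all_hits$start, all_hits$strand)
  pkey <- paste(planted$start, planted$strand)
  truth <- list(
    motif_positions = planted,
    nick_positions = sort(planted$start + (k - 1L) %/% 2L),
    all_hits = all_hits,
    background_hits = all_hits[!key %in% pkey, , drop = FALSE])
  list(genome = g, truth = truth)
}

#' Generate a CDS annotation at a target coding density
#'
#' Tiles the genome with CDS blocks (length ~ U(600, 1200) bp rounded to
#' codons) separated by gaps sized so that the expected coding density
#' matches the target; strands are random, and the first CDS is labelled
#' "terminase large subunit".
#'
#' @param genome A [genome()] object.
#' @param coding_density_target Desired fraction of bases covered by CDS.
#' @param seed RNG seed.
#' @return An `AnnotatedGenome`.
#' @export
make_annotation <- function(genome, coding_density_target = 0.89,
                            seed = 1L) {
  set.seed(seed)
  L <- genome$length
  d <- coding_density_target
  starts <- integer(0); ends <- integer(0); strands <- character(0)
  pos <- 0L
  while (pos < L - 300L) {
    len <- 3L * as.integer(round(stats::runif(1, 600, 1200) / 3))
    len <- min(len, L - pos)
    if (len >= 150L) {
      starts <- c(starts, pos)
      ends <- c(ends, pos + len)
      strands <- c(strands, sample(c("+", "-"), 1))
    }
    gap <- as.integer(round(len * (1 - d) / d * stats::runif(1, 0.8, 1.2)))
    pos <- pos + len + max(1L, gap)
  }
  # trim or extend the final CDS so the realised density matches the
  # target to within a codon
  target_bp <- round(coding_density_target * L)
  delta <- target_bp - sum(ends - starts)
  n <- length(ends)
  ends[n] <- min(L, max(starts[n] + 150L, ends[n] + 3L * round(delta / 3)))
  cds <- data.frame(
    start = starts, end = ends, strand = strands,
    product = c("terminase large subunit",
                rep("hypothetical protein", length(starts) - 1L)),
    id = sprintf("%s_CDS_%04d", genome$id, seq_along(starts)),
    stringsAsFactors = FALSE)
  annotated_genome(genome, cds)
}

# randomly sheared linear molecules: fragment start may precede the first
# base or run past the last one; the read is clipped to the genome, so
# coverage is uniform from edge to edge (no terminal ramp)
draw_strand_reads <- function(total_bp, spec, L) {
  starts <- integer(0); ends <- integer(0)
  while (sum(ends - starts) < total_bp) {
    lens <- as.integer(round(stats::rnorm(512, spec$read_length_mean,
                                          spec$read_length_sd)))
    lens <- lens[lens >= spec$read_length_min]
    s <- as.integer(floor(stats::runif(length(lens), -(lens - 1), L)))
    b_start <- pmax(0L, s)
    b_end <- pmin(L, s + lens)
    keep <- b_end - b_start >= 1L
    starts <- c(starts, b_start[keep])
    ends <- c(ends, b_end[keep])
  }
  covered <- cumsum(ends - starts)
  n <- which(covered >= total_bp)[1]
  data.frame(start = starts[seq_len(n)], end = ends[seq_len(n)])
}

split_at_nicks <- function(s, e, nicks, spec) {
  cuts <- nicks[nicks > s & nicks < e]
  if (length(cuts) > 0L && spec$readthrough_prob > 0)
    cuts <- cuts[stats::runif(length(cuts)) >= spec$readthrough_prob]
  if (length(cuts) == 0L) return(cbind(s, e))
  trim <- spec$nick_end_trim
  bounds_s <- c(s, cuts + trim + 1L)
  bounds_e <- c(cuts - trim, e)
  keep <- bounds_e - bounds_s >= spec$read_length_min
  cbind(bounds_s[keep], bounds_e[keep])
}

#' Simulate native and WGA long-read sets over a nicked genome
#'
#' Reads model randomly sheared linear molecules: lengths are
#' truncated-normal, fragment positions uniform, and fragments overhanging
#' a terminus are clipped to the genome, so expected coverage is uniform
#' from edge to edge. Strands are assigned uniformly. Native reads on the nicked
#' strand are split at every nick they span (losing `nick_end_trim` bases
#' on each side of the nick; sub-minimum fragments are discarded), which
#' produces the abrupt one-strand depth troughs at nick sites. Control
#' (WGA) reads are never split.
#'
#' @param genome A [genome()] from [make_genome()].
#' @param truth The matching ground-truth list.
#' @param spec The [simulation_spec()] used.
#' @return List with `native` and `control`, each a data.frame of reads
#'   (`start`, `end` 0-based half-open, `strand`).
#' @export
simulate_reads <- function(genome, truth, spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  set.seed(spec$seed + 1000003L)
  L <- genome$length
  total_bp <- spec$mean_depth * L          # per strand
  draw_set <- function(nicked) {
    reads <- list()
    for (strand in c("+", "-")) {
      rd <- draw_strand_reads(total_bp, spec, L)
      if (nicked && strand == spec$nick_strand &&
          length(truth$nick_positions) > 0L) {
        frags <- do.call(rbind, mapply(
          function(s, e) split_at_nicks(s, e, truth$nick_positions, spec),
          rd$start, rd$end, SIMPLIFY = FALSE))
        reads[[strand]] <- data.frame(start = frags[, 1], end = frags[, 2],
                                      strand = strand,
                                      stringsAsFactors = FALSE)
      } else {
        reads[[strand]] <- data.frame(start = rd$start, end = rd$end,
                                      strand = strand,
                                      stringsAsFactors = FALSE)
      }
    }
    out <- rbind(reads[["+"]], reads[["-"]])
    out <- out[order(out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  native <- draw_set(nicked = TRUE)
  control <- draw_set(nicked = FALSE)
  list(native = native, control = control)
}

#' Per-base strand coverage of a simulated read set
#'
#' @param reads data.frame from [simulate_reads()] (`start`, `end`,
#'   `strand`).
#' @param genome The genome the reads were drawn from.
#' @param sample_label `"native"` or `"wga"`.
#' @return A [strand_coverage()] object.
#' @export
coverage_from_reads <- function(reads, genome,
                                sample_label = c("native", "wga")) {
  sample_label <- match.arg(sample_label)
  depth_for <- function(sel) {
    if (!any(sel)) return(integer(genome$length))
    ir <- IRanges::IRanges(start = reads$start[sel] + 1L,
                           end = reads$end[sel])
    as.integer(IRanges::coverage(ir, width = genome$length))
  }
  strand_coverage(genome$id, depth_for(reads$strand == "+"),
                  depth_for(reads$strand == "-"), sample_label)
}

#' Write simulated reads as a sorted SAM file
#'
#' Minimal coordinate-sorted SAM: flag 0/16 by strand, MAPQ 60, all-match
#' CIGAR, SEQ in reference orientation. With `error_rate > 0`, uniform
#' substitutions are applied to SEQ only (alignment coordinates stay exact).
#'
#' @param reads data.frame from [simulate_reads()].
#' @param genome The source [genome()].
#' @param path Output `.sam` path.
#' @param error_rate Per-base substitution probability for SEQ.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, genome, path, error_rate = 0) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$id, genome$length))
  if (nrow(reads) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  reads <- reads[order(reads$start, reads$end), , drop = FALSE]
  seqs <- substring(genome$seq, reads$start + 1L, reads$end)
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(ch)) < error_rate
      ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  recs <- sprintf("r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                  seq_len(nrow(reads)),
                  ifelse(reads$strand == "+", 0L, 16L),
                  genome$id, reads$start + 1L,
                  reads$end - reads$start, seqs)
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Specification for a synthetic phage family
#'
#' Describes a two-group family: a focal clade whose genomes carry many
#' same-strand copies of the motif (biased towards the second half of the
#' terL-oriented genome), and an outgroup with only Poisson-distributed
#' chance-level occurrences on random strands. Proteomes descend from
#' shared ancestors with per-site substitution rates calibrated so that
#' expected pairwise identity is `within_identity` inside a group and
#' `between_identity` across groups.
#'
#' @param n_in_clade,n_outgroup Group sizes.
#' @param proteins_per_genome Proteins per genome.
#' @param protein_length Protein length (aa).
#' @param within_identity,between_identity Target pairwise identities.
#' @param clade_motif_range Integer range (min, max) of planted same-strand
#'   motifs per clade genome.
#' @param outgroup_motif_lambda Poisson mean of outgroup occurrences.
#' @param genome_length Family genome length in bp.
#' @param motif Planted motif.
#' @param second_half_bias Probability that a clade motif is planted in the
#'   second half of the terL-oriented genome.
#' @return A list of class `FamilySpec`.
#' @export
family_spec <- function(n_in_clade = 10L, n_outgroup = 10L,
                        proteins_per_genome = 8L, protein_length = 100L,
                        within_identity = 0.9, between_identity = 0.2,
                        clade_motif_range = c(8L, 12L),
                        outgroup_motif_lambda = 0.7,
                        genome_length = 20000L, motif = "WACTRTGAC",
                        second_half_bias = 0.85) {
  stopifnot(within_identity > 0, within_identity < 1,
            between_identity > 0, between_identity <= within_identity,
            n_in_clade >= 1, n_outgroup >= 0)
  motif <- as_motif(motif)
  structure(as.list(environment()), class = "FamilySpec")
}

mutate_protein <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

plant_motifs <- function(seq, positions, variants, strand_vec, k) {
  for (i in seq_along(positions)) {
    ins <- if (strand_vec[i] == "+") variants[i] else revcomp_seq(variants[i])
    substring(seq, positions[i] + 1L, positions[i] + k) <- ins
  }
  seq
}

#' Generate a synthetic phage family with planted clades
#'
#' Builds each genome in a canonical terL-oriented frame (terL CDS first,
#' plus strand, clade motifs planted all on the plus strand with a
#' second-half positional bias), then hides that frame behind a random
#' rotation (anchored in an intergenic gap) and an optional
#' reverse-complement, so that [reorient_to_terl()] has real work to do.
#'
#' @param fspec A [family_spec()].
#' @param seed RNG seed.
#' @return List with `genomes` (list of `AnnotatedGenome`), `proteomes`
#'   (list of [protein_set()]) and `truth` (clade assignment, orthology,
#'   per-genome planted motif records in both frames, transforms).
#' @export
make_family <- function(fspec, seed = 1L) {
  stopifnot(inherits(fspec, "FamilySpec"))
  set.seed(seed)
  k <- fspec$motif$k
  kmers <- expand_motif(fspec$motif)
  m_rate <- 1 - sqrt(fspec$within_identity)
  f_shared <- fspec$between_identity / fspec$within_identity
  root <- vapply(seq_len(fspec$proteins_per_genome), function(i)
    paste(sample(AA20, fspec$protein_length, replace = TRUE),
          collapse = ""), "")
  anc_out <- vapply(root, mutate_protein, "", rate = 1 - f_shared,
                    USE.NAMES = FALSE)
  n_total <- fspec$n_in_clade + fspec$n_outgroup
  ids <- sprintf("fam%02d", seq_len(n_total))
  in_clade <- c(rep(TRUE, fspec$n_in_clade), rep(FALSE, fspec$n_outgroup))
  genomes <- vector("list", n_total)
  proteomes <- vector("list", n_total)
  motif_truth <- vector("list", n_total)
  transforms <- vector("list", n_total)
  L <- fspec$genome_length
  for (gidx in seq_len(n_total)) {
    anc <- if (in_clade[gidx]) root else anc_out
    prots <- vapply(anc, mutate_protein, "", rate = m_rate,
                    USE.NAMES = FALSE)
    names(prots) <- sprintf("%s_p%03d", ids[gidx], seq_along(prots))
    # canonical frame: terL CDS at position 0 (matches terL reorientation),
    # remaining CDS head-to-tail with intergenic gaps
    cds_len <- 3L * fspec$protein_length
    gaps <- as.integer(stats::runif(fspec$proteins_per_genome, 60, 160))
    starts <- cumsum(c(0L, (cds_len + gaps)[-fspec$proteins_per_genome]))
    if (max(starts) + cds_len > L - 200L)
      stop("infeasible packing: proteome does not fit in genome_length")
    seq <- random_seq(L, 0.5)
    # choose how the canonical frame will be hidden (rotation anchored in
    # an intergenic gap, optional flip) before planting, so that no motif
    # is planted across the future rotation junction
    gap_choice <- sample(seq_len(fspec$proteins_per_genome), 1L)
    gap_lo <- starts[gap_choice] + cds_len + 10L
    gap_hi <- if (gap_choice == fspec$proteins_per_genome) L - 10L
              else starts[gap_choice + 1L] - 10L
    rot <- as.integer(stats::runif(1, gap_lo, gap_hi)) %% L
    flip <- stats::runif(1) < 0.5
    # plant motifs in the canonical frame
    if (in_clade[gidx]) {
      n_m <- sample(seq(fspec$clade_motif_range[1],
                        fspec$clade_motif_range[2]), 1L)
      second <- stats::runif(n_m) < fspec$second_half_bias
      pos <- as.integer(ifelse(second,
                               stats::runif(n_m, L / 2, L - 200 - k),
                               stats::runif(n_m, 200, L / 2 - k)))
      pos <- sort(pos)
      pos <- pos[c(TRUE, diff(pos) >= k + 10L)]   # avoid overlaps
      strands <- rep("+", length(pos))
    } else {
      n_m <- stats::rpois(1L, fspec$outgroup_motif_lambda)
      pos <- if (n_m > 0)
        sort(as.integer(stats::runif(n_m, 200, L - 200 - k))) else integer(0)
      pos <- pos[c(if (length(pos) > 0) TRUE, diff(pos) >= k + 10L)]
      strands <- sample(c("+", "-"), length(pos), replace = TRUE)
    }
    keep <- !(pos > rot - k & pos < rot)   # never span the junction
    pos <- pos[keep]; strands <- strands[keep]
    vars <- if (length(pos) > 0)
      sample(kmers, length(pos), replace = TRUE) else character(0)
    seq <- plant_motifs(seq, pos, vars, strands, k)
    g_canon <- genome(ids[gidx], seq)
    cds <- data.frame(
      start = starts, end = starts + cds_len, strand = "+",
      product = c("terminase large subunit",
                  rep("hypothetical protein",
                      fspec$proteins_per_genome - 1L)),
      id = names(prots), stringsAsFactors = FALSE)
    seq_raw <- rotate_seq(g_canon$seq, rot)
    cds_raw <- cds
    cds_raw$start <- (cds$start - rot) %% L
    cds_raw$end <- cds_raw$start + cds_len
    pos_raw <- (pos - rot) %% L
    strands_raw <- strands
    if (flip) {
      seq_raw <- revcomp_seq(seq_raw)
      cds_raw <- flip_cds(cds_raw, L)
      pos_raw <- L - (pos_raw + k)
      strands_raw <- ifelse(strands_raw == "+", "-", "+")
    }
    g_raw <- genome(ids[gidx], seq_raw)
    genomes[[gidx]] <- annotated_genome(g_raw, cds_raw)
    proteomes[[gidx]] <- protein_set(ids[gidx], prots)
    motif_truth[[gidx]] <- list(
      canonical = data.frame(start = pos, strand = strands,
                             variant = vars, stringsAsFactors = FALSE),
      raw = data.frame(start = pos_raw, strand = strands_raw,
                       variant = vars, stringsAsFactors = FALSE))
    transforms[[gidx]] <- list(rotation = rot, flipped = flip)
  }
  names(genomes) <- names(proteomes) <- ids
  names(motif_truth) <- names(transforms) <- ids
  orthology <- lapply(seq_len(fspec$proteins_per_genome), function(p)
    sprintf("%s_p%03d", ids, p))
  list(genomes = genomes, proteomes = proteomes,
       truth = list(
         clade_assignment = stats::setNames(
           ifelse(in_clade, "clade", "outgroup"), ids),
         orthology = orthology,
         motifs = motif_truth,
         transforms = transforms))
}
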