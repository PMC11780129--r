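#' Construct a genome object
#'
#' A `Genome` holds one named nucleotide sequence together with its length
#' and base composition. Base frequencies are computed over A/C/G/T only;
#' ambiguous bases (N and other IUPAC codes) are excluded from the
#' denominator so that the composition can feed the motif expectation model.
#'
#' @param id Sequence identifier.
#' @param seq Nucleotide sequence (character scalar). Lowercase is folded to
#'   uppercase and U is mapped to T.
#' @return An object of class `Genome`: a list with elements `id`, `seq`,
#'   `length` and `base_freqs` (named fraction vector over A, C, G, T).
#' @examples
#' g <- genome("g", "ACGT")
#' g$base_freqs
#' @export
genome <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  if (nchar(seq) == 0L)
    stop("genome '", id, "': empty sequence")
  bad <- gsub(paste0("[", paste(names(IUPAC_CODES), collapse = ""), "]"),
              "", seq)
  if (nchar(bad) > 0L)
    stop("genome '", id, "': illegal characters (not IUPAC nucleotide codes): ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = " "))
  counts <- base_counts(seq)
  tot <- sum(counts)
  if (tot == 0L)
    stop("genome '", id, "': no unambiguous A/C/G/T bases")
  structure(list(id = id, seq = seq, length = nchar(seq),
                 base_freqs = counts / tot),
            class = "Genome")
}

base_counts <- function(seq) {
  x <- Biostrings::BString(seq)
  lf <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  stats::setNames(as.numeric(lf), c("A", "C", "G", "T"))
}

#' @export
print.Genome <- function(x, ...) {
  gc <- sum(x$base_freqs[c("G", "C")])
  cat(sprintf("Genome '%s': %d bp, GC %.1f%%\n", x$id, x$length, 100 * gc))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' Sequences are uppercased, U is mapped to T, and any character outside the
#' IUPAC nucleotide alphabet is an error naming the offending record.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named list of [genome()] objects, one per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  gs <- lapply(seq_along(ss), function(i)
    genome(ids[i], as.character(ss[[i]])))
  stats::setNames(gs, ids)
}

#' Write genomes to a FASTA file
#'
#' @param genomes A `Genome` or list of `Genome` objects.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "Genome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(ss) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read CDS annotations from GFF3
#'
#' Reads the CDS features of a GFF3 file for one genome, converting the GFF
#' 1-based inclusive coordinates to the package-internal 0-based half-open
#' convention. Features are sorted by start.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [genome()] object; only features on `genome$id` are kept.
#' @return An `AnnotatedGenome`: list with elements `genome` and `cds`, the
#'   latter a data.frame with columns `start`, `end` (0-based half-open),
#'   `strand`, `product`, `id`.
#' @export
read_gff_cds <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == genome$id]
  if (length(gr) == 0L)
    stop("no CDS features for genome '", genome$id, "' in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol in CDS features: ",
         paste(unique(strand[!strand %in% c("+", "-")]), collapse = " "))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(start0 < 0L) || any(end0 > genome$length))
    stop("CDS feature outside [1, ", genome$length, "] for genome '",
         genome$id, "'")
  product <- if (!is.null(gr$product)) as.character(gr$product) else
    rep(NA_character_, length(gr))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("%s_CDS_%04d", genome$id, seq_along(gr))
  ids[is.na(ids)] <- sprintf("%s_CDS_%04d", genome$id, which(is.na(ids)))
  product[is.na(product)] <- ""
  cds <- data.frame(start = start0, end = end0, strand = strand,
                    product = product, id = ids,
                    stringsAsFactors = FALSE)
  cds <- cds[order(cds$start, cds$end), , drop = FALSE]
  rownames(cds) <- NULL
  annotated_genome(genome, cds)
}

#' Construct an annotated genome
#'
#' @param genome A [genome()] object.
#' @param cds data.frame with columns `start`, `end` (0-based half-open,
#'   within the genome), `strand` (`+`/`-`), `product`, `id`.
#' @return An object of class `AnnotatedGenome`.
#' @export
annotated_genome <- function(genome, cds) {
  stopifnot(inherits(genome, "Genome"), is.data.frame(cds))
  req <- c("start", "end", "strand", "product", "id")
  if (!all(req %in% names(cds)))
    stop("cds must have columns: ", paste(req, collapse = ", "))
  if (nrow(cds) > 0L) {
    if (any(cds$start < 0L) || any(cds$end > genome$length) ||
        any(cds$start >= cds$end))
      stop("CDS intervals must satisfy 0 <= start < end <= genome length")
    if (any(!cds$strand %in% c("+", "-")))
      stop("CDS strand must be '+' or '-'")
    cds <- cds[order(cds$start, cds$end), , drop = FALSE]
    rownames(cds) <- NULL
  }
  structure(list(genome = genome, cds = cds), class = "AnnotatedGenome")
}

#' Write CDS annotations as GFF3
#'
#' Internal 0-based half-open coordinates are written back as GFF3 1-based
#' inclusive, so that [read_gff_cds()] followed by `write_gff_cds()` is an
#' involution on coordinates.
#'
#' @param annotated An `AnnotatedGenome`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff_cds <- function(annotated, path) {
  stopifnot(inherits(annotated, "AnnotatedGenome"))
  cds <- annotated$cds
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     annotated$genome$id, annotated$genome$length))
  if (nrow(cds) > 0L) {
    attr_col <- sprintf("ID=%s;product=%s", cds$id, cds$product)
    lines <- c(lines, sprintf("%s\tphagenick\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              annotated$genome$id, cds$start + 1L, cds$end,
                              cds$strand, attr_col))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a strand coverage object
#'
#' @param genome_id Genome identifier.
#' @param depth_fwd,depth_rev Non-negative integer depth vectors, one value
#'   per genome base, for the forward and reverse strand.
#' @param sample_label `"native"` or `"wga"`.
#' @return An object of class `StrandCoverage`.
#' @export
strand_coverage <- function(genome_id, depth_fwd, depth_rev,
                            sample_label = c("native", "wga")) {
  sample_label <- match.arg(sample_label)
  stopifnot(length(depth_fwd) == length(depth_rev),
            all(depth_fwd >= 0), all(depth_rev >= 0))
  structure(list(genome_id = genome_id,
                 depth_fwd = as.integer(depth_fwd),
                 depth_rev = as.integer(depth_rev),
                 sample_label = sample_label),
            class = "StrandCoverage")
}

# reference-space width of an alignment from its CIGAR (M/D/N/=/X consume)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Load strand-specific per-base depth
#'
#' Accepts either read alignments (SAM or BAM; SAM files are converted on the
#' fly) or a precomputed depth table (TSV with columns `pos`, `depth_fwd`,
#' `depth_rev`, `pos` 0-based). From alignments, a read contributes +1 to
#' every reference base it spans (CIGAR reference space), on the strand given
#' by its alignment orientation; secondary and supplementary alignments are
#' excluded. Long reads are treated as single-end; no pairing logic.
#'
#' @param source Path to a `.sam`, `.bam` or `.tsv` file.
#' @param genome A [genome()] object the alignments/table refer to.
#' @param sample_label `"native"` or `"wga"`.
#' @param min_mapq Minimum mapping quality; default 0 keeps everything
#'   (small non-repetitive phage genomes rarely need a MAPQ filter).
#' @return A [strand_coverage()] object.
#' @export
load_strand_coverage <- function(source, genome,
                                 sample_label = c("native", "wga"),
                                 min_mapq = 0L) {
  sample_label <- match.arg(sample_label)
  if (!file.exists(source)) stop("file not found: ", source)
  ext <- tolower(tools::file_ext(source))
  if (ext == "tsv") {
    tab <- utils::read.table(source, header = TRUE, sep = "\t",
                             comment.char = "#")
    req <- c("pos", "depth_fwd", "depth_rev")
    if (!all(req %in% names(tab)))
      stop("depth TSV must have columns: ", paste(req, collapse = ", "))
    if (nrow(tab) != genome$length)
      stop("depth TSV has ", nrow(tab), " rows but genome '", genome$id,
           "' is ", genome$length, " bp")
    tab <- tab[order(tab$pos), ]
    return(strand_coverage(genome$id, tab$depth_fwd, tab$depth_rev,
                           sample_label))
  }
  bam <- source
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(source, dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, mapqFilter = min_mapq,
    what = c("rname", "pos", "cigar", "strand"))
  aln <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(aln$pos)
  rname <- as.character(aln$rname)[keep]
  if (length(rname) > 0L && any(rname != genome$id))
    stop("reference-name mismatch: alignments reference '",
         unique(rname[rname != genome$id])[1], "' but genome is '",
         genome$id, "'")
  pos <- aln$pos[keep]
  w <- cigar_ref_width(aln$cigar[keep])
  strand <- as.character(aln$strand)[keep]
  depth_for <- function(sel) {
    if (!any(sel)) return(integer(genome$length))
    ir <- IRanges::IRanges(start = pos[sel], width = w[sel])
    ir <- IRanges::restrict(ir, start = 1L, end = genome$length)
    as.integer(IRanges::coverage(ir, width = genome$length))
  }
  strand_coverage(genome$id,
                  depth_for(strand == "+"),
                  depth_for(strand == "-"),
                  sample_label)
}

#' Write a strand depth table as TSV
#'
#' Columns `pos` (0-based), `depth_fwd`, `depth_rev`; round-trips exactly
#' through [load_strand_coverage()].
#'
#' @param cov A [strand_coverage()] object.
#' @param path Output path (should end in `.tsv`).
#' @return Invisibly, `path`.
#' @export
write_depth_tsv <- function(cov, path) {
  stopifnot(inherits(cov, "StrandCoverage"))
  tab <- data.frame(pos = seq_along(cov$depth_fwd) - 1L,
                    depth_fwd = cov$depth_fwd,
                    depth_rev = cov$depth_rev)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write nick calls as BED6
#'
#' 0-based half-open intervals, one record per call; the strand column is the
#' nicked (depleted) strand and the score column is the motif-association
#' flag (1/0, or `.` when association was not assessed).
#'
#' @param calls A data.frame of nick calls (see [associate_motif_hits()]),
#'   or of drop intervals (see [detect_drops()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_nick_bed <- function(calls, path) {
  lines <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(calls) > 0L) {
    score <- if ("motif_associated" %in% names(calls))
      as.character(as.integer(calls$motif_associated))
    else rep(".", nrow(calls))
    lines <- c(lines, sprintf("%s\t%d\t%d\t.\t%s\t%s",
                              calls$genome_id, calls$start, calls$end,
                              score, calls$strand))
  }
  writeLines(lines, path)
  invisible(path)
}
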