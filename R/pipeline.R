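# end-to-end orchestration: nick analysis on one genome, family surveys
# across a genome collection, and synthetic bundle writers

pkg_header <- function() {
  sprintf("# phagenick %s | %s",
          as.character(utils::packageVersion("phagenick")),
          format(Sys.time(), "%Y-%m-%d"))
}

prepare_outdir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    stop("output directory ", out_dir,
         " is not empty; use force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_dir
}

write_tsv_report <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(), con)
  if (!is.null(params))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(x) paste(format(x),
                                                        collapse = ","), "")),
               con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

rolling_mean <- function(x, window) {
  if (window <= 1L) return(as.numeric(x))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- window %/% 2L
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Run the full nick analysis on one genome
#'
#' Loads the genome, native and control coverage (SAM/BAM or depth TSV),
#' detects one-strand coverage drops, scans for the motif, associates drops
#' with motif hits, and (when an annotation is given) computes positional
#' statistics. Writes `nicks.bed`, `motif_stats.tsv`, `depth_native.tsv`,
#' `depth_smoothed.tsv` (rolling mean, default window 1000 bp),
#' `positions.tsv` (if annotated), `report.json` and `summary.txt` into
#' `out_dir`. Outputs are byte-reproducible given identical inputs. On any
#' error, partial outputs are removed.
#'
#' @param fasta Genome FASTA path (first record is analysed).
#' @param native,control Native / WGA alignments (`.sam`/`.bam`) or depth
#'   tables (`.tsv`).
#' @param gff Optional GFF3 with CDS features.
#' @param pattern IUPAC motif pattern (default `"WACTRTGAC"`).
#' @param out_dir Output directory.
#' @param params A [drop_params()] list.
#' @param window Motif-association window in bp.
#' @param smooth_window Rolling-mean window for the smoothed depth table.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the [nick_report()] list.
#' @export
run_nick_analysis <- function(fasta, native, control, gff = NULL,
                              pattern = "WACTRTGAC", out_dir,
                              params = drop_params(), window = 50,
                              smooth_window = 1000L, force = FALSE) {
  for (f in c(fasta, native, control, gff))
    if (!file.exists(f)) stop("input file not found: ", f)
  prepare_outdir(out_dir, force)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("nick analysis failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    g <- read_fasta(fasta)[[1]]
    cov_n <- load_strand_coverage(native, g, "native")
    cov_c <- load_strand_coverage(control, g, "wga")
    motif <- iupac_motif(pattern)
    intervals <- detect_drops(cov_n, cov_c, params)
    hits <- scan_genome(g, motif)
    calls <- associate_motif_hits(intervals, hits, window)
    stats <- strand_stats(hits, g, motif)
    report <- nick_report(calls, stats)

    p <- file.path(out_dir, "nicks.bed")
    write_nick_bed(calls, p); written <- c(written, p)
    p <- file.path(out_dir, "motif_stats.tsv")
    write_tsv_report(stats, p, list(pattern = pattern)); written <- c(written, p)
    p <- file.path(out_dir, "depth_native.tsv")
    write_depth_tsv(cov_n, p); written <- c(written, p)
    sm <- data.frame(pos = seq_len(g$length) - 1L,
                     native_fwd = round(rolling_mean(cov_n$depth_fwd,
                                                     smooth_window), 3),
                     native_rev = round(rolling_mean(cov_n$depth_rev,
                                                     smooth_window), 3),
                     wga_fwd = round(rolling_mean(cov_c$depth_fwd,
                                                  smooth_window), 3),
                     wga_rev = round(rolling_mean(cov_c$depth_rev,
                                                  smooth_window), 3))
    p <- file.path(out_dir, "depth_smoothed.tsv")
    write_tsv_report(sm, p, list(window = smooth_window))
    written <- c(written, p)
    if (!is.null(gff)) {
      ann <- read_gff_cds(gff, g)
      posrec <- cds_relative_position(hits, ann)
      p <- file.path(out_dir, "positions.tsv")
      write_tsv_report(posrec, p); written <- c(written, p)
    }
    p <- file.path(out_dir, "report.json")
    jsonlite::write_json(report[names(report) != "motif_stats"], p,
                         auto_unbox = TRUE, digits = NA, na = "null")
    written <- c(written, p)
    summary_lines <- c(
      pkg_header(),
      sprintf("genome: %s (%d bp)", g$id, g$length),
      sprintf("nick intervals: %d (+: %d, -: %d)", report$n_intervals,
              report$n_intervals_fwd, report$n_intervals_rev),
      sprintf("motif %s hits: %d (+: %d, -: %d), net %d, expected %.3f",
              pattern, stats$n_fwd + stats$n_rev, stats$n_fwd, stats$n_rev,
              stats$net, stats$expected_per_strand),
      sprintf("motif-associated intervals: %d (fraction %s)",
              report$n_motif_associated,
              format(report$frac_intervals_associated)),
      sprintf("hits with an associated drop: fraction %s",
              format(report$frac_hits_associated)))
    p <- file.path(out_dir, "summary.txt")
    writeLines(summary_lines, p); written <- c(written, p)
    invisible(report)
  }, error = on_fail)
}

#' Survey a genome family: wGRR, clustering and motif conservation
#'
#' Computes per-genome motif strand statistics, the all-pairs wGRR matrix,
#' hierarchical clustering at `cut`, the within/outside-cluster net-motif
#' contrast around a focal genome, and positional statistics on
#' terL-reoriented coordinates for annotated genomes. Genomes lacking a
#' recognisable terL CDS are excluded from positional output with a warning
#' rather than an error.
#'
#' @param genomes Named list of `AnnotatedGenome` (or bare `Genome`)
#'   objects.
#' @param proteomes Named list of [protein_set()] objects (same names).
#' @param pattern IUPAC motif pattern.
#' @param focal Focal genome id (default: first genome).
#' @param cut wGRR clustering threshold.
#' @param out_dir Optional output directory; when given, writes
#'   `wgrr_matrix.tsv` (with leaf order), `clusters.tsv`,
#'   `motif_stats.tsv`, `positions.tsv` and `summary.json`.
#' @param force Overwrite a non-empty output directory.
#' @return List: `stats` (per-genome strand stats), `matrix`, `clusters`,
#'   `summary` (cluster motif contrast), `positions` (terL-reoriented
#'   positional records).
#' @export
run_family_survey <- function(genomes, proteomes, pattern = "WACTRTGAC",
                              focal = NULL, cut = 0.5, out_dir = NULL,
                              force = FALSE) {
  motif <- iupac_motif(pattern)
  bare <- lapply(genomes, function(g)
    if (inherits(g, "AnnotatedGenome")) g$genome else g)
  ids <- vapply(bare, `[[`, "", "id")
  if (is.null(focal)) focal <- ids[1]
  stats <- do.call(rbind, lapply(seq_along(bare), function(i) {
    hits <- scan_genome(bare[[i]], motif)
    strand_stats(hits, bare[[i]], motif)
  }))
  mat <- wgrr_matrix(proteomes)
  clusters <- cluster_genomes(mat, cut = cut)
  summary <- if (length(bare) > 1L)
    cluster_motif_summary(clusters$assignment, stats, focal) else
    list(within_mean = stats$net[1], outside_mean = NA_real_,
         n_within = 1L, n_outside = 0L, focal_cluster = 1L)
  positions <- list()
  for (i in seq_along(genomes)) {
    ann <- genomes[[i]]
    if (!inherits(ann, "AnnotatedGenome") || nrow(ann$cds) == 0L) next
    reo <- tryCatch(reorient_to_terl(ann), error = function(e) e)
    if (inherits(reo, "error")) {
      warning("genome '", ids[i], "' excluded from positional output: ",
              conditionMessage(reo), call. = FALSE)
      next
    }
    hits_r <- scan_genome(reo$annotated$genome, motif)
    positions[[ids[i]]] <- cds_relative_position(hits_r, reo$annotated)
  }
  pos_df <- if (length(positions) > 0L) do.call(rbind, positions) else
    cds_relative_position(
      data.frame(genome_id = character(0), start = integer(0),
                 strand = character(0), matched = character(0)),
      annotated_genome(bare[[1]],
                       data.frame(start = integer(0), end = integer(0),
                                  strand = character(0),
                                  product = character(0),
                                  id = character(0))))
  rownames(pos_df) <- NULL
  res <- list(stats = stats, matrix = mat, clusters = clusters,
              summary = summary, positions = pos_df)
  if (!is.null(out_dir)) {
    prepare_outdir(out_dir, force)
    mat_df <- data.frame(genome_id = rownames(mat),
                         as.data.frame(unclass(mat)), check.names = FALSE)
    write_tsv_report(mat_df, file.path(out_dir, "wgrr_matrix.tsv"),
                     list(leaf_order = paste(clusters$order,
                                             collapse = ",")))
    write_tsv_report(
      data.frame(genome_id = names(clusters$assignment),
                 cluster = as.integer(clusters$assignment)),
      file.path(out_dir, "clusters.tsv"), list(cut = cut))
    write_tsv_report(stats, file.path(out_dir, "motif_stats.tsv"),
                     list(pattern = pattern))
    write_tsv_report(pos_df, file.path(out_dir, "positions.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}

#' Write a complete synthetic nicked-genome bundle to disk
#'
#' Writes `genome.fa`, `annotation.gff3`, `native.sam`, `wga.sam`,
#' `native_depth.tsv`, `wga_depth.tsv` and `truth.json`.
#'
#' @param spec A [simulation_spec()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, a list with the simulation objects (`genome`,
#'   `truth`, `reads`, `annotation`).
#' @export
write_nicked_bundle <- function(spec, out_dir, force = FALSE) {
  prepare_outdir(out_dir, force)
  sim <- make_genome(spec)
  ann <- make_annotation(sim$genome, spec$coding_density_target, spec$seed)
  reads <- simulate_reads(sim$genome, sim$truth, spec)
  write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_gff_cds(ann, file.path(out_dir, "annotation.gff3"))
  write_sam(reads$native, sim$genome, file.path(out_dir, "native.sam"),
            error_rate = spec$error_rate)
  write_sam(reads$control, sim$genome, file.path(out_dir, "wga.sam"),
            error_rate = spec$error_rate)
  write_depth_tsv(coverage_from_reads(reads$native, sim$genome, "native"),
                  file.path(out_dir, "native_depth.tsv"))
  write_depth_tsv(coverage_from_reads(reads$control, sim$genome, "wga"),
                  file.path(out_dir, "wga_depth.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(list(genome = sim$genome, truth = sim$truth, reads = reads,
                 annotation = ann))
}

#' Write a complete synthetic family bundle to disk
#'
#' Per genome: `<id>.fa`, `<id>.gff3`, `<id>_proteins.faa`; plus
#' `truth.json`.
#'
#' @param fspec A [family_spec()].
#' @param seed RNG seed.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the [make_family()] result.
#' @export
write_family_bundle <- function(fspec, seed, out_dir, force = FALSE) {
  prepare_outdir(out_dir, force)
  fam <- make_family(fspec, seed)
  for (id in names(fam$genomes)) {
    write_fasta(fam$genomes[[id]]$genome, file.path(out_dir,
                                                    paste0(id, ".fa")))
    write_gff_cds(fam$genomes[[id]], file.path(out_dir,
                                               paste0(id, ".gff3")))
    write_protein_fasta(fam$proteomes[[id]],
                        file.path(out_dir, paste0(id, "_proteins.faa")))
  }
  jsonlite::write_json(fam$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(fam)
}
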