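# Plain-text I/O for the pipeline's external formats: FASTA (60-column),
# FASTQ (Phred+33, constant quality), BED3/BED6 (0-based half-open,
# sorted), and TSV tables with a header row.

#' Write a simulated locus to files
#'
#' Writes the genome FASTA (wrapped at 60 columns), the viewpoint TSV, one
#' FASTQ per replicate (Phred+33, constant Q35) and the truth record (a
#' key-value TSV plus a planted-peak TSV).
#'
#' @param sim A [simulate_locus()] result with reads.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_locus_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "locus_sim"))
  if (is.null(sim$reads)) stop("simulation was run without reads")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             viewpoint = file.path(dir, "viewpoint.tsv"),
             truth_params = file.path(dir, "truth_params.tsv"),
             truth_peaks = file.path(dir, "truth_peaks.tsv"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]], width = 60L)
  write_tsv_plain(sim$viewpoint, paths[["viewpoint"]])
  scn <- sim$scenario
  kv <- tibble::tibble(
    key = c("name", "genome_length", "viewpoint_position", "decay_exponent",
            "dispersion", "n_replicates", "reads_per_replicate", "seed"),
    value = as.character(c(scn$name, scn$genome_length,
                           scn$viewpoint_position, scn$decay_exponent,
                           scn$dispersion, scn$n_replicates,
                           scn$reads_per_replicate, scn$seed)))
  write_tsv_plain(kv, paths[["truth_params"]])
  write_tsv_plain(sim$truth$peaks, paths[["truth_peaks"]])
  for (r in names(sim$reads)) {
    fq <- file.path(dir, paste0(scn$name, "_", r, ".fastq"))
    write_fastq(sim$reads[[r]], fq, prefix = paste0(scn$name, "_", r))
    paths[[r]] <- fq
  }
  invisible(paths)
}

#' Write reads as FASTQ (Phred+33, constant Q35)
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param prefix Read-name prefix.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  qual <- strrep(rawToChar(as.raw(33L + 35L)), nchar(reads))
  lines <- character(4L * length(reads))
  idx <- seq_along(reads)
  lines[4L * idx - 3L] <- paste0("@", prefix, "_", idx)
  lines[4L * idx - 2L] <- reads
  lines[4L * idx - 1L] <- "+"
  lines[4L * idx] <- qual
  writeLines(lines, path)
  invisible(path)
}

#' Write an interval tibble as BED
#'
#' BED3 (or BED6 when `name`/`score` columns are present), 0-based
#' half-open, sorted by chromosome and start.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  tb <- dplyr::arrange(tibble::as_tibble(intervals), .data$chrom, .data$start)
  stopifnot(all(tb$start >= 0), all(tb$end >= tb$start))
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(tb)) {
    tb$score_out <- if ("score" %in% names(tb)) tb$score else 0
    tb$strand_out <- if ("strand" %in% names(tb)) tb$strand else "."
    out <- tb[, c(cols, "name", "score_out", "strand_out")]
  } else {
    out <- tb[, cols]
  }
  out <- as.data.frame(lapply(out, function(col) {
    if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE) else col
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ file into an interval tibble
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end` (+ `name`, `score`, `strand` if
#'   present).
#' @export
read_bed <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(tb) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(tb))]
  tibble::as_tibble(tb)
}

#' Write contact peaks as BED6 and a statistics TSV
#'
#' BED names are `gene:peakN`; BED scores are `-10 * log10(min q)`,
#' capped at 1000.
#'
#' @param peaks A `contact_peaks` object.
#' @param bed_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_peaks <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  pk <- peaks$peaks
  if (!is.null(bed_path)) {
    bed <- tibble::tibble(chrom = pk$chrom, start = pk$start, end = pk$end,
                          name = pk$peak_id,
                          score = pmin(1000, round(-10 * log10(pmax(pk$min_q, 1e-100)))))
    write_bed(bed, bed_path)
  }
  if (!is.null(tsv_path)) write_tsv_plain(pk, tsv_path)
  invisible(c(bed = bed_path, tsv = tsv_path))
}

write_tsv_plain <- function(tb, path) {
  tb <- as.data.frame(tb)
  tb <- tb[, !vapply(tb, is.list, logical(1)), drop = FALSE]
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
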