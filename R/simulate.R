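# Synthetic-data generator: every input the pipeline consumes, with the
# statistical structure the analysis assumes. Reads are structured exactly
# like real 4C reads (reading primer ending in the primary motif, then the
# captured fragment-end sequence across the ligation junction), captured
# fragment ends are drawn with probability proportional to
# distance^(-decay) times the planted enrichment, and replicate counts are
# negative-binomially jittered.

# random ACGT chromosome with restriction motifs seeded at controlled mean
# spacing so fragment density never depends on the random background
generate_chromosome <- function(len, primary_motif, secondary_motif, gseed,
                                mean_primary = 300, mean_secondary = 120) {
  set.seed(gseed)
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  plant <- function(base, motif, mean_gap) {
    ml <- nchar(motif)
    gaps <- pmax(ml + 2, round(stats::runif(ceiling(len / mean_gap) * 2,
                                            0.5, 1.5) * mean_gap))
    pos <- cumsum(gaps)
    pos <- pos[pos + ml - 1 <= len - 10 & pos > 10]
    if (length(pos) == 0) return(base)
    idx <- rep(pos, each = ml) + rep(seq_len(ml) - 1L, times = length(pos))
    base[idx] <- rep(strsplit(motif, "")[[1]], times = length(pos))
    base
  }
  base <- plant(base, secondary_motif, mean_secondary)
  base <- plant(base, primary_motif, mean_primary)
  paste(base, collapse = "")
}

# Deterministic genome for a scenario (shared across reciprocal viewpoints
# through genome_seed). Decoy chromosomes, if requested, are plain random.
scenario_genome <- function(scn) {
  chroms <- stats::setNames(vector("list", scn$n_chromosomes),
                            c(scn$chrom,
                              if (scn$n_chromosomes > 1)
                                paste0(scn$chrom, "_decoy", seq_len(scn$n_chromosomes - 1L))))
  chroms[[scn$chrom]] <- generate_chromosome(
    scn$genome_length, scn$primary_motif, scn$secondary_motif, scn$genome_seed)
  if (scn$n_chromosomes > 1) {
    for (i in seq_len(scn$n_chromosomes - 1L)) {
      chroms[[i + 1L]] <- generate_chromosome(
        max(1e5, scn$genome_length / 10), scn$primary_motif,
        scn$secondary_motif, derive_seed(scn$genome_seed, paste0("decoy", i)))
    }
  }
  Biostrings::DNAStringSet(unlist(chroms))
}

#' Simulate a 4C viewpoint experiment
#'
#' Generates the toy genome, digests it, builds the unique fragment-end
#' map, derives the viewpoint reading primer from the viewpoint fragment's
#' cut site, and samples per-replicate reads. Each read is the reading
#' primer (terminating in the primary motif) followed by the captured
#' fragment-end sequence across the ligation junction, so the demultiplexer
#' and quantifier see data with the same structure as a real run.
#'
#' Captured fragment ends are drawn among unique, informative (non-blind)
#' cis fragment ends with probability proportional to
#' `distance^(-decay_exponent)` times the planted enrichment; the viewpoint
#' fragment and its two neighbours (self-ligation territory) are not
#' sampled. Per-replicate counts are negative-binomial around the expected
#' allocation of `reads_per_replicate`.
#'
#' @param scenario A [locus_scenario()].
#' @param genome,map Optional precomputed genome/fragment-end map (must
#'   match the scenario's `genome_seed`); avoids regeneration when several
#'   viewpoints share one genome.
#' @param emit_reads If `FALSE`, skip read-string assembly and return only
#'   the per-end truth counts (fast path for simulation studies; the read
#'   path is exercised by the full pipeline).
#' @return A list of class `locus_sim`: `scenario`, `genome`, `fragments`,
#'   `map`, `viewpoint` (one-row tibble: gene, reading_primer, chrom,
#'   start, end, primary, secondary), `reads` (named list of character
#'   vectors per replicate, or `NULL`), and `truth` (planted peaks plus the
#'   per-end per-replicate sampled counts).
#' @export
simulate_locus <- function(scenario, genome = NULL, map = NULL,
                           emit_reads = TRUE) {
  scn <- validate_locus_scenario(scenario)
  if (is.null(genome)) genome <- scenario_genome(scn)
  primary <- restriction_enzyme("primary", scn$primary_motif)
  secondary <- restriction_enzyme("secondary", scn$secondary_motif)
  fragments <- digest_genome(genome, primary)
  if (is.null(map)) {
    map <- build_fragment_end_map(fragments, genome, secondary,
                                  end_length = 36L, primary = primary)
  }
  mlen <- nchar(scn$primary_motif)
  chr_frags <- fragments[fragments$chrom == scn$chrom, ]
  vp_row <- chr_frags[chr_frags$start <= scn$viewpoint_position &
                        scn$viewpoint_position < chr_frags$end, ]
  if (nrow(vp_row) != 1L) stop("viewpoint position does not fall in a fragment")
  vp_idx <- vp_row$frag_index

  # reading primer: last (primer_length - motif) bases of the viewpoint
  # fragment plus the motif of the downstream cut site
  p_start <- vp_row$end - (scn$primer_length - mlen)
  if (p_start < 0) stop("viewpoint fragment shorter than the reading primer")
  primer <- as.character(Biostrings::extractAt(
    genome[[scn$chrom]],
    IRanges::IRanges(start = p_start + 1L, end = vp_row$end + mlen))[[1L]])
  stopifnot(endsWith(primer, scn$primary_motif))

  viewpoint <- tibble::tibble(
    gene = scn$name, reading_primer = primer, chrom = scn$chrom,
    start = vp_row$start, end = vp_row$end,
    primary = scn$primary_motif, secondary = scn$secondary_motif
  )

  # sampling pool: unique informative cis ends outside self-ligation
  # territory, whose extended read window fits the chromosome
  ext_len <- scn$read_length - scn$primer_length + mlen
  chr_len <- scn$genome_length
  pool <- map[map$chrom == scn$chrom & map$unique & map$has_secondary_site &
                !(map$frag_index %in% (vp_idx + (-1:1))), ]
  fits <- ifelse(pool$side == "left",
                 pool$frag_start + ext_len <= chr_len,
                 pool$frag_end - (ext_len - mlen) >= 0 &
                   pool$frag_end + mlen <= chr_len)
  pool <- pool[fits, ]

  dist <- pmax(abs(pool$pos - scn$viewpoint_position), 1)
  enr <- rep(1, nrow(pool))
  pk <- scn$planted_peaks
  if (nrow(pk) > 0) {
    for (i in seq_len(nrow(pk))) {
      inside <- pool$pos >= pk$start[i] & pool$pos < pk$end[i]
      enr[inside] <- pk$enrichment[i]
    }
  }
  p <- dist^(-scn$decay_exponent) * enr
  mu <- scn$reads_per_replicate * p / sum(p)

  counts <- matrix(0L, nrow = nrow(pool), ncol = scn$n_replicates)
  for (r in seq_len(scn$n_replicates)) {
    set.seed(derive_seed(scn$seed, paste0("reads_rep", r, "_vp",
                                          scn$viewpoint_position)))
    counts[, r] <- stats::rnbinom(nrow(pool), mu = mu, size = 1 / scn$dispersion)
  }

  reads <- NULL
  if (emit_reads) {
    # extended end sequence = full read payload after the primer, plus the
    # shared junction motif at its start
    left <- pool$side == "left"
    starts <- ifelse(left, pool$frag_start + 1L,
                     pool$frag_end - (ext_len - mlen) + 1L)
    ends <- ifelse(left, pool$frag_start + ext_len, pool$frag_end + mlen)
    wins <- Biostrings::extractAt(genome[[scn$chrom]],
                                  IRanges::IRanges(start = starts, end = ends))
    wins[!left] <- Biostrings::reverseComplement(wins[!left])
    payload <- substr(as.character(wins), mlen + 1L, ext_len)
    read_seq <- paste0(primer, payload)
    reads <- lapply(seq_len(scn$n_replicates), function(r) {
      rep(read_seq, counts[, r])
    })
    names(reads) <- paste0("rep", seq_len(scn$n_replicates))
  }

  end_counts <- tibble::as_tibble(cbind(
    pool[, c("chrom", "frag_index", "side", "pos")],
    stats::setNames(as.data.frame(counts),
                    paste0("rep", seq_len(scn$n_replicates)))
  ))
  end_counts$expected <- mu

  truth <- list(
    peaks = scn$planted_peaks,
    end_counts = end_counts,
    reads_per_replicate = scn$reads_per_replicate,
    n_replicates = scn$n_replicates,
    seed = scn$seed
  )

  structure(list(scenario = scn, genome = genome, fragments = fragments,
                 map = map, viewpoint = viewpoint, reads = reads,
                 truth = truth),
            class = "locus_sim")
}

#' @export
print.locus_sim <- function(x, ...) {
  cat(sprintf("<locus_sim> %s: %d fragment(s), %d replicate(s)%s\n",
              x$scenario$name, nrow(x$fragments), x$scenario$n_replicates,
              if (is.null(x$reads)) " (truth counts only)" else
                sprintf(", ~%g reads/replicate", x$scenario$reads_per_replicate)))
  invisible(x)
}

#' Simulate epigenomic interval tracks for a locus scenario
#'
#' Planted peaks whose index is in `track_overlap_indices` receive a
#' sub-interval covered by ATAC, DNase and H3K27ac (staggered so the three
#' assays corroborate but do not coincide); other peaks receive none. The
#' TAD track partitions the chromosome at `tad_boundaries`. All intervals
#' are 0-based half-open and sorted.
#'
#' @param scenario A [locus_scenario()].
#' @return A list of class `epigenome_tracks` with tibbles `atac`, `dnase`,
#'   `h3k27ac`, `tads` (columns `chrom`, `start`, `end`).
#' @export
simulate_tracks <- function(scenario) {
  scn <- validate_locus_scenario(scenario)
  pk <- scn$planted_peaks[scn$track_overlap_indices, , drop = FALSE]
  mk <- function(f1, f2) {
    if (nrow(pk) == 0) {
      return(tibble::tibble(chrom = character(0), start = numeric(0),
                            end = numeric(0)))
    }
    w <- pk$end - pk$start
    dplyr::arrange(tibble::tibble(chrom = scn$chrom,
                                  start = round(pk$start + f1 * w),
                                  end = round(pk$start + f2 * w)),
                   .data$start)
  }
  bounds <- unique(c(0, scn$tad_boundaries, scn$genome_length))
  tads <- tibble::tibble(chrom = scn$chrom,
                         start = bounds[-length(bounds)],
                         end = bounds[-1])
  structure(list(
    atac = mk(0.20, 0.70),
    dnase = mk(0.30, 0.80),
    h3k27ac = mk(0.25, 0.75),
    tads = tads
  ), class = "epigenome_tracks")
}

#' Simulate assay data: luciferase wells, SNP-array probes, qPCR Ct values
#'
#' Luciferase: 3 independent experiments x 3 wells per construct; the
#' normalized activity (firefly/renilla) of each construct is lognormal
#' around `planted fold change x negative-control level`, with a shared
#' per-experiment transfection-efficiency factor that pairing against the
#' within-experiment negative control removes. Probe array: uniformly
#' spaced probes, `probes_inside_deletion` of them inside the planted
#' deletion with logR shifted by `logR_shift`. Ct table: planted expression
#' ratios encoded against two housekeeping genes.
#'
#' @param scenario An [assay_scenario()].
#' @return A list of class `assay_sim` with tibbles `wells` (construct,
#'   experiment, firefly, renilla), `probes` (id, chrom, pos, logR, BAF),
#'   `cts` (sample, target, replicate, ct) and a `truth` list of the
#'   planted values.
#' @export
simulate_assays <- function(scenario) {
  scn <- validate_assay_scenario(scenario)
  set.seed(derive_seed(scn$seed, "assays"))
  sdlog <- sqrt(log(1 + scn$luciferase_cv^2))

  folds <- scn$construct_fold_changes
  if (!scn$negative_control %in% names(folds)) {
    folds <- c(folds, stats::setNames(1, scn$negative_control))
  }
  wells <- tidyr::expand_grid(
    construct = names(folds), experiment = 1:3, well = 1:3)
  exp_eff <- stats::setNames(c(1, 0.8, 1.25), 1:3) # transfection efficiency
  renilla <- if (sdlog > 0) stats::rlnorm(nrow(wells), log(1000), sdlog) else
    rep(1000, nrow(wells))
  noise <- if (sdlog > 0)
    stats::rlnorm(nrow(wells), -sdlog^2 / 2, sdlog) else rep(1, nrow(wells))
  wells <- dplyr::mutate(
    wells,
    renilla = renilla,
    firefly = renilla * exp_eff[as.character(.data$experiment)] *
      folds[.data$construct] * noise
  )
  wells <- dplyr::select(wells, "construct", "experiment", "firefly", "renilla")

  probes <- tibble::tibble(id = character(0), chrom = character(0),
                           pos = numeric(0), logR = numeric(0),
                           BAF = numeric(0))
  del_truth <- NULL
  if (!is.null(scn$deletion_interval)) {
    d <- scn$deletion_interval
    k <- scn$probes_inside_deletion
    first_inside <- d$start + scn$probe_spacing / 2
    inside <- first_inside + (seq_len(k) - 1) * scn$probe_spacing
    if (k > 0 && any(inside >= d$end)) {
      stop("deletion interval too narrow for the requested probes")
    }
    nf <- scn$n_flanking_probes
    left <- first_inside - seq_len(nf) * scn$probe_spacing
    right_anchor <- if (k > 0) inside[k] else first_inside
    right <- right_anchor + seq_len(nf + 5L) * scn$probe_spacing
    right <- right[right >= d$end][seq_len(nf)] # flanking probes stay outside
    pos <- sort(c(left[left >= 1], inside, right))
    affected <- pos >= d$start & pos < d$end
    probes <- tibble::tibble(
      id = sprintf("synprobe_%05d", seq_along(pos)),
      chrom = d$chrom,
      pos = pos,
      logR = stats::rnorm(length(pos), 0, scn$logR_noise_sd) +
        ifelse(affected, scn$logR_shift, 0),
      BAF = round(stats::runif(length(pos)), 3)
    )
    del_truth <- list(interval = d, n_probes_inside = sum(affected))
  }

  samples <- names(scn$ct_effects)
  if (!scn$ct_reference %in% samples) {
    samples <- c(scn$ct_reference, samples)
    scn$ct_effects <- c(stats::setNames(1, scn$ct_reference), scn$ct_effects)
  }
  base_ct <- c(25, stats::setNames(c(20, 22), scn$ct_housekeeping))
  cts <- tidyr::expand_grid(sample = samples,
                            target = c(scn$ct_target, scn$ct_housekeeping),
                            replicate = 1:3)
  ref_ratio <- scn$ct_effects[[scn$ct_reference]]
  cts <- dplyr::mutate(
    cts,
    ct = ifelse(.data$target == scn$ct_target,
                base_ct[[1]] - log2(scn$ct_effects[.data$sample] / ref_ratio),
                base_ct[.data$target]) +
      stats::rnorm(dplyr::n(), 0, scn$ct_noise_sd)
  )

  structure(list(
    wells = wells, probes = probes, cts = cts,
    truth = list(construct_fold_changes = folds,
                 deletion = del_truth,
                 ct_effects = scn$ct_effects,
                 ct_reference = scn$ct_reference,
                 seed = scn$seed)
  ), class = "assay_sim")
}
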