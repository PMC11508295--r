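# Scenario definitions for the synthetic-data generator.
#
# A locus scenario describes one viewpoint experiment on a toy chromosome:
# where the viewpoint sits, which contact peaks are planted on top of the
# power-law distance decay, how noisy the replicates are, which planted
# peaks are covered by open-chromatin/H3K27ac tracks, and where the TAD
# boundaries lie. The bundled fixtures reproduce the per-gene architecture
# of the four SCA loci studied with this pipeline (number of contact peaks,
# number of putative enhancers, which reciprocal interactions confirm, and
# the reporter fold changes).

#' Define a synthetic 4C locus scenario
#'
#' @param name Scenario label.
#' @param genome_length Chromosome length in bp.
#' @param n_chromosomes Number of chromosomes (contacts are cis-only; decoy
#'   chromosomes beyond the first carry no signal).
#' @param chrom Name of the viewpoint chromosome.
#' @param primary_motif,secondary_motif Restriction motifs (ACGT).
#' @param viewpoint_position Viewpoint position in bp (0-based).
#' @param planted_peaks Tibble/data.frame with columns `start`, `end`
#'   (0-based half-open bp) and `enrichment` (>= 1): regions of elevated
#'   contact planted on the decay background.
#' @param decay_exponent Power-law exponent of contact decay with distance
#'   (> 0).
#' @param dispersion Negative-binomial overdispersion of replicate counts
#'   (> 0; variance = mu + dispersion * mu^2).
#' @param n_replicates Number of biological replicates.
#' @param reads_per_replicate Target read depth per replicate.
#' @param track_overlap_indices Indices (1-based, into `planted_peaks`) of
#'   peaks that receive ATAC + DNase + H3K27ac cover and hence become
#'   putative enhancers downstream.
#' @param tad_boundaries Sorted bp positions partitioning the chromosome
#'   into TADs.
#' @param seed Integer seed driving all randomness of the scenario.
#' @param genome_seed Optional separate seed for the genome sequence, so
#'   that several scenarios (e.g. reciprocal viewpoints) share one genome.
#' @param read_length Read length in bp (default 75, single-end).
#' @param primer_length Reading-primer length in bp (default 20; the primer
#'   terminates in the primary motif).
#' @return A validated list of class `locus_scenario`.
#' @export
locus_scenario <- function(name,
                           genome_length = 2e6,
                           n_chromosomes = 1L,
                           chrom = "chrS",
                           primary_motif = "CATG",
                           secondary_motif = "GATC",
                           viewpoint_position = genome_length / 2,
                           planted_peaks = NULL,
                           decay_exponent = 1,
                           dispersion = 0.05,
                           n_replicates = 3L,
                           reads_per_replicate = 5e5,
                           track_overlap_indices = integer(0),
                           tad_boundaries = numeric(0),
                           seed = 1L,
                           genome_seed = NULL,
                           read_length = 75L,
                           primer_length = 20L) {
  if (is.null(planted_peaks)) {
    planted_peaks <- tibble::tibble(start = numeric(0), end = numeric(0),
                                    enrichment = numeric(0))
  }
  planted_peaks <- tibble::as_tibble(planted_peaks)
  scn <- structure(list(
    name = name,
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    chrom = chrom,
    primary_motif = toupper(primary_motif),
    secondary_motif = toupper(secondary_motif),
    viewpoint_position = as.numeric(viewpoint_position),
    planted_peaks = planted_peaks,
    decay_exponent = decay_exponent,
    dispersion = dispersion,
    n_replicates = as.integer(n_replicates),
    reads_per_replicate = as.numeric(reads_per_replicate),
    track_overlap_indices = as.integer(track_overlap_indices),
    tad_boundaries = as.numeric(tad_boundaries),
    seed = as.integer(seed),
    genome_seed = if (is.null(genome_seed)) derive_seed(seed, "genome") else
      as.integer(genome_seed),
    read_length = as.integer(read_length),
    primer_length = as.integer(primer_length)
  ), class = "locus_scenario")
  validate_locus_scenario(scn)
  scn
}

validate_locus_scenario <- function(scn) {
  pk <- scn$planted_peaks
  if (nrow(pk) > 0) {
    if (any(pk$enrichment < 1)) stop("invalid scenario field `planted_peaks`: enrichment must be >= 1")
    if (any(pk$end <= pk$start)) stop("invalid scenario field `planted_peaks`: empty or reversed interval")
    if (is.unsorted(pk$start, strictly = TRUE)) {
      stop("invalid scenario field `planted_peaks`: peaks must be sorted by start")
    }
    if (nrow(pk) > 1 && any(pk$start[-1] < pk$end[-nrow(pk)])) {
      stop("invalid scenario field `planted_peaks`: peaks must be disjoint")
    }
    inside <- pk$start <= scn$viewpoint_position & scn$viewpoint_position < pk$end
    if (any(inside)) stop("invalid scenario field `planted_peaks`: a peak contains the viewpoint")
    if (any(pk$start < 0 | pk$end > scn$genome_length)) {
      stop("invalid scenario field `planted_peaks`: peak outside the chromosome")
    }
  }
  toi <- scn$track_overlap_indices
  if (length(toi) > 0 && (any(toi < 1) || any(toi > nrow(pk)))) {
    stop("invalid scenario field `track_overlap_indices`: indices must address planted peaks")
  }
  if (scn$decay_exponent <= 0) stop("invalid scenario field `decay_exponent`: must be > 0")
  if (scn$dispersion <= 0) stop("invalid scenario field `dispersion`: must be > 0")
  if (scn$n_replicates < 1) stop("invalid scenario field `n_replicates`: must be >= 1")
  if (scn$viewpoint_position <= 0 || scn$viewpoint_position >= scn$genome_length) {
    stop("invalid scenario field `viewpoint_position`: must lie inside the chromosome")
  }
  if (is.unsorted(scn$tad_boundaries, strictly = TRUE)) {
    stop("invalid scenario field `tad_boundaries`: must be strictly increasing")
  }
  invisible(scn)
}

#' @export
print.locus_scenario <- function(x, ...) {
  cat(sprintf("<locus_scenario> %s: %g bp, viewpoint @ %g, %d planted peak(s), %d replicate(s), seed %d\n",
              x$name, x$genome_length, x$viewpoint_position,
              nrow(x$planted_peaks), x$n_replicates, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Bundled per-gene fixtures.
#
# Each fixture plants the contact-peak architecture observed for one SCA
# gene: number of significant contact peaks at the promoter viewpoint,
# which of them carry epigenomic (ATAC/DNase/H3K27ac) cover and so become
# PutEs, which PutE viewpoints see the promoter (and each other) in the
# reciprocal experiment, and the reporter fold change of each cloned
# construct. Peak width is 8 kb, enrichment 5x over the decay background,
# and peaks sit 120-880 kb from the viewpoint, within the ~1 Mb span where
# 4C signal is informative.

fixture_table <- function() {
  w <- 8000
  peak <- function(starts) tibble::tibble(start = starts, end = starts + w,
                                          enrichment = 5)
  list(
    atxn1 = list(
      peaks = peak(c(520e3, 600e3, 780e3, 880e3, 1200e3, 1430e3)),
      track_overlap = c(2L, 5L),
      tads = c(750e3, 1420e3),
      reciprocal = list(PutE1 = "promoter", PutE2 = "promoter"),
      folds = c(PutE1 = 2.4, PutE2 = 7.2)
    ),
    atxn3 = list(
      peaks = peak(c(400e3, 550e3, 700e3, 820e3, 900e3, 1150e3, 1300e3, 1500e3)),
      track_overlap = c(1L, 3L, 5L, 6L, 8L),
      tads = c(300e3, 1750e3),
      reciprocal = list(PutE1 = "promoter", PutE2 = "promoter",
                        PutE3 = character(0), PutE4 = "promoter",
                        PutE5 = character(0)),
      folds = c(PutE1 = 59.4, PutE2 = 5.9, PutE3 = 1.1, PutE4 = 1.3,
                PutE5 = 1.2)
    ),
    tbp = list(
      peaks = peak(c(700e3, 1200e3, 1450e3)),
      track_overlap = c(1L, 2L),
      tads = c(500e3, 1600e3),
      reciprocal = list(PutE1 = c("promoter", "PutE2"),
                        PutE2 = c("promoter", "PutE1")),
      folds = c(PutE1 = 6.7, PutE2 = 27.1)
    ),
    itpr1 = list(
      peaks = peak(c(150e3, 300e3, 480e3, 640e3, 800e3, 1120e3, 1350e3,
                     1500e3, 1620e3, 1750e3, 1880e3)),
      track_overlap = c(2L, 3L, 5L, 7L, 8L, 9L, 10L),
      tads = c(250e3, 1280e3),
      reciprocal = list(
        PutE1 = "PutE2",
        PutE2 = c("promoter", "PutE1"),
        PutE3 = character(0),
        PutE4 = c("PutE6", "PutE7"),
        PutE5 = c("PutE6", "PutE7"),
        PutE6 = c("PutE4", "PutE5", "PutE7"),
        PutE7 = c("promoter", "PutE4", "PutE5", "PutE6")
      ),
      folds = c(PutE1_A = 9.5, PutE1_B = 4.6, PutE2 = 23.9, PutE4 = 1.2,
                PutE5_A = 1.1, PutE5_B = 6.5, PutE6 = 6.9, PutE7_A = 7.3,
                PutE7_B = 1.0)
    )
  )
}

#' Bundled locus fixtures
#'
#' Returns one of the four bundled locus scenarios (`"atxn1"`, `"atxn3"`,
#' `"tbp"`, `"itpr1"`). Each plants the contact-peak and enhancer
#' architecture of the corresponding SCA gene: 6, 8, 3 and 11 promoter
#' contact peaks of which 2, 5, 2 and 7 carry epigenomic cover.
#' The scenario carries extra fields used by the downstream stages:
#' `reciprocal_targets` (which elements each PutE viewpoint contacts) and
#' `construct_folds` (planted reporter fold change per cloned construct).
#'
#' @param gene One of `"atxn1"`, `"atxn3"`, `"tbp"`, `"itpr1"`.
#' @param seed Integer seed (default 1).
#' @param ... Overrides passed on to [locus_scenario()] (e.g.
#'   `n_replicates`, `reads_per_replicate`).
#' @return A `locus_scenario` with fixture extras.
#' @export
#' @examples
#' fixture_scenario("atxn1")
fixture_scenario <- function(gene = c("atxn1", "atxn3", "tbp", "itpr1"),
                             seed = 1L, ...) {
  gene <- match.arg(gene)
  fx <- fixture_table()[[gene]]
  args <- list(
    name = gene,
    planted_peaks = fx$peaks,
    track_overlap_indices = fx$track_overlap,
    tad_boundaries = fx$tads,
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  scn <- do.call(locus_scenario, args)
  scn$reciprocal_targets <- fx$reciprocal
  scn$construct_folds <- fx$folds
  scn
}

#' Reciprocal-viewpoint scenario for a putative enhancer
#'
#' Builds the locus scenario of the reciprocal 4C experiment in which the
#' viewpoint is moved to a putative enhancer. The genome (and hence the
#' fragment map) is shared with the promoter scenario through
#' `genome_seed`; the planted peaks become the elements that this PutE
#' viewpoint is designed to contact (the promoter region and/or other
#' PutEs), per the fixture's `reciprocal_targets`. Reciprocal experiments
#' use two replicates, matching how PutE viewpoints are analysed.
#'
#' @param scenario A fixture scenario from [fixture_scenario()].
#' @param pute Name of the element, e.g. `"PutE2"`.
#' @param promoter_halfwidth Half-width in bp of the planted promoter
#'   contact (default 4000).
#' @param n_replicates Replicates for the reciprocal experiment (default 2).
#' @return A `locus_scenario` for the reciprocal viewpoint.
#' @export
reciprocal_scenario <- function(scenario, pute, promoter_halfwidth = 4000,
                                n_replicates = 2L) {
  targets <- scenario$reciprocal_targets
  if (is.null(targets) || !pute %in% names(targets)) {
    stop("scenario has no reciprocal design for element ", pute)
  }
  toi <- scenario$track_overlap_indices
  pute_peaks <- scenario$planted_peaks[toi, , drop = FALSE]
  idx <- match(pute, paste0("PutE", seq_along(toi)))
  vp <- (pute_peaks$start[idx] + pute_peaks$end[idx]) / 2

  tg <- targets[[pute]]
  ivs <- purrr::map_dfr(tg, function(t) {
    if (t == "promoter") {
      tibble::tibble(start = scenario$viewpoint_position - promoter_halfwidth,
                     end = scenario$viewpoint_position + promoter_halfwidth)
    } else {
      j <- match(t, paste0("PutE", seq_along(toi)))
      tibble::tibble(start = pute_peaks$start[j], end = pute_peaks$end[j])
    }
  })
  enr <- attr(scenario, "reciprocal_enrichment") %||% 5
  pk <- if (nrow(ivs) > 0) {
    dplyr::arrange(dplyr::mutate(ivs, enrichment = enr), .data$start)
  } else NULL

  locus_scenario(
    name = paste0(scenario$name, "_", pute),
    genome_length = scenario$genome_length,
    n_chromosomes = scenario$n_chromosomes,
    chrom = scenario$chrom,
    primary_motif = scenario$primary_motif,
    secondary_motif = scenario$secondary_motif,
    viewpoint_position = vp,
    planted_peaks = pk,
    decay_exponent = scenario$decay_exponent,
    dispersion = scenario$dispersion,
    n_replicates = n_replicates,
    reads_per_replicate = scenario$reads_per_replicate,
    seed = derive_seed(scenario$seed, paste0("reciprocal_", pute)),
    genome_seed = scenario$genome_seed,
    tad_boundaries = scenario$tad_boundaries,
    read_length = scenario$read_length,
    primer_length = scenario$primer_length
  )
}

# ---------------------------------------------------------------------------

#' Define a synthetic assay scenario (luciferase, SNP array, qPCR)
#'
#' @param construct_fold_changes Named numeric: planted reporter fold change
#'   per construct relative to the negative control (> 0).
#' @param luciferase_cv Coefficient of variation of well-level lognormal
#'   noise (>= 0).
#' @param negative_control Name of the negative-control construct.
#' @param deletion_interval `NULL`, or `list(chrom=, start=, end=)` of a
#'   planted heterozygous deletion on the probe array (positions as printed
#'   on arrays, i.e. 1-based).
#' @param probes_inside_deletion Number of probes planted inside the
#'   deletion (>= 0).
#' @param probe_spacing Probe spacing in bp.
#' @param n_flanking_probes Unaffected probes generated on each side.
#' @param logR_shift logR shift applied to probes inside the deletion
#'   (negative for a deletion).
#' @param logR_noise_sd Gaussian sd of baseline logR noise.
#' @param ct_effects Named numeric: planted expression ratio of each sample
#'   relative to `ct_reference` (> 0).
#' @param ct_reference Reference sample for the qPCR simulation.
#' @param ct_target Target gene label.
#' @param ct_housekeeping Two housekeeping gene labels.
#' @param ct_noise_sd Gaussian sd on simulated Ct values (cycles).
#' @param seed Integer seed.
#' @return A validated list of class `assay_scenario`.
#' @export
assay_scenario <- function(construct_fold_changes = c(candidate = 2.5),
                           luciferase_cv = 0.1,
                           negative_control = "stuffer",
                           deletion_interval = NULL,
                           probes_inside_deletion = 0L,
                           probe_spacing = 2000,
                           n_flanking_probes = 50L,
                           logR_shift = -1.0,
                           logR_noise_sd = 0.05,
                           ct_effects = c(Control1 = 1),
                           ct_reference = "Control1",
                           ct_target = "ITPR1",
                           ct_housekeeping = c("GAPDH", "ACTB"),
                           ct_noise_sd = 0.05,
                           seed = 1L) {
  scn <- structure(list(
    construct_fold_changes = construct_fold_changes,
    luciferase_cv = luciferase_cv,
    negative_control = negative_control,
    deletion_interval = deletion_interval,
    probes_inside_deletion = as.integer(probes_inside_deletion),
    probe_spacing = as.numeric(probe_spacing),
    n_flanking_probes = as.integer(n_flanking_probes),
    logR_shift = logR_shift,
    logR_noise_sd = logR_noise_sd,
    ct_effects = ct_effects,
    ct_reference = ct_reference,
    ct_target = ct_target,
    ct_housekeeping = ct_housekeeping,
    ct_noise_sd = ct_noise_sd,
    seed = as.integer(seed)
  ), class = "assay_scenario")
  validate_assay_scenario(scn)
  scn
}

validate_assay_scenario <- function(scn) {
  if (any(scn$construct_fold_changes <= 0)) {
    stop("invalid scenario field `construct_fold_changes`: must be > 0")
  }
  if (scn$luciferase_cv < 0) stop("invalid scenario field `luciferase_cv`: must be >= 0")
  if (scn$probes_inside_deletion < 0) {
    stop("invalid scenario field `probes_inside_deletion`: must be >= 0")
  }
  if (!is.null(scn$deletion_interval)) {
    d <- scn$deletion_interval
    if (!all(c("chrom", "start", "end") %in% names(d))) {
      stop("invalid scenario field `deletion_interval`: needs chrom, start, end")
    }
    width <- d$end - d$start
    if (scn$probes_inside_deletion > 0 &&
        width < scn$probe_spacing * scn$probes_inside_deletion) {
      stop("invalid scenario field `deletion_interval`: too narrow for ",
           scn$probes_inside_deletion, " probes at spacing ", scn$probe_spacing)
    }
  }
  if (any(scn$ct_effects <= 0)) stop("invalid scenario field `ct_effects`: must be > 0")
  invisible(scn)
}

#' Bundled assay fixture per gene
#'
#' Luciferase fold changes are the fixture's `construct_folds`; for the
#' `itpr1` fixture a 20-probe deletion is planted on the SNP array and the
#' qPCR table plants a patient whose expression matches one control but is
#' 4.5-fold below the other two.
#'
#' @param gene Fixture gene name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [assay_scenario()].
#' @export
fixture_assay_scenario <- function(gene = c("atxn1", "atxn3", "tbp", "itpr1"),
                                   seed = 1L, ...) {
  gene <- match.arg(gene)
  folds <- fixture_table()[[gene]]$folds
  args <- list(construct_fold_changes = folds, luciferase_cv = 0.1, seed = seed)
  if (gene == "itpr1") {
    args$deletion_interval <- list(chrom = "chr3", start = 3799881, end = 3840471)
    args$probes_inside_deletion <- 20L
    args$probe_spacing <- 2000
    args$logR_shift <- -1.0
    args$ct_effects <- c(Control1 = 1, Control2 = 4.5, Control3 = 4.5,
                         Patient = 1)
    args$ct_reference <- "Control1"
  }
  args <- utils::modifyList(args, list(...))
  do.call(assay_scenario, args)
}
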