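# End-to-end orchestration of the enhancer-identification cascade on a
# locus scenario: simulate -> quantify -> call peaks -> delineate PutEs ->
# assign TADs -> reciprocal confirmation -> reporter scoring -> active
# enhancers.

#' Run the full enhancer-identification pipeline on a locus fixture
#'
#' Simulates the promoter viewpoint, quantifies and smooths the contact
#' profile, calls contact peaks (three replicates, alphaFDR 0.05),
#' delineates PutEs with the scenario's epigenomic tracks, assigns TADs,
#' runs a reciprocal viewpoint simulation for every PutE and confirms
#' promoter interactions (two replicates, alphaFDR 0.2), computes the
#' mutual-interaction matrix, scores the scenario's luciferase constructs,
#' and classifies active enhancers.
#'
#' @param scenario A [fixture_scenario()] (needs the fixture extras
#'   `reciprocal_targets` and `construct_folds`).
#' @param k Smoothing window (default 21 fragment ends).
#' @param promoter_params,reciprocal_params Peak-calling parameter sets.
#' @param promoter_pad Padding in bp added around the viewpoint fragment
#'   to form the promoter region used for reciprocal confirmation
#'   (default 2000).
#' @param from_truth Use the generator's truth counts instead of the read
#'   path (faster; the read path is validated elsewhere).
#' @param assay_seed Seed for the assay simulation (defaults to the
#'   scenario seed).
#' @return A list of class `enhancer_screen`: `sim`, `profile`, `peaks`,
#'   `tracks`, `putes`, `tad_assignment`, `rputes`, `interactions`,
#'   `reporter`, `classification`, `active_enhancers`.
#' @export
run_locus_pipeline <- function(scenario, k = 21L,
                               promoter_params = peak_call_params(
                                 alpha_fdr = 0.05, q_wr = 1, q_wd = 1.5),
                               reciprocal_params = peak_call_params(
                                 alpha_fdr = 0.2, q_wr = 1, q_wd = 1.5),
                               promoter_pad = 2000,
                               from_truth = FALSE,
                               assay_seed = NULL) {
  if (is.null(scenario$reciprocal_targets)) {
    stop("scenario lacks the fixture extras; use fixture_scenario()")
  }
  sim <- simulate_locus(scenario, emit_reads = !from_truth)
  profile <- quantify_viewpoint(sim, k = k, from_truth = from_truth)
  peaks <- call_peaks(profile, promoter_params)

  tracks <- simulate_tracks(scenario)
  putes <- delineate_putes(peaks, tracks)

  vp <- sim$viewpoint
  promoter_region <- list(chrom = vp$chrom,
                          start = vp$start - promoter_pad,
                          end = vp$end + promoter_pad)
  elements <- dplyr::bind_rows(
    tibble::tibble(name = "promoter", chrom = vp$chrom,
                   start = promoter_region$start, end = promoter_region$end),
    putes[, c("name", "chrom", "start", "end")]
  )
  tad_assignment <- assign_tads(elements, tracks$tads)

  recip_sets <- list()
  rputes <- putes[0, ]
  for (i in seq_len(nrow(putes))) {
    nm <- putes$name[i]
    rscn <- reciprocal_scenario(scenario, nm)
    rsim <- simulate_locus(rscn, genome = sim$genome, map = sim$map,
                           emit_reads = !from_truth)
    rprofile <- quantify_viewpoint(rsim, k = k, from_truth = from_truth)
    rpeaks <- call_peaks(rprofile, reciprocal_params, gene = nm)
    recip_sets[[nm]] <- rpeaks
    rputes <- dplyr::bind_rows(
      rputes, confirm_reciprocal(putes[i, ], rpeaks, promoter_region))
  }
  interactions <- mutual_interactions(recip_sets, elements)

  assays <- simulate_assays(fixture_assay_scenario(
    scenario$name, seed = assay_seed %||% scenario$seed))
  reporter <- luciferase_fold_change(assays$wells, "stuffer")
  reporter$element <- sub("_[A-Za-z]$", "", reporter$construct)
  reporter <- reporter[reporter$construct != "stuffer", ]

  classification <- classify_active_enhancers(rputes, reporter)
  structure(list(
    sim = sim, profile = profile, peaks = peaks, tracks = tracks,
    putes = putes, tad_assignment = tad_assignment, rputes = rputes,
    interactions = interactions, reporter = reporter,
    classification = classification,
    active_enhancers = classification[classification$active, ]
  ), class = "enhancer_screen")
}

#' @export
print.enhancer_screen <- function(x, ...) {
  cat(sprintf(
    "<enhancer_screen> %s: %d contact peak(s), %d PutE(s), %d confirmed R-PutE(s), %d active enhancer(s)\n",
    x$sim$scenario$name, nrow(x$peaks$peaks), nrow(x$putes),
    sum(x$rputes$reciprocal_confirmed), nrow(x$active_enhancers)))
  invisible(x)
}
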