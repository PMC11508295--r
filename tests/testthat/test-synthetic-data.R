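# The synthetic-data generator: scenario validation, truth records,
# determinism, statistical structure, and output formats.

test_that("scenario validation names the offending field", {
  expect_error(locus_scenario("x", planted_peaks = data.frame(
    start = 100, end = 200, enrichment = 0.5)), "planted_peaks")
  expect_error(locus_scenario("x", viewpoint_position = 1000,
                              genome_length = 2000,
                              planted_peaks = data.frame(
                                start = 500, end = 1500, enrichment = 2)),
               "planted_peaks")
  expect_error(locus_scenario("x", planted_peaks = data.frame(
    start = c(100, 150), end = c(200, 250), enrichment = 2)),
    "planted_peaks")
  expect_error(locus_scenario("x", track_overlap_indices = 3L),
               "track_overlap_indices")
  expect_error(locus_scenario("x", decay_exponent = 0), "decay_exponent")
  expect_error(locus_scenario("x", dispersion = -1), "dispersion")
})

test_that("null architecture yields an empty truth peak list and pure decay", {
  scn <- small_scenario(seed = 3)
  sim <- simulate_locus(scn, emit_reads = FALSE)
  expect_equal(nrow(sim$truth$peaks), 0L)
  # with enrichment 1 everywhere, capture frequency regressed on
  # log-distance recovers -decay_exponent (here 1) within simulation error
  ec <- sim$truth$end_counts
  total <- ec$rep1 + ec$rep2 + ec$rep3
  d <- abs(ec$pos - scn$viewpoint_position)
  bins <- cut(log(d), breaks = 25)
  dens <- tapply(total, bins, mean)
  mid <- tapply(log(d), bins, mean)
  keep <- !is.na(dens) & dens > 0
  slope <- stats::coef(stats::lm(log(dens[keep]) ~ mid[keep]))[[2]]
  expect_lt(abs(slope - (-scn$decay_exponent)), 0.1)
})

test_that("fixture truth records plant the per-gene peak architecture", {
  expect_equal(nrow(fixture_scenario("atxn1")$planted_peaks), 6L)
  expect_equal(nrow(fixture_scenario("atxn3")$planted_peaks), 8L)
  expect_equal(nrow(fixture_scenario("tbp")$planted_peaks), 3L)
  expect_equal(nrow(fixture_scenario("itpr1")$planted_peaks), 11L)
  sim <- simulate_locus(fixture_scenario("atxn1"), emit_reads = FALSE)
  expect_equal(nrow(sim$truth$peaks), 6L)
})

test_that("fixed seed reproduces byte-identical FASTQ; seeds differ, truth does not", {
  scn <- small_scenario(seed = 11)
  sim1 <- simulate_locus(scn)
  sim2 <- simulate_locus(scn)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_locus_sim(sim1, d1); write_locus_sim(sim2, d2)
  f1 <- file.path(d1, "toy_rep1.fastq"); f2 <- file.path(d2, "toy_rep1.fastq")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  sim3 <- simulate_locus(small_scenario(seed = 12))
  expect_false(identical(sim1$truth$end_counts$rep1,
                         sim3$truth$end_counts$rep1))
  expect_identical(sim1$truth$peaks, sim3$truth$peaks)
  # generated FASTQ parses under a standard reader
  parsed <- Biostrings::readDNAStringSet(f1, format = "fastq")
  expect_equal(length(parsed), length(sim1$reads$rep1))
  expect_true(all(Biostrings::width(parsed) == scn$read_length))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("reads are primer + captured fragment-end sequence", {
  scn <- small_scenario(seed = 5)
  sim <- simulate_locus(scn)
  primer <- sim$viewpoint$reading_primer
  expect_true(endsWith(primer, scn$primary_motif))
  expect_true(all(startsWith(sim$reads$rep1[1:100], primer)))
  expect_true(all(nchar(sim$reads$rep1) == scn$read_length))
})

test_that("track simulation covers exactly the requested planted peaks", {
  scn <- fixture_scenario("itpr1")
  tr <- simulate_tracks(scn)
  pk <- scn$planted_peaks
  covered <- vapply(seq_len(nrow(pk)), function(i) {
    all(vapply(list(tr$atac, tr$dnase, tr$h3k27ac), function(t)
      any(interval_overlap_bp(t$start, t$end, pk$start[i], pk$end[i]) > 0),
      logical(1)))
  }, logical(1))
  expect_equal(which(covered), scn$track_overlap_indices)
  expect_equal(sum(covered), 7L)

  # all indices / empty indices
  scn_all <- small_scenario(peaks = data.frame(
    start = c(1e5, 2e5), end = c(1.1e5, 2.1e5), enrichment = c(2, 2)),
    track_overlap_indices = 1:2)
  tr_all <- simulate_tracks(scn_all)
  expect_equal(nrow(tr_all$atac), 2L)
  scn_none <- small_scenario(peaks = data.frame(
    start = 1e5, end = 1.1e5, enrichment = 2))
  tr_none <- simulate_tracks(scn_none)
  expect_equal(nrow(tr_none$atac), 0L)
  expect_equal(nrow(tr_none$h3k27ac), 0L)

  # BEDs are sorted, half-open, non-negative; TADs partition the chromosome
  for (t in list(tr$atac, tr$dnase, tr$h3k27ac, tr$tads)) {
    expect_true(all(t$start >= 0))
    expect_true(all(t$end > t$start))
    expect_false(is.unsorted(t$start))
  }
  expect_equal(tr$tads$start[-1], tr$tads$end[-nrow(tr$tads)])
  expect_equal(max(tr$tads$end), scn$genome_length)
})

test_that("assay scenario validation and planted-value identities", {
  expect_error(assay_scenario(construct_fold_changes = c(a = -1)),
               "construct_fold_changes")
  expect_error(assay_scenario(luciferase_cv = -0.1), "luciferase_cv")
  expect_error(assay_scenario(deletion_interval = list(chrom = "chr1",
                                                       start = 100, end = 1200),
                              probes_inside_deletion = 5L,
                              probe_spacing = 1000),
               "too narrow")
  # cv 0: fold change recovered exactly
  as0 <- simulate_assays(assay_scenario(
    construct_fold_changes = c(cand = 1.0), luciferase_cv = 0))
  res <- luciferase_fold_change(as0$wells, "stuffer")
  expect_equal(res$fold_change[res$construct == "cand"], 1.0)
  expect_false(res$active[res$construct == "cand"])
  # no noise: planted expression ratio recovered exactly
  asq <- simulate_assays(assay_scenario(
    ct_effects = c(Control1 = 1, S = 0.25), ct_noise_sd = 0))
  expr <- relative_expression(asq$cts, "ITPR1", c("GAPDH", "ACTB"), "Control1")
  expect_equal(expr$fold_change[expr$sample == "S"], 0.25)
})

test_that("planted deletion produces the requested probe support", {
  as <- simulate_assays(fixture_assay_scenario("itpr1", seed = 1))
  expect_equal(as$truth$deletion$n_probes_inside, 20L)
  expect_false(is.unsorted(as$probes$pos, strictly = TRUE))
})
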