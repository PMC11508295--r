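# Monotone background fitting and contact-peak calling.

test_that("pool-adjacent-violators equals the exhaustive monotone-fit oracle", {
  # non-increasing input is a fixed point
  expect_equal(pava_nonincreasing(c(9, 7, 7, 3, 1)), c(9, 7, 7, 3, 1))
  # constant input stays constant
  expect_equal(pava_nonincreasing(rep(2, 6)), rep(2, 6))
  # a single local bump is pooled to the block mean
  expect_equal(pava_nonincreasing(c(5, 4, 6, 3)), c(5, 5, 5, 3))
  # exhaustive check against a brute-force least-squares oracle on all
  # binary-valued vectors up to length 8 and ternary up to length 5
  for (n in 1:8) {
    grid <- expand.grid(rep(list(c(0, 2)), n))
    for (i in seq_len(nrow(grid))) {
      y <- as.numeric(grid[i, ])
      expect_equal(pava_nonincreasing(y), brute_monotone_fit(y),
                   tolerance = 1e-10)
    }
  }
  for (n in 1:5) {
    grid <- expand.grid(rep(list(c(0, 1, 3)), n))
    for (i in seq_len(nrow(grid))) {
      y <- as.numeric(grid[i, ])
      expect_equal(pava_nonincreasing(y), brute_monotone_fit(y),
                   tolerance = 1e-10)
    }
  }
})

test_that("background fit is per side, floored, and skips thin sides", {
  decay <- 3000 / (1:40)
  prof <- toy_profile(values_up = decay, values_down = decay, k = 1)
  bg <- fit_background(prof, floor = 0.5)
  expect_equal(nrow(bg), 80L)
  expect_true(all(bg$background >= 0.5))
  # decreasing-with-distance input: background equals the (normalized) input
  up <- bg[bg$side == "upstream", ]
  expect_equal(up$background, up$mean_signal, tolerance = 1e-9)
  # a side with < 20 ends is skipped with a warning
  thin <- toy_profile(values_up = decay[1:5], values_down = decay, k = 1)
  expect_warning(bg2 <- fit_background(thin), "upstream")
  expect_equal(unique(bg2$side), "downstream")
})

test_that("a profile equal to its own background yields zero peaks", {
  decay <- 3000 / (1:60)
  prof <- toy_profile(values_up = decay, values_down = decay, k = 1)
  pk <- call_peaks(prof, peak_call_params())
  expect_equal(nrow(pk$peaks), 0L)
})

test_that("a planted 10-end bump at 5x enrichment is called exactly once", {
  decay <- 3000 / (1:60)
  bump <- decay
  bump[40:49] <- bump[40:49] * 5
  prof <- toy_profile(values_up = decay, values_down = bump, k = 1)
  pk <- call_peaks(prof, peak_call_params())
  expect_equal(nrow(pk$peaks), 1L)
  expect_equal(pk$peaks$side, "downstream")
  # the called interval covers the planted ends up to one fragment end of
  # edge resolution (the windowed sign test cannot resolve the outermost
  # end of a bump; grid spacing is 1000 bp)
  down <- prof[prof$rep == "rep1" & prof$side == "downstream", ]
  down <- down[order(down$distance), ]
  planted_start <- down$frag_start[40]
  planted_end <- down$frag_end[49]
  expect_lte(pk$peaks$start, planted_start + 1000)
  expect_gte(pk$peaks$end, planted_end - 1000)
})

test_that("raising qWd or lowering alphaFDR never increases the peak count", {
  scn <- fixture_scenario("atxn1", seed = 2)
  prof <- quantify_viewpoint(simulate_locus(scn, emit_reads = FALSE),
                             from_truth = TRUE)
  n_peaks <- function(p) nrow(call_peaks(prof, p)$peaks)
  base <- n_peaks(peak_call_params())
  expect_lte(n_peaks(peak_call_params(q_wd = 2.5)), base)
  expect_lte(n_peaks(peak_call_params(q_wd = 4)),
             n_peaks(peak_call_params(q_wd = 2.5)))
  expect_lte(n_peaks(peak_call_params(alpha_fdr = 0.01)), base)
  expect_lte(n_peaks(peak_call_params(alpha_fdr = 1e-6)),
             n_peaks(peak_call_params(alpha_fdr = 0.01)))
})

test_that("called peaks are disjoint and avoid masked viewpoint ends", {
  scn <- fixture_scenario("itpr1", seed = 3)
  sim <- simulate_locus(scn, emit_reads = FALSE)
  prof <- quantify_viewpoint(sim, from_truth = TRUE)
  pk <- call_peaks(prof)$peaks
  pk <- pk[order(pk$start), ]
  if (nrow(pk) > 1) expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
  masked <- prof[prof$masked & prof$rep == "rep1", ]
  expect_true(all(interval_overlap_bp(
    rep(min(masked$frag_start), nrow(pk)), rep(max(masked$frag_end), nrow(pk)),
    pk$start, pk$end) == 0))
})

test_that("planted-truth recovery: recall and precision 1 at enrichment 3", {
  peaks3 <- data.frame(start = c(1.2e5, 3.8e5, 4.8e5),
                       end = c(1.28e5, 3.88e5, 4.88e5),
                       enrichment = 3)
  for (s in 1:5) {
    scn <- small_scenario(seed = s, peaks = peaks3,
                          reads_per_replicate = 5e5)
    sim <- simulate_locus(scn, emit_reads = FALSE)
    pk <- call_peaks(quantify_viewpoint(sim, from_truth = TRUE))$peaks
    hits <- vapply(seq_len(nrow(peaks3)), function(i)
      any(interval_overlap_bp(pk$start, pk$end,
                              peaks3$start[i], peaks3$end[i]) > 0),
      logical(1))
    expect_true(all(hits), label = paste("recall, seed", s))
    fp <- vapply(seq_len(nrow(pk)), function(j)
      !any(interval_overlap_bp(pk$start[j], pk$end[j],
                               peaks3$start, peaks3$end) > 0), logical(1))
    expect_false(any(fp), label = paste("precision, seed", s))
  }
})

test_that("replicate-grid mismatches and single replicates are rejected", {
  decay <- 3000 / (1:30)
  prof <- toy_profile(values_up = decay, values_down = decay, n_reps = 1, k = 1)
  expect_error(call_peaks(prof), "2 replicates")
  prof2 <- toy_profile(values_up = decay, values_down = decay, k = 1)
  prof2 <- prof2[!(prof2$rep == "rep2" & prof2$frag_index == 3), ]
  expect_error(call_peaks(prof2, peak_call_params()), "grid")
})

test_that("promoter overlap uses half-open intersection", {
  pk <- tibble::tibble(chrom = "c", start = 100, end = 200,
                       peak_id = "p1", gene = "g")
  expect_true(promoter_overlap(pk, list(chrom = "c", start = 150, end = 160))$overlaps)
  expect_false(promoter_overlap(pk, list(chrom = "c", start = 200, end = 210))$overlaps)
  expect_false(promoter_overlap(pk, list(chrom = "other", start = 150, end = 160))$overlaps)
  ov <- promoter_overlap(pk, list(chrom = "c", start = 190, end = 250))
  expect_equal(ov$peaks$overlap_bp, 10)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(peak_call_params(alpha_fdr = 0), "alpha_fdr")
  expect_error(peak_call_params(alpha_fdr = 1), "alpha_fdr")
  expect_error(peak_call_params(q_wd = 0.5), "q_wd")
  expect_error(peak_call_params(q_wr = -1), "q_wr")
})
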