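# SNP-array CNV calling, breakpoint delimitation, control filtering and
# the overlap report.

probe_array <- function(logR, chrom = "chr1", spacing = 1000) {
  tibble::tibble(id = sprintf("rs%04d", seq_along(logR)), chrom = chrom,
                 pos = seq_along(logR) * spacing, logR = logR, BAF = 0.5)
}

test_that("interval size follows printed-coordinate arithmetic", {
  expect_equal(interval_size(3797792, 3838896), 41104)
  expect_equal(interval_size(3799881, 3840471), 40590)
  expect_equal(interval_size(5, 5), 0)
  expect_error(interval_size(10, 5), ">=")
  # translation invariance and additivity over abutting intervals
  expect_equal(interval_size(100, 250), interval_size(100 + 777, 250 + 777))
  expect_equal(interval_size(100, 180) + interval_size(180, 250),
               interval_size(100, 250))
})

test_that("runs shorter than min_probes are discarded as artifacts", {
  lr <- rep(0, 60)
  lr[20:28] <- -1 # 9 consecutive probes below threshold
  expect_equal(nrow(call_cnvs(probe_array(lr))), 0L)
  lr[20:29] <- -1 # 10 probes: called
  calls <- call_cnvs(probe_array(lr))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "deletion")
  expect_equal(calls$n_probes, 10L)
  # all-normal array: empty call list
  expect_equal(nrow(call_cnvs(probe_array(rep(0, 60)))), 0L)
  expect_error(call_cnvs(probe_array(rep(0, 5))[c(2, 1, 3, 4, 5), ]),
               "sorted")
})

test_that("minimal/maximal intervals and delimitation come from flanking probes", {
  lr <- rep(0, 50)
  lr[11:30] <- -0.9
  calls <- call_cnvs(probe_array(lr, spacing = 2000))
  expect_equal(calls$n_probes, 20L)
  expect_equal(calls$min_start, 11 * 2000)
  expect_equal(calls$min_end, 30 * 2000)
  expect_equal(calls$max_start, 10 * 2000)
  expect_equal(calls$max_end, 31 * 2000)
  expect_equal(calls$delim_centromeric, 2000)
  expect_equal(calls$delim_telomeric, 2000)
  expect_equal(calls$size, interval_size(calls$min_start, calls$min_end))
  expect_equal(calls$flank_left_id, "rs0010")
  expect_equal(calls$flank_right_id, "rs0031")
  # minimal interval nested in maximal interval
  expect_lte(calls$max_start, calls$min_start)
  expect_gte(calls$max_end, calls$min_end)
  # duplications are typed by the positive threshold
  lr2 <- rep(0, 50); lr2[5:20] <- 0.6
  expect_equal(call_cnvs(probe_array(lr2))$type, "duplication")
})

test_that("planted deletions are recovered with nested intervals (seeds 1-5)", {
  for (s in 1:5) {
    scn <- fixture_assay_scenario("itpr1", seed = s)
    as <- simulate_assays(scn)
    calls <- call_cnvs(as$probes)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$type, "deletion")
    expect_equal(calls$n_probes, 20L)
    d <- scn$deletion_interval
    # minimal interval inside the planted deletion, planted inside maximal
    expect_gte(calls$min_start, d$start)
    expect_lte(calls$min_end, d$end)
    expect_lte(calls$max_start, d$start)
    expect_gte(calls$max_end, d$end)
  }
})

test_that("control-database filtering uses reciprocal overlap and frequency", {
  lr <- rep(0, 60); lr[11:30] <- -0.9
  calls <- call_cnvs(probe_array(lr, spacing = 1000))
  # empty database: everything retained
  kept <- filter_controls(calls, tibble::tibble(
    chrom = character(0), start = numeric(0), end = numeric(0),
    type = character(0), freq = numeric(0)))
  expect_equal(nrow(kept), 1L)
  # matching locus at nonzero frequency with control_max_freq 0: removed
  db <- tibble::tibble(chrom = "chr1", start = 11000, end = 30000,
                       type = "deletion", freq = 0.01)
  kept2 <- filter_controls(calls, db)
  expect_equal(nrow(kept2), 0L)
  expect_equal(nrow(attr(kept2, "removed")), 1L)
  # 10% reciprocal overlap: retained
  db3 <- tibble::tibble(chrom = "chr1", start = 28100, end = 47100,
                        type = "deletion", freq = 0.2)
  expect_equal(nrow(filter_controls(calls, db3)), 1L)
  # wrong type never matches
  db4 <- tibble::tibble(chrom = "chr1", start = 11000, end = 30000,
                        type = "duplication", freq = 0.5)
  expect_equal(nrow(filter_controls(calls, db4)), 1L)
})

test_that("the overlap report separates peak-only hits and TAD disruption", {
  calls <- tibble::tibble(
    chrom = "chr3", type = "deletion", n_probes = 20L,
    min_start = 3797792, min_end = 3838896,
    max_start = NA_real_, max_end = NA_real_, size = 41104,
    delim_centromeric = NA_real_, delim_telomeric = NA_real_,
    flank_left_id = NA_character_, flank_right_id = NA_character_,
    control_frequency = NA_real_, probe_ids = list("x"))
  elements <- list(
    peaks = tibble::tibble(chrom = "chr3", start = 3836985, end = 3845608,
                           name = "peak_broad"),
    putes = tibble::tibble(chrom = "chr3", start = 3841000, end = 3842000,
                           name = "PutE1"),
    active_enhancers = tibble::tibble(chrom = character(0), start = numeric(0),
                                      end = numeric(0)),
    tad_boundaries = tibble::tibble(chrom = "chr3", pos = 3800000))
  rep <- overlap_report(calls, elements)
  hit <- rep[rep$element_class == "peaks", ]
  expect_equal(hit$overlap_bp, 3838896 - 3836985) # 1911 bp
  expect_true(all(rep$peak_not_pute))
  expect_true(all(rep$disrupts_tad_boundary))
  # a call disjoint from everything reports an empty annotation
  calls2 <- calls
  calls2$min_start <- 1e6; calls2$min_end <- 1.1e6
  rep2 <- overlap_report(calls2, elements)
  expect_equal(nrow(rep2), 1L)
  expect_true(is.na(rep2$element_class))
  expect_false(rep2$peak_not_pute)
  expect_false(rep2$disrupts_tad_boundary)
  # genome build labels must agree
  attr(calls, "build") <- "GRCh37"
  el2 <- elements
  attr(el2$peaks, "build") <- "GRCh38"
  expect_error(overlap_report(calls, el2), "build")
})
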