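# PutE delineation, TAD assignment, reciprocal confirmation, mutual
# interactions, and active-enhancer classification.

tracks_of <- function(atac, dnase, h3k27ac, chrom = "c") {
  mk <- function(m) tibble::tibble(chrom = chrom, start = m[, 1], end = m[, 2])
  list(atac = mk(atac), dnase = mk(dnase), h3k27ac = mk(h3k27ac))
}

test_that("PutE delineation is open-chromatin AND H3K27ac interval algebra", {
  pk <- tibble::tibble(chrom = "c", start = 0, end = 1000, peak_id = "p1",
                       gene = "g")
  tr <- tracks_of(rbind(c(100, 300)), rbind(c(250, 400)), rbind(c(200, 350)))
  pe <- delineate_putes(pk, tr, min_len = 50, merge_gap = 0)
  expect_equal(nrow(pe), 1L)
  expect_equal(c(pe$start, pe$end), c(200, 350))
  expect_equal(pe$open_evidence, "both")
  # no H3K27ac overlap: no PutE
  tr2 <- tracks_of(rbind(c(100, 300)), rbind(c(250, 400)), rbind(c(2000, 2100)))
  expect_equal(nrow(delineate_putes(pk, tr2)), 0L)
  # intersection mode requires both open-chromatin assays
  pe_int <- delineate_putes(pk, tr, min_len = 10, merge_gap = 0,
                            open_mode = "intersection")
  expect_equal(c(pe_int$start, pe_int$end), c(250, 300))
  # min_len drops slivers
  expect_equal(nrow(delineate_putes(pk, tr, min_len = 200)), 0L)
})

test_that("nearby PutE slivers merge within merge_gap and number genomically", {
  pk <- tibble::tibble(chrom = "c", start = 0, end = 5000,
                       peak_id = "p1", gene = "g")
  tr <- tracks_of(rbind(c(100, 600), c(800, 1300), c(3000, 3500)),
                  rbind(c(100, 600), c(800, 1300), c(3000, 3500)),
                  rbind(c(0, 5000)))
  pe <- delineate_putes(pk, tr, min_len = 200, merge_gap = 500)
  expect_equal(nrow(pe), 2L)          # first two merge across the 200 bp gap
  expect_equal(pe$name, c("PutE1", "PutE2"))
  expect_equal(pe$start, c(100, 3000))
  expect_equal(pe$end, c(1300, 3500))
})

test_that("the itpr1 fixture delineates 7 PutEs from 11 peaks", {
  scn <- fixture_scenario("itpr1")
  tr <- simulate_tracks(scn)
  pk <- scn$planted_peaks
  pk$chrom <- scn$chrom
  pe <- delineate_putes(pk, tr)
  expect_equal(nrow(pe), 7L)
  expect_equal(pe$name, paste0("PutE", 1:7))
  # every PutE lies inside its parent peak
  parent <- pk[match(pe$peak_id, paste0("peak", seq_len(nrow(pk)))), ]
  expect_true(all(pe$start >= parent$start & pe$end <= parent$end))
  # PutEs of one gene are pairwise disjoint
  expect_true(all(pe$start[-1] >= pe$end[-nrow(pe)]))
})

test_that("TAD assignment uses the midpoint with the half-open rule", {
  tads <- tibble::tibble(chrom = "c", start = c(0, 1000, 2000),
                         end = c(1000, 2000, 3000))
  el <- tibble::tibble(
    name = c("promoter", "inTad", "nextTad", "onBoundary", "outside"),
    chrom = "c",
    start = c(100, 400, 1200, 950, 3500),
    end = c(200, 500, 1300, 1050, 3600))
  asg <- assign_tads(el, tads)
  expect_equal(asg$tad, c("TAD1", "TAD1", "TAD2", "TAD2", NA))
  # midpoint of [950,1050) is 1000 = TAD2 start: half-open puts it in TAD2
  expect_equal(asg$vs_promoter,
               c("promoter", "intra-TAD", "inter-TAD", "inter-TAD",
                 "unassigned"))
  expect_error(assign_tads(el, tibble::tibble(chrom = "c",
                                              start = c(0, 500),
                                              end = c(1000, 1500))),
               "overlap")
})

test_that("reciprocal confirmation requires a peak over the promoter", {
  pute <- tibble::tibble(pute = 1L, name = "PutE1", chrom = "c",
                         start = 5000, end = 6000, peak_id = "p1", gene = "g")
  promoter <- list(chrom = "c", start = 100, end = 400)
  rpk <- tibble::tibble(chrom = "c", start = 50, end = 300, peak_id = "r1",
                        gene = "PutE1")
  conf <- confirm_reciprocal(pute, rpk, promoter)
  expect_true(conf$reciprocal_confirmed)
  expect_equal(conf$confirming_peak, "r1")
  expect_equal(conf$rpute_name, "R-PutE1")
  none <- confirm_reciprocal(pute, rpk[0, ], promoter)
  expect_false(none$reciprocal_confirmed)
  expect_equal(none$rpute_name, "PutE1")
})

test_that("mutual interactions require both directions", {
  el <- tibble::tibble(name = c("promoter", "PutE1", "PutE2"),
                       chrom = "c",
                       start = c(0, 1000, 2000), end = c(100, 1500, 2500))
  empty <- tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), peak_id = character(0))
  # empty peak sets: all-false matrix, no pairs
  m0 <- mutual_interactions(list(PutE1 = empty, PutE2 = empty), el)
  expect_false(any(m0$matrix))
  expect_equal(nrow(m0$mutual), 0L)
  # one-directional overlap is excluded
  p1_sees_p2 <- tibble::tibble(chrom = "c", start = 2100, end = 2200,
                               peak_id = "x", gene = "PutE1")
  m1 <- mutual_interactions(list(PutE1 = p1_sees_p2, PutE2 = empty), el)
  expect_true(m1$matrix["PutE1", "PutE2"])
  expect_equal(nrow(m1$mutual), 0L)
  # both directions: a single unordered pair
  p2_sees_p1 <- tibble::tibble(chrom = "c", start = 1200, end = 1300,
                               peak_id = "y", gene = "PutE2")
  m2 <- mutual_interactions(list(PutE1 = p1_sees_p2, PutE2 = p2_sees_p1), el)
  expect_equal(nrow(m2$mutual), 1L)
  expect_setequal(unlist(m2$mutual[1, c("a", "b")]), c("PutE1", "PutE2"))
})

test_that("active-enhancer classification partitions and flags correctly", {
  rp <- tibble::tibble(name = paste0("PutE", 1:4),
                       reciprocal_confirmed = c(TRUE, TRUE, FALSE, FALSE))
  rr <- tibble::tibble(construct = c("PutE1", "PutE2_A", "PutE2_B", "PutE3",
                                     "PutE4"),
                       fold_change = c(2.0, 1.2, 6.9, 6.9, 1.1))
  cl <- classify_active_enhancers(rp, rr)
  # inclusive two-fold threshold
  expect_true(cl$active[cl$name == "PutE1"])
  # fragments: any active fragment makes the element active
  expect_true(cl$active[cl$name == "PutE2"])
  expect_equal(cl$fold_change[cl$name == "PutE2"], 6.9)
  # active but unconfirmed is reported separately, not as an enhancer
  expect_false(cl$active[cl$name == "PutE3"])
  expect_equal(cl$category[cl$name == "PutE3"],
               "active region, interaction unconfirmed")
  expect_equal(cl$category[cl$name == "PutE4"], "not active")
  # no element lost
  expect_setequal(cl$name, rp$name)
  # a confirmed element without a reporter result is an error naming it
  expect_error(classify_active_enhancers(rp, rr[rr$construct != "PutE1", ]),
               "PutE1")
})
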