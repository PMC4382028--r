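# shared scaffold: 20 markers at 1-kb spacing
cmap <- snp_map("chrIV", seq_len(20) * 1000)

test_that("combining sectors yields the four-chromatid region bookkeeping", {
  red <- c(rep("HET", 5), rep("HOM_A", 5), rep("HOM_A", 10))
  white <- c(rep("HET", 5), rep("HET", 5), rep("HOM_B", 10))
  seg_r <- segment_profile(red, cmap, min_run = 1)
  seg_w <- segment_profile(white, cmap, min_run = 1)
  reg <- combine_sectors(seg_r, seg_w, cmap)
  expect_equal(reg$type, c("het_het", "conv_3_1", "reciprocal"))
  expect_equal(reg$count_A, c(2L, 3L, 2L))
  expect_equal(reg$count_B, c(2L, 1L, 2L))
  expect_equal(reg$donor, c(NA, "A", NA))

  # both sectors homozygous for the same parent: 4:0
  white40 <- c(rep("HET", 5), rep("HOM_A", 5), rep("HOM_B", 10))
  reg40 <- combine_sectors(seg_r, segment_profile(white40, cmap, min_run = 1),
                           cmap)
  expect_equal(reg40$type[2L], "conv_4_0")
  expect_equal(reg40$count_A[2L], 4L)
})

test_that("conversion classes follow the zone structure", {
  mk <- function(red, white) event_from_calls(red, white, cmap)
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  # single contiguous 3:1 region
  ev <- mk(c(rep(H, 10), rep(B, 10)), c(rep(H, 5), rep(B, 5), rep(A, 10)))
  expect_equal(ev$class, "SIMPLE_3_1")
  # identical transitions in red and white: conversionless crossover
  ev <- mk(c(rep(H, 10), rep(B, 10)), c(rep(H, 10), rep(A, 10)))
  expect_equal(ev$class, "NO_GC")
  # single contiguous 4:0 region
  ev <- mk(c(rep(H, 5), rep(B, 5), rep(B, 10)),
           c(rep(H, 5), rep(B, 5), rep(A, 10)))
  expect_equal(ev$class, "SIMPLE_4_0")
  # 4:0 core with an adjacent same-donor 3:1 flank
  ev <- mk(c(rep(H, 8), rep(B, 2), rep(B, 10)),
           c(rep(H, 5), rep(B, 5), rep(A, 10)))
  expect_equal(ev$class, "HYBRID_4_0_3_1")
  # interior return to heterozygosity: complex
  ev <- mk(c(rep(H, 10), rep(B, 10)),
           c(rep(H, 5), rep(B, 2), rep(H, 3), rep(B, 2), rep(A, 8)))
  expect_equal(ev$class, "COMPLEX")
  # donor switch between conversion regions: complex
  ev <- mk(c(rep(H, 5), rep(A, 3), rep(H, 2), rep(B, 10)),
           c(rep(H, 8), rep(B, 2), rep(A, 10)))
  expect_equal(ev$class, "COMPLEX")
})

test_that("a sector pair without reciprocal distal LOH is not an RCO", {
  H <- "HET"; B <- "HOM_B"
  seg_r <- segment_profile(c(rep(H, 10), rep(B, 10)), cmap, min_run = 1)
  seg_w <- segment_profile(rep(H, 20), cmap, min_run = 1)
  reg <- combine_sectors(seg_r, seg_w, cmap)
  expect_error(classify_event(reg), "not a reciprocal")
})

test_that("lesion timing follows the tract class", {
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  mk <- function(red, white) event_from_calls(red, white, cmap)
  expect_equal(mk(c(rep(H, 10), rep(B, 10)),
                  c(rep(H, 5), rep(B, 5), rep(A, 10)))$timing, "G2")
  expect_equal(mk(c(rep(H, 8), rep(B, 2), rep(B, 10)),
                  c(rep(H, 5), rep(B, 5), rep(A, 10)))$timing, "G1")
  expect_equal(mk(c(rep(H, 10), rep(B, 10)),
                  c(rep(H, 10), rep(A, 10)))$timing, "UNCLASSIFIED")
  # complex with a 4:0 region is G1, without one G2
  cx_40 <- mk(c(rep(H, 5), rep(B, 3), rep(H, 2), rep(B, 10)),
              c(rep(H, 5), rep(B, 2), rep(H, 3), rep(A, 10)))
  expect_equal(cx_40$class, "COMPLEX")
  expect_equal(cx_40$timing, "G1")
  cx_31 <- mk(c(rep(H, 10), rep(B, 10)),
              c(rep(H, 3), rep(B, 2), rep(H, 5), rep(A, 10)))
  expect_equal(cx_31$class, "COMPLEX")
  expect_equal(cx_31$timing, "G2")
})

test_that("donor inference picks the over-represented homolog", {
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  mk <- function(red, white) event_from_calls(red, white, cmap)
  # 3:1 regions biased to A (white converted to HOM_A ahead of reciprocal)
  ev <- mk(c(rep(H, 10), rep(B, 10)), c(rep(H, 5), rep(A, 5), rep(A, 10)))
  expect_equal(ev$donor, "A")
  # 4:0 forced
  ev <- mk(c(rep(H, 5), rep(A, 5), rep(B, 10)),
           c(rep(H, 5), rep(A, 5), rep(A, 10)))
  expect_equal(ev$donor, "A")
  # disagreeing regions
  ev <- mk(c(rep(H, 5), rep(A, 3), rep(H, 2), rep(B, 10)),
           c(rep(H, 8), rep(B, 2), rep(A, 10)))
  expect_equal(ev$donor, "MIXED")
  # conversionless: undefined
  ev <- mk(c(rep(H, 10), rep(B, 10)), c(rep(H, 10), rep(A, 10)))
  expect_true(is.na(ev$donor))
})

test_that("tract lengths average the flanking and in-tract marker distances", {
  m <- snp_map("chrIV", c(90000, 99000, 100000, 103000, 108000, 109000,
                          115000, 120000))
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  # tract covers markers 100,000-108,000; flanks at 99,000 and 109,000
  red <- c(H, H, H, H, H, B, B, B)
  white <- c(H, H, A, A, A, A, A, A)
  ev <- event_from_calls(red, white, m)
  expect_equal(ev$class, "SIMPLE_3_1")
  expect_equal(ev$min_bp, 8000)
  expect_equal(ev$max_bp, 10000)
  expect_equal(ev$avg_bp, 9000)
})

test_that("conversionless crossovers use the 1-bp minimal tract convention", {
  m <- snp_map("chrIV", c(30000, 40000, 50000, 60001, 70000))
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  ev <- event_from_calls(c(H, H, H, B, B), c(H, H, H, A, A), m)
  expect_equal(ev$class, "NO_GC")
  expect_equal(ev$min_bp, 1)
  expect_equal(ev$max_bp, 10001)
  expect_equal(ev$avg_bp, 5001)
})

test_that("single-marker tracts floor the minimum length at 1 bp", {
  m <- snp_map("chrIV", seq_len(8) * 1000)
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  ev <- event_from_calls(c(H, H, H, H, H, B, B, B),
                         c(H, H, H, H, A, A, A, A), m)
  expect_equal(ev$class, "SIMPLE_3_1")
  expect_equal(ev$min_bp, 1)
  expect_equal(ev$max_bp, 2000)
  expect_equal(ev$avg_bp, (1 + 2000) / 2)
})

test_that("tracts reaching the map edge are flagged open-ended", {
  m <- snp_map("chrIV", seq_len(8) * 1000)
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  # fully reciprocal pair: conversionless and open-ended
  ev <- event_from_calls(rep(B, 8), rep(A, 8), m)
  expect_equal(ev$class, "NO_GC")
  expect_true(ev$open_ended)
  expect_true(is.na(ev$max_bp))
  # conversion tract starting at the first marker
  ev2 <- event_from_calls(c(rep(H, 6), B, B), c(rep(A, 6), A, A), m)
  expect_true(ev2$open_ended)
  expect_true(is.na(ev2$avg_bp))
})

test_that("swapping parental labels preserves class and timing, flips donor", {
  map <- generate_snp_map(400, 2e5, seed = 21)
  truths <- simulate_rco_cohort(map, 40, seed = 22)
  for (tr in truths) {
    pr <- noiseless_pair(tr)
    ev <- analyze_sector_pair(pr$red, pr$white, map, min_run = 1)
    sw_red <- ratio_profile(map, pr$red$ratio_B, pr$red$ratio_A)
    sw_white <- ratio_profile(map, pr$white$ratio_B, pr$white$ratio_A)
    ev_sw <- analyze_sector_pair(sw_red, sw_white, map, min_run = 1)
    expect_equal(ev_sw$class, ev$class)
    expect_equal(ev_sw$timing, ev$timing)
    if (!is.na(ev$donor) && ev$donor %in% c("A", "B"))
      expect_equal(ev_sw$donor, setdiff(c("A", "B"), ev$donor))
    expect_equal(ev_sw$min_bp, ev$min_bp)
    expect_equal(ev_sw$avg_bp, ev$avg_bp)
  }
})

test_that("breakpoint histogram counts tract inclusion additively", {
  m <- snp_map("chrIV", seq_len(20) * 1000)
  expect_equal(as.integer(breakpoint_histogram(list(), m)), rep(0L, 20))
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  ev1 <- event_from_calls(c(rep(H, 8), rep(B, 12)),
                          c(rep(H, 4), rep(A, 4), rep(A, 12)), m)
  ev2 <- event_from_calls(c(rep(H, 12), rep(B, 8)),
                          c(rep(H, 7), rep(A, 5), rep(A, 8)), m)
  h <- breakpoint_histogram(list(ev1, ev2), m)
  # ev1 tract markers 5..8, ev2 tract markers 8..12: marker 8 counted twice
  expect_equal(as.integer(h)[8L], 2L)
  expect_equal(as.integer(h)[5L], 1L)
  expect_equal(as.integer(h)[15L], 0L)
  expect_true(all(as.integer(h) <= 2L))
  # hotspot query: events overlapping a stated interval
  expect_equal(count_tract_overlaps(list(ev1, ev2), 7500, 8500), 2L)
  expect_equal(count_tract_overlaps(list(ev1, ev2), 11000, 12000), 1L)
  expect_equal(count_tract_overlaps(list(ev1, ev2), 15000, 16000), 0L)
})

test_that("avg tract length is exactly the midpoint of min and max", {
  map <- generate_snp_map(600, 3e5, seed = 31)
  truths <- simulate_rco_cohort(map, 60, seed = 32)
  for (tr in truths) {
    pr <- noiseless_pair(tr)
    ev <- analyze_sector_pair(pr$red, pr$white, map, min_run = 1)
    if (!ev$open_ended)
      expect_identical(ev$avg_bp, (ev$min_bp + ev$max_bp) / 2)
  }
})
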