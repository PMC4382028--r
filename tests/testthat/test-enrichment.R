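test_that("crossover windows span the conversion from last-het to first-hom", {
  m <- snp_map("chrIV", c(90000, 99000, 100000, 103000, 108000, 109000,
                          115000, 120000))
  H <- "HET"; A <- "HOM_A"; B <- "HOM_B"
  ev <- event_from_calls(c(H, H, H, H, H, B, B, B),
                         c(H, H, A, A, A, A, A, A), m)
  w <- co_windows(list(ev))
  expect_equal(nrow(w), 1L)
  expect_equal(w$left_bp, 99000)
  expect_equal(w$right_bp, 109000)

  # conversionless crossover: window = the shared transition interval
  ev0 <- event_from_calls(c(H, H, H, H, H, B, B, B),
                          c(H, H, H, H, H, A, A, A), m)
  w0 <- co_windows(list(ev0))
  expect_equal(w0$left_bp, 108000)
  expect_equal(w0$right_bp, 109000)

  # one window per event
  ww <- co_windows(rep(list(ev), 88))
  expect_equal(nrow(ww), 88L)

  # event with no proximal heterozygous flank is skipped with a warning
  ev_open <- event_from_calls(rep(B, 8), rep(A, 8), m)
  expect_warning(w_open <- co_windows(list(ev_open)), "skipped")
  expect_equal(nrow(w_open), 0L)
})

test_that("window fraction is summed length over screened space", {
  win1 <- data.frame(event_id = "1", left_bp = 1000, right_bp = 2000)
  expect_equal(window_fraction(win1, 1e5, 1), 0.01)
  none <- data.frame(event_id = character(0), left_bp = numeric(0),
                     right_bp = numeric(0))
  expect_equal(window_fraction(none, 1e5, 1), 0)
  # overlapping windows are summed per event unless merging is requested
  win2 <- data.frame(event_id = c("1", "2"),
                     left_bp = c(1000, 1500), right_bp = c(2000, 2500))
  expect_equal(window_fraction(win2, 1e5, 1), 0.02)
  expect_equal(window_fraction(win2, 1e5, 1, merge = TRUE), 0.015)
  expect_error(window_fraction(win1, 500, 1), "f > 1")
})

test_that("expected counts scale features by sectors and window fraction", {
  # the worked example: 28 ARS elements per screened region, 88 sectors
  expect_equal(round(expected_count(28, 88, 2.12e-2)), 52)
  expect_equal(expected_count(0, 88, 0.02), 0)
  expect_equal(expected_count(10, 1, 0.5), 5)
  expect_error(expected_count(10, 1, 1.5), "\\[0, 1\\]")
})

test_that("observed counts respect interval overlap and the midpoint rule", {
  win <- data.frame(event_id = c("e1", "e2"),
                    left_bp = c(10000, 50000), right_bp = c(20000, 60000))
  iv <- data.frame(chrom = "chrIV",
                   start = c(12000, 19500, 30000, 59000),
                   end = c(13000, 26000, 31000, 75000))
  plain <- feature_track("feat", iv)
  # features 1 (inside), 2 (straddles e1 edge), 4 (straddles e2 edge)
  expect_equal(observed_count(plain, win), 3L)
  # midpoint rule drops the straddlers whose midpoints fall outside
  mid <- feature_track("feat", iv, midpoint_rule = TRUE)
  expect_equal(observed_count(mid, win), 1L)
})

test_that("indexed overlap counting matches a brute-force all-pairs scan", {
  set.seed(77)
  for (rep in 1:3) {
    fs <- sort(sample.int(1e6, 1000))
    fe <- fs + sample.int(5000, 1000)
    wl <- sort(sample.int(1e6, 50))
    wr <- wl + sample.int(20000, 50)
    tk <- feature_track("rand", data.frame(chrom = "c", start = fs, end = fe))
    win <- data.frame(event_id = as.character(seq_along(wl)),
                      left_bp = wl, right_bp = wr)
    expect_equal(observed_count(tk, win),
                 brute_overlap_pairs(fs, fe, wl, wr))
  }
})

test_that("merging adjacent windows of one sector keeps observed counts", {
  # two touching windows from the same sector vs their union
  split_w <- data.frame(event_id = c("e1", "e1"),
                        left_bp = c(10000, 20000), right_bp = c(20000, 30000))
  union_w <- data.frame(event_id = "e1", left_bp = 10000, right_bp = 30000)
  set.seed(78)
  fs <- sort(sample.int(50000, 300))
  tk <- feature_track("f", data.frame(chrom = "c", start = fs,
                                      end = fs + 500))
  expect_equal(observed_count(tk, split_w), observed_count(tk, union_w))
})

test_that("the two-cell chi-square matches its defining formula", {
  z <- enrichment_test(52, 52, 2464)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)

  obs <- 104; exp <- 52; n <- 2464
  hand <- (obs - exp)^2 / exp + (obs - exp)^2 / (n - exp)
  tst <- enrichment_test(obs, exp, n)
  expect_equal(tst$statistic, hand)
  expect_equal(tst$p_value, pchisq(hand, 1, lower.tail = FALSE))
  expect_false(tst$low_expected)
  expect_true(enrichment_test(2, 2.5, 100)$low_expected)
  expect_error(enrichment_test(10, 0, 100), "positive")
  expect_error(enrichment_test(200, 52, 100), "n_total")
})

test_that("uniform features give observed/expected near 1 at large counts", {
  set.seed(79)
  wl <- seq(50000, 950000, by = 100000)
  win <- data.frame(event_id = as.character(seq_along(wl)),
                    left_bp = wl, right_bp = wl + 10000)
  f <- window_fraction(win, 1e6, 1)
  pos <- sample.int(1e6, 10000, replace = TRUE)
  tk <- feature_track("unif", data.frame(chrom = "c", start = pos, end = pos))
  obs <- observed_count(tk, win)
  expect_lt(abs(obs / expected_count(10000, 1, f) - 1), 0.1)
})

test_that("run_enrichment assembles the per-class table", {
  wl <- c(10000, 200000)
  win <- data.frame(event_id = c("1", "2"), left_bp = wl,
                    right_bp = wl + 10000)
  t1 <- feature_track("ars", data.frame(chrom = "c",
                                        start = c(12000, 500000),
                                        end = c(12500, 500100)))
  t2 <- feature_track("ty", data.frame(chrom = "c", start = 205000,
                                       end = 230000),
                      midpoint_rule = TRUE)
  res <- run_enrichment(list(t1, t2), win, region_length = 1e6,
                        n_sectors = 2)
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$class, c("ars", "ty"))
  expect_equal(res$observed, c(1L, 0L))
  expect_equal(res$n_total, c(4L, 2L))
  expect_true(all(res$f == 0.01))
  res_b <- run_enrichment(list(t1, t2), win, 1e6, 2, bonferroni = TRUE)
  expect_equal(res_b$p_adj, pmin(1, res_b$p * 2))
})
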