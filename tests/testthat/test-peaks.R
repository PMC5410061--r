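# helpers for small constructed coverage fixtures
flat_track <- function(len = 20000L, depth = 5L, id = "t",
                       spikes = NULL) {
  v <- rep.int(depth, len)
  if (!is.null(spikes))
    for (i in seq_len(nrow(spikes)))
      v[(spikes$start[i] + 1L):spikes$end[i]] <- spikes$depth[i]
  coverage_track(list(chr1 = v), sample_id = id)
}

test_that("identical IP and input yield no peaks; bad inputs error", {
  tr <- flat_track()
  expect_equal(n_peaks(call_peaks(tr, tr)), 0L)
  empty <- coverage_track(list(chr1 = rep.int(0L, 1000L)), "empty")
  expect_error(call_peaks(tr, empty), "empty input library")
  other <- coverage_track(list(chr2 = rep.int(5L, 1000L)), "other")
  expect_error(call_peaks(tr, other), "chr1")
})

test_that("an enriched window is detected with the Poisson survival P-value", {
  # input 5 reads per 100-nt window; IP spike of 50 reads in one window
  input <- flat_track(depth = 5L, id = "input")
  ip <- flat_track(depth = 5L, id = "ip",
                   spikes = data.frame(start = 10000L, end = 10100L, depth = 50L))
  ps <- call_peaks(ip, input)
  expect_equal(n_peaks(ps), 1L)
  pk <- ps$peaks
  expect_true(pk$start <= 10000L && pk$end >= 10100L)
  expect_true(pk$summit >= 10000L && pk$summit < 10100L)
  # survival-function oracle at the peak level: P(X >= x | lambda)
  lib_ratio <- ip$total_reads / input$total_reads
  lam <- 5 / 100 * (pk$end - pk$start) * lib_ratio
  expect_equal(pk$p_value, sum(dpois(pk$ip_count:2000, lam)), tolerance = 1e-9)
  expect_lt(pk$p_value, 1e-5)
  # fold >= min_fold gate: a 1.5x window is never called at min_fold 2
  ip2 <- flat_track(depth = 5L, id = "ip2",
                    spikes = data.frame(start = 10000L, end = 10100L, depth = 300L))
  expect_equal(n_peaks(call_peaks(ip2, input, min_fold = 100)), 0L)
})

test_that("summit is the leftmost position of maximal IP depth", {
  input <- flat_track(depth = 5L, id = "input")
  v <- rep.int(5L, 20000L)
  v[10001:10100] <- 60L
  v[10030] <- 80L
  v[10060] <- 80L                       # tie: leftmost wins
  ip <- coverage_track(list(chr1 = v), "ip")
  ps <- call_peaks(ip, input)
  expect_equal(ps$peaks$summit[1], 10029L)
})

test_that("overlap_fraction matches the worked examples and brute force", {
  expect_equal(overlap_fraction(100, 200, 100, 200), 1.0)
  expect_equal(overlap_fraction(0, 100, 50, 150), 0.5)
  expect_equal(overlap_fraction(0, 100, 200, 300), 0)
  expect_error(overlap_fraction(5, 5, 0, 10), "zero-length")
  set.seed(31)
  for (i in 1:200) {
    a <- sort(sample.int(500, 2)); a[2] <- a[2] + 1L
    b <- sort(sample.int(500, 2)); b[2] <- b[2] + 1L
    f <- overlap_fraction(a[1], a[2], b[1], b[2])
    expect_identical(f, overlap_fraction(b[1], b[2], a[1], a[2]))  # symmetric
    expect_equal(f, bf_overlap_fraction(a, b))
    # reciprocal denominator is the longer interval
    expect_equal(overlap_fraction(a[1], a[2], b[1], b[2], reciprocal = TRUE),
                 f * min(a[2] - a[1], b[2] - b[1]) /
                   max(a[2] - a[1], b[2] - b[1]))
  }
})

test_that("recurrence follows the >=50% rule and is idempotent", {
  a <- mk_peak_set(data.frame(
    name = c("a1", "a2"), chrom = "chr1",
    start = c(0L, 1000L), end = c(100L, 1150L),
    summit = c(50L, 1075L), ip_count = c(40, 60), input_count = c(5, 5),
    fold = 4, p_value = 1e-10, stringsAsFactors = FALSE), "A")
  b <- mk_peak_set(data.frame(
    name = c("b1", "b2"), chrom = "chr1",
    start = c(49L, 2000L), end = c(149L, 2100L),
    summit = c(99L, 2050L), ip_count = c(35, 50), input_count = c(5, 5),
    fold = 4, p_value = 1e-10, stringsAsFactors = FALSE), "B")
  r <- recurrent_peaks(a, b)
  # a1 vs b1: overlap 51/100 >= 0.5 -> recurrent, union [0,149)
  expect_equal(nrow(r$peaks), 1L)
  expect_equal(r$peaks$start, 0L)
  expect_equal(r$peaks$end, 149L)
  expect_equal(r$peaks$ip_count, 40 + 35)
  # just under threshold: no recurrence
  b2 <- b; b2$peaks$start[1] <- 51L; b2$peaks$end[1] <- 151L
  expect_equal(nrow(recurrent_peaks(a, b2)$peaks), 1L - 1L)
  # idempotence: recurrent_peaks(A, A) preserves A's intervals
  rr <- recurrent_peaks(a, a)
  expect_equal(rr$peaks[, c("start", "end")], a$peaks[, c("start", "end")],
               ignore_attr = TRUE)
})

test_that("common/specific classification partitions both peak sets", {
  set.seed(41)
  x <- mk_peak_set(random_peak_df(30, prefix = "x"), "X")
  y <- mk_peak_set(random_peak_df(30, prefix = "y"), "Y")
  cc <- classify_common_specific(x, y)
  expect_equal(nrow(cc$common) + n_peaks(cc$x_specific), n_peaks(x))
  expect_equal(length(cc$y_common_names) + n_peaks(cc$y_specific), n_peaks(y))
  # disjoint sets: all specific
  y_far <- y
  y_far$peaks$start <- y_far$peaks$start + 10000000L
  y_far$peaks$end <- y_far$peaks$end + 10000000L
  cc2 <- classify_common_specific(x, y_far)
  expect_equal(nrow(cc2$common), 0L)
  expect_equal(n_peaks(cc2$x_specific), n_peaks(x))
  expect_equal(n_peaks(cc2$y_specific), n_peaks(y))
  # identical sets: all common
  cc3 <- classify_common_specific(x, x)
  expect_equal(nrow(cc3$common), n_peaks(x))
  expect_equal(n_peaks(cc3$x_specific), 0L)
})

test_that("replicate reproducibility is recovered through recurrence", {
  # one condition so every replicate dropout hits the measured pair
  cfg <- sim_config(seed = 55, n_genes = 250, genome_size = 2.5e6,
                    n_conditions = 1, reproducibility = 0.8,
                    methylated_fraction = 1, frac_common = 1,
                    rpkm_meanlog = log(40), rpkm_sdlog = 0.3)
  expt <- simulate_experiment(cfg)
  tr <- expt$tracks$cond1
  p1 <- call_peaks(tr[[1]]$ip, tr[[1]]$input)
  p2 <- call_peaks(tr[[2]]$ip, tr[[2]]$input)
  rec <- recurrent_peaks(p1, p2)
  truth <- expt$annotation$truth
  both <- is.na(truth$drop_cond) | truth$drop_cond != "cond1"
  # planted both-replicate peaks recovered as recurrent ~ reproducibility
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    w <- pmin(rec$peaks$end, truth$end[i]) - pmax(rec$peaks$start, truth$start[i])
    any(rec$peaks$chrom == truth$chrom[i] &
          w >= 0.5 * pmin(rec$peaks$end - rec$peaks$start,
                          truth$end[i] - truth$start[i]))
  }, logical(1))
  frac <- mean(hit)
  se <- sqrt(0.8 * 0.2 / nrow(truth))
  expect_gt(frac, 0.8 - 3 * se - 0.05)   # allowance for caller misses
  expect_lt(frac, 0.8 + 3 * se + 0.02)
  # dropped peaks are (almost) never recurrent
  expect_lt(mean(hit[!both]), 0.1)
})
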