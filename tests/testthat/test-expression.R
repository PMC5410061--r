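test_that("RPKM follows the exact formula with its identities", {
  expect_equal(rpkm(10, 2, 1.0), 5.0)
  expect_equal(rpkm(0, 2, 1.0), 0.0)
  expect_error(rpkm(10, 0, 1), "exon_kb")
  expect_error(rpkm(10, 2, 0), "library_m")
  set.seed(91)
  cnt <- sample(0:5000, 50)
  kb <- runif(50, 0.2, 20)
  lm <- runif(50, 1, 60)
  # independent recomputation, element by element
  oracle <- vapply(1:50, function(i) cnt[i] / kb[i] / lm[i], numeric(1))
  expect_equal(rpkm(cnt, kb, lm), oracle, tolerance = 1e-12)
  # linear in count; doubling count and library restores the value
  expect_equal(rpkm(2 * cnt, kb, lm), 2 * rpkm(cnt, kb, lm))
  expect_equal(rpkm(2 * cnt, kb, 2 * lm), rpkm(cnt, kb, lm))
})

test_that("expression tables reproduce known depth and drive DEG calls", {
  models <- structure(list(
    t1 = mk_tx("t1", gene = "g1", exons = cbind(0L, 2000L), cds_tx = c(200L, 1200L)),
    t2 = mk_tx("t2", gene = "g2", exons = cbind(5000L, 7000L), cds_tx = c(200L, 1200L))),
    class = "transcript_models")
  mk_track <- function(d1, d2, id) {
    v <- integer(10000L)
    v[1:2000] <- d1
    v[5001:7000] <- d2
    coverage_track(list(chr1 = v), id)
  }
  ex <- expression_table(mk_track(50L, 10L, "x"), models)
  expect_equal(ex$count, c(50 * 2000, 10 * 2000) / 100)
  lib_m <- attr(ex, "library_reads") / 1e6
  expect_equal(ex$rpkm, ex$count / (2 * lib_m), tolerance = 1e-12)
  # x has gene g1 4x higher; libraries equal
  ey <- expression_table(mk_track(13L, 47L, "y"), models)
  degs <- call_degs(ex, ey)
  expect_equal(degs$direction, c("x-high", "y-high"))
  expect_true(all(degs$p_value < 0.05))
  # identical libraries: no DEGs
  expect_false(any(call_degs(ex, ex)$deg))
  # symmetry: swapping conditions flips direction, preserves P
  rev <- call_degs(ey, ex)
  expect_equal(rev$p_value, degs$p_value, tolerance = 1e-10)
  expect_equal(rev$direction, c("y-high", "x-high"))
})

test_that("Fisher exact P matches enumeration, fisher.test, and the flat table", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p_value, 1.0)
  # full enumeration over fixed margins for [[5,0],[0,5]]
  enum_p <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c
    p_obs <- exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k))
    tot <- 0
    for (aa in max(0, k - n2):min(k, m)) {
      pp <- exp(lchoose(m, aa) + lchoose(n2, k - aa) - lchoose(m + n2, k))
      if (pp <= p_obs * (1 + 1e-7)) tot <- tot + pp
    }
    min(1, tot)
  }
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p_value, enum_p(5, 0, 0, 5),
               tolerance = 1e-12)
  set.seed(92)
  for (i in 1:100) {
    cells <- as.vector(stats::rmultinom(1, sample(4:200, 1), runif(4, 0.05, 1)))
    p1 <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    expect_equal(p1, enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    p2 <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
    expect_equal(p1, p2, tolerance = 1e-8)
  }
  # Haldane-corrected odds ratio when a cell is empty
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$odds_ratio,
               (5.5 * 5.5) / (0.5 * 0.5))
})

test_that("the Fisher statistic has power at OR 4 with hundreds of DE genes", {
  set.seed(93)
  n <- 500
  # joint presence probabilities with odds ratio 4 at balanced margins
  pxy <- c(0.40, 0.165, 0.165, 0.27)   # OR = (.40*.27)/(.165^2) ~ 4
  cells <- as.vector(stats::rmultinom(1, n, pxy))
  p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
  expect_lt(p, 0.001)
})

test_that("association table construction follows its descriptor", {
  models <- structure(lapply(1:6, function(i)
    mk_tx(sprintf("t%d", i), gene = sprintf("g%d", i),
          exons = cbind((i - 1L) * 5000L, (i - 1L) * 5000L + 1400L),
          cds_tx = c(200L, 900L))), class = "transcript_models")
  names(models) <- sprintf("t%d", 1:6)
  pk <- function(gene_i, name) data.frame(
    name = name, chrom = "chr1",
    start = (gene_i - 1L) * 5000L + 600L, end = (gene_i - 1L) * 5000L + 700L,
    summit = (gene_i - 1L) * 5000L + 650L,
    ip_count = 50, input_count = 5, fold = 5, p_value = 1e-9,
    stringsAsFactors = FALSE)
  peaks_x <- mk_peak_set(rbind(pk(1, "x1"), pk(2, "x2")), "X")  # genes g1, g2
  peaks_y <- mk_peak_set(pk(2, "y1"), "Y")                      # gene g2
  degs <- data.frame(gene_id = sprintf("g%d", 1:6),
                     direction = c("x-high", "x-high", "x-high",
                                   "y-high", "y-high", "none"),
                     stringsAsFactors = FALSE)
  res <- methylation_expression_association(degs, peaks_x, peaks_y, models)
  xh <- res[["x-high"]]
  expect_true(xh$computable)
  expect_equal(xh$n_genes, 3L)
  expect_equal(xh$n_peak_x, 2L)       # g1, g2 have x peaks
  expect_equal(xh$n_peak_y, 1L)       # only g2 has a y peak
  expect_equal(sum(xh$table), 3)
  expect_match(xh$descriptor, "peak presence in x")
  # alternative construction
  res2 <- methylation_expression_association(
    degs, peaks_x, peaks_y, models, construction = "direction_by_presence")
  expect_equal(sum(res2[["x"]]$table), 5)     # all DE genes
  expect_match(res2[["x"]]$descriptor, "direction x-high")
  # no DE genes in a direction -> flagged not computable
  res3 <- methylation_expression_association(
    degs[degs$direction == "x-high", ], peaks_x, peaks_y, models)
  expect_false(res3[["y-high"]]$computable)
})
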