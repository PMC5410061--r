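# one coding transcript fixture used across blocks:
# exon 0-1400, 5'UTR 200 / CDS 900 / 3'UTR 300
fixture_models <- function() {
  m <- mk_tx(exons = cbind(0L, 1400L), cds_tx = c(200L, 900L))
  structure(list(t1 = m), class = "transcript_models")
}

peak_at <- function(summit, chrom = "chr1", name = "p1") {
  data.frame(name = name, chrom = chrom, start = summit - 50L,
             end = summit + 50L, summit = summit,
             ip_count = 50, input_count = 5, fold = 5, p_value = 1e-9,
             stringsAsFactors = FALSE)
}

test_that("summit-exclusive assignment labels summits by segment", {
  models <- fixture_models()
  # stop codon at transcript coordinate 1100 (genomic 1100 on + strand)
  expect_equal(assign_segment(peak_at(1100L), models)$segment, "stop codon")
  expect_equal(assign_segment(peak_at(50L), models)$segment, "5'UTR")
  expect_equal(assign_segment(peak_at(650L), models)$segment, "CDS")
  expect_equal(assign_segment(peak_at(99999L), models)$segment, "other")
  # exactly one label per peak (function property)
  asn <- assign_segment(rbind(peak_at(1100L), peak_at(50L, name = "p2")), models)
  expect_equal(nrow(asn), 2L)
  expect_false(any(is.na(asn$segment)))
})

test_that("multi-membership assignment returns every touched label", {
  models <- fixture_models()
  # peak spanning the CDS/stop-window boundary touches both labels
  labs <- assign_segment(peak_at(1005L), models, mode = "multi")[[1]]
  expect_true(all(c("CDS", "stop codon") %in% labs))
  # intergenic part contributes "other"
  labs2 <- assign_segment(peak_at(1395L), models, mode = "multi")[[1]]
  expect_true("other" %in% labs2)
})

test_that("segment table: empty input warns; exclusive percentages sum to 100", {
  models <- fixture_models()
  expect_warning(tab0 <- segment_table(meripr:::empty_peaks(), models), "empty")
  expect_true(all(tab0$count == 0))
  p <- do.call(rbind, lapply(c(50L, 250L, 650L, 1100L, 1300L),
                             function(s) peak_at(s, name = paste0("p", s))))
  tab <- segment_table(p, models)
  expect_equal(sum(tab$percent), 100, tolerance = 1e-6)
  expect_gte(sum(tab$multi_percent), sum(tab$percent))
})

test_that("60-bin metagene conserves depth and is flat under uniform coverage", {
  ann <- shared_ann()
  models <- longest_coding_transcripts(ann$models)
  # uniform depth 100 over every exonic base
  lens <- vapply(ann$genome, length, integer(1))
  v <- lapply(lens, function(n) integer(n))
  for (m in models)
    for (i in seq_along(m$exon_starts))
      v[[m$chrom]][(m$exon_starts[i] + 1L):m$exon_ends[i]] <- 100L
  track <- coverage_track(v, "uniform")
  prof <- metagene_60bin(track, models)
  expect_equal(nrow(prof), 60L)
  expect_lt(max(prof$value) / min(prof$value), 1.05)
  # conservation: un-normalised bin sums reproduce total depth per gene
  gt <- attr(prof, "gene_totals")
  for (m in models)
    expect_equal(unname(gt[m$transcript_id]), 100 * m$width)
  # a 600-nt transcript yields ten 10-nt bins
  m600 <- mk_tx("m600", exons = cbind(0L, 600L), cds_tx = c(100L, 300L))
  bounds <- floor(600 * (0:60) / 60)
  expect_true(all(diff(bounds) == 10L))
})

test_that("three-part metagene localises summit mass", {
  models <- fixture_models()
  # all summits just before the stop codon (CDS coordinate ~1)
  p <- do.call(rbind, lapply(1:20, function(i)
    peak_at(1095L, name = paste0("s", i))))
  prof <- metagene_3part(p, models, bins_per_part = 10L)
  cds <- prof[prof$part == "CDS", ]
  expect_equal(cds$value[10], 1)
  expect_true(all(cds$value[-10] == 0))
  # uniform summits are roughly flat within each part
  set.seed(61)
  pu <- do.call(rbind, lapply(1:400, function(i)
    peak_at(sample(60:1340, 1), name = paste0("u", i))))
  pf <- metagene_3part(pu, models, bins_per_part = 5L)
  expect_true(all(abs(pf$value[pf$part == "CDS"] - 0.2) < 0.12))
})

test_that("stop-skewed planting yields a CDS-end peak above the CDS start", {
  ann <- shared_ann()
  models <- longest_coding_transcripts(ann$models)
  tr <- ann$truth
  p <- data.frame(name = tr$peak_id, chrom = tr$chrom, start = tr$start,
                  end = tr$end, summit = tr$summit,
                  ip_count = 50, input_count = 5, fold = 5, p_value = 1e-9,
                  stringsAsFactors = FALSE)
  prof <- metagene_3part(p, models)
  cds <- prof$value[prof$part == "CDS"]
  expect_gt(cds[length(cds)], cds[1])    # end of CDS more pronounced than start
})

test_that("density by expression partitions transcripts and averages correctly", {
  models <- fixture_models()
  # 12 transcripts across 3 groups, 5 peaks on one of them
  models <- structure(lapply(1:12, function(i) {
    mk_tx(sprintf("t%02d", i), gene = sprintf("g%02d", i),
          exons = cbind((i - 1L) * 5000L, (i - 1L) * 5000L + 1400L),
          cds_tx = c(200L, 900L))
  }), class = "transcript_models")
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  expr <- data.frame(gene_id = sprintf("g%02d", 1:12), rpkm = 3 + (1:12))
  p <- do.call(rbind, lapply(1:5, function(i)
    peak_at(600L + 150L * i, name = paste0("d", i))))  # all on gene g01
  d <- density_by_expression(p, expr, models, n_groups = 3L)
  expect_equal(d$n_transcripts, c(4L, 4L, 4L))
  expect_equal(sum(d$n_peaks), 5L)
  expect_equal(d$density[1], 5 / 4)
  # group densities weighted by sizes average to the global density
  expect_equal(sum(d$density * d$n_transcripts) / sum(d$n_transcripts),
               attr(d, "global_density"))
  # zero peaks -> all densities zero
  d0 <- density_by_expression(p[0, ], expr, models, n_groups = 3L)
  expect_true(all(d0$density == 0))
  # fewer expressed transcripts than groups errors
  expect_error(density_by_expression(p, expr[1:5, ], models, n_groups = 11L),
               "fewer expressed")
})
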