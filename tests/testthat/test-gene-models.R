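test_that("GTF import converts 1-based closed coordinates and UTR/CDS lengths", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t1400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t201\t1100\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t2000\t2200\t.\t+\t.\tgene_id "g2"; transcript_id "t2";'),
    gtf)
  models <- read_gtf(gtf)
  expect_length(models, 2L)
  t1 <- models[["t1"]]
  expect_equal(t1$exon_starts, 0L)
  expect_equal(t1$exon_ends, 1400L)
  expect_equal(t1$utr5_len, 200L)
  expect_equal(t1$cds_len, 900L)
  expect_equal(t1$utr3_len, 300L)
  expect_true(t1$coding)
  expect_false(models[["t2"]]$coding)
})

test_that("malformed GTF lines and exon-incompatible CDS are rejected", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "not a gtf line"), bad)
  expect_error(read_gtf(bad), "malformed GTF line 2")
  out <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\tCDS\t50\t300\t.\t+\t0\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t1000\t1500\t.\t+\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tsrc\tCDS\t1100\t1400\t.\t+\t0\tgene_id "g2"; transcript_id "t2";'),
    out)
  expect_warning(models <- read_gtf(out), "rejected")
  expect_length(models, 1L)
  expect_identical(names(models), "t2")
})

test_that("minus-strand transcript coordinate 0 is the rightmost exonic base", {
  m <- mk_tx(strand = "-", exons = cbind(c(100L, 400L), c(200L, 500L)))
  expect_equal(genomic_to_tx(m, 499L), 0L)
  expect_equal(genomic_to_tx(m, 100L), m$width - 1L)
  expect_equal(tx_to_genomic(m, 0L), 499L)
  # intron position maps to NA
  expect_true(is.na(genomic_to_tx(m, 300L)))
})

test_that("genomic<->transcript mapping round-trips on random transcripts", {
  set.seed(11)
  for (i in 1:50) {
    m <- random_tx(i)
    gpos <- bf_tx_positions(m)
    tx <- genomic_to_tx(m, gpos)
    expect_identical(tx, seq.int(0L, m$width - 1L))       # brute-force map
    expect_identical(tx_to_genomic(m, tx), gpos)          # identity back
  }
})

test_that("six-segment partition matches the worked layout and clips windows", {
  m <- mk_tx(exons = cbind(0L, 1400L), cds_tx = c(200L, 900L))
  p <- partition_transcript(m, w = 100L)
  expect_equal(unname(p$segments[["start codon"]]), cbind(100L, 300L),
               ignore_attr = TRUE)
  expect_equal(unname(p$segments[["stop codon"]]), cbind(1000L, 1200L),
               ignore_attr = TRUE)
  expect_equal(unname(p$segments[["5'UTR"]]), cbind(0L, 100L), ignore_attr = TRUE)
  expect_equal(unname(p$segments[["CDS"]]), cbind(300L, 1000L), ignore_attr = TRUE)
  expect_equal(unname(p$segments[["3'UTR"]]), cbind(1200L, 1400L),
               ignore_attr = TRUE)
  # w = 0: codon windows vanish, partition reduces to the three regions
  p0 <- partition_transcript(m, w = 0L)
  expect_equal(nrow(p0$segments[["start codon"]]), 0L)
  expect_equal(nrow(p0$segments[["stop codon"]]), 0L)
  expect_equal(unname(p0$segments[["CDS"]]), cbind(200L, 1100L), ignore_attr = TRUE)
  # w larger than the transcript: clipped, never an error
  pw <- partition_transcript(m, w = 5000L)
  lens <- vapply(pw$segments, function(s) sum(s[, 2] - s[, 1]), numeric(1))
  expect_equal(sum(lens), m$width)
})

test_that("the six segments tile random transcripts exactly once per base", {
  set.seed(12)
  for (i in 1:200) {
    m <- random_tx(i)
    w <- sample(c(0L, 10L, 50L, 100L, 500L), 1L)
    p <- partition_transcript(m, w)
    hits <- integer(m$width)
    for (lab in names(p$segments)) {
      s <- p$segments[[lab]]
      for (r in seq_len(nrow(s)))
        hits[(s[r, 1] + 1L):s[r, 2]] <- hits[(s[r, 1] + 1L):s[r, 2]] + 1L
    }
    expect_true(all(hits == 1L))
    # per-base labels agree with the independent rule
    tpos <- sample.int(m$width, min(25L, m$width)) - 1L
    expect_identical(segment_at(p, tpos),
                     vapply(tpos, function(t) bf_segment_label(m, t, w),
                            character(1)))
  }
})

test_that("strand reversal preserves segment lengths", {
  set.seed(13)
  for (i in 1:20) {
    m <- random_tx(i)
    flip <- if (m$strand == "+") "-" else "+"
    # rebuild the same exonic structure on the other strand with the CDS
    # occupying the same transcript-coordinate range
    m2 <- mk_tx("flip", chrom = m$chrom, strand = flip,
                exons = cbind(m$exon_starts, m$exon_ends),
                cds_tx = c(m$utr5_len, m$cds_len))
    p1 <- partition_transcript(m, 50L)
    p2 <- partition_transcript(m2, 50L)
    l1 <- vapply(p1$segments, function(s) sum(s[, 2] - s[, 1]), numeric(1))
    l2 <- vapply(p2$segments, function(s) sum(s[, 2] - s[, 1]), numeric(1))
    expect_equal(l1, l2)
  }
})

test_that("segment BED export projects to sorted genomic BED6 records", {
  m <- mk_tx(exons = cbind(c(0L, 700L), c(500L, 1600L)), cds_tx = c(200L, 900L))
  models <- structure(list(t1 = m), class = "transcript_models")
  bed <- tempfile(fileext = ".bed")
  n <- write_segments_bed(models, bed, w = 100L)
  df <- read.table(bed, sep = "\t", quote = "")
  expect_equal(nrow(df), n)
  expect_true(all(df$V2 < df$V3))
  # records tile the exons exactly once
  bases <- unlist(apply(df, 1, function(r)
    seq.int(as.integer(r[2]), as.integer(r[3]) - 1L)))
  expect_identical(sort(as.integer(bases)), sort(bf_tx_positions(m)))
})
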