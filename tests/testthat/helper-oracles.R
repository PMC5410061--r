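# Brute-force oracles and small fixture builders shared across tests.
# Every oracle works per base / by exhaustive loops, independently of the
# interval algebra it checks.

# transcript_model from an exon matrix and optional transcript-coordinate
# CDS range (cds_tx = c(utr5_len, cds_len))
mk_tx <- function(id = "t1", gene = id, chrom = "chr1", strand = "+",
                  exons, cds_tx = NULL) {
  tmp <- transcript_model(id, gene, chrom, strand, exons[, 1], exons[, 2])
  if (is.null(cds_tx)) return(tmp)
  g <- tx_to_genomic(tmp, c(cds_tx[1], cds_tx[1] + cds_tx[2] - 1L))
  transcript_model(id, gene, chrom, strand, exons[, 1], exons[, 2],
                   cds_start = min(g), cds_end = max(g) + 1L)
}

# enumerated genomic positions of a transcript in transcript order
bf_tx_positions <- function(model) {
  g <- unlist(lapply(seq_along(model$exon_starts), function(i)
    model$exon_starts[i]:(model$exon_ends[i] - 1L)))
  if (model$strand == "-") rev(g) else g
}

# random coding transcript fixture
random_tx <- function(i, chrom = "chr1", max_exons = 4L) {
  n_ex <- sample.int(max_exons, 1L)
  widths <- sample(30:300, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1L) sample(20:200, n_ex - 1L, replace = TRUE) else integer(0)
  start <- sample.int(10000L, 1L)
  starts <- start + c(0L, cumsum(widths[-n_ex] + gaps))
  L <- sum(widths)
  u5 <- sample.int(max(1L, L %/% 3), 1L)
  cds <- sample.int(max(1L, L - u5 - 5L), 1L)
  mk_tx(sprintf("rt%03d", i), chrom = chrom,
        strand = sample(c("+", "-"), 1L),
        exons = cbind(starts, starts + widths),
        cds_tx = c(u5, cds))
}

# per-base segment label (independent of partition_transcript's interval
# construction): region label, overridden by codon windows, contested
# bases split at the codon midpoint
bf_segment_label <- function(model, t, w) {
  if (!model$coding) return("other")
  sc <- model$start_codon; sp <- model$stop_codon
  lab <- if (t < model$utr5_len) "5'UTR"
         else if (t < sc + model$cds_len) "CDS"
         else "3'UTR"
  in_start <- t >= sc - w & t < sc + w
  in_stop <- t >= sp - w & t < sp + w
  if (in_start && in_stop) {
    if (t < floor((sc + sp) / 2)) "start codon" else "stop codon"
  } else if (in_start) "start codon"
  else if (in_stop) "stop codon"
  else lab
}

# per-base fractional overlap of two 0-based half-open intervals
bf_overlap_fraction <- function(a, b) {
  ia <- seq.int(a[1], a[2] - 1L)
  ib <- seq.int(b[1], b[2] - 1L)
  length(intersect(ia, ib)) / min(length(ia), length(ib))
}

# random non-overlapping peak data.frame on one chromosome
random_peak_df <- function(n, chrom = "chr1", span = 100000L, prefix = "p") {
  starts <- sort(sample.int(span, n))
  widths <- sample(50:400, n, replace = TRUE)
  ends <- starts + widths
  keep <- c(TRUE, starts[-1L] >= cummax(ends[-n]))
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(name = sprintf("%s%03d", prefix, seq_along(starts)),
             chrom = chrom, start = starts, end = ends,
             summit = starts + (ends - starts) %/% 2L,
             ip_count = sample(20:200, length(starts), replace = TRUE),
             input_count = sample(5:20, length(starts), replace = TRUE),
             fold = 4, p_value = runif(length(starts), 1e-30, 1e-6),
             stringsAsFactors = FALSE)
}

mk_peak_set <- function(df, id = "s1") {
  meripr:::new_peak_set(df, id, params = list(ip_reads = 1e5, input_reads = 1e5))
}

# brute-force best partner (max overlap fraction of the shorter interval,
# ties to leftmost partner) for every row of a against b
bf_best_partner <- function(a, b) {
  out <- data.frame(partner = rep(NA_integer_, nrow(a)), frac = 0)
  for (i in seq_len(nrow(a))) {
    best <- NA_integer_; bf <- 0
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      f <- bf_overlap_fraction(c(a$start[i], a$end[i]), c(b$start[j], b$end[j]))
      if (f <= 0) next
      if (f > bf + 1e-12 ||
          (abs(f - bf) <= 1e-12 && !is.na(best) && b$start[j] < b$start[best])) {
        best <- j; bf <- f
      }
    }
    out$partner[i] <- best; out$frac[i] <- bf
  }
  out
}

# brute-force recurrent output intervals: union of each recurrent rep1 peak
# with its best partner, then merged by per-base union
bf_recurrent_intervals <- function(a, b, threshold = 0.5) {
  bp <- bf_best_partner(a, b)
  sel <- which(!is.na(bp$partner) & bp$frac >= threshold)
  if (!length(sel)) return(data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0)))
  base_cov <- list()
  for (i in sel) {
    j <- bp$partner[i]
    bases <- seq.int(min(a$start[i], b$start[j]), max(a$end[i], b$end[j]) - 1L)
    ch <- a$chrom[i]
    base_cov[[ch]] <- union(base_cov[[ch]], bases)
  }
  out <- do.call(rbind, lapply(names(base_cov), function(ch) {
    v <- sort(base_cov[[ch]])
    brk <- c(0L, which(diff(v) > 1L), length(v))
    data.frame(chrom = ch, start = v[brk[-length(brk)] + 1L],
               end = v[brk[-1L]] + 1L)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# small simulated annotation reused by several files (built once per run)
shared_ann <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_annotation(sim_config(seed = 404, n_genes = 60,
                                               genome_size = 6e5))
    cache
  }
})
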