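# Enrichment peak detection (IP vs input) and the overlap algebra used for
# replicate recurrence and cross-condition comparison.
#
# The caller is a deliberate simplification of the MACS idea for depth-level
# data: sliding windows are tested against a Poisson background whose rate
# is the larger of the genome-wide input rate and the input rate in a
# +/- 2.5 kb neighbourhood (a local-lambda background), after scaling the
# input to the IP library size. There is no fragment-shift model and no
# Mfold candidate-training step; a minimum fold-enrichment filter stands in
# for the Mfold band. This deviation is recorded in the peak-set metadata.

peak_columns <- c("name", "chrom", "start", "end", "summit",
                  "ip_count", "input_count", "fold", "p_value")

empty_peaks <- function() {
  data.frame(name = character(0), chrom = character(0),
             start = integer(0), end = integer(0), summit = integer(0),
             ip_count = numeric(0), input_count = numeric(0),
             fold = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}

new_peak_set <- function(peaks, sample_id, params = list()) {
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks, sample_id = sample_id, params = params),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peak(s)\n", x$sample_id, nrow(x$peaks)))
  if (nrow(x$peaks)) print(head(x$peaks, 5))
  invisible(x)
}

#' Number of peaks in a peak set
#' @param set a \code{peak_set}.
#' @return Integer count.
#' @export
n_peaks <- function(set) nrow(set$peaks)

# ---- caller -----------------------------------------------------------------

#' Call enrichment peaks from IP versus input coverage
#'
#' Slides windows along each reference, converts windowed depth to read
#' counts (depth sum / fragment length), and tests the IP count against a
#' Poisson rate derived from the input: the largest of the genome-wide
#' input rate, the input rate in a window extended by
#' \code{local_halfwidth} on each side, and the window's own input rate
#' (the local-lambda hierarchy; the last term protects highly expressed
#' genes whose neighbourhood average is diluted by introns), scaled to the
#' IP library size.
#' Windows with upper-tail \code{P <= p_cutoff} and library-scaled fold
#' enrichment \code{>= min_fold} are merged (gap \code{<= merge_gap}) into
#' peaks; each peak's counts, fold, P-value and summit (leftmost position
#' of maximal IP depth) are then recomputed over the merged interval.
#'
#' @param ip,input \code{\link{coverage_track}} objects on the same
#'   references.
#' @param p_cutoff Poisson upper-tail P-value cutoff (default 1e-5).
#' @param min_fold minimum library-scaled IP/input fold (default 2).
#' @param window sliding-window width in nt (default 100).
#' @param step window step in nt (default \code{window / 2}).
#' @param merge_gap maximum gap between significant windows merged into one
#'   peak (default 100 nt).
#' @param local_halfwidth half-width of the local background neighbourhood
#'   (default 2500 nt).
#' @return A \code{peak_set}; peaks are non-overlapping within the sample,
#'   coordinates 0-based half-open.
#' @export
call_peaks <- function(ip, input, p_cutoff = 1e-5, min_fold = 2,
                       window = 100L, step = window %/% 2L,
                       merge_gap = 100L, local_halfwidth = 2500L) {
  stopifnot(is(ip, "coverage_track"), is(input, "coverage_track"))
  if (input$depth_sum <= 0) stop("empty input library: background undefined")
  missing_ref <- setdiff(names(ip$depth), names(input$depth))
  if (length(missing_ref))
    stop("reference present in IP but not input: ", paste(missing_ref, collapse = ", "))
  fraglen <- ip$fragment_len
  lib_ratio <- ip$total_reads / input$total_reads
  genome_len <- sum(as.numeric(track_seqlengths(input)[names(ip$depth)]))
  genome_rate <- input$depth_sum / genome_len        # depth per base
  rows <- list()
  for (chrom in names(ip$depth)) {
    ipr <- ip$depth[[chrom]]
    inr <- input$depth[[chrom]]
    len <- length(ipr)
    if (length(inr) != len)
      stop("reference length mismatch for ", chrom)
    starts <- seq.int(1L, max(1L, len - window + 1L), by = step)
    widths <- pmin(window, len - starts + 1L)
    ip_sum <- IRanges::viewSums(IRanges::Views(ipr, start = starts, width = widths))
    nz <- which(ip_sum > 0)
    if (!length(nz)) next
    s <- starts[nz]; wd <- widths[nz]
    ls <- pmax(1L, s - local_halfwidth)
    le <- pmin(len, s + wd - 1L + local_halfwidth)
    loc_sum <- IRanges::viewSums(IRanges::Views(inr, start = ls, width = le - ls + 1L))
    loc_rate <- loc_sum / (le - ls + 1)
    win_rate <- IRanges::viewSums(IRanges::Views(inr, start = s, width = wd)) / wd
    lam <- pmax(loc_rate, win_rate, genome_rate) * wd / fraglen * lib_ratio
    x <- round(ip_sum[nz] / fraglen)
    p <- ppois(x - 1, lam, lower.tail = FALSE)
    cand <- which(x > 0 & p <= p_cutoff & x / lam >= min_fold)
    if (!length(cand)) next
    merged <- IRanges::reduce(IRanges::IRanges(s[cand], width = wd[cand]),
                              min.gapwidth = merge_gap + 1L)
    ms <- IRanges::start(merged); me <- IRanges::end(merged)
    for (i in seq_along(ms)) {
      pk_ip <- as.integer(ipr[ms[i]:me[i]])
      ipc <- max(1, round(sum(pk_ip) / fraglen))
      pls <- max(1L, ms[i] - local_halfwidth)
      ple <- min(len, me[i] + local_halfwidth)
      pk_in <- sum(as.integer(inr[ms[i]:me[i]]))
      lrate <- max(sum(as.integer(inr[pls:ple])) / (ple - pls + 1),
                   pk_in / (me[i] - ms[i] + 1), genome_rate)
      lam_pk <- lrate * (me[i] - ms[i] + 1) / fraglen * lib_ratio
      inc <- pk_in / fraglen
      pv <- max(ppois(ipc - 1, lam_pk, lower.tail = FALSE), .Machine$double.xmin)
      rows[[length(rows) + 1L]] <- data.frame(
        name = NA_character_, chrom = chrom,
        start = ms[i] - 1L, end = me[i],
        summit = ms[i] - 1L + which.max(pk_ip) - 1L,
        ip_count = ipc, input_count = inc,
        fold = ipc / lam_pk, p_value = pv,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- if (length(rows)) do.call(rbind, rows) else empty_peaks()
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  if (nrow(peaks))
    peaks$name <- sprintf("%s_peak_%d", ip$sample_id, seq_len(nrow(peaks)))
  new_peak_set(peaks, sample_id = ip$sample_id,
               params = list(p_cutoff = p_cutoff, min_fold = min_fold,
                             window = window, step = step,
                             merge_gap = merge_gap,
                             local_halfwidth = local_halfwidth,
                             fragment_len = fraglen,
                             ip_reads = ip$total_reads,
                             input_reads = input$total_reads,
                             caller = "poisson-local-lambda (MACS-like, no shifting model, no Mfold training)"))
}

# ---- overlap algebra --------------------------------------------------------

#' Fractional overlap of two intervals
#'
#' Overlap length divided by the length of the shorter interval (the
#' lenient, symmetric reading of "at least 50\% overlapping lengths"); with
#' \code{reciprocal = TRUE} the denominator is the longer interval, so a
#' threshold on the result requires the fraction of both intervals.
#'
#' @param a_start,a_end,b_start,b_end interval bounds, 0-based half-open;
#'   vectorised.
#' @param reciprocal use the longer interval as denominator.
#' @return Numeric vector in \code{[0, 1]}; 0 when disjoint.
#' @export
overlap_fraction <- function(a_start, a_end, b_start, b_end, reciprocal = FALSE) {
  if (any(a_end <= a_start) || any(b_end <= b_start))
    stop("zero-length interval")
  inter <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  denom <- if (reciprocal) pmax(a_end - a_start, b_end - b_start)
           else pmin(a_end - a_start, b_end - b_start)
  inter / denom
}

# Best-overlap pairing: for each row of a, the index of its best partner in
# b (max overlap fraction, ties to the leftmost partner) and the fraction.
best_overlap_pairs <- function(a, b, reciprocal = FALSE) {
  partner <- rep(NA_integer_, nrow(a))
  frac <- rep(0, nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(partner = partner, frac = frac))
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == chrom)
    bi <- which(b$chrom == chrom)
    ira <- IRanges::IRanges(a$start[ai] + 1L, a$end[ai])
    irb <- IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    hits <- IRanges::findOverlaps(ira, irb)
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    f <- overlap_fraction(a$start[ai][qh], a$end[ai][qh],
                          b$start[bi][sh], b$end[bi][sh],
                          reciprocal = reciprocal)
    # best fraction, tie -> leftmost partner start
    o <- order(qh, -f, b$start[bi][sh])
    first <- o[!duplicated(qh[o])]
    partner[ai[qh[first]]] <- bi[sh[first]]
    frac[ai[qh[first]]] <- f[first]
  }
  data.frame(partner = partner, frac = frac)
}

#' Replicate-recurrent peaks
#'
#' A peak of \code{rep1} is recurrent when it shares at least
#' \code{threshold} fractional overlap (see \code{\link{overlap_fraction}})
#' with some peak of \code{rep2}. Each recurrent peak is emitted as the
#' interval union of the matched pair; counts are pooled across the two
#' replicates, the P-value is recomputed from the pooled Poisson rate, and
#' overlapping output intervals are re-merged.
#'
#' @param rep1,rep2 \code{peak_set} objects of two biological replicates.
#' @param threshold minimum overlap fraction (default 0.5).
#' @param reciprocal require the fraction of both intervals.
#' @return A \code{peak_set} of recurrent peaks.
#' @export
recurrent_peaks <- function(rep1, rep2, threshold = 0.5, reciprocal = FALSE) {
  stopifnot(is(rep1, "peak_set"), is(rep2, "peak_set"))
  a <- rep1$peaks; b <- rep2$peaks
  sample_id <- paste(rep1$sample_id, rep2$sample_id, sep = "+")
  params <- rep1$params
  params$recurrence_threshold <- threshold
  params$reciprocal <- reciprocal
  ip_lib <- sum(rep1$params$ip_reads, rep2$params$ip_reads)
  in_lib <- sum(rep1$params$input_reads, rep2$params$input_reads)
  lib_ratio <- if (length(in_lib) && !is.na(in_lib) && in_lib > 0) ip_lib / in_lib else 1
  bp <- best_overlap_pairs(a, b, reciprocal = reciprocal)
  sel <- which(!is.na(bp$partner) & bp$frac >= threshold)
  if (!length(sel))
    return(new_peak_set(empty_peaks(), sample_id, params))
  pair <- data.frame(
    chrom = a$chrom[sel],
    start = pmin(a$start[sel], b$start[bp$partner[sel]]),
    end = pmax(a$end[sel], b$end[bp$partner[sel]]),
    a_idx = sel, b_idx = bp$partner[sel])
  rows <- list()
  for (chrom in unique(pair$chrom)) {
    pc <- pair[pair$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(pc$start + 1L, pc$end)
    merged <- IRanges::reduce(ir)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, merged))
    for (g in seq_along(merged)) {
      members <- which(grp == g)
      ai <- unique(pc$a_idx[members]); bi <- unique(pc$b_idx[members])
      ipc <- sum(a$ip_count[ai]) + sum(b$ip_count[bi])
      inc <- sum(a$input_count[ai]) + sum(b$input_count[bi])
      lam <- max(inc * lib_ratio, .Machine$double.eps)
      top <- ai[which.max(a$ip_count[ai])]
      rows[[length(rows) + 1L]] <- data.frame(
        name = NA_character_, chrom = chrom,
        start = IRanges::start(merged)[g] - 1L,
        end = IRanges::end(merged)[g],
        summit = a$summit[top],
        ip_count = ipc, input_count = inc,
        fold = ipc / lam,
        p_value = max(ppois(round(ipc) - 1, lam, lower.tail = FALSE),
                      .Machine$double.xmin),
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  peaks$name <- sprintf("%s_peak_%d", sample_id, seq_len(nrow(peaks)))
  params$ip_reads <- ip_lib
  params$input_reads <- in_lib
  new_peak_set(peaks, sample_id, params)
}

#' Classify peaks of two conditions as common or condition-specific
#'
#' Every peak of \code{x} is either paired with its best-overlap partner in
#' \code{y} (fraction \code{>= threshold}; ties to the leftmost partner) or
#' declared x-specific, and symmetrically for \code{y}. Pairing follows the
#' standard tissue/condition comparison rule: common at >= 50\% overlapping
#' lengths, specific below.
#'
#' @param x,y \code{peak_set} objects (typically replicate-recurrent sets)
#'   for two conditions.
#' @param threshold minimum overlap fraction (default 0.5).
#' @param reciprocal require the fraction of both intervals.
#' @return A list of class \code{peak_comparison}:
#'   \code{common} (data.frame of x-side pairs with both peaks' coordinates
#'   and counts), \code{x_specific} and \code{y_specific}
#'   (\code{peak_set}s), and \code{y_common_names} (names of y peaks with a
#'   partner, so that \code{nrow(common) + n_peaks(x_specific) == n_peaks(x)}
#'   and \code{length(y_common_names) + n_peaks(y_specific) == n_peaks(y)}).
#' @export
classify_common_specific <- function(x, y, threshold = 0.5, reciprocal = FALSE) {
  stopifnot(is(x, "peak_set"), is(y, "peak_set"))
  bx <- best_overlap_pairs(x$peaks, y$peaks, reciprocal = reciprocal)
  by <- best_overlap_pairs(y$peaks, x$peaks, reciprocal = reciprocal)
  x_common <- which(!is.na(bx$partner) & bx$frac >= threshold)
  y_common <- which(!is.na(by$partner) & by$frac >= threshold)
  common <- if (length(x_common)) {
    xi <- x_common; yi <- bx$partner[x_common]
    data.frame(
      x_name = x$peaks$name[xi], y_name = y$peaks$name[yi],
      chrom = x$peaks$chrom[xi],
      start = pmin(x$peaks$start[xi], y$peaks$start[yi]),
      end = pmax(x$peaks$end[xi], y$peaks$end[yi]),
      x_start = x$peaks$start[xi], x_end = x$peaks$end[xi],
      y_start = y$peaks$start[yi], y_end = y$peaks$end[yi],
      x_summit = x$peaks$summit[xi],
      x_count = x$peaks$ip_count[xi], y_count = y$peaks$ip_count[yi],
      overlap = bx$frac[x_common],
      stringsAsFactors = FALSE)
  } else {
    data.frame(x_name = character(0), y_name = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               x_start = integer(0), x_end = integer(0),
               y_start = integer(0), y_end = integer(0),
               x_summit = integer(0),
               x_count = numeric(0), y_count = numeric(0),
               overlap = numeric(0), stringsAsFactors = FALSE)
  }
  multi <- sum(duplicated(bx$partner[x_common]))
  if (multi > 0)
    message(multi, " multi-pair collision(s): several x peaks share a y partner")
  out <- list(
    common = common,
    x_specific = new_peak_set(x$peaks[setdiff(seq_len(nrow(x$peaks)), x_common), ,
                                      drop = FALSE],
                              paste0(x$sample_id, "_specific"), x$params),
    y_specific = new_peak_set(y$peaks[setdiff(seq_len(nrow(y$peaks)), y_common), ,
                                      drop = FALSE],
                              paste0(y$sample_id, "_specific"), y$params),
    y_common_names = y$peaks$name[y_common],
    threshold = threshold, reciprocal = reciprocal,
    x_sample = x$sample_id, y_sample = y$sample_id)
  class(out) <- "peak_comparison"
  out
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat(sprintf("<peak_comparison> %s vs %s: %d common pair(s), %d x-specific, %d y-specific\n",
              x$x_sample, x$y_sample, nrow(x$common),
              n_peaks(x$x_specific), n_peaks(x$y_specific)))
  invisible(x)
}

# ---- BED export -------------------------------------------------------------

#' Write a peak set as BED6+4
#'
#' Columns: chrom, start, end, name, score (\code{-10 log10 P}, capped at
#' 10000), strand ("."), then summit, ip_count, input_count, fold.
#'
#' @param set a \code{peak_set}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_peaks_bed <- function(set, path) {
  p <- set$peaks
  df <- data.frame(
    chrom = p$chrom, start = p$start, end = p$end, name = p$name,
    score = round(pmin(10000, -10 * log10(p$p_value)), 2),
    strand = ".",
    summit = p$summit, ip_count = round(p$ip_count, 3),
    input_count = round(p$input_count, 3), fold = round(p$fold, 4))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
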