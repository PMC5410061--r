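# Placing peaks on transcripts: six-segment tabulation, metagene profiles,
# and peak density stratified by expression level.

# Footprint table of a transcript_models list (one row per transcript).
transcript_footprints <- function(models) {
  data.frame(
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start = vapply(models, function(m) m$exon_starts[1L], integer(1)),
    end = vapply(models, function(m) m$exon_ends[length(m$exon_ends)], integer(1)),
    width = vapply(models, `[[`, integer(1), "width"),
    stringsAsFactors = FALSE)
}

# Host transcript of each genomic position (longest transcript wins ties);
# NA where no transcript footprint overlaps.
host_transcript <- function(chrom, pos, models) {
  fp <- transcript_footprints(models)
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    si <- which(fp$chrom == ch)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(pos[qi] + 1L, width = 1L),
      IRanges::IRanges(fp$start[si] + 1L, fp$end[si]))
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    o <- order(qh, -fp$width[si][sh], fp$transcript_id[si][sh])
    first <- o[!duplicated(qh[o])]
    out[qi[qh[first]]] <- fp$transcript_id[si][sh[first]]
  }
  out
}

#' Assign peaks to transcript segments
#'
#' In \code{"summit"} mode (the default, summit-exclusive) each peak's
#' summit is mapped into the coordinate system of its host transcript (the
#' longest transcript whose footprint covers the summit) and labelled with
#' the segment containing that base; peaks whose summit hits no transcript,
#' or falls in an intron, are labelled \code{"other"}. This makes the label
#' a function: exactly one segment per peak. In \code{"multi"} mode a peak
#' receives every segment label that any of its exonic bases touches (plus
#' \code{"other"} for bases outside any transcript), matching a
#' multi-membership tabulation in which percentages can exceed 100.
#'
#' @param peaks a \code{peak_set} or a peak data.frame with \code{chrom},
#'   \code{start}, \code{end}, \code{summit}.
#' @param models a \code{transcript_models} list (typically
#'   \code{\link{longest_coding_transcripts}} output).
#' @param w codon-window half-width (nt).
#' @param mode \code{"summit"} or \code{"multi"}.
#' @return For \code{"summit"}: a data.frame with \code{segment},
#'   \code{transcript_id}, \code{gene_id} per peak. For \code{"multi"}: a
#'   list of label character vectors per peak.
#' @export
assign_segment <- function(peaks, models, w = 100L, mode = c("summit", "multi")) {
  mode <- match.arg(mode)
  p <- if (is(peaks, "peak_set")) peaks$peaks else peaks
  parts <- lapply(models, partition_transcript, w = w)
  gene_of <- vapply(models, `[[`, character(1), "gene_id")
  if (mode == "summit") {
    host <- host_transcript(p$chrom, p$summit, models)
    segment <- rep("other", nrow(p))
    for (i in which(!is.na(host))) {
      m <- models[[host[i]]]
      t <- genomic_to_tx(m, p$summit[i])
      if (is.na(t)) next                       # intronic summit
      lab <- segment_at(parts[[host[i]]], t)
      if (!is.na(lab)) segment[i] <- lab
    }
    data.frame(name = p$name, segment = segment,
               transcript_id = host,
               gene_id = ifelse(is.na(host), NA_character_, gene_of[host]),
               stringsAsFactors = FALSE)
  } else {
    fp <- transcript_footprints(models)
    lapply(seq_len(nrow(p)), function(i) {
      labs <- character(0)
      covered <- 0L
      cand <- which(fp$chrom == p$chrom[i] & fp$start < p$end[i] &
                      fp$end > p$start[i])
      for (tid in fp$transcript_id[cand]) {
        m <- models[[tid]]
        # exonic bases of the peak on this transcript
        tpos <- genomic_to_tx(m, p$start[i]:(p$end[i] - 1L))
        tpos <- tpos[!is.na(tpos)]
        if (!length(tpos)) next
        covered <- max(covered, length(tpos))
        labs <- union(labs, unique(segment_at(parts[[tid]], tpos)))
      }
      if (covered < p$end[i] - p$start[i]) labs <- union(labs, "other")
      sort(labs)
    })
  }
}

#' Six-segment peak tabulation
#'
#' Counts and percentages of peaks per transcript segment, in both the
#' summit-exclusive mode (percentages sum to 100) and the multi-membership
#' mode (each peak counted in every segment it touches, so percentages may
#' exceed 100) side by side.
#'
#' @param peaks a \code{peak_set}.
#' @param models a \code{transcript_models} list.
#' @param w codon-window half-width (nt).
#' @return A data.frame of class \code{segment_table}: one row per segment
#'   label with \code{count}, \code{percent} (summit-exclusive) and
#'   \code{multi_count}, \code{multi_percent}; total peak count as
#'   attribute \code{n_peaks}.
#' @export
segment_table <- function(peaks, models, w = 100L) {
  p <- if (is(peaks, "peak_set")) peaks$peaks else peaks
  n <- nrow(p)
  if (n == 0L) {
    warning("empty peak set: segment table of zeros")
    tab <- data.frame(segment = SEGMENT_LEVELS, count = 0L, percent = 0,
                      multi_count = 0L, multi_percent = 0)
    return(structure(tab, class = c("segment_table", "data.frame"), n_peaks = 0L))
  }
  excl <- assign_segment(p, models, w = w, mode = "summit")
  cnt <- table(factor(excl$segment, levels = SEGMENT_LEVELS))
  multi <- assign_segment(p, models, w = w, mode = "multi")
  mcnt <- table(factor(unlist(multi), levels = SEGMENT_LEVELS))
  tab <- data.frame(
    segment = SEGMENT_LEVELS,
    count = as.integer(cnt), percent = 100 * as.integer(cnt) / n,
    multi_count = as.integer(mcnt), multi_percent = 100 * as.integer(mcnt) / n,
    stringsAsFactors = FALSE)
  structure(tab, class = c("segment_table", "data.frame"), n_peaks = n)
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("Six-segment peak distribution (%d peaks)\n", attr(x, "n_peaks")))
  print.data.frame(cbind(x[1], round(x[-1], 2)), row.names = FALSE)
  invisible(x)
}

# ---- metagene profiles ------------------------------------------------------

#' 60-bin whole-gene metagene profile of read depth
#'
#' Each coding gene's spliced depth profile is divided into \code{n_bins}
#' equal bins (boundaries \code{floor(L * i / n_bins)}, so the bins tile the
#' transcript exactly); the per-bin value is depth-sum per kilobase of bin
#' per million mapped reads, averaged across genes.
#'
#' @param track a \code{coverage_track}.
#' @param models a \code{transcript_models} list.
#' @param library_size mapped reads; defaults to the track's total.
#' @param n_bins number of bins (default 60).
#' @return An object of class \code{metagene_profile}: data.frame
#'   (\code{bin}, \code{value}) with attributes \code{n_genes},
#'   \code{n_excluded} (transcripts shorter than \code{n_bins}),
#'   \code{gene_totals} (un-normalised per-gene depth recovered from the
#'   bin sums) and \code{normalization}.
#' @export
metagene_60bin <- function(track, models, library_size = NULL, n_bins = 60L) {
  if (is.null(library_size)) library_size <- track$total_reads
  lib_m <- library_size / 1e6
  acc <- numeric(n_bins)
  n_used <- 0L; n_excl <- 0L
  gene_totals <- numeric(0)
  for (m in models) {
    if (!m$coding) next
    if (m$width < n_bins) { n_excl <- n_excl + 1L; next }
    d <- spliced_depth(track, m)
    bounds <- floor(m$width * (0:n_bins) / n_bins)
    bin_sum <- diff(c(0, cumsum(as.numeric(d))[bounds[-1L]]))
    bin_len <- diff(bounds)
    acc <- acc + (bin_sum / (bin_len / 1000)) / lib_m
    gene_totals[m$transcript_id] <- sum(bin_sum)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no usable coding transcripts for metagene profile")
  prof <- data.frame(bin = seq_len(n_bins), value = acc / n_used)
  structure(prof, class = c("metagene_profile", "data.frame"),
            n_genes = n_used, n_excluded = n_excl,
            gene_totals = gene_totals,
            normalization = "depth per kb of bin per million mapped reads, averaged over genes")
}

#' Three-part metagene profile of peak summits
#'
#' Summit positions are rescaled to \code{[0, 1)} within their transcript
#' part (5'UTR, CDS or 3'UTR), histogrammed into \code{bins_per_part} bins
#' per part, normalised by the summit count of the part, and concatenated
#' 5'UTR | CDS | 3'UTR.
#'
#' @param peaks a \code{peak_set}.
#' @param models a \code{transcript_models} list.
#' @param bins_per_part bins per part (default 20).
#' @return An object of class \code{metagene_profile}: data.frame with
#'   \code{bin}, \code{part}, \code{position} (part-relative bin centre),
#'   \code{count} and \code{value} (count / part total).
#' @export
metagene_3part <- function(peaks, models, bins_per_part = 20L) {
  p <- if (is(peaks, "peak_set")) peaks$peaks else peaks
  host <- host_transcript(p$chrom, p$summit, models)
  parts <- c("5'UTR", "CDS", "3'UTR")
  part_of <- character(0); rel <- numeric(0)
  for (i in which(!is.na(host))) {
    m <- models[[host[i]]]
    if (!m$coding) next
    t <- genomic_to_tx(m, p$summit[i])
    if (is.na(t)) next
    if (t < m$utr5_len) {
      part_of <- c(part_of, "5'UTR"); rel <- c(rel, t / max(1L, m$utr5_len))
    } else if (t < m$utr5_len + m$cds_len) {
      part_of <- c(part_of, "CDS"); rel <- c(rel, (t - m$utr5_len) / m$cds_len)
    } else {
      part_of <- c(part_of, "3'UTR")
      rel <- c(rel, (t - m$utr5_len - m$cds_len) / max(1L, m$utr3_len))
    }
  }
  bins <- pmin(bins_per_part - 1L, floor(rel * bins_per_part))
  out <- do.call(rbind, lapply(parts, function(pt) {
    cnt <- tabulate(bins[part_of == pt] + 1L, nbins = bins_per_part)
    tot <- sum(cnt)
    data.frame(bin = seq_len(bins_per_part) +
                 bins_per_part * (match(pt, parts) - 1L),
               part = pt,
               position = (seq_len(bins_per_part) - 0.5) / bins_per_part,
               count = cnt,
               value = if (tot > 0) cnt / tot else 0)
  }))
  structure(out, class = c("metagene_profile", "data.frame"),
            n_summits = length(part_of),
            normalization = "per-part summit fraction")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d bins (%s)\n", nrow(x), attr(x, "normalization")))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$bin, x$value, type = "l", xlab = "bin",
                 ylab = "normalized signal", ...)
  if (!is.null(x$part))
    graphics::abline(v = range(x$bin[x$part == "CDS"]) + c(-0.5, 0.5),
                     lty = 2, col = "grey40")
  invisible(x)
}

# ---- density by expression --------------------------------------------------

#' Peak density stratified by expression level
#'
#' Transcripts with RPKM above \code{min_rpkm} are ordered by RPKM and cut
#' into \code{n_groups} equal-count groups (remainder to the last,
#' highest-expression group); per-group density is assigned peaks per
#' transcript. Peaks are assigned to the host transcript of their summit.
#'
#' @param peaks a \code{peak_set}.
#' @param expression data.frame with \code{gene_id} and \code{rpkm}.
#' @param models a \code{transcript_models} list.
#' @param n_groups number of expression groups (default 11).
#' @param min_rpkm expression floor (default 2).
#' @return An object of class \code{density_by_expression}: data.frame
#'   (\code{group}, \code{n_transcripts}, \code{n_peaks}, \code{density},
#'   \code{mean_rpkm}) with the global density (total peaks / expressed
#'   transcripts) as attribute \code{global_density}.
#' @export
density_by_expression <- function(peaks, expression, models,
                                  n_groups = 11L, min_rpkm = 2) {
  p <- if (is(peaks, "peak_set")) peaks$peaks else peaks
  expr <- expression[expression$rpkm > min_rpkm, , drop = FALSE]
  if (nrow(expr) < n_groups)
    stop("fewer expressed transcripts (", nrow(expr), ") than groups (", n_groups, ")")
  host <- host_transcript(p$chrom, p$summit, models)
  gene_of <- vapply(models, `[[`, character(1), "gene_id")
  peak_gene <- ifelse(is.na(host), NA_character_, gene_of[host])
  peak_gene <- peak_gene[!is.na(peak_gene) & peak_gene %in% expr$gene_id]
  counts <- table(peak_gene)
  expr <- expr[order(expr$rpkm, expr$gene_id), , drop = FALSE]
  n <- nrow(expr)
  base <- n %/% n_groups
  sizes <- rep(base, n_groups)
  sizes[n_groups] <- sizes[n_groups] + n - base * n_groups
  grp <- rep(seq_len(n_groups), sizes)
  pk <- as.integer(counts[expr$gene_id]); pk[is.na(pk)] <- 0L
  out <- data.frame(
    group = seq_len(n_groups),
    n_transcripts = sizes,
    n_peaks = as.integer(tapply(pk, grp, sum)),
    mean_rpkm = as.numeric(tapply(expr$rpkm, grp, mean)))
  out$density <- out$n_peaks / out$n_transcripts
  structure(out, class = c("density_by_expression", "data.frame"),
            global_density = sum(pk) / n, min_rpkm = min_rpkm)
}

#' @export
print.density_by_expression <- function(x, ...) {
  cat(sprintf("Peak density by expression group (global %.3f peaks/transcript, RPKM > %g)\n",
              attr(x, "global_density"), attr(x, "min_rpkm")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
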