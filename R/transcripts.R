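# Transcript models: strand-aware spliced coordinate systems and the
# six-segment partition used throughout the m6A analyses.
#
# All internal coordinates are 0-based half-open; GTF is read as 1-based
# closed and converted on entry.

SEGMENT_LEVELS <- c("5'UTR", "start codon", "CDS", "stop codon", "3'UTR", "other")

#' Build a transcript model
#'
#' A transcript model holds the strand-aware exonic structure of one
#' transcript plus, for coding transcripts, the CDS boundaries, and derives
#' the spliced length and the transcript-coordinate positions of the start
#' and stop codons. Transcript coordinate 0 is the 5' end of the mature
#' transcript, i.e. the genomically leftmost exonic base on the plus strand
#' and the rightmost on the minus strand.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom reference sequence name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exon_starts,exon_ends exon intervals, 0-based half-open, on
#'   \code{chrom}; must be non-overlapping.
#' @param cds_start,cds_end genomic CDS boundaries (0-based half-open), or
#'   \code{NA} for a non-coding transcript.
#' @return An object of class \code{transcript_model} with fields
#'   \code{width} (spliced length), \code{coding}, \code{utr5_len},
#'   \code{cds_len}, \code{utr3_len}, \code{start_codon} and
#'   \code{stop_codon} (transcript coordinates; the stop codon position is
#'   the first base past the CDS, i.e. the CDS/3'UTR boundary).
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1L,
            strand %in% c("+", "-"))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (any(exon_ends <= exon_starts))
    stop("empty exon in transcript ", transcript_id)
  n <- length(exon_starts)
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n]))
    stop("overlapping exons in transcript ", transcript_id)
  widths <- exon_ends - exon_starts
  cum <- c(0L, cumsum(widths))          # plus-strand offset of each exon start
  m <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exon_starts = exon_starts,
    exon_ends = exon_ends,
    cum = cum,
    width = cum[n + 1L],
    coding = !is.na(cds_start) && !is.na(cds_end),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end)
  ), class = "transcript_model")
  if (m$coding) {
    if (cds_end <= cds_start)
      stop("empty CDS in transcript ", transcript_id)
    first <- genomic_to_tx(m, if (strand == "+") m$cds_start else m$cds_end - 1L)
    last <- genomic_to_tx(m, if (strand == "+") m$cds_end - 1L else m$cds_start)
    if (is.na(first) || is.na(last))
      stop("CDS boundary outside exons in transcript ", transcript_id)
    cds_len <- sum(pmax(0L, pmin(exon_ends, m$cds_end) - pmax(exon_starts, m$cds_start)))
    if (last - first + 1L != cds_len)
      stop("CDS not contained in exonic footprint of transcript ", transcript_id)
    m$utr5_len <- first
    m$cds_len <- cds_len
    m$utr3_len <- m$width - first - cds_len
    m$start_codon <- first            # tx coord of first coding base
    m$stop_codon <- first + cds_len   # tx coord just past last coding base
  } else {
    m$utr5_len <- m$cds_len <- m$utr3_len <- NA_integer_
    m$start_codon <- m$stop_codon <- NA_integer_
  }
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d [%s], %d exon(s), %d nt spliced\n",
              x$transcript_id, x$gene_id, x$chrom,
              x$exon_starts[1L], x$exon_ends[length(x$exon_ends)],
              x$strand, length(x$exon_starts), x$width))
  if (x$coding)
    cat(sprintf("  5'UTR %d nt | CDS %d nt | 3'UTR %d nt\n",
                x$utr5_len, x$cds_len, x$utr3_len))
  else cat("  non-coding\n")
  invisible(x)
}

#' Map genomic positions to transcript coordinates
#'
#' @param model a \code{\link{transcript_model}}.
#' @param gpos integer vector of genomic positions (0-based).
#' @return Integer vector of 0-based transcript coordinates; \code{NA} for
#'   non-exonic positions.
#' @export
genomic_to_tx <- function(model, gpos) {
  gpos <- as.integer(gpos)
  idx <- findInterval(gpos, model$exon_starts)
  ok <- idx >= 1L & gpos < model$exon_ends[pmax(idx, 1L)]
  plus <- rep(NA_integer_, length(gpos))
  plus[ok] <- model$cum[idx[ok]] + (gpos[ok] - model$exon_starts[idx[ok]])
  if (model$strand == "+") plus else model$width - 1L - plus
}

#' Map transcript coordinates to genomic positions
#'
#' Inverse of \code{\link{genomic_to_tx}} on exonic positions.
#'
#' @param model a \code{\link{transcript_model}}.
#' @param tpos integer vector of 0-based transcript coordinates.
#' @return Integer vector of genomic positions; \code{NA} where \code{tpos}
#'   is outside \code{[0, width)}.
#' @export
tx_to_genomic <- function(model, tpos) {
  tpos <- as.integer(tpos)
  plus <- if (model$strand == "+") tpos else model$width - 1L - tpos
  ok <- !is.na(plus) & plus >= 0L & plus < model$width
  idx <- findInterval(plus, model$cum, rightmost.closed = FALSE)
  out <- rep(NA_integer_, length(tpos))
  out[ok] <- model$exon_starts[idx[ok]] + (plus[ok] - model$cum[idx[ok]])
  out
}

#' Project a transcript-coordinate interval onto the genome
#'
#' Returns the genomic interval(s) covering transcript range
#' \code{[tstart, tend)}, split at exon boundaries.
#'
#' @param model a \code{\link{transcript_model}}.
#' @param tstart,tend 0-based half-open transcript range.
#' @return A data.frame with columns \code{start}, \code{end} (0-based
#'   half-open genomic, sorted by start).
#' @export
tx_interval_to_genomic <- function(model, tstart, tend) {
  tstart <- max(0L, as.integer(tstart))
  tend <- min(model$width, as.integer(tend))
  if (tend <= tstart)
    return(data.frame(start = integer(0), end = integer(0)))
  # plus-strand offsets of the range
  if (model$strand == "+") { ps <- tstart; pe <- tend }
  else { ps <- model$width - tend; pe <- model$width - tstart }
  n <- length(model$exon_starts)
  s <- pmax(model$cum[seq_len(n)], ps)
  e <- pmin(model$cum[-1L], pe)
  keep <- e > s
  out <- data.frame(
    start = model$exon_starts[keep] + (s[keep] - model$cum[seq_len(n)][keep]),
    end = model$exon_starts[keep] + (e[keep] - model$cum[seq_len(n)][keep]))
  out[order(out$start), , drop = FALSE]
}

# ---- GTF input --------------------------------------------------------------

#' Read transcript models from a GTF annotation
#'
#' Parses an Ensembl-dialect GTF (1-based closed coordinates) into
#' \code{\link{transcript_model}} objects. Transcripts need at least one
#' \code{exon} feature; transcripts without \code{CDS} features are retained
#' but flagged non-coding. Transcripts whose CDS is not contained in the
#' exonic footprint are rejected with a warning (the warning reports the
#' rejected count).
#'
#' @param path path to a GTF file.
#' @return A named list of \code{transcript_model} objects (class
#'   \code{transcript_models}), with an attribute \code{n_rejected}.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path, " (expected 9 tab-separated fields)")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon/CDS features in ", path)
  tx_ids <- unique(gr$transcript_id)
  models <- vector("list", length(tx_ids))
  names(models) <- tx_ids
  n_rejected <- 0L
  for (tid in tx_ids) {
    sub <- gr[gr$transcript_id == tid]
    ex <- sub[sub$type == "exon"]
    if (length(ex) == 0L) next
    cds <- sub[sub$type == "CDS"]
    cs <- if (length(cds)) min(GenomicRanges::start(cds)) - 1L else NA_integer_
    ce <- if (length(cds)) max(GenomicRanges::end(cds)) else NA_integer_
    m <- tryCatch(
      transcript_model(
        transcript_id = tid,
        gene_id = ex$gene_id[1L],
        chrom = as.character(GenomicRanges::seqnames(ex))[1L],
        strand = as.character(GenomicRanges::strand(ex))[1L],
        exon_starts = GenomicRanges::start(ex) - 1L,
        exon_ends = GenomicRanges::end(ex),
        cds_start = cs, cds_end = ce),
      error = function(e) e)
    if (inherits(m, "error")) n_rejected <- n_rejected + 1L else models[[tid]] <- m
  }
  models <- models[!vapply(models, is.null, logical(1))]
  if (n_rejected > 0L)
    warning(n_rejected, " transcript(s) rejected (CDS outside exonic footprint)")
  structure(models, class = "transcript_models", n_rejected = n_rejected)
}

#' @export
print.transcript_models <- function(x, ...) {
  nc <- sum(vapply(x, `[[`, logical(1), "coding"))
  cat(sprintf("<transcript_models> %d transcripts (%d coding, %d non-coding)\n",
              length(x), nc, length(x) - nc))
  invisible(x)
}

#' @export
`[.transcript_models` <- function(x, i) {
  structure(NextMethod(), class = "transcript_models")
}

#' Select the longest coding transcript per gene
#'
#' Analyses default to one isoform per gene: the longest (spliced length)
#' coding transcript, ties broken by transcript id. Set
#' \code{all_isoforms = TRUE} to keep everything.
#'
#' @param models a \code{transcript_models} list.
#' @param all_isoforms keep all isoforms instead.
#' @return A filtered \code{transcript_models} list.
#' @export
longest_coding_transcripts <- function(models, all_isoforms = FALSE) {
  if (all_isoforms) return(models)
  coding <- models[vapply(models, `[[`, logical(1), "coding")]
  if (length(coding) == 0L)
    return(structure(list(), class = "transcript_models"))
  genes <- vapply(coding, `[[`, character(1), "gene_id")
  widths <- vapply(coding, `[[`, integer(1), "width")
  ids <- vapply(coding, `[[`, character(1), "transcript_id")
  o <- order(genes, -widths, ids)
  keep <- o[!duplicated(genes[o])]
  structure(coding[sort(keep)], class = "transcript_models")
}

# ---- segment partition ------------------------------------------------------

#' Partition a coding transcript into six non-overlapping segments
#'
#' Splits \code{[0, width)} of a coding transcript into 5'UTR, start-codon
#' window, CDS, stop-codon window, 3'UTR and other. Codon windows are
#' \code{[codon - w, codon + w)} clipped to the transcript and take
#' precedence over the UTR/CDS labels they overlap, so the six labels tile
#' the transcript exactly once per base. If the CDS is shorter than
#' \code{2w} the two codon windows would collide; the contested bases are
#' split at the midpoint between the two codon positions.
#'
#' For non-coding transcripts the whole transcript is labelled "other".
#'
#' @param model a \code{\link{transcript_model}}.
#' @param w codon-window half-width in nt (default 100).
#' @return An object of class \code{segment_partition}: a named list of
#'   two-column matrices (\code{start}, \code{end}; 0-based half-open
#'   transcript coordinates), one per segment label.
#' @export
partition_transcript <- function(model, w = 100L) {
  stopifnot(w >= 0L)
  w <- as.integer(w)
  L <- model$width
  empty <- cbind(start = integer(0), end = integer(0))
  iv <- function(s, e) {
    s <- max(0L, s); e <- min(L, e)
    if (e <= s) empty else cbind(start = s, end = e)
  }
  if (!model$coding) {
    segs <- list(iv(0L, 0L), iv(0L, 0L), iv(0L, 0L), iv(0L, 0L), iv(0L, 0L),
                 iv(0L, L))
  } else {
    sc <- model$start_codon
    sp <- model$stop_codon
    sw_s <- max(0L, sc - w); sw_e <- min(L, sc + w)
    tw_s <- max(0L, sp - w); tw_e <- min(L, sp + w)
    if (tw_s < sw_e) {            # short CDS: split contested span at midpoint
      mid <- as.integer(floor((sc + sp) / 2))
      sw_e <- min(sw_e, mid)
      tw_s <- max(tw_s, mid)
    }
    segs <- list(
      iv(0L, sw_s),               # residual 5'UTR
      iv(sw_s, sw_e),             # start-codon window
      iv(sw_e, tw_s),             # residual CDS
      iv(tw_s, tw_e),             # stop-codon window
      iv(tw_e, L),                # residual 3'UTR
      empty)                      # other (empty for coding transcripts)
  }
  names(segs) <- SEGMENT_LEVELS
  structure(list(transcript_id = model$transcript_id, w = w, width = L,
                 coding = model$coding, segments = segs),
            class = "segment_partition")
}

#' @export
print.segment_partition <- function(x, ...) {
  lens <- vapply(x$segments, function(m) sum(m[, "end"] - m[, "start"]), numeric(1))
  cat(sprintf("<segment_partition> %s (w=%d, %d nt)\n", x$transcript_id, x$w, x$width))
  print(lens)
  invisible(x)
}

#' Segment label at a transcript coordinate
#'
#' @param partition a \code{\link{partition_transcript}} result.
#' @param tpos vector of 0-based transcript coordinates.
#' @return Character vector of segment labels; positions outside
#'   \code{[0, width)} get \code{NA}.
#' @export
segment_at <- function(partition, tpos) {
  out <- rep(NA_character_, length(tpos))
  for (lab in SEGMENT_LEVELS) {
    m <- partition$segments[[lab]]
    if (nrow(m) == 0L) next
    for (i in seq_len(nrow(m)))
      out[!is.na(tpos) & tpos >= m[i, "start"] & tpos < m[i, "end"]] <- lab
  }
  out
}

# ---- BED export -------------------------------------------------------------

#' Write segment tracks as BED6
#'
#' Projects each transcript's six segments back to genomic coordinates
#' (split at exon boundaries) and writes BED6 with the segment label as the
#' feature name (0-based half-open, as BED requires).
#'
#' @param models a \code{transcript_models} list.
#' @param path output file.
#' @param w codon-window half-width passed to
#'   \code{\link{partition_transcript}}.
#' @return Invisibly, the number of BED records written.
#' @export
write_segments_bed <- function(models, path, w = 100L) {
  rows <- list()
  for (m in models) {
    p <- partition_transcript(m, w)
    for (lab in SEGMENT_LEVELS) {
      seg <- p$segments[[lab]]
      for (i in seq_len(nrow(seg))) {
        g <- tx_interval_to_genomic(m, seg[i, "start"], seg[i, "end"])
        if (nrow(g))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = m$chrom, start = g$start, end = g$end,
            name = lab, score = 0L, strand = m$strand)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = integer(0), strand = character(0))
  df <- df[order(df$chrom, df$start), ]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}
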