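# Per-base read-depth tracks for one sequencing library (IP or input).
# Depth is stored run-length encoded per reference sequence; read counts
# are recovered from depth as depth-sum / fragment length, since the
# libraries are ~100-nt fragmented RNA.

#' Build a coverage track
#'
#' @param depth a named list (or \code{RleList}) of per-base integer depth
#'   vectors, one per reference sequence.
#' @param sample_id library identifier.
#' @param fragment_len nominal fragment length in nt used to convert
#'   depth sums to read counts (default 100).
#' @param total_reads total mapped reads; computed from the depth when
#'   omitted.
#' @return An object of class \code{coverage_track}.
#' @export
coverage_track <- function(depth, sample_id = "sample",
                           fragment_len = 100L, total_reads = NULL) {
  if (is.null(names(depth)) || any(!nzchar(names(depth))))
    stop("depth must be a named list of per-reference vectors")
  depth <- lapply(depth, function(v) if (is(v, "Rle")) v else S4Vectors::Rle(as.integer(v)))
  if (any(vapply(depth, function(v) any(S4Vectors::runValue(v) < 0), logical(1))))
    stop("negative depth")
  sums <- vapply(depth, function(v) sum(as.numeric(S4Vectors::runValue(v)) *
                                          S4Vectors::runLength(v)), numeric(1))
  if (is.null(total_reads)) total_reads <- sum(sums) / fragment_len
  structure(list(depth = depth, sample_id = sample_id,
                 fragment_len = fragment_len,
                 total_reads = as.numeric(total_reads),
                 depth_sum = sum(sums)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d reference(s), %.3g total depth, %.3g reads (fragment %d nt)\n",
              x$sample_id, length(x$depth), x$depth_sum, x$total_reads, x$fragment_len))
  invisible(x)
}

#' Reference sequence lengths of a coverage track
#' @param track a \code{coverage_track}.
#' @return Named integer vector.
#' @export
track_seqlengths <- function(track) {
  vapply(track$depth, length, integer(1))
}

#' Write a coverage track as bedGraph
#'
#' Four-column bedGraph (chrom, 0-based start, end, depth); zero-depth runs
#' are omitted.
#'
#' @param track a \code{coverage_track}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track$sample_id), con)
  for (chrom in names(track$depth)) {
    r <- track$depth[[chrom]]
    len <- S4Vectors::runLength(r)
    val <- S4Vectors::runValue(r)
    ends <- cumsum(as.numeric(len))
    starts <- ends - len
    keep <- val != 0L
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%d", chrom,
                         as.integer(starts[keep]), as.integer(ends[keep]),
                         as.integer(val[keep])), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Tolerates track/browser/comment lines. Positions not covered by any
#' record get depth 0.
#'
#' @param path bedGraph file.
#' @param seqlengths optional named vector of reference lengths; inferred
#'   from the records when omitted.
#' @param sample_id,fragment_len passed to \code{\link{coverage_track}}.
#' @return A \code{coverage_track}.
#' @export
read_bedgraph <- function(path, seqlengths = NULL, sample_id = basename(path),
                          fragment_len = 100L) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chroms <- if (is.null(seqlengths)) {
    vapply(split(GenomicRanges::end(gr),
                 as.character(GenomicRanges::seqnames(gr))), max, numeric(1))
  } else seqlengths
  depth <- lapply(names(chroms), function(ch) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (!length(sub))
      return(S4Vectors::Rle(0L, as.integer(chroms[[ch]])))
    ir <- IRanges::IRanges(GenomicRanges::start(sub), GenomicRanges::end(sub))
    IRanges::coverage(ir, weight = as.integer(round(sub$score)),
                      width = as.integer(chroms[[ch]]))
  })
  names(depth) <- names(chroms)
  coverage_track(depth, sample_id = sample_id, fragment_len = fragment_len)
}

# Spliced per-base depth of one transcript (5'->3' orientation).
spliced_depth <- function(track, model) {
  r <- track$depth[[model$chrom]]
  if (is.null(r)) stop("reference ", model$chrom, " absent from track ", track$sample_id)
  parts <- lapply(seq_along(model$exon_starts), function(i)
    as.integer(r[(model$exon_starts[i] + 1L):model$exon_ends[i]]))
  v <- unlist(parts, use.names = FALSE)
  if (model$strand == "-") rev(v) else v
}
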