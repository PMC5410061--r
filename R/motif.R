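# RRACH consensus motif enrichment around peak summits.
#
# The statistic is deliberately simple and fully specified: among the
# top-ranked peaks, count summit windows containing at least one RRACH
# pentamer, and compare with the same count after dinucleotide-preserving
# shuffles of the very same windows. This replaces a de novo motif finder
# with a calibrated enrichment test for the known m6A consensus.

#' RRACH motif enrichment in peak summit windows
#'
#' Takes the \code{top_n} peaks by significance, extracts
#' \code{summit +/- flank} from the genome (reverse-complemented for peaks
#' hosted on minus-strand transcripts; plus strand when no host is known),
#' counts windows containing at least one RRACH match, and computes an
#' empirical upper-tail P-value against \code{n_shuffles}
#' dinucleotide-preserving shuffles of the same windows. Also returns the
#' position-frequency matrix of the best (most central) RRACH match per hit
#' window, for logo plotting.
#'
#' @param peaks a \code{peak_set}.
#' @param genome a \code{DNAStringSet} (names = reference sequences).
#' @param models optional \code{transcript_models} list used to orient
#'   windows by host-transcript strand.
#' @param top_n number of highest-ranked peaks to use (default 1000; all
#'   peaks, with a warning, when fewer are available).
#' @param flank half-window in nt around the summit (default 25, i.e. ~50
#'   nt windows).
#' @param n_shuffles shuffle rounds for the null (default 1000).
#' @return An object of class \code{motif_enrichment}: \code{n_windows},
#'   \code{obs_hits} (windows with >= 1 match), \code{obs_matches} (total
#'   matches), \code{null_hits} (vector), \code{p_value}, \code{pfm} (4 x 5
#'   position-frequency matrix) and parameters.
#' @export
motif_enrichment <- function(peaks, genome, models = NULL, top_n = 1000L,
                             flank = 25L, n_shuffles = 1000L) {
  p <- if (is(peaks, "peak_set")) peaks$peaks else peaks
  if (nrow(p) == 0L) stop("no peaks for motif analysis")
  missing_ref <- setdiff(unique(p$chrom), names(genome))
  if (length(missing_ref))
    stop("genome lacks sequence(s): ", paste(missing_ref, collapse = ", "))
  if (top_n > nrow(p)) {
    warning("top_n (", top_n, ") exceeds available peaks (", nrow(p), "); using all")
    top_n <- nrow(p)
  }
  p <- p[order(p$p_value, p$chrom, p$start), , drop = FALSE][seq_len(top_n), , drop = FALSE]
  strand <- rep("+", nrow(p))
  if (!is.null(models)) {
    host <- host_transcript(p$chrom, p$summit, models)
    ok <- !is.na(host)
    strand[ok] <- vapply(models[host[ok]], `[[`, character(1), "strand")
  }
  seqs <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    len <- length(genome[[p$chrom[i]]])
    s <- max(1L, p$summit[i] + 1L - flank)
    e <- min(len, p$summit[i] + 1L + flank)
    w <- Biostrings::subseq(genome[[p$chrom[i]]], s, e)
    if (strand[i] == "-") w <- Biostrings::reverseComplement(w)
    seqs[i] <- as.character(w)
  }
  matches <- count_rrach(seqs)
  obs_hits <- sum(matches > 0)
  null_hits <- rrach_null_hits(seqs, as.integer(n_shuffles))
  p_value <- (1 + sum(null_hits >= obs_hits)) / (n_shuffles + 1)
  # position-frequency matrix of the most central match per hit window
  hit_seqs <- seqs[matches > 0]
  pfm <- matrix(0L, nrow = 4, ncol = 5,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  if (length(hit_seqs)) {
    dss <- Biostrings::DNAStringSet(hit_seqs)
    ml <- Biostrings::vmatchPattern("RRACH", dss, fixed = FALSE)
    centre <- (nchar(hit_seqs) - 4) / 2
    best <- vapply(seq_along(hit_seqs), function(i) {
      st <- Biostrings::startIndex(ml)[[i]]
      st[which.min(abs(st - 1 - centre[i]))]
    }, numeric(1))
    pent <- Biostrings::DNAStringSet(substr(hit_seqs, best, best + 4))
    pfm <- Biostrings::consensusMatrix(pent)[c("A", "C", "G", "T"), , drop = FALSE]
  }
  structure(list(n_windows = length(seqs), obs_hits = obs_hits,
                 obs_matches = sum(matches),
                 null_hits = as.integer(null_hits), p_value = p_value,
                 pfm = pfm, top_n = top_n, flank = flank,
                 n_shuffles = n_shuffles),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("<motif_enrichment> RRACH in %d/%d summit windows (null mean %.1f), empirical P = %.4g\n",
              x$obs_hits, x$n_windows, mean(x$null_hits), x$p_value))
  invisible(x)
}
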