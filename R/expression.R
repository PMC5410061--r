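# Expression from input coverage (RPKM), exact-test differential
# expression, and the Fisher test linking expression direction to peak
# presence.

#' Reads per kilobase of exon model per million mapped reads
#'
#' \code{RPKM = count / (exon_kb * library_m)}, exactly.
#'
#' @param count exonic read count (vectorised).
#' @param exon_kb exon model length in kilobases (> 0).
#' @param library_m uniquely mapped library reads in millions (> 0).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(count, exon_kb, library_m) {
  if (any(exon_kb <= 0)) stop("exon_kb must be positive")
  if (any(library_m <= 0)) stop("library_m must be positive")
  count / (exon_kb * library_m)
}

#' Gene expression table from input coverage
#'
#' Per gene: exonic read count (spliced depth sum divided by the nominal
#' fragment length), exon model length in kb, and RPKM against the track's
#' library size.
#'
#' @param track an input \code{coverage_track}.
#' @param models a \code{transcript_models} list (one transcript per gene).
#' @return A data.frame: \code{gene_id}, \code{transcript_id},
#'   \code{count}, \code{exon_kb}, \code{rpkm}; library size (reads) as
#'   attribute \code{library_reads}.
#' @export
expression_table <- function(track, models) {
  lib_m <- track$total_reads / 1e6
  rows <- lapply(models, function(m) {
    cnt <- sum(as.numeric(spliced_depth(track, m))) / track$fragment_len
    data.frame(gene_id = m$gene_id, transcript_id = m$transcript_id,
               count = cnt, exon_kb = m$width / 1000,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rpkm <- rpkm(out$count, out$exon_kb, lib_m)
  attr(out, "library_reads") <- track$total_reads
  out
}

#' Call differentially expressed genes between two conditions
#'
#' Per gene, the condition-2 count is rescaled by the library-size ratio
#' and tested against the condition-1 count with the exact conditional
#' binomial test (see \code{\link{conditional_binomial_p}}); a gene is a
#' DEG when \code{P <= p_cutoff} and its library-normalised fold change
#' (larger over smaller) is \code{>= min_fold}.
#'
#' @param expr_x,expr_y \code{\link{expression_table}} data.frames over the
#'   same genes (condition-pooled counts are fine).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @param min_fold minimum normalised fold change (default 2).
#' @return A data.frame (class \code{deg_table}): per gene counts, rescaled
#'   count, fold, P-value, \code{deg} call and \code{direction}
#'   (\code{x-high} / \code{y-high} / \code{none}).
#' @export
call_degs <- function(expr_x, expr_y, p_cutoff = 0.05, min_fold = 2) {
  if (!identical(expr_x$gene_id, expr_y$gene_id))
    stop("expression tables must cover the same genes in the same order")
  lib_x <- attr(expr_x, "library_reads")
  lib_y <- attr(expr_y, "library_reads")
  if (is.null(lib_x) || is.null(lib_y))
    stop("expression tables lack library_reads attribute")
  y_scaled <- expr_y$count * lib_x / lib_y
  p <- conditional_binomial_p(expr_x$count, y_scaled)
  xp <- ifelse(expr_x$count == 0, expr_x$count + 1, expr_x$count)
  yp <- ifelse(y_scaled == 0, y_scaled + 1, y_scaled)
  lfc <- log2(xp / yp)
  deg <- p <= p_cutoff & abs(lfc) >= log2(min_fold)
  out <- data.frame(
    gene_id = expr_x$gene_id,
    count_x = expr_x$count, count_y = expr_y$count,
    count_y_scaled = y_scaled,
    log2_fold = lfc, p_value = p, deg = deg,
    direction = ifelse(!deg, "none", ifelse(lfc > 0, "x-high", "y-high")),
    stringsAsFactors = FALSE)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "p_cutoff") <- p_cutoff
  attr(out, "min_fold") <- min_fold
  out
}

#' Two-sided Fisher exact P-value for a 2x2 table
#'
#' Hypergeometric summation: with margins fixed, the P-value is the sum of
#' the probabilities of all tables whose probability does not exceed that
#' of the observed table (with the customary 1 + 1e-7 relative tolerance).
#' The odds ratio uses a Haldane 0.5 correction when any cell is zero.
#'
#' @param a,b,c,d cell counts, row-wise (\code{[a b; c d]}).
#' @return List with \code{p_value}, \code{odds_ratio} and \code{table}.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b                 # row 1 total
  n2 <- c + d                # row 2 total
  k <- a + c                 # column 1 total
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  orr <- if (any(c(a, b, c, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  else (a * d) / (b * c)
  list(p_value = p, odds_ratio = orr,
       table = matrix(c(a, c, b, d), 2, 2))
}

#' Association between expression direction and peak presence
#'
#' For each differential-expression direction, builds a 2x2 table over the
#' DE genes of that direction and tests it with the two-sided Fisher exact
#' test. The default construction (\code{"presence_by_presence"})
#' cross-tabulates peak presence in condition x against peak presence in
#' condition y over, e.g., the x-high genes — the counts of x-high genes
#' with a peak in x versus in y are reported alongside. The alternative
#' construction (\code{"direction_by_presence"}) tabulates DE direction
#' (x-high / y-high) against peak presence in one condition over all DE
#' genes. The construction descriptor is embedded in the result.
#'
#' @param degs a \code{\link{call_degs}} table.
#' @param peaks_x,peaks_y \code{peak_set}s of the two conditions.
#' @param models a \code{transcript_models} list.
#' @param construction table construction descriptor.
#' @return A list of class \code{association_result}, one element per DE
#'   direction (plus per-condition elements for the alternative
#'   construction), each with the 2x2 \code{table}, \code{odds_ratio},
#'   \code{p_value}, the headline counts \code{n_peak_x}/\code{n_peak_y},
#'   and \code{descriptor}; directions with no DE genes are flagged
#'   \code{computable = FALSE}.
#' @export
methylation_expression_association <- function(degs, peaks_x, peaks_y, models,
                                               construction = c("presence_by_presence",
                                                                "direction_by_presence")) {
  construction <- match.arg(construction)
  gx <- genes_from_peaks(peaks_x, models)
  gy <- genes_from_peaks(peaks_y, models)
  out <- list()
  if (construction == "presence_by_presence") {
    for (dir in c("x-high", "y-high")) {
      genes <- degs$gene_id[degs$direction == dir]
      if (!length(genes)) {
        out[[dir]] <- list(computable = FALSE, descriptor = sprintf(
          "no %s DE genes", dir))
        next
      }
      in_x <- genes %in% gx
      in_y <- genes %in% gy
      a <- sum(in_x & in_y); b <- sum(in_x & !in_y)
      cc <- sum(!in_x & in_y); d <- sum(!in_x & !in_y)
      f <- fisher_exact_2x2(a, b, cc, d)
      out[[dir]] <- list(
        computable = TRUE, table = f$table,
        odds_ratio = f$odds_ratio, p_value = f$p_value,
        n_genes = length(genes),
        n_peak_x = sum(in_x), n_peak_y = sum(in_y),
        descriptor = sprintf(
          "over %d %s genes: peak presence in x (rows) vs peak presence in y (columns)",
          length(genes), dir))
    }
  } else {
    for (cond in c("x", "y")) {
      gset <- if (cond == "x") gx else gy
      de <- degs[degs$direction %in% c("x-high", "y-high"), , drop = FALSE]
      if (!nrow(de)) {
        out[[cond]] <- list(computable = FALSE, descriptor = "no DE genes")
        next
      }
      xh <- de$direction == "x-high"
      present <- de$gene_id %in% gset
      a <- sum(xh & present); b <- sum(xh & !present)
      cc <- sum(!xh & present); d <- sum(!xh & !present)
      f <- fisher_exact_2x2(a, b, cc, d)
      out[[cond]] <- list(
        computable = TRUE, table = f$table,
        odds_ratio = f$odds_ratio, p_value = f$p_value,
        n_genes = nrow(de),
        descriptor = sprintf(
          "over %d DE genes: direction x-high (rows) vs peak presence in %s (columns)",
          nrow(de), cond))
    }
  }
  structure(out, class = "association_result", construction = construction)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> construction: %s\n", attr(x, "construction")))
  for (nm in names(x)) {
    el <- x[[nm]]
    if (isTRUE(el$computable))
      cat(sprintf("  %s: OR = %.3f, P = %.3g (%s)\n", nm, el$odds_ratio,
                  el$p_value, el$descriptor))
    else cat(sprintf("  %s: not computable (%s)\n", nm, el$descriptor))
  }
  invisible(x)
}
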