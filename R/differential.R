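# Intensity differences of common peaks: robust M-A normalisation over the
# common-peak set followed by an exact conditional test, in the spirit of
# MAnorm for ChIP-seq. Under the assumption that most common peaks do not
# change, a robust line fitted to M = log2(x1/x2) against
# A = (log2 x1 + log2 x2)/2 captures library-size and intensity-dependent
# bias; its residuals are the normalised log2 fold changes. The per-peak
# P-value is an exact binomial test conditional on the (rescaled) total
# count, which replaces MAnorm's Bayesian posterior with an exact,
# parameter-free statistic.

#' Robust M-A normalisation over common peaks
#'
#' Fits M on A by iteratively reweighted least squares with Huber weights
#' (20 iterations, via \code{MASS::rlm}) over the common peaks; the
#' residuals are the normalised log2 fold changes M-tilde. A is centred
#' before fitting, so the reported intercept is the normalisation at the
#' typical peak intensity, i.e. the global log2 library scaling. Zero
#' counts get a +1 pseudo-count. When A is essentially constant the fit
#' falls back to an intercept-only (median-type) normalisation with a
#' warning.
#'
#' @param x1,x2 read counts of each common peak in conditions 1 and 2
#'   (e.g. columns \code{x_count}, \code{y_count} of
#'   \code{\link{classify_common_specific}}'s \code{common} table).
#' @return An object of class \code{ma_fit} with components \code{M},
#'   \code{A}, \code{coefficients} (intercept, slope), \code{fitted},
#'   \code{Mtilde}, \code{x1}, \code{x2}.
#' @export
ma_fit <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  if (length(x1) < 10L)
    stop("need at least 10 common peaks to fit the M-A normalisation")
  if (any(x1 < 0) || any(x2 < 0)) stop("negative counts")
  x1p <- ifelse(x1 == 0, x1 + 1, x1)
  x2p <- ifelse(x2 == 0, x2 + 1, x2)
  M <- log2(x1p / x2p)
  A <- 0.5 * log2(x1p * x2p)
  if (stats::var(A) < 1e-12) {
    warning("degenerate A variance: intercept-only normalisation")
    fit <- MASS::rlm(M ~ 1, psi = MASS::psi.huber, maxit = 20)
    coefs <- c(intercept = unname(stats::coef(fit)[1]), slope = 0)
    fitted <- rep(coefs[1], length(M))
  } else {
    # A is centred so the intercept is the fitted normalisation at the
    # typical peak intensity (the global log2 scaling), not an
    # extrapolation to A = 0
    Ac <- A - mean(A)
    fit <- MASS::rlm(M ~ Ac, psi = MASS::psi.huber, maxit = 20)
    coefs <- c(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]))
    fitted <- unname(stats::fitted(fit))
  }
  structure(list(M = M, A = A, coefficients = coefs, fitted = fitted,
                 Mtilde = M - fitted, x1 = x1, x2 = x2,
                 n = length(x1),
                 method = "IRLS Huber M~A over common peaks (20 iterations); exact conditional binomial test replaces MAnorm's Bayesian P-value"),
            class = "ma_fit")
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("<ma_fit> %d common peaks; M = %.4f + %.4f A; median Mtilde %.4f\n",
              x$n, x$coefficients[1], x$coefficients[2], median(x$Mtilde)))
  invisible(x)
}

#' @export
coef.ma_fit <- function(object, ...) object$coefficients

#' @export
residuals.ma_fit <- function(object, ...) object$Mtilde

#' @export
plot.ma_fit <- function(x, ...) {
  graphics::plot(x$A, x$M, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "A = (log2 x1 + log2 x2)/2", ylab = "M = log2(x1/x2)", ...)
  o <- order(x$A)
  graphics::lines(x$A[o], x$fitted[o], col = "red3", lwd = 2)
  invisible(x)
}

#' Exact two-sided conditional binomial P-value
#'
#' Under the null that two (normalised) counts share one rate, the first
#' count given the total n = k1 + k2 is Binomial(n, 1/2). The two-sided P
#' is \code{min(1, 2 * min(P(X <= k1), P(X >= k1)))}.
#'
#' @param k1,k2 non-negative integer counts (vectorised).
#' @return Numeric vector of P-values in (0, 1].
#' @export
conditional_binomial_p <- function(k1, k2) {
  k1 <- round(k1); k2 <- round(k2)
  n <- k1 + k2
  lo <- pbinom(k1, n, 0.5)
  hi <- pbinom(k1 - 1, n, 0.5, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lo, hi))
  p[n == 0] <- 1
  p
}

#' Call dynamic methylated peaks (DMPs)
#'
#' Rescales the condition-2 count by the fitted M-A normalisation at each
#' peak's A, tests x1 against the rescaled x2 with the exact conditional
#' binomial test, and calls a peak dynamic when \code{P <= p_cutoff} and
#' \code{|Mtilde| >= log2(min_fold)} (the normalised change fold,
#' two-sided).
#'
#' @param fit an \code{\link{ma_fit}}.
#' @param p_cutoff P-value cutoff (default 0.01).
#' @param min_fold minimum normalised fold change (default 2).
#' @param peak_ids optional peak identifiers.
#' @return A data.frame (class \code{dmp_table}): \code{x1}, \code{x2},
#'   \code{x2_scaled}, \code{M}, \code{A}, \code{Mtilde}, \code{p_value},
#'   \code{dmp} (logical call), \code{direction}.
#' @export
call_dmps <- function(fit, p_cutoff = 0.01, min_fold = 2, peak_ids = NULL) {
  stopifnot(is(fit, "ma_fit"))
  x2s <- fit$x2 * 2^(fit$fitted)      # rescale condition 2 onto condition 1
  p <- conditional_binomial_p(fit$x1, x2s)
  dmp <- p <= p_cutoff & abs(fit$Mtilde) >= log2(min_fold)
  out <- data.frame(
    peak_id = if (is.null(peak_ids)) sprintf("common_%d", seq_len(fit$n)) else peak_ids,
    x1 = fit$x1, x2 = fit$x2, x2_scaled = x2s,
    M = fit$M, A = fit$A, Mtilde = fit$Mtilde,
    p_value = p, dmp = dmp,
    direction = ifelse(!dmp, "none", ifelse(fit$Mtilde > 0, "x-high", "y-high")),
    stringsAsFactors = FALSE)
  class(out) <- c("dmp_table", "data.frame")
  attr(out, "p_cutoff") <- p_cutoff
  attr(out, "min_fold") <- min_fold
  out
}

#' Genes overlapped by a set of peaks
#'
#' The set of gene ids whose transcript footprint overlaps at least one
#' peak by any amount; used to derive the specifically/dynamically
#' methylated gene sets from specific/dynamic peak lists.
#'
#' @param peaks a \code{peak_set} or peak data.frame.
#' @param models a \code{transcript_models} list.
#' @return Sorted character vector of gene ids.
#' @export
genes_from_peaks <- function(peaks, models) {
  p <- if (is(peaks, "peak_set")) peaks$peaks else peaks
  if (nrow(p) == 0L) return(character(0))
  fp <- transcript_footprints(models)
  hit <- logical(nrow(fp))
  for (ch in unique(p$chrom)) {
    si <- which(fp$chrom == ch)
    if (!length(si)) next
    pi <- which(p$chrom == ch)
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(fp$start[si] + 1L, fp$end[si]),
      IRanges::IRanges(p$start[pi] + 1L, p$end[pi]))
    hit[si] <- hit[si] | ov > 0
  }
  sort(unique(fp$gene_id[hit]))
}

#' Classify methylated genes by codon-window peak location
#'
#' Genes with at least one peak whose summit falls in the start-codon
#' window and one in the stop-codon window are PeakBoth; genes with only
#' one of the two are PeakStart or PeakStop; remaining methylated genes are
#' "others". The subgroups partition the methylated genes (those hosting at
#' least one peak summit).
#'
#' @param peaks a \code{peak_set}.
#' @param models a \code{transcript_models} list.
#' @param w codon-window half-width (nt).
#' @return A data.frame with \code{gene_id}, \code{subgroup}
#'   (\code{PeakStart}/\code{PeakStop}/\code{PeakBoth}/\code{others}) and
#'   \code{peak_ids} (comma-separated supporting peaks).
#' @export
classify_gene_subgroups <- function(peaks, models, w = 100L) {
  asn <- assign_segment(peaks, models, w = w, mode = "summit")
  asn <- asn[!is.na(asn$gene_id), , drop = FALSE]
  if (nrow(asn) == 0L)
    return(data.frame(gene_id = character(0), subgroup = character(0),
                      peak_ids = character(0), stringsAsFactors = FALSE))
  by_gene <- split(asn, asn$gene_id)
  out <- do.call(rbind, lapply(by_gene, function(d) {
    has_start <- any(d$segment == "start codon")
    has_stop <- any(d$segment == "stop codon")
    sub <- if (has_start && has_stop) "PeakBoth"
           else if (has_start) "PeakStart"
           else if (has_stop) "PeakStop"
           else "others"
    data.frame(gene_id = d$gene_id[1L], subgroup = sub,
               peak_ids = paste(d$name, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
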