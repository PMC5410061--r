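# Synthetic MeRIP-Seq generator with planted ground truth.
#
# The generator emulates the structure of a two-condition, two-replicate
# MeRIP-Seq experiment at the coverage level: gene models with
# 5'UTR/CDS/3'UTR structure placed without overlap on a synthetic genome,
# expression-proportional input depth with Poisson noise, IP depth
# fold-enriched inside planted peaks (placed preferentially near stop
# codons), an RRACH pentamer written at a configurable fraction of peak
# summits, and peaks that are common between conditions,
# condition-specific, intensity-shifted, or dropped from one replicate.
# Coverage is generated directly as per-base depth: alignment is upstream
# of this toolkit and depth is what all downstream statistics consume.

# the 12 RRACH pentamers on the DNA alphabet (R = A/G, the methylated A at
# position 3, then C, then H = A/C/T)
RRACH_PENTAMERS <- as.character(outer(
  outer(c("A", "G"), c("A", "G"), paste0),
  paste0("AC", c("A", "C", "T")), paste0))

#' Simulation configuration
#'
#' Defaults describe the desk-scale study profile: a 5 Mb genome split over
#' two chromosomes, 500 coding genes, two conditions with two replicates
#' each, mean input depth 30 at the reference expression level, 8-fold IP
#' enrichment inside 150-nt planted peaks, placement weights skewed to the
#' stop-codon window, RRACH planted at 80\% of summits, 60\% of peaks
#' common between conditions, 15\% of common peaks intensity-shifted
#' 4-fold, and replicate reproducibility 0.85.
#'
#' @param seed RNG seed; every draw in the generator descends from it.
#' @param n_genes number of genes.
#' @param genome_size total genome size in bp.
#' @param n_chroms number of chromosomes (genome split evenly).
#' @param utr5_meanlog,utr5_sdlog,cds_meanlog,cds_sdlog,utr3_meanlog,utr3_sdlog
#'   log-normal parameters of the segment length distributions (nt).
#' @param max_exons maximum exons per gene (uniform 1..max).
#' @param intron_meanlog,intron_sdlog log-normal intron length parameters.
#' @param rpkm_meanlog,rpkm_sdlog log-normal RPKM distribution.
#' @param ref_rpkm RPKM at which a gene has mean input depth
#'   \code{input_depth}.
#' @param input_depth mean input depth per expressed base at
#'   \code{ref_rpkm}.
#' @param fragment_len nominal fragment length (nt) linking depth to reads.
#' @param peak_width planted peak width (nt).
#' @param enrichment_fold IP/input fold inside planted peaks (>= 1).
#' @param placement_weights named probabilities that a planted peak centres
#'   in the stop-codon window, residual CDS, start-codon window, residual
#'   3'UTR or residual 5'UTR; must sum to 1.
#' @param codon_window codon-window half-width used when placing peaks.
#' @param motif_rate fraction of planted summits that receive an RRACH
#'   pentamer (the methylated A at the summit).
#' @param methylated_fraction fraction of genes carrying peaks.
#' @param peaks_per_gene maximum planted peaks per methylated gene
#'   (uniform 1..max).
#' @param frac_common probability a planted peak is common to both
#'   conditions (otherwise specific to a random condition).
#' @param frac_shifted fraction of common peaks whose intensity is shifted.
#' @param shift_fold multiplicative intensity shift (>= 1) applied in one
#'   random condition.
#' @param n_conditions,n_replicates experiment layout.
#' @param reproducibility probability a peak is planted in both replicates
#'   of a condition; otherwise it is unplanted in one random replicate.
#' @param de_fraction fraction of genes differentially expressed between
#'   conditions.
#' @param de_fold expression fold applied to DE genes in one random
#'   condition.
#' @param smooth smooth the planted IP enrichment profile with a 100-nt
#'   moving average (approximates fragment-level autocorrelation).
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_genes = 500L, genome_size = 5e6,
                       n_chroms = 2L,
                       utr5_meanlog = log(200), utr5_sdlog = 0.25,
                       cds_meanlog = log(1200), cds_sdlog = 0.35,
                       utr3_meanlog = log(400), utr3_sdlog = 0.35,
                       max_exons = 4L,
                       intron_meanlog = log(300), intron_sdlog = 0.5,
                       rpkm_meanlog = log(20), rpkm_sdlog = 1,
                       ref_rpkm = 20, input_depth = 30,
                       fragment_len = 100L,
                       peak_width = 150L, enrichment_fold = 8,
                       placement_weights = c("stop codon" = 0.40,
                                             "CDS" = 0.25,
                                             "start codon" = 0.15,
                                             "3'UTR" = 0.12,
                                             "5'UTR" = 0.08),
                       codon_window = 100L,
                       motif_rate = 0.8,
                       methylated_fraction = 0.6, peaks_per_gene = 2L,
                       frac_common = 0.6, frac_shifted = 0.15,
                       shift_fold = 4,
                       n_conditions = 2L, n_replicates = 2L,
                       reproducibility = 0.85,
                       de_fraction = 0.1, de_fold = 4,
                       smooth = FALSE) {
  cfg <- as.list(environment())
  if (abs(sum(placement_weights) - 1) > 1e-8)
    stop("placement_weights must sum to 1")
  if (!all(names(placement_weights) %in% setdiff(SEGMENT_LEVELS, "other")))
    stop("placement_weights names must be transcript segments")
  rates <- c(motif_rate, methylated_fraction, frac_common, frac_shifted,
             reproducibility, de_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (enrichment_fold < 1 || shift_fold < 1 || de_fold < 1)
    stop("all folds must be >= 1")
  if (n_genes < 0 || genome_size <= 0) stop("invalid genome dimensions")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d: %d genes on %.2g bp (%d chrom), %dx%d libraries, depth %g, fold %g\n",
              x$seed, x$n_genes, x$genome_size, x$n_chroms,
              x$n_conditions, x$n_replicates, x$input_depth, x$enrichment_fold))
  invisible(x)
}

# One random gene structure (lengths only).
sim_gene_structure <- function(cfg) {
  u5 <- max(30L, round(rlnorm(1, cfg$utr5_meanlog, cfg$utr5_sdlog)))
  cds <- 3L * max(60L, round(rlnorm(1, cfg$cds_meanlog, cfg$cds_sdlog) / 3))
  u3 <- max(30L, round(rlnorm(1, cfg$utr3_meanlog, cfg$utr3_sdlog)))
  L <- u5 + cds + u3
  n_ex <- sample.int(cfg$max_exons, 1L)
  breaks <- if (n_ex > 1L) sort(sample.int(L - 1L, n_ex - 1L)) else integer(0)
  widths <- diff(c(0L, breaks, L))
  introns <- if (n_ex > 1L)
    pmax(30L, round(rlnorm(n_ex - 1L, cfg$intron_meanlog, cfg$intron_sdlog)))
  else integer(0)
  list(u5 = u5, cds = cds, u3 = u3, L = L,
       exon_widths = as.integer(widths), introns = as.integer(introns))
}

#' Simulate a gene annotation with planted peak ground truth
#'
#' Places non-overlapping coding genes on a synthetic genome, plants m6A
#' peaks according to the placement weights, plants RRACH pentamers at a
#' fraction of summits, draws per-gene expression (with DE genes between
#' conditions), and returns the genome sequence carrying the planted
#' motifs. Deterministic under \code{cfg$seed}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list of class \code{sim_annotation}: \code{genome}
#'   (\code{DNAStringSet}), \code{models} (\code{transcript_models}),
#'   \code{truth} (data.frame of planted peaks), \code{rpkm} (gene x
#'   condition matrix of true RPKM), \code{de} (data.frame of per-gene DE
#'   status) and \code{config}.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(is(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom_len <- as.integer(floor(cfg$genome_size / cfg$n_chroms))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  models <- list()
  if (cfg$n_genes > 0) {
    cursor <- 1L; chrom_i <- 1L
    for (g in seq_len(cfg$n_genes)) {
      st <- sim_gene_structure(cfg)
      footprint <- sum(st$exon_widths) + sum(st$introns)
      gap <- as.integer(round(runif(1, 500, 2000)))
      while (cursor + gap + footprint >= chrom_len) {
        chrom_i <- chrom_i + 1L
        if (chrom_i > cfg$n_chroms)
          stop("genome too small to place ", cfg$n_genes, " genes (placed ", g - 1L, ")")
        cursor <- 1L
      }
      gstart <- cursor + gap
      exon_starts <- gstart + c(0L, cumsum(st$exon_widths[-length(st$exon_widths)] +
                                             st$introns))
      exon_ends <- exon_starts + st$exon_widths
      strand <- sample(c("+", "-"), 1L)
      tid <- sprintf("tx%04d", g)
      tmp <- transcript_model(tid, sprintf("gene%04d", g), chroms[chrom_i],
                              strand, exon_starts, exon_ends)
      # genomic CDS bounds from the transcript-coordinate CDS range
      cds_tx <- c(st$u5, st$u5 + st$cds - 1L)
      gpos <- tx_to_genomic(tmp, cds_tx)
      models[[tid]] <- transcript_model(tid, sprintf("gene%04d", g),
                                        chroms[chrom_i], strand,
                                        exon_starts, exon_ends,
                                        cds_start = min(gpos),
                                        cds_end = max(gpos) + 1L)
      cursor <- gstart + footprint
    }
  }
  models <- structure(models, class = "transcript_models")
  truth <- simulate_truth(cfg, models)
  # expression with DE genes
  n <- length(models)
  base_rpkm <- rlnorm(n, cfg$rpkm_meanlog, cfg$rpkm_sdlog)
  de_gene <- rbinom(n, 1L, cfg$de_fraction) == 1L
  de_cond <- ifelse(de_gene, sample.int(cfg$n_conditions, n, replace = TRUE), NA)
  rpkm <- matrix(rep(base_rpkm, cfg$n_conditions), ncol = cfg$n_conditions,
                 dimnames = list(vapply(models, `[[`, character(1), "gene_id"),
                                 paste0("cond", seq_len(cfg$n_conditions))))
  for (c_i in seq_len(cfg$n_conditions))
    rpkm[which(de_gene & de_cond == c_i), c_i] <-
      rpkm[which(de_gene & de_cond == c_i), c_i] * cfg$de_fold
  de <- data.frame(gene_id = rownames(rpkm), de = de_gene,
                   high_condition = ifelse(de_gene, paste0("cond", de_cond), NA),
                   stringsAsFactors = FALSE)
  # genome sequence: uniform random bases, then plant motifs at summits
  seqs <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE))
  names(seqs) <- chroms
  if (nrow(truth)) {
    for (i in which(truth$motif)) {
      m <- models[[truth$transcript_id[i]]]
      penta <- strsplit(truth$motif_seq[i], "")[[1]]
      if (m$strand == "-")
        penta <- rev(c(A = "T", C = "G", G = "C", T = "A")[penta])
      pos <- (truth$summit[i] - 2L):(truth$summit[i] + 2L) + 1L
      seqs[[m$chrom]][pos] <- penta
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms
  structure(list(genome = genome, models = models, truth = truth,
                 rpkm = rpkm, de = de, config = cfg),
            class = "sim_annotation")
}

#' Plant ground-truth peaks on a set of transcript models
#'
#' Consumes the current RNG stream (called by
#' \code{\link{simulate_annotation}}; usable directly when only planted
#' intervals are needed). Each methylated gene receives 1..peaks_per_gene
#' peaks; each peak's summit is drawn uniformly within a transcript segment
#' sampled from the placement weights, the peak interval is the summit
#' +/- half the peak width restricted to the summit's exon, and summits
#' within a gene are kept at least \code{peak_width + 250} nt apart so
#' neighbouring planted peaks stay resolvable.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param models a \code{transcript_models} list (one transcript per gene).
#' @return A data.frame of planted peaks with condition membership, shift
#'   folds, replicate dropouts and motif assignments.
#' @export
simulate_truth <- function(cfg, models) {
  rows <- list()
  cond_names <- paste0("cond", seq_len(cfg$n_conditions))
  for (m in models) {
    if (!m$coding) next
    if (rbinom(1L, 1L, cfg$methylated_fraction) == 0L) next
    part <- partition_transcript(m, cfg$codon_window)
    n_pk <- sample.int(cfg$peaks_per_gene, 1L)
    summits <- integer(0)
    for (k in seq_len(n_pk)) {
      placed <- FALSE
      for (try in 1:10) {
        lab <- sample(names(cfg$placement_weights), 1L,
                      prob = cfg$placement_weights)
        seg <- part$segments[[lab]]
        seg_len <- sum(seg[, "end"] - seg[, "start"])
        if (seg_len == 0L) next
        # uniform position over the (possibly split) segment
        off <- sample.int(seg_len, 1L) - 1L
        cum <- cumsum(seg[, "end"] - seg[, "start"])
        ri <- which(off < cum)[1L]
        tsum <- seg[ri, "start"] + off - c(0L, cum)[ri]
        if (length(summits) &&
            min(abs(summits - tsum)) < cfg$peak_width + 250L) next
        placed <- TRUE
        break
      }
      if (!placed) next
      summits <- c(summits, tsum)
      half <- cfg$peak_width %/% 2L
      ts <- max(0L, tsum - half)
      te <- min(m$width, tsum - half + cfg$peak_width)
      g_sum <- tx_to_genomic(m, tsum)
      proj <- tx_interval_to_genomic(m, ts, te)
      row <- proj[proj$start <= g_sum & g_sum < proj$end, , drop = FALSE]
      gs <- row$start[1L]; ge <- row$end[1L]
      # transcript coordinates of the exon-restricted genomic interval
      tt <- sort(genomic_to_tx(m, c(gs, ge - 1L)))
      cond <- if (runif(1) < cfg$frac_common) "both"
              else sample(cond_names, 1L)
      shifted <- cond == "both" && runif(1) < cfg$frac_shifted
      shift_cond <- if (shifted) sample(cond_names, 1L) else NA_character_
      drop_cond <- NA_character_; drop_rep <- NA_integer_
      if (cfg$n_replicates > 1L && runif(1) > cfg$reproducibility) {
        drop_cond <- if (cond == "both") sample(cond_names, 1L) else cond
        drop_rep <- sample.int(cfg$n_replicates, 1L)
      }
      motif_ok <- FALSE
      exon_i <- findInterval(g_sum, m$exon_starts)
      if (g_sum - 2L >= m$exon_starts[exon_i] && g_sum + 2L < m$exon_ends[exon_i])
        motif_ok <- runif(1) < cfg$motif_rate
      rows[[length(rows) + 1L]] <- data.frame(
        peak_id = NA_character_, gene_id = m$gene_id,
        transcript_id = m$transcript_id, chrom = m$chrom, strand = m$strand,
        start = gs, end = ge, summit = g_sum,
        tx_start = tt[1L], tx_end = tt[2L] + 1L, tx_summit = tsum,
        segment = lab, condition = cond,
        shift_fold = if (shifted) cfg$shift_fold else 1,
        shift_cond = shift_cond,
        drop_cond = drop_cond, drop_rep = drop_rep,
        motif = motif_ok,
        motif_seq = if (motif_ok) sample(RRACH_PENTAMERS, 1L) else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak_id = character(0), gene_id = character(0),
               transcript_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               summit = integer(0), tx_start = integer(0),
               tx_end = integer(0), tx_summit = integer(0),
               segment = character(0), condition = character(0),
               shift_fold = numeric(0), shift_cond = character(0),
               drop_cond = character(0), drop_rep = integer(0),
               motif = logical(0), motif_seq = character(0),
               stringsAsFactors = FALSE)
  if (nrow(truth))
    truth$peak_id <- sprintf("planted_%04d", seq_len(nrow(truth)))
  truth
}

#' Simulate IP and input coverage for every library
#'
#' Input depth at each exonic base of gene g is
#' Poisson(\code{input_depth * rpkm_g / ref_rpkm}); IP depth uses the same
#' rate multiplied by \code{enrichment_fold} (times any planted shift)
#' inside planted peaks present in that condition and replicate.
#' Deterministic under \code{cfg$seed}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param ann a \code{\link{simulate_annotation}} result.
#' @return Nested list \code{tracks[[condition]][[replicate]]} with
#'   elements \code{ip} and \code{input} (\code{coverage_track}s).
#' @export
simulate_coverage <- function(cfg, ann) {
  stopifnot(is(cfg, "sim_config"), is(ann, "sim_annotation"))
  set.seed(cfg$seed + 1L)
  chrom_len <- vapply(ann$genome, length, integer(1))
  cond_names <- paste0("cond", seq_len(cfg$n_conditions))
  truth <- ann$truth
  tracks <- list()
  for (c_i in seq_len(cfg$n_conditions)) {
    cond <- cond_names[c_i]
    tracks[[cond]] <- list()
    for (r in seq_len(cfg$n_replicates)) {
      ipv <- lapply(chrom_len, function(n) integer(n))
      inv <- lapply(chrom_len, function(n) integer(n))
      for (m in ann$models) {
        lam <- cfg$input_depth * ann$rpkm[m$gene_id, cond] / cfg$ref_rpkm
        L <- m$width
        mult <- rep(1, L)
        pk <- truth[truth$gene_id == m$gene_id, , drop = FALSE]
        if (nrow(pk)) {
          for (i in seq_len(nrow(pk))) {
            present <- pk$condition[i] %in% c("both", cond) &&
              !(identical(pk$drop_cond[i], cond) && identical(pk$drop_rep[i], r))
            if (!present) next
            f <- cfg$enrichment_fold *
              if (!is.na(pk$shift_cond[i]) && pk$shift_cond[i] == cond)
                pk$shift_fold[i] else 1
            mult[(pk$tx_start[i] + 1L):pk$tx_end[i]] <- f
          }
        }
        if (cfg$smooth && L > 100L) {
          sm <- stats::filter(mult, rep(1 / 100, 100), sides = 2)
          mult <- ifelse(is.na(sm), mult, as.numeric(sm))
        }
        d_in <- rpois(L, lam)
        d_ip <- rpois(L, lam * mult)
        gpos <- tx_to_genomic(m, 0:(L - 1L)) + 1L
        inv[[m$chrom]][gpos] <- inv[[m$chrom]][gpos] + d_in
        ipv[[m$chrom]][gpos] <- ipv[[m$chrom]][gpos] + d_ip
      }
      tracks[[cond]][[r]] <- list(
        ip = coverage_track(ipv, sprintf("%s_rep%d_IP", cond, r),
                            fragment_len = cfg$fragment_len),
        input = coverage_track(inv, sprintf("%s_rep%d_input", cond, r),
                               fragment_len = cfg$fragment_len))
    }
  }
  tracks
}

#' Simulate a complete MeRIP-Seq experiment
#'
#' Convenience wrapper: \code{\link{simulate_annotation}} followed by
#' \code{\link{simulate_coverage}}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List of class \code{sim_experiment} with \code{annotation},
#'   \code{tracks} and \code{config}.
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  ann <- simulate_annotation(cfg)
  tracks <- simulate_coverage(cfg, ann)
  structure(list(annotation = ann, tracks = tracks, config = cfg),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d genes, %d planted peaks, %d condition(s) x %d replicate(s)\n",
              length(x$annotation$models), nrow(x$annotation$truth),
              x$config$n_conditions, x$config$n_replicates))
  invisible(x)
}

# ---- writers ---------------------------------------------------------------

#' Write transcript models as an Ensembl-dialect GTF
#'
#' Emits exon and CDS features, 1-based closed coordinates.
#'
#' @param models a \code{transcript_models} list.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_gtf <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id, m$transcript_id)
    for (i in seq_along(m$exon_starts))
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                         m$chrom, m$exon_starts[i] + 1L, m$exon_ends[i],
                         m$strand, attrs), con)
    if (m$coding) {
      cds <- data.frame(start = pmax(m$exon_starts, m$cds_start),
                        end = pmin(m$exon_ends, m$cds_end))
      cds <- cds[cds$end > cds$start, , drop = FALSE]
      for (i in seq_len(nrow(cds)))
        writeLines(sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                           m$chrom, cds$start[i] + 1L, cds$end[i],
                           m$strand, attrs), con)
    }
  }
  invisible(path)
}

#' Write the simulated genome as FASTA
#' @param genome a \code{DNAStringSet}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
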