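# End-to-end orchestration: simulate (or load) -> call -> recur -> compare
# -> annotate -> differential methylation -> expression -> association,
# with a config snapshot, per-stage logging and a checksum manifest so a
# rerun under the same config and seed is byte-identical.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Pool several coverage tracks (element-wise depth sum).
pool_tracks <- function(tracks, sample_id = "pooled") {
  depth <- tracks[[1L]]$depth
  if (length(tracks) > 1L)
    for (t in tracks[-1L])
      for (ch in names(depth)) depth[[ch]] <- depth[[ch]] + t$depth[[ch]]
  coverage_track(depth, sample_id = sample_id,
                 fragment_len = tracks[[1L]]$fragment_len)
}

#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis with its standard
#' default (peak P 1e-5, overlap 0.5, DMP P 0.01 fold 2, DEG P 0.05
#' fold 2, RPKM floor 2, 11 expression groups, 60 metagene bins, 100-nt
#' codon window, motif top 1000 / 25-nt flank), plus either a simulation
#' block or input file paths.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every random draw of the run.
#' @param sim a \code{\link{sim_config}} (its seed is overridden by
#'   \code{seed}); set to \code{NULL} when supplying files.
#' @param inputs list with \code{gtf}, \code{fasta} and \code{tracks} --
#'   a nested list \code{tracks[[condition]][[replicate]]} of
#'   \code{list(ip=, input=)} bedGraph paths; ignored when \code{sim} is
#'   given.
#' @param p_peak,min_fold_peak,peak_window,merge_gap caller thresholds.
#' @param overlap overlap-fraction threshold for recurrence and
#'   common/specific classification.
#' @param p_dmp,fold_dmp dynamic-peak thresholds.
#' @param p_deg,fold_deg differential-expression thresholds.
#' @param min_rpkm,n_expr_groups expression-stratified density parameters.
#' @param metagene_bins whole-gene metagene bins.
#' @param codon_window codon-window half-width (nt).
#' @param motif_top_n,motif_flank,motif_shuffles motif-stage parameters.
#' @param write_coverage also export every library as bedGraph.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                       inputs = NULL,
                       p_peak = 1e-5, min_fold_peak = 2,
                       peak_window = 100L, merge_gap = 100L,
                       overlap = 0.5,
                       p_dmp = 0.01, fold_dmp = 2,
                       p_deg = 0.05, fold_deg = 2,
                       min_rpkm = 2, n_expr_groups = 11L,
                       metagene_bins = 60L, codon_window = 100L,
                       motif_top_n = 1000L, motif_flank = 25L,
                       motif_shuffles = 1000L,
                       write_coverage = FALSE) {
  if (!is.null(sim)) { sim$seed <- as.integer(seed) }
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Run the full m6A methylome analysis pipeline
#'
#' Executes every stage on simulated or supplied data and writes all
#' tables and tracks plus a manifest of MD5 checksums; a rerun with the
#' same configuration and seed reproduces identical outputs. Any stage
#' error aborts with the stage name.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param quiet suppress stage logging to stderr.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}); its \code{results} element carries the main
#'   in-memory objects.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(is(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  log_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    if (!quiet)
      message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    r
  }
  files <- character(0)
  add <- function(path) files <<- c(files, path)

  # ---- inputs ----
  if (!is.null(cfg$sim)) {
    expt <- log_stage("simulate", simulate_experiment(cfg$sim))
    ann <- expt$annotation
    models <- ann$models
    genome <- ann$genome
    tracks <- expt$tracks
    log_stage("write-inputs", {
      write_genome_fasta(genome, out("genome.fa")); add(out("genome.fa"))
      write_gtf(models, out("annotation.gtf")); add(out("annotation.gtf"))
      write_tsv(ann$truth, out("ground_truth.tsv")); add(out("ground_truth.tsv"))
    })
  } else {
    if (is.null(cfg$inputs)) stop("stage 'inputs' failed: neither sim nor inputs given")
    expt <- NULL
    models <- log_stage("read-gtf", read_gtf(cfg$inputs$gtf))
    genome <- log_stage("read-fasta", Biostrings::readDNAStringSet(cfg$inputs$fasta))
    names(genome) <- sub("\\s.*", "", names(genome))
    seqlens <- stats::setNames(vapply(genome, length, integer(1)), names(genome))
    tracks <- log_stage("read-coverage", lapply(cfg$inputs$tracks, function(cond)
      lapply(cond, function(rep_paths) list(
        ip = read_bedgraph(rep_paths$ip, seqlengths = seqlens),
        input = read_bedgraph(rep_paths$input, seqlengths = seqlens)))))
  }
  cfg_snapshot <- cfg
  cfg_snapshot$out_dir <- NULL          # environment, not analysis config
  cfg_snapshot$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
  jsonlite::write_json(unclass(cfg_snapshot), out("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  add(out("config.json"))
  models_use <- longest_coding_transcripts(models)
  conds <- names(tracks)

  if (!is.null(cfg$write_coverage) && isTRUE(cfg$write_coverage))
    log_stage("write-coverage", for (cond in conds)
      for (r in seq_along(tracks[[cond]])) {
        for (what in c("ip", "input")) {
          f <- out(sprintf("%s_rep%d_%s.bedgraph", cond, r,
                           if (what == "ip") "IP" else "input"))
          write_bedgraph(tracks[[cond]][[r]][[what]], f); add(f)
        }
      })

  # ---- peak calling and recurrence ----
  peak_sets <- log_stage("call-peaks", {
    ps <- list()
    for (cond in conds) {
      ps[[cond]] <- list()
      for (r in seq_along(tracks[[cond]])) {
        s <- call_peaks(tracks[[cond]][[r]]$ip, tracks[[cond]][[r]]$input,
                        p_cutoff = cfg$p_peak, min_fold = cfg$min_fold_peak,
                        window = cfg$peak_window, merge_gap = cfg$merge_gap)
        f <- out(sprintf("peaks_%s_rep%d.bed", cond, r))
        write_peaks_bed(s, f); add(f)
        ps[[cond]][[r]] <- s
      }
    }
    ps
  })
  recurrent <- log_stage("recurrence", {
    rs <- list()
    for (cond in conds) {
      acc <- peak_sets[[cond]][[1L]]
      for (r in seq_along(peak_sets[[cond]])[-1L])
        acc <- recurrent_peaks(acc, peak_sets[[cond]][[r]],
                               threshold = cfg$overlap)
      f <- out(sprintf("recurrent_%s.bed", cond))
      write_peaks_bed(acc, f); add(f)
      rs[[cond]] <- acc
    }
    rs
  })

  # ---- comparison ----
  cmp <- log_stage("compare", {
    cc <- classify_common_specific(recurrent[[1L]], recurrent[[2L]],
                                   threshold = cfg$overlap)
    write_tsv(cc$common, out("common_peaks.tsv")); add(out("common_peaks.tsv"))
    write_peaks_bed(cc$x_specific, out(sprintf("specific_%s.bed", conds[1L])))
    add(out(sprintf("specific_%s.bed", conds[1L])))
    write_peaks_bed(cc$y_specific, out(sprintf("specific_%s.bed", conds[2L])))
    add(out(sprintf("specific_%s.bed", conds[2L])))
    cc
  })

  # ---- annotation ----
  seg_tabs <- log_stage("segment-tables", {
    st <- list()
    for (cond in conds) {
      st[[cond]] <- segment_table(recurrent[[cond]], models_use,
                                  w = cfg$codon_window)
      f <- out(sprintf("segment_table_%s.tsv", cond))
      write_tsv(cbind(sample = cond, as.data.frame(st[[cond]])), f); add(f)
    }
    st
  })
  metagene <- log_stage("metagene", {
    ip_pool <- pool_tracks(lapply(tracks[[1L]], `[[`, "ip"),
                           paste0(conds[1L], "_IP_pooled"))
    m60 <- metagene_60bin(ip_pool, models_use, n_bins = cfg$metagene_bins)
    write_tsv(as.data.frame(m60), out("metagene_60bin.tsv"))
    add(out("metagene_60bin.tsv"))
    m3 <- metagene_3part(recurrent[[1L]], models_use)
    write_tsv(as.data.frame(m3), out("metagene_3part.tsv"))
    add(out("metagene_3part.tsv"))
    list(m60 = m60, m3 = m3)
  })
  expr_tabs <- log_stage("expression", {
    et <- list()
    for (cond in conds) {
      pooled <- pool_tracks(lapply(tracks[[cond]], `[[`, "input"),
                            paste0(cond, "_input_pooled"))
      et[[cond]] <- expression_table(pooled, models_use)
      f <- out(sprintf("expression_%s.tsv", cond))
      write_tsv(et[[cond]], f); add(f)
    }
    et
  })
  dens <- log_stage("density-by-expression", {
    d <- density_by_expression(recurrent[[1L]], expr_tabs[[1L]], models_use,
                               n_groups = cfg$n_expr_groups,
                               min_rpkm = cfg$min_rpkm)
    write_tsv(as.data.frame(d), out("density_by_expression.tsv"))
    add(out("density_by_expression.tsv"))
    d
  })
  motif <- log_stage("motif", {
    mo <- suppressWarnings(motif_enrichment(
      recurrent[[1L]], genome, models = models_use,
      top_n = cfg$motif_top_n, flank = cfg$motif_flank,
      n_shuffles = cfg$motif_shuffles))
    jsonlite::write_json(list(n_windows = mo$n_windows,
                              obs_hits = mo$obs_hits,
                              obs_matches = mo$obs_matches,
                              null_mean = mean(mo$null_hits),
                              p_value = mo$p_value),
                         out("motif.json"), auto_unbox = TRUE, digits = NA)
    add(out("motif.json"))
    pfm <- as.data.frame(mo$pfm)
    names(pfm) <- paste0("pos", seq_len(ncol(pfm)))
    write_tsv(cbind(base = rownames(mo$pfm), pfm), out("motif_pfm.tsv"))
    add(out("motif_pfm.tsv"))
    mo
  })

  # ---- differential methylation ----
  dmp <- log_stage("dynamic-peaks", {
    if (nrow(cmp$common) >= 10L) {
      fit <- ma_fit(cmp$common$x_count, cmp$common$y_count)
      tab <- call_dmps(fit, p_cutoff = cfg$p_dmp, min_fold = cfg$fold_dmp,
                       peak_ids = cmp$common$x_name)
      tab <- cbind(tab, chrom = cmp$common$chrom,
                   start = cmp$common$start, end = cmp$common$end)
    } else {
      fit <- NULL
      tab <- data.frame()
      message("fewer than 10 common peaks: dynamic-peak stage skipped")
    }
    write_tsv(tab, out("dmp_table.tsv")); add(out("dmp_table.tsv"))
    list(fit = fit, table = tab)
  })
  subgroups <- log_stage("gene-subgroups", {
    sg <- list()
    for (cond in conds)
      sg[[cond]] <- classify_gene_subgroups(recurrent[[cond]], models_use,
                                            w = cfg$codon_window)
    write_tsv(do.call(rbind, lapply(conds, function(cond)
      cbind(sample = cond, sg[[cond]]))), out("gene_subgroups.tsv"))
    add(out("gene_subgroups.tsv"))
    sg
  })
  gene_sets <- log_stage("gene-sets", {
    dyn_peaks <- if (nrow(dmp$table) && any(dmp$table$dmp))
      data.frame(chrom = dmp$table$chrom[dmp$table$dmp],
                 start = dmp$table$start[dmp$table$dmp],
                 end = dmp$table$end[dmp$table$dmp],
                 name = dmp$table$peak_id[dmp$table$dmp],
                 summit = dmp$table$start[dmp$table$dmp])
    else empty_peaks()
    gs <- list(
      specific_x = genes_from_peaks(cmp$x_specific, models_use),
      specific_y = genes_from_peaks(cmp$y_specific, models_use),
      dynamic = genes_from_peaks(dyn_peaks, models_use))
    df <- do.call(rbind, lapply(names(gs), function(nm)
      if (length(gs[[nm]])) data.frame(set = nm, gene_id = gs[[nm]])
      else data.frame(set = character(0), gene_id = character(0))))
    write_tsv(df, out("gene_sets.tsv")); add(out("gene_sets.tsv"))
    gs
  })

  # ---- expression association ----
  assoc <- log_stage("association", {
    degs <- call_degs(expr_tabs[[1L]], expr_tabs[[2L]],
                      p_cutoff = cfg$p_deg, min_fold = cfg$fold_deg)
    write_tsv(degs, out("deg_table.tsv")); add(out("deg_table.tsv"))
    as_res <- methylation_expression_association(
      degs, recurrent[[1L]], recurrent[[2L]], models_use)
    jsonlite::write_json(
      lapply(as_res, function(el) {
        if (isTRUE(el$computable))
          list(table = el$table, odds_ratio = el$odds_ratio,
               p_value = el$p_value, n_genes = el$n_genes,
               n_peak_x = el$n_peak_x, n_peak_y = el$n_peak_y,
               descriptor = el$descriptor)
        else list(computable = FALSE, descriptor = el$descriptor)
      }),
      out("association.json"), auto_unbox = TRUE, digits = NA)
    add(out("association.json"))
    list(degs = degs, association = as_res)
  })

  # ---- manifest ----
  files <- sort(unique(files))
  manifest <- list(
    package = "meripr",
    version = as.character(utils::packageVersion("meripr")),
    seed = cfg$seed,
    mode = if (!is.null(cfg$sim)) "simulation" else "files",
    n_outputs = length(files),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$results <- list(
    models = models_use, peak_sets = peak_sets, recurrent = recurrent,
    comparison = cmp, segment_tables = seg_tabs, metagene = metagene,
    density = dens, motif = motif, dmp = dmp, subgroups = subgroups,
    gene_sets = gene_sets, expression = expr_tabs,
    degs = assoc$degs, association = assoc$association,
    truth = if (!is.null(expt)) expt$annotation$truth else NULL)
  invisible(manifest)
}
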