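#' Pipeline configuration
#'
#' Bundles all stage configurations for [run_pipeline()]: the synthetic
#' data generator (or paths to existing probe files), within-array
#' normalization method, peak caller parameters, mark polarities, the
#' promoter-call tier and the integration settings. The resolved
#' configuration is serialised (YAML) next to every run's outputs so a run
#' is reproducible from its run directory alone.
#'
#' @param simulation a [simulation_config()]; used when `probe_files` is
#'   `NULL` and also supplies the promoter model dimensions.
#' @param peaks a [peak_caller_config()].
#' @param within_array_method `"a_lowess"` or `"gc_bins"`.
#' @param polarity named mark-polarity vector.
#' @param tier stringency tier for promoter calls.
#' @param bin_size expression bin size for the integration stage.
#' @param fold_change_thresholds thresholds for
#'   [fold_change_score_analysis()] (used when two or more cell types are
#'   simulated).
#' @param qc_hard_fail abort downstream stages when a QC report fails.
#' @param rng_seed global seed; propagated into stage configs that do not
#'   set their own.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            peaks = peak_caller_config(),
                            within_array_method = "a_lowess",
                            polarity = default_mark_polarity(),
                            tier = "strict",
                            bin_size = 100,
                            fold_change_thresholds = seq(1.5, 7, by = 0.5),
                            qc_hard_fail = FALSE,
                            rng_seed = 1L) {
  structure(list(simulation = simulation, peaks = peaks,
                 within_array_method = within_array_method,
                 polarity = polarity, tier = tier, bin_size = bin_size,
                 fold_change_thresholds = fold_change_thresholds,
                 qc_hard_fail = qc_hard_fail,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param file YAML path.
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(unclass_recursive(config), file)
  invisible(file)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for writing) / ignored on read.
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  sim <- raw$simulation
  sim$marks <- as.data.frame(lapply(sim$marks, unlist), stringsAsFactors = FALSE)
  cfg <- pipeline_config(
    simulation = do.call(simulation_config, sim),
    peaks = do.call(peak_caller_config, raw$peaks),
    within_array_method = raw$within_array_method,
    polarity = unlist(raw$polarity), tier = raw$tier,
    bin_size = raw$bin_size,
    fold_change_thresholds = unlist(raw$fold_change_thresholds),
    qc_hard_fail = isTRUE(raw$qc_hard_fail), rng_seed = raw$rng_seed)
  cfg
}

log_msg <- function(logfile, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

read_peak_table <- function(file) {
  df <- read_tsv(file)
  structure(df, class = c("peak_set", "data.frame"),
            mark = df$mark[1], cell_type = df$cell_type[1])
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> normalize (within-array, quantile, average) ->
#' call peaks -> annotate -> integrate -> QC in order, writing each
#' stage's outputs (tab-separated tables, BED and GFF exports, QC
#' reports) into per-stage subdirectories of `outdir` together with the
#' resolved configuration. Stages whose outputs already exist are skipped
#' (delete a stage directory to re-run from there); re-running with the
#' same seed reproduces the tables byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory (created if missing).
#' @param force re-run all stages even when outputs exist.
#' @return `outdir`, invisibly; side effect: stage outputs on disk.
#' @export
run_pipeline <- function(config, outdir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "pipeline.log")
  write_pipeline_config(config, file.path(outdir, "config.yaml"))
  sim <- config$simulation
  cts <- sim$cell_types
  marks <- sim$marks$mark
  dirs <- vapply(c("simulate", "normalize", "peaks", "annotate", "integrate", "qc"),
                 function(d) file.path(outdir, d), character(1))
  done <- function(d) !force && dir.exists(d) && length(list.files(d)) > 0

  # --- simulate ------------------------------------------------------------
  model_file <- file.path(dirs["simulate"], "promoter_model.tsv")
  if (!done(dirs["simulate"])) {
    log_msg(logfile, "stage simulate: %d genes, %d marks, %d replicates",
            sim$n_genes, length(marks), sim$n_replicates)
    dir.create(dirs["simulate"], showWarnings = FALSE)
    exp <- simulate_experiment(sim)
    write_promoter_model(exp$model, model_file)
    for (ct in cts) for (mk in marks) for (r in seq_len(sim$n_replicates))
      write_probe_table(exp$arrays[[ct]][[mk]][[r]],
                        file.path(dirs["simulate"],
                                  sprintf("%s_%s_rep%d.probes.tsv", ct, mk, r)))
  } else log_msg(logfile, "stage simulate: outputs present, skipped")
  genes <- read_promoter_model(model_file)

  # --- normalize -----------------------------------------------------------
  avg_file <- function(ct, mk) file.path(dirs["normalize"],
                                         sprintf("%s_%s.averaged.tsv", ct, mk))
  rep_file <- function(ct, mk, r) file.path(dirs["normalize"],
                                            sprintf("%s_%s_rep%d.quantile.tsv", ct, mk, r))
  if (!done(dirs["normalize"])) {
    log_msg(logfile, "stage normalize: method=%s", config$within_array_method)
    dir.create(dirs["normalize"], showWarnings = FALSE)
    for (ct in cts) for (mk in marks) {
      tracks <- lapply(seq_len(sim$n_replicates), function(r) {
        sig <- read_probe_table(file.path(dirs["simulate"],
                                          sprintf("%s_%s_rep%d.probes.tsv", ct, mk, r)))
        within_array_normalize(
          ma_transform(sig, array_id = sprintf("%s_%s_rep%d", ct, mk, r),
                       mark = mk, cell_type = ct),
          method = config$within_array_method)
      })
      qn <- if (length(tracks) >= 2) quantile_normalize(tracks) else {
        lapply(tracks, function(t) { t$state <- "quantile"; t })
      }
      for (r in seq_along(qn)) write_ratio_track(qn[[r]], rep_file(ct, mk, r))
      avg <- suppressWarnings(
        average_replicates(qn, array_id = sprintf("%s_%s_avg", ct, mk)))
      write_ratio_track(avg, avg_file(ct, mk))
    }
  } else log_msg(logfile, "stage normalize: outputs present, skipped")

  # --- peaks ---------------------------------------------------------------
  peak_file <- function(ct, mk) file.path(dirs["peaks"],
                                          sprintf("%s_%s.peaks.tsv", ct, mk))
  if (!done(dirs["peaks"])) {
    log_msg(logfile, "stage peaks: window=%d bp, min_probes=%d, %d permutations",
            config$peaks$window_bp, config$peaks$min_probes,
            config$peaks$n_permutations)
    dir.create(dirs["peaks"], showWarnings = FALSE)
    for (ct in cts) for (mk in marks) {
      ps <- call_peaks(read_ratio_track(avg_file(ct, mk)), config$peaks)
      write_tsv(as.data.frame(ps), peak_file(ct, mk), "peaks", config$peaks)
      write_peaks_bed(ps, file.path(dirs["peaks"],
                                    sprintf("%s_%s.peaks.bed", ct, mk)))
    }
  } else log_msg(logfile, "stage peaks: outputs present, skipped")

  # --- annotate ------------------------------------------------------------
  call_file <- function(ct, mk) file.path(dirs["annotate"],
                                          sprintf("%s_%s.calls.tsv", ct, mk))
  assign_file <- function(ct, mk) file.path(dirs["annotate"],
                                            sprintf("%s_%s.assigned.tsv", ct, mk))
  if (!done(dirs["annotate"])) {
    log_msg(logfile, "stage annotate: window -%d/+%d bp, tier=%s",
            sim$window_upstream, sim$window_downstream, config$tier)
    dir.create(dirs["annotate"], showWarnings = FALSE)
    for (ct in cts) for (mk in marks) {
      ps <- read_peak_table(peak_file(ct, mk))
      asn <- assign_peaks_to_tss(ps, genes, upstream_bp = sim$window_upstream,
                                 downstream_bp = sim$window_downstream)
      write_tsv(as.data.frame(asn), assign_file(ct, mk), "annotate")
      write_peaks_gff(asn, file.path(dirs["annotate"],
                                     sprintf("%s_%s.assigned.gff", ct, mk)))
      write_tsv(call_promoter_state(asn, genes, tier = config$tier),
                call_file(ct, mk), "annotate")
    }
  } else log_msg(logfile, "stage annotate: outputs present, skipped")

  # --- integrate -----------------------------------------------------------
  if (!done(dirs["integrate"])) {
    log_msg(logfile, "stage integrate: bin_size=%d", config$bin_size)
    dir.create(dirs["integrate"], showWarnings = FALSE)
    for (ct in cts) {
      ptab <- do.call(rbind, lapply(marks, function(mk) {
        a <- read_tsv(assign_file(ct, mk))
        a[!is.na(a$gene_id), c("gene_id", "mark", "cell_type", "tier",
                               "bound_area", "score_log2")]
      }))
      net <- net_enrichment(ptab, genes, polarity = config$polarity,
                            expression_col = paste0("expression_", ct))
      write_tsv(net, file.path(dirs["integrate"],
                               sprintf("%s.net_enrichment.tsv", ct)), "integrate")
      if (!is.null(net$expression) && nrow(net) >= 2 * config$bin_size) {
        bins <- correlate_net_with_expression(net, bin_size = config$bin_size)
        write_tsv(bins$bins, file.path(dirs["integrate"],
                                       sprintf("%s.expression_bins.tsv", ct)),
                  "integrate")
      }
    }
    if (length(cts) >= 2) {
      calls_of <- function(ct) do.call(rbind, lapply(marks, function(mk)
        read_tsv(call_file(ct, mk))))
      e1 <- stats::setNames(genes[[paste0("expression_", cts[1])]], genes$gene_id)
      e2 <- stats::setNames(genes[[paste0("expression_", cts[2])]], genes$gene_id)
      fc <- fold_change_score_analysis(calls_of(cts[1]), calls_of(cts[2]),
                                       e1, e2,
                                       thresholds = config$fold_change_thresholds)
      write_tsv(fc, file.path(dirs["integrate"], "fold_change.tsv"), "integrate")
    }
  } else log_msg(logfile, "stage integrate: outputs present, skipped")

  # --- qc ------------------------------------------------------------------
  if (!done(dirs["qc"])) {
    log_msg(logfile, "stage qc")
    dir.create(dirs["qc"], showWarnings = FALSE)
    qc_rows <- list()
    for (ct in cts) for (mk in marks) {
      qn <- lapply(seq_len(sim$n_replicates), function(r)
        read_ratio_track(rep_file(ct, mk, r)))
      conc <- replicate_concordance(qn, rng_seed = config$rng_seed)
      conc$metrics$metric <- paste(ct, mk, conc$metrics$metric, sep = ".")
      qc_rows[[length(qc_rows) + 1]] <- conc$metrics
      asn <- read_tsv(assign_file(ct, mk))
      hist <- tss_distance_histogram(
        structure(asn, class = c("promoter_assignment", "data.frame")),
        upstream_bp = sim$window_upstream, downstream_bp = sim$window_downstream)
      write_tsv(hist$counts, file.path(dirs["qc"],
                                       sprintf("%s_%s.tss_histogram.tsv", ct, mk)), "qc")
    }
    qc_all <- do.call(rbind, qc_rows)
    write_tsv(qc_all, file.path(dirs["qc"], "qc_metrics.tsv"), "qc")
    if (config$qc_hard_fail && any(qc_all$verdict == "fail"))
      stopf("QC hard-fail: %d failing metric(s); see %s",
            sum(qc_all$verdict == "fail"), file.path(dirs["qc"], "qc_metrics.tsv"))
  } else log_msg(logfile, "stage qc: outputs present, skipped")

  log_msg(logfile, "pipeline complete: %s", outdir)
  invisible(outdir)
}
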