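new_qc_report <- function(stage, metrics) {
  stopifnot(all(c("metric", "value", "threshold", "verdict") %in% names(metrics)))
  structure(list(stage = stage, metrics = metrics), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n_fail <- sum(x$metrics$verdict == "fail")
  cat(sprintf("QC report [%s]: %s (%d metric(s), %d fail)\n", x$stage,
              if (n_fail) "FAIL" else "PASS", nrow(x$metrics), n_fail))
  print.data.frame(x$metrics, digits = 4)
  invisible(x)
}

#' Does a QC report pass?
#'
#' @param report a `qc_report`.
#' @return `TRUE` when no metric has verdict `"fail"`.
#' @export
qc_pass <- function(report) !any(report$metrics$verdict == "fail")

#' MA-plot centring report for within-array normalization
#'
#' Quantifies the visual MA-plot check: on a clean array the unenriched
#' probe bulk clusters around M = 0 with no dependence on A. The report
#' gives the median M within each A-decile before and after normalization;
#' a post-normalization decile whose |median M| exceeds `tolerance` fails.
#'
#' @param track_before,track_after `ratio_track`s on the same probe set
#'   (before and after [within_array_normalize()]).
#' @param tolerance allowed |median M| per decile after normalization.
#' @param n_quantiles number of A bins (deciles by default).
#' @return A `qc_report` (stage `within_array`).
#' @export
ma_plot_report <- function(track_before, track_after, tolerance = 0.05,
                           n_quantiles = 10) {
  stopifnot(inherits(track_before, "ratio_track"),
            inherits(track_after, "ratio_track"))
  if (!identical(track_before$probes$probe_id, track_after$probes$probe_id))
    stopf("tracks do not share a probe set")
  brk <- unique(stats::quantile(track_before$probes$a,
                                probs = seq(0, 1, length.out = n_quantiles + 1)))
  bin <- cut(track_before$probes$a, breaks = brk, include.lowest = TRUE)
  med_b <- tapply(track_before$probes$m, bin, stats::median)
  med_a <- tapply(track_after$probes$m, bin, stats::median)
  metrics <- rbind(
    data.frame(metric = sprintf("decile%02d_median_m_before", seq_along(med_b)),
               value = as.numeric(med_b), threshold = tolerance,
               verdict = ifelse(abs(med_b) <= tolerance, "pass", "warn")),
    data.frame(metric = sprintf("decile%02d_median_m_after", seq_along(med_a)),
               value = as.numeric(med_a), threshold = tolerance,
               verdict = ifelse(abs(med_a) <= tolerance, "pass", "fail"))
  )
  rownames(metrics) <- NULL
  new_qc_report("within_array", metrics)
}

#' Replicate concordance report
#'
#' Pairwise Pearson correlation of M between replicate tracks (on a seeded
#' random subsample of at most `n_subsample` probes when tracks are large)
#' plus per-track five-number summaries. After quantile normalization the
#' sorted M vectors of replicates are identical, so the summaries must
#' agree exactly; a summary spread beyond `summary_tolerance` fails for
#' quantile-state tracks and warns earlier in the pipeline (where a large
#' spread flags a scale shift between arrays). Correlations below `min_r`
#' warn.
#'
#' @param tracks list of >= 2 replicate `ratio_track`s.
#' @param min_r warning threshold on pairwise r.
#' @param summary_tolerance allowed across-track range per five-number
#'   summary statistic.
#' @param n_subsample probe subsample size for the correlations.
#' @param rng_seed seed for the subsample.
#' @return A `qc_report` (stage = common track state).
#' @export
replicate_concordance <- function(tracks, min_r = 0.5, summary_tolerance = 0.1,
                                  n_subsample = 10000, rng_seed = 1L) {
  if (length(tracks) < 2) stopf("need at least two replicate tracks")
  ids <- tracks[[1]]$probes$probe_id
  for (t in tracks[-1]) if (!identical(t$probes$probe_id, ids))
    stopf("tracks do not share a probe set")
  state <- tracks[[1]]$state
  M <- vapply(tracks, function(t) t$probes$m, numeric(length(ids)))
  sel <- if (length(ids) > n_subsample) {
    with_seed(derive_seed(rng_seed, "concordance"), sample(length(ids), n_subsample))
  } else seq_along(ids)
  pairs <- utils::combn(ncol(M), 2)
  cors <- apply(pairs, 2, function(p) stats::cor(M[sel, p[1]], M[sel, p[2]]))
  fn <- apply(M, 2, stats::fivenum)   # min, lower hinge, median, upper hinge, max
  spread <- apply(fn, 1, function(v) diff(range(v)))
  tol <- if (state %in% c("quantile", "averaged")) 1e-8 else summary_tolerance
  metrics <- rbind(
    data.frame(metric = sprintf("pearson_r_%d_%d", pairs[1, ], pairs[2, ]),
               value = cors, threshold = min_r,
               verdict = ifelse(cors >= min_r, "pass", "warn")),
    data.frame(metric = paste0("fivenum_range_",
                               c("min", "lower", "median", "upper", "max")),
               value = spread, threshold = tol,
               verdict = ifelse(spread <= tol,
                                "pass",
                                if (state %in% c("quantile", "averaged")) "fail" else "warn"))
  )
  rownames(metrics) <- NULL
  new_qc_report(state, metrics)
}

#' Peak convergence across replicates and normalization stages
#'
#' Peak counts fragment unpredictably, so convergence is judged on the
#' total strict-tier bound area (bp). Each labelled peak set contributes
#' its strict bound bp and peak count; a set whose bound bp deviates from
#' the median across sets by more than `outlier_factor`-fold is flagged —
#' such outliers can represent failed ChIP assays or array processing.
#'
#' @param peaksets named list of `peak_set`s (e.g. one per replicate, or
#'   per normalization stage).
#' @param outlier_factor allowed fold deviation from the median strict
#'   bound bp.
#' @return A `qc_report` (stage `peaks`).
#' @export
peak_convergence_report <- function(peaksets, outlier_factor = 2) {
  if (is.null(names(peaksets)) || any(names(peaksets) == ""))
    names(peaksets) <- sprintf("set%d", seq_along(peaksets))
  bp <- vapply(peaksets, function(p) sum(p$bound_area[p$tier == "strict"]),
               numeric(1))
  cnt <- vapply(peaksets, function(p) sum(p$tier == "strict"), numeric(1))
  med <- stats::median(bp)
  ok <- if (med > 0) bp <= outlier_factor * med & bp >= med / outlier_factor
        else bp == 0
  metrics <- rbind(
    data.frame(metric = paste0("strict_bound_bp_", names(peaksets)),
               value = bp, threshold = outlier_factor,
               verdict = ifelse(ok, "pass", "fail")),
    data.frame(metric = paste0("strict_peak_count_", names(peaksets)),
               value = cnt, threshold = NA_real_, verdict = "info")
  )
  rownames(metrics) <- NULL
  new_qc_report("peaks", metrics)
}

#' Histogram of peak distances from the TSS
#'
#' Counts assigned peak midpoints in fixed-width bins of signed,
#' strand-oriented distance from the TSS across the tiled window
#' (negative = upstream). With several assignments (e.g. replicates) the
#' per-bin counts are compared by Pearson correlation; replicates should
#' show highly similar distance distributions.
#'
#' @param assignments a [assign_peaks_to_tss()] result or a named list of
#'   them.
#' @param bin_width histogram bin width, bp.
#' @param upstream_bp,downstream_bp window extents, bp.
#' @param min_similarity warn threshold on pairwise histogram correlation.
#' @return list of class `tss_histogram`: `counts` data.frame
#'   (`bin_start`, `bin_end`, one count column per assignment) and
#'   `report`, a `qc_report` (stage `annotation`).
#' @export
tss_distance_histogram <- function(assignments, bin_width = 500,
                                   upstream_bp = 8200, downstream_bp = 3000,
                                   min_similarity = 0.5) {
  if (inherits(assignments, "promoter_assignment"))
    assignments <- list(peaks = assignments)
  breaks <- seq(-upstream_bp, downstream_bp + bin_width, by = bin_width)
  breaks[length(breaks)] <- downstream_bp  # last bin may be short
  breaks <- unique(breaks)
  counts <- data.frame(bin_start = breaks[-length(breaks)],
                       bin_end = breaks[-1])
  for (nm in names(assignments)) {
    d <- as.data.frame(assignments[[nm]])$tss_distance
    d <- d[!is.na(d)]
    counts[[nm]] <- if (length(d))
      as.integer(table(cut(d, breaks = breaks, right = FALSE,
                           include.lowest = TRUE)))
    else 0L
  }
  metrics <- data.frame(metric = character(0), value = numeric(0),
                        threshold = numeric(0), verdict = character(0))
  if (length(assignments) > 1) {
    pairs <- utils::combn(length(assignments), 2)
    sim <- apply(pairs, 2, function(p) {
      v1 <- counts[[names(assignments)[p[1]]]]
      v2 <- counts[[names(assignments)[p[2]]]]
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
      stats::cor(v1, v2)
    })
    metrics <- data.frame(
      metric = sprintf("histogram_r_%s_%s", names(assignments)[pairs[1, ]],
                       names(assignments)[pairs[2, ]]),
      value = sim, threshold = min_similarity,
      verdict = ifelse(!is.na(sim) & sim >= min_similarity, "pass", "warn"))
  }
  structure(list(counts = counts,
                 report = new_qc_report("annotation", metrics)),
            class = "tss_histogram")
}

#' @export
print.tss_histogram <- function(x, ...) {
  cat("peak-to-TSS distance histogram (strand-oriented bp):\n")
  print.data.frame(x$counts)
  invisible(x)
}
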