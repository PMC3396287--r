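#' Peak caller configuration
#'
#' Parameters of the sliding-window, cutoff-ramp detection of enriched
#' regions. A region requires at least `min_probes` adjacent probes above a
#' cutoff inside a `window_bp`-wide sliding window; cutoffs are swept from
#' `cutoff_high_pct` down to `cutoff_low_pct` percent of a theoretical
#' maximum enrichment value in steps of `cutoff_step_pct` (the defaults give
#' 16 levels, 90% to 15%). False discovery rates are estimated by permuting
#' the probe ratios and re-running the full sweep.
#'
#' @param window_bp sliding-window width, bp.
#' @param min_probes minimum number of adjacent above-cutoff probes.
#' @param cutoff_high_pct,cutoff_low_pct,cutoff_step_pct cutoff ramp as
#'   percentages of the theoretical maximum.
#' @param theoretical_max_rule `"mean_plus_6sd"` (default) or
#'   `"max_observed"`; see [theoretical_max()].
#' @param n_permutations permutations used for FDR estimation. FDRs are
#'   Monte-Carlo estimates; 20 permutations keeps desk-scale runtime while
#'   the standard error of each estimate stays reportable.
#' @param permutation_scope `"within_chromosome"` (preserves per-chromosome
#'   probe counts) or `"genome_wide"`.
#' @param max_gap_factor probes further apart than
#'   `max_gap_factor * probe_spacing` are not "adjacent"; runs break there.
#' @param probe_spacing array probe spacing, bp; inferred from the track
#'   (median inter-probe distance) when `NULL`.
#' @param rng_seed seed for the permutations.
#' @return list of class `peak_caller_config`.
#' @export
peak_caller_config <- function(window_bp = 500, min_probes = 4,
                               cutoff_high_pct = 90, cutoff_low_pct = 15,
                               cutoff_step_pct = 5,
                               theoretical_max_rule = c("mean_plus_6sd", "max_observed"),
                               n_permutations = 20,
                               permutation_scope = c("within_chromosome", "genome_wide"),
                               max_gap_factor = 2, probe_spacing = NULL,
                               rng_seed = 1L) {
  if (window_bp <= 0) stopf("window_bp must be positive")
  if (min_probes < 1) stopf("min_probes must be >= 1")
  if (cutoff_low_pct >= cutoff_high_pct)
    stopf("cutoff_low_pct must be below cutoff_high_pct")
  if (cutoff_step_pct <= 0) stopf("cutoff_step_pct must be positive")
  structure(list(
    window_bp = as.integer(window_bp), min_probes = as.integer(min_probes),
    cutoff_high_pct = cutoff_high_pct, cutoff_low_pct = cutoff_low_pct,
    cutoff_step_pct = cutoff_step_pct,
    theoretical_max_rule = match.arg(theoretical_max_rule),
    n_permutations = as.integer(n_permutations),
    permutation_scope = match.arg(permutation_scope),
    max_gap_factor = max_gap_factor,
    probe_spacing = if (is.null(probe_spacing)) NULL else as.integer(probe_spacing),
    rng_seed = as.integer(rng_seed)
  ), class = "peak_caller_config")
}

cutoff_levels <- function(config) {
  seq(config$cutoff_high_pct, config$cutoff_low_pct, by = -config$cutoff_step_pct)
}

infer_spacing <- function(track, config) {
  if (!is.null(config$probe_spacing)) return(config$probe_spacing)
  d <- unlist(lapply(split(track$probes$position, track$probes$chromosome), diff))
  d <- d[d > 0]
  if (!length(d)) return(100L)
  as.integer(stats::median(d))
}

#' Theoretical maximum enrichment of a track
#'
#' Anchor of the cutoff ramp. The default rule `mean_plus_6sd` returns
#' `mean(M) + 6*sd(M)`, a robust stand-in for the saturating enrichment an
#' array could show; `max_observed` returns `max(M)`.
#'
#' @param track a `ratio_track` in state `averaged`.
#' @param rule `"mean_plus_6sd"` or `"max_observed"`.
#' @return A log2-ratio value.
#' @export
theoretical_max <- function(track, rule = c("mean_plus_6sd", "max_observed")) {
  stopifnot(inherits(track, "ratio_track"))
  rule <- match.arg(rule)
  check_state(track, "averaged")
  m <- track$probes$m
  if (length(m) < 10)
    stopf("theoretical maximum needs at least 10 probes (got %d)", length(m))
  if (rule == "max_observed") return(max(m))
  s <- stats::sd(m)
  mean(m) + 6 * (if (is.na(s)) 0 else s)
}

# Core region finder on one chromosome. A 500 bp window "hits" when it
# contains >= min_probes above-cutoff probes that are adjacent (consecutive
# on the array, inter-probe gap <= max_gap). Overlapping hit windows are
# merged; each merged span becomes one region bounded by its outermost
# above-cutoff probes, with end = last probe start + probe spacing.
regions_one_chromosome <- function(pos, m, cutoff, min_probes, window_bp,
                                   max_gap, spacing) {
  above <- m > cutoff
  idx <- which(above)
  k <- length(idx)
  if (k < min_probes) return(NULL)
  run <- cumsum(c(TRUE, diff(idx) > 1L | diff(pos[idx]) > max_gap))
  ii <- seq_len(k - min_probes + 1L)
  last <- ii + min_probes - 1L
  ok <- run[ii] == run[last] & (pos[idx[last]] - pos[idx[ii]]) < window_bp
  if (!any(ok)) return(NULL)
  # union of hit windows for the minimal subset starting at idx[i]:
  # starts s with s <= pos[idx[i]] and s + window_bp > pos[idx[last]]
  lo <- pos[idx[last][ok]] - window_bp + 1L
  hi <- pos[idx[ii][ok]] + window_bp          # exclusive
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  hmax <- cummax(hi)
  grp <- cumsum(c(TRUE, lo[-1] > hmax[-length(hmax)]))
  glo <- tapply(lo, grp, min)
  ghi <- tapply(hi, grp, max)
  out <- lapply(seq_along(glo), function(g) {
    sel <- idx[pos[idx] >= glo[g] & pos[idx] < ghi[g]]
    data.frame(start = pos[sel[1]], end = pos[sel[length(sel)]] + spacing,
               n_probes = length(sel), mean_m = mean(m[sel]))
  })
  do.call(rbind, out)
}

#' Candidate enriched regions at a single cutoff
#'
#' Slides a `window_bp`-wide window across each chromosome of an averaged
#' track; a window is a hit when it contains at least `min_probes` adjacent
#' probes with M above `cutoff`, overlapping hit windows are merged, and
#' each merged span is reported as a region bounded by its outermost
#' above-cutoff probes (0-based half-open; end = last probe start + probe
#' spacing).
#'
#' @param track a `ratio_track` in state `averaged`, sorted by position.
#' @param cutoff log2-ratio threshold.
#' @param config a [peak_caller_config()].
#' @return data.frame with columns `chromosome`, `start`, `end`,
#'   `n_probes`, `mean_m` (zero rows when nothing is found).
#' @export
call_peaks_at_cutoff <- function(track, cutoff, config = peak_caller_config()) {
  stopifnot(inherits(track, "ratio_track"))
  check_state(track, "averaged")
  if (!is_sorted_by_position(track$probes))
    stopf("track probes are not sorted by (chromosome, position)")
  spacing <- infer_spacing(track, config)
  max_gap <- config$max_gap_factor * spacing
  out <- lapply(split(track$probes, track$probes$chromosome), function(p) {
    r <- regions_one_chromosome(p$position, p$m, cutoff, config$min_probes,
                                config$window_bp, max_gap, spacing)
    if (is.null(r)) return(NULL)
    cbind(data.frame(chromosome = p$chromosome[1], stringsAsFactors = FALSE), r)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0), mean_m = numeric(0))
  rownames(out) <- NULL
  out[order(out$chromosome, out$start, method = "radix"), , drop = FALSE]
}

# Per-chromosome (position, m) vectors, built once per track so the cutoff
# sweep and every permutation avoid repeated data.frame splits.
track_chr_data <- function(track) {
  lapply(split(seq_len(nrow(track$probes)), track$probes$chromosome),
         function(ix) list(pos = track$probes$position[ix],
                           m = track$probes$m[ix]))
}

# Full cutoff sweep on pre-split chromosome data: regions at every ramp
# level, plus the per-peak score = highest level at which a detection
# overlaps the final (lowest-cutoff) region. Shared by the observed call
# and every permutation.
sweep_chr_data <- function(chrs, config, tmax, spacing) {
  pcts <- cutoff_levels(config)
  max_gap <- config$max_gap_factor * spacing
  per_level <- lapply(pcts, function(p) {
    cut <- p / 100 * tmax
    out <- lapply(names(chrs), function(ch) {
      r <- regions_one_chromosome(chrs[[ch]]$pos, chrs[[ch]]$m, cut,
                                  config$min_probes, config$window_bp,
                                  max_gap, spacing)
      if (is.null(r)) return(NULL)
      cbind(data.frame(chromosome = ch, stringsAsFactors = FALSE), r)
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(out)) NULL else out
  })
  final <- per_level[[length(per_level)]]
  if (is.null(final))
    return(data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      mean_m = numeric(0), score_pct = numeric(0)))
  score <- rep(NA_real_, nrow(final))
  for (li in seq_along(pcts)) {
    lv <- per_level[[li]]
    if (is.null(lv)) next
    todo <- which(is.na(score))
    if (!length(todo)) break
    for (i in todo) {
      hit <- lv$chromosome == final$chromosome[i] &
        lv$start < final$end[i] & lv$end > final$start[i]
      if (any(hit)) score[i] <- pcts[li]
    }
  }
  final$score_pct <- score  # regions exist at the lowest level, so never NA
  final <- final[order(final$chromosome, final$start, method = "radix"), ,
                 drop = FALSE]
  rownames(final) <- NULL
  final
}

sweep_regions <- function(track, config, tmax) {
  sweep_chr_data(track_chr_data(track), config, tmax, infer_spacing(track, config))
}

#' Call peaks on an averaged ratio track
#'
#' Runs the full cutoff ramp (from `cutoff_high_pct` down to
#' `cutoff_low_pct` percent of the theoretical maximum), merges each peak's
#' detections across levels, scores every peak by the highest cutoff at
#' which it is detected, attaches permutation FDRs via [permutation_fdr()],
#' and assigns stringency tiers: strict (FDR <= 0.05, the tier used for
#' promoter calls), relaxed (0.05 < FDR <= 0.2, quality control only),
#' discarded otherwise.
#'
#' @param track a `ratio_track` in state `averaged`.
#' @param config a [peak_caller_config()].
#' @return A `peak_set`: data.frame with columns `chromosome`, `start`,
#'   `end`, `n_probes`, `mean_m`, `score_pct`, `score_log2`, `bound_area`,
#'   `fdr`, `tier`, `mark`, `cell_type`, with the track's theoretical
#'   maximum and the configuration in attributes.
#' @export
call_peaks <- function(track, config = peak_caller_config()) {
  stopifnot(inherits(track, "ratio_track"))
  check_state(track, "averaged")
  empty <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      mean_m = numeric(0), score_pct = numeric(0),
                      score_log2 = numeric(0), bound_area = integer(0),
                      fdr = numeric(0), tier = character(0),
                      mark = character(0), cell_type = character(0))
  if (nrow(track$probes) == 0)
    return(new_peak_set(empty, NA_real_, config, track))
  tmax <- theoretical_max(track, config$theoretical_max_rule)
  if (!is.finite(tmax) || tmax <= 0) {
    warnf("non-positive theoretical maximum (%.3f); no peaks called", tmax)
    return(new_peak_set(empty, tmax, config, track))
  }
  peaks <- sweep_regions(track, config, tmax)
  if (nrow(peaks) == 0) return(new_peak_set(empty, tmax, config, track))
  peaks$score_log2 <- peaks$score_pct / 100 * tmax
  peaks$bound_area <- peaks$end - peaks$start
  peaks$fdr <- permutation_fdr(track, peaks, config, tmax = tmax)
  peaks$tier <- ifelse(peaks$fdr <= 0.05, "strict",
                       ifelse(peaks$fdr <= 0.2, "relaxed", "discarded"))
  peaks$mark <- track$mark
  peaks$cell_type <- track$cell_type
  new_peak_set(peaks, tmax, config, track)
}

new_peak_set <- function(df, tmax, config, track) {
  structure(df, class = c("peak_set", "data.frame"),
            theoretical_max = tmax, config = config,
            mark = track$mark, cell_type = track$cell_type)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set [%s / %s]: %d peaks (%d strict, %d relaxed), %d bp strict bound area\n",
              attr(x, "mark"), attr(x, "cell_type"), nrow(x),
              sum(x$tier == "strict"), sum(x$tier == "relaxed"),
              sum(x$bound_area[x$tier == "strict"])))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more peaks\n", nrow(x) - 10))
  invisible(x)
}

#' @export
summary.peak_set <- function(object, ...) {
  data.frame(
    mark = attr(object, "mark"), cell_type = attr(object, "cell_type"),
    n_peaks = nrow(object),
    n_strict = sum(object$tier == "strict"),
    n_relaxed = sum(object$tier == "relaxed"),
    strict_bound_bp = sum(object$bound_area[object$tier == "strict"]),
    theoretical_max = attr(object, "theoretical_max"),
    stringsAsFactors = FALSE
  )
}

#' Permutation false discovery rates for observed peaks
#'
#' Estimates, for every observed peak score level s, the expected number of
#' equal-or-higher-scoring peaks arising from spatially unstructured data:
#' probe M values are randomly permuted (within each chromosome by default,
#' preserving per-chromosome probe counts) `n_permutations` times, the full
#' cutoff sweep is re-run on each permutation, and
#' `FDR(s) = mean permuted count of peaks with score >= s / observed count
#' with score >= s`, clipped to \[0, 1\] and made monotone non-increasing
#' in s. Each peak receives the FDR of its score.
#'
#' @param track the averaged `ratio_track` the peaks were called on.
#' @param observed_peaks data.frame of observed peaks with a `score_pct`
#'   column (as produced internally by [call_peaks()]).
#' @param config a [peak_caller_config()]; `rng_seed` drives the
#'   permutations.
#' @param tmax theoretical maximum used for the sweep (recomputed from the
#'   track when omitted).
#' @return Numeric vector of FDRs, one per observed peak; `numeric(0)` when
#'   no peaks were observed.
#' @export
permutation_fdr <- function(track, observed_peaks, config = peak_caller_config(),
                            tmax = NULL) {
  stopifnot(inherits(track, "ratio_track"))
  if (nrow(observed_peaks) == 0) return(numeric(0))
  if (is.null(tmax)) tmax <- theoretical_max(track, config$theoretical_max_rule)
  scores <- sort(unique(observed_peaks$score_pct))      # ascending
  obs_ge <- vapply(scores, function(s) sum(observed_peaks$score_pct >= s), numeric(1))
  chrs <- track_chr_data(track)
  spacing <- infer_spacing(track, config)
  perm_ge <- matrix(0, nrow = config$n_permutations, ncol = length(scores))
  for (b in seq_len(config$n_permutations)) {
    pc <- with_seed(derive_seed(config$rng_seed, "perm", track$mark,
                                track$cell_type, b), {
      if (config$permutation_scope == "within_chromosome") {
        lapply(chrs, function(ch)
          list(pos = ch$pos, m = ch$m[sample(length(ch$m))]))
      } else {
        allm <- sample(unlist(lapply(chrs, `[[`, "m")))
        off <- 0L
        lapply(chrs, function(ch) {
          mm <- allm[off + seq_along(ch$m)]
          off <<- off + length(ch$m)
          list(pos = ch$pos, m = mm)
        })
      }
    })
    pp <- sweep_chr_data(pc, config, tmax, spacing)
    if (nrow(pp))
      perm_ge[b, ] <- vapply(scores, function(s) sum(pp$score_pct >= s), numeric(1))
  }
  raw <- pmin(1, pmax(0, colMeans(perm_ge) / obs_ge))
  # monotone non-increasing in score: running max from the top score down
  adj <- rev(cummax(rev(raw)))
  adj[match(observed_peaks$score_pct, scores)]
}

#' Merge fragmented peaks for reporting (diagnostic)
#'
#' Hybridisation artifacts can split one enriched region into several
#' adjacent peaks, which is why peak counts are not used as a quantitative
#' measure downstream. For quality-control comparisons this helper merges
#' peaks separated by at most `gap_bp` into single reported intervals; the
#' original peaks are retained in an attribute.
#'
#' @param peakset a `peak_set` (or a data.frame with `chromosome`, `start`,
#'   `end`).
#' @param gap_bp maximum gap, bp, between peaks that are merged.
#' @return data.frame of merged intervals (`chromosome`, `start`, `end`,
#'   `bound_area`, `n_source_peaks`), original peaks in attribute
#'   `"original"`.
#' @export
merge_fragmented_peaks <- function(peakset, gap_bp = 100) {
  df <- as.data.frame(peakset)
  if (nrow(df) == 0) {
    out <- data.frame(chromosome = character(0), start = integer(0),
                      end = integer(0), bound_area = integer(0),
                      n_source_peaks = integer(0))
    attr(out, "original") <- df
    return(out)
  }
  out <- do.call(rbind, lapply(split(df, df$chromosome), function(p) {
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)  # to 1-based closed
    red <- IRanges::reduce(ir, min.gapwidth = gap_bp + 1L)
    ov <- IRanges::countOverlaps(red, ir)
    data.frame(chromosome = p$chromosome[1],
               start = IRanges::start(red) - 1L, end = IRanges::end(red),
               n_source_peaks = ov, stringsAsFactors = FALSE)
  }))
  out$bound_area <- out$end - out$start
  out <- out[order(out$chromosome, out$start, method = "radix"),
             c("chromosome", "start", "end", "bound_area", "n_source_peaks")]
  rownames(out) <- NULL
  attr(out, "original") <- df
  out
}
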