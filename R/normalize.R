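track_states <- c("raw", "within_array", "quantile", "averaged")

#' Construct a log2 ratio track
#'
#' The substrate of all analysis stages: per-probe M (log2 ChIP/input
#' ratio) and A (average log2 intensity) values for one array, with a
#' normalization state that only moves forward through
#' raw -> within_array -> quantile -> averaged.
#'
#' @param probes data.frame with columns `probe_id`, `chromosome`,
#'   `position`, `m`, `a` (optionally `gc_fraction`); rows are sorted by
#'   (chromosome, position) on construction.
#' @param array_id,mark,cell_type identifiers.
#' @param state normalization state.
#' @return An object of class `ratio_track`.
#' @export
ratio_track <- function(probes, array_id, mark, cell_type, state = "raw") {
  needed <- c("probe_id", "chromosome", "position", "m", "a")
  if (!all(needed %in% names(probes)))
    stopf("track probes need columns: %s", paste(needed, collapse = ", "))
  state <- match.arg(state, track_states)
  if (anyDuplicated(probes$probe_id)) stopf("duplicated probe ids in track")
  if (!all(is.finite(probes$m)) || !all(is.finite(probes$a)))
    stopf("M and A values must be finite")
  probes <- sort_by_position(probes)
  rownames(probes) <- NULL
  structure(list(array_id = array_id, mark = mark, cell_type = cell_type,
                 probes = probes, state = state),
            class = "ratio_track")
}

check_state <- function(track, required) {
  if (track$state != required)
    stopf("track '%s' is in state '%s' but '%s' is required (states advance raw -> within_array -> quantile -> averaged)",
          track$array_id, track$state, required)
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf("ratio_track %s [%s / %s], state=%s: %d probes on %d chromosome(s)\n",
              x$array_id, x$mark, x$cell_type, x$state, nrow(x$probes),
              length(unique(x$probes$chromosome))))
  cat(sprintf("  M: median %.3f, IQR %.3f; A: median %.3f\n",
              stats::median(x$probes$m), stats::IQR(x$probes$m),
              stats::median(x$probes$a)))
  invisible(x)
}

#' MA plot of a ratio track
#'
#' Average log2 intensity A on the x axis against the log2 ratio M on the y
#' axis, with a lowess trend line. On a clean array the unenriched bulk of
#' probes hugs the M = 0 line with no dependence on A; curvature is the
#' signature of intensity-dependent dye bias.
#'
#' @param x a [ratio_track()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.ratio_track <- function(x, ...) {
  graphics::plot(x$probes$a, x$probes$m, pch = ".", xlab = "A", ylab = "M",
                 main = sprintf("%s (%s, %s)", x$array_id, x$mark, x$state), ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::lines(stats::lowess(x$probes$a, x$probes$m, f = 0.3), col = "red")
  invisible(x)
}

#' MA transform of probe-level two-channel intensities
#'
#' Converts red/green channel intensities to M = log2(R/G) and
#' A = 0.5 * log2(R * G) per probe. Probes with a non-positive intensity in
#' either channel cannot be log-transformed and are dropped with a warning;
#' if more than `max_reject_fraction` of probes are affected the array is
#' rejected outright.
#'
#' @param signals probe-signal data.frame (`probe_id`, `chromosome`,
#'   `position`, `signal_r`, `signal_g`, optional `gc_fraction`) as written
#'   by [simulate_array()] or read with [read_probe_table()].
#' @param array_id,mark,cell_type identifiers for the resulting track.
#' @param max_reject_fraction hard-error threshold on the rejected-probe
#'   fraction.
#' @return A `ratio_track` in state `raw`.
#' @export
ma_transform <- function(signals, array_id = "array1", mark = "mark",
                         cell_type = "cellA", max_reject_fraction = 0.05) {
  needed <- c("probe_id", "chromosome", "position", "signal_r", "signal_g")
  if (!all(needed %in% names(signals)))
    stopf("signals need columns: %s", paste(needed, collapse = ", "))
  bad <- !is.finite(signals$signal_r) | !is.finite(signals$signal_g) |
    signals$signal_r <= 0 | signals$signal_g <= 0
  if (any(bad)) {
    if (mean(bad) > max_reject_fraction)
      stopf("%.1f%% of probes have non-positive intensities (limit %.1f%%); array rejected",
            100 * mean(bad), 100 * max_reject_fraction)
    warnf("rejected %d probe(s) with non-positive intensities", sum(bad))
    signals <- signals[!bad, , drop = FALSE]
  }
  probes <- data.frame(
    probe_id = signals$probe_id, chromosome = signals$chromosome,
    position = signals$position,
    m = log2(signals$signal_r / signals$signal_g),
    a = 0.5 * log2(signals$signal_r * signals$signal_g),
    stringsAsFactors = FALSE
  )
  if (!is.null(signals$gc_fraction)) probes$gc_fraction <- signals$gc_fraction
  ratio_track(probes, array_id, mark, cell_type, state = "raw")
}

#' Within-array normalization of a two-colour track
#'
#' Removes intensity-dependent dye bias from a single array so that the
#' unenriched probe bulk is centred on M = 0 at every intensity. Two
#' methods are provided:
#' \describe{
#'   \item{`a_lowess`}{subtract a lowess trend of M on A (local regression
#'     with span `span`).}
#'   \item{`gc_bins`}{standardise M within probe-GC bins: subtract the bin
#'     median and rescale the bin's robust spread (MAD) to the median
#'     across-bin spread, so log2-ratio units are preserved. Requires a
#'     `gc_fraction` column.}
#' }
#' After either method the median M within every A-decile should lie within
#' `tolerance` of 0 (see [ma_plot_report()]).
#'
#' @param track a `ratio_track` in state `raw`.
#' @param method `"a_lowess"` or `"gc_bins"`.
#' @param span lowess span for `a_lowess`.
#' @param n_bins number of GC bins for `gc_bins`.
#' @param tolerance documented centring tolerance (not enforced here).
#' @return A `ratio_track` in state `within_array`.
#' @export
within_array_normalize <- function(track, method = c("a_lowess", "gc_bins"),
                                   span = 0.3, n_bins = 20, tolerance = 0.05) {
  stopifnot(inherits(track, "ratio_track"))
  method <- match.arg(method)
  check_state(track, "raw")
  p <- track$probes
  if (method == "a_lowess") {
    fit <- stats::lowess(p$a, p$m, f = span)
    trend <- stats::approx(fit$x, fit$y, xout = p$a, rule = 2, ties = mean)$y
    p$m <- p$m - trend
  } else {
    if (is.null(p$gc_fraction))
      stopf("gc_bins normalization requires a gc_fraction column on the track")
    brk <- unique(stats::quantile(p$gc_fraction, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(p$gc_fraction, breaks = brk, include.lowest = TRUE)
    med <- tapply(p$m, bin, stats::median)
    scl <- tapply(p$m, bin, stats::mad)
    ref <- stats::median(scl[scl > 0], na.rm = TRUE)
    if (!is.finite(ref) || ref == 0) ref <- 1
    rescale <- ifelse(is.na(scl) | scl == 0, 1, scl / ref)
    p$m <- (p$m - med[bin]) / rescale[bin]
  }
  out <- track
  out$probes <- p
  out$state <- "within_array"
  attr(out, "within_array_method") <- method
  out
}

# In-package quantile normalization is delegated to limma; this wrapper
# enforces the replicate-only contract and the probe-set match.
#' Quantile normalization across replicate arrays
#'
#' Makes the marginal M distributions of replicate arrays identical by
#' replacing each rank's values with their across-array mean (ties receive
#' the mean of the tied ranks' means). This is a between-array step applied
#' only to replicates of one mark in one cell type: applying it across cell
#' types would erase genuine biological differences in signal range, so
#' tracks from different cell types (or marks) are refused.
#'
#' Missing M values are imputed with the track median for rank alignment
#' and flagged in an `imputed` column of the output probes.
#'
#' @param tracks list of `ratio_track`s in state `within_array`, sharing one
#'   probe set, mark and cell type.
#' @return List of `ratio_track`s in state `quantile`, same order.
#' @export
quantile_normalize <- function(tracks) {
  if (!is.list(tracks) || length(tracks) < 2)
    stopf("quantile normalization needs at least two replicate tracks")
  lapply(tracks, function(t) { stopifnot(inherits(t, "ratio_track")); check_state(t, "within_array") })
  if (length(unique(vapply(tracks, function(t) t$cell_type, character(1)))) > 1)
    stopf("tracks come from different cell types; quantile normalization is restricted to replicate arrays of one cell type (between-cell-type differences are biology, not batch)")
  if (length(unique(vapply(tracks, function(t) t$mark, character(1)))) > 1)
    stopf("tracks carry different marks; quantile normalization is restricted to replicates of one mark")
  ids <- tracks[[1]]$probes$probe_id
  for (t in tracks[-1]) if (!identical(t$probes$probe_id, ids))
    stopf("probe sets differ between tracks; quantile normalization requires a shared probe set")
  M <- vapply(tracks, function(t) t$probes$m, numeric(length(ids)))
  imputed <- is.na(M)
  if (any(imputed)) {
    for (j in seq_len(ncol(M)))
      M[imputed[, j], j] <- stats::median(M[, j], na.rm = TRUE)
  }
  Mq <- limma::normalizeQuantiles(M, ties = TRUE)
  Map(function(t, j) {
    t$probes$m <- Mq[, j]
    t$probes$imputed <- imputed[, j]
    t$state <- "quantile"
    t
  }, tracks, seq_along(tracks))
}

#' Average replicate tracks
#'
#' Combines quantile-normalized replicate arrays into a single track by the
#' per-probe arithmetic mean of M (and of A). The averaged track is the
#' input of peak calling.
#'
#' @param tracks list of `ratio_track`s in state `quantile` sharing a probe
#'   set. A single track is passed through with a warning.
#' @param array_id identifier for the averaged track.
#' @return A `ratio_track` in state `averaged`.
#' @export
average_replicates <- function(tracks, array_id = "avg") {
  if (inherits(tracks, "ratio_track")) tracks <- list(tracks)
  lapply(tracks, function(t) { stopifnot(inherits(t, "ratio_track")); check_state(t, "quantile") })
  if (length(tracks) == 1) {
    warnf("single replicate: averaging is a pass-through")
    out <- tracks[[1]]
    out$array_id <- array_id
    out$state <- "averaged"
    return(out)
  }
  ids <- tracks[[1]]$probes$probe_id
  for (t in tracks[-1]) if (!identical(t$probes$probe_id, ids))
    stopf("probe sets differ between tracks; cannot average")
  out <- tracks[[1]]
  out$probes$m <- rowMeans(vapply(tracks, function(t) t$probes$m, numeric(length(ids))))
  out$probes$a <- rowMeans(vapply(tracks, function(t) t$probes$a, numeric(length(ids))))
  out$probes$imputed <- NULL
  out$array_id <- array_id
  out$state <- "averaged"
  out
}
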