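# Shared fixtures and independent oracles, built in code at test time.

# Single-mark configuration shortcuts -------------------------------------

one_mark <- function(mark = "H3K4me3", polarity = "activating",
                     profile = "tss_double_peak", effect = 2, fraction = 0.4) {
  data.frame(mark = mark, polarity = polarity, profile = profile,
             effect = effect, fraction = fraction, stringsAsFactors = FALSE)
}

clean_config <- function(...) {
  # no distortions: round-trip configs
  simulation_config(dye_bias_amplitude = 0, noise_sd = 0,
                    array_scale_shifts = rep(0, 3), ...)
}

# Construct an averaged ratio_track directly from an M vector (unit-test
# substrate for the peak caller).
make_track <- function(m, spacing = 100, chromosome = "chr1", start = 0,
                       state = "averaged", mark = "mark", cell_type = "cellA") {
  n <- length(m)
  ratio_track(data.frame(
    probe_id = sprintf("p%05d", seq_len(n)), chromosome = rep(chromosome, n),
    position = as.integer(start + (seq_len(n) - 1L) * spacing),
    m = m, a = rep(10, n), stringsAsFactors = FALSE
  ), "t1", mark, cell_type, state = state)
}

# Brute-force region oracle ------------------------------------------------
# Enumerates every integer window start; a window hits when it contains
# >= min_probes above-cutoff probes forming a run of consecutive array
# probes with inter-probe gaps <= max_gap; overlapping hit windows are
# merged and each merged span reported by its outermost above-cutoff
# probes. Independent of the package's vectorised implementation.
oracle_regions <- function(pos, m, cutoff, min_probes = 4, window = 500,
                           max_gap = 200, spacing = 100) {
  above <- m > cutoff
  empty <- data.frame(start = integer(0), end = integer(0), n_probes = integer(0))
  if (sum(above) < min_probes) return(empty)
  starts <- seq(min(pos) - window + 1L, max(pos))
  hit <- logical(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    inw <- which(pos >= s & pos < s + window)
    iw <- inw[above[inw]]
    if (length(iw) < min_probes) next
    r <- cumsum(c(TRUE, diff(iw) > 1 | diff(pos[iw]) > max_gap))
    if (max(tabulate(r)) >= min_probes) hit[k] <- TRUE
  }
  if (!any(hit)) return(empty)
  hs <- starts[hit]
  grp <- cumsum(c(TRUE, diff(hs) >= window))  # windows overlap iff start diff < width
  out <- do.call(rbind, lapply(split(hs, grp), function(ss) {
    lo <- min(ss); hi <- max(ss) + window     # merged window span [lo, hi)
    sel <- which(above & pos >= lo & pos < hi)
    data.frame(start = pos[sel[1]], end = pos[sel[length(sel)]] + spacing,
               n_probes = length(sel))
  }))
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

# One full small coupled experiment (activating + silencing mark, coupled
# expression), normalised, peak-called and annotated. Expensive, so it is
# computed once per test session and memoised for every file that needs it.
.fixture_cache <- new.env(parent = emptyenv())

coupled_run <- function() {
  if (!is.null(.fixture_cache$coupled)) return(.fixture_cache$coupled)
  cfg <- simulation_config(
    n_genes = 1000, n_replicates = 2,
    marks = rbind(one_mark("H3K4me3", "activating", "tss_double_peak", 2, 0.4),
                  one_mark("H3K27me3", "silencing", "broad_domain", 1.5, 0.25)),
    rng_seed = 42
  )
  exp <- simulate_experiment(cfg)
  pc <- peak_caller_config(n_permutations = 10, probe_spacing = 100, rng_seed = 42)
  res <- lapply(cfg$marks$mark, function(mk) {
    tracks <- lapply(seq_len(cfg$n_replicates), function(r)
      within_array_normalize(ma_transform(exp$arrays$cellA[[mk]][[r]],
                                          array_id = paste0(mk, "_r", r),
                                          mark = mk, cell_type = "cellA")))
    avg <- average_replicates(quantile_normalize(tracks))
    ps <- call_peaks(avg, pc)
    asn <- assign_peaks_to_tss(ps, exp$model$genes)
    list(peaks = ps, assignment = asn,
         calls = call_promoter_state(asn, exp$model$genes))
  })
  names(res) <- cfg$marks$mark
  ptab <- do.call(rbind, lapply(res, function(x) assigned_peak_table(x$assignment)))
  net <- net_enrichment(ptab, exp$model$genes,
                        polarity = default_mark_polarity(),
                        expression_col = "expression_cellA")
  .fixture_cache$coupled <- list(config = cfg, model = exp$model, marks = res,
                                 peak_table = ptab, net = net)
  .fixture_cache$coupled
}

# Simulated, normalised, averaged null track (no enriched genes): the
# substrate of FDR-behaviour checks.
null_averaged_track <- function(seed, n_genes = 40, n_replicates = 2) {
  cfg <- simulation_config(n_genes = n_genes, n_replicates = n_replicates,
                           marks = one_mark(fraction = 0),
                           array_scale_shifts = rep(0, n_replicates),
                           rng_seed = seed)
  model <- build_promoter_model(cfg)
  tracks <- lapply(seq_len(n_replicates), function(r)
    within_array_normalize(ma_transform(simulate_array(model, "H3K4me3", r, cfg),
                                        array_id = paste0("r", r),
                                        mark = "H3K4me3", cell_type = "cellA")))
  average_replicates(quantile_normalize(tracks))
}
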