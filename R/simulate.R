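#' Default histone-mark descriptors for simulated experiments
#'
#' One row per antibody condition of a typical promoter tiling-array study:
#' the trimethylated H3K4 promoter mark (double peak flanking the TSS with a
#' trough at the TSS itself), acetylated H3, the elongation-associated
#' H3K79me2 and RNA polymerase II (highest in the gene body), and the broad
#' silencing domains of H3K27me3 and H3K9me3. Effect sizes are log2
#' enrichment at the profile maximum; `fraction` is the proportion of genes
#' truly carrying the mark.
#'
#' @return A data.frame with columns `mark`, `polarity`, `profile`,
#'   `effect`, `fraction`.
#' @export
default_marks <- function() {
  data.frame(
    mark     = c("H3K4me3", "H3ac", "H3K79me2", "PolII", "H3K27me3", "H3K9me3"),
    polarity = c("activating", "activating", "activating", "activating",
                 "silencing", "silencing"),
    profile  = c("tss_double_peak", "tss_double_peak", "gene_body", "gene_body",
                 "broad_domain", "broad_domain"),
    effect   = c(2.0, 1.8, 1.8, 1.5, 1.5, 1.2),
    fraction = c(0.4, 0.35, 0.3, 0.3, 0.25, 0.15),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic tiling-array generator
#'
#' Describes a simulated promoter tiling-array experiment: the promoter
#' model (number of genes, probe spacing, strand-oriented window of
#' `window_upstream` + `window_downstream` bp around each TSS), the marks
#' assayed, and the non-biological distortions the normalization stages must
#' remove (a smooth intensity-dependent dye-bias curve, per-replicate
#' between-array scale shifts, Gaussian log2 replicate noise).
#'
#' @param n_genes number of simulated genes.
#' @param probe_spacing distance between adjacent probe starts, bp.
#' @param window_upstream,window_downstream extent of the tiled window on
#'   each side of the TSS, in transcription orientation, bp. The defaults
#'   tile 11.2 kb (-8.2 kb to +3 kb).
#' @param marks data.frame of mark descriptors as from [default_marks()].
#' @param cell_types character vector of cell-type labels; truth marks and
#'   expression are drawn independently per cell type.
#' @param n_replicates replicate arrays per (mark, cell type).
#' @param dye_bias_amplitude amplitude (log2 units) of the quadratic-in-A
#'   dye-bias curvature added to M on every array.
#' @param array_scale_shifts per-replicate additive log2 offsets emulating
#'   between-array intensity shifts; defaults to offsets spread over
#'   +/- 0.25 across replicates.
#' @param noise_sd per-probe Gaussian log2 noise, sd.
#' @param baseline_a,baseline_a_sd,gc_a_slope parameters of the per-probe
#'   average log2 intensity A: `baseline_a + gc_a_slope*(gc - 0.5)` plus
#'   Gaussian jitter of sd `baseline_a_sd`. Tying A to probe GC lets the
#'   GC-binned within-array normalization stand in for an intensity model.
#' @param expression_log2_mean,expression_log2_sd log-normal baseline of
#'   simulated expression (log2 scale).
#' @param expression_coupling additive log2 expression effect of each truth
#'   mark (positive for activating, negative for silencing marks).
#' @param overlap_fraction fraction of genes placed so their tiled window
#'   overlaps the previous gene's window (exercises unique TSS assignment).
#' @param n_chromosomes,intergenic_gap genome layout: genes are distributed
#'   round-robin over chromosomes with `intergenic_gap` bp between windows.
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200,
                              probe_spacing = 100,
                              window_upstream = 8200,
                              window_downstream = 3000,
                              marks = default_marks(),
                              cell_types = "cellA",
                              n_replicates = 3,
                              dye_bias_amplitude = 0.5,
                              array_scale_shifts = NULL,
                              noise_sd = 0.25,
                              baseline_a = 10,
                              baseline_a_sd = 0.3,
                              gc_a_slope = 4,
                              expression_log2_mean = 6,
                              expression_log2_sd = 1.5,
                              expression_coupling = 2,
                              overlap_fraction = 0,
                              n_chromosomes = 5,
                              intergenic_gap = 5000,
                              rng_seed = 1L) {
  if (probe_spacing <= 0) stopf("probe_spacing must be positive")
  if (window_upstream + window_downstream < 4 * probe_spacing)
    stopf("tiled window (%d bp) is shorter than 4 probe spacings; it cannot contain a minimal peak",
          window_upstream + window_downstream)
  needed <- c("mark", "polarity", "profile", "effect", "fraction")
  if (!all(needed %in% names(marks)))
    stopf("marks must have columns: %s", paste(needed, collapse = ", "))
  if (anyDuplicated(marks$mark)) stopf("duplicated mark names in config")
  if (!all(marks$polarity %in% c("activating", "silencing")))
    stopf("mark polarity must be 'activating' or 'silencing'")
  if (!all(marks$profile %in% c("tss_double_peak", "gene_body", "broad_domain")))
    stopf("unknown spatial profile in marks")
  if (any(marks$effect <= 0)) stopf("mark effect sizes must be positive")
  if (is.null(array_scale_shifts)) {
    array_scale_shifts <- if (n_replicates == 1) 0 else
      seq(-0.25, 0.25, length.out = n_replicates)
  }
  if (length(array_scale_shifts) != n_replicates)
    stopf("array_scale_shifts must have one entry per replicate")
  structure(list(
    n_genes = as.integer(n_genes), probe_spacing = as.integer(probe_spacing),
    window_upstream = as.integer(window_upstream),
    window_downstream = as.integer(window_downstream),
    marks = marks, cell_types = cell_types,
    n_replicates = as.integer(n_replicates),
    dye_bias_amplitude = dye_bias_amplitude,
    array_scale_shifts = array_scale_shifts, noise_sd = noise_sd,
    baseline_a = baseline_a, baseline_a_sd = baseline_a_sd,
    gc_a_slope = gc_a_slope,
    expression_log2_mean = expression_log2_mean,
    expression_log2_sd = expression_log2_sd,
    expression_coupling = expression_coupling,
    overlap_fraction = overlap_fraction,
    n_chromosomes = as.integer(n_chromosomes),
    intergenic_gap = as.integer(intergenic_gap),
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

# Mark-specific spatial enrichment profile evaluated at strand-oriented
# distance d from the TSS (negative = upstream). Shapes are generator
# internals; only their qualitative contracts are part of the interface:
# tss_double_peak has maxima flanking the TSS with a trough at d = 0,
# gene_body peaks downstream of the TSS, broad_domain covers the window.
profile_value <- function(profile, d) {
  switch(profile,
    tss_double_peak = {
      v <- exp(-((d + 600)^2) / (2 * 350^2)) + exp(-((d - 600)^2) / (2 * 350^2))
      v / (1 + exp(-(1200^2) / (2 * 350^2)))
    },
    gene_body = exp(-((d - 1500)^2) / (2 * 800^2)),
    broad_domain = exp(-(d^2) / (2 * 3000^2)),
    stopf("unknown spatial profile '%s'", profile)
  )
}

#' Build a simulated promoter model and probe layout
#'
#' Places `n_genes` promoters on a small synthetic genome, tiles each
#' strand-oriented window `[tss - window_upstream, tss + window_downstream)`
#' with probes every `probe_spacing` bp, draws per-gene ground-truth mark
#' assignments from each mark's enriched fraction, and draws expression from
#' a log-normal baseline shifted up by activating and down by silencing
#' truth marks. Coordinates are 0-based half-open.
#'
#' @param config a [simulation_config()].
#' @return A list of class `promoter_model` with elements `genes`
#'   (gene_id, chromosome, window_start, window_end, tss, strand, one
#'   `expression_<cell type>` column per cell type), `probes` (probe_id,
#'   chromosome, position, gc_fraction, sorted by chromosome/position),
#'   `truth` (gene_id x cell_type x mark logical long table: simulation
#'   ground truth, never consumed by the analysis stages), and `config`.
#' @export
build_promoter_model <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$rng_seed, "model"), {
    n <- config$n_genes
    W <- config$window_upstream + config$window_downstream
    chroms <- sprintf("chr%d", ((seq_len(n) - 1L) %% config$n_chromosomes) + 1L)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    overlap <- rep(FALSE, n)
    if (config$overlap_fraction > 0 && n > 1) {
      cand <- which(duplicated(chroms))  # never the first gene on a chromosome
      k <- min(length(cand), round(config$overlap_fraction * n))
      if (k > 0) overlap[sample(cand, k)] <- TRUE
    }
    window_start <- integer(n)
    cursor <- stats::setNames(rep(1000L, config$n_chromosomes),
                              sprintf("chr%d", seq_len(config$n_chromosomes)))
    for (i in seq_len(n)) {
      ch <- chroms[i]
      if (overlap[i]) {
        # slide back so this window overlaps the previous one by half a window
        window_start[i] <- max(0L, cursor[ch] - config$intergenic_gap -
                                 as.integer(floor(W / 2)))
      } else {
        window_start[i] <- cursor[ch]
      }
      cursor[ch] <- window_start[i] + W + config$intergenic_gap
    }
    tss <- ifelse(strand == "+", window_start + config$window_upstream,
                  window_start + config$window_downstream)
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n)), chromosome = chroms,
      window_start = window_start, window_end = window_start + W,
      tss = as.integer(tss), strand = strand, stringsAsFactors = FALSE
    )

    # probe layout: union of per-gene tilings, deduplicated within chromosome
    probes <- do.call(rbind, lapply(split(genes, genes$chromosome), function(g) {
      pos <- sort(unique(unlist(lapply(seq_len(nrow(g)), function(i)
        seq(g$window_start[i], g$window_end[i] - 1L, by = config$probe_spacing)))))
      data.frame(chromosome = g$chromosome[1], position = as.integer(pos),
                 stringsAsFactors = FALSE)
    }))
    probes <- sort_by_position(probes)
    rownames(probes) <- NULL
    probes$probe_id <- sprintf("P%06d", seq_len(nrow(probes)))
    probes$gc_fraction <- round(stats::runif(nrow(probes), 0.25, 0.75), 4)
    probes <- probes[, c("probe_id", "chromosome", "position", "gc_fraction")]

    # ground truth and expression, independently per cell type
    truth <- do.call(rbind, lapply(config$cell_types, function(ct) {
      do.call(rbind, lapply(seq_len(nrow(config$marks)), function(j) {
        data.frame(gene_id = genes$gene_id, cell_type = ct,
                   mark = config$marks$mark[j],
                   enriched = stats::runif(n) < config$marks$fraction[j],
                   stringsAsFactors = FALSE)
      }))
    }))
    for (ct in config$cell_types) {
      base <- stats::rnorm(n, config$expression_log2_mean, config$expression_log2_sd)
      tct <- truth[truth$cell_type == ct, ]
      sign_of <- ifelse(config$marks$polarity == "activating", 1, -1)
      names(sign_of) <- config$marks$mark
      shift <- tapply(tct$enriched * sign_of[tct$mark], tct$gene_id, sum)
      genes[[paste0("expression_", ct)]] <- 2^(base + config$expression_coupling *
                                                 as.numeric(shift[genes$gene_id]))
    }
    structure(list(genes = genes, probes = probes, truth = truth, config = config),
              class = "promoter_model")
  })
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("promoter_model: %d genes on %d chromosomes, %d probes (%d bp spacing)\n",
              nrow(x$genes), length(unique(x$genes$chromosome)), nrow(x$probes),
              x$config$probe_spacing))
  cat(sprintf("  window: -%d/+%d bp around TSS; cell types: %s\n",
              x$config$window_upstream, x$config$window_downstream,
              paste(x$config$cell_types, collapse = ", ")))
  invisible(x)
}

#' True per-probe log2 enrichment of a mark
#'
#' Evaluates the generator's noiseless log2 ChIP/input ratio for one mark in
#' one cell type: the mark's spatial profile scaled by its effect size at
#' every gene carrying the mark in the simulation ground truth, summed where
#' tiled windows overlap, and 0 elsewhere.
#'
#' @param model a [build_promoter_model()] result.
#' @param mark mark name present in the model's configuration.
#' @param cell_type cell type label (defaults to the first configured one).
#' @return Numeric vector of log2 ratios, one per probe in `model$probes`.
#' @export
true_log2_ratio <- function(model, mark, cell_type = model$config$cell_types[1]) {
  stopifnot(inherits(model, "promoter_model"))
  j <- match(mark, model$config$marks$mark)
  if (is.na(j)) stopf("unknown mark '%s'; configured marks: %s", mark,
                      paste(model$config$marks$mark, collapse = ", "))
  if (!cell_type %in% model$config$cell_types)
    stopf("unknown cell type '%s'", cell_type)
  prof <- model$config$marks$profile[j]
  eff <- model$config$marks$effect[j]
  tr <- model$truth
  hit <- tr$gene_id[tr$cell_type == cell_type & tr$mark == mark & tr$enriched]
  m <- numeric(nrow(model$probes))
  if (!length(hit)) return(m)
  pos_by_chr <- split(seq_len(nrow(model$probes)), model$probes$chromosome)
  g <- model$genes[model$genes$gene_id %in% hit, ]
  for (i in seq_len(nrow(g))) {
    idx <- pos_by_chr[[g$chromosome[i]]]
    p <- model$probes$position[idx]
    lo <- findInterval(g$window_start[i] - 0.5, p) + 1L
    hi <- findInterval(g$window_end[i] - 0.5, p)
    if (hi < lo) next
    sel <- idx[lo:hi]
    d <- if (g$strand[i] == "+") model$probes$position[sel] - g$tss[i]
         else g$tss[i] - model$probes$position[sel]
    m[sel] <- m[sel] + eff * profile_value(prof, d)
  }
  m
}

# Smooth quadratic-in-A dye-bias curvature, the minimal distortion that
# produces a banana-shaped raw MA plot. Mean-centred under a symmetric A
# distribution.
dye_bias_curve <- function(a, amplitude) {
  if (amplitude == 0) return(numeric(length(a)))
  span <- max(abs(a - mean(a)))
  if (span == 0) return(numeric(length(a)))
  z <- (a - mean(a)) / span
  amplitude * (3 * z^2 - 1) / 2
}

#' Simulate one two-colour array
#'
#' Generates probe-level channel intensities for one replicate hybridisation
#' of one mark: the true log2 ratio from [true_log2_ratio()] is distorted by
#' the configured quadratic-in-A dye-bias curve, the replicate's scale
#' shift, and Gaussian log2 noise, then back-computed into red (ChIP) and
#' green (input) channel intensities `R = 2^(A + M/2)`, `G = 2^(A - M/2)`.
#'
#' @param model a [build_promoter_model()] result.
#' @param mark mark name.
#' @param replicate replicate index in `1..n_replicates`.
#' @param config a [simulation_config()]; defaults to the model's.
#' @param cell_type cell type label.
#' @return data.frame with columns `probe_id`, `chromosome`, `position`,
#'   `signal_r`, `signal_g`, `gc_fraction` (a probe-signal table).
#' @export
simulate_array <- function(model, mark, replicate = 1L,
                           config = model$config,
                           cell_type = config$cell_types[1]) {
  stopifnot(inherits(model, "promoter_model"))
  if (replicate < 1 || replicate > config$n_replicates)
    stopf("replicate must be in 1..%d", config$n_replicates)
  m_true <- true_log2_ratio(model, mark, cell_type)
  with_seed(derive_seed(config$rng_seed, "array", mark, cell_type, replicate), {
    n <- nrow(model$probes)
    a <- config$baseline_a + config$gc_a_slope * (model$probes$gc_fraction - 0.5) +
      stats::rnorm(n, 0, config$baseline_a_sd)
    m <- m_true + dye_bias_curve(a, config$dye_bias_amplitude) +
      config$array_scale_shifts[replicate] +
      (if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0)
    data.frame(
      probe_id = model$probes$probe_id, chromosome = model$probes$chromosome,
      position = model$probes$position,
      signal_r = 2^(a + m / 2), signal_g = 2^(a - m / 2),
      gc_fraction = model$probes$gc_fraction, stringsAsFactors = FALSE
    )
  })
}

#' Simulate a whole tiling-array experiment
#'
#' Convenience wrapper building the promoter model and all replicate arrays
#' for every configured (mark, cell type) pair.
#'
#' @param config a [simulation_config()].
#' @return list of class `simulated_experiment` with `model` and `arrays`, a
#'   nested list `arrays[[cell_type]][[mark]][[replicate]]` of probe-signal
#'   tables.
#' @export
simulate_experiment <- function(config) {
  model <- build_promoter_model(config)
  arrays <- lapply(stats::setNames(nm = config$cell_types), function(ct) {
    lapply(stats::setNames(nm = config$marks$mark), function(mk) {
      lapply(seq_len(config$n_replicates), function(r)
        simulate_array(model, mk, r, config, ct))
    })
  })
  structure(list(model = model, arrays = arrays, config = config),
            class = "simulated_experiment")
}

#' Simulate ChIP-qPCR threshold-cycle tables
#'
#' Generates Ct values for ChIP and input reactions at a set of genomic
#' regions so that the true percent-input (per [percent_input()]) equals the
#' simulated enrichment at the region:
#' `ct_chip = ct_input - log2(1/input_fraction) - log2(pct/100)`, with
#' optional Gaussian replicate jitter on both roles. When `model` is given,
#' a region's enrichment defaults to
#' `100 * input_fraction * 2^(mean true log2 ratio over its probes)`; a
#' region table may instead carry an `enrichment_pct` column overriding the
#' model lookup (and then `model` may be `NULL`).
#'
#' @param model a [build_promoter_model()] result, or `NULL`.
#' @param mark mark name (ignored when all regions carry `enrichment_pct`).
#' @param regions data.frame with `region_id` and either
#'   `chromosome`/`start`/`end` or `enrichment_pct`.
#' @param input_fraction fraction of chromatin reserved as input, in (0, 1).
#' @param n_replicates qPCR replicates per region and role.
#' @param jitter_sd Ct replicate jitter, cycles.
#' @param ct_input_base mean input Ct.
#' @param cell_type cell type label.
#' @param rng_seed seed (defaults to the model's configured seed).
#' @return data.frame with columns `sample_id`, `region_id`, `role`
#'   (chip/input), `replicate`, `ct`.
#' @export
simulate_qpcr <- function(model, mark, regions, input_fraction = 0.1,
                          n_replicates = 3, jitter_sd = 0.15,
                          ct_input_base = 25,
                          cell_type = if (!is.null(model)) model$config$cell_types[1] else "cellA",
                          rng_seed = if (!is.null(model)) model$config$rng_seed else 1L) {
  if (input_fraction <= 0 || input_fraction >= 1)
    stopf("input_fraction must be in (0, 1)")
  if (is.null(regions$region_id)) stopf("regions must have a region_id column")
  pct <- if (!is.null(regions$enrichment_pct)) {
    regions$enrichment_pct
  } else {
    m_true <- true_log2_ratio(model, mark, cell_type)
    vapply(seq_len(nrow(regions)), function(i) {
      sel <- model$probes$chromosome == regions$chromosome[i] &
        model$probes$position >= regions$start[i] &
        model$probes$position < regions$end[i]
      100 * input_fraction * 2^(if (any(sel)) mean(m_true[sel]) else 0)
    }, numeric(1))
  }
  if (any(pct <= 0)) stopf("simulated enrichment must be positive")
  with_seed(derive_seed(rng_seed, "qpcr", mark %||% "", cell_type), {
    out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      ct_in <- ct_input_base + stats::rnorm(n_replicates, 0, jitter_sd)
      ct_ch <- ct_input_base - log2(1 / input_fraction) - log2(pct[i] / 100) +
        stats::rnorm(n_replicates, 0, jitter_sd)
      data.frame(
        sample_id = paste0(cell_type, "_", mark %||% "na"),
        region_id = regions$region_id[i],
        role = rep(c("chip", "input"), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2),
        ct = c(ct_ch, ct_in), stringsAsFactors = FALSE
      )
    }))
    rownames(out) <- NULL
    out
  })
}
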