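test_that("the MA-plot report flags injected dye bias and clears after correction", {
  cfg <- simulation_config(n_genes = 20, marks = one_mark(fraction = 0.2),
                           dye_bias_amplitude = 0.5, n_replicates = 1,
                           array_scale_shifts = 0, rng_seed = 41)
  model <- build_promoter_model(cfg)
  raw <- ma_transform(simulate_array(model, "H3K4me3", 1, cfg))
  norm <- within_array_normalize(raw)
  rep1 <- ma_plot_report(raw, norm)
  before <- rep1$metrics[grepl("before", rep1$metrics$metric), ]
  after <- rep1$metrics[grepl("after", rep1$metrics$metric), ]
  expect_true(any(before$verdict == "warn"))     # bias visible pre-normalization
  expect_true(all(after$verdict == "pass"))
  expect_true(qc_pass(rep1))
  # a bias-free array passes on both sides
  cfg0 <- clean_config(n_genes = 20, marks = one_mark(fraction = 0.2), rng_seed = 41)
  model0 <- build_promoter_model(cfg0)
  raw0 <- ma_transform(simulate_array(model0, "H3K4me3", 1, cfg0))
  rep0 <- ma_plot_report(raw0, within_array_normalize(raw0), tolerance = 0.06)
  expect_true(all(rep0$metrics$verdict == "pass"))
  # constant-M track: every decile median equals the constant
  const <- make_track(rep(0.3, 100), state = "raw")
  const$probes$a <- seq(8, 12, length.out = 100)
  repc <- ma_plot_report(const, const, tolerance = 1)
  expect_true(all(abs(repc$metrics$value - 0.3) < 1e-12))
})

test_that("replicate concordance reports exact r = 1 for identical tracks", {
  t1 <- make_track(rnorm(200), state = "within_array")
  rep1 <- replicate_concordance(list(t1, t1))
  r <- rep1$metrics$value[rep1$metrics$metric == "pearson_r_1_2"]
  expect_equal(r, 1)
  # independent noise tracks decorrelate
  set.seed(15)
  a <- make_track(rnorm(5000), state = "within_array")
  b <- make_track(rnorm(5000), state = "within_array")
  rep2 <- replicate_concordance(list(a, b))
  expect_lt(abs(rep2$metrics$value[rep2$metrics$metric == "pearson_r_1_2"]), 0.1)
  # post-quantile tracks must have byte-equal summaries
  qn <- quantile_normalize(list(a, b))
  rep3 <- replicate_concordance(qn)
  spread <- rep3$metrics[grepl("fivenum", rep3$metrics$metric), ]
  expect_true(all(spread$value == 0))
  expect_true(all(spread$verdict == "pass"))
})

test_that("peak convergence flags a dead replicate", {
  live <- function(seed) {
    set.seed(seed)
    m <- rnorm(400, 0, 0.25)
    for (s in c(50, 150, 300)) m[s:(s + 5)] <- 2.5
    call_peaks(make_track(m), peak_caller_config(n_permutations = 5, rng_seed = seed))
  }
  dead <- call_peaks(make_track(rnorm(400, 0, 0.25)),
                     peak_caller_config(n_permutations = 5, rng_seed = 3))
  ok <- peak_convergence_report(list(r1 = live(1), r2 = live(2), r3 = live(4)))
  expect_true(qc_pass(ok))
  bad <- peak_convergence_report(list(r1 = live(1), r2 = live(2), r3 = dead))
  expect_false(qc_pass(bad))
  flagged <- bad$metrics[bad$metrics$metric == "strict_bound_bp_r3", ]
  expect_identical(flagged$verdict, "fail")
})

test_that("the TSS-distance histogram localises peak mass where it was placed", {
  genes <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
                      tss = c(20000L, 60000L), strand = "+",
                      stringsAsFactors = FALSE)
  near <- structure(data.frame(chromosome = "chr1",
                               start = c(19500, 20100, 59600),
                               end = c(19900, 20500, 60000),
                               tier = "strict", stringsAsFactors = FALSE),
                    class = c("peak_set", "data.frame"))
  asn <- assign_peaks_to_tss(near, genes)
  h <- tss_distance_histogram(asn)
  counts <- h$counts$peaks
  central <- h$counts$bin_start >= -1000 & h$counts$bin_end <= 1000
  expect_equal(sum(counts[central]), 3)
  expect_equal(sum(counts[!central]), 0)
  # empty calls give an all-zero histogram
  h0 <- tss_distance_histogram(assign_peaks_to_tss(near[0, , drop = FALSE], genes))
  expect_true(all(h0$counts$peaks == 0))
  # downstream (gene-body) peaks land at positive distances
  body <- structure(data.frame(chromosome = "chr1", start = 21500, end = 22000,
                               tier = "strict", stringsAsFactors = FALSE),
                    class = c("peak_set", "data.frame"))
  hb <- tss_distance_histogram(assign_peaks_to_tss(body, genes))
  expect_equal(sum(hb$counts$peaks[hb$counts$bin_start >= 0]), 1)
})

test_that("injected failure modes are detected across seeded simulations", {
  detect_bias <- detect_shift <- logical(50)
  for (i in 1:50) {
    cfg <- simulation_config(n_genes = 8, marks = one_mark(fraction = 0.25),
                             dye_bias_amplitude = 0.5, noise_sd = 0.25,
                             n_replicates = 2, array_scale_shifts = c(0, 0.5),
                             rng_seed = 1000 + i)
    model <- build_promoter_model(cfg)
    raws <- lapply(1:2, function(r)
      ma_transform(simulate_array(model, "H3K4me3", r, cfg),
                   array_id = paste0("r", r), mark = "H3K4me3"))
    # dye bias: pre-normalization decile medians out of tolerance
    rep_ma <- ma_plot_report(raws[[1]], within_array_normalize(raws[[1]]))
    detect_bias[i] <- any(rep_ma$metrics$verdict != "pass" |
                            grepl("before", rep_ma$metrics$metric) &
                              abs(rep_ma$metrics$value) > 0.05)
    # scale shift: five-number summaries disagree across replicates
    rep_cc <- replicate_concordance(raws)
    spread <- rep_cc$metrics[rep_cc$metrics$metric == "fivenum_range_median", ]
    detect_shift[i] <- spread$verdict != "pass"
  }
  expect_gte(mean(detect_bias), 0.95)
  expect_gte(mean(detect_shift), 0.95)
  # dead replicate: spike-free replicate flagged by peak convergence
  detect_dead <- logical(20)
  for (i in 1:20) {
    set.seed(2000 + i)
    live <- lapply(1:2, function(r) {
      m <- rnorm(400, 0, 0.25)
      for (s in c(60, 200, 330)) m[s:(s + 5)] <- 2.5
      call_peaks(make_track(m), peak_caller_config(n_permutations = 5,
                                                   rng_seed = 2000 + i + r))
    })
    dead <- call_peaks(make_track(rnorm(400, 0, 0.25)),
                       peak_caller_config(n_permutations = 5, rng_seed = i))
    rep_pc <- peak_convergence_report(list(r1 = live[[1]], r2 = live[[2]],
                                           r3 = dead))
    detect_dead[i] <- !qc_pass(rep_pc)
  }
  expect_gte(mean(detect_dead), 0.95)
})
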