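wa_track <- function(m, ...) make_track(m, state = "within_array", ...)

test_that("the MA transform follows the log2 channel algebra", {
  sig <- data.frame(probe_id = c("p1", "p2"), chromosome = "chr1",
                    position = c(0L, 100L),
                    signal_r = c(100, 400), signal_g = c(100, 100))
  tr <- ma_transform(sig)
  expect_equal(tr$probes$m, c(0, 2))
  expect_equal(tr$probes$a, c(log2(100), 0.5 * log2(40000)))
  expect_identical(tr$state, "raw")
})

test_that("non-positive intensities are rejected per probe, arrays above 5% fail", {
  sig <- data.frame(probe_id = sprintf("p%02d", 1:50), chromosome = "chr1",
                    position = (0:49) * 100L,
                    signal_r = rep(100, 50), signal_g = rep(100, 50))
  sig$signal_r[1] <- 0
  expect_warning(tr <- ma_transform(sig), "rejected 1 probe")
  expect_equal(nrow(tr$probes), 49)
  sig$signal_r[1:5] <- 0
  expect_error(ma_transform(sig), "rejected")
})

test_that("within-array normalization flattens an injected quadratic dye bias", {
  cfg <- simulation_config(n_genes = 30, marks = one_mark(fraction = 0.2),
                           dye_bias_amplitude = 0.5, noise_sd = 0.25,
                           n_replicates = 1, array_scale_shifts = 0,
                           rng_seed = 21)
  model <- build_promoter_model(cfg)
  raw <- ma_transform(simulate_array(model, "H3K4me3", 1, cfg))
  decile_medians <- function(track) {
    bin <- cut(track$probes$a,
               breaks = quantile(track$probes$a, probs = seq(0, 1, 0.1)),
               include.lowest = TRUE)
    as.numeric(tapply(track$probes$m, bin, median))
  }
  expect_gt(max(abs(decile_medians(raw))), 0.05)   # the bias is visible
  norm <- within_array_normalize(raw, method = "a_lowess")
  expect_lt(max(abs(decile_medians(norm))), 0.05)
  expect_identical(norm$state, "within_array")
  # gc_bins corrects dye bias through the GC component of intensity, so it
  # is exercised on an array whose intensity is GC-determined
  cfg_gc <- simulation_config(n_genes = 30, marks = one_mark(fraction = 0.2),
                              dye_bias_amplitude = 0.5, noise_sd = 0.25,
                              baseline_a_sd = 0.05, n_replicates = 1,
                              array_scale_shifts = 0, rng_seed = 22)
  model_gc <- build_promoter_model(cfg_gc)
  raw_gc <- ma_transform(simulate_array(model_gc, "H3K4me3", 1, cfg_gc))
  norm_gc <- within_array_normalize(raw_gc, method = "gc_bins")
  expect_gt(max(abs(decile_medians(raw_gc))), 0.05)
  expect_lt(max(abs(decile_medians(norm_gc))), 0.05)
})

test_that("within-array normalization barely moves an already centred track", {
  set.seed(1)
  n <- 2000
  probes <- data.frame(probe_id = sprintf("p%04d", 1:n), chromosome = "chr1",
                       position = (0:(n - 1)) * 100L,
                       m = rnorm(n, 0, 0.2), a = runif(n, 8, 12))
  tr <- ratio_track(probes, "t", "mk", "ct", state = "raw")
  norm <- within_array_normalize(tr, method = "a_lowess")
  expect_lt(max(abs(norm$probes$m - tr$probes$m)), 0.05)
})

test_that("within-array normalization is independent of genomic position", {
  set.seed(2)
  n <- 500
  m <- rnorm(n, 0, 0.3); a <- runif(n, 8, 12)
  base <- data.frame(probe_id = sprintf("p%04d", 1:n), chromosome = "chr1",
                     position = (0:(n - 1)) * 100L, m = m, a = a)
  perm <- base
  perm$position <- rev(base$position)   # same (m, a) pairs, new layout
  out1 <- within_array_normalize(ratio_track(base, "t", "mk", "ct"), "a_lowess")
  out2 <- within_array_normalize(ratio_track(perm, "t", "mk", "ct"), "a_lowess")
  expect_equal(out2$probes$m[match(base$probe_id, out2$probes$probe_id)],
               out1$probes$m[match(base$probe_id, out1$probes$probe_id)])
})

test_that("gc_bins requires a gc_fraction column", {
  tr <- make_track(rnorm(100), state = "raw")
  expect_error(within_array_normalize(tr, method = "gc_bins"), "gc_fraction")
})

test_that("quantile normalization matches the closed form on three probes", {
  out <- quantile_normalize(list(wa_track(c(1, 2, 3)), wa_track(c(2, 4, 6))))
  expect_equal(out[[1]]$probes$m, c(1.5, 3, 4.5))
  expect_equal(out[[2]]$probes$m, c(1.5, 3, 4.5))
  expect_identical(out[[1]]$state, "quantile")
})

test_that("quantile normalization fixes identical replicates and is idempotent", {
  set.seed(3)
  m1 <- rnorm(300); m2 <- m1 + rnorm(300, 0, 0.1)
  same <- quantile_normalize(list(wa_track(m1), wa_track(m1)))
  expect_equal(same[[1]]$probes$m, m1)
  once <- quantile_normalize(list(wa_track(m1), wa_track(m2)))
  again <- quantile_normalize(lapply(once, function(t) { t$state <- "within_array"; t }))
  expect_equal(again[[1]]$probes$m, once[[1]]$probes$m, tolerance = 1e-12)
  expect_equal(again[[2]]$probes$m, once[[2]]$probes$m, tolerance = 1e-12)
})

test_that("quantile normalization equalises distributions, preserves ranks and the grand mean", {
  set.seed(4)
  tracks <- list(wa_track(rnorm(500, 0.3, 1.2)), wa_track(rnorm(500, -0.1, 0.8)),
                 wa_track(rnorm(500, 0, 1)))
  out <- quantile_normalize(tracks)
  # sorted vectors identical across replicates (box/whisker summaries equal)
  expect_equal(sort(out[[1]]$probes$m), sort(out[[2]]$probes$m))
  expect_equal(sort(out[[2]]$probes$m), sort(out[[3]]$probes$m))
  expect_equal(fivenum(out[[1]]$probes$m), fivenum(out[[3]]$probes$m))
  # within-track rank order preserved
  for (j in 1:3)
    expect_equal(order(out[[j]]$probes$m), order(tracks[[j]]$probes$m))
  # grand mean preserved
  expect_equal(mean(sapply(out, function(t) mean(t$probes$m))),
               mean(sapply(tracks, function(t) mean(t$probes$m))),
               tolerance = 1e-12)
})

test_that("quantile normalization refuses cross-cell-type and mismatched inputs", {
  t1 <- wa_track(rnorm(50))
  t2 <- wa_track(rnorm(50), cell_type = "cellB")
  expect_error(quantile_normalize(list(t1, t2)), "cell type")
  t3 <- wa_track(rnorm(50), mark = "other")
  expect_error(quantile_normalize(list(t1, t3)), "different marks")
  t4 <- wa_track(rnorm(40))
  expect_error(quantile_normalize(list(t1, t4)), "probe set")
  raw <- make_track(rnorm(50), state = "raw")
  expect_error(quantile_normalize(list(t1, raw)), "state")
})

test_that("replicate averaging is the per-probe arithmetic mean", {
  q <- function(m) make_track(m, state = "quantile")
  avg <- average_replicates(list(q(c(0, 1, 4)), q(c(2, 1, 0))))
  expect_equal(avg$probes$m, c(1, 1, 2))
  expect_identical(avg$state, "averaged")
  trip <- average_replicates(list(q(c(1, 2, 3)), q(c(1, 2, 3)), q(c(1, 2, 3))))
  expect_equal(trip$probes$m, c(1, 2, 3))
  # oracle: brute-force per-probe sum / n on random tracks
  set.seed(5)
  ms <- replicate(4, rnorm(30), simplify = FALSE)
  avg4 <- average_replicates(lapply(ms, q))
  expect_equal(avg4$probes$m, Reduce(`+`, ms) / 4)
  expect_warning(single <- average_replicates(list(q(c(1, 2, 3)))), "pass-through")
  expect_identical(single$state, "averaged")
})

test_that("replicate correlation does not degrade from raw to quantile state", {
  cfg <- simulation_config(n_genes = 40, marks = one_mark(fraction = 0.5),
                           n_replicates = 2, rng_seed = 31)
  model <- build_promoter_model(cfg)
  raws <- lapply(1:2, function(r)
    ma_transform(simulate_array(model, "H3K4me3", r, cfg),
                 array_id = paste0("r", r), mark = "H3K4me3"))
  qn <- quantile_normalize(lapply(raws, within_array_normalize))
  r_raw <- cor(raws[[1]]$probes$m, raws[[2]]$probes$m)
  r_qn <- cor(qn[[1]]$probes$m, qn[[2]]$probes$m)
  expect_gte(r_qn, r_raw - 0.02)
})
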