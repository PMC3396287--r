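#' Percent-input enrichment from qPCR threshold cycles
#'
#' Expresses ChIP recovery at a region as a percentage of total input
#' chromatin. Because only a fraction of the chromatin is reserved as input
#' (one tenth by default), the input Ct is first corrected by the log2 of
#' the dilution factor `DF = 1/input_fraction`:
#' \deqn{\%input = 100 \times 2^{(Ct_{input} - \log_2 DF) - Ct_{ChIP}}}
#' so that one PCR cycle corresponds to an exact factor of two, a ChIP
#' reaction recovering as much material as the total input reads 100%, and
#' equal raw Ct values read `100 * input_fraction` percent.
#'
#' `formula = "literal"` instead evaluates the raw expression
#' `100 * 2^(ct_chip - ct_input * DF)` in which the dilution factor
#' multiplies the input cycle number; it is retained only for comparison and
#' is not recommended (cycle numbers are not multiplicative in DF).
#'
#' @param ct_chip,ct_input threshold cycles of the ChIP and input reactions
#'   (vectors recycle).
#' @param input_fraction fraction of chromatin reserved as input, in (0, 1).
#' @param formula `"dilution_adjusted"` (default) or `"literal"`.
#' @return Numeric vector of percentages (> 0).
#' @examples
#' percent_input(25 - log2(10), 25)          # 100
#' percent_input(25, 25)                     # 10, with the default 1/10 input
#' @export
percent_input <- function(ct_chip, ct_input, input_fraction = 0.1,
                          formula = c("dilution_adjusted", "literal")) {
  formula <- match.arg(formula)
  if (is.null(input_fraction) || is.na(input_fraction))
    stopf("input_fraction is required to adjust the input Ct")
  if (input_fraction <= 0 || input_fraction >= 1)
    stopf("input_fraction must be in (0, 1)")
  if (!all(is.finite(ct_chip)) || !all(is.finite(ct_input)))
    stopf("Ct values must be finite")
  df <- 1 / input_fraction
  if (formula == "literal")
    return(100 * 2^(ct_chip - ct_input * df))
  100 * 2^((ct_input - log2(df)) - ct_chip)
}

#' Percent input from a replicate Ct table
#'
#' Averages replicate Ct values on the cycle scale within each
#' (sample, region, role), applies [percent_input()], and propagates the
#' replicate Ct standard deviations to the percentage scale by the delta
#' method.
#'
#' @param ct_table data.frame with columns `sample_id`, `region_id`, `role`
#'   (`"chip"`/`"input"`), `ct`, and optionally `replicate`.
#' @param input_fraction fraction of chromatin reserved as input.
#' @return data.frame with one row per (sample, region): mean Ct per role,
#'   `percent_input`, and `percent_sd`.
#' @export
summarize_percent_input <- function(ct_table, input_fraction = 0.1) {
  needed <- c("sample_id", "region_id", "role", "ct")
  if (!all(needed %in% names(ct_table)))
    stopf("ct_table must have columns: %s", paste(needed, collapse = ", "))
  if (!all(ct_table$role %in% c("chip", "input")))
    stopf("role must be 'chip' or 'input'")
  out <- do.call(rbind, lapply(
    split(ct_table, list(ct_table$sample_id, ct_table$region_id), drop = TRUE),
    function(g) {
      chip <- g$ct[g$role == "chip"]; input <- g$ct[g$role == "input"]
      if (!length(chip) || !length(input))
        stopf("region '%s' is missing a chip or input measurement; pair them before summarising",
              g$region_id[1])
      p <- percent_input(mean(chip), mean(input), input_fraction)
      se2 <- stats::var(chip) / length(chip) + stats::var(input) / length(input)
      data.frame(sample_id = g$sample_id[1], region_id = g$region_id[1],
                 ct_chip = mean(chip), ct_input = mean(input),
                 n_replicates = length(chip), percent_input = p,
                 percent_sd = p * log(2) * sqrt(ifelse(is.na(se2), 0, se2)),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$region_id), , drop = FALSE]
}

#' Qualify a qPCR primer set from a standard-curve experiment
#'
#' Before primer sets are used for percent-input quantification they must
#' amplify with near-perfect efficiency: across a template dilution series
#' the threshold cycle should drop by exactly one per doubling of template
#' mass, and melt-curve analysis must show a single amplicon. The slope of
#' Ct against log2(mass) is fitted by least squares; amplification
#' efficiency is reported as `2^(-1/slope) - 1` (1.0 = perfect doubling).
#'
#' @param ct_by_mass data.frame with columns `mass_ng` and `ct` (mean Ct at
#'   each template mass); at least three mass points are required.
#' @param single_amplicon logical from melt-curve inspection; `FALSE` fails
#'   the primer set regardless of slope.
#' @param slope_tolerance maximum allowed deviation of the fitted slope
#'   from -1.
#' @param mass_range the template mass range (ng) a complete standard curve
#'   should span.
#' @return list of class `primer_qualification`: `slope`, `efficiency`,
#'   `single_amplicon`, `complete_range`, `pass`.
#' @export
qualify_primers <- function(ct_by_mass, single_amplicon = TRUE,
                            slope_tolerance = 0.1, mass_range = c(0.1, 20)) {
  if (!all(c("mass_ng", "ct") %in% names(ct_by_mass)))
    stopf("ct_by_mass must have columns mass_ng and ct")
  if (nrow(ct_by_mass) < 3)
    stopf("at least 3 mass points are required for a standard curve (got %d)",
          nrow(ct_by_mass))
  if (any(ct_by_mass$mass_ng <= 0)) stopf("template masses must be positive")
  fit <- stats::lm(ct ~ log2(mass_ng), data = ct_by_mass)
  slope <- unname(stats::coef(fit)[2])
  structure(list(
    slope = slope,
    efficiency = 2^(-1 / slope) - 1,
    single_amplicon = isTRUE(single_amplicon),
    complete_range = min(ct_by_mass$mass_ng) <= mass_range[1] &&
      max(ct_by_mass$mass_ng) >= mass_range[2],
    slope_tolerance = slope_tolerance,
    pass = isTRUE(single_amplicon) && abs(slope + 1) <= slope_tolerance
  ), class = "primer_qualification")
}

#' @export
print.primer_qualification <- function(x, ...) {
  cat(sprintf("primer qualification: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  slope (Ct vs log2 mass): %.3f (tolerance %.2f around -1)\n",
              x$slope, x$slope_tolerance))
  cat(sprintf("  efficiency: %.3f; single amplicon: %s; covers 0.1-20 ng: %s\n",
              x$efficiency, x$single_amplicon, x$complete_range))
  invisible(x)
}
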