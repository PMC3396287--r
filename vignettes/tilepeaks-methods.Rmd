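---
title: "Methods: promoter tiling-array ChIP-chip analysis with tilepeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter tiling-array ChIP-chip analysis with tilepeaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilepeaks)
```

# Scope and model

tilepeaks implements the data-preparation and data-analysis side of
ChIP-chip experiments on two-colour promoter tiling microarrays, the kind
used for miniaturised chromatin profiling of rare cell populations (of the
order of 10,000 cells per immunoprecipitation). The arrays tile an 11.2 kb
window — 8.2 kb upstream to 3 kb downstream of each annotated
transcription start site (TSS), in transcription orientation — with probes
roughly every 100 bp. Each hybridisation produces two channel intensities
per probe, R (ChIP) and G (input); all downstream analysis operates on

$$M = \log_2(R/G), \qquad A = \tfrac12 \log_2(R \cdot G).$$

The pipeline stages are:

1. **Within-array normalization** — remove intensity-dependent dye bias so
   the unenriched probe bulk sits on $M = 0$ at every $A$.
2. **Quantile normalization across replicate arrays only** — equalise
   signal ranges between replicates; never across cell types, where range
   differences are biology.
3. **Replicate averaging** — per-probe mean of $M$.
4. **Peak calling** — sliding-window detection with a cutoff ramp and
   permutation FDR.
5. **Promoter annotation** — unique assignment of each peak to the most
   proximate TSS whose window contains it; present/absent promoter calls.
6. **Integration** — the signed net-enrichment statistic and its relation
   to gene expression.
7. **QC** — MA-plot centring, replicate concordance, peak convergence,
   TSS-distance histograms.

A ChIP-qPCR module (percent-input quantification and primer
qualification) covers the locus-level assay that precedes and validates
array work.

# Peak calling

An averaged track is scanned with a 500 bp sliding window. A window is a
hit when it contains at least 4 *adjacent* above-cutoff probes — adjacent
meaning consecutive on the array layout with an inter-probe gap of at most
twice the probe spacing (larger gaps break adjacency; the tiled design has
no probes between promoter windows, so runs never leak across genes).
Overlapping hit windows are merged and each merged span is reported as one
region bounded by its outermost above-cutoff probes (0-based half-open;
the end is the last probe start plus the probe spacing).

Cutoffs are not a single threshold but a ramp: from 90% down to 15% of a
*theoretical maximum enrichment value* in 5% steps (16 levels). A peak's
**score** is the highest cutoff percentage at which it is still detected;
the score is also carried on the log2 scale
(`score_pct / 100 * theoretical_max`), which is what the integration stage
uses. Because the above-cutoff probe set only grows as the cutoff falls,
lowering the ramp floor can only extend or merge peaks, never remove them.

The theoretical maximum has no single standard definition, so two rules
are exposed: the default
`mean(M) + 6 * sd(M)` (a saturation-style heuristic) and `max(M)`. The
downstream behaviour that matters — false-discovery control and spike
recovery — is insensitive to the choice, and the test suite exercises
both.

**False discovery rates** are estimated by permutation: probe $M$ values
are shuffled (within each chromosome by default, preserving
per-chromosome probe counts) and the entire cutoff sweep is re-run, 20
times by default. For each observed score level $s$,

$$\mathrm{FDR}(s) = \frac{\overline{\#\{\text{permuted peaks with score} \ge s\}}}
                        {\#\{\text{observed peaks with score} \ge s\}},$$

clipped to $[0,1]$ and made monotone non-increasing in $s$. Twenty
permutations keep desk-scale runtime; the estimates are Monte-Carlo and
the smallest non-zero FDR resolvable is $1/20 \cdot 1/\#\text{observed}$,
which is adequate for the two tiers actually used: **strict**
(FDR $\le 0.05$; the only tier that drives biology) and **relaxed**
($0.05 <$ FDR $\le 0.2$; quality control only).

Peak *counts* are deliberately never interpreted quantitatively: random
intensity drop-outs inside an enriched region split one broad peak into
several small ones. `merge_fragmented_peaks()` exists only to demonstrate
this in QC; the quantitative currency is bound area (bp) and score.

# Promoter calls and net enrichment

Tiled windows overlap, so a peak may fall in several genes' windows. Each
peak is assigned to exactly one gene: among the genes whose
strand-oriented window contains the peak midpoint, the one with the
smallest |midpoint − TSS| wins; exact ties go to the gene earlier in
coordinate order (deterministic). The midpoint was chosen as the peak's
reference point for symmetry; an any-overlap candidate mode is available
behind a flag. A promoter is **enriched** for a mark when it carries at
least one strict-tier peak.

Net enrichment condenses a promoter's chromatin state into one signed
number. With strict peaks only, each peak contributes
$\text{bound area} \times \text{score}$ (log2 scale); per-mark sums are
formed, and

$$\mathrm{net} = \frac{S_{\mathrm{act}}}{\max(1, n_{\mathrm{act}})}
             - \frac{S_{\mathrm{sil}}}{\max(1, n_{\mathrm{sil}})},$$

where $n_{\mathrm{act}}$ and $n_{\mathrm{sil}}$ count the activating and
silencing marks *present* (at least one strict peak) at that promoter.
Dividing by the number of present marks — rather than the number assayed —
keeps promoters assayed with more antibodies from dominating the scale
while leaving absent marks neutral; an unnormalized variant is
switchable. The statistic is additive in
peaks, so fragmenting one region into several with the same total
area × score leaves it unchanged — the reason area, not count, is used.
Default polarities: H3K4me3, H3ac, H3K79me2, H3K36me3 and PolII
activating; H3K27me3 and H3K9me3 silencing.

For expression integration, genes are sorted by expression and grouped
into consecutive bins of 100 genes (the last bin may be short and is
flagged); per-bin mean expression and mean net enrichment are reported
with a Spearman correlation across bins. The fold-change analysis uses 12
thresholds (1.5 to 7 in 0.5 steps) per direction; expression ratios get a
pseudocount of 1 expression unit, and a promoter without a strict peak
scores 0.

# Within-array and between-array normalization

Vendor within-array normalization tools are proprietary black boxes; the
operative contract is the QC criterion — after correction, the probe bulk
must show no M-vs-A trend. Two methods satisfying that contract are
provided:

* `a_lowess` (default): subtract a lowess trend of M on A (span 0.3).
* `gc_bins`: standardise M within probe-GC bins — subtract the bin
  median, and rescale each bin's robust spread (MAD) to the median
  across-bin spread so that log2-ratio units are preserved (dividing by
  the raw per-bin MAD would re-express M in noise-SD units and break the
  downstream score scale). This is the closer analogue of
  sequence-model-based correction, and removes dye bias exactly insofar
  as intensity is GC-determined.

The "bias removed" tolerance is |median M| < 0.05 per A-decile: 0.05
log2 units is well below the smallest effect the peak caller acts on.

Quantile normalization uses the standard rank-mean transform
(`limma::normalizeQuantiles`, ties averaged), applied strictly within
replicate groups of one mark in one cell type — the function refuses
cross-cell-type input. It operates on M values — the peak caller's
substrate — rather than on per-channel intensities. Missing probe values
are median-imputed for rank alignment and flagged in the output.

# The synthetic-data generator

Every stage is tested against generated data, so the generator is
first-class code. It emulates, per array:

* the promoter tiling layout (11.2 kb windows, 100 bp spacing, genes
  distributed over chromosomes with 5 kb gaps; optionally overlapping
  windows to exercise unique TSS assignment);
* mark-specific spatial enrichment: a double peak flanking the TSS with a
  trough at the TSS itself (promoter marks such as H3K4me3), gene-body
  maxima downstream of the TSS (H3K79me2/H3K36me3-like), and broad
  domains (H3K27me3/H3K9me3-like). Shapes are piecewise-Gaussian mixtures
  and generator-private; only the qualitative contracts are asserted;
* a smooth quadratic-in-A dye-bias curve (default amplitude 0.5 log2
  units) — the minimal distortion producing the banana-shaped raw MA
  plot;
* per-replicate scale shifts (default spread ±0.25 log2 units) emulating
  between-array hybridisation differences;
* Gaussian log2 replicate noise (default sd 0.25);
* probe intensity tied to a per-probe GC fraction, so the GC-binned
  normalization has something to work with;
* expression coupled to ground truth: a log-normal baseline (log2 mean 6,
  sd 1.5) shifted by +2 log2 units per activating truth mark and −2 per
  silencing mark.

The assay's established parameters (window extents, probe spacing, the
500 bp window, 4-probe minimum, 90/15% cutoff ramp, FDR tiers, bins of
100, the 12 fold-change thresholds, the 1/10 input fraction) are the
package defaults. Noise magnitudes and effect sizes for real arrays are
not standardised anywhere; the defaults above are one-time choices of
plausible magnitudes for two-colour promoter arrays and are documented,
not claimed to match any particular deposited dataset. Channel intensities are back-computed as
$R = 2^{A + M/2}$, $G = 2^{A - M/2}$, so with distortions disabled the MA
transform recovers the true ratio exactly — the round-trip anchor of the
test suite.

What the generator does **not** model: probe sequence design and
cross-hybridisation, amplification bias from whole-genome amplification,
scanner image artifacts, spatial (print-tip) effects, and correlated
noise between neighbouring probes. Passing tests therefore demonstrate
that the *procedure* is implemented correctly and controls its error
rates under its own assumptions — not that those assumptions exhaust real
array pathology.

# Numerical and design choices

* Coordinates are 0-based half-open internally; BED output stays 0-based
  half-open, GFF output is 1-based inclusive.
* Window extents are applied in transcription orientation (upstream = 5'
  of the TSS on the gene's strand): 8.2 kb upstream, 3 kb downstream,
  consistent with promoter-array designs that tile far into the upstream
  regulatory region.
* Quantile-normalization ties receive the mean of the tied ranks' means
  (deterministic, permutation-invariant).
* Degenerate inputs: empty tracks yield empty peak sets; a constant track
  has theoretical maximum equal to the constant (sd 0); zero observed
  peaks short-circuit the FDR computation; a single replicate passes
  through averaging with a warning.
* All randomness (generator, permutations, QC subsampling) flows from
  integer seeds through derived sub-stream seeds, so every result is
  bit-reproducible and library code never perturbs the caller's RNG
  state.
* The qPCR percent-input formula is implemented with the dilution factor
  as a log2 correction of the input Ct
  ($\%\,\mathrm{input} = 100 \cdot 2^{(Ct_{in} - \log_2 DF) - Ct_{ChIP}}$,
  $DF = 1/\text{input fraction}$): one cycle is exactly a factor of two
  and a fully-recovered ChIP reads 100%. The widely reprinted raw
  expression with $DF$ multiplying the cycle number inside the exponent
  is dimensionally unsound; it remains available behind
  `formula = "literal"` for comparison.

# Problem sizes

The test suite runs the full pipeline at sizes chosen to exercise every
code path while staying interactive: 1,000 genes × 2 marks ×
2 replicates for the integration fixture, 50 × 40-gene null experiments
for false-discovery behaviour, 50 constructed 200-probe tracks for spike
recovery, and 10–60-gene experiments elsewhere. The whole suite completes
in well under a minute on one core; the standalone acceptance script
(50 null experiments of 200 genes each, full pipeline) in about half a
minute.

# Known limitations

* FDR estimates with 20 permutations are coarse near the strict threshold;
  raise `n_permutations` for publication-grade calls.
* The permutation null destroys all spatial autocorrelation, including
  any that is technical rather than biological; on real arrays with
  correlated probe noise the FDR is anti-conservative to an unknown
  degree.
* Cross-cell-type comparability is intentionally out of scope beyond a
  user-driven housekeeping-gene inspection; no normalization is applied
  across cell types.
* Single-TSS promoter models only; multi-isoform TSS clusters, enhancers
  and CpG-island context are not represented.

# A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = simulation_config(n_genes = 200, rng_seed = 1),
  peaks = peak_caller_config(n_permutations = 20, rng_seed = 1)
)
run_pipeline(cfg, "tilepeaks_run")
```

This writes per-stage directories (`simulate/`, `normalize/`, `peaks/`,
`annotate/`, `integrate/`, `qc/`) with tab-separated tables, BED and GFF
exports and QC metrics, plus the resolved configuration; deleting a stage
directory and re-running resumes from that stage, and the same seed
reproduces every table byte for byte.
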