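---
title: "Methods: activity scoring, sorting simulation and enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity scoring, sorting simulation and enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agscope)
```

This vignette documents the models behind `agscope`, the defaults and why
they were chosen, what the synthetic-data generators do and do not emulate,
and the numerical decisions that a maintainer would otherwise have to reverse
engineer from the code.

## Single-cell activity scoring

Cells incubated with D₂O incorporate deuterium into C–D bonds in proportion
to their metabolic activity. The per-cell score is

$$\%CD = 100 \cdot \frac{I_{CD}}{I_{CD} + I_{CH}},$$

with band integrals over C–D (2,040–2,300 cm⁻¹) and C–H (2,800–3,100 cm⁻¹).

**Baseline correction.** `integrateBand()` subtracts the straight line
through the window's endpoint intensities and clips negative residuals to
zero before the trapezoid. This choice makes %CD exactly invariant under
intensity scaling and under any additive *linear* baseline (a property the
test suite asserts), at the cost of not modelling curved fluorescence
backgrounds. Proprietary preprocessing pipelines for this kind of data are
not publicly specified; the endpoint baseline is the simplest rule with a
provable invariance, and it is applied per band so local drift is tolerated.

**Validity.** A spectrum is valid when both the C–H and phenylalanine
(990–1,015 cm⁻¹, around the ~1,000 marker) peak heights exceed
`snrMin = 3` times the robust noise level, estimated as the scaled MAD of the
silent 1,850–1,900 cm⁻¹ window's residuals about its endpoint baseline.
Three-sigma is the conventional detection limit; "clear peak" has no sharper
published definition for this assay.

**Thresholding.** The activity cutoff is `mean + 3·SD` of water-control %CD
values, with the sample SD (n − 1): the estimator is not specified more
precisely in the field's descriptions, and the sample SD is the conservative
small-n choice. Classification is strictly greater-than at the boundary — a
cell exactly at the threshold is *inactive* — because threshold semantics are
otherwise unspecified and strictness is conservative. Controls are pooled
across donors by default (`scoreActivity(controlCondition=)`); per-donor
thresholds can be fitted by subsetting. Note that `mean + 3·SD` is *not*
monotone in every single control value: raising a below-mean control shrinks
the SD faster than it raises the mean (e.g. controls {1,2,3} give 5 but
{1.5,2,3} give 4.46). The property tests therefore assert location/scale
equivariance rather than the naive per-value monotonicity.

**Condition comparison.** `compareActivity()` is a one-way fixed-effects
ANOVA on cells pooled over donors, matching how per-cell activity differences
are conventionally reported for this assay; it ignores donor clustering, so
its p-values describe the pooled-cell population, not a donor-level
inference.

## Sorting model

The sorter decides in real time from raw integrated signal, so the indices
use *uncorrected* trapezoid integrals:

* `Pc` = cell-band (1,620–1,670 cm⁻¹) integral of the cell spectrum divided
  by the same integral of the surrounding-medium spectrum. A ratio (not a
  difference) is used because the published threshold 1.1 is dimensionless
  and sits just above the background value of 1.
* `PL` = C–D integral over the silent reference (1,850–1,900 cm⁻¹) integral
  within the cell spectrum. The reference denominator is floored at 1e-12
  intensity-area units; a non-positive *background* cell-band integral is an
  error because no meaningful `Pc` exists for it.

Collection requires **both** `Pc > 1.1` and `PL > 6.0`, strictly — the two
indices capture different requirements (a cell is present; it is labelled)
and must hold jointly. `simulateSortRun()` misdirects each decided cell
independently with probability `1 − accuracy` (default 0.983), symmetrically
for both outlets since only a single accuracy figure is published; duration
is `n / throughput` at 500 cells/h; colonies are Binomial(n collected,
`cultivationP`). Cell count is conserved for every seed (tested).

## Enrichment statistics

Per genus and donor, with relative abundances A (treated) and B
(donor-matched no-amendment control, same timepoint),

$$EF = \frac{2A}{A+B} - 1 \in [-1, 1],$$

antisymmetric in (A, B), with EF(0, 0) := 0 — the 0/0 case carries no
evidence of change and zero is the only symmetric completion.

**Calling rule.** For each genus a one-sample z across donors,
`z = mean(EF) / (SD/√n)`, two-sided normal p, Benjamini–Hochberg adjustment
across the genera of the stratum, and `enriched = (mean EF > 0) & (p_adj <
0.05)`. The SD is floored at 1e-8 so unanimous responses give a finite,
extreme z rather than a division failure. The z construction is one of two
defensible readings of "z-scores derived from relative-abundance
comparisons"; the per-donor two-proportion alternative operates on counts
rather than EFs and is deliberately not the default, since the EF is the
published effect scale. With n = 10 donors a normal reference for a
statistic with an estimated SD is slightly anticonservative: its exact
type-I error at nominal 0.05 is
`2·(1 − pt(qnorm(0.975), 9)) ≈ 0.082`. The acceptance suite asserts the
empirical null rejection rate against that derived value, not against a
literal 5%.

**PERMANOVA.** Implemented directly (not delegated) as sequential (Type I)
sums of squares on the Gower-centred matrix
`G = −½·C·D²·C`: for cumulative hat matrices `H_k` of the model terms,
`SS_k = tr(H_k G) − tr(H_{k−1} G)`, pseudo-F against the residual mean
square, and p-values `(1 + #{F* ≥ F}) / (1 + nPerm)` under free row/column
permutations of `G` — the same conventions as `adonis2` with `by = "terms"`,
which the test suite uses as an independent cross-check of SS, R² and F.
Donor is entered before treatment by default so the treatment term is tested
after donor structure is absorbed; 999 permutations by default. Permutations
are free (unrestricted): with a donor term in the model this matches the
default behaviour of the reference implementation, though restricted
within-donor permutation schemes exist and are out of scope here.

**PCoA** is classical metric scaling via `stats::cmdscale`; axes with
non-positive eigenvalues are dropped rather than corrected (Bray–Curtis
matrices are generally non-Euclidean; the retained axes are the standard
reporting surface).

## Growth and coculture

`aucTrapezoid()` integrates OD600 over time above an explicit blank level
with negative values clipped; `growthBoost()` subtracts each replicate's
first-timepoint OD as its blank (plate blanking is rarely reported for this
assay; the first read is the only blank consistently available), then
reports the **ratio** of mean AUCs — a heatmap of "growth relative to
control" is only dimensionless as a ratio — with a two-sided Student's
equal-variance t-test on the 3 + 3 replicate AUCs (Welch via
`varEqual = FALSE`).

qPCR standard curves are least squares on `Cq ~ log10(copies)` with
efficiency `10^(−1/slope) − 1`; quantification inverts the curve. The
coculture analysis reports *both* defensible fold-change readings — the
within-arm 24 h vs 0 h L2FC and the coculture-vs-monoculture t-test at 24 h —
because a single contrast cannot simultaneously produce the published L2FC
bars and an n = 6 t-test. The L2FC pseudocount defaults to the smallest
positive quantified copy number in the run, keeping zero wells finite without
dominating the scale. The focal degrader's own L2FC (coculture vs
monoculture) is reported when its quantifications are supplied, to flag
growth suppression of the degrader by its partner.

## Synthetic data: what it does and does not emulate

* **Spectra** are sums of Gaussian peaks (FWHM 40 cm⁻¹ for C–D/C–H,
  12 cm⁻¹ for phenylalanine, 30 cm⁻¹ for the amide band) on a 1 cm⁻¹ grid
  over 400–3,200 cm⁻¹, plus a linear baseline and white noise. Real
  lineshapes are Voigt-like and backgrounds curved; Gaussians on a linear
  baseline are the simplest shape for which the generator's ground truth
  (`cdFraction`) provably equals the noise-free band ratio (relative error
  < 1e-6, tested). Passing %CD-recovery tests therefore demonstrates correct
  integration and baseline algebra, not robustness to fluorescence or cosmic
  rays, which are out of scope.
* **Count tables** draw donor-specific baseline proportions log-normally
  (SD 1 on the log scale — enough donor structure that the donor term
  dominates a PERMANOVA, as it does in real incubations) and then sample
  multinomially at fixed depth (default 50,000 reads, a typical 16S library
  size); planted genera are multiplied by the effect size and renormalised in
  treated samples at timepoints after 0 h. Renormalisation means planting an
  enrichment induces mild compositional depletion of the other genera — a
  real feature of relative-abundance data that the calling rule's
  `mean EF > 0` condition must (and does) resist.
* **Growth curves** are logistic with lag; the unboosted arm is a flat
  no-growth baseline at OD 0.05, emulating a strain that cannot use the
  substrate. Diauxie, death phases and plate-edge effects are not modelled.
* **qPCR** is exactly log-linear with Gaussian Cq noise and triplicate
  wells; inhibition and plateau effects are not modelled.
* **Census** generation is deterministic: a composition table expanded
  record by record with round-robin donor assignment. The packaged
  composition (`agIsolateComposition()`) is the 98-isolate, 16-species,
  three-phylum census of the underlying study.

Problem sizes in the test and acceptance suites (100-seed spectrum recovery,
50-seed enrichment simulations at 10 donors × 20 genera × 50,000 reads,
500 null PERMANOVAs at 199 permutations) were chosen as the smallest designs
whose Monte-Carlo error is well below the asserted tolerances.

## Degenerate inputs and tie-breaks

* Band windows outside the spectrum, or with fewer than two points, are
  errors naming the window; an all-zero spectrum is *invalid*, not an error.
* `computeCdFraction` errors when both band integrals vanish (no signal).
* `growthBoost`/`cocultureAnalysis` return `t = 0, p = 1` when all values are
  identical (a self-comparison), rather than erroring inside `t.test`.
* A zero mean control AUC flags the boost as undefined (`NA`) instead of
  returning infinity.
* Representative isolates are selected one per species by lowest isolate id —
  the real selection used recovery frequency and growth, which are not
  reproducible from a census table, so the rule is made deterministic and
  documented.

## Known limitations

The activity ANOVA ignores donor clustering; PERMANOVA permutations are
unrestricted; the z-based enrichment call is mildly anticonservative at small
donor numbers (quantified above); spectra are treated as already
wavenumber-calibrated and despiked; and none of the generators simulate
instrument physics or read-level sequence data.
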