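---
title: "Single-cell infrared phenomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell infrared phenomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irpheno)
```

## The problem

Single-cell Fourier-transform infrared (FTIR) microspectroscopy measures,
for each cell deposited on an IR-transparent window, a mid-infrared
absorbance spectrum over roughly 4,000-650 cm⁻¹. The spectrum is a
fingerprint of the cell's biochemical composition: CH stretching and
bending bands report membrane fatty acids, the amide bands report
proteins, and the 1,300-900 cm⁻¹ bands report carbohydrates and nucleic
acids. Because the measurement is per cell, the *spread* of spectra within
a treatment group quantifies cell-to-cell heterogeneity — information that
is lost when only group-average spectra are analysed. `irpheno` implements
that analysis end to end: preprocessing, a 14-dimensional per-cell feature
matrix, cell-to-cell Euclidean distance statistics, region-scoped PCA, and
a companion module for classifying drug-combination effects.

## Preprocessing chain

The chain applied by `preprocess_set()` is, in fixed order:

1. **(optional) Mie-EMSC** on the raw absorbance (`emsc_mie_correct()`),
2. **9-point moving-average smoothing** (`smooth_spectra()`),
3. **linear automatic baseline correction** (`baseline_linear()`),
4. **Savitzky-Golay second derivative** (`second_derivative()`).

The scattering correction runs first because the Mie baseline is a
distortion of the raw absorbance; the derivative runs last because it is
the input of peak detection and PCA. Each step appends a provenance tag,
and downstream stages check those tags rather than trusting the caller.

**Smoothing.** A centred moving average of odd width (default 9 points,
i.e. ~17 cm⁻¹ at the default 2 cm⁻¹ spacing). At the edges the window
shrinks symmetrically, which keeps constants and straight lines exactly
invariant everywhere, including the end points.

**Baseline.** "Linear automatic" baseline correction is implemented as a
deterministic two-point rule: subtract the straight line through the
minimum of the first 5% and the minimum of the last 5% of the grid.
Anchor selection and subtraction are iterated to a fixed point (one or two
passes in practice), at which both end-segment minima are exactly zero.
The fixed-point form was chosen over a single pass because it makes the
operation exactly idempotent — re-correcting corrected data is a no-op —
and over a convex-hull "rubber band" because a single linear segment is
the standard single-segment automatic correction and is easier to reason
about in tests.

**Second derivative.** Savitzky-Golay filtering (local least-squares
polynomial fits; default window 9, polynomial order 3, matching the
smoothing scale since neither is otherwise constrained), scaled by the
grid spacing so results are in a.u./cm² and invariant to the digital point
spacing. Edge points come from the one-sided polynomial fits of the
Savitzky-Golay projection matrix. Absorption maxima become sharp negative
minima, which both resolves overlapping bands and annihilates any
residual linear baseline.

**Mie-EMSC.** Each spectrum is regressed on a design matrix containing the
reference spectrum (cohort mean by default), polynomial baseline terms up
to order 2, and nine van de Hulst extinction curves spanning a sphere
diameter × refractive-index grid (5-20 µm × 1.20-1.45). The corrected
spectrum is `(raw − fitted interferents) / b` with `b` the reference
coefficient; a `|b| ≤ 1e-6` fit aborts with the cell named rather than
dividing by a near-zero scale. The interferent basis uses the
*non-resonant* van de Hulst extinction curve
`Q(ρ) = 2 − (4/ρ)sin ρ + (4/ρ²)(1 − cos ρ)`, `ρ = 2πd(n−1)w`; a full
resonant (complex-index, Kramers-Kronig) treatment distorts band shapes
near strong absorptions, but the downstream features depend on *peak
positions*, which the non-resonant correction preserves. More curves or
iterations can be configured; with `emsc_iterations > 1` the corrected
cohort mean becomes the next pass's reference.

Whether PCA should see Mie-corrected or uncorrected derivatives is
genuinely open; both paths are supported via the `emsc` flag of
`preprocess_set()`, and the default (off) assumes cohorts without gross
scattering artifacts. Simulated cohorts with `mie_amplitude > 0` should
set `emsc = TRUE`.

## The 14-peak feature matrix

`detect_peaks()` takes the cohort-mean second-derivative spectrum, finds
local minima inside each region of the region table, ranks them by depth
and keeps the expected count per region — 4 in the fatty-acid intervals
(3,000-2,800 and 1,480-1,300 cm⁻¹), 7 in the protein interval
(1,800-1,480 cm⁻¹), 3 in the carbohydrate interval (1,300-900 cm⁻¹).
Depth ties break toward the higher wavenumber. Consensus detection on the
cohort mean (rather than per cell) guarantees a common 14-dimensional
basis, which Euclidean distances require; `build_feature_matrix()` then
honours per-cell peak shifts by refining each consensus position to the
cell's own derivative minimum within ±8 cm⁻¹ (falling back to the
consensus position, with a logged note, when no in-region minimum exists
there). A wavenumber on a shared region boundary (1,480, 1,300 cm⁻¹)
belongs to the higher-wavenumber region only, so the three subregional
point sets partition the grid and squared subregional distances add
exactly to the full squared distance.

The matrix entry is the cell's processed absorbance at the refined
position (`value_source = "original_absorbance"`). The alternative,
`"second_derivative_depth"` (the negated derivative value), is retained
because band depth in the second derivative is less sensitive to residual
baseline; the absorbance convention is the default because the feature is
meant to be the cell's extracted spectral intensity. No cell is ever
silently imputed: a cell is either represented at its refined or consensus
position, with fallbacks recorded in `fm$notes`.

`prominence_quantile` defaults to 0 (pure top-N by depth); there is no
principled prominence threshold for these spectra, and top-N with a known
expected count is both simpler and order-free.

## Distances, histograms, PCA

`distance_matrix()` computes all k² cell-to-cell Euclidean distances
`D_Eu(p, q) = sqrt(Σ(pᵢ − qᵢ)²)` over a scope of the feature columns
(all 14, or the 4/7/3 subregional vectors). The full k × k matrix is the
heatmap object; the k(k−1)/2 unique unordered pairs feed the histogram
and the heterogeneity index (mean, median, IQR). Larger distances mean
lower cell-to-cell similarity. Features are *not* standardised before
distances by default — the measured absorbances are on a common scale and
rescaling would change the statistic; a `standardize` flag exists for
users who want it.

`pca_spectra()` performs mean-centred, unscaled PCA of the
second-derivative spectra (not of the 14-dim feature matrix) over the
full spectrum or one region's wavenumbers. Centring without unit-variance
scaling is the spectroscopic standard: wavenumber channels share units,
and scaling would inflate noise channels. Components are ordered by
explained variance; each loading's sign is fixed so its
largest-magnitude element is positive, making score plots reproducible.
`group_silhouette()` summarises group separation on the first two score
columns as a mean silhouette width; the test-suite thresholds (> 0.5 for
"clusters separately", < 0.2 for "dispersed") are this package's
quantitative surrogates for those qualitative descriptions.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code: it generates the study
conditions every downstream stage is validated against. Each cell is

```
A(w) = Σ_b amp_b · exp(−(w − c_b)²/2σ_b²) + mie + drift + noise
amp_b = amplitude_b · effect_group,b · LogNormal(cv)
```

with a mean-one log-normal cell factor, a per-cell van de Hulst baseline
(random diameter 8-20 µm, index 1.30-1.40) scaled by `mie_amplitude`, a
random linear drift, and additive Gaussian noise. One seeded generator
per call, with per-cell draws consumed in cell-id order, makes cohorts
bitwise reproducible and independent of iteration strategy.

Defaults and why:

* **14 Gaussian bands** at canonical cell-FTIR positions (2,960, 2,924,
  2,872, 2,852; 1,740, 1,696, 1,656, 1,628, 1,584, 1,544, 1,514; 1,240,
  1,084, 1,050 cm⁻¹), 4/7/3 across the regions. Centres were chosen on
  the default 2 cm⁻¹ grid, and widths (FWHM 10-26 cm⁻¹) chosen so that
  every band survives 9-point smoothing as a distinct second-derivative
  minimum — the defining property of the default table, since it is the
  ground truth for peak-detection tests. Gaussian shapes (not Voigt) keep
  the band sum analytic for oracles; peak positions, not shapes, drive
  the features. No default band sits in the 1,480-1,300 cm⁻¹ fatty-acid
  bending interval, mirroring the convention that peaks 1-4 are the CH
  stretching bands; users can add bending bands, and detection follows
  whatever the region table and expected counts say.
* **cell_cv = 0.15**: a 15% coefficient of variation of band amplitudes
  is a realistic magnitude for biochemical cell-to-cell variability in
  cultured lines.
* **noise_sd = 0.002 a.u.**: consistent with a well-measured absorbance
  spectrum of peak height ~1 a.u. (S/N of several hundred).
* **drift_sd = 0.005 a.u.**, Mie off by default: baseline artifacts are
  opt-in so that tests isolate the effect under study.

What the generator does *not* emulate: water-vapour and CO₂ lines,
detector nonlinearity, resonant (absorption-coupled) Mie dispersion,
band-shape changes from conformational shifts, and correlated amplitude
structure across bands. Passing tests therefore demonstrate that the
pipeline recovers the generative structure under realistic noise,
variability and non-resonant scattering — not that it is robust to every
artifact of beamline data.

## Drug-combination module

For one dose pair with single-agent responses `Pa`, `Pb` and combined
response `P(a+b)` (fractions of the same kind), three null models are
implemented:

* **Additivity (CDI)**: `CDI = P(a+b) / (Pa·Pb)`; < 1 synergy, = 1
  additivity, > 1 antagonism (boundary band ±0.05 by default).
* **Statistical (Bliss) independence**: expected
  `1 − (1−Pa)(1−Pb)`; the excess `P(a+b) − expected` calls synergy or
  antagonism by sign (band ±0.01), requiring inhibition-kind input.
* **Pharmacological independence (HSA)**: expected `max(Pa, Pb)`, same
  excess convention, inhibition-kind input.

The CDI ratio is evaluated on whichever response kind the caller
supplies, and conversion between viability and inhibition is only ever
explicit (`to_inhibition()`): the ratio is not invariant under
`p → 1 − p`, so a silent coercion would change the verdict. (On a single
consistent measurement, CDI on *viability* is algebraically the Bliss
ratio, so viability-CDI antagonism cannot coexist with Bliss synergy;
with CDI on *inhibition* the two models can genuinely disagree, which is
exactly the configuration the consensus report is for. One published
description of the Bliss rule states the comparison in a form —
`P(a+b) + (1−Pa)(1−Pb) < 1` implying synergy — that contradicts the
excess-over-expectation direction it defines in the same breath; this
package follows the defining rule, synergy iff
`P(a+b) > 1 − (1−Pa)(1−Pb)`.) `interaction_report()` runs all three
models and reports a 2-of-3 majority consensus, labelled `"discordant"`
when no majority exists.

`fit_ic50_4pl()` fits
`r(c) = bottom + (top − bottom)/(1 + (c/IC50)^hill)` by bounded
Levenberg-Marquardt least squares, multi-started over Hill slopes
{0.5, 1, 2, 4} with `bottom ∈ [0, 0.5]`, `top ∈ [0.5, 1.1]`, and returns
the relative IC50 (the fitted inflection). It warns when the
dose-response is weakly monotone (Spearman |ρ| < 0.5) and refuses
constant responses. `mass_to_molar()` converts µg/mL to µM exactly
(`conc/M × 1000`); printed tables conventionally round to 2 decimals, so
comparisons against published conversions should allow ±0.02 µM for
last-digit rounding.

## Numerical conventions and degenerate inputs

* Spectra are stored high-to-low wavenumber (spectrometer convention);
  ascending input grids are reversed on load. Interval membership is
  always `lo ≤ w ≤ hi`, independent of storage order.
* Grid alignment on load is exact-match only; a cell whose grid differs
  is reported by id, never interpolated.
* Wide-table output uses `%.17g` formatting, so write-then-read is
  bitwise the identity.
* Distance computation uses the expanded-square form with negative
  round-off clamped at zero and explicit symmetrisation.
* PCA refuses zero-variance input; EMSC refuses near-zero reference
  coefficients; peak detection fails loudly, naming the region, when a
  region has fewer minima than expected.

## Problem sizes in the test suite

The suite validates parameter recovery at 100 cells/group (matching the
200-cell cohort scale the feature matrix is designed around), Monte-Carlo
IC50 recovery on 200 simulated assays of 6 doses × 3 replicates at 5%
noise, heterogeneity monotonicity on 40-cell cohorts over a 3-point
`cell_cv` grid, and scattering correction on 30-cell Mie-contaminated
cohorts. These sizes give stable statistics at interactive runtimes and
are stated here as the package's chosen validation conditions.

## Known limitations

* The Mie correction is non-resonant; strongly scattering samples with
  derivative-shaped band distortions need a resonant RMieS treatment.
* Consensus peak detection assumes the cohort mean exhibits all expected
  bands; a cohort in which a band is absent in most cells fails loudly
  rather than degrading.
* The interaction module evaluates single dose pairs; full dose-matrix
  methods (Chou-Talalay combination indices, Loewe isoboles) are out of
  scope.
* `heterogeneity_index()` describes distance distributions; it performs
  no inferential test between groups.
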