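# irpheno

Single-cell infrared "phenomics" in R: quantify cell-to-cell biochemical
heterogeneity from single-cell FTIR microspectroscopy, and classify
drug-combination effects with the three classical interaction models.

## Who this is for

Spectroscopists and pharmacologists who collect mid-infrared absorbance
spectra of individual cells (synchrotron or benchtop FTIR microscopes,
4,000–650 cm⁻¹) and want a reproducible route from raw spectra to
per-cell features, heterogeneity statistics and treatment comparisons —
plus anyone who needs the companion drug-combination calculations (CDI,
Bliss, HSA, 4PL IC50) without a spreadsheet.

## What it computes

**Spectral pipeline.** Raw spectra are smoothed (9-point moving average),
baseline-corrected (linear automatic correction), optionally
Mie-scattering-corrected (EMSC with a van de Hulst extinction-curve
basis), and differentiated twice (Savitzky–Golay). On the cohort-mean
second derivative, the 14 absorption-band minima are detected — 4 in the
fatty-acid region (3,000–2,800, 1,480–1,300 cm⁻¹), 7 in the protein
region (1,800–1,480 cm⁻¹), 3 in the carbohydrate region
(1,300–900 cm⁻¹) — giving each cell a 14-dimensional spectral absorption
vector. Cell-to-cell similarity is then the Euclidean distance

D_Eu(p, q) = √Σᵢ (pᵢ − qᵢ)²

computed over all k² cell pairs (heatmap) and summarised over the
k(k−1)/2 unique pairs (histogram; mean/median/IQR heterogeneity index),
on the full 14-dimensional vectors or the 4/7/3 subregional vectors.
Mean-centred PCA of the second-derivative spectra, scoped to the full
spectrum or a single region, shows which biochemical component drives
group separation.

**Drug combinations.** For a dose pair with single-agent responses Pa,
Pb and combined response P(a+b):

* CDI = P(a+b)/(Pa·Pb) — <1 synergy, =1 additivity, >1 antagonism;
* Bliss: expected = 1 − (1−Pa)(1−Pb), synergy iff observed exceeds it;
* HSA: expected = max(Pa, Pb), same excess convention;

with a 2-of-3 consensus report, viability↔inhibition conversion,
µg/mL↔µM dose conversion, and four-parameter logistic IC50 fitting.

A seeded synthetic single-cell generator (`simulate_cohort()`) produces
cohorts with known band amplitudes, group effects, log-normal cell
variability, Mie baselines and noise, so the whole pipeline is testable
against generative truth.

## Worked example

Two 50-cell groups whose carbohydrate bands differ (combination-treated
cells at 60% of control intensity):

```r
library(irpheno)

design <- cohort_design(
  n_cells = c(untreated = 50, combo = 50),
  group_effects = list(combo = c(rep(1.1, 4), rep(1, 7), rep(0.6, 3))),
  cell_cv = 0.15, noise_sd = 0.002, seed = 2024)
cohort <- simulate_cohort(design)

proc  <- preprocess_set(cohort)            # smooth -> baseline -> 2nd deriv
peaks <- detect_peaks(proc$derivative)
peaks
#> <ir_peak_set> 14 peaks
#>   fatty_acid    2960, 2924, 2874, 2850
#>   protein       1740, 1696, 1656, 1626, 1584, 1544, 1512
#>   carbohydrate  1240, 1084, 1050

fm <- build_feature_matrix(proc$absorbance, proc$derivative, peaks)
distance_matrix(fm, "carbohydrate_3")
#> <ir_distance_matrix> 100 x 100 (10000 distances, 4950 unique pairs), scope carbohydrate_3
#> mean unique-pair distance: 0.172

group_silhouette(pca_spectra(proc$derivative, "carbohydrate"))
#> [1] 0.6655653     # groups separate in the carbohydrate region...
group_silhouette(pca_spectra(proc$derivative, "protein"))
#> [1] 0.006196379   # ...but not in the protein region
```

The 14 detected peaks split 4/7/3 across the regions, and the silhouette
contrast (0.67 vs 0.006) localises the treatment effect to the
carbohydrate bands — exactly the generative difference.

A dose pair where the three interaction models disagree (single-agent
inhibition 0.605 each, combined 0.88):

```r
m <- combination_measurement(0.605, 0.605, 0.88, "inhibition")
rep <- interaction_report(m)
rep$additivity_cdi
#> <additivity_cdi> statistic = 2.404 (expected 1) -> antagonism
rep$statistical_independence
#> <statistical_independence> statistic = 0.03603 (expected 0.844) -> synergy
rep$pharmacological_independence
#> <pharmacological_independence> statistic = 0.275 (expected 0.605) -> synergy
rep$consensus
#> [1] "synergy"
```

The CDI ratio (2.40) calls antagonism while both independence models call
synergy — the combined inhibition 0.88 exceeds the Bliss expectation 0.84
and both single agents — so the majority consensus is synergy.

`run_pipeline(pipeline_config(out_dir = "run1"))` executes the whole
chain (simulate/load → preprocess → peaks → features → distances → PCA)
and writes every artifact plus a checksummed manifest; reruns with the
same config are bitwise identical.

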