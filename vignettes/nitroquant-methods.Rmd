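---
title: "Internal-standard MALDI-TOF quantification of nitroaromatic explosives: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-standard MALDI-TOF quantification of nitroaromatic explosives: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitroquant)
```

## The quantification problem

MALDI-TOF MS of soil extracts on a 1,5-diaminonaphthalene (DAN) matrix
produces, within the 120–300 Da window, radical anions of the
nitroaromatic contaminants and — through in-source reduction of one nitro
group to a nitroso group — fragment ions 16 Da below each parent. The
raw ion yield of a MALDI spot is notoriously variable (crystallization,
laser coupling), so absolute intensities are useless for quantification.
Two devices make it work:

1. **Internal-standard normalization.** 5-chloro-2,4-dinitrotoluene
   (CDNT), a structural analogue absent from the environment, is spiked
   into every deposition at 25 ng/µL. Every target channel is read as the
   ratio to the CDNT radical-anion abundance at m/z 216. Because the
   dominant variability multiplies *all* peaks of a spot equally, the
   ratio cancels it.
2. **Interference-corrected calibration.** TNT contributes signal at
   m/z 197/181 — the ADNT channels. Ignoring this inflates ADNT estimates
   whenever TNT dominates, which on contaminated sites it usually does.
   A bivariate classical-least-squares calibration with a TNT term, and a
   sequential inversion (TNT first, then ADNT corrected by the fitted TNT
   contribution), removes the bias.

Positional isomers (2-/4-ADNT, 2,4-/2,6-DNT) yield identical channels;
all results are therefore isomer-group sums.

## The forward model

For channel $j$ belonging to analyte group $g(j)$, the IS-normalized
abundance is modeled as

$$A_j = a_j + r_j\,c_{g(j)} + \sum_k \kappa_{jk}\,c_k,$$

linear in each concentration, with $\kappa$ nonzero by default only for
TNT into m/z 197 and 181 (the only cross-interference the method needs to
correct; its default magnitude is 25 % of the ADNT response factors).
The synthetic generator renders this model as Gaussian peaks
($\sigma$ = 0.05 Da) on a uniform 120–300 Da grid with 0.01 Da steps,
adds the CDNT peaks (216 and its fragment at 200 at half height), the DAN
matrix ions at the observed m/z 156/157, and four noise terms:

| term | form | default | what it emulates |
|---|---|---|---|
| spot noise | lognormal multiplier shared by all peaks of a spot | CV 0.08 | crystallization / laser variability; *the reason IS normalization works* |
| peak noise | independent lognormal per peak | CV 0.03 | residual per-ion variability that normalization cannot cancel |
| baseline | half-normal additive | sd 1e-4 of the IS peak height | detector/chemical background |
| mass jitter | one normal shift per spectrum | sd 0.1 Da | calibration drift; exercises the alignment step |

Concentration units are ng/µL of deposited solution throughout; response
factors are "normalized abundance per ng/µL". Response-factor defaults
(0.030/0.020 for TNT 227/211 down to 0.003 for NT 137) encode the
observed ionization ranking, NT poorest. TNB, DNB and NT are quantified
on their molecular-anion channel only: TNB's oxygen-loss fragment would
fall on m/z 197 and collide with the ADNT radical anion, and the weak
ionizers show no usable fragment. The generator is first-class, tested
code: every study design (calibration series, TNT × ADNT interference
grid, soil study) derives all its randomness from one master seed through
a documented deterministic split, so any figure can be regenerated
exactly.

What the generator does **not** emulate: ionization saturation at high
load, matrix-suppression chemistry, nonlinear mass-axis warp, isotope
envelopes (a simulator option left off by default), shot-level raster
statistics (a spot is one averaged spectrum), and real soil-matrix
effects on fragmentation yield. Passing tests therefore demonstrate the
*statistical* machinery — normalization, calibration, inversion,
validation — under the stated noise structure, not instrument-specific
detection limits. Published instrument values (e.g. a TNT LOD of 0.5
ng/µL) are treated as documentation, not as test targets.

## Preprocessing choices

Processing order is fixed: **recalibrate → TIC-normalize → extract**.
TIC normalization is scale-only and alignment is intensity-preserving up
to interpolation, so the order of the first two steps is immaterial (a
test asserts this); extraction must come last.

* **Mass recalibration** matches reference ions always present in an
  acquisition — the IS at 216 and the DAN ions at 156/157 — within a
  ±0.5 Da window (apexes refined by three-point parabola). One match
  fits a shift, two or more a shift + stretch by least squares; the
  intensities are then resampled onto the canonical grid by linear
  interpolation. No match is an error, not a silent pass-through.
* **"Ion abundance"** is the maximum intensity within ±0.5 Da of the
  channel — robust at fixed peak width; the unit-resolution channels are
  ≥ 14 Da apart except 211/213, still separable at this tolerance. Peak
  *area* would differ only by a constant factor at fixed width and
  cancels in the IS ratio.
* **The IS contract:** if the 216 abundance does not exceed 5× the
  robust baseline noise (MAD), extraction errors out — without the IS
  there is no quantification. Blanks still contain the IS (it is added
  with the matrix), which is what makes blank calibration points usable.
* Baseline subtraction is omitted: the simulated baseline is orders of
  magnitude below the peaks. For real spectra with chemical background
  this is a documented limitation.
* Normalization happens per spot, then spots are averaged — the IS
  corrects each deposition individually, so averaging ratios (not
  averaging then normalizing) is the consistent order.

## Calibration and inversion

* **Simple model:** unweighted OLS of mean normalized abundance on
  concentration ("classical" least squares; a 1/x weighting option
  exists but is off by default). Blanks are included. Reported range is
  [lowest nonzero level, highest level]; default levels 0, 1, 5, 10, 25,
  50, 75 ng/µL (endpoints fixed by the method's working range; interior
  levels are a design choice). A flat response degrades to a flagged
  degenerate model (slope 0, R² 0, LOD undefined) rather than an error.
* **Interference model:** $A = a + b_{own} c_{ADNT} + b_{TNT} c_{TNT}$,
  fitted on a full 4 × 4 cross of TNT × ADNT levels (0, 5, 25, 75). The
  full cross makes the design well-conditioned; rank deficiency (e.g.
  proportional concentrations) is rejected by name.
* **LOD:** 3.3 σ<sub>resid</sub>/slope (ICH-style) — the published
  instrument LODs are empirical and not reproducible from synthetic
  data, so a formula had to be chosen; this is the standard one.
* **Sequential inversion:** TNT from 227/211 (simple), averaged; each
  ADNT channel corrected by $b_{TNT}\hat c_{TNT}$ then inverted;
  channels averaged unweighted. When $\hat c_{TNT}$ is below its LOD the
  point estimate is still propagated — substituting zero would
  systematically inflate ADNT. Negative estimates are flagged, never
  clamped, so replicate means stay unbiased. No outlier rejection across
  channels is attempted.

## Validation statistics

* **PCA** of the spectra × channels abundance matrix: column-centered,
  unscaled (all abundances already share the normalized scale; scaling
  is an option), with a deterministic sign convention (largest loading
  positive). The specificity property is tested with replicate spectra
  of single-analyte samples at one representative concentration
  (25 ng/µL, default noise): there the within-group scatter is purely
  noise-driven and the analyte centroids must separate by > 3× the mean
  within-group distance — the score-space analogue of "different
  analytes occupy different corners". Mixing concentration series into
  one group would conflate the concentration trajectory with group
  scatter and test nothing about specificity.
* **Two-way ANOVA** (balanced, with interaction, classical sums of
  squares): response = normalized abundance, factors = target channel ×
  concentration level, replicates = spots. The original report does not
  state its factor layout; this one is the natural reading of
  "analyte specificity" (channel effect) and "concentration dependency"
  (level effect), and the module accepts any labeled balanced layout.
  Unbalanced designs are rejected (Type-II/III decompositions are out of
  scope).

Both routines delegate the numerics to `stats::prcomp` and `stats::aov`;
the test suite verifies them against independent brute-force oracles
(eigendecomposition of the covariance; hand-computed sums of squares).

## Numerical and reproducibility choices

* Nominal masses use integer mass numbers (C 12, H 1, N 14, O 16,
  Cl 35); monoisotopic masses use lightest-isotope exact masses with
  ¹²C ≡ 12. The electron mass (0.55 mDa) is ignored for anion m/z —
  negligible at 0.5 Da extraction tolerance.
* DAN's ions are stored as observed literals 156/157 (they arise from
  reduction chemistry, not from the intact C₁₀H₁₀N₂, nominal 158).
* Seeds: every simulation entry point takes one master seed; sub-seeds
  are derived as `(48271·seed + 7919·index) mod (2³¹ − 19) + 1`. Every
  artifact records its seed and a config hash.
* Problem sizes used by the test suite and the acceptance script — a
  7-level triplicate calibration series, a 4×4 triplicate interference
  grid, 20–50 seeded quantification trials, a 1000-render noise-model
  check — were chosen as the smallest designs at which the Monte-Carlo
  properties under test are stable.

## Known limitations

* The pipeline assumes linear response over the calibration range; no
  saturation model. Real spectra of gram-per-kilogram contamination need
  dilution first.
* Identification is mass-only; co-eluting isobars outside the panel
  would be misread. The registry is extensible but the interference
  correction is implemented for the one documented interference
  (TNT → ADNT).
* Replicate SD is the only uncertainty reported; calibration-band
  prediction intervals are not propagated.
* mzML support covers one spectrum per file (profile mode) via `mzR`;
  vendor raw formats are out of scope.
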