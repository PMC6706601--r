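# nitroquant

Quantification of nitroaromatic explosives in soil extracts from
negative-mode MALDI-TOF mass spectra.

Former production and testing sites leave soils contaminated with
2,4,6-trinitrotoluene (TNT) and its degradation products —
aminodinitrotoluenes (ADNT), dinitrotoluenes (DNT), trinitrobenzene (TNB),
dinitrobenzene (DNB), nitrotoluene (NT). Screening such sites calls for a
fast, cheap, high-throughput assay; MALDI-TOF MS with a
1,5-diaminonaphthalene (DAN) matrix delivers spectra in seconds, but
quantification requires an internal-standard calibration and a correction
for spectral interference between TNT and the ADNT channels. `nitroquant`
implements that workflow end to end for analytical chemists evaluating or
deploying the approach: a seeded synthetic-spectrum generator with known
ground truth, preprocessing, calibration, interference-corrected
quantification, soil-unit reporting, and statistical validation.

## The model

Nitroaromatics ionize in negative mode as radical anions [M]<sup>•−</sup>
(TNT m/z 227, ADNT 197, DNT 182, TNB 213, DNB 168, NT 137) and, through
in-source reduction of a nitro to a nitroso group, as oxygen-loss
fragments [M−O]<sup>•−</sup> 16 Da below the parent (TNT 211, ADNT 181,
DNT 166). The internal standard 5-chloro-2,4-dinitrotoluene (CDNT, spiked
at 25 ng/µL) gives a constant reference at m/z 216; each target channel's
abundance is expressed as the ratio A = I(channel)/I(216), which cancels
spot-to-spot variability.

Calibration is classical least squares. For most channels the simple
model suffices:

    A_j = a_j + b_j · c

For the ADNT channels, TNT leaks signal into m/z 197/181, so a bivariate
(classical least squares) model is fitted on a TNT × ADNT design grid:

    A_j = a_j + b_j · c_ADNT + k_j · c_TNT

Quantification inverts these sequentially: TNT is estimated first from its
own channels, its fitted contribution is subtracted from the ADNT
channels, and estimates from radical-anion and fragment channels are
averaged. Extract concentrations (ng/µL) convert to soil concentrations
by mg/kg = c · V<sub>extract</sub> (mL) · dilution / m<sub>soil</sub> (g);
with the standard 2 g / 4 mL extraction, 0.5 ng/µL in the extract equals
1 mg/kg in soil. Limits of detection use LOD = 3.3 σ<sub>resid</sub> /
slope.

## Worked example

Simulate calibration data, fit the models, and quantify a synthetic soil
extract (40 mg/kg TNT, 10 mg/kg ADNT) with the interference correction:

```r
library(nitroquant)

model <- signal_model()                       # default noise: spot CV 0.08, peak CV 0.03
cal   <- simulate_calibration_series(model = model, n_spots = 3, seed = 1)
ab    <- spectra_to_abundance(cal$spectra, quant_channels(model))
models <- fit_calibration_set(ab, cal$design)

grid   <- simulate_interference_grid(model = model, n_spots = 3, seed = 2)
gab    <- spectra_to_abundance(grid$spectra, quant_channels(model))
models <- fit_interference_set(models, gab, grid$design)

models[["197"]]
#> <calibration_model interference> m/z 197 (ADNT_197)
#>   A = -0.012585 + 0.032552 * c + 0.0082454 * c_TNT
#>   resid SD 0.0334 | R2 0.9991 | range 5-75 ng/uL | LOD 3.38 | n 16

soil <- simulate_soil_study(list(site_1 = c(TNT = 40, ADNT = 10)),
                            model = model, seed = 3)
q <- quantify_sample(soil$spectra, models, quant_channels(model),
                     method = "sequential",
                     provenance = list(soil_mass_g = 2, extract_volume_ml = 4,
                                       dilution_factor = 1),
                     reference = c(TNT = 40, ADNT = 10),
                     reference_units = "soil")
q[q$group %in% c("TNT", "ADNT"), ]
#>   group n  mean    sd rsd_pct deviation_pct below_lod negative soil_mg_per_kg
#> 1  ADNT 3  5.26 0.166    3.15          5.25     FALSE    FALSE           10.5
#> 6   TNT 3 20.51 0.387    1.89          2.55     FALSE    FALSE           41.0
```

The `mean` column is the extract concentration (ng/µL; 40 mg/kg soil is
20 ng/µL extract under the 2 g / 4 mL extraction), `soil_mg_per_kg` the
back-converted soil concentration, `rsd_pct` the triplicate precision and
`deviation_pct` the deviation from the supplied reference. Fitting the
interference model matters: simple inversion of the same sample's ADNT
channels would be biased upward by the TNT contribution (here +8.2e-3 per
ng/µL TNT in the 197 channel).

A command-line interface wrapping the same functions is in
`exec/nitroquant` (subcommands `simulate`, `calibrate`, `quantify`,
`validate`, `report`).

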