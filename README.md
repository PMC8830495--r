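# amidesom

Protein secondary-structure estimation from Amide I infrared absorbance
spectra using a Kohonen self-organising map (SOM) trained on a reference
set of proteins with known structure.

The Amide I band (1,600–1,700 cm⁻¹, backbone C=O stretching) encodes
secondary structure — helix absorbs near 1,654 cm⁻¹, β-sheet near 1,631
and 1,678 cm⁻¹ — but the band is broad and featureless, so quantification
from a single spectrum is ill-posed. `amidesom` instead learns the
spectrum→structure mapping from a reference library: a square SOM
organises the reference spectra by similarity, each map node carries a
spectrum and a structure vector (helix, sheet, other on the unit simplex),
and an unknown spectrum is estimated from its *k* best-matching nodes by
inverse-distance averaging:

    f̂ = Σⱼ (1/dⱼ) fⱼ / Σⱼ (1/dⱼ),   dⱼ = ‖x − wⱼ‖₂ over the k BMUs

with the reconstruction quality reported as
`NRMSD = sqrt(Σ(obs − pred)² / Σ obs²)`.

The package is aimed at spectroscopists validating IR structure-fitting
workflows (e.g. biopharmaceutical batch comparison) and includes the full
supporting machinery:

* leave-one-out validation (`loov`, `deviation_table`),
* ATR ↔ transmission conversion via the evanescent-wave penetration depth
  (`penetration_depth`, `atr_to_transmission`, `transmission_to_atr`),
* Fourier self-deconvolution with re-zero/re-normalise (`fsd`,
  `rezero_renormalize`),
* two Gaussian band-fitting estimators for comparison
  (`fit_direct_method`, `fit_second_derivative_method`),
* spectral preprocessing (baseline, Amide I normalisation, scaled water
  subtraction judged by flatness near 2,100 cm⁻¹, vapour diagnostics),
* text-format I/O (columnar training/test files, two-column spectra) and a
  synthetic Amide I generator so everything is testable without
  instrument data.

## Worked example

Train a map on a 50-member synthetic reference set, predict an unknown,
and validate by leave-one-out:

```r
library(amidesom)

refset <- make_reference_set(50, synthetic_model(noise_sd = 0.005), seed = 1)
map <- som_train(refset, som_config(map_dim = 40, n_steps = 50000, seed = 1))
map
#> <som_map 40x40: 51-point grid, 50 reference placements>

unknown <- synth_spectrum(structure_fractions(0.35, 0.25), seed = 99,
                          label = "unknown")
pred <- predict(map, unknown)
pred
#> <som_prediction 'unknown': helix 0.380 sheet 0.233 other 0.387, NRMSD 0.0419>
pred$bmus
#>   node row col  distance grid_distance
#> 1 1056  27  16 0.1358023      0.000000
#> 2 1016  26  16 0.1385374      1.000000
#> 3  977  25  17 0.1482259      2.236068
#> 4 1096  28  16 0.1502805      1.000000
#> 5 1017  26  17 0.1528951      1.414214
```

The true generating fractions were (0.35, 0.25, 0.40); the map estimates
(0.38, 0.23, 0.39). The five BMUs cluster tightly on the map
(`grid_distance` ≤ 2.2), and the reconstruction NRMSD is 0.042 — both
signs of a trustworthy fit; scattered BMUs or a large NRMSD flag
predictions to distrust.

```r
res <- loov(refset, som_config(map_dim = 40, n_steps = 5000, seed = 1))
res
#> <loov_result: 50 members (50 in summary)>
#>   mean |helix deviation| 0.0623
#>   mean |sheet deviation| 0.0549
#>   mean NRMSD 0.0709
```

So on this synthetic set the method recovers helix and sheet content to a
mean absolute error of ~6% — the few-percent scale expected of
reference-set IR fitting. `deviation_table(res)` returns the per-member
deviations ordered by decreasing helix content with the conventional
`5 × NRMSD` overlay column.

A command-line wrapper over the same functions ships in
`inst/cli/amidesom` (subcommands `synth`, `train`, `predict`, `loov`,
`convert`, `bandfit`, `fsd`; every run writes a JSON manifest of its
resolved options for reproducibility).

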