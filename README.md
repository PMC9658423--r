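# anthostab

Anthocyanins are the pH-sensitive flavylium pigments that color most red and
purple plant extracts. When ferric iron is present it chelates the B-ring
*ortho*-dihydroxyl groups and co-pigments the chromophore, shifting the hue
(bathochromic shift of the visible absorption maximum) and its intensity
(hyperchromic shift). How strongly an extract responds depends on its
acylation and glycosylation pattern, so the magnitude of these shifts is a
practical color-stability score for food colorant quality control.

`anthostab` implements that scoring and the chemometric pipeline that
predicts it from surface-enhanced Raman (SERS) spectra:

* **Stability indexes.** From paired UV-vis spectra (control vs.
  iron-treated, at pH 3 and pH 6), per replicate:
  index 1/2 = Δλ_max at pH 3/6 (nm), index 3/4 = ΔA_max (AU), and the
  pooled scores index 5 = √((I₁² + I₂²)/2), index 6 = √((I₃² + I₄²)/2),
  aggregated as mean ± SD over replicates. The pH-differential pigment
  quantitation C = A·MW·DF·1000 / (ε·l) (cyanidin-3-glucoside equivalents,
  MW = 449.2 g/mol, ε = 26 900 L·mol⁻¹·cm⁻¹) is included.
* **Chemometrics.** Savitzky–Golay second derivative → SNV (statistics over
  400–1800 cm⁻¹) → region selection (370–918, 1099–1692 cm⁻¹), then PCA
  for class structure and NIPALS PLS1 per index, with leave-one-out
  cross-validation (PRESS/RMSECV, parsimonious factor choice), a
  class-stratified 75/25 split (RMSEP, R²), and loading-spectrum band
  diagnostics against reference anthocyanin SERS assignments.
* **Synthetic study generator.** Latent per-extract stability values drive
  band positions/intensities of Lorentzian SERS signatures (inter-ring band
  at 1340 − 0.25·s₁ cm⁻¹, an acyl marker at ~1300 cm⁻¹ decaying with s₁)
  plus fluorescence baselines, log-normal scatter and noise — so the whole
  pipeline is testable end to end against known ground truth.

## Worked example

```r
library(anthostab)

study <- simulate_study(sim_config(seed = 1))        # 9 extracts x 20 SERS replicates
compute_indexes(study$uvvis[["sample03"]], sample_id = "sample03")
#> <stability_indexes: sample03, 2 replicate(s)>
#>   index1:   35.000 +/- 0.000 nm
#>   index2:   37.500 +/- 3.536 nm
#>   index3:   -0.178 +/- 0.005 AU
#>   index4:    0.182 +/- 0.001 AU
#>   index5:   36.292 +/- 1.827 nm
#>   index6:    0.180 +/- 0.002 AU

pp <- preprocess_chain(study$sers)                   # 2nd derivative, SNV, regions
pp$y <- study$truth$s1[match(pp$labels, study$truth$sample_id)]
sp <- split_train_validation(pp, seed = 1)           # 135 / 45
cv <- loocv(sp$train, max_factors = 10)
#> <pls_validation: LOOCV over 135 spectra, 10 candidate factor(s)>
#>   chosen factors: 10 (RMSECV 1.161, cross-validated R2 0.9947)
fit <- pls1(sp$train, n_factors = cv$chosen_factors)
evaluate(fit, sp$validation)                         # RMSEP 1.00 nm, R2 0.996
head(loading_diagnostics(fit), 2)
#>                  factor rank position    loading                          sign matched_center                                  assignment
#> 1 0 (regression vector)    1     1325 -0.4459428 negative (positive influence)           1330 inter-ring stretching (B ring, C-H bending)
#> 2 0 (regression vector)    2     1340  0.4186362 positive (negative influence)           1330 inter-ring stretching (B ring, C-H bending)
```

The index table says extract `sample03` red-shifts by ~35 nm under iron —
an unstable colorant. The PLS1 model recovers the latent bathochromic shift
from the SERS matrix with RMSEP ≈ 1 nm, and the band diagnostics identify
the inter-ring stretching region near 1330 cm⁻¹ as the dominant predictor,
with the derivative-scale sign annotation (negative loading excursion =
positive influence of the original band intensity).

The same flow is scriptable: `run_pipeline(pipeline_config(...))` writes
indexes, six per-index models, validation metrics, diagnostics and a
reproducibility manifest into a run directory, and `inst/scripts/anthostab`
exposes `simulate | indexes | train | predict | report` subcommands over a
YAML config.

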