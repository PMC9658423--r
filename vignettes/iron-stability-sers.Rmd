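---
title: "Scoring iron-induced anthocyanin color stability and predicting it from SERS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring iron-induced anthocyanin color stability and predicting it from SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthostab)
```

## The measurement model

Anthocyanin extracts respond to ferric iron by co-pigmentation: Fe³⁺
chelates B-ring *ortho*-dihydroxyls, red-shifting the visible absorption
band and changing its intensity. `anthostab` quantifies this per extract
from four UV-vis spectra per replicate — control and iron-treated arms at
pH 3 and pH 6 — as six stabilization indexes:

* index 1, 2: bathochromic shift Δλ_max (nm) at pH 3 and pH 6, signed
  (negative = hypsochromic);
* index 3, 4: hyperchromic shift ΔA (AU) at pH 3 and pH 6, signed;
* index 5 = √((I₁² + I₂²)/2), index 6 = √((I₃² + I₄²)/2): root-mean-square
  pooling across the two pH arms.

Large absolute indexes mean large iron-induced color change, i.e. *low*
stability. Acylated anthocyanins (red radish, purple sweet potato) resist
chelation and score low; non-acylated ones (elderberry, black currant,
acai) score high.

Two conventions deserve explanation because the definitions admit
alternatives:

**Replicate-level RMS, then mean.** Indexes 1–6 are computed per replicate
and then aggregated as mean ± sample SD (n−1). The alternative — RMS of the
mean shifts — differs whenever replicates disagree, and cannot produce an
SD for indexes 5/6 at all. The per-replicate path is the package default;
`rms_index()` applied to mean shifts remains available for desk arithmetic
on published tables.

**Hyperchromic shift as difference of window maxima.** `hyperchromic_shift()`
defaults to max(treated) − max(control) over the analysis window. The
alternative reading — treated absorbance *at the control's* λ_max — is
implemented behind `mode = "at_control_peak"`. The two coincide exactly
when the band does not shift and differ by O(Δλ²/σ²) otherwise; the maxima
difference was chosen because it is well defined even when the treated band
moves far from the control peak.

λ_max is reported on the sampled grid (5 nm steps by default) with ties
broken toward the shorter wavelength; a three-point parabolic sub-grid
refinement exists behind `refine = TRUE` but is off by default so that
shift estimates inherit the acquisition grid's resolution honestly. All
axis windows are closed intervals.

The pH-differential quantitation `ph_differential_concentration()`
implements C = A·MW·DF·1000/(ε·l) with A = (A520−A700)\_{pH 1.0} −
(A520−A700)\_{pH 4.5} and cyanidin-3-glucoside constants (MW 449.2 g/mol,
ε 26 900 L·mol⁻¹·cm⁻¹, l = 1 cm). A negative differential absorbance is
returned as a negative concentration with a warning rather than clamped:
it flags an assay problem the caller should see.

## The SERS → index regression

The predictive claim is that an extract's SERS fingerprint carries enough
structural information (acylation, glycosylation, B-ring substitution) to
predict its iron stability without running the iron assay. The pipeline:

1. **Second derivative** (Savitzky–Golay, window 9 points, polynomial
   order 3, by `signal::sgolayfilt`). The derivative separates overlapping
   bands and annihilates smooth fluorescence baselines. Edge points use the
   one-sided polynomial fits embedded in the SG projection matrix — no
   reflection padding — so the filter is exact for polynomials up to the
   fit order at *every* point and results are bit-reproducible. The window
   and order are configuration; 9/3 is the common instrument-software
   default and suits bands of ~8–10 cm⁻¹ half-width sampled at 1 cm⁻¹.
2. **SNV** with statistics over 400–1800 cm⁻¹, applied to the whole row.
   Computing mean/SD on a wide reference range and then selecting regions
   afterwards follows the stated order of operations of the original
   workflow; consequently row means over the finally selected features are
   generally nonzero, which is intended and tested.
3. **Region selection**: 370–918 and 1099–1692 cm⁻¹ (closed intervals,
   1143 features on a 1 cm⁻¹ grid). These bracket the skeleton-bending and
   ring-stretching fingerprints while dropping the quiet 919–1098 cm⁻¹
   stretch and the band-free ends.

PLS1 is fitted by NIPALS on mean-centered data, one model per index —
single-response models match the per-index reporting and keep the loading
spectra interpretable. The factor count is chosen by leave-one-out
cross-validation via PRESS with a parsimony tie-break (smallest count
attaining the minimum). Two numerical choices matter:

* **Kernel-form LOOCV.** Each fold's NIPALS sequence is run on the
  (n−1)×(n−1) centered Gram matrix rather than the n×p spectra; the
  predictions are algebraically identical (the test suite checks agreement
  with per-fold refits to 1e-10) and the cost drops by roughly the ratio
  p/n. When the response deflates to zero before the screened maximum
  (noise-free low-rank data), later factor counts inherit the last
  achievable prediction instead of erroring.
* **PRESS near-tie guard.** A factor count whose PRESS is within
  1e-10·SS_tot of the minimum counts as attaining it. On noise-free data
  PRESS beyond the true latent dimension differs from the minimum only by
  rounding noise (~1e-30 vs ~1e-28); without the guard the argmin would be
  decided by that noise. On any realistically noisy data the guard is far
  below PRESS differences and the rule is a pure argmin.

Internal validation uses a class-stratified 75/25 replicate split (15/5 of
20 per extract, 135/45 overall). This mirrors the original design but
shares extracts between train and validation, so its R² reflects
within-class interpolation. `split_train_validation()` therefore also
offers `leave_sample_out`, which holds out whole extracts; its validation
R² is lower in the median — the package documents the leakage direction
rather than hiding it. R² is reported both as the squared Pearson
correlation of predicted vs. actual (the convention of the instrument
software this mirrors, and the default) and as the coefficient of
determination, since the two diverge under prediction bias.

`loading_diagnostics()` ranks local extrema of the loading spectra and the
regression vector by magnitude and matches them to reference anthocyanin
band assignments within a tolerance (default 15 cm⁻¹, roughly the observed
inter-extract wavenumber spread of a band). On second-derivative data a
*negative* loading excursion marks a band whose original intensity pushes
the prediction up; the sign is annotated rather than flipped.

## What the synthetic generator emulates

No raw spectra ship with the package, so `simulate_study()` generates a
study with known ground truth: per extract a latent quadruple
(s₁, s₂) ~ bathochromic shifts in [−5, 55] nm with the pH 6 shift biased
above the pH 3 one, and (s₃, s₄) hyperchromic shifts in [−0.25, 0.10] and
[0.10, 0.56] AU — ranges chosen to span the published per-extract index
tables.

* **UV-vis**: a Gaussian flavylium band (520 nm/0.90 AU at pH 3;
  545 nm/0.55 AU at pH 6, widths 35/38 nm) over a mild linear baseline;
  the treated arm shifts center by s and height by Δ. With noise off,
  index recovery is exact to half the 5 nm grid step (the baseline tilt
  displaces the argmax by < 0.02 nm, far below grid rounding).
* **SERS**: a sum of Lorentzians at the recurring anthocyanin band
  positions. Two bands encode the truth, mirroring the qualitative
  structure–stability correlations the method exploits: the inter-ring
  stretching band sits at 1340 − 0.25·s₁ cm⁻¹ (stable extracts at higher
  wavenumber) and a ~1300 cm⁻¹ acyl marker has amplitude 0.5·exp(−s₁/10);
  a weak linear amplitude trend on the 1605 cm⁻¹ band keeps part of the
  encoding linear. Replicates add a random polynomial fluorescence
  baseline (order 3), log-normal multiplicative scatter
  (`exp(N(0, 0.15))` — log-normal precisely so that SNV is the correct
  normalizer by construction) and additive noise (SD 0.01 of the strongest
  band). Within-class variance is not calibrated to any measured data; the
  defaults were chosen once to give visually plausible PCA class
  separation.

What passing tests on this generator do show: the preprocessing removes
the nuisance terms it claims to remove; PRESS finds planted latent
dimensions; the full pipeline recovers a planted stability→spectrum
relation (median cross-validated R² ≥ 0.9 at study scale over 5 seeds);
and the band diagnostics point at the planted bands. What they cannot
show: performance on real extracts, where band shapes, chemical
interferents, and replicate covariance are unmodelled; the hyperchromic
indexes in particular are predicted poorly from the synthetic SERS spectra
(by design only the bathochromic truth is strongly encoded), which matches
the original study's observation that hyperchromic models underperform but
is not evidence about real spectra.

## Degenerate inputs and edge policies

* Flat spectra in a λ_max window return the window's low edge with a
  degenerate-spectrum warning.
* Zero-variance rows are an SNV error naming the row; zero-variance
  responses are a PLS error.
* Requesting more factors than the centered rank names the achievable
  rank. Extrapolating resampling, empty crop windows, mismatched axes and
  malformed CSV cells are errors naming the offending location.
* Ties at equal maxima resolve to the smallest axis value, everywhere.

## Problem sizes

Tests and reference runs use the study-scale design (9 extracts × 20
replicates, 1701-point Raman grid) where the claim concerns that design,
and reduced sizes (e.g. 6 × 5) for multi-seed property sweeps; each test
states its size. The full pipeline run at study scale completes in a few
seconds on one core, dominated by the Savitzky–Golay pass and the
per-index LOOCV.

## Known limitations

* No pH-dependent speciation chemistry: flavylium/quinoidal equilibria are
  collapsed into the two fixed band prototypes.
* No physically meaningful SERS enhancement model; amplitudes are
  relative.
* `leave_sample_out` with 9 classes yields high-variance validation
  metrics; treat per-split R² values as noisy.
* PLS2, O-PLS, variable selection beyond loading ranking, and PLS-DA are
  out of scope.
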