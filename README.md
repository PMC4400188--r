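# cardioflux

Quantitative analysis of dynamic hyperpolarized ¹³C-pyruvate cardiac MR
studies, exercisable end to end on synthetic data.

Hyperpolarized [1-¹³C]pyruvate lets one watch, in real time and in vivo,
the ¹³C label flow from pyruvate into lactate, alanine and — via pyruvate
dehydrogenase (PDH) — bicarbonate/CO₂. The package is aimed at MR
spectroscopists and cardiac-metabolism researchers who need the full
analysis chain of such a study in reusable, tested form:

* **Synthetic data generation** — first-order label-flux kinetics
  integrated by RK4 with per-excitation cos θ losses, rendered into noisy
  complex FID series (60 repetitions, TR 1 s, 5° excitation, sweep width
  13 593 Hz, 2048 points by default); CINE segmentation-area tables from an
  analytic contracting-ventricle geometry; factorial cohort tables drawn
  from group-level mean/SD/n specifications.
* **Spectral quantification** — DC-offset correction from the last half of
  the acquired points, then prior-knowledge-constrained time-domain fitting
  (Lorentzian peaks, frequencies bounded ±20 Hz around a shift table,
  shared zero-order phase, non-negative amplitudes) by bounded
  Levenberg–Marquardt with an analytic Jacobian.
* **Kinetics** — per-product rate constants k (s⁻¹) from the measured-input
  model x̂(t) = ∫ k·P(s)·e^(−ρ(t−s)) ds driven by the observed pyruvate
  curve; the bicarbonate rate is the in-vivo PDH-flux proxy, the lactate
  rate the glycolytic proxy. A Monte-Carlo recovery harness measures bias
  and RMSE of the whole simulate→render→quantify→fit chain.
* **[2-¹³C] ratios** — 30-s summed-spectrum acetylcarnitine/citrate/
  glutamate : pyruvate ratios from the detected pyruvate appearance.
* **CINE volumetrics** — EDV/ESV by slice summation, SV = EDV − ESV,
  EF = SV/EDV, CO = SV × HR, CI = CO/BW, LV mass = myocardial area ×
  thickness × 1.05.
* **Cohort statistics** — per-timepoint two-way surgery × diet ANOVA
  (Type II sums of squares), conditional Bonferroni-corrected
  pooled-variance t tests (m = 4), mean ± SD summaries.

## Worked example

```r
library(cardioflux)

acq   <- acquisition_params()            # 60 reps, TR 1 s, 5 deg
truth <- kinetic_truth()                 # k_lac 0.015, PDH 0.008 s^-1
m     <- simulate_kinetics(truth, acq)
fids  <- render_fids(m, c1_shift_table(), acq,
                     noise_sd = peak_snr_noise_sd(truth, acq, 50), seed = 1)
peaks <- quantify_series(fids, peak_priors(c1_shift_table()))
fit   <- fit_kinetics(peaks)
fit
#> Label-flux estimates (measured pyruvate input):
#>       product        k     rho     k_se   rho_se          rss converged
#> 1     lactate 0.014940 0.04342 0.000174 0.000724 0.0001963229      TRUE
#> 2     alanine 0.007803 0.04193 0.000154 0.001210 0.0001607101      TRUE
#> 3 bicarbonate 0.007229 0.04453 0.000157 0.001370 0.0001564867      TRUE
#>   boundary n_used
#> 1    FALSE     58
#> 2    FALSE     58
#> 3    FALSE     58
```

The recovered rates sit within a few standard errors of the ground truth
(lactate 0.015, alanine 0.008, bicarbonate 0.9 × 0.008 = 0.0072 s⁻¹), and
the fitted decay ≈ 0.043 s⁻¹ equals the simulated relaxation (0.04)
plus the RF sampling loss (−ln cos 5° ≈ 0.0038 s⁻¹ at TR 1 s).

Volumetrics from printed group means:

```r
fi <- functional_indices(edv_ul = 550, esv_ul = 120, hr_bpm = 350)
str(fi)
#> List of 3
#>  $ sv_ul    : num 430        # stroke volume, uL
#>  $ ef       : num 0.782      # ejection fraction -> 78%
#>  $ co_ml_min: num 150        # cardiac output 150.5 -> 150 mL/min
```

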