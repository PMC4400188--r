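---
title: "Models and methods in cardioflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cardioflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioflux)
```

cardioflux implements the quantitative chain of an in-vivo hyperpolarized
¹³C-pyruvate cardiac study: dynamic MR spectra are simulated or read in,
metabolite peaks are quantified per repetition, label-flux rate constants
are estimated from the resulting time courses, CINE segmentation areas are
turned into volumetric function indices, and group effects are tested with
the per-timepoint factorial ANOVA customary in such cohorts. This vignette
explains each model, the tunable parameters, and the design choices made
where the problem was genuinely open.

## The kinetic model

After an intravenous bolus of hyperpolarized [1-¹³C]pyruvate, the ¹³C label
appears in lactate (via LDH), alanine (via ALT) and bicarbonate/CO₂ (via
pyruvate dehydrogenase, PDH). The simulator integrates the unidirectional
first-order system

$$\frac{dM_p}{dt} = u(t) - \Big(\rho_p + \sum_x k_{px}\Big) M_p, \qquad
\frac{dM_x}{dt} = k_{px} M_p - \rho_x M_x,$$

where $u(t)$ is the injection input, $k_{px}$ (s⁻¹) is the label flux into
product $x$, and the effective decays $\rho$ lump longitudinal relaxation
and any back-flux. Conversion outflux is included in the pyruvate equation
so that with all decays and the flip angle at zero the total magnetization
is conserved — a property the test suite checks to 1e-9. Each excitation
multiplies every pool by $\cos\theta$ and the recorded signal is
proportional to $M\sin\theta$; integration is fixed-step RK4 with 10
sub-steps per TR, which matches the constant-input closed form
$(kP_0/\rho)(1 - e^{-\rho t})$ to better than 1e-6.

Default ground-truth values are chosen once to be representative of rodent
heart at 7 T: $k_{p\to lac} = 0.015$, $k_{p\to ala} = 0.008$ and a PDH rate
of $0.008$ s⁻¹ (split 90/10 between bicarbonate and CO₂ via the pH
equilibrium fraction), effective product decay $1/25$ s⁻¹, pyruvate
effective decay $0.05$ s⁻¹, and a 10-s trapezoidal injection starting at
the first excitation. Published in-vivo rates and apparent decay times are
of exactly these magnitudes; none of these defaults is revisited by any
test.

The **estimator** deliberately differs from the simulator: rather than
modelling the injection, it conditions on the *measured* pyruvate curve and
fits, per product,

$$\hat x(t_n) = \int_0^{t_n} k_{px}\, P(s)\, e^{-\rho_x (t_n - s)}\, ds,$$

with $P$ linearly interpolated between repetitions and the integral
evaluated by an exact-decay trapezoidal recursion on a grid 10× finer than
TR. This is the standard measured-input formulation for hyperpolarized
kinetics: it makes the estimates independent of the injection shape and
invariant to global amplitude rescaling, both verified as properties in the
suite. The per-excitation RF loss ($-\ln\cos\theta/TR \approx 0.0038$ s⁻¹
at 5°, TR 1 s) is absorbed into $\rho_x$, which is bounded to
$[0.01, 1]$ s⁻¹ with start $1/30$ s⁻¹ — the loss is not separately
identifiable at these settings, and the noiseless round-trip indeed
recovers $\rho_x = 0.04 + 0.0038$. The fit window runs from pyruvate
appearance (first repetition reaching 5 % of the pyruvate maximum — a
shift-invariant rule) to the last usable repetition; repetitions whose
spectral fit failed are excluded rather than interpolated, to avoid
fabricating data.

## Spectral quantification

Peak areas are obtained by time-domain nonlinear least squares on the
free induction decay, in the tradition of prior-knowledge-constrained
(AMARES-style) fitting:

* Lorentzian lineshape only; linewidths bounded in [2, 200] Hz, start 20 Hz.
* Frequencies bounded within ±20 Hz of a configurable shift table.
* One zero-order phase shared across peaks; amplitudes non-negative.
* Bounded Levenberg–Marquardt with an analytic Jacobian; amplitudes start
  from magnitude-spectrum bin heights at the prior frequencies.

The shift table defaults (lactate +1000 Hz, alanine +570 Hz, pyruvate
hydrate +630 Hz, bicarbonate −1320 Hz, CO₂ −6130 Hz relative to pyruvate)
are editable placeholders: all internal checks only require that simulator
and fitter agree on them, and a study against real data would substitute
its own calibrated table.

Before fitting, each FID is DC-offset corrected by subtracting the complex
mean of its last half. One numerical subtlety is worth recording: for a
resonance sitting exactly at 0 Hz whose linewidth leaves a non-negligible
tail at the end of the acquisition window (e.g. 20 Hz over a 151 ms
window), the tail mean is of order 1e-3 of the amplitude, and the DC rule
then biases that amplitude at the same order. This is a property of the
correction itself, not of the optimizer; oracle-precision checks in the
suite therefore use linewidths of 50–60 Hz (plausible in vivo at 7 T),
for which the tail has fully decayed and the rule is exact to better than
1e-6.

Two optimizer tolerances are used. The default is tight (`ftol` 1e-13) so
that noiseless oracle comparisons are limited by the model, not the
stopping rule. Monte-Carlo studies on noisy data use `ftol` 1e-6 /
`ptol` 1e-5: parameter changes at that level are several orders of
magnitude below the noise-induced uncertainty, and the looser rule roughly
halves the cost of a fit without measurably moving the estimates.

Uncertainties are local-curvature (Cramér–Rao-style) standard errors from
the Jacobian at the solution. Fits that do not converge are flagged and
their repetitions recorded as missing, never silently retained.

## [2-¹³C]pyruvate ratio analysis

Label from carbon-2 reports on TCA-cycle entry, but the downstream signals
(acetylcarnitine, citrate, glutamate) are weak. The analysis therefore
sums the complex FIDs over the 30 s following pyruvate appearance, fits
the summed FID once, and reports each metabolite amplitude normalized to
pyruvate. Appearance is declared when a quick matched-filter pyruvate
amplitude exceeds 5× the standard deviation of that estimator, with the
noise level measured on the signal-free first repetition; in a noiseless
simulation the threshold degenerates gracefully to "first non-zero
repetition". Because summation is linear, a constant metabolite:pyruvate
amplitude ratio passes through the whole procedure unchanged, which the
suite verifies to 1e-6.

## CINE volumetrics

Volumes use simple Simpson-style slice summation — areas × slice thickness,
summed over contiguous slices, 1 mm³ = 1 µL — with ED/ES selected as the
frames of largest/smallest cavity volume (ties to the earliest frame).
Then SV = EDV − ESV, EF = SV/EDV, CO = SV × HR, CI = CO/body weight, and
LV mass = myocardial area × thickness × 1.05 mg/mm³, evaluated at the ED
frame by default (the frame is configurable; the choice matters little for
an incompressible wall). Frames and slices are indexed 1-based throughout,
following the host language's convention. Report output rounds the way
such studies print their tables — volumes to 10 µL, EF to integer percent,
CO to 10 mL/min — but stored values always keep full precision.

The CINE generator models the cavity as a truncated-ellipsoid stack of
elliptical cross sections contracting smoothly over the cycle, wrapped in
an incompressible wall (constant myocardial cross-section per slice). Its
default geometry (mid-ventricular cavity radius 4.3 mm, wall 1.8 mm, 8
slices of 1.6 mm, EF 0.78) yields EDV ≈ 560 µL, ESV ≈ 125 µL and LV mass
≈ 700 mg — a typical adult-rat left ventricle. Because cavity areas scale
as $1 - c\,g(f)$ with a smooth cyclic $g$, the generator knows its own
EDV/ESV/EF analytically, and the analysis round-trips them to 1e-9.

## Cohort statistics

Each measure is analysed per timepoint with a two-way surgery × diet ANOVA
including interaction. Group sizes in such cohorts are unequal (6–11), so
main effects use Type II sums of squares, which reduce to the classical
decomposition when balanced — the suite asserts equality with an
independent brute-force cell-means oracle to 1e-9, and a 2000-replicate
null simulation keeps each effect's type-I error inside [0.04, 0.06] at
α = 0.05. When (and only when) the interaction is significant at 0.05,
four pooled-variance unpaired t tests are run (surgery within each diet,
diet within each surgery) with Bonferroni correction for m = 4; the
adjusted p is min(1, 4p). Tests are two-sided throughout and no correction
is applied across measures or weeks, matching the per-timepoint framing.

## The synthetic study and what it can show

`run_study()` chains everything: per animal it draws rate constants
(lognormal between-animal CV 10 %), renders a 60-repetition FID series at
peak-pyruvate SNR 50, quantifies and fits it, simulates a CINE table with
2 % segmentation noise, and assembles a per-animal cohort table that the
statistics stage analyses. All randomness derives from one root seed via
named substreams, so identical configurations give byte-identical CSV
outputs.

The default configuration raises the AAB groups' lactate rate constant by
a factor 1.3 at weeks 9 and 14 only, leaving PDH flux untouched — the
qualitative pattern of progressive glycolytic remodelling under pressure
overload. With n = 8 per group and ≈10 % per-animal spread, a 30 % rate
difference is a large effect, so its detection is expected; "no change"
cells are assessed with an equivalence bound (group-mean ratio within
1 ± 0.15, half the induced effect) rather than a non-significant p value,
because a null-hypothesis test on a no-effect cell is a coin flip at the
5 % level by construction and says nothing about effect size.

### What the generator does not emulate

Synthetic data here share the statistical structure, not the physics, of a
real experiment: no B₀/B₁ inhomogeneity, baseline roll, gating jitter,
respiratory motion, chemical-shift displacement, or non-Lorentzian
lineshapes; metabolite shifts are placeholders; injection timing is
idealized; CINE areas come from an analytic geometry rather than
segmentation of images; and cohort values are independent across weeks,
whereas real animals are followed serially. Passing tests therefore
demonstrate correctness of the estimators under their stated model, and
calibration of the statistics — not robustness to every artefact of real
acquisitions.

### Problem sizes used by the validation harness

Monte-Carlo checks use 100 replicates for noisy parameter recovery, 3 for
noiseless, 2000 for the ANOVA null calibration, and a single full
synthetic study (4 groups × 3 weeks × 8 animals) for the pattern-level
check; these sizes give Monte-Carlo standard errors comfortably below the
margins being asserted.

## Known limitations

* The spectral model is strictly Lorentzian with a shared zero-order
  phase; heavily overlapped resonances (e.g. alanine vs pyruvate hydrate
  60 Hz apart at large linewidth) trade amplitude between each other at
  low SNR.
* The kinetic model is unidirectional; exchange back-flux biases $k$
  interpretation (not its fit quality) and is lumped into $\rho_x$.
* CO₂ and bicarbonate are fitted separately by default; the PDH-flux proxy
  is the bicarbonate rate. An optional combined mode sums the two signals
  first for users who prefer the pH-equilibrium-pooled rate.
* The statistics layer deliberately analyses each timepoint independently
  and does not model the repeated-measures structure.

## A worked example

```{r example, eval = FALSE}
acq <- acquisition_params()          # 60 reps, TR 1 s, 5 deg, 13593 Hz
truth <- kinetic_truth()
m <- simulate_kinetics(truth, acq)
fids <- render_fids(m, c1_shift_table(), acq,
                    noise_sd = peak_snr_noise_sd(truth, acq, 50), seed = 1)
peaks <- quantify_series(fids, peak_priors(c1_shift_table()))
fit <- fit_kinetics(peaks)
fit$estimates[, c("product", "k", "k_se")]
```
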