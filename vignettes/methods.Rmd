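---
title: "Stroke-volume estimation from pulse waves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroke-volume estimation from pulse waves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(svpulse)
```

`svpulse` estimates left-ventricular stroke volume (SV, mL) from nine
non-invasive inputs — age, gender, weight, height, brachial systolic and
diastolic pressure, pulse pressure, mean arterial pressure, and
carotid-femoral pulse wave velocity (cfPWV) — using a gradient-boosting
regressor trained entirely on simulated physiology. This vignette documents
the models, the numerical choices, and what the synthetic experiments do and
do not establish.

## The 1-D pulse-wave model

Each arterial segment is a tapered distensible tube. In terms of
cross-sectional area $A(x,t)$, volumetric flow $Q(x,t)$ and pressure
$P(x,t)$, the solver integrates the cross-section-averaged continuity and
momentum equations

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x P = -k_f \pi \frac{\mu}{\rho} \frac{Q}{A},$$

with blood density $\rho = 1050$ kg/m³ and viscosity $\mu = 0.004$ Pa·s.
The friction source is a Poiseuille-type term with a configurable profile
coefficient ($k_f = 22$ by default, a common value for blunt velocity
profiles in large arteries; $k_f = 8$ recovers the parabolic profile). The
wall law ties area to pressure through the local reference area
$A_{\mathrm{ref}}(x)$ (linear diameter taper) and the distensibility $D$
(input units $10^{-3}$/mmHg):

$$A(P) = A_{\mathrm{ref}}\left(1 + D (P - P_{\mathrm{ref}})\right),$$

which makes the local wave speed $c = \sqrt{A / (\rho D A_{\mathrm{ref}})}$,
equal to the Bramwell-Hill speed $\sqrt{1/(\rho D)}$ at the reference
pressure. An exponentially stiffening variant (positive
`nonlinearity` coefficient) is available per segment; the linear default is
exactly testable against the Bramwell-Hill closed form, which is why it was
chosen.

Numerics: an explicit MacCormack predictor-corrector on each segment
(default target spacing 1.5 cm, at least 3 nodes per segment), with the
global time step set by a CFL number (default 0.8) against the fastest wave
speed evaluated at 250 mmHg. Boundary coupling uses Riemann invariants
$W_\pm = u \pm 2c$ (exact for the linear wall law) traced back along the
characteristics with the taper and friction source terms
($\dot W_\pm = -k_f \pi \mu u /(\rho A) \mp u c\, A_{\mathrm{ref}}'/A_{\mathrm{ref}}$);
omitting those source terms sustains a spurious steady-state flux leak of
order 10% on tapered segments, which is why they are part of the boundary
treatment. Junctions enforce static-pressure continuity and exact flow
conservation via a small Newton solve (a total-pressure option is a
possible extension; static continuity is the common 1-D default). Leaves
are closed by three-element Windkessels whose capacitor is updated
implicitly. Cycles repeat until the root pressure waveform changes by less
than $10^{-3}$ (relative, max norm) between cycles, up to 15 cycles;
non-convergence is flagged, never silently accepted. A single-cycle mode
(`max_cycles = 1`) supports transient wave experiments such as the
Bramwell-Hill validation, which is run as a first-passage measurement in a
10 m uniform tube with an impedance-matched terminal — in a short periodic
tube the closed inflow end re-reflects terminal echoes and corrupts
foot detection, so first passage is the meaningful experiment.

The packaged default network is a deliberately reduced nine-segment tree
(aortic root to iliac/femoral, plus carotid and subclavian/brachial
branches). Its geometry, distensibilities and Windkessel values are package
defaults — synthetic, not a published geometry — chosen once so that the
reference state (cardiac output 5.5 L/min, heart rate 75 bpm, ejection time
0.23 s) produces physiological brachial pressures (about 105/76 mmHg) and a
total peripheral resistance of exactly 1.0 mmHg·s/mL. A reduced tree keeps
every measurable the pipeline needs (brachial pressures, carotid and
femoral transit) while remaining fully reproducible from the repository.

## Synthetic cohort generation

Subject profiles are drawn per age-decade and gender stratum (6 × 2 strata)
from independent Gaussians for height, weight, heart rate, aortic
distensibility, total peripheral resistance (TPR) and mean arterial
pressure (MAP); the packaged table reproduces published population values,
with 833 draws per stratum (9,996 profiles) as the study-scale default.
Draws are truncated to the mean ± 3 SD band and strict positivity by
redraw: plain Gaussians occasionally produce negative resistances or
distensibilities that no solver can accept. No inter-parameter correlation
is imposed.

Boundary conditions per subject follow the printed closures: cardiac output
$CO = MAP/TPR$, stroke volume $SV = CO \cdot 60 / HR$, and ejection time
from the Weissler regression $ET = 0.266 + 0.0011(SV - 82) -
0.0009(HR - 73)$ s, clamped to $(0.05, 0.95 \cdot \text{period})$ with a
warning. Geometry scales per subject: all lengths by height/180 cm; all
diameters by the ratio of a linear aortic-diameter model (intercepts by
gender, +0.009 cm/year of age, +0.45 cm per m² of Du Bois body surface
area; package defaults, config-replaceable) to its value for the reference
subject. All segment distensibilities and terminal compliances scale by the
sampled-to-reference aortic distensibility ratio; terminal resistances by a
common factor placing the parallel combination exactly at the sampled TPR.
Within each terminal, the proximal/distal resistance split is re-balanced
so the proximal element tracks the stiffened bed's characteristic impedance
($\propto 1/\sqrt{\text{distensibility scale}}$, capped at half the
terminal total). Without this, terminal wave reflections vary strongly with
the sampled TPR at fixed stiffness, which injects irreducible noise into
the cfPWV-stiffness relationship (TPR is not an estimator input); the
re-split reduced that spurious sensitivity from ~25% to a few percent in
one-factor sweeps while leaving every total resistance untouched.

Features are extracted from the converged cycle: SBP/DBP as the extremes
and MAP as the time average of the left-brachial waveform (the cuff
formula DBP + PP/3 is used only for clinical tables, mirroring what each
setting can actually measure), and cfPWV as the anatomical carotid-femoral
path length along the tree divided by the foot-to-foot delay. No 0.8
correction applies to the synthetic path — that factor compensates surface
tape-measure distances in the clinic (`clinical_path_length()`). The
regression target is the imposed inflow stroke volume, fixed before the
solve and never derived from the waveforms. Non-convergent solves are
dropped with a logged count; a stratum losing more than 20% aborts.

What the generator does not emulate: measurement noise on the simulated
waveforms, inter-parameter physiological correlations (e.g. stiffness-MAP
coupling), disease states, and the venous side of the circulation. Passing
the synthetic parameter-recovery tests therefore shows that the estimator
inverts the simulator's own physics, not that it attains any particular
accuracy on patients.

## The gradient-boosting estimator

Training performs an exhaustive grid search — boosting rounds
{60, 80, 100, 120}, learning rate {0.2, 0.4, 0.6}, maximum depth
{3, 5, 8, 10}, per-split feature subsampling "sqrt" (3 of 9 features), and
minimum samples per leaf {1, 3, 5} — with shuffled 5-fold cross-validation
scored by held-out $R^2$, then refits the winner on the full dataset
(squared-error loss; gender coded M = 0, F = 1; age as the stratum
midpoint, with 75 standing in for the open-ended >70 group). Ties resolve
to the earlier grid point; training is deterministic given the seed
(single-threaded boosting, seeded folds and feature subsampling). The
backing implementation is `xgboost` with `min_child_weight` for the leaf
constraint and `colsample_bynode` for the per-split subsampling. Model
bundles persist the raw booster plus schema, selected hyperparameters, CV
score, seed and a config hash; loading verifies a schema checksum.

At desk scale the package exercises this at 200 profiles per stratum
(2,400 training records) with a fresh 600-record cohort held out, which
keeps the full grid search plus both cohorts within minutes on one CPU
while preserving the stratified structure of the study-scale dataset.

## Clinical-style evaluation

`average_repeats()` averages up to three repeats of SBP/DBP/HR per setting
(a single available repeat is tolerated and flagged), takes the mean of the
two PWV readings, computes cuff MAP as DBP + PP/3 (the conventional cuff
formula; configurable), and derives the reference stroke volume from
thermodilution output as $SV = CO \cdot 1000 / HR_{\mathrm{cath}}$.
`coherence_filter()` excludes a patient when MAP or HR differ by more than
25% between the PWV-assessment and catheterization settings, with the
catheterization value as the denominator (it anchors the reference SV; a
symmetric-mean denominator is available). `sv_agreement()` reports Pearson
r (p from the t distribution on n − 2 df), MAE, RMSE, RMSE normalized by
the reference range, and Bland-Altman bias with limits of agreement
bias ± 1.96 SD. Two sign/scale conventions are fixed deliberately: bias is
mean(predicted − reference), so an underestimating predictor shows a
negative bias; and the Bland-Altman SD is the population SD (denominator
n), matching the descriptive convention of the numerical ecosystem this
pipeline mirrors. The Wilcoxon signed-rank test uses the exact distribution
below n = 25 and the continuity-corrected normal approximation otherwise;
cross-cohort feature comparisons use Welch's unequal-variance t-test.
Degenerate inputs fail loudly: a zero reference range (undefined nRMSE), a
constant pair of series, or fewer than three pairs are errors, and a fully
identical paired comparison reports NaN by convention.

## Synthetic patient tables

`generate_patient_table()` emulates the clinical measurement protocol on
simulated subjects: a ground-truth profile per patient (drawn from the
population sampler and, by default, pushed through the 1-D solver so BP,
cfPWV and SV are mutually consistent), repeat-level cuff noise, systematic
relative shifts between the PWV and catheterization settings, a
configurable fraction of frankly incoherent patients (shifts drawn in
±[0.28, 0.40]), two noisy PWV readings, optional missing repeats, and a
thermodilution reference with additive noise (default SD 5 mL —
thermodilution itself is not noise-free). The default composition mirrors a
catheterization cohort skewed toward the over-70 strata (8 M + 8 F of >70
among 27). Ground truth is written to a separate sidecar so truth-known
tests can compare. In the noiseless limit the averaged table equals the
ground truth exactly and the coherence filter keeps everyone, which pins
the whole pipeline's plumbing.

## Design decisions on open points

- **Measurement sites.** The carotid site sits on the proximal common
  carotid (10% along the branch) and the femoral site at 95% of the
  iliac-femoral segment. This maximizes the carotid-femoral transit
  distance on the reduced tree and keeps the foot estimates away from
  branch-specific reflection patterns; mid-branch placements gave visibly
  noisier stiffness recovery.
- **BSA, not BMI**, enters the aortic-diameter model, consistent with the
  diameter literature the model emulates.
- **Age encoding** uses stratum midpoints because the generator is
  stratum-based; a continuous-age generator would make this a real
  covariate.
- **The hyperparameter grid** is the printed five-dimensional grid above.
  One published account of the tuned optimum quotes a rounds value outside
  its own grid; the grid, not the quoted optimum, is authoritative here.
- **Windkessel/junction invariants** reuse the linear-law form
  $u \pm 2c$ under the stiffening wall law as a local approximation; the
  default wall law is linear, where they are exact.

## Known limitations

The reduced tree produces stiffer, wider-pulse-pressure extremes in the
oldest strata than a full anatomical network would (discrete reflections
are stronger with few segments, and scaling terminal compliances down by
the full distensibility ratio compounds it); Gaussian tails can produce
physiologically degenerate subjects (pulse pressures of hundreds of mmHg)
that remain in the dataset by design. cfPWV on the synthetic tree uses the
exact anatomical path, so its absolute scale is not comparable to
tape-measure clinical values. The estimator's synthetic-cohort accuracy is
an upper bound tied to the simulator's own physics; nothing here validates
clinical accuracy, for which real paired measurements would be required.
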