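---
title: "Calibrated estimation of relative cerebral oxygen metabolism from optical imaging"
author: "rcmro2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated estimation of relative cerebral oxygen metabolism from optical imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmro2)
```

## The model

Steady-state Fick's law states that tissue consumes the oxygen difference
between arterial inflow and venous outflow, CMRO₂ = CBF·(C_a − C_v). With
arterial blood fully saturated and essentially all blood oxygen bound to
hemoglobin, the oxygen extraction fraction equals C_HbR/C_HbT, and ratios
to the pre-stimulus baseline give

rCMRO₂ = rCBF · rOEF, rOEF = (1 + a)/(1 + b),

with a = ΔC_HbR/C_HbR,0 and b = ΔC_HbT/C_HbT,0. The hemoglobin changes come
from modified Beer–Lambert unmixing of two reflectance wavelengths chosen
for complementary sensitivity: 580 nm (total hemoglobin) and 620 nm
(deoxy-hemoglobin). Absorbance changes are natural-log,
ΔA_λ = −ln(I_λ(t)/I_λ,0), and the per-sample 2×2 system is solved
independently at every time point (`unmix`); no temporal regularization is
applied, so ΔC_HbT = ΔC_HbO + ΔC_HbR holds exactly by construction.

Three model families trade measurements against assumptions:

* **Model 1** (`model1`), rCBF·(1 + γ_R a)/(1 + γ_T b): the compartment
  coefficients γ_R, γ_T weight each fractional change by the venous volume
  fraction it represents. γ_R = γ_T = 1 recovers plain Fick scaling.
* **Model 2** (`model2`), (1 + b)^{1/α}·(1 + γ_R a)/(1 + γ_T b): when no
  flow measurement exists, Grubb's power law rCBV = rCBF^α (total
  hemoglobin proxying blood volume) supplies the flow term. Whenever
  rCBF = (1 + b)^{1/α} holds exactly, Model 2 equals Model 1 to machine
  precision — this identity is a test anchor.
* **Model 3** (`model3`), rCBF^{1−α}·(1 + k·x): the calibrated-fMRI-style
  single-wavelength form. x is the 620 nm absorbance change (using
  rC_HbR ≈ 1 + ΔA₆₂₀) or rC_HbR − 1 in the idealized variant; k absorbs
  baseline HbR concentration, compartment weighting and optical constants,
  so x enters unscaled.

## Calibration from an isometabolic stimulus

Mild hypercapnia (≤ 10 % CO₂) raises flow without changing oxygen
metabolism, pinning rCMRO₂ = 1 over a calibration window (the last 30 s of
a 90 s CO₂ delivery, following 30 s of rest). Imposing unity on the window
means constrains (γ_R, γ_T) to one line in coefficient space — a single
run cannot identify both coefficients. `calibrateGammas` returns the point
on that line closest to (1, 1) (Euclidean orthogonal projection), anchoring
at the uninformed assumption; the projection is validated against a dense
brute-force line search. With hypercapnia-signed inputs (a < 0, b > 0) the
orthogonal projection necessarily moves both coordinates to the same side
of (1, 1); per-animal pairs that straddle (1, 1) on average can therefore
arise from run-to-run variability but not from a single noise-free
projection, a structural property worth keeping in mind when comparing
cohort summaries. A per-timepoint least-squares variant with a ridge pull
toward (1, 1) is available behind `perTimepoint = TRUE`.

The Grubb exponent is estimated per run as α = ln(rC_HbT)/ln(rCBF) at the
window means (`estimateAlpha`), and k follows in closed form as
k = (rCBF^{α−1} − 1)/x̄ (`calibrateK`). Because (1 + b̄)^{1/α̂} equals the
measured flow mean exactly when α̂ comes from the same means, the flow-free
Model 2 calibration reproduces Model 1's (γ_R, γ_T) — the package exploits
this instead of re-solving. `aggregateCalibrations` pools coefficients
across runs (different CO₂ levels included) by arithmetic mean with n−1
standard deviations. Calibrated values outside [0, 1] (γ_R) or above 1
(γ_T) are reported as-is, never clipped.

## Windowing conventions

All windows are half-open [start, end) with t = 0 at stimulus onset; the
endpoint convention matters at the sampling rate and is fixed package-wide.
Hypercapnia runs normalize to the 30 s before onset and average the last
30 s of stimulation. Whisker runs normalize each trial to the 5 s before
its own onset, epoch-average the 12 trials on a common −5…+30 s base, and
report, per signal, the mean over the 2 s window centered on that signal's
own peak absolute deviation within [0, stim + 4) s (ties broken toward the
earliest sample). Scenario traces are computed per time sample and reduced
by the same rule, so the scalar rCMRO₂ change is the windowed statistic of
the model trace, not the model of windowed statistics (the two agree on
plateaus).

## The synthetic-data generator

`generateRun` forward-models one experiment: the flow ratio follows an
exponential rise toward its plateau during stimulation and exponential
relaxation afterwards; total hemoglobin is Grubb-coupled
(rC_HbT = rCBF^α); deoxy-hemoglobin is obtained by inverting Model 1 (or,
in `mode = "model3"`, the idealized single-wavelength form) against the
ground-truth rCMRO₂ profile, which shares the flow kernel scaled to its own
plateau; oxy-hemoglobin closes the mass balance; intensities follow the
forward Beer–Lambert matrix as I = I₀·e^{−ΔA} with multiplicative Gaussian
noise; the LDF trace is emitted at 100 Hz with independent noise, while
optical traces are emitted at 10 Hz, forcing the block-mean downsampling
path to be exercised.

Choices that were genuinely open, and how they were fixed:

* **Response shape.** Hypercapnia: 10 s rise, 20 s fall, no post-stimulus
  hold. Whisker: 1 s rise, a 2 s post-stimulus hold, 5 s fall — evoked
  hemodynamic responses outlast a 6 s stimulus by a couple of seconds
  before relaxing, and with a 36 s inter-trial interval this leaves < 0.1 %
  residual signal at the next trial's baseline window. The hold also makes
  the 2 s peak-centered statistic read the plateau rather than the falling
  edge, which is what ties the recovered change to the injected one.
* **Within-frame flow.** Flow is held constant within each 0.1 s imaging
  frame, so the emitted 100 Hz LDF is a sample-and-hold of the 10 Hz
  profile and block-mean downsampling is exactly inverse to emission. This
  keeps the Grubb coupling exact at the trace level; a band-limited
  interpolant would add a ~10⁻³ rise-phase discrepancy that is measurement
  physics, not model content.
* **Compartment coefficients.** Ground-truth γ defaults to (1, 1), the
  standard literature assumption. A single isometabolic constraint
  identifies only a line; the closest-to-(1, 1) rule returns the generating
  pair exactly when that pair is the nearest point to (1, 1), so unity
  defaults make end-to-end recovery identifiable. Non-unity values remain
  injectable (`gammaRTrue`, `gammaTTrue`) and are used to test the
  isometabolic-consistency property itself.
* **Noise.** Multiplicative Gaussian, independent across samples and
  channels, fractional sd `noiseSd` (default 0). Camera and LDF noise
  magnitudes of the real instruments are not characterized here; 1 % is
  used as a working level in the robustness tests, not as an estimate of
  any instrument.
* **Scales.** Baseline intensity 1000 counts, baseline LDF 250 perfusion
  units; only ratios propagate downstream.
* **Study conditions.** Hypercapnia plateaus default to the group-mean flow
  increases of the two CO₂ levels (+29.17 % and +113.67 %); whisker runs
  default to a 15 % flow increase and a 5.5 % metabolic response; the
  Grubb exponent defaults to 0.38; baselines default to C_HbT,0 = 280 μM
  and S₀ = 0.75.

What the generator does **not** emulate: spatial heterogeneity of the
hemodynamic response (a single active compartment drives the ROI),
arterial/venous compartments beyond the γ coefficients, physiological
fluctuations (vasomotion, heart beat), capnometry, or instrument drift
other than the common-mode illumination term of the image-stack fixture.
Passing tests therefore demonstrate internal consistency and correct
inversion of the stated forward model, not robustness to every artifact of
real recordings.

`generateImageStack` renders a run into two toy image stacks: a smooth
baseline pattern whose ROI pixels scale with the run's intensity ratio,
multiplied everywhere by a common-mode illumination drift, then rigidly
translated along a smooth sub-pixel trajectory in the Fourier domain, with
the injected shifts and drift stored as ground truth.

## Image preprocessing

Registration is 2D Fourier cross-correlation with a local upsampled-DFT
refinement: the integer peak comes from the full inverse FFT, then a
±0.75 px neighborhood is evaluated at 1/upsample px resolution by a
matrix-multiply DFT. The default upsample of 20 (0.05 px) matches the
precision the tests demand; each frame is aligned to the first frame of the
experiment and corrected by the negative of its estimated shift. Constant
(zero-variance) frames have no registration signal and raise an error.

Illumination correction regresses the control-region mean trace (regions
over bone or head-bar, which see lamp fluctuations but no hemodynamics) out
of each pixel's time course. The fit includes an intercept and only the
control-trace component is removed, so each pixel's temporal mean — and
with it the absolute I₀ needed for absorbance — is preserved. A constant
control trace carries no drift information and the correction degrades to a
warning no-op rather than an error: a drift-free stack passes through
unchanged. The fixed processing order is register → intensity-correct →
extract ROI → (LDF) downsample → normalize.

Degenerate inputs are refused rather than repaired: non-positive
intensities, zero or near-zero baseline means, unmixing matrices with
condition number above 10⁸, non-integer rate ratios in downsampling, and
model denominators ≤ 0 (states incompatible with the model at the given
noise level) all raise errors; trailing partial downsampling blocks are
dropped with a warning.

## Optical constants

The default `OpticsTable` uses the standard tabulated hemoglobin extinction
spectra (50104/37020 cm⁻¹ M⁻¹ for HbO₂/HbR at 580 nm, 942/6509.6 at
620 nm), converted to natural-log μM⁻¹ mm⁻¹, with pathlength factors
0.45 mm at 580 nm and 1.7 mm at 620 nm — literature-typical values for
cortical reflectance, short where absorption is strong. Users with
calibrated constants should supply their own table (`OpticsTable`, with a
`base = "log10"` convenience for decadic tabulations). Every correctness
test is a forward/inverse round trip, so no package result hinges on these
defaults; they set the scale of k and of concentration outputs.

## Numerical choices and fixture sizes

* Calibration unity is enforced exactly at the window means; evaluated as
  the window mean of the model trace it holds to ~10⁻⁸ on a plateau (the
  discrepancy is the covariance of the window's residual rise).
* Identifiability tests for α and k use an extended 200 s stimulation so
  the calibration window sits on the asymptotic plateau: window means of a
  still-rising exponential carry a Jensen-gap bias of order 10⁻⁸ that would
  mask a 10⁻⁹ recovery check; at the plateau the log-ratio identity is
  exact.
* The end-to-end recovery checks use cohorts of three synthetic animals
  (one hypercapnia calibration run, one 12-trial whisker run each) and,
  for the noisy variant, twenty seeded cohorts at 1 % measurement noise —
  sizes chosen so the full suite runs in seconds while the cohort means
  are stable to well under the tolerances being asserted.
* Peak localization ties are broken toward the earliest sample; the 2 s
  peak window is clipped at trace edges.
* The baseline sweep re-runs summary, calibration, aggregation and
  evaluation per grid point; the default single-point grid reproduces the
  unswept pipeline bit-exactly. Measured-source Model 3 rows are invariant
  to S₀ because neither rCBF nor ΔA₆₂₀ touches the Beer–Lambert baselines;
  the idealized variant depends on S₀ through C_HbR,0 by definition and is
  deliberately not asserted invariant.

## Known limitations

Model 3 with the measured 620 nm signal inherits the single-wavelength
approximation rC_HbR ≈ 1 + ΔA₆₂₀: the 620 nm absorbance also carries an
oxy-hemoglobin term whose relative weight differs between the hypercapnic
calibration state and an evoked response, so the calibrated k transfers
imperfectly across stimulus types — visible in the scenario tables as
larger Model 3 changes, and consistent with the idealized variant matching
the reference. Statistical comparisons are raw paired t-tests without
multiple-testing correction. The pipeline supports exactly two wavelengths;
the 2×2 unmixing structure is load-bearing. No comparison against external
PET/fMRI values is attempted.
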