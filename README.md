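# rcmro2

Relative cerebral oxygen metabolism (rCMRO₂) from two-wavelength intrinsic
optical imaging and laser-Doppler flowmetry, with hypercapnia-based
calibration.

## The problem

Wide-field reflectance imaging at a total-hemoglobin-sensitive wavelength
(580 nm) and a deoxy-hemoglobin-sensitive wavelength (620 nm), combined with
a laser-Doppler flowmetry (LDF) measurement of cerebral blood flow (CBF),
is a standard way to estimate changes in the cerebral metabolic rate of
oxygen (CMRO₂) in rodent cortex. The estimate rests on steady-state Fick's
law,

    rCMRO₂ = rCBF · rOEF,        rOEF = (1 + a) / (1 + b),

where the `r` prefix denotes a ratio to the pre-stimulus baseline,
`a = ΔC_HbR / C_HbR,0` and `b = ΔC_HbT / C_HbT,0` are fractional deoxy- and
total-hemoglobin changes obtained by modified Beer–Lambert (MBLL) unmixing
of the absorbance changes `ΔA_λ = −ln(I_λ(t) / I_λ,0)`:

    [ΔA₅₈₀]   [ε_HbO,580·D₅₈₀   ε_HbR,580·D₅₈₀] [ΔC_HbO]
    [ΔA₆₂₀] = [ε_HbO,620·D₆₂₀   ε_HbR,620·D₆₂₀] [ΔC_HbR]

Three model families are implemented, differing in which measurements they
require:

- **Model 1 (2 wavelengths + LDF)** — `rCMRO₂ = rCBF·(1 + γ_R a)/(1 + γ_T b)`,
  where γ_R and γ_T are vascular-compartment volume-fraction coefficients.
- **Model 2 (2 wavelengths only)** — flow is replaced by the Grubb coupling
  `rCBV = rCBF^α`, giving `rCMRO₂ = (1 + b)^{1/α}·(1 + γ_R a)/(1 + γ_T b)`.
- **Model 3 (1 wavelength + LDF)** — the calibrated-fMRI-style form
  `rCMRO₂ = rCBF^{1−α}·(1 + k·x)`, with `x` the 620 nm absorbance change
  (or, in an idealized variant, `rC_HbR − 1`) and `k` a calibration
  coefficient absorbing baseline HbR and optical factors.

Mild hypercapnia (≤ 10 % CO₂) raises CBF without changing oxygen
metabolism, so an isometabolic CO₂ run pins rCMRO₂ = 1 over a calibration
window and identifies (γ_R, γ_T) — as the solution closest to (1, 1) on the
constraint line — as well as `k` and the Grubb exponent
`α = ln rC_HbT / ln rCBF`. The package evaluates nine scenarios
(Models 1–3 × per-run calibrated / cross-run average / uncalibrated) and a
sensitivity sweep over the assumed baselines `C_HbT,0` and `S₀`.

Because raw recordings are rarely shareable, the package also ships a
forward-model generator (`generateRun`, `generateImageStack`) that emits
LDF traces, two-wavelength optical traces and toy image stacks from known
ground truth — every pipeline stage is testable against exact expected
values, including sub-pixel registration and illumination correction.

## Worked example

Calibrate on a synthetic 8 % CO₂ run, then score a whisker-stimulation run
with a known 6 % metabolic response:

```r
library(rcmro2)

calRun     <- generateRun(hypercapniaParadigm(), hypercapniaTruth("8%", seed = 1L))
calSummary <- co2ResponseSummary(calRun)
cal        <- calibrateRun(calSummary, source = "mouse-01/8pct")
cal
#> CalibrationResult [n = 1, mouse-01/8pct]
#>   gammaR = 1, gammaT = 1
#>   k = 16.5, kIdeal = 1, alpha = 0.38

stimRun <- generateRun(whiskerParadigm(), whiskerTruth(rcmro2Peak = 1.06, seed = 2L))
tab <- evaluateScenarios(whiskerTrialSummary(stimRun), cal = cal,
                         avg = aggregateCalibrations(list(cal)))
tab[, c("scenario", "change_pct", "pct_error")]
#>        scenario change_pct pct_error
#> 1   Model 1-Cal       5.95  0.00e+00
#> 2   Model 1-Avg       5.95  0.00e+00
#> 3     Model 1-1       5.95  9.06e-06
#> 4   Model 2-Cal       5.95  8.05e-02
#> 5   Model 2-Avg       5.95  8.05e-02
#> 6     Model 2-1       5.95  8.05e-02
#> 7   Model 3-Cal      11.40  9.18e+01
#> 8   Model 3-Avg      11.40  9.18e+01
#> 9 Model 3-Ideal       5.95  3.06e-02
```

Reading the output: the run was generated with Grubb exponent 0.38 and the
calibration recovers it; `k = 16.5` is the single-wavelength coefficient
that forces rCMRO₂ = 1 on the CO₂ window. On the whisker run the injected
6 % metabolic response is recovered as a 5.95 % change (`change_pct` is the
2 s peak-centered mean of rCMRO₂ − 1; the small shortfall is the residual
rise/relax shape inside the window). `pct_error` is relative to the
Model 1-Cal reference. The measured-signal Model 3 rows overshoot because
the 620 nm absorbance also carries an oxy-hemoglobin contribution whose
relative weight differs between the hypercapnic calibration state and the
evoked response — the idealized variant, fed the true `rC_HbR`, recovers the
reference. A baseline sweep is one call:

```r
baselineSensitivitySweep(list(calRun), list(stimRun),
                         chbt0Grid = c(70, 140, 280),
                         s0Grid = c(0.75, 0.65, 0.55))
```

A command-line wrapper with `simulate` / `calibrate` / `cmro2` / `sweep`
subcommands lives at `inst/cli/rcmro2.R`; runs are exchanged as plain
CSV/JSON/YAML directories (`writeRun` / `readRun`) and image stacks as
multi-page TIFF.

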