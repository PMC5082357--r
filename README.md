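# ewavekit

Kinematic analysis of early diastolic filling from pulsed-wave Doppler
echocardiograms, for cardiology researchers quantifying diastolic
function beyond conventional velocity/interval measurements.

Early transmitral flow (the E-wave) is modeled as the recoil of a damped
loaded spring: with inertial mass fixed at m = 1 g,

```
x''(t) + c·x'(t) + k·x(t) = 0,   x(0) = x0,  x'(0) = 0
```

so each E-wave is fully described by three constants — chamber stiffness
`k` (g/s²), viscoelastic damping `c` (g/s) and load `x0` (cm).  In the
physiological (underdamped) regime the speed of flow is

```
v(t) = (k·x0/ω)·e^(−ct/2)·sin(ωt),   ω = √(k − c²/4),   t ∈ [0, π/ω]
```

Fitting this curve to the detected spectral envelope yields the
constants, from which the package derives peak velocity, acceleration
and deceleration times, VTI, the peak driving (`k·x0`) and resistive
(`c·Vmax`) forces, filling energy `½k·x0²`, the damping index `c² − 4k`,
the kinematic filling efficiency index (KFEI), a relaxation-time
estimate, and — across beats acquired under varying load — the
load-independent index `M` (slope of `k·x0` vs `c·Vmax`) with intercept
`B`.

The package provides:

- **`modelVelocity()`, `derivedIndices()`, `triadFromParams()` /
  `paramsFromTriad()`** — the model, its closed forms, and the
  acceleration-time/deceleration-time/peak-velocity parameterization and
  its exact inversion;
- **`detectEnvelope()`, `zeroTail()`, `tangentShorten()`** — top-down
  spectral-envelope detection with a velocity-jump rule, and the two
  deceleration-shortening procedures;
- **`fitPDF()`, `fitWithShortening()`, `autofitSequence()`** —
  Levenberg–Marquardt estimation with physical bounds, and the
  semi-automatic multi-beat loop (template matching by normalized cross
  correlation, 1/3-cycle and 35%-of-peak stop rules, 40% parameter
  discard rule);
- **`readDopplerDicom()`, `splitCine()`, `exportResults()`,
  `saveSession()`** — calibrated DICOM ultrasound-region input, cine
  splitting, spreadsheet export and a portable JSON session container;
- **`coefficientOfVariation()`, `icc()`, `percentageDifference()`** —
  reproducibility statistics between repeated analyses;
- **`synthTrace()`, `synthStrip()`, `synthCine()`, `synthDicom()`** —
  seeded synthetic Doppler generators with exact ground truth, used
  throughout the test suite.

## Worked example

```r
library(ewavekit)

p <- pdfParameters(c = 17.3, k = 135, x0 = 11.4)
round(derivedIndices(p), 3)
#>     vmax  vmax_ms       at     edec duration      vti      kx0    cvmax
#>   58.620    0.586    0.094  310.740    0.405   11.743   15.390   10.141
#>   energy     beta     kfei      tau
#>    0.877 -240.710   51.505  128.148

# render the same wave as a calibrated Doppler strip, write it as DICOM,
# read it back and re-estimate the constants from the pixels alone
spec <- syntheticSpec(p, seed = 7)
synthDicom(spec, "demo.dcm")
strip <- readDopplerDicom("demo.dcm")$strips[[1]]
fit <- fitPDF(detectEnvelope(strip, detectionSettings(0, ewaveDuration(p),
              zeroTail = FALSE, tangentShorten = FALSE)))
fitParams(fit)
#> PDFParameters: c = 17.32 g/s, k = 135.21 g/s^2, x0 = 11.41 cm (underdamped)
```

The derived values read: peak velocity 58.6 cm/s, deceleration time
311 ms, VTI 11.7 cm, peak driving force 15.4 mN, filling energy
0.88 mJ, damping index −241 g²/s² and a filling efficiency of 51.5% —
i.e. this wave carries 51.5% of the flow an undamped wave with the same
stiffness and load would carry.  Re-estimating through the rendered
image recovers the generating constants to a fraction of a percent.

A command-line wrapper ships at `inst/cli/ewavekit.R`
(`fit`, `autofit`, `simulate`, `export`, `stats` subcommands).

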