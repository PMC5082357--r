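---
title: "Kinematic E-wave analysis: model, pipeline and validation"
author: "ewavekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic E-wave analysis: model, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewavekit)
```

## The model

Early diastolic transmitral flow is treated as the recoil of a damped
loaded spring.  With inertial mass fixed at 1 g (the standard
convention, so that all constants carry per-gram units), displacement
obeys

$$\ddot x + c\,\dot x + k\,x = 0, \qquad x(0) = x_0,\quad \dot x(0) = 0,$$

and the measured Doppler velocity is the speed $|\dot x(t)|$.  Three
constants describe each E-wave: stiffness $k$ (g/s², proportional to
chamber stiffness $dP/dV$), viscoelastic damping $c$ (g/s, energy loss
from impaired relaxation), and load $x_0$ (cm, the end-systolic
compression of the elastic myocardium).  The damping regime is decided
by $c^2 - 4k$: physiological E-waves are underdamped ($c^2 < 4k$), with

$$v(t) = \frac{k x_0}{\omega} e^{-ct/2} \sin(\omega t),
  \qquad \omega = \sqrt{k - c^2/4},$$

a wave that starts at zero, peaks at $t_{peak} = \arctan(2\omega/c)/\omega$,
and ends at its first zero, $\pi/\omega$.  Critically damped and
overdamped waves decay without a zero crossing; `ewavekit` evaluates all
three closed forms and keeps them continuous across the boundary
(discriminants within $10^{-9}\,k$ of zero use the critical form, whose
limit both neighbours share).

### Derived indices

All indices follow from the constants alone: peak velocity, acceleration
time, deceleration time $E_{dec}$ (peak to terminus), VTI
($x_0(1 + e^{-c\pi/2\omega})$ underdamped, quadrature otherwise), peak
driving force $k x_0$ and peak resistive force $c\,V_{max}$ (converted
dyn → mN), filling energy $\tfrac12 k x_0^2$ (erg → mJ), the damping
index $c^2 - 4k$, and KFEI — the wave's VTI over the VTI $2x_0$ of an
undamped wave with the same $k$ and $x_0$, which reduces to the closed
form $100\,(1 + e^{-c\pi/2\omega})/2$ and therefore depends on $(c, k)$
only.

Two deliberately documented conventions:

- **Terminus of non-oscillatory waves.**  Critically damped and
  overdamped velocities never return to zero; their duration is defined
  as the time where speed has decayed to 1% of the peak
  (`decayFraction`, configurable), which keeps $E_{dec}$ and VTI finite.
- **Relaxation-time estimate.**  The time constant of isovolumic
  pressure decay is approximated from the constants as
  $\tau = c/k$ (in ms, $\times 1000$): the relaxation time of a
  viscoelastic element with damping $c$ and stiffness $k$.  It is
  positive, grows with impaired relaxation ($c$), shrinks with a stiffer
  chamber, and ignores load; an undamped wave returns a flagged missing
  value.  This is an index, not an invasive measurement, and other
  published approximations exist — treat absolute values with care.

### The triad parameterization

Each underdamped wave is equivalently described by its acceleration time
$AT$, deceleration time $DT$ and peak velocity: with
$\omega = \pi/(AT + DT)$, $c = 2\omega/\tan(\omega\,AT)$,
$k = \omega^2 + c^2/4$ and $x_0$ from the peak amplitude.
`paramsFromTriad()` is the exact inverse of `triadFromParams()`
(verified to $10^{-6}$ relative on 1,000 random draws); $AT = DT$ gives
the undamped wave and $AT > DT$ is rejected as non-physical, since it
would need negative damping.  This inversion also initializes the
optimizer (below) and supports the three-landmark workflow in which a
user marks start, peak and end instead of fitting every sample.

## From pixels to a trace

A `DopplerStrip` is a calibrated pixel matrix: columns are time
(`dtPerCol` s each, pixel-center convention: column $j$ represents
$(j - \tfrac12)\,\Delta t$), rows are velocity (`dvPerRow` cm/s each)
relative to a baseline row.  `detectEnvelope()` searches each column of
the detection window from the top down for the first pixel at or above
a brightness threshold.  Candidates are screened by a jump rule: a
velocity differing from the last *accepted* velocity by more than
`maxJump` is kept but flagged rejected, so an isolated noise pixel
cannot poison subsequent columns; the reference for the first sample is
zero, because flow is about to begin.  Rejected samples stay in the
trace for inspection.

Defaults, all user-overridable: threshold = Otsu's threshold of the
window (the bimodal band/background split), `maxJump` = 25% of the
strip's velocity span per column step, and when no end point is given,
the window is trimmed to 75% of the estimated wave duration after a
full-width first pass — mirroring the clinical recommendation to stop
detection before the artifact-prone late deceleration phase.

Two optional procedures shorten the fitted deceleration limb toward the
clinical convention, both enabled by default and independently
switchable:

- **zero tail** replaces the last two accepted velocities with zero (a
  wave that ends must end at zero);
- **tangent shortening** fits once, takes the tangent to the fitted
  curve where velocity has fallen to 70% of peak, extrapolates it to
  the baseline — the line clinicians draw to mark deceleration time —
  substitutes that segment for the fitted curve, and refits.

Both procedures *by construction* shorten $E_{dec}$ even on a clean
wave (for the worked example below the tangent's baseline intercept is
0.317 s against a model terminus of 0.405 s); their purpose is to
counteract bright non-E-wave signal during deceleration, which biases
naive detection upward.  The tests therefore assert directional
contracts — on artifact-bearing strips the shortened fit is strictly
closer to the true $E_{dec}$; with both flags off the pipeline is the
identity composition — rather than pretending the procedures are
neutral.

## Fitting

`fitPDF()` minimizes $\sum_i (v(p, t_i) - v_i)^2$ over accepted samples
with Levenberg–Marquardt (via `minpack.lm`).  The physical bounds
$k > 0$, $x_0 > 0$, $c \ge 0$ are enforced by optimizing in transformed
coordinates ($\log k$, $\log x_0$, softplus $c$), keeping the residual
smooth at the $c = 0$ boundary rather than clipping.  Initialization
comes from the closed-form triad inversion of the trace's empirical
$(AT, DT, V_{max})$, which is near-exact on clean data; a non-physical
empirical triad falls back to mid-range adult values (c = 15 g/s,
k = 170 g/s², x0 = 11 cm).  Times are re-referenced so the user-marked
onset (`tStart`) is $t = 0$ — onset placement, not optimizer behavior,
is the dominant error source, which is why the start is an explicit
setting.  No goodness-of-fit verdict is produced; the residual norm is
recorded for diagnostics only.

The semi-automatic loop (`autofitSequence()`) propagates a user-accepted
seed fit: the onset of each subsequent beat is found by normalized cross
correlation against a template cut around the seed onset (full strip
height, ±0.03 s; matches below a 0.6 correlation floor discard the
beat); detection runs from the onset to the earlier of 1/3 of a cardiac
cycle and the point where velocity falls below 35% of that beat's peak;
and a fit is kept only when each of $c, k, x_0$ lies within 40%
(relative) of the mean over previously accepted beats, seed included.
Every beat lands in exactly one of accepted/discarded, with a reason.
The cycle length comes from an explicit option, heart-rate metadata, or
the strip's own extent, in that order.

Across beats acquired under varying load, `loadIndependence()` regresses
peak driving force on peak resistive force by unweighted ordinary least
squares; the slope $M$ is the load-independent index and the intercept
$B$ is reported in mN.  Slope estimates are sensitive to outliers and to
the spread of loading states, which is why the multi-beat machinery
reports per-beat forces for inspection.

## DICOM, sessions and export

`readDopplerDicom()` locates the spectral-Doppler ultrasound region by
its region-type metadata, crops the pixels to it, and maps the region's
physical deltas into the strip calibration; multi-frame cines yield one
strip per frame, and `splitCine()` cuts long strips at onset-aligned
cycle starts using heart-rate metadata or the autocorrelation of column
intensity sums.  The reader/writer implements the Explicit VR Little
Endian transfer syntax — the syntax the package itself writes — and
fails loudly, naming the offending attribute or syntax, on anything
else; a temporal resolution implying a sweep speed under the
recommended 100 mm/s earns a warning, never a failure.  When several
spectral regions exist, the largest wins (logged).

Sessions persist as a self-describing JSON container (schema version
1.0) holding strips, traces, settings and fits at full double
precision; version mismatches raise an explicit migration error, and
anonymized saves carry no case or source identification.  Exports write
one row per beat plus mean/SD summary rows and $M$/$B$ to CSV/TSV
(UTF-8, '.' decimal, 15 significant digits); a cumulative study
database appends one summary row per case and refuses a mismatched
header rather than silently drifting schema.

## Reproducibility statistics

Two repeated analyses are compared per case (the per-patient mean is
the unit of analysis): the coefficient of variation is
$100\,\mathrm{SD}(a - b)/\overline{(a,b)}$, reported as a positive
magnitude even for negative-valued parameters; the percentage
difference is $100\,|a-b| / ((a+b)/2)$ per case, summarized by mean and
SD, with zero-mean cases excluded and reported; and the ICC is the
two-way random-effects single-measure form computed from the
case-by-analysis ANOVA mean squares.  The absolute-agreement form
ICC(2,1) is the default because repeated analyses of the same images
should agree in value, not merely rank; ICC(3,1) is available where a
systematic offset between observers should be ignored.

## The synthetic generators, and what passing tests show

`synthStrip()` renders a filled bright spectral band from the baseline
up to the model envelope (the appearance of PW Doppler, where
brightness reflects the amount of blood at each velocity), with
seeded uniform fill intensities, optional background speckle, optional
supra-envelope artifacts during the deceleration phase — the failure
mode the shortening procedures target, placed *above* the true envelope
because non-E-wave signal usually has higher velocity — an optional
late-diastolic A-wave, and optional Gaussian velocity jitter on the
drawn envelope while the returned ground truth stays the clean model
curve.  Default geometry: 0.004 s/column (a 100 mm/s sweep at 0.4 mm
pixel pitch), 1 (cm/s)/row, 170 rows with the baseline at row 160, one
0.8 s cycle per beat with the E-wave at the cycle start.  Generators
are pure functions of (spec, seed).

This emulation is phenomenological: there is no transducer or beam
physics, no spectral broadening, no gain-dependent blooming, no wall
filter, and the A-wave is a scaled copy of the E-wave.  Passing tests
therefore demonstrate that the *algorithms* are correct against known
ground truth — detection reads the envelope it was shown to one pixel,
fitting recovers generating constants, the quoted behavioral rules fire
exactly — not that clinical accuracy on vendor images will match; on
real data, onset placement and E/A overlap remain the user's judgment.

## Numerical choices and problem sizes

Regime tolerance $10^{-9} k$ on the discriminant; quadrature relative
tolerance $10^{-10}$; root finding to $10^{-12}$ s; LM with up to 500
iterations and $10^{-14}$ convergence tolerances.  The validation suite
uses 1,000 random parameter draws for the closed-form and triad-identity
checks, 200 draws for triad round trips in the model tests, 40 draws
for noise-free recovery, and 50 seeded replicates for each Monte-Carlo
recovery statement (velocity noise σ = 3 cm/s); random draws sample
the reported cohort ranges (c 10.6–32.8 g/s, k 106.5–294.8 g/s²,
x0 7.7–17.9 cm) restricted to the clearly underdamped region.  These
sizes make the full suite run in well under a minute while leaving the
Monte-Carlo standard errors far below the tested tolerances.

## Known limitations

- The relaxation-time estimate is one of several published
  approximations; only its qualitative behavior is guaranteed.
- The DICOM layer targets the package's own explicit-little-endian
  files; vendor-specific encodings (compressed syntaxes, non-8-bit
  data, implicit VR) are rejected with explicit errors rather than
  half-read.
- `xlsx` export is not provided; use CSV/TSV.
- No A-wave detection or E/A-overlap classification is attempted; waves
  whose crossover exceeds half the peak velocity should be excluded by
  the analyst.
- Cine splitting assumes reasonably regular rhythm; heavy ectopy will
  defeat both the metadata and autocorrelation period estimates.
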