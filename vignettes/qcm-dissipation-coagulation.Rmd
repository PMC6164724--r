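---
title: "Measuring clot times from QCM dissipation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring clot times from QCM dissipation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcmcoag)
```

## The measurement principle

A shear-mode quartz resonator driven at its fundamental (here 10 MHz)
radiates an evanescent shear wave into the liquid it touches. The wave
decays over the sensing depth

$$\delta = \sqrt{\eta / (\pi f_0 \rho)},$$

about 210 nm for blood plasma ($\eta = 1.42\times10^{-3}$ Pa s,
$\rho = 1.03\times10^{3}$ kg/m$^3$) at 10 MHz, so the sensor only sees
the first few hundred nanometres above its electrode. When plasma clots,
the fibrin network that builds up within (and beyond) that layer is a
soft, lossy solid; the resonator's energy loss per cycle — its
dissipation factor $D = 1/Q = \mathrm{BW}/f_s$ — rises by far more than
the instrument noise floor, which makes $D(t)$ the natural clotting
signal. Frequency shift alone would be misleading here: the
Sauerbrey mass reading assumes a rigid film
($|\Delta D| < 1\times10^{-6}$ per 10 Hz of $|\Delta f|$), while
coagulating plasma runs at roughly $2.5\times10^{-6}$ per 10 Hz
(`rigidity_check()` classifies this).

The dissipation shift of a crystal carrying a thin Kelvin–Voigt film
(shear modulus $\mu_1$, viscosity $\eta_1$, thickness $h_1$) under a
semi-infinite Newtonian liquid is

$$\Delta D \approx \frac{1}{\pi f_0 \rho_0 h_0}\left\{
  \frac{\eta}{\delta} + 2 h_1 \left(\frac{\eta}{\delta}\right)^{2}
  \frac{\eta_1 \omega}{\mu_1^2 + \omega^2 \eta_1^2}\right\},
\qquad \omega = 2\pi f_0 .$$

The first term is the bulk-liquid loading; for a 10 MHz AT-cut crystal
in plasma it evaluates to $\approx 4.9\times10^{-4}$, which is why the
trace simulator's default baseline dissipation is $5\times10^{-4}$. The
film term is non-negative, linear in $h_1$, and vanishes for a bare
crystal.

The crystal density and thickness are not instrument-reported values;
the defaults ($\rho_0 = 2648$ kg/m$^3$, $h_0 = 1.67\times10^{-4}$ m,
i.e. shear velocity $\approx 3340$ m/s over $2 f_0$) are textbook AT-cut
quartz numbers and are documented as assumptions.

## What the simulator emulates — and what it does not

`trace_scenario()` / `simulate_trace()` generate the canonical
coagulation record: a settled baseline with a small drift, a short
loading fluctuation when the trigger reagent is pipetted in, a slow
dissipation gain as fibrin begins to deposit, a rapid logistic rise as
the thrombin burst accelerates polymerisation, and a plateau. Gaussian
white noise is added to the dissipation channel; the frequency channel
is an inverted linear image of dissipation,
$f(t) = f_0 - c\,(D(t) - D_\mathrm{base})$.

Defaults, with units and provenance:

| parameter | default | meaning |
|---|---|---|
| `baseline_D` | 5e-4 | bulk-plasma Kelvin–Voigt loading of a 10 MHz crystal |
| `drift_rate` | 2e-6 /min | stability of a settled chip before reagent addition |
| `noise_sd` | 2.5e-6 | liquid-phase short-term stability (1e-6 for a dry chip) |
| `artifact_amplitude`, `artifact_duration` | 5e-6, 8 s | pipetting bump, half-sine |
| `slow_rise_rate` | 1e-7 /s | pre-burst fibrin deposition |
| `sigmoid_amplitude`, `sigmoid_width` | 1e-4, 2.5 s | thrombin-burst rise (logistic) |
| `freq_coupling` | 4e6 Hz per unit D | inverse of the 2.5e-6-per-10-Hz coagulation ratio |
| `sample_interval`, `duration` | 1 s, 600 s | a one-sample-per-second 10-minute assay |

The logistic was chosen for the burst because it matches the
rapid-rise-then-plateau morphology and has a closed-form maximum-slope
time (its centre), giving an exact ground truth. The ground truth
returned by `simulate_trace()` is the derivative argmax of the
noiseless, *artifact-free* curve: the loading bump is an acquisition
nuisance, and defining truth on the artifact-free curve keeps it
meaningful even in stress tests where the artifact is made to out-slew
the burst. The seed is a mandatory scenario field; there is no hidden
RNG state anywhere in the package.

What the simulator does **not** capture about real blood: non-Gaussian
and non-white noise (bubbles, electrode wetting), sample-to-sample
morphology differences (fibrinogen level changes both amplitude and
burst steepness), temperature excursions, sensor-to-sensor coating
variability, and anticoagulated samples that never clot (these appear
only as the `no clot` error path). Passing the simulation-based tests
therefore demonstrates the *signal-processing chain* is correct under
the stated noise model, not that clinical agreement would reach any
particular R².

## The sweep and its calibration

The electronics measure the resonance curve point by point: at each
frequency the excitation is mixed with 0° and 90° references and
low-pass filtered, once with open switches (dark), once through a
reference path (calibration), once through the crystal (measurement).
The calibrated magnitude is

$$\mathrm{Magnitude}(f_n) = M_\mathrm{mea}(f_n) - M_\mathrm{cali}(f_n),
\qquad
M_x = 20\log_{10}\sqrt{(V_{x,0}-V_{\mathrm{dark},0})^2 +
                       (V_{x,90}-V_{\mathrm{dark},90})^2}.$$

Dark subtraction removes any constant offset exactly; the ratio form
cancels any gain common to the two pathways, so voltages are arbitrary
units and no ADC model is needed. A dark-corrected measurement vector of
exactly zero maps to a −200 dB sentinel (never −Inf) so downstream
fitting stays total. The default sweep is 200 equally spaced points from
9.98 to 10.02 MHz, endpoints included (grid step ≈ 201.005 Hz).

## Resonance fitting: why the cubic lives in reciprocal power

The fitter must read $f_s$ and the half-power bandwidth off a sampled
curve whose bandwidth can be *smaller than the grid step* (at
$D = 10^{-5}$, BW = 100 Hz against ≈201 Hz spacing). Two candidate
readings of "fit a third-order polynomial" were prototyped:

* a cubic in the dB domain around the peak, with the −3 dB crossings
  interpolated linearly from the measured points — this fails badly for
  narrow resonances (a cubic cannot represent the peak level, and linear
  interpolation across a sub-grid peak lands the crossings far out;
  observed errors 10–4500 %);
* a cubic in the **reciprocal linear-power** domain: for a Lorentzian,
  $1/|H|^2$ is *exactly* a parabola in frequency, so a cubic fitted over
  a wide window represents the entire peak and both flanks, the cubic
  term absorbing mild asymmetry. $f_s$ is the polynomial's minimiser,
  and the half-power frequencies are the roots of $y = 2\,y_\mathrm{min}$
  on either side — both read from the same fitted curve.

The second reading is implemented. Numerical choices: the fit window is
the contiguous run of points within 30 dB of the grid maximum (falling
back to the nearest 25 % of points per side if that run has fewer than
8 points); the design matrix is centred and scaled before `lm.fit`; the
minimum is located by `optimize` and the crossings by `uniroot`, both at
square-root machine tolerance; the half-power level is exactly
$20\log_{10}\sqrt{2} \approx 3.0103$ dB; ties between equal grid maxima
resolve to the lowest frequency; a spectrum whose maximum sits on the
sweep boundary raises a `no resonance` error, and a half-power level
never crossed inside the span raises `bandwidth exceeds sweep`. On the
default sweep the worst noiseless recovery error across
$D \in [10^{-5}, 5\times10^{-4}]$ and arbitrary peak placement is below
$2\times10^{-4}$ %, and the estimate is unbiased under 0.01 dB spectrum
noise.

## Endpoint detection

The clot time is defined kinetically: the **start point** is the
instant the trigger reagent is added (the calcium-chloride starter for
APTT, the thromboplastin reagent for PT — the start-event convention is
recorded in every result), and the **end point** is the peak of the
first derivative of the dissipation curve, i.e. the moment of fastest
fibrin build-up. The derivative is a centred moving average (default 11
samples) followed by central differences — transparent, phase-free, and
adequate at one sample per second; the end points use one-sided
differences so the output keeps the input length.

Because pipetting shakes the chamber, the first seconds after the start
event are excluded from the peak search by a **blanking** window
(default 10 s). The peak is the *global* maximum after blanking, not
the first local one: the burst-phase peak is the defining feature, and
blanking, not peak ordering, handles the artifact. Increasing blanking
can therefore never move the detected end point earlier. QC flags
record a drifting or uncheckable baseline, a peak sitting on the search
boundary, and a peak slope below a floor (5 × the robust noise scale of
the pre-start derivative) that would indicate a flat or anticoagulated
sample; a trace with no positive slope at all raises a `no clot` error
rather than returning a spurious time.

The baseline gate fits a least-squares line to the pre-event window
(default 60 s) and passes when the drift is within 2×10⁻⁶/min **and**
the peak-to-peak residual stays within the same allowance scaled to the
window. At the liquid-phase noise level (sd 2.5×10⁻⁶) the residual
criterion is strict — essentially every realistic trace carries the
`baseline_drift` flag — which is intentional: the flag is informational
and never blocks the clot-time computation.

With the default scenario (burst amplitude 1e-4, width 2.5 s, noise sd
2.5e-6, 11-sample smoothing) the smoothed-derivative peak stands about
5 × above its noise-induced jitter at ±3 samples, which is the margin
behind the Monte-Carlo recovery test (≥95/100 replicates within ±3
samples).

## Cross-calibration

Device clot times are longer than the reference analyzer's (the assay
runs at room temperature, which consistently prolongs clotting, and the
derivative-peak endpoint is a kinetic rather than optical criterion),
but the prolongation is consistent, so an affine map suffices:
ordinary least squares of reference times on device times, with the
device reading as predictor because that is what a point-of-care user
has in hand. The headline statistic is the **adjusted** R² (the plain
R² is kept alongside); `n ≥ 3` is required since the adjusted R² is
undefined below that, and constant device times are a degenerate-fit
error. The intercept is left free — nothing in the physics forces the
map through the origin. Rescaling device times by $c$ rescales the
slope by $1/c$ and leaves R² unchanged, which the tests verify.

The end-to-end property test simulates 12 samples whose programmed
clot times are an affine image of assigned reference values, runs the
full simulate → detect → calibrate pipeline at liquid-level noise, and
requires adjusted R² ≥ 0.98. This is a *structural analogue* of a
clinical method comparison, not a reproduction of one: it shows the
pipeline preserves affine structure through detection noise, nothing
more.

## Problem sizes and determinism

All tests run on desk-scale inputs chosen as representative rather than
exhaustive: 200-point sweeps, 600-sample traces, 100-replicate
Monte-Carlo batches, 200-replicate bias checks. Every stochastic stage
takes an explicit seed (`trace_scenario()` refuses to run without one)
and restores the caller's RNG state, so identical inputs and seeds give
byte-identical outputs — the writers format numbers at 15 significant
digits so that write → read → write round-trips are byte-identical too.

## Known limitations

Only the fundamental resonance is modelled (no overtones, no
Butterworth–Van Dyke equivalent circuit, no phase-based fitting); the
analog chain is represented by its ideal post-filter contract (no LPF
transients, mixer nonlinearity or ADC quantisation); temperature enters
only through the affine calibration, not as a viscosity model; and the
fibrinogen/thrombin-time assays are out of scope. These mirror the
boundaries of the instrument concept the package models.
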