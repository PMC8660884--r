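---
title: "Quantitative calcium imaging from frequency-domain FLIM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative calcium imaging from frequency-domain FLIM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caflits)
```

## The measurement model

Homodyne frequency-domain FLIM excites the sample with light modulated at
frequency $f$ (default 75.1 MHz) and gain-modulates the detector at the
same frequency, stepping the detector phase through $K$ uniform offsets
$\theta_k = 2\pi k/K$. A fluorophore with lifetime-dependent phase shift
$\Phi$ and modulation ratio $M$ produces frame means

$$I_k = A\,[1 + m_\mathrm{ex} m_\mathrm{det}\, M \cos(\theta_k - \Phi)] + B,$$

where $m_\mathrm{ex} m_\mathrm{det}$ is the instrument modulation depth
and $B$ a background offset. `demodulate()` recovers $(A, M, \Phi)$ per
pixel by the first-harmonic DFT, which on uniform steps is identical to a
linear least-squares fit of $a + b\cos\theta_k + c\sin\theta_k$ (a
property-tested equivalence) and is the exact single-harmonic estimator.
We use $K = 12$ by default; any $K \ge 3$ gives the same answer on
noise-free single-harmonic data, larger $K$ averages more noise.

`reference_calibrate()` removes the unknown instrument phase and
modulation using a reference fluorophore of known mono-exponential
lifetime (Alexa488 at 4.05 ns by default; Erythrosin B at 0.086 ns for
short-lifetime calibration). Because both $m_\mathrm{ex} m_\mathrm{det}$
and any instrument phase cancel exactly in this step, their simulated
values never affect calibrated results — also property-tested. The
reference spatial mean is 5 %-trimmed per tail so isolated dead or hot
pixels cannot bias the calibration.

A decay maps to phasor coordinates through

$$\Phi = \arctan(\omega\tau_\varphi), \quad
  M = \frac{1}{\sqrt{1 + (\omega\tau_M)^2}}, \quad
  G = M\cos\Phi,\; S = M\sin\Phi,$$

with $\omega = 2\pi f$. Mono-exponential decays lie on the universal
semicircle $(G - \tfrac12)^2 + S^2 = \tfrac14$; mixtures of two states lie
on the chord between the states' phasors. That chord geometry is the core
of the quantification.

## Two-state unmixing and concentration conversion

The sensor has a calcium-free (apo) state with phase/modulation lifetimes
1.40/1.80 ns and a calcium-bound state at 2.78/3.01 ns. For a pixel
phasor $(G, S)$, `line_fraction()` computes the projection onto the
apo→saturated chord,

$$a = \frac{dG\,dG_{max} + dS\,dS_{max}}{dG_{max}^2 + dS_{max}^2},$$

which is 0 at the apo anchor and 1 at the saturated anchor. The projection
is orthogonal, so off-chord noise displaces $a$ only in second order.
Because phasor mixing weights components by brightness and the bound state
is $R$ times brighter, the molecular bound fraction is

$$F = \frac{a}{R(1 - a) + a}.$$

Finally `concentration_from_fraction()` inverts the calibration Hill
model $f(L) = f_{min} + (f_{max} - f_{min})/((K_d/L)^n + 1)$. The
composition of these maps sends a known simulated concentration back to
itself; the suite asserts relative error below $10^{-3}$ across
20 nM–1.8 µM noise-free.

An algebraic consequence worth knowing: the map from free calcium to line
fraction is itself a Hill curve with the same coefficient $n$ and midpoint
$K_d R^{-1/n}$. The package therefore fits calibrations both on $F$
(`hill_on_F`) and directly on $a$ (`hill_on_a`); the two give identical
concentrations, and the a-route needs no intensity correction at
quantification time.

### Out-of-range pixels

The chord projection can land outside $[0, 1]$ (noise, or pixels not
described by the two-state model). Policy: `line_fraction()` returns the
value as-is with an `in_range` flag; `concentration_from_fraction()`
clamps the response to a relative margin of $10^{-4}$ inside
$(f_{min}, f_{max})$ and reports those pixels in `in_range_mask` as
out-of-range (or returns `NaN` with `clamp = FALSE`). Images never raise
errors pixel-wise. Physically impossible phasors ($M > 1.05$ or
$\Phi \notin [-0.05, \pi/2]$, thresholds configurable) are invalidated as
`NaN` during lifetime conversion; small excursions within those
tolerances are clipped to the physical boundary.

### Session correction

Day-to-day instrument drift is corrected by forcing a measured
saturated-state control (ionomycin/Triton + calcium) onto the
calibration's saturated anchor: an additive phase offset and a
multiplicative modulation factor, estimated from the ROI-mean control
phasor rather than per pixel (the control is a single physical state; a
per-pixel estimate would only add noise). Applying the estimated
correction maps the control exactly onto the anchor by construction.

### Background correction

Background removal operates on the per-pixel mean intensity *and* the
complex fundamental, subtracting the mean of a user-indicated pure
background region before any normalization by dc. Subtracting the complex
fundamental — not just intensity — removes the background's lifetime
contribution; by linearity of the DFT this is exact for an additive
background. Whether commercial FLIM software subtracts before or after
normalization is generally unspecified; pre-normalization subtraction is
the only choice under which "removing a background region's lifetime" is
well defined, and is what this package does. Pixels driven to
non-positive dc are invalidated.

## Calibration fitting

`fit_hill()` fits the four-parameter Hill model by bounded nonlinear
least squares (the `port` algorithm of `nls`). Initialization:
$K_d^{(0)}$ = geometric mean of the positive concentrations, $n^{(0)}=1$,
$f_{min}^{(0)}/f_{max}^{(0)}$ from the responses at the concentration
extremes; bounds $K_d \in [\min(x_{>0})/100,\; 100\max x]$,
$n \in [0.1, 10]$. The zero-ligand point is evaluated through the model's
limit $f(0) = f_{min}$ (the $(K_d/L)^n$ form is singular at $L = 0$).
`port` sometimes stops with "false convergence" at a perfectly good
optimum — routinely on exactly-fitting synthetic data — so fits run
`warnOnly` from a small ladder of $K_d$ starts, keep the lowest residual
norm, and treat stop codes 7/8 as converged while recording the solver
message in the diagnostics. Constant responses are rejected as degenerate
rather than fitted.

`calibrate_in_situ()` composes the pipeline for permeabilization
experiments: per concentration and replicate the equilibrium phasor is
the mean of all samples at least 6 minutes (`min_delay = 360` s,
configurable) past digitonin addition; anchors are the mean equilibria of
the lowest and highest buffer; then chord projection, intensity
correction with the supplied $R$, and Hill fits on both $F$ and $a$.
Anchors come from the extreme concentrations rather than a total
least-squares chord fit — the extremes are replicated, measured states,
and a noise-free saturating buffer pins them exactly. (At a 39 µM top
buffer the occupancy is not exactly 1, which is why recovered in vitro
$K_d$ can sit a few 0.01 % away from the generating value; this is
intrinsic to anchoring at finite saturation, as any real calibration
does.) `calibrate_wells()` runs the same analysis on well-level phasors
without the time dimension.

The detection range takes the replicate spread of $F$ at the two extreme
buffers: the lowest reliably measurable fraction is
$\bar F_0 + t_{0.975, n-1}\,\mathrm{SD}$, the highest
$\bar F_{sat} - t_{0.975, n-1}\,\mathrm{SD}$, both mapped through the
Hill inverse. The half-width uses Student-$t$ on the sample SD (not the
SEM): the question is where a *single* future calibration-quality
measurement becomes distinguishable from the asymptotes, not where the
mean does. Zero replicate spread collapses the range to the clamping
margins and is flagged `degenerate` instead of being reported as a
spuriously wide range.

## Characterization assays

**pH models.** The calcium-free state follows a one-site
Henderson–Hasselbalch curve with Hill coefficient
($\mathrm{p}K_a$ 4.36 [0.86]); the bound state needs two sites
(4.71 [0.70] and 5.91 [3.58]). Fits are bounded least squares with
$f_{min} \le 0$ allowed (plate-reader backgrounds can overshoot zero
after subtraction). The two-site fit multistarts over a grid of 20
$(\mathrm{p}K_{a,1}, \Delta\mathrm{p}K_a)$ pairs with the second
transition parameterized as $\mathrm{p}K_{a,2} = \mathrm{p}K_{a,1} +
\Delta$, $\Delta > 0$, which enforces ordering and removes label
switching; the lowest-SSR fit wins. The amplitudes of the packaged pH
models ($f_{min} = 0$, apo $f_{max} = 1000$, sat $f_{max} = 3510$,
$f_{med} = 1000$ counts) are chosen so the high-pH intensity contrast
reproduces the sensor's in vitro dynamic range of 3.51; the
`dynamic_range_curve()` of the two models is then stable over the
biological range — the suite asserts a coefficient of variation below 5 %
on pH 6.2–9.0. (The steep second transition at 5.91 leaves the 6.2
endpoint a few percent below the plateau, so "flat" is asserted as CV,
not as an endpoint-to-plateau band.)

**Relative quantum yield.** For each dilution series the through-origin
least-squares slope $s = \sum A_{440} I_{em} / \sum A_{440}^2$ of
integrated emission on absorbance is computed, and
$QY_s = QY_r \times s_s / s_r$ against the mTurquoise2 reference
($QY_r = 0.93$). The slope is defined with emission as the response —
under that convention a brighter state has the larger slope and the ratio
carries $QY$ the right way up. Validity requires the low-absorbance
window $0.002 < A_{440} < 0.02$; records outside it trigger a warning.
Absorbance spectra are offset-corrected by their 631–650 nm mean, and
emission is integrated by trapezoid over 450–650 nm on the native grid.
A user-supplied per-wavelength detector-sensitivity curve is accepted
(identity by default).

**Extinction coefficient.** Alkali denaturation frees the chromophore
(known $\varepsilon_{462} = 46$ mM⁻¹cm⁻¹); Beer–Lambert turns the
denatured absorbance into chromophore concentration and the native
$A_{440}$ into $\varepsilon_{440} = 46\,A_{440}/A_{462}$ — a pure ratio,
invariant to common scaling.

**Plate screens.** Screening wells are normalized as
$(I - I_{bg})/I_{EB}$ against an Erythrosin B reference well, and the
intensity fold-change is the series maximum over the first read.
Magnesium sensitivity is summarized per Mg level as mean bound-state over
mean free-state intensity with a delta-method SD.

## The synthetic-data generator

Every downstream stage is tested against data generated from the packaged
ground-truth model, so the generator's assumptions bound what the tests
demonstrate. It emulates:

- homodyne single-harmonic phase stacks (uniform steps, optional Poisson
  shot noise on counts or Gaussian noise on tables) — no higher
  harmonics, no PSF, no photobleaching, no camera artifacts;
- two-state mixtures whose phasor is the intensity-weighted complex sum
  of the pure-state phasors and whose brightness scales as
  $(1-F) + RF$;
- calibration time series sampled every 20 s that relax
  single-exponentially (default rate 0.02 s⁻¹, so the residual transient
  is below $10^{-3}$ of the step after the 6-minute window) from a
  resting 100 nM phasor to the buffer equilibrium after digitonin;
- an 11-step buffer ladder: 0 plus 10 log-spaced concentrations from
  17 nM to 39 µM — the ladder endpoints are the documented kit range, the
  log spacing and interior values are this package's choice;
- titration, pH and dilution-series spectra tables evaluated directly
  from the model curves, with Gaussian-on-Gaussian spectra shapes.

Passing tests therefore show estimator correctness and noise behaviour
under this forward model; they do not exercise real-data failure modes
such as autofluorescence mixtures, multi-exponential decays, saturated
pixels or detector nonlinearity.

Two presets package the ground truth. The in situ preset carries
$K_d = 265$ nM, $n = 1.63$, $R = 3.02$; the in vitro preset
$R = 3.51$ with lifetime-mode $K_d = 372$ nM and intensity-mode
$K_d = 360$ nM, $n = 1.51$. The occupancy and intensity-mode Hill
parameters are stored separately because the two readouts of the same
titration yield separately fitted apparent constants. The in vitro
lifetime-mode Hill coefficient is not tabulated anywhere; the preset uses
$n = 1.5$ as a representative value for this sensor family — it cancels
out of every test that compares recovered to generating parameters.

## Problem sizes and runtime choices

The test suite runs on small images (typically 8×8; 256×256 for the
full-frame lifetime recovery check, which demodulates in milliseconds via
a single matrix product), 11-concentration calibration ladders with 3
replicates, 200 seeded stochastic replicates for Hill-recovery statistics
and 100 for Poisson-bias statistics. These sizes put the whole suite in
the tens-of-seconds range while keeping the stochastic assertions
well-powered; all estimators are closed-form or small fits, so nothing
changes qualitatively at camera-resolution scale.

## Known limitations

- Single-frequency, single-harmonic analysis only; no TCSPC, no
  multi-frequency global fitting, no higher-harmonic phasors.
- The two-state chord model assumes exactly two emitting species;
  contaminating autofluorescence must be removed by the background
  correction or it biases $a$.
- Anchors from extreme buffers assume the top buffer saturates the
  sensor; a top buffer near $K_d$ would bias the chord.
- The detection-range convention ($t$ on the sample SD) is one of several
  defensible readings of a "95 % CI" rule; it is configurable through
  `conf_level` but the SD-vs-SEM choice is fixed.
- ROI tools consume masks or label images; no segmentation or tracking is
  provided.
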