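---
title: "Methods: radiochromic film characterization for proton beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiochromic film characterization for proton beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonfilm)
```

## Scope and shape

`protonfilm` implements the full measurement chain of a radiochromic-film
(EBT3/EBT4) characterization study for clinical proton beams: scanner image
→ ROI statistics → net optical density (netOD) with uncertainty →
batch-specific dose calibration and inversion → darkening kinetics →
film-versus-chamber comparison along depth and lateral profiles. The
repository is organised as an analysis workflow — the numbered scripts under
`analysis/` are thin narrative drivers over the package functions, which is
where every computation lives and what the tests exercise. No measured film
data ship with the package: a seeded synthetic-data generator produces every
input with the statistical structure the analyses assume, so the pipeline is
fully testable offline.

## The netOD measurement model

A flatbed transmission scan gives 16-bit counts per channel. For a film
piece scanned before (`I0`) and after (`I`) irradiation,

$$\mathrm{netOD} = \log_{10}(I_0 / I),$$

with `I0`, `I` taken as ROI channel means. Two uncertainty conventions are
implemented (`sigma_form`):

* **standard** (default): $\sigma = \frac{1}{\ln 10}\sqrt{(s_0/I_0)^2 + (s/I)^2}$,
  the first-order propagation of the log-ratio. It retains a finite noise
  floor as netOD → 0, which is the physically sensible behaviour for
  low-dose films.
* **scaled**: the same quantity multiplied by netOD, a convention that
  appears in parts of the film literature. It vanishes at netOD = 0, which
  is why it is not the default; both forms are available and neither is
  endorsed beyond that argument.

The signal errors $s_0, s$ default to the standard error of the ROI mean
(`sd/sqrt(n)`), because the ROI *mean* is the estimator entering netOD; a
`pixel_sd` flag switches to raw pixel standard deviations when a per-pixel
noise figure is wanted instead. The "central film region" convention is a
centered rectangle covering 50 % of each dimension (`central_roi()`), which
keeps cut edges out of the statistics; the exact ROI is always overridable.
ROI coordinates are 0-based and half-open throughout. A slightly negative
netOD within 3σ is retained rather than clamped, to avoid biasing low-dose
statistics; more negative values raise an error ("film lighter than
baseline").

Mean-of-map and map-of-means netOD differ by a Jensen gap bounded by
$\sigma^2 \ln 10 / 2$; this is documented and tested on synthetic frames.

## Dose-response calibration

Per channel, netOD follows the rational model

$$\mathrm{netOD}(D) = \frac{a\,D}{1 + b\,D^{n}},\qquad a>0,\ b\ge 0,\ n>0,$$

linear at low dose with a saturating correction. Built-in presets carry the
fitted parameters of three characterized batches (B1, B2: EBT4; B4: EBT3);
across them $n$ spans roughly 0.66–2.1, so the fitter uses a multi-start
strategy: $a_0$ from the secant through the two lowest distinct doses, and
$(b_0, n_0)$ over $\{0.01, 0.1, 0.5\}\times\{0.7, 1.0, 1.5, 2.0\}$, damped
Levenberg–Marquardt (via `minpack.lm`) from each start, smallest final SSE
winning and ties broken toward the smallest $n$. Convergence tolerances are
a relative SSE change below $10^{-10}$ or 500 iterations. When netOD
uncertainties are supplied the fit can be $1/\sigma^2$-weighted; unweighted
is the default since weighting is a study choice, not a model property.
Fit quality is reported as $R^2 = 1 - SS_{res}/SS_{tot}$ and RMSE, with
RMSE < $10^{-3}$ the conventional acceptance gate for noise-free
calibration data.

The rational model has no closed-form inverse. Following common practice,
an empirical inverse $D = a'\,\mathrm{netOD} + b'\,\mathrm{netOD}^{n'}$ is
fitted to 512 equally spaced doses over the calibrated range, weighted
$1/D^2$ so the *relative* dose error is minimized. A caveat discovered
during development and worth stating plainly: this three-parameter form
cannot represent the exact inverse of the rational model over a 0.25–20 Gy
range — its best achievable maximum relative error is a few percent at the
range extremes (≈2.3 % for the B1 red parameters, found by direct minimax
optimization). `fit_inverse()` therefore records its true round-trip error
as a diagnostic and warns above 2 %, and `netod_to_dose()` by default
polishes the empirical estimate with Newton iterations on the strictly
monotone forward model, making dose recovery exact to numerical tolerance
(the `refine = FALSE` path reproduces the plain empirical inversion). Dose
uncertainty is first-order propagation, $\sigma_D = \sigma_{netOD} /
(d\,\mathrm{netOD}/dD)$, evaluated on the curve actually used.

## Darkening kinetics

Post-irradiation polymerization is modeled as

$$\mathrm{netOD}(t) = \mathrm{netOD}_\infty - C_1 e^{-t/T_1} - C_2 e^{-t/T_2},$$

fitted by Levenberg–Marquardt with multi-starts over $T_1 \in \{0.5, 2, 8\}$ h
and $T_2 \in \{12, 24, 72\}$ h (biexponentials are ill-conditioned; a single
start is not trustworthy), amplitudes initialized from the endpoint
deficits, and parameters canonicalized to $T_1 \le T_2$. The default time
grid is the usual stability protocol: 0, 0.5, 1, 2, 4, 8, 24, 48, 120 h.

The model-independent **differential growth rate** is the numerical
derivative of netOD normalized to the 48-h value, in %/h and reported
positive while the film darkens. Differentiation uses three-point Lagrange
weights on the nonuniform grid (one-sided two-point at the ends), which is
exact for linear data and second-order on uniform grids. The 48-h
normalization takes the measured sample when the grid contains 48 h and
linear interpolation otherwise. The **plateau** is declared where the rate
falls below 0.05 %/h: solved by root bracketing on the analytic rate for a
fitted model (the rate is monotone decreasing), or the first grid time where
the numerical rate settles below threshold for a raw series. Scan-delay
correction factors $\mathrm{netOD}(48)/\mathrm{netOD}(t_{scan})$ allow early
readout to be projected to the 48-h reference.

No triexponential extension is provided: committing to a higher-order
functional form invites overfitting on nine time points, which is exactly
why the growth-rate statistic is numerical rather than model-based. Control
film correction for scanner drift is not modeled; the series are assumed
already corrected upstream, and a multiplicative or additive pre-step can be
applied to the series before fitting if needed.

## Characterization statistics

All percent statistics are symmetric (divide by the mean of the pair) except
the sensitivity deviation, which divides by the model prediction because the
question there is "how far is the measurement from the calibration curve".
Specifically:

* **reproducibility / batch variation**: symmetric percent difference of
  group-mean netOD per channel at a matched dose;
* **energy dependence**: $100 \cdot \max_g |\bar y_g - \bar y| / \bar y$
  over energy groups at one dose — for an energy-independent film this sits
  within measurement noise and shrinks like $1/\sqrt{\text{films per group}}$;
* **resolvability**: doses A and B are resolvable when
  $|\Delta \mathrm{netOD}| > k\sqrt{2}\,\sigma_{netOD}$ with $k = 2$
  (≈95 % two-sided separation of two equal-variance measurements); $k$ is a
  parameter, since the choice of confidence is a policy, not physics;
* **noise-to-signal**: mean over doses of $100\,\sigma/\mathrm{netOD}$ per
  channel, excluding zero dose — orders the channels red < green < blue,
  which is the practical reason the red channel is the dosimetry channel.

## Beam profiles and LET under-response

Film near the Bragg peak under-responds because the high ionization density
of slow protons locally saturates the active layer ("quenching"). The
package quantifies this, it does not correct it. Film and chamber profiles
are compared on a common grid (linear interpolation only — at a 1-mm native
step a spline would overshoot at the sharp peak) through
$100\,(\mathrm{film}/\mathrm{chamber} - 1)$; `peak_under_response()`
averages this over a window at the chamber maximum. Beyond the distal
fall-off the dose gradient makes film/chamber matching meaningless, so
points where the chamber reads below 1 % of its maximum are flagged
unreliable rather than reported as differences. Lateral profiles are
normalized to the central axis, characterized by 50/20/5 % level crossings
found by searching outward from the field center, and compared in
percentage points (film % − chamber %), with the relative form emitted
alongside.

## The synthetic-data generator

The generator emulates the study's inputs, not the scanner hardware:

* **Scan pairs**: unexposed signal `I0_mean` (default 42 000 counts, a
  typical flatbed transmission level — arbitrary but fixed) attenuated by
  the batch's dose response, $I = I_0\,10^{-\mathrm{netOD}(D)}$, with
  independent per-pixel multiplicative Gaussian noise per channel (defaults
  0.010, 0.016, 0.038 for R, G, B — chosen once to reproduce the red <
  green < blue noise-to-signal ordering of transmission film scans) and
  clipping to [0, 65535] with a metadata flag when more than 1 % of pixels
  clip. Simulated pieces are 32 × 32 px by default: large enough for stable
  ROI statistics (central ROI = 256 px), small enough that the full
  pipeline, tests and acceptance runs stay fast.
* **Calibration series**: the standard dose ladder 0.25–20 Gy (0.25-Gy
  steps to 1 Gy, 1-Gy steps to 10, 2-Gy steps to 20; 18 points), run
  through the scan simulator and the actual netOD stage rather than drawn
  directly, so generator bugs cannot hide downstream.
* **Kinetics series**: the biexponential with additive noise proportional
  to netOD$_\infty$. No published numeric values exist for the kinetics
  parameters; the fixture defaults (netOD$_\infty$ = 0.4, $C_1$ = 0.05,
  $T_1$ = 1 h, $C_2$ = 0.03, $T_2$ = 12 h for red) are stated fixtures
  chosen to give the characteristic fast rise, ≈80 % of final netOD at
  t = 0 and a plateau near 30 h — not measured values.
* **Depth profiles**: a parametric stand-in for a pristine ≈150 MeV Bragg
  curve — entrance plateau with a slow linear rise blending into a skewed
  peak (Gaussian rise of width `peak_sigma`, steeper Gaussian fall-off of
  width `distal_falloff_sigma`), maximum exactly at `peak_depth`
  (default 157 mm) with a peak-to-plateau ratio of 3.5. Film quenching is a
  depth-ramped multiplicative deficit rising linearly from zero at
  `quench_onset` (15 mm) before the peak to `quench_max` (default 0.18) at
  and beyond it — a generator knob consistent with the 13–20 % scale of
  reported film under-response, not a physics claim.
* **Lateral profiles**: a flat 100-mm field with error-function penumbrae
  (`penumbra_sigma` = 3 mm), normalized to 100 % on axis, crossing 50 %
  exactly at the field edges by construction; film equals chamber by
  default, matching the observed penumbra agreement.

Everything is bit-reproducible under a fixed integer seed; sub-seeds for
replicate films are derived deterministically and kept inside 32-bit range.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real films: lateral scanner-response artifacts,
Newton-ring and film-orientation effects, cut-edge damage, dose-rate
effects, LET-correction physics, and any real beam's measured depth-dose.
Passing tests show the *pipeline arithmetic* is right under the stated
statistical structure, no more.

## Numerical choices and degenerate inputs

* All nonlinear fits run `minpack.lm::nls.lm` on explicit residual
  functions with box constraints; the `nls`-object route is avoided because
  it fails spuriously at boundary solutions (e.g. an exactly linear
  calibration fitting with $b = 0$, or a constant kinetics series fitting
  with $C_1 = C_2 = 0$).
* Monotonicity of every preset response is asserted at construction on a
  0.01-Gy grid.
* `netod_map` marks pixels with zero post-signal `NA` instead of erroring;
  profile comparison marks chamber-zero points `NA` likewise.
* Ties and floats: SSE ties in the calibration multi-start break toward the
  smallest exponent; level crossings interpolate linearly and return `NA`
  for levels never crossed; resampling refuses extrapolation outright.

## Problem sizes

Defaults used by the tests, the analysis scripts and the acceptance script:
32 × 32 px films, the 18-point dose ladder, 5 films per measurement group,
3 calibration replicates per dose, 100-replicate seeded property checks for
fit-recovery statements and 200 for the noisy-R² claim. These sizes were
chosen as the smallest at which the group statistics are stable; all are
function arguments and scale up freely.

## Known limitations

* The empirical inverse form's few-percent structural error (addressed by
  the Newton polish, but present in any downstream use of the raw
  $a', b', n'$ parameters).
* Single-channel dosimetry only: no multichannel (triple-channel)
  reconstruction, by design.
* The Bragg stand-in is parametric; quantitative depth-dose conclusions
  transfer to measured beams only through the comparison statistics, not
  the curve shape.
* No LET correction models — quantification of under-response only.
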