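---
title: "Strength-duration analysis of pulse-width-varied TMS: models, estimators and their precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strength-duration analysis of pulse-width-varied TMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtms)
```

# The measurement problem

Controllable-pulse-parameter TMS (cTMS) devices can vary the width of the
induced electric-field pulse. Measuring the resting motor threshold (RMT) at
several pulse widths traces a *strength-duration curve*, summarized by two
parameters of axonal membrane excitability: the **rheobase** $V_{th\infty}$
(the threshold extrapolated to an infinitely long pulse, in % of maximum
stimulator output, %MSO) and the **strength-duration time constant**
$\tau_m$ (SDTC, in microseconds), a proxy for voltage-gated sodium channel
dynamics. Because sodium-channel-blocking drugs shift these parameters, the
strength-duration curve can dissociate drug mechanisms that a single
threshold cannot.

This package implements the full estimation chain on trial-level data —
stimulus intensity and peak-to-peak motor evoked potential (MEP) amplitude —
together with a synthetic generator of the complete crossover study design,
so that the chain can be validated by parameter recovery without access to
human data.

# Models

## Membrane response and the depolarization factor

The axonal membrane is modeled as a first-order (leaky RC) integrator driven
by the normalized electric-field pulse $e(t)$:

$$\tau_m \frac{dy}{dt} + y = e(t), \qquad y(0) = 0 .$$

The **depolarization factor** $r(\tau_m, t_p) = \max_t y(t)$ measures how
effectively a unit-amplitude pulse of width $t_p$ depolarizes the membrane;
$r \to 1$ for an infinitely long plateau, and for an ideal rectangular pulse
$r = 1 - e^{-t_p/\tau_m}$ (the Lapicque form). The modeled threshold is

$$V'_{th}(t_p) = \frac{V_{th\infty}}{r(\tau_m, t_p)} ,$$

which decreases with pulse width and tends to the rheobase.

The cTMS pulse is idealized as a *pseudorectangular* waveform: an initial
phase of width $t_p$ (unit amplitude, optionally with a small linear droop)
followed by a longer opposite-sign phase whose relative amplitude is the
M-ratio (default 0.2, with a second-phase width of $5 t_p$). We define the
M-ratio as (smaller phase)/(larger phase) so it lies in $[0,1)$; device
documentation sometimes quotes the inverse, but with the initial phase
normalized to 1 the convention used here is unambiguous. With no droop, the
membrane response peaks exactly at the end of the initial phase, before the
reversed phase begins, so the factor coincides with the rectangular value —
which is why the Lapicque expression serves as an exact oracle for the
default family. Whether $r$ is conceptually a function of the pair
$(\tau_m, t_p)$ or only of their ratio is moot here: the implementation
computes it from the waveform, which subsumes the ratio form in the
rectangular case.

Numerically, $y(t)$ is propagated *exactly* over the pulse's
piecewise-linear segments (piecewise-exponential closed form, including
interior stationary points), so the result does not depend on the sampling
step; an implicit-trapezoid integrator (`depolarization_factor_numeric()`)
is retained purely as an independent cross-check. The trapezoid scheme is
first-order-accurate at the waveform's jump discontinuities, so agreement is
asserted at $10^{-3}$ rather than machine precision.

## Input-output curves and threshold inversion

MEP amplitudes at a fixed pulse width follow a sigmoid in stimulus intensity
$x$. On the $\log_{10}$ amplitude scale the Boltzmann form is

$$y = y_l + \frac{y_h - y_l}{1 + \exp\left(\frac{x_m - x}{s}\right)},$$

with lower/upper saturation levels $y_l, y_h$ ($\log_{10}$ mV), midpoint
$x_m$ and spread $s$ (both %MSO). Per session (one subject in one
condition) the asymptotes are fixed across pulse widths: $y_l$ is the 10th
percentile of the pre-stimulus background-EMG amplitudes and $y_h$ the 90th
percentile of the MEP amplitudes, pooled over the whole session. Only
$(x_m, s)$ are fitted, by least squares on the *median* $\log_{10}$
response at each delivered intensity. The RMT is then read off the fitted
curve as the intensity at the 0.05 mV criterion:

$$\mathrm{RMT} = x_m - s \,
  \ln\!\left(\frac{y_h - y_l}{y^* - y_l} - 1\right), \qquad
  y^* = \log_{10}(0.05).$$

## Strength-duration fit

Given thresholds $V_{th}(t_p)$ at two or more widths, the parameters
minimize the normalized least-squares criterion

$$Q(V_{th\infty}, \tau_m) \;=\; \sum_{p}
  \left(\frac{V'_{th}(t_p)}{V_{th}(t_p)} - 1\right)^{2},$$

i.e. squared *relative* errors, which weight the widths equally despite
their very different absolute thresholds and make the fit scale-equivariant
(rescaling all thresholds rescales the rheobase and leaves the SDTC
unchanged). A shared-SDTC mode (one $\tau_m$ per condition, individual
rheobases) is provided as a sensitivity analysis against per-subject
overfitting.

## Statistical layer

Crossover effects are analyzed with linear mixed-effects models (lme4):

* thresholds: `rmt ~ condition * pulse_width + (1 | subject)`;
* SDTC and rheobase: `value ~ condition + (1 | subject)`;
* drug-minus-placebo differences: the same interaction model on the paired
  differences;
* `sdtc ~ rheobase * condition + (1 | subject)` for the parameter
  relationship, plus per-condition ordinary regressions.

Omnibus tests are marginal (Type III) Wald F tests computed under
sum-to-zero contrasts; contrasts are treatment-coded against placebo.
Denominator degrees of freedom default to the residual rule
$N_{obs} - \mathrm{rank}(X)$ — e.g. $39 - 3 = 36$ for the scalar models and
$117 - 9 = 108$ for the threshold model — with Satterthwaite approximation
(lmerTest) available as an option. Effect sizes are Cohen $d$ = estimate /
residual SD. No multiplicity correction is applied. A random pulse-width
slope can be requested for the threshold model; it falls back to the
intercept-only structure (with a note) when the fit is singular, which is
the typical outcome at this design size.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| pulse widths | 30, 60, 120 | us | the three cTMS settings of the design |
| output ceilings | 100 / 73 / 50 | %MSO | device energy limits per width |
| M-ratio | 0.2 | — | unidirectional pseudorectangular pulse |
| second-phase width | $5 t_p$ | us | long, low reversed phase |
| MEP criterion | 0.05 | mV | threshold definition |
| spread bounds | [0.5, 50] | %MSO | brackets physiological I-O slopes |
| SDTC search range | [50, 2000] | us | brackets reported cortical/peripheral values |
| SDTC grid | 400 log-spaced nodes | — | global 1-D profile search |
| percentile rule | type 7 | — | interpolated order statistics, deterministic |

# The synthetic study generator

`sim_config()` encodes the design: 13 subjects, three conditions, three
pulse widths, 11 intensity levels at 80–164% of a preliminary RMT (itself
the true threshold plus a ±2 %MSO uniform jitter, emulating the 5-of-10
relative-frequency estimate), 10 trials per level, intensities rounded to
1 %MSO and capped at the per-width ceiling.

Latent subjects draw (rheobase, SDTC) from a bivariate normal. Defaults are
**SDTC 550 ± 120 us** — matching the scale of reported cortical values —
and **rheobase 3.6 ± 0.6 %MSO**, chosen so that the implied true thresholds
(≈ 68 / 35 / 18 %MSO at 30 / 60 / 120 us) lie inside the device ceilings;
under the first-order membrane model the rheobase *must* be below
$V_{th}(120) \cdot (1 - e^{-120/\tau_m}) \approx 0.2\, V_{th}(120)$, so
%MSO-scale rheobase values quoted for other waveform models would place
every threshold far above the stimulator's range. Draws whose thresholds
would not be measurable under every condition (above 92% of a ceiling) are
redrawn, mirroring the implicit enrolment constraint of a real study; a
configuration for which almost no draw is feasible raises an error rather
than silently truncating the population.

Trial variability is Gaussian on $\log_{10}$ amplitude (SD 0.25),
consistent with the log-domain analysis; each recorded amplitude is the
maximum of the sigmoid draw and an independent lognormal background-EMG
draw (median 0.01 mV, geometric SD 1.3), which is exactly the mechanism
that makes the 10th/90th-percentile asymptote rule meaningful. The
generating sigmoid passes through $y^*$ exactly at the true threshold, so
the noiseless round-trip is exact by construction. One master seed drives
deterministic per-session streams, so any session is reproducible in
isolation.

Drug effects transform the latent parameters per condition:
`rheobase' = (rheobase + additive) * threshold_scale`,
`sdtc' = sdtc * sdtc_scale + additive`. Defaults: carbamazepine scales all
thresholds by 1.15 (proportional pattern, unchanged SDTC); lacosamide
scales the rheobase by 1.57 and the SDTC by 0.65, producing a near-flat
≈ +2 %MSO threshold shift at every width. The proportional form is
deliberate: under the Lapicque model the width profile of a proportional
effect is nearly invariant to a subject's latent parameters, whereas
additive shifts calibrated at the population mean reverse sign within ±1 SD
of the latent SDTC and therefore cannot produce a coherent cohort-level
pattern. The magnitudes are internal to this idealized model and are not
comparable to parameter shifts quoted for other depolarization-factor
definitions: a flat threshold shift *requires* a large proportional SDTC
change here.

# Numerical choices

* **I-O fit**: bounded deterministic least squares (`nlminb`), midpoint
  initialized at the intensity nearest the mid-level, spread multi-started
  at {2, 5, 10} %MSO, objective tolerance $10^{-10}$, followed by an
  L-BFGS-B polish (`factr = 10`) so noiseless inversions are exact to
  $<10^{-6}$ %MSO. Spread hitting a bound is flagged, not hidden.
* **SD fit**: the criterion is quadratic in the rheobase at fixed
  $\tau_m$, with closed-form minimizer
  $\sum a_p / \sum a_p^2$, $a_p = 1/(r_p V_p)$; the remaining 1-D profile
  is minimized on a 400-node log grid plus golden-section refinement.
  This is deterministic and, verified against exhaustive 2-D grids, global.
  Optima within tolerance of the search bounds are flagged as `boundary`.
* **Degenerate inputs**: non-positive amplitudes are clipped to
  $10^{-4}$ mV with a warning on ingest (a log transform requires
  positivity; real peak-to-peak EMG noise is never 0); sessions whose noise
  floor exceeds the 0.05 mV criterion are rejected with a data-quality
  error; all-zero difference tables short-circuit the mixed model.
* **Percentiles** use interpolated order statistics (type 7). Exact
  log/percentile commutation holds when the percentile position lands on an
  order statistic; with interpolation the two differ only by the curvature
  of the log across one inter-order gap (tested at $10^{-2}$).
* $R^2$ of an I-O fit is computed on the median points — the quantity the
  fit actually minimizes — not on raw trials.

# Estimator precision: what recovery simulations show

With the design's three pulse widths all far below the time constant
($t_p \le 120 \ \mu s \ll \tau_m \approx 550\ \mu s$), the factor
$1 - e^{-t_p/\tau_m}$ is nearly linear in $t_p$, and the curvature that
separates $\tau_m$ from $V_{th\infty}$ is second order. The threshold ratio
$V_{th}(30)/V_{th}(120)$ changes by only ≈ 0.08% per 1% change in
$\tau_m$, so ≈ 1–2% relative threshold errors — the level produced by 10
trials/intensity with 0.25 log₁₀ trial noise — amplify roughly tenfold into
SDTC and rheobase errors, with strongly anti-correlated errors along the
fit's ridge. Across 50 simulated cohorts at the default noise the median
absolute error is ≈ 17% for both parameters. Two further systematic
components are inherent to the published asymptote rule and present for
real data too: the 10th percentile of background EMG sits below the
operative lower plateau of recorded max(MEP, background) amplitudes, and
the session-wide 90th percentile of MEPs sits below the true upper plateau
when the top intensities do not fully saturate; both bias inverted
thresholds by a few tenths of a %MSO in a width-dependent way that the
model can only absorb as an SDTC shift.

Three practical consequences, each visible in the test suite:

1. group contrasts (the study's actual inferences) are far more stable than
   individual parameters, because within-subject estimation error cancels
   in the crossover design;
2. the shared-SDTC sensitivity fit trades variance for bias exactly as
   intended;
3. the strong inverse SDTC-rheobase correlation across individuals arises
   in part from estimation covariance even when the generating parameters
   are uncorrelated — a caveat for interpreting such correlations as purely
   physiological. The package quantifies this on synthetic data but does
   not adjudicate how much of the real-data correlation is artifactual.

What passing recovery tests do **not** show: the generator draws lognormal
trial noise around a stationary sigmoid and cannot emulate slow excitability
drift, coil repositioning error, inter-trial dependence, or EMG artifacts;
real-data precision may be worse, and the asymptote-rule biases above take
different sizes for different noise-floor/plateau configurations.

# Known limitations

* Three thresholds constrain two parameters: individual fits have one
  residual degree of freedom and wide sampling variance (reported with each
  fit); widths beyond 120 us would identify $\tau_m$ far better.
* The pseudorectangular idealization ignores waveform droop and ringing of
  real coils (droop is available as a parameter but defaults to 0).
* The mixed-model denominator df use the residual rule by design (matching
  the design's printed-df convention); Satterthwaite is available but both
  are approximations at $n = 13$.
* Amplitude processing starts at peak-to-peak values; raw EMG windowing,
  filtering and artifact rejection are upstream of this package.

# A minimal worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)            # the full 13-subject design
pipe <- run_pipeline(config = cfg, shared_sdtc = TRUE)
pipe                                    # prints the text report
```

The `analysis/` directory decomposes the same computation into staged,
re-runnable scripts (simulate, fit I-O, fit strength-duration, statistics)
whose intermediate CSV/JSON artifacts live under `results/`.
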