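---
title: "Models, conventions, and design decisions in dnflight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions, and design decisions in dnflight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnflight)
```

This vignette is the package's own account of its science: the models it
implements, the numerical conventions it fixes where the experimental
literature is silent, and what its synthetic-data validation does and does
not establish about real recordings.

## The aerodynamic power model

Tethered flies regulate flight force mostly through wingbeat amplitude
$\Phi$ and frequency $n$. The mechanical power their asynchronous flight
muscles must deliver, per unit muscle mass, is modeled as the sum of two
terms, with the thorax assumed to store and return inertial power
elastically so that wing acceleration is not a net muscle cost:

$$P^*_\mathrm{ind} = \kappa \frac{F_t}{m_M}
  \sqrt{\frac{F_t}{2\rho\,\Phi R^2}}, \qquad
P^*_\mathrm{pro} = \frac{\rho\, S\, n^3 \Phi^3 R^3\,
  \hat{r}_3^3(S)\, \overline{|\mathrm{d}\hat\phi/\mathrm{d}\hat t|^3}\,
  \bar{C}_{D,\mathrm{pro}}}{16\, m_M}.$$

Induced power is the actuator-disc momentum cost of supporting the flight
force $F_t$: the swept disc area grows with $\Phi$, so induced power
*falls* as the stroke widens. Profile power is the blade-element cost of
wing drag and grows like $(n\Phi)^3$ (or $(n\Phi)^{2.5}$ when the drag
coefficient itself is taken Reynolds-dependent). The flapping-wing
Reynolds number is $Re = S n \Phi / \nu$.

Parameters, units, and defaults (`morphometrics()`,
`default_morphometrics()`):

| parameter | meaning | default | why |
|---|---|---|---|
| `F_t` (N) | total flight force | $10^{-5}$ | weight of a ~1 mg fly in hovering |
| `R` (m) | wing length | $2.4\times10^{-3}$ | field-typical *D. melanogaster* |
| `S` (m²) | area of both wings | $3.6\times10^{-6}$ | ~1.8 mm² per wing |
| `m_M` (kg) | flight-muscle mass | $3\times10^{-7}$ | ~30 % of body mass |
| `rho`, `nu` | air density, viscosity | 1.2, $1.5\times10^{-5}$ | sea-level air |
| `kappa` | induced-power correction | 1.2 | periodic vortex wake |
| `r3_hat_cubed` | third area moment, cubed | 0.195 | $\hat r_3(S)\approx0.58$ |
| `mean_abs_angvel_cubed` | $\overline{|\mathrm{d}\hat\phi/\mathrm{d}\hat t|^3}$ | $\tfrac{32}{3}\pi^2 \approx 105.3$ | sinusoidal stroke, see below |
| `cd_pro_fixed` | fixed $\bar C_{D,\mathrm{pro}}$ | `NULL` | Re mode $7/\sqrt{Re}$ is the default |

These are documented plausible values for a ~1 mg fly, not measurements of
any particular animal; absolute power levels should be read as
order-of-magnitude realistic.

**Angular-velocity normalization.** The $1/16$ prefactor of the profile
term is dimensionally valid under any normalization of
$\hat\phi$, but it is *physically* exact — i.e., it reproduces a direct
blade-element integration $\tfrac12 \rho \bar C_D \int c r^3\,\mathrm{d}r\,
\overline{|\dot\phi|^3}$ — only when stroke position is normalized by the
half-amplitude $\Phi/2$ and time by the wingbeat period. Under that
convention a sinusoidal stroke gives
$\overline{|\mathrm{d}\hat\phi/\mathrm{d}\hat t|^3} = \tfrac{32}{3}\pi^2$,
the package default. With the (superficially natural) full-amplitude
normalization the same formula underestimates profile power by a factor of
$2^3 = 8$ and misorders the two power terms at fly-typical kinematics.
With the correct convention, profile power dominates induced power at
flight kinematics, which is what makes mechanical power approximately
proportional to $(n\Phi)^3$ and the isolines hyperbolic.

**Units.** Wingbeat trackers report degrees; the aerodynamic formulas need
radians. All public interfaces accept degrees by default with an explicit
`unit` flag (`kinematic_state(n, phi, unit = "deg")`); everything internal
is radians.

**Drag-coefficient modes.** The Reynolds-based approximation
$7/\sqrt{Re}$ is the default; a fixed measured coefficient (e.g. 1.36 from
dynamically scaled robot experiments) can be set per `morphometrics()`
instance and then overrides globally. With a fixed coefficient,
$\log P^*_\mathrm{pro}$ is exactly linear in $\log(n\Phi)$ with slope 3;
in Re mode the slope is exactly 2.5. Both identities are asserted in the
test suite to $10^{-10}$.

### Isoline solver numerics

At fixed $n$, $P^*_\mathrm{mech}(\Phi)$ is U-shaped: induced power
diverges as $\Phi \to 0$, profile power as $\Phi$ grows. `solve_isoline()`
therefore first locates the minimum by golden-section search
(`optimize`, tolerance $10^{-10}$), then root-finds on the ascending,
profile-dominated branch with Brent's method (`uniroot`, x-tolerance
$\approx$ machine precision) inside $\Phi \in (10^{-3}, 2\pi-10^{-3})$.
Each returned point is required to satisfy
$|P^*_\mathrm{mech} - P_\mathrm{level}| \le 10^{-9} P_\mathrm{level}$;
grid frequencies with no root in range are omitted and reported in the
`omitted_n` attribute, and a level unreachable on the whole grid is an
explicit error. The ascending branch is the one observed behaviorally
(amplitude falls as frequency rises along a fixed budget), and it makes
$\Phi$ strictly decreasing in $n$ along every curve. In the profile-only
diagnostic limit ($\kappa = 0$, fixed drag coefficient) the isoline is
exactly $n\Phi = \mathrm{const}$, which the tests use as a closed-form
oracle. `bounding_power()` is then simply the maximum of
$P^*_\mathrm{mech}$ over an observed $(n, \Phi)$ trajectory — the level of
the smallest isoline containing the data cloud.

## Optogenetic screen analysis

Each fly receives 30 light pulses (100 ms) at 10 s intervals. Scoring
conventions:

- **Windows.** Baseline = mean bilateral wingbeat amplitude over the 0.5 s
  before onset; response = mean over the 0.5 s starting at onset. Sample
  windows are half-open, $[-0.5, 0)$ and $[0, 0.5)$ s, so the onset sample
  is counted exactly once. The experimental description is silent on this
  point; the convention is fixed here and asserted in tests
  (1000 ± 1 samples at 1 kHz).
- **Metric.** The window mean is the primary score; a peak-within-window
  variant is exposed (`metric = "peak"`) because screen figures in this
  literature sometimes plot peak change. Default = mean.
- **Aggregation.** Trials average to one value per fly; lines summarize
  flies by median and interquartile range using the linear-interpolation
  quantile definition (`stats::quantile` type 7 — conventions differ
  between packages, so this is stated rather than assumed). Ranking ties
  break lexicographically by line identifier.
- **Dose–response.** Ordinary least squares of response on the number of
  targeted cell pairs, on line medians by default (several lines may share
  a cell count); a per-fly fit is available. $r^2$ is computed as
  $1 - \mathrm{RSS}/\mathrm{TSS}$, identical to the squared Pearson
  correlation of fitted vs observed for an intercept OLS fit but defined
  also at zero slope.
- **Interaction test.** Whether baseline subtraction changes the
  dose–response slope is tested on *per-fly* observations with
  `lm(value ~ n_pairs * mode)`; the observation unit is a deliberate
  choice (a median-level test with ~15 points per mode would be severely
  underpowered). The test inherits the usual OLS assumptions, including
  homoscedasticity across modes.
- **Frequency coupling.** OLS of per-fly frequency change on baseline
  frequency; the zero crossing $-b/a$ is reported when the slope is
  nonzero, `NA` otherwise.

## Imaging pipeline

Order of operations is fixed and documented (the experimental description
interleaves it): register → select ROIs and background on the registered
activity stack → per-channel background-subtracted ROI means → ratiometric
normalization → $F_0$ → ΔF/F.

- **Registration.** Reference = time-averaged tdTomato image. Per-frame
  integer displacement = peak of the 2-D circular cross-correlation
  (computed by FFT); the opposite shift is applied to both channels, with
  exposed pixels filled by the frame's median. Sub-pixel refinement is
  deliberately out of scope — the recovered quantity is the injected
  integer shift, and the tests require exact recovery up to ±3 px.
  All-zero frames get zero shift with a warning.
- **Percentile rules.** ROIs = top 20 % of pixels by temporal variance
  within each lateral half (split at the middle column); background =
  dimmest 20 % of the field of view by temporal mean. Counts are floors,
  ties break in raster (column-major) order, so mask sizes are exact and
  reproducible.
- **Ratiometric normalization.** Applied to the background-subtracted
  per-frame ROI means of each channel (not pixel-wise), cancelling z-drift
  that scales both channels alike. The denominator is floored at
  $0.05 \times \mathrm{median}$ to avoid blow-up on dim frames.
- **ΔF/F.** $F_0$ = mean of the lowest 10 % of $F_t$;
  $\Delta F/F = (F_t - F_0)/\max(F_t - F_0)$, so the session maximum is
  exactly 1 per fly per side and the measure is invariant to positive
  affine transforms of raw intensity. A robust (e.g. high-percentile)
  maximum would resist outlier frames but is not the default because the
  plain maximum is the stated convention of the normalization.
- **Lag correction.** The tracker reports at time $t$ the wing state from
  $t - 30\,\mathrm{ms}$; `lag_correct_behavior()` re-interpolates the
  series onto its own clock so samples reflect their timestamps. A flag
  prevents accidental double correction. Behavior is then linearly
  interpolated onto frame times.
- **Epoch averages.** Per-epoch baseline = mean of the 1 s immediately
  before stimulus onset (the experimental description shows
  baseline-subtracted traces without stating the window; 1 s spans several
  frames at ~13 Hz while staying inside the 3 s inter-epoch gap). CIs are
  percentile bootstrap over flies (2.5/97.5 %), resampling with
  replacement, deterministic given `(seed, n_boot)`; with a single fly the
  epoch repetitions are the resampling unit instead. All bootstrap
  helpers restore the global RNG state.
- **Tuning curves and pixel maps.** Both signals are z-scored; activity is
  binned into equal-occupancy bins. Pixel correlation maps use raw
  registered pixel series — Pearson correlation is invariant to the affine
  ΔF/F scaling, so per-pixel normalization would be wasted work.
  Zero-variance pixels get $r = 0$ and a flag. The bilateral summary
  reports the 2×2 side-by-wing correlation table together with the
  left–right wingbeat correlation, because the two wings' amplitudes are
  themselves negatively coupled during asymmetric stimuli and any
  ipsilateral anticorrelation must be read against that confound.

## Synthetic data: what it emulates, and what it does not

`simulate_wingbeat_session()` drives amplitude as a saturating exponential
(rise time constant 0.12 s toward a 40° step over a 0.5 s effective
actuation window, then 0.4 s decay) and couples frequency to amplitude
(0.3 Hz/deg) *until the mechanical power implied by the power model would
exceed a muscle power cap*, at which point frequency is clamped to the
constant-power isoline value at the current amplitude. The default cap is
defined as $P^*_\mathrm{mech}$ at (200 Hz, 160°) under the morphometrics
in use, encoding the empirical observations that the amplitude–frequency
tradeoff engages near a 160° amplitude and that activation lowers
frequency in flies whose baseline frequency is above roughly 200 Hz.
Because the coupling runs through `solve_isoline`'s closed-form inverse,
every optogenetic simulation also exercises the aerodynamic module.

`simulate_dose_response()` draws per-fly baseline-subtracted responses as
$\mathrm{intercept} + \mathrm{slope}\times n_\mathrm{pairs} +
\mathcal{N}(0, \sigma)$ and raw responses by adding an independent per-fly
baseline; an optional distinct raw-mode slope provides the alternative for
power checks of the interaction test. The default conditions used in the
recovery checks are 15 lines targeting 1–15 cell pairs, 8 flies per line,
per-fly noise SD 4°, and generating slope 2.77°/pair.

`simulate_imaging_session()` builds latent per-side activity by low-pass
filtering pattern-specific drives (single-exponential calcium kernel,
$\tau = 0.6$ s; yaw right raises right-side and lowers left-side
activity, etc.), couples each wing's amplitude to the *contralateral*
side's activity with positive gain (+8°/unit) and to the ipsilateral side
with negative gain (−3°/unit), injects the 30 ms tracker delay into the
recorded 32 Hz behavior, and renders two-channel movies: Gaussian arbors
scaled by activity (GCaMP) or static with deliberately unequal left/right
amplitudes (tdTomato — the asymmetry keeps the registration
cross-correlation peak unique), sharing integer jitter shifts, a slow
multiplicative gain drift standing in for z-motion, and
intensity-dependent Gaussian shot noise. Noise models are Gaussian on
behavior and scaled-Gaussian on photon counts — stated here because no
noise model is prescribed experimentally.

**Not emulated:** non-rigid or sub-pixel motion, photobleaching, neuropil
contamination, saturating indicator dynamics, spike-level structure,
wing-tracking artifacts, and closed-loop feedback between behavior and
stimulus. Passing the recovery tests therefore shows the pipeline is
correct and well-conditioned under its stated assumptions, not that those
assumptions hold for any particular microscope.

## Problem sizes and determinism

The shipped tests and the acceptance script use deliberately small
problem sizes chosen to probe each property, not to mimic full sessions:
360–1100-frame movies of 32×64 px, 2–5-trial optogenetic sessions at
100–500 Hz sampling, 500-replicate calibration and coverage runs with
500-sample bootstraps. Every stochastic component takes an explicit seed,
restores the global RNG state, and is bit-reproducible given its
configuration; end-to-end drivers echo their seeds into their JSON
reports.

## Known limitations

- The power model is quasi-steady: no unsteady aerodynamics, no lift
  coefficient estimation, and inertial power is assumed fully elastically
  stored.
- Registration is translation-only and integer-pixel.
- The interaction test relies on OLS homoscedasticity; with grossly
  unequal BLS/RAW variances its p-values are approximate.
- The ratiometric correction assumes z-motion scales both fluorophores
  identically within the ROI.
- Absolute power levels depend on morphometrics that are typically not
  measured in the same animals as the kinematics; isoline *levels* should
  be treated as approximate even when the isoline *shape* is informative.
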