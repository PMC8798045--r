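---
title: "Quantifying microtubule dynamics and lattice binding from TIRF kymographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule dynamics and lattice binding from TIRF kymographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtkymo)
```

## Scope

In vitro reconstitution with TIRF microscopy is the standard assay for
measuring how a microtubule-associated protein changes microtubule behavior:
dynamic extensions are grown from stabilized seeds, imaged over minutes, and
quantified from kymographs (space–time images with one axis along the
filament). `mtkymo` implements the quantitative stages of such a study —
dynamic-instability parameters, templated-nucleation concentration
dependence, end-velocity/end-intensity coupling, single-molecule residence
kinetics and cooperativity, curvature–intensity regression, and lattice
damage/severing intensity analysis — together with a stochastic generator of
synthetic trajectories, binding events, and rendered kymographs with known
ground truth, so that every stage can be validated by parameter recovery.

## Dynamic instability

The generator (`simulate_dynamic_instability()`) uses the classic two-state
model: a growing end advances at `v_g` (nm/s) and switches to shrinkage at
`v_s` (nm/s) after an exponential waiting time with catastrophe rate `f_c`
(s^-1); shrinkage reverts to growth with rescue rate `f_r` (s^-1). A
shrinking end that reaches the seed boundary (position 0) restarts growth
there; that forced transition is not a rescue. Positions are sampled on the
frame grid (default 5 s) and may carry additive Gaussian tracking noise; the
phase record (`truth_phases`) is always noiseless.

`compute_dynamics()` pools one or more phase annotations:

* catastrophe frequency = number of catastrophes / total time in growth,
  with counting error `sqrt(n)` over the same denominator;
* rescue per shrinkage length = rescues / total length shrunk (um^-1),
  counting error `sqrt(n)` over the same denominator;
* dynamicity = (length grown + length shrunk) / observation time, with
  error `pixel_size * N / T` where `N` is the number of marked points and
  `T` the observation time (pixel size defaults to 160 nm);
* growth and shrinkage rates are per-phase slopes pooled with duration
  (growth) or length (shrinkage) weights; the reported SE is the weighted
  SE across phases. Pooling weights are a design choice: the duration
  weighting makes the growth rate equal total displacement over total time,
  the natural maximum-likelihood pooling for a constant-velocity phase.

The literature describes the catastrophe/rescue uncertainties only as
"counting errors"; we implement the Poisson form `sqrt(n)/denominator`.
Replicates (e.g. experimental days) are combined by `weighted_mean_se()`
with inverse-variance weights, the combined SE being `1/sqrt(sum(1/SE^2))`.

### Event detection and its visibility limit

`segment_phases()` replaces manual kymograph marking with a hysteresis
changepoint detector: it tracks the running extremum of the trace and calls
a transition when the trace reverses by at least `min_event_displacement`
(default 480 nm = 3 pixels, mirroring the common "3 pixel" marking
convention); reversals below the threshold merge into the surrounding
phase. Interior vertices are then refined to the intersection of the lines
fitted to the adjacent phases, which removes frame-quantization bias, so on
a noiseless sawtooth the corners are recovered exactly.

Any displacement-threshold rule — automatic or manual — censors excursions
smaller than the threshold. At a regime with slow growth (7.6 nm/s), fast
shrinkage (100 nm/s) and frequent rescue (0.02 s^-1), a large fraction of
catastrophe–rescue excursions never travels 480 nm (we measure ~35% of
catastrophes and most rescues at this regime, from sub-threshold seed
bounces and chains of partial rescues), so the detection path estimates
*apparent* parameters, systematically below the generative ones. This is a
property of the estimand, not a defect of the detector: validation of the
estimator formulas therefore uses exact annotations (the generator's phase
record, via `segment_phases(use_truth = TRUE)`), while the detector itself
is validated by exact corner recovery on noiseless traces and by checking
that under realistic tracking noise (40 nm) it finds at least 90% of the
transitions it finds on the corresponding noiseless traces, within 2
frames. Users comparing conditions should hold the threshold fixed across
conditions, since the apparent rates depend on it.

When counting rescues, a shrink-to-growth vertex at the seed is excluded.
The `seed_zone` tolerance defaults to 0 (exact contact), correct for
noiseless annotations; for vertices marked on noisy kymographs a tolerance
of about one pixel is appropriate.

## End velocity and end intensity

`fit_segment_velocities()` fits ordinary least squares lines in consecutive
non-overlapping 2-minute windows anchored at the first sample (a trailing
window shorter than 60 s is dropped — the convention is ours, the sources
are silent). Leading windows with negative slope are eliminated until the
first positive-slope window, so every trajectory starts with a growth
segment; later negative windows are kept. `classify_segments()` marks
windows with velocity strictly below −2.5 nm/s as shrinking and excludes
them from growth statistics; a window at exactly −2.5 nm/s is retained.

`end_intensity()` implements the 5/3/5-pixel scheme: per frame, the probe
intensity is the mean over a 5-pixel lattice window ending at the tracked
end position minus the mean over a 5-pixel solution background window whose
near edge is 3 pixels beyond the end on the solution side. Frames with
fewer than 5 background pixels inside the image are eliminated. Sub-pixel
end positions are rounded to the nearest pixel, since the measurement is
defined on kymograph pixels. Intensities are reported in raw
background-subtracted units; the normalization producing published
arbitrary-unit values is not uniquely defined in the sources, so any
min–max rescaling is left to the user and documented as such.

## Templated nucleation

A seed counts as nucleated if any extension exceeds 480 nm (strictly)
within the 15-minute window. The fraction–concentration relation is fitted
with the Hill-type sigmoid

y(x) = x^s / (C^s + x^s),

where `C` (uM) is the half-maximal concentration — the form is sometimes
typeset as `x^s/(C + x^s)`, but only the `C^s` reading makes `C` a
half-max with concentration units, so that reading is adopted. Errors on
fractions follow the counting rule `sqrt(N)/total`, with `1/total` when no
seed nucleated; the published prose reads literally "N/total", which
conflicts with its own zero-count special case, so the square-root form is
the default and the literal reading is available as an option.

`fit_sigmoid()` uses bounded Levenberg–Marquardt with deterministic
initialization (`C0` = concentration whose fraction is nearest 0.5,
`s0 = 4`, bounds `C` in (0, 10·max x), `s` in (0, 50)); the start avoids
the flat-likelihood region at small `s`. Confidence intervals come from the
linearized covariance at the optimum. The default fit is unweighted
(matching the published convention, which does not state weighting); under
binomial sampling noise the unweighted CI mildly undercovers (~88% at
nominal 95% in our simulations) because the pooled residual variance
misrepresents heteroscedastic binomial errors, while the inverse-variance
weighted option is calibrated (~94%). Coverage validation therefore uses
the weighted fit; point estimates are indistinguishable between the two on
noiseless data.

## Single-molecule kinetics

`dwell_times()` selects events by their start time (events straddling an
interval boundary are assigned, not split), computes residences
`t_off − t_on`, and reports arithmetic mean ± sample SE. Events truncated
by the end of observation are excluded by default — the convention used
when measuring visibly complete events from kymographs — with an option to
include them as lower bounds. Exclusion biases long-dwell regimes downward
when dwells approach the remaining observation time; the validation
scenarios therefore simulate movies long enough that the analyzed intervals
leave ample runway. The association rate is
`n_events / (duration × length × concentration)` (events um^-1 nM^-1 s^-1)
with Poisson counting error, and conditions are compared with the
two-sided Wilcoxon rank-sum test.

### The cooperative lattice generator

`simulate_binding()` runs an exact continuous-time (Gillespie) simulation
on a 1-D lattice of 8 nm sites (one dimer length; protofilament
multiplicity is ignored because the observables are per-um line
densities). Cooperativity is phenomenological: the association rate of an
empty site is multiplied by `1 + coop_on * rho_local` (occupied fraction
within ±2 sites) and the dissociation rate divided by
`1 + coop_off * n_nearest_neighbors`. Both multipliers at zero recover
independent binding with exponential dwells of mean `1/k_off` — the
control regime (`k_off = 1/12 s^-1` giving 12 s dwells).

The "spiking" validation scenario emulates single-molecule imaging in a
micromolar unlabeled background: `conc = 1000` nM, `k_on = 3e-4`
events um^-1 nM^-1 s^-1, `coop_on = 30`, `coop_off = 10`, 25% labeled, on
a 4 um seed imaged for 30 min with the first two 5-minute intervals
analyzed. Strong on-cooperativity makes arrivals nucleation-limited:
sticky clusters form slowly and spread, so occupancy — and with it the
*typical* labeled dwell — rises through the analyzed intervals, and the
late-interval dwell distribution separates from the independent control at
rank-sum p < 0.001. Under this minimal lattice model the three observed
features of the real system (minutes-scale loading, a saturated dwell near
39 s, and a wholesale distribution shift) cannot all be matched at once:
calibrating `coop_off` to the 39 s dwell collapses the temporal trend
because occupancy equilibrates within a minute. The frozen scenario
reproduces the phenomenon (direction and significance of the cooperativity
effect) at a longer dwell scale; absolute dwell magnitudes are validated
separately with the independent-binding generator at `k_off = 1/12` and
`1/39`. The generator does not model photobleaching, blinking, multi-layer
assembly, or the stretch-initiation statistics of the real protein, so
passing these checks validates the analysis code, not the biological
model.

## Curvature

`polyline_curvature()` estimates unsigned curvature from the circumscribed
circle of three consecutive points of the (optionally smoothed) trace —
the Menger curvature `4A/(abc)`. Smoothing (default window 5) suppresses
pixel-scale tracing noise at the cost of a small inward bias on tightly
curved arcs (~1.6% at 50 points per full circle); for noiseless geometric
traces use `smoothing = 1`, which is exact. Samples are grouped in
0.1 um^-1 bins (bin k covers `(k·w, (k+1)·w]`, boundary values going to
the lower bin, zero curvature into the first bin); within each bin,
intensity outliers beyond 3 scaled median absolute deviations from the bin
median are removed — the default rule of common `isoutlier`-style
routines, flagging ~0.3% of Gaussian data — and the bin mean ± SD is
computed on the remainder. The intensity–curvature relation is then an
ordinary least-squares fit to the bin means (so the result is invariant to
per-bin sample counts), reported as slope with 95% CI and the two-sided p
for zero slope.

## Lattice-level intensity analyses

* `masked_field_intensity()`: the microtubule mask is an Otsu threshold on
  the time-averaged lattice channel dilated by 1 pixel (a fixed, automatic
  stand-in for manual masking), and the probe channel is summed inside the
  mask per frame.
* `region_compare()`: Welch's unequal-variance t-test across microtubules
  on per-microtubule region means (seed versus pre-existing lattice).
* `stretch_profile()`: once a probe stretch reaches 2 um, a 20-pixel
  linescan centered on the initiation pixel is divided by its center
  value; offsets are signed toward the growth direction.
* `severing_timecourse()`: intensities are normalized per microtubule to
  the 0–60 s baseline mean; per field of view the threshold time is the
  first frame at which the mean normalized uncoated-control intensity is
  below 20% for two consecutive frames; coated microtubules are sampled at
  that time; populations are combined as inverse-SE^2 weighted means after
  3-scaled-MAD outlier removal. The threshold time is determined per field
  (fields whose control never crosses are excluded with a message).
* `rolling_ball_background()`: grayscale morphological opening with a
  disc structuring element (radius 5 px by default) subtracted from the
  image; ridges narrower than the ball survive at full height, broad
  plateaus are removed, output is clamped at zero.

## Reproducibility and numerical conventions

Every stochastic function takes its seed from `sim_config(rng_seed = ...)`
(or an explicit argument) and scopes it locally, so repeated calls are
bit-identical and no global RNG state leaks. File formats carry physical
units only (s, nm, um); pixel conversions happen inside image-facing
operations. Validation problem sizes were chosen to make Monte-Carlo error
comfortably smaller than the tested tolerances while keeping the suite
quick: 500 trajectories of 600 s for dynamic-instability recovery,
10^4 seeds per condition and 100 replicate fits for sigmoid coverage,
~150–400 events per dwell estimate, 100 replicate curvature regressions,
and 30 replicate severing fields. The exponential waiting-time oracle uses
a long (3×10^4 s) observation window because completed phases in short
movies are right-censored draws whose conditional mean lies well below
`1/f_c`.

## Known limitations

* Threshold-based phase detection estimates apparent, threshold-dependent
  event frequencies (see above); cross-condition comparisons must share
  one threshold.
* The cooperative binding model is phenomenological; its parameters are
  not estimates of molecular rate constants.
* Kymograph rendering uses a 1-D Gaussian PSF along the filament and
  ignores protofilament structure, labeling stoichiometry and
  photophysics.
* Automatic filament tracing, image registration and end tracking are out
  of scope: traces and end positions are inputs (or generator truth), and
  inputs are assumed registered.
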