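---
title: "Modelling thermal chamber preference and warm-stimulus calcium responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling thermal chamber preference and warm-stimulus calcium responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodrift)
```

## Scope

`thermodrift` implements the computational analysis of a two-chamber thermal
preference assay and of warm-stimulus calcium imaging of cultured sensory
neurons:

1. **Trajectory stage** — keypoint-tracking output is cleaned, quality
   controlled, converted to 1 Hz normalized positions, segmented into
   chamber visits, and summarised as preference time courses, rolling visit
   lengths and crossing counts.
2. **Decision model** — visit lengths are modelled as first-passage times
   of a drift–diffusion process; drift `v` and across-visit drift
   variability `sv` are estimated hierarchically over genotype ×
   temperature combination × chamber with per-animal random effects, and
   candidate models are compared by PSIS-LOO.
3. **Calcium stage** — fluorescence matrices are neuropil-corrected,
   normalized to ΔF/F0, stimuli are split into dynamic and static phases,
   responders are classified, and response onsets and per-field-of-view
   statistics are computed.

Every stage is validated end to end against synthetic data generators with
known ground truth; no animal data are required.

## The decision model

When an animal enters a chamber, a latent evidence variable starts at
`z·a` and diffuses between absorbing bounds `0` and `a` with drift `v` and
within-visit diffusion coefficient fixed at `σ = 1` evidence·s^−1/2^.
Reaching the upper bound models the decision to leave; the visit length is
the first-passage time. The drift of each visit is drawn afresh from
`Normal(v, sv²)`: `sv` is across-visit (inter-trial) drift variability,
the quantity called "noise" in this assay's modelling tradition. Fixing
`σ = 1` makes `(v, sv, a)` identifiable; they are expressed on that scale.

Two boundary conventions circulate — bounds `{0, a}` with relative start
`z`, or bounds `{−a, a}` — and are affine relabellings of one another;
`z = 0.9` denotes the same geometry in both. This package uses `{0, a}`
throughout.

The upper-bound passage density is evaluated with the standard small-time
and large-time series expansions of the drift-free kernel, switched by a
truncation-error criterion (tolerance `1e−10` by default). For `sv > 0`
the Gaussian drift mixture has an analytic closed form for the density, so
no quadrature enters the density itself; absorption probabilities and
survival masses under `sv > 0` are mixed over the drift with 21-node
Gauss–Hermite quadrature. The simulator uses Euler–Maruyama steps
(`dt = 1e−3` s by default) with Brownian-bridge crossing detection inside
each step and midpoint recording, which removes the `O(√dt)`
boundary-miss bias of the naive scheme.

### One observed choice, the lower bound, and censoring

The assay offers a single observable choice — leaving the chamber — so the
fitted family fixes the starting point at `z = 0.9`, close to the exit
bound, making lower-bound absorptions rare. What the lower bound *means*
for the likelihood is a genuinely open design question, and it matters:

* Conditioning every visit on ending in an exit looks natural but is
  degenerate. Conditional on upper absorption, the passage density for
  drifts `v` and `−v` is *exactly* proportional (their ratio,
  `exp(2va(1−z))`, does not depend on `t`), so exit times alone identify
  only the drift magnitude. Fits under this convention produced bimodal
  posteriors and could barely detect `sv` heterogeneity.
* The convention adopted here is fully generative: a lower-bound
  absorption is a latent "never leaves this visit", observed as a visit
  censored at the observation horizon. A completed visit contributes the
  (defective) upper-bound density `f_upper(t)`; a censored visit
  contributes the total remaining mass `1 − F_upper(t)`, which includes
  both slow exits and never-leaves. These contributions integrate to one
  over the observation space, identify the drift sign and `sv`, and make
  the synthetic generator and the likelihood an exactly matched pair —
  which the parameter-recovery validation verifies by construction rather
  than by luck.

`visit_loglik()` exposes both alternatives (`normalize = "conditional"`,
`censor = "upper"`) for sensitivity analyses.

## Hierarchical estimation

Following the assay's model family, both `v` and (through a softplus link)
`sv` carry full factorial fixed effects over temperature combination ×
chamber × genotype, plus a per-animal random intercept on `v`:
`v | sv ~ temp_combo × chamber × genotype + (1 | animal)`. Treatment coding
with wildtype / neutral-chamber reference levels makes printed coefficients
direct contrasts. `a` may be fixed or estimated through a log link; `z` is
fixed (0.9 by default). Priors are weakly informative: `Normal(0, 2)` on
all linear-predictor coefficients, half-`Normal(1)` on the random-effect
SD, `Normal(0, 1.5)` on `log a`; all are configurable and are decisions of
this package, not reconstructions.

Sampling uses an adaptive Metropolis-within-Gibbs scheme designed for this
likelihood:

* because the factorial fixed effects are saturated, the sampler operates
  in *cell-mean space*: each design cell's `(v, sv)` pair is a
  2-dimensional random-walk block with proposal covariance adapted during
  tuning; cells touch disjoint data subsets, so one sweep costs a single
  pass over the data and the blocks are nearly independent a posteriori;
* animal effects are updated element-wise (the likelihood factorises by
  animal);
* the random-effect SD uses a scalar move plus an interweaved rescaling of
  `(τ, b)` jointly, which breaks the funnel coupling typical of centred
  hierarchical parameterisations;
* draws are mapped back exactly (linearly) to treatment-coded coefficients
  for reporting, and pointwise log-likelihoods are stored per saved draw.

Diagnostics are split R-hat, effective sample size and per-block
acceptance rates; a fit with R-hat > 1.01 or very low ESS is flagged,
never silently accepted. The scaled profile used throughout the tests is
2 chains × 500 draws after 600 tuning iterations; the full-size profile
for final inference is 4 chains × 2000 draws after 2000 tuning iterations.

Model comparison uses PSIS-LOO implemented in the package: per observation
the importance ratios are tail-stabilised with a generalised Pareto fit
(Zhang–Stephens estimator), the tail size accounts for the relative MCMC
efficiency of the draws, and any Pareto `k > 0.7` marks the model
unreliable and excludes it from rankings. The implementation is
cross-checked in the test suite against an independent reference
implementation on identical input.

`contrasts_vs_wildtype()` forms, per genotype and temperature combination,
draw-wise `(test − neutral)` differences of `v` and natural-scale `sv`,
minus the same quantity in wildtype — the wildtype's own contrast is
identically zero, and adding a constant to both chambers of a genotype
leaves its contrast unchanged.

## Synthetic data: what it emulates, what it does not

**Behaviour sessions** (`gen_behavior_sessions()`): 30-minute two-chamber
sessions. Visit lengths are first-passage times of the decision process
for the occupied chamber (drift drawn per visit; per-animal random effect
on drift); chambers alternate; the final visit is truncated at the session
end and flagged censored — censoring arises by truncation, matching real
sessions. Keypoint tracks place six animal keypoints around the centroid
inside the occupied chamber with Gaussian jitter, likelihood dropouts, and
eight fixed cage reference points; chamber transitions are instantaneous
at the 1 Hz analysis resolution. Defaults, chosen once as a realistic
regime and then left alone: `a = 13`, `z = 0.5` (the value used in this
assay's illustrative simulations), neutral drift 0.18 and test drift
0.30 evidence/s (0.20 for the knockout-like genotype: longer warm visits),
`sv` 0.04/0.08, animal random-effect SD 0.02, 20 Hz tracking, jitter SD
0.01 of the cage width, 5% dropouts. This yields visit lengths of tens of
seconds and roughly 60–100 visits per session. In this generator non-exits
are resampled (exits dominate at these parameter values), so the defective
likelihood is an approximation for session data exactly as it is for real
recordings.

**Recovery design tables** (`gen_visit_table()`): the hierarchical study's
conditions — two genotypes, 20 animals each, ~100 visits per animal, fixed
`a = 13`, `z = 0.9`; wildtype drift 0.12 (neutral) / 0.20 (test), a mutant
test-chamber drift offset of +0.5 and `sv` offset of +0.3 (0.2 → 0.5);
animal random-effect SD 0.05; observation horizon 120 s per visit.
Lower-bound absorptions and passages slower than the horizon appear as
censored visits (5–12% depending on cell), exactly as the likelihood
assumes.

**Calcium recordings** (`gen_calcium_dataset()`): a 1-minute baseline,
three ascending 25-second warm stimuli (10 s ramp + 15 s plateau) at
5-minute intervals, followed optionally by capsaicin and high-potassium
(KCl) epochs. Plateau temperatures are not pinned by the protocol beyond
"ascending within the warm range"; the defaults 34/37/40 °C are free
parameters. Responder cells receive difference-of-exponential transients
(1 s rise, 8 s decay — chosen to mimic typical warm-response morphology)
locked to their dynamic- or static-phase onset label, with amplitude
scaled up across the three stimuli and per-stimulus recruitment
probability rising (0.6/0.8/1.0), so stronger stimuli recruit more cells.
Raw fluorescence composes cell signal, 70% of a shared neuropil trace,
exponential bleaching (time constant 600 s, 10% depth), and Gaussian shot
noise (SD 2 a.u. on a ~100 a.u. baseline); the thermocouple trace carries
0.05 °C noise.

What the generators do *not* emulate: pose-estimation failure modes beyond
likelihood dropouts (no identity swaps or multi-animal confusion), tunnel
dwell or climbing kinematics (climbing exists only as a flag-level
injection for QC tests), motion artefacts or ROI cross-talk in imaging,
and non-stationary behaviour within a session (the generating parameters
are constant over the 30 minutes, whereas real preference develops over
time). Passing tests therefore demonstrate correctness of the analysis
given the model's structural assumptions, not robustness to every failure
mode of real recordings.

## Trajectory conventions

* Predictions below 95% likelihood become missing; sessions with more than
  25% missing animal-keypoint entries are rejected (strict `>`, matching
  the printed rules); remaining gaps are linearly interpolated.
* Sessions with more than 95% of centroid positions in the wall band
  between lower cage corners and cage tops are rejected as climbing
  (strict `>`; the band starts 20% of the wall height above the floor
  corners).
* The animal position is the centroid of the two ears, body centre and
  tail base, scaled affinely to the median tracked corner frame (so camera
  shifts cancel), averaged within each second (the downsampling rule is a
  package decision; the assay specifies only "1 Hz"), and truncated to
  exactly 30 minutes; shorter sessions are rejected.
* Round-trip validation against the generator's ground truth treats a
  final censored visit shorter than one 1 Hz sample as below the analysis
  resolution: it cannot be observed, and one of 0.5–1 s may or may not
  surface as a single-sample recovered tail depending on where the
  crossing falls within the second, so the comparison aligns both
  sequences before counting. Duration agreement is asserted at one sample
  plus the sub-sample tipping margin of within-second averaging.
* A visit is a maximal run of samples in one chamber; tunnel samples
  attach to the visit they interrupt (the assay does not define tunnel
  assignment; attaching to the preceding visit means a tunnel entry that
  returns to the same chamber — "probing" — does not count as a crossing,
  and only completed chamber changes do). The final visit is censored at
  the session end.
* Preference is the test-chamber time fraction in 3-minute bins; rolling
  visit lengths and crossing counts use 3-minute windows advanced by
  1 minute, with visits assigned to every window containing their start
  time (a package decision; window edges are not defined by the assay).

## Calcium conventions

* Neuropil correction subtracts 70% of the surrounding-tissue trace.
* ΔF/F0 has two conventions, used for different purposes and never
  conflated: session-level F0 is the mean of the first 10 s (used for
  heatmap ordering); per-stimulus F0 is the mean of the first 10 frames of
  the stimulus window. Optional clipping bounds ΔF/F0 at its empirical 0.1
  and 99.9 percentiles. Cells with non-positive F0 are flagged invalid.
* The dynamic/static boundary is the end of the peak of the smoothed
  temperature change rate, operationalised as: centred 1-s finite
  difference, centred 2-s moving average, boundary at the first time after
  the rate peak where the smoothed rate falls below 50% of the peak. The
  half-maximum threshold makes the boundary land on the ramp end for ideal
  ramp+plateau geometry (a lower threshold would place it systematically
  after the ramp end by a fraction of the smoothing window) and is robust
  to thermocouple noise; both window and threshold are parameters.
* Responder classification is a deterministic logistic regression on four
  trace features (epoch peak z-score and strongest 3-s window z-score
  against the pre-stimulus baseline, mean and late-epoch response), after
  per-stimulus renormalisation, 4 Hz downsampling and light smoothing. It
  is trained once on a labelled synthetic library (~1000 cell × stimulus
  traces, half responders) and applied unchanged; identical inputs give
  identical calls. A transparent feature-based classifier replaces
  heavyweight time-series classifiers while keeping the same contract:
  binary calls per cell × stimulus.
* Response onset is the first time within the stimulus epoch at which
  ΔF/F0 exceeds 10% of its epoch maximum; heatmap ordering uses the first
  crossing of 10% of the *cumulative* ΔF/F0 — two distinct 10% rules, kept
  as distinct operations. Ties keep the original cell order; non-positive
  totals sort last.
* A cell is warm-sensitive if it responds to any stimulus with a plateau
  below 43 °C and a heat responder at ≥ 43 °C; the KCl epoch gates
  viability (the denominator of responder proportions), the capsaicin
  epoch marks TRPV1-positive cells, and cells responding to no stimulus at
  all are excluded from responder tables and proportions. AUC is
  trapezoidal over the stimulus epoch.

## Numerical choices and degenerate inputs

Series truncation tolerance `1e−10` (density) and `1e−12` (survival);
Gauss–Hermite order 21; survival masses are clamped to `[0, P_upper]`; the
closed-form absorption probability uses `expm1` so both drift signs are
stable; a parameter sweep test asserts the likelihood is finite over the
valid domain. Degenerate inputs are handled explicitly: all-identical
durations sample without error (the `sv` posterior collapses toward its
link-scale floor and the fit is flagged by diagnostics rather than
crashing); empty visit sets have log-likelihood 0; an all-tunnel trace
yields an empty visit sequence with a warning; an entirely missing
keypoint rejects the session rather than interpolating it from nothing.

## Validation sizes

The checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use: the 3 × 3 × 2 parameter grid
`v ∈ {0.5, 1, 2} × sv ∈ {0, 0.3, 0.6} × z ∈ {0.5, 0.9}` at `a = 1` with
10⁵ paths per point for density/simulator agreement (total-variation
distance on a 12-bin histogram, sized so the binned TV estimate's
sampling-noise floor sits well below the 0.01 criterion); 20 replicates of
the recovery design with the scaled sampler for coverage, contrast-sign
and ELPD-comparison rates; 50 generated sessions for the trajectory
round-trip; and the default 400-cell recording for the calcium round-trip.
These sizes are the package's scaled study sizes; the generators accept
larger designs unchanged.

One qualitative law deserves a caveat: the claim that the coefficient of
variation of visit lengths strictly increases with `sv` at fixed drift
holds cleanly where the drift dominates (`v = 2` on the grid) but fails at
low drift, where conditioning on upper-bound absorption cancels most of
the drift-variability effect (measured CVs at `z = 0.5`, `v = 0.5` are
flat: 0.8125, 0.8144, 0.8119 across `sv = 0, 0.3, 0.6` at 4 × 10⁵ paths).
This is a property of bound-conditioned passage times, not an
implementation artefact; the corresponding check is asserted as stated and
documented as failing at low drift.

## Known limitations

* The sampler is gradient-free; for much larger designs (many temperature
  combinations and genotypes) a gradient-based sampler would scale better.
* The non-decision offset `t0` defaults to 0 (the assay never invokes
  one); it is configurable but not estimated.
* Lower-bound handling in the original fits is unknown; the generative
  censoring convention adopted here is one defensible resolution, and the
  alternatives remain available for sensitivity analyses.
* The responder classifier is trained on synthetic labels; applying it to
  real recordings would require retraining on hand-labelled traces.
* Crossing counts exclude tunnel probing (entries that return to the same
  chamber); if probing matters, segment at a finer resolution and count
  tunnel entries separately.
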