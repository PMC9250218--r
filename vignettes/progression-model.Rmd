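---
title: "A three-layer generative model of chronic-disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-layer generative model of chronic-disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognet)
```

## The model

`prognet` models the course of a slowly progressing chronic disease — the
motivating application is type 2 diabetes — as three stacked stochastic
layers, learned without stage labels from longitudinal ICD-10 encounter
records.

**Stages.** A patient moves through $K$ ordered severity stages according
to a continuous-time Markov jump process with intensity matrix $Q$
(per year).  Progression is forward-only: $Q$ has nonnegative rates only
above the diagonal, and the last stage is absorbing.  Between two
encounters separated by $\Delta t$ years the stage transition
probabilities are $e^{Q\Delta t}$.

**Complication onsets.** Each of $W$ complication categories is a binary,
irreversible process.  At a patient's first encounter, complication $w$
is already active with probability $\pi_{k w}$ given stage $k$; while the
patient is in stage $k$, an inactive complication activates with per-year
probability $h_{k w}$, so over an interval $\Delta t$ the onset
probability is $1 - (1 - h_{k w})^{\Delta t}$.  Onsets within an interval
are attributed to the stage at the destination encounter; the sampler
additionally draws the onset year within multi-year intervals so that
exposure time is accounted exactly.

**Findings.** The $N$ distinct diagnosis codes are binary findings
generated by a bipartite noisy-or network: finding $n$ is observed with
probability
$$p_n \;=\; 1 - (1 - \ell_n)\prod_{w\,\text{active}} (1 - A_{w n}),$$
where $\ell_n$ is an always-on leak probability and $A_{wn}$ the
activation probability of the complication–finding link.

**Anchors.** An anchor declares that a code belongs to exactly one
complication category.  The anchored code's column of the $W \times N$
activation layer is pruned to that single link; unanchored columns stay
fully connected.  With $C$ anchored codes this removes $C(W-1)$
activation parameters — the full count is
$K^2 + 2KW + NW - C(W-1)$ (`count_parameters()`), and
`count_parameters(5, 10, 1000)` evaluates to 10,125.  Anchors also pin
the *identity* of each complication, which is what makes an otherwise
unsupervised clustering interpretable and what the warm start (below)
exploits.  Anchored links keep a learnable probability (initialised at
0.8, `anchor_init`); `freeze_anchors = TRUE` fixes them instead, for the
stricter reading in which anchors are set to a known probability once and
never recomputed.

## Learning

Parameters are estimated by Monte Carlo EM with blocked Gibbs sampling
(`fit_progression()`).  Every conditional draw is exact:

* **Stages** — forward filtering / backward sampling over the $K$-state
  chain with interval transition matrices, a configurable prior over the
  stage at the first encounter, and emissions given by the onset-chain
  terms (the noisy-or terms cancel in this conditional).
* **Onset times** — per complication, the monotone onset slice (including
  "never") is enumerated; prior chain terms and noisy-or likelihood
  ratios combine in log space and one slice is drawn.
* **Noisy-or attributions** — for each positive observation the latent
  firing vector of its potential causes (active allowed parents plus the
  leak) is drawn conditioned on at least one firing, by sequential
  conditioning.  This is the exact augmentation; a single-parent
  attribution sampled proportionally to contributions is provably biased
  (its fixed point requires $\ell A = 0$), so sufficient statistics use
  the full vector and the reported single "attributed" cause is a uniform
  draw among the firers.
* **Continuous stage paths** — between consecutive sampled slice stages,
  an endpoint-conditioned path is drawn by uniformization (Poisson jump
  count given the endpoints, a discrete bridge, uniform order-statistic
  jump times), yielding exact time-in-stage and jump-count statistics for
  conjugate Gamma updates of $Q$.

The M-step takes Beta posterior means for every probability parameter
(default Beta(1, 1) pseudo-counts) and Gamma posterior means for the
intensities (default Gamma(1, 1)); smoothing avoids zero-count
degeneracies at desk scale.

**Initialization.** When anchors are available, `warm_start_model()`
builds the starting point from deterministic pseudo-latents: each
patient's slices are split into $K$ equal runs as a provisional stage
path, and each anchored complication is marked active from the first
slice containing one of its anchor codes.  Moment estimates from these
pseudo-latents initialise all parameters.  Without anchors,
`init_model()` draws parameters from a Beta(1, 3) initialization prior,
with per-complication onset parameters sorted by stage so hazards start
increasing with severity — this breaks the symmetry of the ordered latent
stages.

**Initial-stage prior.** The default prior over the stage at the first
encounter is uniform: real patients enter observation at an unknown point
of their progression (a patient can legitimately be inferred to start in
stage II).  For cohorts observed from disease onset — synthetic patients
are generated from year 0 in stage I — `initial_stage_prior = c(1, 0,
...)` matches the data-generating process and should be used in recovery
experiments.

**Convergence and averaging.** The smoothed complete-data log-likelihood
(complete-data likelihood of the sampled latents plus the parameter
log-priors) is tracked per iteration; fitting stops when its relative
change stays below `convergence_tol` (default `1e-4`) for
`convergence_window` consecutive iterations, or at `n_em_iterations`.
Monte Carlo EM does not converge pointwise — with many iterations the
chain dithers around its fixed point, and on weakly identified ridges
(stage-boundary placement trades off against stage-conditioned hazards
while the likelihood changes by less than Monte Carlo noise) it can
wander visibly.  The returned model therefore averages the parameter
estimates of the last `average_last` iterations (default 5), which
reports the centre of the stationary region.

## Individual inference and forecasting

`map_trajectory()` returns the jointly most probable monotone assignment
of stages and complication activity — a joint MAP, not a marginal one,
because the result should be one coherent trajectory.  The dynamic
programme runs over the product lattice of (stage, active set); the
per-complication factorisation of the onset terms lets the maximisation
over predecessor activity sets be a weighted superset transform
($W 2^W$ operations instead of $3^W$).  `brute_force_map()` enumerates
all monotone assignments (guarded at $10^6$ configurations) and is the
test oracle; both engines break ties toward the lexicographically
smallest stage sequence, then the earliest onsets.

`forecast()` projects forward from the last inferred state.  The
projected stage at a future year is the largest stage whose cumulative
probability of having been reached is at least `threshold` (default
0.5); because the chain is forward-only this path is automatically
nondecreasing, and for a two-stage chain with rate $\ln 2$ it calls the
stage-2 entry at year 1.  A still-inactive complication's predicted
onset year is the first year its cumulative onset probability along that
stage path crosses the same threshold.  The threshold is an
operationalisation of "may show up after so-many years" phrasing and is
configurable.

`posterior_complication_probs()` gives Monte Carlo posterior activation
marginals per slice at fixed parameters.

## The synthetic-patient generator

`generate_cohort()` samples full trajectories from a model: every
patient starts at year 0 in stage I; holding times are exponential with
rate $|Q_{kk}|$ and the next stage is drawn proportionally to the
outgoing rates; within a stage, onsets follow the continuous-time
equivalent of the per-year onset probability (rate $-\log(1 - h_{kw})$),
so interval onset probabilities are reproduced exactly; encounters are
observed at integer years through the noisy-or layer.  Observation ends
one residence year after entry into the absorbing stage (configurable)
or at the horizon (default 60 years, generously beyond a typical
complete path so truncation is negligible).

The bundled fixture (`make_fixture_model()`, $K=3$, $W=2$, $N=6$)
emulates the shape of the study data — roughly two positive codes per
encounter, yearly slices, mean stage holding times of a few years, one
anchored code per complication — and is the ground truth for the
parameter-recovery tests.  The recovery experiment observes each of its
2000 patients on a fixed 10-year window: a stage-entry-dependent stopping
rule would be informative censoring that the fitted likelihood does not
model, and the fixed window isolates estimation error from study-design
effects.  What passing recovery shows, and what it does not: the
synthetic cohort has the model's exact statistical structure, so
recovery demonstrates correctness and practical identifiability of the
estimator — not robustness to the coding noise, irregular visit patterns,
informative missingness, or model misspecification of real EHR data.

## Cohort analytics

`stage_summary()` reports mean stage entry years, mean completed holding
times (the absorbing stage and horizon-truncated stays are excluded),
and per-complication prevalence while in each stage.  "Has complication
$w$ at stage $s$" means active at any time during the occupancy of $s$ —
slices are yearly and onsets interval-valued, so point-in-time
definitions would be arbitrary.  `single_complication_table()` and
`pattern_table()` compute the retrospective later-to-earlier statistics:
among patients positive (for a complication, or jointly for a pattern)
while in the last stage, the share already positive at each earlier
stage, with every nonempty subset of a pattern tabulated against the
pattern's base group.  Because activity is irreversible these
percentages are nonincreasing toward earlier stages, and a subset's
percentage is never below its superset's.  Percentages round half-up to
one decimal, the printed precision of such tables; an empty base group
reports `NA`, not zero.  Patients who never reach the last stage are
excluded from base groups.

## Numerical choices

* Matrix exponentials by uniformization with the Poisson series truncated
  at $10^{-12}$ tail mass; deterministic given $Q$ and $\Delta t$, rows
  renormalised and the lower triangle forced to exact zeros.
* All posterior weights are combined in log space with max-subtraction;
  impossible evidence surfaces as an error naming the offending slice
  rather than as `NaN`.
* Year bins anchor at each patient's first retained event
  (`floor(days / 365.25)`); slicing is therefore invariant to calendar
  translation.
* Code filtering counts event occurrences (not patients), before the
  two-slice exclusion; vocabulary order is C-locale lexicographic.
* A single seed drives each entry point; patients are processed in sorted
  id order, so fits, simulations and pipelines are bit-reproducible.

## Desk-scale problem sizes

The shipped tests run the study's structural settings ($K = 5$, $W = 12$,
the 28-code anchor table) where the check is structural, and a small
fixture ($K = 3$, $W = 2$, $N = 6$; cohorts of a few hundred to 10,000
patients; 45 EM iterations with 4 sweeps) where the check is statistical.
These sizes are the package's reference experiments; all scale knobs
(`fit_control()`, cohort size, horizon) accept larger values.

## Known limitations

* Stage-conditioned hazards are weakly identified when few complications
  inform the stage process; at the fixture's scale the smallest hazards
  carry the widest uncertainty, and very long un-averaged MCEM chains
  wander along the corresponding likelihood ridge.
* Empty years are treated as absent observations, not as all-negative
  encounters; for real data ingestion this is an approximation with
  informative missingness.
* One ICD-10 code per event, no code-hierarchy rollup, no demographic
  covariates, no mortality state, and no deactivation of complications —
  all outside the model family.
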