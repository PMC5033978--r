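---
title: "Modeling and estimating motor-memory decay in error-clamp trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and estimating motor-memory decay in error-clamp trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(clampdecay)
library(dplyr)
```

## The scientific question

When people reach through a velocity-dependent force field, they build a
motor memory that compensates for the perturbation. That memory can be read
out with *error-clamp* (EC) trials: a stiff virtual spring-damper channel
constrains the hand to a straight line, and the lateral force the hand
pushes into the channel wall — normalized by peak speed, the *Force at Peak
Velocity* (FPV, N·s·m⁻¹) — measures how much compensation is still being
expressed. Over a run of EC trials the memory decays. The question this
package operationalizes is whether that decay is purely passive, or whether
the *visual feedback available during the clamp* actively drives unlearning:
a cohort is split into three feedback conditions for EC trials — an
expanding **arc** (distance information only, no direction), a veridical
straight **cursor**, and an **augmented-error** cursor that follows a path
curved 1 cm to the left — and the per-condition decay rates are estimated
and compared.

Because no raw data from the original experiment are available, the package
pairs the estimation machinery with a calibrated synthetic-cohort generator,
so the full analysis can be exercised, validated, and power-checked end to
end.

## The trial protocol

`build_schedule()` constructs the experiment plan: 192 familiarization
trials, then 617 trials in 22 blocks — a baseline null block N1, ten
force-field blocks of 18 field trials each, ten 30-trial EC blocks, a
45-trial washout N2, and the recall probe EC10 placed immediately after
washout (order N1, FF1, EC1, …, FF9, EC9, FF10, N2, EC10). Small numbers of
*interspersed* error-clamp trials (IEC) probe adaptation inside N1 and each
FF block; they are placed pseudo-randomly but never in a block's first three
trials, so block-entry behavior is field-driven.

The published totals pin down 192/617/22/18/30, but not the individual N1,
N2 and IEC counts. The defaults — N1 = 66 null + 6 IEC, 2 IEC per FF block,
N2 = 45 — are an explicit assumption chosen to satisfy the printed totals;
every count is configurable through `protocol_config()`.

## The simulator

Two fidelity tiers share one learner.

**Trajectory tier.** The hand is a 1 kg point mass tracking a minimum-jerk
reference with a PD controller (`kp` = 300 N/m, `kd` = 35 N·s/m) plus exact
feedforward of the reference acceleration, integrated at 1 kHz. The
environment follows the trial phase: nothing (null), the clockwise curl
field `F = (g·vy, −g·vx)` with `g` = 15 N·s/m, or the channel
(5000 N/m, 30 N·s/m) in which lateral tracking is ceded to the wall. The
learner contributes an anticipatory lateral force `−z·g·vy`, so on channel
trials the wall-force readout at peak velocity equals `−z·g` to within a few
tenths of a percent (the basis of the readout-consistency tests).

The reference duration (765 ms) deserves a note: movement time is measured
from the 2.25 cm onset radius to arrival within 0.75 cm of the target, a
window that spans only ~52% of a minimum-jerk profile, so a 765 ms reference
yields a *measured* movement time of ~400 ms — the middle of the instructed
400 ± 50 ms window. Per-trial duration jitter (12%) gives a movement-time SD
of ~48 ms, which puts the probability of landing in the 350–450 ms success
window near 0.70, matching the published recall-block success probability
(0.70 ± 0.17).

**Fast tier.** For statistical work (hundreds of replicate cohorts) the
metric-level tier skips the physics and generates the per-trial metrics
directly from the learner state: FPV = `−g·z` + Gaussian execution noise
(SD 1.4 N·s·m⁻¹, chosen to match within-block FPV variability of order
1–2), movement times from the calibrated N(400, 48) distribution, and
directional errors from the normalized lateral deviation. Both tiers are
deterministic given `(seed, group)`.

**The learner.** A standard two-state model: fast and slow compensation
states with `z_i ← retention_i·z_i + learn_i·error`, retention
(0.92, 0.996) and learning gains (0.08, 0.01), behavioral compensation
`z = z_fast + z_slow` (clipped to [−0.5, 1.5]). On field and null trials the
error is the signed lateral deviation at peak velocity normalized by reach
length (measured from the path in the trajectory tier; `(field − z)·d_field`
with `d_field` = 0.12 in the fast tier).

The error-clamp error model is the package's central modeling decision. The
hand runs straight in the channel, so the only usable error is the mismatch
between the trajectory the adapted motor system *predicts* and the visual
feedback it *receives*. We model this mismatch as proportional to the
adaptation state itself:

* arc — no trajectory feedback, error 0: decay is passive, retention-only;
* cursor — error `−z · clamp_error_scale`: an adapted system predicts a
  curved path, the clamped cursor shows a straight one, and the mismatch
  grows with adaptation;
* augmented — the cursor's leftward arc adds its normalized mid-reach offset
  (1 cm / 15 cm) on top, so the error is nonzero even for an unadapted
  learner.

Two alternatives were considered and rejected. An error proportional to
`(1 − z)` (the *residual* expected deviation) is dynamically unstable: the
error grows as the state falls, so every feedback condition diverges past
zero to the clip — and it contradicts the observation that the cursor
condition's unlearning *accelerates* as adaptation builds up. An error
proportional to `z·d_field` alone is stable but far too weak: the slow
state's drain per trial would be ~0.0005·z, and the cursor condition would
be indistinguishable from the arc. `clamp_error_scale` = 2 was calibrated
once, by a small sweep, against the published group decay rates: the
defaults give fitted rates of about −0.08 (arc) and −0.26 (cursor), matching
the published −0.08 and −0.26, with the augmented condition near −0.28
(published −0.25).

**Between-participant variability.** Retention factors, learning gains,
deviation scale and clamp-error scale are jittered per participant
(`cohort_params()`), which is what gives the subsampling bootstrap a
non-degenerate distribution.

**What the generator does not emulate.** (1) The learner has a single
shared slow state, so unlearning during EC blocks also lowers measured
re-adaptation in the cursor/augmented groups, whereas the original study
found statistically indistinguishable adaptation across groups; reproducing
that would require the multi-context (environment-gated) recall model,
which is out of scope. (2) No arm biomechanics, no visual feedback delay, no
reinforcement-learning module. (3) Peak-velocity distributions and force
profiles beyond the calibration targets are unconstrained by the source
study and should not be over-interpreted. Passing tests therefore validate
the estimation machinery and the qualitative feedback-condition effects, not
trial-level realism.

## Trial metrics

Onset is the first sample at least 2.25 cm from the start center; end the
first sample within 0.75 cm of the target center (both inclusive at the
boundary — on a 1 ms grid the difference from a strict inequality is at most
one sample). Movement time is end minus onset; a trial whose thresholds are
never crossed carries a `failure_flag` and is excluded from block means and
success counts (but logged and imputed in decay series). Peak velocity is
the maximum of speed `|v|` (not of the forward component), earliest sample
on ties. Directional error is the signed angle between the onset→target
vector and the onset→position-at-peak-velocity vector, clockwise positive;
both signed and absolute block means are exported. The success window
350–450 ms is inclusive at both ends. FPV is defined only on channel trials
and requires peak speed above 0.05 m/s.

## Decay-rate estimation

The per-participant decay series averages FPV at each within-block position
across EC1–EC9, giving one 30-point series per participant
(`ec_series()`); failed trials are imputed with the same-position mean of
the remaining blocks, and the imputation count is reported.

`fit_exponential()` fits `y = a·e^(b·x) + c` by least squares with `x` the
1-based trial position. Numerically, (a, c) are linear given b and are
profiled out exactly, so the problem reduces to one dimension: b is located
on a deterministic 61-point grid over [−5, 0.5], refined by Brent search
(tolerance 1e−10) and polished by damped Gauss–Newton on all three
parameters. The procedure is deterministic, recovers noiseless model data to
machine precision, and needs no starting values — which matters when the
resampling layer requests tens of thousands of fits. A constant series is
degenerate (`a = 0`, `c = mean(y)`, `b` pinned at 0, `converged = FALSE`).
The 1-based `x` convention affects only the `a` ↔ `a·e^b` factorization,
not b or c.

`compare_decay()` implements the group comparison: all `choose(15, 12) =
455` subsets of each group are enumerated exhaustively in lexicographic
order; subset *i* of group A is paired with subset *i* of group B (the
pairing is a convention — any fixed pairing yields the same marginal
distributions); each subset's pointwise-average series is fitted, and the
per-iteration differences in initial state (a + c), rate (b) and asymptote
(c) form the bootstrap distribution. On the same iteration the 24 selected
participants are relabeled at random into two pseudo-groups and refitted,
forming the permutation distribution. The p-value per parameter is the
proportion of permutation differences exceeding the mean bootstrap
difference, compared on absolute values (two-sided) by default; the
literal one-sided rule is available via `tail = "greater"`. p-values are
therefore multiples of 1/455. For replicated calibration studies,
`max_subsets` thins the iterations by seeded sampling without replacement.

## Problem sizes used by the test suite

The suite validates null calibration with 200 replicate fast-tier
experiments of two 15-participant pseudo-groups drawn from one generator,
thinned to 100 subsets per comparison, and checks that the rejection rate of
p ≤ 0.05 for the rate difference stays near the nominal level; the
feedback-effect checks use 20 replicate three-group cohorts with the full
455-subset procedure. These sizes give Monte-Carlo error small enough for
the stated acceptance bands while keeping the default `devtools::test()`
run in the low minutes.

## A complete run

```{r, eval = FALSE}
res <- run_pipeline(default_config(), seed = 1, out_dir = "results")
res$fit_report$groups          # per-group subsample fit distributions
res$fit_report$comparisons     # three pairwise comparisons, p per parameter
```

```{r, fig.alt = "Group-average decay of the force at peak velocity"}
tab <- simulate_cohort(default_config(), seed = 1)
plot_ec_decay(ec_series(tab))
```

## Known limitations

Group-level *magnitudes* (asymptotes, initial states) depend on the
calibration constants and should be read qualitatively; only the protocol
constants, the combinatorics, the fit/permutation machinery and the
direction and separation of the feedback-condition effects are asserted by
the tests. The permutation p-value inherits the original procedure's
granularity (1/455) and its one-sided-versus-absolute ambiguity, which the
`tail` switch makes explicit.
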