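# clampdecay

Motor memories formed during force-field adaptation decay when the
perturbation is removed. `clampdecay` is an R package for studying that
decay as it is measured in *error-clamp* (channel) trials, where a stiff
virtual spring–damper wall constrains reaches to a straight line and the
lateral force pushed into the wall — normalized by peak speed, the **Force
at Peak Velocity** (FPV, N·s·m⁻¹) — reads out the remaining compensation.
The package is aimed at sensorimotor-control researchers who want to
simulate force-field/error-clamp cohorts under different visual-feedback
conditions, extract the standard trial metrics, and estimate and compare
decay rates with a resampling procedure that is robust to unstable
individual-participant fits.

## What it computes

The decay of the group-average FPV across a 30-trial error-clamp block is
modeled as a single exponential

> y = a·e^(b·x) + c

with amplitude *a*, per-trial decay rate *b*, asymptote *c*, and initial
state *a + c* (x = 1, …, 30 is trial position). Because individual fits are
unstable, inference uses an exhaustive **subsampling bootstrap**: all
C(15, 12) = 455 subsets of each 15-participant group are enumerated, each
subset's average series is fitted, and per-iteration parameter differences
between groups form the bootstrap distribution. A **permutation test**
relabels each iteration's 24 participants into two random pseudo-groups and
refits; the p-value per parameter is the proportion of permutation
differences exceeding the mean bootstrap difference.

The package also contains the full surrounding pipeline: the 617-trial /
22-block alternating protocol builder, a two-tier cohort simulator (full
1 kHz point-mass trajectories through curl field and channel, or a fast
metric-level tier sharing the same two-state learner), per-trial metric
extraction (movement time, directional error, FPV, success), and block-level
summaries exported in tidy long format for external ANOVA software.

## Worked example

```r
library(clampdecay)
library(dplyr)

# Simulate the default cohort: 3 feedback groups (arc / cursor / augmented)
# x 15 participants x 809 trials, fast tier
tab <- simulate_cohort(default_config(), seed = 1)

# Per-participant 30-trial decay series (FPV averaged across EC1-EC9)
s <- ec_series(tab)

# Fit the arc group's grand-average series
arc <- filter(s, group == "arc") |>
  group_by(position) |> summarise(force = mean(force))
fit_exponential(arc$force)
#> Single-exponential decay fit: y = a*exp(b*x) + c
#>   a = -1.51, b = -0.09944, c = -0.7249  (initial state a+c = -2.235)
#>   r^2 = 0.9260 on 30 points; converged: TRUE

# Full bootstrap + permutation comparison of two feedback conditions
compare_decay(s, "arc", "cursor", seed = 1)
#> Decay comparison: arc vs cursor (455 iterations, k = 12, absolute tail)
#> # A tibble: 3 x 3
#>   parameter     mean_diff      p
#>   <chr>             <dbl>  <dbl>
#> 1 initial_state    -0.361 0.281
#> 2 b                 0.162 0.0176
#> 3 c                -0.651 0.0220
```

Read: the two groups start from a statistically indistinguishable initial
state (p = 0.28), but the arc group — which receives no trajectory feedback
during the clamp — decays more slowly (its rate *b* is 0.16 per trial less
negative, p = 0.018) and retains a more negative asymptote (p = 0.022):
visual feedback during error-clamp trials actively speeds unlearning.

`run_pipeline(config, seed, out_dir = "results")` executes the whole chain
(simulate → metrics → summaries → decay fits → all three pairwise
comparisons) and writes the trial table, block summaries, subsample fits,
difference samples, a JSON fit report, and the configuration echo. A thin
command-line wrapper with `run` / `simulate` / `analyze` / `validate`
subcommands is installed at `inst/cli/clampdecay`.

## Package layout

- `R/protocol.R` — trial schedule construction and validation
- `R/simulate.R`, `R/cohort.R` — physics primitives, trial integrator,
  two-state learner, cohort tiers
- `R/metrics.R` — per-trial metric extraction
- `R/decayfit.R` — exponential fit (variable projection), subsampling
  bootstrap, permutation comparison
- `R/summaries.R` — block-level summaries and tidy exports
- `R/pipeline.R`, `R/config.R`, `R/plots.R` — orchestration, configuration,
  ggplot2 visualization
- `vignettes/motor-memory-decay.Rmd` — the model, its assumptions, numerical
  choices and limitations
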