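---
title: "Modelling reciprocal sleep-smartphone dynamics from wearable and screen-time data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reciprocal sleep-smartphone dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

Whether evening smartphone use harms sleep is contested: cross-sectional
associations are weak and inconsistent, and the causal arrow may run both
ways (poor sleep can also drive more phone use). Distinguishing these
stories requires intensive longitudinal data — the same people measured
daily — and a model that separates two very different quantities:

* **within-person dynamics** — on a day a person uses their phone more than
  *they usually do*, do they sleep more or less that night, and what happens
  the next day?
* **between-person differences** — do people who habitually use their phone
  more sleep habitually less?

`sleepscreen` implements a complete pipeline for such a study design:
14 consecutive days of smartwatch sleep staging (awake / REM / core / deep),
watch step counts, and phone screen-time reports per participant. Six
person-day variables are built: total smartphone use (TSU), smartphone use
in bed (SUiB), and total / core / deep / REM sleep, all in seconds.

## Pipeline overview

1. **Ingestion** (`read_sleep_xml()`, `read_steps_xml()`,
   `read_usage_table()`, `pseudonymize()`): the watch export dialect is
   parsed with both stage-resolved and legacy sleep vocabularies (legacy
   unspecified "asleep" maps to core, the closest stage; "in bed" records
   are recognized but are not sleep stages and are counted separately);
   timestamps carry their own UTC offsets and are re-expressed in a single
   configured study timezone (default Europe/Brussels) because all nightly
   rules are clock-time rules. Screen time enters as a hand-coded CSV of
   daily totals and hourly seconds — the computational boundary starts at
   the coded table, as the source reports are screenshots coded by hand.
2. **In-bed inference** (`epoch_steps()`, `detect_inbed()`): described below.
3. **Panel construction** (`aggregate_sleep()`, `compute_tsu()`,
   `compute_suib()`, `build_panel()`, `filter_missing()`).
4. **Decomposition and imputation** (`decompose_panel()`, `impute_panel()`).
5. **Model fit and diagnostics** (`dsem_spec()`, `dsem_fit()`, `vif()`,
   `ppc_mean()`, `loo_compare()`).
6. **Synthetic generator** (`synth_config()`, `simulate_panel()`,
   `calibrate_between()`, `simulate_raw()`): every stage above is testable
   without access to any real cohort.

## In-bed detection from step counts

Step records are rastered onto a 10-minute epoch grid, apportioning each
record's steps proportionally to temporal overlap. Epochs never touched by
any record are *missing*, not zero — but inside a nightly search window a
coverage gap is read as inactivity evidence (a quiet watch), while a window
with no coverage at all yields a missing night.

Within each nightly window (default 20:00 to 12:00 the next day, spanning
midnight) the detector finds the longest sustained run of low-activity
epochs (fewer than 5 steps). Interior activity bursts short enough are
absorbed as wake-after-sleep-onset (WASO); a sustained burst confirms a bed
exit and terminates the run. All thresholds live in `detector_params()`:

| parameter | default | meaning |
|---|---|---|
| `epoch_minutes` | 10 min | raster resolution |
| `low_step_threshold` | 5 steps/epoch | low-activity cut |
| `window_start` / `window_end` | 20:00 / 12:00 | nightly search window |
| `min_inbed_hours` | 3 h | minimum interval duration |
| `max_waso_epochs` | 3 epochs (30 min) | longest absorbable burst |
| `confirm_exit_epochs` | 3 epochs (30 min) | activity run confirming an exit |

With both burst cuts at 3 epochs the rules overlap at a burst of exactly 3;
exit confirmation takes precedence (bursts of 1-2 epochs are WASO, 3 or
more end the interval). The detector is property-tested against a
brute-force enumeration of all candidate spans under the same rules, and
one interval is kept per night (the longest; ties to the earliest) because
the analysis models one nightly in-bed period. A night is indexed by the
evening's calendar date, so the same-day ordering "daytime use -> evening
in-bed use -> night sleep" is temporally coherent.

## Panel variables

Sleep-stage records are assigned to the nightly window containing their
midpoint; overlapping same-stage records are merged (union) before
summation; awake time is excluded and total sleep = REM + core + deep.
In-bed use prorates each clock hour's coded seconds by the fraction of the
hour covered by the interval (usage is taken uniform within the hour) and
is capped at the day's total use. Participants with 7 or more missing days
on either the sleep block or the screen-time block are excluded (the rule
is inclusive at exactly 7).

## Decomposition, lags, and standardization

Each variable is split into a between component (person mean, centered at
the grand mean of person means) and a within component (daily deviation
from the person's own mean), with the lag-1 copy decomposed against the
lagged series' own observed mean (days 1..13) — distinct from the current
series' mean, because both are observed means, not latent quantities. The
current series is centered on all its observed days; day-1 rows drop out of
the lagged design.

Standardization is the one place where a design choice materially shapes
the coefficient scale. Design columns are standardized per level: within
columns by the pooled within-person SD, between columns by the SD of person
means. The *outcome* is standardized by its **total** SD over design rows —
exactly what scaling every column of the model frame produces. Two
consequences are worth spelling out:

* a within path equals the within-standardized regression slope shrunk by
  the outcome's within/total SD ratio, and a between path equals the
  between-level slope shrunk by the between/total ratio — both levels share
  one interpretable scale;
* had the outcome instead been standardized per level, the between-level
  "stability" coefficient (person mean of a series regressed on the person
  mean of its own lagged copy) would collapse to the correlation of two
  13-day overlapping means of the same series. That correlation has a
  mechanical floor around 0.9 — the two means share 12 of their 13 days —
  regardless of how small the trait variance is, making moderate published
  stability values unrepresentable. Total-SD outcome scaling removes the
  artifact because the between share of the outcome's variance enters the
  coefficient.

## The two-level model and its estimation

For each outcome \(y\), with \(i\) indexing persons and \(t\) days,

\[
y_{it} = \alpha_i + \sum_k \beta^W_k\, x^W_{k,it} + \sum_k \beta^B_k\, \bar x^B_{k,i} + \varepsilon_{it},
\qquad \alpha_i \sim N(0, \tau^2),\ \varepsilon_{it} \sim N(0, \sigma^2),
\]

where the within columns are the own lag plus cross paths at their
specified timing, and each has a matching person-mean column at the between
level. Timing rule: autoregressive paths are lagged; TSU and SUiB act on
all sleep outcomes the same day, and TSU on SUiB the same day; every other
cross path is lagged. The current paths are recursive in the causal order
TSU -> SUiB -> sleep, so no cycles arise. Model 1 carries
(total sleep, TSU, SUiB); Model 2 replaces total sleep by the three stages.

Estimation is Gibbs sampling with fully conjugate conditionals:
\(\beta \sim N(0, 10^2)\) per standardized coefficient, and
half-Student-t(3, 0, 2.5) priors on \(\sigma\) and \(\tau\) via the
inverse-gamma scale-mixture representation. "Uninformative" priors are
instantiated as these weakly-informative defaults because truly flat priors
harm sampling; on standardized data they are effectively flat. Two chains
of 5000 iterations (half warmup) per outcome, per imputation. Residuals
across outcomes are independent given the random intercepts — a documented
limitation rather than an option, as is the absence of random slopes.

Missing cells are completed by chained-equation imputation (m = 5): normal
linear conditionals on the same-day values of the other variables, the
person's observed mean, and day-of-week indicators, with parameter
uncertainty drawn per sweep; imputation operates on the raw panel and the
decomposition is recomputed per completed panel so centering always uses
observed-scale means. Imputations are pooled by concatenating posterior
draws — the Bayesian analogue of pooling — and chain seeds derive from the
completed data's content, so pooled results are invariant to imputation
order. Convergence is monitored with rank-normalized split R-hat (flagged,
never thrown, at 1.01); significance is the 95% credible interval excluding
zero; collinearity via VIF on the within design; absolute fit via posterior
predictive checks on outcome means; model comparison via hand-rolled
PSIS-LOO (generalized-Pareto-smoothed importance ratios, profile-likelihood
tail fit), with pointwise contributions summed over outcomes per
participant-day and averaged across imputations.

## The synthetic generator

The generator is the exact generative mirror of the fitted model. Per
person, stable traits and a lag-1 structural VAR (contemporaneous matrix
strictly lower-triangular in the causal order) run on a Gaussian latent
scale with unit stationary variance, are combined with a per-variable
between/within variance ratio (ICC), and map to non-negative duration
seconds through a softplus transform whose latent mean/SD are solved
numerically (Gauss-Hermite quadrature) so the observed margins match the
configured anchors exactly. Defaults reproduce the study conditions:
68 participants, 14 days, anchors TSU 3.85/2.34 h, SUiB 0.54/0.73 h, total
sleep 7.30/1.38 h (core 4.98/1.16, deep 0.73/0.35, REM 1.55/0.57), and
day-level MCAR missingness of 5% per block (the residual missingness of a
retained participant is not reported in the source; 5% is a realistic
choice fixed once). The softplus latent scale is used because raw seconds
would need heavy truncation that biases recovery; in-bed use is additionally
capped at total use, the cap's anchor distortion is corrected by solving the
in-bed anchor against the *capped* margin over the exact joint latent
normal, and cap frequency is counted in the truth record (flagged when it
exceeds 5% of days).

Three design choices reduce Monte-Carlo noise so that a single simulated
cohort carries the population structure rather than a noisy draw of it —
standard variance-reduction, fixed before any acceptance measurement:

* traits and innovations are drawn as random permutations of the exact
  standard-normal quantile grid (stratified marginals), so nonlinear
  functionals of the draws also sit at their population values;
* columns are recentred and whitened to exact first and second moments;
* each day's innovations are orthogonalized in-sample against the traits
  and the previous state, enforcing the population moment conditions
  \(E[e_t] = 0\), \(\mathrm{Cov}(e_t, w_{t-1}) = 0\), \(\mathrm{Cov}(e_t, u) = 0\)
  exactly in every finite cohort.

Because the configured coefficients are interpreted on the observed
standardized scale while the dynamics run on the latent scale,
`calibrate_between()` closes the loop: it tunes the per-variable ICCs to
the between-level stability targets and refines the latent coefficient
matrices until the population fitted paths (large-N simulation with common
random numbers, OLS as the probability limit of the Bayesian fit) match the
configured targets, typically to within 0.01-0.015. Between-level structure
is an independent trait per variable rather than explicit between
regressions — stability coefficients are not directly parameterizable
without circularity — and a stability target below the feasible floor
(overlapping person means of the same series retain a positive association
even with zero trait variance) is reported as such in the calibration
record; targets at or beyond |1| are rejected.

What the generator does **not** emulate: circadian texture beyond the
day/night activity contrast, realistic WASO placement, app content,
non-MCAR missingness, and any measurement error in the watch's sleep
staging (stages are taken as given). Tests passing on synthetic data
therefore validate the pipeline's arithmetic and the estimator's
statistical behaviour, not the watch's classifier or the MCAR assumption.

## Numerical choices and degenerate inputs

* Epoch apportionment uses exact interval overlap; zero-length step records
  land in their start epoch.
* Stationarity of the implied within transition matrix is enforced at
  configuration time (spectral radius < 1); residual SDs giving unit
  stationary variance are found by fixed-point iteration to 1e-10.
* Tie-break for equally long in-bed runs: the earliest wins.
* A constant MCMC chain yields R-hat `NaN` (flagged) rather than an error;
  duplicated design columns yield VIF above 1e6 with a flag.
* Imputed durations are floored at zero; a variable with no observed values
  is an error.
* The panel interchange CSV rounds seconds to integers; a read-write cycle
  is byte-identical.

## Problem sizes

Recovery experiments run at the study's native size (N = 68, T = 14; 2
chains x 5000 iterations; m = 5), with generator calibration measured on
6000-person populations. The test suite's property checks use 10-120
random fixtures per invariant, replicate-study checks 8-20 studies at
reduced iteration counts, and the raw-stream round trip an 8-16 person
subset — sizes chosen so the full suite exercises every code path at
meaningful scale while remaining quick to run routinely.

## Known limitations

* The in-bed detector's defaults encode common actigraphy practice; the
  source design states only the qualitative rule, so absolute parameter
  values are conventions, config-exposed and sensitivity-testable.
* Observed-mean centering at T = 14 leaves small-sample artifacts (the
  -1/(T-1) autocorrelation of within deviations); latent-centering DSEM as
  in specialized SEM software is out of scope.
* Between-level cross paths are generated as zero (independent traits);
  only stability targets are calibrated.
* No residual correlations across outcomes and no random slopes.
* LOO comparability across models with different outcome sets inherits the
  usual caveat that pointwise densities sum over different outcome blocks;
  comparisons here are made on a common cohort and reported with their SE.
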