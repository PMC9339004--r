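---
title: "Modeling evidence accumulation in parietal cortex: behavioral weights and convolutional Poisson GLMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling evidence accumulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and its algebra

The package models a sequential probabilistic-reasoning task. A subject
fixates; a red and a green saccade target appear (one inside the recorded
neuron's response field, `T_in`); 533 ms later six colored shapes are shown
in sequence, each for 333 ms with a 133 ms gap (epoch pitch 466 ms). Each
shape carries a fixed *assigned weight* $W$ on the base-10 log-odds scale,
and each target's probability of paying a large reward is the base-10
logistic of the summed weights of the same-colored shapes:

$$P(\mathrm{large} \mid s) = \frac{10^{s}}{1 + 10^{s}},
\qquad s = \sum_i W_i .$$

The red and green probabilities are computed independently from their own
colors' shapes, so they do not sum to one. After a variable delay
(433/533/633 ms) the fixation point disappears and the subject reports its
choice with a saccade.

Every stimulus maps to the regressor variables of the encoding model
through a small algebra, all on the log-odds scale of the weights:

* `sw` — the shape's (subjective) weight;
* `color` — +1 red, −1 green;
* `configuration` — +1 when `T_in` is red;
* `consistency` = `color × configuration` (does the stimulus color match
  `T_in`?);
* `color_evidence` = `sw × color` (evidence for the *red* target);
* `evidence` = `sw × consistency` (evidence for `T_in`);
* `sw_in`, `sw_out` — the weight routed to the matching / opposite target;
  exactly one is nonzero and `sw_in − sw_out = evidence`.

These identities are exact by construction and are asserted bit-exactly in
the test suite. The reference frame of `color_evidence` (evidence toward
red, rather than toward the stimulus-colored target) is a convention fixed
here once; the two readings differ only by relabeling.

The running sum of `sw_in − sw_out` through an epoch is the *accumulated
evidence*, the quantity that parietal ramping activity tracks.

# Behavioral models

`fit_logit10()` is a Bernoulli maximum-likelihood fit with the base-10
logit link $P(\mathrm{red}) = 1/(1+10^{-Q})$. It is computed as a
natural-log logistic fit whose coefficients and standard errors are
divided by $\ln 10$; the equivalence is tested to $10^{-8}$. There is no
regularization: perfect separation and rank-deficient designs raise
errors (naming the collinear columns) rather than silently shrinking.

Two designs are built on this core:

* **Subjective weights** (`fit_subjective_weights`): one column per shape,
  $N_{\mathrm{red},i} - N_{\mathrm{green},i}$, the signed count of shape
  $i$'s appearances. The coefficients $\beta_{1..6}$ are the subjective
  weights $SW$ — the leverage the subject actually assigns each shape.
  The difference coding shares one coefficient across colors.
* **Epoch leverage** (`fit_epoch_leverage`): one column per serial
  position, $SW_{\mathrm{red},i} - SW_{\mathrm{green},i}$, zero for the
  color not shown. A fully used epoch has a coefficient near 1; an
  ignored epoch near 0.

`psychometric_curve()` bins trials into equal-count groups of
$\sum W_{\mathrm{red}} - \sum W_{\mathrm{green}}$ (9 bins by default; the
binning is a presentation choice) and reports red-choice fractions with
binomial standard errors.

# The convolutional Poisson GLM

Spike trains are binned at $\Delta = 10$ ms on a clock whose origin is
target onset; the model window runs from target onset to the go cue, so
bins beyond each trial's go cue are masked out (`NA` padding). Event
onsets falling inside a bin are assigned to that bin. The rate model is

$$\lambda_t = \exp\Big(\beta_0 + \sum_i (k_i * f(x_i))(t)\Big),$$

with counts $r_t \sim \mathrm{Poisson}(\Delta\lambda_t)$ and the
negative log-likelihood (dropping $\log r_t!$)

$$\mathrm{NLL} = \sum_t \big[\Delta\lambda_t - r_t \log(\Delta\lambda_t)\big].$$

Each variable has a per-lag kernel $k_i$: 150 lags (1500 ms) for
stimulus-locked variables, 300 lags (3000 ms) for target-locked ones.
Contributions of late stimuli extending past the go cue are truncated at
the end of the trial. Two regressor semantics are provided:

* **impulse mode** (default): each event places an impulse of amplitude
  $x_i$ at its onset bin and the kernel support carries the full temporal
  effect. This is the reading under which the plotted "response kernels"
  (with structure such as the early dip) are the $k_i$ themselves.
* **boxcar mode**: the amplitude is held for the variable's nominal
  duration (1500/3000 ms) from onset and convolved with a shorter kernel
  (`boxcar_kernel_lags`). This is the literal boxcar-convolution reading;
  the two cannot both be literal, so both are implemented and impulse is
  the default.

A global intercept (log baseline rate, spikes/s) is always included:
without it the baseline is only identifiable through the stimulus-onset
kernel inside its support.

## Fitting

The NLL is convex in all parameters. The default fitter is Newton /
Fisher scoring (IRLS) on the exact likelihood with the analytic gradient,
implemented in compiled code over the sparse design, with step halving on
the NLL. Kernels start at zero and the intercept at the log mean rate;
convergence is declared when the relative NLL change falls below
$10^{-9}$ or the gradient sup-norm below $10^{-6}$; non-convergence is
flagged and the partial fit returned. A quasi-Newton path
(`method = "bfgs"`, `optim` with the same analytic gradient) reaches the
same optimum and serves as an independent cross-check in the tests,
together with a dense-matrix oracle on a tiny problem.

Numerical choices: a relative diagonal damping of $10^{-8}$ is added to
the normal equations only to keep the Cholesky factorization viable when
lag columns are numerically collinear — the step still targets the exact
(unregularized) MLE, and no penalty enters the objective. IRLS weights
are capped at the count equivalent of 1000 spikes/s to stabilize early
iterations. Five-fold cross-validation (`crossvalidate`) uses seeded
trial-level folds and reports held-out NLL against the closed-form
intercept-only model.

# Shuffle-null inference

Encoding significance uses trial-shuffle nulls: a variable's per-trial
values are permuted across trials (event times fixed) and the full GLM is
refit. With several variables, one common permutation can be applied to
all of them per shuffle ("joint" mode, the cohort default), so one refit
yields a null draw for every variable while preserving their mutual
correlations; the per-variable mode of the classic procedure is the
single-variable case. The study's convention is 100 shuffles; the test
suite uses 20 for single-CPU runs.

Per lag, the observed kernel weight is converted to
$t = (\mathrm{obs} - \bar{k}_{\mathrm{null}})/s_{\mathrm{null}}$ and
tested two-tailed with $df = S - 1$ at $p < 0.01$ (the shuffle ensemble
is the only replicate structure available for a single neuron). Lags with
zero null variance are marked untestable.

## The longest-run gate, ties, and latency

A neuron is declared to encode a variable only when its longest run of
significant lags clears the null longest-run distribution, built by
testing each shuffled kernel against the remaining shuffles
(leave-one-out) — the compute-matched version of repeating the whole
procedure per shuffle. Two numerical choices matter here:

* **Tie-break.** Run durations are multiples of 10 ms, so the null run
  distribution is heavily tied; a strict exceedance rule on raw durations
  is far more stringent than its nominal 5% level, and a non-strict rule
  far more liberal. Ties in duration are therefore ordered by the run's
  peak $|t|$, mapped into a sub-bin term that can never reorder two
  different durations.
* **Exceedance rule.** The gate is the exact Monte Carlo rule
  $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(S+1) \le 0.05$, which
  converges to "above the 95th percentile" as $S$ grows and has
  guaranteed level for exchangeable nulls. The test suite verifies the
  resulting false-positive rate on 200 null neurons against the 99%
  binomial band around 5%.

The *encoding latency* is the onset of the first run whose scored
duration itself clears the gate — "significant" qualifies the duration,
so an isolated 10-ms blip before the true onset does not define the
latency — and the *encoding sign* is the sign of the mean kernel weight
over that first qualifying run. Latency estimated this way still
overestimates slow-rising kernels (a sustained kernel planted at 680 ms
is typically detected 50–150 ms later); the ordering of latencies across
variables is the robust quantity, mirroring how the original analysis is
interpreted.

## CPD, population tests, selectivity, model II regression

The coefficient of partial determination of variable $i$ is

$$\mathrm{CPD}_i = \frac{\mathrm{SSE}(X_{-i}) - \mathrm{SSE}(X_{\mathrm{all}})}
{\mathrm{SSE}(X_{-i})},$$

where the reduced model is *refit* after shuffling variable $i$ across
trials (not merely zeroed), repeated `n_rep` times (study convention
100) and averaged. SSE is taken between observed counts and
model-implied expected counts per bin.

`population_kernel_test()` runs a per-lag one-sample t test of neuron
kernels against zero at $p < 0.01$, uncorrected. `swin_swout_classify()`
averages the `sw_in` and `sw_out` kernels over a late window (750–1500 ms
or 1000–1750 ms after stimulus onset, per cohort), judges each against
the null window means, and splits doubly selective neurons by whether the
*sum* of the two selectivities differs from zero — equal-but-opposite
routing leaves the sum at zero. `model2_regression()` is reduced major
axis, $\mathrm{slope} = \mathrm{sign}(r)\,s_y/s_x$; its significance uses
a seeded permutation of $y$ (the exact published procedure for this
significance is not specified; the permutation test is the labeled
substitute).

# The synthetic-data generator

`generate_dataset()` emulates the structure of the study's data: a trial
table (six timed stimuli per trial, target configuration, choice,
reward) and per-neuron 10-ms binned spike counts, with per-neuron seeds
derived from one master seed so regeneration is byte-identical.

* **Choices** come from a base-10 logistic agent,
  $P(\mathrm{red}) = 1/(1+10^{-Q})$ with per-shape leverages and optional
  per-epoch gains (an epoch-ignoring agent is the planted fixture for the
  leverage analysis).
* **Spikes** are inhomogeneous Poisson draws whose log rate is built by
  the *same* regressor code path the fitting uses, from planted kernels:
  a negative weight transient (onset ≈ 200 ms, peak 200–400 ms, gone by
  1000 ms), a negative consistency transient (onset ≈ 350 ms), a
  sustained positive evidence kernel (onset ≈ 680 ms), matching routing
  templates, or all-zero null neurons. Template onsets echo the reported
  latency ordering and are test fixtures, not claims about the recordings.
  Rates are clipped at 1000 spikes/s (with a warning) so degenerate
  amplitudes cannot overflow the exponential.
* **Defaults** chosen once: baseline rates 10–40 spikes/s (typical
  parietal range; the source does not report its distribution), kernel
  amplitudes 0.3–0.5 in log-rate units (clearly detectable at a few
  hundred trials without saturating the rate).

What the generator does *not* emulate: refractoriness, adaptation,
spike-history effects, correlated noise across neurons, rate drift, and
eye-movement covariates. Passing tests therefore show that the pipeline
recovers what it assumes — Poisson spiking driven by event-locked
kernels — not that real parietal data satisfy those assumptions.

# Test problem sizes

The suite validates the pipeline at sizes chosen for a single-CPU run:
kernel recovery on 10 planted neurons × 1000 trials at the full 150-lag
support (recovery correlation > 0.8 for weight and evidence); null
calibration on 200 neurons × 200 trials with 20 shuffles and a 25-lag
support; latency ordering on 30 neurons × 200 trials with a 110-lag
support (planted onsets 200/350/680 ms); behavioral recovery at 50,000
trials; Wald coverage over 300 replicate fits of 10,000 trials; and an
end-to-end smoke run of 5 neurons × 100 trials executed twice under one
seed and compared file-by-file. `scripts/acceptance.R` recomputes the
headline quantities from scratch at similar scales.

# Known limitations

* The per-bin t test treats the shuffle ensemble as the null replicate
  structure; with 20 shuffles its tails are coarse, which the run-level
  exceedance rule absorbs but individual per-lag p-values inherit.
* Latency is upward-biased for slow-rising kernels (see above).
* Boxcar mode rebuilds the design per shuffle and is slower; it is meant
  for comparison, not cohort-scale inference.
* No spike-history or coupling filters, no smooth (raised-cosine) kernel
  bases, no FDR across neurons — matching the modeled analysis, which
  relies on the longest-run permutation gate alone.
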