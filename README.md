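# evacc

Analysis tools for neural **ev**idence **acc**umulation in a sequential
probabilistic-reasoning task: behavioral subjective-weight estimation with
base-10 logistic regression, and convolutional Poisson GLMs with per-lag
temporal kernels for 10-ms binned spike trains, with shuffle-null
significance, encoding latency/sign, coefficients of partial
determination, and selectivity classification. A synthetic-data generator
produces task trials, choices and inhomogeneous Poisson spike trains with
planted kernels, so every stage of the pipeline can be validated by
parameter recovery and calibration.

## The problem

In the task, a subject watches six sequentially presented colored shapes
(333 ms on, 133 ms gap). Each shape has an assigned weight *W*; a
target's probability of paying a large reward is the base-10 logistic of
the summed same-colored weights,

    P(large | s) = 10^s / (1 + 10^s),    s = Σ W_i .

Choosing well requires weighing each shape by *W*, signing it by whether
its color matches the target in the neuron's response field
(`consistency`), and accumulating the resulting `evidence` across the six
epochs. The package implements the analyses that ask where along this
stimulus-to-evidence transformation parietal neurons sit:

* **Behavior** — subjective weights from choices,
  `Q = β0 + Σ β_i (N_red_i − N_green_i)` with `P(red) = 1/(1+10^−Q)`;
  epoch-leverage regression; psychometric curves.
* **Encoding** — a Poisson GLM whose log rate is the sum of per-lag
  kernels convolved with event-locked regressors (weight, color,
  consistency, evidence, color evidence, sw_in/sw_out, stimulus/target
  onset), fit by unregularized maximum likelihood on 10-ms bins with
  trial-end truncation and five-fold cross-validation.
* **Inference** — trial-shuffle null kernels; per-lag two-tailed t tests
  (p < 0.01); a longest-significant-duration gate at the 95th percentile
  of the shuffle distribution; encoding latency and sign; CPD by
  shuffle-and-refit; population kernel tests; sw_in/sw_out selectivity
  categories; reduced-major-axis (model II) regression.

## Worked example

```r
library(evacc)
shapes <- shape_set()                         # weights -0.9 ... +0.9
trials <- sample_trials(400, shapes, seed = 7)
trials <- simulate_choices(trials, agent_spec(shapes$weight), seed = 8)

fit_subjective_weights(trials)
#> Subjective weights (base-10 logistic, 400 trials; bias 0.027)
#>  shape_id      sw     se        p
#>         1 -1.0145 0.1195 2.11e-17
#>         2 -0.4864 0.0795 9.61e-10
#>         3 -0.2813 0.0728 1.11e-04
#>         4  0.2936 0.0797 2.32e-04
#>         5  0.5262 0.0862 1.05e-09
#>         6  0.9595 0.1134 2.67e-17
```

The recovered subjective weights track the generating weights
(−0.9 … +0.9) within a standard error or two even at 400 trials, and the
bias is near zero. Now a synthetic neuron that suppresses its rate
transiently with the shape's weight and ramps with the accumulated
evidence:

```r
vars <- c("stimulus_onset", "weight", "evidence")
derived <- derive_stimulus_vars(trials, shapes)
rs <- build_regressors(trials, derived, vars, support_shape_lags = 100)
neuron <- make_neuron_spec(c("weight_neg_transient", "evidence_sustained"),
                           variables = vars, support_shape_lags = 100,
                           baseline_rate = 30)
counts <- simulate_spike_counts(neuron, rs, seed = 9)

kernel_glm(counts, rs)
#> Convolutional Poisson GLM (10-ms bins)
#>   400 trials, 154700 bins, 47618 spikes
#>   intercept 3.405 (baseline 30.1 sp/s); NLL 102298.24 (initial 103725.19)
#>   irls, 4 iterations, converged

encoding_analysis(counts, rs, seed = 10, n_shuffles = 20)
#> Encoding analysis (20 shuffles, alpha 0.01)
#>  variable significant longest_run_ms null_run_ms latency_ms     sign cpd
#>    weight        TRUE            440          10        250 negative
#>  evidence        TRUE            190          10        780 positive
```

The fitted intercept recovers the 30 sp/s baseline. Both planted
variables are flagged against their trial-shuffle nulls; the weight
encoding is negative with a short latency (planted onset 200 ms) and the
evidence encoding is positive with a long latency (planted onset 680 ms;
slow-rising kernels are detected late), reproducing the
weight-before-evidence ordering the analysis is designed to expose.
`run_pipeline(out_dir, seed = 1)` chains simulate → fit-behavior →
fit-glm → infer → summarize and writes JSON results plus a manifest; a
thin command-line wrapper with the same subcommands is installed at
`inst/cli/evacc`.

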