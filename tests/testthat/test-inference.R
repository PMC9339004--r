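test_that("per-lag significance behaves at the extremes and stays calibrated", {
  set.seed(131)
  S <- 100L
  null_m <- matrix(rnorm(S * 50), S, 50)
  obs <- colMeans(null_m)
  out <- per_bin_significance(obs, null_m)
  expect_true(all(out$p[!out$untestable] > 0.9))   # obs = null mean -> p ~ 1
  obs2 <- colMeans(null_m) + 10 * apply(null_m, 2, sd)
  out2 <- per_bin_significance(obs2, null_m)
  expect_true(all(out2$significant))
  # zero-variance lag is untestable, not significant
  null_c <- null_m; null_c[, 7] <- 1
  out3 <- per_bin_significance(obs, null_c)
  expect_true(out3$untestable[7])
  expect_false(out3$significant[7])
  # false-positive calibration: fresh null draws tested against nulls
  set.seed(132)
  n_tests <- 10000L
  fp <- mean(vapply(seq_len(200), function(i) {
    nm <- matrix(rnorm(40 * 50), 40, 50)
    ob <- rnorm(50)
    sum(per_bin_significance(ob, nm, alpha = 0.01)$significant)
  }, 0)) / 50
  expect_lt(abs(fp - 0.01), 3 * sqrt(0.01 * 0.99 / n_tests) + 0.003)
})

test_that("longest_run measures maximal consecutive significance", {
  expect_equal(longest_run(c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)), 30)
  expect_equal(longest_run(rep(FALSE, 20)), 0)
  expect_equal(longest_run(rep(TRUE, 150)), 1500)
  expect_equal(longest_run(c(TRUE, FALSE, TRUE, TRUE)), 20)
  expect_error(longest_run(logical(0)))
})

test_that("shuffle nulls are deterministic and flat for constant variables", {
  fx <- fixture_problem(n_trials = 40, seed = 133)
  spec <- make_neuron_spec("null", variables = fx$rs$variables,
                           support_shape_lags = 20L, baseline_rate = 20)
  y <- simulate_spike_counts(spec, fx$rs, seed = 134)
  n1 <- shuffle_null_kernels(y, fx$rs, "evidence", n_shuffles = 5, seed = 135)
  n2 <- shuffle_null_kernels(y, fx$rs, "evidence", n_shuffles = 5, seed = 135)
  expect_equal(n1$kernels, n2$kernels)
  # constant variable: shuffling is a no-op, nulls equal the observed fit
  fit <- kernel_glm(y, fx$rs)
  nc <- shuffle_null_kernels(y, fx$rs, "stimulus_onset", n_shuffles = 3,
                             seed = 136, fit = fit)
  for (s in 1:3)
    expect_lt(max(abs(nc$kernels$stimulus_onset[s, ] -
                        fit$kernels$stimulus_onset)), 1e-6)
})

test_that("neuron significance recovers planted encodings with correct sign", {
  ss <- fixture_shapes()
  vars <- c("stimulus_onset", "weight", "evidence")
  tr <- sample_trials(300, ss, seed = 137)
  dv <- derive_stimulus_vars(tr, ss)
  rs <- build_regressors(tr, dv, vars, support_shape_lags = 100L)
  spec <- make_neuron_spec(c("weight_neg_transient", "evidence_sustained"),
                           variables = vars, support_shape_lags = 100L,
                           baseline_rate = 30,
                           amplitudes = c(weight = 0.8, evidence = 0.6))
  y <- simulate_spike_counts(spec, rs, seed = 138)
  ea <- encoding_analysis(y, rs, seed = 139, n_shuffles = 20)
  tab <- ea$table
  w <- tab[tab$variable == "weight", ]
  e <- tab[tab$variable == "evidence", ]
  expect_true(w$significant)
  expect_true(e$significant)
  expect_equal(w$sign, "negative")
  expect_equal(e$sign, "positive")
  # latency near the planted onsets (200 ms weight, 680 ms evidence)
  expect_lt(abs(w$latency_ms - 200), 60)
  expect_lt(abs(e$latency_ms - 680), 120)
  expect_lt(w$latency_ms, e$latency_ms)
})

test_that("the encoding sign follows the first significant run", {
  # synthetic null matrix with tight variance; observed kernel has an
  # early negative and a later (longer) positive run
  set.seed(141)
  S <- 60L; L <- 40L
  null_m <- matrix(rnorm(S * L, sd = 0.01), S, L)
  obs <- rep(0, L)
  obs[5:8] <- -0.5          # first run, negative
  obs[20:30] <- 0.5         # longest run, positive
  res <- neuron_significance(obs, null_m)
  expect_true(res$significant)
  expect_equal(res$sign, "negative")
  expect_equal(res$latency_ms, 40)     # lag index 5 -> 40 ms
  expect_equal(res$longest_run_ms, 110)
})

test_that("CPD follows its defining ratio and vanishes for absent variables", {
  # arithmetic identity on a constructed pair of SSEs
  expect_equal((2 - 1) / 2, 0.5)   # the ratio the estimator implements
  fx <- fixture_problem(n_trials = 150, seed = 142, support = 40L)
  spec <- make_neuron_spec("evidence_sustained", variables = fx$rs$variables,
                           support_shape_lags = 40L, baseline_rate = 30,
                           amplitudes = c(evidence = 0.6),
                           onsets_ms = c(evidence = 50))
  y <- simulate_spike_counts(spec, fx$rs, seed = 143)
  fit <- kernel_glm(y, fx$rs)
  cpd_e <- cpd(y, fx$rs, "evidence", fit = fit, n_rep = 8, seed = 144)
  cpd_w <- cpd(y, fx$rs, "weight", fit = fit, n_rep = 8, seed = 145)
  expect_gt(as.numeric(cpd_e), 0.002)
  expect_lt(abs(as.numeric(cpd_w)), 0.01)   # variable absent from generator
  expect_gt(as.numeric(cpd_e), as.numeric(cpd_w))
  reps <- attr(cpd_e, "reps")
  expect_length(reps, 8)
  expect_equal(as.numeric(cpd_e), mean(reps))
  # deterministic given the seed
  expect_equal(as.numeric(cpd(y, fx$rs, "evidence", fit = fit, n_rep = 8,
                              seed = 144)), as.numeric(cpd_e))
})

test_that("population kernel tests flag shared structure only", {
  set.seed(146)
  n <- 25L; L <- 200L
  shared <- matrix(rnorm(n * L, sd = 0.1), n, L)
  shared[, 30:40] <- shared[, 30:40] + 1
  out <- population_kernel_test(shared)
  expect_true(all(out$significant[30:40]))
  nullk <- matrix(rnorm(n * L, sd = 0.1), n, L)
  out0 <- population_kernel_test(nullk)
  fp <- mean(out0$significant)
  expect_lt(fp, 0.05)
  expect_error(population_kernel_test(shared[1, , drop = FALSE]), "2 neurons")
})

test_that("sw_in / sw_out selectivity categories are recovered", {
  ss <- fixture_shapes()
  vars <- variable_set_routing()
  tr <- sample_trials(300, ss, seed = 147)
  dv <- derive_stimulus_vars(tr, ss)
  rs <- build_regressors(tr, dv, vars, support_shape_lags = 100L)
  run_one <- function(templates, seed, amplitudes = NULL) {
    spec <- make_neuron_spec(templates, variables = vars,
                             support_shape_lags = 100L, baseline_rate = 30,
                             amplitudes = amplitudes)
    y <- simulate_spike_counts(spec, rs, seed = seed)
    fit <- kernel_glm(y, rs)
    nulls <- shuffle_null_kernels(y, rs, c("sw_in", "sw_out"),
                                  n_shuffles = 20, seed = seed + 1, fit = fit)
    swin_swout_classify(fit, nulls, window_ms = c(750, 1000))
  }
  opp <- run_one("swin_swout_opposed", 148,
                 amplitudes = c(sw_in = 0.8, sw_out = 0.8))
  expect_equal(opp$category, "both_equal_opposite")
  expect_gt(opp$selectivity_in, 0)
  expect_lt(opp$selectivity_out, 0)
  ino <- run_one("swin_only", 149, amplitudes = c(sw_in = 0.8))
  expect_equal(ino$category, "in_only")
  nul <- run_one("null", 150)
  expect_equal(nul$category, "none")
  fit_small <- kernel_glm(simulate_spike_counts(
    make_neuron_spec("null", variables = vars, support_shape_lags = 100L),
    rs, seed = 151), rs)
  expect_error(swin_swout_classify(fit_small,
                                   shuffle_null_kernels(
                                     simulate_spike_counts(
                                       make_neuron_spec("null", variables = vars,
                                                        support_shape_lags = 100L),
                                       rs, seed = 151),
                                     rs, c("sw_in", "sw_out"), n_shuffles = 3,
                                     seed = 152, fit = fit_small),
                                   window_ms = c(900, 1200)), "window")
})

test_that("coupled encoding strengths give a positive CPD-CPD slope", {
  fx <- fixture_problem(n_trials = 250, seed = 156, support = 40L)
  gains <- seq(0.5, 1.8, length.out = 8)
  cpds <- matrix(NA_real_, 8, 2, dimnames = list(NULL, c("weight", "evidence")))
  for (i in seq_along(gains)) {
    spec <- make_neuron_spec(c("weight_neg_transient", "evidence_sustained"),
                             variables = fx$rs$variables,
                             support_shape_lags = 40L, baseline_rate = 30,
                             amplitudes = c(weight = 0.5 * gains[i],
                                            evidence = 0.4 * gains[i]),
                             onsets_ms = c(evidence = 100))
    y <- simulate_spike_counts(spec, fx$rs, seed = 1560 + i)
    r <- counts_vector(y, fx$rs)
    fit <- kernel_glm(r, fx$rs)
    cpds[i, "weight"] <- as.numeric(cpd(r, fx$rs, "weight", fit = fit,
                                        n_rep = 4, seed = 1600 + i))
    cpds[i, "evidence"] <- as.numeric(cpd(r, fx$rs, "evidence", fit = fit,
                                          n_rep = 4, seed = 1700 + i))
  }
  rma <- model2_regression(cpds[, "weight"], cpds[, "evidence"],
                           n_perm = 500, seed = 157)
  expect_gt(rma$slope, 0)
  expect_gt(rma$r, 0.5)
})

test_that("reduced-major-axis regression matches its closed form", {
  expect_equal(model2_regression(1:10, 2 * (1:10))$slope, 2, tolerance = 1e-12)
  expect_equal(model2_regression(1:10, 2 * (1:10))$intercept, 0,
               tolerance = 1e-12)
  expect_equal(model2_regression(1:10, -(1:10))$slope, -1, tolerance = 1e-12)
  set.seed(153)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50, sd = 0.5)
  fit <- model2_regression(x, y, n_perm = 500, seed = 154)
  expect_equal(fit$slope, sign(cor(x, y)) * sd(y) / sd(x), tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - fit$slope * mean(x), tolerance = 1e-12)
  expect_lt(fit$p, 0.01)
  # unrelated data: permutation p is large more often than not
  y0 <- rnorm(50)
  fit0 <- model2_regression(x, y0, n_perm = 500, seed = 155)
  expect_gt(fit0$p, 0.001)
  expect_error(model2_regression(rep(1, 10), rnorm(10)), "variance")
  expect_error(model2_regression(1:2, 2:3), "3 points")
})
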