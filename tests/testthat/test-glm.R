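test_that("the Poisson NLL matches closed-form values", {
  fx <- fixture_problem(n_trials = 5, seed = 111)
  rs <- fx$rs
  p1 <- sum(rs$support) + 1L
  # intercept 0 (lambda = 1 sp/s), zero kernels, all counts zero
  r0 <- rep(0, rs$n_rows)
  out <- nll_and_gradient(c(0, numeric(p1 - 1L)), rs, r0)
  expect_equal(out$nll, 0.01 * rs$n_rows, tolerance = 1e-12)
  # one spike in one bin at Delta*lambda = 0.02: adds 0.02 - log(0.02)
  r1 <- r0; r1[17] <- 1
  out2 <- nll_and_gradient(c(log(2), numeric(p1 - 1L)), rs, r1)
  expect_equal(out2$nll - 0.02 * rs$n_rows, -log(0.02), tolerance = 1e-10)
})

test_that("the analytic gradient matches central finite differences", {
  fx <- fixture_problem(n_trials = 3, seed = 112,
                        variables = c("stimulus_onset", "evidence"),
                        support = 4L)
  rs <- fx$rs
  spec <- make_neuron_spec("null", variables = rs$variables,
                           support_shape_lags = 4L, baseline_rate = 30)
  y <- simulate_spike_counts(spec, rs, seed = 113)
  r <- counts_vector(y, rs)
  set.seed(114)
  beta <- rnorm(sum(rs$support) + 1L, sd = 0.2)
  out <- nll_and_gradient(beta, rs, r)
  h <- 1e-6
  fd <- vapply(seq_along(beta), function(j) {
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    (nll_and_gradient(bp, rs, r)$nll - nll_and_gradient(bm, rs, r)$nll) / (2 * h)
  }, 0)
  expect_lt(max(abs(out$gradient - fd) / pmax(abs(fd), 1)), 1e-5)
})

test_that("fitting a homogeneous neuron recovers baseline and flat kernels", {
  fx <- fixture_problem(n_trials = 800, seed = 115)
  spec <- make_neuron_spec("null", variables = fx$rs$variables,
                           support_shape_lags = 20L, baseline_rate = 20)
  y <- simulate_spike_counts(spec, fx$rs, seed = 116)
  fit <- kernel_glm(y, fx$rs)
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept - log(20)), 0.05)
  expect_lt(sqrt(mean(unlist(fit$kernels)^2)), 0.05)
  expect_lte(fit$nll, fit$nll_initial)
  # refitting from the optimum does not move
  refit <- kernel_glm(y, fx$rs, start = fit$beta)
  expect_lt(abs(refit$nll - fit$nll), 1e-8 * (abs(fit$nll) + 1))
  expect_lte(refit$n_iter, 1L)
  expect_error(kernel_glm(matrix(0L, fx$rs$n_trials, max(fx$rs$n_bins)) +
                            ifelse(is.na(y), NA, 0L), fx$rs), "degenerate")
})

test_that("IRLS and quasi-Newton reach the same optimum as a naive oracle", {
  # tiny 2-variable problem solved three ways
  fx <- fixture_problem(n_trials = 8, seed = 117,
                        variables = c("stimulus_onset", "evidence"),
                        support = 5L)
  rs <- fx$rs
  spec <- make_neuron_spec("null", variables = rs$variables,
                           support_shape_lags = 5L, baseline_rate = 25)
  y <- simulate_spike_counts(spec, rs, seed = 118)
  r <- counts_vector(y, rs)
  fit_a <- kernel_glm(r, rs, method = "irls")
  fit_b <- kernel_glm(r, rs, method = "bfgs")
  # independent dense-matrix oracle of the same likelihood
  Xd <- cbind(1, as.matrix(rs$X))
  nll_dense <- function(b) {
    eta <- Xd %*% b + log(0.01)
    sum(exp(eta)) - sum(r * eta)
  }
  oracle <- optim(c(log(mean(r) / 0.01), numeric(ncol(Xd) - 1)), nll_dense,
                  method = "BFGS", control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(abs(fit_a$nll - oracle$value), 1e-4)
  expect_lt(max(abs(fit_a$beta - oracle$par)), 1e-3)
  expect_lt(max(abs(fit_a$beta - fit_b$beta)), 1e-4)
})

test_that("planted kernels are recovered and improve with more data", {
  ss <- fixture_shapes()
  vars <- c("stimulus_onset", "weight", "evidence")
  rmse_at <- function(n, seed) {
    tr <- sample_trials(n, ss, seed = seed)
    dv <- derive_stimulus_vars(tr, ss)
    rs <- build_regressors(tr, dv, vars, support_shape_lags = 60L)
    spec <- make_neuron_spec(c("weight_neg_transient", "evidence_sustained"),
                             variables = vars, support_shape_lags = 60L,
                             baseline_rate = 30,
                             onsets_ms = c(evidence = 250))
    y <- simulate_spike_counts(spec, rs, seed = seed + 1L)
    fit <- kernel_glm(y, rs)
    c(rmse = sqrt(mean((fit$kernels$weight - spec$kernels$weight)^2 +
                       (fit$kernels$evidence - spec$kernels$evidence)^2)),
      cor_w = cor(fit$kernels$weight, spec$kernels$weight),
      cor_e = cor(fit$kernels$evidence, spec$kernels$evidence))
  }
  small <- vapply(1:4, function(i) rmse_at(100, 1190 + 7 * i), numeric(3))
  large <- vapply(1:4, function(i) rmse_at(800, 1290 + 7 * i), numeric(3))
  expect_true(all(large["rmse", ] < small["rmse", ]))
  expect_true(all(large["cor_w", ] > 0.8))
  expect_true(all(large["cor_e", ] > 0.8))
})

test_that("prediction satisfies the intercept moment condition", {
  fx <- fixture_problem(n_trials = 200, seed = 121)
  spec <- make_neuron_spec("weight_neg_transient", variables = fx$rs$variables,
                           support_shape_lags = 20L, baseline_rate = 25)
  y <- simulate_spike_counts(spec, fx$rs, seed = 122)
  fit <- kernel_glm(y, fx$rs)
  mu <- predict(fit, type = "counts")
  expect_true(all(mu > 0))
  expect_lt(abs(sum(mu) - fit$n_spikes) / fit$n_spikes, 1e-6)
  # rate type is counts / Delta
  expect_equal(predict(fit, type = "rate"), mu / 0.01)
  # zero kernels predict the constant baseline
  fit0 <- fit
  fit0$beta[-1] <- 0
  expect_equal(unique(round(evacc:::model_eta(fit0$beta, fx$rs), 12)),
               round(fit0$beta[1] + log(0.01), 12))
  # matrix form mirrors the NA padding of the counts
  pm <- predict(fit, as_matrix = TRUE)
  expect_identical(is.na(pm), is.na(y))
})

test_that("masked padding beyond the go cue leaves the likelihood unchanged", {
  fx <- fixture_problem(n_trials = 30, seed = 123)
  spec <- make_neuron_spec("null", variables = fx$rs$variables,
                           support_shape_lags = 20L, baseline_rate = 15)
  y <- simulate_spike_counts(spec, fx$rs, seed = 124)
  fit <- kernel_glm(y, fx$rs)
  y_pad <- cbind(y, matrix(NA_integer_, nrow(y), 25))
  fit_pad <- kernel_glm(y_pad, fx$rs)
  expect_identical(fit$nll, fit_pad$nll)
  expect_identical(fit$beta, fit_pad$beta)
})

test_that("cross-validation folds are seeded and favor the true model", {
  ss <- fixture_shapes()
  vars <- c("stimulus_onset", "evidence")
  tr <- sample_trials(250, ss, seed = 125)
  dv <- derive_stimulus_vars(tr, ss)
  rs <- build_regressors(tr, dv, vars, support_shape_lags = 40L)
  spec <- make_neuron_spec("evidence_sustained", variables = vars,
                           support_shape_lags = 40L, baseline_rate = 30,
                           amplitudes = c(evidence = 0.5),
                           onsets_ms = c(evidence = 100))
  y <- simulate_spike_counts(spec, rs, seed = 126)
  cv <- crossvalidate(y, rs, k_folds = 5, seed = 127)
  cv2 <- crossvalidate(y, rs, k_folds = 5, seed = 127)
  expect_identical(attr(cv, "fold"), attr(cv2, "fold"))
  expect_equal(cv$test_nll, cv2$test_nll)
  # an encoding neuron beats the intercept-only model in >= 4/5 folds
  expect_gte(sum(cv$test_nll < cv$null_test_nll), 4)
  # a null neuron shows no systematic held-out advantage
  y0 <- simulate_spike_counts(make_neuron_spec("null", variables = vars,
                                               support_shape_lags = 40L,
                                               baseline_rate = 30),
                              rs, seed = 128)
  cv0 <- crossvalidate(y0, rs, k_folds = 5, seed = 129)
  expect_lt(mean(cv0$null_test_nll - cv0$test_nll),
            3 * sd(cv0$null_test_nll - cv0$test_nll) + 1)
  expect_error(crossvalidate(y[1:3, ], subset_regressors(rs, 1:3),
                             k_folds = 5, seed = 1), "folds|trials")
})
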