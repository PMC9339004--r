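#' Poisson negative log-likelihood and analytic gradient
#'
#' The model's log rate is `intercept + sum_i (k_i * f(x_i))(t)` (log
#' spikes/s); with bin width `Delta` = 0.01 s the per-bin mean count is
#' `Delta * lambda_t` and the negative log-likelihood, dropping the
#' `log r!` constant, is `sum_t [Delta lambda_t - r_t log(Delta lambda_t)]`.
#' The gradient with respect to the intercept and every kernel lag is
#' `X1' (Delta lambda - r)` with `X1 = [1, X]`.
#'
#' @param beta parameter vector: intercept followed by all kernel lags in
#'   the column order of `rs`
#' @param rs a [build_regressors()] result
#' @param r counts in regressor row order (see [counts_vector()]), or a
#'   trials-by-bins matrix
#' @return list with elements `nll` and `gradient`
#' @export
nll_and_gradient <- function(beta, rs, r) {
  stopifnot(inherits(rs, "regressor_set"))
  if (is.matrix(r)) r <- counts_vector(r, rs)
  X <- rs$X
  if (anyNA(X@x)) stop("regressors contain NA")
  if (length(beta) != ncol(X) + 1L)
    stop("'beta' must have one intercept plus one entry per kernel lag")
  eta <- beta[1L] + as.numeric(X %*% beta[-1L]) + log(rs$delta_s)
  mu <- exp(eta)                       # expected counts per bin
  nll <- sum(mu) - sum(r * eta)
  resid <- mu - r
  g <- c(sum(resid), as.numeric(Matrix::crossprod(X, resid)))
  list(nll = nll, gradient = g)
}

model_eta <- function(beta, rs) {
  beta[1L] + as.numeric(rs$X %*% beta[-1L]) + log(rs$delta_s)
}

# IRLS (Newton / Fisher scoring) on the exact NLL with step halving;
# the inner loop lives in compiled code (src/irls.cpp). A tiny relative
# diagonal damping keeps the normal equations solvable when
# near-collinear lag columns make the Hessian singular to machine
# precision; it is a linear-algebra safeguard, not regularization of the
# fit (the damped step still targets the undamped optimum).
fit_irls <- function(X, r, delta_s, beta0, rel_tol = 1e-9, grad_tol = 1e-6,
                     max_iter = 100L) {
  .irls_fit_cpp(X, r, beta0, log(delta_s), rel_tol, grad_tol,
                as.integer(max_iter), 1000 * delta_s)
}

#' Fit the convolutional Poisson GLM
#'
#' Maximum-likelihood fit of per-lag kernel weights (plus a global
#' intercept on the log spikes/s scale) to 10-ms binned spike counts,
#' with no regularization. The default `"irls"` method is Newton / Fisher
#' scoring on the exact likelihood with analytic gradient and step
#' halving; `"bfgs"` runs quasi-Newton `optim()` with the same analytic
#' gradient and reaches the same (unique, convex) optimum. Kernels start
#' at zero and the intercept at the log mean rate; the fit is
#' deterministic given the data.
#'
#' @param counts trials-by-bins count matrix (`NA`-padded past the go
#'   cue), or a vector already in regressor row order
#' @param rs a [build_regressors()] result
#' @param method `"irls"` or `"bfgs"`
#' @param start optional warm-start parameter vector (intercept first)
#' @param rel_tol convergence tolerance on the relative NLL change
#' @param grad_tol convergence tolerance on the gradient sup-norm
#' @param max_iter iteration cap
#' @return An object of class `"kernel_glm"` with components `intercept`,
#'   `kernels` (named list of per-lag weights), `beta`, `nll`,
#'   `nll_initial`, `converged`, `n_iter`, `n_spikes`, and the regressor
#'   set used.
#' @examples
#' \donttest{
#' ss <- shape_set()
#' tr <- sample_trials(60, ss, seed = 1)
#' dv <- derive_stimulus_vars(tr, ss)
#' rs <- build_regressors(tr, dv, c("stimulus_onset", "evidence"),
#'                        support_shape_lags = 30)
#' ns <- make_neuron_spec("null", variables = rs$variables,
#'                        support_shape_lags = 30, baseline_rate = 20)
#' y <- simulate_spike_counts(ns, rs, seed = 2)
#' fit <- kernel_glm(y, rs)
#' coef(fit)[1]   # close to log(20)
#' }
#' @export
kernel_glm <- function(counts, rs, method = c("irls", "bfgs"), start = NULL,
                       rel_tol = 1e-9, grad_tol = 1e-6, max_iter = 100L) {
  method <- match.arg(method)
  stopifnot(inherits(rs, "regressor_set"))
  r <- if (is.matrix(counts)) counts_vector(counts, rs) else counts
  if (length(r) != rs$n_rows) stop("counts do not match the regressor rows")
  n_spikes <- sum(r)
  if (n_spikes == 0)
    stop("degenerate data: zero spikes in the model window (intercept MLE is -Inf)")
  p1 <- sum(rs$support) + 1L
  beta0 <- if (is.null(start)) c(log(mean(r) / rs$delta_s), numeric(p1 - 1L))
           else start
  if (length(beta0) != p1) stop("'start' has the wrong length")
  init <- nll_and_gradient(beta0, rs, r)

  if (method == "irls") {
    res <- fit_irls(rs$X, r, rs$delta_s, beta0, rel_tol, grad_tol, max_iter)
  } else {
    fn <- function(b) nll_and_gradient(b, rs, r)$nll
    gr <- function(b) nll_and_gradient(b, rs, r)$gradient
    op <- stats::optim(beta0, fn, gr, method = "BFGS",
                       control = list(maxit = 2000, reltol = rel_tol))
    res <- list(beta = op$par, nll = op$value,
                converged = op$convergence == 0, n_iter = op$counts[["function"]],
                gradient_max = max(abs(gr(op$par))))
  }
  if (!res$converged)
    warning("kernel_glm did not converge; returning the partial fit")
  kernels <- lapply(rs$col_index, function(ix) res$beta[-1L][ix])
  names(kernels) <- rs$variables
  structure(list(intercept = res$beta[1L], kernels = kernels,
                 beta = res$beta, nll = res$nll, nll_initial = init$nll,
                 converged = res$converged, n_iter = res$n_iter,
                 gradient_max = res$gradient_max,
                 n_spikes = n_spikes, method = method,
                 regressors = rs, counts = r),
            class = "kernel_glm")
}

#' @export
print.kernel_glm <- function(x, ...) {
  cat("Convolutional Poisson GLM (10-ms bins)\n")
  cat(sprintf("  %d trials, %d bins, %d spikes\n",
              x$regressors$n_trials, x$regressors$n_rows, x$n_spikes))
  cat(sprintf("  intercept %.3f (baseline %.1f sp/s); NLL %.2f (initial %.2f)\n",
              x$intercept, exp(x$intercept), x$nll, x$nll_initial))
  cat(sprintf("  %s, %d iterations, %sconverged\n", x$method, x$n_iter,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.kernel_glm <- function(object, ...) {
  rms <- vapply(object$kernels, function(k) sqrt(mean(k^2)), 0)
  out <- list(intercept = object$intercept,
              baseline_rate = exp(object$intercept),
              kernel_rms = rms, nll = object$nll,
              df = length(object$beta), converged = object$converged)
  class(out) <- "summary.kernel_glm"
  out
}

#' @export
print.summary.kernel_glm <- function(x, ...) {
  cat(sprintf("Baseline rate %.2f sp/s (intercept %.3f), NLL %.3f, %d parameters\n",
              x$baseline_rate, x$intercept, x$nll, x$df))
  cat("Kernel root-mean-square weight by variable:\n")
  print(round(x$kernel_rms, 4))
  invisible(x)
}

#' @export
coef.kernel_glm <- function(object, ...) {
  nm <- unlist(lapply(object$regressors$variables, function(v)
    paste0(v, "_lag", seq_len(object$regressors$support[v]) - 1L)))
  stats::setNames(object$beta, c("(Intercept)", nm))
}

#' @export
logLik.kernel_glm <- function(object, ...) {
  ll <- -object$nll - sum(lgamma(object$counts + 1))
  structure(ll, df = length(object$beta), nobs = length(object$counts),
            class = "logLik")
}

#' Predicted firing rate of a fitted kernel model
#'
#' @param object a `kernel_glm`
#' @param rs optional new `regressor_set` (defaults to the training set)
#' @param type `"rate"` for spikes/s, `"counts"` for expected counts per
#'   bin (`Delta * lambda`)
#' @param as_matrix return a trials-by-bins matrix (`NA`-padded) instead
#'   of a flat vector in row order
#' @param ... unused
#' @return predicted values, all strictly positive
#' @export
predict.kernel_glm <- function(object, rs = NULL, type = c("rate", "counts"),
                               as_matrix = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(rs)) rs <- object$regressors
  eta <- model_eta(object$beta, rs)
  out <- if (type == "counts") exp(eta) else exp(eta) / rs$delta_s
  if (as_matrix) rows_to_matrix(out, rs) else out
}

rows_to_matrix <- function(x, rs) {
  m <- matrix(NA_real_, rs$n_trials, max(rs$n_bins))
  for (t in seq_len(rs$n_trials))
    m[t, seq_len(rs$n_bins[t])] <- x[(rs$row_offset[t] + 1L):rs$row_offset[t + 1L]]
  m
}

#' @export
residuals.kernel_glm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- predict(object, type = "counts")
  res <- object$counts - mu
  if (type == "pearson") res <- res / sqrt(mu)
  res
}

#' @export
simulate.kernel_glm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, type = "counts")
  out <- replicate(nsim, stats::rpois(length(mu), mu), simplify = FALSE)
  lapply(out, rows_to_matrix, rs = object$regressors)
}

#' @export
plot.kernel_glm <- function(x, variables = x$regressors$variables, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)))
  on.exit(graphics::par(old))
  for (v in variables) {
    k <- x$kernels[[v]]
    t_ms <- (seq_along(k) - 1L) * x$regressors$bin_ms
    plot(t_ms, k, type = "l", xlab = "lag (ms)", ylab = "kernel weight",
         main = v, ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Five-fold cross-validation of the kernel model
#'
#' Trials are shuffled into `k_folds` folds with a seeded permutation;
#' the model is refit on each training split and scored on the held-out
#' trials. The held-out NLL of the intercept-only model (closed form) is
#' reported alongside for reference.
#'
#' @param counts trials-by-bins count matrix
#' @param rs a `regressor_set`
#' @param k_folds number of folds (default 5)
#' @param seed integer seed for the fold assignment
#' @param ... passed to [kernel_glm()]
#' @return data frame with one row per fold: train / test NLL for the
#'   full and intercept-only models, and per-bin normalized test NLL
#' @export
crossvalidate <- function(counts, rs, k_folds = 5L, seed, ...) {
  stopifnot(inherits(rs, "regressor_set"))
  if (missing(seed)) stop("'seed' is required for the fold shuffle")
  n <- rs$n_trials
  if (n < k_folds) stop("need at least as many trials as folds")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k_folds), n))
  r_all <- if (is.matrix(counts)) counts_vector(counts, rs) else counts
  out <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    test_trials <- which(fold == f)
    test_rows <- rs$row_trial %in% test_trials
    rs_train <- subset_regressors(rs, which(fold != f))
    rs_test <- subset_regressors(rs, test_trials)
    fit <- kernel_glm(r_all[!test_rows], rs_train, ...)
    r_test <- r_all[test_rows]
    eta_test <- model_eta(fit$beta, rs_test)
    test_nll <- sum(exp(eta_test)) - sum(r_test * eta_test)
    mu0 <- mean(r_all[!test_rows])
    null_test_nll <- length(r_test) * mu0 - sum(r_test) * log(mu0)
    out[[f]] <- data.frame(fold = f, n_test_trials = length(test_trials),
                           train_nll = fit$nll, test_nll = test_nll,
                           null_test_nll = null_test_nll,
                           test_nll_per_bin = test_nll / length(r_test))
  }
  res <- do.call(rbind, out)
  attr(res, "fold") <- fold
  res
}

#' Restrict a regressor set to a subset of trials
#'
#' @param rs a `regressor_set`
#' @param trials integer indices of trials to keep
#' @return a `regressor_set` over the kept trials
#' @export
subset_regressors <- function(rs, trials) {
  stopifnot(inherits(rs, "regressor_set"))
  keep_rows <- rs$row_trial %in% trials
  new_trial <- match(rs$row_trial[keep_rows], trials)
  n_bins <- rs$n_bins[trials]
  values <- lapply(rs$values, function(m) m[trials, , drop = FALSE])
  out <- rs
  out$X <- rs$X[keep_rows, , drop = FALSE]
  out$n_trials <- length(trials)
  out$n_bins <- n_bins
  out$row_offset <- c(0L, cumsum(n_bins))
  out$n_rows <- sum(n_bins)
  out$row_trial <- new_trial
  out$values <- values
  out$triplets <- NULL      # subset matrices are static; no fast shuffles
  out$dims <- dim(out$X)
  out
}
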