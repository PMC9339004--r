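#' Null kernel distributions by trial shuffling
#'
#' Builds the permutation null for one or more variables' kernels: the
#' variables' per-trial values are permuted across trials (event times
#' stay in place), the full GLM is refit, and the resulting kernels are
#' stored. With a single variable this is the classic per-variable
#' shuffle. With several variables one common trial permutation is
#' applied to all of them per shuffle ("joint" mode), so a single refit
#' yields a null draw for every shuffled variable at once while
#' preserving their mutual correlation.
#'
#' A variable that is constant across trials is unchanged by shuffling,
#' so its "null" kernels simply refit the observed data.
#'
#' @param counts trials-by-bins count matrix, or a vector in regressor
#'   row order
#' @param rs a [build_regressors()] result
#' @param variables variables to shuffle (default: every variable whose
#'   values vary across trials)
#' @param n_shuffles number of shuffles (>= 2; the study's convention is
#'   100)
#' @param seed integer seed; shuffles are deterministic given it
#' @param fit optional observed [kernel_glm()] fit, reused as a warm
#'   start
#' @param method fitting method, see [kernel_glm()]
#' @return An object of class `"null_kernels"`: per-variable matrices of
#'   shuffled-fit kernel weights (`n_shuffles` rows), the seed, and the
#'   count of failed refits (an error if more than 10\% fail).
#' @export
shuffle_null_kernels <- function(counts, rs, variables = trial_varying(rs),
                                 n_shuffles = 100L, seed, fit = NULL,
                                 method = "irls") {
  stopifnot(inherits(rs, "regressor_set"), all(variables %in% rs$variables))
  if (n_shuffles < 2) stop("'n_shuffles' must be >= 2")
  if (missing(seed)) stop("'seed' is required")
  r <- if (is.matrix(counts)) counts_vector(counts, rs) else counts
  if (is.null(fit)) fit <- kernel_glm(r, rs, method = method)
  set.seed(as.integer(seed))
  perms <- replicate(n_shuffles, sample.int(rs$n_trials), simplify = FALSE)
  kernels <- lapply(variables, function(v)
    matrix(NA_real_, n_shuffles, rs$support[v]))
  names(kernels) <- variables
  failed <- 0L
  for (s in seq_len(n_shuffles)) {
    rs_s <- shuffle_regressors(rs, variables, perms[[s]])
    f_s <- tryCatch(
      suppressWarnings(kernel_glm(r, rs_s, method = method, start = fit$beta)),
      error = function(e) NULL)
    if (is.null(f_s)) { failed <- failed + 1L; next }
    for (v in variables) kernels[[v]][s, ] <- f_s$kernels[[v]]
  }
  if (failed > 0.1 * n_shuffles)
    stop(sprintf("%d of %d shuffle refits failed", failed, n_shuffles))
  keep <- !is.na(kernels[[variables[1L]]][, 1L])
  kernels <- lapply(kernels, function(m) m[keep, , drop = FALSE])
  structure(list(kernels = kernels, variables = variables,
                 n_shuffles = sum(keep), seed = as.integer(seed),
                 failed = failed, observed = fit$kernels[variables]),
            class = "null_kernels")
}

#' @export
print.null_kernels <- function(x, ...) {
  cat(sprintf("Shuffle null: %d shuffles (%d failed) for %s\n",
              x$n_shuffles, x$failed, paste(x$variables, collapse = ", ")))
  invisible(x)
}

col_sds <- function(m) {
  mu <- colMeans(m)
  sqrt(colSums((m - rep(mu, each = nrow(m)))^2) / (nrow(m) - 1L))
}

#' Per-lag significance of a kernel against its shuffle null
#'
#' At each lag the observed kernel weight is converted to a t statistic
#' against the shuffle distribution, `t = (obs - mean(null)) / sd(null)`,
#' and tested two-tailed with `df = n_shuffles - 1`. Lags where the null
#' has zero variance are marked untestable (and not significant).
#'
#' @param observed numeric kernel (one weight per lag)
#' @param null_kernels matrix of shuffled kernels (shuffles x lags), or a
#'   `"null_kernels"` object plus `variable`
#' @param alpha two-tailed significance level (default 0.01)
#' @param variable variable name when `null_kernels` is a
#'   `"null_kernels"` object
#' @return list with `t`, `p`, `significant` (logical per lag) and
#'   `untestable`
#' @export
per_bin_significance <- function(observed, null_kernels, alpha = 0.01,
                                 variable = NULL) {
  if (inherits(null_kernels, "null_kernels")) {
    if (is.null(variable)) stop("'variable' is required with a null_kernels object")
    null_kernels <- null_kernels$kernels[[variable]]
  }
  stopifnot(is.matrix(null_kernels), length(observed) == ncol(null_kernels))
  S <- nrow(null_kernels)
  if (S < 2) stop("need at least 2 shuffles")
  mu <- colMeans(null_kernels)
  sd0 <- col_sds(null_kernels)
  untestable <- sd0 == 0
  t <- (observed - mu) / sd0
  t[untestable] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df = S - 1L)
  sig <- !is.na(p) & p < alpha
  list(t = t, p = p, significant = sig, untestable = untestable)
}

#' Longest consecutive run of significant lags
#'
#' @param trace logical vector (per-lag significance)
#' @param bin_ms bin width in ms (default 10)
#' @return run duration in ms (0 if no lag is significant)
#' @export
longest_run <- function(trace, bin_ms = 10) {
  stopifnot(is.logical(trace), length(trace) > 0)
  r <- rle(trace)
  runs <- r$lengths[r$values]
  if (!length(runs)) 0 else max(runs) * bin_ms
}

# Run table of a significance trace: start/end lag index, duration, and
# a scored duration with a continuous tie-break. Durations live on a
# 10-ms grid, so their null distribution is heavily tied and a strict
# exceedance rule would be far more stringent than its nominal level;
# ties are ordered by the run's peak |t|, mapped into (0, bin_ms) so the
# secondary term can never reorder two different durations.
run_table <- function(sig, t, bin_ms) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep))
    return(data.frame(start = integer(), end = integer(),
                      duration_ms = numeric(), score = numeric()))
  starts <- starts[keep]; ends <- ends[keep]
  peak <- vapply(seq_along(starts), function(i)
    max(abs(t[starts[i]:ends[i]])), 0)
  dur <- (ends - starts + 1L) * bin_ms
  data.frame(start = starts, end = ends, duration_ms = dur,
             score = dur + (1 - 1 / (1 + peak)) * bin_ms * 0.999)
}

# trace-level score: the best scored run duration; traces without any
# significant run fall back to a sub-bin value from the global peak |t|
run_score <- function(sig, t, bin_ms) {
  tab <- run_table(sig, t, bin_ms)
  if (nrow(tab)) return(max(tab$score))
  peak <- suppressWarnings(max(abs(t), na.rm = TRUE))
  if (!is.finite(peak)) peak <- 0
  (1 - 1 / (1 + peak)) * bin_ms * 0.999
}

#' Neuron-level encoding significance, latency and sign
#'
#' The multiple-comparison gate of the encoding analysis: the observed
#' kernel's longest significant duration (per-lag test at `alpha`) is
#' compared with the 95th percentile of the null longest-duration
#' distribution, obtained by testing each shuffled kernel against the
#' remaining shuffles (leave-one-out). A neuron encodes the variable only
#' if its longest run exceeds that percentile. The encoding latency is
#' the beginning of the *first* significant run (not necessarily the
#' longest), and the encoding sign is the sign of the mean kernel weight
#' over that first run.
#'
#' @param observed numeric kernel
#' @param null_kernels shuffles-by-lags matrix or `"null_kernels"` object
#' @param alpha per-lag two-tailed level (default 0.01)
#' @param run_quantile percentile of the null run distribution used as
#'   the gate (default 0.95)
#' @param bin_ms bin width (ms)
#' @param variable variable name when passing a `"null_kernels"` object
#' @return An object of class `"encoding_result"`: `significant`,
#'   `longest_run_ms`, `null_run_ms` (95th percentile of the null run
#'   durations), `latency_ms` (`NA` when not significant), `sign`
#'   (`"positive"`, `"negative"` or `"none"`), plus the per-lag `p`
#'   values and significance trace.
#' @details Run durations are multiples of the bin width, so the null
#'   longest-run distribution is heavily tied and a strict exceedance
#'   rule on raw durations would be far more stringent than its nominal
#'   level. Ties in duration are therefore broken by the peak |t| of the
#'   trace (a secondary term strictly smaller than one bin), and the
#'   gate compares these scores.
#' @export
neuron_significance <- function(observed, null_kernels, alpha = 0.01,
                                run_quantile = 0.95, bin_ms = 10,
                                variable = NULL) {
  if (inherits(null_kernels, "null_kernels")) {
    if (is.null(variable)) stop("'variable' is required with a null_kernels object")
    null_kernels <- null_kernels$kernels[[variable]]
  }
  S <- nrow(null_kernels)
  obs <- per_bin_significance(observed, null_kernels, alpha)
  obs_run <- longest_run(obs$significant, bin_ms)
  obs_score <- run_score(obs$significant, obs$t, bin_ms)
  null_scores <- vapply(seq_len(S), function(s) {
    ps <- per_bin_significance(null_kernels[s, ],
                               null_kernels[-s, , drop = FALSE], alpha)
    run_score(ps$significant, ps$t, bin_ms)
  }, 0)
  null_runs <- bin_ms * (null_scores %/% bin_ms)
  gate <- stats::quantile(null_scores, run_quantile, names = FALSE)
  # exact Monte Carlo exceedance rule: equivalent to demanding the
  # observed score lie above the `run_quantile` point of the null set,
  # with guaranteed level (1 - run_quantile) for exchangeable nulls
  p_perm <- (1 + sum(null_scores >= obs_score)) / (S + 1)
  significant <- p_perm <= (1 - run_quantile) && obs_run > 0
  latency <- NA_real_
  sign_lab <- "none"
  if (significant) {
    # latency: onset of the first run whose scored duration itself clears
    # the null gate (isolated sub-gate blips do not define the latency);
    # the exceedance rule guarantees at least one such run exists
    tab <- run_table(obs$significant, obs$t, bin_ms)
    qualifying <- tab[tab$score > gate, , drop = FALSE]
    if (!nrow(qualifying)) qualifying <- tab[which.max(tab$score), , drop = FALSE]
    fr <- qualifying[1L, ]
    latency <- (fr$start - 1L) * bin_ms
    m <- mean(observed[fr$start:fr$end])
    sign_lab <- if (m > 0) "positive" else "negative"
  }
  structure(list(significant = significant, longest_run_ms = obs_run,
                 null_run_ms = stats::quantile(null_runs, run_quantile,
                                               names = FALSE),
                 null_runs_ms = null_runs, score = obs_score,
                 score_gate = gate, p_perm = p_perm,
                 latency_ms = unname(latency), sign = sign_lab,
                 p = obs$p, significant_lags = obs$significant,
                 untestable = obs$untestable, alpha = alpha),
            class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf("Encoding: %s (longest run %g ms vs null gate %g ms)\n",
              if (x$significant) "significant" else "not significant",
              x$longest_run_ms, x$null_run_ms))
  if (x$significant)
    cat(sprintf("  latency %g ms, sign %s\n", x$latency_ms, x$sign))
  invisible(x)
}

#' Coefficient of partial determination of a variable
#'
#' Quantifies the response variance uniquely explained by one variable:
#' `CPD = (SSE_reduced - SSE_full) / SSE_reduced`, where `SSE_full` is
#' the sum of squared errors (observed counts minus model-implied
#' expected counts) of the full fit and `SSE_reduced` that of a model
#' refit after the variable's per-trial values are shuffled across
#' trials. The shuffle-and-refit is repeated `n_rep` times and the CPD
#' averaged.
#'
#' @param counts trials-by-bins count matrix or row-order vector
#' @param rs a `regressor_set`
#' @param variable the variable whose unique contribution is measured
#' @param fit the fitted full model (computed if `NULL`)
#' @param n_rep number of shuffle repetitions (study convention: 100)
#' @param seed integer seed
#' @param method fitting method
#' @return the averaged CPD (attribute `"reps"` carries the per-shuffle
#'   values)
#' @export
cpd <- function(counts, rs, variable, fit = NULL, n_rep = 100L, seed,
                method = "irls") {
  stopifnot(inherits(rs, "regressor_set"), variable %in% rs$variables)
  if (missing(seed)) stop("'seed' is required")
  r <- if (is.matrix(counts)) counts_vector(counts, rs) else counts
  if (is.null(fit)) fit <- kernel_glm(r, rs, method = method)
  mu_full <- exp(model_eta(fit$beta, rs))
  sse_full <- sum((r - mu_full)^2)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_rep), function(s) {
    rs_s <- shuffle_regressors(rs, variable, sample.int(rs$n_trials))
    f_s <- suppressWarnings(kernel_glm(r, rs_s, method = method,
                                       start = fit$beta))
    sse_red <- sum((r - exp(model_eta(f_s$beta, rs_s)))^2)
    if (sse_red == 0) stop("reduced-model SSE is zero; CPD undefined")
    (sse_red - sse_full) / sse_red
  }, 0)
  structure(mean(reps), reps = reps)
}

#' Population-level kernel test
#'
#' One-sample two-tailed t test of the neuron kernels against zero at
#' every lag (uncorrected), with the population mean and standard error.
#'
#' @param kernels neurons-by-lags matrix (one row per neuron)
#' @param alpha per-lag level (default 0.01)
#' @param bin_ms bin width (ms)
#' @return data frame with `lag_ms`, `mean`, `se`, `t`, `p`,
#'   `significant`
#' @export
population_kernel_test <- function(kernels, alpha = 0.01, bin_ms = 10) {
  kernels <- as.matrix(kernels)
  n <- nrow(kernels)
  if (n < 2) stop("need kernels from at least 2 neurons")
  mu <- colMeans(kernels)
  se <- col_sds(kernels) / sqrt(n)
  t <- mu / se
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  data.frame(lag_ms = (seq_along(mu) - 1L) * bin_ms, mean = mu, se = se,
             t = t, p = p, significant = !is.na(p) & p < alpha)
}

#' Classify a neuron's sw_in / sw_out selectivity
#'
#' Selectivity for each routing variable is the mean kernel weight over a
#' fixed late time window; its significance is judged against the window
#' means of the shuffle-null kernels (two-tailed, `alpha`). Neurons
#' selective for both variables are split by whether the *sum* of the
#' two selectivities differs from zero (tested against the null
#' distribution of the sum): equal-but-opposite coding leaves the sum at
#' zero.
#'
#' @param fit a [kernel_glm()] fit over the routing variable set
#' @param nulls a `"null_kernels"` object containing `sw_in` and
#'   `sw_out`
#' @param window_ms two-element window (ms after stimulus onset), e.g.
#'   `c(750, 1500)`; must lie inside the kernel support
#' @param alpha significance level (default 0.01)
#' @return list with `category` (`"none"`, `"both_equal_opposite"`,
#'   `"both_different"`, `"in_only"`, `"out_only"`), the two
#'   selectivities and the three p-values
#' @export
swin_swout_classify <- function(fit, nulls, window_ms = c(750, 1500),
                                alpha = 0.01) {
  stopifnot(inherits(fit, "kernel_glm"), inherits(nulls, "null_kernels"),
            all(c("sw_in", "sw_out") %in% names(fit$kernels)),
            all(c("sw_in", "sw_out") %in% nulls$variables))
  bin_ms <- fit$regressors$bin_ms
  L <- length(fit$kernels$sw_in)
  lag_ms <- (seq_len(L) - 1L) * bin_ms
  idx <- which(lag_ms >= window_ms[1] & lag_ms < window_ms[2])
  if (!length(idx) || window_ms[2] > L * bin_ms)
    stop("selectivity window lies outside the kernel support")
  sel_in <- mean(fit$kernels$sw_in[idx])
  sel_out <- mean(fit$kernels$sw_out[idx])
  null_in <- rowMeans(nulls$kernels$sw_in[, idx, drop = FALSE])
  null_out <- rowMeans(nulls$kernels$sw_out[, idx, drop = FALSE])
  S <- length(null_in)
  p_of <- function(obs, null) {
    s <- stats::sd(null)
    if (s == 0) return(NA_real_)
    2 * stats::pt(-abs((obs - mean(null)) / s), df = S - 1L)
  }
  p_in <- p_of(sel_in, null_in)
  p_out <- p_of(sel_out, null_out)
  p_sum <- p_of(sel_in + sel_out, null_in + null_out)
  sig_in <- !is.na(p_in) && p_in < alpha
  sig_out <- !is.na(p_out) && p_out < alpha
  category <- if (sig_in && sig_out) {
    if (!is.na(p_sum) && p_sum < alpha) "both_different" else "both_equal_opposite"
  } else if (sig_in) "in_only" else if (sig_out) "out_only" else "none"
  list(category = category, selectivity_in = sel_in, selectivity_out = sel_out,
       p_in = p_in, p_out = p_out, p_sum = p_sum, window_ms = window_ms)
}

#' Reduced-major-axis (model II) regression
#'
#' Symmetric regression for two jointly noisy quantities (e.g. two CPDs
#' across neurons): `slope = sign(r) * sd(y) / sd(x)`,
#' `intercept = mean(y) - slope * mean(x)`. Significance is assessed by a
#' seeded permutation test of `y` against `x` on the correlation
#' magnitude.
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance)
#' @param n_perm number of permutations (default 1000)
#' @param seed integer seed
#' @return list with `slope`, `intercept`, `r`, `p` and `n`
#' @export
model2_regression <- function(x, y, n_perm = 1000L, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; slope undefined")
  r <- stats::cor(x, y)
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  if (slope == 0) slope <- stats::sd(y) / stats::sd(x)  # r exactly 0: sign convention +
  intercept <- mean(y) - slope * mean(x)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i)
    abs(stats::cor(x, sample(y))), 0)
  p <- (1 + sum(perm >= abs(r))) / (n_perm + 1)
  list(slope = slope, intercept = intercept, r = r, p = p, n = length(x))
}

#' Per-neuron encoding analysis driver
#'
#' Fits the observed model, builds a joint shuffle null over all
#' trial-varying variables, and summarizes significance, longest run,
#' latency, sign and (optionally) CPD per variable.
#'
#' @param counts trials-by-bins count matrix
#' @param rs a `regressor_set`
#' @param seed integer seed (shuffles)
#' @param n_shuffles shuffle count (study convention 100)
#' @param alpha per-lag level
#' @param variables variables to test (default: all trial-varying)
#' @param cpd_reps CPD shuffle repetitions per variable (0 skips CPD)
#' @param method fitting method
#' @return An object of class `"encoding_analysis"`: the fit, the null
#'   set, per-variable `"encoding_result"`s and a summary `table`.
#' @export
encoding_analysis <- function(counts, rs, seed, n_shuffles = 100L,
                              alpha = 0.01, variables = trial_varying(rs),
                              cpd_reps = 0L, method = "irls") {
  r <- if (is.matrix(counts)) counts_vector(counts, rs) else counts
  fit <- kernel_glm(r, rs, method = method)
  nulls <- shuffle_null_kernels(r, rs, variables, n_shuffles, seed = seed,
                                fit = fit, method = method)
  results <- lapply(variables, function(v)
    neuron_significance(fit$kernels[[v]], nulls, alpha = alpha,
                        bin_ms = rs$bin_ms, variable = v))
  names(results) <- variables
  cpds <- rep(NA_real_, length(variables))
  if (cpd_reps > 0)
    cpds <- vapply(seq_along(variables), function(i)
      as.numeric(cpd(r, rs, variables[i], fit = fit, n_rep = cpd_reps,
                     seed = seed + 7919L * i, method = method)), 0)
  tab <- data.frame(
    variable = variables,
    significant = vapply(results, `[[`, TRUE, "significant"),
    longest_run_ms = vapply(results, `[[`, 0, "longest_run_ms"),
    null_run_ms = vapply(results, `[[`, 0, "null_run_ms"),
    latency_ms = vapply(results, `[[`, 0, "latency_ms"),
    sign = vapply(results, `[[`, "", "sign"),
    cpd = cpds, row.names = NULL)
  structure(list(fit = fit, nulls = nulls, results = results, table = tab,
                 seed = as.integer(seed), alpha = alpha),
            class = "encoding_analysis")
}

#' @export
print.encoding_analysis <- function(x, ...) {
  cat(sprintf("Encoding analysis (%d shuffles, alpha %.3g)\n",
              x$nulls$n_shuffles, x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}
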