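#' Behavioral agent specification
#'
#' A generative choice model on the base-10 logit scale: the agent's
#' choice leverage is `Q = beta0 + sum_i sw[i] * (N_red_i - N_green_i)`
#' and it chooses red with probability `1 / (1 + 10^-Q)`. Setting an
#' entry of `sw` to zero makes the agent ignore that shape; the
#' `epoch_gain` vector (default all ones) scales each epoch's
#' contribution, so an agent that ignores, say, the final epoch can be
#' planted for leverage-recovery tests.
#'
#' @param sw six per-shape leverages (subjective weights, log10 odds)
#' @param beta0 choice bias
#' @param epoch_gain six multiplicative gains, one per epoch
#' @return an object of class `"agent_spec"`
#' @export
agent_spec <- function(sw = shape_set()$weight, beta0 = 0,
                       epoch_gain = rep(1, 6)) {
  stopifnot(length(sw) == 6, all(is.finite(sw)), is.finite(beta0),
            length(epoch_gain) == 6, all(is.finite(epoch_gain)))
  structure(list(sw = as.numeric(sw), beta0 = as.numeric(beta0),
                 epoch_gain = as.numeric(epoch_gain)),
            class = "agent_spec")
}

#' Simulate choices from a trial table
#'
#' Draws independent red/green choices with
#' `P(red) = 1 / (1 + 10^-Q)`, `Q` the agent's summed leverage over the
#' six stimuli (red stimuli add their shape's leverage, green stimuli
#' subtract it).
#'
#' @param trials a `trial_table`
#' @param agent an [agent_spec()]
#' @param seed integer seed
#' @return the trial table with `choice` / `chosen_color` filled in; the
#'   per-trial `Q` is attached as attribute `"Q"`
#' @export
simulate_choices <- function(trials, agent = agent_spec(), seed) {
  stopifnot(inherits(trials, "trial_table"), inherits(agent, "agent_spec"))
  if (missing(seed)) stop("'seed' is required")
  shp <- shape_mat(trials)
  col <- color_mat(trials)
  lev <- matrix(agent$sw[shp], nrow(trials), 6L) * col
  lev <- lev * rep(agent$epoch_gain, each = nrow(trials))
  Q <- agent$beta0 + rowSums(lev)
  set.seed(as.integer(seed))
  p_red <- 1 / (1 + 10^(-Q))
  chosen <- ifelse(stats::runif(nrow(trials)) < p_red, "red", "green")
  out <- set_choices(trials, chosen)
  attr(out, "Q") <- Q
  out
}

raised_cosine_rise <- function(t, onset, rise) {
  u <- pmin(pmax((t - onset) / rise, 0), 1)
  (1 - cos(pi * u)) / 2
}

# transient: raised-cosine rise from onset to peak, cosine decay to zero
# at `end`; exactly zero outside [onset, end]
transient_kernel <- function(lags_ms, onset, peak, end, amplitude) {
  k <- numeric(length(lags_ms))
  up <- lags_ms > onset & lags_ms <= peak
  dn <- lags_ms > peak & lags_ms < end
  k[up] <- raised_cosine_rise(lags_ms[up], onset, peak - onset)
  k[dn] <- (1 + cos(pi * (lags_ms[dn] - peak) / (end - peak))) / 2
  amplitude * k
}

sustained_kernel <- function(lags_ms, onset, rise, amplitude) {
  amplitude * raised_cosine_rise(lags_ms, onset, rise)
}

#' Planted-neuron specifications
#'
#' Builds the ground-truth kernels of a synthetic neuron from named
#' templates, loosely shaped after the encoding profiles the analyses are
#' meant to detect:
#' \describe{
#'   \item{`null`}{all kernels exactly zero (homogeneous Poisson).}
#'   \item{`weight_neg_transient`}{a negative transient on the shape
#'     weight kernel: onset ~200 ms, peak 200-400 ms, back to zero by
#'     1000 ms.}
#'   \item{`consistency_route`}{a negative transient on the color
#'     consistency kernel, onset ~350 ms.}
#'   \item{`color_evidence_route`}{the same transient shape on the color
#'     evidence kernel (the alternative computation route).}
#'   \item{`evidence_sustained`}{a positive evidence kernel, zero at lag
#'     0, onset ~680 ms, sustained to the end of the support.}
#' }
#' Templates combine additively, so
#' `c("weight_neg_transient", "consistency_route", "evidence_sustained")`
#' plants a neuron carrying the full transformation profile.
#'
#' @param templates character vector of template names (see Details)
#' @param variables the variable list the neuron is defined over
#' @param baseline_rate baseline firing rate in spikes/s (must lie in
#'   (0.1, 200))
#' @param amplitudes named numeric overrides of the template amplitudes
#'   (names `weight`, `consistency`, `color_evidence`, `evidence`,
#'   `sw_in`, `sw_out`); defaults 0.5 / 0.4 / 0.4 / 0.3 / 0.3 / 0.3
#' @param onsets_ms named numeric overrides of the template onsets
#'   (defaults: weight 200, consistency 350, color_evidence 350,
#'   evidence 680)
#' @param support_shape_lags,support_target_lags kernel supports in 10-ms
#'   lags
#' @param bin_ms bin width (ms)
#' @return an object of class `"neuron_spec"`: baseline log rate plus one
#'   ground-truth kernel per variable
#' @export
make_neuron_spec <- function(templates = "null",
                             variables = variable_set_decomposition(),
                             baseline_rate = 20,
                             amplitudes = NULL, onsets_ms = NULL,
                             support_shape_lags = 150L,
                             support_target_lags = 300L,
                             bin_ms = 10) {
  known <- c("null", "weight_neg_transient", "consistency_route",
             "color_evidence_route", "evidence_sustained",
             "swin_swout_opposed", "swin_only", "swout_only")
  bad <- setdiff(templates, known)
  if (length(bad)) stop(sprintf("unknown template(s): %s", paste(bad, collapse = ", ")))
  if (!is.finite(baseline_rate) || baseline_rate <= 0.1 || baseline_rate >= 200)
    stop("'baseline_rate' must lie in (0.1, 200) spikes/s")
  amp <- c(weight = 0.5, consistency = 0.4, color_evidence = 0.4,
           evidence = 0.3, sw_in = 0.3, sw_out = 0.3)
  if (!is.null(amplitudes)) {
    stopifnot(all(names(amplitudes) %in% names(amp)), all(is.finite(amplitudes)))
    amp[names(amplitudes)] <- amplitudes
  }
  ons <- c(weight = 200, consistency = 350, color_evidence = 350,
           evidence = 680, sw_in = 680, sw_out = 680)
  if (!is.null(onsets_ms)) {
    stopifnot(all(names(onsets_ms) %in% names(ons)))
    ons[names(onsets_ms)] <- onsets_ms
  }
  support <- ifelse(variables %in% .target_variables,
                    support_target_lags, support_shape_lags)
  names(support) <- variables
  kernels <- lapply(variables, function(v) numeric(support[v]))
  names(kernels) <- variables
  lags_of <- function(v) {
    if (!(v %in% variables))
      stop(sprintf("template targets variable '%s' absent from 'variables'", v))
    (seq_len(support[v]) - 1L) * bin_ms
  }
  add_to <- function(v, k) kernels[[v]] <<- kernels[[v]] + k
  for (tpl in unique(templates)) {
    if (tpl == "null") next
    if (tpl == "weight_neg_transient") {
      add_to("weight", transient_kernel(lags_of("weight"), ons["weight"],
                                        ons["weight"] + 100, 1000,
                                        -amp["weight"]))
    } else if (tpl == "consistency_route") {
      add_to("consistency", transient_kernel(lags_of("consistency"),
                                             ons["consistency"],
                                             ons["consistency"] + 150, 1100,
                                             -amp["consistency"]))
    } else if (tpl == "color_evidence_route") {
      add_to("color_evidence", transient_kernel(lags_of("color_evidence"),
                                                ons["color_evidence"],
                                                ons["color_evidence"] + 150, 1100,
                                                -amp["color_evidence"]))
    } else if (tpl == "evidence_sustained") {
      add_to("evidence", sustained_kernel(lags_of("evidence"), ons["evidence"],
                                          200, amp["evidence"]))
    } else if (tpl == "swin_swout_opposed") {
      k <- sustained_kernel(lags_of("sw_in"), ons["sw_in"], 200, amp["sw_in"])
      lags_of("sw_out")
      add_to("sw_in", k); add_to("sw_out", -k)
    } else if (tpl == "swin_only") {
      add_to("sw_in", sustained_kernel(lags_of("sw_in"), ons["sw_in"], 200,
                                       amp["sw_in"]))
    } else if (tpl == "swout_only") {
      add_to("sw_out", sustained_kernel(lags_of("sw_out"), ons["sw_out"], 200,
                                        -amp["sw_out"]))
    }
  }
  structure(list(baseline_log_rate = log(baseline_rate), kernels = kernels,
                 variables = variables, support = support,
                 templates = templates, bin_ms = bin_ms),
            class = "neuron_spec")
}

#' @export
print.neuron_spec <- function(x, ...) {
  cat(sprintf("Synthetic neuron: baseline %.1f sp/s; templates: %s\n",
              exp(x$baseline_log_rate), paste(x$templates, collapse = " + ")))
  nz <- names(Filter(function(k) any(k != 0), x$kernels))
  cat("  nonzero kernels:", if (length(nz)) paste(nz, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Simulate 10-ms binned spike counts from a planted neuron
#'
#' Inhomogeneous Poisson simulation through the exact regressor code path
#' the fitting uses: the log rate is
#' `baseline + sum_i (k_i * f(x_i))(t)` (spikes/s), rates are clipped at
#' 1000 sp/s with a warning, and counts are Poisson with mean
#' `Delta * lambda_t`, `Delta` = 0.01 s.
#'
#' @param spec a [make_neuron_spec()] result whose variables and supports
#'   match `rs`
#' @param rs a [build_regressors()] result
#' @param seed integer seed
#' @return trials-by-bins integer count matrix, `NA`-padded past the go
#'   cue
#' @export
simulate_spike_counts <- function(spec, rs, seed) {
  stopifnot(inherits(spec, "neuron_spec"), inherits(rs, "regressor_set"))
  if (missing(seed)) stop("'seed' is required")
  if (!identical(spec$variables, rs$variables) ||
      !all(spec$support == rs$support))
    stop("neuron spec and regressor set disagree on variables or supports")
  beta <- c(spec$baseline_log_rate, unlist(spec$kernels, use.names = FALSE))
  log_rate <- model_eta(beta, rs) - log(rs$delta_s)   # log spikes/s
  cap <- log(1000)
  if (any(log_rate > cap)) {
    warning("simulated rate clipped at 1000 spikes/s")
    log_rate <- pmin(log_rate, cap)
  }
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(log_rate), exp(log_rate) * rs$delta_s)
  rows_to_matrix(counts, rs)
}

#' Generate a full synthetic dataset
#'
#' Emulates the structure of the study's deposited data: a trial table
#' with simulated choices and rewards, plus per-neuron binned spike
#' counts driven by planted kernels. Per-neuron seeds are derived
#' deterministically from the master seed, so regeneration is
#' byte-identical.
#'
#' @param n_neurons,n_trials cohort size
#' @param templates list of template character vectors, recycled across
#'   neurons (default: a mix of the transformation profile and null
#'   neurons)
#' @param master_seed integer master seed
#' @param shapes a [shape_set()]
#' @param config a [task_config()]
#' @param agent an [agent_spec()]
#' @param variables variable list for the regressors / planted kernels
#' @param baseline_rates baseline rates in spikes/s, recycled across
#'   neurons
#' @param ... further arguments to [build_regressors()] and
#'   [make_neuron_spec()] (supports, mode, bin width)
#' @return an object of class `"synthetic_dataset"`: `trials`, `derived`,
#'   `regressors`, `counts` (list of matrices), `specs`, `agent`,
#'   `shapes`, `config`, `master_seed`
#' @export
generate_dataset <- function(n_neurons, n_trials,
                             templates = list(c("weight_neg_transient",
                                                "consistency_route",
                                                "evidence_sustained"),
                                              "null"),
                             master_seed,
                             shapes = shape_set(),
                             config = task_config(),
                             agent = agent_spec(shapes$weight),
                             variables = variable_set_decomposition(),
                             baseline_rates = c(10, 20, 30, 40),
                             support_shape_lags = 150L,
                             support_target_lags = 300L,
                             mode = "impulse", bin_ms = 10) {
  if (n_neurons < 1 || n_trials < 1) stop("cohort sizes must be >= 1")
  if (missing(master_seed)) stop("'master_seed' is required")
  master_seed <- as.integer(master_seed)
  if (!is.list(templates)) templates <- list(templates)
  trials <- sample_trials(n_trials, shapes, config, seed = master_seed)
  trials <- simulate_choices(trials, agent, seed = master_seed + 1L)
  trials <- assign_reward(trials, config, seed = master_seed + 2L)
  derived <- derive_stimulus_vars(trials, shapes)
  rs <- build_regressors(trials, derived, variables, config, mode = mode,
                         support_shape_lags = support_shape_lags,
                         support_target_lags = support_target_lags,
                         bin_ms = bin_ms)
  tpl_of <- function(i) templates[[((i - 1L) %% length(templates)) + 1L]]
  rate_of <- function(i) baseline_rates[((i - 1L) %% length(baseline_rates)) + 1L]
  specs <- lapply(seq_len(n_neurons), function(i)
    make_neuron_spec(tpl_of(i), variables = variables,
                     baseline_rate = rate_of(i),
                     support_shape_lags = support_shape_lags,
                     support_target_lags = support_target_lags,
                     bin_ms = bin_ms))
  neuron_seeds <- master_seed + 1000L + seq_len(n_neurons)
  counts <- lapply(seq_len(n_neurons), function(i)
    simulate_spike_counts(specs[[i]], rs, seed = neuron_seeds[i]))
  names(counts) <- sprintf("neuron_%03d", seq_len(n_neurons))
  structure(list(trials = trials, derived = derived, regressors = rs,
                 counts = counts, specs = specs, agent = agent,
                 shapes = shapes, config = config,
                 master_seed = master_seed, neuron_seeds = neuron_seeds),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d neurons x %d trials (master seed %d)\n",
              length(x$counts), nrow(x$trials), x$master_seed))
  cat(sprintf("  variables: %s\n", paste(x$regressors$variables, collapse = ", ")))
  invisible(x)
}
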