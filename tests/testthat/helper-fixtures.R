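# Small shared fixtures, generated in code at test time.

fixture_shapes <- function() shape_set()

# compact regressor problem: few trials, short supports, three variables
fixture_problem <- function(n_trials = 60, seed = 101,
                            variables = c("stimulus_onset", "weight", "evidence"),
                            support = 20L) {
  ss <- fixture_shapes()
  tr <- sample_trials(n_trials, ss, seed = seed)
  dv <- derive_stimulus_vars(tr, ss)
  rs <- build_regressors(tr, dv, variables, support_shape_lags = support,
                         support_target_lags = 2L * support)
  list(shapes = ss, trials = tr, derived = dv, rs = rs)
}

fixture_null_counts <- function(rs, rate = 20, seed = 7) {
  spec <- make_neuron_spec("null", variables = rs$variables,
                           baseline_rate = rate,
                           support_shape_lags = unname(rs$support[
                             setdiff(rs$variables, c("target_onset", "target_config"))][1]),
                           support_target_lags = if (any(rs$variables %in%
                             c("target_onset", "target_config")))
                             unname(rs$support["target_onset"]) else 300L)
  simulate_spike_counts(spec, rs, seed = seed)
}

# manual trial table with fully controlled fields (bypasses sampling)
manual_trials <- function(shape, color, tin_color, end_delay = 433,
                          p_red = 0.5, p_green = 0.5) {
  n <- nrow(shape)
  out <- data.frame(trial_id = seq_len(n))
  for (k in 1:6) out[[paste0("shape_", k)]] <- shape[, k]
  for (k in 1:6) out[[paste0("color_", k)]] <- color[, k]
  out$tin_color <- tin_color
  out$end_delay_ms <- rep_len(end_delay, n)
  out$p_red <- rep_len(p_red, n)
  out$p_green <- rep_len(p_green, n)
  out$choice <- NA_character_
  out$chosen_color <- NA_character_
  out$reward <- NA_character_
  class(out) <- c("trial_table", "data.frame")
  out
}
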