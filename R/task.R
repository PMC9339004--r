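#' Shape set: the stimulus pool and its assigned weights
#'
#' The task draws each of the six stimuli in a trial from a pool of six
#' shapes, each carrying a fixed assigned weight \eqn{W} on the base-10
#' log-odds scale: positive weights push the same-colored target's
#' large-reward probability above 0.5. Subjective weights \eqn{SW} -- the
#' behaviorally estimated leverage of each shape -- can be attached either
#' at construction or later via [set_subjective_weights()].
#'
#' @param weights numeric vector of six assigned weights (log10 odds units).
#'   The default spans weak and strong cues symmetrically.
#' @param subjective optional numeric vector of six subjective weights; if
#'   `NULL`, the assigned weights are used wherever subjective weights are
#'   requested.
#' @return An object of class `"shape_set"`: a data frame with columns
#'   `shape_id` (1..6), `weight`, and `sw`.
#' @examples
#' ss <- shape_set()
#' ss$weight
#' @export
shape_set <- function(weights = c(-0.9, -0.5, -0.3, 0.3, 0.5, 0.9),
                      subjective = NULL) {
  if (length(weights) != 6L || !is.numeric(weights) || !all(is.finite(weights)))
    stop("'weights' must be six finite numeric values")
  if (is.null(subjective)) subjective <- weights
  if (length(subjective) != 6L || !all(is.finite(subjective)))
    stop("'subjective' must be six finite numeric values")
  out <- data.frame(shape_id = 1:6, weight = as.numeric(weights),
                    sw = as.numeric(subjective))
  class(out) <- c("shape_set", "data.frame")
  out
}

#' @rdname shape_set
#' @param x a `shape_set`
#' @param sw six subjective weights to attach
#' @export
set_subjective_weights <- function(x, sw) {
  stopifnot(inherits(x, "shape_set"))
  if (length(sw) != 6L || !all(is.finite(sw)))
    stop("'sw' must be six finite numeric values")
  x$sw <- as.numeric(sw)
  x
}

#' Task timing and reward configuration
#'
#' Event timing of the probabilistic-reasoning task, on a clock whose
#' origin is target onset: targets appear 567 ms after fixation; the first
#' of six stimuli appears 533 ms after the targets; each stimulus is shown
#' for 333 ms followed by a 133 ms gap (epoch pitch 466 ms); after the
#' sixth stimulus a variable delay of 433/533/633 ms precedes the go cue.
#'
#' Two reward schemes are supported. Under `"probabilistic"` the chosen
#' target pays a large reward with its reward probability and a small
#' reward otherwise. Under `"better_only"` reward is delivered only when
#' the target with the higher reward probability was chosen (large with
#' probability `P(chosen)`, else small); choosing the worse target yields
#' `none` by default, or a small reward if `none_for_worse = FALSE`.
#'
#' @param t_targets_ms targets onset after fixation acquisition (ms)
#' @param t_first_stim_ms first stimulus onset after target onset (ms)
#' @param stim_on_ms stimulus display duration (ms)
#' @param stim_gap_ms inter-stimulus gap (ms)
#' @param end_delay_choices_ms delay options between last stimulus offset
#'   and the go cue (ms)
#' @param reward_scheme `"probabilistic"` or `"better_only"`
#' @param none_for_worse under `"better_only"`, whether the worse choice
#'   gets no reward (`TRUE`, default) or a small reward
#' @param reward_large,reward_small reward magnitudes (arbitrary units,
#'   bookkeeping only)
#' @return An object of class `"task_config"`.
#' @export
task_config <- function(t_targets_ms = 567, t_first_stim_ms = 533,
                        stim_on_ms = 333, stim_gap_ms = 133,
                        end_delay_choices_ms = c(433, 533, 633),
                        reward_scheme = c("probabilistic", "better_only"),
                        none_for_worse = TRUE,
                        reward_large = 2, reward_small = 1) {
  reward_scheme <- match.arg(reward_scheme)
  durs <- c(t_targets_ms, t_first_stim_ms, stim_on_ms, stim_gap_ms,
            end_delay_choices_ms)
  if (!all(is.finite(durs)) || any(durs <= 0))
    stop("all task durations must be positive and finite")
  cfg <- list(t_targets_ms = t_targets_ms, t_first_stim_ms = t_first_stim_ms,
              stim_on_ms = stim_on_ms, stim_gap_ms = stim_gap_ms,
              epoch_pitch_ms = stim_on_ms + stim_gap_ms,
              end_delay_choices_ms = end_delay_choices_ms,
              reward_scheme = reward_scheme, none_for_worse = none_for_worse,
              reward_large = reward_large, reward_small = reward_small)
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task configuration\n")
  cat(sprintf("  targets at %g ms post fixation; first stimulus %g ms post targets\n",
              x$t_targets_ms, x$t_first_stim_ms))
  cat(sprintf("  6 stimuli: %g ms on + %g ms gap (pitch %g ms)\n",
              x$stim_on_ms, x$stim_gap_ms, x$epoch_pitch_ms))
  cat(sprintf("  end delay in {%s} ms; reward scheme: %s\n",
              paste(x$end_delay_choices_ms, collapse = ", "), x$reward_scheme))
  invisible(x)
}

#' Reward probability from summed shape weights
#'
#' A target's probability of paying the large reward is a base-10 logistic
#' function of the summed assigned weights \eqn{s} of the same-colored
#' shapes in the trial: \eqn{P = 10^s / (1 + 10^s)}. The red and green
#' target probabilities are computed independently from their own colors'
#' shapes, so they need not sum to one.
#'
#' @param weight_sum numeric vector of summed weights (log10 odds units)
#' @return probabilities in (0, 1), same length as `weight_sum`
#' @seealso [reward_logodds()] for the inverse map
#' @examples
#' reward_probability(c(-1, 0, 1))
#' @export
reward_probability <- function(weight_sum) {
  if (!is.numeric(weight_sum) || length(weight_sum) == 0 ||
      !all(is.finite(weight_sum)))
    stop("'weight_sum' must be finite numeric")
  # 1/(1+10^-s) is the overflow-safe form for large |s|
  1 / (1 + 10^(-weight_sum))
}

#' @rdname reward_probability
#' @param p probabilities in (0, 1)
#' @export
reward_logodds <- function(p) {
  if (!is.numeric(p) || !all(is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly inside (0, 1)")
  log10(p / (1 - p))
}

#' Sample trials of the probabilistic-reasoning task
#'
#' Each trial draws six stimuli i.i.d. uniformly (with replacement) from
#' the six-shape pool; each stimulus is independently red or green with
#' probability 1/2; the color of the target in the neuron's response field
#' (`tin_color`) is random per trial; the end delay is uniform over the
#' configured choices. Reward probabilities `p_red` and `p_green` are the
#' base-10 logistic of each color's summed assigned weights.
#'
#' @param n number of trials
#' @param shapes a [shape_set()]
#' @param config a [task_config()]
#' @param seed integer seed (required; trials are reproducible)
#' @return A `trial_table`: a data frame with one row per trial and columns
#'   `trial_id`, `shape_1..6`, `color_1..6` (+1 red, -1 green),
#'   `tin_color`, `end_delay_ms`, `p_red`, `p_green`, plus `choice`,
#'   `chosen_color` and `reward` columns initialized to `NA` until a
#'   choice is simulated and a reward assigned.
#' @export
sample_trials <- function(n, shapes = shape_set(), config = task_config(),
                          seed) {
  stopifnot(inherits(shapes, "shape_set"), inherits(config, "task_config"))
  if (missing(seed)) stop("'seed' is required for reproducible sampling")
  if (n < 1) stop("'n' must be >= 1")
  set.seed(as.integer(seed))
  shp <- matrix(sample.int(6L, n * 6L, replace = TRUE), n, 6L)
  col <- matrix(sample(c(1L, -1L), n * 6L, replace = TRUE), n, 6L)
  tin <- sample(c("red", "green"), n, replace = TRUE)
  delay <- sample(config$end_delay_choices_ms, n, replace = TRUE)
  w <- matrix(shapes$weight[shp], n, 6L)
  s_red <- rowSums(w * (col == 1L))
  s_green <- rowSums(w * (col == -1L))
  out <- data.frame(trial_id = seq_len(n))
  for (k in 1:6) out[[paste0("shape_", k)]] <- shp[, k]
  for (k in 1:6) out[[paste0("color_", k)]] <- col[, k]
  out$tin_color <- tin
  out$end_delay_ms <- delay
  out$choice <- NA_character_
  out$chosen_color <- NA_character_
  out$reward <- NA_character_
  out$p_red <- reward_probability(s_red)
  out$p_green <- reward_probability(s_green)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' @rdname sample_trials
#' @export
sample_trial <- function(shapes = shape_set(), config = task_config(), seed) {
  sample_trials(1L, shapes, config, seed)
}

shape_mat <- function(trials) unname(as.matrix(trials[paste0("shape_", 1:6)]))
color_mat <- function(trials) unname(as.matrix(trials[paste0("color_", 1:6)]))

#' Record choices on a trial table
#'
#' Fills the `choice` (`"T_in"`/`"T_out"`) and `chosen_color` columns;
#' `chosen_color` is kept consistent with `choice` and `tin_color`.
#'
#' @param trials a `trial_table`
#' @param chosen_color character vector, `"red"`/`"green"`, one per trial
#' @return the trial table with choices filled in
#' @export
set_choices <- function(trials, chosen_color) {
  stopifnot(inherits(trials, "trial_table"),
            length(chosen_color) == nrow(trials),
            all(chosen_color %in% c("red", "green")))
  trials$chosen_color <- chosen_color
  trials$choice <- ifelse(chosen_color == trials$tin_color, "T_in", "T_out")
  trials
}

#' Assign reward outcomes to chosen targets
#'
#' Under the probabilistic scheme the chosen target pays `large` with its
#' reward probability and `small` otherwise. Under the better-only scheme
#' reward is delivered only when the target with the higher reward
#' probability was chosen (ties count as better); the worse choice pays
#' `none` (or `small` if the configuration says so).
#'
#' @param trials a `trial_table` with choices recorded
#' @param config a [task_config()]
#' @param seed integer seed
#' @return the trial table with the `reward` column filled
#' @export
assign_reward <- function(trials, config = task_config(), seed) {
  stopifnot(inherits(trials, "trial_table"), inherits(config, "task_config"))
  if (any(is.na(trials$choice)))
    stop("trials are missing choices; call set_choices() first")
  if (missing(seed)) stop("'seed' is required")
  set.seed(as.integer(seed))
  p_chosen <- ifelse(trials$chosen_color == "red", trials$p_red, trials$p_green)
  p_other <- ifelse(trials$chosen_color == "red", trials$p_green, trials$p_red)
  u <- stats::runif(nrow(trials))
  reward <- ifelse(u < p_chosen, "large", "small")
  if (config$reward_scheme == "better_only") {
    worse <- p_chosen < p_other
    reward[worse] <- if (config$none_for_worse) "none" else "small"
  }
  trials$reward <- reward
  trials
}

#' Per-stimulus regressor variables
#'
#' Maps each of a trial's six stimuli to the variables the encoding model
#' uses, all defined on the base-10 log-odds scale of the shape weights:
#' \describe{
#'   \item{sw}{the stimulus shape's (subjective) weight}
#'   \item{color}{+1 red, -1 green}
#'   \item{consistency}{+1 when the stimulus color matches the color of
#'     the in-field target, -1 otherwise (`color * configuration`)}
#'   \item{color_evidence}{evidence in favor of the red target,
#'     `sw * color`}
#'   \item{evidence}{evidence in favor of the in-field target,
#'     `sw * consistency`}
#'   \item{sw_in, sw_out}{the weight routed to the target matching /
#'     not matching the stimulus color; exactly one is nonzero and
#'     `sw_in - sw_out = evidence`}
#' }
#' The target configuration is +1 when the in-field target is red.
#'
#' @param trials a `trial_table`
#' @param shapes a [shape_set()]
#' @param use_subjective use subjective weights (`TRUE`, default) or the
#'   assigned weights
#' @return An object of class `"derived_vars"`: a list of n-by-6 matrices
#'   (`sw`, `color`, `consistency`, `color_evidence`, `evidence`, `sw_in`,
#'   `sw_out`) plus the per-trial `configuration` vector.
#' @export
derive_stimulus_vars <- function(trials, shapes = shape_set(),
                                 use_subjective = TRUE) {
  stopifnot(inherits(trials, "trial_table"), inherits(shapes, "shape_set"))
  shp <- shape_mat(trials)
  if (any(!(shp %in% shapes$shape_id)))
    stop("trial table contains shape ids outside the shape set")
  wvec <- if (use_subjective) shapes$sw else shapes$weight
  sw <- matrix(wvec[shp], nrow(trials), 6L)
  color <- color_mat(trials)
  configuration <- ifelse(trials$tin_color == "red", 1, -1)
  consistency <- color * configuration
  evidence <- sw * consistency
  color_evidence <- sw * color
  sw_in <- sw * (consistency == 1)
  sw_out <- sw * (consistency == -1)
  structure(list(sw = sw, color = color, consistency = consistency,
                 color_evidence = color_evidence, evidence = evidence,
                 sw_in = sw_in, sw_out = sw_out,
                 configuration = configuration),
            class = "derived_vars")
}

#' Accumulated evidence through an epoch
#'
#' The running difference between the total weight routed to the in-field
#' target and the total routed to the other target,
#' \eqn{\sum_{j \le e} SW_{in,j} - SW_{out,j}}, the quantity the
#' population's ramping activity tracks.
#'
#' @param derived a [derive_stimulus_vars()] result
#' @param through_epoch epoch 1..6 up to (and including) which evidence is
#'   summed
#' @return numeric vector, one value per trial
#' @export
accumulated_evidence <- function(derived, through_epoch) {
  stopifnot(inherits(derived, "derived_vars"))
  if (length(through_epoch) != 1 || !(through_epoch %in% 1:6))
    stop("'through_epoch' must be a single epoch in 1..6")
  d <- derived$sw_in - derived$sw_out
  rowSums(d[, seq_len(through_epoch), drop = FALSE])
}

#' Trial timeline on the 10-ms bin clock
#'
#' Places the task's events on a 0-based, half-open bin grid
#' \eqn{[t, t + bin)} whose origin is target onset. The model window runs
#' from target onset to the go cue (fixation offset), so a trial spans
#' `floor((t_first_stim + 6 * pitch + end_delay) / bin)` bins; onsets
#' falling inside a bin are assigned to that bin.
#'
#' @param end_delay_ms per-trial end delay(s), or a `trial_table`
#' @param config a [task_config()]
#' @param bin_ms bin width in ms (default 10)
#' @return A list with `bin_ms`, `stim_onset_bins` (six 0-based bins,
#'   identical across trials), `target_onset_bin` (0), and `n_bins`
#'   (vector, one per trial).
#' @export
trial_timeline <- function(end_delay_ms, config = task_config(), bin_ms = 10) {
  stopifnot(inherits(config, "task_config"))
  if (length(bin_ms) != 1 || !is.finite(bin_ms) || bin_ms <= 0 ||
      bin_ms != round(bin_ms))
    stop("'bin_ms' must be a positive integer bin width")
  if (inherits(end_delay_ms, "trial_table")) end_delay_ms <- end_delay_ms$end_delay_ms
  if (!all(end_delay_ms %in% config$end_delay_choices_ms))
    stop("end delays outside the configured choices")
  onsets <- config$t_first_stim_ms + (0:5) * config$epoch_pitch_ms
  total <- config$t_first_stim_ms + 6 * config$epoch_pitch_ms + end_delay_ms
  list(bin_ms = bin_ms,
       stim_onset_bins = as.integer(onsets %/% bin_ms),
       target_onset_bin = 0L,
       n_bins = as.integer(total %/% bin_ms))
}
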