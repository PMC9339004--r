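#' Variable presets for the encoding model
#'
#' Two standard variable sets are used throughout: the evidence
#' decomposition set (stimulus onset, shape weight, stimulus color,
#' evidence, color consistency, color evidence, target onset, target
#' configuration) and the routing set (stimulus onset, stimulus color,
#' sw_in, sw_out). Any subset of the variable names below can also be
#' passed directly to [build_regressors()].
#'
#' @format NULL
#' @name variable_sets
NULL

.shape_variables <- c("stimulus_onset", "weight", "color", "evidence",
                      "consistency", "color_evidence", "sw_in", "sw_out")
.target_variables <- c("target_onset", "target_config")

#' @rdname variable_sets
#' @export
variable_set_decomposition <- function() {
  c("stimulus_onset", "weight", "color", "evidence", "consistency",
    "color_evidence", "target_onset", "target_config")
}

#' @rdname variable_sets
#' @export
variable_set_routing <- function() {
  c("stimulus_onset", "color", "sw_in", "sw_out")
}

# per-trial event amplitudes for one variable: n x n_events matrix
variable_values <- function(variable, trials, derived) {
  n <- nrow(trials)
  switch(variable,
    stimulus_onset = matrix(1, n, 6L),
    weight = derived$sw,
    color = derived$color,
    evidence = derived$evidence,
    consistency = derived$consistency,
    color_evidence = derived$color_evidence,
    sw_in = derived$sw_in,
    sw_out = derived$sw_out,
    target_onset = matrix(1, n, 1L),
    target_config = matrix(derived$configuration, n, 1L),
    stop(sprintf("unknown variable '%s'", variable))
  )
}

#' Build time-resolved regressors for the spike-train GLM
#'
#' Turns a trial table into the design matrix of the convolutional Poisson
#' GLM on the 10-ms bin clock. Each task variable contributes one column
#' per kernel lag. In `"impulse"` mode (the default) a variable places an
#' impulse of its per-stimulus amplitude at each event-onset bin, and the
#' kernel support (150 lags = 1500 ms for stimulus-locked variables, 300
#' lags = 3000 ms for target-locked variables) carries the full temporal
#' effect. In `"boxcar"` mode the amplitude is held for the variable's
#' nominal duration (1500 / 3000 ms) from the onset and convolved with a
#' shorter kernel whose support is set by `boxcar_kernel_lags`.
#' Contributions from late stimuli that extend past the go cue are
#' truncated at the end of each trial.
#'
#' @param trials a `trial_table`
#' @param derived a [derive_stimulus_vars()] result for the same trials
#' @param variables character vector of variable names (see
#'   [variable_sets]); events outside the model window are an error
#' @param config a [task_config()]
#' @param mode `"impulse"` (default) or `"boxcar"`
#' @param support_shape_lags,support_target_lags kernel supports, in 10-ms
#'   lags, for stimulus-locked and target-locked variables
#' @param boxcar_kernel_lags kernel support in boxcar mode
#' @param bin_ms bin width (ms)
#' @return An object of class `"regressor_set"` holding the sparse design
#'   matrix (without intercept), the per-variable column map, the
#'   row-to-trial map and everything needed to permute a variable's
#'   per-trial values across trials without rebuilding the matrix.
#' @export
build_regressors <- function(trials, derived, variables = variable_set_decomposition(),
                             config = task_config(),
                             mode = c("impulse", "boxcar"),
                             support_shape_lags = 150L,
                             support_target_lags = 300L,
                             boxcar_kernel_lags = 30L,
                             bin_ms = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(trials, "trial_table"), inherits(derived, "derived_vars"))
  bad <- setdiff(variables, c(.shape_variables, .target_variables))
  if (length(bad)) stop(sprintf("unknown variable(s): %s", paste(bad, collapse = ", ")))
  tl <- trial_timeline(trials, config, bin_ms)
  n <- nrow(trials)
  n_bins <- tl$n_bins
  row_offset <- c(0L, cumsum(n_bins))   # 0-based row offsets per trial
  n_rows <- row_offset[n + 1L]
  if (any(tl$stim_onset_bins >= n_bins[1L]))
    stop("stimulus events fall outside the model window")

  is_shape <- variables %in% .shape_variables
  support <- ifelse(is_shape, support_shape_lags, support_target_lags)
  names(support) <- variables
  if (mode == "boxcar") {
    box_len <- support                  # boxcar duration = nominal support
    support[] <- boxcar_kernel_lags
  }
  col_offset <- c(0L, cumsum(support))
  col_index <- lapply(seq_along(variables), function(v)
    (col_offset[v] + 1L):col_offset[v + 1L])
  names(col_index) <- variables
  p <- sum(support)

  values <- lapply(variables, variable_values, trials = trials, derived = derived)
  names(values) <- variables
  event_bins <- lapply(variables, function(v)
    if (v %in% .shape_variables) tl$stim_onset_bins else 0L)
  names(event_bins) <- variables

  # triplet skeleton: one entry per (variable, trial, event, output bin, lag)
  ti <- tj <- tt <- tval_id <- vector("list", length(variables))
  # tval_id indexes into the stacked per-variable value matrices so that
  # shuffled amplitudes can be written straight into the matrix's x slot
  val_offset <- 0L
  for (v in seq_along(variables)) {
    eb <- event_bins[[v]]
    E <- length(eb)
    L <- support[v]
    if (mode == "impulse") {
      # grid over (event, lag)
      e_g <- rep(seq_len(E), times = L)
      l_g <- rep(seq_len(L) - 1L, each = E)
      b_g <- eb[e_g] + l_g
    } else {
      D <- box_len[v]
      e_g <- rep(seq_len(E), times = L * D)
      l_g <- rep(rep(seq_len(L) - 1L, each = E), times = D)
      d_g <- rep(seq_len(D) - 1L, each = E * L)
      b_g <- eb[e_g] + l_g + d_g
    }
    m <- length(b_g)
    trial_g <- rep(seq_len(n), each = m)
    b_all <- rep(b_g, times = n)
    keep <- b_all < n_bins[trial_g]       # truncate at the go cue
    trial_k <- trial_g[keep]
    ti[[v]] <- row_offset[trial_k] + b_all[keep] + 1L
    tj[[v]] <- col_offset[v] + rep(l_g, times = n)[keep] + 1L
    tt[[v]] <- trial_k
    tval_id[[v]] <- val_offset + (rep(e_g, times = n)[keep] - 1L) * n + trial_k
    val_offset <- val_offset + n * E
  }
  ti <- unlist(ti); tj <- unlist(tj); tval_id <- unlist(tval_id)

  has_dups <- mode == "boxcar"
  if (!has_dups) {
    # learn the internal ordering once: build with triplet ids as values,
    # then every amplitude update is a single vector write into X@x
    X <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                              dims = c(n_rows, p))
    perm <- as.integer(X@x)
    X@x <- numeric(length(perm))
  } else {
    X <- NULL
    perm <- NULL
  }

  rs <- structure(list(
    X = X, variables = variables, col_index = col_index, support = support,
    mode = mode, bin_ms = bin_ms, delta_s = bin_ms / 1000,
    n_trials = n, n_bins = n_bins, n_rows = n_rows,
    row_offset = row_offset,
    row_trial = rep(seq_len(n), times = n_bins),
    event_bins = event_bins, values = values,
    triplets = list(i = ti, j = tj, val_id = tval_id, perm = perm),
    dims = c(n_rows, p)
  ), class = "regressor_set")
  rs$X <- regressor_matrix(rs)
  rs
}

# stack per-variable value matrices into the flat vector tval_id indexes
stacked_values <- function(rs, values = rs$values) {
  unlist(lapply(rs$variables, function(v) as.numeric(values[[v]])),
         use.names = FALSE)
}

#' Materialize the sparse design matrix of a regressor set
#'
#' @param rs a `regressor_set`
#' @param values optional replacement list of per-variable amplitude
#'   matrices (used internally for trial shuffles)
#' @return a `dgCMatrix` with one column per kernel lag
#' @export
regressor_matrix <- function(rs, values = rs$values) {
  stopifnot(inherits(rs, "regressor_set"))
  vals <- stacked_values(rs, values)[rs$triplets$val_id]
  if (!is.null(rs$triplets$perm)) {
    X <- rs$X
    if (is.null(X))
      X <- Matrix::sparseMatrix(i = rs$triplets$i, j = rs$triplets$j,
                                x = vals, dims = rs$dims)
    else
      X@x <- vals[rs$triplets$perm]
    X
  } else {
    Matrix::sparseMatrix(i = rs$triplets$i, j = rs$triplets$j, x = vals,
                         dims = rs$dims)
  }
}

#' Permute a variable's per-trial values across trials
#'
#' Implements the trial-shuffle used for null kernel distributions: the
#' named variables' per-trial amplitude rows are permuted by a common
#' trial permutation while every event time is kept in place.
#'
#' @param rs a `regressor_set`
#' @param variables variables to shuffle (default: all whose values vary
#'   across trials)
#' @param perm an integer permutation of the trials
#' @return a new `regressor_set` with the same skeleton and permuted
#'   amplitudes
#' @export
shuffle_regressors <- function(rs, variables = trial_varying(rs), perm) {
  stopifnot(inherits(rs, "regressor_set"),
            all(variables %in% rs$variables),
            length(perm) == rs$n_trials)
  values <- rs$values
  for (v in variables) values[[v]] <- values[[v]][perm, , drop = FALSE]
  rs$values <- values
  rs$X <- regressor_matrix(rs, values)
  rs
}

#' @rdname shuffle_regressors
#' @export
trial_varying <- function(rs) {
  stopifnot(inherits(rs, "regressor_set"))
  rs$variables[vapply(rs$values, function(m)
    any(m != rep(m[1L, ], each = nrow(m))), logical(1))]
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("Regressor set (%s mode): %d trials, %d bins, %d kernel columns\n",
              x$mode, x$n_trials, x$n_rows, sum(x$support)))
  cat("  variables:", paste(sprintf("%s[%d]", x$variables, x$support),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Flatten binned spike counts to the regressor row order
#'
#' Counts are stored as a trials-by-bins matrix padded with `NA` beyond
#' each trial's go cue; this drops the padding and lines counts up with
#' the design-matrix rows.
#'
#' @param counts matrix of 10-ms binned counts (trials x bins, `NA`-padded)
#' @param rs the `regressor_set` the counts belong with
#' @return integer vector of length `rs$n_rows`
#' @export
counts_vector <- function(counts, rs) {
  stopifnot(inherits(rs, "regressor_set"), nrow(counts) == rs$n_trials)
  r <- unlist(lapply(seq_len(rs$n_trials), function(t)
    counts[t, seq_len(rs$n_bins[t])]), use.names = FALSE)
  if (anyNA(r)) stop("counts contain NA inside the model window")
  if (any(r < 0) || any(r != round(r)))
    stop("counts must be non-negative integers")
  r
}
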