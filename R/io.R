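trial_csv_columns <- function() {
  c("trial_id", paste0("shape_", 1:6), paste0("color_", 1:6),
    "tin_color", "end_delay_ms", "choice", "chosen_color", "reward",
    "p_red", "p_green")
}

#' Read and write trial tables
#'
#' Trial tables are stored as plain CSV with one row per trial. Reading
#' validates the schema (missing columns are named) and the row contents
#' (shape ids 1..6, colors +1/-1, probabilities in (0,1)); malformed rows
#' are rejected with their row numbers.
#'
#' @param path CSV file path
#' @param trials a `trial_table`
#' @return `read_trials()` returns a `trial_table`; `write_trials()`
#'   returns the path invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_csv_columns(), names(df))
  if (length(missing_cols))
    stop("trial CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  shp <- as.matrix(df[paste0("shape_", 1:6)])
  col <- as.matrix(df[paste0("color_", 1:6)])
  bad <- which(rowSums(matrix(!(shp %in% 1:6), nrow(df))) > 0 |
               rowSums(matrix(!(col %in% c(-1, 1)), nrow(df))) > 0 |
               !(df$tin_color %in% c("red", "green")) |
               !is.finite(df$p_red) | df$p_red <= 0 | df$p_red >= 1 |
               !is.finite(df$p_green) | df$p_green <= 0 | df$p_green >= 1 |
               !is.finite(df$end_delay_ms) | df$end_delay_ms <= 0)
  if (length(bad))
    stop("malformed trial row(s): ", paste(utils::head(bad, 20), collapse = ", "))
  df$choice[df$choice %in% c("", "NA")] <- NA
  df$chosen_color[df$chosen_color %in% c("", "NA")] <- NA
  df$reward[df$reward %in% c("", "NA")] <- NA
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  stopifnot(inherits(trials, "trial_table"))
  utils::write.csv(as.data.frame(trials)[trial_csv_columns()], path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write binned spike counts
#'
#' Per-neuron counts are stored as CSV with one row per trial and one
#' column per 10-ms bin (`bin_0`, `bin_1`, ...); bins past a trial's go
#' cue are empty (`NA`). Reading validates that all present values are
#' non-negative integers.
#'
#' @param counts trials-by-bins integer matrix (`NA`-padded)
#' @param path CSV file path
#' @return `read_spike_counts()` returns the count matrix;
#'   `write_spike_counts()` returns the path invisibly.
#' @export
read_spike_counts <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  df <- utils::read.csv(path)
  m <- as.matrix(df)
  dimnames(m) <- list(NULL, colnames(df))
  vals <- m[!is.na(m)]
  if (any(vals < 0) || any(vals != round(vals)))
    stop("spike counts must be non-negative integers: ", path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_spike_counts
#' @export
write_spike_counts <- function(counts, path) {
  stopifnot(is.matrix(counts))
  df <- as.data.frame(counts)
  names(df) <- paste0("bin_", seq_len(ncol(counts)) - 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write task configuration as YAML
#'
#' Serializes the shape set (assigned and subjective weights), the task
#' timing/reward configuration and optionally the generative agent to a
#' single YAML file.
#'
#' @param shapes a [shape_set()]
#' @param config a [task_config()]
#' @param agent optional [agent_spec()]
#' @param path YAML file path
#' @return `read_config()` returns a list with elements `shapes`,
#'   `config` and (possibly `NULL`) `agent`.
#' @export
write_config <- function(shapes, config, path, agent = NULL) {
  stopifnot(inherits(shapes, "shape_set"), inherits(config, "task_config"))
  obj <- list(shapes = list(weights = shapes$weight, subjective = shapes$sw),
              task = unclass(config))
  if (!is.null(agent)) obj$agent <- unclass(agent)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- yaml::read_yaml(path)
  if (is.null(obj$shapes) || is.null(obj$task))
    stop("config YAML must contain 'shapes' and 'task' sections")
  shapes <- shape_set(obj$shapes$weights, obj$shapes$subjective)
  tk <- obj$task
  config <- task_config(tk$t_targets_ms, tk$t_first_stim_ms, tk$stim_on_ms,
                        tk$stim_gap_ms, unlist(tk$end_delay_choices_ms),
                        tk$reward_scheme, tk$none_for_worse,
                        tk$reward_large, tk$reward_small)
  agent <- if (!is.null(obj$agent))
    agent_spec(unlist(obj$agent$sw), obj$agent$beta0,
               unlist(obj$agent$epoch_gain))
  list(shapes = shapes, config = config, agent = agent)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `trials.csv`, `config.yaml`, one `neuron_NNN.csv` per neuron
#' and `ground_truth.json` (templates, baseline rates, per-neuron seeds
#' and planted kernels). Regeneration from the same master seed is
#' byte-identical.
#'
#' @param ds a [generate_dataset()] result
#' @param dir output directory (created if needed)
#' @return `read_dataset()` returns a list with `trials`, `counts`,
#'   `shapes`, `config`, `agent` and `ground_truth`.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create dataset directory: ", dir)
  write_trials(ds$trials, file.path(dir, "trials.csv"))
  write_config(ds$shapes, ds$config, file.path(dir, "config.yaml"),
               agent = ds$agent)
  for (i in seq_along(ds$counts))
    write_spike_counts(ds$counts[[i]],
                       file.path(dir, sprintf("neuron_%03d.csv", i)))
  gt <- list(master_seed = ds$master_seed,
             neuron_seeds = ds$neuron_seeds,
             variables = ds$regressors$variables,
             support = as.list(ds$regressors$support),
             mode = ds$regressors$mode,
             neurons = lapply(ds$specs, function(s)
               list(templates = s$templates,
                    baseline_rate = exp(s$baseline_log_rate),
                    kernels = s$kernels)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  trials <- read_trials(file.path(dir, "trials.csv"))
  cfg <- read_config(file.path(dir, "config.yaml"))
  files <- sort(list.files(dir, pattern = "^neuron_\\d+\\.csv$",
                           full.names = TRUE))
  counts <- lapply(files, read_spike_counts)
  names(counts) <- sub("\\.csv$", "", basename(files))
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE)
  list(trials = trials, counts = counts, shapes = cfg$shapes,
       config = cfg$config, agent = cfg$agent, ground_truth = gt)
}

#' Write an analysis result object as JSON
#'
#' @param object a list-like result
#' @param path output path
#' @export
write_results <- function(object, path) {
  jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records the seed, package version and MD5 of every input/output file
#' of a pipeline run (no timestamps, so reruns are byte-identical).
#'
#' @param seed the run seed
#' @param files character vector of file paths to fingerprint
#' @param extra optional named list merged into the manifest
#' @param path output JSON path
#' @export
write_manifest <- function(seed, files, path, extra = list()) {
  files <- files[file.exists(files)]
  manifest <- c(list(seed = seed,
                     package = "evacc",
                     version = as.character(utils::packageVersion("evacc")),
                     files = as.list(stats::setNames(
                       unname(tools::md5sum(files)), basename(files)))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
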