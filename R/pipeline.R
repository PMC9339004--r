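#' End-to-end analysis pipeline on synthetic data
#'
#' Runs the full chain deterministically under one seed: simulate a
#' cohort (trials, choices, rewards, spike trains), write the dataset to
#' disk, read it back, fit the behavioral models (subjective weights,
#' epoch leverage, psychometric curve), fit the encoding GLM per neuron,
#' run the shuffle-null inference, build the descriptive summaries, and
#' write JSON results plus a run manifest.
#'
#' @param out_dir output directory
#' @param seed integer master seed for every stochastic step
#' @param n_neurons,n_trials cohort size
#' @param n_shuffles shuffles for the significance null
#' @param variables regressor variables (a small set keeps smoke runs
#'   fast)
#' @param support_shape_lags,support_target_lags kernel supports (lags)
#' @param templates planted templates, recycled over neurons
#' @param cpd_reps CPD shuffle repetitions (0 skips CPD)
#' @param psth_epoch epoch for the PSTH / rate-evidence summaries
#' @return (invisibly) a list with the dataset, fits, per-neuron
#'   encoding tables, summaries and the written file paths
#' @export
run_pipeline <- function(out_dir, seed, n_neurons = 5L, n_trials = 100L,
                         n_shuffles = 5L,
                         variables = c("stimulus_onset", "weight", "evidence"),
                         support_shape_lags = 30L, support_target_lags = 60L,
                         templates = list(c("weight_neg_transient",
                                            "evidence_sustained"), "null"),
                         cpd_reps = 0L, psth_epoch = 3L) {
  if (missing(seed)) stop("'seed' is required")
  seed <- as.integer(seed)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)

  ds <- generate_dataset(n_neurons, n_trials, templates = templates,
                         master_seed = seed, variables = variables,
                         support_shape_lags = support_shape_lags,
                         support_target_lags = support_target_lags)
  data_dir <- file.path(out_dir, "dataset")
  write_dataset(ds, data_dir)
  back <- read_dataset(data_dir)

  sw_fit <- fit_subjective_weights(back$trials)
  ep_fit <- fit_epoch_leverage(back$trials, sw_fit$sw$sw)
  psych <- psychometric_curve(back$trials, back$shapes,
                              n_bins = min(9L, n_trials %/% 5L))
  behavior_path <- file.path(out_dir, "behavior.json")
  write_results(list(
    bias = unname(coef(sw_fit)[1]),
    subjective_weights = sw_fit$sw,
    epoch_leverage = ep_fit$epochs,
    psychometric = as.data.frame(psych)), behavior_path)

  derived <- derive_stimulus_vars(back$trials, back$shapes)
  rs <- build_regressors(back$trials, derived, variables,
                         config = back$config,
                         support_shape_lags = support_shape_lags,
                         support_target_lags = support_target_lags)
  encodings <- vector("list", length(back$counts))
  for (i in seq_along(back$counts)) {
    encodings[[i]] <- encoding_analysis(back$counts[[i]], rs,
                                        seed = seed + 100L + i,
                                        n_shuffles = n_shuffles,
                                        cpd_reps = cpd_reps)
  }
  names(encodings) <- names(back$counts)
  enc_tab <- do.call(rbind, lapply(seq_along(encodings), function(i)
    cbind(neuron = names(encodings)[i], encodings[[i]]$table)))
  encoding_path <- file.path(out_dir, "encoding.json")
  write_results(list(n_shuffles = n_shuffles, table = enc_tab), encoding_path)

  psth <- psth_by_quintile(back$counts, back$trials, derived, psth_epoch,
                           config = back$config)
  rate_fit <- rate_vs_evidence_fit(back$counts, back$trials, derived,
                                   psth_epoch, config = back$config)
  summary_path <- file.path(out_dir, "summary.json")
  write_results(list(psth = as.data.frame(psth), rate_vs_evidence = rate_fit$fits),
                summary_path)

  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(seed,
                 c(list.files(data_dir, full.names = TRUE),
                   behavior_path, encoding_path, summary_path),
                 manifest_path,
                 extra = list(n_neurons = n_neurons, n_trials = n_trials,
                              n_shuffles = n_shuffles,
                              variables = as.list(variables)))
  invisible(list(dataset = ds, behavior = list(sw = sw_fit, epochs = ep_fit,
                                               psychometric = psych),
                 encodings = encodings, encoding_table = enc_tab,
                 psth = psth, rate_vs_evidence = rate_fit,
                 paths = c(dataset = data_dir, behavior = behavior_path,
                           encoding = encoding_path, summary = summary_path,
                           manifest = manifest_path)))
}
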