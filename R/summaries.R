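#' Population PSTH by accumulated-evidence quintile
#'
#' Splits trials by choice (in-field vs out-field target), then within
#' each choice group into `n_groups` equal-count groups of the
#' accumulated evidence through the given epoch, and averages the firing
#' rate (counts / bin width) across trials and then across neurons,
#' aligned to that epoch's stimulus onset.
#'
#' @param counts a trials-by-bins matrix or a list of them (one per
#'   neuron)
#' @param trials the `trial_table`
#' @param derived the [derive_stimulus_vars()] result
#' @param epoch epoch 1..6 whose onset is the alignment event
#' @param config a [task_config()]
#' @param n_groups number of evidence groups per choice (default 5,
#'   i.e. quintiles; boundaries computed per choice group, group sizes
#'   within one trial of each other)
#' @param window_ms alignment window around stimulus onset
#' @param smoothing_ms width of an optional causal boxcar smoother
#'   (0 = raw bins)
#' @param bin_ms bin width (ms)
#' @return A `"psth_summary"` data frame: `choice`, `quintile`,
#'   `time_ms`, `rate` (sp/s, mean across neurons), `se` (across
#'   neurons), `n_trials`. Empty groups are dropped with a warning.
#' @export
psth_by_quintile <- function(counts, trials, derived, epoch,
                             config = task_config(), n_groups = 5L,
                             window_ms = c(-100, 800), smoothing_ms = 0,
                             bin_ms = 10) {
  if (is.matrix(counts)) counts <- list(counts)
  stopifnot(inherits(trials, "trial_table"), epoch %in% 1:6)
  tl <- trial_timeline(trials, config, bin_ms)
  onset <- tl$stim_onset_bins[epoch]
  b <- onset + seq(window_ms[1] %/% bin_ms,
                   window_ms[2] %/% bin_ms - 1L)
  if (min(b) < 0 || max(b) >= min(tl$n_bins))
    stop("alignment window extends outside the model window")
  time_ms <- (b - onset) * bin_ms
  acc <- accumulated_evidence(derived, epoch)
  rows <- list()
  for (ch in c("T_in", "T_out")) {
    i_ch <- which(trials$choice == ch)
    if (!length(i_ch)) { warning(sprintf("no %s trials; group dropped", ch)); next }
    g <- ceiling(rank(acc[i_ch], ties.method = "first") * n_groups / length(i_ch))
    for (q in seq_len(n_groups)) {
      i_q <- i_ch[g == q]
      if (!length(i_q)) { warning("empty evidence group dropped"); next }
      per_neuron <- vapply(counts, function(m)
        colMeans(m[i_q, b + 1L, drop = FALSE]) / (bin_ms / 1000), numeric(length(b)))
      rate <- rowMeans(per_neuron)
      se <- if (length(counts) > 1) apply(per_neuron, 1, stats::sd) / sqrt(length(counts))
            else rep(NA_real_, length(b))
      if (smoothing_ms > 0) {
        k <- max(1L, smoothing_ms %/% bin_ms)
        rate <- as.numeric(stats::filter(rate, rep(1 / k, k), sides = 1))
      }
      rows[[length(rows) + 1L]] <-
        data.frame(choice = ch, quintile = q, time_ms = time_ms,
                   rate = rate, se = se, n_trials = length(i_q))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "epoch") <- epoch
  class(out) <- c("psth_summary", "data.frame")
  out
}

#' @export
plot.psth_summary <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(x$quintile), "Zissou 1")
  plot(range(x$time_ms), range(x$rate, na.rm = TRUE), type = "n",
       xlab = "time from stimulus onset (ms)", ylab = "rate (sp/s)", ...)
  for (ch in unique(x$choice)) for (q in unique(x$quintile)) {
    d <- x[x$choice == ch & x$quintile == q, ]
    graphics::lines(d$time_ms, d$rate, col = cols[q],
                    lty = if (ch == "T_in") 1 else 2)
  }
  invisible(x)
}

#' Firing rate versus accumulated evidence, per epoch
#'
#' For each choice group, averages the population firing rate over a
#' post-onset window (300-800 ms by default, spanning into the next
#' epoch as the task's 466-ms pitch dictates), bins trials into six
#' equal-count groups of accumulated evidence, and fits an ordinary
#' least-squares line to the six bin means. The slope's two-tailed
#' p-value is reported without multiple-comparison adjustment.
#'
#' @inheritParams psth_by_quintile
#' @param window_ms averaging window after stimulus onset (ms)
#' @param n_bins number of equal-count evidence bins (6)
#' @return list with `fits` (data frame: epoch, choice, slope, intercept,
#'   p_slope) and `bins` (per-bin means)
#' @export
rate_vs_evidence_fit <- function(counts, trials, derived, epoch,
                                 config = task_config(),
                                 window_ms = c(300, 800), n_bins = 6L,
                                 bin_ms = 10) {
  if (is.matrix(counts)) counts <- list(counts)
  stopifnot(epoch %in% 1:6)
  tl <- trial_timeline(trials, config, bin_ms)
  onset <- tl$stim_onset_bins[epoch]
  b <- onset + seq(window_ms[1] %/% bin_ms, window_ms[2] %/% bin_ms - 1L)
  if (max(b) >= min(tl$n_bins))
    stop("averaging window extends outside the model window")
  acc <- accumulated_evidence(derived, epoch)
  pop <- Reduce(`+`, lapply(counts, function(m)
    rowMeans(m[, b + 1L, drop = FALSE]))) / length(counts) / (bin_ms / 1000)
  fits <- list(); bins <- list()
  for (ch in c("T_in", "T_out")) {
    i_ch <- which(trials$choice == ch)
    if (length(i_ch) < n_bins)
      stop(sprintf("fewer than %d %s trials", n_bins, ch))
    g <- ceiling(rank(acc[i_ch], ties.method = "first") * n_bins / length(i_ch))
    bt <- do.call(rbind, lapply(seq_len(n_bins), function(k) {
      i <- i_ch[g == k]
      data.frame(epoch = epoch, choice = ch, bin = k, n = length(i),
                 evidence = mean(acc[i]), rate = mean(pop[i]))
    }))
    lmfit <- stats::lm(rate ~ evidence, data = bt)
    sm <- summary(lmfit)$coefficients
    fits[[ch]] <- data.frame(epoch = epoch, choice = ch,
                             slope = sm["evidence", "Estimate"],
                             intercept = sm["(Intercept)", "Estimate"],
                             se_slope = sm["evidence", "Std. Error"],
                             p_slope = sm["evidence", "Pr(>|t|)"])
    bins[[ch]] <- bt
  }
  list(fits = do.call(rbind, c(fits, make.row.names = FALSE)),
       bins = do.call(rbind, c(bins, make.row.names = FALSE)))
}

#' Compare two latency distributions
#'
#' Classic two-sample t test with pooled variance (not Welch), two
#' tailed, as used for comparing encoding-latency distributions across
#' variables or cohorts.
#'
#' @param latencies_a,latencies_b numeric vectors (each >= 2 values)
#' @return list with `t`, `df`, `p`, and the two means
#' @export
latency_compare <- function(latencies_a, latencies_b) {
  if (length(latencies_a) < 2 || length(latencies_b) < 2)
    stop("each latency set needs at least 2 values")
  tt <- tryCatch(stats::t.test(latencies_a, latencies_b, var.equal = TRUE),
                 error = function(e)
                   stop("degenerate latency sets: ", conditionMessage(e)))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(latencies_a), mean_b = mean(latencies_b))
}
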