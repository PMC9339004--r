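test_that("reward probability follows the base-10 logistic rule", {
  expect_equal(reward_probability(0), 0.5)
  expect_equal(reward_probability(1), 10 / 11, tolerance = 1e-12)
  expect_equal(reward_probability(-1), 1 / 11, tolerance = 1e-12)
  # strictly increasing and complementary under sign flip
  s <- seq(-4, 4, by = 0.25)
  p <- reward_probability(s)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  expect_equal(reward_probability(-s), 1 - p, tolerance = 1e-12)
  expect_error(reward_probability(NaN), "finite")
  expect_error(reward_probability(Inf), "finite")
})

test_that("reward probability and base-10 log odds are inverse maps", {
  s <- c(-4, -0.3, 0, 0.42, 2, 4)
  expect_lt(max(abs(reward_logodds(reward_probability(s)) - s)), 1e-12)
  p <- c(1e-6, 0.25, 0.5, 0.9, 1 - 1e-6)
  expect_lt(max(abs(reward_probability(reward_logodds(p)) - p)), 1e-12)
  expect_error(reward_logodds(0), "inside")
  expect_error(reward_logodds(1), "inside")
})

test_that("trial sampling honors structure, determinism and uniformity", {
  ss <- fixture_shapes()
  tr <- sample_trials(500, ss, seed = 3)
  expect_s3_class(tr, "trial_table")
  expect_equal(nrow(tr), 500)
  shp <- as.matrix(tr[paste0("shape_", 1:6)])
  col <- as.matrix(tr[paste0("color_", 1:6)])
  expect_true(all(shp %in% 1:6))
  expect_true(all(col %in% c(-1, 1)))
  # n_red + n_green = 6 is structural
  expect_true(all(rowSums(col == 1) + rowSums(col == -1) == 6))
  expect_true(all(tr$end_delay_ms %in% c(433, 533, 633)))
  expect_identical(tr, sample_trials(500, ss, seed = 3))

  big <- sample_trials(10000, ss, seed = 4)   # 60,000 stimulus draws
  f_shape <- tabulate(as.matrix(big[paste0("shape_", 1:6)]), 6) / 60000
  se_shape <- sqrt((1 / 6) * (5 / 6) / 60000)
  expect_true(all(abs(f_shape - 1 / 6) < 3 * se_shape))
  f_red <- mean(as.matrix(big[paste0("color_", 1:6)]) == 1)
  expect_lt(abs(f_red - 0.5), 3 * sqrt(0.25 / 60000))
})

test_that("red and green reward probabilities are computed independently", {
  ss <- fixture_shapes()
  tr <- sample_trials(300, ss, seed = 9)
  w <- matrix(ss$weight[as.matrix(tr[paste0("shape_", 1:6)])], 300)
  col <- as.matrix(tr[paste0("color_", 1:6)])
  expect_equal(tr$p_red, reward_probability(rowSums(w * (col == 1))))
  expect_equal(tr$p_green, reward_probability(rowSums(w * (col == -1))))
  # the two probabilities do not generally sum to 1
  expect_gt(max(abs(tr$p_red + tr$p_green - 1)), 0.05)
})

test_that("reward assignment matches both schemes", {
  ss <- fixture_shapes()
  tr <- sample_trials(50000, ss, seed = 5)
  tr <- set_choices(tr, sample(c("red", "green"), nrow(tr), replace = TRUE))
  expect_error(assign_reward(sample_trials(3, ss, seed = 1), seed = 1),
               "choice")

  prob <- assign_reward(tr, task_config(), seed = 6)
  expect_true(all(prob$reward %in% c("large", "small")))
  p_chosen <- ifelse(tr$chosen_color == "red", tr$p_red, tr$p_green)
  expect_lt(abs(mean(prob$reward == "large") - mean(p_chosen)),
            3 * sqrt(0.25 / nrow(tr)))
  # near-degenerate probabilities give (almost) always large
  hi <- which(p_chosen > 0.999)
  expect_true(length(hi) > 50)
  expect_true(mean(prob$reward[hi] == "large") > 0.99)

  bet <- assign_reward(tr, task_config(reward_scheme = "better_only"), seed = 6)
  p_other <- ifelse(tr$chosen_color == "red", tr$p_green, tr$p_red)
  worse <- p_chosen < p_other
  expect_true(all(bet$reward[worse] == "none"))
  expect_true(all(bet$reward[!worse] %in% c("large", "small")))
  soft <- assign_reward(tr, task_config(reward_scheme = "better_only",
                                        none_for_worse = FALSE), seed = 6)
  expect_true(all(soft$reward[worse] == "small"))
})

test_that("derived stimulus variables obey their defining identities", {
  ss <- fixture_shapes()
  tr <- sample_trials(10000, ss, seed = 21)
  dv <- derive_stimulus_vars(tr, ss)
  cfgn <- ifelse(tr$tin_color == "red", 1, -1)
  expect_identical(dv$consistency, dv$color * cfgn)
  expect_identical(dv$evidence, dv$sw * dv$consistency)
  expect_identical(dv$color_evidence, dv$sw * dv$color)
  expect_identical(dv$evidence, dv$color_evidence * cfgn)
  expect_true(all(dv$sw_in * dv$sw_out == 0))
  expect_identical(dv$sw_in + dv$sw_out, dv$sw)
  expect_identical(dv$sw_in - dv$sw_out, dv$evidence)
})

test_that("hand-built stimuli map to the documented variable values", {
  # one trial: epoch-1 shape with sw +0.5 shown green, T_in red
  ss <- shape_set(weights = c(-0.9, -0.5, -0.3, 0.3, 0.5, 0.9))
  tr <- manual_trials(shape = matrix(c(5, 1, 1, 1, 1, 1), 1),
                      color = matrix(c(-1, 1, 1, 1, 1, 1), 1),
                      tin_color = "red")
  dv <- derive_stimulus_vars(tr, ss)
  expect_equal(dv$consistency[1, 1], -1)
  expect_equal(dv$evidence[1, 1], -0.5)
  expect_equal(dv$color_evidence[1, 1], -0.5)
  expect_equal(dv$sw_in[1, 1], 0)
  expect_equal(dv$sw_out[1, 1], 0.5)
  # sw -0.3 shown red with T_in red
  tr2 <- manual_trials(shape = matrix(c(3, 1, 1, 1, 1, 1), 1),
                       color = matrix(1, 1, 6), tin_color = "red")
  dv2 <- derive_stimulus_vars(tr2, ss)
  expect_equal(dv2$consistency[1, 1], 1)
  expect_equal(dv2$evidence[1, 1], -0.3)
  expect_equal(dv2$color_evidence[1, 1], -0.3)
  expect_equal(dv2$sw_in[1, 1], -0.3)
  expect_equal(dv2$sw_out[1, 1], 0)
  expect_error(derive_stimulus_vars(
    manual_trials(matrix(7, 1, 6), matrix(1, 1, 6), "red"), ss), "shape")
})

test_that("accumulated evidence is the running sw_in minus sw_out sum", {
  ss <- shape_set(weights = c(-0.9, -0.5, -0.3, 0.3, 0.5, 0.9))
  # epochs: sw_out +0.9 (epoch 1), sw_in +0.5, sw_in -0.3 (epochs 2-3)
  tr <- manual_trials(shape = matrix(c(6, 5, 3, 1, 1, 1), 1),
                      color = matrix(c(-1, 1, 1, 1, 1, 1), 1),
                      tin_color = "red")
  dv <- derive_stimulus_vars(tr, ss)
  expect_equal(accumulated_evidence(dv, 1), -0.9)
  expect_equal(accumulated_evidence(dv, 3), -0.7)
  expect_error(accumulated_evidence(dv, 0), "epoch")
  expect_error(accumulated_evidence(dv, 7), "epoch")
  # at epoch 6 it equals the total evidence
  trs <- sample_trials(200, ss, seed = 31)
  dvs <- derive_stimulus_vars(trs, ss)
  expect_equal(accumulated_evidence(dvs, 6), rowSums(dvs$evidence))
})

test_that("the trial timeline places events on the documented bins", {
  tl <- trial_timeline(c(433, 533, 633), task_config())
  expect_equal(tl$stim_onset_bins[1], 53)
  expect_equal(tl$stim_onset_bins[2], 99)
  expect_equal(tl$stim_onset_bins, c(53, 99, 146, 193, 239, 286))
  expect_equal(tl$n_bins, c(376, 386, 396))
  expect_equal(tl$target_onset_bin, 0L)
  expect_error(trial_timeline(433, task_config(), bin_ms = 2.5), "bin")
  expect_error(trial_timeline(400, task_config()), "delay")
})
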