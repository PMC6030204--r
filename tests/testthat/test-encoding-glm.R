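glm_session <- function(seed = 3, n_trials_per_block = 40) {
  cfg <- generator_config(n_neurons = 2,
                          archetype_mix = c(choice = 0.5, stimulus = 0.5),
                          noise_sd = 0.1,
                          n_trials_per_block = n_trials_per_block,
                          seed = seed)
  generate_session(cfg)$session
}

test_that("design-matrix column counts match the model definitions", {
  s <- glm_session()
  expect_equal(ncol(build_design_matrix(s, "full")$X), 112)
  expect_equal(ncol(build_design_matrix(s, "stimulus_only")$X), 43)
  expect_equal(ncol(build_design_matrix(s, "motor_only")$X), 27)
  expect_equal(ncol(build_design_matrix(s, "stim_engagement")$X), 86)
})

test_that("onset predictors carry a single 1 at the stimulus-onset frame", {
  tr <- make_trials(c("Hit", "CR"))
  ep <- trial_epochs(5)
  s <- imaging_session(tr, matrix(rnorm(2 * ep$frames_per_trial), 1))
  d <- build_design_matrix(s, "full")
  W <- d$frames_per_trial
  s_tar_lag0 <- d$X[, which(d$labels == "S_tar")[1]]
  # trial 1 is the target (A) trial: one onset tick there, none on trial 2
  expect_equal(which(s_tar_lag0[1:W] == 1), ep$stim_onset_frame)
  expect_true(all(s_tar_lag0[(W + 1):(2 * W)] == 0))
  # engaged stimulus-duration predictor spans the stimulus frames
  e_tar_lag0 <- d$X[, which(d$labels == "E_tar")[1]]
  expect_equal(which(e_tar_lag0[1:W] == 1),
               intersect(ep$stim, seq_len(W)))
  # lags never bleed across the trial boundary
  s_tar_lag20 <- d$X[, which(d$labels == "S_tar")[21]]
  expect_true(all(s_tar_lag20[(W + 1):(2 * W)] == 0))
})

test_that("ridge matches the closed-form normal-equation oracle", {
  set.seed(10)
  for (rep in 1:5) {
    X <- cbind(1, matrix(rnorm(50 * 19), 50, 19))
    y <- rnorm(50)
    lambda <- 10^runif(1, -2, 2)
    beta <- fit_ridge(X, y, lambda)
    D <- diag(c(0, rep(1, 19)))
    oracle <- solve(t(X) %*% X + lambda * D, t(X) %*% y)
    expect_lt(max(abs(beta - oracle)), 1e-8)
  }
  expect_error(fit_ridge(cbind(1, rnorm(5)), rnorm(5), -1), "nonnegative")
})

test_that("ridge limits: exact recovery at 0, shrinkage to mean at Inf", {
  set.seed(4)
  X <- cbind(1, matrix(rnorm(60 * 10), 60, 10))
  beta_true <- rnorm(11)
  y <- as.numeric(X %*% beta_true)
  expect_lt(max(abs(fit_ridge(X, y, 0) - beta_true)), 1e-8)
  b_inf <- fit_ridge(X, y, 1e12)
  expect_lt(max(abs(b_inf[-1])), 1e-6)
  expect_equal(b_inf[1], mean(y), tolerance = 1e-4)
})

test_that("lambda selection stays on the grid and reacts to noise", {
  s <- glm_session(seed = 6, n_trials_per_block = 20)
  d <- build_design_matrix(s, "stimulus_only")
  set.seed(2)
  beta_true <- rnorm(ncol(d$X), 0, 0.3)
  y_clean <- as.numeric(d$X %*% beta_true)
  grid <- 10^seq(-2, 4, length.out = 13)
  bigger <- 0
  for (i in 1:20) {
    set.seed(100 + i)
    y_noisy <- 0.1 * y_clean + rnorm(length(y_clean), 0, 1)
    l_clean <- select_lambda(d, y_clean, seed = i)$lambda
    l_noisy <- select_lambda(d, y_noisy, seed = i)$lambda
    expect_true(l_clean >= min(grid) && l_clean <= max(grid))
    expect_true(l_noisy >= min(grid) && l_noisy <= max(grid))
    bigger <- bigger + (l_noisy > l_clean)
  }
  expect_gte(bigger / 20, 0.8)
  # deterministic given the seed
  expect_identical(select_lambda(d, y_clean, seed = 9)$lambda,
                   select_lambda(d, y_clean, seed = 9)$lambda)
})

test_that("holdout R2 has the documented fixed points", {
  y <- rnorm(40)
  expect_equal(evaluate_r2(y, y), 1)
  expect_equal(evaluate_r2(y, rep(mean(y), 40)), 0)
  expect_lt(evaluate_r2(y, rep(mean(y) + 10, 40)), 0)
  expect_true(is.na(evaluate_r2(rep(1, 10), rnorm(10))))
})

test_that("components plus bias reproduce the full prediction", {
  s <- glm_session()
  fit <- fit_encoding_glm(s, 1, seed = 5)
  cs <- component_prediction(fit, "stimulus")
  ce <- component_prediction(fit, "engagement")
  cm <- component_prediction(fit, "motor")
  total <- cs$trace + ce$trace + cm$trace + coef(fit)["bias"]
  expect_lt(max(abs(total - predict(fit))), 1e-10)
  # engagement component is identically zero on passive-trial frames
  passive_rows <- fit$design$trial_types[fit$design$trial_ids] %in%
    c("PassiveT", "PassiveNT")
  expect_true(all(ce$trace[passive_rows] == 0))
  # motor component appears on both Hit and FA lick trials
  for (ty in c("Hit", "FA")) {
    rows <- fit$design$trial_types[fit$design$trial_ids] == ty
    if (any(rows)) expect_gt(max(abs(cm$trace[rows])), 0)
  }
})

test_that("train/test separation is airtight and order-insensitive", {
  s <- glm_session()
  fit <- fit_encoding_glm(s, 1, seed = 8)
  expect_length(intersect(fit$split$train, fit$split$test), 0)
  expect_setequal(c(fit$split$train, fit$split$test),
                  seq_len(nrow(s$trials)))
  # about 20% per condition held out
  frac <- length(fit$split$test) / nrow(s$trials)
  expect_gt(frac, 0.12); expect_lt(frac, 0.3)
})

test_that("fitted coefficients recover a planted coefficient vector", {
  s <- glm_session(seed = 12)
  d <- build_design_matrix(s, "full")
  set.seed(3)
  beta_true <- c(0, rnorm(111, 0, 0.5))
  y <- as.numeric(d$X %*% beta_true) + rnorm(nrow(d$X), 0, 0.1)
  lam <- select_lambda(d, y, seed = 2)$lambda
  beta_hat <- fit_ridge(d, y, lam)
  # late-lag stimulus columns have no support inside the 5 s trial window
  # (the lag reaches past the window end), so only supported coefficients
  # are identifiable
  supported <- colSums(abs(d$X)) > 0 & d$labels != "bias"
  expect_gt(cor(beta_hat[supported], beta_true[supported]), 0.95)
})

test_that("bootstrap comparison: identical models are never 'worse'", {
  s <- glm_session()
  split <- glm_trial_split(build_design_matrix(s, "full"), seed = 4)
  fit <- fit_encoding_glm(s, 1, seed = 4, split = split)
  cmp <- bootstrap_model_comparison(fit, fit, n_boot = 300, seed = 1)
  expect_equal(cmp$p_worse_than_full, 1)  # ties count as not-worse
  expect_equal(cmp$relative_r2, 1)
})

test_that("stimulus-only model is flagged worse for a choice cell", {
  cfg <- generator_config(n_neurons = 1, archetype_mix = c(choice = 1),
                          noise_sd = 0.1, n_trials_per_block = 40,
                          seed = 17)
  s <- generate_session(cfg)$session
  split <- glm_trial_split(build_design_matrix(s, "full"), seed = 2)
  fit_full <- fit_encoding_glm(s, 1, "full", seed = 2, split = split)
  fit_stim <- fit_encoding_glm(s, 1, "stimulus_only", seed = 2,
                               split = split)
  cmp <- bootstrap_model_comparison(fit_full, fit_stim, n_boot = 400,
                                    seed = 3)
  expect_lt(cmp$p_worse_than_full, 0.05)
  expect_lt(cmp$p_significant_full, 0.05)
  expect_lt(cmp$relative_r2, 0.8)
})

test_that("a pure-noise cell yields no significant model fit", {
  cfg <- generator_config(n_neurons = 1, archetype_mix = c(silent = 1),
                          noise_sd = 0.1, n_trials_per_block = 40,
                          seed = 23)
  s <- generate_session(cfg)$session
  fit <- fit_encoding_glm(s, 1, seed = 1)
  cmp <- bootstrap_model_comparison(fit, fit, n_boot = 300, seed = 2)
  expect_gte(cmp$p_significant_full, 0.05)
})
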