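#' Build the lagged binary design matrix for the encoding model
#'
#' The model regresses a z-scored calcium trace on lagged binary task
#' predictors over the first 5 s of each trial (from cue onset),
#' concatenated across trials:
#' \itemize{
#'   \item a constant bias;
#'   \item target- and non-target-stimulus onset predictors (1 only at the
#'     stimulus-onset frame, engaged or passive), lags 0-20;
#'   \item a constant engagement offset (1 on every engaged-trial frame);
#'   \item engaged-stimulus duration predictors (1 for all frames of
#'     stimulus presentation on engaged trials, per identity), lags 0-20;
#'   \item a lick predictor (1 during lick bouts), lags -10..15
#'     (anti-causal lags capture pre-bout activity).
#' }
#' Lags never cross trial boundaries: predictor support is zeroed outside
#' its own trial window. The full model has 112 columns; the
#' `stimulus_only`, `motor_only` and `stim_engagement` variants have 43,
#' 27 and 86.
#'
#' @param session an [imaging_session()].
#' @param variant "full", "stimulus_only", "motor_only" or
#'   "stim_engagement".
#' @return list of class `glm_design` with `X` (frames x coefficients),
#'   `labels` (column component labels), `trial_ids` (row to trial map),
#'   `trial_types` (6-level condition per trial), `variant`.
#' @export
build_design_matrix <- function(session,
                                variant = c("full", "stimulus_only",
                                            "motor_only",
                                            "stim_engagement")) {
  variant <- match.arg(variant)
  ep <- session$epochs
  W <- length(ep$glm_window)
  trials <- session$trials
  n_tr <- nrow(trials)
  target <- if (session$contingency == "original") "A" else "B"
  stim_lags <- 0:20
  lick_lags <- -10:15

  lag_block <- function(base, lags) {
    # column for lag i holds base[t - i] within the trial window
    out <- matrix(0, W, length(lags))
    for (k in seq_along(lags)) {
      i <- lags[k]
      src <- seq_len(W) - i
      ok <- src >= 1 & src <= W
      out[ok, k] <- base[src[ok]]
    }
    out
  }

  onset_vec <- function() { v <- numeric(W); v[ep$stim_onset_frame] <- 1; v }
  stim_dur_vec <- function() {
    v <- numeric(W); v[intersect(ep$stim, seq_len(W))] <- 1; v
  }

  blocks <- vector("list", n_tr)
  for (tr in seq_len(n_tr)) {
    eng <- trials$condition[tr] == "Engaged"
    is_tar <- trials$stimulus[tr] == target
    zero <- numeric(W)
    s_tar <- if (is_tar) onset_vec() else zero
    s_nt <- if (!is_tar) onset_vec() else zero
    e_const <- if (eng) rep(1, W) else zero
    e_tar <- if (eng && is_tar) stim_dur_vec() else zero
    e_nt <- if (eng && !is_tar) stim_dur_vec() else zero
    lick <- zero
    lt <- if (nzchar(trials$lick_times[tr]))
      as.numeric(strsplit(trials$lick_times[tr], ";", fixed = TRUE)[[1]])
    else numeric(0)
    if (length(lt)) {
      bouts <- detect_lick_bouts(lt)
      for (b in seq_len(nrow(bouts))) {
        f1 <- floor(bouts$start[b] * session$frame_rate) + 1L
        f2 <- ceiling(max(bouts$end[b], bouts$start[b] + 1e-9) *
                        session$frame_rate)
        f <- f1:f2
        lick[f[f >= 1 & f <= W]] <- 1
      }
    }
    blocks[[tr]] <- cbind(
      bias = 1,
      lag_block(s_tar, stim_lags), lag_block(s_nt, stim_lags),
      e_const,
      lag_block(e_tar, stim_lags), lag_block(e_nt, stim_lags),
      lag_block(lick, lick_lags)
    )
  }
  X <- do.call(rbind, blocks)
  labels <- c("bias",
              rep("S_tar", length(stim_lags)), rep("S_nt", length(stim_lags)),
              "E_const",
              rep("E_tar", length(stim_lags)), rep("E_nt", length(stim_lags)),
              rep("L", length(lick_lags)))
  keep <- switch(variant,
    full = rep(TRUE, length(labels)),
    stimulus_only = labels %in% c("bias", "S_tar", "S_nt"),
    motor_only = labels %in% c("bias", "L"),
    stim_engagement = labels != "L")
  trial_types <- ifelse(trials$condition == "Passive",
                        ifelse(trials$stimulus == target, "PassiveT",
                               "PassiveNT"),
                        trials$outcome)
  structure(list(X = X[, keep, drop = FALSE], labels = labels[keep],
                 trial_ids = rep(seq_len(n_tr), each = W),
                 trial_types = trial_types, variant = variant,
                 frames_per_trial = W), class = "glm_design")
}

#' Ridge regression with unpenalised bias
#'
#' Minimises `||y - X b||^2 + lambda * ||b_penalised||^2`, where the bias
#' column is unpenalised; solved in closed form from the normal equations.
#'
#' @param design a `glm_design` (or plain matrix; then all columns but the
#'   first are penalised).
#' @param y response, length nrow(X).
#' @param lambda ridge penalty, >= 0.
#' @return coefficient vector.
#' @export
fit_ridge <- function(design, y, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  X <- if (inherits(design, "glm_design")) design$X else design
  labels <- if (inherits(design, "glm_design")) design$labels
            else c("bias", rep("x", ncol(X) - 1))
  stopifnot(nrow(X) == length(y))
  pen <- as.numeric(labels != "bias")
  A <- crossprod(X) + lambda * diag(pen, ncol(X))
  as.numeric(solve(A, crossprod(X, y)))
}

#' Coefficient of determination on held-out frames
#'
#' `R^2 = 1 - SSE / SST`, SST taken around the mean of the evaluated
#' frames; negative when the model does worse than a horizontal line.
#'
#' @param y observed, `yhat` predicted values (same frames).
#' @return R^2 (possibly negative), NA when y has zero variance.
#' @export
evaluate_r2 <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}

#' Cross-validated ridge-penalty selection
#'
#' Five-fold cross-validation over a log-spaced grid in [1e-2, 1e4]
#' (13 points, two per decade). Folds split by trial, stratified by trial
#' type; the lambda maximising mean held-fold R^2 wins (first/smallest on
#' ties).
#'
#' @param design a `glm_design`.
#' @param y response over all design rows.
#' @param train_trials trial indices available for CV.
#' @param folds number of folds.
#' @param grid candidate lambdas.
#' @param seed seed for fold assignment.
#' @return list with `lambda`, `cv_r2` (per grid point).
#' @export
select_lambda <- function(design, y, train_trials = NULL, folds = 5,
                          grid = 10^seq(-2, 4, length.out = 13), seed = 1) {
  if (is.null(train_trials)) train_trials <- unique(design$trial_ids)
  if (stats::sd(y[design$trial_ids %in% train_trials]) == 0) {
    warning("zero-variance response; returning grid maximum")
    return(list(lambda = max(grid), cv_r2 = rep(NA_real_, length(grid))))
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  types <- design$trial_types[train_trials]
  fold_of <- integer(length(train_trials))
  for (ty in unique(types)) {
    idx <- sample(which(types == ty))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  cv <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    hold_tr <- train_trials[fold_of == f]
    if (!length(hold_tr)) next
    fit_tr <- setdiff(train_trials, hold_tr)
    rows_fit <- design$trial_ids %in% fit_tr
    rows_hold <- design$trial_ids %in% hold_tr
    Xf <- design$X[rows_fit, , drop = FALSE]
    Xh <- design$X[rows_hold, , drop = FALSE]
    XtX <- crossprod(Xf); Xty <- crossprod(Xf, y[rows_fit])
    pen <- diag(as.numeric(design$labels != "bias"), ncol(Xf))
    for (g in seq_along(grid)) {
      beta <- tryCatch(as.numeric(solve(XtX + grid[g] * pen, Xty)),
                       error = function(e) NULL)
      if (is.null(beta)) next
      cv[f, g] <- evaluate_r2(y[rows_hold], as.numeric(Xh %*% beta))
    }
  }
  mean_r2 <- colMeans(cv, na.rm = TRUE)
  list(lambda = grid[which.max(mean_r2)], cv_r2 = mean_r2)
}

#' Fit the encoding model for one neuron
#'
#' End-to-end: z-scores the neuron's trace over the session, sets aside
#' `test_frac` of trials from each of the six conditions (Hit, CR, Miss,
#' FA, passive target, passive non-target) for testing, selects the ridge
#' penalty by five-fold cross-validation on the training trials, fits the
#' final model, and evaluates held-out R^2.
#'
#' @param session an [imaging_session()].
#' @param neuron trace-matrix row.
#' @param variant model variant (see [build_design_matrix()]).
#' @param test_frac held-out fraction per condition.
#' @param folds CV folds.
#' @param grid lambda grid.
#' @param seed seed governing the split and fold assignment.
#' @param split optional precomputed list(train, test) of trial indices,
#'   to evaluate several variants on identical splits.
#' @return object of class `encoding_fit`.
#' @export
fit_encoding_glm <- function(session, neuron, variant = "full",
                             test_frac = 0.2, folds = 5,
                             grid = 10^seq(-2, 4, length.out = 13),
                             seed = 1, split = NULL) {
  design <- build_design_matrix(session, variant)
  tr_full <- session$traces[neuron, ]
  z <- (tr_full - mean(tr_full)) / stats::sd(tr_full)
  ep <- session$epochs
  rows_keep <- as.vector(vapply(seq_len(nrow(session$trials)), function(i)
    (i - 1L) * ep$frames_per_trial + ep$glm_window,
    integer(length(ep$glm_window))))
  y <- z[rows_keep]
  if (is.null(split)) split <- glm_trial_split(design, test_frac, seed)
  rows_train <- design$trial_ids %in% split$train
  rows_test <- design$trial_ids %in% split$test
  sel <- select_lambda(design, y, train_trials = split$train,
                       folds = folds, grid = grid, seed = seed)
  Xtr <- design$X[rows_train, , drop = FALSE]
  pen <- diag(as.numeric(design$labels != "bias"), ncol(Xtr))
  beta <- as.numeric(solve(crossprod(Xtr) + sel$lambda * pen,
                           crossprod(Xtr, y[rows_train])))
  yhat <- as.numeric(design$X %*% beta)
  structure(list(
    coefficients = stats::setNames(beta, make.unique(design$labels)),
    labels = design$labels, lambda = sel$lambda, cv_r2 = sel$cv_r2,
    variant = variant, neuron = neuron,
    split = split, design = design, y = y, fitted = yhat,
    r2_test = evaluate_r2(y[rows_test], yhat[rows_test]),
    r2_train = evaluate_r2(y[rows_train], yhat[rows_train])
  ), class = "encoding_fit")
}

#' Stratified train/test trial split for the encoding model
#'
#' @param design a `glm_design`.
#' @param test_frac fraction per condition set aside for testing.
#' @param seed seed.
#' @return list with `train` and `test` trial-index vectors.
#' @export
glm_trial_split <- function(design, test_frac = 0.2, seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  types <- design$trial_types
  test <- integer(0)
  for (ty in unique(types)) {
    idx <- which(types == ty)
    n_test <- if (length(idx) >= 2) max(1L, round(test_frac * length(idx)))
              else 0L
    if (n_test > 0) test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(types), test), test = sort(test))
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf(
    "Encoding model (%s), neuron %d: %d coefficients, lambda = %.3g\n",
    x$variant, x$neuron, length(x$coefficients), x$lambda))
  cat(sprintf("  R2 train = %.3f, R2 test = %.3f (%d train / %d test trials)\n",
              x$r2_train, x$r2_test, length(x$split$train),
              length(x$split$test)))
  invisible(x)
}

#' @export
coef.encoding_fit <- function(object, ...) object$coefficients

#' @export
predict.encoding_fit <- function(object, ...) object$fitted

#' @export
residuals.encoding_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.encoding_fit <- function(x, trial_type = NULL, ...) {
  W <- x$design$frames_per_trial
  types <- x$design$trial_types
  if (is.null(trial_type)) trial_type <- names(sort(table(types),
                                                    decreasing = TRUE))[1]
  idx <- which(types == trial_type)
  obs <- matrix(x$y, nrow = W)[, idx, drop = FALSE]
  fit <- matrix(x$fitted, nrow = W)[, idx, drop = FALSE]
  t_ax <- (seq_len(W) - 1) / (W / 5)
  graphics::plot(t_ax, rowMeans(obs), type = "l", xlab = "time from cue (s)",
                 ylab = "z-scored dF/F",
                 main = sprintf("neuron %d, %s trials", x$neuron, trial_type),
                 ...)
  graphics::lines(t_ax, rowMeans(fit), col = 2, lty = 2)
  graphics::legend("topleft", c("observed", "model"), col = c(1, 2),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Single-component model prediction
#'
#' Prediction using only one predictor group's coefficients (others set to
#' zero, bias excluded), in units of z-scored dF/F. The component-strength
#' summary averages the component prediction over 0-4 s after stimulus
#' onset (clipped to the 5 s trial window) on the preferred trial type
#' (Hit or CR for stimulus/engagement; Hit for motor).
#'
#' @param fit a full-model `encoding_fit`.
#' @param component "stimulus", "engagement" or "motor".
#' @param preferred "Hit" or "CR" (used for stimulus/engagement strength).
#' @return list with `trace` (per-frame component prediction over all
#'   trials) and `strength`.
#' @export
component_prediction <- function(fit, component = c("stimulus",
                                                    "engagement", "motor"),
                                 preferred = "Hit") {
  component <- match.arg(component)
  cols <- switch(component,
    stimulus = fit$labels %in% c("S_tar", "S_nt"),
    engagement = fit$labels %in% c("E_const", "E_tar", "E_nt"),
    motor = fit$labels == "L")
  if (!any(cols)) stop("fit lacks the ", component, " component (variant ",
                       fit$variant, ")")
  trace <- as.numeric(fit$design$X[, cols, drop = FALSE] %*%
                        fit$coefficients[cols])
  W <- fit$design$frames_per_trial
  rate <- W / 5
  onset <- round(1.5 * rate) + 1
  win <- onset:min(W, onset + round(4 * rate) - 1)
  use_type <- if (component == "motor") "Hit" else preferred
  idx <- which(fit$design$trial_types == use_type)
  strength <- if (length(idx)) {
    m <- matrix(trace, nrow = W)[, idx, drop = FALSE]
    mean(rowMeans(m)[win])
  } else NA_real_
  list(trace = trace, strength = strength, component = component)
}

#' Bootstrap comparison of full and partial encoding models
#'
#' Resamples the held-out test trials with replacement `n_boot` times and
#' recomputes each model's R^2 per iteration. `p_significant_*` is the
#' fraction of iterations with R^2 <= 0 (model no better than a horizontal
#' line); `p_worse_than_full` is the fraction of iterations in which the
#' partial model's R^2 is at least the full model's (one-sided).
#'
#' @param fit_full,fit_partial `encoding_fit`s sharing the same test
#'   split.
#' @param n_boot bootstrap iterations.
#' @param seed seed.
#' @return list with `p_significant_full`, `p_significant_partial`,
#'   `p_worse_than_full`, `relative_r2` (partial / full point estimates).
#' @export
bootstrap_model_comparison <- function(fit_full, fit_partial,
                                       n_boot = 2000, seed = 1) {
  if (!identical(fit_full$split$test, fit_partial$split$test))
    stop("fits use different test splits")
  test <- fit_full$split$test
  if (length(test) < 2) stop("need at least 2 test trials")
  W <- fit_full$design$frames_per_trial
  rows_of <- function(tr) rep((tr - 1) * W, each = W) + seq_len(W)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  r2f <- r2p <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    samp <- sample(test, length(test), replace = TRUE)
    rows <- rows_of(samp)
    yb <- fit_full$y[rows]
    r2f[b] <- evaluate_r2(yb, fit_full$fitted[rows])
    r2p[b] <- evaluate_r2(yb, fit_partial$fitted[rows])
  }
  list(p_significant_full = mean(r2f <= 0),
       p_significant_partial = mean(r2p <= 0),
       p_worse_than_full = mean(r2p >= r2f),
       relative_r2 = fit_partial$r2_test / fit_full$r2_test)
}
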