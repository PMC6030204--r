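#' Naka-Rushton (hyperbolic ratio) contrast-response function
#'
#' `R(C) = R_max * C^n / (C^n + C50^n) + R0`: a saturating curve with
#' half-saturation contrast `C50`, steepness exponent `n`, saturation
#' amplitude `R_max` and baseline `R0`.
#'
#' @param C contrast, percent (>= 0).
#' @param r_max,c50,n,r0 curve parameters (`c50 > 0`).
#' @return response at each contrast.
#' @export
naka_rushton <- function(C, r_max, c50, n, r0 = 0) {
  stopifnot(all(C >= 0), c50 > 0)
  r_max * C^n / (C^n + c50^n) + r0
}

# per contrast x condition means, trial counts and variance-of-the-mean
# weights shared by the fitter and the GOF test
.nr_aggregate <- function(responses) {
  stopifnot(all(c("contrast", "condition", "response") %in%
                  names(responses)))
  agg <- stats::aggregate(response ~ contrast + condition, responses,
                          function(x) c(m = mean(x), v = stats::var(x),
                                        n = length(x)))
  dat <- data.frame(contrast = agg$contrast, condition = agg$condition,
                    mean = agg$response[, "m"],
                    var_mean = agg$response[, "v"] / agg$response[, "n"],
                    n = agg$response[, "n"])
  if (all(!is.finite(dat$var_mean)) || all(dat$var_mean == 0, na.rm = TRUE)) {
    warning("all response variances zero; using unweighted fit")
    dat$weight <- 1
  } else {
    w <- dat$var_mean
    w[!is.finite(w) | w <= 0] <- min(w[is.finite(w) & w > 0])
    dat$weight <- w
  }
  dat
}

#' Build a contrast_fit from known parameters
#'
#' Wraps given Naka-Rushton parameters and a trial data set into a
#' `contrast_fit` so that [bootstrap_gof()] and [predict.contrast_fit()]
#' can evaluate a hypothesised (e.g. planted) model without refitting.
#'
#' @param responses per-trial response data.frame (`contrast`,
#'   `condition`, `response`).
#' @param engaged,passive lists with `r_max`, `c50`, `r0`.
#' @param n shared exponent.
#' @return a `contrast_fit`.
#' @export
contrast_fit_from_params <- function(responses, engaged, passive, n) {
  structure(list(engaged = engaged, passive = passive, n = n,
                 objective = NA_real_, data = .nr_aggregate(responses),
                 converged = TRUE, gof_asl = NA_real_, excluded = NA),
            class = "contrast_fit")
}

# variance-weighted SSE between model and per-cell means
.nr_objective <- function(par, dat) {
  # par: rmax_e, c50_e, r0_e, rmax_p, c50_p, r0_p, n (shared)
  pred <- ifelse(dat$condition == "Engaged",
                 naka_rushton(dat$contrast, par[1], par[2], par[7], par[3]),
                 naka_rushton(dat$contrast, par[4], par[5], par[7], par[6]))
  sum((pred - dat$mean)^2 / dat$weight)
}

#' Fit Naka-Rushton curves to engaged and passive responses jointly
#'
#' Both conditions are fit simultaneously with the exponent `n`
#' constrained equal across conditions (7 parameters), minimising the sum
#' over data points of squared error divided by the variance of that point
#' (variance of the mean response at each contrast). Optimisation is
#' bounded multi-start L-BFGS-B; with all-zero variances an unweighted fit
#' is performed with a warning.
#'
#' @param responses data.frame of per-trial responses with columns
#'   `contrast` (percent), `condition` ("Engaged"/"Passive"), `response`
#'   (dF/F).
#' @param bounds list of parameter bounds (defaults: `r_max` in [0, 10],
#'   `c50` in [1, 100], `n` in [0.5, 6], `r0` in [-10, 10]).
#' @param n_starts number of multi-start initialisations.
#' @return object of class `contrast_fit` with per-condition `r_max`,
#'   `c50`, `r0`, shared `n`, per-point data summary, convergence flag.
#' @export
fit_contrast_response <- function(responses,
                                  bounds = list(r_max = c(0, 10),
                                                c50 = c(1, 100),
                                                n = c(0.5, 6),
                                                r0 = c(-10, 10)),
                                  n_starts = 8) {
  dat <- .nr_aggregate(responses)
  lower <- c(bounds$r_max[1], bounds$c50[1], bounds$r0[1],
             bounds$r_max[1], bounds$c50[1], bounds$r0[1], bounds$n[1])
  upper <- c(bounds$r_max[2], bounds$c50[2], bounds$r0[2],
             bounds$r_max[2], bounds$c50[2], bounds$r0[2], bounds$n[2])
  rng_e <- range(dat$mean[dat$condition == "Engaged"])
  rng_p <- if (any(dat$condition == "Passive"))
    range(dat$mean[dat$condition == "Passive"]) else c(0, 0)
  cgrid <- exp(seq(log(2), log(60), length.out = 4))
  ngrid <- c(1, 2, 4)
  starts <- expand.grid(c50 = cgrid, n = ngrid)
  starts <- starts[seq_len(min(n_starts * 3, nrow(starts))), ]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- c(max(diff(rng_e), 1e-3), starts$c50[s], rng_e[1],
              max(diff(rng_p), 1e-3), starts$c50[s], rng_p[1],
              starts$n[s])
    par0 <- pmin(pmax(par0, lower), upper)
    opt <- tryCatch(
      stats::optim(par0, .nr_objective, dat = dat, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best))
    return(structure(list(converged = FALSE), class = "contrast_fit"))
  p <- best$par
  structure(list(
    engaged = list(r_max = p[1], c50 = p[2], r0 = p[3]),
    passive = list(r_max = p[4], c50 = p[5], r0 = p[6]),
    n = p[7], objective = best$value, data = dat,
    converged = best$convergence == 0 || best$value < Inf,
    gof_asl = NA_real_, excluded = NA
  ), class = "contrast_fit")
}

#' @export
print.contrast_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) { cat("contrast fit: not converged\n")
    return(invisible(x)) }
  cat(sprintf(
    "Naka-Rushton fit (shared n = %.2f)\n  engaged: R_max %.3f, C50 %.1f%%, R0 %.3f\n  passive: R_max %.3f, C50 %.1f%%, R0 %.3f\n",
    x$n, x$engaged$r_max, x$engaged$c50, x$engaged$r0,
    x$passive$r_max, x$passive$c50, x$passive$r0))
  if (!is.na(x$gof_asl))
    cat(sprintf("  bootstrap GOF ASL = %.3f (%s)\n", x$gof_asl,
                if (isTRUE(x$excluded)) "excluded" else "retained"))
  invisible(x)
}

#' @export
coef.contrast_fit <- function(object, ...) {
  c(r_max_engaged = object$engaged$r_max, c50_engaged = object$engaged$c50,
    r0_engaged = object$engaged$r0, r_max_passive = object$passive$r_max,
    c50_passive = object$passive$c50, r0_passive = object$passive$r0,
    n = object$n)
}

#' @export
predict.contrast_fit <- function(object, contrast,
                                 condition = "Engaged", ...) {
  pp <- if (condition == "Engaged") object$engaged else object$passive
  naka_rushton(contrast, pp$r_max, pp$c50, object$n, pp$r0)
}

#' @export
plot.contrast_fit <- function(x, ...) {
  d <- x$data
  cs <- exp(seq(log(max(min(d$contrast), 0.5)), log(max(d$contrast)),
                length.out = 50))
  graphics::plot(d$contrast[d$condition == "Engaged"],
                 d$mean[d$condition == "Engaged"], log = "x",
                 xlab = "contrast (%)", ylab = "response (dF/F)",
                 pch = 16, ...)
  graphics::points(d$contrast[d$condition == "Passive"],
                   d$mean[d$condition == "Passive"], pch = 1)
  graphics::lines(cs, predict(x, cs, "Engaged"))
  graphics::lines(cs, predict(x, cs, "Passive"), lty = 2)
  graphics::legend("topleft", c("engaged", "passive"), pch = c(16, 1),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Bootstrap goodness-of-fit test for a contrast-response fit
#'
#' Tests the null hypothesis that the mean response at each point equals
#' the model prediction. The observed prediction error `e_obs` is the sum
#' of squared differences between per-point mean responses and model
#' predictions. Trials are shifted so their cell means equal the model
#' predictions, then resampled (within contrast x condition) `n_boot`
#' times; each resample yields an error `e_i` computed exactly like
#' `e_obs`. The achieved significance level (ASL) is the proportion of
#' `e_i` at least as large as `e_obs`; fits with ASL < 0.10 are excluded.
#'
#' The error statistic is deliberately unweighted: reusing the
#' variance-weighted fitting objective would make the test anticonservative
#' (frozen weights understate the bootstrap error's spread) or
#' conservative (re-estimated weights overstate it), whereas the plain SSE
#' lets the bootstrap replicate the observed statistic's null distribution
#' and keeps the 10% exclusion rule calibrated.
#'
#' @param fit a `contrast_fit`.
#' @param responses the per-trial response data.frame used for the fit.
#' @param n_boot bootstrap samples.
#' @param seed seed.
#' @param asl_cutoff exclusion threshold.
#' @return the fit with `gof_asl` and `excluded` filled in.
#' @export
bootstrap_gof <- function(fit, responses, n_boot = 1000, seed = 1,
                          asl_cutoff = 0.10) {
  stopifnot(inherits(fit, "contrast_fit"))
  dat <- fit$data
  pred <- ifelse(dat$condition == "Engaged",
                 predict(fit, dat$contrast, "Engaged"),
                 predict(fit, dat$contrast, "Passive"))
  e_obs <- sum((pred - dat$mean)^2)
  cell_of <- interaction(responses$contrast, responses$condition,
                         drop = TRUE)
  key <- interaction(dat$contrast, dat$condition, drop = TRUE)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # null-conforming data: shift each cell so its mean equals the model
  shifted <- split(responses$response, cell_of)
  shifted <- lapply(levels(cell_of), function(lv) {
    i <- match(lv, as.character(key))
    shifted[[lv]] - mean(shifted[[lv]]) + pred[i]
  })
  names(shifted) <- levels(cell_of)
  ord <- match(as.character(key), levels(cell_of))
  e_boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    m_b <- vapply(levels(cell_of), function(lv) {
      x <- shifted[[lv]]
      mean(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    e_boot[b] <- sum((pred - m_b[ord])^2)
  }
  fit$gof_asl <- mean(e_boot >= e_obs)
  fit$excluded <- fit$gof_asl < asl_cutoff
  fit
}

#' Contrast / engagement modulation profile of one neuron
#'
#' Contrast modulation: ROC index of engaged high-contrast (32, 64%) vs
#' engaged low-contrast (2, 4%) responses. Engagement modulation: engaged
#' vs passive at high contrasts only. Both carry permutation significance.
#'
#' @param nr a [neuron_response()] from a variable-contrast session.
#' @param high,low contrast sets, percent.
#' @param n_perm,seed permutation settings.
#' @param min_trials minimum trials per side.
#' @return list with `contrast_index`, `engagement_index` (roc_index or
#'   NULL) and `group` (see [classify_modulation_group()]).
#' @export
modulation_profile <- function(nr, high = c(32, 64), low = c(2, 4),
                               n_perm = 2000, seed = 1, min_trials = 5) {
  target <- if (nr$contingency == "original") "A" else "B"
  on_target <- nr$trials$stimulus == target
  eng <- on_target & nr$trials$condition == "Engaged"
  pas <- on_target & nr$trials$condition == "Passive"
  hi_e <- which(eng & nr$trials$contrast %in% high)
  lo_e <- which(eng & nr$trials$contrast %in% low)
  ci <- if (length(hi_e) >= min_trials && length(lo_e) >= min_trials)
    permutation_significance(nr$stim_resp[hi_e], nr$stim_resp[lo_e],
                             n_perm = n_perm, seed = seed)
  else NULL
  hi_p <- which(pas & nr$trials$contrast %in% high)
  ei <- if (length(hi_e) >= min_trials && length(hi_p) >= min_trials)
    permutation_significance(nr$stim_resp[hi_e], nr$stim_resp[hi_p],
                             n_perm = n_perm, seed = seed + 1)
  else NULL
  list(contrast_index = ci, engagement_index = ei,
       group = classify_modulation_group(ci, ei))
}

#' Modulation group from the two significance flags
#'
#' @param contrast_index,engagement_index `roc_index` objects (or NULL).
#' @return "contrast_only", "engagement_only", "both" or "neither".
#' @export
classify_modulation_group <- function(contrast_index, engagement_index) {
  sig_pos <- function(ri) !is.null(ri) && isTRUE(ri$significant) &&
    ri$index > 0
  cs <- sig_pos(contrast_index); es <- sig_pos(engagement_index)
  if (cs && es) "both"
  else if (cs) "contrast_only"
  else if (es) "engagement_only"
  else "neither"
}

#' Spatial organisation of modulation groups
#'
#' For task-responsive, target-preferring neurons with 2-D positions
#' (planes collapsed): per-cell mean Euclidean distance to same-group and
#' other-group cells, |index difference| of cell pairs binned by distance
#' (40 um bins), the Pearson correlation of pairwise |index difference|
#' with distance, and a clustered signed-rank test of within-vs-across
#' distance differences (clusters = imaging fields).
#'
#' @param profiles data.frame with columns `x`, `y` (um), `group`,
#'   `index` (the modulation index) and optionally `field` (cluster id).
#' @param bin_um distance bin width.
#' @return list with `per_cell` (within/across mean distances),
#'   `binned` (distance bin vs mean |index difference|), `correlation`,
#'   `within_vs_across` (clustered test, NA if a single field).
#' @export
spatial_group_stats <- function(profiles, bin_um = 40) {
  stopifnot(nrow(profiles) >= 2)
  if (is.null(profiles$field)) profiles$field <- "field1"
  n <- nrow(profiles)
  D <- as.matrix(stats::dist(profiles[, c("x", "y")]))
  same <- outer(profiles$group, profiles$group, "==")
  diag(same) <- NA
  per_cell <- data.frame(
    within = vapply(seq_len(n), function(i)
      mean(D[i, which(same[i, ])]), numeric(1)),
    across = vapply(seq_len(n), function(i)
      mean(D[i, which(!same[i, ])]), numeric(1)),
    group = profiles$group, field = profiles$field
  )
  ut <- upper.tri(D)
  d_pair <- D[ut]
  di_pair <- abs(outer(profiles$index, profiles$index, "-"))[ut]
  bins <- floor(d_pair / bin_um) * bin_um + bin_um / 2
  binned <- stats::aggregate(di_pair, list(bin = bins), mean)
  names(binned) <- c("distance", "mean_abs_dindex")
  corr <- if (stats::sd(d_pair) > 0 && stats::sd(di_pair) > 0)
    stats::cor(d_pair, di_pair) else NA_real_
  ok <- is.finite(per_cell$within) & is.finite(per_cell$across)
  test <- if (sum(ok) >= 2) {
    tryCatch(clustered_rank_test(per_cell$within[ok] - per_cell$across[ok],
                                 per_cell$field[ok],
                                 method = "signed_rank"),
             error = function(e) NULL)
  } else NULL
  list(per_cell = per_cell, binned = binned, correlation = corr,
       within_vs_across = test)
}
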