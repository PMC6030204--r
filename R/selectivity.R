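#' Per-trial response summary of one neuron
#'
#' Sorts one neuron's trace by trial and computes, per trial: the baseline
#' (mean dF/F over the 1 s before stimulus onset), the stimulus-window
#' response (mean over the last 1.6 s of the stimulus, baseline
#' subtracted), the response-period mean (1.5 s after stimulus offset,
#' baseline subtracted), and the trial segment over the first 5 s from cue
#' onset (baseline subtracted, one value per frame).
#'
#' @param session an [imaging_session()].
#' @param neuron row index into the trace matrix.
#' @return list of class `neuron_response` with vectors `baseline`,
#'   `stim_resp`, `resp_period`, matrix `segments` (trials x frames), the
#'   trial table and epochs.
#' @export
neuron_response <- function(session, neuron) {
  ep <- session$epochs
  tr <- session$traces[neuron, ]
  n_tr <- nrow(session$trials)
  fpt <- ep$frames_per_trial
  seg_all <- matrix(tr, nrow = n_tr, ncol = fpt, byrow = TRUE)
  base <- rowMeans(seg_all[, ep$baseline, drop = FALSE])
  structure(list(
    neuron = neuron,
    baseline = base,
    stim_resp = rowMeans(seg_all[, ep$stim_window, drop = FALSE]) - base,
    resp_period = rowMeans(seg_all[, ep$response, drop = FALSE]) - base,
    segments = seg_all[, ep$glm_window, drop = FALSE] - base,
    trials = session$trials, epochs = ep,
    contingency = session$contingency
  ), class = "neuron_response")
}

# trial-index helper: rows of the trial table matching an outcome set
.trials_of <- function(nr, outcomes) which(nr$trials$outcome %in% outcomes)

#' Task-responsiveness test
#'
#' A neuron is task-responsive if, on Hit or on CR trials, (a) its
#' stimulus-window dF/F significantly exceeds the pre-stimulus baseline
#' (two-sample two-tailed t-test across trials at `p_thresh` with a
#' positive mean difference), and (b) its trial-averaged response exceeds
#' the baseline mean by at least `snr_sd` baseline standard deviations at
#' some frame of the stimulus or response period (signal-to-noise
#' criterion). Each trial type needs at least `min_trials` trials; if
#' neither type has enough the neuron is excluded (NA), which is distinct
#' from non-responsive (FALSE).
#'
#' @param nr a [neuron_response()].
#' @param p_thresh t-test significance threshold.
#' @param snr_sd SNR threshold in baseline SD units.
#' @param min_trials minimum trials per tested type.
#' @param outcomes trial types tested (default Hit and CR).
#' @return TRUE/FALSE, or NA when too few trials.
#' @export
classify_task_responsive <- function(nr, p_thresh = 0.01, snr_sd = 2,
                                     min_trials = 5,
                                     outcomes = c("Hit", "CR")) {
  ep <- nr$epochs
  tested <- 0L
  for (oc in outcomes) {
    idx <- .trials_of(nr, oc)
    if (length(idx) < min_trials) next
    tested <- tested + 1L
    stim_means <- nr$stim_resp[idx] + nr$baseline[idx]
    base_means <- nr$baseline[idx]
    if (stats::sd(c(stim_means, base_means)) == 0) next
    tt <- tryCatch(stats::t.test(stim_means, base_means),
                   error = function(e) NULL)
    sig <- !is.null(tt) && tt$p.value < p_thresh &&
      mean(stim_means) > mean(base_means)
    if (!sig) next
    # SNR criterion on the trial-averaged, baseline-subtracted waveform
    avg <- colMeans(matrix(nr$segments[idx, ], nrow = length(idx)))
    base_fr <- avg[ep$baseline]
    thr <- mean(base_fr) + snr_sd * stats::sd(base_fr)
    probe <- intersect(c(ep$stim, ep$response), seq_along(avg))
    if (any(avg[probe] > thr, na.rm = TRUE)) return(TRUE)
  }
  if (tested == 0L) return(NA)
  FALSE
}

#' Stimulus preference of a responsive neuron
#'
#' Target- vs non-target-preferring, from the mean engaged
#' stimulus-window response (Hit/Miss vs FA/CR trials). Ties resolve to
#' target with an attribute flag.
#'
#' @param nr a [neuron_response()].
#' @return "target" or "nontarget" (attribute `tie` when tied).
#' @export
stimulus_preference <- function(nr) {
  tar <- .trials_of(nr, c("Hit", "Miss"))
  nt <- .trials_of(nr, c("FA", "CR"))
  m_tar <- mean(nr$stim_resp[tar])
  m_nt <- mean(nr$stim_resp[nt])
  if (m_tar == m_nt) return(structure("target", tie = TRUE))
  if (m_tar > m_nt) "target" else "nontarget"
}

#' Task-gating test
#'
#' A responsive neuron is task-gated if it fails the responsiveness test
#' for its preferred stimulus during passive trials. Returns NA
#' (undetermined) when the session has no (or too few) passive trials of
#' the preferred stimulus.
#'
#' @param nr a [neuron_response()].
#' @param min_trials minimum passive trials required.
#' @return TRUE (gated) / FALSE / NA (undetermined).
#' @export
classify_task_gated <- function(nr, min_trials = 5) {
  pref <- stimulus_preference(nr)
  target_stim <- if (nr$contingency == "original") "A" else "B"
  stim <- if (pref == "target") target_stim else setdiff(c("A", "B"),
                                                         target_stim)
  oc <- paste0("Passive", stim)
  if (length(.trials_of(nr, oc)) < min_trials) return(NA)
  resp_passive <- classify_task_responsive(nr, outcomes = oc,
                                           min_trials = min_trials)
  if (is.na(resp_passive)) return(NA)
  !resp_passive
}

# outcome sets defining each comparison (positive class first)
.comparison_sets <- function(comparison) {
  switch(comparison,
    "Hit>CR" = list(pos = "Hit", neg = "CR"),
    "Hit>FA" = list(pos = "Hit", neg = "FA"),
    "FA>CR" = list(pos = "FA", neg = "CR"),
    "Miss>CR" = list(pos = "Miss", neg = "CR"),
    "Hit>Miss" = list(pos = "Hit", neg = "Miss"),
    "Engaged>Passive" = list(pos = c("Hit", "Miss", "FA", "CR"),
                             neg = c("PassiveA", "PassiveB")),
    "A>B" = list(pos = NULL, neg = NULL),  # resolved on stimulus identity
    stop("unknown comparison: ", comparison)
  )
}

#' ROC selectivity between two trial types
#'
#' Computes the ROC-based selectivity index (positive class named first)
#' on baseline-subtracted stimulus-window responses, with permutation
#' significance. With `epoch = "time_resolved"` the index is evaluated
#' independently in each 200 ms time bin (one frame at 5 Hz) over the
#' first 5 s of the trial. Comparisons with fewer than `min_trials` trials
#' in either class return NULL (exclusion).
#'
#' @param nr a [neuron_response()].
#' @param comparison one of "Hit>CR", "Hit>FA", "FA>CR", "Miss>CR",
#'   "Hit>Miss", "Engaged>Passive", "A>B".
#' @param epoch "stimulus" (last 1.6 s window) or "time_resolved".
#' @param min_trials minimum trials per class.
#' @param n_perm,seed permutation-test settings.
#' @param drop_trailing_misses exclude the end-of-session Miss run before
#'   Miss-based comparisons.
#' @param engaged_only restrict "A>B" to engaged trials.
#' @return for "stimulus": a `roc_index`; for "time_resolved": a list with
#'   `bins` (data.frame time, index) and the per-bin indices; NULL when
#'   excluded.
#' @export
compute_selectivity <- function(nr, comparison,
                                epoch = c("stimulus", "time_resolved"),
                                min_trials = 5, n_perm = 2000, seed = 1,
                                drop_trailing_misses = TRUE,
                                engaged_only = TRUE) {
  epoch <- match.arg(epoch)
  keep <- rep(TRUE, nrow(nr$trials))
  if (drop_trailing_misses) keep <- keep_after_trailing_misses(nr$trials)
  if (comparison == "A>B") {
    pool <- if (engaged_only) nr$trials$condition == "Engaged" else
      rep(TRUE, nrow(nr$trials))
    pos_idx <- which(keep & pool & nr$trials$stimulus == "A")
    neg_idx <- which(keep & pool & nr$trials$stimulus == "B")
  } else {
    sets <- .comparison_sets(comparison)
    pos_idx <- intersect(which(keep), .trials_of(nr, sets$pos))
    neg_idx <- intersect(which(keep), .trials_of(nr, sets$neg))
  }
  if (length(pos_idx) < min_trials || length(neg_idx) < min_trials)
    return(NULL)
  if (epoch == "stimulus") {
    res <- permutation_significance(nr$stim_resp[pos_idx],
                                    nr$stim_resp[neg_idx],
                                    n_perm = n_perm, seed = seed)
    res$comparison <- comparison
    return(res)
  }
  nb <- ncol(nr$segments)
  idx_series <- vapply(seq_len(nb), function(b)
    roc_index(nr$segments[pos_idx, b], nr$segments[neg_idx, b])$index,
    numeric(1))
  list(comparison = comparison,
       bins = data.frame(
         time = (seq_len(nb) - 0.5) / (nb / 5),
         index = idx_series),
       n_pos = length(pos_idx), n_neg = length(neg_idx))
}

#' Population time-resolved selectivity test
#'
#' At each time bin, tests whether the average selectivity across neurons
#' differs from zero using the clustered signed-rank test (clusters =
#' imaging fields).
#'
#' @param bin_indices matrix neurons x bins of time-resolved indices.
#' @param cluster_ids imaging-field id per neuron.
#' @return data.frame with one row per bin: `bin`, `mean_index`, `p`.
#' @export
time_resolved_population_test <- function(bin_indices, cluster_ids) {
  out <- lapply(seq_len(ncol(bin_indices)), function(b) {
    ct <- clustered_rank_test(bin_indices[, b], cluster_ids,
                              method = "signed_rank")
    data.frame(bin = b, mean_index = mean(bin_indices[, b]),
               p = ct$p_value)
  })
  do.call(rbind, out)
}

#' Engagement modulation index
#'
#' ROC index comparing engaged vs passive responses to the neuron's
#' preferred stimulus; in the variable-contrast task only high-contrast
#' trials are used.
#'
#' @param nr a [neuron_response()].
#' @param high_contrasts contrasts counted as high (used when the session
#'   has multiple contrasts).
#' @param min_trials minimum trials per condition.
#' @param n_perm,seed permutation-test settings.
#' @return a `roc_index` (positive = engaged larger), or NULL when a
#'   condition is missing.
#' @export
engagement_modulation_index <- function(nr, high_contrasts = c(32, 64),
                                        min_trials = 5, n_perm = 2000,
                                        seed = 1) {
  pref <- stimulus_preference(nr)
  target_stim <- if (nr$contingency == "original") "A" else "B"
  stim <- if (pref == "target") target_stim else setdiff(c("A", "B"),
                                                         target_stim)
  sel <- nr$trials$stimulus == stim
  if (length(unique(nr$trials$contrast)) > 1)
    sel <- sel & nr$trials$contrast %in% high_contrasts
  eng <- which(sel & nr$trials$condition == "Engaged")
  pas <- which(sel & nr$trials$condition == "Passive")
  if (length(eng) < min_trials || length(pas) < min_trials) return(NULL)
  permutation_significance(nr$stim_resp[eng], nr$stim_resp[pas],
                           n_perm = n_perm, seed = seed)
}

#' Lick-count-matched trial selection
#'
#' Splits FA trials into low-lick (1-3 licks) and high-lick (>= 5 licks)
#' subsets and randomly selects Hit trials with 5-9 licks whose mean lick
#' count matches the FA-high subset. Sessions lacking `min_trials` trials
#' in any bin are excluded (NULL).
#'
#' @param trials trial table with an `n_licks` column.
#' @param min_trials minimum trials per subset.
#' @param seed seed for the random Hit selection.
#' @return list with integer trial-row vectors `fa_low`, `fa_high`,
#'   `hit_matched`, or NULL when excluded.
#' @export
match_lick_counts <- function(trials, min_trials = 5, seed = 1) {
  fa <- which(trials$outcome == "FA")
  hit <- which(trials$outcome == "Hit")
  fa_low <- fa[trials$n_licks[fa] >= 1 & trials$n_licks[fa] <= 3]
  fa_high <- fa[trials$n_licks[fa] >= 5]
  hit_pool <- hit[trials$n_licks[hit] >= 5 & trials$n_licks[hit] <= 9]
  if (length(fa_low) < min_trials || length(fa_high) < min_trials ||
      length(hit_pool) < min_trials) return(NULL)
  target_mean <- mean(trials$n_licks[fa_high])
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  # greedy draw: repeatedly sample subsets and keep the best count match
  n_sel <- max(min_trials, min(length(hit_pool), length(fa_high)))
  best <- NULL; best_err <- Inf
  for (i in 1:200) {
    cand <- sample(hit_pool, n_sel)
    err <- abs(mean(trials$n_licks[cand]) - target_mean)
    if (err < best_err) { best <- cand; best_err <- err }
    if (best_err < 0.1) break
  }
  list(fa_low = fa_low, fa_high = fa_high, hit_matched = sort(best))
}

#' Per-field population fractions with bootstrap CIs
#'
#' Computes a per-field fraction (e.g. task-gated among responsive) and
#' bootstraps across fields.
#'
#' @param flags logical per-neuron indicator (NA = excluded).
#' @param field_ids imaging-field id per neuron.
#' @param n_boot,seed bootstrap settings.
#' @return list with `per_field`, `mean`, `se`.
#' @export
population_fraction <- function(flags, field_ids, n_boot = 2000, seed = 1) {
  ok <- !is.na(flags)
  pf <- tapply(flags[ok], field_ids[ok], mean)
  ci <- bootstrap_fraction_ci(as.numeric(pf), n_boot = n_boot, seed = seed)
  list(per_field = pf, mean = ci$mean, se = ci$se)
}
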