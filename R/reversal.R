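#' Matched responsive neurons across a contingency-reversal pair
#'
#' A neuron is kept only if it shows a significant stimulus response
#' (p < 0.01 t-test with SNR criterion, per stimulus) to either grating in
#' both sessions. Sessions are assumed to index the same neurons (after
#' ROI alignment); alignment-flagged ROIs can be dropped via `exclude`.
#'
#' @param session_before,session_after matched [imaging_session()]s.
#' @param exclude neuron indices to drop (e.g. flagged by
#'   [align_rois_across_sessions()]).
#' @param min_trials minimum trials per stimulus for the responsiveness
#'   test.
#' @return integer vector of matched neuron indices (possibly empty, with
#'   a warning).
#' @export
select_matched_cells <- function(session_before, session_after,
                                 exclude = integer(0), min_trials = 5) {
  n <- nrow(session_before$traces)
  stopifnot(nrow(session_after$traces) == n)
  resp_either <- function(session, j) {
    nr <- neuron_response(session, j)
    # significant response to either grating, tested per stimulus on
    # engaged trials of that stimulus
    for (st in c("A", "B")) {
      oc <- unique(nr$trials$outcome[nr$trials$stimulus == st &
                                       nr$trials$condition == "Engaged"])
      r <- classify_task_responsive(nr, outcomes = oc,
                                    min_trials = min_trials)
      if (isTRUE(r)) return(TRUE)
    }
    FALSE
  }
  keep <- setdiff(seq_len(n), exclude)
  matched <- keep[vapply(keep, function(j)
    resp_either(session_before, j) && resp_either(session_after, j),
    logical(1))]
  if (!length(matched)) warning("no neurons responsive in both sessions")
  matched
}

#' Classify a neuron by its selectivity before and after reversal
#'
#' Selectivity is signed toward Stimulus A in both sessions. Neurons not
#' significant in both sessions are non-selective (NS); otherwise the sign
#' pattern decides: stable positive = StimA, stable negative = StimB,
#' positive-then-negative = Go (follows the rewarded stimulus),
#' negative-then-positive = NoGo.
#'
#' @param s_before,s_after selectivity indices toward Stimulus A.
#' @param sig_before,sig_after permutation-significance flags.
#' @param first_target which grating was rewarded in the first session
#'   ("A" unless the stimulus labels have been swapped); the Go/NoGo
#'   quadrants follow the reward, so they flip with this convention while
#'   the stimulus-stable groups do not.
#' @return one of "StimA", "StimB", "Go", "NoGo", "NS".
#' @export
classify_reversal_group <- function(s_before, s_after, sig_before,
                                    sig_after, first_target = c("A", "B")) {
  first_target <- match.arg(first_target)
  if (!isTRUE(sig_before) || !isTRUE(sig_after)) return("NS")
  if (s_before == 0 || s_after == 0) return("NS")
  if (s_before > 0 && s_after > 0) return("StimA")
  if (s_before < 0 && s_after < 0) return("StimB")
  toward_first_target <- s_before > 0
  if (first_target == "B") toward_first_target <- !toward_first_target
  if (toward_first_target) "Go" else "NoGo"
}

#' Per-neuron reversal records for a matched session pair
#'
#' For each matched neuron: the A-vs-B selectivity index with permutation
#' significance in each session, the reversal group, and the engagement
#' and error (FA vs CR) modulation indices averaged over the two sessions.
#'
#' @param pair list with `before` and `after` sessions (e.g. from
#'   [generate_reversal_pair()]).
#' @param matched neuron indices from [select_matched_cells()].
#' @param n_perm,seed permutation settings.
#' @param min_trials minimum trials per class for each index.
#' @return data.frame with one row per matched neuron: `neuron`,
#'   `s_before`, `s_after`, `sig_before`, `sig_after`, `group`,
#'   `engagement_mod`, `error_mod`.
#' @export
reversal_records <- function(pair, matched, n_perm = 2000, seed = 1,
                             min_trials = 5) {
  one <- function(j) {
    nr1 <- neuron_response(pair$before, j)
    nr2 <- neuron_response(pair$after, j)
    s1 <- compute_selectivity(nr1, "A>B", min_trials = min_trials,
                              n_perm = n_perm, seed = seed + j)
    s2 <- compute_selectivity(nr2, "A>B", min_trials = min_trials,
                              n_perm = n_perm, seed = seed + j)
    em <- mean(c(
      .opt_index(engagement_modulation_index(nr1, n_perm = n_perm,
                                             seed = seed + j,
                                             min_trials = min_trials)),
      .opt_index(engagement_modulation_index(nr2, n_perm = n_perm,
                                             seed = seed + j,
                                             min_trials = min_trials))),
      na.rm = TRUE)
    errm <- mean(c(
      .opt_index(compute_selectivity(nr1, "FA>CR", min_trials = min_trials,
                                     n_perm = n_perm, seed = seed + j)),
      .opt_index(compute_selectivity(nr2, "FA>CR", min_trials = min_trials,
                                     n_perm = n_perm, seed = seed + j))),
      na.rm = TRUE)
    if (is.null(s1) || is.null(s2))
      return(data.frame(neuron = j, s_before = NA_real_,
                        s_after = NA_real_, sig_before = NA,
                        sig_after = NA, group = "NS",
                        engagement_mod = em, error_mod = errm))
    data.frame(neuron = j, s_before = s1$index, s_after = s2$index,
               sig_before = s1$significant, sig_after = s2$significant,
               group = classify_reversal_group(s1$index, s2$index,
                                               s1$significant,
                                               s2$significant),
               engagement_mod = em, error_mod = errm)
  }
  out <- do.call(rbind, lapply(matched, one))
  rownames(out) <- NULL
  out
}

.opt_index <- function(ri) if (is.null(ri)) NA_real_ else ri$index

#' Per-group modulation summaries with a clustered comparison
#'
#' Summarises engagement and error modulation per reversal group and
#' compares the Go group against the stimulus-stable groups
#' (StimA + StimB) with a clustered rank-sum test (clusters = imaging
#' fields). Empty groups are omitted.
#'
#' @param records data.frame from [reversal_records()].
#' @param field_ids imaging-field id per record (cluster); a single id is
#'   allowed (the test then warns).
#' @return list with `summary` (per-group n / mean engagement and error
#'   modulation) and `go_vs_stim` (clustered test or NULL when either side
#'   is empty).
#' @export
group_modulation_summary <- function(records, field_ids = NULL) {
  if (is.null(field_ids)) field_ids <- rep("field1", nrow(records))
  present <- records$group != "NS"
  groups <- unique(records$group[present])
  summ <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$group == g, ]
    data.frame(group = g, n = nrow(r),
               engagement_mod = mean(r$engagement_mod, na.rm = TRUE),
               error_mod = mean(r$error_mod, na.rm = TRUE))
  }))
  go <- records$group == "Go"
  stim <- records$group %in% c("StimA", "StimB")
  test <- NULL
  if (any(go) && any(stim)) {
    vals <- records$engagement_mod[go | stim]
    lab <- ifelse(records$group[go | stim] == "Go", "Go", "Stim")
    fld <- field_ids[go | stim]
    # with several fields, cluster at the field-by-group level; a single
    # field has no between-field correlation to absorb, so the test
    # reduces to the per-neuron rank-sum
    cl <- if (length(unique(fld)) > 1) paste(fld, lab) else
      seq_along(vals)
    test <- tryCatch(
      suppressWarnings(clustered_rank_test(vals, cl, group_labels = lab,
                                           method = "rank_sum")),
      error = function(e) NULL)
  }
  list(summary = summ, go_vs_stim = test)
}
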