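#' Behavioural d-prime with rate truncation
#'
#' d' = qnorm(hit rate) - qnorm(false-alarm rate). Rates are truncated to
#' [0.01, 0.99] before the probit transform, which caps d' at
#' qnorm(0.99) - qnorm(0.01) = 4.65.
#'
#' @param hit_rate,fa_rate proportions in [0, 1].
#' @return d-prime (unitless).
#' @export
compute_dprime <- function(hit_rate, fa_rate) {
  if (any(hit_rate < 0 | hit_rate > 1, na.rm = TRUE) ||
      any(fa_rate < 0 | fa_rate > 1, na.rm = TRUE))
    stop("rates must lie in [0, 1]")
  h <- pmin(pmax(hit_rate, 0.01), 0.99)
  f <- pmin(pmax(fa_rate, 0.01), 0.99)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Group licks into bouts
#'
#' A lick bout is a maximal run of licks with successive inter-lick
#' intervals strictly below 1 s; a gap of exactly 1 s starts a new bout.
#'
#' @param lick_times numeric vector of lick timestamps (seconds), sorted;
#'   unsorted input is sorted with a warning.
#' @param max_ili inter-lick interval threshold in seconds (licks with a
#'   gap `< max_ili` share a bout).
#' @return data.frame with one row per bout: `start`, `end`, `n_licks`.
#' @export
detect_lick_bouts <- function(lick_times, max_ili = 1) {
  if (length(lick_times) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_licks = integer(0)))
  if (is.unsorted(lick_times)) {
    warning("lick times unsorted; sorting")
    lick_times <- sort(lick_times)
  }
  # new bout wherever the gap to the previous lick is >= max_ili
  bout_id <- cumsum(c(1, as.integer(diff(lick_times) >= max_ili)))
  data.frame(
    start = tapply(lick_times, bout_id, min),
    end = tapply(lick_times, bout_id, max),
    n_licks = as.integer(tapply(lick_times, bout_id, length)),
    row.names = NULL
  )
}

#' Label a trial outcome
#'
#' The target stimulus is defined by the reward contingency (A under the
#' original contingency, B after reversal). Engaged trials are labelled
#' Hit/Miss for target stimuli and FA/CR for non-targets according to
#' whether the animal licked during the response window; passive trials
#' are PassiveA/PassiveB.
#'
#' @param condition "Engaged" or "Passive".
#' @param stimulus "A" or "B".
#' @param licked_in_response logical.
#' @param contingency "original" or "reversed".
#' @return one of "Hit", "Miss", "FA", "CR", "PassiveA", "PassiveB".
#' @export
label_trial <- function(condition, stimulus, licked_in_response,
                        contingency = c("original", "reversed")) {
  contingency <- match.arg(contingency)
  condition <- match.arg(condition, c("Engaged", "Passive"))
  stimulus <- match.arg(stimulus, c("A", "B"))
  if (condition == "Passive") return(paste0("Passive", stimulus))
  target <- if (contingency == "original") "A" else "B"
  if (stimulus == target) {
    if (licked_in_response) "Hit" else "Miss"
  } else {
    if (licked_in_response) "FA" else "CR"
  }
}

#' Summarise session performance
#'
#' Hit and false-alarm rates over engaged trials, truncated d-prime and the
#' session inclusion criterion (d' > 1 and hit - FA rate > 30 percentage
#' points, both strict).
#'
#' @param trials trial table (see [imaging_session()]).
#' @return list of class `performance_summary` with `hit_rate`, `fa_rate`,
#'   `d_prime`, `n_go`, `n_nogo`, `pass_criterion`.
#' @export
performance_summary <- function(trials) {
  go <- trials$outcome %in% c("Hit", "Miss")
  nogo <- trials$outcome %in% c("FA", "CR")
  if (!any(go) || !any(nogo))
    stop("need at least one go and one no-go engaged trial")
  hit_rate <- mean(trials$outcome[go] == "Hit")
  fa_rate <- mean(trials$outcome[nogo] == "FA")
  d <- compute_dprime(hit_rate, fa_rate)
  out <- list(hit_rate = hit_rate, fa_rate = fa_rate, d_prime = d,
              n_go = sum(go), n_nogo = sum(nogo),
              pass_criterion = (d > 1) && ((hit_rate - fa_rate) > 0.30))
  class(out) <- "performance_summary"
  out
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("hit rate %.3f (n=%d), FA rate %.3f (n=%d), d' = %.3f, %s\n",
              x$hit_rate, x$n_go, x$fa_rate, x$n_nogo, x$d_prime,
              if (x$pass_criterion) "passes criterion" else "below criterion"))
  invisible(x)
}

#' Session performance criterion
#'
#' @param summary a `performance_summary`.
#' @return TRUE iff d' > 1 and hit - FA rate > 30 percentage points.
#' @export
check_session_criterion <- function(summary) {
  isTRUE(summary$d_prime > 1) &&
    isTRUE((summary$hit_rate - summary$fa_rate) > 0.30)
}

#' Drop consecutive end-of-session Miss trials
#'
#' Runs of Miss trials at the end of a session reflect loss of motivation
#' rather than perceptual failure and are excluded from error-trial
#' analyses. Returns the logical keep-mask over trials.
#'
#' @param trials trial table.
#' @return logical vector, FALSE for the trailing engaged-Miss run.
#' @export
keep_after_trailing_misses <- function(trials) {
  keep <- rep(TRUE, nrow(trials))
  i <- nrow(trials)
  while (i >= 1 && trials$outcome[i] == "Miss") {
    keep[i] <- FALSE
    i <- i - 1
  }
  keep
}
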