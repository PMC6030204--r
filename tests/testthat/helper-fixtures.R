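# shared small fixtures, built in code at test time

# session with a single archetype at high SNR
archetype_session <- function(archetype, n_neurons = 4, noise_sd = 0.05,
                              n_trials_per_block = 50, seed = 42, ...) {
  mix <- stats::setNames(1, archetype)
  cfg <- generator_config(n_neurons = n_neurons, archetype_mix = mix,
                          noise_sd = noise_sd,
                          n_trials_per_block = n_trials_per_block,
                          seed = seed, ...)
  generate_session(cfg)
}

# hand-built trial table (engaged only unless passive rows given)
make_trials <- function(outcomes, stimulus = NULL, n_licks = 0,
                        contrast = 100) {
  n <- length(outcomes)
  if (is.null(stimulus))
    stimulus <- ifelse(outcomes %in% c("Hit", "Miss", "PassiveA"), "A", "B")
  condition <- ifelse(grepl("^Passive", outcomes), "Passive", "Engaged")
  n_licks <- rep_len(n_licks, n)
  lick_times <- vapply(seq_len(n), function(i) {
    if (n_licks[i] == 0) return("")
    paste(round(3.7 + (seq_len(n_licks[i]) - 1) / 7, 3), collapse = ";")
  }, character(1))
  data.frame(trial = seq_len(n), block = 1L, condition = condition,
             stimulus = stimulus, contrast = rep_len(contrast, n),
             outcome = outcomes, n_licks = n_licks,
             lick_times = lick_times, stringsAsFactors = FALSE)
}

# brute-force auROC oracle: pairwise comparison with half credit for ties
auroc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# per-trial Naka-Rushton response data for a known cell
nr_responses <- function(r_max_e, c50, n_exp, r0, r_max_p,
                         contrasts = c(2, 4, 8, 16, 32, 64),
                         trials_per_contrast = 25, noise_sd = 0) {
  do.call(rbind, lapply(contrasts, function(C) rbind(
    data.frame(contrast = C, condition = "Engaged",
               response = naka_rushton(C, r_max_e, c50, n_exp, r0) +
                 stats::rnorm(trials_per_contrast, 0, noise_sd)),
    data.frame(contrast = C, condition = "Passive",
               response = naka_rushton(C, r_max_p, c50, n_exp, 0) +
                 stats::rnorm(trials_per_contrast, 0, noise_sd))
  )))
}
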