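#' Configuration for the synthetic session generator
#'
#' The generator emulates the structure the analyses assume: the fixed task
#' timing (0.5 s cue, 1 s delay, 2 s stimulus, 1.5 s response window, 3 s
#' ITI), slow GCaMP6s-like calcium kinetics (double-exponential kernel),
#' configurable hit/false-alarm behaviour, and neuron archetypes:
#' \describe{
#'   \item{stimulus}{driven by its preferred grating in engaged and passive
#'     trials alike (engagement gain 0).}
#'   \item{choice}{driven during the lick bout on engaged lick trials
#'     (Hit/FA), regardless of stimulus identity.}
#'   \item{mixed}{stimulus drive with a random engagement gain plus a
#'     choice-locked component.}
#'   \item{engagement_gated}{stimulus drive on engaged trials only
#'     (engagement gain 1).}
#'   \item{silent}{noise only.}
#' }
#' With more than one contrast level, stimulus drive follows a planted
#' Naka-Rushton contrast-response curve per neuron.
#'
#' @param n_neurons number of neurons.
#' @param archetype_mix named proportions over
#'   stimulus/choice/mixed/engagement_gated/silent; must sum to 1.
#' @param hit_rate,fa_rate lick probabilities on engaged target/non-target
#'   trials.
#' @param contrasts stimulus contrasts in percent; `100` for the
#'   full-contrast task, `c(2,4,8,16,32,64)` for the variable-contrast task.
#' @param n_trials_per_block,n_blocks trials per block and number of blocks;
#'   blocks alternate Engaged, Passive starting Engaged, and each passive
#'   block replays the stimulus/contrast sequence of the preceding engaged
#'   block.
#' @param frame_rate volumetric stack rate, Hz.
#' @param kernel_tau_rise,kernel_tau_decay calcium kernel time constants,
#'   seconds.
#' @param noise_sd additive Gaussian noise on dF/F.
#' @param amplitude peak stimulus drive in dF/F units.
#' @param neuropil_coeff_true contamination coefficient used when rendering
#'   movies.
#' @param seed integer seed; the whole generation is deterministic given it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_neurons = 50,
                             archetype_mix = c(stimulus = 0.35, choice = 0.2,
                                               mixed = 0.15,
                                               engagement_gated = 0.2,
                                               silent = 0.1),
                             hit_rate = 0.9, fa_rate = 0.2,
                             contrasts = 100,
                             n_trials_per_block = 40, n_blocks = 4,
                             frame_rate = 5,
                             kernel_tau_rise = 0.2, kernel_tau_decay = 1.5,
                             noise_sd = 0.1, amplitude = 1,
                             neuropil_coeff_true = 0.7,
                             seed = 1) {
  arch <- c("stimulus", "choice", "mixed", "engagement_gated", "silent")
  mix <- rep(0, 5); names(mix) <- arch
  mix[names(archetype_mix)] <- archetype_mix
  if (abs(sum(mix) - 1) > 1e-8) stop("archetype_mix must sum to 1")
  if (n_neurons < 1) stop("need at least one neuron")
  if (n_trials_per_block < 1 || n_blocks < 1) stop("need at least one trial")
  if (any(c(hit_rate, fa_rate) < 0 | c(hit_rate, fa_rate) > 1))
    stop("rates must lie in [0, 1]")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  structure(list(
    n_neurons = as.integer(n_neurons), archetype_mix = mix,
    hit_rate = hit_rate, fa_rate = fa_rate, contrasts = contrasts,
    n_trials_per_block = as.integer(n_trials_per_block),
    n_blocks = as.integer(n_blocks), frame_rate = frame_rate,
    kernel_tau_rise = kernel_tau_rise, kernel_tau_decay = kernel_tau_decay,
    noise_sd = noise_sd, amplitude = amplitude,
    neuropil_coeff_true = neuropil_coeff_true, seed = as.integer(seed)
  ), class = "generator_config")
}

# double-exponential calcium impulse response, peak-normalised
.calcium_kernel <- function(frame_rate, tau_rise, tau_decay) {
  t <- seq(0, 6 * tau_decay, by = 1 / frame_rate)
  k <- if (tau_rise > 0) exp(-t / tau_decay) - exp(-t / tau_rise)
       else exp(-t / tau_decay)
  if (max(k) <= 0) k[1] <- 1
  k / max(k)
}

# exact archetype allocation by largest remainder
.allocate_archetypes <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

.gen_ground_truth <- function(config) {
  n <- config$n_neurons
  arch <- .allocate_archetypes(config$archetype_mix, n)
  pref <- ifelse(arch %in% c("stimulus", "mixed", "engagement_gated"),
                 sample(c("A", "B"), n, replace = TRUE), NA_character_)
  eg <- rep(NA_real_, n)
  eg[arch == "stimulus"] <- 0
  eg[arch == "engagement_gated"] <- 1
  eg[arch == "mixed"] <- stats::runif(sum(arch == "mixed"))
  cg <- rep(0, n)
  cg[arch == "choice"] <- 1
  cg[arch == "mixed"] <- stats::runif(sum(arch == "mixed"), 0.3, 1)
  multi_c <- length(config$contrasts) > 1
  gt <- data.frame(
    neuron = seq_len(n), archetype = arch, preferred = pref,
    engagement_gain = eg, choice_gain = cg,
    amplitude = rep(config$amplitude, n),
    nr_rmax = if (multi_c) rep(config$amplitude, n) else NA_real_,
    nr_c50 = if (multi_c) stats::runif(n, 5, 30) else NA_real_,
    nr_n = if (multi_c) rep(2, n) else NA_real_,
    nr_r0 = if (multi_c) rep(0, n) else NA_real_,
    centroid_x = stats::runif(n, 10, 54),
    centroid_y = stats::runif(n, 10, 54),
    plane = 1L, disp_x = 0, disp_y = 0,
    stringsAsFactors = FALSE
  )
  gt
}

.gen_trials <- function(config, contingency) {
  ep <- trial_epochs(config$frame_rate)
  ntb <- config$n_trials_per_block
  stim_seq <- contr_seq <- cond_seq <- NULL
  last_eng_stim <- NULL; last_eng_contr <- NULL
  for (b in seq_len(config$n_blocks)) {
    engaged <- (b %% 2) == 1
    if (engaged || is.null(last_eng_stim)) {
      s <- sample(c("A", "B"), ntb, replace = TRUE)
      cc <- if (length(config$contrasts) > 1)
        sample(config$contrasts, ntb, replace = TRUE)
      else rep(config$contrasts, ntb)
      if (engaged) { last_eng_stim <- s; last_eng_contr <- cc }
    } else {
      s <- last_eng_stim; cc <- last_eng_contr
    }
    stim_seq <- c(stim_seq, s)
    contr_seq <- c(contr_seq, cc)
    cond_seq <- c(cond_seq, rep(if (engaged) "Engaged" else "Passive", ntb))
  }
  n_tr <- length(stim_seq)
  target <- if (contingency == "original") "A" else "B"
  licked <- rep(FALSE, n_tr)
  eng <- cond_seq == "Engaged"
  is_tar <- stim_seq == target
  licked[eng & is_tar] <- stats::runif(sum(eng & is_tar)) < config$hit_rate
  licked[eng & !is_tar] <- stats::runif(sum(eng & !is_tar)) < config$fa_rate
  lick_times <- character(n_tr)
  for (i in which(licked)) {
    n_l <- sample(4:8, 1)
    start <- ep$stim_off + stats::runif(1, 0.05, 0.3)
    gaps <- (1 / 7) * stats::runif(n_l - 1, 0.8, 1.2)
    lick_times[i] <- paste(round(start + cumsum(c(0, gaps)), 3),
                           collapse = ";")
  }
  outcome <- vapply(seq_len(n_tr), function(i)
    label_trial(cond_seq[i], stim_seq[i], licked[i], contingency),
    character(1))
  data.frame(trial = seq_len(n_tr),
             block = rep(seq_len(config$n_blocks), each = ntb),
             condition = cond_seq, stimulus = stim_seq,
             contrast = contr_seq, outcome = outcome,
             n_licks = vapply(strsplit(lick_times, ";"), function(x)
               length(x[nzchar(x)]), integer(1)),
             lick_times = lick_times, stringsAsFactors = FALSE)
}

# per-trial drive laid on the frame clock, convolved with the calcium
# kernel, plus iid Gaussian noise
.synth_traces <- function(trials, gt, config) {
  ep <- trial_epochs(config$frame_rate)
  fpt <- ep$frames_per_trial
  n_fr <- nrow(trials) * fpt
  kern <- .calcium_kernel(config$frame_rate, config$kernel_tau_rise,
                          config$kernel_tau_decay)
  cmax <- max(config$contrasts)
  traces <- matrix(0, config$n_neurons, n_fr)
  lick_frames <- lapply(seq_len(nrow(trials)), function(i) {
    s <- trials$lick_times[i]
    if (!nzchar(s)) return(integer(0))
    lt <- as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    bouts <- detect_lick_bouts(lt)
    f <- unlist(lapply(seq_len(nrow(bouts)), function(b)
      (floor(bouts$start[b] * config$frame_rate) + 1L):
        ceiling(max(bouts$end[b], bouts$start[b] + 1e-9) * config$frame_rate)))
    f[f >= 1 & f <= fpt]
  })
  for (j in seq_len(config$n_neurons)) {
    g <- gt[j, ]
    if (g$archetype == "silent") {
      drive <- numeric(n_fr)
    } else {
      drive <- numeric(n_fr)
      for (i in seq_len(nrow(trials))) {
        off <- (i - 1L) * fpt
        eng <- trials$condition[i] == "Engaged"
        # stimulus-locked drive on preferred-grating trials
        if (!is.na(g$preferred) && trials$stimulus[i] == g$preferred) {
          amp <- if (!is.na(g$nr_c50))
            naka_rushton(trials$contrast[i], g$nr_rmax, g$nr_c50, g$nr_n,
                         g$nr_r0)
          else g$amplitude
          scale <- if (eng) 1 else 1 - g$engagement_gain
          if (amp * scale != 0) drive[off + ep$stim] <-
              drive[off + ep$stim] + amp * scale
        }
        # choice drive on engaged lick trials: a premotor ramp beginning
        # mid-stimulus and lasting through the lick bout (choice signals
        # precede the overt response, so they are visible in the
        # stimulus-period analysis window)
        if (g$choice_gain > 0 && eng && length(lick_frames[[i]])) {
          cf <- (ep$stim_onset_frame + round(0.4 * config$frame_rate)):
            max(lick_frames[[i]])
          cf <- cf[cf >= 1 & cf <= fpt]
          drive[off + cf] <- drive[off + cf] + g$choice_gain * g$amplitude
        }
      }
    }
    y <- if (any(drive != 0))
      stats::convolve(drive, rev(kern), type = "open")[seq_len(n_fr)]
    else drive
    if (config$noise_sd > 0)
      y <- y + stats::rnorm(n_fr, 0, config$noise_sd)
    traces[j, ] <- y
  }
  traces
}

#' Generate a synthetic imaging session with planted ground truth
#'
#' @param config a [generator_config()].
#' @param contingency reward contingency of the session.
#' @return list with `session` (an [imaging_session()]) and `ground_truth`
#'   (one row per neuron: archetype, preferred stimulus, engagement and
#'   choice gains, planted Naka-Rushton parameters when the task has
#'   multiple contrasts, ROI centroids).
#' @export
generate_session <- function(config, contingency = c("original", "reversed")) {
  contingency <- match.arg(contingency)
  stopifnot(inherits(config, "generator_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  gt <- .gen_ground_truth(config)
  trials <- .gen_trials(config, contingency)
  traces <- .synth_traces(trials, gt, config)
  list(session = imaging_session(trials, traces,
                                 frame_rate = config$frame_rate,
                                 contingency = contingency),
       ground_truth = gt)
}

#' Generate a matched before/after contingency-reversal session pair
#'
#' Both sessions share the same neurons. In the second session the reward
#' contingency is swapped (licks to Stimulus B rewarded): stimulus-coding
#' archetypes keep their grating tuning, while choice-coding archetypes
#' follow the lick response and thus flip their apparent stimulus
#' preference. A planted inter-session displacement (constant vector over
#' the field) is recorded in the ground truth and applied when movies are
#' rendered for the second session.
#'
#' @param config a [generator_config()].
#' @param displacement planted inter-session shift in pixels, `c(dx, dy)`.
#' @return list with `before`, `after` (sessions) and `ground_truth`.
#' @export
generate_reversal_pair <- function(config, displacement = c(0, 0)) {
  stopifnot(inherits(config, "generator_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  gt <- .gen_ground_truth(config)
  gt$disp_x <- displacement[1]; gt$disp_y <- displacement[2]
  trials1 <- .gen_trials(config, "original")
  traces1 <- .synth_traces(trials1, gt, config)
  trials2 <- .gen_trials(config, "reversed")
  traces2 <- .synth_traces(trials2, gt, config)
  list(before = imaging_session(trials1, traces1, config$frame_rate,
                                "original", field_id = "pre"),
       after = imaging_session(trials2, traces2, config$frame_rate,
                               "reversed", field_id = "post"),
       ground_truth = gt)
}

#' Render a synthetic pixel movie from a session
#'
#' Each neuron is drawn as a disk whose brightness follows
#' `f0_soma * (1 + dF/F)`, contaminated by a smooth neuropil background
#' (`neuropil_coeff` of the local background adds to soma pixels, matching
#' the subtraction model used in preprocessing). Per-frame rigid jitter of
#' the stated integer amplitude is applied and returned alongside.
#'
#' @param session an [imaging_session()].
#' @param ground_truth the matching ground-truth table (for centroids).
#' @param motion_amplitude max |shift| in pixels per frame (integer jitter).
#' @param dim image height/width in pixels.
#' @param radius soma disk radius, pixels.
#' @param f0_soma baseline somatic fluorescence, a.u.
#' @param bg mean background (neuropil) fluorescence, a.u.
#' @param neuropil_coeff fraction of local background contaminating soma
#'   pixels.
#' @param apply_displacement add the ground-truth inter-session
#'   displacement to all centroids (for the post-reversal session).
#' @param seed seed for jitter and background noise.
#' @return list with `movie` (array height x width x frames) and
#'   `shifts` (frames x 2 matrix of the planted rigid jitter, dx = column
#'   shift, dy = row shift).
#' @export
generate_movie <- function(session, ground_truth, motion_amplitude = 0,
                           dim = c(64, 64), radius = 3, f0_soma = 100,
                           bg = 30, neuropil_coeff = 0.7,
                           apply_displacement = FALSE, seed = 1) {
  cx <- ground_truth$centroid_x
  cy <- ground_truth$centroid_y
  if (apply_displacement) {
    cx <- cx + ground_truth$disp_x
    cy <- cy + ground_truth$disp_y
  }
  if (any(cx < 1 | cx > dim[2] | cy < 1 | cy > dim[1]))
    stop("ROI centroid out of frame bounds")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n_fr <- ncol(session$traces)
  h <- dim[1]; w <- dim[2]
  # static smooth spatial profile of the neuropil background
  prof <- matrix(stats::rnorm(h * w), h, w)
  prof <- .gauss_blur(prof, 6)
  prof <- 1 + 0.2 * prof / max(abs(prof))
  npil_t <- as.numeric(stats::filter(stats::rnorm(n_fr, 0, 0.15),
                                     rep(1 / 5, 5), sides = 1))
  npil_t[is.na(npil_t)] <- 0
  disks <- lapply(seq_along(cx), function(j) {
    rr <- pmax(1, round(cy[j]) - radius):pmin(h, round(cy[j]) + radius)
    cc <- pmax(1, round(cx[j]) - radius):pmin(w, round(cx[j]) + radius)
    gr <- expand.grid(r = rr, c = cc)
    gr <- gr[(gr$r - cy[j])^2 + (gr$c - cx[j])^2 <= radius^2, ]
    as.matrix(gr)
  })
  shifts <- matrix(0L, n_fr, 2, dimnames = list(NULL, c("dx", "dy")))
  if (motion_amplitude > 0) {
    a <- as.integer(round(motion_amplitude))
    shifts[, 1] <- sample(-a:a, n_fr, replace = TRUE)
    shifts[, 2] <- sample(-a:a, n_fr, replace = TRUE)
  }
  movie <- array(0, c(h, w, n_fr))
  for (t in seq_len(n_fr)) {
    fr <- bg * prof * (1 + npil_t[t])
    for (j in seq_along(disks)) {
      px <- disks[[j]]
      fr[px] <- f0_soma * (1 + session$traces[j, t]) + neuropil_coeff * fr[px]
    }
    movie[, , t] <- .shift_image(fr, shifts[t, 2], shifts[t, 1],
                                 fill = stats::median(fr))
  }
  list(movie = movie, shifts = shifts)
}

# integer shift of an image: positive dy moves content down, positive dx
# moves content right; vacated pixels take `fill`
.shift_image <- function(img, dy, dx, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

# separable Gaussian blur (small sigma utility for masks/backgrounds)
.gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1),
                               nrow(m)), , drop = FALSE]
  m1 <- pad(img, r)
  m1 <- apply(m1, 2, function(col) stats::filter(col, k, sides = 2))
  m1 <- m1[(r + 1):(r + nrow(img)), , drop = FALSE]
  m2 <- t(pad(t(m1), r))
  m2 <- t(apply(m2, 1, function(row) stats::filter(row, k, sides = 2)))
  m2[, (r + 1):(r + ncol(img)), drop = FALSE]
}

#' Write / read a movie as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages scaled by `scale`; the
#' round-trip is exact to single precision.
#'
#' @param movie array height x width x frames.
#' @param path output .tif path.
#' @param scale divisor applied before writing (values must land in
#'   [0, 1]).
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   the reconstructed array.
#' @export
write_movie_tiff <- function(movie, path, scale = 2^15) {
  pages <- lapply(seq_len(dim(movie)[3]), function(t) movie[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale = 2^15) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale
  arr
}
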