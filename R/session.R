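#' Task epoch layout on the imaging frame clock
#'
#' The task has a fixed trial structure: a 0.5 s auditory cue, a 1 s delay,
#' a 2 s drifting-grating stimulus, a 1.5 s response window during which the
#' lick spout is within reach, and a 3 s inter-trial interval (8 s per trial).
#' Imaging runs at a fixed volumetric stack rate (5 Hz by default), so every
#' epoch is expressed as a set of trial-relative frame indices. Event times
#' are snapped to the frame grid: the stimulus onset (nominally 1.5 s after
#' cue onset) is placed at frame `round(1.5 * frame_rate) + 1`.
#'
#' At 5 Hz this yields 40 frames per trial, a 10-frame stimulus period, an
#' 8-frame analysis window covering the last 1.6 s of the stimulus, and a
#' 5-frame (1 s) pre-stimulus baseline.
#'
#' @param frame_rate imaging stack rate in Hz.
#' @return a list with integer frame-index vectors `baseline`, `stim`,
#'   `stim_window` (last 1.6 s of the stimulus), `response` (1.5 s after
#'   stimulus offset), `glm_window` (first 5 s from cue onset), scalars
#'   `frames_per_trial`, `stim_onset_frame`, and the epoch boundary times in
#'   seconds (`cue_on`, `stim_on`, `stim_off`, `spout_off`, `trial_dur`).
#' @export
trial_epochs <- function(frame_rate = 5) {
  stopifnot(frame_rate > 0)
  cue_dur <- 0.5; delay <- 1; stim_dur <- 2; resp_dur <- 1.5; iti <- 3
  trial_dur <- cue_dur + delay + stim_dur + resp_dur + iti
  fpt <- round(trial_dur * frame_rate)
  stim_on_f <- round((cue_dur + delay) * frame_rate) + 1L
  stim_len <- round(stim_dur * frame_rate)
  stim <- stim_on_f:(stim_on_f + stim_len - 1L)
  win_len <- round(1.6 * frame_rate)
  stim_window <- stim[(stim_len - win_len + 1L):stim_len]
  base_len <- round(1 * frame_rate)
  baseline <- (stim_on_f - base_len):(stim_on_f - 1L)
  resp_len <- round(resp_dur * frame_rate)
  response <- (stim[stim_len] + 1L):min(stim[stim_len] + resp_len, fpt)
  glm_window <- 1L:min(round(5 * frame_rate), fpt)
  list(
    baseline = as.integer(baseline), stim = as.integer(stim),
    stim_window = as.integer(stim_window), response = as.integer(response),
    glm_window = as.integer(glm_window),
    frames_per_trial = as.integer(fpt),
    stim_onset_frame = as.integer(stim_on_f),
    cue_on = 0, stim_on = (stim_on_f - 1L) / frame_rate,
    stim_off = (stim_on_f - 1L + stim_len) / frame_rate,
    spout_off = (stim_on_f - 1L + stim_len) / frame_rate + resp_dur,
    trial_dur = trial_dur
  )
}

#' Construct an imaging session
#'
#' The central exchange object: a trial table plus the per-neuron dF/F trace
#' matrix laid out on a common frame clock, with trials occupying contiguous,
#' equal-length frame blocks.
#'
#' @param trials data.frame with one row per trial; required columns
#'   `trial`, `condition` ("Engaged"/"Passive"), `stimulus` ("A"/"B"),
#'   `contrast` (percent), `outcome` (Hit/Miss/FA/CR/PassiveA/PassiveB),
#'   `lick_times` (semicolon-separated seconds from cue onset, "" if none).
#' @param traces numeric matrix, neurons x frames; frame count must equal
#'   `nrow(trials) * frames_per_trial`.
#' @param frame_rate imaging stack rate in Hz.
#' @param contingency "original" (Stimulus A rewarded) or "reversed".
#' @param field_id optional identifier of the imaged field.
#' @return an object of class `imaging_session`.
#' @export
imaging_session <- function(trials, traces, frame_rate = 5,
                            contingency = c("original", "reversed"),
                            field_id = "field1") {
  contingency <- match.arg(contingency)
  ep <- trial_epochs(frame_rate)
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  req <- c("trial", "condition", "stimulus", "contrast", "outcome", "lick_times")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols))
    stop("trial table missing columns: ", paste(missing_cols, collapse = ", "))
  traces <- as.matrix(traces)
  if (ncol(traces) != nrow(trials) * ep$frames_per_trial)
    stop("trace matrix has ", ncol(traces), " frames; expected ",
         nrow(trials) * ep$frames_per_trial)
  structure(list(
    trials = as.data.frame(trials), traces = traces,
    frame_rate = frame_rate, epochs = ep,
    contingency = contingency, field_id = field_id
  ), class = "imaging_session")
}

#' @export
print.imaging_session <- function(x, ...) {
  tb <- table(x$trials$outcome)
  cat("Imaging session (", x$field_id, "): ",
      nrow(x$traces), " neurons, ", nrow(x$trials), " trials, ",
      x$frame_rate, " Hz, contingency ", x$contingency, "\n", sep = "")
  cat("  outcomes:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Frames belonging to one trial
#'
#' @param session an `imaging_session`.
#' @param trial_idx trial number (1-based row of the trial table).
#' @return integer vector of absolute frame indices.
#' @export
trial_frames <- function(session, trial_idx) {
  fpt <- session$epochs$frames_per_trial
  (trial_idx - 1L) * fpt + seq_len(fpt)
}

#' Lick timestamps of one trial
#'
#' @param session an `imaging_session`.
#' @param trial_idx trial number.
#' @return numeric vector of lick times in seconds from cue onset
#'   (length 0 when the animal did not lick).
#' @export
trial_licks <- function(session, trial_idx) {
  s <- session$trials$lick_times[trial_idx]
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Write / read a session as delimited text
#'
#' The on-disk store is plain text: `trials.tsv` (one row per trial) and
#' `traces.tsv` (neurons x frames matrix, tab-separated) plus a one-line
#' `meta.tsv` carrying the frame rate and contingency.
#'
#' @param session an `imaging_session`.
#' @param dir directory to create/populate.
#' @return `write_session` returns `dir` invisibly; `read_session` returns
#'   the reconstructed `imaging_session`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(session$trials, file.path(dir, "trials.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(session$traces),
                     file.path(dir, "traces.tsv"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.frame(frame_rate = session$frame_rate,
                                contingency = session$contingency,
                                field_id = session$field_id),
                     file.path(dir, "meta.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_session
#' @param dir directory previously written by `write_session`.
#' @export
read_session <- function(dir) {
  trials <- as.data.frame(data.table::fread(file.path(dir, "trials.tsv"),
                                            colClasses = list(character = "lick_times")))
  if (!"lick_times" %in% names(trials)) trials$lick_times <- ""
  trials$lick_times[is.na(trials$lick_times)] <- ""
  traces <- as.matrix(data.table::fread(file.path(dir, "traces.tsv"),
                                        header = FALSE))
  dimnames(traces) <- NULL
  meta <- data.table::fread(file.path(dir, "meta.tsv"))
  imaging_session(trials, traces, frame_rate = meta$frame_rate,
                  contingency = meta$contingency, field_id = meta$field_id)
}
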