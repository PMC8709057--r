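#' Construct a single stimulus-locked EEG trial
#'
#' An `eeg_trial` holds one multi-channel, stimulus-locked recording segment
#' in microvolts, together with its class label and provenance. The time of
#' column `i` (1-based) relative to stimulus onset is `(i - 1 - onset_index) / fs`
#' seconds, i.e. sample indices are 0-based in the time arithmetic used
#' throughout the package.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (default 128, the wireless headset rate).
#' @param label trial class, `"P300"` or `"nonP300"`.
#' @param provenance one of `"real"`, `"synthetic"`, `"fake"`.
#' @param subject_id subject identifier string.
#' @param onset_index 0-based sample index of the stimulus onset (default 0:
#'   the trial starts at the onset).
#' @param channel_names optional character vector of channel names.
#' @return an object of class `eeg_trial`.
#' @examples
#' tr <- eeg_trial(matrix(rnorm(14 * 128), 14), fs = 128, label = "nonP300")
#' tr
#' @export
eeg_trial <- function(data, fs = 128, label = c("nonP300", "P300"),
                      provenance = c("synthetic", "real", "fake"),
                      subject_id = "S1", onset_index = 0L,
                      channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_arg("`data` must be a numeric channels x samples matrix")
  if (!all(is.finite(data))) stop_arg("trial data must be finite")
  label <- match.arg(label)
  provenance <- match.arg(provenance)
  check_number(fs, "fs", lower = 1e-9)
  check_number(onset_index, "onset_index", lower = 0, integer = TRUE)
  if (onset_index >= ncol(data)) stop_arg("`onset_index` beyond trial end")
  if (!is.null(channel_names)) {
    if (length(channel_names) != nrow(data))
      stop_arg("`channel_names` length must equal the channel count")
    rownames(data) <- channel_names
  }
  structure(
    list(data = data, fs = fs, n_channels = nrow(data), label = label,
         provenance = provenance, subject_id = as.character(subject_id),
         onset_index = as.integer(onset_index)),
    class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %s ch x %s samples @ %g Hz | label=%s | %s | %s\n",
              x$n_channels, ncol(x$data), x$fs, x$label, x$provenance,
              x$subject_id))
  invisible(x)
}

#' @export
as.matrix.eeg_trial <- function(x, ...) x$data

# duration covered after onset, in seconds
trial_span <- function(trial) {
  (ncol(trial$data) - 1L - trial$onset_index) / trial$fs
}

#' Bundle trials into a per-subject dataset
#'
#' @param trials list of [eeg_trial] objects from one subject.
#' @param subject_id subject identifier; defaults to the first trial's.
#' @return an object of class `subject_dataset` with the ordered trial list
#'   and per-label counts.
#' @export
subject_dataset <- function(trials, subject_id = NULL) {
  if (!length(trials) || !all(vapply(trials, inherits, TRUE, "eeg_trial")))
    stop_arg("`trials` must be a non-empty list of eeg_trial objects")
  subject_id <- subject_id %||% trials[[1L]]$subject_id
  labs <- vapply(trials, `[[`, "", "label")
  structure(
    list(trials = trials, subject_id = as.character(subject_id),
         n_trials = length(trials),
         counts = c(P300 = sum(labs == "P300"),
                    nonP300 = sum(labs == "nonP300"))),
    class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> %s: %d trials (%d P300, %d nonP300)\n",
              x$subject_id, x$n_trials, x$counts[["P300"]],
              x$counts[["nonP300"]]))
  invisible(x)
}

#' Trial labels of a dataset
#' @param dataset a `subject_dataset` or `hacked_dataset`.
#' @return character vector of labels, one per trial.
#' @export
trial_labels <- function(dataset) {
  vapply(dataset$trials, `[[`, "", "label")
}

#' Per-channel amplitude limits of a trial stream
#'
#' Returns the per-channel `(min, max)` envelope over a collection of trials,
#' the quantity a winsorizing artifact-rejection stage would key on and the
#' `EEG_lims` input of the modulated-noise forgery.
#'
#' @param x an `eeg_trial`, a list of them, or a `subject_dataset`.
#' @return numeric matrix, channels x 2, columns `min` and `max`.
#' @export
channel_limits <- function(x) {
  trials <- if (inherits(x, "eeg_trial")) list(x)
            else if (inherits(x, c("subject_dataset", "hacked_dataset"))) x$trials
            else x
  mins <- do.call(pmin, lapply(trials, function(t) apply(t$data, 1L, min)))
  maxs <- do.call(pmax, lapply(trials, function(t) apply(t$data, 1L, max)))
  cbind(min = mins, max = maxs)
}

#' Grand-average waveform of a trial collection
#'
#' Element-wise mean of the channel x sample matrices over all trials with
#' the requested label, the standard way event-related potentials are
#' isolated from background EEG.
#'
#' @param x a list of trials or a `subject_dataset`.
#' @param label optional label filter (`"P300"` or `"nonP300"`).
#' @return channels x samples matrix of the averaged waveform.
#' @export
grand_average <- function(x, label = NULL) {
  trials <- if (inherits(x, c("subject_dataset", "hacked_dataset"))) x$trials else x
  if (!is.null(label)) {
    trials <- Filter(function(t) t$label == label, trials)
  }
  if (!length(trials)) stop_arg("no trials to average")
  Reduce(`+`, lapply(trials, `[[`, "data")) / length(trials)
}
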