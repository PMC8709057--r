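# Serialization: one directory per subject with a JSON manifest plus
# per-trial delimited-text arrays; delimited-text and EDF import for real
# recordings. No EDF reader exists in the supported R environment, so a
# minimal reader for the standard 16-bit EDF layout is implemented here.

#' Write a subject dataset to a directory
#'
#' Layout: `manifest.json` (subject id, sampling rate, channel names,
#' per-trial label/provenance/file list) plus one `trial_NNNN.csv` per
#' trial (channels x samples, one row per channel, no header).
#'
#' @param dataset a `subject_dataset` or `hacked_dataset`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly. For hacked datasets a
#'   `substitutions.json` sidecar records the substituted indices and the
#'   attack kind.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, c("subject_dataset", "hacked_dataset")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- dataset$trials
  files <- sprintf("trial_%04d.csv", seq_along(trials))
  for (i in seq_along(trials)) {
    write.table(trials[[i]]$data, file.path(dir, files[i]), sep = ",",
                row.names = FALSE, col.names = FALSE)
  }
  t1 <- trials[[1L]]
  manifest <- list(
    subject_id = dataset$subject_id, fs = t1$fs,
    n_channels = t1$n_channels,
    channel_names = rownames(t1$data) %||% paste0("ch", seq_len(t1$n_channels)),
    onset_index = t1$onset_index,
    trials = data.frame(
      file = files,
      label = vapply(trials, `[[`, "", "label"),
      provenance = vapply(trials, `[[`, "", "provenance")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (inherits(dataset, "hacked_dataset")) {
    jsonlite::write_json(
      list(attack_kind = dataset$attack_kind,
           substituted_indices = dataset$substituted_indices),
      file.path(dir, "substitutions.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a subject dataset from a directory
#'
#' @param dir a directory written by [write_dataset()].
#' @return a `subject_dataset` (or `hacked_dataset` when a substitutions
#'   sidecar is present).
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  trials <- lapply(seq_len(nrow(man$trials)), function(i) {
    m <- as.matrix(read.csv(file.path(dir, man$trials$file[i]),
                            header = FALSE))
    dimnames(m) <- NULL
    eeg_trial(m, fs = man$fs, label = man$trials$label[i],
              provenance = man$trials$provenance[i],
              subject_id = man$subject_id,
              onset_index = man$onset_index %||% 0L,
              channel_names = man$channel_names)
  })
  ds <- subject_dataset(trials, man$subject_id)
  side <- file.path(dir, "substitutions.json")
  if (file.exists(side)) {
    sub <- jsonlite::read_json(side, simplifyVector = TRUE)
    ds <- structure(
      c(unclass(ds),
        list(substituted_indices = as.integer(sub$substituted_indices),
             attack_kind = sub$attack_kind, params = NULL)),
      class = "hacked_dataset")
  }
  ds
}

#' Import a delimited-text recording as a trial
#'
#' Reads a channels x samples (or samples x channels, with
#' `transpose = TRUE`) delimited file into an [eeg_trial] with
#' `provenance = "real"`.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param sep field separator (default comma).
#' @param transpose set when the file stores one channel per column.
#' @param label,subject_id,onset_index trial metadata.
#' @return an [eeg_trial].
#' @export
import_delimited <- function(path, fs, sep = ",", transpose = FALSE,
                             label = "nonP300", subject_id = "imported",
                             onset_index = 0L) {
  m <- as.matrix(read.table(path, sep = sep, header = FALSE))
  dimnames(m) <- NULL
  if (transpose) m <- t(m)
  eeg_trial(m, fs = fs, label = label, provenance = "real",
            subject_id = subject_id, onset_index = onset_index)
}

#' Import an EDF recording
#'
#' Minimal reader for the standard European Data Format (16-bit integer
#' samples): parses the ASCII header, reads every data record, applies the
#' per-signal physical calibration, and returns the continuous signals.
#' Signals with differing sampling rates are returned as-is per signal.
#'
#' @param path EDF file path.
#' @return list with `signals` (list of numeric vectors), `labels`,
#'   `fs` (per-signal sampling rates), `n_records`, `record_duration`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  version <- rd(8)
  patient <- rd(80)
  recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)                                   # reserved
  n_records <- as.integer(rd(8))
  record_duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(nc) vapply(seq_len(ns), function(i) rd(nc), "")
  labels <- fld(16)
  transducer <- fld(80); phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80)
  spr <- as.integer(fld(8))                # samples per record per signal
  fld(32)                                  # reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  sig <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        raw * gain[i] + offset[i]
    }
  }
  list(signals = sig, labels = labels, fs = spr / record_duration,
       n_records = n_records, record_duration = record_duration,
       physical_dimension = phys_dim, patient = patient,
       recording = recording)
}

#' Slice an imported EDF recording into stimulus-locked trials
#'
#' @param edf a [read_edf()] result with equal per-signal rates.
#' @param onsets 0-based sample indices of the stimulus onsets.
#' @param n_samples samples per trial.
#' @param labels per-onset labels (recycled).
#' @param subject_id subject identifier.
#' @return list of [eeg_trial] objects with `provenance = "real"`.
#' @export
edf_to_trials <- function(edf, onsets, n_samples, labels = "nonP300",
                          subject_id = "imported") {
  fs <- unique(edf$fs)
  if (length(fs) != 1L) stop_arg("signals have differing sampling rates")
  m <- do.call(rbind, edf$signals)
  rownames(m) <- edf$labels
  labels <- rep_len(labels, length(onsets))
  lapply(seq_along(onsets), function(i) {
    i0 <- onsets[i] + 1L
    if (i0 + n_samples - 1L > ncol(m)) stop_arg("trial %d beyond recording", i)
    eeg_trial(m[, i0:(i0 + n_samples - 1L), drop = FALSE], fs = fs,
              label = labels[i], provenance = "real",
              subject_id = subject_id)
  })
}

# Internal EDF writer used by the test suite to round-trip the reader on
# synthetic signals (16-bit EDF, one data record per second).
write_edf <- function(path, signals, labels, fs, phys_range = c(-200, 200)) {
  ns <- length(signals)
  spr <- as.integer(fs)
  n_records <- length(signals[[1L]]) %/% spr
  con <- file(path, "wb")
  on.exit(close(con))
  wf <- function(x, nc) {
    s <- sprintf("%-*s", nc, substr(x, 1, nc))
    writeBin(charToRaw(s), con)
  }
  header_bytes <- 256L + 256L * ns
  wf("0", 8); wf("synthetic patient", 80); wf("synthetic recording", 80)
  wf("01.01.26", 8); wf("00.00.00", 8)
  wf(as.character(header_bytes), 8); wf("", 44)
  wf(as.character(n_records), 8); wf("1", 8); wf(as.character(ns), 4)
  for (l in labels) wf(l, 16)
  for (i in seq_len(ns)) wf("synthetic", 80)
  for (i in seq_len(ns)) wf("uV", 8)
  for (i in seq_len(ns)) wf(as.character(phys_range[1]), 8)
  for (i in seq_len(ns)) wf(as.character(phys_range[2]), 8)
  for (i in seq_len(ns)) wf("-32768", 8)
  for (i in seq_len(ns)) wf("32767", 8)
  for (i in seq_len(ns)) wf("none", 80)
  for (i in seq_len(ns)) wf(as.character(spr), 8)
  for (i in seq_len(ns)) wf("", 32)
  gain <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      x <- signals[[i]][((r - 1L) * spr + 1L):(r * spr)]
      d <- as.integer(round((x - phys_range[1]) / gain)) - 32768L
      writeBin(d, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
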