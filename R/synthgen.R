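# Synthetic EEG generation: pink-noise background, a parietal-weighted P300
# deflection, and a small visual evoked response common to both classes.
# Defaults emulate a 14-channel, 128 Hz P300-speller recording with 240
# target and 1200 non-target trials per subject.

#' EMOTIV EPOC-style channel montage
#' @return character vector of the 14 channel names.
#' @export
epoc_channels <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2",
    "P8", "T8", "FC6", "F4", "F8", "AF4")
}

# Fixed topographies over the montage above. The P300 is strongest over
# parietal sites; the common visual evoked response is occipital-weighted.
p300_topography <- function(channels = epoc_channels()) {
  g <- c(AF3 = 0.3, F7 = 0.3, F3 = 0.3, FC5 = 0.6, T7 = 0.6, P7 = 1,
         O1 = 1, O2 = 1, P8 = 1, T8 = 0.6, FC6 = 0.6, F4 = 0.3,
         F8 = 0.3, AF4 = 0.3)
  unname(g[channels])
}

vep_topography <- function(channels = epoc_channels()) {
  g <- c(AF3 = 0.1, F7 = 0.1, F3 = 0.15, FC5 = 0.2, T7 = 0.3, P7 = 0.8,
         O1 = 1, O2 = 1, P8 = 0.8, T8 = 0.3, FC6 = 0.2, F4 = 0.15,
         F8 = 0.1, AF4 = 0.1)
  unname(g[channels])
}

#' Generate seeded 1/f (pink) noise
#'
#' Pink noise is synthesised by spectral shaping: white Gaussian noise is
#' transformed to the frequency domain, its amplitude spectrum is multiplied
#' by \eqn{1/\sqrt{f}} (so power falls as \eqn{1/f}), and the result is
#' transformed back. The output is zero-mean with unit standard deviation,
#' and identical `(n_samples, seed)` pairs yield identical sequences.
#'
#' @param n_samples number of samples (>= 0).
#' @param seed integer seed.
#' @return numeric vector of length `n_samples`.
#' @examples
#' pn <- make_pink_noise(1024, seed = 1)
#' @export
make_pink_noise <- function(n_samples, seed = 1L) {
  check_number(n_samples, "n_samples", lower = 0, integer = TRUE)
  n <- as.integer(n_samples)
  if (n == 0L) return(numeric(0))
  w <- with_seed(seed, rnorm(n))
  if (n < 4L) return(w - mean(w))
  W <- fft(w)
  # frequency bin index |k| in cycles per record; DC removed, 1/sqrt(f) mask
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)             # fold to |f|
  mask <- c(0, 1 / sqrt(k[-1]))
  x <- Re(fft(W * mask, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

#' Canonical single-channel P300 deflection
#'
#' A positive Gaussian-shaped deflection with a given peak latency, peak
#' amplitude and full-width-at-half-maximum, truncated to zero outside
#' +/- 3 standard deviations of the peak (bounded support). The P300 peak of
#' healthy adults falls in the 250-500 ms post-stimulus window, which the
#' default latency respects.
#'
#' @param fs sampling rate in Hz.
#' @param n_samples length of the returned waveform (default: 1 s worth).
#' @param peak_latency peak latency in ms (default 300).
#' @param amplitude peak amplitude in microvolts (>= 0; default 6).
#' @param width full width at half maximum in ms (> 0; default 80).
#' @return numeric vector of length `n_samples`; sample `i` (0-based) is at
#'   time `i / fs`.
#' @examples
#' w <- make_p300_template(fs = 128)
#' which.max(w) - 1L   # sample index of the peak: round(0.300 * 128) = 38
#' @export
make_p300_template <- function(fs = 128, n_samples = round(fs),
                               peak_latency = 300, amplitude = 6,
                               width = 80) {
  check_number(fs, "fs", lower = 1e-9)
  check_number(n_samples, "n_samples", lower = 1, integer = TRUE)
  check_number(peak_latency, "peak_latency", lower = 0)
  check_number(amplitude, "amplitude", lower = 0)
  if (width <= 0) stop_arg("`width` must be positive")
  t_ms <- (seq_len(n_samples) - 1) / fs * 1000
  sigma <- width / (2 * sqrt(2 * log(2)))   # FWHM -> sd
  w <- amplitude * exp(-0.5 * ((t_ms - peak_latency) / sigma)^2)
  w[abs(t_ms - peak_latency) > 3 * sigma] <- 0
  w
}

#' Subject generation profile
#'
#' Collects every tunable of the synthetic world: montage, sampling rate,
#' background noise level, P300 morphology and its trial-to-trial
#' variability, the common visual evoked response, and the amplitude bound
#' applied as a soft clip after generation.
#'
#' @param subject_id identifier.
#' @param fs sampling rate in Hz.
#' @param n_samples samples per trial (must cover 600 ms post onset).
#' @param channels channel names (length sets the channel count).
#' @param bg_rms pink-noise background RMS per channel, microvolts.
#' @param sensor_sd white sensor-noise standard deviation, microvolts.
#' @param p300_amplitude mean P300 peak amplitude, microvolts.
#' @param p300_latency mean P300 peak latency, ms.
#' @param p300_width P300 FWHM, ms.
#' @param latency_jitter_sd trial-to-trial latency jitter sd, ms (truncated
#'   at 2 sd so the peak stays inside the canonical window).
#' @param amplitude_shape shape of the Gamma(shape, rate = shape)
#'   trial-to-trial amplitude multiplier (mean 1).
#' @param p300_gain per-channel P300 topography weights.
#' @param vep_gain per-channel weights of the common evoked response.
#' @param vep_amplitudes amplitudes (microvolts) of the biphasic early
#'   visual evoked response shared by both classes.
#' @param amplitude_bound soft-clip bound R in microvolts (default 100),
#'   matching the winsorizing envelope assumed downstream by the integrity
#'   scheme.
#' @return a list of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S1", fs = 128, n_samples = 128,
                            channels = epoc_channels(), bg_rms = 10,
                            sensor_sd = 2, p300_amplitude = 6,
                            p300_latency = 300, p300_width = 80,
                            latency_jitter_sd = 10, amplitude_shape = 16,
                            p300_gain = p300_topography(channels),
                            vep_gain = vep_topography(channels),
                            vep_amplitudes = c(n1 = -1.5, p2 = 2),
                            amplitude_bound = 100) {
  check_number(fs, "fs", lower = 1e-9)
  check_number(n_samples, "n_samples", lower = 2, integer = TRUE)
  if ((n_samples - 1) / fs < 0.6)
    stop_arg("trial must cover at least 0-600 ms post onset")
  stopifnot(length(p300_gain) == length(channels),
            length(vep_gain) == length(channels))
  structure(
    list(subject_id = subject_id, fs = fs, n_samples = as.integer(n_samples),
         channels = channels, n_channels = length(channels), bg_rms = bg_rms,
         sensor_sd = sensor_sd, p300_amplitude = p300_amplitude,
         p300_latency = p300_latency, p300_width = p300_width,
         latency_jitter_sd = latency_jitter_sd,
         amplitude_shape = amplitude_shape, p300_gain = p300_gain,
         vep_gain = vep_gain, vep_amplitudes = vep_amplitudes,
         amplitude_bound = amplitude_bound),
    class = "subject_profile")
}

# deterministic evoked-response waveform common to target and non-target
# flashes (every flash is a visual stimulus)
vep_waveform <- function(profile) {
  a <- profile$vep_amplitudes
  make_p300_template(profile$fs, profile$n_samples, 130, abs(a[[1L]]), 60) *
    sign(a[[1L]]) +
    make_p300_template(profile$fs, profile$n_samples, 190, abs(a[[2L]]), 70) *
    sign(a[[2L]])
}

#' Synthesise one EEG trial
#'
#' Each channel is an independent pink-noise background (plus white sensor
#' noise), a small occipital visual evoked response common to both classes,
#' and -- for P300 trials -- the parietal-weighted P300 deflection with
#' trial-specific amplitude (Gamma-distributed, mean 1) and latency jitter.
#' The result is soft-clipped at the profile's amplitude bound.
#'
#' @param label `"P300"` or `"nonP300"`.
#' @param profile a [subject_profile()].
#' @param seed integer seed; identical seeds yield bit-identical trials.
#' @return an [eeg_trial] with `provenance = "synthetic"`.
#' @export
synth_trial <- function(label = c("nonP300", "P300"),
                        profile = subject_profile(), seed = 1L) {
  label <- match.arg(label)
  p <- profile
  with_seed(seed, {
    nch <- p$n_channels
    ns <- p$n_samples
    bg <- matrix(0, nch, ns)
    for (ch in seq_len(nch)) {
      # per-channel pink background; seeded by the already-set stream
      w <- rnorm(ns)
      W <- fft(w)
      k <- c(0, seq_len(ns - 1))
      k <- pmin(k, ns - k)
      mask <- c(0, 1 / sqrt(k[-1]))
      x <- Re(fft(W * mask, inverse = TRUE)) / ns
      x <- x - mean(x)
      bg[ch, ] <- x / max(sd(x), 1e-12) * p$bg_rms
    }
    bg <- bg + matrix(rnorm(nch * ns, sd = p$sensor_sd), nch, ns)
    bg <- bg + p$vep_gain %o% vep_waveform(p)
    if (label == "P300") {
      amp <- p$p300_amplitude * rgamma(1, shape = p$amplitude_shape,
                                       rate = p$amplitude_shape)
      jit <- max(-2, min(2, rnorm(1))) * p$latency_jitter_sd
      tpl <- make_p300_template(p$fs, ns, p$p300_latency + jit, amp,
                                p$p300_width)
      bg <- bg + p$p300_gain %o% tpl
    }
    bg <- soft_clip(bg, p$amplitude_bound)
    eeg_trial(bg, fs = p$fs, label = label, provenance = "synthetic",
              subject_id = p$subject_id, onset_index = 0L,
              channel_names = p$channels)
  })
}

#' Subject-specific morphology variant
#'
#' Real P300 morphology differs between people: peak latency, amplitude,
#' width and scalp topography all vary. This derives a deterministic
#' per-subject variant of the default profile (latency drawn in
#' 265-340 ms, amplitude and width within ~15%, per-channel topography
#' gains perturbed log-normally), so that a forger averaging donor
#' subjects never has an exact statistical copy of the victim's response
#' -- the situation the attack model assumes.
#'
#' @param subject_index positive integer identifying the subject.
#' @param seed population seed; `(seed, subject_index)` fixes the variant.
#' @param subject_id identifier stored in the profile.
#' @return a [subject_profile()].
#' @export
subject_profile_variant <- function(subject_index, seed = 1L,
                                    subject_id = paste0("S", subject_index)) {
  check_number(subject_index, "subject_index", lower = 1, integer = TRUE)
  with_seed(mix_seed(seed, 31L * subject_index), {
    lat <- max(265, min(340, rnorm(1, 300, 25)))
    amp <- 6 * exp(rnorm(1, 0, 0.15))
    wid <- 80 * exp(rnorm(1, 0, 0.10))
    gain <- pmin(1, p300_topography() * exp(rnorm(14, 0, 0.15)))
    vep <- c(n1 = -1.5, p2 = 2) * exp(rnorm(2, 0, 0.2))
    subject_profile(subject_id = subject_id, p300_amplitude = amp,
                    p300_latency = lat, p300_width = wid,
                    p300_gain = gain, vep_amplitudes = vep)
  })
}

#' Synthesise one subject's trial set from a profile
#'
#' @param profile a [subject_profile()].
#' @param n_p300,n_non trial counts per class.
#' @param seed seed; the dataset (including its label shuffle) is a pure
#'   function of `(profile, n_p300, n_non, seed)`.
#' @return a [subject_dataset].
#' @export
synth_subject <- function(profile, n_p300 = 240, n_non = 1200, seed = 1L) {
  check_number(n_p300, "n_p300", lower = 1, integer = TRUE)
  check_number(n_non, "n_non", lower = 1, integer = TRUE)
  labs <- c(rep("P300", n_p300), rep("nonP300", n_non))
  ord <- with_seed(mix_seed(seed, 100003L), sample.int(length(labs)))
  labs <- labs[ord]
  trials <- lapply(seq_along(labs), function(i) {
    synth_trial(labs[i], profile, seed = mix_seed(seed, 1000000L + i))
  })
  subject_dataset(trials, profile$subject_id)
}

#' Synthesise a multi-subject P300 dataset
#'
#' At full scale each subject contributes 240 P300 and 1200 non-P300 trials
#' (the 1:5 target/non-target ratio of a 6 x 6 speller matrix). A `scale`
#' below 1 shrinks both counts proportionally, preserving the ratio. Trial
#' order within a subject is a deterministic seeded shuffle. By default
#' every subject gets their own morphology variant
#' ([subject_profile_variant()]), reproducing the between-subject
#' variability the attack model relies on.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed master seed; the whole collection is a pure function of it.
#' @param scale fraction of the full per-subject trial counts.
#' @param profile_fn function `(subject_index)` returning a
#'   [subject_profile()]; override to control morphology explicitly.
#' @return list of [subject_dataset] objects.
#' @examples
#' dss <- synth_dataset(1, seed = 7, scale = 0.05)
#' dss[[1]]
#' @export
synth_dataset <- function(n_subjects = 5, seed = 1L, scale = 1,
                          profile_fn = NULL) {
  check_number(n_subjects, "n_subjects", lower = 1, integer = TRUE)
  check_number(scale, "scale", lower = 1e-9, upper = 1)
  n_p3 <- round(240 * scale)
  n_np <- round(1200 * scale)
  if (n_p3 < 1 || n_np < 1) stop_arg("`scale` too small: empty class")
  profile_fn <- profile_fn %||%
    function(s) subject_profile_variant(s, seed = seed)
  lapply(seq_len(n_subjects), function(s) {
    synth_subject(profile_fn(s), n_p3, n_np,
                  seed = mix_seed(seed, s * 7919L))
  })
}
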