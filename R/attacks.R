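# Fake-trial forgery: noise-based attacks calibrated by SNR, and the
# modulated-noise/median-filter attack built from donor-subject class
# averages, amplitude-corrected to stay inside the victim's winsorizing
# limits. Forged trials are spliced into a dataset by seeded random
# substitution of same-class slots.

#' Named attack presets
#'
#' The five canonical attack configurations: additive white Gaussian noise
#' at 20 and 40 dB SNR, and modulated-noise attacks combining an
#' order-3 or order-9 median filter with low (`alpha1 = 0.01`) or high
#' (`alpha1 = 0.5`) pink-noise modulation depth.
#'
#' @return named list of attack parameter sets.
#' @export
attack_presets <- function() {
  list(
    AWGN20 = list(type = "awgn", snr_db = 20),
    AWGN40 = list(type = "awgn", snr_db = 40),
    MF3_001 = list(type = "mnmf", filter_order = 3L, alpha1 = 0.01),
    MF9_001 = list(type = "mnmf", filter_order = 9L, alpha1 = 0.01),
    MF9_05 = list(type = "mnmf", filter_order = 9L, alpha1 = 0.5))
}

#' Additive white Gaussian noise attack
#'
#' Per channel, the mean signal power \eqn{P} is measured and zero-mean
#' Gaussian noise of variance \eqn{P / 10^{SNR/10}} is added, so the
#' realized SNR of signal vs. added noise equals the request. The label is
#' preserved; provenance becomes `"fake"`.
#'
#' @param trial an [eeg_trial].
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed noise seed.
#' @return the attacked [eeg_trial].
#' @export
awgn_attack <- function(trial, snr_db = 20, seed = 1L) {
  stopifnot(inherits(trial, "eeg_trial"))
  check_number(snr_db, "snr_db")
  x <- trial$data
  pw <- rowMeans(x^2)
  sdv <- sqrt(pw / 10^(snr_db / 10))
  noise <- with_seed(seed,
    matrix(rnorm(length(x)), nrow(x)) * sdv)
  out <- trial
  out$data <- x + noise
  out$provenance <- "fake"
  out
}

#' Sliding-window median filter
#'
#' Replaces each sample by the median of the centered window of `n`
#' samples. At the sequence edges, where the centered window would extend
#' past the data, the window shrinks to the available samples, so the
#' output has the same length as the input.
#'
#' @param x numeric vector.
#' @param n odd positive filter order.
#' @return filtered vector of the same length.
#' @examples
#' median_filter(c(1, 5, 2, 8, 3), 3)  # 3 2 5 3 5.5
#' @export
median_filter <- function(x, n) {
  check_number(n, "n", lower = 1, integer = TRUE)
  if (n %% 2 == 0) stop_arg("median filter order must be odd")
  if (n == 1L) return(x)
  h <- (n - 1L) %/% 2L
  L <- length(x)
  vapply(seq_len(L), function(m) {
    median(x[max(1L, m - h):min(L, m + h)])
  }, numeric(1))
}

#' Build forgery templates from donor recordings
#'
#' Averages the donor trials per class into the channel x sample matrices
#' `mP3` (P300) and `mNP3` (non-P300), then median-filters each channel of
#' each class mean to keep only the morphology common across donors. The
#' donors must come from subjects other than the victim -- the attacker has
#' no access to the victim's own recordings.
#'
#' @param donor_trials list of trials, a `subject_dataset`, or a list of
#'   `subject_dataset`s; must contain both classes.
#' @param filter_order odd median-filter order `n` (1 = no filtering).
#' @param alpha1 default pink-noise modulation depth stored with the
#'   template.
#' @return object of class `attack_template` with fields `mP3`, `mNP3`,
#'   `MF_mP3`, `MF_mNP3`, `filter_order`, `alpha1`, `fs`.
#' @export
build_templates <- function(donor_trials, filter_order = 9L, alpha1 = 0.01) {
  trials <-
    if (inherits(donor_trials, c("subject_dataset", "hacked_dataset"))) {
      donor_trials$trials
    } else if (length(donor_trials) &&
               inherits(donor_trials[[1L]], "subject_dataset")) {
      unlist(lapply(donor_trials, `[[`, "trials"), recursive = FALSE)
    } else donor_trials
  labs <- vapply(trials, `[[`, "", "label")
  if (!all(c("P300", "nonP300") %in% labs))
    stop_arg("donor set must contain both P300 and nonP300 trials")
  avg <- function(lab) grand_average(trials, lab)
  mP3 <- avg("P300")
  mNP3 <- avg("nonP300")
  mf <- function(m) t(apply(m, 1L, median_filter, n = filter_order))
  structure(
    list(mP3 = mP3, mNP3 = mNP3, MF_mP3 = mf(mP3), MF_mNP3 = mf(mNP3),
         filter_order = as.integer(filter_order), alpha1 = alpha1,
         fs = trials[[1L]]$fs, channels = rownames(mP3)),
    class = "attack_template")
}

#' @export
print.attack_template <- function(x, ...) {
  cat(sprintf(
    "<attack_template> %d ch x %d samples, median order %d, alpha1=%g\n",
    nrow(x$mP3), ncol(x$mP3), x$filter_order, x$alpha1))
  invisible(x)
}

#' Modulated-noise / median-filter fake trial
#'
#' Forges one trial as
#' \deqn{MN\_MF[ch, t] = (1 + \alpha_1\, pn[ch, t]) \cdot MF\_sig[ch, t] \cdot k[ch]}
#' where `MF_sig` is the median-filtered class-mean template (class chosen
#' at random unless forced), `pn` is per-channel unit-RMS pink noise and
#' `k[ch] <= 1` shrinks each channel so the forged amplitude never exceeds
#' the victim stream's observed per-channel limits -- evading
#' winsorizing-based artifact rejection. The `*` of the construction is
#' amplitude modulation (the attack is "modulated noise"); a convolution
#' variant is available via `operator = "convolve"`.
#'
#' @param tmpl an [build_templates()] template.
#' @param victim_lims channels x 2 `(min, max)` matrix from
#'   [channel_limits()] of the victim stream.
#' @param alpha1 pink-noise modulation depth (defaults to the template's).
#' @param class_seed seed of the random class selection.
#' @param noise_seed seed of the pink-noise draw.
#' @param class force `"P300"` or `"nonP300"` instead of random selection.
#' @param operator `"modulate"` (default) or `"convolve"` (circular
#'   convolution of `alpha1 * pn` with `MF_sig`, then `k`-scaled).
#' @param subject_id victim subject identifier for the forged trial.
#' @return an [eeg_trial] with `provenance = "fake"`.
#' @export
mnmf_attack <- function(tmpl, victim_lims, alpha1 = NULL, class_seed = 1L,
                        noise_seed = 2L, class = NULL,
                        operator = c("modulate", "convolve"),
                        subject_id = "victim") {
  stopifnot(inherits(tmpl, "attack_template"))
  operator <- match.arg(operator)
  alpha1 <- alpha1 %||% tmpl$alpha1
  check_number(alpha1, "alpha1", lower = 0)
  cls <- class %||% with_seed(class_seed,
    sample(c("P300", "nonP300"), 1L))
  sig <- if (cls == "P300") tmpl$MF_mP3 else tmpl$MF_mNP3
  if (all(sig == 0)) stop_arg("degenerate all-zero template")
  nch <- nrow(sig)
  ns <- ncol(sig)
  if (nrow(victim_lims) != nch) stop_arg("victim_lims channel mismatch")
  pn <- matrix(0, nch, ns)
  with_seed(noise_seed, {
    for (ch in seq_len(nch)) {
      w <- rnorm(ns)
      W <- fft(w)
      kk <- c(0, seq_len(ns - 1))
      kk <- pmin(kk, ns - kk)
      mask <- c(0, 1 / sqrt(kk[-1]))
      p <- Re(fft(W * mask, inverse = TRUE)) / ns
      p <- p - mean(p)
      pn[ch, ] <- p / max(sd(p), 1e-12)
    }
  })
  wave <- if (operator == "modulate") {
    (1 + alpha1 * pn) * sig
  } else {
    t(vapply(seq_len(nch), function(ch) {
      Re(fft(fft(1 + alpha1 * pn[ch, ]) * fft(sig[ch, ]), inverse = TRUE)) / ns
    }, numeric(ns)))
  }
  # per-channel shrink-only correction: forged amplitude must stay inside
  # the victim's winsorizing envelope
  lim <- pmax(abs(victim_lims[, 1L]), abs(victim_lims[, 2L]))
  peak <- apply(abs(wave), 1L, max)
  k <- ifelse(peak > 0, pmin(1, lim / peak), 1)
  out <- wave * k
  eeg_trial(out, fs = tmpl$fs, label = cls, provenance = "fake",
            subject_id = subject_id, onset_index = 0L,
            channel_names = tmpl$channels)
}

#' Splice fake trials into a dataset
#'
#' Substitutes `n_fake` randomly selected trials of the victim's dataset
#' with forged ones. Selection draws a seeded Mersenne-Twister permutation
#' prefix (default seed 4, the canonical choice); substitution is
#' same-slot: each fake trial carries the class label of the trial it
#' replaces, so the dataset composition is preserved. At full scale the
#' defaults substitute 400 of 1440 trials (27.8% fake).
#'
#' @param dataset a [subject_dataset].
#' @param attack_kind a name from [attack_presets()] or a preset-shaped
#'   list.
#' @param templates an [build_templates()] template (required for
#'   modulated-noise attacks).
#' @param n_fake number of substitutions; defaults to the canonical
#'   fraction `round(n_trials * 400 / 1440)`.
#' @param selection_seed seed of the substitution-position draw (default 4).
#' @param attack_seed base seed of the per-trial forgery randomness.
#' @return object of class `hacked_dataset`: the modified trial list plus
#'   `substituted_indices` and `attack_kind`.
#' @export
inject <- function(dataset, attack_kind, templates = NULL, n_fake = NULL,
                   selection_seed = 4L, attack_seed = 1L) {
  stopifnot(inherits(dataset, "subject_dataset"))
  preset <- if (is.character(attack_kind)) {
    kinds <- attack_presets()
    if (!attack_kind %in% names(kinds))
      stop_arg("unknown attack kind '%s'", attack_kind)
    kinds[[attack_kind]]
  } else attack_kind
  kind_name <- if (is.character(attack_kind)) attack_kind else
    preset$type
  n <- dataset$n_trials
  n_fake <- n_fake %||% round(n * 400 / 1440)
  check_number(n_fake, "n_fake", lower = 0, upper = n, integer = TRUE)
  idx <- if (n_fake > 0) {
    with_seed(selection_seed, sample.int(n, n_fake))
  } else integer(0)

  trials <- dataset$trials
  if (preset$type == "mnmf") {
    if (is.null(templates)) stop_arg("modulated-noise attacks need donor templates")
    want <- preset$filter_order %||% templates$filter_order
    if (templates$filter_order != want) {
      # re-filter the stored raw class means at the preset's order
      mf <- function(m) t(apply(m, 1L, median_filter, n = want))
      templates$MF_mP3 <- mf(templates$mP3)
      templates$MF_mNP3 <- mf(templates$mNP3)
      templates$filter_order <- as.integer(want)
    }
    lims <- channel_limits(dataset)
  }
  for (j in seq_along(idx)) {
    i <- idx[j]
    victim <- trials[[i]]
    fake <- switch(preset$type,
      awgn = awgn_attack(victim, preset$snr_db,
                         seed = mix_seed(attack_seed, i)),
      mnmf = mnmf_attack(templates, lims, alpha1 = preset$alpha1,
                         class = victim$label,
                         noise_seed = mix_seed(attack_seed, i),
                         subject_id = dataset$subject_id),
      stop_arg("unknown attack type '%s'", preset$type))
    fake$label <- victim$label
    trials[[i]] <- fake
  }
  structure(
    list(trials = trials, subject_id = dataset$subject_id,
         n_trials = n,
         counts = dataset$counts,
         substituted_indices = sort(idx), attack_kind = kind_name,
         params = preset),
    class = "hacked_dataset")
}

#' @export
print.hacked_dataset <- function(x, ...) {
  cat(sprintf(
    "<hacked_dataset> %s: %d trials, %d substituted (%s), %.1f%% fake\n",
    x$subject_id, x$n_trials, length(x$substituted_indices), x$attack_kind,
    100 * length(x$substituted_indices) / x$n_trials))
  invisible(x)
}
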