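# Preprocessing and feature extraction: 50-600 ms windowing, zero-phase
# 8th-order Butterworth low-pass at 15 Hz, per-channel detrending,
# average-based decimation by 4, and per-trial z-scoring. Applied
# identically to training and testing data.
#
# No IIR-filter package is available in the target environment, so the
# Butterworth design (bilinear transform) and the zero-phase forward-
# backward pass (odd-reflection padding, steady-state initial conditions)
# are implemented here; they reproduce the scipy.signal conventions to
# floating-point accuracy.

#' Preprocessing configuration
#'
#' @param window_start,window_end post-onset analysis window in ms
#'   (half-open: samples with `window_start <= t < window_end` are kept,
#'   where the time of 0-based sample `i` is `i / fs`).
#' @param filter_order Butterworth order designed once and applied
#'   forward-backward (zero phase; effective magnitude response squared).
#' @param cutoff low-pass cutoff frequency in Hz.
#' @param decim_factor decimation factor of the average-based downsampler.
#' @param detrend `"channel"`: subtract each channel's own mean over the
#'   window; `"global"`: subtract the scalar mean of the whole windowed
#'   trial.
#' @param normalize `"trial"`: z-score the flattened trial jointly (the
#'   default; one feature vector feeds one classifier); `"channel"`:
#'   z-score each channel separately before flattening.
#' @return a list of class `prep_config`.
#' @export
prep_config <- function(window_start = 50, window_end = 600,
                        filter_order = 8, cutoff = 15, decim_factor = 4,
                        detrend = c("channel", "global"),
                        normalize = c("trial", "channel")) {
  check_number(window_start, "window_start", lower = 0)
  check_number(window_end, "window_end")
  if (window_start >= window_end) stop_arg("window_start must be < window_end")
  check_number(filter_order, "filter_order", lower = 1, integer = TRUE)
  check_number(cutoff, "cutoff", lower = 1e-9)
  check_number(decim_factor, "decim_factor", lower = 1, integer = TRUE)
  structure(
    list(window_start = window_start, window_end = window_end,
         filter_order = as.integer(filter_order), cutoff = cutoff,
         decim_factor = as.integer(decim_factor),
         detrend = match.arg(detrend), normalize = match.arg(normalize)),
    class = "prep_config")
}

#' Digital Butterworth low-pass design
#'
#' Designs an order-`order` digital Butterworth low-pass via the analog
#' prototype and the bilinear transform with frequency prewarping; DC gain
#' is exactly 1.
#'
#' @param order filter order.
#' @param cutoff -3 dB cutoff in Hz; must be below the Nyquist rate.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order, cutoff, fs) {
  check_number(order, "order", lower = 1, integer = TRUE)
  check_number(fs, "fs", lower = 1e-9)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop_arg("`cutoff` must lie in (0, fs/2)")
  k <- seq_len(order)
  p <- exp(1i * (pi * (2 * k - 1) / (2 * order) + pi / 2))  # prototype poles
  warped <- 2 * fs * tan(pi * cutoff / fs)
  p <- warped * p
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)                               # bilinear
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))             # zeros at z = -1
  g <- sum(a) / sum(b)                                      # H(z=1) = 1
  list(b = b * g, a = a)
}

poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
  cf
}

# steady-state initial filter conditions (direct form II transposed), so a
# step input produces no startup transient
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- matrix(0, n - 1, n - 1)
  comp[, 1] <- -a[2:n] / a[1]
  if (n > 2) comp[cbind(seq_len(n - 2), 2:(n - 1))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - comp, B)
}

# IIR filtering of every ROW of X (direct form II transposed), vectorized
# across rows; Zi is rows x (ntaps-1) initial state or NULL
iir_filter_rows <- function(b, a, X, Zi = NULL) {
  n <- length(a)
  nr <- nrow(X)
  nc <- ncol(X)
  Y <- matrix(0, nr, nc)
  Z <- if (is.null(Zi)) matrix(0, nr, n - 1) else Zi
  for (i in seq_len(nc)) {
    xi <- X[, i]
    yi <- b[1] * xi + Z[, 1]
    if (n > 2) {
      for (j in seq_len(n - 2)) {
        Z[, j] <- b[j + 1] * xi + Z[, j + 1] - a[j + 1] * yi
      }
    }
    Z[, n - 1] <- b[n] * xi - a[n] * yi
    Y[, i] <- yi
  }
  Y
}

# zero-phase forward-backward filtering of every row, with odd-reflection
# padding of 3 * ntaps samples at both ends
filtfilt_rows <- function(b, a, X) {
  ntaps <- max(length(a), length(b))
  padlen <- 3L * ntaps
  nx <- ncol(X)
  if (nx <= padlen)
    stop_arg("signal too short for zero-phase filtering (need > %d samples)",
             padlen)
  left <- 2 * X[, 1] - X[, (padlen + 1):2, drop = FALSE]
  right <- 2 * X[, nx] - X[, (nx - 1):(nx - padlen), drop = FALSE]
  ext <- cbind(left, X, right)
  zi <- lfilter_zi(b, a)
  Y <- iir_filter_rows(b, a, ext, ext[, 1] %o% zi)
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y <- iir_filter_rows(b, a, Y, Y[, 1] %o% zi)
  Y <- Y[, ncol(Y):1, drop = FALSE]
  Y[, (padlen + 1):(padlen + nx), drop = FALSE]
}

# 0-based sample indices (relative to onset) inside [start, end) ms
window_indices <- function(fs, window_start, window_end) {
  lo <- ceiling(window_start / 1000 * fs - 1e-9)
  hi <- ceiling(window_end / 1000 * fs - 1e-9) - 1
  if (hi < lo) stop_arg("empty analysis window")
  seq.int(lo, hi)
}

#' Extract the post-onset analysis window of a trial
#'
#' Keeps the samples whose post-onset time `t = i / fs` (0-based `i`)
#' satisfies `window_start <= t < window_end` (half-open window). At the
#' default 50-600 ms and 128 Hz this keeps indices 7..76, i.e. 70 samples.
#'
#' @param trial an [eeg_trial].
#' @param cfg a [prep_config()].
#' @return channels x samples numeric matrix.
#' @export
window_trial <- function(trial, cfg = prep_config()) {
  stopifnot(inherits(trial, "eeg_trial"))
  idx <- window_indices(trial$fs, cfg$window_start, cfg$window_end)
  cols <- trial$onset_index + idx + 1L
  if (max(cols) > ncol(trial$data))
    stop_arg("trial too short for the %g-%g ms window",
             cfg$window_start, cfg$window_end)
  trial$data[, cols, drop = FALSE]
}

#' Zero-phase Butterworth low-pass of a windowed trial
#'
#' Applies the configured Butterworth design forward and backward along
#' each channel (zero group delay; effective magnitude response is the
#' squared one-pass response). Output length equals input length.
#'
#' @param x channels x samples matrix (a vector is treated as one channel).
#' @param cfg a [prep_config()].
#' @param fs sampling rate in Hz.
#' @return filtered matrix of the same dimensions.
#' @export
lowpass_zero_phase <- function(x, cfg = prep_config(), fs = 128) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!all(is.finite(x))) stop_arg("input must be finite")
  fl <- butter_lowpass(cfg$filter_order, cfg$cutoff, fs)
  filtfilt_rows(fl$b, fl$a, x)
}

#' Detrend a windowed trial
#'
#' `"channel"` mode subtracts each channel's mean over the analysis window
#' (per-channel baseline removal); `"global"` subtracts the single scalar
#' mean of the whole windowed trial.
#'
#' @param x channels x samples matrix.
#' @param mode `"channel"` or `"global"`.
#' @return detrended matrix; in `"channel"` mode every channel mean is 0.
#' @export
detrend_global_mean <- function(x, mode = c("channel", "global")) {
  mode <- match.arg(mode)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!length(x)) stop_arg("empty input")
  if (mode == "channel") x - rowMeans(x) else x - mean(x)
}

#' Average-based downsampling
#'
#' Replaces non-overlapping blocks of `factor` consecutive samples by their
#' mean; a trailing remainder shorter than `factor` is discarded. With the
#' default window (70 samples at 128 Hz) and factor 4 this yields 17
#' samples per channel at 32 Sa/s.
#'
#' @param x channels x samples matrix (vector = one channel).
#' @param factor positive integer decimation factor.
#' @return channels x floor(samples / factor) matrix of block means.
#' @export
downsample_by_mean <- function(x, factor = 4) {
  check_number(factor, "factor", lower = 1, integer = TRUE)
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1L)
  factor <- as.integer(factor)
  nb <- ncol(x) %/% factor
  if (nb == 0L) stop_arg("fewer samples than one block")
  xt <- x[, seq_len(nb * factor), drop = FALSE]
  y <- xt %*% kronecker(diag(nb), matrix(1 / factor, factor, 1))
  if (vec) drop(y) else y
}

#' Per-trial feature normalization
#'
#' Flattens the matrix in (channel, sample) order -- channel 1's samples,
#' then channel 2's, ... -- and z-scores to zero mean and unit standard
#' deviation (denominator n - 1). Scaling the input leaves the output
#' unchanged.
#'
#' @param x channels x samples matrix.
#' @param scope `"trial"` (joint z-score, default) or `"channel"`.
#' @return numeric feature vector with attributes `layout` (the ordering
#'   descriptor) and `dim_orig`.
#' @export
normalize_trial <- function(x, scope = c("trial", "channel")) {
  scope <- match.arg(scope)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (scope == "channel") {
    s <- apply(x, 1L, sd)
    if (any(s <= 0)) stop_arg("zero-variance channel: cannot normalize")
    x <- (x - rowMeans(x)) / s
  }
  v <- as.vector(t(x))
  s <- sd(v)
  if (scope == "trial") {
    if (!is.finite(s) || s <= 0)
      stop_arg("zero-variance trial: cannot normalize")
    v <- (v - mean(v)) / s
  }
  structure(v, layout = "channel-major (channel, decimated sample)",
            dim_orig = dim(x))
}

#' Full preprocessing chain for one trial
#'
#' window -> zero-phase low-pass -> detrend -> average-decimate ->
#' z-score, in that order. At the defaults (14 channels, 128 Hz) the
#' feature length is 14 x 17 = 238.
#'
#' @param trial an [eeg_trial].
#' @param cfg a [prep_config()].
#' @return numeric feature vector with attribute `label`.
#' @export
extract_features <- function(trial, cfg = prep_config()) {
  x <- window_trial(trial, cfg)
  x <- lowpass_zero_phase(x, cfg, fs = trial$fs)
  x <- detrend_global_mean(x, cfg$detrend)
  x <- downsample_by_mean(x, cfg$decim_factor)
  v <- normalize_trial(x, cfg$normalize)
  attr(v, "label") <- trial$label
  v
}

#' Preprocess a whole collection of trials at once
#'
#' Identical to calling [extract_features()] per trial, but the filtering
#' runs on all channels of all trials in one vectorized pass, which is an
#' order of magnitude faster for campaign-sized datasets.
#'
#' @param x a `subject_dataset`, `hacked_dataset`, or list of trials.
#' @param cfg a [prep_config()].
#' @return list with `features` (trials x features matrix) and `labels`.
#' @export
extract_features_batch <- function(x, cfg = prep_config()) {
  trials <- if (inherits(x, c("subject_dataset", "hacked_dataset"))) x$trials else x
  if (!length(trials)) stop_arg("no trials")
  fs <- trials[[1L]]$fs
  wins <- lapply(trials, window_trial, cfg = cfg)
  nch <- nrow(wins[[1L]])
  big <- do.call(rbind, wins)
  big <- lowpass_zero_phase(big, cfg, fs = fs)
  big <- downsample_by_mean(
    if (cfg$detrend == "channel") big - rowMeans(big) else big,
    cfg$decim_factor)
  n <- length(trials)
  feat <- matrix(0, n, nch * ncol(big))
  for (i in seq_len(n)) {
    xi <- big[((i - 1L) * nch + 1L):(i * nch), , drop = FALSE]
    if (cfg$detrend == "global") xi <- xi - mean(xi)
    feat[i, ] <- normalize_trial(xi, cfg$normalize)
  }
  list(features = feat, labels = vapply(trials, `[[`, "", "label"))
}
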