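# Shared fixtures: everything is generated in code at test time.

# small, fast profile: full montage and rate, shorter bookkeeping elsewhere
tiny_profile <- function(subject_id = "T1") {
  subject_profile(subject_id = subject_id)
}

# small two-class dataset (12 P300 + 60 nonP300 by default)
tiny_dataset <- function(seed = 101, scale = 0.05, subjects = 1) {
  synth_dataset(subjects, seed = seed, scale = scale)
}

# brute-force sliding median with the shrink-at-edges policy; the
# independent oracle for the packaged median filter
oracle_median_filter <- function(x, n) {
  h <- (n - 1) %/% 2
  L <- length(x)
  sapply(seq_len(L), function(m) median(x[max(1, m - h):min(L, m + h)]))
}

# independent confusion-matrix metric oracle (plain formula transcription)
oracle_metrics <- function(tp, tn, fp, fn) {
  list(A = (tp + tn) / (tp + tn + fp + fn),
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# two separable Gaussian blobs for classifier sanity checks
blob_data <- function(n_per_class = 100, sep = 2, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 2, sep), ncol = 2),
             matrix(rnorm(n_per_class * 2, -sep), ncol = 2))
  list(x = x, y = rep(c("P300", "nonP300"), each = n_per_class))
}

# random bounded frame for BHR tests
random_frame <- function(n_channels = 14, n_samples = 16, bound = 100,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n_channels * n_samples, -bound, bound), n_channels)
}

# enumeration oracle for the analysis window: 0-based indices i with
# 0.05 <= i/fs < 0.6
window_indices_oracle <- function(fs) {
  i <- 0:(2 * fs)
  i[i / fs >= 0.05 & i / fs < 0.6]
}

# random ordered 4-tuple distinct from `avoid` (if given)
random_tuple <- function(n = 14, avoid = NULL) {
  repeat {
    t4 <- sample.int(n, 4)
    if (is.null(avoid) || any(t4 != avoid)) return(t4)
  }
}
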