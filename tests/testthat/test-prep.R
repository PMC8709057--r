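test_that("analysis window keeps half-open [50, 600) ms samples", {
  prof <- tiny_profile()
  tr <- synth_trial("nonP300", prof, seed = 1)
  w <- window_trial(tr, prep_config())
  # fs = 128: 0-based indices 7..76 inclusive -> 70 samples
  expect_equal(ncol(w), 70)
  expect_identical(w, tr$data[, 8:77])

  # integer-aligned rate: fs = 1000 keeps indices 50..599 (550 samples)
  tr2 <- eeg_trial(matrix(rnorm(2 * 1000), 2), fs = 1000, label = "nonP300")
  expect_equal(ncol(window_trial(tr2, prep_config())), 550)

  # window beyond the trial end is a data error
  short <- eeg_trial(matrix(rnorm(2 * 40), 2), fs = 128, label = "nonP300")
  expect_error(window_trial(short, prep_config()), "too short")
})

test_that("Butterworth design matches the reference implementation", {
  # frozen oracle: scipy.signal.butter(8, 15, fs=128)
  fl <- butter_lowpass(8, 15, 128)
  b_ref <- c(7.011441810666415e-05, 5.609153448533132e-04,
             1.963203706986596e-03, 3.926407413973192e-03,
             4.908009267466490e-03, 3.926407413973192e-03,
             1.963203706986596e-03, 5.609153448533132e-04,
             7.011441810666415e-05)
  a_ref <- c(1, -4.233841605746147, 8.384782529806564, -9.942427619247514,
             7.647300224702220, -3.881875628015500, 1.264260508787802,
             -0.2407066741662926, 0.02045755491417290)
  expect_equal(fl$b, b_ref, tolerance = 1e-10)
  expect_equal(fl$a, a_ref, tolerance = 1e-10)
  expect_error(butter_lowpass(8, 64, 128), "cutoff")
  expect_error(butter_lowpass(8, 70, 128), "cutoff")
})

test_that("zero-phase filtering matches the reference and its contracts", {
  # frozen oracle: scipy.signal.filtfilt(b, a, x) on a 64-sample mixture
  t <- (0:63) / 128
  x <- sin(2 * pi * 5 * t) + 0.3 * sin(2 * pi * 30 * t)
  y <- drop(lowpass_zero_phase(x, prep_config(), fs = 128))
  ref <- c(-1.428030181839e-03, 2.418286547104e-01, -7.069856165125e-01,
           9.704292891103e-01, -8.652648276341e-01, 3.137413546646e-01,
           -5.974085445199e-02)
  expect_equal(y[c(1, 2, 17, 32, 48, 63, 64)], ref, tolerance = 1e-8)
  expect_length(y, length(x))

  # DC gain is exactly 1
  const <- matrix(3.7, 2, 100)
  expect_equal(lowpass_zero_phase(const, fs = 128), const, tolerance = 1e-9)

  # stopband: 30 Hz attenuated by >= 40 dB; passband: 5 Hz within 1 dB.
  # (The analytic squared-magnitude response of an 8th-order design at
  # fc = 15 gives ~96 dB at 30 Hz and ~0.003 dB at 5 Hz.)
  tt <- (0:1279) / 128
  mid <- 200:1080   # ignore edge transients
  hi <- drop(lowpass_zero_phase(sin(2 * pi * 30 * tt), fs = 128))
  lo <- drop(lowpass_zero_phase(sin(2 * pi * 5 * tt), fs = 128))
  att_hi <- 20 * log10(sqrt(mean(hi[mid]^2)) / sqrt(0.5))
  att_lo <- 20 * log10(sqrt(mean(lo[mid]^2)) / sqrt(0.5))
  expect_lt(att_hi, -40)
  expect_gt(att_lo, -1)

  # zero phase: no group delay for a band-limited input
  sig <- drop(lowpass_zero_phase(sin(2 * pi * 5 * tt), fs = 128))
  cc <- ccf(sig[mid], sin(2 * pi * 5 * tt)[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("detrending removes the configured mean", {
  x <- rbind(c(1, 2, 3), c(10, 10, 10))
  d <- detrend_global_mean(x)
  expect_equal(d[1, ], c(-1, 0, 1))
  expect_equal(d[2, ], c(0, 0, 0))
  expect_true(all(abs(rowMeans(detrend_global_mean(matrix(rnorm(300), 3)))) < 1e-12))
  g <- detrend_global_mean(x, "global")
  expect_equal(mean(g), 0)
  expect_false(all(abs(rowMeans(g)) < 1e-12))
})

test_that("average-based downsampling takes block means and truncates", {
  expect_equal(drop(downsample_by_mean(c(1, 2, 3, 4, 5, 6, 7, 8), 4)),
               c(2.5, 6.5))
  expect_equal(ncol(downsample_by_mean(matrix(rnorm(2 * 70), 2), 4)), 17)
  x <- matrix(rnorm(30), 2)
  expect_identical(downsample_by_mean(x, 1), x)
  expect_error(downsample_by_mean(x, 0), "factor")
})

test_that("per-trial normalization z-scores and is scale invariant", {
  x <- matrix(rnorm(40), 4)
  v <- normalize_trial(x)
  expect_lt(abs(mean(v)), 1e-9)
  expect_equal(sd(v), 1, tolerance = 1e-9)
  expect_equal(as.numeric(v), as.numeric(normalize_trial(10 * x)))
  # flattening is channel-major
  expect_equal(length(v), 40)
  expect_equal(v[1:10] * sd(as.vector(t(x))) + mean(x), x[1, ],
               tolerance = 1e-12)
  expect_error(normalize_trial(matrix(0, 3, 5)), "zero-variance")
})

test_that("feature extraction has the derived length and is deterministic", {
  prof <- tiny_profile()
  tr <- synth_trial("P300", prof, seed = 2)
  f1 <- extract_features(tr)
  expect_length(f1, 14 * 17)   # 70-sample window -> 17 blocks x 14 channels
  expect_identical(as.numeric(f1),
                   as.numeric(extract_features(synth_trial("P300", prof, seed = 2))))
  expect_lt(abs(mean(f1)), 1e-9)
  expect_equal(sd(f1), 1, tolerance = 1e-9)

  # output length is a pure function of (fs, cfg): enumeration oracle
  for (fs in c(128, 256, 500)) {
    n_keep <- sum(seq(0, fs - 1) / fs >= 0.05 & seq(0, fs - 1) / fs < 0.6)
    tr_fs <- eeg_trial(matrix(rnorm(3 * 2 * fs), 3), fs = fs,
                       label = "nonP300")
    expect_length(extract_features(tr_fs), 3 * (n_keep %/% 4))
  }
})

test_that("batch feature extraction equals the per-trial path", {
  ds <- tiny_dataset(seed = 5, scale = 0.02)[[1]]
  fb <- extract_features_batch(ds)
  expect_equal(fb$labels, trial_labels(ds))
  for (i in c(1, 7, length(ds$trials))) {
    expect_equal(fb$features[i, ],
                 as.numeric(extract_features(ds$trials[[i]])),
                 tolerance = 1e-10)
  }
})
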