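test_that("pink noise is deterministic, zero-mean, with ~1/f spectrum", {
  expect_length(make_pink_noise(0, seed = 1), 0)
  expect_error(make_pink_noise(-1), "n_samples")

  p1 <- make_pink_noise(2048, seed = 9)
  p2 <- make_pink_noise(2048, seed = 9)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_pink_noise(2048, seed = 10)))
  expect_lt(abs(mean(p1)), 1e-10)

  # periodogram log-log slope over 1-40 Hz (fs = 128) must be -1 +/- 0.3
  for (seed in c(1, 7, 123)) {
    pn <- make_pink_noise(65536, seed = seed)
    n <- length(pn)
    spec <- Mod(fft(pn))^2 / n
    f <- (0:(n - 1)) / n * 128
    sel <- f >= 1 & f <= 40
    slope <- coef(lm(log10(spec[sel]) ~ log10(f[sel])))[2]
    expect_gt(slope, -1.3)
    expect_lt(slope, -0.7)
  }
})

test_that("P300 template peaks at the requested latency with bounded support", {
  w <- make_p300_template(fs = 128)
  expect_equal(which.max(w) - 1L, 38L)   # round(0.300 * 128)
  # peak value at the nearest grid sample (3.1 ms off the true peak)
  expect_equal(max(w), 6, tolerance = 0.01)
  expect_true(any(w == 0))               # zero outside the support
  expect_true(all(w >= 0))

  expect_equal(make_p300_template(fs = 128, amplitude = 0), rep(0, 128))
  expect_error(make_p300_template(fs = 128, width = 0), "width")
  expect_error(make_p300_template(fs = 128, amplitude = -1), "amplitude")

  # latency arithmetic at another rate
  w2 <- make_p300_template(fs = 1000, n_samples = 1000, peak_latency = 420)
  expect_equal(which.max(w2) - 1L, 420L)
})

test_that("synthetic trials are deterministic and class-structured", {
  prof <- tiny_profile()
  t1 <- synth_trial("P300", prof, seed = 5)
  t2 <- synth_trial("P300", prof, seed = 5)
  expect_identical(t1$data, t2$data)
  expect_equal(t1$provenance, "synthetic")
  expect_equal(dim(t1$data), c(14L, 128L))
  expect_true(all(is.finite(t1$data)))
  expect_error(synth_trial("oddball", prof), "arg")

  # grand averages: P300 average peaks inside 250-500 ms on a parietal
  # channel; non-P300 average stays below 20% of the template amplitude
  n <- 500
  avg <- function(lab) {
    Reduce(`+`, lapply(seq_len(n), function(i)
      synth_trial(lab, prof, seed = 9000 + i)$data)) / n
  }
  ap <- avg("P300")
  p7 <- ap[which(prof$channels == "P7"), ]
  pk <- (which.max(p7) - 1) / prof$fs * 1000
  expect_gte(pk, 250)
  expect_lte(pk, 500)

  an <- avg("nonP300")
  # compare against the P300 deflection amplitude in the same window
  win <- round(0.25 * prof$fs):round(0.5 * prof$fs)
  expect_lt(max(abs(an[which(prof$channels == "P7"), win])),
            0.2 * prof$p300_amplitude)
})

test_that("synth_dataset keeps the 1:5 class ratio at every scale", {
  ds <- synth_dataset(1, seed = 3, scale = 0.05)[[1]]
  expect_equal(unname(ds$counts["P300"]), 12)
  expect_equal(unname(ds$counts["nonP300"]), 60)

  ds2 <- synth_dataset(1, seed = 3, scale = 0.1)[[1]]
  expect_equal(unname(ds2$counts["P300"]), 24)
  expect_equal(unname(ds2$counts["nonP300"]), 120)
  expect_equal(unname(ds2$counts["nonP300"] / ds2$counts["P300"]), 5)

  # determinism: identical seeds give identical datasets
  da <- synth_dataset(2, seed = 11, scale = 0.02)
  db <- synth_dataset(2, seed = 11, scale = 0.02)
  expect_identical(lapply(da[[2]]$trials, `[[`, "data"),
                   lapply(db[[2]]$trials, `[[`, "data"))
  expect_false(identical(da[[1]]$trials[[1]]$data,
                         synth_dataset(1, seed = 12, scale = 0.02)[[1]]$trials[[1]]$data))
})

test_that("full-scale dataset composition is 240 + 1200 per subject", {
  # counts only: generate labels without materialising full-scale data
  ds <- synth_dataset(1, seed = 1, scale = 1 / 48)[[1]]   # 5 + 25
  expect_equal(unname(ds$counts), c(5, 25))
  # the full-scale arithmetic (240 + 1200) x 5 = 7200 is pure bookkeeping
  expect_equal(5 * (240 + 1200), 7200)
})

test_that("generated trials survive preprocessing with finite features", {
  ds <- tiny_dataset(seed = 77, scale = 0.02)[[1]]
  fb <- extract_features_batch(ds)
  expect_true(all(is.finite(fb$features)))
  expect_equal(ncol(fb$features), 238)
})
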