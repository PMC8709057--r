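test_that("AWGN attack calibrates noise variance to the requested SNR", {
  # long trial so the realized SNR estimate is tight (+/- 0.5 dB)
  x <- matrix(make_pink_noise(1e5, seed = 1) * 10, nrow = 1)
  tr <- eeg_trial(x, fs = 128, label = "nonP300")
  for (snr in c(20, 40)) {
    at <- awgn_attack(tr, snr, seed = 3)
    noise <- at$data - x
    realized <- 10 * log10(mean(x^2) / mean(noise^2))
    expect_lt(abs(realized - snr), 0.5)
    expect_equal(at$provenance, "fake")
    expect_equal(at$label, tr$label)
  }
  # variance identity at 20 dB: var = P / 100
  at20 <- awgn_attack(tr, 20, seed = 5)
  expect_equal(mean((at20$data - x)^2), mean(x^2) / 100, tolerance = 0.02)
  # vanishing-noise limit
  at_inf <- awgn_attack(tr, 300, seed = 2)
  expect_lt(max(abs(at_inf$data - x)), 1e-6)
  # determinism
  expect_identical(awgn_attack(tr, 20, seed = 7)$data,
                   awgn_attack(tr, 20, seed = 7)$data)
})

test_that("median filter matches the brute-force sliding-median oracle", {
  expect_equal(median_filter(c(1, 5, 2, 8, 3), 3), c(3, 2, 5, 3, 5.5))
  expect_equal(median_filter(rep(4, 10), 9), rep(4, 10))
  x <- rnorm(25)
  expect_identical(median_filter(x, 1), x)
  expect_error(median_filter(x, 4), "odd")
  expect_error(median_filter(x, -3), "n")

  set.seed(99)
  for (i in 1:1000) {
    n <- sample(c(3, 9), 1)
    x <- rnorm(sample(10:30, 1))
    expect_equal(median_filter(x, n), oracle_median_filter(x, n))
  }
})

test_that("donor templates average and median-filter per class", {
  prof <- tiny_profile()
  # identical donors: the class mean equals the single trial
  t1 <- synth_trial("P300", prof, seed = 1)
  t2 <- synth_trial("nonP300", prof, seed = 2)
  tmpl1 <- build_templates(list(t1, t1, t2), filter_order = 1)
  expect_equal(tmpl1$mP3, t1$data)
  expect_equal(tmpl1$mNP3, t2$data)
  # order 1 median filter is the identity
  expect_equal(tmpl1$MF_mP3, tmpl1$mP3)

  expect_error(build_templates(list(t1, t1)), "both")

  # averaged + filtered P300 template peaks inside the canonical window
  ds <- synth_dataset(1, seed = 42, scale = 0.5)[[1]]
  tmpl <- build_templates(ds, filter_order = 9)
  p7 <- tmpl$MF_mP3[which(epoc_channels() == "P7"), ]
  pk_ms <- (which.max(p7) - 1) / tmpl$fs * 1000
  expect_gte(pk_ms, 250)
  expect_lte(pk_ms, 500)
  # median filter of each channel of the mean matches the oracle
  ch <- 3
  expect_equal(tmpl$MF_mNP3[ch, ], oracle_median_filter(tmpl$mNP3[ch, ], 9))
})

test_that("modulated-noise forgery respects the winsorizing envelope", {
  ds <- tiny_dataset(seed = 8, scale = 0.05)[[1]]
  tmpl <- build_templates(ds, filter_order = 9)
  lims <- channel_limits(ds)

  # zero modulation depth: output is exactly k * MF_sig
  f0 <- mnmf_attack(tmpl, lims, alpha1 = 0, class = "P300", noise_seed = 1)
  lim <- pmax(abs(lims[, 1]), abs(lims[, 2]))
  k <- pmin(1, lim / apply(abs(tmpl$MF_mP3), 1, max))
  expect_equal(f0$data, tmpl$MF_mP3 * k, tolerance = 1e-12)
  expect_equal(f0$provenance, "fake")

  # winsorizing safety at high modulation depth, several seeds
  for (s in 1:20) {
    fk <- mnmf_attack(tmpl, lims, alpha1 = 0.5, class_seed = s,
                      noise_seed = s)
    expect_true(all(apply(abs(fk$data), 1, max) <= lim + 1e-12))
  }

  # determinism and random class selection
  fa <- mnmf_attack(tmpl, lims, class_seed = 5, noise_seed = 6)
  fb <- mnmf_attack(tmpl, lims, class_seed = 5, noise_seed = 6)
  expect_identical(fa$data, fb$data)
  expect_identical(fa$label, fb$label)
  cls <- vapply(1:40, function(s)
    mnmf_attack(tmpl, lims, class_seed = s)$label, "")
  expect_true(all(c("P300", "nonP300") %in% cls))

  zero <- tmpl
  zero$MF_mP3[] <- 0
  expect_error(mnmf_attack(zero, lims, class = "P300"), "degenerate")
})

test_that("inject substitutes same-slot fakes with seeded selection", {
  ds <- tiny_dataset(seed = 21, scale = 0.1)[[1]]   # 24 + 120 trials
  tmpl <- build_templates(tiny_dataset(seed = 22, scale = 0.05)[[1]],
                          filter_order = 9)
  hd <- inject(ds, "MF9_001", templates = tmpl)
  expect_s3_class(hd, "hacked_dataset")
  # default keeps the canonical 400/1440 fraction
  expect_length(hd$substituted_indices, round(144 * 400 / 1440))
  expect_false(is.unsorted(hd$substituted_indices))
  expect_true(!anyDuplicated(hd$substituted_indices))

  # same-slot substitution preserves labels and composition
  expect_equal(trial_labels(hd), trial_labels(ds))
  prov <- vapply(hd$trials, `[[`, "", "provenance")
  expect_true(all(prov[hd$substituted_indices] == "fake"))
  expect_true(all(prov[-hd$substituted_indices] == "synthetic"))
  # untouched trials are bit-identical
  i_keep <- setdiff(seq_len(ds$n_trials), hd$substituted_indices)[1]
  expect_identical(hd$trials[[i_keep]]$data, ds$trials[[i_keep]]$data)

  # empty substitution leaves the dataset unchanged
  h0 <- inject(ds, "AWGN20", n_fake = 0)
  expect_length(h0$substituted_indices, 0)
  expect_identical(lapply(h0$trials, `[[`, "data"),
                   lapply(ds$trials, `[[`, "data"))

  # selection determinism: same seed, same index set
  h1 <- inject(ds, "AWGN20", n_fake = 30, selection_seed = 4)
  h2 <- inject(ds, "AWGN40", n_fake = 30, selection_seed = 4)
  expect_identical(h1$substituted_indices, h2$substituted_indices)
  expect_error(inject(ds, "AWGN20", n_fake = 1000), "n_fake")
  expect_error(inject(ds, "nope"), "unknown")
})

test_that("attack presets enumerate the five canonical configurations", {
  pr <- attack_presets()
  expect_named(pr, c("AWGN20", "AWGN40", "MF3_001", "MF9_001", "MF9_05"))
  expect_equal(pr$AWGN20$snr_db, 20)
  expect_equal(pr$AWGN40$snr_db, 40)
  expect_equal(pr$MF3_001$filter_order, 3L)
  expect_equal(pr$MF9_05$alpha1, 0.5)
})
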