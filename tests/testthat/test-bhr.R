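test_that("tuple generator is deterministic, distinct and uniform", {
  expect_error(next_tuple(bhr_prng(1), 3), "n_channels")

  # determinism per (seed, iteration)
  expect_identical(tuple_at(5, 17, 14), tuple_at(5, 17, 14))
  p1 <- bhr_prng(5)
  t1 <- next_tuple(p1, 14)
  expect_identical(t1, tuple_at(5, 0, 14))
  expect_identical(next_tuple(p1, 14), tuple_at(5, 1, 14))
  expect_equal(p1$iteration, 2L)

  # all tuples have 4 distinct in-range indices
  for (i in 1:200) {
    t4 <- tuple_at(3, i, 14)
    expect_length(unique(t4), 4)
    expect_true(all(t4 >= 1 & t4 <= 14))
  }

  # 14 * 13 * 12 * 11 = 24,024 possible arrangements (enumeration)
  g <- as.matrix(expand.grid(a = 1:14, b = 1:14, c = 1:14, d = 1:14))
  distinct <- apply(g, 1, function(r) length(unique(r)) == 4)
  expect_equal(sum(distinct), 24024)

  # marginal uniformity of each role over 1e5 draws (chi-square)
  draws <- t(vapply(1:100000, function(i) tuple_at(99, i, 14), integer(4)))
  for (role in 1:4) {
    tab <- tabulate(draws[, role], 14)
    p <- chisq.test(tab)$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("arrangement codes biject onto ordered distinct tuples", {
  n <- 6
  M <- n * (n - 1) * (n - 2) * (n - 3)
  tuples <- p300guard:::code_to_tuple(0:(M - 1), n)
  expect_equal(nrow(unique(tuples)), M)
  expect_true(all(apply(tuples, 1, function(r) length(unique(r)) == 4)))
})

test_that("encoding follows the mixing algebra with bounded denominators", {
  cfg <- bhr_config()
  # worked numeric identity: s_a = 10, s_b = -5
  fr <- matrix(0, 14, 1)
  fr[1, ] <- 10; fr[2, ] <- -5; fr[3, ] <- 7
  mx <- bhr_encode(fr, c(1, 2, 3, 4), cfg)
  ua <- 2010; ub <- 995
  expect_equal(mx$data[3, 1], ua * ub / (ua + ub))
  expect_equal(mx$data[4, 1], ua * ub / (ua - ub))
  x <- mx$data[3, 1]; y <- mx$data[4, 1]
  expect_equal(2 * x * y / (x + y), ub)
  # slot b raw, passthrough channels untouched
  expect_identical(mx$data[2, ], fr[2, ])
  expect_identical(mx$data[5:14, ], fr[5:14, ])

  # all-zero frame stays well-defined
  z <- bhr_encode(matrix(0, 14, 8), c(4, 8, 1, 2), cfg)
  expect_true(all(is.finite(z$data)))

  # amplitude bound is enforced; denominator bound follows from it
  expect_error(bhr_encode(matrix(150, 14, 4), c(1, 2, 3, 4), cfg),
               "amplitude")
  set.seed(31)
  for (i in 1:50) {
    fr <- random_frame()
    t4 <- random_tuple()
    s <- fr
    ua <- s[t4[1], ] + cfg$offset_c1
    ub <- s[t4[2], ] + cfg$offset_c2
    expect_gte(min(abs(ua - ub)),
               cfg$offset_c1 - cfg$offset_c2 - 2 * cfg$amplitude_bound)
  }

  expect_error(bhr_config(offset_c1 = 1100, offset_c2 = 1000), "C1 - C2")
  expect_error(bhr_config(offset_c2 = 50), "C2 > R")
})

test_that("untampered frames round-trip losslessly except channel d", {
  cfg <- bhr_config()
  set.seed(7)
  for (i in 1:300) {
    fr <- random_frame()
    t4 <- random_tuple()
    res <- bhr_decode_verify(bhr_encode(fr, t4, cfg), t4, cfg)
    expect_equal(res$verdict, "legitimate")
    rel <- function(est, truth) max(abs(est - truth) / (abs(truth) + 1))
    expect_lt(rel(res$a_hat, fr[t4[1], ]), 1e-9)
    expect_lt(rel(res$b_hat, fr[t4[2], ]), 1e-9)
    expect_lt(rel(res$c_hat, fr[t4[3], ]), 1e-9)
    # passthrough channels recovered verbatim; d policy-filled
    others <- setdiff(1:14, t4)
    expect_identical(res$frame[others, ], fr[others, ])
    expect_true(all(res$frame[t4[4], ] == 0))
  }
  # reference-copy fill policy
  cfg_rc <- bhr_config(d_fill_policy = "reference_copy")
  fr <- random_frame(seed = 8)
  t4 <- c(2, 9, 13, 5)
  res <- bhr_decode_verify(bhr_encode(fr, t4, cfg_rc), t4, cfg_rc)
  expect_equal(res$frame[5, ], res$b_hat)
})

test_that("single-sample tampering of any mixed slot is detected", {
  cfg <- bhr_config()
  set.seed(17)
  for (i in 1:500) {
    fr <- random_frame()
    t4 <- random_tuple()
    mx <- bhr_encode(fr, t4, cfg)
    slot <- sample(t4[2:4], 1)              # b, c or d slot
    at <- sample(ncol(fr), 1)
    mx$data[slot, at] <- mx$data[slot, at] + sample(c(-1, 1), 1) * 0.01
    expect_equal(bhr_decode_verify(mx, t4, cfg)$verdict, "compromised")
  }
  # a 0.1 uV perturbation on slot c as well (propagates through b-hat)
  fr <- random_frame(seed = 3)
  t4 <- c(1, 2, 3, 4)
  mx <- bhr_encode(fr, t4, cfg)
  mx$data[3, 5] <- mx$data[3, 5] + 0.1
  expect_equal(bhr_decode_verify(mx, t4, cfg)$verdict, "compromised")
})

test_that("forgeries pass only under the exactly matching tuple", {
  cfg <- bhr_config()
  fr <- random_frame(seed = 23)
  truth <- c(6, 11, 3, 14)
  # correct guess: indistinguishable, accepted
  expect_equal(bhr_decode_verify(bhr_forge(fr, truth, cfg), truth,
                                 cfg)$verdict, "legitimate")
  # swapped c/d roles only: caught (the b-hat identity alone would pass;
  # the plausibility screen on the reconstruction rejects it)
  expect_equal(bhr_decode_verify(bhr_forge(fr, truth[c(1, 2, 4, 3)], cfg),
                                 truth, cfg)$verdict, "compromised")

  # exhaustive: all 24,023 wrong guesses are rejected for one frame
  fr8 <- random_frame(n_samples = 8, seed = 29)
  enc <- lapply(1:24024 - 1L, function(code)
    drop(p300guard:::code_to_tuple(code, 14L)))
  verdicts <- vapply(enc, function(guess) {
    bhr_decode_verify(bhr_forge(fr8, guess, cfg), truth, cfg)$verdict
  }, "")
  expect_equal(sum(verdicts == "legitimate"), 1L)
  match_idx <- which(verdicts == "legitimate")
  expect_equal(enc[[match_idx]], truth)
})

test_that("random wrong-tuple forgeries never pass (sampled sweep)", {
  cfg <- bhr_config()
  set.seed(41)
  for (i in 1:1000) {
    fr <- random_frame(n_samples = 8)
    truth <- random_tuple()
    guess <- random_tuple(avoid = truth)
    res <- bhr_decode_verify(bhr_forge(fr, guess, cfg), truth, cfg)
    expect_equal(res$verdict, "compromised")
  }
})

test_that("inhibition forces compromised trials to the safe class", {
  expect_equal(bhr_inhibit("compromised", "P300"),
               list(label = "nonP300", warning = TRUE))
  expect_equal(bhr_inhibit("compromised", "nonP300"),
               list(label = "nonP300", warning = TRUE))
  expect_equal(bhr_inhibit("legitimate", "P300"),
               list(label = "P300", warning = FALSE))
  res <- structure(list(verdict = "compromised"),
                   class = "reconstruction_result")
  expect_true(bhr_inhibit(res, "P300")$warning)
})
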