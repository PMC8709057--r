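# Brain Hacking Recognizer (BHR): a pseudo-random channel-mixing integrity
# scheme for the headset-to-framework link.
#
# Per iteration, a PRNG synchronized between transmitter and receiver draws
# an ordered tuple (a, b, c, d) of four distinct channels. The transmitter
# sends channel b raw and replaces channels c, d, a by algebraic mixes of
# the offset signals u_a = s_a + C1, u_b = s_b + C2, v_c = s_c + C2:
#
#     slot c:  x = u_a u_b / (u_a + u_b)
#     slot d:  y = u_a u_b / (u_a - u_b)
#     slot a:  z = u_a v_c / (u_a + v_c)
#
# The receiver, knowing the tuple, recovers 1/u_b = (1/x + 1/y) / 2 and
# compares the estimate b-hat with the raw slot b. A mismatch marks the
# frame compromised. On a match, a and c are reconstructed through
# 1/u_a = 1/x - 1/u_b and 1/v_c = 1/z - 1/u_a, and additionally screened
# for physical plausibility (|a-hat|, |c-hat| within the amplitude bound):
# the b-hat identity alone is symmetric in the c/d slots and blind to the
# role-a channel, so the plausibility screen is what defeats forgeries
# that guess b and {c, d} correctly but not the full ordered tuple.
#
# The affine offsets C1 > C2 keep every denominator bounded away from zero
# (|u_a - u_b| >= C1 - C2 - 2R for signals bounded by R) and the offset
# signals strictly positive. Channel d's original content is sacrificed
# (four slots carry three signals plus redundancy) and policy-filled on
# reconstruction.

#' BHR configuration
#'
#' @param n_channels number of transmitted channels N (>= 4; default 14).
#' @param offset_c1 role-a affine offset C1 in microvolts (default 2000).
#' @param offset_c2 role-b/c offset C2 in microvolts (default 1000).
#' @param amplitude_bound admissible signal bound R in microvolts (default
#'   100): encoding requires |samples| <= R and reconstruction must land
#'   inside it.
#' @param tau relative verification tolerance (default 1e-6) on
#'   `max |b_hat - b| / (|b| + 1)`.
#' @param d_fill_policy content of the sacrificed channel d after
#'   reconstruction: `"zeros"` or `"reference_copy"` (copy of b-hat).
#' @return object of class `bhr_config`. The constructor enforces
#'   `C1 - C2 > 2R` (denominator safety) and `C2 > R` (positive offsets).
#' @export
bhr_config <- function(n_channels = 14L, offset_c1 = 2000,
                       offset_c2 = 1000, amplitude_bound = 100,
                       tau = 1e-6,
                       d_fill_policy = c("zeros", "reference_copy")) {
  check_number(n_channels, "n_channels", lower = 4, integer = TRUE)
  check_number(offset_c1, "offset_c1")
  check_number(offset_c2, "offset_c2")
  check_number(amplitude_bound, "amplitude_bound", lower = 1e-12)
  check_number(tau, "tau", lower = 0)
  if (offset_c1 - offset_c2 <= 2 * amplitude_bound)
    stop_arg("need C1 - C2 > 2R to bound the mixing denominators")
  if (offset_c2 <= amplitude_bound)
    stop_arg("need C2 > R so offset signals stay positive")
  structure(
    list(n_channels = as.integer(n_channels), offset_c1 = offset_c1,
         offset_c2 = offset_c2, amplitude_bound = amplitude_bound,
         tau = tau, d_fill_policy = match.arg(d_fill_policy)),
    class = "bhr_config")
}

#' Synchronized BHR pseudo-random tuple generator
#'
#' Software stand-in for the hardware-seeded generator replicated on both
#' link ends: the tuple at a given `(seed, iteration)` pair is a pure
#' function of the pair, so transmitter and receiver holding the same seed
#' and counter always agree.
#'
#' @param seed integer seed shared by both ends.
#' @param iteration starting iteration counter (default 0).
#' @return mutable object of class `bhr_prng`.
#' @export
bhr_prng <- function(seed = 1L, iteration = 0L) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$iteration <- as.integer(iteration)
  class(e) <- "bhr_prng"
  e
}

#' @export
print.bhr_prng <- function(x, ...) {
  cat(sprintf("<bhr_prng> seed=%d iteration=%d\n", x$seed, x$iteration))
  invisible(x)
}

#' Tuple at an explicit (seed, iteration) pair
#'
#' @param seed,iteration the generator coordinates.
#' @param n_channels channel count N (>= 4).
#' @return ordered integer 4-tuple of distinct 1-based channel indices,
#'   uniform over all `N(N-1)(N-2)(N-3)` arrangements.
#' @export
tuple_at <- function(seed, iteration, n_channels = 14L) {
  check_number(n_channels, "n_channels", lower = 4, integer = TRUE)
  with_seed(mix_seed(seed, iteration), sample.int(n_channels, 4L))
}

#' Draw the next channel tuple and advance the generator
#'
#' @param prng a [bhr_prng()].
#' @param n_channels channel count N (>= 4).
#' @return ordered integer 4-tuple `(a, b, c, d)` of distinct 1-based
#'   channel indices.
#' @export
next_tuple <- function(prng, n_channels = 14L) {
  stopifnot(inherits(prng, "bhr_prng"))
  t4 <- tuple_at(prng$seed, prng$iteration, n_channels)
  prng$iteration <- prng$iteration + 1L
  t4
}

# bijection between 0-based arrangement codes and ordered distinct
# 4-tuples; vectorized over codes. Used by the campaign so the index-level
# and signal-level modes consume the identical uniform code stream.
code_to_tuple <- function(code, n) {
  i1 <- code %% n
  r <- code %/% n
  i2 <- r %% (n - 1)
  r <- r %/% (n - 1)
  i3 <- r %% (n - 2)
  i4 <- r %/% (n - 2)
  m <- length(code)
  out <- matrix(0L, m, 4L)
  for (t in seq_len(m)) {
    avail <- seq_len(n)
    a <- avail[i1[t] + 1L]; avail <- avail[-(i1[t] + 1L)]
    b <- avail[i2[t] + 1L]; avail <- avail[-(i2[t] + 1L)]
    cc <- avail[i3[t] + 1L]; avail <- avail[-(i3[t] + 1L)]
    d <- avail[i4[t] + 1L]
    out[t, ] <- c(a, b, cc, d)
  }
  out
}

check_tuple <- function(tuple, n) {
  if (length(tuple) != 4L || anyDuplicated(tuple) ||
      any(tuple < 1L) || any(tuple > n))
    stop_arg("tuple must be 4 distinct channel indices in 1..%d", n)
  as.integer(tuple)
}

frame_data <- function(frame) {
  if (inherits(frame, "eeg_trial")) frame$data
  else if (inherits(frame, "mixed_frame")) frame$data
  else as.matrix(frame)
}

#' Encode a frame for transmission (transmitter side)
#'
#' Applies the channel mixing under the given tuple: slot b carries its
#' raw signal; slots c, d, a carry the mixes x, y, z defined above; all
#' remaining channels pass through untouched. Encoding refuses frames
#' whose amplitude exceeds the configured bound R (such frames would be
#' winsorized anyway), which also guarantees every mixing denominator is
#' at least `C1 - C2 - 2R` in magnitude.
#'
#' @param frame channels x samples matrix (or [eeg_trial]) with
#'   `|samples| <= R`.
#' @param tuple ordered 4-tuple from the synchronized generator.
#' @param cfg a [bhr_config()].
#' @param iteration iteration tag stored with the frame.
#' @return object of class `mixed_frame`.
#' @export
bhr_encode <- function(frame, tuple, cfg = bhr_config(),
                       iteration = NA_integer_) {
  s <- frame_data(frame)
  if (nrow(s) != cfg$n_channels)
    stop_arg("frame has %d channels; config says %d", nrow(s),
             cfg$n_channels)
  tuple <- check_tuple(tuple, cfg$n_channels)
  if (max(abs(s)) > cfg$amplitude_bound)
    stop_arg("frame amplitude exceeds the bound R = %g", cfg$amplitude_bound)
  a <- tuple[1L]; b <- tuple[2L]; cc <- tuple[3L]; d <- tuple[4L]
  ua <- s[a, ] + cfg$offset_c1
  ub <- s[b, ] + cfg$offset_c2
  vc <- s[cc, ] + cfg$offset_c2
  out <- s
  out[b, ] <- s[b, ]
  out[cc, ] <- ua * ub / (ua + ub)
  out[d, ] <- ua * ub / (ua - ub)
  out[a, ] <- ua * vc / (ua + vc)
  structure(list(data = out, iteration = iteration,
                 n_channels = cfg$n_channels),
            class = "mixed_frame")
}

#' @export
print.mixed_frame <- function(x, ...) {
  cat(sprintf("<mixed_frame> %d ch x %d samples, iteration=%s\n",
              nrow(x$data), ncol(x$data), format(x$iteration)))
  invisible(x)
}

#' Attacker-side forgery of a mixed frame
#'
#' The threat model grants the attacker full knowledge of the mixing
#' methodology but not the generator seed or iteration: the forger applies
#' the genuine encoder under its own guessed tuple. If the guess equals
#' the true tuple the forgery is indistinguishable; any other guess is
#' caught by verification.
#'
#' @param fake_frame channels x samples matrix of the fake signal
#'   (`|samples| <= R`).
#' @param guessed_tuple the attacker's ordered 4-tuple guess.
#' @param cfg a [bhr_config()].
#' @return a `mixed_frame` forged under the guessed tuple.
#' @export
bhr_forge <- function(fake_frame, guessed_tuple, cfg = bhr_config()) {
  bhr_encode(fake_frame, guessed_tuple, cfg)
}

#' Verify and reconstruct a received frame (receiver side)
#'
#' Recovers `b_hat` from slots c and d through
#' `1/u_b = (1/x + 1/y) / 2` and compares it with the raw slot b. If the
#' maximal relative deviation `epsilon` exceeds `tau`, or any
#' reconstruction is non-finite or lands outside the admissible amplitude
#' bound, the verdict is `"compromised"` and no reconstruction is emitted.
#' Otherwise the frame is rebuilt: channels a, b, c from their estimates,
#' channel d per the fill policy, all passthrough channels verbatim.
#'
#' @param mixed a `mixed_frame` (or raw matrix) as received.
#' @param tuple the true ordered 4-tuple from the synchronized generator.
#' @param cfg a [bhr_config()].
#' @return object of class `reconstruction_result`: `verdict`
#'   (`"legitimate"` or `"compromised"`), `epsilon`, and on success the
#'   reconstructed `frame` plus `a_hat`, `b_hat`, `c_hat`.
#' @export
bhr_decode_verify <- function(mixed, tuple, cfg = bhr_config()) {
  r <- frame_data(mixed)
  tuple <- check_tuple(tuple, cfg$n_channels)
  a <- tuple[1L]; b <- tuple[2L]; cc <- tuple[3L]; d <- tuple[4L]
  x <- r[cc, ]; y <- r[d, ]; sb <- r[b, ]; z <- r[a, ]

  compromised <- function(eps) {
    structure(list(verdict = "compromised", epsilon = eps, frame = NULL,
                   a_hat = NULL, b_hat = NULL, c_hat = NULL),
              class = "reconstruction_result")
  }

  e <- (1 / x + 1 / y) / 2          # = 1/u_b on a legitimate frame
  ub <- 1 / e
  b_hat <- ub - cfg$offset_c2
  if (!all(is.finite(b_hat))) return(compromised(Inf))
  eps <- max(abs(b_hat - sb) / (abs(sb) + 1))
  if (!is.finite(eps) || eps > cfg$tau) return(compromised(eps))

  f <- 1 / x - e                    # = 1/u_a
  ua <- 1 / f
  a_hat <- ua - cfg$offset_c1
  vc <- 1 / (1 / z - f)
  c_hat <- vc - cfg$offset_c2
  lim <- cfg$amplitude_bound + 1e-6
  if (!all(is.finite(a_hat)) || !all(is.finite(c_hat)) ||
      max(abs(a_hat)) > lim || max(abs(c_hat)) > lim)
    return(compromised(eps))

  frame <- r
  frame[a, ] <- a_hat
  frame[b, ] <- b_hat
  frame[cc, ] <- c_hat
  frame[d, ] <- if (cfg$d_fill_policy == "zeros") 0 else b_hat
  structure(list(verdict = "legitimate", epsilon = eps, frame = frame,
                 a_hat = a_hat, b_hat = b_hat, c_hat = c_hat),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf("<reconstruction_result> %s (epsilon=%.3g)\n", x$verdict,
              x$epsilon))
  invisible(x)
}

#' Attack inhibition policy
#'
#' The safe failure mode of a P300 speller is the negative class: a false
#' positive would spell, a false negative merely waits. A compromised
#' frame therefore forces the final label to `"nonP300"` and raises an
#' attack warning regardless of the classifier output; a legitimate frame
#' passes the classifier output through.
#'
#' @param verdict `"legitimate"` or `"compromised"` (or a
#'   `reconstruction_result`).
#' @param classifier_output the classifier's label.
#' @return list with `label` and logical `warning`.
#' @export
bhr_inhibit <- function(verdict, classifier_output) {
  if (inherits(verdict, "reconstruction_result")) verdict <- verdict$verdict
  if (identical(verdict, "compromised")) {
    list(label = "nonP300", warning = TRUE)
  } else {
    list(label = classifier_output, warning = FALSE)
  }
}
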