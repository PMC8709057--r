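# Monte Carlo attack-rejection campaign: an attacker who knows the mixing
# methodology but not the generator state forges every trial of every
# session under an independent uniform guess of the ordered 4-tuple; the
# defender's tuple is refreshed each trial. Success = the forgery passes
# verification, which (for random frames) happens exactly when the guess
# equals the truth.

#' Campaign configuration
#'
#' @param n_sessions number of simulated sessions (default 100,000).
#' @param trials_per_session attack trials per session (default 1,440, one
#'   whole dataset).
#' @param n_channels channel count N (default 14).
#' @param mode `"index_level"` (fast path: success iff the attacker's
#'   tuple code equals the defender's) or `"signal_level"` (full
#'   forge/encode/verify per trial). Both modes consume the identical
#'   uniform code stream, so shared seeds give identical success patterns.
#' @param master_seed seed of the whole campaign.
#' @param frame_samples samples per forged frame in signal-level mode.
#' @return object of class `session_config`.
#' @export
session_config <- function(n_sessions = 100000L, trials_per_session = 1440L,
                           n_channels = 14L,
                           mode = c("index_level", "signal_level"),
                           master_seed = 1L, frame_samples = 16L) {
  check_number(n_sessions, "n_sessions", lower = 1, integer = TRUE)
  check_number(trials_per_session, "trials_per_session", lower = 0,
               integer = TRUE)
  check_number(n_channels, "n_channels", lower = 4, integer = TRUE)
  check_number(frame_samples, "frame_samples", lower = 1, integer = TRUE)
  structure(
    list(n_sessions = as.integer(n_sessions),
         trials_per_session = as.integer(trials_per_session),
         n_channels = as.integer(n_channels), mode = match.arg(mode),
         master_seed = as.integer(master_seed),
         frame_samples = as.integer(frame_samples)),
    class = "session_config")
}

#' Analytic attack-rejection probability
#'
#' With N channels there are `N(N-1)(N-2)(N-3)` ordered arrangements of
#' four distinct channel indices; a uniformly guessing attacker succeeds
#' with probability one over that count, so the rejection probability is
#' \deqn{1 - \frac{1}{N(N-1)(N-2)(N-3)}.}
#' At N = 14 this is 1 - 1/24024, a 99.996% rejection rate.
#'
#' @param n_channels N >= 4.
#' @return rejection probability.
#' @examples
#' analytic_rejection_probability(14)  # 0.9999584
#' @export
analytic_rejection_probability <- function(n_channels) {
  check_number(n_channels, "n_channels", lower = 4, integer = TRUE)
  n <- n_channels
  1 - 1 / (n * (n - 1) * (n - 2) * (n - 3))
}

#' Run the Monte Carlo attack-rejection campaign
#'
#' Per attack trial the defender's tuple comes from the synchronized
#' generator stream and the attacker independently draws a uniform ordered
#' 4-tuple guess. The index-level mode counts a success iff the two agree;
#' the signal-level mode actually forges a bounded random frame under the
#' guess, encodes nothing else, and runs receiver-side verification. The
#' campaign is chunked and vectorized; the full 100,000 x 1,440 default
#' runs in well under five minutes on one CPU in index-level mode.
#'
#' @param cfg a [session_config()].
#' @return object of class `session_report` with per-session success
#'   counts, totals, the rejection rate and the success-count histogram.
#' @export
run_campaign <- function(cfg = session_config()) {
  stopifnot(inherits(cfg, "session_config"))
  n <- cfg$n_channels
  M <- n * (n - 1) * (n - 2) * (n - 3)
  ns <- cfg$n_sessions
  tps <- cfg$trials_per_session

  if (tps == 0L) {
    return(new_session_report(integer(ns), cfg))
  }

  successes <- integer(ns)
  chunk_sessions <- max(1L, as.integer(2e6 %/% tps))
  bcfg <- bhr_config(n_channels = n)
  trial_counter <- 0L
  with_seed(cfg$master_seed, {
    done <- 0L
    while (done < ns) {
      k <- min(chunk_sessions, ns - done)
      nt <- k * tps
      rd <- sample.int(M, nt, replace = TRUE)   # defender tuple codes
      ra <- sample.int(M, nt, replace = TRUE)   # attacker guesses
      if (cfg$mode == "index_level") {
        succ <- rd == ra
      } else {
        td <- code_to_tuple(rd - 1L, n)
        ta <- code_to_tuple(ra - 1L, n)
        succ <- logical(nt)
        for (t in seq_len(nt)) {
          fake <- with_seed(
            mix_seed(cfg$master_seed, trial_counter + t),
            matrix(runif(n * cfg$frame_samples, -bcfg$amplitude_bound,
                         bcfg$amplitude_bound), n))
          forged <- bhr_forge(fake, ta[t, ], bcfg)
          succ[t] <- bhr_decode_verify(forged, td[t, ],
                                       bcfg)$verdict == "legitimate"
        }
      }
      successes[(done + 1L):(done + k)] <-
        colSums(matrix(succ, nrow = tps))
      trial_counter <- trial_counter + nt
      done <- done + k
    }
  })
  new_session_report(successes, cfg)
}

new_session_report <- function(successes, cfg) {
  total <- as.double(cfg$n_sessions) * cfg$trials_per_session
  tot_succ <- sum(successes)
  structure(
    list(successes_per_session = successes,
         n_sessions = cfg$n_sessions,
         trials_per_session = cfg$trials_per_session,
         n_channels = cfg$n_channels,
         total_trials = total, total_successes = tot_succ,
         rejection_rate = if (total == 0) 1 else 1 - tot_succ / total,
         mode = cfg$mode, master_seed = cfg$master_seed),
    class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf(
    "<session_report> %s sessions x %s trials (N=%d, %s)\n",
    format(x$n_sessions, big.mark = ","),
    format(x$trials_per_session, big.mark = ","), x$n_channels, x$mode))
  cat(sprintf("  successes: %s / %s  |  rejection rate: %.5f%%\n",
              format(x$total_successes, big.mark = ","),
              format(x$total_trials, big.mark = ",", scientific = FALSE),
              100 * x$rejection_rate))
  invisible(x)
}

#' Histogram of per-session attack successes
#'
#' @param report a [run_campaign()] report.
#' @return data frame with columns `successes` (0, 1, 2, ...) and
#'   `sessions` (exact integer counts; the zero bin is included and the
#'   counts sum to the session total).
#' @export
success_histogram <- function(report) {
  stopifnot(inherits(report, "session_report"))
  mx <- if (length(report$successes_per_session))
    max(report$successes_per_session) else 0L
  counts <- tabulate(report$successes_per_session + 1L, nbins = mx + 1L)
  data.frame(successes = 0:mx, sessions = counts)
}
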