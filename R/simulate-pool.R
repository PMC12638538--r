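# Motoneuron-pool surrogate: exponential recruitment-threshold spacing,
# linear rate coding with saturation, renewal discharge with a target ISI
# CoV, and twitch-summation force with band-limited physiological tremor.
# This is a statistical stand-in for decomposed vastus lateralis data,
# not a biophysical model: it exists so that every downstream metric has
# a known injected ground truth.

#' Pool configuration
#'
#' @param n_units Number of motor units in the pool.
#' @param recruitment_range Ratio of the largest to smallest recruitment
#'   threshold; thresholds follow the standard exponential spacing
#'   `thr_i = exp(i * log(range) / n) / range`, so the last unit is
#'   recruited only at maximal excitation.
#' @param onset_rate_pps Discharge rate at recruitment (pps).
#' @param peak_rate_pps Saturation rate (pps).
#' @param rate_gain_pps Rate gain per unit of excitation above threshold.
#' @param isi_cov Target inter-spike-interval coefficient of variation of
#'   the renewal process (Gaussian ISIs truncated at +/- 3 SD).
#' @param twitch_peak_range Ratio of strongest to weakest twitch.
#' @param twitch_tc_s Contraction-time range (s), strongest units fastest.
#' @param seed Integer seed used when the caller does not manage the RNG.
#' @return A list of class `pool_config`.
#' @export
pool_config <- function(n_units = 120, recruitment_range = 30,
                        onset_rate_pps = 6, peak_rate_pps = 35,
                        rate_gain_pps = 10, isi_cov = 0.13,
                        twitch_peak_range = 30,
                        twitch_tc_s = c(0.11, 0.05), seed = 1L) {
  stopifnot(n_units >= 1, isi_cov >= 0, isi_cov < 1,
            onset_rate_pps < peak_rate_pps, recruitment_range > 1)
  structure(list(n_units = as.integer(n_units),
                 recruitment_range = recruitment_range,
                 onset_rate_pps = onset_rate_pps,
                 peak_rate_pps = peak_rate_pps,
                 rate_gain_pps = rate_gain_pps,
                 isi_cov = isi_cov,
                 twitch_peak_range = twitch_peak_range,
                 twitch_tc_s = twitch_tc_s,
                 seed = as.integer(seed)),
            class = "pool_config")
}

#' Recruitment thresholds of a pool (fractions of maximal excitation)
#' @param pool A [pool_config()].
#' @export
recruitment_fractions <- function(pool) {
  i <- seq_len(pool$n_units)
  pmin(1, exp(i * log(pool$recruitment_range) / pool$n_units) /
         pool$recruitment_range)
}

# Gaussian renewal intervals with mean 1 and CoV `cov`, truncated at
# +/- 3 SD by inverse-transform sampling (draw count is deterministic,
# which keeps seeded streams stable across refactors).
rtrunc_intervals <- function(n, cov) {
  if (cov == 0) return(rep(1, n))
  lo <- stats::pnorm(-3); hi <- stats::pnorm(3)
  u <- stats::runif(n, lo, hi)
  pmax(1e-6, 1 + cov * stats::qnorm(u))
}

# Renewal spike times under a time-varying rate profile via time warping:
# unit-mean intervals are accumulated in operational time
# Lambda(t) = integral of rate, and mapped back through its inverse.
renewal_spikes <- function(rate_t, fs, cov) {
  lam <- cumsum(rate_t) / fs
  total <- lam[length(lam)]
  if (total < 1) return(numeric())
  n_draw <- ceiling(total + 4 * sqrt(max(total, 1)) + 8)
  x <- cumsum(rtrunc_intervals(n_draw, cov))
  x <- x[x <= total]
  if (!length(x)) return(numeric())
  tt <- seq_along(rate_t) / fs
  keep <- lam > 0 & c(TRUE, diff(lam) > 0)
  stats::approx(lam[keep], tt[keep], xout = x, ties = "ordered")$y
}

twitch_kernel <- function(peak, tc_s, fs) {
  t <- seq(0, 5 * tc_s, by = 1 / fs)
  peak * (t / tc_s) * exp(1 - t / tc_s)
}

# 1-3 Hz band-limited unit-variance noise (physiological force tremor band)
band_noise <- function(n, fs, band = c(1, 3)) {
  x <- stats::rnorm(n + 4L * fs)
  b <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(b, x)[2L * fs + seq_len(n)]
  y / stats::sd(y)
}

#' Simulate one isometric contraction of a motor unit pool
#'
#' Units whose recruitment threshold is at or below the excitation are
#' active; an active unit's mean rate is
#' `onset + gain * (excitation - threshold)` capped at the peak rate,
#' optionally scaled by `rate_multiplier`. Discharges are renewal
#' processes at the configured ISI CoV; force is the sum of
#' twitch-convolved trains plus 1-3 Hz band-limited tremor, scaled so
#' the plateau mean equals `excitation_fraction * mvc_N`.
#'
#' @param pool A [pool_config()].
#' @param excitation_fraction Constant drive in (0, 1], or a numeric
#'   vector sampled at `fs` describing a full profile (e.g. a trapezoid).
#' @param duration_s Contraction duration (ignored when a profile vector
#'   is given).
#' @param mvc_N Simulated maximal force used for scaling (default 300).
#' @param fs Force sampling rate in Hz (default 1000).
#' @param fs_cov_target Target post-filter force-steadiness CoV on the
#'   plateau; tremor is calibrated to hit it. `NA` adds no tremor.
#' @param rate_multiplier Multiplies every unit's mean rate (exercise
#'   effect injection).
#' @param limb_lp_hz Zero-phase low-pass applied to the twitch-summed
#'   force before tremor is added, emulating limb/transducer mechanical
#'   smoothing (default 5 Hz; `NA` disables).
#' @return List with `trains` (list of [mu_train()], active units only),
#'   `force` (a [force_trace()]), and `plateau_window`.
#' @export
simulate_pool_contraction <- function(pool, excitation_fraction,
                                      duration_s = NULL, mvc_N = 300,
                                      fs = 1000, fs_cov_target = NA_real_,
                                      rate_multiplier = 1, limb_lp_hz = 5) {
  if (length(excitation_fraction) == 1L) {
    stopifnot(excitation_fraction > 0, excitation_fraction <= 1,
              !is.null(duration_s))
    exc <- rep(excitation_fraction, round(duration_s * fs))
    plateau <- c(0, duration_s)
  } else {
    exc <- excitation_fraction
    lev <- max(exc)
    on <- which(abs(exc - lev) <= 1e-12)
    plateau <- c(on[1L], on[length(on)]) / fs
  }
  n <- length(exc)
  thr <- recruitment_fractions(pool)
  peaks <- exp(seq(0, log(pool$twitch_peak_range), length.out = pool$n_units))
  tcs <- exp(seq(log(pool$twitch_tc_s[1L]), log(pool$twitch_tc_s[2L]),
                 length.out = pool$n_units))

  force <- numeric(n)
  trains <- list()
  for (i in seq_len(pool$n_units)) {
    if (thr[i] > max(exc)) next
    rate <- ifelse(exc >= thr[i],
                   pmin(pool$peak_rate_pps,
                        pool$onset_rate_pps + pool$rate_gain_pps * (exc - thr[i])),
                   0) * rate_multiplier
    st <- renewal_spikes(rate, fs, pool$isi_cov)
    if (length(st) < 2L) next
    # PNR emulates decomposition quality; most units comfortably clear
    # the 30 dB gate, a realistic minority does not
    trains[[length(trains) + 1L]] <-
      mu_train(sprintf("u%03d", i), st, pnr_db = stats::rnorm(1L, 36, 3.5))
    k <- twitch_kernel(peaks[i], tcs[i], fs)
    K <- length(k)
    idx <- pmin(n, pmax(1L, round(st * fs)))
    contrib <- numeric(n + K)
    for (s in idx) {
      span <- s:(s + K - 1L)
      contrib[span] <- contrib[span] + k
    }
    force <- force + contrib[seq_len(n)]
  }

  pw <- c(plateau[1L] + 1, plateau[2L] - 1)   # 1 s guard off each edge
  target <- max(exc) * mvc_N
  if (length(trains)) {
    if (is.finite(limb_lp_hz) && limb_lp_hz < fs / 2) {
      bl <- signal::butter(2, limb_lp_hz / (fs / 2), type = "low")
      force <- zp_filter(bl, force, padlen = min(n - 1L, 2000L))
    }
    pidx <- max(1L, round(pw[1L] * fs)):min(n, round(pw[2L] * fs))
    force <- force * target / mean(force[pidx])
    if (is.finite(fs_cov_target)) {
      b <- signal::butter(4, 20 / (fs / 2), type = "low")
      cur <- stats::sd(zp_filter(b, force, padlen = min(n - 1L, 1000L))[pidx]) / target
      if (cur < fs_cov_target) {
        extra_sd <- target * sqrt(fs_cov_target^2 - cur^2)
        tremor <- band_noise(n, fs)
        # orthogonalize against the twitch ripple over the plateau and
        # normalize there, so the injected CoV adds in exact quadrature
        fc <- force[pidx] - mean(force[pidx])
        tremor[pidx] <- tremor[pidx] - sum(tremor[pidx] * fc) / sum(fc^2) * fc
        tremor <- tremor / stats::sd(tremor[pidx])
        force <- force + extra_sd * tremor
      }
    }
  } else {
    force <- force + 0.5 * stats::rnorm(n)   # noise-only floor, no units
  }

  list(trains = trains,
       force = force_trace(force, fs = fs,
                           target_fraction = if (max(exc) < 1) max(exc) else NA_real_),
       plateau_window = pw)
}

#' Trapezoidal excitation profile
#'
#' `0 -> ramp (ramp_s) -> hold (hold_s at level) -> ramp down -> rest`,
#' sampled at `fs`; the standard submaximal contraction shape.
#'
#' @param level Plateau excitation fraction (e.g. 0.25).
#' @param ramp_s,hold_s,rest_s Segment durations in seconds.
#' @param fs Sampling rate.
#' @export
trapezoid_profile <- function(level = 0.25, ramp_s = 5, hold_s = 20,
                              rest_s = 1, fs = 1000) {
  c(rep(0, round(rest_s * fs)),
    seq(0, level, length.out = round(ramp_s * fs)),
    rep(level, round(hold_s * fs)),
    seq(level, 0, length.out = round(ramp_s * fs)),
    rep(0, round(rest_s * fs)))
}
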