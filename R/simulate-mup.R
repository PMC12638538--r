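# Intramuscular MUP-train surrogate: a template built from a handful of
# Gaussian-derivative fibre contributions at 50 kHz, plus per-discharge
# realizations in which each fibre's latency jitters independently (the
# substrate of near-fibre jiggle) and baseline noise is added.

gauss_deriv_lobe <- function(t, centre_s, sigma_s, amp_uV) {
  u <- (t - centre_s) / sigma_s
  # first derivative of a Gaussian, normalized to peak amplitude amp_uV
  -amp_uV * u * exp(0.5 - u^2 / 2)
}

#' Simulate a motor unit potential train
#'
#' The template is a sum of Gaussian-derivative lobes (one per fibre)
#' at nominal latencies; each realization re-draws every fibre latency
#' with SD `jitter_us` and adds white baseline noise, emulating
#' neuromuscular-junction transmission variability. Zero jitter and zero
#' noise reproduce the template exactly in every realization.
#'
#' @param seed Integer seed (`NA` to use the caller's RNG state).
#' @param jitter_us Per-fibre latency jitter SD in microseconds.
#' @param n_discharges Number of realizations (>= 2).
#' @param fs Sampling rate (default 50 kHz).
#' @param n_fibres Number of near-fibre contributions (default 4).
#' @param noise_uV Baseline noise SD per realization sample (default 0).
#' @param duration_ms Template span (default 15 ms).
#' @param amp_scale Multiplies all fibre amplitudes (effect injection).
#' @return A [mup_template()] with `realizations` attached. If cursor
#'   detection fails on the template the attribute `flagged` is `TRUE`.
#' @export
simulate_mup_train <- function(seed = NA_integer_, jitter_us = 25,
                               n_discharges = 100, fs = 50000,
                               n_fibres = 4, noise_uV = 0.2,
                               duration_ms = 15, amp_scale = 1) {
  stopifnot(n_discharges >= 2)
  if (!is.na(seed)) set.seed(seed)
  n <- round(duration_ms * 1e-3 * fs)
  t <- (seq_len(n) - 1L) / fs
  mid <- duration_ms * 1e-3 / 2
  centres <- mid + stats::runif(n_fibres, -1.2e-3, 1.2e-3)
  sigmas <- stats::runif(n_fibres, 2.5e-4, 5e-4)
  amps <- amp_scale * stats::runif(n_fibres, 80, 350)

  template <- rowSums(vapply(seq_len(n_fibres), function(f)
    gauss_deriv_lobe(t, centres[f], sigmas[f], amps[f]), numeric(n)))

  # baseline noise band-limited to the acquisition band (10 kHz guard),
  # emulating post-editing residual noise rather than raw white noise
  noise_bank <- if (noise_uV > 0) {
    bb <- signal::butter(2, 10000 / (fs / 2), type = "low")
    nm <- matrix(stats::rnorm(n * n_discharges, 0, noise_uV), n, n_discharges)
    apply(nm, 2L, function(col) zp_filter(bb, col))
  } else matrix(0, n, n_discharges)

  real <- vapply(seq_len(n_discharges), function(j) {
    dtau <- stats::rnorm(n_fibres, 0, jitter_us * 1e-6)
    w <- rowSums(vapply(seq_len(n_fibres), function(f)
      gauss_deriv_lobe(t, centres[f] + dtau[f], sigmas[f], amps[f]),
      numeric(n)))
    w + noise_bank[, j]
  }, numeric(n))

  tp <- mup_template(template, fs = fs, n_discharges = n_discharges,
                     realizations = real)
  placed <- try(place_cursors(tp, noise_uV = noise_uV), silent = TRUE)
  if (inherits(placed, "try-error")) {
    attr(tp, "flagged") <- TRUE
    tp
  } else placed
}
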