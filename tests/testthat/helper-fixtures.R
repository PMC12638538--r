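# Shared fixture builders. Everything is generated in code; no stored data.

# ideal trapezoid force trace: rest, linear ramp, hold, ramp down, rest
ideal_trapezoid <- function(hold_N = 100, ramp_s = 5, hold_s = 20, fs = 1000,
                            rest_s = 1) {
  samples <- c(rep(0, rest_s * fs),
               seq(0, hold_N, length.out = ramp_s * fs),
               rep(hold_N, hold_s * fs),
               seq(hold_N, 0, length.out = ramp_s * fs),
               rep(0, rest_s * fs))
  force_trace(samples, fs = fs, target_fraction = 0.25)
}

# perfectly regular spike train at `rate` pps on [start, start + dur)
regular_train <- function(rate = 8, dur = 10, start = 0, mu_id = "m1",
                          pnr = 35, leg = NA, timepoint = NA, track_id = NA) {
  mu_train(mu_id, start + seq(0, dur - 1e-9, by = 1 / rate), pnr_db = pnr,
           leg = leg, timepoint = timepoint, track_id = track_id)
}

# train with a prescribed ISI sequence (first spike at t0)
isi_train <- function(isis, t0 = 0.5, mu_id = "m1", pnr = 35) {
  mu_train(mu_id, cumsum(c(t0, isis)), pnr_db = pnr)
}

# template from an explicit waveform with manually valid cursors
manual_template <- function(v, fs = 50000, onset, end, neg = NULL, pos = NULL,
                            n_discharges = 50, realizations = NULL) {
  if (is.null(neg)) neg <- onset + 1L
  if (is.null(pos)) pos <- end - 1L
  mup_template(v, fs = fs,
               cursors = list(onset = onset, end = end,
                              positive_peak = pos, negative_peak = neg),
               n_discharges = n_discharges, realizations = realizations)
}

# piecewise-linear waveform through (sample, uV) knots
pl_wave <- function(knots_x, knots_y, n) {
  stats::approx(knots_x, knots_y, xout = seq_len(n), rule = 2)$y
}

# a Gaussian lobe (for NFM oracles)
gauss_lobe <- function(n = 750, fs = 50000, centre_s = 0.0075,
                       sigma_s = 5e-4, amp = 100) {
  t <- (seq_len(n) - 1) / fs
  amp * exp(-(t - centre_s)^2 / (2 * sigma_s^2))
}

# a tiny complete session for IO tests
tiny_session <- function() {
  tr <- force_trace(c(0, 1, 2, 3, 2, 1), fs = 2,
                    annotations = data.frame(label = "mvc", start_s = 0.5,
                                             end_s = 2.0),
                    target_fraction = NA_real_)
  t1 <- mu_train("u001", c(0.1, 0.35, 0.61), pnr_db = 33.5,
                 leg = "exercise", timepoint = "pre", track_id = "trk01")
  t2 <- mu_train("u002", c(0.2, 0.5, 0.75, 1.1), pnr_db = 29.1,
                 leg = "exercise", timepoint = "pre")
  tp <- manual_template(pl_wave(c(1, 40, 50, 60, 100), c(0, 0, -80, 0, 0), 100),
                        fs = 25000, onset = 30, end = 70, neg = 49, pos = 68,
                        n_discharges = 41,
                        realizations = cbind(r1 = rep(0.5, 100),
                                             r2 = rep(-0.5, 100)))
  structure(list(subject_id = "S01", leg = "exercise", timepoint = "pre",
                 mvc_N = NA_real_, forces = list(tr), trains = list(t1, t2),
                 templates = list(m01 = tp)),
            class = "mu_session")
}
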