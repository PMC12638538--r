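# Spike-train (HDsEMG) metrics: inclusion filtering, instantaneous and
# phase-specific firing rates, ISI variability, recruitment /
# derecruitment thresholds, pre-post track matching and the cumulative
# spike train.
#
# ISI hygiene: inter-spike intervals outside [0.02, 0.5] s (i.e. rates
# outside 2-50 pps) are treated as decomposition artifacts and excluded
# from rate and variability metrics; exclusion counts are attached as an
# attribute so nothing is silently dropped.

ISI_MIN_S <- 0.02
ISI_MAX_S <- 0.5

#' Filter spike trains by decomposition quality
#'
#' Retains motor units with pulse-to-noise ratio at or above the
#' threshold (inclusive). The excluded units are attached as the
#' `"excluded"` attribute for auditing.
#'
#' @param trains List of [mu_train()] objects.
#' @param pnr_min_db Inclusion threshold in dB (default 30).
#' @return The retained sub-list, with attribute `excluded` naming the
#'   dropped `mu_id`s and their PNRs.
#' @export
filter_trains <- function(trains, pnr_min_db = 30) {
  if (!length(trains)) return(trains)
  pnr <- vapply(trains, function(x) x$pnr_db, numeric(1L))
  keep <- pnr >= pnr_min_db
  out <- trains[keep]
  attr(out, "excluded") <- data.frame(
    mu_id = vapply(trains[!keep], function(x) x$mu_id, ""),
    pnr_db = pnr[!keep], stringsAsFactors = FALSE)
  out
}

#' Instantaneous firing rates of a train
#'
#' `rate_k = 1 / (t_k - t_(k-1))`, assigned to the later spike of each
#' interval, in pulses per second.
#'
#' @param train A [mu_train()].
#' @return Numeric vector of length `n_spikes - 1`, or `NA` if the train
#'   has fewer than two spikes (undefined, not an error).
#' @export
instantaneous_rates <- function(train) {
  t <- train$spike_times_s
  if (length(t) < 2L) return(NA_real_)
  1 / diff(t)
}

clean_isis <- function(isi) {
  ok <- isi >= ISI_MIN_S & isi <= ISI_MAX_S
  structure(isi[ok], n_excluded = sum(!ok))
}

#' Phase-specific mean firing rates
#'
#' Recruitment-phase rate is the mean of the first `n_obs` instantaneous
#' rates, derecruitment-phase the mean of the last `n_obs`, and the
#' plateau rate the mean instantaneous rate of spikes falling inside the
#' plateau window. Out-of-range ISIs are excluded first (see module
#' notes); a phase with too few observations yields `NA` for that phase
#' only.
#'
#' @param train A [mu_train()].
#' @param plateau_window Numeric `c(start_s, end_s)`.
#' @param n_obs Number of observations per transient phase (default 5).
#' @return Named numeric: `fr_recruitment`, `fr_plateau`,
#'   `fr_derecruitment` (pps).
#' @export
phase_firing_rates <- function(train, plateau_window, n_obs = 5) {
  t <- train$spike_times_s
  out <- c(fr_recruitment = NA_real_, fr_plateau = NA_real_,
           fr_derecruitment = NA_real_)
  if (length(t) < 2L) return(out)
  isi <- diff(t)
  ok <- isi >= ISI_MIN_S & isi <= ISI_MAX_S
  rates <- 1 / isi[ok]
  if (length(rates) >= n_obs) {
    out["fr_recruitment"] <- mean(rates[seq_len(n_obs)])
    out["fr_derecruitment"] <- mean(rates[length(rates) - n_obs + seq_len(n_obs)])
  }
  # plateau: rate_k belongs to spike k; require both bounding spikes inside
  tk <- t[-1L][ok]
  tk0 <- t[-length(t)][ok]
  inside <- tk >= plateau_window[1L] & tk <= plateau_window[2L] &
    tk0 >= plateau_window[1L]
  if (sum(inside) >= 1L) out["fr_plateau"] <- mean(1 / isi[ok][inside])
  out
}

#' ISI coefficient of variation over the plateau
#'
#' Sample SD / mean of the inter-spike intervals whose bounding spikes
#' both fall inside the window, after artifact-ISI exclusion.
#'
#' @inheritParams phase_firing_rates
#' @return Dimensionless CoV, or `NA` if fewer than 3 qualifying spikes.
#' @export
isi_cov <- function(train, plateau_window) {
  t <- train$spike_times_s
  t <- t[t >= plateau_window[1L] & t <= plateau_window[2L]]
  if (length(t) < 3L) return(NA_real_)
  isi <- clean_isis(diff(t))
  if (length(isi) < 2L) return(NA_real_)
  stats::sd(isi) / mean(isi)
}

#' Recruitment and derecruitment force thresholds
#'
#' Force level at the first and last discharge, obtained by linear
#' interpolation of the (filtered) force trace at the spike times.
#'
#' @param train A [mu_train()].
#' @param filtered_force A [force_trace()], already low-pass filtered.
#' @return Named numeric `c(recruit_N, derecruit_N)`.
#' @export
recruitment_thresholds <- function(train, filtered_force) {
  t <- train$spike_times_s
  dur <- trace_duration(filtered_force)
  if (min(t) < 0 || max(t) > dur + 1e-9)
    stop("spike times of mu_id ", train$mu_id, " fall outside the force trace")
  tt <- trace_time(filtered_force)
  v <- stats::approx(tt, filtered_force$samples, xout = c(min(t), max(t)),
                     rule = 2)$y
  c(recruit_N = v[1L], derecruit_N = v[2L])
}

# normalized cross-correlation of two waveforms, maximized over lags
ncc_max <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  da <- sqrt(sum(a^2)); db <- sqrt(sum(b^2))
  if (da == 0 || db == 0) return(0)
  # convolve() reverses its second argument internally, so passing b
  # unreversed yields the cross-correlation over all lags
  cc <- stats::convolve(a, b, type = "open")
  max(cc) / (da * db)
}

# exact maximum-weight one-to-one assignment (bitmask DP over columns);
# rows/cols with no admissible partner stay unmatched. Exact up to 14
# columns; caller orients the smaller side as columns.
assign_lsap <- function(score, min_score) {
  n <- nrow(score); m <- ncol(score)
  adm <- score >= min_score
  if (m > 14L) return(assign_greedy(score, min_score))
  full <- bitwShiftL(1L, m) - 1L
  NEG <- -Inf
  best <- matrix(NEG, n + 1L, full + 1L)
  best[1L, 1L] <- 0
  choice <- array(NA_integer_, dim = c(n + 1L, full + 1L))
  for (i in seq_len(n)) {
    for (mask in 0:full) {
      cur <- best[i, mask + 1L]
      if (!is.finite(cur)) next
      # leave row i unmatched
      if (cur > best[i + 1L, mask + 1L]) {
        best[i + 1L, mask + 1L] <- cur
        choice[i + 1L, mask + 1L] <- 0L
      }
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (adm[i, j] && bitwAnd(mask, bit) == 0L) {
          v <- cur + score[i, j]
          if (v > best[i + 1L, bitwOr(mask, bit) + 1L]) {
            best[i + 1L, bitwOr(mask, bit) + 1L] <- v
            choice[i + 1L, bitwOr(mask, bit) + 1L] <- j
          }
        }
      }
    }
  }
  mask <- which.max(best[n + 1L, ]) - 1L
  match <- integer(n)
  for (i in rev(seq_len(n))) {
    j <- choice[i + 1L, mask + 1L]
    match[i] <- j
    if (!is.na(j) && j > 0L) mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  match
}

assign_greedy <- function(score, min_score) {
  n <- nrow(score); m <- ncol(score)
  match <- integer(n)
  used <- logical(m)
  ord <- order(score, decreasing = TRUE)
  for (k in ord) {
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (match[i] == 0L && !used[j] && score[i, j] >= min_score) {
      match[i] <- j; used[j] <- TRUE
    }
  }
  match
}

#' Match motor units across timepoints
#'
#' Externally provided track links (matching non-`NA` `track_id`s on both
#' sides) are accepted verbatim. Otherwise units are paired by the
#' normalized cross-correlation of their spike-triggered templates, using
#' the one-to-one assignment that maximizes total correlation subject to
#' every accepted pair correlating at least `min_corr`; leftover units
#' stay untracked.
#'
#' @param pre_trains,post_trains Lists of [mu_train()] from the same leg.
#' @param pre_templates,post_templates Optional lists of waveforms (or
#'   [mup_template()] objects), parallel to the train lists.
#' @param min_corr Minimum admissible correlation (default 0.8).
#' @return data.frame with columns `pre_mu`, `post_mu`, `correlation`,
#'   `track_id`.
#' @export
match_tracks <- function(pre_trains, post_trains, pre_templates = NULL,
                         post_templates = NULL, min_corr = 0.8) {
  pre_ids <- vapply(pre_trains, function(x) x$mu_id, "")
  post_ids <- vapply(post_trains, function(x) x$mu_id, "")
  pre_tr <- vapply(pre_trains, function(x) x$track_id, "")
  post_tr <- vapply(post_trains, function(x) x$track_id, "")

  if (any(!is.na(pre_tr) & pre_tr != "NA") && any(!is.na(post_tr) & post_tr != "NA")) {
    shared <- intersect(pre_tr[!is.na(pre_tr)], post_tr[!is.na(post_tr)])
    shared <- setdiff(shared, c(NA_character_, "NA"))
    if (length(shared)) {
      return(data.frame(
        pre_mu = pre_ids[match(shared, pre_tr)],
        post_mu = post_ids[match(shared, post_tr)],
        correlation = NA_real_, track_id = shared,
        stringsAsFactors = FALSE))
    }
  }

  if (is.null(pre_templates) || is.null(post_templates))
    stop("templates are required when no external track links are present")
  wf <- function(x) if (inherits(x, "mup_template")) x$voltage_uV else as.numeric(x)
  pre_w <- lapply(pre_templates, wf)
  post_w <- lapply(post_templates, wf)
  score <- outer(seq_along(pre_w), seq_along(post_w),
                 Vectorize(function(i, j) ncc_max(pre_w[[i]], post_w[[j]])))
  score <- matrix(score, nrow = length(pre_w))

  flip <- length(post_w) > length(pre_w) && length(pre_w) <= 14L
  match <- if (flip) {
    m2 <- assign_lsap(t(score), min_corr)
    out <- integer(length(pre_w))
    out[m2[m2 > 0L]] <- which(m2 > 0L)
    out
  } else assign_lsap(score, min_corr)

  got <- which(match > 0L)
  data.frame(pre_mu = pre_ids[got], post_mu = post_ids[match[got]],
             correlation = score[cbind(got, match[got])],
             track_id = sprintf("trk%02d", seq_along(got)),
             stringsAsFactors = FALSE)
}

#' Cumulative spike train and its pre-to-post change
#'
#' Each tracked train is binarized at `bin_s`, summed across units,
#' smoothed and averaged over the analysis window, giving the mean CST
#' rate (a proxy for net neural drive) per timepoint, plus the absolute
#' and percentage pre-to-post deltas.
#'
#' @param trains List of [mu_train()] objects carrying `timepoint` and
#'   `track_id`; only track ids present at both timepoints contribute.
#' @param window Numeric `c(start_s, end_s)` analysis window, or a list
#'   `list(pre = ..., post = ...)` when the two timepoints have their
#'   own plateau windows.
#' @param bin_s Bin width in seconds (default 0.001).
#' @param smooth `"hann"` (default, 0.4 s window), `"rect"` or `"none"`.
#'   The window mean is insensitive to this choice for stationary trains
#'   away from edges; with `"none"` it equals spike count / duration
#'   exactly.
#' @param smooth_s Smoothing window length in seconds.
#' @return A list of class `cst_result`: `mean_pps` (named, pre/post),
#'   `delta_abs_pps`, `delta_pct`, `n_tracked`.
#' @export
cumulative_spike_train <- function(trains, window, bin_s = 0.001,
                                   smooth = c("hann", "rect", "none"),
                                   smooth_s = 0.4) {
  smooth <- match.arg(smooth)
  if (!is.list(window)) window <- list(pre = window, post = window)
  tp <- vapply(trains, function(x) x$timepoint, "")
  tid <- vapply(trains, function(x) x$track_id, "")
  shared <- intersect(tid[tp == "pre"], tid[tp == "post"])
  shared <- setdiff(shared, c(NA_character_, "NA"))
  if (!length(shared))
    return(structure(list(mean_pps = c(pre = NA_real_, post = NA_real_),
                          delta_abs_pps = NA_real_, delta_pct = NA_real_,
                          n_tracked = 0L), class = "cst_result"))

  mean_rate <- function(sub, window) {
    edges <- seq(window[1L], window[2L], by = bin_s)
    nb <- length(edges) - 1L
    counts <- numeric(nb)
    for (tr in sub) {
      t <- tr$spike_times_s
      t <- t[t >= window[1L] & t < window[2L]]
      if (length(t))
        counts <- counts + tabulate(findInterval(t, edges), nbins = nb)
    }
    rate <- counts / bin_s
    if (smooth != "none") {
      L <- max(3L, round(smooth_s / bin_s))
      k <- if (smooth == "hann") {
        w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
        w / sum(w)
      } else rep(1 / L, L)
      # zero-padded convolution, central segment: kernel mass (and hence
      # the window mean) is preserved exactly for spikes > L/2 bins from
      # the window edges
      full <- stats::convolve(rate, rev(k), type = "open")
      off <- (L - 1L) %/% 2L
      rate <- full[(off + 1L):(off + nb)]
    }
    mean(rate)
  }

  keep <- function(when) trains[tp == when & tid %in% shared]
  m <- c(pre = mean_rate(keep("pre"), window$pre),
         post = mean_rate(keep("post"), window$post))
  d <- unname(m["post"] - m["pre"])
  structure(list(mean_pps = m, delta_abs_pps = d,
                 delta_pct = if (m["pre"] > 0) 100 * d / unname(m["pre"]) else NA_real_,
                 n_tracked = length(shared)),
            class = "cst_result")
}
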