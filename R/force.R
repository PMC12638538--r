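# Force-signal metrics: MVC extraction, plateau identification, force
# steadiness. The filtering convention throughout is a zero-phase
# (forward-backward) 4th-order Butterworth low-pass at 20 Hz, so the
# effective magnitude response is the squared single-pass response:
# |H(f)|^2 = 1 / (1 + (f/fc)^8). Zero-phase filtering keeps force values
# aligned in time with spike trains, which matters for recruitment
# thresholds.

# zero-phase filtering with odd-reflection padding, so constants pass
# unchanged and edge transients stay out of the analysed span
zp_filter <- function(b, x, padlen = min(length(x) - 1L, 512L)) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen <= 0L) return(as.numeric(signal::filtfilt(b, x)))
  left <- 2 * x[1L] - x[(padlen + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  as.numeric(signal::filtfilt(b, c(left, x, right)))[padlen + seq_len(n)]
}

#' Low-pass filter a force trace
#'
#' Zero-phase (forward-backward) Butterworth low-pass with DC gain 1.
#' The effective attenuation is the square of the single-pass magnitude
#' response (gain 0.5 at the cutoff rather than 0.7071).
#'
#' @param trace A [force_trace()].
#' @param cutoff_hz Cutoff frequency (default 20 Hz).
#' @param order Filter order for a single pass (default 4).
#' @return A filtered `force_trace` with the same metadata.
#' @export
lowpass_force <- function(trace, cutoff_hz = 20, order = 4) {
  if (trace$fs <= 2 * cutoff_hz)
    stop("sampling rate (", trace$fs, " Hz) must exceed twice the cutoff (",
         cutoff_hz, " Hz)")
  b <- signal::butter(order, cutoff_hz / (trace$fs / 2), type = "low")
  y <- zp_filter(b, trace$samples,
                 padlen = min(length(trace$samples) - 1L,
                              ceiling(10 * trace$fs / cutoff_hz)))
  force_trace(y, fs = trace$fs, annotations = trace$annotations,
              target_fraction = trace$target_fraction)
}

#' Extract MVC from maximal-effort traces
#'
#' The per-trial maximum of the low-pass-filtered force inside each
#' MVC-annotated window is taken, and the highest of the trial maxima is
#' the MVC. Traces without an `"mvc"` annotation but with no
#' `target_fraction` are treated as single whole-trace MVC efforts.
#'
#' @param traces A list of [force_trace()] objects (or a single trace).
#' @param filter Apply [lowpass_force()] first (default `TRUE`).
#' @param reference_mvc_N Optional earlier MVC against which a percent
#'   change is computed.
#' @return A list of class `mvc_result`: `mvc_N`, `trial_maxima_N`,
#'   `percent_change` (NA unless a reference was given).
#' @export
extract_mvc <- function(traces, filter = TRUE, reference_mvc_N = NA_real_) {
  if (inherits(traces, "force_trace")) traces <- list(traces)
  maxima <- numeric()
  for (tr in traces) {
    f <- if (filter) lowpass_force(tr) else tr
    a <- f$annotations
    win <- a[a$label == "mvc", , drop = FALSE]
    if (nrow(win) == 0L) {
      if (is.finite(tr$target_fraction)) next  # submaximal trace, skip
      maxima <- c(maxima, max(f$samples))
    } else {
      for (i in seq_len(nrow(win))) {
        idx <- window_index(f, win$start_s[i], win$end_s[i])
        maxima <- c(maxima, max(f$samples[idx]))
      }
    }
  }
  if (!length(maxima)) stop("no MVC-annotated trace supplied")
  structure(list(mvc_N = max(maxima), trial_maxima_N = maxima,
                 percent_change = if (is.finite(reference_mvc_N))
                   percent_change(reference_mvc_N, max(maxima)) else NA_real_),
            class = "mvc_result")
}

window_index <- function(trace, start_s, end_s) {
  i0 <- max(1L, 1L + ceiling(start_s * trace$fs - 1e-9))
  i1 <- min(length(trace$samples), 1L + floor(end_s * trace$fs + 1e-9))
  if (i1 < i0) stop("empty window [", start_s, ", ", end_s, "] s")
  i0:i1
}

#' Locate the hold plateau of a trapezoidal contraction
#'
#' Returns the longest contiguous window in which the filtered force
#' stays within `tol_fraction` of the target and that lasts at least
#' `min_s` seconds. An explicit `"plateau"` annotation, when present,
#' overrides detection.
#'
#' @param trace A [force_trace()] (filtered internally unless
#'   `filter = FALSE`).
#' @param target_N Target hold force in newtons.
#' @param tol_fraction Allowed deviation as a fraction of target
#'   (default 0.05).
#' @param min_s Minimum qualifying duration (default 5 s).
#' @param filter Low-pass first (default `TRUE`).
#' @return Numeric `c(start_s, end_s)`.
#' @export
find_plateau <- function(trace, target_N, tol_fraction = 0.05, min_s = 5,
                         filter = TRUE) {
  a <- trace$annotations
  ann <- a[a$label == "plateau", , drop = FALSE]
  if (nrow(ann)) return(c(ann$start_s[1L], ann$end_s[1L]))
  f <- if (filter) lowpass_force(trace) else trace
  ok <- abs(f$samples - target_N) <= tol_fraction * target_N
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= min_s * f$fs)
  if (!length(good)) {
    stop("no window of >= ", min_s, " s within ", 100 * tol_fraction,
         "% of ", target_N, " N (closest approach ",
         signif(min(abs(f$samples - target_N)), 4), " N off target)")
  }
  k <- good[which.max(r$lengths[good])]
  c((starts[k] - 1L) / f$fs, (ends[k] - 1L) / f$fs)
}

#' Force steadiness (coefficient of variation of force)
#'
#' Sample SD (n - 1) divided by the mean of the low-pass-filtered force
#' inside the plateau window.
#'
#' @param trace A [force_trace()].
#' @param window Numeric `c(start_s, end_s)`; defaults to the whole trace.
#' @param filter Low-pass first (default `TRUE`).
#' @return A list of class `force_steadiness_result`: `cov`,
#'   `plateau_window`, `mean_N`, `sd_N`.
#' @export
force_steadiness <- function(trace, window = NULL, filter = TRUE) {
  f <- if (filter) lowpass_force(trace) else trace
  if (is.null(window)) window <- c(0, trace_duration(f))
  idx <- window_index(f, window[1L], window[2L])
  x <- f$samples[idx]
  m <- mean(x)
  if (m <= 0) stop("mean force in window is not positive (", signif(m, 4), " N)")
  s <- stats::sd(x)
  structure(list(cov = s / m, plateau_window = window, mean_N = m, sd_N = s),
            class = "force_steadiness_result")
}

#' Pick the steadiest trapezoid repeat
#'
#' Ranks submaximal (trapezoid) traces by the coefficient of variation of
#' the raw force over their detected plateau and returns the index of the
#' least-variable one — an automated stand-in for selecting the
#' contraction "with the least variation" by eye.
#'
#' @param traces List of trapezoid [force_trace()] objects.
#' @param target_N Hold target in newtons.
#' @return Integer index into `traces`.
#' @export
pick_steadiest_trapezoid <- function(traces, target_N) {
  if (inherits(traces, "force_trace")) traces <- list(traces)
  covs <- vapply(traces, function(tr) {
    w <- find_plateau(tr, target_N)
    force_steadiness(tr, w, filter = FALSE)$cov
  }, numeric(1L))
  which.min(covs)
}
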