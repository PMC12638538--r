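#' Construct a force trace
#'
#' A uniformly sampled isometric force signal with optional trial
#' annotations. All force values are newtons and all times seconds;
#' readers are responsible for unit conversion before construction.
#'
#' @param samples Numeric vector of force samples (N). Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param annotations Optional data.frame with columns `label`, `start_s`,
#'   `end_s` marking trial windows (e.g. `"mvc"` efforts, `"trapezoid"`
#'   holds). Windows must lie within the trace and must not overlap
#'   within a label.
#' @param target_fraction Target force as a fraction of MVC for submaximal
#'   contractions (e.g. 0.25), or `NA` for maximal efforts.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(samples, fs, annotations = NULL, target_fraction = NA_real_) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  samples <- as.numeric(samples)
  if (!all(is.finite(samples)))
    stop("force samples must all be finite")
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(), start_s = numeric(),
                              end_s = numeric(), stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "start_s", "end_s") %in% names(annotations)))
    annotations <- annotations[, c("label", "start_s", "end_s")]
  }
  x <- structure(list(samples = samples, fs = fs, annotations = annotations,
                      target_fraction = as.numeric(target_fraction)),
                 class = "force_trace")
  validate_force_trace(x)
  x
}

#' @rdname force_trace
#' @param x A `force_trace`.
#' @export
validate_force_trace <- function(x) {
  dur <- length(x$samples) / x$fs
  a <- x$annotations
  if (nrow(a)) {
    if (any(a$start_s < 0) || any(a$end_s > dur + 1e-9) || any(a$end_s <= a$start_s))
      stop("annotation windows must satisfy 0 <= start < end <= duration (",
           signif(dur, 6), " s)")
    for (lab in unique(a$label)) {
      w <- a[a$label == lab, , drop = FALSE]
      w <- w[order(w$start_s), , drop = FALSE]
      if (nrow(w) > 1L && any(w$start_s[-1L] < w$end_s[-nrow(w)] - 1e-9))
        stop("overlapping annotation windows for label '", lab, "'")
    }
  }
  invisible(x)
}

#' Duration of a force trace in seconds
#' @param x A `force_trace`.
#' @export
trace_duration <- function(x) length(x$samples) / x$fs

#' Time axis of a force trace (seconds, first sample at t = 0)
#' @param x A `force_trace`.
#' @export
trace_time <- function(x) (seq_along(x$samples) - 1L) / x$fs

#' Construct a motor unit spike train
#'
#' Ordered discharge (firing) times of one decomposed motor unit within a
#' single contraction, with the decomposition quality metadata used for
#' inclusion filtering.
#'
#' @param mu_id Identifier, coerced to character.
#' @param spike_times_s Strictly increasing discharge times in seconds;
#'   duplicates are rejected, not deduplicated, because decomposition
#'   output should never contain them.
#' @param pnr_db Pulse-to-noise ratio in dB (finite scalar).
#' @param leg `"exercise"`, `"control"` or `NA`.
#' @param timepoint `"pre"`, `"post"` or `NA`.
#' @param track_id Optional identifier shared by the pre- and
#'   post-intervention instances of a tracked unit.
#' @return An object of class `mu_train`.
#' @export
mu_train <- function(mu_id, spike_times_s, pnr_db, leg = NA_character_,
                     timepoint = NA_character_, track_id = NA_character_) {
  spike_times_s <- as.numeric(spike_times_s)
  if (any(!is.finite(spike_times_s)))
    stop("spike times must be finite (mu_id ", mu_id, ")")
  if (length(spike_times_s) > 1L && any(diff(spike_times_s) <= 0))
    stop("spike times must be strictly increasing (mu_id ", mu_id, ")")
  if (length(pnr_db) != 1L || !is.finite(pnr_db))
    stop("pnr_db must be a finite scalar (mu_id ", mu_id, ")")
  if (!is.na(leg)) leg <- match.arg(leg, c("exercise", "control"))
  if (!is.na(timepoint)) timepoint <- match.arg(timepoint, c("pre", "post"))
  structure(list(mu_id = as.character(mu_id), spike_times_s = spike_times_s,
                 pnr_db = as.numeric(pnr_db), leg = leg, timepoint = timepoint,
                 track_id = as.character(track_id)),
            class = "mu_train")
}

#' Number of spikes in a train
#' @param x A `mu_train`.
#' @export
n_spikes <- function(x) length(x$spike_times_s)

#' Construct a motor unit potential template
#'
#' The averaged (template) MUP waveform of one motor unit potential train,
#' sampled at the intramuscular acquisition rate (nominally 50 kHz), with
#' marker cursors and, optionally, the per-discharge realizations used for
#' near-fibre jiggle.
#'
#' @param voltage_uV Numeric template waveform in microvolts.
#' @param fs Sampling rate in Hz.
#' @param cursors Named list or vector with 0-based sample indices
#'   `onset`, `end`, `positive_peak`, `negative_peak`, or `NULL` if not
#'   yet placed (see [place_cursors()]).
#' @param n_discharges Number of MUPs in the train (>= 1).
#' @param realizations Optional matrix, one column per discharge, each the
#'   same length as the template.
#' @return An object of class `mup_template`.
#' @export
mup_template <- function(voltage_uV, fs, cursors = NULL, n_discharges = 1L,
                         realizations = NULL) {
  voltage_uV <- as.numeric(voltage_uV)
  if (!all(is.finite(voltage_uV))) stop("template voltages must be finite")
  if (fs <= 0) stop("fs must be positive")
  if (n_discharges < 1L) stop("n_discharges must be >= 1")
  if (!is.null(realizations)) {
    realizations <- as.matrix(realizations)
    if (nrow(realizations) != length(voltage_uV))
      stop("realizations must have the same length as the template")
  }
  x <- structure(list(voltage_uV = voltage_uV, fs = fs,
                      cursors = cursors, n_discharges = as.integer(n_discharges),
                      realizations = realizations),
                 class = "mup_template")
  if (!is.null(cursors)) validate_cursors(x)
  x
}

validate_cursors <- function(x) {
  cu <- x$cursors
  need <- c("onset", "end", "positive_peak", "negative_peak")
  if (!all(need %in% names(cu))) stop("cursors must name ", paste(need, collapse = ", "))
  cu <- lapply(cu[need], as.integer)
  n <- length(x$voltage_uV)
  if (any(unlist(cu) < 0L) || any(unlist(cu) >= n)) stop("cursor out of template range")
  if (!(cu$onset < cu$negative_peak && cu$negative_peak < cu$end))
    stop("cursors must satisfy onset < negative_peak < end")
  if (!(cu$onset < cu$positive_peak && cu$positive_peak < cu$end))
    stop("cursors must satisfy onset < positive_peak < end")
  invisible(x)
}

#' Long-format metric rows
#'
#' The common long table: one value per (subject, leg, timepoint,
#' optional motor unit, metric). This is the interchange format between
#' the extraction stages and the mixed-model layer.
#'
#' @param subject_id,leg,timepoint,metric Character vectors (recycled).
#' @param value Numeric metric values.
#' @param mu_id Optional motor unit identifier (`NA` for subject-level
#'   metrics such as MVC).
#' @param units Unit string per metric value.
#' @return A data.frame with the canonical column order.
#' @export
metric_rows <- function(subject_id, leg, timepoint, metric, value,
                        mu_id = NA_character_, units = "") {
  if (length(value) == 0L)
    return(data.frame(subject_id = character(), leg = character(),
                      timepoint = character(), mu_id = character(),
                      metric = character(), value = numeric(),
                      units = character(), stringsAsFactors = FALSE))
  df <- data.frame(subject_id = as.character(subject_id),
                   leg = as.character(leg),
                   timepoint = as.character(timepoint),
                   mu_id = as.character(mu_id),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  key <- df[, c("subject_id", "leg", "timepoint", "mu_id", "metric")]
  if (anyDuplicated(key))
    stop("metric rows must be unique per (subject, leg, timepoint, mu, metric)")
  df
}

#' Percent change between two values
#'
#' `100 * (post - pre) / pre`, the convention used for pre- to
#' post-intervention changes (e.g. MVC declines reported as negative
#' percentages).
#'
#' @param pre,post Numeric (vectorised).
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("percent change undefined for pre = 0")
  100 * (post - pre) / pre
}
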