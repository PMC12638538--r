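# Intramuscular MUP-template morphology: cursor placement, area, turns,
# negative-peak ratio, the near-fibre MUP operator and near-fibre jiggle,
# plus the MUPT exclusion rules. Sample indices in cursors are 0-based.

#' Place onset/end/peak cursors on a MUP template
#'
#' Peaks are the global extrema (negative peak = minimum, positive peak =
#' maximum). Onset and end are the outermost samples belonging to a
#' supra-threshold run — |v| above `max(10, 3 * noise_uV)` microvolts
#' sustained for at least 0.1 ms — so brief noise blips outside the MUP
#' are ignored. Templates that already carry cursors are returned
#' unchanged (manual override path).
#'
#' @param template A [mup_template()].
#' @param noise_uV Baseline noise SD estimate in microvolts (default 0).
#' @return The template with `cursors` filled in (0-based indices).
#' @export
place_cursors <- function(template, noise_uV = 0) {
  if (!is.null(template$cursors)) return(template)
  v <- template$voltage_uV
  th <- max(10, 3 * noise_uV)
  min_run <- max(1L, round(1e-4 * template$fs))
  above <- abs(v) >= th
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= min_run)
  if (!length(good))
    stop("no supra-threshold region (threshold ", signif(th, 4), " uV)")
  onset <- starts[good[1L]] - 1L                  # 0-based
  end <- ends[good[length(good)]] - 1L
  span <- (onset + 1L):(end + 1L)                 # peaks live inside the MUP
  neg <- span[which.min(v[span])] - 1L
  pos <- span[which.max(v[span])] - 1L
  # widen minimally so the ordering invariants hold strictly
  onset <- max(0L, min(onset, neg - 1L, pos - 1L))
  end <- min(length(v) - 1L, max(end, neg + 1L, pos + 1L))
  template$cursors <- list(onset = onset, end = end,
                           positive_peak = pos, negative_peak = neg)
  validate_cursors(template)
  template
}

#' MUP area
#'
#' Integral of |voltage| between the onset and end cursors, i.e.
#' `sum(|v_i|) * dt` with `dt` in milliseconds, giving microvolt
#' milliseconds.
#'
#' @param template A [mup_template()] with cursors placed.
#' @return Area in uV ms.
#' @export
mup_area <- function(template) {
  cu <- template$cursors
  if (is.null(cu)) stop("cursors must be placed before computing area")
  idx <- (cu$onset:cu$end) + 1L
  sum(abs(template$voltage_uV[idx])) * 1000 / template$fs
}

#' MUP turns
#'
#' Number of significant direction changes between the onset and end
#' cursors: local extrema are accepted as turns when the amplitude change
#' from the previously accepted turn (or from the onset value, for the
#' first) strictly exceeds `min_height_uV` and the direction alternates.
#' A same-direction extremum that is more extreme than the last accepted
#' turn replaces its value without incrementing the count, so
#' sub-threshold ripple riding on a larger excursion is ignored.
#'
#' @param template A [mup_template()] with cursors placed.
#' @param min_height_uV Threshold amplitude change (default 20 uV).
#' @return Integer turn count.
#' @export
mup_turns <- function(template, min_height_uV = 20) {
  cu <- template$cursors
  if (is.null(cu)) stop("cursors must be placed before counting turns")
  v <- template$voltage_uV[(cu$onset:cu$end) + 1L]

  # interior local extrema (plateau-safe: zero-slope runs collapsed)
  d <- diff(v)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(0L)
  s <- sign(d[nz])
  flip <- which(s[-1L] != s[-length(s)])
  if (!length(flip)) return(0L)
  ext_val <- v[nz[flip] + 1L]
  ext_dir <- s[flip]                  # +1 = local max, -1 = local min

  count <- 0L
  ref <- v[1L]                        # onset value is the first reference
  last_dir <- 0L
  for (k in seq_along(ext_val)) {
    val <- ext_val[k]; dir <- ext_dir[k]
    if (count > 0L && dir == last_dir) {
      # same-direction extremum: keep the more extreme as the turn value
      if ((dir > 0L && val > ref) || (dir < 0L && val < ref)) ref <- val
    } else if (abs(val - ref) > min_height_uV) {
      count <- count + 1L
      ref <- val
      last_dir <- dir
    }
  }
  count
}

#' Negative peak ratio
#'
#' |rise| / |fall| of the template's negative peak, where rise and fall
#' are the amplitude differences across fixed windows (default 500 us)
#' before and after the negative-peak cursor.
#'
#' @param template A [mup_template()] with cursors placed.
#' @param window_us Window half-span in microseconds (default 500).
#' @return Dimensionless ratio, or `NA` if the fall is exactly zero.
#' @export
negative_peak_ratio <- function(template, window_us = 500) {
  cu <- template$cursors
  if (is.null(cu)) stop("cursors must be placed first")
  w <- round(window_us * 1e-6 * template$fs)
  p <- cu$negative_peak + 1L                       # to 1-based
  v <- template$voltage_uV
  if (p - w < 1L || p + w > length(v))
    stop("negative peak closer than ", window_us, " us to the template edge")
  rise <- abs(v[p] - v[p - w])
  fall <- abs(v[p + w] - v[p])
  if (fall == 0) return(NA_real_)
  rise / fall
}

#' Near-fibre MUP operator
#'
#' Second-order temporal differentiation (discrete double difference
#' scaled by 1/dt^2) emphasizing fibres close to the recording surface,
#' followed by a zero-phase second-order 10 kHz low-pass that suppresses
#' sample-to-sample noise above the physiological band. The f^2 response
#' of the differentiator itself provides the low-frequency attenuation.
#' Output has the same length as the input (edge samples zero).
#'
#' @param x Numeric waveform (uV) or a [mup_template()].
#' @param fs Sampling rate in Hz (taken from the template if one is
#'   given). Must be at least 20 kHz.
#' @param lowpass_hz Guard low-pass cutoff (default 10000); `NA` disables.
#' @return Numeric waveform, uV / s^2 scale.
#' @export
near_fibre_mup <- function(x, fs = NULL, lowpass_hz = 10000) {
  if (inherits(x, "mup_template")) { fs <- x$fs; x <- x$voltage_uV }
  if (is.null(fs)) stop("fs is required for plain waveforms")
  if (fs < 20000) stop("near-fibre derivation requires fs >= 20 kHz")
  n <- length(x)
  d2 <- c(0, diff(x, differences = 2L), 0) * fs^2
  if (is.finite(lowpass_hz) && lowpass_hz < fs / 2) {
    b <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
    d2 <- zp_filter(b, d2)
  }
  stopifnot(length(d2) == n)
  d2
}

#' Near-fibre jiggle
#'
#' Shape variability of consecutive near-fibre MUPs, an index of
#' neuromuscular-junction transmission instability:
#' `100 * mean_j( integral |NFM_(j+1) - NFM_j| ) / integral |mean NFM|`,
#' evaluated over the NFM duration with temporally ordered
#' (consecutive-pair) differences. Realizations whose NFM correlates
#' poorly with the mean NFM (below `isolation_corr`) are treated as
#' contaminated by other units and excluded.
#'
#' @param template A [mup_template()] with per-discharge realizations, or
#'   a plain matrix of realizations (columns = discharges).
#' @param fs Sampling rate (taken from the template if one is given).
#' @param isolation_corr Minimum correlation with the mean NFM for a
#'   realization to count as isolated (default 0.5; set to `-Inf` to
#'   disable).
#' @return A list of class `nf_result`: `nf_jiggle_pct`, `nfm_template`
#'   (mean NFM), `n_isolated`. Jiggle is `NA` with fewer than 2 isolated
#'   realizations.
#' @export
nf_jiggle <- function(template, fs = NULL, isolation_corr = 0.5) {
  if (inherits(template, "mup_template")) {
    fs <- template$fs
    real <- template$realizations
  } else real <- as.matrix(template)
  if (is.null(fs)) stop("fs is required for plain realization matrices")
  if (is.null(real) || ncol(real) < 2L)
    return(structure(list(nf_jiggle_pct = NA_real_, nfm_template = NULL,
                          n_isolated = if (is.null(real)) 0L else ncol(real)),
                     class = "nf_result"))
  nfm <- apply(real, 2L, near_fibre_mup, fs = fs)
  mean_nfm <- rowMeans(nfm)
  if (is.finite(isolation_corr) && stats::sd(mean_nfm) > 0) {
    cors <- apply(nfm, 2L, function(col)
      if (stats::sd(col) > 0) stats::cor(col, mean_nfm) else 1)
    iso <- cors >= isolation_corr
    nfm <- nfm[, iso, drop = FALSE]
  }
  n_iso <- ncol(nfm)
  if (n_iso < 2L)
    return(structure(list(nf_jiggle_pct = NA_real_, nfm_template = mean_nfm,
                          n_isolated = n_iso), class = "nf_result"))
  mean_nfm <- rowMeans(nfm)
  dt <- 1 / fs
  # integrate over the NFM duration: the span where the mean NFM is
  # above 5% of its own peak, padded by 0.25 ms, not the whole template
  # (which would let baseline noise swamp the numerator)
  amp <- abs(mean_nfm)
  hot <- which(amp >= 0.05 * max(amp))
  pad <- round(2.5e-4 * fs)
  span <- max(1L, hot[1L] - pad):min(length(amp), hot[length(hot)] + pad)
  diffs <- vapply(seq_len(n_iso - 1L), function(j)
    sum(abs(nfm[span, j + 1L] - nfm[span, j])) * dt, numeric(1L))
  denom <- sum(amp[span]) * dt
  jig <- if (denom == 0) NA_real_ else 100 * mean(diffs) / denom
  structure(list(nf_jiggle_pct = jig, nfm_template = mean_nfm,
                 n_isolated = n_iso), class = "nf_result")
}

#' Filter motor unit potential trains
#'
#' Retains MUPTs with at least `min_mups` discharges and no
#' multi-unit contamination. Contamination is taken from an externally
#' supplied flag when present; otherwise a train is flagged when more
#' than `max_poor_fraction` of its realizations correlate with the
#' template below `corr_min`.
#'
#' @param templates List of [mup_template()] objects; an element may
#'   carry a logical `contaminated` field as the external flag.
#' @param min_mups Minimum discharge count (default 40; trains with
#'   fewer than 40 are excluded, 40 itself is retained).
#' @param corr_min,max_poor_fraction Contamination rule parameters.
#' @return The retained sub-list, with attribute `excluded` giving the
#'   reason per dropped train.
#' @export
filter_mupts <- function(templates, min_mups = 40, corr_min = 0.8,
                         max_poor_fraction = 0.2) {
  reasons <- character()
  keep <- logical(length(templates))
  for (k in seq_along(templates)) {
    tp <- templates[[k]]
    if (tp$n_discharges < min_mups) { reasons[k] <- "too_few_mups"; next }
    contaminated <- tp$contaminated
    if (is.null(contaminated)) {
      contaminated <- FALSE
      if (!is.null(tp$realizations) && ncol(tp$realizations) >= 2L &&
          stats::sd(tp$voltage_uV) > 0) {
        cors <- apply(tp$realizations, 2L, function(col)
          if (stats::sd(col) > 0) stats::cor(col, tp$voltage_uV) else 0)
        contaminated <- mean(cors < corr_min) > max_poor_fraction
      }
    }
    if (isTRUE(contaminated)) { reasons[k] <- "multi_mu" } else {
      keep[k] <- TRUE; reasons[k] <- ""
    }
  }
  out <- templates[keep]
  attr(out, "excluded") <- data.frame(index = which(!keep),
                                      reason = reasons[!keep],
                                      stringsAsFactors = FALSE)
  out
}
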