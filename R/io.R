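# Session storage layout
# -----------------------
# One session = one (subject, leg, timepoint). On disk:
#   manifest.json          bookkeeping + per-record metadata
#   force_<k>.tsv          time_s \t force_N       (one file per effort)
#   trains.tsv             mu_id \t spike_time_s   (or spike_sample, see below)
#   template_<mu>.tsv      template_uV [\t r1 \t r2 ...]
# All numbers are written as decimal text with 10 significant digits; the
# write -> read -> write cycle is byte-stable, which the tests rely on.

fmt_num <- function(x) sprintf("%.10g", x)

#' Write a session to disk
#'
#' Serializes a session (force traces, spike trains, MUP templates and the
#' manifest tying them together) into a directory in the package's
#' delimited-text/JSON layout.
#'
#' @param session A `mu_session` as returned by [read_session()] or built
#'   by the simulator.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(subject_id = session$subject_id, leg = session$leg,
              timepoint = session$timepoint)
  if (!is.null(session$mvc_N) && is.finite(session$mvc_N))
    man$mvc_N <- session$mvc_N

  man$force <- lapply(seq_along(session$forces), function(k) {
    tr <- session$forces[[k]]
    path <- sprintf("force_%02d.tsv", k)
    tt <- trace_time(tr)
    writeLines(c("time_s\tforce_N",
                 paste(fmt_num(tt), fmt_num(tr$samples), sep = "\t")),
               file.path(dir, path))
    rec <- list(path = path, fs = tr$fs)
    if (is.finite(tr$target_fraction)) rec$target_fraction <- tr$target_fraction
    if (nrow(tr$annotations)) {
      rec$annotations <- lapply(seq_len(nrow(tr$annotations)), function(i)
        list(label = tr$annotations$label[i],
             start_s = tr$annotations$start_s[i],
             end_s = tr$annotations$end_s[i]))
    }
    rec
  })

  if (length(session$trains)) {
    lines <- "mu_id\tspike_time_s"
    for (tr in session$trains)
      lines <- c(lines, paste(tr$mu_id, fmt_num(tr$spike_times_s), sep = "\t"))
    writeLines(lines, file.path(dir, "trains.tsv"))
    man$trains <- list(
      path = "trains.tsv",
      units = lapply(unname(session$trains), function(tr) {
        u <- list(mu_id = tr$mu_id, pnr_db = tr$pnr_db)
        if (!is.na(tr$track_id)) u$track_id <- tr$track_id
        u
      }))
  }

  if (length(session$templates)) {
    man$templates <- lapply(seq_along(session$templates), function(k) {
      tp <- session$templates[[k]]
      mu <- names(session$templates)[k]
      if (is.null(mu) || !nzchar(mu)) mu <- as.character(k)
      path <- sprintf("template_%s.tsv", mu)
      m <- cbind(template_uV = tp$voltage_uV, tp$realizations)
      hdr <- c("template_uV",
               if (!is.null(tp$realizations))
                 sprintf("r%d", seq_len(ncol(tp$realizations))))
      writeLines(c(paste(hdr, collapse = "\t"),
                   apply(m, 1L, function(r) paste(fmt_num(r), collapse = "\t"))),
                 file.path(dir, path))
      rec <- list(mu_id = mu, path = path, fs = tp$fs,
                  n_discharges = tp$n_discharges)
      if (!is.null(tp$cursors)) rec$cursors <- as.list(tp$cursors)
      rec
    })
  }

  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest_path)
}

#' Read a session from its manifest
#'
#' Loads every record named by a session manifest, normalizes units
#' (seconds, newtons, microvolts) and invariant-checks each record.
#' Spike trains may be stored either as seconds (`spike_time_s` column)
#' or as 0-based sample indices (`spike_sample` column, converted using
#' the manifest's train `fs`).
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A `mu_session`: list with `subject_id`, `leg`, `timepoint`,
#'   `mvc_N`, `forces` (list of [force_trace()]), `trains` (list of
#'   [mu_train()]), `templates` (named list of [mup_template()]).
#' @export
read_session <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)

  forces <- lapply(man$force, function(rec) {
    path <- file.path(dir, rec$path)
    if (!file.exists(path)) stop("missing force file: ", rec$path)
    df <- utils::read.delim(path)
    scale <- if (identical(rec$force_unit, "kN")) 1000 else 1
    ann <- NULL
    if (!is.null(rec$annotations)) {
      ann <- do.call(rbind, lapply(rec$annotations, function(a)
        data.frame(label = a$label, start_s = a$start_s, end_s = a$end_s,
                   stringsAsFactors = FALSE)))
    }
    force_trace(df$force_N * scale, fs = rec$fs, annotations = ann,
                target_fraction = if (is.null(rec$target_fraction)) NA_real_
                                  else rec$target_fraction)
  })

  trains <- list()
  if (!is.null(man$trains)) {
    path <- file.path(dir, man$trains$path)
    if (!file.exists(path)) stop("missing train file: ", man$trains$path)
    df <- utils::read.delim(path, colClasses = c(mu_id = "character"))
    if ("spike_sample" %in% names(df)) {
      if (is.null(man$trains$fs))
        stop("trains stored as sample indices require an fs in the manifest")
      df$spike_time_s <- df$spike_sample / man$trains$fs
    }
    meta <- man$trains$units
    names(meta) <- vapply(meta, function(u) as.character(u$mu_id), "")
    trains <- lapply(meta, function(u) {
      mu <- as.character(u$mu_id)
      mu_train(mu, df$spike_time_s[df$mu_id == mu], pnr_db = u$pnr_db,
               leg = man$leg, timepoint = man$timepoint,
               track_id = if (is.null(u$track_id)) NA_character_ else u$track_id)
    })
  }

  templates <- list()
  if (!is.null(man$templates)) {
    templates <- lapply(man$templates, function(rec) {
      path <- file.path(dir, rec$path)
      if (!file.exists(path)) stop("missing template file: ", rec$path)
      df <- utils::read.delim(path)
      scale <- if (identical(rec$voltage_unit, "mV")) 1000 else 1
      real <- NULL
      if (ncol(df) > 1L) real <- as.matrix(df[, -1L, drop = FALSE]) * scale
      mup_template(df$template_uV * scale, fs = rec$fs,
                   cursors = if (is.null(rec$cursors)) NULL
                             else lapply(rec$cursors, as.integer),
                   n_discharges = rec$n_discharges, realizations = real)
    })
    names(templates) <- vapply(man$templates, function(r) as.character(r$mu_id), "")
  }

  mvc <- if (is.null(man$mvc_N)) NA_real_ else as.numeric(man$mvc_N)
  if (!is.na(mvc) && mvc <= 0) stop("manifest mvc_N must be positive")

  structure(list(subject_id = as.character(man$subject_id),
                 leg = man$leg, timepoint = man$timepoint, mvc_N = mvc,
                 forces = forces, trains = trains, templates = templates),
            class = "mu_session")
}

#' Write / read long-format metric tables
#'
#' Tab-delimited long format, losslessly round-trippable at 10
#' significant digits.
#'
#' @param rows A data.frame from [metric_rows()].
#' @param path Output path.
#' @export
write_metrics <- function(rows, path) {
  cols <- c("subject_id", "leg", "timepoint", "mu_id", "metric", "value", "units")
  stopifnot(all(cols %in% names(rows)))
  rows <- rows[, cols]
  lines <- paste(cols, collapse = "\t")
  if (nrow(rows)) {
    lines <- c(lines, paste(rows$subject_id, rows$leg, rows$timepoint,
                            rows$mu_id, rows$metric, fmt_num(rows$value),
                            rows$units, sep = "\t"))
  }
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write metrics to ", path)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    subject_id = "character", leg = "character", timepoint = "character",
    mu_id = "character", metric = "character", value = "numeric",
    units = "character"))
  df
}
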