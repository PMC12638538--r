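# Pipeline orchestration: simulate -> extract -> stats -> report, fully
# reproducible from one seed. Reports are timestamp-free so identical
# configurations produce byte-identical bundles.

#' Extract every metric from one session
#'
#' Runs the force stage (MVC, steadiest-trapezoid selection, plateau
#' detection, force steadiness), the discharge stage (PNR filtering,
#' phase firing rates, ISI CoV, recruitment/derecruitment thresholds)
#' and the MUP stage (MUPT exclusion, area, turns, negative-peak ratio,
#' near-fibre jiggle) on a loaded session.
#'
#' @param session A `mu_session` from [read_session()].
#' @param baseline_mvc_N Baseline (pre-intervention) MVC of this leg,
#'   used to set the 25% target; defaults to the session's own MVC
#'   (correct for pre sessions).
#' @return List: `rows` (metric data.frame), `mvc_N`, `plateau_window`,
#'   `trains` (the PNR-retained trains), `trapezoid` (selected trace).
#' @export
extract_session_metrics <- function(session, baseline_mvc_N = NA_real_) {
  mvc <- extract_mvc(session$forces)
  if (!is.finite(baseline_mvc_N)) baseline_mvc_N <- mvc$mvc_N

  is_trap <- vapply(session$forces, function(f) is.finite(f$target_fraction),
                    logical(1L))
  rows <- metric_rows(session$subject_id, session$leg, session$timepoint,
                      "mvc_N", mvc$mvc_N, units = "N")
  plateau <- NULL; trains <- list(); trap_f <- NULL
  if (any(is_trap)) {
    traps <- session$forces[is_trap]
    target_N <- traps[[1L]]$target_fraction * baseline_mvc_N
    best <- pick_steadiest_trapezoid(traps, target_N)
    trap <- traps[[best]]
    plateau <- find_plateau(trap, target_N)
    fsr <- force_steadiness(trap, plateau)
    rows <- rbind(rows, metric_rows(session$subject_id, session$leg,
                                    session$timepoint, "fs_cov", fsr$cov))
    trap_f <- lowpass_force(trap)

    trains <- filter_trains(session$trains)
    for (tr in trains) {
      fr <- phase_firing_rates(tr, plateau)
      cov <- isi_cov(tr, plateau)
      th <- recruitment_thresholds(tr, trap_f)
      vals <- c(fr_recruitment = unname(fr["fr_recruitment"]),
                fr_plateau = unname(fr["fr_plateau"]),
                fr_derecruitment = unname(fr["fr_derecruitment"]),
                isi_cov = cov,
                recruit_threshold_N = unname(th["recruit_N"]),
                derecruit_threshold_N = unname(th["derecruit_N"]))
      un <- c("pps", "pps", "pps", "", "N", "N")
      ok <- !is.na(vals)
      if (any(ok))
        rows <- rbind(rows, metric_rows(session$subject_id, session$leg,
                                        session$timepoint, names(vals)[ok],
                                        vals[ok], mu_id = tr$mu_id,
                                        units = un[ok]))
    }
  }

  if (length(session$templates)) {
    kept <- filter_mupts(session$templates)
    for (k in seq_along(kept)) {
      tp <- place_cursors(kept[[k]], noise_uV = 2)
      mu <- names(kept)[k]
      jig <- nf_jiggle(tp)
      vals <- c(mup_area_uVms = mup_area(tp),
                mup_turns = mup_turns(tp),
                neg_peak_ratio = negative_peak_ratio(tp),
                nf_jiggle_pct = jig$nf_jiggle_pct)
      un <- c("uV.ms", "count", "", "%")
      ok <- !is.na(vals)
      rows <- rbind(rows, metric_rows(session$subject_id, session$leg,
                                      session$timepoint, names(vals)[ok],
                                      vals[ok], mu_id = paste0("iemg_", mu),
                                      units = un[ok]))
    }
  }

  list(rows = rows, mvc_N = mvc$mvc_N, plateau_window = plateau,
       trains = trains, trapezoid = trap_f)
}

#' Run configuration
#'
#' @param seed Master seed for the whole run.
#' @param outdir Output directory for the report bundle.
#' @param spec,pool,effects Cohort, pool and effect configurations.
#' @param stages Character subset of
#'   `c("simulate", "extract", "stats", "report")`.
#' @export
run_config <- function(seed = 1L, outdir = "crossmu_run",
                       spec = cohort_spec(), pool = pool_config(),
                       effects = effect_config(),
                       stages = c("simulate", "extract", "stats", "report")) {
  structure(list(seed = as.integer(seed), outdir = outdir, spec = spec,
                 pool = pool, effects = effects, stages = stages),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate -> extract -> stats -> report. Emits under `outdir`:
#' `sessions/` (the synthetic session tree), `metrics.tsv` (long
#' metric table), `model_table.tsv` (one row per metric: EMM (CI) per
#' cell, R2m/R2c, leg/time/interaction p), `cst_summary.tsv` (per-leg
#' cumulative-spike-train deltas + repeated-measures t), and
#' `correlation.tsv` (per-leg delta-FR vs delta-MVC Pearson), plus
#' `run_manifest.json` recording the seed and package versions.
#'
#' @param config A [run_config()].
#' @return List of in-memory results (metrics, model results, CST and
#'   correlation summaries), invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sess_dir <- file.path(out, "sessions")

  if ("simulate" %in% config$stages) {
    index <- tryCatch(
      generate_cohort(config$spec, config$pool, config$effects,
                      seed = config$seed, dir = sess_dir),
      error = function(e) stop("stage simulate failed: ", conditionMessage(e)))
  } else {
    index <- utils::read.delim(file.path(sess_dir, "index.tsv"))
    index$manifest <- file.path(sess_dir, index$manifest)
  }

  extraction <- tryCatch(extract_cohort(index, sess_dir),
                         error = function(e)
                           stop("stage extract failed: ", conditionMessage(e)))
  write_metrics(extraction$rows, file.path(out, "metrics.tsv"))

  results <- NULL
  if ("stats" %in% config$stages) {
    results <- tryCatch(stats_stage(extraction),
                        error = function(e)
                          stop("stage stats failed: ", conditionMessage(e)))
  }

  if ("report" %in% config$stages && !is.null(results)) {
    tab <- render_tables(results$models)
    utils::write.table(tab, file.path(out, "model_table.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(results$cst_table, file.path(out, "cst_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(results$correlation, file.path(out, "correlation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           package = as.character(utils::packageVersion("crossmu")),
           r_version = paste(R.version$major, R.version$minor, sep = "."),
           n_subjects = config$spec$n_subjects),
      file.path(out, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(metrics = extraction$rows, cst = extraction$cst,
                 results = results))
}

# extraction over a cohort index: pre sessions first so each leg's
# baseline MVC is available to normalize the post session's 25% target
extract_cohort <- function(index, sess_dir) {
  rows <- NULL
  cst <- NULL
  per_subject_fr <- NULL
  for (sid in unique(index$subject_id)) {
    for (leg in c("exercise", "control")) {
      pre_i <- index[index$subject_id == sid & index$leg == leg &
                       index$timepoint == "pre", ]
      post_i <- index[index$subject_id == sid & index$leg == leg &
                        index$timepoint == "post", ]
      pre <- extract_session_metrics(read_session(pre_i$manifest[1L]))
      post <- extract_session_metrics(read_session(post_i$manifest[1L]),
                                      baseline_mvc_N = pre$mvc_N)
      rows <- rbind(rows, pre$rows, post$rows)

      both <- c(pre$trains, post$trains)
      if (length(both)) {
        res <- cumulative_spike_train(
          both, window = list(pre = pre$plateau_window,
                              post = post$plateau_window))
        cst <- rbind(cst, data.frame(
          subject_id = sid, leg = leg,
          cst_pre_pps = unname(res$mean_pps["pre"]),
          cst_post_pps = unname(res$mean_pps["post"]),
          delta_abs_pps = res$delta_abs_pps, delta_pct = res$delta_pct,
          n_tracked = res$n_tracked, stringsAsFactors = FALSE))
      }
    }
  }
  list(rows = rows, cst = cst)
}

stats_stage <- function(extraction) {
  rows <- extraction$rows
  subject_level <- c("mvc_N", "fs_cov")
  mu_level <- c("fr_recruitment", "fr_plateau", "fr_derecruitment", "isi_cov",
                "recruit_threshold_N", "derecruit_threshold_N",
                "mup_area_uVms", "mup_turns", "neg_peak_ratio",
                "nf_jiggle_pct")
  models <- list()
  for (m in intersect(c(subject_level, mu_level), unique(rows$metric))) {
    d <- rows[rows$metric == m, ]
    fit <- try(suppressWarnings(fit_lmm(d, nested = FALSE)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    models[[m]] <- list(metric = m, model = fit, emm = emm_cells(fit),
                        r2 = nakagawa_r2(fit), p = lmm_pvalues(fit))
  }

  cst <- extraction$cst
  cst_table <- NULL
  if (!is.null(cst)) {
    wide <- merge(cst[cst$leg == "exercise", ], cst[cst$leg == "control", ],
                  by = "subject_id", suffixes = c("_ex", "_co"))
    tt_abs <- paired_t(wide$delta_abs_pps_ex, wide$delta_abs_pps_co)
    tt_pct <- paired_t(wide$delta_pct_ex, wide$delta_pct_co)
    cst_table <- data.frame(
      measure = c("delta_abs_pps", "delta_pct"),
      mean_exercise = c(mean(wide$delta_abs_pps_ex), mean(wide$delta_pct_ex)),
      mean_control = c(mean(wide$delta_abs_pps_co), mean(wide$delta_pct_co)),
      t = c(tt_abs$t, tt_pct$t), p = c(tt_abs$p, tt_pct$p),
      stringsAsFactors = FALSE)
  }

  correlation <- NULL
  for (leg in c("exercise", "control")) {
    d_mvc <- delta_by_subject(rows, "mvc_N", leg)
    d_fr <- delta_by_subject(rows, "fr_plateau", leg)
    shared <- intersect(names(d_mvc), names(d_fr))
    if (length(shared) >= 3L) {
      ct <- pearson_delta_correlation(d_fr[shared], d_mvc[shared])
      correlation <- rbind(correlation, data.frame(
        leg = leg, r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE))
    }
  }
  list(models = models, cst_table = cst_table, correlation = correlation)
}

delta_by_subject <- function(rows, metric, leg) {
  d <- rows[rows$metric == metric & rows$leg == leg, ]
  pre <- tapply(d$value[d$timepoint == "pre"], d$subject_id[d$timepoint == "pre"],
                mean)
  post <- tapply(d$value[d$timepoint == "post"],
                 d$subject_id[d$timepoint == "post"], mean)
  shared <- intersect(names(pre), names(post))
  stats::setNames(post[shared] - pre[shared], shared)
}

metric_digits <- function(metric) {
  switch(metric,
         mvc_N = 0L, recruit_threshold_N = 1L, derecruit_threshold_N = 1L,
         fs_cov = 3L, isi_cov = 3L,
         fr_recruitment = 2L, fr_plateau = 2L, fr_derecruitment = 2L,
         mup_area_uVms = 0L, mup_turns = 2L, neg_peak_ratio = 2L,
         nf_jiggle_pct = 1L, 2L)
}

#' Render model results as a publication-style table
#'
#' One row per metric, four `EMM (lower-upper)` cells (control/exercise
#' by pre/post), R2m/R2c and the leg, time and interaction p-values,
#' formatted to a per-metric precision (forces as integers, rates to 2
#' decimal places, CoV to 3).
#'
#' @param models The `models` element of a pipeline stats stage (list of
#'   per-metric results).
#' @return data.frame, one row per metric.
#' @export
render_tables <- function(models) {
  fmt_cell <- function(emdf, leg, tp, dg) {
    r <- emdf[emdf$leg == leg & emdf$timepoint == tp, ]
    if (!nrow(r)) return("NA")
    sprintf("%.*f (%.*f-%.*f)", dg, r$emmean, dg, r$lower.CL, dg, r$upper.CL)
  }
  out <- NULL
  for (m in names(models)) {
    x <- models[[m]]
    dg <- metric_digits(m)
    emdf <- x$emm$emms
    out <- rbind(out, data.frame(
      metric = m,
      control_pre = fmt_cell(emdf, "control", "pre", dg),
      exercise_pre = fmt_cell(emdf, "exercise", "pre", dg),
      control_post = fmt_cell(emdf, "control", "post", dg),
      exercise_post = fmt_cell(emdf, "exercise", "post", dg),
      r2_marginal = sprintf("%.2f", x$r2["r2_marginal"]),
      r2_conditional = sprintf("%.2f", x$r2["r2_conditional"]),
      p_leg = sprintf("%.3f", x$p["leg"]),
      p_time = sprintf("%.3f", x$p["time"]),
      p_interaction = sprintf("%.3f", x$p["leg_x_time"]),
      stringsAsFactors = FALSE))
  }
  out
}
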