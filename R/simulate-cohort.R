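# Bilateral pre/post cohort generation. The defaults encode the study
# conditions the pipeline is meant to reproduce: 13 subjects, two legs,
# two timepoints, three maximal efforts plus trapezoidal 25%-MVC holds
# per session, exercise-leg post-intervention effects on MVC and plateau
# firing rate, cell-specific force-steadiness targets, and no change in
# intramuscular MUP properties.

#' Intervention effect configuration
#'
#' Multipliers applied to the post-intervention sessions. Defaults
#' reflect an acute unilateral fatiguing bout: a 14.8% exercise-leg and
#' 6.9% control-leg MVC decline, an exercise-leg plateau firing-rate
#' increase of 8.66/7.32, per-cell force-steadiness CoV targets, and
#' unchanged MUP morphology.
#'
#' @param mvc_multiplier_exercise,mvc_multiplier_control Post/pre MVC
#'   ratios per leg.
#' @param plateau_fr_multiplier_exercise,plateau_fr_multiplier_control
#'   Post/pre firing-rate ratios per leg.
#' @param fs_cov_targets Named numeric: force-steadiness CoV per
#'   `leg_timepoint` cell.
#' @param mup_amp_multiplier Post/pre MUP amplitude ratio (1 = no change).
#' @param fr_mvc_coupling Strength of the compensatory link between a
#'   subject's exercise-leg MVC loss beyond the mean and their
#'   firing-rate increase (0 disables). Centred, so cell means are
#'   unaffected.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(mvc_multiplier_exercise = 0.852,
                          mvc_multiplier_control = 0.931,
                          plateau_fr_multiplier_exercise = 8.66 / 7.32,
                          plateau_fr_multiplier_control = 1.0,
                          fs_cov_targets = c(control_pre = 0.024,
                                             exercise_pre = 0.025,
                                             control_post = 0.021,
                                             exercise_post = 0.027),
                          mup_amp_multiplier = 1.0,
                          fr_mvc_coupling = 1.5) {
  stopifnot(mvc_multiplier_exercise > 0, mvc_multiplier_control > 0,
            plateau_fr_multiplier_exercise > 0,
            plateau_fr_multiplier_control > 0,
            all(fs_cov_targets > 0), mup_amp_multiplier > 0)
  structure(as.list(environment()), class = "effect_config")
}

#' Cohort specification
#'
#' @param n_subjects Number of subjects (default 13).
#' @param mvc_baseline_N Named baseline MVC means per leg (N).
#' @param mvc_subject_sd_N Between-subject MVC SD (N).
#' @param mvc_resid_sd_N Within-subject (leg/occasion) MVC SD (N).
#' @param fr_subject_sd_pps Between-subject firing-rate intercept SD.
#' @param n_decomposed Decomposed units reported per session.
#' @param track_prob Probability a pre unit is re-identified post.
#' @param n_mup_trains Intramuscular MUP trains per session.
#' @param ramp_s,hold_s Trapezoid ramp and hold durations (s).
#' @param n_mvc_efforts Maximal efforts per session (default 3).
#' @param n_trapezoids Trapezoid repeats per session (the extraction
#'   stage picks the steadiest, default 2).
#' @param fs_force Force sampling rate (Hz).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13,
                        mvc_baseline_N = c(exercise = 296, control = 286),
                        mvc_subject_sd_N = 109, mvc_resid_sd_N = 16,
                        fr_subject_sd_pps = 1.0,
                        n_decomposed = 14, track_prob = 0.61,
                        n_mup_trains = 6,
                        ramp_s = 5, hold_s = 20,
                        n_mvc_efforts = 3, n_trapezoids = 2,
                        fs_force = 1000) {
  stopifnot(n_subjects >= 2, hold_s > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# deterministic sub-seed per (subject, purpose); one shared stream per
# subject, split by purpose, so toggling one effect never reshuffles
# unrelated draws. Kept well below 2^31.
sub_seed <- function(seed, subject, purpose) {
  purpose_id <- match(purpose, c("traits", "discharge", "force", "mup", "roster"))
  (seed * 97L + subject * 131L + purpose_id * 7919L) %% 2000000011L
}

#' Generate a bilateral pre/post cohort on disk
#'
#' Writes one session directory per (subject, leg, timepoint) under
#' `dir`, each with force traces (MVC efforts + trapezoid repeats),
#' decomposed spike trains with PNR metadata and pre/post track links,
#' and MUP templates with per-discharge realizations. Post-intervention
#' sessions are regenerated with the effect multipliers applied;
#' per-subject random intercepts are drawn once and shared across
#' timepoints. Fully reproducible from `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param pool A [pool_config()].
#' @param effects An [effect_config()].
#' @param seed Integer master seed.
#' @param dir Output directory.
#' @return data.frame index of written manifests (subject, leg,
#'   timepoint, manifest path), invisibly the same as on disk.
#' @export
generate_cohort <- function(spec = cohort_spec(), pool = pool_config(),
                            effects = effect_config(), seed = 1L, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- NULL
  for (s in seq_len(spec$n_subjects)) {
    sid <- sprintf("S%02d", s)

    set.seed(sub_seed(seed, s, "traits"))
    b_mvc <- stats::rnorm(1L, 0, spec$mvc_subject_sd_N)
    b_fr <- stats::rnorm(1L, 0, spec$fr_subject_sd_pps)
    eps_mvc <- stats::rnorm(4L, 0, spec$mvc_resid_sd_N)     # leg x time
    fs_scatter <- exp(stats::rnorm(1L, 0, 0.2))
    # subject's exercise-leg MVC multiplier scatters around the mean
    # effect in proportion to the effect itself (no intervention effect,
    # no response heterogeneity); the centred excess drives the
    # compensatory FR coupling
    mult_dev <- stats::rnorm(1L, 0, 0.54 *
                               abs(1 - effects$mvc_multiplier_exercise))

    set.seed(sub_seed(seed, s, "roster"))
    rosters <- list()
    for (leg in c("exercise", "control")) {
      thr <- recruitment_fractions(pool)
      candidates <- which(thr <= 0.25)
      pre_set <- sort(sample(candidates, min(spec$n_decomposed, length(candidates))))
      kept <- pre_set[stats::runif(length(pre_set)) < spec$track_prob]
      fresh <- setdiff(candidates, pre_set)
      post_set <- sort(c(kept, sample(fresh, min(length(fresh),
                                                 spec$n_decomposed - length(kept)))))
      rosters[[leg]] <- list(pre = pre_set, post = post_set, tracked = kept)
    }

    cell <- 0L
    for (timepoint in c("pre", "post")) {
      for (leg in c("exercise", "control")) {
        cell <- cell + 1L
        mvc_mult <- if (timepoint == "pre") 1 else if (leg == "exercise")
          effects$mvc_multiplier_exercise + mult_dev else
          effects$mvc_multiplier_control
        fr_mult <- if (timepoint == "pre") 1 else if (leg == "exercise")
          effects$plateau_fr_multiplier_exercise *
            (1 - effects$fr_mvc_coupling * mult_dev) else
          effects$plateau_fr_multiplier_control
        mvc_true <- (spec$mvc_baseline_N[[leg]] + b_mvc) * mvc_mult + eps_mvc[cell]
        mvc_true <- max(mvc_true, 50)
        fs_target <- effects$fs_cov_targets[[paste(leg, timepoint, sep = "_")]] *
          fs_scatter
        baseline_mvc <- (spec$mvc_baseline_N[[leg]] + b_mvc) + eps_mvc[
          if (leg == "exercise") 1L else 2L]

        session <- build_session(
          sid, leg, timepoint, spec, pool, effects,
          mvc_true = mvc_true, baseline_mvc = max(baseline_mvc, 50),
          fr_shift = b_fr, fr_mult = fr_mult, fs_target = fs_target,
          roster = rosters[[leg]],
          seed_discharge = sub_seed(seed, s, "discharge") + cell,
          seed_mup = sub_seed(seed, s, "mup") + cell)

        sdir <- file.path(dir, sid, paste(leg, timepoint, sep = "_"))
        mp <- write_session(session, sdir)
        index <- rbind(index, data.frame(
          subject_id = sid, leg = leg, timepoint = timepoint,
          manifest = mp, stringsAsFactors = FALSE))
      }
    }
  }
  # the on-disk index stores manifest paths relative to `dir`, so a
  # generated tree is relocatable and byte-identical across runs
  rel <- index
  rel$manifest <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", dir),
                             "/?"), "", rel$manifest)
  utils::write.table(rel, file.path(dir, "index.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(index)
}

build_session <- function(sid, leg, timepoint, spec, pool, effects,
                          mvc_true, baseline_mvc, fr_shift, fr_mult,
                          fs_target, roster, seed_discharge, seed_mup) {
  fs <- spec$fs_force
  pool_s <- pool
  pool_s$onset_rate_pps <- pool$onset_rate_pps + fr_shift

  set.seed(seed_discharge)
  # --- maximal efforts: multiplicative shortfall per trial, so the
  # extracted max is an (essentially) unbiased fraction of true MVC at
  # both timepoints and percent changes are preserved
  forces <- list()
  for (k in seq_len(spec$n_mvc_efforts)) {
    shortfall <- 1 - abs(stats::rnorm(1L, 0, 0.02))
    prof <- c(rep(0, fs), seq(0, 1, length.out = fs), rep(1, 2L * fs),
              seq(1, 0, length.out = fs), rep(0, fs))
    sim <- simulate_pool_contraction(pool_s, prof, mvc_N = mvc_true * shortfall,
                                     fs = fs)
    tr <- sim$force
    tr$annotations <- data.frame(label = "mvc", start_s = 1,
                                 end_s = trace_duration(tr) - 1,
                                 stringsAsFactors = FALSE)
    forces[[k]] <- tr
  }

  # --- trapezoid repeats at 25% of *baseline* MVC (the protocol's
  # normalization). Pool excitation stays at 0.25 in all cells so the
  # configured firing-rate multiplier IS the injected plateau-rate
  # truth, cleanly recoverable downstream; force is scaled to the
  # newton target.
  target_N <- 0.25 * baseline_mvc
  trains <- list()
  sims <- vector("list", spec$n_trapezoids)
  plateau_cov <- numeric(spec$n_trapezoids)
  for (k in seq_len(spec$n_trapezoids)) {
    prof <- trapezoid_profile(0.25, ramp_s = spec$ramp_s,
                              hold_s = spec$hold_s, fs = fs)
    sim <- simulate_pool_contraction(pool_s, prof, mvc_N = baseline_mvc,
                                     fs = fs, fs_cov_target = fs_target,
                                     rate_multiplier = fr_mult)
    tr <- sim$force
    tr$target_fraction <- 0.25
    # the hold window is protocol-defined, so it is written out as an
    # explicit plateau annotation (detection remains available for
    # unannotated recordings)
    tr$annotations <- data.frame(
      label = c("trapezoid", "plateau"),
      start_s = c(0, sim$plateau_window[1L]),
      end_s = c(trace_duration(tr), sim$plateau_window[2L]),
      stringsAsFactors = FALSE)
    forces[[spec$n_mvc_efforts + k]] <- tr
    pidx <- window_index(tr, sim$plateau_window[1L], sim$plateau_window[2L])
    plateau_cov[k] <- stats::sd(tr$samples[pidx]) / mean(tr$samples[pidx])
    sims[[k]] <- sim
  }
  # spike trains come from the steadiest repeat — the one the operator
  # (and the extraction stage, using the same raw-CoV rule) selects
  all_trains <- sims[[which.min(plateau_cov)]]$trains

  # --- decomposition roster: keep the session's roster units, attach
  # track ids to those identified at both timepoints
  ids <- vapply(all_trains, function(x) x$mu_id, "")
  want <- sprintf("u%03d", roster[[timepoint]])
  for (mu in intersect(want, ids)) {
    tr <- all_trains[[match(mu, ids)]]
    tr$leg <- leg; tr$timepoint <- timepoint
    unit_no <- as.integer(sub("u", "", mu))
    if (unit_no %in% roster$tracked)
      tr$track_id <- sprintf("%s_%s_t%03d", sid, leg, unit_no)
    trains[[length(trains) + 1L]] <- tr
  }

  set.seed(seed_mup)
  templates <- list()
  amp <- if (timepoint == "post") effects$mup_amp_multiplier else 1
  for (k in seq_len(spec$n_mup_trains)) {
    nd <- sample(30:170, 1L)
    templates[[sprintf("m%02d", k)]] <-
      simulate_mup_train(seed = NA, jitter_us = 25, n_discharges = nd,
                         n_fibres = sample(3:6, 1L), amp_scale = amp)
  }

  structure(list(subject_id = sid, leg = leg, timepoint = timepoint,
                 mvc_N = NA_real_, forces = forces, trains = trains,
                 templates = templates),
            class = "mu_session")
}

#' Simulate a cohort at the metric level
#'
#' Draws subject-level MVC / force-steadiness values and MU-level plateau
#' firing rates directly from the hierarchical generative model (subject
#' random intercepts, cell-mean effects, residual noise), bypassing
#' signal synthesis. This is the statistical-calibration companion to
#' [generate_cohort()]: type-I error, coverage and power of the
#' mixed-model layer are properties of this distributional structure,
#' not of the signal chain, and hundreds of replicates are needed to
#' measure them.
#'
#' @param n_subjects Number of subjects (default 13).
#' @param n_mu_per_cell Motor units per subject and cell (default 12).
#' @param effects An [effect_config()]; set all multipliers to 1 for a
#'   null cohort.
#' @param spec A [cohort_spec()] supplying baselines and variances.
#' @param fr_baseline_pps Named pre-intervention plateau-rate means.
#' @param fr_mu_sd_pps MU-level residual SD of the plateau rate.
#' @param seed `NA` to use the caller's RNG state.
#' @return List of data.frames: `mvc`, `fs`, `fr_plateau` (MU-level),
#'   and `deltas` (per-subject exercise/control MVC and FR changes).
#' @export
simulate_metric_cohort <- function(n_subjects = 13, n_mu_per_cell = 12,
                                   effects = effect_config(),
                                   spec = cohort_spec(),
                                   fr_baseline_pps = c(exercise = 7.32,
                                                       control = 7.43),
                                   fr_mu_sd_pps = 1.8,
                                   seed = NA_integer_) {
  if (!is.na(seed)) set.seed(seed)
  cells <- expand.grid(leg = c("control", "exercise"),
                       timepoint = c("pre", "post"),
                       stringsAsFactors = FALSE)
  mvc <- fs <- fr <- deltas <- NULL
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    b_mvc <- stats::rnorm(1L, 0, spec$mvc_subject_sd_N)
    b_fr <- stats::rnorm(1L, 0, spec$fr_subject_sd_pps)
    fs_scatter <- exp(stats::rnorm(1L, 0, 0.2))
    # effect-proportional fatigue-response heterogeneity (zero under null)
    mult_dev <- stats::rnorm(1L, 0, 0.54 *
                               abs(1 - effects$mvc_multiplier_exercise))
    vals <- list()
    for (i in seq_len(nrow(cells))) {
      leg <- cells$leg[i]; tp <- cells$timepoint[i]
      mvc_mult <- if (tp == "pre") 1 else if (leg == "exercise")
        effects$mvc_multiplier_exercise + mult_dev else
        effects$mvc_multiplier_control
      fr_mult <- if (tp == "pre") 1 else if (leg == "exercise")
        effects$plateau_fr_multiplier_exercise *
          (1 - effects$fr_mvc_coupling * mult_dev) else
        effects$plateau_fr_multiplier_control
      v_mvc <- (spec$mvc_baseline_N[[leg]] + b_mvc) * mvc_mult +
        stats::rnorm(1L, 0, spec$mvc_resid_sd_N)
      v_fs <- effects$fs_cov_targets[[paste(leg, tp, sep = "_")]] * fs_scatter *
        exp(stats::rnorm(1L, 0, 0.1))
      v_fr <- (fr_baseline_pps[[leg]] + b_fr) * fr_mult +
        stats::rnorm(n_mu_per_cell, 0, fr_mu_sd_pps)
      vals[[paste(leg, tp, sep = "_")]] <- list(mvc = v_mvc, fr = mean(v_fr))
      mvc <- rbind(mvc, data.frame(subject_id = sid, leg = leg, timepoint = tp,
                                   value = v_mvc, stringsAsFactors = FALSE))
      fs <- rbind(fs, data.frame(subject_id = sid, leg = leg, timepoint = tp,
                                 value = v_fs, stringsAsFactors = FALSE))
      fr <- rbind(fr, data.frame(subject_id = sid, leg = leg, timepoint = tp,
                                 mu_id = sprintf("%s_%s_%s_m%02d", sid, leg, tp,
                                                 seq_len(n_mu_per_cell)),
                                 value = v_fr, stringsAsFactors = FALSE))
    }
    deltas <- rbind(deltas, data.frame(
      subject_id = sid,
      delta_mvc_exercise = vals$exercise_post$mvc - vals$exercise_pre$mvc,
      delta_mvc_control = vals$control_post$mvc - vals$control_pre$mvc,
      delta_fr_exercise = vals$exercise_post$fr - vals$exercise_pre$fr,
      delta_fr_control = vals$control_post$fr - vals$control_pre$fr,
      stringsAsFactors = FALSE))
  }
  list(mvc = mvc, fs = fs, fr_plateau = fr, deltas = deltas)
}
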