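# Leg x time inference layer: REML linear mixed models with subject
# (and, for MU-level metrics, MU-within-subject) random intercepts,
# Satterthwaite fixed-effect tests, estimated marginal means with
# pairwise contrasts, two Cohen's d constructions, and Nakagawa's
# marginal / conditional R^2.

#' Fit the leg x time mixed model for one metric
#'
#' `value ~ leg * time + (1 | subject)`, with an additional
#' `(1 | subject:mu)` intercept when MU-level rows are supplied
#' (`nested = TRUE`, or auto-detected from a non-NA `mu_id` column).
#' Fitted by REML with sum-to-zero factor contrasts so that the type-III
#' tests of Leg, Time and Leg x Time are meaningful; denominator degrees
#' of freedom are Satterthwaite by default (Kenward-Roger on request).
#' Singular random-effect fits are flagged, not refit.
#'
#' @param rows data.frame with columns `subject_id`, `leg`, `timepoint`,
#'   `value`, optionally `mu_id` (long format, see [metric_rows()]).
#' @param nested Force or suppress the MU-within-subject intercept;
#'   `NULL` (default) auto-detects.
#' @param ddf `"Satterthwaite"` (default) or `"Kenward-Roger"`.
#' @return An object of class `mu_lmm`: the `lmerTest` fit plus the
#'   type-III fixed-effect table (`anova`), `singular` flag and the `ddf`
#'   method used.
#' @export
fit_lmm <- function(rows, nested = NULL, ddf = "Satterthwaite") {
  stopifnot(all(c("subject_id", "leg", "timepoint", "value") %in% names(rows)))
  d <- rows
  d$leg <- factor(d$leg, levels = c("control", "exercise"))
  d$timepoint <- factor(d$timepoint, levels = c("pre", "post"))
  if (any(is.na(d$leg)) || any(is.na(d$timepoint)))
    stop("leg must be control/exercise and timepoint pre/post")
  if (nlevels(droplevels(d$leg)) < 2L || nlevels(droplevels(d$timepoint)) < 2L)
    stop("both legs and both timepoints must be present")
  if (length(unique(d$subject_id)) < 2L) stop("at least 2 subjects required")
  if (is.null(nested))
    nested <- "mu_id" %in% names(d) && any(!is.na(d$mu_id)) &&
      any(duplicated(paste(d$subject_id, d$leg, d$timepoint)))
  form <- if (nested)
    value ~ leg * timepoint + (1 | subject_id) + (1 | subject_id:mu_id)
  else value ~ leg * timepoint + (1 | subject_id)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      form, data = d, REML = TRUE,
      contrasts = list(leg = "contr.sum", timepoint = "contr.sum"))),
    error = function(e) stop("mixed model failed to converge: ",
                             conditionMessage(e)))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular random-effect fit (a variance component is zero)")
  a <- stats::anova(fit, type = 3L, ddf = ddf)
  structure(list(fit = fit, anova = a, nested = nested, singular = singular,
                 ddf = ddf, data = d),
            class = "mu_lmm")
}

#' Fixed-effect p-values of a fitted leg x time model
#' @param model A `mu_lmm`.
#' @return Named numeric: `leg`, `time`, `leg_x_time`.
#' @export
lmm_pvalues <- function(model) {
  a <- model$anova
  p <- a[["Pr(>F)"]]
  names(p) <- rownames(a)
  c(leg = unname(p["leg"]), time = unname(p["timepoint"]),
    leg_x_time = unname(p["leg:timepoint"]))
}

#' Estimated marginal means and pairwise contrasts
#'
#' Cell EMMs for the four (leg, timepoint) cells with model-based 95%
#' CIs, and the pairwise contrasts between them. Contrast p-values are
#' unadjusted by default (Tukey adjustment on request).
#'
#' @param model A `mu_lmm` from [fit_lmm()].
#' @param adjust Multiplicity adjustment for contrasts (default
#'   `"none"`).
#' @return List with data.frames `emms` (leg, timepoint, emmean,
#'   lower.CL, upper.CL, SE, df) and `contrasts` (contrast, estimate,
#'   SE, df, p.value, cohens_d where d is the nested construction).
#' @export
emm_cells <- function(model, adjust = "none") {
  em <- emmeans::emmeans(model$fit, ~ leg * timepoint,
                         lmer.df = tolower(model$ddf))
  emdf <- as.data.frame(em)
  ctr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = adjust))
  ctr$cohens_d <- vapply(ctr$estimate, function(est)
    cohens_d_nested(model, est), numeric(1L))
  list(emms = emdf, contrasts = ctr)
}

#' Cohen's d from paired data
#'
#' `mean(post - pre) / sd(post - pre)` with the sample (n - 1) SD — the
#' within-subject-differences construction used for non-hierarchical
#' metrics such as MVC and force steadiness.
#'
#' @param pre,post Paired numeric vectors of equal length (>= 2).
#' @return d, or `NA` when the difference SD is zero.
#' @export
cohens_d_paired <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- post - pre
  s <- stats::sd(d)
  if (s == 0) {
    # post identical to pre is a true null (d = 0); any other constant
    # difference has no finite standardized size
    return(if (mean(d) == 0) 0 else NA_real_)
  }
  mean(d) / s
}

#' Cohen's d for a contrast from a hierarchical model
#'
#' EMM contrast divided by the square root of the total random variance
#' (all random-intercept components plus the residual), the
#' nested-structure-aware standardization.
#'
#' @param model A `mu_lmm`.
#' @param contrast Numeric contrast estimate (difference of EMMs).
#' @return Standardized d (sign follows the contrast).
#' @export
cohens_d_nested <- function(model, contrast) {
  vc <- as.data.frame(lme4::VarCorr(model$fit))
  total <- sum(vc$vcov)
  contrast / sqrt(total)
}

#' Nakagawa marginal and conditional R-squared
#'
#' For a Gaussian mixed model: `R2m = var_f / (var_f + var_r + var_e)`
#' and `R2c = (var_f + var_r) / (var_f + var_r + var_e)`, where `var_f`
#' is the variance of the fixed-effect predictions, `var_r` the summed
#' random-intercept variances and `var_e` the residual variance.
#'
#' @param model A `mu_lmm`, or a list with elements `var_fixed`,
#'   `var_random`, `var_resid` for direct plug-in.
#' @return Named numeric `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(model) {
  if (inherits(model, "mu_lmm")) {
    var_f <- stats::var(stats::predict(model$fit, re.form = NA))
    vc <- as.data.frame(lme4::VarCorr(model$fit))
    var_e <- vc$vcov[vc$grp == "Residual"]
    var_r <- sum(vc$vcov[vc$grp != "Residual"])
  } else {
    var_f <- model$var_fixed; var_r <- sum(model$var_random)
    var_e <- model$var_resid
  }
  tot <- var_f + var_r + var_e
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

#' Repeated-measures t-test on per-subject leg deltas
#'
#' Paired t on (exercise delta - control delta), the comparison applied
#' to per-subject pre-to-post CST changes.
#'
#' @param delta_exercise,delta_control Per-subject deltas, paired by
#'   position.
#' @return List `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t <- function(delta_exercise, delta_control) {
  stopifnot(length(delta_exercise) == length(delta_control))
  n <- length(delta_exercise)
  if (n < 2L) stop("paired t requires n >= 2")
  d <- delta_exercise - delta_control
  if (stats::sd(d) == 0) {
    # degenerate: identical differences everywhere
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = n - 1, p = if (t == 0) 1 else 0,
                mean_difference = mean(d)))
  }
  ht <- stats::t.test(delta_exercise, delta_control, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_difference = unname(ht$estimate))
}

#' Pearson correlation between per-subject deltas
#'
#' Product-moment correlation (two-sided test) between, e.g., the
#' pre-to-post change in plateau firing rate and the change in MVC.
#'
#' @param delta_fr,delta_mvc Per-subject deltas (n >= 3).
#' @return List `r`, `p`, `n`; `r` is `NA` when either input has zero
#'   variance.
#' @export
pearson_delta_correlation <- function(delta_fr, delta_mvc) {
  stopifnot(length(delta_fr) == length(delta_mvc))
  if (length(delta_fr) < 3L) stop("correlation requires n >= 3")
  if (stats::sd(delta_fr) == 0 || stats::sd(delta_mvc) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(delta_fr)))
  ht <- stats::cor.test(delta_fr, delta_mvc)
  list(r = unname(ht$estimate), p = ht$p.value, n = length(delta_fr))
}

#' Type-I error / power of the leg x time interaction by simulation
#'
#' Repeatedly simulates metric-level cohorts ([simulate_metric_cohort()])
#' and records how often the interaction is significant at `alpha`.
#' With null effects this estimates the type-I error; with injected
#' effects, the power.
#'
#' @param metric `"mvc"` (subject-level) or `"fr_plateau"` (MU-level,
#'   nested).
#' @param n_reps Number of replicate cohorts.
#' @param effects An [effect_config()] (use all-1 multipliers for null).
#' @param n_subjects Cohort size per replicate.
#' @param alpha Significance level (default 0.05).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List `rejection_rate`, `p_values`.
#' @export
calibrate_interaction <- function(metric = c("mvc", "fr_plateau"),
                                  n_reps = 200, effects = effect_config(),
                                  n_subjects = 13, alpha = 0.05, seed = 1L) {
  metric <- match.arg(metric)
  p <- vapply(seq_len(n_reps), function(r) {
    co <- simulate_metric_cohort(n_subjects = n_subjects, effects = effects,
                                 seed = seed + r)
    d <- co[[metric]]
    # metric-level replicates mimic the non-tracked tables: each MU is
    # observed once, so the model carries the subject intercept only
    m <- suppressWarnings(fit_lmm(d, nested = FALSE))
    unname(lmm_pvalues(m)["leg_x_time"])
  }, numeric(1L))
  list(rejection_rate = mean(p < alpha), p_values = p)
}

#' Null effect configuration (all multipliers 1, common FS target)
#' @export
null_effects <- function() {
  effect_config(mvc_multiplier_exercise = 1, mvc_multiplier_control = 1,
                plateau_fr_multiplier_exercise = 1,
                plateau_fr_multiplier_control = 1,
                fs_cov_targets = c(control_pre = 0.024, exercise_pre = 0.024,
                                   control_post = 0.024, exercise_post = 0.024),
                mup_amp_multiplier = 1, fr_mvc_coupling = 0)
}
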