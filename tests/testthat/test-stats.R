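# small balanced design used across several blocks
balanced_rows <- function(cell_means, n_subj = 6, subj_sd = 0, resid_sd = 0,
                          seed = 1) {
  set.seed(seed)
  b <- rnorm(n_subj, 0, subj_sd)
  out <- NULL
  for (s in seq_len(n_subj)) for (leg in c("control", "exercise"))
    for (tp in c("pre", "post")) {
      mu <- cell_means[[paste(leg, tp, sep = "_")]]
      out <- rbind(out, data.frame(
        subject_id = sprintf("S%02d", s), leg = leg, timepoint = tp,
        value = mu + b[s] + rnorm(1, 0, resid_sd), stringsAsFactors = FALSE))
    }
  out
}

test_that("noiseless additive data recover the generating contrasts exactly", {
  cm <- list(control_pre = 10, control_post = 12, exercise_pre = 11,
             exercise_post = 16)
  rows <- balanced_rows(cm, subj_sd = 2, resid_sd = 0)
  m <- suppressWarnings(fit_lmm(rows))
  em <- emm_cells(m)$emms
  cell <- function(leg, tp) em$emmean[em$leg == leg & em$timepoint == tp]
  # every cell contrast equals the generating contrast (the common
  # subject-mean offset cancels)
  expect_equal(cell("control", "post") - cell("control", "pre"), 2,
               tolerance = 1e-6)
  expect_equal(cell("exercise", "post") - cell("exercise", "pre"), 5,
               tolerance = 1e-6)
  expect_equal(cell("exercise", "pre") - cell("control", "pre"), 1,
               tolerance = 1e-6)
  # and the interaction
  expect_equal((cell("exercise", "post") - cell("exercise", "pre")) -
                 (cell("control", "post") - cell("control", "pre")), 3,
               tolerance = 1e-6)
})

test_that("EMMs equal raw cell means of subject means on balanced data", {
  cm <- list(control_pre = 5, control_post = 6, exercise_pre = 5.5,
             exercise_post = 8)
  rows <- balanced_rows(cm, subj_sd = 3, resid_sd = 1, seed = 42)
  m <- suppressWarnings(fit_lmm(rows))
  em <- emm_cells(m)$emms
  direct <- aggregate(value ~ leg + timepoint, rows, mean)
  for (i in seq_len(nrow(direct))) {
    expect_equal(em$emmean[em$leg == direct$leg[i] &
                             em$timepoint == direct$timepoint[i]],
                 direct$value[i], tolerance = 1e-6)
  }
  # each EMM confidence interval contains its EMM
  expect_true(all(em$lower.CL < em$emmean & em$emmean < em$upper.CL))
})

test_that("model guards: factor levels, subject count, p-value table", {
  rows <- balanced_rows(list(control_pre = 1, control_post = 1,
                             exercise_pre = 1, exercise_post = 1),
                        resid_sd = 1)
  bad <- rows; bad$leg <- "left"
  expect_error(fit_lmm(bad), "control/exercise")
  solo <- rows[rows$subject_id == "S01", ]
  expect_error(fit_lmm(solo), "2 subjects")
  m <- suppressWarnings(fit_lmm(rows))
  p <- lmm_pvalues(m)
  expect_named(p, c("leg", "time", "leg_x_time"))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("paired Cohen's d matches hand and brute-force computation", {
  expect_equal(cohens_d_paired(c(0, 0), c(1, 3)), sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d_paired(1:5, 1:5), 0)
  expect_true(is.na(cohens_d_paired(c(1, 2, 3), c(3, 4, 5))))  # constant diff

  set.seed(9)
  for (r in 1:20) {
    pre <- rnorm(13, 100, 15); post <- rnorm(13, 95, 15)
    brute <- mean(post - pre) /
      sqrt(sum(((post - pre) - mean(post - pre))^2) / 12)
    expect_equal(cohens_d_paired(pre, post), brute, tolerance = 1e-12)
  }
})

test_that("nested Cohen's d standardizes by the total random variance", {
  rows <- balanced_rows(list(control_pre = 0, control_post = 0,
                             exercise_pre = 0, exercise_post = 4),
                        n_subj = 8, subj_sd = 1, resid_sd = 1, seed = 3)
  m <- suppressWarnings(fit_lmm(rows))
  vc <- as.data.frame(lme4::VarCorr(m$fit))
  expect_equal(cohens_d_nested(m, 0), 0)
  expect_equal(cohens_d_nested(m, 4), 4 / sqrt(sum(vc$vcov)), tolerance = 1e-12)
  expect_equal(cohens_d_nested(m, -4), -cohens_d_nested(m, 4))
})

test_that("Nakagawa R2: plug-in arithmetic and model-based properties", {
  direct <- nakagawa_r2(list(var_fixed = 2, var_random = 1, var_resid = 1))
  expect_equal(unname(direct), c(0.5, 0.75))

  # no random variance: marginal equals conditional
  d2 <- nakagawa_r2(list(var_fixed = 3, var_random = 0, var_resid = 1))
  expect_equal(unname(d2[1]), unname(d2[2]))

  # null fixed effects: R2m ~ 0 and R2c ~ the intraclass correlation
  set.seed(11)
  rows <- balanced_rows(list(control_pre = 50, control_post = 50,
                             exercise_pre = 50, exercise_post = 50),
                        n_subj = 40, subj_sd = 3, resid_sd = 1)
  m <- suppressWarnings(fit_lmm(rows))
  r2 <- nakagawa_r2(m)
  expect_lt(r2["r2_marginal"], 0.02)
  expect_equal(unname(r2["r2_conditional"]), 9 / 10, tolerance = 0.1)
  expect_true(r2["r2_marginal"] <= r2["r2_conditional"])
  expect_true(r2["r2_conditional"] <= 1)
})

test_that("repeated-measures t on leg deltas matches hand computation", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  ht <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(ht$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)   # 3.4641
  expect_equal(ht$df, 2)

  flipped <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(flipped$t, -ht$t, tolerance = 1e-12)
  expect_error(paired_t(1, 1), "n >= 2")
})

test_that("delta correlation: perfect, orthogonal and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  neg <- pearson_delta_correlation(-2 * x + 3, x)
  expect_equal(neg$r, -1, tolerance = 1e-12)

  orth <- pearson_delta_correlation(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  expect_equal(orth$r, 0, tolerance = 1e-12)

  flat <- pearson_delta_correlation(rep(2, 5), x)
  expect_true(is.na(flat$r))
  expect_error(pearson_delta_correlation(1:2, 1:2), "n >= 3")
})

test_that("compensatory coupling yields negative exercise-leg delta correlations", {
  neg_frac <- 0
  ctrl_r <- numeric(40)
  for (r in 1:40) {
    co <- simulate_metric_cohort(seed = 500 + r)
    ex <- pearson_delta_correlation(co$deltas$delta_fr_exercise,
                                    co$deltas$delta_mvc_exercise)
    ctl <- pearson_delta_correlation(co$deltas$delta_fr_control,
                                     co$deltas$delta_mvc_control)
    neg_frac <- neg_frac + (ex$r < 0)
    ctrl_r[r] <- ctl$r
  }
  expect_gt(neg_frac / 40, 0.9)
  expect_lt(abs(mean(ctrl_r)), 0.3)   # control-leg correlations centre near 0
})
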