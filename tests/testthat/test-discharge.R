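test_that("PNR filtering is inclusive at the threshold and audited", {
  mk <- function(id, pnr) regular_train(mu_id = id, pnr = pnr)
  got <- filter_trains(list(mk("a", 28), mk("b", 30), mk("c", 35)))
  expect_length(got, 2L)
  expect_setequal(vapply(got, function(x) x$mu_id, ""), c("b", "c"))
  expect_identical(attr(got, "excluded")$mu_id, "a")

  all_in <- list(mk("a", 31), mk("b", 40))
  expect_length(filter_trains(all_in), 2L)
  expect_length(filter_trains(list()), 0L)
})

test_that("instantaneous rates are ISI reciprocals assigned to the later spike", {
  expect_equal(instantaneous_rates(regular_train(rate = 8, dur = 2)),
               rep(8, 15))
  tr <- isi_train(c(0.2, 0.18, 0.15, 0.13, 0.12))
  expect_equal(instantaneous_rates(tr),
               c(5, 5.55555555555556, 6.66666666666667, 7.69230769230769,
                 8.33333333333333))
  one <- mu_train("m", 0.5, pnr_db = 35)
  expect_true(is.na(instantaneous_rates(one)))
})

test_that("phase rates use first/last 5 rates and window-bounded plateau rates", {
  # constant 8 pps: all phases 8
  tr <- regular_train(rate = 8, dur = 30)
  fr <- phase_firing_rates(tr, plateau_window = c(10, 20))
  expect_equal(unname(fr), c(8, 8, 8))

  # slowing-then-steady onset: recruitment = mean of the 5 reciprocals
  tr2 <- isi_train(c(0.2, 0.18, 0.15, 0.13, 0.12, rep(0.125, 100)))
  fr2 <- phase_firing_rates(tr2, plateau_window = c(2, 8))
  expect_equal(unname(fr2["fr_recruitment"]),
               mean(1 / c(0.2, 0.18, 0.15, 0.13, 0.12)), tolerance = 1e-12)
  expect_equal(unname(fr2["fr_recruitment"]), 6.64957264957265)
  expect_equal(unname(fr2["fr_plateau"]), 8, tolerance = 1e-9)
  expect_equal(unname(fr2["fr_derecruitment"]), 8, tolerance = 1e-9)

  # phase rates are invariant to a time-origin shift
  sh <- mu_train("m", tr2$spike_times_s + 100, pnr_db = 35)
  expect_equal(phase_firing_rates(sh, c(102, 108)), fr2)

  # too few spikes: transient phases undefined, no error
  few <- isi_train(c(0.1, 0.1, 0.1))
  fr3 <- phase_firing_rates(few, c(0, 1))
  expect_true(is.na(fr3["fr_recruitment"]))
  expect_false(is.na(fr3["fr_plateau"]))
})

test_that("artifact ISIs outside [0.02, 0.5] s are excluded from rate metrics", {
  # a 1 s dropout gap and a 5 ms doublet must not distort the phase rates
  isis <- c(rep(0.125, 30), 1.0, rep(0.125, 30), 0.005, rep(0.125, 30))
  tr <- isi_train(isis, t0 = 0.1)
  fr <- phase_firing_rates(tr, c(0, sum(isis) + 1))
  expect_equal(unname(fr["fr_plateau"]), 8, tolerance = 1e-9)
  expect_equal(isi_cov(tr, c(0, sum(isis) + 1)), 0, tolerance = 1e-9)
})

test_that("ISI CoV matches hand computation with n-1 SD", {
  expect_equal(isi_cov(regular_train(rate = 10, dur = 10), c(0, 10)), 0)
  tr <- isi_train(c(0.1, 0.12, 0.11, 0.13, 0.09), t0 = 0.5)
  got <- isi_cov(tr, c(0, 2))
  expect_equal(got, sd(c(0.1, 0.12, 0.11, 0.13, 0.09)) / 0.11, tolerance = 1e-12)
  expect_equal(got, 0.143739, tolerance = 1e-4)
  two <- mu_train("m", c(0.1, 0.3), pnr_db = 35)
  expect_true(is.na(isi_cov(two, c(0, 1))))
})

test_that("recruitment thresholds interpolate force at the bounding spikes", {
  fs <- 1000
  ramp <- force_trace(10 * (0:(10 * fs)) / fs, fs = fs)  # 10 N/s from 0
  tr <- mu_train("m", c(1.2, 2.0, 3.0, 4.4), pnr_db = 35)
  th <- recruitment_thresholds(tr, ramp)
  expect_equal(unname(th["recruit_N"]), 12, tolerance = 1e-6)
  expect_equal(unname(th["derecruit_N"]), 44, tolerance = 1e-6)

  flat <- force_trace(rep(25, 5 * fs), fs = fs)
  th2 <- recruitment_thresholds(mu_train("m", c(0.5, 3.2), pnr_db = 35), flat)
  expect_equal(unname(th2["derecruit_N"]), 25)

  zero <- mu_train("m", c(0, 1), pnr_db = 35)
  expect_equal(unname(recruitment_thresholds(zero, ramp)["recruit_N"]), 0)

  out <- mu_train("m", c(1, 11), pnr_db = 35)
  expect_error(recruitment_thresholds(out, force_trace(rep(1, 5000), fs = fs)),
               "outside")
})

test_that("externally provided track links pass through unchanged", {
  pre <- list(regular_train(mu_id = "p1", timepoint = "pre", track_id = "tA"),
              regular_train(mu_id = "p2", timepoint = "pre"))
  post <- list(regular_train(mu_id = "q1", timepoint = "post", track_id = "tA"))
  got <- match_tracks(pre, post)
  expect_identical(got$pre_mu, "p1")
  expect_identical(got$post_mu, "q1")
  expect_identical(got$track_id, "tA")
})

test_that("template matching recovers permutations and respects min_corr", {
  # three distinct *shapes* (matching is lag-invariant, so shifted copies
  # of one shape would be indistinguishable)
  t <- (0:499) / 50000
  g <- function(sigma) 100 * exp(-(t - 5e-3)^2 / (2 * sigma^2))
  dg <- function(sigma) -100 * (t - 5e-3) / sigma * exp(-(t - 5e-3)^2 / (2 * sigma^2))
  tpl <- list(g(3e-4), g(9e-4), dg(4e-4))

  mk <- function(ids, tp) lapply(ids, function(i)
    regular_train(mu_id = i, timepoint = tp))

  # identical sets, shuffled: perfect bijection with correlation 1
  perm <- c(3, 1, 2)
  got <- match_tracks(mk(c("a", "b", "c"), "pre"), mk(c("x", "y", "z"), "post"),
                      pre_templates = tpl, post_templates = tpl[perm])
  expect_identical(nrow(got), 3L)
  expect_true(all(got$correlation > 0.999))
  expect_identical(got$post_mu[match(c("a", "b", "c"), got$pre_mu)],
                   c("x", "y", "z")[match(1:3, perm)])

  # one post template unrelated (noise): only 2 admissible matches, and
  # the assignment agrees with the exhaustive-permutation oracle
  set.seed(5)
  tpl_post <- tpl
  tpl_post[[2]] <- rnorm(500)
  got2 <- match_tracks(mk(c("a", "b", "c"), "pre"), mk(c("x", "y", "z"), "post"),
                       pre_templates = tpl, post_templates = tpl_post)
  expect_identical(nrow(got2), 2L)

  score <- outer(seq_along(tpl), seq_along(tpl_post), Vectorize(function(i, j)
    crossmu:::ncc_max(tpl[[i]], tpl_post[[j]])))
  best <- -Inf
  for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))) {
    s <- sum(ifelse(score[cbind(1:3, p)] >= 0.8, score[cbind(1:3, p)], 0))
    best <- max(best, s)
  }
  expect_equal(sum(got2$correlation), best, tolerance = 1e-9)
})

test_that("mean CST with rectangular smoothing equals count/duration", {
  mk <- function(id, rate, tp, start) regular_train(
    rate = rate, dur = 9, start = start, mu_id = id, timepoint = tp,
    track_id = paste0("t", id))
  trains <- list(mk("a", 8, "pre", 0.5), mk("b", 8, "pre", 0.51),
                 mk("c", 8, "pre", 0.52),
                 mk("a", 8, "post", 0.5), mk("b", 8, "post", 0.51),
                 mk("c", 8, "post", 0.52))
  w <- c(0, 10)
  counts <- 3 * 72   # each train: 72 spikes in [0.5, 9.5)
  res_rect <- cumulative_spike_train(trains, w, smooth = "rect")
  expect_equal(unname(res_rect$mean_pps["pre"]), counts / 10, tolerance = 1e-9)
  res_none <- cumulative_spike_train(trains, w, smooth = "none")
  expect_equal(unname(res_none$mean_pps["pre"]), counts / 10, tolerance = 1e-12)

  # identical pre and post: zero deltas
  expect_equal(res_rect$delta_abs_pps, 0, tolerance = 1e-9)
  expect_equal(res_rect$delta_pct, 0, tolerance = 1e-7)

  # post rates x 1.2 (7.5 s span so both counts are exact): delta 20%
  mk2 <- function(id, rate, tp) regular_train(rate = rate, dur = 7.5,
                                              start = 0.5, mu_id = id,
                                              timepoint = tp,
                                              track_id = paste0("t", id))
  faster <- list(mk2("a", 8, "pre"), mk2("b", 8, "pre"),
                 mk2("a", 9.6, "post"), mk2("b", 9.6, "post"))
  res3 <- cumulative_spike_train(faster, w)
  expect_equal(res3$delta_pct, 20, tolerance = 0.02)

  # no shared track ids: undefined marker
  none <- cumulative_spike_train(list(mk("a", 8, "pre", 1),
                                      mk("zz", 8, "post", 1)), w)
  expect_true(is.na(none$delta_abs_pps))
  expect_identical(none$n_tracked, 0L)
})

test_that("per-timepoint plateau windows are honoured in the CST", {
  mk <- function(tp, start) regular_train(rate = 10, dur = 8, start = start,
                                          mu_id = "a", timepoint = tp,
                                          track_id = "ta")
  res <- cumulative_spike_train(list(mk("pre", 1.5), mk("post", 11.5)),
                                window = list(pre = c(1, 10),
                                              post = c(11, 20)),
                                smooth = "none")
  expect_equal(unname(res$mean_pps["pre"]), unname(res$mean_pps["post"]),
               tolerance = 1e-12)
})
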