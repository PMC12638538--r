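test_that("cursor placement brackets a rectangular pulse and honours overrides", {
  fs <- 50000
  v <- numeric(1000)
  v[400:649] <- 100                       # 5 ms pulse, 0-based 399..648
  tp <- mup_template(v, fs = fs, n_discharges = 50)
  got <- place_cursors(tp, noise_uV = 1)
  expect_lte(abs(got$cursors$onset - 399L), 1L)
  expect_lte(abs(got$cursors$end - 648L), 1L)

  noise_tp <- mup_template(rnorm(1000, 0, 2), fs = fs, n_discharges = 50)
  expect_error(place_cursors(noise_tp, noise_uV = 2), "supra-threshold")

  manual <- manual_template(v, onset = 100L, end = 900L, neg = 500L, pos = 450L)
  expect_identical(place_cursors(manual)$cursors$onset, 100L)
})

test_that("MUP area matches closed forms for simple pulse geometries", {
  fs <- 50000
  # rectangular 100 uV x 5 ms: area = 500 uV.ms
  v <- numeric(1000); v[401:650] <- 100
  rect <- manual_template(v, onset = 400L, end = 649L)
  expect_equal(mup_area(rect), 500, tolerance = 1e-6)

  # triangular, peak 100 uV, base 4 ms: area = 200 uV.ms
  tri <- pl_wave(c(400, 500, 600), c(0, 100, 0), 1000)
  tri_tp <- manual_template(tri, onset = 399L, end = 599L)
  expect_equal(mup_area(tri_tp), 200, tolerance = 0.01)

  # biphasic +/-100 uV rectangular lobes, 2 ms each: |.| makes them add
  bi <- numeric(1000); bi[301:400] <- 100; bi[401:500] <- -100
  bi_tp <- manual_template(bi, onset = 300L, end = 499L, neg = 450L, pos = 350L)
  expect_equal(mup_area(bi_tp), 400, tolerance = 1e-6)

  # homogeneity: area is linear in amplitude and in duration
  expect_equal(mup_area(manual_template(3 * v, onset = 400L, end = 649L)),
               3 * mup_area(rect), tolerance = 1e-9)
  v2 <- numeric(2000); v2[401:900] <- 100   # twice the duration
  expect_equal(mup_area(manual_template(v2, onset = 400L, end = 899L)),
               2 * mup_area(rect), tolerance = 1e-9)
})

test_that("turns counting applies the 20 uV hysteresis rule", {
  n <- 2000
  mono <- pl_wave(c(100, 500, 900), c(0, 60, 0), n)
  expect_identical(mup_turns(manual_template(mono, onset = 50L, end = 1000L)), 1L)

  tri <- pl_wave(c(100, 300, 600, 900, 1100), c(0, 60, -120, 40, 0), n)
  expect_identical(mup_turns(manual_template(tri, onset = 50L, end = 1200L)), 3L)

  # a 15 uV ripple between +60 and +75 is rejected; count stays 2
  rip <- pl_wave(c(100, 300, 400, 500, 800, 1100), c(0, 60, 45, 75, -120, 0), n)
  expect_identical(mup_turns(manual_template(rip, onset = 50L, end = 1200L)), 2L)

  # sub-threshold ripple never changes the count when every monotone run
  # of the clean wave terminates at an interior extremum (gentle tail)
  tri2 <- pl_wave(c(100, 300, 600, 900, 1100), c(0, 60, -120, 40, 32), n)
  expect_identical(mup_turns(manual_template(tri2, onset = 50L, end = 1200L)), 3L)
  rippled <- tri2 + 3 * sin(seq_len(n) / 3)
  expect_identical(mup_turns(manual_template(rippled, onset = 50L, end = 1200L)),
                   3L)

  # amplitude scaling by k > 1 preserves the count when all changes
  # already clear the threshold
  expect_identical(mup_turns(manual_template(2.5 * tri, onset = 50L, end = 1200L)),
                   3L)
})

test_that("negative peak ratio is rise/fall over fixed 500 us windows", {
  fs <- 50000
  w <- round(500e-6 * fs)   # 25 samples
  n <- 1000

  sym <- pl_wave(c(500 - w, 500, 500 + w), c(0, -100, 0), n)
  tp <- manual_template(sym, onset = 300L, end = 700L, neg = 499L, pos = 650L)
  expect_equal(negative_peak_ratio(tp), 1.0, tolerance = 1e-9)

  asym <- pl_wave(c(500 - w, 500, 500 + w), c(-20, -100, -60), n)
  tp2 <- manual_template(asym, onset = 300L, end = 700L, neg = 499L, pos = 650L)
  expect_equal(negative_peak_ratio(tp2), 2.0, tolerance = 1e-9)

  # invariance to vertical offset and amplitude scaling
  for (k in c(2, 10)) for (off in c(-40, 55)) {
    tp3 <- manual_template(k * asym + off, onset = 300L, end = 700L,
                           neg = 499L, pos = 650L)
    expect_equal(negative_peak_ratio(tp3), 2.0, tolerance = 1e-9)
  }

  edge <- manual_template(sym, onset = 1L, end = 999L, neg = 10L, pos = 900L)
  expect_error(negative_peak_ratio(edge), "edge")
})

test_that("the near-fibre operator is the second derivative on smooth inputs", {
  fs <- 50000
  n <- 750
  # linear ramp: second derivative is zero (edges excluded)
  ramp <- seq(0, 100, length.out = n)
  nfm <- near_fibre_mup(ramp, fs = fs)
  expect_lt(max(abs(nfm[10:(n - 10)])), 1e-6 * fs^2 * 1e-6)

  # Gaussian lobe, sigma 0.5 ms: matches the analytic second derivative
  # within 1% RMS
  t <- (seq_len(n) - 1) / fs
  sigma <- 5e-4; c0 <- 0.0075; A <- 100
  g <- gauss_lobe(n, fs, c0, sigma, A)
  d2_analytic <- A * exp(-(t - c0)^2 / (2 * sigma^2)) *
    ((t - c0)^2 / sigma^4 - 1 / sigma^2)
  nfm_g <- near_fibre_mup(g, fs = fs)
  i <- 50:(n - 50)
  rel_rms <- sqrt(mean((nfm_g[i] - d2_analytic[i])^2)) /
    sqrt(mean(d2_analytic[i]^2))
  expect_lt(rel_rms, 0.01)

  # linearity: NFM of a sum is the sum of NFMs
  g2 <- gauss_lobe(n, fs, 0.005, 3e-4, 60)
  expect_equal(near_fibre_mup(g + g2, fs = fs),
               near_fibre_mup(g, fs = fs) + near_fibre_mup(g2, fs = fs),
               tolerance = 1e-9)

  expect_error(near_fibre_mup(g, fs = 10000), "20 kHz")
})

test_that("near-fibre jiggle: identity, constructed value, and invariances", {
  fs <- 50000
  tpl <- gauss_lobe() - 0.8 * gauss_lobe(centre_s = 0.0082, sigma_s = 4e-4)

  same <- matrix(rep(tpl, 4), ncol = 4)
  expect_equal(nf_jiggle(same, fs = fs)$nf_jiggle_pct, 0)

  # realizations alternating template +/- 0.1 * template: consecutive
  # NFM differences have area 0.2 x template NFM area, mean NFM is the
  # template, so jiggle = 20% by linearity of the operator
  alt <- cbind(1.1 * tpl, 0.9 * tpl, 1.1 * tpl, 0.9 * tpl)
  expect_equal(nf_jiggle(alt, fs = fs)$nf_jiggle_pct, 20, tolerance = 1e-6)

  # global amplitude scaling of the whole set leaves jiggle unchanged
  expect_equal(nf_jiggle(7.3 * alt, fs = fs)$nf_jiggle_pct, 20,
               tolerance = 1e-6)

  # fewer than 2 realizations: undefined
  expect_true(is.na(nf_jiggle(matrix(tpl, ncol = 1), fs = fs)$nf_jiggle_pct))

  # jiggle grows with injected latency jitter (paired seeds)
  jig <- function(jit, seed) {
    tp <- simulate_mup_train(seed = seed, jitter_us = jit, n_discharges = 40,
                             noise_uV = 0)
    nf_jiggle(tp)$nf_jiggle_pct
  }
  wins <- vapply(1:20, function(s) jig(50, s) > jig(25, s), logical(1))
  expect_true(all(wins))
})

test_that("MUPT exclusion enforces the 40-MUP and contamination rules", {
  mk <- function(nd) {
    tpl <- gauss_lobe()
    manual_template(tpl, onset = 300L, end = 450L, neg = 380L, pos = 374L,
                    n_discharges = nd,
                    realizations = cbind(tpl, tpl, tpl))
  }
  got <- filter_mupts(list(mk(39), mk(40), mk(41)))
  expect_length(got, 2L)
  expect_identical(attr(got, "excluded")$reason, "too_few_mups")

  expect_length(filter_mupts(list(mk(100))), 1L)

  # 30% of realizations poorly correlated with the template: multi-MU
  set.seed(8)
  tpl <- gauss_lobe()
  bad <- cbind(matrix(rep(tpl, 7), ncol = 7),
               matrix(rnorm(750 * 3, 0, 50), ncol = 3))
  cont <- manual_template(tpl, onset = 300L, end = 450L, neg = 380L,
                          pos = 374L, n_discharges = 100, realizations = bad)
  got2 <- filter_mupts(list(cont))
  expect_length(got2, 0L)
  expect_identical(attr(got2, "excluded")$reason, "multi_mu")

  # an externally supplied clean flag overrides the heuristic
  cont$contaminated <- FALSE
  expect_length(filter_mupts(list(cont)), 1L)
})
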