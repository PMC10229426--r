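flat_movie <- function(value = 1, n_t = 100, nr = 2, nc = 2, pre = 2) {
  structure(list(data = array(value, c(nr, nc, n_t)),
                 times = (0:(n_t - 1)) / 5 - pre, frame_rate = 5,
                 pre_window = pre, n_trials_averaged = 20L),
            class = "trial_movie")
}
full_mask <- function(nr = 2, nc = 2) {
  structure(list(data = matrix(TRUE, nr, nc), n_foreground = nr * nc),
            class = "mask_image")
}
make_rt <- function(times, vals) {
  structure(list(times = times, dl_over_l0 = vals, n_trials_averaged = 20L,
                 subject_id = ""), class = "response_trace")
}

test_that("ROI response traces average delta-L/L0 over the mask", {
  # uniform ratio-1 movie -> flat zero trace with onset-zeroed time axis
  tr <- roi_response_trace(flat_movie(1), full_mask())
  expect_equal(tr$dl_over_l0, rep(0, 100))
  expect_equal(tr$times[11], 0)
  # two-pixel mean
  mv <- flat_movie(1, n_t = 1, nr = 1, nc = 2)
  mv$data[1, 1, 1] <- 1.1; mv$data[1, 2, 1] <- 1.3
  expect_equal(roi_response_trace(mv, full_mask(1, 2))$dl_over_l0, 0.2)
})

test_that("windowed AUCs integrate by trapezoid and add up", {
  times <- seq(-2, 17.8, by = 0.2)
  # zero trace
  z <- split_auc(make_rt(times, numeric(100)))
  expect_equal(z$early_auc, 0); expect_equal(z$late_auc, 0)

  # triangle pulse of height h on [0, 2]: area = h
  h <- 0.4
  tri <- pmax(0, h * (1 - abs(times - 1)))
  st <- split_auc(make_rt(times, tri))
  expect_equal(st$early_auc, h, tolerance = 0.01)
  expect_equal(st$late_auc, 0, tolerance = 1e-12)

  # additivity: [0,2] + [2,6] = [0,6]
  set.seed(5)
  noisy <- make_rt(times, stats::rnorm(100))
  st2 <- split_auc(noisy)
  total <- split_auc(noisy, early_window = c(0, 6), late_window = c(6, 7))
  expect_equal(st2$early_auc + st2$late_auc, total$early_auc, tolerance = 1e-12)

  expect_error(split_auc(make_rt(times, tri), late_window = c(2, 30)),
               "outside the trace range")
  expect_error(split_auc(make_rt(times, tri), early_window = c(0, 3),
                         late_window = c(2, 6)), "overlap")
})

test_that("group comparisons reproduce the pooled-variance Student's t", {
  # textbook case: pooled SD = 1, t = -3.674, df = 4
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)  # -3.674
  expect_equal(cmp$degrees_of_freedom, 4)
  expect_equal(cmp$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), df = 4),
               tolerance = 1e-6)

  # identical constant groups: degenerate, p = 1 by convention
  expect_warning(cmp0 <- compare_groups(c(1, 1, 1), c(1, 1, 1)), "convention")
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$t_statistic, 0)
  # paired with b = a: zero-variance differences, same convention
  expect_warning(cmpp <- compare_groups(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
                 "convention")
  expect_equal(cmpp$p_value, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3), paired = TRUE), "equal length")
})

test_that("t-test p-values agree with a permutation test on moderate samples", {
  set.seed(77)
  n <- 15
  for (shift in c(0, 0.5, 1)) {
    a <- stats::rnorm(n); b <- stats::rnorm(n) + shift
    p_t <- compare_groups(a, b)$p_value
    pool <- c(a, b)
    obs <- abs(mean(a) - mean(b))
    perm <- replicate(4000, {
      idx <- sample.int(2 * n, n)
      abs(mean(pool[idx]) - mean(pool[-idx]))
    })
    p_perm <- (sum(perm >= obs - 1e-12) + 1) / 4001
    expect_lt(abs(p_t - p_perm), 0.03)
  }
})

test_that("time course summaries find the peak and total integral", {
  # monotone ramp peaks at the final sample
  tr <- make_trace(seq(0, 10, length.out = 51), frame_rate = 1)
  sm <- summarize_timecourse(tr)
  expect_equal(sm$peak_value, 10)
  expect_equal(sm$time_to_peak, 50)
  expect_equal(sm$total_integrated, pracma::trapz(0:50, seq(0, 10, length.out = 51)))

  # simulated substrate curve: time to peak within one sample of closed form
  kin <- substrate_kinetics(t_offset = 0)
  tt <- seq(0, 3600, by = 0.2)
  tr2 <- list(values = substrate_trace(kin, tt), times = tt)
  sm2 <- summarize_timecourse(tr2)
  expect_equal(sm2$time_to_peak / 60, substrate_peak_time(kin), tolerance = 0.01)

  # linearity: scaling a trace by 2.5 scales its peak by exactly 2.5
  tr3 <- list(values = 2.5 * tr2$values, times = tt)
  expect_equal(summarize_timecourse(tr3)$peak_value / sm2$peak_value, 2.5)
  expect_error(summarize_timecourse(list(values = c(NA, NA), times = 1:2)),
               "non-missing")
})

test_that("early-AUC test keeps its nominal false-positive rate on null cohorts", {
  # 200 null cohorts (no stimulus-locked response), 3 vs 3 subjects each,
  # 24 x 24 px, 120 s recordings: rejection rate must sit inside the exact
  # binomial 95% band around alpha = 0.05
  n_cohorts <- 200
  rejections <- 0L
  for (ch in seq_len(n_cohorts)) {
    aucs <- vapply(1:6, function(s) {
      subject_aucs(7000 + ch * 10 + s)[["early"]]
    }, numeric(1))
    p <- compare_groups(aucs[1:3], aucs[4:6])$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  lo <- stats::qbinom(0.025, n_cohorts, 0.05)
  hi <- stats::qbinom(0.975, n_cohorts, 0.05)
  expect_gte(rejections, lo)
  expect_lte(rejections, hi)
})

test_that("the default calcium response is detectable in small cohorts", {
  # 12 cohorts with the 0.10-amplitude calcium kernel vs kernel-free
  # controls: at least 80% should reject at alpha = 0.05
  hits <- 0L
  for (ch in 1:12) {
    ca <- vapply(1:3, function(s) {
      subject_aucs(3100 + ch * 10 + s,
                   kernels = list(response_kernel("calcium")))[["early"]]
    }, numeric(1))
    ctl <- vapply(4:6, function(s) {
      subject_aucs(3100 + ch * 10 + s)[["early"]]
    }, numeric(1))
    if (compare_groups(ca, ctl)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 10)
})

test_that("hemodynamic-only cohorts show a late response but no early one", {
  # high photon flux so the small baseline-normalization ratio bias is
  # negligible against the 3-SE bands
  kin <- substrate_kinetics(amplitude = 1e5)
  run <- function(seed) {
    sched <- short_sched(5)
    sim <- simulate_bli_video(kinetics = kin,
                              kernels = list(response_kernel("hemodynamic")),
                              schedule = sched, geometry = small_geom(),
                              duration = 120, seed = seed)
    an <- suppressWarnings(
      bli_trial_average(sim$video, sched, dark = camera_model()$dark_offset,
                        n_first = "all", keep_trials = FALSE))
    st <- split_auc(roi_response_trace(an$movie, an$mask))
    c(st$early_auc, st$late_auc)
  }
  aucs <- vapply(2200 + 1:3, run, numeric(2))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  # early AUC bounded by the chain's residual budget (1e-3 pointwise over a
  # 2 s window); an SE-based zero test is not meaningful here because the
  # filter's interaction with the stimulation block leaves a deterministic
  # ~1e-3-scale residual shared by all subjects
  expect_lt(abs(mean(aucs[1, ])), 2e-3)
  expect_gt(mean(aucs[2, ]), 3 * se(aucs[2, ]))         # clear late component
  expect_gt(mean(aucs[2, ]), 0.1)
})
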