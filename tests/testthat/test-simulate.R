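test_that("identical seeds give bit-identical stacks", {
  sched <- short_sched(2)
  a <- simulate_bli_video(schedule = sched, geometry = tiny_geom(),
                          duration = 60, seed = 11)
  b <- simulate_bli_video(schedule = sched, geometry = tiny_geom(),
                          duration = 60, seed = 11)
  expect_identical(a$video$data, b$video$data)
  c <- simulate_bli_video(schedule = sched, geometry = tiny_geom(),
                          duration = 60, seed = 12)
  expect_false(identical(a$video$data, c$video$data))
})

test_that("noiseless null movie equals dark offset plus scaled profile", {
  sched <- stimulus_schedule(1, 1, 19, 5)
  cam <- camera_model()
  geom <- tiny_geom()
  kin <- substrate_kinetics()
  sim <- simulate_bli_video(kinetics = kin, kernels = list(), camera = cam,
                            schedule = sched, geometry = geom,
                            duration = 30, seed = 1, noise = FALSE)
  times <- frame_times(sim$video)
  sub <- substrate_trace(kin, times)
  for (f in c(1, 50, 150)) {
    expected <- cam$dark_offset +
      cam$em_gain * geom$profile * sub[f] * cam$exposure
    expect_equal(sim$video$data[, , f], expected, tolerance = 1e-12)
  }
  # truth traces have one value per frame and the mask is nonempty
  expect_length(sim$truth$substrate_trace, n_frames(sim$video))
  expect_length(sim$truth$hemo_trace, n_frames(sim$video))
  expect_gt(sum(sim$truth$head_mask_true), 0)
})

test_that("noise model is unbiased: Monte-Carlo pixel mean within 3 SE", {
  sched <- stimulus_schedule(1, 1, 1, 0)
  cam <- camera_model()
  geom <- head_geometry(6, 6, semi_axes = c(2.5, 2.5))
  noiseless <- simulate_bli_video(kernels = list(), camera = cam,
                                  schedule = sched, geometry = geom,
                                  duration = 2.5, seed = 1, noise = FALSE)
  px <- c(3, 3, 2)
  draws <- vapply(1:500, function(s) {
    simulate_bli_video(kernels = list(), camera = cam, schedule = sched,
                       geometry = geom, duration = 2.5,
                       seed = 1000 + s)$video$data[px[1], px[2], px[3]]
  }, numeric(1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - noiseless$video$data[px[1], px[2], px[3]]),
            3 * se)
})

test_that("count variance grows linearly with expected photons at the predicted slope", {
  # brightness ladder: plateau pixels share one lambda per frame, and the
  # substrate envelope sweeps lambda across frames
  cam <- camera_model()
  kin <- substrate_kinetics(amplitude = 500)
  sched <- stimulus_schedule(1, 1, 19, 5)
  geom <- full_geom()
  sim <- simulate_bli_video(kinetics = kin, kernels = list(), camera = cam,
                            schedule = sched, geometry = geom,
                            duration = 120, seed = 5)
  plateau <- sim$truth$profile >= 1 - 1e-12
  m <- sim$video$data
  dim(m) <- c(64 * 64, dim(m)[3])
  m <- m[as.vector(plateau), ]
  lam <- sim$truth$substrate_trace * cam$exposure       # photons at plateau
  frames <- seq(10, ncol(m), by = 10)
  v <- apply(m[, frames], 2, stats::var)
  fit <- stats::lm(v ~ lam[frames])
  pred_slope <- cam$em_gain^2 * cam$excess_noise_factor^2
  expect_lt(abs(unname(coef(fit)[2]) / pred_slope - 1), 0.1)
})

test_that("a schedule extending past the video end is rejected with the last valid onset", {
  sched <- stimulus_schedule(5, 1, 19, 20)   # onsets up to 100 s
  expect_error(
    simulate_bli_video(schedule = sched, geometry = tiny_geom(),
                       duration = 60, seed = 1),
    "last onset inside the recording is 40")
})
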