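# Shared simulation fixtures. Heavy noiseless reference simulations are
# memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small geometries keep per-test simulations fast
tiny_geom <- function() head_geometry(16, 16, semi_axes = c(5.5, 4))
small_geom <- function() head_geometry(24, 24, semi_axes = c(8, 6))
full_geom <- function() head_geometry(64, 64)

# 5-cycle schedule starting 20 s in: 120 s recordings, 5 retained trials
short_sched <- function(n = 5) stimulus_schedule(n, 1, 19, 20)

default_kernels <- function() {
  list(response_kernel("hemodynamic"), response_kernel("calcium"))
}

# one simulated subject -> early/late AUC of the trial-averaged ROI trace
subject_aucs <- function(seed, kernels = list(), geometry = small_geom(),
                         schedule = short_sched(), duration = 120,
                         camera = camera_model(), n_first = "all") {
  sim <- simulate_bli_video(kernels = kernels, camera = camera,
                            schedule = schedule, geometry = geometry,
                            duration = duration, seed = seed)
  an <- suppressWarnings(
    bli_trial_average(sim$video, schedule, dark = camera$dark_offset,
                      n_first = n_first, keep_trials = FALSE))
  st <- split_auc(roi_response_trace(an$movie, an$mask))
  c(early = st$early_auc, late = st$late_auc)
}

# noiseless full-protocol (57 cycles) reference runs at 16 x 16
full_null_noiseless <- function() memo("full_null", {
  sched <- stimulus_schedule(57, 1, 19, 60)
  sim <- simulate_bli_video(kernels = list(), schedule = sched,
                            geometry = tiny_geom(), duration = 1200,
                            seed = 1, noise = FALSE)
  list(sim = sim, sched = sched)
})

full_kernel_noiseless <- function() memo("full_kernel", {
  sched <- stimulus_schedule(57, 1, 19, 60)
  sim <- simulate_bli_video(kernels = default_kernels(), schedule = sched,
                            geometry = tiny_geom(), duration = 1200,
                            seed = 1, noise = FALSE)
  an <- bli_trial_average(sim$video, sched, dark = camera_model()$dark_offset,
                          n_first = 20)
  list(sim = sim, sched = sched, analysis = an)
})

# plain trace_series constructor for filter tests
make_trace <- function(values, frame_rate = 5) {
  structure(list(values = values, frame_rate = frame_rate, t0 = 0,
                 label = "test"), class = "trace_series")
}
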