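#' Simulate a head-fixed BLI video with known ground truth
#'
#' Generates an EM-CCD video of a luminous head region whose brightness
#' follows substrate pharmacokinetics, optionally modulated by
#' stimulus-locked hemodynamic and calcium response kernels. The expected
#' photoelectron count of pixel `(r, c)` in the frame at time `t` is
#'
#' `profile(r, c) * substrate(t) * (1 + hemo(t) + calcium(t)) * exposure`
#'
#' and camera counts are `dark_offset` plus gain-amplified, excess-noise
#' scaled Poisson counts plus Gaussian read noise (see [camera_model()]).
#' Ground-truth component traces are returned alongside the stack, so every
#' downstream analysis stage can be validated against what was injected.
#'
#' @param kinetics A [substrate_kinetics()].
#' @param kernels List of [response_kernel()] objects (possibly empty); at
#'   most one of each kind is typical.
#' @param camera A [camera_model()].
#' @param schedule A [stimulus_schedule()]; must end before the video does.
#' @param geometry A [head_geometry()].
#' @param duration Recording length in seconds; default runs one full cycle
#'   past the last onset.
#' @param seed Integer RNG seed; identical seeds give bit-identical stacks.
#' @param noise If `FALSE`, return the noiseless expectation (plus
#'   `dark_offset`) instead of random counts.
#' @return A list with `video` (a [video_stack()]) and `truth`, a list of
#'   class `sim_truth` with per-frame `substrate_trace` (photons/s),
#'   `hemo_trace` and `calcium_trace` (fractional delta-L/L0),
#'   `head_mask_true`, `profile` and `seed`.
#' @examples
#' sim <- simulate_bli_video(schedule = stimulus_schedule(3, 1, 19, 20),
#'                           duration = 90, seed = 1,
#'                           geometry = head_geometry(32, 32, semi_axes = c(10, 8)))
#' sim$video
#' @export
simulate_bli_video <- function(kinetics = substrate_kinetics(),
                               kernels = list(response_kernel("hemodynamic"),
                                              response_kernel("calcium")),
                               camera = camera_model(),
                               schedule = stimulus_schedule(),
                               geometry = head_geometry(),
                               duration = NULL,
                               seed = 1L,
                               noise = TRUE) {
  stopifnot(inherits(kinetics, "substrate_kinetics"),
            inherits(camera, "camera_model"),
            inherits(schedule, "stim_schedule"),
            inherits(geometry, "head_geometry"))
  if (inherits(kernels, "response_kernel")) kernels <- list(kernels)
  lapply(kernels, function(k) stopifnot(inherits(k, "response_kernel")))
  if (is.null(duration)) {
    duration <- schedule$onsets[length(schedule$onsets)] + schedule$cycle_length
  }
  n_fr <- floor(duration * camera$frame_rate)
  if (n_fr < 1) stop("`duration` too short for a single frame")
  times <- (seq_len(n_fr) - 1) / camera$frame_rate
  last_ok <- schedule$onsets[schedule$onsets <= times[n_fr]]
  if (length(last_ok) < length(schedule$onsets)) {
    stop(sprintf(
      "schedule extends past the video end (%.1f s); last onset inside the recording is %g s",
      times[n_fr], if (length(last_ok)) last_ok[length(last_ok)] else NA_real_))
  }

  sub <- substrate_trace(kinetics, times)
  hemo <- numeric(n_fr)
  calc <- numeric(n_fr)
  for (k in kernels) {
    m <- schedule_modulation(k, schedule, times)
    if (k$kind == "hemodynamic") hemo <- hemo + m else calc <- calc + m
  }

  # expected photoelectrons: pixels x frames
  profile_vec <- as.vector(geometry$profile)
  rate_t <- sub * (1 + hemo + calc) * camera$exposure
  lambda <- outer(profile_vec, rate_t)

  if (noise) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
    counts <- .emccd_counts(lambda, camera)
    counts[counts < 0] <- 0
  } else {
    counts <- camera$dark_offset + camera$em_gain * lambda
  }
  dim(counts) <- c(geometry$nrow, geometry$ncol, n_fr)

  truth <- structure(
    list(substrate_trace = sub, hemo_trace = hemo, calcium_trace = calc,
         head_mask_true = geometry$mask_true, profile = geometry$profile,
         times = times, seed = as.integer(seed)),
    class = "sim_truth")
  list(video = video_stack(counts, camera$frame_rate, camera$exposure, t0 = 0),
       truth = truth)
}
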