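#' Stimulus-locked response kernels
#'
#' Fractional luminescence responses evoked by a single stimulus, expressed
#' as a causal kernel of time since stimulus onset. Two shapes are provided:
#'
#' * `"hemodynamic"`: a delayed gamma-variate. Activity-evoked blood flow
#'   delivers extra substrate and oxygen seconds after the stimulus; the
#'   default kernel is supported on 2-6 s after onset and peaks at 3 s,
#'   matching the late bilateral response of luciferase-only animals.
#' * `"calcium"`: a difference of exponentials starting at onset and peaking
#'   near 1 s, modelling the fast indicator-mediated calcium response that
#'   only calcium-sensitive reporters show.
#'
#' Kernels are peak-normalized so their maximum equals `amplitude` (a
#' fractional delta-L/L0; the default 0.10 is the ~10% modulation seen in
#' vivo), are zero before `onset_delay`, and are truncated to zero
#' `duration` seconds after `onset_delay`.
#'
#' @param kind `"hemodynamic"` or `"calcium"`.
#' @param amplitude Peak fractional response (delta-L/L0), >= 0.
#' @param onset_delay Seconds from stimulus onset to response onset.
#' @param duration Support length in seconds after `onset_delay`; the kernel
#'   is zero outside `[onset_delay, onset_delay + duration]`.
#' @param alpha,beta Gamma-variate shape/scale (hemodynamic): the
#'   unnormalized form is `s^alpha * exp(-s/beta)` on shifted time
#'   `s = t - onset_delay`, peaking at `s = alpha * beta`.
#' @param tau_rise,tau_decay Rise/decay time constants in seconds (calcium):
#'   `exp(-s/tau_decay) - exp(-s/tau_rise)` with `tau_decay > tau_rise`.
#' @return An object of class `response_kernel`.
#' @seealso [kernel_values()], [kernel_peak_time()]
#' @export
response_kernel <- function(kind = c("hemodynamic", "calcium"),
                            amplitude = 0.10,
                            onset_delay = if (kind == "hemodynamic") 2 else 0,
                            duration = 4,
                            alpha = 2, beta = 0.5,
                            tau_rise = 0.55, tau_decay = 2) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  if (onset_delay < 0 || duration <= 0) {
    stop("`onset_delay` must be >= 0 and `duration` > 0")
  }
  if (kind == "hemodynamic") {
    if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be > 0")
  } else {
    if (tau_rise <= 0 || tau_decay <= tau_rise) {
      stop("need 0 < tau_rise < tau_decay")
    }
  }
  structure(list(kind = kind, amplitude = amplitude,
                 onset_delay = onset_delay, duration = duration,
                 alpha = alpha, beta = beta,
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "response_kernel")
}

# unnormalized kernel shape on shifted time s >= 0
.kernel_shape <- function(kernel, s) {
  if (kernel$kind == "hemodynamic") {
    s^kernel$alpha * exp(-s / kernel$beta)
  } else {
    exp(-s / kernel$tau_decay) - exp(-s / kernel$tau_rise)
  }
}

#' Time of kernel peak relative to stimulus onset
#'
#' Closed form: `onset_delay + alpha*beta` for the gamma-variate,
#' `onset_delay + tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)` for the
#' difference of exponentials. Defaults give 3 s (hemodynamic) and ~1 s
#' (calcium).
#'
#' @param kernel A [response_kernel()].
#' @return Peak time in seconds after stimulus onset.
#' @export
kernel_peak_time <- function(kernel) {
  stopifnot(inherits(kernel, "response_kernel"))
  s_pk <- if (kernel$kind == "hemodynamic") {
    kernel$alpha * kernel$beta
  } else {
    tr <- kernel$tau_rise; td <- kernel$tau_decay
    tr * td / (td - tr) * log(td / tr)
  }
  kernel$onset_delay + min(s_pk, kernel$duration)
}

#' Evaluate a response kernel
#'
#' @param kernel A [response_kernel()].
#' @param t Times in seconds relative to stimulus onset (any sign).
#' @return Fractional delta-L/L0 values: nonnegative, zero for
#'   `t < onset_delay` and for `t > onset_delay + duration`, with maximum
#'   `amplitude`.
#' @export
kernel_values <- function(kernel, t) {
  stopifnot(inherits(kernel, "response_kernel"))
  out <- numeric(length(t))
  s <- t - kernel$onset_delay
  keep <- s > 0 & s <= kernel$duration
  if (!any(keep)) return(out)
  s_pk <- kernel_peak_time(kernel) - kernel$onset_delay
  peak <- .kernel_shape(kernel, s_pk)
  out[keep] <- kernel$amplitude * .kernel_shape(kernel, s[keep]) / peak
  out
}

#' Superpose kernel responses over a stimulus schedule
#'
#' Sums one kernel copy per stimulus onset, evaluated at the given
#' acquisition times. With the default kernels (support <= 6 s, cycle 20 s)
#' successive copies never overlap.
#'
#' @param kernel A [response_kernel()], or `NULL` for an all-zero trace.
#' @param schedule A [stimulus_schedule()].
#' @param times Acquisition times in seconds.
#' @return Fractional delta-L/L0 modulation, one value per time point.
#' @export
schedule_modulation <- function(kernel, schedule, times) {
  stopifnot(inherits(schedule, "stim_schedule"))
  out <- numeric(length(times))
  if (is.null(kernel) || kernel$amplitude == 0) return(out)
  for (on in schedule$onsets) {
    rel <- times - on
    win <- rel > kernel$onset_delay & rel <= kernel$onset_delay + kernel$duration
    if (any(win)) out[win] <- out[win] + kernel_values(kernel, rel[win])
  }
  out
}
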