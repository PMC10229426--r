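# trapezoidal integral of (times, values) restricted to [from, to],
# interpolating the endpoints when they fall between samples
.trapz_window <- function(times, values, from, to) {
  if (from >= to) stop("integration window is empty")
  if (from < times[1] - 1e-9 || to > times[length(times)] + 1e-9) {
    stop(sprintf("window [%g, %g] s extends outside the trace range [%g, %g] s",
                 from, to, times[1], times[length(times)]))
  }
  inside <- times > from & times < to
  tt <- c(from, times[inside], to)
  vv <- c(stats::approx(times, values, xout = from)$y,
          values[inside],
          stats::approx(times, values, xout = to)$y)
  pracma::trapz(tt, vv)
}

#' Cortical response trace from a trial-averaged movie
#'
#' Averages delta-L/L0 over the mask at each trial time point, giving the
#' stimulus-locked cortical response waveform with its time axis zeroed at
#' stimulus onset (negative times are pre-stimulus baseline).
#'
#' @param movie A `trial_movie` from [average_trials()].
#' @param mask A `mask_image`; only foreground pixels contribute.
#' @param subject_id Optional label carried through to group tables.
#' @return An object of class `response_trace`: list with `times` (s,
#'   relative to onset), `dl_over_l0`, `n_trials_averaged` and `subject_id`.
#' @export
roi_response_trace <- function(movie, mask, subject_id = "") {
  stopifnot(inherits(movie, "trial_movie"), inherits(mask, "mask_image"))
  d <- dim(movie$data)
  if (!all(dim(mask$data) == d[1:2])) stop("mask and movie sizes differ")
  if (mask$n_foreground < 1) stop("mask has no foreground pixels")
  m <- movie$data
  dim(m) <- c(d[1] * d[2], d[3])
  vals <- colMeans(m[as.vector(mask$data), , drop = FALSE], na.rm = TRUE) - 1
  structure(list(times = movie$times, dl_over_l0 = vals,
                 n_trials_averaged = movie$n_trials_averaged,
                 subject_id = subject_id),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  pk <- which.max(x$dl_over_l0)
  cat(sprintf(
    "Response trace%s: %d points over [%g, %g] s, %d trials averaged\n",
    if (nzchar(x$subject_id)) paste0(" (", x$subject_id, ")") else "",
    length(x$times), min(x$times), max(x$times), x$n_trials_averaged))
  cat(sprintf("  peak delta-L/L0 = %.4f at %g s\n", x$dl_over_l0[pk], x$times[pk]))
  invisible(x)
}

#' Early / late response areas under the curve
#'
#' Trapezoidal integrals of delta-L/L0 over an early post-stimulus window
#' (default 0-2 s, capturing the fast calcium component) and a late window
#' (default 2-6 s, capturing the hemodynamic component), split at the 2 s
#' time point.
#'
#' @param trace A `response_trace`.
#' @param split_time Boundary between the windows, s (default 2).
#' @param early_window,late_window Two-element numeric windows in seconds
#'   after onset; defaults `c(0, split_time)` and `c(split_time, 6)`. Must
#'   be disjoint, post-onset and inside the trace.
#' @return An object of class `response_stats`: list with `early_auc`,
#'   `late_auc` (delta-L/L0 x s), `split_time`, `early_window`,
#'   `late_window` and `subject_id`.
#' @export
split_auc <- function(trace, split_time = 2,
                      early_window = c(0, split_time),
                      late_window = c(split_time, 6)) {
  stopifnot(inherits(trace, "response_trace"))
  for (w in list(early_window, late_window)) {
    if (length(w) != 2L || w[1] >= w[2]) stop("windows must be increasing pairs")
    if (w[1] < 0) stop("windows must be post-onset (start >= 0 s)")
  }
  if (early_window[2] > late_window[1] && late_window[2] > early_window[1]) {
    stop("early and late windows overlap")
  }
  structure(
    list(early_auc = .trapz_window(trace$times, trace$dl_over_l0,
                                   early_window[1], early_window[2]),
         late_auc = .trapz_window(trace$times, trace$dl_over_l0,
                                  late_window[1], late_window[2]),
         split_time = split_time,
         early_window = early_window, late_window = late_window,
         subject_id = trace$subject_id),
    class = "response_stats")
}

#' @export
print.response_stats <- function(x, ...) {
  cat(sprintf("AUC split at %g s: early [%g, %g] s = %.4f; late [%g, %g] s = %.4f\n",
              x$split_time, x$early_window[1], x$early_window[2], x$early_auc,
              x$late_window[1], x$late_window[2], x$late_auc))
  invisible(x)
}

#' Student's t comparison of two groups of per-subject statistics
#'
#' Two-tailed Student's t-test: pooled-variance unpaired by default, or
#' paired. When both groups are constant with equal means (zero pooled
#' variance), `t = 0` and `p = 1` are returned by convention with a warning.
#'
#' @param a,b Numeric vectors of per-subject statistics (n >= 2 each;
#'   equal lengths when `paired = TRUE`).
#' @param paired Paired test? Default `FALSE` (unpaired, pooled variance).
#' @return An object of class `group_comparison`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `paired`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (anyNA(a) || anyNA(b)) stop("groups must not contain missing values")
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (paired && length(a) != length(b)) stop("paired groups must have equal length")
  res <- tryCatch(
    stats::t.test(a, b, paired = paired, var.equal = TRUE,
                  alternative = "two.sided"),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$statistic)) {
    # degenerate: zero variance; equal means => no evidence of a difference
    warning("zero variance in the comparison; returning t = 0, p = 1 by convention")
    tstat <- 0; df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    p <- 1
  } else {
    tstat <- unname(res$statistic); df <- unname(res$parameter)
    p <- res$p.value
  }
  structure(list(t_statistic = tstat, degrees_of_freedom = df, p_value = p,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b), paired = paired),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s two-tailed Student's t-test: t = %.4f, df = %g, p = %.4g\n",
              if (x$paired) "Paired" else "Unpaired",
              x$t_statistic, x$degrees_of_freedom, x$p_value))
  cat(sprintf("  group means: %.4g (n = %d) vs %.4g (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

#' Summarize a whole-recording time course
#'
#' Peak value, time to peak and trapezoidal total integral of a scalar
#' brightness time course, e.g. the masked mean trace of a full recording.
#'
#' @param trace A `trace_series`, or a list with `values` and either
#'   `frame_rate` (s^-1) or `times` (s).
#' @return A list of class `timecourse_summary`: `peak_value`,
#'   `time_to_peak` (s), `total_integrated` (value x s).
#' @export
summarize_timecourse <- function(trace) {
  if (inherits(trace, "trace_series")) {
    vals <- trace$values
    times <- trace$t0 + (seq_along(vals) - 1) / trace$frame_rate
  } else {
    vals <- trace$values
    times <- if (!is.null(trace$times)) trace$times
             else (seq_along(vals) - 1) / trace$frame_rate
  }
  keep <- !is.na(vals)
  if (sum(keep) < 2) stop("need at least 2 non-missing samples")
  vals <- vals[keep]; times <- times[keep]
  pk <- which.max(vals)
  structure(list(peak_value = vals[pk], time_to_peak = times[pk],
                 total_integrated = pracma::trapz(times, vals)),
            class = "timecourse_summary")
}

#' @export
print.timecourse_summary <- function(x, ...) {
  cat(sprintf("Time course: peak %.4g at %.4g s; total integral %.4g\n",
              x$peak_value, x$time_to_peak, x$total_integrated))
  invisible(x)
}
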