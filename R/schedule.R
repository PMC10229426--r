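#' Build a periodic stimulus schedule
#'
#' Constructs the timing of a block of identical stimulation cycles, each
#' consisting of an "on" period followed by an "off" period. The default
#' in vivo design is 57 cycles of a 1 s foot vibration followed by 19 s of
#' rest (20 s cycle length), starting 60 s after acquisition onset.
#'
#' @param n_cycles Number of stimulation cycles (>= 1).
#' @param on_duration Stimulus-on duration in seconds (> 0).
#' @param off_duration Inter-stimulus rest duration in seconds (> 0).
#' @param start_delay Time of the first stimulus onset, in seconds from
#'   acquisition start (>= 0).
#'
#' @return An object of class `stim_schedule`: a list with `onsets` (seconds,
#'   strictly increasing), `on_duration`, `cycle_length` and `n_cycles`.
#' @examples
#' sched <- stimulus_schedule(57, 1, 19, 60)
#' head(sched$onsets)
#' @export
stimulus_schedule <- function(n_cycles = 57, on_duration = 1, off_duration = 19,
                              start_delay = 60) {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("`n_cycles` must be a single integer >= 1")
  }
  if (on_duration <= 0 || off_duration <= 0) {
    stop("`on_duration` and `off_duration` must be positive")
  }
  if (start_delay < 0) stop("`start_delay` must be >= 0")
  cycle <- on_duration + off_duration
  onsets <- start_delay + (seq_len(n_cycles) - 1) * cycle
  structure(
    list(onsets = onsets, on_duration = on_duration,
         cycle_length = cycle, n_cycles = as.integer(n_cycles)),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("Stimulus schedule: %d cycles, %g s on / %g s off (cycle %g s)\n",
              x$n_cycles, x$on_duration, x$cycle_length - x$on_duration,
              x$cycle_length))
  cat(sprintf("  first onset %g s, last onset %g s\n",
              x$onsets[1], x$onsets[length(x$onsets)]))
  invisible(x)
}

#' Write / read a stimulus schedule as CSV
#'
#' The CSV has one row per cycle with columns `onset_s` and `on_s`.
#'
#' @param schedule A `stim_schedule`.
#' @param path File path.
#' @return `write_schedule_csv` returns `path` invisibly; `read_schedule_csv`
#'   returns a `stim_schedule` (the off duration is inferred from the onset
#'   spacing, which must be constant).
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "stim_schedule"))
  utils::write.csv(
    data.frame(onset_s = schedule$onsets, on_s = schedule$on_duration),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("onset_s", "on_s") %in% names(tab))) {
    stop("schedule CSV must have columns `onset_s` and `on_s`")
  }
  onsets <- tab$onset_s
  if (length(onsets) < 1L) stop("schedule CSV is empty")
  on_dur <- tab$on_s[1]
  if (length(onsets) == 1L) {
    # single cycle: spacing cannot be inferred, use on-duration as off-duration
    return(stimulus_schedule(1, on_dur, on_dur, onsets[1]))
  }
  gaps <- diff(onsets)
  if (max(abs(gaps - gaps[1])) > 1e-9) {
    stop("onsets in schedule CSV are not evenly spaced")
  }
  stimulus_schedule(length(onsets), on_dur, gaps[1] - on_dur, onsets[1])
}
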