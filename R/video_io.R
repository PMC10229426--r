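#' Write / read a BLI video as multi-page TIFF with a JSON sidecar
#'
#' Videos are stored as multi-page 16-bit grayscale TIFF. Counts are written
#' as integers clipped to `[0, 65535]`; the sidecar JSON (same path with
#' `.json` appended) records `frame_rate`, `exposure`, `t0`, and optionally
#' `dark_offset`, `seed` and the stimulus schedule, so a recording round-trips
#' with its acquisition metadata.
#'
#' @param video A [video_stack()].
#' @param path TIFF file path.
#' @param dark_offset Optional camera dark level to record in the sidecar.
#' @param seed Optional simulation seed to record.
#' @param schedule Optional [stimulus_schedule()] to embed.
#' @return `write_bli_video` returns `path` invisibly. `read_bli_video`
#'   returns a list with `video` (a [video_stack()]), `dark_offset`, `seed`
#'   and `schedule` (each `NULL` when absent from the sidecar).
#' @export
write_bli_video <- function(video, path, dark_offset = NULL, seed = NULL,
                            schedule = NULL) {
  stopifnot(inherits(video, "video_stack"))
  d <- dim(video$data)
  frames <- lapply(seq_len(d[3]), function(f) {
    fr <- video$data[, , f]
    fr[is.na(fr)] <- 0
    pmin(pmax(round(fr), 0), 65535) / 65535  # tiff package expects [0,1]
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  meta <- list(frame_rate = video$frame_rate, exposure = video$exposure,
               t0 = video$t0)
  if (!is.null(dark_offset)) meta$dark_offset <- dark_offset
  if (!is.null(seed)) meta$seed <- seed
  if (!is.null(schedule)) {
    meta$schedule <- list(onsets = schedule$onsets,
                          on_duration = schedule$on_duration)
  }
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bli_video
#' @export
read_bli_video <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("sidecar JSON not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1]  # tolerate grayscale-as-RGB
    arr[, , f] <- round(fr * 65535)
  }
  sched <- NULL
  if (!is.null(meta$schedule)) {
    on_d <- meta$schedule$on_duration
    onsets <- meta$schedule$onsets
    gap <- if (length(onsets) > 1) diff(onsets)[1] else 2 * on_d
    sched <- stimulus_schedule(length(onsets), on_d, gap - on_d, onsets[1])
  }
  list(video = video_stack(arr, meta$frame_rate, meta$exposure,
                           t0 = if (is.null(meta$t0)) 0 else meta$t0),
       dark_offset = meta$dark_offset, seed = meta$seed, schedule = sched)
}

#' Write / read a scalar trace as CSV
#'
#' Columns: `frame` (1-based), `time_s`, `value`.
#'
#' @param trace A `trace_series` (e.g. from [masked_mean_trace()]).
#' @param path CSV path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `trace_series` (frame rate inferred from the time column).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "trace_series"))
  n <- length(trace$values)
  utils::write.csv(
    data.frame(frame = seq_len(n),
               time_s = trace$t0 + (seq_len(n) - 1) / trace$frame_rate,
               value = trace$values),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(tab))) {
    stop("trace CSV must have columns `time_s` and `value`")
  }
  dt <- diff(tab$time_s)
  if (length(dt) < 1 || max(abs(dt - dt[1])) > 1e-9) {
    stop("trace CSV must be evenly sampled in time")
  }
  structure(list(values = tab$value, frame_rate = 1 / dt[1],
                 t0 = tab$time_s[1], label = basename(path)),
            class = "trace_series")
}
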