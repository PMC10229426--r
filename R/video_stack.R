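#' Video stack container
#'
#' A grayscale video as a numeric `rows x cols x frames` array with timing
#' metadata. Frame `f` (1-based) is acquired at time `t0 + (f - 1)/frame_rate`
#' seconds. Missing pixels are `NA` and are propagated, never zero-filled.
#'
#' @param data Numeric 3-D array, `rows x cols x frames`.
#' @param frame_rate Frames per second (> 0).
#' @param exposure Exposure time per frame, s (> 0).
#' @param t0 Acquisition start time, s (default 0).
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(data, frame_rate, exposure = 1 / frame_rate, t0 = 0) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a rows x cols x frames array")
  }
  if (dim(data)[3] < 1L) stop("need at least one frame")
  if (frame_rate <= 0 || exposure <= 0) {
    stop("`frame_rate` and `exposure` must be > 0")
  }
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  structure(list(data = data, frame_rate = frame_rate, exposure = exposure,
                 t0 = t0),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Video stack: %d x %d px, %d frames @ %g Hz (%.1f s), t0 = %g s\n",
              d[1], d[2], d[3], x$frame_rate, d[3] / x$frame_rate, x$t0))
  invisible(x)
}

#' Frame acquisition times
#'
#' @param video A [video_stack()].
#' @return Times in seconds, one per frame: `t0 + (0:(n-1))/frame_rate`.
#' @export
frame_times <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  video$t0 + (seq_len(dim(video$data)[3]) - 1) / video$frame_rate
}

#' Number of frames
#' @param video A [video_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(video) {
  stopifnot(inherits(video, "video_stack"))
  dim(video$data)[3]
}
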