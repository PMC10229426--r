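#' Subtract the camera dark baseline
#'
#' Removes the camera bias/dark level from every frame. Results are clipped
#' at zero: bioluminescence intensities are photon counts and cannot be
#' negative. Timing metadata is unchanged.
#'
#' @param video A [video_stack()].
#' @param dark Scalar dark level, or a `rows x cols` matrix of per-pixel
#'   dark values.
#' @return A dark-subtracted [video_stack()].
#' @export
subtract_dark <- function(video, dark) {
  stopifnot(inherits(video, "video_stack"))
  d <- dim(video$data)
  if (is.matrix(dark)) {
    if (!all(dim(dark) == d[1:2])) {
      stop("per-pixel `dark` must match the frame size")
    }
  } else if (length(dark) != 1L) {
    stop("`dark` must be a scalar or a rows x cols matrix")
  }
  if (any(!is.finite(dark))) stop("`dark` must be finite")
  if (all(dark >= max(video$data, na.rm = TRUE))) {
    warning("dark level exceeds the stack maximum everywhere; output is all zero")
  }
  out <- video$data - as.vector(dark)  # recycles per-pixel dark across frames
  out[out < 0] <- 0
  video$data <- out
  video
}

# One filtering pass started in steady state for the first sample, so a
# constant input passes through with no transient at all.
.filter_steady <- function(bf, x) {
  b <- bf$b; a <- bf$a
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(x[1] * dc, length(a) - 1)))
}

# Otsu threshold on an arbitrary-range image via EBImage (which expects [0,1])
.otsu_threshold <- function(img, levels = 256L) {
  v <- img[is.finite(img)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  # EBImage::otsu works on [0,1]; rescale and map the threshold back
  scaled <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(scaled, range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

#' Compute a static head mask from a video
#'
#' Builds one binary mask per recording by thresholding the temporal-mean
#' image of the (dark-subtracted) stack: the strongly luminescent head
#' stands out from the dark field, so an intensity threshold separates it.
#' The default method is Otsu's threshold followed by retention of the
#' largest connected component; alternatively a fixed fraction of the mean
#' image's maximum can be used.
#'
#' @param video A dark-subtracted [video_stack()].
#' @param method `"otsu"` (default) or `"fraction"`.
#' @param fraction For `method = "fraction"`: keep pixels above
#'   `fraction * max` of the temporal-mean image (default 0.5).
#' @param keep_largest Keep only the largest connected component
#'   (default `TRUE`).
#' @return An object of class `mask_image`: list with logical matrix `data`
#'   and `n_foreground`.
#' @export
compute_head_mask <- function(video, method = c("otsu", "fraction"),
                              fraction = 0.5, keep_largest = TRUE) {
  stopifnot(inherits(video, "video_stack"))
  method <- match.arg(method)
  mean_img <- rowMeans(video$data, dims = 2, na.rm = TRUE)
  th <- switch(method,
    otsu = .otsu_threshold(mean_img),
    fraction = fraction * max(mean_img, na.rm = TRUE))
  mask <- mean_img > th
  mask[is.na(mask)] <- FALSE
  if (keep_largest && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  if (!any(mask)) {
    stop("head mask is empty; lower the threshold (try method = \"fraction\" ",
         "with a smaller `fraction`)")
  }
  structure(list(data = mask, n_foreground = sum(mask)), class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("Binary mask: %d x %d px, %d foreground (%.1f%%)\n",
              nrow(x$data), ncol(x$data), x$n_foreground,
              100 * x$n_foreground / length(x$data)))
  invisible(x)
}

#' Mean intensity inside the mask, per frame
#'
#' The scalar time course of the recording: for each frame, the mean over
#' foreground pixels, ignoring missing values. A frame whose foreground is
#' entirely missing yields `NA`.
#'
#' @param video A [video_stack()].
#' @param mask A `mask_image` of matching spatial size.
#' @return An object of class `trace_series`: list with `values`,
#'   `frame_rate`, `t0` and `label`.
#' @export
masked_mean_trace <- function(video, mask) {
  stopifnot(inherits(video, "video_stack"), inherits(mask, "mask_image"))
  d <- dim(video$data)
  if (!all(dim(mask$data) == d[1:2])) stop("mask and video sizes differ")
  m <- video$data
  dim(m) <- c(d[1] * d[2], d[3])
  vals <- colMeans(m[as.vector(mask$data), , drop = FALSE], na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  structure(list(values = vals, frame_rate = video$frame_rate, t0 = video$t0,
                 label = "masked mean"),
            class = "trace_series")
}

#' Zero-phase Butterworth lowpass smoothing
#'
#' Smooths a scalar trace with an order-`order` Butterworth lowpass applied
#' forward and backward (zero phase), so the slow substrate-decay envelope
#' is tracked without temporal lag. The trace is extended by odd reflection
#' at both ends before filtering to suppress edge transients, then cropped
#' back. The two-pass squared magnitude response at frequency `f` is
#' `1 / (1 + (f/cutoff)^(2*order))`; DC gain is 1.
#'
#' The default cutoff (0.02 Hz) sits well below the 0.05 Hz stimulus-cycle
#' frequency of the standard 20 s design, so stimulus-locked responses pass
#' into the decay-corrected movie essentially unattenuated while the
#' pharmacokinetic decay is captured.
#'
#' @param trace A `trace_series` with no missing values (interpolate first,
#'   e.g. with [stats::approx()]).
#' @param cutoff Lowpass cutoff in Hz; must be below the Nyquist frequency.
#' @param order Filter order (default 4).
#' @return A smoothed `trace_series` of the same length.
#' @export
lowpass_smooth <- function(trace, cutoff = 0.02, order = 4) {
  stopifnot(inherits(trace, "trace_series"))
  fs <- trace$frame_rate
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop(sprintf("`cutoff` must lie in (0, Nyquist = %g Hz)", fs / 2))
  }
  x <- trace$values
  if (anyNA(x)) stop("trace contains missing values; interpolate before smoothing")
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd (point-symmetric) reflection absorbs trends at the record ends
  p <- min(n - 1, ceiling(10 * fs / cutoff))
  if (p > 0) {
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  } else {
    xp <- x
  }
  y <- .filter_steady(bf, xp)                 # forward
  y <- rev(.filter_steady(bf, rev(y)))        # backward: zero phase
  trace$values <- y[(p + 1):(p + n)]
  trace$label <- sprintf("%s (lowpass %g Hz, order %d)", trace$label, cutoff, order)
  trace
}

#' Correct the substrate-decay envelope
#'
#' Divides each frame elementwise by the corresponding value of the smoothed
#' masked-mean trace, flattening the slow rise-and-decay of global
#' bioluminescence so that stimulus-locked modulations survive as fractional
#' fluctuations around 1 inside the mask.
#'
#' @param video A dark-subtracted [video_stack()].
#' @param smoothed A `trace_series` from [lowpass_smooth()], same length as
#'   the video; must be strictly positive.
#' @return A decay-corrected [video_stack()] of unit scale.
#' @export
decay_correct <- function(video, smoothed) {
  stopifnot(inherits(video, "video_stack"), inherits(smoothed, "trace_series"))
  d <- dim(video$data)
  s <- smoothed$values
  if (length(s) != d[3]) stop("smoothed trace length differs from frame count")
  bad <- which(!is.finite(s) | s <= 0)
  if (length(bad)) {
    stop(sprintf("smoothed trace is nonpositive or missing at frame %d (t = %.2f s)",
                 bad[1], video$t0 + (bad[1] - 1) / video$frame_rate))
  }
  m <- video$data
  # divide each frame by its smoothed value: recycle 1/s across pixels
  m <- m * rep(1 / s, each = d[1] * d[2])
  dim(m) <- d
  video$data <- m
  video
}

#' Split a recording into stimulus-locked trials
#'
#' Cuts the video into windows of `span` seconds starting `pre_window`
#' seconds before each stimulus onset (half-open `[start, start + span)`),
#' mapping times to frames by nearest-frame rounding. Trials that would
#' start before the recording or run past its end are dropped; the dropped
#' count is reported via a message and stored in the result.
#'
#' With the standard design (5 Hz, `pre_window = 2`, `span = 20`) each trial
#' has 100 frames and the stimulus onset falls at trial frame 11 (1-based;
#' trial time axis value 0 s).
#'
#' @param video A [video_stack()] (typically decay-corrected).
#' @param schedule A [stimulus_schedule()].
#' @param pre_window Seconds of pre-stimulus baseline included (>= 0,
#'   `< span`).
#' @param span Trial length in seconds (default: the cycle length).
#' @return An object of class `trial_tensor`: list with `data`
#'   (`rows x cols x time x trials` array), `times` (trial time axis in
#'   seconds relative to stimulus onset), `pre_window`, `span`,
#'   `frame_rate`, `trial_onsets` (retained onsets) and `n_dropped`.
#' @export
epoch_trials <- function(video, schedule, pre_window = 2,
                         span = schedule$cycle_length) {
  stopifnot(inherits(video, "video_stack"), inherits(schedule, "stim_schedule"))
  if (pre_window < 0 || pre_window >= span) {
    stop("need 0 <= pre_window < span")
  }
  d <- dim(video$data)
  fs <- video$frame_rate
  n_t <- round(span * fs)
  starts <- round((schedule$onsets - pre_window - video$t0) * fs) + 1L
  ok <- starts >= 1L & (starts + n_t - 1L) <= d[3]
  n_drop <- sum(!ok)
  if (!any(ok)) stop("no trial fits inside the recording")
  if (n_drop > 0) {
    message(sprintf("epoch_trials: dropped %d of %d trials outside the recording",
                    n_drop, length(ok)))
  }
  starts <- starts[ok]
  tens <- array(NA_real_, c(d[1], d[2], n_t, length(starts)))
  for (i in seq_along(starts)) {
    tens[, , , i] <- video$data[, , starts[i]:(starts[i] + n_t - 1L)]
  }
  structure(
    list(data = tens,
         times = (seq_len(n_t) - 1) / fs - pre_window,
         pre_window = pre_window, span = span, frame_rate = fs,
         trial_onsets = schedule$onsets[ok], n_dropped = n_drop),
    class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Trial tensor: %d trials x %d frames (%g s, %g s pre-stimulus), %d x %d px\n",
    d[4], d[3], x$span, x$pre_window, d[1], d[2]))
  if (x$n_dropped > 0) cat(sprintf("  %d trials dropped at epoching\n", x$n_dropped))
  invisible(x)
}

#' Normalize each trial to its own baseline
#'
#' Divides every pixel of every trial by that pixel's mean over the first
#' `baseline` seconds of the trial, converting intensities to L/L0 ratios
#' (delta-L/L0 = ratio - 1). After normalization the baseline-window mean of
#' every pixel is 1. Pixels whose baseline mean is zero, negative or missing
#' are set entirely to `NA` for that trial, with a warning giving the count.
#'
#' @param trials A `trial_tensor` from [epoch_trials()].
#' @param baseline Baseline window length in seconds, measured from the
#'   trial start; must not exceed `pre_window` so the baseline is fully
#'   pre-stimulus. Default 1.
#' @return A `trial_tensor` of L/L0 ratios, with `$normalized = TRUE` and
#'   `$baseline` recorded.
#' @export
normalize_trials <- function(trials, baseline = 1) {
  stopifnot(inherits(trials, "trial_tensor"))
  if (baseline <= 0 || baseline > trials$pre_window) {
    stop("need 0 < baseline <= pre_window")
  }
  d <- dim(trials$data)
  nb <- round(baseline * trials$frame_rate)
  if (nb < 1) stop("baseline window shorter than one frame")
  npx <- d[1] * d[2]
  m <- trials$data
  dim(m) <- c(npx, d[3], d[4])
  n_bad <- 0L
  for (i in seq_len(d[4])) {
    b <- rowMeans(m[, seq_len(nb), i, drop = FALSE], na.rm = TRUE)
    bad <- !is.finite(b) | b <= 0
    n_bad <- n_bad + sum(bad)
    b[bad] <- NA_real_
    m[, , i] <- m[, , i] / b  # recycles b down each column (per pixel)
  }
  if (n_bad > 0) {
    warning(sprintf(
      "normalize_trials: %d pixel-trials had nonpositive or missing baseline means and were set to NA",
      n_bad))
  }
  dim(m) <- d
  trials$data <- m
  trials$normalized <- TRUE
  trials$baseline <- baseline
  trials
}

#' Average trials into a response movie
#'
#' Pointwise mean of the first `n_first` trials (missing values ignored),
#' yielding the trial-averaged L/L0 movie. The default follows the standard
#' protocol of averaging the first 20 trials; pass `n_first = "all"` to use
#' every trial.
#'
#' @param trials A normalized `trial_tensor`.
#' @param n_first Number of leading trials to average (default 20), or
#'   `"all"`.
#' @return An object of class `trial_movie`: list with `data`
#'   (`rows x cols x time` array of L/L0 ratios; delta-L/L0 = data - 1),
#'   `times`, `frame_rate`, `pre_window` and `n_trials_averaged`.
#' @export
average_trials <- function(trials, n_first = 20) {
  stopifnot(inherits(trials, "trial_tensor"))
  d <- dim(trials$data)
  if (identical(n_first, "all")) n_first <- d[4]
  if (n_first < 1 || n_first != round(n_first)) {
    stop("`n_first` must be a positive integer or \"all\"")
  }
  if (n_first > d[4]) {
    stop(sprintf("requested the first %d trials but only %d are available",
                 n_first, d[4]))
  }
  sel <- trials$data[, , , seq_len(n_first), drop = FALSE]
  avg <- rowMeans(sel, dims = 3, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  structure(
    list(data = avg, times = trials$times, frame_rate = trials$frame_rate,
         pre_window = trials$pre_window,
         n_trials_averaged = as.integer(n_first)),
    class = "trial_movie")
}

#' Temporally integrate a window of frames
#'
#' Per-pixel sum of the (dark-subtracted) frames whose acquisition times lie
#' in `[t_start, t_end]`, e.g. to form a minutes-long integrated luminescent
#' image from video-rate frames.
#'
#' @param video A [video_stack()].
#' @param t_start,t_end Window bounds in seconds (inclusive).
#' @return A `rows x cols` matrix of summed intensities.
#' @export
integrate_frames <- function(video, t_start, t_end) {
  stopifnot(inherits(video, "video_stack"))
  if (t_start >= t_end) stop("need t_start < t_end")
  tt <- frame_times(video)
  idx <- which(tt >= t_start & tt <= t_end)
  if (!length(idx)) stop("no frames fall inside the integration window")
  rowSums(video$data[, , idx, drop = FALSE], dims = 2)
}

#' Run the full trial-averaging chain
#'
#' Convenience wrapper: dark subtraction, head masking, masked mean trace,
#' Butterworth smoothing, decay correction, epoching, per-trial baseline
#' normalization and trial averaging, returning all intermediates.
#'
#' @param video A raw [video_stack()].
#' @param schedule A [stimulus_schedule()].
#' @param dark Dark level passed to [subtract_dark()] (0 to skip).
#' @param pre_window,span,baseline,n_first,cutoff,order Stage parameters;
#'   see the individual stage functions.
#' @param mask Optionally a precomputed `mask_image`; default recomputed
#'   with [compute_head_mask()].
#' @param keep_trials Keep the full per-trial tensor in the result (default
#'   `TRUE`); set `FALSE` to save memory when only the averaged movie is
#'   needed.
#' @return A list of class `bli_analysis` with `movie` (a `trial_movie`),
#'   `mask`, `trace_raw`, `trace_smooth`, `trials`, `n_dropped` and the
#'   parameter set used.
#' @export
bli_trial_average <- function(video, schedule, dark = 0,
                              pre_window = 2, span = schedule$cycle_length,
                              baseline = 1, n_first = 20,
                              cutoff = 0.02, order = 4, mask = NULL,
                              keep_trials = TRUE) {
  v <- if (is.matrix(dark) || dark != 0) subtract_dark(video, dark) else video
  if (is.null(mask)) mask <- compute_head_mask(v)
  d <- dim(v$data)
  fs <- v$frame_rate
  # pixels outside the mask never contribute downstream (they are missing by
  # construction), so all frame-level arithmetic runs on the foreground
  # submatrix only; results are scattered back into full frames at the end
  fg <- which(as.vector(mask$data))
  m <- v$data
  dim(m) <- c(d[1] * d[2], d[3])
  m <- m[fg, , drop = FALSE]

  vals <- colMeans(m, na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  trace <- structure(list(values = vals, frame_rate = fs, t0 = v$t0,
                          label = "masked mean"), class = "trace_series")
  if (anyNA(trace$values)) {
    ok <- which(!is.na(trace$values))
    trace$values <- stats::approx(ok, trace$values[ok],
                                  xout = seq_along(trace$values),
                                  rule = 2)$y
  }
  smooth <- lowpass_smooth(trace, cutoff = cutoff, order = order)
  s <- smooth$values
  bad <- which(!is.finite(s) | s <= 0)
  if (length(bad)) {
    stop(sprintf("smoothed trace is nonpositive or missing at frame %d (t = %.2f s)",
                 bad[1], v$t0 + (bad[1] - 1) / fs))
  }
  m <- m * rep(1 / s, each = length(fg))

  # epoch the foreground submatrix
  if (pre_window < 0 || pre_window >= span) stop("need 0 <= pre_window < span")
  n_t <- round(span * fs)
  starts <- round((schedule$onsets - pre_window - v$t0) * fs) + 1L
  ok_tr <- starts >= 1L & (starts + n_t - 1L) <= d[3]
  n_drop <- sum(!ok_tr)
  if (!any(ok_tr)) stop("no trial fits inside the recording")
  if (n_drop > 0) {
    message(sprintf("epoch_trials: dropped %d of %d trials outside the recording",
                    n_drop, length(ok_tr)))
  }
  starts <- starts[ok_tr]
  ntr <- length(starts)
  tens <- array(NA_real_, c(length(fg), n_t, ntr))
  for (i in seq_len(ntr)) {
    tens[, , i] <- m[, starts[i]:(starts[i] + n_t - 1L)]
  }

  # per-trial per-pixel baseline normalization
  if (baseline <= 0 || baseline > pre_window) stop("need 0 < baseline <= pre_window")
  nb <- round(baseline * fs)
  n_bad <- 0L
  for (i in seq_len(ntr)) {
    b <- rowMeans(tens[, seq_len(nb), i, drop = FALSE], na.rm = TRUE)
    badpx <- !is.finite(b) | b <= 0
    n_bad <- n_bad + sum(badpx)
    b[badpx] <- NA_real_
    tens[, , i] <- tens[, , i] / b
  }
  if (n_bad > 0) {
    warning(sprintf(
      "%d pixel-trials had nonpositive or missing baseline means and were set to NA",
      n_bad))
  }

  times <- (seq_len(n_t) - 1) / fs - pre_window
  trials <- NULL
  if (keep_trials) {
    full <- array(NA_real_, c(d[1] * d[2], n_t, ntr))
    full[fg, , ] <- tens
    dim(full) <- c(d[1], d[2], n_t, ntr)
    trials <- structure(
      list(data = full, times = times, pre_window = pre_window, span = span,
           frame_rate = fs, trial_onsets = schedule$onsets[ok_tr],
           n_dropped = n_drop, normalized = TRUE, baseline = baseline),
      class = "trial_tensor")
  }

  n_use <- if (identical(n_first, "all")) ntr else min(n_first, ntr)
  avg_fg <- rowMeans(tens[, , seq_len(n_use), drop = FALSE], dims = 2, na.rm = TRUE)
  avg_fg[is.nan(avg_fg)] <- NA_real_
  avg <- matrix(NA_real_, d[1] * d[2], n_t)
  avg[fg, ] <- avg_fg
  dim(avg) <- c(d[1], d[2], n_t)
  movie <- structure(
    list(data = avg, times = times, frame_rate = fs, pre_window = pre_window,
         n_trials_averaged = as.integer(n_use)),
    class = "trial_movie")

  structure(
    list(movie = movie, mask = mask, trace_raw = trace, trace_smooth = smooth,
         trials = trials, n_dropped = n_drop,
         params = list(pre_window = pre_window, span = span,
                       baseline = baseline, n_first = n_use,
                       cutoff = cutoff, order = order)),
    class = "bli_analysis")
}

#' @export
print.bli_analysis <- function(x, ...) {
  cat("Stimulus-locked BLI analysis\n")
  print(x$mask)
  d <- dim(x$trials$data)
  cat(sprintf("  %d trials retained (%d dropped), %d averaged\n",
              d[4], x$n_dropped, x$movie$n_trials_averaged))
  cat(sprintf("  movie: %d frames spanning [%g, %g] s around stimulus onset\n",
              length(x$movie$times), min(x$movie$times), max(x$movie$times)))
  invisible(x)
}
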