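#' EM-CCD camera model
#'
#' Acquisition and noise parameters of an electron-multiplying CCD. Photon
#' (photoelectron) counts are Poisson; electron multiplication applies a
#' gain `em_gain` and inflates the Poisson variance by the square of the
#' excess noise factor (sqrt(2) for a well-operated EM register); Gaussian
#' read noise is added after gain. Defaults follow a typical head-fixed BLI
#' acquisition: 200 ms exposure, 5 Hz frame rate, 4 x 4 binning.
#'
#' @param exposure Exposure time per frame, s.
#' @param frame_rate Frames per second; `frame_rate * exposure` must be <= 1.
#' @param binning On-chip binning factor (positive integer).
#' @param em_gain Electron-multiplying gain, counts per photoelectron (> 0).
#' @param read_noise_sd Read noise standard deviation, counts (>= 0).
#' @param excess_noise_factor Multiplicative-gain excess noise factor (>= 1
#'   in practice; >= 0 accepted, 1 = ideal photon counting).
#' @param dark_offset Camera bias/dark level added to every pixel, counts.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(exposure = 0.2, frame_rate = 5, binning = 4,
                         em_gain = 50, read_noise_sd = 10,
                         excess_noise_factor = sqrt(2), dark_offset = 100) {
  if (exposure <= 0 || frame_rate <= 0) {
    stop("`exposure` and `frame_rate` must be > 0")
  }
  if (frame_rate * exposure > 1 + 1e-12) {
    stop("`frame_rate * exposure` must be <= 1")
  }
  if (binning < 1 || binning != round(binning)) {
    stop("`binning` must be a positive integer")
  }
  if (em_gain <= 0) stop("`em_gain` must be > 0")
  if (read_noise_sd < 0 || excess_noise_factor < 0 || dark_offset < 0) {
    stop("noise parameters must be >= 0")
  }
  structure(list(exposure = exposure, frame_rate = frame_rate,
                 binning = as.integer(binning), em_gain = em_gain,
                 read_noise_sd = read_noise_sd,
                 excess_noise_factor = excess_noise_factor,
                 dark_offset = dark_offset),
            class = "camera_model")
}

# Draw EM-CCD counts for a matrix/vector of expected photoelectrons `lambda`.
# Scaled-Poisson model: counts = dark + G*F^2 * Pois(lambda/F^2) + N(0, read^2),
# giving mean dark + G*lambda and variance G^2 F^2 lambda + read^2.
.emccd_counts <- function(lambda, camera) {
  f2 <- camera$excess_noise_factor^2
  n <- length(lambda)
  if (f2 == 0) {
    sig <- camera$em_gain * lambda
  } else {
    sig <- camera$em_gain * f2 * stats::rpois(n, lambda / f2)
  }
  out <- camera$dark_offset + sig
  if (camera$read_noise_sd > 0) {
    out <- out + stats::rnorm(n, 0, camera$read_noise_sd)
  }
  out
}
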