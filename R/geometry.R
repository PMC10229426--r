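#' Head geometry for simulated BLI frames
#'
#' An elliptical luminous "head" region on a dark field: the emission
#' profile is 1 on a central elliptical plateau and falls off smoothly
#' (Gaussian in the elliptical radial coordinate) at the rim, emulating the
#' bright-head-on-black appearance of dorsal BLI video. Bilateral
#' stimulus-locked responses are applied uniformly inside the head.
#'
#' @param nrow,ncol Frame size in pixels (after binning).
#' @param center Ellipse center `c(row, col)`; defaults to the frame center.
#' @param semi_axes Ellipse semi-axes `c(row, col)` in pixels.
#' @param edge_sd Rim falloff scale in pixels (> 0); the profile drops to
#'   0.5 about `0.83 * edge_sd` px outside the ellipse.
#' @return An object of class `head_geometry` with the profile matrix
#'   (`$profile`, values in (0, 1]) and the true head mask
#'   (`$mask_true`, profile >= 0.5).
#' @export
head_geometry <- function(nrow = 64, ncol = 64,
                          center = c((nrow + 1) / 2, (ncol + 1) / 2),
                          semi_axes = c(22, 16), edge_sd = 1) {
  if (nrow < 4 || ncol < 4) stop("frame must be at least 4 x 4")
  if (any(semi_axes <= 0) || edge_sd <= 0) {
    stop("`semi_axes` and `edge_sd` must be > 0")
  }
  r <- matrix(seq_len(nrow), nrow, ncol)
  c_ <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  # elliptical radial coordinate: 1 on the ellipse boundary
  rho <- sqrt(((r - center[1]) / semi_axes[1])^2 +
              ((c_ - center[2]) / semi_axes[2])^2)
  # distance outside the ellipse, in px, approximated along the local radius
  scale_px <- mean(semi_axes)
  d_out <- pmax(rho - 1, 0) * scale_px  # matrix first: pmax keeps dim
  profile <- exp(-d_out^2 / (2 * edge_sd^2))
  mask_true <- profile >= 0.5
  if (!any(mask_true)) stop("head mask is empty; enlarge `semi_axes`")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 profile = profile, mask_true = mask_true),
            class = "head_geometry")
}
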