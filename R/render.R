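#' Pseudocolor a trial-averaged response movie
#'
#' Maps delta-L/L0 values through a diverging blue-white-red lookup table
#' clamped to `[vmin, vmax]` (defaults -0.3 and +0.3), then modulates the
#' color brightness pixelwise by the normalized luminescence intensity so
#' that dim regions stay dark. Missing values render black.
#'
#' @param movie A `trial_movie` (L/L0 ratios) from [average_trials()], or a
#'   plain `rows x cols x time` array of delta-L/L0 values.
#' @param vmin,vmax Color limits in delta-L/L0 (`vmin < vmax`).
#' @param luminance `NULL` (no modulation), a `rows x cols` image, or a
#'   per-frame `trace_series`/numeric vector; values are normalized to
#'   `[0, 1]` by their maximum before use.
#' @param n_colors Size of the lookup table.
#' @return A `rows x cols x 3 x time` array of RGB values in `[0, 1]`.
#' @export
render_pseudocolor <- function(movie, vmin = -0.3, vmax = 0.3,
                               luminance = NULL, n_colors = 256L) {
  if (vmin >= vmax) stop("need vmin < vmax")
  dl <- if (inherits(movie, "trial_movie")) movie$data - 1 else movie
  if (length(dim(dl)) != 3L) stop("`movie` must be a rows x cols x time array")
  d <- dim(dl)
  lut <- grDevices::colorRamp(c("blue", "white", "red"))(
    seq(0, 1, length.out = n_colors)) / 255
  idx <- (pmin(pmax(dl, vmin), vmax) - vmin) / (vmax - vmin)
  idx <- round(idx * (n_colors - 1)) + 1L
  na <- is.na(idx)
  idx[na] <- 1L

  lum <- NULL
  if (!is.null(luminance)) {
    if (inherits(luminance, "trace_series")) luminance <- luminance$values
    lmax <- max(luminance, na.rm = TRUE)
    if (lmax <= 0) stop("`luminance` must have a positive maximum")
    lum <- pmin(pmax(luminance / lmax, 0), 1)
  }

  out <- array(0, c(d[1], d[2], 3L, d[3]))
  for (ch in 1:3) {
    v <- lut[idx, ch]
    v[na] <- 0
    dim(v) <- d
    if (!is.null(lum)) {
      if (is.matrix(lum)) {
        v <- v * as.vector(lum)
      } else {
        v <- sweep(v, 3, lum[seq_len(d[3])], "*")
      }
    }
    out[, , ch, ] <- v
  }
  out
}
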