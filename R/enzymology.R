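#' Fit the Michaelis-Menten model to a substrate titration
#'
#' Nonlinear least-squares fit of `v = Vmax * S / (Km + S)` to
#' luminescence-versus-concentration data, e.g. a twofold dilution series of
#' substrate read against fixed enzyme. Replicate points are fit pooled, not
#' as means. The fit is unweighted by default; supply `weights` for weighted
#' least squares.
#'
#' The optimizer is seeded from the Lineweaver-Burk linearization
#' (`1/v = Km/Vmax * 1/S + 1/Vmax`) and restarted from 5 perturbed seeds;
#' the lowest-RSS solution is returned, making the fit deterministic for a
#' given data set.
#'
#' @param concentrations Substrate concentrations, uM (>= 0; at least 5
#'   distinct positive levels).
#' @param luminescence Measured luminescence (initial velocities), same
#'   length (>= 0).
#' @param weights Optional nonnegative weights for weighted least squares.
#' @return An object of class `mm_fit` with components `vmax`, `km`,
#'   `se_vmax`, `se_km`, `rss`, `df_residual`, `fitted`, `residuals` and
#'   `data`. Standard errors come from the asymptotic covariance of the
#'   least-squares fit.
#' @examples
#' s <- 15 / 2^(0:7)
#' v <- 100 * s / (5 + s)
#' fit <- fit_michaelis_menten(rep(s, 3), rep(v, 3))
#' coef(fit)
#' @export
fit_michaelis_menten <- function(concentrations, luminescence, weights = NULL) {
  s <- as.numeric(concentrations); v <- as.numeric(luminescence)
  if (length(s) != length(v)) stop("concentration and luminescence lengths differ")
  if (any(is.na(s)) || any(is.na(v))) stop("titration data must not contain NA")
  if (any(s < 0) || any(v < 0)) stop("concentrations and luminescence must be >= 0")
  lv <- length(unique(s[s > 0]))
  if (lv < 5) stop("need at least 5 distinct positive concentration levels")
  if (is.null(weights)) weights <- rep(1, length(s))
  if (any(weights < 0)) stop("weights must be >= 0")

  # Lineweaver-Burk seed on positive points
  pos <- s > 0 & v > 0
  lb <- stats::lm(I(1 / v[pos]) ~ I(1 / s[pos]))
  vmax0 <- unname(1 / stats::coef(lb)[1])
  km0 <- unname(stats::coef(lb)[2]) * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(s[pos])

  dat <- data.frame(s = s, v = v)
  # 5 multistarts: the Lineweaver-Burk seed plus perturbed copies
  seeds <- cbind(vmax0 * c(1, 0.5, 2, 1, 2),
                 km0 * c(1, 2, 0.5, 3, 1))
  best <- NULL
  for (i in seq_len(nrow(seeds))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = dat,
                        start = list(vmax = seeds[i, 1], km = seeds[i, 2]),
                        weights = weights,
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("Michaelis-Menten fit failed to converge from all starts; ",
         "check that velocities increase and saturate with concentration")
  }
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  if (cf["km"] > 4 * max(s)) {
    warning("Km estimate lies far above the highest concentration tested; ",
            "the design does not bracket Km")
  } else if (cf["km"] < min(s[s > 0]) / 4) {
    warning("Km estimate lies far below the lowest concentration tested")
  }
  structure(
    list(vmax = unname(cf["vmax"]), km = unname(cf["km"]),
         se_vmax = unname(se["vmax"]), se_km = unname(se["km"]),
         rss = best$rss, df_residual = length(v) - 2L,
         fitted = as.numeric(stats::fitted(fit)),
         residuals = as.numeric(stats::residuals(fit)),
         data = dat, weights = weights),
    class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  Vmax = %.6g +/- %.3g\n  Km   = %.6g +/- %.3g uM\n",
              x$vmax, x$se_vmax, x$km, x$se_km))
  cat(sprintf("  RSS = %.4g on %d residual df (%d points)\n",
              x$rss, x$df_residual, nrow(x$data)))
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  out <- data.frame(estimate = c(object$vmax, object$km),
                    std_error = c(object$se_vmax, object$se_km),
                    row.names = c("vmax", "km"))
  cat("Michaelis-Menten nonlinear least-squares fit\n\n")
  print(out)
  cat(sprintf("\nResidual sum of squares: %.6g (df = %d)\n",
              object$rss, object$df_residual))
  invisible(out)
}

#' @export
coef.mm_fit <- function(object, ...) c(vmax = object$vmax, km = object$km)

#' @export
fitted.mm_fit <- function(object, ...) object$fitted

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$s else {
    if (is.list(newdata)) newdata$s else as.numeric(newdata)
  }
  object$vmax * s / (object$km + s)
}

#' Relative turnover number from two matched fits
#'
#' At matched enzyme concentration, `kcat` ratios equal `Vmax` ratios, so
#' two titrations of the same enzyme against different substrates yield the
#' relative kcat directly as `vmax_a / vmax_b`. The standard error is
#' propagated to first order:
#' `se = ratio * sqrt((se_a/vmax_a)^2 + (se_b/vmax_b)^2)`.
#'
#' @param fit_a,fit_b `mm_fit` objects from the same enzyme preparation.
#' @param enzyme_conc_equal Assertion that both titrations used the same
#'   enzyme concentration; must be `TRUE` or the ratio is not a kcat ratio.
#' @return A list with `ratio` and `se`.
#' @export
relative_kcat <- function(fit_a, fit_b, enzyme_conc_equal = TRUE) {
  stopifnot(inherits(fit_a, "mm_fit"), inherits(fit_b, "mm_fit"))
  if (!isTRUE(enzyme_conc_equal)) {
    stop("relative kcat is undefined unless both titrations used the same ",
         "enzyme concentration (`enzyme_conc_equal` must be TRUE)")
  }
  ratio <- fit_a$vmax / fit_b$vmax
  se <- ratio * sqrt((fit_a$se_vmax / fit_a$vmax)^2 +
                     (fit_b$se_vmax / fit_b$vmax)^2)
  list(ratio = ratio, se = se)
}

#' Simulate a substrate titration
#'
#' Generates luminescence readings from the Michaelis-Menten model with
#' multiplicative lognormal-free Gaussian noise, for testing fit recovery.
#' The default design mirrors a twofold dilution series with top
#' concentration 15 uM and 3 technical replicates.
#'
#' @param vmax,km True parameters.
#' @param concentrations Concentration levels, uM.
#' @param n_rep Technical replicates per level.
#' @param noise_cv Multiplicative noise coefficient of variation (0 for
#'   noiseless data).
#' @param seed Optional RNG seed.
#' @return A data.frame with `concentration_uM`, `luminescence`,
#'   `replicate`.
#' @export
simulate_titration <- function(vmax = 100, km = 5,
                               concentrations = 15 / 2^(0:7),
                               n_rep = 3, noise_cv = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  s <- rep(concentrations, each = n_rep)
  mu <- vmax * s / (km + s)
  v <- if (noise_cv > 0) mu * (1 + stats::rnorm(length(mu), 0, noise_cv)) else mu
  v[v < 0] <- 0
  data.frame(concentration_uM = s, luminescence = v,
             replicate = rep(seq_len(n_rep), times = length(concentrations)))
}

#' Read a titration CSV
#'
#' Expects columns `concentration_uM`, `luminescence` and optionally
#' `replicate`.
#'
#' @param path CSV path.
#' @return A data.frame suitable for [fit_michaelis_menten()].
#' @examples
#' d <- read_titration_csv(system.file("extdata", "synthetic_titration.csv",
#'                                     package = "bliq"))
#' fit_michaelis_menten(d$concentration_uM, d$luminescence)
#' @export
read_titration_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("concentration_uM", "luminescence")
  if (!all(need %in% names(tab))) {
    stop("titration CSV must have columns ", paste(need, collapse = ", "))
  }
  tab
}

#' Fit a one-site binding curve
#'
#' Least-squares fit of `y = y0 + (ymax - y0) * c / (c + kd)` to a response
#' measured across ligand concentrations, e.g. the brightness of a calcium
#' indicator titrated with calcium. Returns the dissociation constant `kd`
#' (same units as `conc`), the apo response `y0` and the saturating
#' response `ymax`.
#'
#' @param conc Ligand concentrations (>= 0, at least 4 distinct levels).
#' @param response Measured responses, same length.
#' @return An object of class `binding_fit` with `kd`, `y0`, `ymax`, their
#'   standard errors, `rss`, `fitted` and `data`. `coef()`, `print()` and
#'   `predict()` methods are provided.
#' @examples
#' ca <- 10^seq(0, 4, length.out = 12)
#' y <- calcium_to_brightness(ca, calcium_indicator())
#' fit_one_site_binding(ca, y)  # recovers kd = 110 nM
#' @export
fit_one_site_binding <- function(conc, response) {
  conc <- as.numeric(conc); response <- as.numeric(response)
  if (length(conc) != length(response)) stop("input lengths differ")
  if (any(is.na(conc)) || any(is.na(response))) stop("inputs must not contain NA")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (length(unique(conc)) < 4) stop("need at least 4 distinct concentrations")
  y0_0 <- min(response); ymax_0 <- max(response)
  if (ymax_0 <= y0_0 ||
      stats::cor(conc, response, method = "spearman") <= 0) {
    stop("response does not increase with concentration")
  }
  half <- y0_0 + (ymax_0 - y0_0) / 2
  kd0 <- stats::approx(response, conc, xout = half, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
  dat <- data.frame(c = conc, y = response)
  fit <- minpack.lm::nlsLM(y ~ y0 + (ymax - y0) * c / (c + kd), data = dat,
                           start = list(y0 = y0_0, ymax = ymax_0, kd = kd0),
                           lower = c(-Inf, -Inf, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3), names(cf)))
  structure(
    list(kd = unname(cf["kd"]), y0 = unname(cf["y0"]), ymax = unname(cf["ymax"]),
         se_kd = unname(se["kd"]), se_y0 = unname(se["y0"]),
         se_ymax = unname(se["ymax"]),
         rss = sum(stats::residuals(fit)^2),
         fitted = as.numeric(stats::fitted(fit)), data = dat),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("One-site binding fit\n")
  cat(sprintf("  Kd   = %.6g +/- %.3g\n  y0   = %.6g\n  ymax = %.6g\n",
              x$kd, x$se_kd, x$y0, x$ymax))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kd = object$kd, y0 = object$y0, ymax = object$ymax)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$data$c else {
    if (is.list(newdata)) newdata$c else as.numeric(newdata)
  }
  object$y0 + (object$ymax - object$y0) * cc / (cc + object$kd)
}

#' Peak-normalize an emission spectrum
#'
#' Divides intensities by the spectrum maximum so the peak equals 1;
#' wavelengths are unchanged. Idempotent.
#'
#' @param wavelengths Wavelengths in nm, increasing.
#' @param intensities Nonnegative intensities, same length, with a positive
#'   maximum.
#' @return A data.frame with `wavelength_nm` and normalized `intensity`.
#' @export
normalize_emission_spectrum <- function(wavelengths, intensities) {
  if (length(wavelengths) != length(intensities)) stop("input lengths differ")
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  pk <- max(intensities, na.rm = TRUE)
  if (!is.finite(pk) || pk <= 0) stop("spectrum has no positive peak")
  data.frame(wavelength_nm = wavelengths, intensity = intensities / pk)
}
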