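test_that("noiseless titrations recover Vmax and Km to 6 significant digits", {
  d <- simulate_titration(100, 5, noise_cv = 0)
  fit <- fit_michaelis_menten(d$concentration_uM, d$luminescence)
  expect_lt(abs(fit$vmax - 100) / 100, 5e-7)
  expect_lt(abs(fit$km - 5) / 5, 5e-7)
  # twofold dilution series from 15 uM top is a valid design
  expect_equal(sort(unique(d$concentration_uM), decreasing = TRUE)[1], 15)
  expect_equal(nrow(d), 8 * 3)
})

test_that("fitted RSS beats every point of a parameter grid around the optimum", {
  set.seed(12)
  d <- simulate_titration(80, 3, noise_cv = 0.08, n_rep = 3)
  fit <- suppressWarnings(
    fit_michaelis_menten(d$concentration_uM, d$luminescence))
  s <- d$concentration_uM; v <- d$luminescence
  grid_v <- seq(0.7 * fit$vmax, 1.3 * fit$vmax, length.out = 200)
  grid_k <- seq(0.5 * fit$km, 2 * fit$km, length.out = 200)
  rss <- outer(grid_v, grid_k, function(vm, km) {
    vapply(seq_along(vm), function(i) {
      sum((v - vm[i] * s / (km[i] + s))^2)
    }, numeric(1))
  })
  expect_lte(fit$rss, min(rss) + 1e-9)
})

test_that("luminescence rescaling scales Vmax and leaves Km untouched", {
  d <- simulate_titration(100, 5, noise_cv = 0)
  f1 <- fit_michaelis_menten(d$concentration_uM, d$luminescence)
  f2 <- fit_michaelis_menten(d$concentration_uM, d$luminescence * 37)
  expect_equal(f2$vmax / f1$vmax, 37, tolerance = 1e-8)
  expect_equal(f2$km, f1$km, tolerance = 1e-8)
})

test_that("model methods expose coefficients, predictions and residuals", {
  d <- simulate_titration(100, 5, noise_cv = 0)
  fit <- fit_michaelis_menten(d$concentration_uM, d$luminescence)
  expect_named(coef(fit), c("vmax", "km"))
  expect_equal(predict(fit, newdata = list(s = 5)),
               coef(fit)[["vmax"]] / 2, tolerance = 1e-6)
  expect_equal(fitted(fit) + residuals(fit), d$luminescence, tolerance = 1e-9)
  expect_output(print(fit), "Vmax")
})

test_that("relative kcat is the Vmax ratio with propagated uncertainty", {
  d1 <- simulate_titration(133, 4, noise_cv = 0)
  d2 <- simulate_titration(100, 2.5, noise_cv = 0)
  fa <- fit_michaelis_menten(d1$concentration_uM, d1$luminescence)
  fb <- fit_michaelis_menten(d2$concentration_uM, d2$luminescence)
  rk <- relative_kcat(fa, fb)
  expect_equal(rk$ratio, 1.33, tolerance = 1e-6)
  expect_equal(relative_kcat(fa, fa)$ratio, 1)
  expect_error(relative_kcat(fa, fb, enzyme_conc_equal = FALSE),
               "same.*enzyme concentration")
})

test_that("the propagated ratio SE matches a parametric bootstrap", {
  set.seed(8)
  d1 <- simulate_titration(133, 4, noise_cv = 0.05)
  d2 <- simulate_titration(100, 2.5, noise_cv = 0.05)
  fa <- fit_michaelis_menten(d1$concentration_uM, d1$luminescence)
  fb <- fit_michaelis_menten(d2$concentration_uM, d2$luminescence)
  rk <- relative_kcat(fa, fb)

  # bootstrap oracle: resimulate from each fitted curve with the residual
  # noise level and refit (single-start nls, independent of the package path)
  one_vmax <- function(fit) {
    s <- fit$data$s
    mu <- fit$vmax * s / (fit$km + s)
    sdres <- sqrt(fit$rss / fit$df_residual)
    v <- mu + stats::rnorm(length(mu), 0, sdres)
    cf <- tryCatch(stats::coef(minpack.lm::nlsLM(
      v ~ vm * s / (km + s), data = data.frame(s = s, v = v),
      start = list(vm = fit$vmax, km = fit$km), lower = c(1e-12, 1e-12))),
      error = function(e) c(vm = NA_real_, km = NA_real_))
    unname(cf["vm"])
  }
  ratios <- replicate(2000, one_vmax(fa) / one_vmax(fb))
  boot_se <- stats::sd(ratios, na.rm = TRUE)
  expect_lt(abs(rk$se / boot_se - 1), 0.10)
})

test_that("noisy titrations recover Km with small median relative error", {
  set.seed(20)
  errs <- replicate(100, {
    d <- simulate_titration(100, 5, noise_cv = 0.05, n_rep = 3)
    f <- suppressWarnings(fit_michaelis_menten(d$concentration_uM, d$luminescence))
    abs(f$km - 5) / 5
  })
  expect_lte(stats::median(errs), 0.10)
})

test_that("degenerate titrations are rejected", {
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(1, 2, 3)), "lengths differ|5 distinct")
  expect_error(fit_michaelis_menten(rep(c(1, 2, 3, 4), 2), rep(1, 8)),
               "5 distinct")
  expect_error(fit_michaelis_menten(15 / 2^(0:7), -(1:8)), ">= 0")
})

test_that("one-site binding fits recover the dissociation constant", {
  ca <- 10^seq(0, 4, length.out = 12)
  m <- calcium_indicator(kd = 110, dynamic_range = 8)
  fit <- fit_one_site_binding(ca, calcium_to_brightness(ca, m))
  expect_equal(fit$kd, 110, tolerance = 1e-6)
  expect_equal(fit$y0, 1, tolerance = 1e-6)
  expect_equal(fit$ymax, 8, tolerance = 1e-6)
  expect_named(coef(fit), c("kd", "y0", "ymax"))
  expect_error(fit_one_site_binding(ca, rev(calcium_to_brightness(ca, m))),
               "does not increase")
})

test_that("emission spectra normalize to unit peak, idempotently", {
  wl <- seq(400, 750, by = 5)
  inten <- 5000 * exp(-((wl - 589) / 40)^2)
  sp <- normalize_emission_spectrum(wl, inten)
  expect_equal(max(sp$intensity), 1)
  expect_equal(sp$wavelength_nm[which.max(sp$intensity)], 589, tolerance = 2.5)
  # idempotence
  sp2 <- normalize_emission_spectrum(sp$wavelength_nm, sp$intensity)
  expect_equal(sp2$intensity, sp$intensity)
  # argmax preserved for random positive spectra
  set.seed(3)
  for (i in 1:5) {
    y <- stats::runif(length(wl), 0.1, 10)
    expect_equal(which.max(normalize_emission_spectrum(wl, y)$intensity),
                 which.max(y))
  }
  expect_error(normalize_emission_spectrum(wl, numeric(length(wl))),
               "positive peak")
  expect_error(normalize_emission_spectrum(rev(wl), inten), "increasing")
})

test_that("titration CSVs load with the expected columns", {
  d <- read_titration_csv(system.file("extdata", "synthetic_titration.csv",
                                      package = "bliq"))
  expect_true(all(c("concentration_uM", "luminescence") %in% names(d)))
  expect_equal(nrow(d), 24)
  fit <- suppressWarnings(fit_michaelis_menten(d$concentration_uM, d$luminescence))
  # generated from vmax 120, km 3.5 with 4% noise; recovery within ~15%
  expect_lt(abs(fit$km - 3.5) / 3.5, 0.15)
  expect_lt(abs(fit$vmax - 120) / 120, 0.1)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_titration_csv(bad), "concentration_uM")
})
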