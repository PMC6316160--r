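test_that("LSPR peak detection finds the band and refines the apex", {
  uv <- simulate_uvvis_spectrum(2e-4, noise_sd = 0)
  pk <- find_lspr_peak(uv)
  expect_equal(pk$lambda_max, 526, tolerance = 1 / 526)
  expect_false(pk$edge)

  # symmetric triangular peak: exact apex
  wl <- 400:700
  tri <- tibble::tibble(wavelength = wl,
                        absorbance = pmax(0, 1 - abs(wl - 550) / 40) + 0.1)
  expect_equal(find_lspr_peak(tri)$lambda_max, 550, tolerance = 1e-6)

  # window contract: out-of-window maximum is ignored
  two <- tibble::tibble(
    wavelength = 300:800,
    absorbance = exp(-((300:800) - 520)^2 / 200) +
      5 * exp(-((300:800) - 750)^2 / 200))
  expect_equal(find_lspr_peak(two, c(400, 700))$lambda_max, 520,
               tolerance = 1e-3)

  # maximum on the window edge raises the truncation warning
  ramp <- tibble::tibble(wavelength = 300:800,
                         absorbance = seq(0, 1, length.out = 501))
  expect_warning(pe <- find_lspr_peak(ramp, c(400, 700)),
                 class = "sersuptake_edge_warning")
  expect_true(pe$edge)
})

test_that("through-origin Beer-Lambert fit recovers exact and noisy series", {
  fit <- fit_beer_lambert(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  # synthetic dilution series with 0.1% noise keeps R^2 >= 0.999
  conc <- seq(2e-5, 2e-4, length.out = 6)
  a <- withr::with_seed(7, sapply(conc, function(c0) {
    sp <- simulate_uvvis_spectrum(c0, noise_sd = 0.001 * c0 * 4000)
    find_lspr_peak(sp)$a_max
  }))
  noisy <- fit_beer_lambert(conc, a)
  expect_gte(noisy$r_squared, 0.999)

  expect_error(fit_beer_lambert(c(0, 0), c(0, 1)),
               class = "sersuptake_fit_error")
  expect_error(fit_beer_lambert(c(1e-4, 1e-4), c(0.4, 0.41)),
               class = "sersuptake_fit_error")
})

test_that("concentration estimation inverts the calibration", {
  fit <- fit_beer_lambert(c(1e-5, 1e-4), c(1e-5, 1e-4) * 4000)
  expect_equal(estimate_concentration(0, fit), 0)
  # round trip at c
  c0 <- 7.3e-5
  a0 <- find_lspr_peak(simulate_uvvis_spectrum(c0, noise_sd = 0))$a_max
  conc_series <- seq(2e-5, 2e-4, length.out = 6)
  a_series <- sapply(conc_series, function(x)
    find_lspr_peak(simulate_uvvis_spectrum(x, noise_sd = 0))$a_max)
  fit2 <- fit_beer_lambert(conc_series, a_series)
  expect_equal(estimate_concentration(a0, fit2), c0, tolerance = 1e-10)
  # 1% absorbance noise on 6 standards keeps recovery within 3%
  err <- withr::with_seed(21, {
    a_noisy <- sapply(conc_series, function(x) {
      sp <- simulate_uvvis_spectrum(x, noise_sd = 0.01 * x * 4000)
      find_lspr_peak(sp)$a_max
    })
    fitn <- fit_beer_lambert(conc_series, a_noisy)
    abs(estimate_concentration(a0, fitn) - c0) / c0
  })
  expect_lt(err, 0.03)
  bad <- fit_beer_lambert(c(1, 2), c(-2, -4))
  expect_error(estimate_concentration(1, bad), class = "sersuptake_fit_error")
})

test_that("stability series flags flat and collapsing colloids correctly", {
  sp <- simulate_uvvis_spectrum(1e-4, noise_sd = 0)
  flat <- stability_series(list(sp, sp, sp), days = c(0, 10, 30), 1e-4)
  expect_true(is_stable(flat))
  expect_equal(length(unique(flat$normalized_absorbance)), 1)

  half <- simulate_uvvis_spectrum(0.5e-4, noise_sd = 0)
  unstable <- stability_series(list(sp, half), days = c(0, 30), 1e-4)
  expect_false(is_stable(unstable))

  # 30-day constant-signal series with 2% noise stays stable
  series <- withr::with_seed(5, lapply(seq(0, 30, by = 5), function(d)
    simulate_uvvis_spectrum(1e-4, noise_sd = 0.02 * 0.4)))
  st <- stability_series(series, days = seq(0, 30, by = 5), 1e-4)
  expect_true(is_stable(st))
})

test_that("aggregation index is near zero when monodisperse and grows with the shoulder", {
  base <- simulate_uvvis_spectrum(1e-4, noise_sd = 0)
  expect_lt(aggregation_index(base), 0.2)
  idx <- sapply(c(0, 0.1, 0.3, 0.6), function(s)
    aggregation_index(simulate_uvvis_spectrum(1e-4, shoulder = s,
                                              noise_sd = 0)))
  expect_true(all(diff(idx) > 0))
  flat <- tibble::tibble(wavelength = 300:800, absorbance = 0.5)
  expect_equal(suppressWarnings(aggregation_index(flat)), 1)
  narrow <- tibble::tibble(wavelength = 500:600, absorbance = 0.5)
  expect_error(aggregation_index(narrow), class = "sersuptake_window_error")
})

test_that("scale invariance: k x spectrum scales a_max, not lambda_max", {
  uv <- simulate_uvvis_spectrum(1e-4, noise_sd = 0)
  uvk <- dplyr::mutate(uv, absorbance = absorbance * 3)
  p1 <- find_lspr_peak(uv); p2 <- find_lspr_peak(uvk)
  expect_equal(p2$a_max, 3 * p1$a_max, tolerance = 1e-12)
  expect_equal(p2$lambda_max, p1$lambda_max)
})
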