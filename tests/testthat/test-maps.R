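test_that("band intensity removes linear baselines and normalizes exposure", {
  wn <- seq(1000, 1160, by = 2)
  ramp <- new_spectrum(wn, 5 + 0.3 * wn, exposure = 1)
  expect_equal(band_intensity(ramp, center = 1078), 0, tolerance = 1e-10)
  expect_equal(band_intensity(ramp, center = 1078, mode = "area"), 0,
               tolerance = 1e-10)

  # single pseudo-Voigt at 1078, amplitude a, zero baseline
  a <- 37
  bt <- tp_band_table()[tp_band_table()$sers_cm1 %in% 1078, ]
  bt$relative_amplitude <- 1
  one <- simulate_tp_spectrum("sers", scale = a, axis = wn, band_table = bt,
                              noise_sd = 0, exposure = 1)
  # a window wide relative to the band keeps the endpoint-baseline bias < 1%
  expect_equal(band_intensity(one, center = 1078, half_window = 40), a,
               tolerance = 0.01)
  # at the default +-20 cm^-1 window the Lorentzian tails cost a few percent
  expect_equal(band_intensity(one, center = 1078), a, tolerance = 0.05)

  # doubled exposure at fixed counts halves the rate
  half <- new_spectrum(wn, one$intensity, exposure = 2)
  expect_equal(band_intensity(half, center = 1078),
               band_intensity(one, center = 1078) / 2)

  expect_error(band_intensity(one, center = 1005),
               class = "sersuptake_window_error")
})

test_that("image reconstruction maps per-pixel band intensity", {
  spec <- tiny_map_spec(noise_sd = 0)
  cell <- simulate_cell_map("PC3", 2, spec, seed = 3)
  img <- reconstruct_image(cell$map, center = 1078, half_window = 20)
  expect_equal(nrow(img), spec$nx * spec$ny)
  # pixel with maximum truth load is the image maximum (noise-free)
  xs <- sort(unique(cell$map$x_um)); ys <- sort(unique(cell$map$y_um))
  top <- img[which.max(img$intensity), ]
  truth_top <- which(cell$truth$load_field == max(cell$truth$load_field),
                     arr.ind = TRUE)
  expect_equal(top$x_um, xs[truth_top[1, 2]])
  expect_equal(top$y_um, ys[truth_top[1, 1]])
  # reconstruction equals per-pixel band_intensity
  one_px <- dplyr::filter(cell$map, x_um == top$x_um, y_um == top$y_um)
  sp <- new_spectrum(one_px$wavenumber_cm1, one_px$intensity,
                     exposure_of(cell$map))
  expect_equal(top$intensity, band_intensity(sp, 1078, 20), tolerance = 1e-10)
})

test_that("PNT2 top-decile pixels sit inside the planted spots", {
  cell <- simulate_cell_map("PNT2", 2, seed = 41)
  img <- reconstruct_image(cell$map)
  thr <- stats::quantile(img$intensity, 0.9)
  xs <- sort(unique(cell$map$x_um)); ys <- sort(unique(cell$map$y_um))
  hot <- img[img$intensity > thr & img$intensity >
               0.2 * max(img$intensity), ]
  for (k in seq_len(nrow(hot))) {
    i <- match(hot$y_um[k], ys); j <- match(hot$x_um[k], xs)
    # within one pixel of a nonzero truth-load pixel (band tails bleed)
    nb <- cell$truth$load_field[max(1, i - 1):min(length(ys), i + 1),
                                max(1, j - 1):min(length(xs), j + 1)]
    expect_gt(max(nb), 0)
  }
})

test_that("sum spectra are additive over disjoint masks", {
  spec <- tiny_map_spec()
  cell <- simulate_cell_map("PC3", 2, spec, seed = 13)
  full <- matrix(TRUE, spec$ny, spec$nx)
  m1 <- full; m1[, 1:4] <- FALSE
  m2 <- full; m2[, 5:8] <- FALSE
  s_full <- sum_spectrum(cell$map, full)
  s1 <- sum_spectrum(cell$map, m1)
  s2 <- sum_spectrum(cell$map, m2)
  expect_equal(s1$intensity + s2$intensity, s_full$intensity,
               tolerance = 1e-12)
  # one-pixel mask returns that pixel's spectrum
  one <- matrix(FALSE, spec$ny, spec$nx); one[3, 4] <- TRUE
  s_one <- sum_spectrum(cell$map, one)
  xs <- sort(unique(cell$map$x_um)); ys <- sort(unique(cell$map$y_um))
  px <- dplyr::filter(cell$map, x_um == xs[4], y_um == ys[3])
  px <- dplyr::arrange(px, wavenumber_cm1)
  expect_equal(s_one$intensity, px$intensity)
  expect_error(sum_spectrum(cell$map, matrix(FALSE, spec$ny, spec$nx)),
               class = "sersuptake_mask_error")
  expect_error(sum_spectrum(cell$map, matrix(TRUE, 3, 3)),
               class = "sersuptake_mask_error")
})

test_that("I1078 recovers the generator truth and scales linearly", {
  cell <- simulate_cell_map("PC3", 2, seed = 17)
  r <- compute_i1078(cell$map, cell$mask)
  expect_equal(r$i1078, cell$truth$i1078, tolerance = 0.05)

  # blank map: statistic stays below 3x the noise floor of the sum spectrum
  spec0 <- tiny_map_spec(base_load = 0)
  blank <- simulate_cell_map("PNT2", 2, spec0, seed = 19)
  r0 <- compute_i1078(blank$map, blank$mask)
  noise_floor <- spec0$noise_sd * sqrt(sum(blank$mask)) / spec0$exposure
  expect_lt(r0$i1078, 3 * noise_floor * 2)

  # linearity in the load scale (noise-free)
  s1 <- tiny_map_spec(noise_sd = 0, load_cv = 0, axis_jitter = 0)
  s2 <- tiny_map_spec(noise_sd = 0, load_cv = 0, axis_jitter = 0,
                      base_load = 4)
  a <- simulate_cell_map("PC3", 2, s1, seed = 23)
  b <- simulate_cell_map("PC3", 2, s2, seed = 23)
  ra <- compute_i1078(a$map, a$mask)
  rb <- compute_i1078(b$map, b$mask)
  expect_equal(rb$i1078, 4 * ra$i1078, tolerance = 1e-6)
})

test_that("area-mode I1078 of the sum equals the sum of per-pixel areas", {
  spec <- tiny_map_spec(noise_sd = 0)
  cell <- simulate_cell_map("PC3", 2, spec, seed = 29)
  whole <- compute_i1078(cell$map, cell$mask, mode = "area")$i1078
  img <- reconstruct_image(cell$map, mode = "area")
  xs <- sort(unique(cell$map$x_um)); ys <- sort(unique(cell$map$y_um))
  idx <- cbind(match(img$y_um, ys), match(img$x_um, xs))
  per_pixel <- sum(img$intensity[cell$mask[idx]])
  expect_equal(whole, per_pixel, tolerance = 1e-9)
})

test_that("mask growth over blank pixels changes I1078 only within noise", {
  spec <- map_spec(nx = 14, ny = 14, cell_semi_axes = c(3, 3))
  cell <- simulate_cell_map("PC3", 2, spec, seed = 31)
  small <- compute_i1078(cell$map, cell$mask)$i1078
  big <- compute_i1078(cell$map, NULL)$i1078
  noise_floor <- spec$noise_sd * sqrt(14 * 14) / spec$exposure
  expect_lt(abs(big - small), 5 * noise_floor)
})

test_that("uptake summaries compute group statistics and percent excess", {
  res <- tibble::tibble(
    cell_id = as.character(1:6),
    cell_line = c("PC3", "PC3", "PC3", "PNT2", "PNT2", "PNT2"),
    time_h = 2,
    i1078 = c(3.5, 3.6, 3.7, 0.9, 1.0, 1.1))
  s <- summarize_uptake(res)
  expect_equal(s$contrasts$percent_excess, 260)
  g <- s$groups
  expect_equal(g$n_cells, c(3, 3))
  expect_equal(g$sem[g$cell_line == "PC3"], sd(c(3.5, 3.6, 3.7)) / sqrt(3))

  res$i1078[res$cell_line == "PC3"] <- c(10.4, 10.5, 10.6)
  expect_equal(summarize_uptake(res)$contrasts$percent_excess, 950)

  res$i1078 <- rep(2, 6)
  expect_equal(summarize_uptake(res)$contrasts$percent_excess, 0)

  solo <- res[res$cell_line == "PC3", ]
  expect_error(summarize_uptake(solo), class = "sersuptake_contrast_error")
  expect_equal(nrow(summarize_uptake(solo, contrast = FALSE)$contrasts), 0)
})

test_that("band shifts follow the reference table on synthetic pairs", {
  ra <- simulate_tp_spectrum("raman", scale = 50, noise_sd = 0)
  se <- simulate_tp_spectrum("sers", scale = 50, noise_sd = 0)
  tb <- band_shift_table(ra, se)
  cc <- tb[tb$raman_nominal == 1096, ]
  expect_equal(cc$shift, 1078 - 1096, tolerance = 0.03)
  expect_true(cc$sers_present)
  sh <- tb[tb$raman_nominal == 920, ]
  expect_false(sh$sers_present)
  expect_true(is.na(sh$sers_detected))
  # identical spectra in both roles -> zero shifts for present bands
  same <- band_shift_table(ra, ra)
  expect_true(all(abs(same$shift[same$sers_present]) < 1e-9))
})

test_that("point-spectrum averaging gives pointwise mean and sd", {
  wn <- seq(900, 1100, by = 4)
  s0 <- new_spectrum(wn, rep(0, length(wn)), 1)
  s2 <- new_spectrum(wn, rep(2, length(wn)), 1)
  av <- average_point_spectra(list(s0, s2))
  expect_true(all(av$mean$intensity == 1))
  expect_true(all(abs(av$sd$intensity - sqrt(2)) < 1e-12))
  same <- average_point_spectra(list(s2, s2, s2))
  expect_true(all(same$sd$intensity == 0))

  # 20 replicates at known noise sd recover sigma within 25%
  reps <- withr::with_seed(3, lapply(1:20, function(i)
    simulate_tp_spectrum("sers", scale = 10, noise_sd = 4, exposure = 1,
                         seed = 500 + i)))
  av2 <- average_point_spectra(reps)
  expect_equal(mean(av2$sd$intensity), 4, tolerance = 0.25)

  bad <- new_spectrum(wn + 1, rep(1, length(wn)), 1)
  expect_error(average_point_spectra(list(s0, bad)),
               class = "sersuptake_axis_error")
})
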