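test_that("binarization selects dark pixels; fixed mode matches a comparison", {
  img <- matrix(200, 20, 20)
  img[5:8, 5:8] <- 50
  bw <- binarize(img)
  expect_identical(bw, img == 50)
  t <- 120
  expect_identical(binarize(img, "fixed", t), img < t)
  expect_error(binarize(matrix(7, 4, 4)), class = "sersuptake_threshold_error")
})

test_that("foreground count on a synthetic frame matches the truth area", {
  spec <- particle_image_spec(n_particles = 60)
  g <- simulate_particle_image(spec, seed = 21)
  bw <- binarize(g$image)
  truth_area <- sum(pi * (g$truth$major_nm / 2) * (g$truth$minor_nm / 2)) /
    spec$pixel_size^2
  expect_equal(sum(bw), truth_area, tolerance = 0.05)
})

test_that("labeling is 8-connected and honors min_area and border exclusion", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE           # 9-px block
  m[5, 5] <- TRUE               # diagonal neighbour of the block
  m[8:9, 7:9] <- TRUE           # separate 6-px block
  regs <- label_regions(m, min_area = 1, exclude_border = FALSE)
  expect_equal(length(unique(regs$label)), 2)
  # diagonal pixel merged with the block
  lab_block <- regs$label[regs$x_px == 2 & regs$y_px == 2]
  expect_equal(regs$label[regs$x_px == 5 & regs$y_px == 5], lab_block)
  # min_area filtering
  regs2 <- label_regions(m, min_area = 7, exclude_border = FALSE)
  expect_equal(length(unique(regs2$label)), 1)
  # everything filtered out -> empty
  expect_equal(nrow(label_regions(m, min_area = 100)), 0)
  # border exclusion drops a region touching the frame
  m2 <- m
  m2[1, 1:3] <- TRUE
  m2[2, 1] <- TRUE
  regs3 <- label_regions(m2, min_area = 1, exclude_border = TRUE)
  expect_equal(length(unique(regs3$label)), 1)   # only the interior block left
})

test_that("region count on synthetic frames equals the ground truth", {
  for (s in c(31, 32)) {
    g <- simulate_particle_image(particle_image_spec(n_particles = 80),
                                 seed = s)
    regs <- label_regions(binarize(g$image))
    expect_equal(length(unique(regs$label)), 80)
  }
})

test_that("roundness matches the analytic value for disks and ellipses", {
  disk <- raster_ellipse_region(30)
  rec <- region_properties(disk, pixel_size = 1)
  expect_gt(rec$roundness, 0.95)
  expect_lt(rec$roundness, 1.05)
  # the pixel union of a rasterized disk fills ~97% of its convex hull
  expect_gt(rec$solidity, 0.95)
  expect_lte(rec$solidity, 1)
  expect_gt(rec$circularity, 0.9)

  # 2:1 ellipse: R -> b/a = 0.5 as resolution grows
  ell <- raster_ellipse_region(60, 30)
  rec2 <- region_properties(ell, pixel_size = 1)
  expect_equal(rec2$roundness, 0.5, tolerance = 0.03)
  expect_equal(rec2$aspect_ratio, 2, tolerance = 0.06)

  # 24 nm disk at 0.5 nm/px
  disk24 <- raster_ellipse_region(24)    # 24 px radius = 12 nm
  rec3 <- region_properties(disk24, pixel_size = 0.5)
  expect_equal(rec3$equivalent_diameter_nm, 24, tolerance = 0.02)
})

test_that("area and d_max agree with brute-force pixel enumeration", {
  shapes <- list(raster_ellipse_region(20),
                 raster_ellipse_region(25, 10),
                 raster_ellipse_region(14, 7))
  for (sh in shapes) {
    rec <- region_properties(sh, pixel_size = 1)
    # brute force: area by counting, d_max by max pairwise distance
    expect_equal(rec$area_px, nrow(sh))
    d_brute <- max(dist(cbind(sh$x_px, sh$y_px)))
    expect_equal(rec$feret_max_nm, d_brute, tolerance = 0.01)
  }
})

test_that("roundness decreases strictly with aspect ratio at fixed area", {
  rs <- sapply(c(1, 1.5, 2, 3, 4), function(k) {
    region_properties(raster_ellipse_region(30 * sqrt(k), 30 / sqrt(k)),
                      pixel_size = 1)$roundness
  })
  expect_true(all(diff(rs) < 0))
})

test_that("descriptors scale correctly with pixel size", {
  sh <- raster_ellipse_region(18)
  r1 <- region_properties(sh, pixel_size = 1)
  r2 <- region_properties(sh, pixel_size = 2.5)
  expect_equal(r2$area_nm2, r1$area_nm2 * 2.5^2)
  expect_equal(r2$feret_max_nm, r1$feret_max_nm * 2.5)
  expect_equal(r2$equivalent_diameter_nm, r1$equivalent_diameter_nm * 2.5)
  expect_equal(r2$roundness, r1$roundness)   # dimensionless
})

test_that("single-pixel regions are flagged degenerate without raising", {
  px <- tibble::tibble(label = 1L, x_px = 5L, y_px = 5L)
  rec <- region_properties(px, pixel_size = 1)
  expect_true(rec$degenerate)
  expect_true(is.finite(rec$roundness))
})

test_that("shape classification applies the roundness thresholds inclusively", {
  expect_equal(classify_shape(c(0.9, 0.5, 0.85, 0.6, 0.7)),
               c("sphere", "rod", "sphere", "rod", "intermediate"))
})

test_that("population statistics count shapes and bin diameters correctly", {
  recs <- tibble::tibble(
    roundness = c(0.9, 0.9, 0.5),
    equivalent_diameter_nm = c(22, 24, 26),
    feret_max_nm = c(23, 25, 40)
  )
  ps <- population_stats(recs)
  expect_equal(ps$fraction_spherical, 2 / 3)
  expect_equal(ps$fraction_rods, 1 / 3)
  expect_equal(sum(ps$histogram$count), 3)

  one <- population_stats(recs[1, ])
  d <- one$descriptors[one$descriptors$descriptor == "equivalent_diameter_nm", ]
  expect_equal(d$mean, d$median)
  expect_equal(d$min, d$max)
  expect_equal(d$sd, 0)
  expect_error(population_stats(recs[0, ]), class = "sersuptake_empty_error")
})

test_that("histogram FWHM matches the Gaussian closed form", {
  h <- gaussian_histogram(mean = 24.3, sd = 4.289, bw = 1)  # off-grid mean

  expect_equal(histogram_fwhm(h), 2.3548 * 4.289, tolerance = 1 / 10.1)
  # scale invariance
  h2 <- h; h2$count <- h2$count * 37
  expect_equal(histogram_fwhm(h2), histogram_fwhm(h))
  # single occupied bin -> one bin width
  h3 <- tibble::tibble(mid = 1:9, count = c(0, 0, 0, 0, 5, 0, 0, 0, 0))
  expect_equal(histogram_fwhm(h3), 1)
  # no crossing on one side -> named error
  h4 <- tibble::tibble(mid = 1:5, count = c(4, 4.5, 5, 2, 0))
  expect_error(histogram_fwhm(h4), class = "sersuptake_histogram_error")
})

test_that("ellipse-based major axis is available behind a flag", {
  ell <- raster_ellipse_region(40, 20)
  feret <- region_properties(ell, pixel_size = 1, major_axis = "feret")
  fit <- region_properties(ell, pixel_size = 1, major_axis = "ellipse")
  expect_equal(fit$feret_max_nm, 80, tolerance = 0.05)
  expect_equal(feret$feret_max_nm, 80, tolerance = 0.02)
})
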