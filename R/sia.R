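# Statistical image analysis of particle micrographs: binarization, 8-connected
# labeling, per-particle morphometry (roundness R = 4A/(pi * d_max^2)), shape
# classification and population statistics.

#' Binarize a particle micrograph
#'
#' Particles are dark objects on a bright background, so foreground pixels are
#' those *darker* than the threshold. With `method = "auto"` the threshold is
#' determined from the gray-level histogram by Otsu's inter-class-variance
#' criterion; `method = "fixed"` compares directly against `threshold`.
#'
#' @param image Numeric matrix of gray levels.
#' @param method `"auto"` (Otsu) or `"fixed"`.
#' @param threshold Gray-level cut for `method = "fixed"`.
#' @return Logical matrix; `TRUE` marks particle pixels.
#' @export
binarize <- function(image, method = c("auto", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.numeric(image))
  if (method == "fixed") {
    if (is.null(threshold)) {
      abort("`threshold` is required when `method = \"fixed\"`.",
            class = "sersuptake_threshold_error")
    }
    return(image < threshold)
  }
  rng <- range(image)
  if (diff(rng) == 0) {
    abort("Cannot auto-threshold a constant image: no threshold separates it.",
          class = "sersuptake_threshold_error")
  }
  scaled <- (image - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(scaled, range = c(0, 1), levels = 256)
  image < rng[1] + t01 * diff(rng)
}

#' Label connected particle regions
#'
#' 8-connected component labeling (two-pass union-find over row runs).
#' Regions smaller than `min_area` pixels are discarded, as are regions
#' touching the image border when `exclude_border = TRUE` (partial particles
#' bias the population statistics).
#'
#' @param binary Logical matrix from [binarize()].
#' @param min_area Minimum region area in pixels.
#' @param exclude_border Drop regions touching the frame edge.
#' @return A tibble with one row per retained pixel: `label`, `x_px` (column),
#'   `y_px` (row). Labels are consecutive integers from 1.
#' @export
label_regions <- function(binary, min_area = 9, exclude_border = TRUE) {
  stopifnot(is.matrix(binary), is.logical(binary))
  nr <- nrow(binary); nc <- ncol(binary)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  run_lab <- integer(0)
  prev_idx <- integer(0)
  for (r in seq_len(nr)) {
    row <- binary[r, ]
    if (!any(row)) { prev_idx <- integer(0); next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    cur_idx <- integer(0)
    for (k in which(keep)) {
      s <- starts[k]; e <- ends[k]
      lab <- NA_integer_
      # 8-connectivity: previous-row runs overlapping [s-1, e+1]
      for (p in prev_idx) {
        if (run_s[p] <= e + 1L && run_e[p] >= s - 1L) {
          root <- find_root(run_lab[p])
          if (is.na(lab)) {
            lab <- root
          } else if (root != lab) {
            parent[max(root, lab)] <- min(root, lab)
            lab <- min(root, lab)
          }
        }
      }
      if (is.na(lab)) {
        lab <- length(parent) + 1L
        parent[lab] <- lab
      }
      run_row <- c(run_row, r); run_s <- c(run_s, s); run_e <- c(run_e, e)
      run_lab <- c(run_lab, lab)
      cur_idx <- c(cur_idx, length(run_lab))
    }
    prev_idx <- cur_idx
  }
  if (length(run_lab) == 0L) {
    return(tibble(label = integer(0), x_px = integer(0), y_px = integer(0)))
  }
  roots <- vapply(run_lab, find_root, integer(1))
  px <- tibble(
    label = rep.int(roots, run_e - run_s + 1L),
    x_px = unlist(lapply(seq_along(run_s), function(i) run_s[i]:run_e[i])),
    y_px = rep.int(run_row, run_e - run_s + 1L)
  )
  if (exclude_border) {
    touching <- unique(px$label[px$x_px == 1L | px$x_px == nc |
                                  px$y_px == 1L | px$y_px == nr])
    px <- px[!px$label %in% touching, , drop = FALSE]
  }
  sizes <- table(px$label)
  keep_lab <- as.integer(names(sizes)[sizes >= min_area])
  px <- px[px$label %in% keep_lab, , drop = FALSE]
  px$label <- match(px$label, sort(unique(px$label)))
  arrange(px, .data$label, .data$y_px, .data$x_px)
}

#' Per-particle morphometric descriptors
#'
#' Computes the full particle record for each labeled region: area, perimeter,
#' centroid, circularity 4*pi*A/P^2, aspect ratio, roundness
#' R = 4*A/(pi * d_max^2) with d_max the maximum Feret (caliper) diameter,
#' solidity A / convex-hull area, Feret extrema and the equivalent (area-
#' preserving) disk diameter sqrt(4A/pi).
#'
#' d_max and the minimum Feret width are measured on the convex hull of pixel
#' centers (max pairwise distance and rotating-calipers width); perimeter and
#' hull area use the convex hull of pixel corner points so that solidity never
#' exceeds 1 on convex shapes. A single-pixel (or collinear) region is
#' returned with `degenerate = TRUE` rather than raising.
#'
#' @param regions Labeled pixel tibble from [label_regions()].
#' @param pixel_size Physical sampling, nm per pixel.
#' @param major_axis `"feret"` (default, literal caliper reading of the major
#'   axis) or `"ellipse"` (major axis of the moment-matched ellipse).
#' @return A tibble with one row per label: `label`, `area_px`, `area_nm2`,
#'   `perimeter_nm`, `centroid_x_px`, `centroid_y_px`, `circularity`,
#'   `aspect_ratio`, `roundness`, `solidity`, `feret_max_nm`, `feret_min_nm`,
#'   `equivalent_diameter_nm`, `degenerate`.
#' @export
region_properties <- function(regions, pixel_size = 1,
                              major_axis = c("feret", "ellipse")) {
  major_axis <- match.arg(major_axis)
  stopifnot(is.data.frame(regions), nrow(regions) > 0, pixel_size > 0)
  split_idx <- split(seq_len(nrow(regions)), regions$label)
  rows <- lapply(split_idx, function(ii) {
    x <- regions$x_px[ii]; y <- regions$y_px[ii]
    one_region_props(x, y, pixel_size, major_axis)
  })
  out <- bind_rows(rows)
  out$label <- as.integer(names(split_idx))
  select(out, "label", dplyr::everything())
}

one_region_props <- function(x, y, pixel_size, major_axis = "feret") {
  n <- length(x)
  area_px <- n
  cx <- mean(x); cy <- mean(y)

  # corner cloud = Minkowski sum of the center hull with the unit pixel square
  ch <- chull(x, y)
  hx <- x[ch]; hy <- y[ch]
  corn_x <- c(hx + 0.5, hx + 0.5, hx - 0.5, hx - 0.5)
  corn_y <- c(hy + 0.5, hy - 0.5, hy + 0.5, hy - 0.5)
  cc <- chull(corn_x, corn_y)
  px_hull <- cbind(corn_x[cc], corn_y[cc])
  hull_area <- polygon_area(px_hull)
  perim <- polygon_perimeter(px_hull)

  degenerate <- n < 3 || length(unique(hx)) * length(unique(hy)) == 1 ||
    polygon_area(cbind(hx, hy)) <= 0
  if (degenerate) {
    d_max <- max(max(dist2_all(hx, hy)), 1)
    f_min <- 1
  } else {
    d_max <- max(dist2_all(hx, hy))
    f_min <- max(min_caliper_width(cbind(hx, hy)), 1)
    if (major_axis == "ellipse") {
      d_max <- ellipse_major_axis(x, y)
    }
  }
  f_min <- min(f_min, d_max)

  roundness <- 4 * area_px / (pi * d_max^2)
  tibble(
    area_px = area_px,
    area_nm2 = area_px * pixel_size^2,
    perimeter_nm = perim * pixel_size,
    centroid_x_px = cx,
    centroid_y_px = cy,
    circularity = 4 * pi * area_px / perim^2,
    aspect_ratio = d_max / f_min,
    roundness = roundness,
    solidity = min(area_px / hull_area, 1),
    feret_max_nm = d_max * pixel_size,
    feret_min_nm = f_min * pixel_size,
    equivalent_diameter_nm = sqrt(4 * area_px / pi) * pixel_size,
    degenerate = degenerate
  )
}

dist2_all <- function(x, y) {
  if (length(x) == 1L) return(0)
  as.matrix(stats::dist(cbind(x, y)))
}

polygon_area <- function(p) {
  if (nrow(p) < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  if (nrow(p) < 2) return(0)
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

# Rotating calipers: minimum over hull edges of the maximum distance of any
# vertex from the edge's supporting line.
min_caliper_width <- function(hull) {
  m <- nrow(hull)
  widths <- vapply(seq_len(m), function(i) {
    a <- hull[i, ]; b <- hull[if (i == m) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nvec <- c(-e[2], e[1]) / len
    max(abs((hull[, 1] - a[1]) * nvec[1] + (hull[, 2] - a[2]) * nvec[2]))
  }, numeric(1))
  min(widths)
}

# Major axis of the second-moment matched ellipse (4 * sqrt(lambda_max) of the
# covariance of pixel centers, the convention used by imaging toolboxes).
ellipse_major_axis <- function(x, y) {
  cv <- stats::cov(cbind(x, y)) * (length(x) - 1) / length(x) +
    diag(1 / 12, 2)   # pixel-square second moment
  4 * sqrt(max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values))
}

#' Classify particle shape from roundness
#'
#' Spherical particles have roundness R >= 0.85 (boundary inclusive); rods
#' have R <= 0.6; anything between is `"intermediate"`.
#'
#' @param records Particle-record tibble with a `roundness` column (or a bare
#'   numeric vector of roundness values).
#' @return The tibble with a `shape_class` column appended (or a character
#'   vector for numeric input).
#' @export
classify_shape <- function(records) {
  cls <- function(r) {
    ifelse(r >= 0.85, "sphere", ifelse(r <= 0.6, "rod", "intermediate"))
  }
  if (is.numeric(records)) return(cls(records))
  stopifnot(is.data.frame(records), "roundness" %in% names(records))
  mutate(records, shape_class = cls(.data$roundness))
}

#' Population statistics of a particle set
#'
#' Mean, median, min, max and standard deviation of every morphometric
#' descriptor, the equivalent-diameter histogram and its FWHM, and the
#' spherical/rod population fractions from the roundness thresholds of
#' [classify_shape()].
#'
#' @param records Particle-record tibble from [region_properties()].
#' @param bin_width Histogram bin width on equivalent diameter, nm.
#' @return An object of class `"population_stats"`: a list with `descriptors`
#'   (tidy per-descriptor statistics), `histogram` (`bin_lo`, `bin_hi`, `mid`,
#'   `count`), `histogram_fwhm` (nm, `NA` if not measurable),
#'   `fraction_spherical`, `fraction_rods`, `mean_diameter` (nm, equivalent),
#'   `mean_feret_max` (nm) and `n_particles`.
#' @export
population_stats <- function(records, bin_width = 2) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must contain at least one particle.",
          class = "sersuptake_empty_error")
  }
  stopifnot(bin_width > 0)
  descriptors <- c("area_nm2", "perimeter_nm", "circularity", "aspect_ratio",
                   "roundness", "solidity", "feret_max_nm", "feret_min_nm",
                   "equivalent_diameter_nm")
  descriptors <- intersect(descriptors, names(records))
  desc <- purrr::map_dfr(descriptors, function(d) {
    v <- records[[d]]
    tibble(descriptor = d, mean = mean(v), median = median(v),
           min = min(v), max = max(v), sd = if (length(v) > 1) sd(v) else 0)
  })
  d <- records$equivalent_diameter_nm
  lo <- floor(min(d) / bin_width) * bin_width - bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- as.vector(table(cut(d, breaks = edges, right = FALSE)))
  hist_tb <- tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1),
                    mid = (head(edges, -1) + tail(edges, -1)) / 2,
                    count = counts)
  fwhm <- tryCatch(histogram_fwhm(hist_tb), error = function(e) NA_real_)
  structure(list(
    descriptors = desc,
    histogram = hist_tb,
    histogram_fwhm = fwhm,
    fraction_spherical = mean(records$roundness >= 0.85),
    fraction_rods = mean(records$roundness <= 0.6),
    mean_diameter = mean(d),
    mean_feret_max = if ("feret_max_nm" %in% names(records))
      mean(records$feret_max_nm) else NA_real_,
    n_particles = nrow(records)
  ), class = "population_stats")
}

#' @export
print.population_stats <- function(x, ...) {
  cat(sprintf(
    "Particle population: n = %d\n  mean equivalent diameter: %.2f nm (histogram FWHM %.2f nm)\n  spherical (R >= 0.85): %.1f%%   rods (R <= 0.6): %.1f%%\n",
    x$n_particles, x$mean_diameter, x$histogram_fwhm,
    100 * x$fraction_spherical, 100 * x$fraction_rods))
  invisible(x)
}

#' @rdname population_stats
#' @param x A `population_stats` object.
#' @param ... Unused.
#' @export
tidy.population_stats <- function(x, ...) x$descriptors

#' @rdname population_stats
#' @export
glance.population_stats <- function(x, ...) {
  tibble(n_particles = x$n_particles,
         mean_diameter_nm = x$mean_diameter,
         histogram_fwhm_nm = x$histogram_fwhm,
         fraction_spherical = x$fraction_spherical,
         fraction_rods = x$fraction_rods)
}

#' Full width at half maximum of a histogram
#'
#' Finds the unique modal bin, then the two half-maximum crossings by linear
#' interpolation between adjacent bin centers on each side of the mode. A
#' histogram with a single occupied bin returns one bin width (degenerate
#' convention).
#'
#' @param histogram Tibble with `mid` (bin centers, increasing) and `count`.
#' @return FWHM in the units of `mid`.
#' @export
histogram_fwhm <- function(histogram) {
  stopifnot(is.data.frame(histogram),
            all(c("mid", "count") %in% names(histogram)))
  mid <- histogram$mid; count <- histogram$count
  check_axis(mid, "mid")
  peak <- max(count)
  imax <- which(count == peak)
  if (length(imax) > 1L) {
    abort("Histogram has no unique global maximum bin.",
          class = "sersuptake_histogram_error")
  }
  half <- peak / 2
  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(imax)) else imax:length(count)
    below <- which(count[idx] < half)
    if (length(below) == 0L) {
      abort(sprintf("Half maximum never crossed on the %s side.", side),
            class = "sersuptake_histogram_error")
    }
    j <- idx[below[1]]                        # first bin below half
    k <- if (side == "left") j + 1L else j - 1L  # adjacent bin above half
    mid[k] + (mid[j] - mid[k]) * (count[k] - half) / (count[k] - count[j])
  }
  cross("right") - cross("left")
}
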