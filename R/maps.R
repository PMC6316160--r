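# Hyperspectral Raman map processing: band intensity extraction, SERS image
# reconstruction, cell-body sum-spectra, the I1078 uptake statistic and
# cell-line/time comparisons.

#' Band intensity of a spectrum
#'
#' Intensity of an analytical band after local linear baseline correction:
#' a straight baseline is drawn between the intensities at the two ends of
#' the `center +- half_window` window and subtracted; `mode = "height"`
#' returns the maximum corrected value in the window, `mode = "area"` the
#' trapezoidal integral. The result is divided by the exposure time, so it is
#' a rate (counts/s) comparable across acquisitions.
#'
#' @param spectrum Spectrum tibble (`wavenumber`, `intensity`) carrying an
#'   `exposure_s` attribute, or any tibble with those columns plus an
#'   explicit `exposure` argument.
#' @param center Band center, cm^-1 (default 1078, the C-C anti-symmetric
#'   stretching SERS band used as the uptake reporter).
#' @param half_window Half window, cm^-1 (default 20).
#' @param mode `"height"` or `"area"`.
#' @param exposure Exposure in seconds; defaults to the spectrum attribute.
#' @return Band intensity in counts/s (or counts/s * cm^-1 for area mode).
#' @export
band_intensity <- function(spectrum, center = 1078, half_window = 20,
                           mode = c("height", "area"),
                           exposure = exposure_of(spectrum)) {
  mode <- match.arg(mode)
  wn <- spectrum$wavenumber; y <- spectrum$intensity
  check_axis(wn, "wavenumber")
  if (center - half_window < min(wn) || center + half_window > max(wn)) {
    abort("Band window extends outside the wavenumber axis.",
          class = "sersuptake_window_error")
  }
  idx <- which(wn >= center - half_window & wn <= center + half_window)
  xw <- wn[idx]; yw <- y[idx]
  n <- length(idx)
  base <- yw[1] + (yw[n] - yw[1]) * (xw - xw[1]) / (xw[n] - xw[1])
  corrected <- yw - base
  out <- if (mode == "height") max(corrected) else trapz(xw, corrected)
  out / exposure
}

#' Reconstruct a band-intensity image from a hyperspectral map
#'
#' Applies [band_intensity()] to every pixel's spectrum and returns the
#' spatial intensity grid: the standard way single-cell SERS maps are turned
#' into uptake images (peak intensity at 1078 cm^-1 per map point).
#'
#' @param map Long-format hyperspectral map tibble (`x_um`, `y_um`,
#'   `wavenumber_cm1`, `intensity`) with an `exposure_s` attribute.
#' @param center,half_window,mode Passed to [band_intensity()].
#' @return A tibble `(x_um, y_um, intensity)` with one row per map pixel.
#' @export
reconstruct_image <- function(map, center = 1078, half_window = 20,
                              mode = c("height", "area")) {
  mode <- match.arg(mode)
  check_map(map)
  exposure <- exposure_of(map)
  wn <- sort(unique(map$wavenumber_cm1))
  if (center - half_window < min(wn) || center + half_window > max(wn)) {
    abort("Band window extends outside the wavenumber axis.",
          class = "sersuptake_window_error")
  }
  sel <- wn[wn >= center - half_window & wn <= center + half_window]
  w <- map[map$wavenumber_cm1 %in% sel, , drop = FALSE]
  w <- arrange(w, .data$y_um, .data$x_um, .data$wavenumber_cm1)
  nwn <- length(sel)
  m <- matrix(w$intensity, nrow = nwn)   # one column per pixel
  xw <- sel
  base <- outer(
    (xw - xw[1]) / (xw[nwn] - xw[1]),
    m[nwn, ] - m[1, ]
  ) + matrix(m[1, ], nrow = nwn, ncol = ncol(m), byrow = TRUE)
  corr <- m - base
  val <- if (mode == "height") {
    apply(corr, 2, max)
  } else {
    wts <- trapz_weights(xw)
    as.vector(wts %*% corr)
  }
  px <- distinct(arrange(map[, c("x_um", "y_um")],
                         .data$y_um, .data$x_um))
  tibble(x_um = px$x_um, y_um = px$y_um, intensity = val / exposure)
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

check_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("x_um", "y_um", "wavenumber_cm1", "intensity") %in%
                  names(map)))
  invisible(map)
}

#' Cell-body sum-spectrum of a hyperspectral map
#'
#' Pointwise sum of the spectra of all pixels inside the cell mask: the
#' single-cell aggregate from which the uptake statistic is read. All pixels
#' share one axis and one exposure, which is preserved on the result.
#'
#' @param map Hyperspectral map tibble.
#' @param mask Logical matrix of the same grid shape (rows = y, columns = x),
#'   or `NULL` for a full-map mask.
#' @return A spectrum tibble (see [new_spectrum()]).
#' @export
sum_spectrum <- function(map, mask = NULL) {
  check_map(map)
  exposure <- exposure_of(map)
  inside <- mask_lookup(map, mask)
  if (!any(inside)) {
    abort("Mask selects no pixels.", class = "sersuptake_mask_error")
  }
  m <- map[inside, , drop = FALSE]
  agg <- summarise(group_by(m, .data$wavenumber_cm1),
                   intensity = sum(.data$intensity), .groups = "drop")
  agg <- arrange(agg, .data$wavenumber_cm1)
  new_spectrum(agg$wavenumber_cm1, agg$intensity, exposure = exposure)
}

# Logical row filter of `map` given a mask matrix (rows = y index).
mask_lookup <- function(map, mask) {
  if (is.null(mask)) return(rep(TRUE, nrow(map)))
  stopifnot(is.matrix(mask), is.logical(mask))
  xs <- sort(unique(map$x_um)); ys <- sort(unique(map$y_um))
  if (nrow(mask) != length(ys) || ncol(mask) != length(xs)) {
    abort(sprintf("Mask is %d x %d but the map grid is %d x %d (rows x cols).",
                  nrow(mask), ncol(mask), length(ys), length(xs)),
          class = "sersuptake_mask_error")
  }
  i <- match(map$y_um, ys); j <- match(map$x_um, xs)
  mask[cbind(i, j)]
}

#' The I1078 uptake statistic of one cell
#'
#' Band intensity (default: baseline-corrected height at 1078 cm^-1,
#' exposure-normalized) of the cell-body sum-spectrum. The statistic is
#' proportional to the number of internalized nanoparticles when acquisition
#' parameters are held constant. Negative baseline-corrected values are
#' floored at zero (and flagged) so the statistic remains a valid abundance
#' proxy.
#'
#' @param map Hyperspectral map tibble.
#' @param mask Logical cell mask (see [sum_spectrum()]).
#' @param cell_id,cell_line,time_h Metadata copied onto the result.
#' @param center,half_window,mode Passed to [band_intensity()].
#' @return One-row tibble: `cell_id`, `cell_line`, `time_h`, `i1078`
#'   (counts/s), `clipped`.
#' @export
compute_i1078 <- function(map, mask = NULL, cell_id = "cell",
                          cell_line = NA_character_, time_h = NA_real_,
                          center = 1078, half_window = 20,
                          mode = c("height", "area")) {
  mode <- match.arg(mode)
  ss <- sum_spectrum(map, mask)
  val <- band_intensity(ss, center = center, half_window = half_window,
                        mode = mode)
  tibble(cell_id = cell_id, cell_line = cell_line, time_h = time_h,
         i1078 = max(val, 0), clipped = val < 0)
}

#' Summarize uptake results across cells, lines and times
#'
#' Per (cell line, time) group mean, standard deviation, standard error and
#' cell count of I1078, plus the percent-excess contrast of the tumor line
#' over the normal line at each matched time:
#' `(mean_PC3 - mean_PNT2) / mean_PNT2 * 100`.
#'
#' @param results Tibble of per-cell rows from [compute_i1078()] (columns
#'   `cell_line`, `time_h`, `i1078`).
#' @param contrast Compute PC3-vs-PNT2 contrasts (default `TRUE`); raising a
#'   named error when a PC3 group lacks its matched PNT2 group.
#' @return An object of class `"uptake_summary"`: list with `groups` and
#'   `contrasts` tibbles.
#' @export
summarize_uptake <- function(results, contrast = TRUE) {
  stopifnot(is.data.frame(results),
            all(c("cell_line", "time_h", "i1078") %in% names(results)))
  if (nrow(results) == 0) {
    abort("`results` must contain at least one cell.",
          class = "sersuptake_empty_error")
  }
  groups <- summarise(group_by(results, .data$cell_line, .data$time_h),
                      mean = mean(.data$i1078),
                      sd = if (n() > 1) sd(.data$i1078) else 0,
                      sem = (if (n() > 1) sd(.data$i1078) else 0) / sqrt(n()),
                      n_cells = n(),
                      .groups = "drop")
  contrasts <- tibble(time_h = numeric(0), mean_pc3 = numeric(0),
                      mean_pnt2 = numeric(0), percent_excess = numeric(0))
  if (contrast) {
    times <- sort(unique(groups$time_h[groups$cell_line == "PC3"]))
    rows <- lapply(times, function(t) {
      m_pc3 <- groups$mean[groups$cell_line == "PC3" & groups$time_h == t]
      m_pnt2 <- groups$mean[groups$cell_line == "PNT2" & groups$time_h == t]
      if (length(m_pnt2) == 0) {
        abort(sprintf("No matched PNT2 group at t = %g h for the contrast.", t),
              class = "sersuptake_contrast_error")
      }
      tibble(time_h = t, mean_pc3 = m_pc3, mean_pnt2 = m_pnt2,
             percent_excess = (m_pc3 - m_pnt2) / m_pnt2 * 100)
    })
    if (length(rows)) contrasts <- bind_rows(rows)
  }
  structure(list(groups = groups, contrasts = contrasts),
            class = "uptake_summary")
}

#' @export
print.uptake_summary <- function(x, ...) {
  cat("Uptake summary (I1078, counts/s)\n")
  print(x$groups)
  if (nrow(x$contrasts)) {
    cat("\nPC3 vs PNT2 percent excess\n")
    print(x$contrasts)
  }
  invisible(x)
}

#' @rdname summarize_uptake
#' @param x An `uptake_summary`.
#' @param ... Unused.
#' @export
tidy.uptake_summary <- function(x, ...) x$groups

#' @rdname summarize_uptake
#' @export
glance.uptake_summary <- function(x, ...) {
  out <- x$contrasts[, c("time_h", "percent_excess")]
  tidyr::pivot_wider(out, names_from = "time_h",
                     values_from = "percent_excess",
                     names_prefix = "percent_excess_")
}

#' Detected Raman-to-SERS band shifts
#'
#' For every band pair of the reference table, detects the local maximum of
#' each trace inside a window of half-width `half_window` centered on the
#' midpoint of the two nominal positions (so both traces are searched over
#' one common window and identical traces give zero shift), and reports the
#' SERS - Raman position difference. A band counts as present only when its
#' baseline-corrected height exceeds `3 x` the local noise estimate *and* 1%
#' of the strongest band in its spectrum; the relative floor keeps absence
#' calls robust on noise-free traces where neighbouring-band tails are tiny
#' but nonzero. The 920 cm^-1 S-H bend is expected absent in SERS.
#'
#' @param raman_spectrum,sers_spectrum Spectrum tibbles sharing units.
#' @param band_table Reference table from [tp_band_table()].
#' @param half_window Detection half window, cm^-1.
#' @return Tibble with `label`, `raman_nominal`, `sers_nominal`,
#'   `raman_detected`, `sers_detected`, `shift` (SERS - Raman, cm^-1; `NA`
#'   when either band is absent), `sers_present`.
#' @export
band_shift_table <- function(raman_spectrum, sers_spectrum,
                             band_table = tp_band_table(),
                             half_window = 15) {
  rows <- lapply(seq_len(nrow(band_table)), function(i) {
    r0 <- band_table$raman_cm1[i]; s0 <- band_table$sers_cm1[i]
    center <- mean(c(r0, s0), na.rm = TRUE)
    rdet <- detect_band(raman_spectrum, center, half_window)
    sdet <- detect_band(sers_spectrum, center, half_window)
    tibble(label = band_table$label[i],
           raman_nominal = r0, sers_nominal = s0,
           raman_detected = rdet$position, sers_detected = sdet$position,
           shift = sdet$position - rdet$position,
           sers_present = sdet$present)
  })
  bind_rows(rows)
}

# Local-maximum band detection with a noise and relative-height floor.
detect_band <- function(spectrum, center, half_window) {
  wn <- spectrum$wavenumber; y <- spectrum$intensity
  idx <- which(wn >= center - half_window & wn <= center + half_window)
  if (length(idx) < 3) return(list(position = NA_real_, present = FALSE))
  xw <- wn[idx]; yw <- y[idx]
  n <- length(idx)
  base <- yw[1] + (yw[n] - yw[1]) * (xw - xw[1]) / (xw[n] - xw[1])
  corr <- yw - base
  imax <- which.max(corr)
  height <- corr[imax]
  noise <- stats::mad(diff(y)) / sqrt(2)
  floor_rel <- 0.01 * (max(y) - min(y))
  present <- height > 3 * noise && height > floor_rel
  if (!present) return(list(position = NA_real_, present = FALSE))
  # parabolic refinement on the discrete maximum when interior
  pos <- xw[imax]
  if (imax > 1 && imax < n) {
    y1 <- corr[imax - 1]; y2 <- corr[imax]; y3 <- corr[imax + 1]
    dd <- y1 - 2 * y2 + y3
    if (dd < 0) {
      pos <- pos + 0.5 * (y1 - y3) / dd * (xw[imax + 1] - xw[imax])
    }
  }
  list(position = pos, present = TRUE)
}

#' Average a set of point spectra
#'
#' Pointwise mean and sample standard deviation over replicate point spectra
#' sharing one axis (the presentation used for probe-reproducibility checks:
#' mean trace +- sd over repeated collection points).
#'
#' @param spectra List of spectrum tibbles with identical wavenumber axes.
#' @return List with `mean` and `sd` spectrum tibbles.
#' @export
average_point_spectra <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 2) {
    abort("Need at least two spectra to average.",
          class = "sersuptake_empty_error")
  }
  ax <- spectra[[1]]$wavenumber
  for (s in spectra) {
    if (length(s$wavenumber) != length(ax) || any(s$wavenumber != ax)) {
      abort("All spectra must share one wavenumber axis.",
            class = "sersuptake_axis_error")
    }
  }
  m <- vapply(spectra, function(s) s$intensity, numeric(length(ax)))
  exposure <- attr(spectra[[1]], "exposure_s", exact = TRUE) %||% 3
  list(mean = new_spectrum(ax, rowMeans(m), exposure),
       sd = new_spectrum(ax, apply(m, 1, sd), exposure))
}
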