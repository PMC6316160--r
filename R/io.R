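# Readers/writers for the package's plain-text interchange formats:
# long-format map TSV with an exposure header, 0/1 mask CSV grids,
# two-column spectrum CSV, and TIFF/PNG particle micrographs.

#' Write and read hyperspectral maps
#'
#' Maps are exchanged as long-format TSV with columns `x_um`, `y_um`,
#' `wavenumber_cm1`, `intensity`, preceded by a `# exposure_s: <s>` header
#' line (and a `# step_um: <um>` line). Reading validates the grid: every
#' (x, y) position must carry the full shared wavenumber axis.
#'
#' @param map Hyperspectral map tibble (see [simulate_cell_map()]).
#' @param path File path.
#' @return `write_map()` returns `path` invisibly; `read_map()` returns the
#'   map tibble with `exposure_s`, `step_um`, `nx`, `ny` attributes.
#' @export
write_map <- function(map, path) {
  check_map(map)
  exposure <- exposure_of(map)
  step <- attr(map, "step_um", exact = TRUE) %||%
    min(diff(sort(unique(map$x_um))))
  writeLines(c(sprintf("# exposure_s: %.10g", exposure),
               sprintf("# step_um: %.10g", step)), path)
  readr::write_tsv(map[, c("x_um", "y_um", "wavenumber_cm1", "intensity")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  header <- readLines(path, n = 10)
  exp_line <- grep("^#\\s*exposure_s:", header, value = TRUE)
  if (length(exp_line) == 0) {
    abort("Map file is missing the `# exposure_s:` header line.",
          class = "sersuptake_io_error")
  }
  exposure <- as.numeric(sub("^#\\s*exposure_s:\\s*", "", exp_line[1]))
  step_line <- grep("^#\\s*step_um:", header, value = TRUE)
  step <- if (length(step_line)) {
    as.numeric(sub("^#\\s*step_um:\\s*", "", step_line[1]))
  } else NA_real_
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("x_um", "y_um", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(tb))) {
    abort(paste0("Map file must have columns ",
                 paste(need, collapse = ", "), "."),
          class = "sersuptake_io_error")
  }
  xs <- sort(unique(tb$x_um)); ys <- sort(unique(tb$y_um))
  wn <- sort(unique(tb$wavenumber_cm1))
  check_axis(wn, "wavenumber_cm1")
  counts <- table(factor(tb$x_um, levels = xs), factor(tb$y_um, levels = ys))
  bad <- which(counts != length(wn), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Ragged map grid: pixel (x = %g, y = %g) has %d of %d axis points.",
      xs[bad[1, 1]], ys[bad[1, 2]],
      counts[bad[1, 1], bad[1, 2]], length(wn)),
      class = "sersuptake_io_error")
  }
  out <- as_tibble(tb[, need])
  attr(out, "exposure_s") <- exposure
  attr(out, "step_um") <- if (is.na(step)) min(diff(xs)) else step
  attr(out, "nx") <- length(xs)
  attr(out, "ny") <- length(ys)
  class(out) <- c("hyperspectral_map", class(out))
  out
}

#' Write and read 0/1 cell-mask grids
#'
#' Masks are CSV grids of 0/1 without header; rows of the file are map rows
#' (y), columns are x.
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  utils::write.table(mask * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  if (!all(m %in% c(0, 1))) {
    abort("Mask grids must contain only 0 and 1.",
          class = "sersuptake_io_error")
  }
  matrix(m == 1, nrow = nrow(m))
}

#' Write and read two-column spectra
#'
#' UV-Vis spectra as `wavelength,absorbance`; Raman spectra as
#' `wavenumber,intensity` with a `# exposure_s:` header.
#'
#' @param spectrum Spectrum tibble.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(is.data.frame(spectrum), ncol(spectrum) >= 2)
  exposure <- attr(spectrum, "exposure_s", exact = TRUE)
  if (!is.null(exposure)) {
    writeLines(sprintf("# exposure_s: %.10g", exposure), path)
    readr::write_csv(spectrum, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(spectrum, path, col_names = TRUE)
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  header <- readLines(path, n = 2)
  exp_line <- grep("^#\\s*exposure_s:", header, value = TRUE)
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if ("wavenumber" %in% names(tb) && length(exp_line)) {
    tb <- new_spectrum(tb$wavenumber, tb$intensity,
                       as.numeric(sub("^#\\s*exposure_s:\\s*", "",
                                      exp_line[1])))
  }
  tb
}

#' Write and read grayscale particle micrographs
#'
#' 8-bit grayscale TIFF or PNG depending on the file extension. Gray values
#' are clipped to \[0, 255\] on write and returned on the 0-255 scale on read.
#'
#' @param image Numeric matrix of gray levels (0-255 scale).
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_particle_image <- function(image, path) {
  stopifnot(is.matrix(image))
  norm <- pmin(pmax(image, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    abort("Unsupported image extension; use .tif/.tiff/.png.",
          class = "sersuptake_io_error")
  }
  invisible(path)
}

#' @rdname write_particle_image
#' @export
read_particle_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    abort("Unsupported image extension; use .tif/.tiff/.png.",
          class = "sersuptake_io_error")
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}
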