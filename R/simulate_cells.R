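#' Calibrated nanoparticle-uptake profiles for PNT2 and PC3 cells
#'
#' Mean nanoparticle-load multipliers, expressed relative to the normal-line
#' (PNT2) level at 2 h. PNT2 uptake saturates by 2 h, so its multiplier is 1
#' at all sampled times. PC3 multipliers are calibrated so the percent-excess
#' statistic (PC3 - PNT2)/PNT2 x 100 computed by [summarize_uptake()] equals
#' 260% at 2 h and 950% at 6 h; the 4 h value is the linear interpolation of
#' the two calibrated points (7.05).
#'
#' @param cell_line `"PNT2"` or `"PC3"`.
#' @param time_h Incubation time, one of 2, 4 or 6 hours.
#' @return A one-row tibble with `cell_line`, `time_h`, `load_multiplier`.
#' @export
#' @examples
#' uptake_profile("PC3", 2)$load_multiplier  # 3.6
uptake_profile <- function(cell_line = c("PNT2", "PC3"), time_h) {
  if (!is.character(cell_line) || !all(cell_line %in% c("PNT2", "PC3"))) {
    abort("`cell_line` must be \"PNT2\" or \"PC3\".",
          class = "sersuptake_cell_line_error")
  }
  cell_line <- match.arg(cell_line)
  if (!is.numeric(time_h) || length(time_h) != 1L || !time_h %in% c(2, 4, 6)) {
    abort("`time_h` must be 2, 4 or 6 hours.",
          class = "sersuptake_time_error")
  }
  pc3 <- c(`2` = 3.6, `4` = (3.6 + 10.5) / 2, `6` = 10.5)
  mult <- if (cell_line == "PNT2") 1 else unname(pc3[as.character(time_h)])
  tibble(cell_line = cell_line, time_h = time_h, load_multiplier = mult)
}

#' Specification for a synthetic single-cell hyperspectral map
#'
#' Defaults emulate the mapping acquisition: a 30 x 30 grid at 2.0 um step
#' (cell-sized field of view), 600-1800 cm^-1 axis at 2 cm^-1, 3 s exposure
#' per pixel. The cell body is an ellipse; its semi-axes are jittered per
#' cell (+-10%) to mimic morphological variability.
#'
#' @param nx,ny Grid points along x and y.
#' @param step Stage step, um (> 0).
#' @param axis Wavenumber axis, cm^-1, strictly increasing.
#' @param exposure Per-pixel exposure, s.
#' @param cell_semi_axes Ellipse semi-axes of the cell mask, grid units
#'   (pixels); default scales with the grid.
#' @param axis_jitter Relative uniform jitter on each semi-axis.
#' @param base_load Mean per-pixel 1078-band height rate (counts/s) for a
#'   load multiplier of 1.
#' @param load_cv Lognormal coefficient of variation of the per-cell total
#'   load around the profile mean.
#' @param baseline Polynomial baseline coefficients, counts/s (see
#'   [simulate_tp_spectrum()]).
#' @param noise_sd Additive Gaussian noise on counts; the default gives a
#'   per-pixel signal-to-noise ratio of about 20 at the 1078 cm^-1 band for
#'   unit load.
#' @param shot_noise If `TRUE`, adds Poisson-like noise with variance equal
#'   to the (non-negative) expected counts.
#' @return A list of class `"map_spec"`.
#' @export
map_spec <- function(nx = 30, ny = 30, step = 2.0,
                     axis = default_wavenumber_axis(),
                     exposure = 3,
                     cell_semi_axes = c(0.30 * nx, 0.36 * ny),
                     axis_jitter = 0.10,
                     base_load = 1,
                     load_cv = 0.15,
                     baseline = c(2, -0.5),
                     noise_sd = 0.05 * 3,
                     shot_noise = FALSE) {
  stopifnot(nx >= 2, ny >= 2, step > 0, exposure > 0,
            length(cell_semi_axes) == 2, all(cell_semi_axes > 0),
            axis_jitter >= 0, base_load >= 0, load_cv >= 0, noise_sd >= 0)
  check_axis(axis, "axis")
  structure(as.list(environment()), class = "map_spec")
}

#' Simulate a single-cell SERS hyperspectral map
#'
#' Generates one cell's spectral cube with known ground truth. Pixels inside
#' the elliptical cell mask carry thiophenol SERS signal whose per-pixel
#' scale is drawn from a cell-line specific load field; pixels outside carry
#' baseline and noise only. The spatial pattern follows the two observed
#' uptake phenotypes: in PNT2 cells the (small) total load is concentrated in
#' one or two isolated spots and the rest of the cell is flat baseline, while
#' in PC3 cells the load is spread over essentially the whole cell body.
#'
#' The per-cell expected total load is
#' `load_multiplier * base_load * n_mask_pixels`, jittered by a lognormal
#' factor of coefficient of variation `load_cv`, so the mean uptake statistic
#' scales with the profile multiplier for both phenotypes.
#'
#' @param cell_line,time_h Passed to [uptake_profile()].
#' @param spec A [map_spec()].
#' @param seed Optional integer seed; the generator is a pure function of
#'   `(cell_line, time_h, spec, seed)`.
#' @return A list with:
#'   * `map`: long-format hyperspectral map tibble (`x_um`, `y_um`,
#'     `wavenumber_cm1`, `intensity`) with attributes `step_um`,
#'     `exposure_s`, `nx`, `ny`;
#'   * `mask`: logical `ny x nx` cell mask;
#'   * `truth`: list with `load_field` (numeric `ny x nx`, counts/s of
#'     1078-band height per pixel) and `i1078` (noise-free sum over mask
#'     pixels of the 1078-band height rate, counts/s).
#' @export
simulate_cell_map <- function(cell_line, time_h, spec = map_spec(),
                              seed = NULL) {
  stopifnot(inherits(spec, "map_spec"))
  prof <- uptake_profile(cell_line, time_h)
  if (2 * spec$cell_semi_axes[1] * (1 + spec$axis_jitter) > spec$nx ||
      2 * spec$cell_semi_axes[2] * (1 + spec$axis_jitter) > spec$ny) {
    abort("Cell mask does not fit inside the map grid.",
          class = "sersuptake_mask_error")
  }
  with_seed_or_not(seed, {
    nx <- spec$nx; ny <- spec$ny
    ax <- spec$cell_semi_axes[1] * runif(1, 1 - spec$axis_jitter, 1 + spec$axis_jitter)
    ay <- spec$cell_semi_axes[2] * runif(1, 1 - spec$axis_jitter, 1 + spec$axis_jitter)
    cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
    gx <- matrix(rep(seq_len(nx), each = ny), nrow = ny)
    gy <- matrix(rep(seq_len(ny), times = nx), nrow = ny)
    mask <- ((gx - cx) / ax)^2 + ((gy - cy) / ay)^2 <= 1
    n_mask <- sum(mask)

    mult <- prof$load_multiplier
    jit <- if (spec$load_cv > 0) {
      s2 <- log(1 + spec$load_cv^2)
      rlnorm(1, meanlog = -s2 / 2, sdlog = sqrt(s2))
    } else 1
    total_load <- mult * spec$base_load * n_mask * jit

    load <- matrix(0, ny, nx)
    if (total_load > 0 && n_mask > 0) {
      if (cell_line == "PNT2") {
        # 1-2 compact endosomal-like spots; the rest of the cell is dark
        n_spots <- sample(1:2, 1)
        idx <- which(mask)
        centers <- sample(idx, n_spots)
        spot <- rep(FALSE, length(mask))
        for (ci in centers) {
          cyx <- arrayInd(ci, dim(mask))
          d2 <- (gx - cyx[2])^2 + (gy - cyx[1])^2
          spot <- spot | (as.vector(d2) <= 1.8^2 & as.vector(mask))
        }
        w <- runif(sum(spot), 0.5, 1.5)
        load[spot] <- total_load * w / sum(w)
      } else {
        # homogeneous dispersion with mild pixel-to-pixel texture
        w <- stats::rgamma(n_mask, shape = 8, rate = 8)
        load[mask] <- total_load * w / sum(w)
      }
    }

    axis <- spec$axis
    unit <- tp_band_sum(axis, "sers")          # 1078 band has amplitude 1
    base <- eval_baseline(axis, spec$baseline)
    rate <- outer(as.vector(load), unit) +
      matrix(base, nrow = ny * nx, ncol = length(axis), byrow = TRUE)
    counts <- rate * spec$exposure
    if (spec$shot_noise) {
      counts <- counts + matrix(
        rnorm(length(counts), 0, sqrt(pmax(counts, 0))), nrow = nrow(counts))
    }
    if (spec$noise_sd > 0) {
      counts <- counts + matrix(rnorm(length(counts), 0, spec$noise_sd),
                                nrow = nrow(counts))
    }

    map <- tibble(
      x_um = rep((as.vector(gx) - 1) * spec$step, times = length(axis)),
      y_um = rep((as.vector(gy) - 1) * spec$step, times = length(axis)),
      wavenumber_cm1 = rep(axis, each = ny * nx),
      intensity = as.vector(counts)
    )
    attr(map, "step_um") <- spec$step
    attr(map, "exposure_s") <- spec$exposure
    attr(map, "nx") <- nx
    attr(map, "ny") <- ny
    class(map) <- c("hyperspectral_map", class(map))

    list(map = map,
         mask = mask,
         truth = list(load_field = load, i1078 = sum(load[mask])))
  })
}
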