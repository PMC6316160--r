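#' Specification for a synthetic particle micrograph
#'
#' Defaults emulate transmission electron micrographs of a nearly monodisperse
#' gold nanosphere population: dark quasi-circular particles on a bright
#' background, Gaussian diameter distribution with mean 24 nm and full width
#' at half maximum 10.1 nm (sd = 10.1/2.3548 nm), and a 3% contamination of
#' nanorods drawn as ellipses of the same equivalent diameter.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Physical sampling, nm per pixel.
#' @param n_particles Number of particles to place.
#' @param diameter_mean,diameter_fwhm Mean and FWHM of the Gaussian diameter
#'   distribution, nm.
#' @param rod_fraction Fraction of particles drawn as rods (ellipses), in
#'   \[0, 1\]. The rod count is `round(rod_fraction * n_particles)` and the
#'   first that many particles are rods, so the count is deterministic.
#' @param rod_aspect Rod major/minor axis ratio (>= 1).
#' @param foreground,background Gray levels of particle interior and support
#'   film (particles are dark: foreground < background).
#' @param noise_sd Additive Gaussian noise, gray levels.
#' @param margin_px Minimum gap kept between particles and to the frame edge,
#'   px; guarantees non-overlap and fully interior particles.
#' @return A list of class `"image_spec"`.
#' @export
particle_image_spec <- function(width = 512, height = 512,
                                pixel_size = 1.0,
                                n_particles = 100,
                                diameter_mean = 24,
                                diameter_fwhm = 10.1,
                                rod_fraction = 0.03,
                                rod_aspect = 3,
                                foreground = 50, background = 200,
                                noise_sd = 8,
                                margin_px = 3) {
  stopifnot(width >= 8, height >= 8, pixel_size > 0, n_particles >= 0,
            diameter_mean > 0, diameter_fwhm > 0,
            rod_fraction >= 0, rod_fraction <= 1, rod_aspect >= 1,
            foreground < background, noise_sd >= 0, margin_px >= 0)
  structure(as.list(environment()), class = "image_spec")
}

#' Simulate a particle micrograph with ground truth
#'
#' Draws anti-aliased dark disks (and ellipses for the rod fraction) on a
#' bright background without mutual overlap, by rejection sampling of centers
#' with a minimum pairwise clearance. Per-pixel gray level interpolates
#' between background and foreground by the analytic area coverage of the
#' particle boundary, then Gaussian read noise is added. The generator is a
#' pure function of `(spec, seed)`.
#'
#' @param spec An [particle_image_spec()].
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per particle before giving up.
#' @return A list with `image` (numeric matrix, rows = y), and `truth`, a
#'   tibble with one row per particle: `x_px`, `y_px` (center), `shape`
#'   (`"sphere"`/`"rod"`), `diameter_nm` (equivalent diameter),
#'   `major_nm`, `minor_nm`, `theta` (rod orientation, radians).
#' @export
simulate_particle_image <- function(spec = particle_image_spec(),
                                    seed = NULL,
                                    max_tries = 200) {
  stopifnot(inherits(spec, "image_spec"))
  with_seed_or_not(seed, {
    n <- spec$n_particles
    img <- matrix(spec$background, nrow = spec$height, ncol = spec$width)
    truth <- tibble(x_px = numeric(0), y_px = numeric(0),
                    shape = character(0), diameter_nm = numeric(0),
                    major_nm = numeric(0), minor_nm = numeric(0),
                    theta = numeric(0))
    if (n > 0) {
      sdev <- spec$diameter_fwhm / (2 * sqrt(2 * log(2)))
      d_nm <- rnorm(n, spec$diameter_mean, sdev)
      d_nm <- pmax(d_nm, 2 * spec$pixel_size)   # physical floor
      n_rods <- round(spec$rod_fraction * n)
      is_rod <- seq_len(n) <= n_rods
      theta <- ifelse(is_rod, runif(n, 0, pi), 0)
      # equal-area ellipse: semi-axes a = r*sqrt(aspect), b = r/sqrt(aspect)
      r_px <- d_nm / 2 / spec$pixel_size
      a_px <- ifelse(is_rod, r_px * sqrt(spec$rod_aspect), r_px)
      b_px <- ifelse(is_rod, r_px / sqrt(spec$rod_aspect), r_px)

      xs <- ys <- numeric(n)
      placed_r <- numeric(0)
      for (i in seq_len(n)) {
        reach <- a_px[i] + spec$margin_px
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          x <- runif(1, 1 + reach, spec$width - reach)
          y <- runif(1, 1 + reach, spec$height - reach)
          if (i == 1L ||
              all((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2 >
                  (placed_r + reach)^2)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "Could not place particle %d without overlap after %d tries; reduce `n_particles` or enlarge the frame.",
            i, max_tries), class = "sersuptake_placement_error")
        }
        xs[i] <- x; ys[i] <- y
        placed_r <- c(placed_r, a_px[i] + spec$margin_px)
        img <- draw_ellipse(img, x, y, a_px[i], b_px[i], theta[i],
                            spec$foreground, spec$background)
      }
      truth <- tibble(x_px = xs, y_px = ys,
                      shape = ifelse(is_rod, "rod", "sphere"),
                      diameter_nm = d_nm,
                      major_nm = 2 * a_px * spec$pixel_size,
                      minor_nm = 2 * b_px * spec$pixel_size,
                      theta = theta)
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                          nrow = nrow(img))
    }
    list(image = img, truth = truth)
  })
}

# Composite one anti-aliased ellipse into `img`. Coverage is approximated by
# a smooth ramp of the signed elliptical distance, one pixel wide.
draw_ellipse <- function(img, cx, cy, a, b, theta, fg, bg) {
  pad <- ceiling(a) + 2L
  x0 <- max(1L, floor(cx - pad)); x1 <- min(ncol(img), ceiling(cx + pad))
  y0 <- max(1L, floor(cy - pad)); y1 <- min(nrow(img), ceiling(cy + pad))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  # approximate signed distance to the ellipse boundary (exact for circles)
  q <- sqrt((u / a)^2 + (v / b)^2)
  dist <- (q - 1) * sqrt((a * b))   # local scale between a and b
  cov <- pmin(pmax(0.5 - dist, 0), 1)
  img[ys, xs] <- img[ys, xs] * (1 - cov) + fg * cov
  img
}
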