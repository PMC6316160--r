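# Shared fixtures, built in code.

# Pixel-center rasterization of an axis-aligned ellipse as a labeled-region
# tibble: all integer (x, y) whose center lies inside.
raster_ellipse_region <- function(a, b = a, cx = a + 5, cy = b + 5,
                                  label = 1L) {
  xs <- seq.int(floor(cx - a - 2), ceiling(cx + a + 2))
  ys <- seq.int(floor(cy - b - 2), ceiling(cy + b + 2))
  g <- expand.grid(x_px = xs, y_px = ys)
  inside <- ((g$x_px - cx) / a)^2 + ((g$y_px - cy) / b)^2 <= 1
  tibble::tibble(label = label, x_px = g$x_px[inside], y_px = g$y_px[inside])
}

# A small map spec that keeps unit tests fast.
tiny_map_spec <- function(...) {
  map_spec(nx = 8, ny = 8, axis = seq(900, 1300, by = 4),
           cell_semi_axes = c(2.4, 2.8), ...)
}

# Analytic Gaussian-shaped histogram (noise-free bin counts).
gaussian_histogram <- function(mean = 24, sd = 4.289, bw = 1,
                               lo = 0, hi = 48) {
  edges <- seq(lo, hi, by = bw)
  mid <- (head(edges, -1) + tail(edges, -1)) / 2
  tibble::tibble(mid = mid, count = 1000 * exp(-(mid - mean)^2 / (2 * sd^2)))
}
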