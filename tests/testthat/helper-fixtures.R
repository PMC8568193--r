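# Fixtures are generated in code at test time; nothing is read from disk.

# Concentric-ring phantom: value depends smoothly on radius inside
# [r_inner, r_outer], 0 elsewhere.  ring_fun takes a radius and returns
# luminance.
annulus_image <- function(size = 201, r_inner = 55, r_outer = 95,
                          ring_fun = function(r) 1000 + 800 * sin(2 * pi * r / 10)) {
  c0 <- (size - 1) / 2
  xy <- seq_len(size) - 1
  r <- sqrt(outer((xy - c0)^2, (xy - c0)^2, "+"))  # rows y, cols x
  img <- matrix(0, size, size)
  inside <- r >= r_inner & r <= r_outer
  img[inside] <- ring_fun(r[inside])
  img
}

# Oracle for straightening a circular band: direct polar resampling of the
# same image at radius rc + offset, uniformly in angle.
polar_resample <- function(img, rc, offsets, n_theta = 720,
                           theta_range = c(0, 2 * pi)) {
  c0 <- (nrow(img) - 1) / 2
  th <- seq(theta_range[1], theta_range[2], length.out = n_theta)
  sapply(offsets, function(d) {
    x <- c0 + (rc + d) * cos(th)
    y <- c0 - (rc + d) * sin(th)
    cementr:::bilinear(img, x, y)
  })  # n_theta x length(offsets)
}

# Control points along a circular arc (not closed, avoids self-crossing).
arc_control_points <- function(rc, size = 201, n = 13, frac = 0.75) {
  c0 <- (size - 1) / 2
  th <- seq(0, 2 * pi * frac, length.out = n)
  cbind(x = c0 + rc * cos(th), y = c0 - rc * sin(th))
}

# Horizontal-band slice: rows band_rows = value, background 0.
band_image <- function(nrow = 21, ncol = 100, band_rows = 9:13, value = 1000) {
  img <- matrix(0, nrow, ncol)
  img[band_rows, ] <- value
  img
}

# Minimal hand-made slice-level estimate for report-writing tests.
fake_slice_estimate <- function(mean, sd = 0, n = 1000) {
  structure(list(level = "slice", per_transect_pairs = integer(0),
                 slice_mean = mean, slice_sd = sd, n_transects = n,
                 screen_threshold = 0, n_redrawn = 0L),
            class = "increment_estimate")
}

# Fast config for tests: fewer transects, everything else at defaults.
test_config <- function(...) run_config(n_transects = 40, ...)
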