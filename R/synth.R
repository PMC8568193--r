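#' Synthetic noisy sine-wave increment pattern
#'
#' Generates the 1D test signal of the counting validation suite: a sine
#' wave with exactly `true_count` full periods across `length_px`
#' samples, offset to non-negative luminance, plus additive Gaussian
#' noise.  The noise level is parameterised by a pattern SNR in (0, 1]:
#' the noise standard deviation is `(1 - snr) * amplitude`, so stepping
#' the SNR down from 0.9 to 0.1 in 0.1 decrements raises the noise
#' standard deviation linearly from 0.1 to 0.9 of the signal amplitude.
#' Pass `noise_sd` to set the noise level directly instead.
#'
#' @param true_count Integer number of increments (full periods), >= 1.
#' @param length_px Number of samples; must be at least `4 * true_count`
#'   so each period is resolved.
#' @param amplitude Signal amplitude in luminance units.
#' @param snr Pattern signal-to-noise level in (0, 1]; 1 means
#'   noise-free.
#' @param noise_sd Optional explicit noise standard deviation,
#'   overriding `snr`.
#' @param seed Optional seed for the noise draw; identical seeds give
#'   identical patterns.
#' @return An object of class `sine_pattern`: list with `values`
#'   (non-negative noisy signal), `clean` (noiseless signal),
#'   `true_count`, `length_px`, `amplitude`, `snr`, `noise_sd`, `seed`.
#' @export
#' @examples
#' p <- make_sine(10, snr = 0.5, seed = 1)
#' p$true_count
make_sine <- function(true_count, length_px = 1000, amplitude = 100,
                      snr = 1, noise_sd = NULL, seed = NULL) {
  if (true_count < 1 || true_count != as.integer(true_count))
    stop("true_count must be an integer >= 1", call. = FALSE)
  if (length_px < 4 * true_count)
    stop("length_px must be at least 4 * true_count (", 4 * true_count,
         ")", call. = FALSE)
  if (is.null(noise_sd)) {
    if (!is.numeric(snr) || snr <= 0 || snr > 1)
      stop("snr must lie in (0, 1]", call. = FALSE)
    noise_sd <- (1 - snr) * amplitude
  }
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(length_px) - 1
  offset <- amplitude + 4 * noise_sd
  clean <- offset + amplitude * sin(2 * pi * true_count * t / length_px)
  values <- clean + if (noise_sd > 0) rnorm(length_px, 0, noise_sd) else 0
  structure(list(values = pmax(values, 0), clean = clean,
                 true_count = as.integer(true_count),
                 length_px = as.integer(length_px), amplitude = amplitude,
                 snr = snr, noise_sd = noise_sd, seed = seed),
            class = "sine_pattern")
}

#' @export
print.sine_pattern <- function(x, ...) {
  cat(sprintf("sine_pattern: %d increments over %d px, amplitude %g, noise sd %g\n",
              x$true_count, x$length_px, x$amplitude, x$noise_sd))
  invisible(x)
}

#' Synthetic banded-tissue phantom image
#'
#' Generates a 2D phantom emulating a straightened cementum band:
#' horizontal light/dark band pairs with a sinusoidal radial profile, an
#' optional monotone radial density gradient rising from the outer
#' surface (row 1) towards the cemento-dentine boundary (last row),
#' optional accessory-increment splitting of named bands over given
#' column ranges, and additive Gaussian noise.  Ground truth (pair count
#' and crest rows) is returned with the image.
#'
#' @param n_pairs True number of increment pairs (bands), >= 1.
#' @param width_px,height_px Image size; `height_px` must be at least
#'   `4 * n_pairs`, and at least `12 * n_pairs` when `split_events` are
#'   requested so the split is resolvable.
#' @param gradient Total luminance rise from the outer row to the
#'   cemento-dentine row (0 disables the gradient).
#' @param split_events Optional list of `list(band = j, cols = c(a, b))`
#'   entries: band `j` (1-based, outer first) is split into two maxima
#'   within 1-based columns `a:b`.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param amplitude Band amplitude in luminance units.
#' @param seed Optional seed for the noise draw.
#' @return An object of class `phantom_image`: list with `pixels`
#'   (height x width matrix, all values >= 0), `n_pairs`, `crest_rows`
#'   (1-based row of each band's luminance crest), `gradient`,
#'   `split_events`, `noise_sd`, `seed`.
#' @export
make_phantom <- function(n_pairs, width_px = 200, height_px = 400,
                         gradient = 0, split_events = NULL, noise_sd = 0,
                         amplitude = 1000, seed = NULL) {
  if (n_pairs < 1 || n_pairs != as.integer(n_pairs))
    stop("n_pairs must be an integer >= 1", call. = FALSE)
  if (height_px < 4 * n_pairs)
    stop("height_px must be at least 4 * n_pairs", call. = FALSE)
  if (length(split_events) && height_px < 12 * n_pairs)
    stop("band splitting needs height_px >= 12 * n_pairs to be resolvable",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- seq_len(height_px) - 1
  offset <- amplitude + 4 * noise_sd + abs(gradient)
  radial <- offset + amplitude * sin(2 * pi * n_pairs * (r + 0.5) / height_px)
  if (gradient != 0) radial <- radial + abs(gradient) * r / (height_px - 1)
  img <- matrix(radial, nrow = height_px, ncol = width_px)
  period <- height_px / n_pairs
  ex <- find_extrema(offset + amplitude * sin(2 * pi * n_pairs * (r + 0.5) / height_px))
  crest_rows <- ex$pos[ex$kind == "peak"]
  for (ev in split_events) {
    j <- ev$band
    if (j < 1 || j > n_pairs) stop("split band index ", j, " out of range",
                                   call. = FALSE)
    cols <- ev$cols[1L]:ev$cols[2L]
    if (min(cols) < 1 || max(cols) > width_px)
      stop("split column range out of image", call. = FALSE)
    # carve a narrow dark groove through the band's crest: the band splits
    # into two maxima inside the affected columns (an accessory increment)
    groove <- 1.5 * amplitude *
      exp(-(r + 1 - crest_rows[j])^2 / (2 * (period / 12)^2))
    img[, cols] <- pmax(img[, cols] - groove, 0)
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd),
                                        height_px, width_px)
  structure(list(pixels = pmax(img, 0), n_pairs = as.integer(n_pairs),
                 crest_rows = crest_rows, gradient = gradient,
                 split_events = split_events, noise_sd = noise_sd,
                 seed = seed),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom_image: %d increment pairs, %dx%d px, gradient %g, noise sd %g\n",
              x$n_pairs, nrow(x$pixels), ncol(x$pixels), x$gradient, x$noise_sd))
  invisible(x)
}
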