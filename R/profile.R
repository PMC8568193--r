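#' Radial luminance profile of one transect
#'
#' A radial profile is the per-row mean luminance of a thin vertical band
#' of a straightened image, ordered outer cementum surface first and
#' cemento-dentine boundary last.  The tissue extent starts at the first
#' value above zero (background fill is exactly 0 by construction of
#' [straighten()]).
#'
#' @param values Numeric vector of non-negative, finite mean luminances.
#' @param origin_column 1-based leftmost column of the band in the source
#'   image (`NA` for free-standing profiles such as synthetic patterns).
#' @param voxel_size_um Pixel edge length in micrometres.
#' @return An object of class `radial_profile`: list with `values`,
#'   `tissue_start` (index of the first value above zero, `NA` if none),
#'   `length_px` (tissue extent in pixels, 0 if none), `origin_column`,
#'   `voxel_size_um`.
#' @export
radial_profile <- function(values, origin_column = NA_integer_,
                           voxel_size_um = 0.66) {
  values <- as.numeric(values)
  if (!length(values) || any(!is.finite(values)) || any(values < 0))
    stop("profile values must be finite and >= 0", call. = FALSE)
  ts <- which(values > 0)[1L]
  structure(list(values = values,
                 tissue_start = if (is.na(ts)) NA_integer_ else as.integer(ts),
                 length_px = if (is.na(ts)) 0L else length(values) - ts + 1L,
                 origin_column = origin_column,
                 voxel_size_um = voxel_size_um),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial_profile: %d px, tissue extent %d px (from index %s)\n",
              length(x$values), x$length_px, format(x$tissue_start)))
  invisible(x)
}

# mean profile of a thickness-wide band starting at 1-based column `left`
band_profile <- function(image, left, thickness_px) {
  radial_profile(rowMeans(image[, left:(left + thickness_px - 1L), drop = FALSE]),
                 origin_column = left)
}

#' Sample random transects from a straightened image
#'
#' Draws `n` band positions uniformly (with replacement) over the valid
#' leftmost columns and averages each band's rows into a radial profile.
#' Random positions minimise autocorrelation between the sampled
#' increment patterns.  Positions are consumed from R's global random
#' number generator; seed it once per pipeline run (see
#' [run_config()]'s `rng_seed`).
#'
#' @param image A straightened image (matrix), width at least
#'   `thickness_px`.
#' @param n Number of transects.
#' @param thickness_px Band width in pixels.
#' @return List of `n` [radial_profile()] objects.
#' @export
sample_transects <- function(image, n = 1000, thickness_px = 10) {
  stopifnot(is.matrix(image))
  n_pos <- ncol(image) - thickness_px + 1L
  if (n_pos < 1L)
    stop("image width ", ncol(image), " is narrower than the transect thickness ",
         thickness_px, call. = FALSE)
  pos <- sample.int(n_pos, n, replace = TRUE)
  lapply(pos, band_profile, image = image, thickness_px = thickness_px)
}

#' Screen transects by tissue length
#'
#' Transects that sample too little tissue (e.g. bands that mostly miss
#' the cementum) are deselected and redrawn.  The acceptance threshold is
#' computed once from the original sample as
#' `mean(lengths) - sd(lengths)` and is not updated during resampling;
#' redrawn transects must meet the original threshold.  Transects with no
#' tissue at all (length 0) are always redrawn.
#'
#' @param profiles List of [radial_profile()]s from [sample_transects()].
#' @param image The straightened image the profiles were drawn from.
#' @param thickness_px Band width used for redraws.
#' @param max_draws Cap on total redraws (default `100 * length(profiles)`);
#'   exceeding it raises an error reporting the threshold and the best
#'   length found, which happens when no valid position exists.
#' @return List with `profiles` (all passing, same length as input),
#'   `threshold` (the length threshold in pixels) and `n_redrawn`.
#' @export
screen_lengths <- function(profiles, image, thickness_px = 10,
                           max_draws = 100L * length(profiles)) {
  if (length(profiles) < 2L) stop("need at least 2 profiles to screen", call. = FALSE)
  lens <- vapply(profiles, `[[`, numeric(1L), "length_px")
  if (all(lens == 0))
    stop("no pixel above zero in any sampled transect", call. = FALSE)
  threshold <- mean(lens) - sd(lens)
  n_pos <- ncol(image) - thickness_px + 1L
  drawn <- 0L; best <- max(lens)
  for (i in seq_along(profiles)) {
    while (profiles[[i]]$length_px < threshold || profiles[[i]]$length_px == 0L) {
      if (drawn >= max_draws)
        stop(sprintf(paste0("length screening failed: threshold %.2f px not met ",
                            "after %d redraws (best length %d px)"),
                     threshold, drawn, as.integer(best)), call. = FALSE)
      drawn <- drawn + 1L
      profiles[[i]] <- band_profile(image, sample.int(n_pos, 1L), thickness_px)
      best <- max(best, profiles[[i]]$length_px)
    }
  }
  cm_log("length screening: threshold %.2f px, %d of %d transects redrawn",
         threshold, drawn, length(profiles))
  list(profiles = profiles, threshold = threshold, n_redrawn = drawn)
}
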