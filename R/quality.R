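#' Extract a square region of interest
#'
#' @param slice 2D greyscale matrix.
#' @param x,y 0-based pixel coordinates of the ROI's top-left corner
#'   (`x` = column, `y` = row).
#' @param size Edge length in pixels (default 150, the conventional ROI
#'   for tomographic image-quality assessment of cementum).
#' @return A `size` x `size` matrix.
#' @export
roi_extract <- function(slice, x, y, size = 150) {
  stopifnot(is.matrix(slice))
  if (x < 0 || y < 0 || x + size > ncol(slice) || y + size > nrow(slice))
    stop("ROI (", x, ",", y, ") of size ", size, " falls outside the slice",
         call. = FALSE)
  slice[(y + 1):(y + size), (x + 1):(x + size)]
}

#' Signal-to-noise ratio of paired ROIs
#'
#' SNR is the mean greyscale value of a tissue (cementum) ROI divided by
#' the sample standard deviation of a background (air) ROI.
#'
#' @param cementum_roi Numeric matrix/vector of tissue pixel values.
#' @param background_roi Numeric matrix/vector of background pixel
#'   values; must not be constant.
#' @return Dimensionless ratio, invariant under multiplicative rescaling
#'   of the image.
#' @export
#' @examples
#' snr(matrix(100, 10, 10), matrix(rnorm(100, 0, 4), 10, 10))
snr <- function(cementum_roi, background_roi) {
  sb <- sd(as.vector(background_roi))
  if (!is.finite(sb) || sb == 0)
    stop("undefined SNR: background ROI has zero variance", call. = FALSE)
  mean(cementum_roi) / sb
}

#' Contrast-to-noise ratio of paired ROIs
#'
#' CNR is the difference of the mean greyscale values of the tissue and
#' background ROIs divided by their pooled standard deviation
#' `sqrt((sd_c^2 + sd_b^2) / 2)` (variances add for independent signals).
#'
#' @inheritParams snr
#' @return Dimensionless ratio, invariant under both multiplicative
#'   rescaling and additive offsets applied to the whole image; its sign
#'   follows the sign of the mean difference.
#' @export
cnr <- function(cementum_roi, background_roi) {
  vc <- var(as.vector(cementum_roi)); vb <- var(as.vector(background_roi))
  pooled <- sqrt((vc + vb) / 2)
  if (!is.finite(pooled) || pooled == 0)
    stop("undefined CNR: both ROIs are constant", call. = FALSE)
  (mean(cementum_roi) - mean(background_roi)) / pooled
}

#' Per-slice and mean image-quality metrics of a stack
#'
#' Computes SNR and CNR for each listed slice from a fixed pair of
#' user-placed ROIs (tissue and background at the same position in every
#' slice) and their means over the listed slices.
#'
#' @param stack A [slice_stack()].
#' @param cementum_xy,background_xy Length-2 vectors, 0-based (x, y)
#'   top-left corners of the tissue and background ROIs.
#' @param size ROI edge length in pixels.
#' @param slice_indices 1-based indices of the slices to assess
#'   (conventionally 10).
#' @return An object of class `quality_metrics`: list with `per_slice`
#'   (data frame of slice, snr, cnr), `mean_snr`, `mean_cnr`,
#'   `n_slices`.
#' @export
stack_quality <- function(stack, cementum_xy, background_xy, size = 150,
                          slice_indices = seq_along(stack$slices)) {
  stopifnot(inherits(stack, "slice_stack"))
  if (!length(slice_indices)) stop("slice_indices is empty", call. = FALSE)
  if (min(slice_indices) < 1L || max(slice_indices) > length(stack$slices))
    stop("slice_indices outside the stack", call. = FALSE)
  # non-overlap check (same placement applies to every slice)
  if (max(abs(cementum_xy - background_xy)) < size)
    stop("cementum and background ROIs overlap", call. = FALSE)
  res <- lapply(slice_indices, function(i) {
    tryCatch({
      s <- stack$slices[[i]]
      cem <- roi_extract(s, cementum_xy[1L], cementum_xy[2L], size)
      bg <- roi_extract(s, background_xy[1L], background_xy[2L], size)
      c(snr = snr(cem, bg), cnr = cnr(cem, bg))
    }, error = function(e) stop("slice ", i, ": ", conditionMessage(e),
                                call. = FALSE))
  })
  per_slice <- data.frame(slice = slice_indices,
                          snr = vapply(res, `[[`, numeric(1L), "snr"),
                          cnr = vapply(res, `[[`, numeric(1L), "cnr"))
  structure(list(per_slice = per_slice,
                 mean_snr = mean(per_slice$snr),
                 mean_cnr = mean(per_slice$cnr),
                 n_slices = length(slice_indices)),
            class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("quality_metrics over %d slice(s): mean SNR %.2f, mean CNR %.2f\n",
              x$n_slices, x$mean_snr, x$mean_cnr))
  invisible(x)
}
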