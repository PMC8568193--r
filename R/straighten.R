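#' User-annotated midline of the cementum band
#'
#' A midline is an ordered polyline of control points drawn along the
#' middle of the cementum band in one slice, together with the number of
#' pixels to sample on each side of it when straightening.
#'
#' @param control_points Two-column matrix or data frame of (x, y) pixel
#'   coordinates, 0-based (`x` = column, `y` = row); at least two points,
#'   consecutive points distinct.
#' @param half_width_px Pixels sampled on each side of the midline
#'   (>= 1); the straightened image has `2 * half_width_px + 1` rows.
#' @return An object of class `midline_path`.
#' @export
midline_path <- function(control_points, half_width_px) {
  cp <- as.matrix(control_points)[, 1:2, drop = FALSE]
  storage.mode(cp) <- "double"
  if (nrow(cp) < 2L) stop("a midline needs at least 2 control points", call. = FALSE)
  if (any(rowSums(abs(diff(cp))) == 0))
    stop("consecutive control points must be distinct", call. = FALSE)
  if (half_width_px < 1 || half_width_px != as.integer(half_width_px))
    stop("half_width_px must be an integer >= 1", call. = FALSE)
  structure(list(control_points = cp, half_width_px = as.integer(half_width_px)),
            class = "midline_path")
}

#' Interpolate a midline to a dense path
#'
#' Fits natural cubic splines x(t), y(t) through the control points
#' (parameterised by cumulative chord length) and resamples the curve at
#' unit arc-length steps, so one output sample corresponds to one pixel
#' of circumferential distance.
#'
#' @param control_points Two-column matrix of (x, y) control points, or a
#'   [midline_path()].
#' @param step_px Arc-length resampling step in pixels.
#' @return A two-column matrix of sub-pixel (x, y) path samples with
#'   attribute `arc_length` (total path length in pixels).  A
#'   self-intersecting path raises a warning, not an error.
#' @export
#' @examples
#' p <- fit_midline(cbind(c(0, 50, 100), c(10, 10, 10)))
#' nrow(p)  # 101 samples along a straight horizontal line
fit_midline <- function(control_points, step_px = 1) {
  if (inherits(control_points, "midline_path"))
    control_points <- control_points$control_points
  cp <- as.matrix(control_points)[, 1:2, drop = FALSE]
  storage.mode(cp) <- "double"
  if (nrow(cp) < 2L) stop("a midline needs at least 2 control points", call. = FALSE)
  seg <- sqrt(rowSums(diff(cp)^2))
  if (any(seg == 0)) stop("consecutive control points must be distinct", call. = FALSE)
  t0 <- c(0, cumsum(seg))
  # dense evaluation of the interpolating spline, then arc-length resampling
  dense_t <- seq(0, t0[length(t0)], length.out = max(20L * ceiling(t0[length(t0)]), 50L))
  xd <- spline(t0, cp[, 1L], method = "natural", xout = dense_t)$y
  yd <- spline(t0, cp[, 2L], method = "natural", xout = dense_t)$y
  s <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  total <- s[length(s)]
  out_s <- seq(0, total, by = step_px)
  path <- cbind(x = approx(s, xd, xout = out_s, ties = "ordered")$y,
                y = approx(s, yd, xout = out_s, ties = "ordered")$y)
  if (path_self_intersects(path)) warning("midline path self-intersects")
  attr(path, "arc_length") <- total
  path
}

# crude self-intersection check on a decimated copy of the path:
# non-neighbouring samples closer than half a pixel indicate a crossing
path_self_intersects <- function(path, stride = 5L) {
  idx <- seq(1L, nrow(path), by = stride)
  p <- path[idx, , drop = FALSE]
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  d <- as.matrix(stats::dist(p))
  gap <- abs(outer(seq_len(n), seq_len(n), "-"))
  any(d[gap > 2L] < 0.5)
}

# bilinear interpolation at 0-based (x, y); vectors x, y must be in bounds
bilinear <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  # clamp so that x0+1 stays a valid column when x is exactly the last index
  x0 <- pmin(x0, ncol(img) - 2L); y0 <- pmin(y0, nrow(img) - 2L)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  i <- y0 + 1L; j <- x0 + 1L
  n <- nrow(img)
  v00 <- img[(j - 1L) * n + i]
  v01 <- img[j * n + i]
  v10 <- img[(j - 1L) * n + i + 1L]
  v11 <- img[j * n + i + 1L]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

# unit normals of a dense path, oriented away from the image centroid
path_normals <- function(path, img_dim) {
  n <- nrow(path)
  tx <- c(path[2L, 1L] - path[1L, 1L],
          (path[3:n, 1L] - path[1:(n - 2L), 1L]) / 2,
          path[n, 1L] - path[n - 1L, 1L])
  ty <- c(path[2L, 2L] - path[1L, 2L],
          (path[3:n, 2L] - path[1:(n - 2L), 2L]) / 2,
          path[n, 2L] - path[n - 1L, 2L])
  len <- sqrt(tx^2 + ty^2)
  nx <- -ty / len; ny <- tx / len
  # consistent field; global sign chosen to point away from the centroid,
  # fixing the outer-surface-first row orientation of the straightened image
  cx <- (img_dim[2L] - 1) / 2; cy <- (img_dim[1L] - 1) / 2
  outward <- mean(nx * (path[, 1L] - cx) + ny * (path[, 2L] - cy))
  if (outward < 0) { nx <- -nx; ny <- -ny }
  cbind(nx = nx, ny = ny)
}

#' Straighten a slice along a midline
#'
#' Resamples the cementum band along the midline spline into a
#' rectangular image: each column is a profile of `2 * half_width + 1`
#' bilinearly interpolated values taken along the local normal of the
#' path, ordered so that row 1 is the outward side (outer cementum
#' surface, the normal direction pointing away from the image centroid)
#' and the last row the cemento-dentine boundary side.  Pixels outside
#' the tissue remain exactly 0, so downstream tissue-extent measurement
#' ("first pixel above zero") is well defined.
#'
#' @param slice A 2D greyscale matrix.
#' @param midline A [midline_path()].
#' @return A matrix of class `straightened_image` with
#'   `2 * half_width_px + 1` rows and one column per unit of arc length.
#'   Attribute `half_width_px` records the sampling half-width.
#' @export
straighten <- function(slice, midline) {
  stopifnot(is.matrix(slice), inherits(midline, "midline_path"))
  hw <- midline$half_width_px
  path <- fit_midline(midline$control_points)
  nrm <- path_normals(path, dim(slice))
  offsets <- seq(hw, -hw)           # row 1 = outward side
  h <- length(offsets); w <- nrow(path)
  xs <- outer(nrm[, "nx"], offsets) + path[, 1L]   # w x h
  ys <- outer(nrm[, "ny"], offsets) + path[, 2L]
  oob <- xs < 0 | xs > ncol(slice) - 1L | ys < 0 | ys > nrow(slice) - 1L
  if (any(oob)) {
    first <- which(oob, arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("normal sampling leaves image bounds at path sample %d",
                        " (offset %+d px); reduce half_width_px or redraw the midline"),
                 first[1L], offsets[first[2L]]), call. = FALSE)
  }
  out <- t(matrix(bilinear(slice, as.vector(xs), as.vector(ys)), nrow = w, ncol = h))
  structure(out, class = c("straightened_image", "matrix", "array"),
            half_width_px = hw)
}

#' Apply one midline to a range of slices
#'
#' Straightens every slice in `slice_range` with the same midline, the
#' usual semi-automated propagation across a stack: one annotation is
#' reused until the tissue drifts out of it.  The fraction of non-zero
#' output pixels ("tissue coverage") is recorded per slice so the user
#' can decide where the midline must be re-drawn; a slice for which the
#' midline leaves the image bounds is skipped with a warning rather than
#' aborting the run.
#'
#' @param stack A [slice_stack()].
#' @param midline A [midline_path()].
#' @param slice_range Integer vector of 1-based slice indices (possibly
#'   empty).
#' @return A list with `images` (named list of straightened images for
#'   the successfully processed slices) and `coverage` (data frame of
#'   slice index and coverage fraction, `NA` for skipped slices).
#' @export
propagate_midline <- function(stack, midline, slice_range = seq_along(stack$slices)) {
  stopifnot(inherits(stack, "slice_stack"))
  if (length(slice_range) &&
      (min(slice_range) < 1L || max(slice_range) > length(stack$slices)))
    stop("slice_range outside the stack", call. = FALSE)
  images <- list()
  coverage <- data.frame(slice = integer(0), coverage = numeric(0))
  for (i in slice_range) {
    res <- tryCatch(straighten(stack$slices[[i]], midline), error = function(e) e)
    if (inherits(res, "error")) {
      warning("slice ", i, " skipped: ", conditionMessage(res), call. = FALSE)
      coverage <- rbind(coverage, data.frame(slice = i, coverage = NA_real_))
      next
    }
    cov <- mean(res > 0)
    cm_log("slice %d straightened, coverage %.3f", i, cov)
    images[[as.character(i)]] <- res
    coverage <- rbind(coverage, data.frame(slice = i, coverage = cov))
  }
  list(images = images, coverage = coverage)
}
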