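#' Greyscale slice stacks
#'
#' A `slice_stack` is an ordered list of 2D greyscale matrices (integer
#' luminance in the declared bit range) sharing identical dimensions, plus
#' the physical voxel size.
#'
#' @param slices List of numeric matrices with identical dimensions.
#' @param voxel_size_um Pixel edge length in micrometres (> 0).
#' @param bit_depth 8 or 16.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, voxel_size_um = 0.66, bit_depth = 16) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("slices must be a non-empty list of matrices", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (voxel_size_um <= 0) stop("voxel_size_um must be > 0", call. = FALSE)
  d <- dim(slices[[1L]])
  for (i in seq_along(slices)) {
    m <- slices[[i]]
    if (!is.matrix(m)) stop("slice ", i, " is not a 2D greyscale matrix", call. = FALSE)
    if (!identical(dim(m), d))
      stop("slice ", i, " has dimensions ", paste(dim(m), collapse = "x"),
           ", expected ", paste(d, collapse = "x"), call. = FALSE)
    if (any(m < 0) || any(m > 2^bit_depth - 1))
      stop("slice ", i, " has values outside the declared ", bit_depth,
           "-bit range", call. = FALSE)
  }
  structure(list(slices = slices, voxel_size_um = voxel_size_um,
                 bit_depth = as.integer(bit_depth)), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1L]])
  cat(sprintf("slice_stack: %d slice(s) of %dx%d px, %d-bit, voxel %.3g um\n",
              length(x$slices), d[1L], d[2L], x$bit_depth, x$voxel_size_um))
  invisible(x)
}

# read one TIFF file; returns list of integer matrices with bit depth attr
read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] == 1L) p <- p[, , 1L]
      else stop("page ", i, " of '", path, "' is not greyscale (",
                dim(p)[3L], " channels)", call. = FALSE)
    }
    bits <- attr(pages[[i]], "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    storage.mode(p) <- "double"
    attr(p, "bits.per.sample") <- as.integer(bits)
    p
  })
}

#' Read a greyscale TIFF stack
#'
#' Reads either a multi-page TIFF file or a directory of single-page TIFF
#' files (ordered lexicographically by filename, matching common beamline
#' export naming) into a [slice_stack()].  Bit depth is taken from the
#' file metadata; non-greyscale or mixed-dimension input is an error
#' naming the offending page.
#'
#' @param path Path to a TIFF file or a directory of TIFF files.
#' @param voxel_size_um Pixel edge length in micrometres.
#' @return A `slice_stack`.
#' @export
read_stack <- function(path, voxel_size_um = 0.66) {
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) stop("no TIFF files found in ", path, call. = FALSE)
    pages <- do.call(c, lapply(files, read_tiff_pages))
  } else {
    pages <- read_tiff_pages(path)
  }
  bits <- unique(vapply(pages, attr, integer(1L), "bits.per.sample"))
  if (length(bits) != 1L)
    stop("mixed bit depths across pages: ", paste(bits, collapse = ", "),
         call. = FALSE)
  slices <- lapply(pages, function(p) { attr(p, "bits.per.sample") <- NULL; p })
  slice_stack(slices, voxel_size_um = voxel_size_um, bit_depth = bits)
}

#' Write a slice stack as a multi-page TIFF
#'
#' Pixel values are written at the stack's declared bit depth; a write
#' followed by [read_stack()] reproduces every pixel value exactly.
#'
#' @param stack A `slice_stack`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  denom <- 2^stack$bit_depth - 1
  tiff::writeTIFF(lapply(stack$slices, function(m) m / denom), path,
                  bits.per.sample = stack$bit_depth)
  invisible(path)
}

#' Read a midline sidecar file
#'
#' The sidecar is a CSV of control points with columns `slice_index`, `x`
#' and `y` in 0-based pixel coordinates (`x` = column, `y` = row).  The
#' on-disk format is a convention of this package; the annotations
#' themselves are user-drawn.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `slice_index`, `x`, `y`.
#' @export
read_midline <- function(path) {
  df <- read.csv(path)
  need <- c("slice_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("midline sidecar must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' Write an increment-count report
#'
#' Writes a delimited (CSV) report with one row per slice (slice index,
#' mean pair count over its transects, the standard deviation and the
#' number of accepted transects) and one summary row per specimen
#' carrying the specimen mean, its rounded count and the spread over
#' slice means.  Output is bitwise-stable for a fixed input.
#'
#' @param estimates A specimen-level estimate from [count_specimen()] or
#'   a (possibly named) list of them.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(estimates, path) {
  if (inherits(estimates, "increment_estimate")) estimates <- list(estimates)
  if (!is.list(estimates) || length(estimates) == 0L)
    stop("estimates must be a non-empty list of specimen estimates", call. = FALSE)
  if (is.null(names(estimates)))
    names(estimates) <- paste0("specimen", seq_along(estimates))
  lines <- "record,specimen,slice_index,mean_pairs,sd_pairs,n,rounded_count"
  for (nm in names(estimates)) {
    est <- estimates[[nm]]
    if (!inherits(est, "increment_estimate") || est$level != "specimen")
      stop("estimates for '", nm, "' is not a specimen-level increment_estimate",
           call. = FALSE)
    for (i in seq_along(est$slices)) {
      s <- est$slices[[i]]
      lines <- c(lines, sprintf("slice,%s,%d,%.2f,%.2f,%d,", nm, i - 1L,
                                s$slice_mean, s$slice_sd, s$n_transects))
    }
    lines <- c(lines, sprintf("specimen,%s,,%.2f,%.2f,%d,%.2f", nm,
                              est$specimen_mean, est$specimen_sd,
                              length(est$slices), est$specimen_count))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
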