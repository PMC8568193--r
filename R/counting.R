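#' Split a transect's tissue extent into equal-length sections
#'
#' Tomographic cementum shows an overarching density gradient from the
#' cemento-dentine boundary out to the surface, so increment statistics
#' are taken per section rather than over the whole transect.  The tissue
#' extent is split into `k` contiguous sections whose lengths differ by
#' at most one pixel; remainder pixels are assigned to the innermost
#' sections (inner cementum is the oldest and densest tissue, where thin
#' increments least afford losing context).
#'
#' @param profile A [radial_profile()] with tissue extent at least `k`.
#' @param k Number of sections.
#' @return List of `k` lists, each with `values` (section luminances) and
#'   `start` (1-based index of the section's first sample within the full
#'   profile).
#' @export
split_sections <- function(profile, k = 5) {
  stopifnot(inherits(profile, "radial_profile"))
  if (profile$length_px < k)
    stop("tissue extent (", profile$length_px, " px) shorter than ", k,
         " sections", call. = FALSE)
  tissue <- profile$values[profile$tissue_start:length(profile$values)]
  n <- length(tissue)
  lens <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) lens[(k - rem + 1L):k] <- lens[1L] + 1L
  ends <- cumsum(lens); starts <- ends - lens + 1L
  lapply(seq_len(k), function(i)
    list(values = tissue[starts[i]:ends[i]],
         start = profile$tissue_start + starts[i] - 1L))
}

#' Smooth a section and compute its statistics
#'
#' Fits a cubic smoothing spline to the section's luminance values to
#' suppress image noise before peak--trough detection, then derives the
#' section statistics used as counting thresholds: the section mean, its
#' standard deviation, and upper/lower cut-offs at
#' `mean +/- cutoff_factor * sd` of the smoothed values.
#'
#' @param values Numeric vector of section luminances (length >= 4).
#' @param cutoff_factor Fraction of the standard deviation forming the
#'   cut-offs (default 0.5).
#' @param spar Optional [stats::smooth.spline()] smoothing parameter;
#'   `NULL` selects it by generalized cross-validation.
#' @return List with `smoothed` (values at the original positions) and
#'   `stats`, itself a list with `mean_g`, `sd`, `upper_cutoff`,
#'   `lower_cutoff`.
#' @export
smooth_section <- function(values, cutoff_factor = 0.5, spar = NULL) {
  n <- length(values)
  if (n < 4L) stop("section too short to smooth (", n, " < 4 samples)",
                   call. = FALSE)
  if (sd(values) == 0) {
    sm <- values
  } else {
    fit <- if (is.null(spar)) smooth.spline(seq_len(n), values, cv = FALSE)
           else smooth.spline(seq_len(n), values, spar = spar)
    sm <- predict(fit, seq_len(n))$y
  }
  mg <- mean(sm); sdg <- sd(sm)
  list(smoothed = sm,
       stats = list(mean_g = mg, sd = sdg,
                    upper_cutoff = mg + cutoff_factor * sdg,
                    lower_cutoff = mg - cutoff_factor * sdg))
}

# interior local extrema of a series, plateaus collapsed to their centre
find_extrema <- function(s) {
  out <- data.frame(kind = character(0), pos = integer(0))
  if (length(s) < 3L) return(out)
  r <- rle(s)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  m <- length(r$values)
  if (m < 3L) return(out)
  v <- r$values
  i <- 2:(m - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  sel <- i[is_max | is_min]
  if (!length(sel)) return(out)
  data.frame(kind = ifelse(is_max[sel - 1L], "peak", "trough"),
             pos = starts[sel] + (r$lengths[sel] - 1L) %/% 2L)
}

#' Detect counted peak--trough events in a smoothed section
#'
#' Peaks are sought among the above-mean values and troughs among the
#' below-mean values (trough detection on the negated series); an
#' extremum is counted only if it extends beyond its cut-off.  Two
#' rejection rules then remove "piggy-back" features caused by accessory
#' increments or residual noise: counted events closer together than
#' `min_separation_px` are merged, keeping the larger departure from the
#' mean (ties: the smaller index); and counted events must alternate
#' peak/trough, a run of same-kind events keeping only its largest
#' departure, so that only one peak is counted for every trough.  The
#' pair count is the number of counted peaks: after alternation
#' enforcement each counted peak heads exactly one light--dark
#' (peak--trough) system, including systems whose trough falls in the
#' neighbouring section.
#'
#' @param smoothed Smoothed section values from [smooth_section()].
#' @param stats Section statistics from [smooth_section()].
#' @param min_separation_px Minimum separation of counted events in
#'   pixels (default 3, i.e. 1.98 um at 0.66 um voxels).
#' @return List with `events` (data frame of `kind`, `position_px` --
#'   1-based index within the section --, `value`, `excess`) and
#'   `n_pairs` (integer pair count; an empty or flat section yields 0).
#' @export
detect_pairs <- function(smoothed, stats, min_separation_px = 3) {
  ev <- find_extrema(smoothed)
  if (nrow(ev)) {
    val <- smoothed[ev$pos]
    keep <- (ev$kind == "peak" & val > stats$upper_cutoff) |
      (ev$kind == "trough" & val < stats$lower_cutoff)
    ev <- ev[keep, , drop = FALSE]
  }
  if (!nrow(ev)) {
    return(list(events = data.frame(kind = character(0), position_px = integer(0),
                                    value = numeric(0), excess = numeric(0)),
                n_pairs = 0L))
  }
  ev$value <- smoothed[ev$pos]
  ev$excess <- abs(ev$value - stats$mean_g)
  # minimum-separation merge (keep larger excess, then smaller index)
  repeat {
    if (nrow(ev) < 2L) break
    close <- which(diff(ev$pos) < min_separation_px)
    if (!length(close)) break
    j <- close[1L]
    ev <- ev[-(if (ev$excess[j] >= ev$excess[j + 1L]) j + 1L else j), , drop = FALSE]
  }
  # strict alternation of counted events
  repeat {
    if (nrow(ev) < 2L) break
    same <- which(ev$kind[-nrow(ev)] == ev$kind[-1L])
    if (!length(same)) break
    j <- same[1L]
    ev <- ev[-(if (ev$excess[j] >= ev$excess[j + 1L]) j + 1L else j), , drop = FALSE]
  }
  events <- data.frame(kind = ev$kind, position_px = ev$pos,
                       value = ev$value, excess = ev$excess)
  list(events = events, n_pairs = sum(events$kind == "peak"))
}

#' Recover increments split across a section boundary
#'
#' An increment whose crest straddles the boundary between two sections
#' presents only an ascending limb to one section and a descending limb
#' to the other, so neither section detects it as a peak.  This pass
#' concatenates the left section's values beyond its last counted event
#' with the right section's values before its first counted event and
#' adds one pair when that limb contains an uncounted apex: an interior
#' local maximum exceeding the upper cut-off of the section it lies in,
#' with the limb also dropping below the lower cut-off of the section
#' containing its minimum (evidence of a full light--dark swing).  The
#' interior condition rejects mere shoulders of already-counted peaks, so
#' a crest fully inside one section adds nothing.  Each boundary
#' contributes at most one pair.
#'
#' @param left,right Lists with elements `smoothed`, `events` (from
#'   [detect_pairs()]) and `stats` (from [smooth_section()]) for two
#'   adjacent sections in profile order.
#' @return Integer 0 or 1.
#' @export
boundary_pass <- function(left, right) {
  nL <- length(left$smoothed)
  tail_start <- if (nrow(left$events)) max(left$events$position_px) + 1L else 1L
  head_end <- if (nrow(right$events)) min(right$events$position_px) - 1L
              else length(right$smoothed)
  limb <- c(if (tail_start <= nL) left$smoothed[tail_start:nL],
            if (head_end >= 1L) right$smoothed[seq_len(head_end)])
  side <- c(if (tail_start <= nL) rep(1L, nL - tail_start + 1L),
            if (head_end >= 1L) rep(2L, head_end))
  m <- length(limb)
  if (m < 3L) return(0L)
  upper <- c(left$stats$upper_cutoff, right$stats$upper_cutoff)
  lower <- c(left$stats$lower_cutoff, right$stats$lower_cutoff)
  ia <- which.max(limb); iv <- which.min(limb)
  apex_interior <- ia > 1L && ia < m &&
    any(limb[seq_len(ia - 1L)] < limb[ia]) && any(limb[(ia + 1L):m] < limb[ia])
  if (apex_interior && limb[ia] > upper[side[ia]] && limb[iv] < lower[side[iv]])
    1L else 0L
}

#' Count increment pairs along one transect
#'
#' The full per-transect procedure: the tissue extent is split into
#' `cfg$n_sections` sections, each section is smoothed and its counted
#' peak--trough events found with the rejection rules of
#' [detect_pairs()], boundary-straddling increments are recovered by
#' [boundary_pass()], and the per-section pair counts are summed.  All
#' statistics are relative, so counts are invariant under affine
#' transforms `a * profile + b` (a > 0) of the luminance scale.
#'
#' @param profile A screened [radial_profile()].
#' @param cfg A [run_config()].
#' @return Integer pair count for the transect.
#' @export
count_transect <- function(profile, cfg = run_config()) {
  secs <- split_sections(profile, cfg$n_sections)
  parts <- lapply(secs, function(s) {
    sm <- smooth_section(s$values, cutoff_factor = cfg$cutoff_factor,
                         spar = cfg$smooth_spar)
    dp <- detect_pairs(sm$smoothed, sm$stats,
                       min_separation_px = cfg$min_separation_px)
    list(smoothed = sm$smoothed, stats = sm$stats, events = dp$events,
         n_pairs = dp$n_pairs)
  })
  total <- sum(vapply(parts, `[[`, integer(1L), "n_pairs"))
  if (length(parts) > 1L) {
    for (i in seq_len(length(parts) - 1L))
      total <- total + boundary_pass(parts[[i]], parts[[i + 1L]])
  }
  as.integer(total)
}

#' Estimate the increment-pair count of one slice
#'
#' Samples `cfg$n_transects` random transects from a straightened image,
#' screens them by tissue length, counts pairs along each accepted
#' transect and summarises the counts: the slice estimate is their mean,
#' with the standard deviation as dispersion.
#'
#' @param image A straightened image (matrix; increments horizontal).
#' @param cfg A [run_config()].
#' @param seed Optional seed applied before sampling; leave `NULL` when
#'   the caller (e.g. [count_stack()]) has already seeded the generator.
#' @return An object of class `increment_estimate` (level `"slice"`)
#'   with `per_transect_pairs`, `slice_mean`, `slice_sd`, `n_transects`,
#'   `screen_threshold`, `n_redrawn`.
#' @export
count_slice <- function(image, cfg = run_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  profiles <- sample_transects(image, n = cfg$n_transects,
                               thickness_px = cfg$transect_thickness_px)
  scr <- screen_lengths(profiles, image,
                        thickness_px = cfg$transect_thickness_px)
  counts <- vapply(scr$profiles, count_transect, integer(1L), cfg = cfg)
  structure(list(level = "slice",
                 per_transect_pairs = counts,
                 slice_mean = mean(counts),
                 slice_sd = if (length(counts) > 1L) sd(counts) else 0,
                 n_transects = length(counts),
                 screen_threshold = scr$threshold,
                 n_redrawn = scr$n_redrawn),
            class = "increment_estimate")
}

#' Aggregate slice estimates to a specimen estimate
#'
#' The specimen mean is the mean of the slice means; the final count is
#' that mean rounded to the nearest integer (default) or, for comparison
#' with expected counts known to half-year eruption uncertainty, to the
#' nearest 0.25 (`rounding_mode = "quarter"`).  Half-way ties round away
#' from zero.
#'
#' @param slice_estimates Non-empty list of slice-level estimates from
#'   [count_slice()].
#' @param rounding_mode `"integer"` or `"quarter"`.
#' @return An `increment_estimate` (level `"specimen"`) with
#'   `specimen_mean`, `specimen_sd` (spread of the slice means),
#'   `specimen_count`, `rounding_mode` and the input `slices`.
#' @export
count_specimen <- function(slice_estimates, rounding_mode = c("integer", "quarter")) {
  rounding_mode <- match.arg(rounding_mode)
  if (!is.list(slice_estimates) || !length(slice_estimates))
    stop("slice_estimates must be a non-empty list", call. = FALSE)
  ok <- vapply(slice_estimates, function(e)
    inherits(e, "increment_estimate") && e$level == "slice", logical(1L))
  if (!all(ok)) stop("all elements must be slice-level increment_estimates",
                     call. = FALSE)
  means <- vapply(slice_estimates, `[[`, numeric(1L), "slice_mean")
  mu <- mean(means)
  count <- switch(rounding_mode,
                  integer = round_half_away(mu),
                  quarter = round_half_away(mu * 4) / 4)
  structure(list(level = "specimen",
                 specimen_mean = mu,
                 specimen_sd = if (length(means) > 1L) sd(means) else 0,
                 specimen_count = count,
                 rounding_mode = rounding_mode,
                 slices = slice_estimates),
            class = "increment_estimate")
}

#' Run the counting pipeline over a set of straightened slices
#'
#' Seeds the random number generator once from `cfg$rng_seed`, counts
#' every slice and aggregates to the specimen estimate, so two runs with
#' the same seed and inputs produce identical reports.
#'
#' @param images List of straightened images (matrices) -- conventionally
#'   the 30 highest-contrast slices of a specimen.
#' @param cfg A [run_config()].
#' @return A specimen-level `increment_estimate`.
#' @export
count_stack <- function(images, cfg = run_config()) {
  if (!is.list(images) || !length(images))
    stop("images must be a non-empty list of straightened slices", call. = FALSE)
  set.seed(cfg$rng_seed)
  slices <- lapply(images, count_slice, cfg = cfg)
  count_specimen(slices, rounding_mode = cfg$rounding_mode)
}

#' @export
print.increment_estimate <- function(x, ...) {
  if (x$level == "slice") {
    cat(sprintf("increment_estimate (slice): mean %.2f pairs, sd %.2f over %d transects\n",
                x$slice_mean, x$slice_sd, x$n_transects))
  } else {
    cat(sprintf("increment_estimate (specimen): mean %.2f pairs over %d slice(s), count %s (%s rounding)\n",
                x$specimen_mean, length(x$slices), format(x$specimen_count),
                x$rounding_mode))
  }
  invisible(x)
}
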