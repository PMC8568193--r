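#' Sine-wave robustness sweep of the counting algorithm
#'
#' Runs the full counting procedure ([count_transect()] with the
#' configured sections, cut-offs and rejection rules) on replicated noisy
#' sine patterns over a grid of true increment counts and SNR levels, and
#' summarises each cell by the mean and standard deviation of the
#' estimated counts.  A cell is flagged *accurate* when its mean is
#' within 0.5 of the true count and *robust* when its standard deviation
#' is below 1 (a larger spread could move an age estimate by more than a
#' year).  Replicate seeds are derived from the master seed by fixed
#' offsets, so every cell is independently reproducible; a failing
#' replicate yields an `NA` cell with a warning rather than aborting the
#' sweep.
#'
#' @param cfg A [run_config()].
#' @param counts Integer vector of true increment counts (default 5:30).
#' @param snrs Numeric vector of pattern SNR levels (default 0.9 down to
#'   0.1; see [make_sine()] for the noise parameterisation).
#' @param reps Replicates per cell (default 30).
#' @param seed Master seed.
#' @param length_px,amplitude Sine pattern geometry, passed to
#'   [make_sine()].
#' @return An object of class `robustness_report`: a data frame with one
#'   row per (true_count, snr) cell and columns `true_count`, `snr`,
#'   `mean_count`, `sd_count`, `n_reps`, `accuracy_flag`
#'   (`|mean - truth| <= 0.5`), `robustness_flag` (`sd < 1`).  The grid
#'   dimensions are stored in attributes `counts` and `snrs`.
#' @export
robustness_sweep <- function(cfg = run_config(), counts = 5:30,
                             snrs = seq(0.9, 0.1, by = -0.1), reps = 30,
                             seed = 1, length_px = 1000, amplitude = 100) {
  grid <- expand.grid(true_count = counts, snr = snrs,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(ci) {
    tc <- grid$true_count[ci]; sn <- grid$snr[ci]
    est <- vapply(seq_len(reps), function(rep) {
      tryCatch({
        p <- make_sine(tc, length_px = length_px, amplitude = amplitude,
                       snr = sn, seed = seed + 1000L * ci + rep)
        count_transect(radial_profile(p$values), cfg)
      }, error = function(e) {
        warning(sprintf("cell (count %d, snr %.1f) replicate %d failed: %s",
                        tc, sn, rep, conditionMessage(e)), call. = FALSE)
        NA_integer_
      })
    }, integer(1L))
    est <- est[!is.na(est)]
    if (!length(est)) c(mean_count = NA_real_, sd_count = NA_real_, n_reps = 0)
    else c(mean_count = mean(est),
           sd_count = if (length(est) > 1L) sd(est) else 0,
           n_reps = length(est))
  })
  res <- do.call(rbind, res)
  report <- cbind(grid, as.data.frame(res))
  report$accuracy_flag <- abs(report$mean_count - report$true_count) <= 0.5
  report$robustness_flag <- report$sd_count < 1
  structure(report, counts = counts, snrs = snrs, reps = reps, seed = seed,
            class = c("robustness_report", "data.frame"))
}

#' Summarise a robustness report
#'
#' Computes, per SNR level, the fraction of true counts whose cells pass
#' the accuracy flag (`|mean - truth| <= 0.5`) and the robustness flag
#' (`sd < 1`).  The summary converts directly to JSON.
#'
#' @param report A complete `robustness_report` from
#'   [robustness_sweep()]; an incomplete grid (missing or all-failed
#'   cells) is an error.
#' @return List with `per_snr` (data frame of `snr`, `accuracy_rate`,
#'   `robustness_rate`, `n_counts`) and the overall rates
#'   `accuracy_rate` and `robustness_rate`.
#' @export
assess_robustness <- function(report) {
  if (!inherits(report, "robustness_report")) stop("not a robustness_report",
                                                   call. = FALSE)
  counts <- attr(report, "counts"); snrs <- attr(report, "snrs")
  if (nrow(report) != length(counts) * length(snrs) ||
      any(is.na(report$mean_count)))
    stop("incomplete robustness grid", call. = FALSE)
  per_snr <- do.call(rbind, lapply(snrs, function(s) {
    sub <- report[report$snr == s, ]
    data.frame(snr = s,
               accuracy_rate = mean(sub$accuracy_flag),
               robustness_rate = mean(sub$robustness_flag),
               n_counts = nrow(sub))
  }))
  list(per_snr = per_snr,
       accuracy_rate = mean(report$accuracy_flag),
       robustness_rate = mean(report$robustness_flag))
}
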