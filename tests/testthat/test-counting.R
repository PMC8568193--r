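test_that("transect sampling is deterministic, uniform over valid positions", {
  img <- matrix(5, 50, 10)  # width equals thickness: one valid position
  set.seed(1)
  p <- sample_transects(img, n = 7, thickness_px = 10)
  expect_length(p, 7L)
  expect_true(all(vapply(p, `[[`, integer(1), "origin_column") == 1L))
  expect_true(all(vapply(p, function(x) all(x$values == 5), logical(1))))
  expect_error(sample_transects(img, 5, thickness_px = 11), "narrower")

  img2 <- matrix(runif(50 * 60), 50, 60)
  set.seed(99); a <- sample_transects(img2, 20)
  set.seed(99); b <- sample_transects(img2, 20)
  expect_identical(a, b)
})

test_that("length screening uses mean - SD of the original sample, computed once", {
  # hand-computed example: lengths {100,100,100,100,40} -> threshold 61.17
  long <- radial_profile(c(rep(0, 20), rep(1, 100)))
  short <- radial_profile(c(rep(0, 80), rep(1, 40)))
  profiles <- c(rep(list(long), 4), list(short))
  img <- rbind(matrix(0, 20, 50), matrix(1, 100, 50))  # every redraw has length 100
  set.seed(5)
  scr <- screen_lengths(profiles, img, thickness_px = 10)
  expect_equal(scr$threshold, mean(c(100, 100, 100, 100, 40)) -
                 sd(c(100, 100, 100, 100, 40)))
  expect_equal(scr$threshold, 61.16718, tolerance = 1e-5)
  expect_gte(scr$n_redrawn, 1L)
  lens <- vapply(scr$profiles, `[[`, integer(1), "length_px")
  expect_true(all(lens >= scr$threshold))
  expect_length(scr$profiles, 5L)

  # equal lengths: threshold = mean, nothing redrawn
  set.seed(5)
  scr2 <- screen_lengths(rep(list(long), 4), img, thickness_px = 10)
  expect_equal(scr2$n_redrawn, 0L)

  # an image with no tissue at all cannot be screened
  zero <- matrix(0, 50, 30)
  set.seed(5)
  pz <- sample_transects(zero, 10)
  expect_error(screen_lengths(pz, zero), "no pixel above zero")
})

test_that("sections split the tissue extent evenly, remainder innermost", {
  p <- radial_profile(c(0, 0, seq_len(100)))
  s <- split_sections(p, 5)
  expect_equal(vapply(s, function(x) length(x$values), integer(1)), rep(20L, 5))
  expect_equal(s[[1]]$start, 3L)

  p2 <- radial_profile(seq_len(103))
  s2 <- split_sections(p2, 5)
  expect_equal(vapply(s2, function(x) length(x$values), integer(1)),
               c(20L, 20L, 21L, 21L, 21L))
  expect_equal(unlist(lapply(s2, `[[`, "values")), as.numeric(1:103))

  expect_equal(length(split_sections(p2, 1)[[1]]$values), 103L)
  expect_error(split_sections(radial_profile(c(1, 1, 1)), 5), "shorter")
})

test_that("smoothing preserves clean signals and degrades gracefully", {
  # noiseless sine: smoothed stays within 1% of the input amplitude
  x <- 100 + 50 * sin(2 * pi * (0:199) / 50)
  sm <- smooth_section(x)
  expect_lt(max(abs(sm$smoothed - x)), 0.01 * 50)

  # constant: untouched, sd 0, cut-offs collapse onto the mean
  smc <- smooth_section(rep(4, 30))
  expect_equal(smc$smoothed, rep(4, 30))
  expect_equal(smc$stats$sd, 0)
  expect_equal(smc$stats$upper_cutoff, 4)
  expect_equal(smc$stats$lower_cutoff, 4)

  # linear ramp: mean is the midpoint, cut-offs symmetric about it
  smr <- smooth_section(seq(0, 10, length.out = 101))
  expect_equal(smr$stats$mean_g, 5, tolerance = 1e-6)
  expect_equal(smr$stats$upper_cutoff - smr$stats$mean_g,
               smr$stats$mean_g - smr$stats$lower_cutoff, tolerance = 1e-9)

  expect_error(smooth_section(c(1, 2, 3)), "too short")
})

test_that("peak-trough detection applies cut-off, separation and alternation rules", {
  # flat section: nothing to count
  smf <- smooth_section(rep(1, 20))
  expect_equal(detect_pairs(smf$smoothed, smf$stats)$n_pairs, 0L)

  # two clean periods: two pairs, events alternating
  x <- 100 + 50 * sin(2 * pi * (0:199) / 100)
  smx <- smooth_section(x)
  dp <- detect_pairs(smx$smoothed, smx$stats)
  expect_equal(dp$n_pairs, 2L)
  expect_true(all(dp$events$kind[-1] != dp$events$kind[-nrow(dp$events)]))

  # two supra-cutoff peaks 2 px apart with one trough: merged to one pair
  s <- c(0, 0, 6, 5, 6.5, 0, -3, -8, -3, 0, 0)
  st <- list(mean_g = 0, sd = 4, upper_cutoff = 2, lower_cutoff = -2)
  dp2 <- detect_pairs(s, st, min_separation_px = 3)
  expect_equal(dp2$n_pairs, 1L)
  expect_equal(nrow(dp2$events), 2L)
  expect_equal(dp2$events$position_px[dp2$events$kind == "peak"], 5L)  # larger excess

  # sub-cutoff wiggles are ignored
  s3 <- c(0, 1, 0, -1, 0, 0, 6, 0, 0, 0, -8, 0, 0)
  dp3 <- detect_pairs(s3, st)
  expect_equal(dp3$n_pairs, 1L)

  # the separation rule also merges a peak-trough pairing closer than 3 px
  s4 <- c(0, 0, 6, 0, -8, 0, 0)
  dp4 <- detect_pairs(s4, st, min_separation_px = 3)
  expect_equal(dp4$n_pairs, 0L)  # trough kept (larger excess), peak dropped
})

test_that("counted events alternate and counts stay bounded on noisy profiles", {
  cfg <- run_config()
  for (seed in 1:8) {
    p <- make_sine(12, snr = 0.5, seed = seed)
    secs <- split_sections(radial_profile(p$values), cfg$n_sections)
    total <- 0L
    for (s in secs) {
      sm <- smooth_section(s$values)
      dp <- detect_pairs(sm$smoothed, sm$stats)
      if (nrow(dp$events) > 1L)
        expect_true(all(dp$events$kind[-1] != dp$events$kind[-nrow(dp$events)]))
      expect_true(all(diff(dp$events$position_px) >= cfg$min_separation_px))
      total <- total + dp$n_pairs
    }
    expect_gte(total, 0L)
    expect_lte(total, 1000 / (2 * cfg$min_separation_px) + cfg$n_sections)
  }
})

test_that("boundary pass recovers crests split across section boundaries", {
  # cosine: every crest sits exactly on a section boundary (or an endpoint)
  t <- 0:999
  y <- 200 + 100 * cos(2 * pi * 5 * t / 1000)
  prof <- radial_profile(y)
  k5 <- count_transect(prof, run_config())
  k1 <- count_transect(prof, run_config(n_sections = 1))
  expect_equal(k1, 4L)  # 4 interior crests; the one at t=0 has no left flank
  expect_equal(k5, k1)

  # crest fully inside a section: the pass must not double count
  ysin <- 200 + 100 * sin(2 * pi * 5 * t / 1000)
  expect_equal(count_transect(radial_profile(ysin), run_config()), 5L)

  # flat flanks contribute nothing
  smf <- smooth_section(rep(1, 50))
  part <- list(smoothed = smf$smoothed, stats = smf$stats,
               events = data.frame(kind = character(0), position_px = integer(0),
                                   value = numeric(0), excess = numeric(0)))
  expect_equal(boundary_pass(part, part), 0L)
})

test_that("counts are invariant under affine rescaling of the luminance", {
  cfg <- run_config()
  for (seed in 1:5) {
    p <- make_sine(9, snr = 0.6, seed = seed)
    c1 <- count_transect(radial_profile(p$values), cfg)
    c2 <- count_transect(radial_profile(3.7 * p$values + 250), cfg)
    expect_identical(c1, c2)
  }
})

test_that("a radial density gradient does not bias the sectioned count", {
  t <- 0:999
  y <- 500 + 100 * sin(2 * pi * 8 * t / 1000) + 0.4 * t  # monotone trend
  cfg <- run_config()
  expect_equal(count_transect(radial_profile(y), cfg), 8L)
  # oracle: explicit linear detrend counted with a single section
  trend <- fitted(lm(y ~ t))
  detr <- y - trend + mean(y)
  expect_equal(count_transect(radial_profile(detr), run_config(n_sections = 1)), 8L)
})

test_that("slice and specimen aggregation follow the configured rounding", {
  est <- count_specimen(lapply(c(10, 10, 10), fake_slice_estimate))
  expect_equal(est$specimen_mean, 10)
  expect_equal(est$specimen_count, 10)

  est2 <- count_specimen(lapply(c(9.3, 9.5), fake_slice_estimate))
  expect_equal(est2$specimen_count, 9)        # 9.4 rounds down to the integer
  est3 <- count_specimen(lapply(c(9.3, 9.5), fake_slice_estimate), "quarter")
  expect_equal(est3$specimen_count, 9.5)      # nearest multiple of 0.25
  est4 <- count_specimen(lapply(c(9.0, 9.25), fake_slice_estimate), "quarter")
  expect_equal(est4$specimen_count, 9.25)     # tie 9.125 rounds away from zero

  expect_error(count_specimen(list()), "non-empty")
})

test_that("clean phantoms are counted exactly; mild noise stays within one pair", {
  cfg <- test_config(rng_seed = 3)
  clean <- make_phantom(9, width_px = 60, height_px = 300)
  est <- count_slice(clean$pixels, cfg, seed = 3)
  expect_equal(est$slice_mean, 9)
  expect_equal(est$slice_sd, 0)

  noisy <- make_phantom(9, width_px = 60, height_px = 300, gradient = 300,
                        noise_sd = 100, seed = 4)
  est2 <- count_slice(noisy$pixels, cfg, seed = 3)
  expect_lte(abs(est2$slice_mean - 9), 1)
})

test_that("the full pipeline is reproducible from the configured seed", {
  ph <- make_phantom(7, width_px = 80, height_px = 280, noise_sd = 80, seed = 21)
  cfg <- test_config(rng_seed = 17)
  r1 <- count_stack(list(ph$pixels, ph$pixels), cfg)
  r2 <- count_stack(list(ph$pixels, ph$pixels), cfg)
  expect_identical(r1, r2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_report(r1, p1); write_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the separation rule converts to physical units", {
  expect_equal(px_to_um(3, 0.66), 1.98)
  expect_error(px_to_um(3, 0), "voxel")
})
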