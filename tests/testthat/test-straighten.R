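test_that("midline interpolation resamples at unit arc length", {
  p <- fit_midline(cbind(c(0, 50, 100), c(10, 10, 10)))
  expect_equal(nrow(p), 101L)
  expect_equal(p[, "y"], rep(10, 101), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(p[, "x"], 0:100, tolerance = 1e-6, ignore_attr = TRUE)

  p2 <- fit_midline(cbind(c(3, 7), c(1, 4)))  # two points: straight segment
  expect_equal(attr(p2, "arc_length"), 5, tolerance = 1e-6)
  steps <- sqrt(rowSums(diff(p2)^2))
  expect_true(all(abs(steps - 1) < 1e-6))

  expect_error(fit_midline(cbind(1, 1)), "at least 2")
  expect_error(midline_path(cbind(c(1, 1), c(2, 2)), 5), "distinct")
})

test_that("a sparsely annotated quarter circle recovers the true arc length", {
  th <- seq(0, pi / 2, length.out = 5)
  cp <- cbind(60 + 50 * cos(th), 60 - 50 * sin(th))
  p <- fit_midline(cp)
  expect_lt(abs(attr(p, "arc_length") - 25 * pi) / (25 * pi), 0.02)
  # path length can never undercut the straight chord
  chord <- sqrt(sum((cp[5, ] - cp[1, ])^2))
  expect_gte(attr(p, "arc_length"), chord)
})

test_that("straightening along an axis-aligned midline is the identity on the band", {
  # asymmetric band values so the outer-surface-first row order is actually
  # checked, with the midline above the image centroid (outward = up)
  img <- matrix(0, 31, 100)
  for (r in 8:14) img[r, ] <- 100 * r
  ml <- midline_path(cbind(c(0, 50, 99), c(10, 10, 10)), half_width_px = 5)
  s <- straighten(img, ml)
  expect_equal(dim(s), c(11L, 100L))
  expect_equal(unclass(s)[, ], img[6:16, ])  # rows y=5..15, outer side first

  ml7 <- midline_path(cbind(c(0, 99), c(10, 10)), half_width_px = 7)
  expect_equal(nrow(straighten(img, ml7)), 15L)

  # output area equals path length x profile height
  expect_equal(prod(dim(s)), 100 * 11)
})

test_that("a midline too close to the border errors, naming the offending sample", {
  img <- band_image(21, 100)
  ml <- midline_path(cbind(c(0, 99), c(3, 3)), half_width_px = 5)
  expect_error(straighten(img, ml), "leaves image bounds at path sample 1")
})

test_that("straightening a circular band matches direct polar resampling", {
  rc <- 75; hw <- 15
  ring_fun <- function(r) 1000 + 800 * sin(2 * pi * r / 30)
  img <- annulus_image(201, r_inner = rc - hw - 5, r_outer = rc + hw + 5,
                       ring_fun = ring_fun)
  ml <- midline_path(arc_control_points(rc, 201, n = 25, frac = 0.7),
                     half_width_px = hw)
  s <- straighten(img, ml)
  expect_equal(nrow(s), 2 * hw + 1)
  # natural-spline end conditions distort the first/last few path samples,
  # as they would for a user annotating beyond the region of interest;
  # fidelity is assessed on the interior columns
  mid <- s[, 10:(ncol(s) - 10)]
  cv <- apply(mid, 1, function(r) sd(r) / mean(r))
  expect_true(all(cv < 0.01))
  # oracle: polar resampling at the corresponding radii (row 1 = outward)
  oracle <- polar_resample(img, rc, offsets = seq(hw, -hw))
  expect_lt(max(abs(rowMeans(mid) - colMeans(oracle))) / diff(range(img)), 0.01)
})

test_that("one midline propagates across a stack with coverage logging", {
  img <- band_image(41, 100, band_rows = 19:23)
  stack <- slice_stack(list(img, img, img), bit_depth = 16)
  ml <- midline_path(cbind(c(0, 99), c(20, 20)), half_width_px = 8)
  res <- propagate_midline(stack, ml)
  expect_length(res$images, 3L)
  expect_identical(res$images[[1]], res$images[[2]])
  expect_identical(res$images[[2]], res$images[[3]])
  expect_equal(res$coverage$coverage, rep(5 / 17, 3), tolerance = 1e-9)

  # empty range: empty output
  res0 <- propagate_midline(stack, ml, integer(0))
  expect_length(res0$images, 0L)

  # band drifting out of the sampled window: coverage decays monotonically
  drift <- lapply(0:9, function(d) band_image(60, 100, band_rows = 19:23 + 3 * d))
  dstack <- slice_stack(drift, bit_depth = 16)
  cov <- propagate_midline(dstack, ml)$coverage$coverage
  expect_true(all(diff(cov) <= 1e-12))
  expect_lt(cov[10], cov[1])
})

test_that("slices the midline cannot cover are skipped with a warning, not an error", {
  stack <- slice_stack(list(band_image(21, 100)), bit_depth = 16)
  ml <- midline_path(cbind(c(0, 99), c(3, 3)), half_width_px = 5)
  expect_warning(res <- propagate_midline(stack, ml), "slice 1 skipped")
  expect_length(res$images, 0L)
  expect_true(is.na(res$coverage$coverage[1]))
})
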