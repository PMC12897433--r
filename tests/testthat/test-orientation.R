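test_that("binarization is strict and defaults to the noise threshold", {
  z <- shg_image(matrix(0L, 20, 20))
  expect_false(any(binarize(z)))
  const <- shg_image(matrix(5L, 20, 20))
  expect_false(any(binarize(const, threshold = 5)))   # strict inequality
  expect_true(all(binarize(const, threshold = 4.9)))
  expect_true(all(binarize(const) == (const$counts > 0.5)))
})

test_that("binarized phantom masks cover the rendered centerline", {
  set.seed(51)
  for (i in 1:20) {
    ang <- runif(1, 0, 180)
    len <- 40
    field <- matrix(0, 80, 80)
    field <- shgfib:::render_fiber(field, 40, 40, ang, len, 1, 20)
    img <- shg_image(round(field))
    mask <- binarize(img)
    th <- ang * pi / 180
    t <- seq(-len / 2 + 0.5, len / 2 - 0.5, by = 0.5)
    rows <- round(40 + t * -sin(th)) + 1
    cols <- round(40 + t * cos(th)) + 1
    expect_gte(mean(mask[cbind(rows, cols)]), 0.9)
  }
})

test_that("hough angle convention matches constructed masks", {
  # horizontal line: normal angle 90, line direction 0
  m <- matrix(FALSE, 50, 50)
  m[25, ] <- TRUE
  ln <- hough_lines(m, min_votes = 10)
  expect_equal(nrow(ln), 1)
  expect_lt(abs(wrap_relative(ln$direction - 0)), 1)
  expect_lt(abs(ln$theta - 90), 1)
  expect_equal(ln$votes, 50)

  # vertical line: direction 90
  m2 <- matrix(FALSE, 50, 50)
  m2[, 25] <- TRUE
  ln2 <- hough_lines(m2, min_votes = 10)
  expect_lt(abs(wrap_relative(ln2$direction - 90)), 1)

  # ideal 45-degree segment (up-right on screen)
  m3 <- matrix(FALSE, 50, 50)
  for (i in 1:50) m3[51 - i, i] <- TRUE
  ln3 <- hough_lines(m3, min_votes = 10)
  expect_lt(abs(wrap_relative(ln3$direction - 45)), 1)

  # two orthogonal lines: two peaks 90 degrees apart
  ln4 <- hough_lines(m | m2, min_votes = 10)
  expect_equal(nrow(ln4), 2)
  expect_lt(abs(abs(wrap_relative(ln4$direction[1] - ln4$direction[2])) - 90), 2)

  # empty mask: empty result, not an error
  expect_equal(nrow(hough_lines(matrix(FALSE, 30, 30))), 0)
})

test_that("single-fiber phantom orientations are recovered within the grid step", {
  cfg <- synth_config(background_rate = 0, fiber_count_range = c(1, 1),
                      angular_sigma = 50)
  set.seed(52)
  err <- replicate(100, {
    img <- generate_image(cfg, TRUE)
    ln <- hough_lines(binarize(img), min_votes = 10)
    abs(wrap_relative(ln$direction[1] - img$fiber_angles_deg))
  })
  expect_gte(mean(err <= 1), 0.99)
})

test_that("relative angles wrap on the period-180 orientation circle", {
  expect_equal(wrap_relative(170 - 10), -20)    # 160 wraps to -20
  expect_equal(wrap_relative(10 - 170), 20)
  r <- relative_angles(c(42, 42, 42), seed = 1)
  expect_equal(r$relative, c(0, 0))
  expect_length(r$relative, 2)
  expect_true(r$reference_index %in% 1:3)
  expect_equal(r$reference_angle, 42)
  r2 <- relative_angles(c(10, 170), seed = 3)
  expect_equal(abs(r2$relative), 20)
  expect_error(relative_angles(numeric(0)), "at least one")
})

test_that("circular width is invariant to the reference choice", {
  # shifting the full angle set by any reference leaves the dispersion fixed
  set.seed(53)
  dirs <- rwrappednorm180(40, 75, 12)
  widths <- vapply(seq_along(dirs), function(ref) {
    circular_sd_180(wrap_relative(dirs - dirs[ref]))
  }, 0)
  expect_lt(max(widths) - min(widths), 1e-9)
})

test_that("angle histograms are proper probability distributions", {
  h1 <- angle_histogram(5)
  expect_equal(sum(h1$prob), 1)
  expect_equal(sum(h1$prob > 0), 1)
  set.seed(54)
  a <- runif(1e5, -90 + 1e-9, 90)
  h <- angle_histogram(a, bin_width = 5)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  p0 <- 5 / 180
  se <- sqrt(p0 * (1 - p0) / 1e5)
  expect_true(all(abs(h$prob - p0) < 3 * se + 1e-9))
  # counting oracle
  set.seed(55)
  b <- runif(200, -89, 90)
  hb <- angle_histogram(b, 10)
  for (i in seq_along(hb$prob)) {
    expect_equal(hb$prob[i],
                 sum(b > hb$breaks[i] & b <= hb$breaks[i + 1]) / 200)
  }
  expect_warning(angle_histogram(a[1:10], bin_width = 7), "adjusted")
})

test_that("distribution width recovers wrapped-normal dispersion", {
  expect_equal(as.numeric(distribution_width(c(3, 3, 3))), 0)
  expect_equal(as.numeric(distribution_width(c(3, 3, 3), "fwhm")), 0)
  set.seed(56)
  w <- mean(replicate(20, {
    as.numeric(distribution_width(wrap_relative(rwrappednorm180(500, 0, 15))))
  }))
  expect_lt(abs(w - 15) / 15, 0.15)
  # tight vs broad dispersion: strict ordering in every paired draw
  set.seed(57)
  for (i in 1:50) {
    tight <- as.numeric(distribution_width(wrap_relative(rwrappednorm180(300, 0, 2.8))))
    broad <- as.numeric(distribution_width(wrap_relative(rwrappednorm180(300, 0, 26))))
    expect_lt(tight, broad)
  }
  # FWHM grows with dispersion too
  set.seed(58)
  f_tight <- as.numeric(distribution_width(wrap_relative(rwrappednorm180(2000, 0, 5)),
                                           "fwhm"))
  f_broad <- as.numeric(distribution_width(wrap_relative(rwrappednorm180(2000, 0, 25)),
                                           "fwhm"))
  expect_lt(f_tight, f_broad)
  expect_error(distribution_width(5), "at least 2")
})

test_that("group orientation analysis pools per-group angles with ground truth recovery", {
  cfg <- synth_config(angular_sigma = 10)
  set.seed(59)
  imgs <- lapply(1:30, function(i) generate_image(cfg, i <= 20))
  groups <- rep(c("S", "AS"), 15)
  positive <- c(rep(TRUE, 20), rep(FALSE, 10))
  o <- fiber_orientation_analysis(imgs, groups, positive, threshold = 5,
                                  pooling = "orientation", seed = 1)
  expect_setequal(o$widths$group, c("S", "AS"))
  expect_true(all(o$widths$n_images == c(10, 10)))
  # recovered group dispersion is near the generating 10 degrees
  expect_true(all(abs(o$widths$width - 10) < 4))
  # histograms are proper
  for (g in o$groups) expect_equal(sum(g$histogram$prob), 1, tolerance = 1e-12)
})
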