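test_that("noise threshold equals one tenth of the DC-dominated DFT maximum", {
  # constant image: DC magnitude is c * N, so normalized threshold is c / 10
  img <- shg_image(matrix(7L, 25, 25))
  expect_equal(noise_threshold(img), 0.7, tolerance = 1e-12)
  expect_equal(noise_threshold(shg_image(matrix(0L, 20, 20))), 0)
  # unnormalized convention scales with pixel count
  expect_equal(noise_threshold(img, normalized = FALSE), 0.7 * 625,
               tolerance = 1e-9)
  # brute-force DFT oracle on a small random matrix
  set.seed(4)
  m <- matrix(rpois(36, 5), 6, 6)
  expect_equal(noise_threshold(m), oracle_noise_threshold(m),
               tolerance = 1e-10)
})

test_that("noise threshold equals mean/10 for non-negative images", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rpois(400, runif(1, 0.1, 50)), 20, 20)
    expect_equal(noise_threshold(m), mean(m) / 10, tolerance = 1e-10)
  }
  img <- generate_image(synth_config(background_rate = 10), FALSE, seed = 1)
  expect_equal(noise_threshold(img), mean(img$counts) / 10, tolerance = 1e-10)
  # SE of the mean of 10^4 Poisson(10) draws is sqrt(10)/100
  expect_lt(abs(noise_threshold(img) - 1), 5 * sqrt(10) / 100 / 10)
})

test_that("window statistics match their closed forms on degenerate windows", {
  w <- matrix(7, 20, 20)
  s <- window_statistics(w, threshold = 10, factor = 0.15)
  expect_equal(unname(s), c(7, 0, 0, 0, 7, 2800, 1), tolerance = 1e-12)
  # tie in the mode goes to the smallest value; 10 is not > 20
  w2 <- matrix(c(rep(0, 200), rep(10, 200)), 20, 20)
  s2 <- window_statistics(w2, threshold = 20, factor = 1)
  expect_equal(unname(s2["frac_above"]), 0)
  expect_equal(unname(s2["mode"]), 0)
  expect_error(window_statistics(matrix(1, 1, 2), 1), "at least 2 x 2")
})

test_that("window statistics agree with a naive loop oracle", {
  set.seed(6)
  for (i in 1:25) {
    w <- matrix(sample(0:12, 400, replace = TRUE), 20, 20)
    thr <- runif(1, 0, 5)
    fac <- runif(1, 0, 2)
    expect_equal(window_statistics(w, thr, fac),
                 oracle_window_stats(w, thr, fac), tolerance = 1e-10)
  }
})

test_that("sliding windows tile the image in row-major order", {
  img <- generate_image(synth_config(), TRUE, seed = 7)
  wf <- sliding_window_features(img, window_size = 20, stride = 5)
  expect_equal(nrow(wf), 17 * 17)
  expect_equal(wf$row[1:3], c(0, 0, 0))
  expect_equal(wf$col[1:3], c(0, 5, 10))
  expect_equal(wf$row[18], 5)
  # single-window image equals whole-image statistics
  sub <- shg_image(img$counts[1:20, 1:20])
  one <- sliding_window_features(sub, 20, 1)
  expect_equal(nrow(one), 1)
  expect_equal(unname(unlist(one[1, window_feature_names])),
               unname(window_statistics(sub$counts, noise_threshold(sub), 0.15)))
  expect_error(sliding_window_features(sub, 30), "smaller")
})

test_that("window sum identity holds: sum = mean x window area", {
  img <- generate_image(synth_config(), TRUE, seed = 8)
  wf <- sliding_window_features(img, 20, stride = 10)
  expect_equal(wf$sum, wf$mean * 400, tolerance = 1e-9)
})

test_that("image features are whole-image window statistics plus the ratio", {
  img <- generate_image(synth_config(), TRUE, seed = 9)
  f <- image_features(img)
  s <- window_statistics(img$counts, noise_threshold(img), 1.0)
  expect_equal(f[c("mean", "std", "mode", "sum", "frac_above")],
               s[c("mean", "std", "mode", "sum", "frac_above")])
  expect_equal(f[["mean_over_std"]], f[["mean"]] / f[["std"]])
  z <- image_features(shg_image(matrix(0L, 20, 20)))
  expect_true(is.na(z["mean_over_std"]))
  expect_equal(unname(z[c("mean", "std", "mode", "frac_above")]), rep(0, 4))
})

test_that("frac_above is monotonically non-increasing in the factor", {
  set.seed(10)
  img <- generate_image(synth_config(), TRUE, seed = 10)
  thr <- noise_threshold(img)
  fracs <- vapply(seq(0, 3, by = 0.25), function(fac) {
    window_statistics(img$counts, thr, fac)[["frac_above"]]
  }, 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("fibrotic phantoms occupy more above-threshold pixels than matched controls", {
  cfg <- synth_config()
  set.seed(11)
  for (i in 1:100) {
    fib <- image_features(generate_image(cfg, TRUE))[["frac_above"]]
    ctl <- image_features(generate_image(cfg, FALSE))[["frac_above"]]
    expect_gt(fib, ctl)
  }
})

test_that("intensity distributions are proper and match a tally oracle", {
  d <- intensity_distribution(c(0, 0, 5, 5))
  expect_equal(d$value, c(0, 5))
  expect_equal(d$prob, c(0.5, 0.5))
  one <- intensity_distribution(rep(3, 10))
  expect_equal(one$prob, 1)
  set.seed(12)
  x <- sample(0:6, 500, replace = TRUE)
  d2 <- intensity_distribution(x)
  expect_equal(sum(d2$prob), 1, tolerance = 1e-12)
  for (i in seq_along(d2$value)) {
    expect_equal(d2$prob[i], sum(x == d2$value[i]) / length(x))
  }
  expect_error(intensity_distribution(numeric(0)), "non-empty")
})
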