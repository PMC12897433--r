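test_that("binary cross-entropy matches closed forms and a loop oracle", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  # saturating correct predictions drive the loss to the clipping floor
  l1 <- bce_loss(c(1, 0), c(1 - 1e-6, 1e-6))
  l2 <- bce_loss(c(1, 0), c(1 - 1e-9, 1e-9))
  expect_gt(l1, l2)
  expect_lt(l2, 1e-8)
  set.seed(41)
  y <- sample(0:1, 50, replace = TRUE)
  p <- runif(50, 0.01, 0.99)
  manual <- 0
  for (i in 1:50) manual <- manual - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  expect_equal(bce_loss(y, p), manual / 50, tolerance = 1e-12)
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_loss(c(0, 2), c(0.1, 0.2)), "binary")
})

test_that("a separable 1-D feature is fit to perfect training accuracy", {
  set.seed(42)
  x <- c(rnorm(100, -5, 0.5), rnorm(100, 5, 0.5))
  y <- rep(c(0, 1), each = 100)
  model <- train_neuron(x, y)
  expect_equal(predict(model, x, type = "class"), y)
  # training loss settles: non-increasing over the final 10% of epochs
  tail_loss <- tail(model$loss_history, 50)
  expect_true(all(diff(tail_loss) <= 1e-8))
})

test_that("uninformative features yield prior-level accuracy", {
  set.seed(43)
  n <- 1000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.4)
  model <- train_neuron(x, y)
  acc <- mean(predict(model, x, type = "class") == y)
  expect_lt(abs(acc - max(mean(y), 1 - mean(y))), 0.1)
})

test_that("symmetric all-zero input keeps the neuron at the origin", {
  x <- rep(0, 20)
  y <- rep(c(0, 1), 10)
  expect_warning(model <- train_neuron(x, y), "zero-variance")
  expect_equal(model$b, 0)
  expect_equal(unique(predict(model, x)), 0.5)
  expect_equal(unique(predict(model, x, type = "class")), 0L)
})

test_that("prediction follows the sigmoid and the strict 0.5 rule", {
  m <- structure(list(w = 1, b = 0, center = 0, scale = 1,
                      feature_names = NULL),
                 class = "shg_neuron")
  expect_equal(predict(m, 0), 0.5)
  expect_equal(predict(m, 0, type = "class"), 0L)  # p = 0.5 is not > 0.5
  expect_gt(predict(m, 30), 1 - 1e-12)
  set.seed(44)
  for (i in 1:10) {
    w <- rnorm(1); b <- rnorm(1); x <- rnorm(1)
    m$w <- w; m$b <- b
    expect_equal(predict(m, x), 1 / (1 + exp(-(w * x + b))), tolerance = 1e-12)
  }
  expect_error(predict(m, matrix(1, 2, 3)), "dimensionality")
})

test_that("classification is invariant to affine feature rescaling", {
  set.seed(45)
  x <- c(rnorm(60, 0, 1), rnorm(60, 4, 1))
  y <- rep(c(0, 1), each = 60)
  m1 <- train_neuron(x, y)
  m2 <- train_neuron(1000 * x + 77, y)
  expect_equal(predict(m1, x, type = "class"),
               predict(m2, 1000 * x + 77, type = "class"))
})

test_that("training guards degenerate splits", {
  expect_error(train_neuron(1:5, rep(1, 5)), "both classes")
  expect_error(train_neuron(matrix(1:10, 5), 1:4), "match")
})

test_that("stratified 20-fold partitions the 160/80 study layout evenly", {
  set.seed(46)
  x <- c(rnorm(160, 0), rnorm(80, 10))
  y <- rep(c(0, 1), c(160, 80))
  cv <- kfold_cv(x, y, k = 20, seed = 1, epochs = 200)
  sizes <- vapply(cv$folds, `[[`, 0, "n")
  expect_true(all(sizes == 12))
  pos <- vapply(cv$folds, function(f) f$confusion["TP"] + f$confusion["FN"], 0)
  neg <- vapply(cv$folds, function(f) f$confusion["TN"] + f$confusion["FP"], 0)
  expect_true(all(pos == 4))
  expect_true(all(neg == 8))
  expect_equal(sum(cv$aggregate), 240)
  # separable data: perfect aggregated metrics
  expect_equal(unname(cv$metrics[c("F1", "sensitivity", "specificity")]),
               c(1, 1, 1))
  expect_error(kfold_cv(x[1:30], y[c(1:15, 161:175)], k = 20),
               "at least k members")
})

test_that("confusion metrics match their formulas", {
  m <- c(TP = 80, FP = 0, FN = 0, TN = 160)
  expect_equal(unname(confusion_metrics(m)), c(1, 1, 1, 1))
  m2 <- c(TP = 1, FP = 1, FN = 1, TN = 1)
  expect_equal(unname(confusion_metrics(m2)), c(0.5, 0.5, 0.5, 0.5))
  set.seed(47)
  for (i in 1:20) {
    cm <- c(TP = rpois(1, 5) + 1, FP = rpois(1, 3), FN = rpois(1, 3),
            TN = rpois(1, 8) + 1)
    got <- confusion_metrics(cm)
    expect_equal(unname(got["F1"]),
                 unname(2 * cm["TP"] / (2 * cm["TP"] + cm["FP"] + cm["FN"])))
    expect_equal(unname(got["sensitivity"]),
                 unname(cm["TP"] / (cm["TP"] + cm["FN"])))
    expect_equal(unname(got["specificity"]),
                 unname(cm["TN"] / (cm["TN"] + cm["FP"])))
    expect_equal(unname(got["accuracy"]), unname((cm["TP"] + cm["TN"]) / sum(cm)))
  }
  expect_error(confusion_metrics(c(TP = 0, FP = 0, FN = 0, TN = 0)),
               "all-zero")
  nas <- suppressWarnings(confusion_metrics(c(TP = 0, FP = 0, FN = 0, TN = 5)))
  expect_true(is.na(nas["sensitivity"]))
  expect_true(is.na(nas["F1"]))
  expect_equal(unname(nas["specificity"]), 1)
})

test_that("classifier F1 degrades monotonically with injected class overlap", {
  # push the two frac_above distributions together by shrinking fiber load
  set.seed(48)
  f1 <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(mix) {
    n <- 120
    x0 <- rnorm(n, 0, 1)
    x1 <- rnorm(n, 6 * (1 - mix), 1)    # overlap grows with mix
    cv <- kfold_cv(c(x0, x1), rep(c(0, 1), each = n), k = 10, seed = 1,
                   epochs = 200)
    unname(cv$metrics["F1"])
  }, 0)
  expect_true(all(diff(f1) <= 0.02))  # allow tiny non-monotonic jitter
  expect_gte(f1[1], 0.98)
  expect_lt(f1[5], 0.8)
})
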