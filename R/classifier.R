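#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1 - y) log(1 - p))` over the samples, with predicted
#' probabilities clipped to `[eps_clip, 1 - eps_clip]` so the loss stays
#' finite at saturated predictions. The clip applies to the loss only, never
#' to reported probabilities.
#'
#' @param labels binary vector (0/1).
#' @param probabilities predicted probabilities, same length.
#' @param eps_clip clipping bound.
#' @return non-negative scalar.
#' @examples
#' bce_loss(1, 0.5)  # log(2)
#' @export
bce_loss <- function(labels, probabilities, eps_clip = 1e-12) {
  if (!length(labels)) stop("empty input")
  if (length(labels) != length(probabilities)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  p <- pmin(pmax(probabilities, eps_clip), 1 - eps_clip)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the single-sigmoid-neuron fibrosis classifier
#'
#' One sigmoid neuron, `p = sigmoid(w . x + b)`, trained by full-batch Adam
#' (beta1 = 0.9, beta2 = 0.999, eps = 1e-8, with bias correction) on the
#' binary cross-entropy loss, learning rate 0.05 by default. Weights and bias
#' start at zero, so given a data ordering the fit is fully deterministic.
#' Features are standardized with training-split statistics that are stored in
#' the model and re-applied at prediction time; a constant (zero-variance)
#' feature is left unscaled with a warning, since the neuron then simply
#' cannot use it.
#'
#' @param x numeric vector (single feature) or matrix, one row per sample.
#' @param y binary labels (0/1); both classes must be present.
#' @param lr Adam learning rate.
#' @param epochs number of full-batch epochs.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param standardize standardize features with training statistics.
#' @return object of class `shg_neuron` with elements `w`, `b` (parameters in
#'   standardized feature space), `center`, `scale`, `loss_history`,
#'   `feature_names` and the hyperparameters.
#' @export
train_neuron <- function(x, y, lr = 0.05, epochs = 500,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features must not contain NA")
  if (nrow(x) != length(y)) stop("x rows must match length(y)")
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  if (length(unique(y)) < 2) stop("both classes must be present in training data")
  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    if (any(scl == 0)) {
      warning("zero-variance feature in training split; left unscaled")
      scl[scl == 0] <- 1
    }
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  }
  d <- ncol(x); n <- nrow(x)
  w <- rep(0, d); b <- 0
  mw <- rep(0, d); vw <- rep(0, d); mb <- 0; vb <- 0
  loss_history <- numeric(epochs)
  for (t in seq_len(epochs)) {
    p <- sigmoid(drop(x %*% w) + b)
    loss_history[t] <- bce_loss(y, p)
    r <- (p - y) / n                # d(mean BCE)/dz
    gw <- drop(crossprod(x, r))
    gb <- sum(r)
    mw <- beta1 * mw + (1 - beta1) * gw
    vw <- beta2 * vw + (1 - beta2) * gw^2
    mb <- beta1 * mb + (1 - beta1) * gb
    vb <- beta2 * vb + (1 - beta2) * gb^2
    bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
    w <- w - lr * (mw / bc1) / (sqrt(vw / bc2) + eps)
    b <- b - lr * (mb / bc1) / (sqrt(vb / bc2) + eps)
  }
  structure(
    list(w = w, b = b, center = ctr, scale = scl,
         feature_names = colnames(x),
         lr = lr, epochs = epochs, beta1 = beta1, beta2 = beta2, eps = eps,
         standardized = standardize, loss_history = loss_history),
    class = "shg_neuron"
  )
}

#' @export
print.shg_neuron <- function(x, ...) {
  cat(sprintf("<shg_neuron> single sigmoid neuron, %d feature(s)\n", length(x$w)))
  cat(sprintf("  trained %d epochs, lr %g (Adam); final loss %.6g\n",
              x$epochs, x$lr, x$loss_history[length(x$loss_history)]))
  cat("  w:", paste(formatC(x$w, digits = 4), collapse = ", "),
      " b:", formatC(x$b, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.shg_neuron <- function(object, ...) {
  c(stats::setNames(object$w, object$feature_names %||%
                      paste0("w", seq_along(object$w))),
    bias = object$b)
}

#' @export
summary.shg_neuron <- function(object, ...) {
  cat("Single-sigmoid-neuron binary classifier\n")
  print(object)
  cat(sprintf("  loss: initial %.6g -> final %.6g over %d epochs\n",
              object$loss_history[1],
              object$loss_history[length(object$loss_history)],
              object$epochs))
  invisible(object)
}

#' @export
plot.shg_neuron <- function(x, ...) {
  graphics::plot(x$loss_history, type = "l", xlab = "epoch",
                 ylab = "binary cross-entropy", main = "Training loss", ...)
  invisible(x)
}

#' Predict fibrosis probability and hard label
#'
#' `p = sigmoid(w . x + b)` on standardized features; the hard label is 1 iff
#' `p > 0.5` (strict, so a perfectly uninformative `p = 0.5` is classified as
#' non-fibrotic).
#'
#' @param object an `shg_neuron`.
#' @param newdata numeric vector or matrix of features.
#' @param type "prob" for probabilities, "class" for hard 0/1 labels.
#' @param ... unused.
#' @export
predict.shg_neuron <- function(object, newdata,
                               type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$w)) {
    if (nrow(x) == length(object$w)) x <- t(x)
    else stop("feature dimensionality does not match the model")
  }
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- sigmoid(drop(x %*% object$w) + object$b)
  if (type == "prob") p else as.integer(p > 0.5)
}

#' Confusion-matrix metrics
#'
#' @param m 2x2 confusion matrix as a named numeric vector or matrix carrying
#'   counts `TP`, `FP`, `FN`, `TN`.
#' @return named vector `F1, sensitivity, specificity, accuracy`;
#'   `F1 = 2 TP / (2 TP + FP + FN)`, `sensitivity = TP / (TP + FN)`,
#'   `specificity = TN / (TN + FP)`. A denominator-zero metric is returned as
#'   `NA` with a warning explaining which count made it undefined.
#' @export
confusion_metrics <- function(m) {
  cm <- as.numeric(m[c("TP", "FP", "FN", "TN")])
  names(cm) <- c("TP", "FP", "FN", "TN")
  if (anyNA(cm) || any(cm < 0) || any(cm != round(cm))) {
    stop("confusion matrix needs non-negative integer counts TP, FP, FN, TN")
  }
  if (sum(cm) == 0) stop("all-zero confusion matrix")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: denominator is zero")
      return(NA_real_)
    }
    num / den
  }
  c(F1 = safe(2 * cm["TP"], 2 * cm["TP"] + cm["FP"] + cm["FN"], "F1"),
    sensitivity = safe(cm["TP"], cm["TP"] + cm["FN"], "sensitivity"),
    specificity = safe(cm["TN"], cm["TN"] + cm["FP"], "specificity"),
    accuracy = (cm["TP"] + cm["TN"]) / sum(cm)) -> out
  names(out) <- c("F1", "sensitivity", "specificity", "accuracy")
  out
}

#' Stratified k-fold cross-validation of the sigmoid neuron
#'
#' Folds are stratified by class (each class shuffled with the seed and dealt
#' round-robin into k folds of near-equal size), so every sample is validated
#' exactly once and every training split contains both classes. A model is
#' trained on the k-1 remaining folds, the held-out fold is predicted, and the
#' per-fold 2x2 confusion matrices are summed element-wise into the aggregate
#' from which F1, sensitivity, specificity and accuracy are computed. An
#' aggregate metric whose denominator is zero is an error (it cannot occur
#' under stratification but is guarded).
#'
#' @param x features (vector or matrix, one row per sample).
#' @param y binary labels.
#' @param k number of folds.
#' @param seed fold-shuffling seed; training itself is deterministic.
#' @param stratified use class-stratified folds (plain folds otherwise).
#' @param lr,epochs passed to [train_neuron()].
#' @return object of class `shg_cv`: `folds` (per-fold confusion matrices and
#'   sizes), `aggregate` (named TP/FP/FN/TN counts summing to `n`), `metrics`,
#'   `k`, `seed`.
#' @export
kfold_cv <- function(x, y, k = 20, seed = 1, stratified = TRUE,
                     lr = 0.05, epochs = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n != length(y)) stop("x rows must match length(y)")
  if (n < k) stop("need at least k samples")
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  set.seed(seed)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k) {
        stop("every class needs at least k members for stratified folds")
      }
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  folds <- vector("list", k)
  agg <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) {
      stop("a class is absent from the training split of fold ", f)
    }
    model <- train_neuron(x[tr, , drop = FALSE], y[tr], lr = lr,
                          epochs = epochs)
    yhat <- predict(model, x[!tr, , drop = FALSE], type = "class")
    yv <- y[!tr]
    cm <- c(TP = sum(yhat == 1 & yv == 1), FP = sum(yhat == 1 & yv == 0),
            FN = sum(yhat == 0 & yv == 1), TN = sum(yhat == 0 & yv == 0))
    folds[[f]] <- list(fold = f, confusion = cm, n = sum(!tr))
    agg <- agg + cm
  }
  metrics <- confusion_metrics(agg)
  if (anyNA(metrics)) {
    stop("aggregate metric undefined: ",
         paste(names(metrics)[is.na(metrics)], collapse = ", "))
  }
  structure(list(folds = folds, aggregate = agg, metrics = metrics,
                 k = k, seed = seed, stratified = stratified),
            class = "shg_cv")
}

#' @export
print.shg_cv <- function(x, ...) {
  cat(sprintf("<shg_cv> %d-fold cross-validation (%s), n = %d\n", x$k,
              if (x$stratified) "stratified" else "plain", sum(x$aggregate)))
  a <- x$aggregate
  cat("  aggregated confusion matrix:\n")
  cat(sprintf("              predicted+  predicted-\n"))
  cat(sprintf("    actual+   %9d  %9d\n", a["TP"], a["FN"]))
  cat(sprintf("    actual-   %9d  %9d\n", a["FP"], a["TN"]))
  cat(sprintf("  F1 %.4f | sensitivity %.4f | specificity %.4f | accuracy %.4f\n",
              x$metrics["F1"], x$metrics["sensitivity"],
              x$metrics["specificity"], x$metrics["accuracy"]))
  invisible(x)
}
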