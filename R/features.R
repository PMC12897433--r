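#' Fourier noise threshold of an image
#'
#' The noise threshold is one tenth of the maximum magnitude of the image's
#' 2-D discrete Fourier transform. By default magnitudes are normalized by the
#' pixel count, so the zero-frequency (DC) magnitude equals the image mean;
#' since for a non-negative image no frequency component can exceed the DC
#' component, the normalized threshold always equals `mean(counts) / 10`.
#'
#' @param image an [shg_image()] or a numeric matrix.
#' @param normalized divide magnitudes by the pixel count (default). With
#'   `FALSE` the raw DFT magnitudes are used and the threshold scales with
#'   image size.
#' @return scalar threshold in intensity units (0 for an all-zero image).
#' @export
noise_threshold <- function(image, normalized = TRUE) {
  m <- if (inherits(image, "shg_image")) image$counts else as.matrix(image)
  if (!length(m)) stop("image must be non-empty")
  mx <- max(Mod(stats::fft(m)))
  if (normalized) mx <- mx / length(m)
  mx / 10
}

window_feature_names <- c("mean", "std", "skewness", "kurtosis", "mode",
                          "sum", "frac_above")

# population moments, integer mode (ties -> smallest), above-threshold
# fraction on a flat pixel vector; the workhorse behind both window-level and
# image-level features
pixel_statistics <- function(x, threshold, factor) {
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  v <- mean(d^2)
  s <- sqrt(v)
  if (s > 0) {
    skew <- mean(d^3) / s^3
    kurt <- mean(d^4) / s^4     # non-excess: 3 for a normal population
  } else {
    skew <- 0; kurt <- 0
  }
  vals <- sort(unique(x))
  mode <- vals[which.max(tabulate(match(x, vals)))]  # first max = smallest value
  c(mean = mu, std = s, skewness = skew, kurtosis = kurt, mode = mode,
    sum = sum(x), frac_above = mean(x > factor * threshold))
}

#' Statistical features of one window
#'
#' Computes, on the flattened pixel vector of a sub-matrix, the first four
#' statistical moments (mean, standard deviation, skewness and kurtosis as the
#' third and fourth standardized moments, population denominators, non-excess
#' kurtosis), the statistical mode of the raw integer counts (ties broken
#' toward the smallest value), the total intensity sum, and the fraction of
#' pixels whose intensity strictly exceeds `factor * threshold`. For a
#' zero-variance window skewness and kurtosis are defined as 0.
#'
#' @param window numeric matrix (at least 2 x 2).
#' @param threshold the image's noise threshold (see [noise_threshold()]).
#' @param factor multiple of the threshold used for the comparison value;
#'   0.15 is the window-level convention ("15 percent of the noise
#'   threshold"), 1.0 the image-level one.
#' @return named numeric vector with elements `mean, std, skewness, kurtosis,
#'   mode, sum, frac_above`.
#' @export
window_statistics <- function(window, threshold, factor = 0.15) {
  window <- as.matrix(window)
  if (nrow(window) < 2 || ncol(window) < 2) {
    stop("window must be at least 2 x 2")
  }
  pixel_statistics(as.vector(window), threshold, factor)
}

#' Sliding-window feature table of an image
#'
#' A square window is displaced across the image with the given stride in both
#' spatial directions; each position yields one [window_statistics()] row. The
#' noise threshold is computed once per image and shared by all its windows.
#' Rows are emitted in row-major order of the 0-based top-left window
#' positions; a `H x W` image yields
#' `(floor((H-w)/stride)+1) * (floor((W-w)/stride)+1)` rows.
#'
#' @param image an [shg_image()].
#' @param window_size window side in pixels.
#' @param stride displacement in pixels in both directions.
#' @param factor threshold multiple, see [window_statistics()].
#' @return data.frame with columns `row`, `col` (0-based top-left position)
#'   and the seven window statistics.
#' @export
sliding_window_features <- function(image, window_size = 20, stride = 1,
                                    factor = 0.15) {
  stopifnot(inherits(image, "shg_image"))
  m <- image$counts
  H <- nrow(m); W <- ncol(m); w <- window_size
  if (H < w || W < w) stop("image smaller than the window")
  thr <- noise_threshold(image)
  rows0 <- seq(0L, H - w, by = stride)
  cols0 <- seq(0L, W - w, by = stride)
  out <- matrix(NA_real_, length(rows0) * length(cols0),
                2 + length(window_feature_names))
  k <- 0L
  for (r in rows0) {
    for (cc in cols0) {
      k <- k + 1L
      out[k, ] <- c(r, cc,
                    pixel_statistics(as.vector(m[(r + 1):(r + w),
                                                 (cc + 1):(cc + w)]),
                                     thr, factor))
    }
  }
  out <- as.data.frame(out)
  names(out) <- c("row", "col", window_feature_names)
  out
}

#' Whole-image feature vector
#'
#' The image-level features used for clustering and classification: arithmetic
#' mean, standard deviation, their ratio, statistical mode, total intensity
#' sum, and the fraction of pixels above `factor` times the image's noise
#' threshold. Moment, mode and tie conventions are identical to
#' [window_statistics()] applied to the full image as a single window.
#'
#' @param image an [shg_image()].
#' @param factor threshold multiple; image-level features default to the full
#'   noise threshold (`factor = 1`).
#' @return named numeric vector `mean, std, mean_over_std, mode, sum,
#'   frac_above`; `mean_over_std` is `NA` (undefined) when `std` is 0.
#' @export
image_features <- function(image, factor = 1.0) {
  stopifnot(inherits(image, "shg_image"))
  s <- pixel_statistics(as.vector(image$counts), noise_threshold(image), factor)
  c(mean = unname(s["mean"]), std = unname(s["std"]),
    mean_over_std = if (s["std"] > 0) unname(s["mean"] / s["std"]) else NA_real_,
    mode = unname(s["mode"]), sum = unname(s["sum"]),
    frac_above = unname(s["frac_above"]))
}

#' Image-level feature table for a dataset
#'
#' @param dataset an `shg_dataset` (or list of [shg_image()]).
#' @param factor threshold multiple passed to [image_features()].
#' @return data.frame: `image_id`, `group`, `animal`, `label` (if available)
#'   and the image-level features.
#' @export
dataset_features <- function(dataset, factor = 1.0) {
  images <- if (inherits(dataset, "shg_dataset")) dataset$images else dataset
  feats <- t(vapply(images, image_features, numeric(6), factor = factor))
  df <- data.frame(
    image_id = vapply(images, function(i) i$image_id %||% NA_character_, ""),
    group = vapply(images, function(i) i$group %||% NA_character_, ""),
    animal = vapply(images, function(i) i$animal %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  if (inherits(dataset, "shg_dataset")) df$label <- dataset$manifest$label
  cbind(df, as.data.frame(feats))
}

#' Empirical intensity probability distribution
#'
#' @param pixels numeric vector of pixel intensities.
#' @return data.frame with columns `value` (distinct observed intensities,
#'   ascending) and `prob` (relative frequencies, summing to 1).
#' @export
intensity_distribution <- function(pixels) {
  if (!length(pixels)) stop("pixel vector must be non-empty")
  tb <- table(pixels)
  data.frame(value = as.numeric(names(tb)),
             prob = as.numeric(tb) / length(pixels))
}
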