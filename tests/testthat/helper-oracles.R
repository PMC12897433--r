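# Independent brute-force oracles used across the suite. These are written as
# plain double loops / direct arithmetic so they stay independent of the
# package's implementations.

# naive re-computation of the seven window statistics
oracle_window_stats <- function(x, threshold, factor) {
  x <- as.vector(x)
  n <- length(x)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  s <- sqrt(m2)
  skew <- if (s > 0) m3 / s^3 else 0
  kurt <- if (s > 0) m4 / s^4 else 0
  counts <- list()
  for (v in x) {
    key <- as.character(v)
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  vals <- as.numeric(names(counts))
  freq <- unlist(counts)
  best <- max(freq)
  mode <- min(vals[freq == best])
  above <- 0
  for (v in x) if (v > factor * threshold) above <- above + 1
  c(mean = mu, std = s, skewness = skew, kurtosis = kurt, mode = mode,
    sum = sum(x), frac_above = above / n)
}

# brute-force 2-D DFT maximum magnitude (no FFT), normalized by pixel count
oracle_noise_threshold <- function(m) {
  H <- nrow(m); W <- ncol(m)
  best <- 0
  for (u in 0:(H - 1)) {
    for (v in 0:(W - 1)) {
      acc <- 0 + 0i
      for (r in 0:(H - 1)) {
        for (cc in 0:(W - 1)) {
          acc <- acc + m[r + 1, cc + 1] *
            exp(-2i * pi * (u * r / H + v * cc / W))
        }
      }
      best <- max(best, Mod(acc))
    }
  }
  best / length(m) / 10
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small, fast phantom configuration for tests that only need structure
tiny_config <- function(...) {
  synth_config(image_height = 40, image_width = 40,
               fiber_length_range = c(15, 25), ...)
}

# a well-separated two-class feature table for selection/clustering tests
separated_table <- function(n_per_class = 100, n_noise = 6, gap = 8,
                            seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * n_noise), ncol = n_noise)
  colnames(x) <- paste0("noise", seq_len(n_noise))
  data.frame(signal = y * gap + rnorm(2 * n_per_class), x, y = y)
}
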