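#' Circular statistics on the orientation half-circle
#'
#' Undirected line orientations identify theta and theta + 180 degrees, so all
#' dispersion statistics here work on the period-180 orientation circle: angles
#' are doubled, mapped to unit vectors, and the usual circular formulas applied.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return `circular_sd_180()` returns the circular standard deviation in
#'   degrees (0 for perfectly aligned input); `wrap_orientation()` maps angles
#'   to `[0, 180)`; `wrap_relative()` maps signed differences to `(-90, 90]`.
#' @examples
#' circular_sd_180(c(10, 10, 10))          # 0
#' circular_sd_180(rnorm(500, 90, 15))     # close to 15
#' @export
circular_sd_180 <- function(angles_deg) {
  if (length(angles_deg) < 2) {
    stop("at least 2 angles are required for a dispersion estimate")
  }
  a <- 2 * angles_deg * pi / 180
  r <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  # r can exceed 1 by rounding error for identical angles
  r <- min(r, 1)
  if (r <= 0) return(Inf)
  sqrt(-2 * log(r)) * 90 / pi
}

#' @rdname circular_sd_180
#' @export
wrap_orientation <- function(angles_deg) {
  angles_deg %% 180
}

#' @rdname circular_sd_180
#' @export
wrap_relative <- function(angles_deg) {
  d <- angles_deg %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}

#' Sample fiber orientations from a wrapped normal on the half-circle
#'
#' Orientations are drawn as `mean + N(0, sigma)` and wrapped to `[0, 180)`
#' (orientation, not direction: theta and theta + 180 are the same fiber).
#'
#' @param n number of draws.
#' @param mean mean orientation in degrees.
#' @param sigma dispersion in degrees; `sigma = 0` returns `mean` exactly.
#' @return numeric vector of orientations in `[0, 180)`.
#' @export
rwrappednorm180 <- function(n, mean = 90, sigma = 10) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(rep(mean %% 180, n))
  (mean + stats::rnorm(n, 0, sigma)) %% 180
}
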