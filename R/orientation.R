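#' Binarize an image at an intensity threshold
#'
#' Pixels strictly above the threshold are foreground. The default threshold
#' is the image's Fourier noise threshold, which for the phantom defaults sits
#' between background photon noise and fiber intensities.
#'
#' @param image an [shg_image()].
#' @param threshold intensity cutoff; default [noise_threshold()] of the image.
#' @return logical matrix of the same shape.
#' @export
binarize <- function(image, threshold = NULL) {
  stopifnot(inherits(image, "shg_image"))
  threshold <- threshold %||% noise_threshold(image)
  image$counts > threshold
}

#' Hough-transform line detection
#'
#' Standard `(rho, theta)` accumulator over a binary mask: `theta` is the line
#' normal angle on a grid covering `[0, 180)` degrees, and
#' `rho = x cos(theta) + y sin(theta)` with x the 0-based column index and y
#' the 0-based row index counted upward from the bottom row, so that angles
#' agree with the package-wide counter-clockwise-from-+x convention. The
#' orientation of the detected line itself is the normal angle plus 90
#' degrees, mapped to `[0, 180)`, and is returned as `direction`.
#'
#' Peaks are extracted greedily in descending vote order. After each accepted
#' peak the mask pixels within `3 * rho_step` of the line (its inliers) are
#' removed and their accumulator contributions subtracted, so a thick fiber
#' cannot re-trigger on the tails of its own accumulator ridge; in addition a
#' non-maximum suppression over a `+/- nms_window` neighborhood in both axes
#' is applied around the peak (the theta axis wraps at 180 degrees with `rho`
#' mirrored). Extraction stops below `min_votes` or at `max_lines`.
#'
#' @param mask logical matrix (from [binarize()]).
#' @param theta_step theta grid resolution, degrees.
#' @param rho_step rho bin width, pixels.
#' @param min_votes minimum accumulator votes for a returned line. The default
#'   20 is half the shortest fiber length of the default phantom
#'   configuration; pass a value matched to your own expected fiber lengths.
#' @param max_lines at most this many lines are returned.
#' @param nms_window suppression half-width, in grid steps, in both axes.
#' @param refine refine each peak below the grid resolution by an iterated
#'   principal-axis fit to its inlier pixels (default). Fibers rendered wider
#'   than one pixel produce a near-plateau around the accumulator maximum, so
#'   the raw grid argmax alone can be off by a few theta steps; the inlier fit
#'   recovers the centerline orientation to a fraction of a degree. `FALSE`
#'   returns raw grid coordinates.
#' @return data.frame with columns `rho` (pixels), `theta` (normal angle,
#'   degrees), `direction` (line orientation, degrees in `[0, 180)`) and
#'   `votes`, ordered by decreasing votes; zero rows for an empty mask.
#' @export
hough_lines <- function(mask, theta_step = 1, rho_step = 1, min_votes = 20,
                        max_lines = 25, nms_window = 5, refine = TRUE) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  empty <- data.frame(rho = numeric(0), theta = numeric(0),
                      direction = numeric(0), votes = numeric(0))
  if (!any(mask)) return(empty)
  min_votes <- max(min_votes, 1)
  H <- nrow(mask); W <- ncol(mask)
  pts <- which(mask, arr.ind = TRUE)
  x <- as.numeric(pts[, 2] - 1)
  y <- as.numeric((H - 1) - (pts[, 1] - 1))    # y axis up
  res <- .hough_detect(x, y, theta_step, rho_step, min_votes,
                       as.integer(max_lines), as.integer(nms_window),
                       isTRUE(refine), sqrt((H - 1)^2 + (W - 1)^2))
  peaks <- data.frame(rho = res$rho, theta = res$theta,
                      direction = (res$theta + 90) %% 180, votes = res$votes)
  peaks <- peaks[order(-peaks$votes), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Fiber angles relative to a randomly chosen reference fiber
#'
#' One detected fiber is selected uniformly at random as the reference; the
#' remaining orientations are expressed as signed differences from it, wrapped
#' to `(-90, 90]` on the period-180 orientation circle. The reference's own
#' (zero) relative angle is excluded from the returned set, but its identity
#' is recorded.
#'
#' @param directions line orientations in degrees.
#' @param seed integer seed for the reference draw; `NULL` uses the current
#'   RNG stream.
#' @return list with `relative` (degrees in `(-90, 90]`, length
#'   `length(directions) - 1`), `reference_index`, `reference_angle`.
#' @export
relative_angles <- function(directions, seed = NULL) {
  if (!length(directions)) stop("at least one detected fiber is required")
  if (!is.null(seed)) set.seed(seed)
  ref <- sample.int(length(directions), 1)
  list(relative = wrap_relative(directions[-ref] - directions[ref]),
       reference_index = ref,
       reference_angle = directions[ref])
}

#' Angular probability histogram
#'
#' Bins tile the relative-angle range `(-90, 90]`; probabilities sum to 1.
#'
#' @param relative_angles degrees in `(-90, 90]`.
#' @param bin_width bin width in degrees; adjusted (with a warning) to the
#'   nearest divisor of 180 if it does not divide 180.
#' @return object of class `shg_angle_hist`: `breaks`, `mids`, `prob`,
#'   `bin_width`, `n`.
#' @export
angle_histogram <- function(relative_angles, bin_width = 5) {
  if (!length(relative_angles)) stop("empty angle set")
  if (180 %% bin_width != 0) {
    nb <- max(1, round(180 / bin_width))
    bin_width <- 180 / nb
    warning("bin_width does not divide 180; adjusted to ", bin_width)
  }
  breaks <- seq(-90, 90, by = bin_width)
  idx <- findInterval(relative_angles, breaks, left.open = TRUE,
                      rightmost.closed = FALSE)
  idx[relative_angles <= -90 | relative_angles > 90] <- NA
  if (anyNA(idx)) stop("relative angles must lie in (-90, 90]")
  prob <- tabulate(idx, nbins = length(breaks) - 1) / length(relative_angles)
  structure(list(breaks = breaks, mids = breaks[-1] - bin_width / 2,
                 prob = prob, bin_width = bin_width,
                 n = length(relative_angles)),
            class = "shg_angle_hist")
}

#' @export
print.shg_angle_hist <- function(x, ...) {
  cat(sprintf("<shg_angle_hist> %d angles, %g-degree bins\n", x$n, x$bin_width))
  nz <- which(x$prob > 0)
  for (i in nz) {
    cat(sprintf("  (%+6.1f, %+6.1f]  %.4f\n", x$breaks[i], x$breaks[i + 1],
                x$prob[i]))
  }
  invisible(x)
}

#' @export
plot.shg_angle_hist <- function(x, ...) {
  graphics::barplot(x$prob, names.arg = formatC(x$mids, format = "g"),
                    xlab = "relative angle (degrees)", ylab = "probability",
                    main = "Angular probability distribution", ...)
  invisible(x)
}

#' Width of an angular distribution
#'
#' Two readings of "distribution width" are provided. `"circular_sd"`
#' (default) is the period-180 circular standard deviation, which is invariant
#' to the choice of reference fiber. `"fwhm"` is the full width at half
#' maximum of the binned angular histogram, smoothed with a 3-bin moving
#' average and linearly interpolated at the half-maximum crossings.
#'
#' @param relative_angles degrees in `(-90, 90]` (any orientation set works:
#'   the statistic is shift-invariant).
#' @param method "circular_sd" or "fwhm".
#' @param bin_width histogram bin width for the FWHM method, degrees.
#' @return width in degrees (0 for perfectly aligned input); carries the
#'   method used as attribute `method`.
#' @export
distribution_width <- function(relative_angles,
                               method = c("circular_sd", "fwhm"),
                               bin_width = 5) {
  method <- match.arg(method)
  if (length(relative_angles) < 2) {
    stop("at least 2 angles are required for a width estimate")
  }
  if (max(relative_angles) - min(relative_angles) == 0) {
    return(structure(0, method = method))
  }
  w <- if (method == "circular_sd") {
    circular_sd_180(relative_angles)
  } else {
    h <- angle_histogram(relative_angles, bin_width)
    p <- h$prob
    k <- length(p)
    sm <- (c(p[1], p[-k]) + p + c(p[-1], p[k])) / 3
    half <- max(sm) / 2
    imax <- which.max(sm)
    interp <- function(i0, i1) {
      # linear interpolation of the half-max crossing between bins i0 and i1
      h$mids[i0] + (half - sm[i0]) / (sm[i1] - sm[i0]) *
        (h$mids[i1] - h$mids[i0])
    }
    left <- h$mids[1] - bin_width / 2
    if (imax >= 2) {
      for (i in seq(imax, 2, by = -1)) {
        if (sm[i - 1] < half && sm[i] >= half) { left <- interp(i - 1, i); break }
      }
    }
    right <- h$mids[k] + bin_width / 2
    if (imax <= k - 1) {
      for (i in seq(imax, k - 1, by = 1)) {
        if (sm[i] >= half && sm[i + 1] < half) { right <- interp(i + 1, i); break }
      }
    }
    right - left
  }
  structure(w, method = method)
}

#' Group-level fiber orientation analysis
#'
#' For every fiber-positive image of each group, fibers are detected by
#' [binarize()] + [hough_lines()]; a per-image random reference fiber converts
#' detections to relative angles, which are pooled across the group's images
#' before histogramming, mirroring a per-group angular-distribution figure.
#' The group width is computed either from those pooled relative angles
#' (`pooling = "relative"`, the default) or from the pooled raw line
#' orientations (`pooling = "orientation"`). The two agree for a single image;
#' across images the relative pooling adds the reference fibers' own sampling
#' noise (inflating dispersion by about sqrt(2) when images share a common
#' mean orientation), so the orientation pooling is the more efficient
#' estimator whenever a common deposition axis exists and is the right choice
#' for phantom-recovery experiments.
#'
#' @param images list of [shg_image()].
#' @param groups group tag per image.
#' @param fiber_positive logical per image: analyze this image's fibers
#'   (typically the classifier's hard labels).
#' @param threshold binarization intensity cutoff; `NULL` (default) uses each
#'   image's noise threshold. With low-photon-count backgrounds an explicit
#'   cutoff between background counts and fiber amplitude gives much cleaner
#'   line masks (the pipeline default is a quarter of the fiber peak
#'   amplitude).
#' @param theta_step,min_votes,max_lines,nms_window passed to [hough_lines()].
#' @param bin_width histogram bin width, degrees.
#' @param width_method passed to [distribution_width()].
#' @param pooling "relative" or "orientation" (see above).
#' @param seed seed for the per-image reference draws.
#' @return object of class `shg_orientation`: per-group list with `angles`
#'   (detected orientations), `relative` (pooled relative angles), `histogram`
#'   and `width`; plus a `widths` data.frame (`group`, `width`, `n_angles`,
#'   `n_images`).
#' @export
fiber_orientation_analysis <- function(images, groups, fiber_positive,
                                       threshold = NULL,
                                       theta_step = 1, min_votes = 20,
                                       max_lines = 25, nms_window = 5,
                                       bin_width = 5,
                                       width_method = "circular_sd",
                                       pooling = c("relative", "orientation"),
                                       seed = 1) {
  pooling <- match.arg(pooling)
  stopifnot(length(images) == length(groups),
            length(images) == length(fiber_positive))
  set.seed(seed)
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g & fiber_positive)
    dirs <- list(); rels <- list()
    for (i in idx) {
      lines <- hough_lines(binarize(images[[i]], threshold),
                           theta_step = theta_step,
                           min_votes = min_votes, max_lines = max_lines,
                           nms_window = nms_window)
      if (nrow(lines) == 0) next
      dirs[[length(dirs) + 1L]] <- lines$direction
      if (nrow(lines) >= 2) {
        rels[[length(rels) + 1L]] <- relative_angles(lines$direction)$relative
      }
    }
    angles <- unlist(dirs) %||% numeric(0)
    rel <- unlist(rels) %||% numeric(0)
    pool <- if (pooling == "relative") rel else
      wrap_relative(angles - mean_orientation_180(angles))
    width <- if (length(pool) >= 2) {
      as.numeric(distribution_width(pool, method = width_method,
                                    bin_width = bin_width))
    } else NA_real_
    hist <- if (length(rel)) angle_histogram(rel, bin_width) else NULL
    out[[g]] <- list(group = g, angles = angles, relative = rel,
                     histogram = hist, width = width,
                     n_images = length(idx))
  }
  widths <- data.frame(
    group = names(out),
    width = vapply(out, function(z) z$width, 0),
    n_angles = vapply(out, function(z) length(z$angles), 0L),
    n_images = vapply(out, function(z) z$n_images, 0L),
    stringsAsFactors = FALSE)
  rownames(widths) <- NULL
  structure(list(groups = out, widths = widths, pooling = pooling,
                 width_method = width_method, seed = seed),
            class = "shg_orientation")
}

# circular mean orientation on the period-180 circle
mean_orientation_180 <- function(angles_deg) {
  a <- 2 * angles_deg * pi / 180
  (atan2(mean(sin(a)), mean(cos(a))) * 90 / pi) %% 180
}

#' @export
print.shg_orientation <- function(x, ...) {
  cat(sprintf("<shg_orientation> %d group(s), width method %s, pooling %s\n",
              nrow(x$widths), x$width_method, x$pooling))
  print(x$widths, row.names = FALSE)
  invisible(x)
}
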