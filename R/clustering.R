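#' K-means clustering for label validation
#'
#' A from-scratch Lloyd iteration, written out the way the analysis uses it to
#' validate specialist labels: Forgy initialization (k distinct data points
#' chosen uniformly at random), alternating nearest-Euclidean-centroid
#' assignment and centroid-as-cluster-mean updates, stopping when the maximum
#' centroid displacement falls below `tol` or after `max_iter` iterations. An
#' emptied cluster is reseeded to the point farthest from that cluster's
#' previous centroid. Within-cluster sum of squares (inertia) is tracked every
#' iteration and is guaranteed non-increasing.
#'
#' Features are z-score standardized by default: the sum and fraction features
#' live on scales that differ by orders of magnitude, and unstandardized
#' Euclidean distance would be dominated by the largest one. Zero-variance
#' columns are left unscaled.
#'
#' @param points numeric matrix or data.frame, one row per observation.
#' @param k number of clusters.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the maximum centroid displacement, in
#'   (standardized) feature units.
#' @param seed integer seed for the initialization.
#' @param standardize z-score features before clustering.
#' @return object of class `shg_kmeans`: `cluster` (integer ids in
#'   `0..k-1`), `centers` (k x d, in the clustering space), `inertia`,
#'   `inertia_trace`, `iterations`, `converged`, `seed`, `standardized`,
#'   `center`/`scale` (standardization constants).
#' @export
shg_kmeans <- function(points, k = 2, max_iter = 500, tol = 1e-6, seed = 1,
                       standardize = TRUE) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) stop("features must be finite")
  n <- nrow(x)
  if (n < k) stop("need at least k points")
  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  }
  set.seed(seed)
  centers <- x[sample(n, k), , drop = FALSE]
  dist2 <- function(x, centers) {
    # n x k squared Euclidean distances
    xx <- rowSums(x^2)
    cc <- rowSums(centers^2)
    outer(xx, cc, "+") - 2 * x %*% t(centers)
  }
  assign_cl <- max.col(-dist2(x, centers), ties.method = "first")
  inertia_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d2 <- dist2(x, centers)
    assign_cl <- max.col(-d2, ties.method = "first")
    inertia_trace <- c(inertia_trace,
                       sum(d2[cbind(seq_len(n), assign_cl)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign_cl == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # reseed an emptied cluster to the point farthest from its centroid
        new_centers[j, ] <- x[which.max(d2[, j]), ]
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  d2 <- dist2(x, centers)
  assign_cl <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assign_cl)])
  inertia_trace <- c(inertia_trace, inertia)
  structure(
    list(cluster = assign_cl - 1L, centers = centers, inertia = inertia,
         inertia_trace = inertia_trace, iterations = iter,
         converged = converged, seed = seed, standardized = standardize,
         center = ctr, scale = scl),
    class = "shg_kmeans"
  )
}

#' @export
print.shg_kmeans <- function(x, ...) {
  cat(sprintf("<shg_kmeans> k = %d, n = %d, %d iteration(s), %s\n",
              nrow(x$centers), length(x$cluster), x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  inertia: %.6g\n", x$inertia))
  cat("  cluster sizes:", paste(tabulate(x$cluster + 1L, nrow(x$centers)),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Agreement between a 2-cluster assignment and binary labels
#'
#' Cluster ids are arbitrary, so agreement is the better of the two
#' cluster-to-label mappings; it therefore lies in `[0.5, 1]` for balanced
#' inputs and equals 1 for a perfect (possibly inverted) match.
#'
#' @param assignment an `shg_kmeans` result or an integer vector of cluster
#'   ids in `{0, 1}`.
#' @param labels binary labels (0/1), same length.
#' @return fraction of matching assignments under the best mapping.
#' @export
label_agreement <- function(assignment, labels) {
  cl <- if (inherits(assignment, "shg_kmeans")) assignment$cluster else assignment
  if (length(cl) != length(labels)) stop("length mismatch")
  max(mean(cl == labels), mean(cl != labels))
}
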