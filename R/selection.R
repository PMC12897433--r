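#' Random-forest importance ranking of window-level features
#'
#' Fits a random forest of CART-style trees (Gini impurity, bootstrap
#' resampling, sqrt(p) candidate features per split) to window-level features
#' against the binary fibrosis label each window inherits from its image, and
#' ranks features by normalized mean decrease in impurity. The mean/std ratio
#' is added to the seven raw window statistics before ranking, since it is one
#' of the image-intensity descriptors the classification stage may use; rows
#' where the ratio is undefined (zero-variance windows) are dropped with a
#' message.
#'
#' The forest itself is delegated to \pkg{randomForest}; hyperparameter
#' defaults (100 trees, unlimited depth, minimum node size 1) are standard
#' practice and recorded in the result.
#'
#' @param feature_table data.frame of window features (columns `mean, std,
#'   skewness, kurtosis, mode, sum, frac_above`; `row`/`col` position columns
#'   and a `mean_over_std` column are accepted and handled).
#' @param labels binary vector (0/1), one per row of `feature_table`.
#' @param n_trees number of trees.
#' @param max_depth maximum tree depth; `NULL` (default) grows full trees.
#' @param seed integer seed; the ranking is deterministic given the seed.
#' @param add_ratio add `mean_over_std` when not already a column.
#' @return object of class `shg_importance`: `importance` (named, sums to 1),
#'   `ranking` (feature names, most important first), `params`, `seed`,
#'   `n_dropped` (rows removed for undefined ratio).
#' @export
rank_features <- function(feature_table, labels, n_trees = 100,
                          max_depth = NULL, seed = 1, add_ratio = TRUE) {
  feature_table <- as.data.frame(feature_table)
  if (!nrow(feature_table)) stop("empty feature table")
  if (nrow(feature_table) != length(labels)) {
    stop("labels must match feature_table rows")
  }
  feature_table <- feature_table[, setdiff(names(feature_table), c("row", "col")),
                                 drop = FALSE]
  if (add_ratio && !"mean_over_std" %in% names(feature_table)) {
    feature_table$mean_over_std <-
      ifelse(feature_table$std > 0, feature_table$mean / feature_table$std, NA)
  }
  keep <- stats::complete.cases(feature_table)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped, " row(s) with undefined features dropped before ranking")
  }
  feature_table <- feature_table[keep, , drop = FALSE]
  labels <- labels[keep]
  y <- factor(labels, levels = c(0, 1))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = feature_table, y = y, ntree = n_trees,
    mtry = max(1, floor(sqrt(ncol(feature_table)))),
    nodesize = 1,
    maxnodes = if (is.null(max_depth)) NULL else 2^max_depth,
    importance = FALSE)
  imp <- rf$importance[, "MeanDecreaseGini"]
  if (sum(imp) <= 0) stop("degenerate forest: zero total impurity decrease")
  imp <- imp / sum(imp)
  structure(
    list(importance = imp,
         ranking = names(sort(imp, decreasing = TRUE)),
         params = list(n_trees = n_trees, max_depth = max_depth,
                       mtry = max(1, floor(sqrt(ncol(feature_table)))),
                       min_node_size = 1),
         seed = seed, n_dropped = n_dropped),
    class = "shg_importance"
  )
}

#' @export
print.shg_importance <- function(x, ...) {
  cat("<shg_importance> normalized mean decrease in Gini impurity\n")
  o <- order(x$importance, decreasing = TRUE)
  for (i in o) {
    cat(sprintf("  %-14s %.4f\n", names(x$importance)[i], x$importance[i]))
  }
  invisible(x)
}

#' @export
plot.shg_importance <- function(x, ...) {
  o <- order(x$importance)
  graphics::barplot(x$importance[o], horiz = TRUE, las = 1,
                    xlab = "normalized importance",
                    main = "Random-forest feature importance", ...)
  invisible(x)
}
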