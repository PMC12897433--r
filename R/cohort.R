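#' Per-group fibrosis percentages from image-level predictions
#'
#' Maps per-image hard fibrosis labels to diet groups. The unit of replication
#' is the animal: for each animal the percentage of its images classified
#' fiber-positive is computed, and group mean and standard deviation (sample
#' SD, n-1 denominator) are taken across that group's animals.
#'
#' @param predictions data.frame with columns `image_id` and `predicted`
#'   (hard 0/1 label), or a named 0/1 vector keyed by image id.
#' @param manifest manifest data.frame (see [read_manifest()]); every
#'   predicted image must be present.
#' @return object of class `shg_group_summary`: data.frame with columns
#'   `group`, `n_animals`, `n_images`, `n_positive`, `mean_pct`, `sd_pct`, and
#'   attribute `per_animal` (data.frame `group`, `animal`, `n_images`,
#'   `n_positive`, `pct`).
#' @export
group_fiber_percentages <- function(predictions, manifest) {
  if (is.data.frame(predictions)) {
    pred <- stats::setNames(predictions$predicted, predictions$image_id)
  } else {
    pred <- predictions
  }
  missing <- setdiff(names(pred), manifest$image_id)
  if (length(missing)) {
    stop("predicted image(s) absent from manifest: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  m <- manifest[manifest$image_id %in% names(pred), , drop = FALSE]
  if (!nrow(m)) stop("no predictions overlap the manifest")
  m$predicted <- as.integer(pred[m$image_id])
  per_animal <- do.call(rbind, lapply(split(m, paste(m$group, m$animal)),
    function(d) data.frame(group = d$group[1], animal = d$animal[1],
                           n_images = nrow(d), n_positive = sum(d$predicted),
                           pct = 100 * mean(d$predicted),
                           stringsAsFactors = FALSE)))
  summary <- do.call(rbind, lapply(split(per_animal, per_animal$group),
    function(d) data.frame(group = d$group[1], n_animals = nrow(d),
                           n_images = sum(d$n_images),
                           n_positive = sum(d$n_positive),
                           mean_pct = mean(d$pct),
                           sd_pct = if (nrow(d) > 1) stats::sd(d$pct) else NA_real_,
                           stringsAsFactors = FALSE)))
  # keep manifest group order
  summary <- summary[match(unique(m$group), summary$group), , drop = FALSE]
  rownames(summary) <- NULL
  rownames(per_animal) <- NULL
  structure(summary, per_animal = per_animal,
            class = c("shg_group_summary", "data.frame"))
}

#' @export
print.shg_group_summary <- function(x, ...) {
  cat("Percentage of images containing visible collagen fibers (mean +/- SD",
      "across animals)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-3s %s  (%d animals, %d/%d images)\n", x$group[i],
                format_mean_sd(x$mean_pct[i], x$sd_pct[i]),
                x$n_animals[i], x$n_positive[i], x$n_images[i]))
  }
  invisible(x)
}

format_mean_sd <- function(mean, sd) {
  if (is.na(sd)) sprintf("%.1f%%", mean)
  else sprintf("%.1f ± %.1f%%", mean, sd)
}

#' Render the cohort report tables
#'
#' Produces the human-readable fibrosis-percentage table (mean +/- SD across
#' animals, one row per group) and, when angular widths are supplied, the
#' angular-distribution-width table. CSV files are written next to the text
#' rendering when `path_prefix` is given.
#'
#' @param summaries an `shg_group_summary` from [group_fiber_percentages()].
#' @param widths optional data.frame `group`, `width` (degrees), e.g. the
#'   `widths` element of [fiber_orientation_analysis()].
#' @param path_prefix if non-`NULL`, writes `<prefix>_percentages.csv`,
#'   `<prefix>_widths.csv` (when widths given) and `<prefix>_report.txt`.
#' @return character vector of report lines, invisibly when writing files.
#' @export
render_report <- function(summaries, widths = NULL, path_prefix = NULL) {
  if (!nrow(summaries)) stop("empty summaries")
  lines <- c("Percentage of images containing visible collagen fibers",
             "Group  Percentage of Images with Fibers")
  for (i in seq_len(nrow(summaries))) {
    lines <- c(lines, sprintf("  %-3s  %s", summaries$group[i],
                              format_mean_sd(summaries$mean_pct[i],
                                             summaries$sd_pct[i])))
  }
  if (!is.null(widths) && nrow(widths)) {
    lines <- c(lines, "",
               "Angular distribution width of collagen fiber orientations",
               "Group  Distribution Width (deg)")
    for (i in seq_len(nrow(widths))) {
      lines <- c(lines, sprintf("  %-3s  %.1f", widths$group[i],
                                widths$width[i]))
    }
  } else {
    lines <- c(lines, "", "No angular widths supplied; width table omitted.")
  }
  if (!is.null(path_prefix)) {
    utils::write.csv(as.data.frame(summaries),
                     paste0(path_prefix, "_percentages.csv"), row.names = FALSE)
    if (!is.null(widths) && nrow(widths)) {
      utils::write.csv(widths, paste0(path_prefix, "_widths.csv"),
                       row.names = FALSE)
    }
    writeLines(lines, paste0(path_prefix, "_report.txt"))
    return(invisible(lines))
  }
  lines
}
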