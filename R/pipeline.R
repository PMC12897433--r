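pipeline_defaults <- function() {
  list(
    # simulate
    image_height = 100, image_width = 100, background_rate = 0.5,
    fiber_count_min = 5, fiber_count_max = 10,
    fiber_length_min = 40, fiber_length_max = 70,
    fiber_thickness_sigma = 1.0, fiber_peak_amplitude = 20,
    mean_orientation = 90,
    n_animals = 6, images_per_animal = 10,
    prevalence_C = 0.08, prevalence_A = 0.24,
    prevalence_S = 0.40, prevalence_AS = 0.62,
    angular_sigma_C = 26, angular_sigma_A = 24,
    angular_sigma_S = 16, angular_sigma_AS = 2.8,
    image_format = "tiff",
    # features
    window_size = 20, window_stride = 5,
    factor_window = 0.15, factor_image = 1.0,
    # selection
    n_trees = 100,
    # clustering
    kmeans_max_iter = 500, kmeans_tol = 1e-6,
    # classifier
    lr = 0.05, epochs = 500, k_folds = 20,
    # orientation
    theta_step = 1, bin_width = 5, width_method = "circular_sd",
    min_votes = 20, max_lines = 25, nms_window = 5,
    binarize_threshold = 5,
    pooling = "relative",
    # global
    seed = 1
  )
}

#' Read a flat key = value pipeline configuration file
#'
#' The file holds one `key = value` pair per line; blank lines and `#`
#' comments are ignored. Unknown keys are rejected before any stage runs;
#' missing keys take the documented defaults (see the `pipeline` vignette
#' section or `shgfib:::pipeline_defaults()`).
#'
#' @param path config file path; `NULL` returns the defaults.
#' @param overrides named list merged over the file values.
#' @return named list of resolved parameters.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      vals[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(vals)) {
    v <- vals[[k]]
    cfg[[k]] <- if (is.character(cfg[[k]])) as.character(v) else as.numeric(v)
  }
  cfg
}

write_resolved_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE), "")),
             path)
}

# one global seed expanded into independent per-stage seeds (kept < 2^31)
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483647L
}

#' Run the full SHG fibrosis analysis pipeline
#'
#' Executes, in order: phantom simulation, window- and image-level feature
#' extraction, random-forest feature ranking, K-means label validation,
#' sigmoid-neuron cross-validated classification, fiber orientation analysis
#' on the images the classifier calls fiber-positive, and the cohort report.
#' Every artifact is written under `out_dir` as plain CSV/text next to the
#' resolved configuration, and the whole run is a deterministic function of
#' `(config, seed)`.
#'
#' @param config a config list from [read_pipeline_config()], a config file
#'   path, or `NULL` for defaults.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config's global seed when non-`NULL`.
#' @return invisibly, a list with the in-memory stage results
#'   (`dataset`, `importance`, `clustering`, `cv`, `orientation`, `summary`)
#'   and `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else if (is.null(config)) read_pipeline_config()
         else config
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(cfg, file.path(out_dir, "config_resolved.txt"))

  ## 1. simulate ------------------------------------------------------------
  sc <- synth_config(
    image_height = cfg$image_height, image_width = cfg$image_width,
    background_rate = cfg$background_rate,
    fiber_count_range = c(cfg$fiber_count_min, cfg$fiber_count_max),
    fiber_length_range = c(cfg$fiber_length_min, cfg$fiber_length_max),
    fiber_thickness_sigma = cfg$fiber_thickness_sigma,
    fiber_peak_amplitude = cfg$fiber_peak_amplitude,
    mean_orientation = cfg$mean_orientation)
  cohorts <- list(
    cohort_spec("C", cfg$n_animals, cfg$images_per_animal,
                cfg$prevalence_C, cfg$angular_sigma_C),
    cohort_spec("A", cfg$n_animals, cfg$images_per_animal,
                cfg$prevalence_A, cfg$angular_sigma_A),
    cohort_spec("S", cfg$n_animals, cfg$images_per_animal,
                cfg$prevalence_S, cfg$angular_sigma_S),
    cohort_spec("AS", cfg$n_animals, cfg$images_per_animal,
                cfg$prevalence_AS, cfg$angular_sigma_AS))
  message("[shgfib] simulate: generating cohort dataset")
  dataset <- generate_dataset(cohorts, sc, seed = stage_seed(cfg$seed, 1L),
                              dir = file.path(out_dir, "images"),
                              format = cfg$image_format)

  ## 2. features ------------------------------------------------------------
  message("[shgfib] features: image-level and window-level statistics")
  img_feats <- dataset_features(dataset, factor = cfg$factor_image)
  utils::write.csv(img_feats, file.path(out_dir, "image_features.csv"),
                   row.names = FALSE)
  win_list <- lapply(seq_along(dataset$images), function(i) {
    wf <- sliding_window_features(dataset$images[[i]],
                                  window_size = cfg$window_size,
                                  stride = cfg$window_stride,
                                  factor = cfg$factor_window)
    wf$image_id <- dataset$manifest$image_id[i]
    wf$label <- dataset$manifest$label[i]
    wf
  })
  win_feats <- do.call(rbind, win_list)
  utils::write.csv(win_feats, file.path(out_dir, "window_features.csv"),
                   row.names = FALSE)

  ## 3. selection -----------------------------------------------------------
  message("[shgfib] select: random-forest feature ranking")
  imp <- rank_features(win_feats[, window_feature_names],
                       win_feats$label, n_trees = cfg$n_trees,
                       seed = stage_seed(cfg$seed, 3L))
  utils::write.csv(data.frame(feature = names(imp$importance),
                              importance = as.numeric(imp$importance)),
                   file.path(out_dir, "importance.csv"), row.names = FALSE)

  ## 4. clustering ----------------------------------------------------------
  message("[shgfib] cluster: K-means label validation")
  km_feats <- as.matrix(img_feats[, c("mean", "std", "mode", "frac_above")])
  km <- shg_kmeans(km_feats, k = 2, max_iter = cfg$kmeans_max_iter,
                   tol = cfg$kmeans_tol, seed = stage_seed(cfg$seed, 4L))
  agree <- label_agreement(km, img_feats$label)
  utils::write.csv(data.frame(image_id = img_feats$image_id,
                              cluster = km$cluster,
                              label = img_feats$label),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  message(sprintf("[shgfib]   cluster/label agreement: %.4f", agree))

  ## 5. classification ------------------------------------------------------
  message("[shgfib] cv: sigmoid neuron, stratified k-fold")
  cv <- kfold_cv(img_feats$frac_above, img_feats$label, k = cfg$k_folds,
                 seed = stage_seed(cfg$seed, 5L),
                 lr = cfg$lr, epochs = cfg$epochs)
  fold_df <- do.call(rbind, lapply(cv$folds, function(f)
    data.frame(fold = f$fold, TP = f$confusion["TP"], FP = f$confusion["FP"],
               FN = f$confusion["FN"], TN = f$confusion["TN"])))
  utils::write.csv(fold_df, file.path(out_dir, "cv_folds.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(metric = names(cv$metrics),
                              value = as.numeric(cv$metrics)),
                   file.path(out_dir, "cv_metrics.csv"), row.names = FALSE)
  model <- train_neuron(img_feats$frac_above, img_feats$label,
                        lr = cfg$lr, epochs = cfg$epochs)
  predicted <- predict(model, img_feats$frac_above, type = "class")
  utils::write.csv(data.frame(image_id = img_feats$image_id,
                              predicted = predicted,
                              label = img_feats$label),
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)

  ## 6. orientation ---------------------------------------------------------
  message("[shgfib] angles: Hough fiber orientation analysis")
  orient <- fiber_orientation_analysis(
    dataset$images, dataset$manifest$group, predicted == 1,
    threshold = cfg$binarize_threshold,
    theta_step = cfg$theta_step, min_votes = cfg$min_votes,
    max_lines = cfg$max_lines, nms_window = cfg$nms_window,
    bin_width = cfg$bin_width, width_method = cfg$width_method,
    pooling = cfg$pooling, seed = stage_seed(cfg$seed, 6L))
  angle_rows <- do.call(rbind, lapply(orient$groups, function(gr)
    if (length(gr$relative))
      data.frame(group = gr$group, relative_angle = gr$relative) else NULL))
  if (!is.null(angle_rows)) {
    utils::write.csv(angle_rows, file.path(out_dir, "angles.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(orient$widths, file.path(out_dir, "widths.csv"),
                   row.names = FALSE)

  ## 7. report --------------------------------------------------------------
  message("[shgfib] report: per-group fibrosis percentages")
  summ <- group_fiber_percentages(
    data.frame(image_id = img_feats$image_id, predicted = predicted),
    dataset$manifest)
  render_report(summ, orient$widths, file.path(out_dir, "cohort"))

  invisible(list(dataset = dataset, importance = imp, clustering = km,
                 agreement = agree, cv = cv, model = model,
                 orientation = orient, summary = summ, out_dir = out_dir,
                 config = cfg))
}
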