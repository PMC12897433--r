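#' SHG intensity images
#'
#' An `shg_image` holds a single-channel photon-count matrix together with its
#' acquisition metadata. The pixel grid uses a 0-based, top-left-origin,
#' row-major convention: row index increases downward, column index rightward.
#' Orientation angles anywhere in the package are measured counter-clockwise
#' (as seen on screen) from the +x (column) axis, i.e. with the y axis taken as
#' pointing up (towards decreasing row index).
#'
#' @param counts integer-valued matrix of non-negative photon counts
#'   (counts per gate; absolute scaling is arbitrary intensity units).
#' @param pixel_pitch physical scan step per pixel in micrometres.
#' @param image_id,group,animal optional metadata carried through the pipeline.
#' @param fiber_angles_deg for synthetic phantoms, the rendered ground-truth
#'   fiber orientations in degrees (empty for fiber-free images).
#' @param min_size minimum allowed image side, in pixels. The analysis assumes
#'   at least one 20 x 20 window fits; pass a smaller value only for toy inputs.
#' @return an object of class `shg_image`.
#' @export
shg_image <- function(counts, pixel_pitch = 10, image_id = NULL, group = NULL,
                      animal = NULL, fiber_angles_deg = numeric(0),
                      min_size = 20) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || length(dim(counts)) != 2) {
    stop("counts must be a 2-D numeric matrix")
  }
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integer-valued")
  if (nrow(counts) < min_size || ncol(counts) < min_size) {
    stop(sprintf("image must be at least %d x %d pixels (got %d x %d)",
                 min_size, min_size, nrow(counts), ncol(counts)))
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, pixel_pitch = pixel_pitch, image_id = image_id,
         group = group, animal = animal,
         fiber_angles_deg = as.numeric(fiber_angles_deg)),
    class = "shg_image"
  )
}

#' @export
print.shg_image <- function(x, ...) {
  cat(sprintf("<shg_image> %d x %d px, pitch %g um/px\n",
              nrow(x$counts), ncol(x$counts), x$pixel_pitch))
  if (!is.null(x$image_id)) cat("  id:    ", x$image_id, "\n")
  if (!is.null(x$group))    cat("  group: ", x$group, "\n")
  if (!is.null(x$animal))   cat("  animal:", x$animal, "\n")
  cat(sprintf("  counts: min %d, max %d, mean %.3f\n",
              min(x$counts), max(x$counts), mean(x$counts)))
  if (length(x$fiber_angles_deg)) {
    cat("  fibers:", length(x$fiber_angles_deg), "rendered\n")
  }
  invisible(x)
}

#' @export
plot.shg_image <- function(x, ...) {
  # top-left origin: first matrix row drawn at the top
  m <- t(x$counts[nrow(x$counts):1, , drop = FALSE])
  graphics::image(m, col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(x$counts) / ncol(x$counts),
                  main = x$image_id %||% "SHG image", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an SHG image to disk
#'
#' Supported formats: 16-bit grayscale uncompressed TIFF (default), 8-bit
#' grayscale PNG, and a whitespace-delimited integer text matrix. Integer data
#' round-trips losslessly through every format up to the format's bit depth
#' (65535 for TIFF, 255 for PNG, unbounded for text); larger counts are an
#' error on write, never a silent clip. 16-bit PNG files can be read but not
#' written.
#'
#' @param image an [shg_image()].
#' @param path output file path.
#' @param format one of "tiff", "png", "text"; default guessed from the file
#'   extension, falling back to "tiff".
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL) {
  stopifnot(inherits(image, "shg_image"))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("tiff", "png", "text"))
  m <- image$counts
  if (format == "tiff" && max(m) > 65535L) {
    stop("counts exceed 65535: cannot be written as 16-bit tiff")
  }
  if (format == "png" && max(m) > 255L) {
    stop("counts exceed 255: cannot be written as 8-bit png")
  }
  switch(format,
    tiff = tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                           compression = "none"),
    png  = png::writePNG(m / 255, path),
    text = utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  )
  invisible(path)
}

#' Read an SHG image from disk
#'
#' @param path file path.
#' @param format one of "tiff", "png", "text"; default guessed from extension.
#' @param ... passed to [shg_image()] (e.g. `image_id`, `group`, `min_size`).
#' @return an [shg_image()].
#' @export
read_image <- function(path, format = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("tiff", "png", "text"))
  m <- switch(format,
    tiff = {
      a <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(a)) == 3) stop("single-channel required: ", path)
      a
    },
    png = {
      a <- png::readPNG(path, info = TRUE)
      if (length(dim(a)) == 3) stop("single-channel required: ", path)
      depth <- tryCatch(attr(a, "info")$bit.depth, error = function(e) NULL)
      round(a * (2^(depth %||% 8) - 1))
    },
    text = {
      m <- as.matrix(utils::read.table(path, header = FALSE))
      dimnames(m) <- NULL
      if (any(m < 0)) stop("negative values in text matrix: ", path)
      m
    }
  )
  shg_image(m, ...)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         tif = , tiff = "tiff",
         png = "png",
         txt = , dat = , text = "text",
         "tiff")
}

manifest_columns <- c("image_id", "path", "group", "animal", "label",
                      "fiber_angles_deg")

#' Read and validate a dataset manifest
#'
#' The manifest is a CSV with columns
#' `image_id,path,group,animal,label,fiber_angles_deg`; `label` is 0 for
#' non-fibrotic and 1 for fibrotic images, `fiber_angles_deg` holds
#' semicolon-separated ground-truth orientations (empty when unknown or
#' fiber-free). Image paths are resolved relative to the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param groups allowed group tags.
#' @param check_files verify that every referenced image file exists.
#' @return a `data.frame` with the manifest columns, paths resolved.
#' @export
read_manifest <- function(path, groups = c("C", "A", "S", "AS"),
                          check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(manifest_columns, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("manifest contains a header but no rows")
    df$label <- integer(0)
    return(df[, manifest_columns])
  }
  if (anyDuplicated(df$image_id)) {
    stop("duplicate image_id in manifest: ",
         paste(unique(df$image_id[duplicated(df$image_id)]), collapse = ", "))
  }
  bad_group <- setdiff(unique(df$group), groups)
  if (length(bad_group)) {
    stop("unknown group tag(s) in manifest: ", paste(bad_group, collapse = ", "))
  }
  df$label <- as.integer(df$label)
  if (any(is.na(df$label)) || !all(df$label %in% c(0L, 1L))) {
    stop("labels must be 0 (non-fibrotic) or 1 (fibrotic)")
  }
  base <- dirname(path)
  abs <- file.path(base, df$path)
  abs[grepl("^(/|[A-Za-z]:)", df$path)] <- df$path[grepl("^(/|[A-Za-z]:)", df$path)]
  if (check_files) {
    missing <- which(!file.exists(abs))
    if (length(missing)) {
      stop(sprintf("manifest row %d: image file not found: %s",
                   missing[1], abs[missing[1]]))
    }
  }
  df$path <- abs
  df[, manifest_columns]
}

#' @rdname read_manifest
#' @param manifest a manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, manifest_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Parse / format the semicolon-separated fiber-angle manifest field
#' @keywords internal
parse_angles <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

format_angles <- function(a) paste(formatC(a, format = "fg", digits = 8),
                                   collapse = ";")

#' Load every image referenced by a manifest
#'
#' @param manifest a manifest `data.frame` from [read_manifest()].
#' @return list of [shg_image()] in manifest row order.
#' @export
load_images <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    read_image(manifest$path[i],
               image_id = manifest$image_id[i],
               group = manifest$group[i],
               animal = manifest$animal[i],
               fiber_angles_deg = parse_angles(manifest$fiber_angles_deg[i]))
  })
}
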