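#' Read a grayscale or colour image (PNG or TIFF)
#'
#' Returns the raw array as stored (values in \[0,1\] for both formats);
#' pass through [to_gray_normalized()] before analysis.
#'
#' @param path image path; format chosen by extension
#'   (.png / .tif / .tiff).
#' @return numeric matrix or rows x cols x channels array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) .stop_validation("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                .stop_validation("unsupported image format: .", ext))
  img
}

#' Write a raster as PNG
#' @param image numeric matrix in \[0,1\] or logical matrix (written as
#'   0/1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) image <- image * 1
  png::writePNG(.clip01(image), path)
  invisible(path)
}

#' Serialize a theme map to disk
#'
#' Writes three artifacts next to each other: the label raster as a PNG
#' (class id / 255; id 0 = outside the macular mask), the class table as
#' CSV (`class_id`, per-channel means, covariance entries, `pixel_count`)
#' and the pairwise transformed-divergence matrix as CSV.
#'
#' @param theme_map a `theme_map`.
#' @param prefix output path prefix; files `<prefix>_labels.png`,
#'   `<prefix>_classes.csv`, `<prefix>_td.csv` are written.
#' @return character vector of written paths, invisibly.
#' @export
write_theme_map <- function(theme_map, prefix) {
  stopifnot(inherits(theme_map, "theme_map"))
  lab <- theme_map$labels
  lab[is.na(lab)] <- 0L
  p1 <- paste0(prefix, "_labels.png")
  png::writePNG(lab / 255, p1)
  cl <- theme_map$classes
  covs <- t(vapply(cl, function(c) as.vector(c$covariance), numeric(9)))
  colnames(covs) <- paste0("cov_", rep(c("faf", "ir", "green"), 3),
                           "_", rep(c("faf", "ir", "green"), each = 3))
  tab <- data.frame(class_id = vapply(cl, `[[`, 1L, "class_id"),
                    mean_faf = vapply(cl, function(c) c$mean[1], numeric(1)),
                    mean_ir = vapply(cl, function(c) c$mean[2], numeric(1)),
                    mean_green = vapply(cl, function(c) c$mean[3], numeric(1)),
                    covs,
                    pixel_count = vapply(cl, `[[`, 1L, "pixel_count"))
  p2 <- paste0(prefix, "_classes.csv")
  write.csv(tab, p2, row.names = FALSE)
  p3 <- paste0(prefix, "_td.csv")
  write.csv(as.data.frame(theme_map$pairwise_td), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognised top-level keys: `image_width`, `preprocess`
#' (`blur_sigma`, `saturation_fraction`, `mask_radius_fraction`),
#' `clustering` (`k_init`, `td_min`, `min_threshold`, `k_floor`,
#' `max_iter`, `min_class_fraction`, `seed`), `thresholds`
#' (`progression_gt`, `regression_lt`), `overlap_threshold`,
#' `registration_model`. Unknown keys are rejected.
#'
#' @param path YAML (.yml/.yaml) or JSON (.json) file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stop_validation("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else .stop_validation("unsupported config format: .", ext)
  known <- c("image_width", "preprocess", "clustering", "thresholds",
             "overlap_threshold", "registration_model")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    .stop_validation("unknown config key: ", paste(bad, collapse = ", "))
  check_sub <- function(part, fn) {
    sub <- raw[[part]]
    if (is.null(sub)) return(NULL)
    bad <- setdiff(names(sub), names(formals(fn)))
    if (length(bad))
      .stop_validation("unknown ", part, " config key: ",
                       paste(bad, collapse = ", "))
    do.call(fn, sub)
  }
  width <- raw$image_width %||% 768
  args <- list(image_width = width)
  pp <- check_sub("preprocess", preprocess_config)
  if (!is.null(pp)) args$preprocess <- pp
  cc <- check_sub("clustering", clustering_config)
  if (!is.null(cc)) args$clustering <- cc
  th <- check_sub("thresholds", change_thresholds)
  if (!is.null(th)) args$thresholds <- th
  if (!is.null(raw$overlap_threshold)) args$overlap_threshold <- raw$overlap_threshold
  if (!is.null(raw$registration_model)) args$registration_model <- raw$registration_model
  do.call(pipeline_config, args)
}

#' Write a phantom visit to disk in the pipeline's input layout
#'
#' Layout inside `dir`: `faf.png`, `ir.png`, `green.png`, `cfp.png`,
#' `landmarks_<channel>.csv`, `annotation.png`, and the ground-truth
#' masks under `truth_*.png`.
#'
#' @param visit a [phantom_visit()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_visit <- function(visit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(visit$channels)) {
    write_image(visit$channels[[ch]], file.path(dir, paste0(ch, ".png")))
    write_landmarks(visit$landmarks[[ch]],
                    file.path(dir, paste0("landmarks_", ch, ".csv")))
  }
  write_image(visit$cfp, file.path(dir, "cfp.png"))
  write_image(visit$annotation, file.path(dir, "annotation.png"))
  write_image(visit$truth$drusen_mask, file.path(dir, "truth_drusen.png"))
  write_image(visit$truth$pigment_mask, file.path(dir, "truth_pigment.png"))
  write_image(visit$truth$vessel_mask, file.path(dir, "truth_vessels.png"))
  invisible(dir)
}

#' Read a visit directory into the in-memory structure
#'
#' Inverse of [write_phantom_visit()] for the analysis inputs (channels,
#' landmarks, annotation).
#'
#' @param dir visit directory.
#' @return visit list consumable by [analyze_visit()].
#' @export
read_visit <- function(dir) {
  chans <- c("faf", "ir", "green")
  channels <- list(); landmarks <- list()
  for (ch in chans) {
    p <- file.path(dir, paste0(ch, ".png"))
    if (!file.exists(p)) .stop_validation("missing channel image: ", p)
    channels[[ch]] <- read_image(p)
    lp <- file.path(dir, paste0("landmarks_", ch, ".csv"))
    landmarks[[ch]] <- if (file.exists(lp)) read_landmarks(lp) else NULL
  }
  ap <- file.path(dir, "annotation.png")
  if (!file.exists(ap)) .stop_validation("missing annotation mask: ", ap)
  list(channels = channels, landmarks = landmarks,
       annotation = to_gray_normalized(read_image(ap)) > 0.5,
       cfp = if (file.exists(file.path(dir, "cfp.png")))
         read_image(file.path(dir, "cfp.png")) else NULL)
}
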