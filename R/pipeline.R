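#' Full pipeline configuration
#'
#' Bundles the stage configurations. `blur_sigma` scales with image
#' width (50 px at a 768-px-wide frame) so the background-estimation
#' scale keeps the same relation to lesion size on smaller rasters.
#'
#' @param image_width expected channel width in pixels (default 768).
#' @param preprocess a [preprocess_config()]; default derived from
#'   `image_width`.
#' @param clustering a [clustering_config()].
#' @param thresholds a [change_thresholds()].
#' @param overlap_threshold annotation-overlap fraction for drusen class
#'   assignment (default 0.5).
#' @param registration_model `"affine"` or `"similarity"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(image_width = 768,
                            preprocess = preprocess_config(
                              blur_sigma = max(3, 50 * image_width / 768)),
                            clustering = clustering_config(min_class_fraction = 0.01),
                            thresholds = change_thresholds(),
                            overlap_threshold = 0.5,
                            registration_model = "affine") {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(clustering, "clustering_config"),
            inherits(thresholds, "change_thresholds"))
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    .stop_validation("overlap_threshold must be in (0, 1]")
  structure(list(preprocess = preprocess, clustering = clustering,
                 thresholds = thresholds,
                 overlap_threshold = overlap_threshold,
                 registration_model = registration_model),
            class = "pipeline_config")
}

#' Analyze one visit: register, preprocess, cluster, assign, quantify
#'
#' Runs the per-visit half of the workflow. Each channel is aligned to
#' the reference grid from its landmark pairs, preprocessed
#' (grayscale, background correction, contrast stretch), stacked under
#' the macular mask, clustered into spectral theme classes, and the
#' classes are assigned as drusen against the visit's expert annotation.
#'
#' @param visit list with `channels` (faf/ir/green rasters),
#'   `landmarks` (per-channel [landmark_set()]; `NULL` if channels are
#'   already on the reference grid), `annotation` (binary matrix).
#' @param config a [pipeline_config()].
#' @param register logical; skip registration when channels are already
#'   aligned.
#' @return list with `theme_map`, `drusen_class_ids`, `mask` (binary
#'   drusen mask), `area` (px), `registration` (per-channel residual
#'   RMSE).
#' @export
analyze_visit <- function(visit, config = pipeline_config(), register = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  chans <- c("faf", "ir", "green")
  if (!all(chans %in% names(visit$channels)))
    .stop_validation("visit must provide faf, ir and green channels")
  shape <- dim(to_gray_normalized(visit$channels[[1]]))
  residuals <- setNames(numeric(3), chans)
  aligned <- list()
  for (ch in chans) {
    img <- to_gray_normalized(visit$channels[[ch]])
    if (register) {
      if (is.null(visit$landmarks[[ch]]))
        .stop_validation("missing landmarks for channel ", ch)
      tr <- estimate_transform(visit$landmarks[[ch]],
                               model = config$registration_model)
      residuals[ch] <- tr$residual_rmse
      img <- warp_image(img, tr, shape)
    }
    aligned[[ch]] <- preprocess_channel(img, config$preprocess)
  }
  mask <- macular_mask(shape, config$preprocess$mask_radius_fraction)
  stack <- multispectral_stack(aligned$faf, aligned$ir, aligned$green, mask)
  tm <- theme_classify(stack, config$clustering)
  ids <- assign_theme_classes(tm, visit$annotation, config$overlap_threshold)
  dm <- drusen_mask(tm, ids)
  list(theme_map = tm, drusen_class_ids = ids, mask = dm,
       area = drusen_area(dm), registration = residuals)
}

#' Analyze a pair of visits and classify the drusen change
#'
#' End-to-end analysis of one eye: [analyze_visit()] on both visits,
#' then percent change in drusen area and its categorical direction.
#'
#' @param visit1,visit2 visit structures (see [analyze_visit()]).
#' @param config a [pipeline_config()].
#' @param register logical, as in [analyze_visit()].
#' @return object of class `mspr_analysis`: `visit1`, `visit2` (per-visit
#'   results), `change` (a [drusen_change()] result).
#' @export
analyze_pair <- function(visit1, visit2, config = pipeline_config(),
                         register = TRUE) {
  r1 <- analyze_visit(visit1, config, register)
  r2 <- analyze_visit(visit2, config, register)
  ch <- withCallingHandlers(
    drusen_change(r1$area, r2$area, config$thresholds),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(visit1 = r1, visit2 = r2, change = ch),
            class = "mspr_analysis")
}

#' @export
print.mspr_analysis <- function(x, ...) {
  cat("Multispectral drusen-change analysis\n")
  cat("  visit 1: k =", x$visit1$theme_map$k, "classes,",
      length(x$visit1$drusen_class_ids), "drusen, area", x$visit1$area, "px\n")
  cat("  visit 2: k =", x$visit2$theme_map$k, "classes,",
      length(x$visit2$drusen_class_ids), "drusen, area", x$visit2$area, "px\n  ")
  print(x$change)
  invisible(x)
}

#' Run the full pipeline over a phantom cohort
#'
#' Applies [analyze_pair()] to every eye of a [phantom_cohort()] and
#' tabulates measured against planted change.
#'
#' @param cohort a [phantom_cohort()].
#' @param config a [pipeline_config()]; the default scales the blur to
#'   the cohort's image width.
#' @param register run the registration stage (default TRUE).
#' @return data.frame: `eye_id,label,true_pct_change,area1_px,area2_px,
#'   measured_pct_change,category,n_drusen_classes_v1,n_drusen_classes_v2`.
#' @export
analyze_cohort <- function(cohort, config = NULL, register = TRUE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (is.null(config)) {
    p1 <- cohort$eyes[[1]]$params
    w <- p1$image_size[2]
    # background scale must exceed the largest druse (including visit-2
    # growth) or lesions are attenuated by the subtraction
    bs <- ceiling(2.6 * p1$drusen_radius_range[2] * 1.16)
    config <- pipeline_config(image_width = w,
                              preprocess = preprocess_config(
                                blur_sigma = max(bs, 50 * w / 768)))
  }
  rows <- lapply(seq_along(cohort$eyes), function(i) {
    eye <- cohort$eyes[[i]]
    res <- analyze_pair(eye$pair$visits[[1]], eye$pair$visits[[2]],
                        config, register)
    data.frame(eye_id = cohort$manifest$eye_id[i], label = eye$label,
               true_pct_change = eye$pair$truth$true_percent_change,
               area1_px = res$visit1$area, area2_px = res$visit2$area,
               measured_pct_change = res$change$percent_change,
               category = res$change$category,
               n_drusen_classes_v1 = length(res$visit1$drusen_class_ids),
               n_drusen_classes_v2 = length(res$visit2$drusen_class_ids))
  })
  do.call(rbind, rows)
}
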