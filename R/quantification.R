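#' Change-classification thresholds
#'
#' Percent-change cut points for the three longitudinal categories:
#' progression when change > `progression_gt`, regression when change
#' < `regression_lt`, stable on the closed interval between them
#' (endpoints inclusive in stable).
#'
#' @param progression_gt upper bound of stable, percent (default +5).
#' @param regression_lt lower bound of stable, percent (default -5).
#' @return list of class `change_thresholds`.
#' @export
change_thresholds <- function(progression_gt = 5, regression_lt = -5) {
  if (!(regression_lt < progression_gt))
    .stop_validation("regression_lt must be below progression_gt")
  structure(list(progression_gt = progression_gt, regression_lt = regression_lt),
            class = "change_thresholds")
}

.change_levels <- c("progression", "stable", "regression")

#' Assign theme classes as drusen against an expert annotation
#'
#' A class is called drusen when at least `overlap_threshold` of its
#' pixels fall inside the expert-annotated drusen mask (majority rule by
#' default). Classes dominated by other lesions — pigmentary
#' abnormalities dark on the green channel, vessels dark everywhere —
#' fail the overlap rule and are never pooled with drusen.
#'
#' @param theme_map a `theme_map` from [theme_classify()].
#' @param annotation logical (or 0/1) matrix on the same grid; `TRUE` =
#'   expert-annotated drusen.
#' @param overlap_threshold minimum in-annotation fraction (default 0.5).
#' @return integer vector of drusen class ids (possibly empty).
#' @export
assign_theme_classes <- function(theme_map, annotation, overlap_threshold = 0.5) {
  stopifnot(inherits(theme_map, "theme_map"))
  if (is.numeric(annotation)) annotation <- annotation > 0.5
  if (!identical(dim(annotation), theme_map$dim))
    .stop_validation("annotation grid does not match the theme map")
  ann <- annotation[theme_map$index]
  ids <- vapply(theme_map$classes, `[[`, 1L, "class_id")
  lab <- theme_map$in_mask_labels
  frac <- vapply(ids, function(id) mean(ann[lab == id]), numeric(1))
  ids[frac >= overlap_threshold]
}

#' Binary drusen mask from assigned theme classes
#'
#' Union of the member classes' pixels (the duochrome step as a pure
#' label-set union: blurring before binarisation would perturb the area).
#' All other in-mask pixels and everything outside the macular mask are
#' `FALSE`.
#'
#' @param theme_map a `theme_map`.
#' @param drusen_class_ids integer class ids (subset of the map's ids).
#' @return logical matrix.
#' @export
drusen_mask <- function(theme_map, drusen_class_ids) {
  stopifnot(inherits(theme_map, "theme_map"))
  ids <- vapply(theme_map$classes, `[[`, 1L, "class_id")
  if (length(drusen_class_ids) && !all(drusen_class_ids %in% ids))
    .stop_validation("unknown theme class id: ",
                     paste(setdiff(drusen_class_ids, ids), collapse = ", "))
  m <- matrix(FALSE, theme_map$dim[1], theme_map$dim[2])
  if (length(drusen_class_ids))
    m[theme_map$index] <- theme_map$in_mask_labels %in% drusen_class_ids
  m
}

#' Drusen area in pixels
#' @param mask logical (or 0/1) drusen mask; `TRUE`/white = drusen.
#' @return integer pixel count.
#' @export
drusen_area <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0.5
  if (!is.logical(mask)) .stop_validation("mask must be logical or 0/1")
  sum(mask)
}

#' Percent change in drusen area between visits
#'
#' `100 * (area2 - area1) / area1`, signed. Two degenerate cases are
#' defined explicitly: no drusen at either visit is 0% (stable); drusen
#' appearing de novo (`area1 == 0, area2 > 0`) has no defined percentage
#' and is flagged as incident drusen (see [drusen_change()]).
#'
#' @param area1,area2 pixel counts at visit 1 and visit 2.
#' @return percent change (`NA` for incident drusen, with a warning).
#' @export
percent_change <- function(area1, area2) {
  if (area1 < 0 || area2 < 0) .stop_validation("areas must be >= 0")
  if (area1 == 0) {
    if (area2 == 0) return(0)
    warning("incident drusen: area undefined at visit 1; percent change undefined")
    return(NA_real_)
  }
  100 * (area2 - area1) / area1
}

#' Classify a percent change as progression, stable or regression
#'
#' Progression when change > `progression_gt` (+5% by default),
#' regression when change < `regression_lt` (-5%), stable on the closed
#' interval in between (both endpoints stable).
#'
#' @param pct percent change (finite).
#' @param thresholds a [change_thresholds()].
#' @return one of `"progression"`, `"stable"`, `"regression"`.
#' @export
classify_change <- function(pct, thresholds = change_thresholds()) {
  stopifnot(inherits(thresholds, "change_thresholds"))
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct))
    .stop_validation("pct must be a single finite number")
  if (pct > thresholds$progression_gt) "progression"
  else if (pct < thresholds$regression_lt) "regression"
  else "stable"
}

#' Longitudinal drusen-change result
#'
#' Combines the two visit areas into the percent change and its
#' categorical direction. Incident drusen (none at visit 1, some at
#' visit 2) is forced to progression with a warning and flagged.
#'
#' @param area1,area2 drusen pixel counts at the two visits.
#' @param thresholds a [change_thresholds()].
#' @return object of class `change_result`: `area_visit1`, `area_visit2`,
#'   `percent_change`, `category`, `incident`.
#' @export
drusen_change <- function(area1, area2, thresholds = change_thresholds()) {
  pct <- withCallingHandlers(percent_change(area1, area2),
                             warning = function(w) invokeRestart("muffleWarning"))
  incident <- area1 == 0 && area2 > 0
  category <- if (incident) {
    warning("incident drusen: category forced to progression")
    "progression"
  } else classify_change(pct, thresholds)
  structure(list(area_visit1 = area1, area_visit2 = area2,
                 percent_change = pct, category = category,
                 incident = incident),
            class = "change_result")
}

#' @export
print.change_result <- function(x, ...) {
  cat("Drusen change: ", x$area_visit1, " -> ", x$area_visit2, " px (",
      if (is.na(x$percent_change)) "incident drusen"
      else sprintf("%+.1f%%", x$percent_change),
      ") => ", x$category, "\n", sep = "")
  invisible(x)
}
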