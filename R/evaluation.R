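#' Three-category confusion summary against expert grading
#'
#' Cross-tabulates expert change categories against a method's categories
#' over the fixed vocabulary progression / stable / regression and
#' derives the agreement statistics used to compare drusen-change
#' methods:
#' \itemize{
#'   \item agreement — trace / n (same category both ways);
#'   \item sensitivity — among eyes the expert called changed
#'     (progression or regression), the fraction the method called
#'     changed \emph{in the same direction}; an expert-regression eye the
#'     method calls progression counts as a miss;
#'   \item specificity — among expert-stable eyes, the fraction the
#'     method also calls stable.
#' }
#' With no expert-stable eyes, specificity is `NA` with
#' `specificity_defined = FALSE` (never silently 0); likewise for
#' sensitivity with no changed eyes.
#'
#' @param expert character vector of expert categories.
#' @param method character vector of the method's categories (same
#'   length).
#' @return object of class `confusion_summary`: `counts` (3x3, expert
#'   rows x method columns), `n`, `agreement`, `sensitivity`,
#'   `specificity`, plus definedness flags.
#' @examples
#' cs <- confusion_summary(c("progression", "stable", "regression"),
#'                         c("progression", "progression", "regression"))
#' cs$agreement
#' @export
confusion_summary <- function(expert, method) {
  if (length(expert) < 1L || length(expert) != length(method))
    .stop_validation("expert and method must be equal-length, non-empty")
  bad <- setdiff(unique(c(expert, method)), .change_levels)
  if (length(bad))
    .stop_validation("unknown change category: ", paste(bad, collapse = ", "))
  e <- factor(expert, levels = .change_levels)
  m <- factor(method, levels = .change_levels)
  counts <- table(expert = e, method = m)
  n <- length(e)
  changed <- e != "stable"
  same_dir <- changed & (m == e)
  sens <- if (any(changed)) sum(same_dir) / sum(changed) else NA_real_
  stab <- e == "stable"
  spec <- if (any(stab)) sum(stab & m == "stable") / sum(stab) else NA_real_
  structure(list(counts = unclass(counts), n = n,
                 agreement = sum(diag(counts)) / n,
                 sensitivity = sens, sensitivity_defined = any(changed),
                 specificity = spec, specificity_defined = any(stab)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("Expert vs method confusion (n = ", x$n, ")\n", sep = "")
  print(x$counts)
  cat(sprintf("agreement %.1f%% | sensitivity %s | specificity %s\n",
              100 * x$agreement,
              if (x$sensitivity_defined) sprintf("%.1f%%", 100 * x$sensitivity) else "undefined",
              if (x$specificity_defined) sprintf("%.1f%%", 100 * x$specificity) else "undefined"))
  invisible(x)
}

#' Agreement within one expert subgroup
#'
#' Fraction of eyes in a given expert category for which the method
#' returns the same category.
#'
#' @param expert,method category vectors as in [confusion_summary()].
#' @param subgroup expert category defining the subgroup.
#' @return fraction in \[0,1\].
#' @export
subgroup_agreement <- function(expert, method, subgroup) {
  subgroup <- match.arg(subgroup, .change_levels)
  sel <- expert == subgroup
  if (!any(sel)) .stop_validation("no eyes in expert subgroup '", subgroup, "'")
  mean(method[sel] == subgroup)
}

#' Bland-Altman agreement summary for paired percent changes
#'
#' Bias (mean difference), 95% limits of agreement (bias +/- 1.96 sd of
#' the differences), and the Pearson correlation of the difference
#' against the pairwise mean (a proportional-bias check).
#'
#' @param x,y equal-length numeric vectors of paired measurements
#'   (n >= 3, finite).
#' @return list with `bias`, `loa` (length-2), `sd_diff`, `r`,
#'   `r_defined`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    .stop_validation("need equal-length vectors with n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    .stop_validation("inputs must be finite")
  d <- x - y
  a <- (x + y) / 2
  s <- sd(d)
  r_def <- s > 0 && sd(a) > 0
  list(bias = mean(d), sd_diff = s,
       loa = mean(d) + c(-1.96, 1.96) * s,
       r = if (r_def) cor(d, a) else 0, r_defined = r_def,
       n = length(x))
}

#' Pearson product-moment correlation with degeneracy flag
#'
#' @param a,b equal-length numeric vectors (n >= 3, finite).
#' @return list with `r` (`NA` when either input has zero variance,
#'   flagged via `defined = FALSE`) and `n`.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    .stop_validation("need equal-length vectors with n >= 3")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    .stop_validation("inputs must be finite")
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, defined = FALSE, n = length(a)))
  list(r = cor(a, b), defined = TRUE, n = length(a))
}

#' Read a cohort grading table
#'
#' Expects columns `eye_id`, `expert`, and for each method `<m>_cat`
#' (categories) with optional `<m>_pct` (percent changes). A bundled
#' 33-eye example in this format ships as
#' `system.file("extdata", "example_gradings.csv", package = "drusenmspr")`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_gradings <- function(path) {
  if (!file.exists(path)) .stop_validation("grading file not found: ", path)
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) .stop_validation("grading table is empty: ", path)
  if (!all(c("eye_id", "expert") %in% names(d)))
    .stop_validation("grading CSV needs eye_id and expert columns")
  if (!length(grep("_cat$", names(d))))
    .stop_validation("grading CSV needs at least one <method>_cat column")
  d
}

#' Evaluate all methods in a grading table against the expert
#'
#' Builds a [confusion_summary()] and per-subgroup agreement for every
#' `<method>_cat` column, and — where two methods carry `<method>_pct`
#' columns — a Bland-Altman comparison and the correlation of their
#' difference with mean drusen change.
#'
#' @param gradings data.frame from [read_gradings()].
#' @return list with one entry per method (`confusion`, `subgroups`) and
#'   optionally `bland_altman` comparing the first two `_pct` methods.
#' @export
evaluate_cohort <- function(gradings) {
  methods <- sub("_cat$", "", grep("_cat$", names(gradings), value = TRUE))
  out <- list(methods = list())
  for (m in methods) {
    cs <- confusion_summary(gradings$expert, gradings[[paste0(m, "_cat")]])
    subs <- vapply(intersect(.change_levels, unique(gradings$expert)),
                   function(s) subgroup_agreement(gradings$expert,
                                                  gradings[[paste0(m, "_cat")]], s),
                   numeric(1))
    out$methods[[m]] <- list(confusion = cs, subgroups = as.list(subs))
  }
  pcts <- paste0(methods, "_pct")
  have <- methods[pcts %in% names(gradings)]
  if (length(have) >= 2L) {
    x <- gradings[[paste0(have[1], "_pct")]]
    y <- gradings[[paste0(have[2], "_pct")]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3L)
      out$bland_altman <- c(list(methods = have[1:2]), bland_altman(x[ok], y[ok]))
  }
  out
}
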