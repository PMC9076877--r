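#' Clustering configuration
#'
#' Parameters of the spectral theme-class segmentation: k-means starting
#' at `k_init` classes, then iterative merging of the least-separable pair
#' until every pairwise transformed divergence reaches `td_min`.
#'
#' @param k_init starting number of classes (default 16).
#' @param td_min minimum acceptable pairwise transformed divergence,
#'   in \[0,2\] (default 1.5).
#' @param min_threshold k-means convergence threshold: iteration stops
#'   when the fraction of pixels changing assignment falls below it
#'   (default 0.01).
#' @param k_floor smallest class count the merge loop may reach
#'   (default 2).
#' @param max_iter maximum Lloyd iterations per fit (default 50).
#' @param min_class_fraction optional post-fit filter: classes holding a
#'   smaller fraction of in-mask pixels are dissolved into their nearest
#'   surviving class. Default 0 (off).
#' @param seed integer seed fixing the k-means initialisation.
#' @return list of class `clustering_config`.
#' @export
clustering_config <- function(k_init = 16L, td_min = 1.5, min_threshold = 0.01,
                              k_floor = 2L, max_iter = 50L,
                              min_class_fraction = 0, seed = 1L) {
  k_init <- as.integer(k_init); k_floor <- as.integer(k_floor)
  if (k_floor < 2L || k_floor > k_init)
    .stop_validation("need 2 <= k_floor <= k_init")
  if (td_min <= 0 || td_min > 2) .stop_validation("td_min must be in (0, 2]")
  if (min_threshold < 0) .stop_validation("min_threshold must be >= 0")
  structure(list(k_init = k_init, td_min = td_min,
                 min_threshold = min_threshold, k_floor = k_floor,
                 max_iter = as.integer(max_iter),
                 min_class_fraction = min_class_fraction,
                 seed = as.integer(seed)),
            class = "clustering_config")
}

# Farthest-point seeding: deterministic given the seed. First center is a
# uniformly drawn pixel; each next center is the point maximising the
# minimum distance to those already chosen (ties -> lowest index).
.seed_centroids <- function(X, k, seed) {
  set.seed(seed)
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  dmin <- rep(Inf, n)
  for (j in seq_len(k)[-1]) {
    d <- rowSums((X - rep(X[idx[j - 1L], ], each = n))^2)
    dmin <- pmin(dmin, d)
    idx[j] <- which.max(dmin)
  }
  X[idx, , drop = FALSE]
}

.assign_nearest <- function(X, centers) {
  n <- nrow(X); k <- nrow(centers)
  D <- matrix(0, n, k)
  for (j in seq_len(k))
    D[, j] <- rowSums((X - rep(centers[j, ], each = n))^2)
  list(labels = max.col(-D, ties.method = "first"),
       sse = sum(D[cbind(seq_len(n), max.col(-D, ties.method = "first"))]))
}

# Lloyd's algorithm with assignment-change-fraction convergence and
# empty-cluster dropping. Within-cluster SSE is asserted non-increasing.
.lloyd <- function(X, centers, min_threshold, max_iter) {
  n <- nrow(X)
  labels <- rep.int(0L, n)
  sse_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    a <- .assign_nearest(X, centers)
    changed <- mean(a$labels != labels)
    labels <- a$labels
    keep <- sort(unique(labels))
    if (length(keep) < nrow(centers)) {            # drop empty clusters
      labels <- match(labels, keep)
      centers <- centers[keep, , drop = FALSE]
    }
    centers <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j)
      colMeans(X[labels == j, , drop = FALSE])))
    sse_trace <- c(sse_trace, a$sse)
    if (it > 1L && a$sse > sse_trace[it - 1L] + 1e-9)
      .stop_numeric("within-cluster SSE increased across Lloyd iterations")
    if (it > 1L && changed < min_threshold) break
  }
  sse <- sum((X - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centers = centers, sse = sse,
       sse_trace = sse_trace, iterations = it)
}

#' Fit k-means theme classes to a multispectral stack
#'
#' One k-means pass (Lloyd's algorithm) over the in-mask 3-channel pixel
#' vectors, either from a deterministic farthest-point seeding or from
#' supplied initial centroids. Convergence is declared when the fraction
#' of pixels changing assignment drops below `config$min_threshold`.
#' Empty clusters are dropped, so fewer than `k` classes may return.
#'
#' @param stack an [multispectral_stack()].
#' @param k number of classes requested.
#' @param init_centroids optional k x 3 matrix of starting centroids.
#' @param config a [clustering_config()].
#' @return a `theme_map` (see [theme_classify()]); its `pairwise_td`
#'   matrix is populated from the fitted class statistics.
#' @export
kmeans_fit <- function(stack, k, init_centroids = NULL,
                       config = clustering_config()) {
  stopifnot(inherits(stack, "mspr_stack"), inherits(config, "clustering_config"))
  X <- stack$pixels
  k <- as.integer(k)
  if (k < 1L || k > nrow(X))
    .stop_validation("k must be between 1 and the in-mask pixel count")
  centers <- if (is.null(init_centroids))
    .seed_centroids(X, k, config$seed) else as.matrix(init_centroids)
  fit <- .lloyd(X, centers, config$min_threshold, config$max_iter)
  labels <- fit$labels
  if (config$min_class_fraction > 0) {
    frac <- tabulate(labels, nbins = nrow(fit$centers)) / length(labels)
    keep <- which(frac >= config$min_class_fraction)
    if (length(keep) >= 1L && length(keep) < nrow(fit$centers)) {
      a <- .assign_nearest(X, fit$centers[keep, , drop = FALSE])
      labels <- a$labels
      fit$centers <- fit$centers[keep, , drop = FALSE]
    }
  }
  .theme_map(stack, labels, fit)
}

.theme_map <- function(stack, labels, fit, history = NULL, exit = NULL) {
  classes <- class_statistics(stack, labels)
  td <- pairwise_td(classes)
  raster <- matrix(NA_integer_, nrow(stack$faf), ncol(stack$faf))
  raster[stack$index] <- labels
  structure(list(labels = raster, in_mask_labels = labels, classes = classes,
                 pairwise_td = td, sse = fit$sse, sse_trace = fit$sse_trace,
                 k = length(classes), history = history, exit = exit,
                 dim = dim(stack$faf), index = stack$index),
            class = "theme_map")
}

#' Per-class spectral statistics
#'
#' Mean vector and covariance of the three channels for every theme
#' class. Covariances are regularised by adding `1e-6 * I` whenever the
#' smallest eigenvalue falls below 1e-6 (8-bit quantisation can make a
#' within-class covariance exactly singular); single-pixel classes fall
#' back to the regularised diagonal. Classes with fewer than 4 pixels are
#' flagged via `small = TRUE`.
#'
#' @param stack an [multispectral_stack()].
#' @param labels integer vector of class labels over in-mask pixels
#'   (values `1..k`).
#' @return list of per-class statistics: `class_id`, `mean` (length-3),
#'   `covariance` (3x3), `pixel_count`, `small`.
#' @export
class_statistics <- function(stack, labels) {
  stopifnot(inherits(stack, "mspr_stack"))
  X <- stack$pixels
  if (length(labels) != nrow(X))
    .stop_validation("labels must cover all in-mask pixels")
  eps <- 1e-6
  lapply(sort(unique(labels)), function(id) {
    P <- X[labels == id, , drop = FALSE]
    n <- nrow(P)
    mu <- setNames(colMeans(P), c("faf", "ir", "green"))
    S <- if (n >= 2L) unname(cov(P)) else diag(0, 3)
    if (!all(is.finite(S))) S <- diag(0, 3)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < eps)
      S <- S + diag(eps, 3)
    list(class_id = as.integer(id), mean = mu, covariance = S,
         pixel_count = n, small = n < 4L)
  })
}

#' Transformed divergence between two theme classes
#'
#' Gaussian class separability statistic used in remote-sensing
#' classification, bounded in \[0,2\]:
#' \deqn{D = \tfrac12 tr[(\Sigma_a-\Sigma_b)(\Sigma_b^{-1}-\Sigma_a^{-1})] +
#'       \tfrac12 tr[(\Sigma_a^{-1}+\Sigma_b^{-1})
#'       (\mu_a-\mu_b)(\mu_a-\mu_b)^T]}
#' \deqn{D_T = 2\,(1 - e^{-D/8})}
#' Identical class models give 0; classes separable with near certainty
#' approach 2.
#'
#' @param a,b per-class statistics entries from [class_statistics()].
#' @return transformed divergence in \[0,2\].
#' @export
transformed_divergence <- function(a, b) {
  Sa <- a$covariance; Sb <- b$covariance
  Sai <- tryCatch(solve(Sa), error = function(e)
    .stop_numeric("singular covariance for class ", a$class_id))
  Sbi <- tryCatch(solve(Sb), error = function(e)
    .stop_numeric("singular covariance for class ", b$class_id))
  dm <- a$mean - b$mean
  D <- 0.5 * sum(diag((Sa - Sb) %*% (Sbi - Sai))) +
       0.5 * sum(diag((Sai + Sbi) %*% (dm %o% dm)))
  min(max(2 * (1 - exp(-D / 8)), 0), 2)
}

#' Pairwise transformed-divergence matrix
#' @param classes list from [class_statistics()].
#' @return symmetric k x k matrix (diagonal 0), dimnames = class ids.
#' @export
pairwise_td <- function(classes) {
  k <- length(classes)
  td <- matrix(0, k, k, dimnames = list(vapply(classes, `[[`, 1L, "class_id"),
                                        vapply(classes, `[[`, 1L, "class_id")))
  if (k < 2L) return(td)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    td[i, j] <- td[j, i] <- transformed_divergence(classes[[i]], classes[[j]])
  td
}

#' Select the least-separable class pair and build merged centroids
#'
#' Finds the pair with the smallest pairwise transformed divergence
#' (ties: smallest (i, j) class-id pair in lexicographic order) and
#' returns k-1 initial centroids for the next fit: the pair replaced by
#' its pixel-count-weighted mean, all other class means unchanged.
#'
#' @param theme_map a `theme_map`.
#' @return list with `pair` (two class ids), `min_td`, and `centroids`
#'   ((k-1) x 3 matrix); `NULL` if only one class remains.
#' @export
merge_least_separable <- function(theme_map) {
  stopifnot(inherits(theme_map, "theme_map"))
  k <- theme_map$k
  if (k < 2L) return(NULL)
  td <- theme_map$pairwise_td
  best <- c(1L, 2L); bestv <- Inf
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    if (td[i, j] < bestv) { bestv <- td[i, j]; best <- c(i, j) }
  cl <- theme_map$classes
  means <- t(vapply(cl, `[[`, numeric(3), "mean"))
  wts <- vapply(cl, `[[`, 1L, "pixel_count")
  i <- best[1]; j <- best[2]
  merged <- (wts[i] * means[i, ] + wts[j] * means[j, ]) / (wts[i] + wts[j])
  centroids <- rbind(means[-c(i, j), , drop = FALSE], merged)
  list(pair = c(cl[[i]]$class_id, cl[[j]]$class_id), min_td = bestv,
       centroids = centroids)
}

#' Segment a multispectral stack into separable spectral theme classes
#'
#' The central fit of the package: k-means clustering of the 3-channel
#' pixel vectors starting at `k_init` classes, followed by an iterative
#' merge loop — while any class pair has transformed divergence below
#' `td_min` and more than `k_floor` classes remain, the least-separable
#' pair is merged (pixel-count-weighted centroid) and k-means is re-run
#' at k-1 from those centroids. Terminates when all pairwise divergences
#' reach `td_min` ("separability") or the class floor is hit ("k_floor").
#'
#' @param stack an [multispectral_stack()].
#' @param config a [clustering_config()].
#' @return object of class `theme_map`: `labels` (integer raster, NA
#'   outside the mask), `classes` (per-class statistics), `pairwise_td`,
#'   `k`, `exit` (termination reason), `history` (k trajectory with the
#'   minimum divergence at each step).
#' @examples
#' ph <- phantom_visit(phantom_params(seed = 7, image_size = c(96, 96),
#'                                    n_drusen = 2, drusen_radius_range = c(6, 10)))
#' st <- multispectral_stack(ph$ref_channels$faf, ph$ref_channels$ir,
#'                           ph$ref_channels$green)
#' tm <- theme_classify(st, clustering_config(k_init = 6, seed = 7))
#' summary(tm)
#' @export
theme_classify <- function(stack, config = clustering_config()) {
  stopifnot(inherits(stack, "mspr_stack"), inherits(config, "clustering_config"))
  k <- min(config$k_init, length(stack$index))
  fit <- kmeans_fit(stack, k, config = config)
  history <- data.frame(k = fit$k, min_td = .min_offdiag(fit$pairwise_td))
  merges <- 0L
  while (fit$k > config$k_floor &&
         .min_offdiag(fit$pairwise_td) < config$td_min) {
    m <- merge_least_separable(fit)
    fit <- kmeans_fit(stack, nrow(m$centroids), init_centroids = m$centroids,
                      config = config)
    merges <- merges + 1L
    history <- rbind(history,
                     data.frame(k = fit$k, min_td = .min_offdiag(fit$pairwise_td)))
    if (merges > config$k_init) .stop_numeric("merge loop failed to terminate")
  }
  fit$exit <- if (.min_offdiag(fit$pairwise_td) >= config$td_min)
    "separability" else "k_floor"
  fit$history <- history
  fit$config <- config
  fit
}

.min_offdiag <- function(td) {
  if (nrow(td) < 2L) return(Inf)
  min(td[upper.tri(td)])
}

#' @export
print.theme_map <- function(x, ...) {
  cat("Spectral theme map: ", x$k, " classes over ",
      length(x$index), " in-mask pixels\n", sep = "")
  if (!is.null(x$exit))
    cat("merge loop exit: ", x$exit, " (min pairwise D_T = ",
        format(.min_offdiag(x$pairwise_td), digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.theme_map <- function(object, ...) {
  counts <- vapply(object$classes, `[[`, 1L, "pixel_count")
  means <- t(vapply(object$classes, `[[`, numeric(3), "mean"))
  colnames(means) <- c("faf", "ir", "green")
  out <- data.frame(class_id = vapply(object$classes, `[[`, 1L, "class_id"),
                    pixel_count = counts, round(means, 4))
  cat("Spectral theme map (", object$k, " classes)\n", sep = "")
  print(out, row.names = FALSE)
  cat("min pairwise D_T:", format(.min_offdiag(object$pairwise_td), digits = 4),
      "| exit:", object$exit %||% "single fit", "\n")
  if (!is.null(object$history)) {
    cat("k trajectory:", paste(object$history$k, collapse = " -> "), "\n")
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Display a theme map as a pseudocoloured image
#' @param x a `theme_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.theme_map <- function(x, ...) {
  z <- x$labels
  graphics::image(t(z[nrow(z):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(max(1L, x$k), "Spectral"),
                  axes = FALSE, asp = nrow(z) / ncol(z), ...)
  invisible(x)
}
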