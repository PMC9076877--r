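#' Landmark pairs for registration
#'
#' Bundles paired landmark coordinates on the moving image and the fixed
#' (reference) image. The workflow this package implements aligns each en
#' face channel (FAF, IR, green SLO) to the reference colour fundus
#' photograph using eight vessel-bifurcation points; any number of pairs
#' >= 3 (affine) or >= 2 (similarity) is accepted.
#'
#' @param moving numeric matrix with 2 columns (row, col), one landmark per
#'   row, in moving-image pixel coordinates (1-based, pixel centers at
#'   integers).
#' @param fixed numeric matrix with 2 columns (row, col) of the matching
#'   points on the fixed/reference grid. Must have the same number of rows
#'   as `moving`.
#' @return An object of class `landmark_set`.
#' @seealso [estimate_transform()], [read_landmarks()]
#' @export
landmark_set <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (ncol(moving) != 2L || ncol(fixed) != 2L)
    .stop_validation("landmarks must have two columns (row, col)")
  if (nrow(moving) != nrow(fixed))
    .stop_validation("moving and fixed landmark counts differ (",
                     nrow(moving), " vs ", nrow(fixed), ")")
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    .stop_validation("landmark coordinates must be finite")
  storage.mode(moving) <- "double"; storage.mode(fixed) <- "double"
  dimnames(moving) <- dimnames(fixed) <- list(NULL, c("row", "col"))
  structure(list(moving = moving, fixed = fixed), class = "landmark_set")
}

#' Read paired landmarks from CSV
#'
#' Expects a header with columns `moving_row,moving_col,fixed_row,fixed_col`
#' and one row per landmark pair.
#'
#' @param path path to the CSV file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) .stop_validation("landmark file not found: ", path)
  d <- read.csv(path, check.names = FALSE)
  need <- c("moving_row", "moving_col", "fixed_row", "fixed_col")
  if (!all(need %in% names(d)))
    .stop_validation("landmark CSV must have columns ",
                     paste(need, collapse = ","), ": ", path)
  num <- lapply(d[need], function(x) suppressWarnings(as.numeric(as.character(x))))
  bad <- which(!Reduce(`&`, lapply(num, function(x) !is.na(x))))
  if (length(bad))
    .stop_validation("landmark CSV has non-numeric/missing values at row ",
                     bad[1L], ": ", path)
  landmark_set(cbind(num$moving_row, num$moving_col),
               cbind(num$fixed_row, num$fixed_col))
}

#' Write paired landmarks to CSV
#' @param landmarks a [landmark_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  d <- data.frame(moving_row = landmarks$moving[, 1],
                  moving_col = landmarks$moving[, 2],
                  fixed_row  = landmarks$fixed[, 1],
                  fixed_col  = landmarks$fixed[, 2])
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Estimate a landmark-based spatial transform
#'
#' Least-squares fit of a 2-D affine (6 parameters) or similarity
#' (rotation + isotropic scale + translation, 4 parameters) transform
#' mapping moving-image coordinates onto the fixed reference grid.
#'
#' The fitted map is `fixed = A %*% moving + b`, stored as the 2x3 matrix
#' `cbind(A, b)` acting on (row, col) column vectors. `residual_rmse` is
#' the root mean squared Euclidean landmark residual in the fixed frame,
#' in pixels.
#'
#' @param landmarks a [landmark_set()].
#' @param model `"affine"` (default) or `"similarity"`.
#' @return An object of class `spatial_transform` with elements `model`,
#'   `parameters` (2x3 matrix), `residual_rmse`.
#' @examples
#' lm <- landmark_set(cbind(c(1, 1, 9, 9), c(1, 9, 1, 9)),
#'                    cbind(c(3, 3, 11, 11), c(2, 10, 2, 10)))
#' estimate_transform(lm)
#' @export
estimate_transform <- function(landmarks, model = c("affine", "similarity")) {
  stopifnot(inherits(landmarks, "landmark_set"))
  model <- match.arg(model)
  mv <- landmarks$moving; fx <- landmarks$fixed
  n <- nrow(mv)
  if (model == "affine") {
    if (n < 3L) .stop_validation("affine fit needs >= 3 landmark pairs")
    X <- cbind(mv, 1)
    qx <- qr(X)
    if (qx$rank < 3L)
      .stop_degenerate("landmarks are collinear or coincident; affine fit is degenerate")
    coefs <- qr.coef(qx, fx)              # 3 x 2: rows (r, c, 1), cols (row', col')
    params <- t(coefs)[, c(1L, 2L, 3L), drop = FALSE]
  } else {
    if (n < 2L) .stop_validation("similarity fit needs >= 2 landmark pairs")
    # fixed_row = a*r - b*c + tr ; fixed_col = b*r + a*c + tc
    X <- rbind(cbind(mv[, 1], -mv[, 2], 1, 0),
               cbind(mv[, 2],  mv[, 1], 0, 1))
    y <- c(fx[, 1], fx[, 2])
    qx <- qr(X)
    if (qx$rank < 4L)
      .stop_degenerate("landmarks coincident; similarity fit is degenerate")
    th <- qr.coef(qx, y)
    params <- rbind(c(th[1], -th[2], th[3]),
                    c(th[2],  th[1], th[4]))
  }
  dimnames(params) <- NULL
  pred <- cbind(mv, 1) %*% t(params)
  rmse <- sqrt(mean(rowSums((fx - pred)^2)))
  structure(list(model = model, parameters = params, residual_rmse = rmse),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("Spatial transform (", x$model, ")\n", sep = "")
  print(round(x$parameters, 6))
  cat("landmark residual RMSE:", format(x$residual_rmse, digits = 4), "px\n")
  invisible(x)
}

.transform_points <- function(transform, pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) == 0L) return(pts)
  cbind(pts, 1) %*% t(transform$parameters)
}

.invert_transform <- function(transform) {
  A <- transform$parameters[, 1:2]
  d <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (!is.finite(d) || abs(d) < 1e-12)
    .stop_degenerate("transform is not invertible (determinant ~ 0)")
  Ai <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2, 2) / d
  bi <- -Ai %*% transform$parameters[, 3]
  structure(list(model = transform$model, parameters = cbind(Ai, bi),
                 residual_rmse = transform$residual_rmse),
            class = "spatial_transform")
}

#' Warp an image onto the fixed reference grid
#'
#' Resamples `image` (defined on the moving grid) onto a target grid using
#' the inverse of `transform` (which maps moving -> fixed coordinates),
#' with bilinear interpolation. Pixels whose pre-image falls outside the
#' moving image footprint are filled with `fill` (default 0; these areas
#' are excluded later by the macular mask).
#'
#' @param image numeric matrix raster.
#' @param transform a `spatial_transform` from [estimate_transform()].
#' @param target_shape integer vector `c(rows, cols)` of the output grid.
#' @param fill fill value outside the source footprint.
#' @return A `target_shape` numeric matrix.
#' @export
warp_image <- function(image, transform, target_shape = dim(image), fill = 0) {
  .check_raster(image)
  stopifnot(inherits(transform, "spatial_transform"))
  inv <- .invert_transform(transform)
  nr <- as.integer(target_shape[1]); nc <- as.integer(target_shape[2])
  # source coordinates of every target pixel center
  tgt <- cbind(rep.int(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  src <- .transform_points(inv, tgt)
  r <- src[, 1]; c <- src[, 2]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  sr <- nrow(image); sc <- ncol(image)
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= sr & ci >= 1 & ci <= sc
    v <- numeric(length(ri)); v[!ok] <- NA_real_
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    v
  }
  v00 <- at(r0, c0);     v01 <- at(r0, c0 + 1)
  v10 <- at(r0 + 1, c0); v11 <- at(r0 + 1, c0 + 1)
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc);       w11 <- fr * fc
  # a corner with (numerically) zero weight never contributes, even if it
  # falls out of bounds; the eps absorbs float noise in fitted transforms
  eps <- 1e-9
  w00[w00 < eps] <- 0; w01[w01 < eps] <- 0
  w10[w10 < eps] <- 0; w11[w11 < eps] <- 0
  v00[w00 == 0 & is.na(v00)] <- 0; v01[w01 == 0 & is.na(v01)] <- 0
  v10[w10 == 0 & is.na(v10)] <- 0; v11[w11 == 0 & is.na(v11)] <- 0
  ws <- w00 + w01 + w10 + w11
  out <- (v00 * w00 + v01 * w01 + v10 * w10 + v11 * w11) / ws
  out[is.na(out)] <- fill
  matrix(out, nr, nc)
}

#' Post-registration alignment report
#'
#' Automated surrogate for visual flicker comparison: reports the landmark
#' residual RMSE between paired points already expressed on the common grid
#' and the normalised (Pearson) cross-correlation of the two images.
#'
#' @param imageA,imageB rasters on the same grid.
#' @param landmarks optional [landmark_set()] whose `moving` points are
#'   the warped positions on the common grid and `fixed` the reference
#'   positions; if `NULL` only the correlation is reported.
#' @return list with `landmark_rmse` (or `NA`) and `correlation`.
#' @export
check_alignment <- function(imageA, imageB, landmarks = NULL) {
  .check_raster(imageA, "imageA"); .check_raster(imageB, "imageB")
  if (!identical(dim(imageA), dim(imageB)))
    .stop_validation("images must share a common grid")
  rmse <- NA_real_
  if (!is.null(landmarks)) {
    stopifnot(inherits(landmarks, "landmark_set"))
    rmse <- sqrt(mean(rowSums((landmarks$fixed - landmarks$moving)^2)))
  }
  r <- if (sd(imageA) == 0 || sd(imageB) == 0) 0 else cor(as.vector(imageA), as.vector(imageB))
  list(landmark_rmse = rmse, correlation = r)
}
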