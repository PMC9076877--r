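#' Preprocessing configuration
#'
#' Parameters for channel preprocessing. The pipeline order is fixed:
#' grayscale conversion, background correction, contrast stretch, macular
#' masking.
#'
#' @param blur_sigma Gaussian sigma (pixels) of the background estimate
#'   subtracted from each channel. Default 50, sized for a ~768-px-wide
#'   macular field; it must exceed the largest druse so lesions survive
#'   the subtraction. Scale proportionally for other image widths (see
#'   [pipeline_config()]).
#' @param saturation_fraction total fraction of pixels saturated by the
#'   contrast stretch (default 0.004, i.e. 0.4%, split 0.2% per tail).
#' @param mask_radius_fraction radius of the default circular macular mask
#'   as a fraction of image width (default 0.45).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(blur_sigma = 50, saturation_fraction = 0.004,
                              mask_radius_fraction = 0.45) {
  if (!is.numeric(blur_sigma) || blur_sigma <= 0)
    .stop_validation("blur_sigma must be > 0")
  if (saturation_fraction < 0 || saturation_fraction >= 0.5)
    .stop_validation("saturation_fraction must be in [0, 0.5)")
  if (mask_radius_fraction <= 0 || mask_radius_fraction > 0.5)
    .stop_validation("mask_radius_fraction must be in (0, 0.5]")
  structure(list(blur_sigma = blur_sigma,
                 saturation_fraction = saturation_fraction,
                 mask_radius_fraction = mask_radius_fraction),
            class = "preprocess_config")
}

#' Convert an image to normalised grayscale
#'
#' Single-channel input is rescaled to \[0,1\] by its bit-depth maximum
#' (255 for 8-bit, 65535 for 16-bit integer data; data already in \[0,1\]
#' is passed through). RGB arrays are reduced by Rec. 709 luminance
#' weights (0.2126, 0.7152, 0.0722).
#'
#' @param image numeric matrix, or rows x cols x 3 array for RGB.
#' @return numeric matrix in \[0,1\].
#' @export
to_gray_normalized <- function(image) {
  if (length(image) == 0L) .stop_validation("empty image")
  if (is.array(image) && length(dim(image)) == 3L) {
    if (dim(image)[3] < 3L) .stop_validation("colour image must have 3 channels")
    w <- c(0.2126, 0.7152, 0.0722)
    image <- matrix(image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3],
                    dim(image)[1], dim(image)[2])
  }
  .check_raster(image)
  mx <- max(image)
  if (mx > 1) {
    depth_max <- if (mx > 255) 65535 else 255
    image <- image / depth_max
  }
  .clip01(image)
}

# Gaussian blur with replicate boundary handling; the kernel is truncated
# to fit small rasters (it can never exceed the image size).
.gaussian_blur <- function(image, sigma) {
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  lim <- min(dim(image))
  if (size > lim) size <- if (lim %% 2L == 1L) lim else lim - 1L
  brush <- EBImage::makeBrush(size = size, shape = "Gaussian", sigma = sigma)
  brush <- brush / sum(brush)
  as.matrix(EBImage::filter2(image, brush, boundary = "replicate"))
}

#' Background correction by Gaussian-blur subtraction
#'
#' Subtracts a Gaussian-blurred copy of the image (the background shading
#' estimate) from the image itself, then re-centres at 0.5 and clips to
#' \[0,1\]: negative local contrast is preserved symmetrically, and a
#' spatially constant offset in the input leaves the output unchanged.
#'
#' @param image grayscale raster in \[0,1\].
#' @param blur_sigma Gaussian sigma in pixels (> 0).
#' @return raster in \[0,1\] centred on 0.5.
#' @export
background_correct <- function(image, blur_sigma) {
  .check_raster(image)
  if (!is.numeric(blur_sigma) || length(blur_sigma) != 1L || blur_sigma <= 0)
    .stop_validation("blur_sigma must be a single value > 0")
  .clip01(image - .gaussian_blur(image, blur_sigma) + 0.5)
}

#' Percentile contrast stretch
#'
#' Linearly rescales so that the lower and upper `saturation_fraction / 2`
#' quantiles map to 0 and 1; values beyond them are clipped. A constant
#' image is returned unchanged with a warning.
#'
#' @param image grayscale raster in \[0,1\].
#' @param saturation_fraction total saturated fraction (default 0.004).
#' @return raster in \[0,1\].
#' @export
contrast_stretch <- function(image, saturation_fraction = 0.004) {
  .check_raster(image)
  if (saturation_fraction < 0 || saturation_fraction >= 0.5)
    .stop_validation("saturation_fraction must be in [0, 0.5)")
  qs <- quantile(image, c(saturation_fraction / 2, 1 - saturation_fraction / 2),
                 names = FALSE)
  if (qs[2] <= qs[1]) {
    warning("constant image: contrast stretch skipped")
    return(image)
  }
  .clip01((image - qs[1]) / (qs[2] - qs[1]))
}

#' Circular macular mask
#'
#' Default analysis mask: a disc centred on the image centre with radius
#' `radius_fraction * cols`. True pixels are analysed.
#'
#' @param shape `c(rows, cols)`.
#' @param radius_fraction disc radius as a fraction of image width.
#' @return logical matrix.
#' @export
macular_mask <- function(shape, radius_fraction = 0.45) {
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (nr < 1L || nc < 1L) .stop_validation("invalid mask shape")
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r2 <- (radius_fraction * nc)^2
  outer(seq_len(nr), seq_len(nc), function(i, j) (i - cr)^2 + (j - cc)^2 <= r2)
}

#' Restrict an image to the macular region
#'
#' Pixels outside the mask are excluded from all downstream statistics
#' (not merely zeroed): the returned object carries the in-mask linear
#' pixel index set that clustering operates on.
#'
#' @param image raster.
#' @param mask logical matrix of the same shape; `TRUE` = analysed.
#' @return list with `image` (unchanged raster), `mask`, and `index`
#'   (integer vector of in-mask linear indices, column-major).
#' @export
apply_macular_mask <- function(image, mask) {
  .check_raster(image)
  if (!is.logical(mask) || !identical(dim(image), dim(mask)))
    .stop_validation("mask must be a logical matrix matching the image shape")
  idx <- which(mask)
  if (length(idx) == 0L) .stop_validation("mask is empty")
  list(image = image, mask = mask, index = idx)
}

#' Preprocess one channel
#'
#' Applies the fixed order: grayscale normalisation, background
#' correction, contrast stretch.
#'
#' @param image raw channel raster (or RGB array).
#' @param config a [preprocess_config()].
#' @return raster in \[0,1\].
#' @export
preprocess_channel <- function(image, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  x <- to_gray_normalized(image)
  x <- background_correct(x, config$blur_sigma)
  contrast_stretch(x, config$saturation_fraction)
}

#' Assemble a multispectral stack
#'
#' Bundles the three aligned, preprocessed channels (FAF, IR, green SLO)
#' and the macular mask into the object the clustering step consumes.
#'
#' @param faf,ir,green preprocessed rasters on the common reference grid.
#' @param mask logical macular mask of the same shape (default: circular
#'   disc of radius 0.45 x width).
#' @return object of class `mspr_stack` with fields `faf`, `ir`, `green`,
#'   `mask`, `index` (in-mask linear indices) and `pixels` (n x 3 matrix
#'   of in-mask channel values, columns faf/ir/green).
#' @export
multispectral_stack <- function(faf, ir, green,
                                mask = macular_mask(dim(faf))) {
  .check_raster(faf, "faf"); .check_raster(ir, "ir"); .check_raster(green, "green")
  if (!identical(dim(faf), dim(ir)) || !identical(dim(faf), dim(green)))
    .stop_validation("channel shapes differ")
  m <- apply_macular_mask(faf, mask)
  px <- cbind(faf = faf[m$index], ir = ir[m$index], green = green[m$index])
  structure(list(faf = faf, ir = ir, green = green,
                 mask = mask, index = m$index, pixels = px),
            class = "mspr_stack")
}

#' @export
print.mspr_stack <- function(x, ...) {
  cat("Multispectral stack: ", nrow(x$faf), "x", ncol(x$faf),
      " px, ", length(x$index), " in-mask pixels\n", sep = "")
  invisible(x)
}
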