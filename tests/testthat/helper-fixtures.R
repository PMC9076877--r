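# Shared helpers: tiny geometric stacks and the bundled grading fixture.

# A minimal 3-channel stack built from explicit pixel vectors: `groups` is
# a list of lists(center = 3-vector, n = count, sd = per-channel sd). The
# raster is 1 x n_total with a full-true mask, so clustering sees exactly
# the pixel population we specify.
make_point_stack <- function(groups, seed = 1) {
  set.seed(seed)
  px <- do.call(rbind, lapply(groups, function(g) {
    cbind(rnorm(g$n, g$center[1], g$sd),
          rnorm(g$n, g$center[2], g$sd),
          rnorm(g$n, g$center[3], g$sd))
  }))
  n <- nrow(px)
  multispectral_stack(matrix(px[, 1], 1, n), matrix(px[, 2], 1, n),
                      matrix(px[, 3], 1, n),
                      mask = matrix(TRUE, 1, n))
}

truth_labels <- function(groups) {
  rep(seq_along(groups), vapply(groups, `[[`, 1, "n"))
}

# Class-statistics entry straight from a mean/covariance pair.
stats_entry <- function(mean, cov, id = 1L, n = 100L) {
  list(class_id = id, mean = mean, covariance = cov, pixel_count = n,
       small = n < 4L)
}

example_gradings_path <- function() {
  system.file("extdata", "example_gradings.csv", package = "drusenmspr")
}

# Small, fast phantom used by tests that only need plausible structure.
small_phantom_params <- function(seed, ...) {
  phantom_params(seed = seed, image_size = c(96L, 96L), n_drusen = 3L,
                 drusen_radius_range = c(5, 9), n_vessels = 2L,
                 pigment_count = 1L, ...)
}
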