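test_that("identity landmark pairs give the identity transform with zero residual", {
  set.seed(11)
  pts <- cbind(runif(8, 1, 100), runif(8, 1, 100))
  tr <- estimate_transform(landmark_set(pts, pts))
  expect_equal(tr$parameters, cbind(diag(2), c(0, 0)), tolerance = 1e-12)
  expect_equal(tr$residual_rmse, 0, tolerance = 1e-10)
})

test_that("a planted affine (rotation 5deg, scale 1.02, translation) is recovered exactly", {
  th <- 5 * pi / 180
  A <- 1.02 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- c(3, -2)
  set.seed(21)
  mv <- cbind(runif(8, 10, 90), runif(8, 10, 90))
  fx <- t(A %*% t(mv) + b)
  tr <- estimate_transform(landmark_set(mv, fx), "affine")
  expect_lt(max(abs(tr$parameters - cbind(A, b))), 1e-9)
  expect_lt(tr$residual_rmse, 1e-9)
  # similarity model recovers the same map (it lies in the model class)
  ts <- estimate_transform(landmark_set(mv, fx), "similarity")
  expect_lt(max(abs(ts$parameters - cbind(A, b))), 1e-9)
})

test_that("residual RMSE under 0.5 px landmark jitter stays below 1.5 px over 100 seeds", {
  th <- -3 * pi / 180
  A <- 0.98 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- c(-4, 7)
  rmses <- vapply(1:100, function(s) {
    set.seed(s)
    mv <- cbind(runif(8, 10, 190), runif(8, 10, 190))
    fx <- t(A %*% t(mv) + b) + matrix(rnorm(16, 0, 0.5), 8, 2)
    estimate_transform(landmark_set(mv, fx))$residual_rmse
  }, numeric(1))
  expect_true(all(rmses <= 1.5))
})

test_that("residual is invariant to reordering of landmark pairs", {
  set.seed(31)
  mv <- cbind(runif(8, 1, 50), runif(8, 1, 50))
  fx <- mv + matrix(rnorm(16, 0, 1), 8, 2)
  r1 <- estimate_transform(landmark_set(mv, fx))$residual_rmse
  o <- sample(8)
  r2 <- estimate_transform(landmark_set(mv[o, ], fx[o, ]))$residual_rmse
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("degenerate and mismatched landmark inputs are rejected", {
  col <- cbind(1:8, 2 * (1:8))               # collinear
  expect_error(estimate_transform(landmark_set(col, col), "affine"),
               class = "mspr_degenerate_error")
  expect_error(landmark_set(cbind(1:4, 1:4), cbind(1:5, 1:5)),
               class = "mspr_validation_error")
  expect_error(estimate_transform(landmark_set(cbind(1:2, 1:2), cbind(1:2, 1:2)),
                                  "affine"),
               class = "mspr_validation_error")
})

test_that("warping with the identity returns the input", {
  set.seed(41)
  img <- matrix(runif(400), 20, 20)
  tr <- estimate_transform(landmark_set(cbind(c(1, 1, 20, 20), c(1, 20, 1, 20)),
                                        cbind(c(1, 1, 20, 20), c(1, 20, 1, 20))))
  expect_equal(warp_image(img, tr), img, tolerance = 1e-12)
})

test_that("an integer translation relocates an impulse exactly", {
  img <- matrix(0, 30, 30); img[10, 12] <- 1
  tr <- structure(list(model = "affine",
                       parameters = cbind(diag(2), c(5, 0)),
                       residual_rmse = 0), class = "spatial_transform")
  out <- warp_image(img, tr, c(30, 30))
  expect_equal(out[15, 12], 1)
  expect_equal(sum(out), 1)
})

test_that("warp then inverse-warp round-trips a smooth image", {
  x <- outer(1:64, 1:64, function(i, j) 0.5 + 0.3 * sin(i / 9) * cos(j / 11))
  th <- 4 * pi / 180
  A <- 1.01 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- c(2.3, -1.7) + (1 - 1.01) * 32       # keep the footprint inside
  tr <- structure(list(model = "affine", parameters = cbind(A, b),
                       residual_rmse = 0), class = "spatial_transform")
  inv <- drusenmspr:::.invert_transform(tr)
  rt <- warp_image(warp_image(x, tr, c(64, 64)), inv, c(64, 64))
  core <- 10:54
  expect_lt(mean(abs(rt[core, core] - x[core, core])),
            0.01 * diff(range(x)))
})

test_that("bilinear warping never overshoots the input value range", {
  set.seed(51)
  img <- matrix(runif(900, 0.2, 0.8), 30, 30)
  th <- 7 * pi / 180
  tr <- structure(list(model = "affine",
                       parameters = cbind(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2),
                                          c(1.5, -2.5)),
                       residual_rmse = 0), class = "spatial_transform")
  out <- warp_image(img, tr, c(30, 30), fill = 0.5)
  expect_gte(min(out), min(img) - 1e-12)
  expect_lte(max(out), max(img) + 1e-12)
})

test_that("alignment report gives residual 0 / correlation 1 for identical inputs", {
  set.seed(61)
  img <- matrix(runif(100), 10, 10)
  pts <- cbind(runif(5, 1, 10), runif(5, 1, 10))
  rep <- check_alignment(img, img, landmark_set(pts, pts))
  expect_equal(rep$landmark_rmse, 0)
  expect_equal(rep$correlation, 1)
})

test_that("alignment report detects a planted 2 px landmark shift", {
  set.seed(71)
  img <- matrix(runif(100), 10, 10)
  pts <- cbind(runif(6, 2, 9), runif(6, 2, 9))
  rep <- check_alignment(img, img, landmark_set(pts + c(2, 0), pts))
  expect_equal(rep$landmark_rmse, 2, tolerance = 0.5)
})

test_that("uncorrelated noise images have correlation near zero", {
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    a <- matrix(rnorm(1600), 40, 40); b <- matrix(rnorm(1600), 40, 40)
    check_alignment(a, b)$correlation
  }, numeric(1))
  expect_true(all(abs(rs) < 0.1))
})

test_that("landmark CSV round-trips through read/write", {
  lm <- landmark_set(cbind(c(1.5, 3, 8), c(2, 4, 9)),
                     cbind(c(2.5, 4, 9), c(3, 5, 10)))
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm2$moving, lm$moving)
  expect_equal(lm2$fixed, lm$fixed)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("moving_row,moving_col,fixed_row,fixed_col", "1,2,3,x"), bad)
  expect_error(read_landmarks(bad), class = "mspr_validation_error")
})
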