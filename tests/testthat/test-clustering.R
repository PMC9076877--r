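test_that("k-means recovers two well-separated clouds, matching brute force", {
  groups <- list(list(center = c(0.1, 0.1, 0.1), n = 6, sd = 0.01),
                 list(center = c(0.9, 0.9, 0.9), n = 6, sd = 0.01))
  st <- make_point_stack(groups, seed = 5)
  tm <- kmeans_fit(st, 2, config = clustering_config(seed = 9))
  lab <- tm$in_mask_labels
  # brute-force oracle: enumerate all 2^12 assignments, minimise SSE
  X <- st$pixels
  best <- NULL; best_sse <- Inf
  for (code in 0:(2^12 - 1)) {
    a <- as.integer(intToBits(code))[1:12]
    if (all(a == 0) || all(a == 1)) next
    sse <- 0
    for (g in 0:1) {
      P <- X[a == g, , drop = FALSE]
      sse <- sse + sum(sweep(P, 2, colMeans(P))^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- a }
  }
  agree <- mean((lab - 1) == best)
  expect_true(agree == 1 || agree == 0)     # up to label swap
  expect_equal(tm$sse, best_sse, tolerance = 1e-9)
})

test_that("identical pixels collapse to a single surviving cluster", {
  st <- make_point_stack(list(list(center = c(0.5, 0.5, 0.5), n = 20, sd = 0)))
  tm <- kmeans_fit(st, 2, config = clustering_config(seed = 3))
  expect_equal(tm$k, 1L)
})

test_that("k-means is bit-reproducible for a fixed seed and validates k", {
  st <- make_point_stack(list(list(center = c(0.2, 0.5, 0.7), n = 40, sd = 0.2)),
                         seed = 8)
  t1 <- kmeans_fit(st, 3, config = clustering_config(seed = 12))
  t2 <- kmeans_fit(st, 3, config = clustering_config(seed = 12))
  expect_identical(t1$in_mask_labels, t2$in_mask_labels)
  expect_identical(t1$classes, t2$classes)
  expect_error(kmeans_fit(st, 0), class = "mspr_validation_error")
  expect_error(kmeans_fit(st, 41), class = "mspr_validation_error")
})

test_that("our Lloyd fit matches stats::kmeans on a well-separated case", {
  groups <- list(list(center = c(0.1, 0.2, 0.1), n = 30, sd = 0.02),
                 list(center = c(0.5, 0.5, 0.5), n = 30, sd = 0.02),
                 list(center = c(0.9, 0.8, 0.9), n = 30, sd = 0.02))
  st <- make_point_stack(groups, seed = 13)
  tm <- kmeans_fit(st, 3, config = clustering_config(seed = 2))
  ref <- stats::kmeans(st$pixels, 3, nstart = 10)
  # same partition up to label permutation
  expect_equal(length(unique(paste(tm$in_mask_labels, ref$cluster))), 3L)
  expect_equal(tm$sse, ref$tot.withinss, tolerance = 1e-8)
})

test_that("within-fit SSE trace is non-increasing", {
  set.seed(77)
  st <- make_point_stack(list(list(center = c(0.3, 0.4, 0.5), n = 200, sd = 0.15)),
                         seed = 77)
  tm <- kmeans_fit(st, 6, config = clustering_config(seed = 4))
  expect_true(all(diff(tm$sse_trace) <= 1e-9))
})

test_that("class statistics match hand computation and are order-invariant", {
  st <- make_point_stack(list(list(center = c(0, 0, 0), n = 2, sd = 0)))
  st$pixels <- rbind(c(0, 0, 0), c(1, 1, 1))
  cs <- class_statistics(st, c(1L, 1L))
  expect_equal(cs[[1]]$mean, c(faf = 0.5, ir = 0.5, green = 0.5))
  # covariance of the pair is 0.5 everywhere, plus the 1e-6 ridge
  expect_equal(cs[[1]]$covariance, matrix(0.5, 3, 3) + diag(1e-6, 3),
               tolerance = 1e-12)
  expect_true(cs[[1]]$small)
  # identical pixels: covariance collapses to the ridge
  st$pixels <- matrix(0.25, 5, 3, dimnames = list(NULL, c("faf", "ir", "green")))
  cs2 <- class_statistics(st, rep(1L, 5))
  expect_equal(cs2[[1]]$covariance, diag(1e-6, 3))
  expect_equal(unname(cs2[[1]]$mean), rep(0.25, 3))
  # permutation invariance
  set.seed(6)
  base <- make_point_stack(list(list(center = c(0.5, 0.5, 0.5), n = 10, sd = 0.2)))
  lab <- rep(1:2, each = 5)
  c1 <- class_statistics(base, lab)
  o <- sample(10)
  perm <- base; perm$pixels <- base$pixels[o, ]
  c2 <- class_statistics(perm, lab[o])
  expect_equal(c1[[1]]$mean, c2[[1]]$mean)
  expect_equal(c1[[2]]$covariance, c2[[2]]$covariance, tolerance = 1e-12)
})

test_that("transformed divergence matches the univariate closed form", {
  iso <- diag(c(1, 1, 1))
  a <- stats_entry(c(0, 0, 0), iso)
  b <- stats_entry(c(1, 0, 0), iso, id = 2L)
  # univariate unit shift at unit variance: D = 1, D_T = 2(1 - e^(-1/8))
  expect_equal(transformed_divergence(a, b), 2 * (1 - exp(-1 / 8)),
               tolerance = 1e-12)
  expect_equal(transformed_divergence(a, b), 0.2350, tolerance = 1e-4)
  # identical statistics
  expect_equal(transformed_divergence(a, a), 0)
  # symmetry with unequal covariances
  s1 <- stats_entry(c(0.1, 0.3, 0.2), diag(c(1, 2, 0.5)))
  s2 <- stats_entry(c(0.4, 0.1, 0.9), diag(c(0.3, 1.5, 1)), id = 2L)
  expect_equal(transformed_divergence(s1, s2), transformed_divergence(s2, s1))
  # saturation: 100 sigma separation is essentially 2, never above 2
  far <- stats_entry(c(100, 0, 0), iso, id = 3L)
  expect_gte(transformed_divergence(a, far), 1.999)
  expect_lte(transformed_divergence(a, far), 2)
})

test_that("divergence stays within [0, 2] over random class pairs", {
  set.seed(99)
  for (i in 1:50) {
    r1 <- matrix(rnorm(9), 3, 3); r2 <- matrix(rnorm(9), 3, 3)
    a <- stats_entry(rnorm(3), crossprod(r1) + diag(1e-3, 3))
    b <- stats_entry(rnorm(3), crossprod(r2) + diag(1e-3, 3), id = 2L)
    d <- transformed_divergence(a, b)
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("least-separable pair selection uses the minimum with lexicographic ties", {
  iso <- diag(1e-4, 3)
  mk_tm <- function(means, counts) {
    classes <- lapply(seq_along(counts), function(i)
      stats_entry(means[[i]], iso, id = i, n = counts[i]))
    structure(list(classes = classes, k = length(classes),
                   pairwise_td = pairwise_td(classes)),
              class = "theme_map")
  }
  tm <- mk_tm(list(c(0, 0, 0), c(0.001, 0, 0), c(1, 1, 1)), c(10L, 30L, 5L))
  m <- merge_least_separable(tm)
  expect_equal(m$pair, c(1L, 2L))
  # weighted centroid: (10 m1 + 30 m2) / 40
  expect_equal(m$centroids[nrow(m$centroids), ],
               (10 * c(0, 0, 0) + 30 * c(0.001, 0, 0)) / 40, tolerance = 1e-12)
  # exact tie: classes 1,2 and 3,4 both at distance d -> pair (1,2) wins
  tm2 <- mk_tm(list(c(0, 0, 0), c(0.5, 0, 0), c(5, 0, 0), c(5.5, 0, 0)),
               rep(10L, 4))
  expect_equal(merge_least_separable(tm2)$pair, c(1L, 2L))
})

test_that("separability loop terminates and reports exactly one exit condition", {
  set.seed(42)
  for (rep in 1:6) {
    groups <- lapply(1:sample(2:4, 1), function(i)
      list(center = runif(3), n = 60, sd = runif(1, 0.01, 0.1)))
    st <- make_point_stack(groups, seed = rep)
    cfg <- clustering_config(k_init = 8, seed = rep)
    tm <- theme_classify(st, cfg)
    expect_lte(nrow(tm$history), cfg$k_init - cfg$k_floor + 1L)
    min_td <- drusenmspr:::.min_offdiag(tm$pairwise_td)
    sep <- min_td >= cfg$td_min
    floor_hit <- tm$k == cfg$k_floor
    expect_true(sep || floor_hit)
    expect_identical(tm$exit, if (sep) "separability" else "k_floor")
    expect_length(tm$exit, 1L)
    # k strictly decreasing across merges
    expect_true(all(diff(tm$history$k) < 0))
  }
})

test_that("two spectrally distant populations resolve to k = 2 with correct labels", {
  groups <- list(list(center = c(0.15, 0.2, 0.15), n = 120, sd = 0.02),
                 list(center = c(0.85, 0.8, 0.85), n = 80, sd = 0.02))
  st <- make_point_stack(groups, seed = 17)
  # the 1% minimum-population filter dissolves spur clusters whose
  # collapsed covariance would otherwise keep them "separable"
  tm <- theme_classify(st, clustering_config(k_init = 8, seed = 17,
                                             min_class_fraction = 0.01))
  expect_equal(tm$k, 2L)
  truth <- truth_labels(groups)
  tab <- table(tm$in_mask_labels, truth)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.99)
})

test_that("homogeneous noise collapses to the class floor", {
  st <- make_point_stack(list(list(center = c(0.5, 0.5, 0.5), n = 400, sd = 0.05)),
                         seed = 23)
  tm <- theme_classify(st, clustering_config(k_init = 8, seed = 23))
  expect_equal(tm$k, 2L)
  expect_identical(tm$exit, "k_floor")
})

test_that("the first fit honours k_init as the maximum class count", {
  st <- make_point_stack(list(list(center = c(0.4, 0.5, 0.6), n = 600, sd = 0.2)),
                         seed = 31)
  tm <- theme_classify(st, clustering_config(seed = 31))
  expect_lte(tm$history$k[1L], 16L)
})
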