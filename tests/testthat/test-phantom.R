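test_that("a lesion-free, noise-free phantom is pure vignetted background", {
  p <- phantom_params(seed = 4, image_size = c(64L, 64L), n_drusen = 0L,
                      pigment_count = 0L, n_vessels = 0L, noise_sigma = 0,
                      misalignment = list(rotation_deg = 0, translation_px = 0,
                                          scale_dev = 0))
  v <- phantom_visit(p)
  expect_equal(sum(v$truth$drusen_mask), 0)
  ctr <- (64 + 1) / 2
  dmax2 <- 2 * ((64 - 1) / 2)^2
  vig <- outer(1:64, 1:64, function(i, j)
    0.55 * (1 - 0.15 * ((i - ctr)^2 + (j - ctr)^2) / dmax2))
  expect_equal(v$channels$faf, vig, tolerance = 1e-12)
  expect_equal(v$channels$green, vig, tolerance = 1e-12)
})

test_that("phantom generation is byte-identical for a fixed seed", {
  p <- small_phantom_params(seed = 7)
  v1 <- phantom_visit(p, 1L)
  v2 <- phantom_visit(p, 1L)
  expect_identical(v1$channels, v2$channels)
  expect_identical(v1$landmarks, v2$landmarks)
  expect_identical(v1$truth, v2$truth)
})

test_that("planted truth mask equals brute-force disc rasterization", {
  p <- phantom_params(seed = 15, image_size = c(96L, 96L), n_drusen = 5L,
                      drusen_radius_range = c(8, 8), n_vessels = 0L,
                      pigment_count = 0L)
  v <- phantom_visit(p)
  geo <- drusenmspr:::.phantom_geometry(p)
  ref <- matrix(FALSE, 96, 96)
  for (i in 1:96) for (j in 1:96)
    for (d in seq_len(nrow(geo$drusen_centers)))
      if ((i - geo$drusen_centers[d, 1])^2 + (j - geo$drusen_centers[d, 2])^2 <=
          geo$drusen_radii[d]^2) ref[i, j] <- TRUE
  expect_identical(v$truth$drusen_mask, ref)
  # drusen appear bright on every channel at the lesion interior
  bg <- median(v$ref_channels$faf[!ref])
  for (ch in c("faf", "ir", "green"))
    expect_gt(mean(v$ref_channels[[ch]][ref]), bg)
})

test_that("paired visits hit the planted area-change target within 1%", {
  for (tgt in c(20, -25)) {
    p <- small_phantom_params(seed = 5, target_percent_change = tgt)
    pair <- phantom_pair(p)
    ratio <- pair$truth$area2 / pair$truth$area1
    expect_gte(ratio, 0.99 * (1 + tgt / 100))
    expect_lte(ratio, 1.01 * (1 + tgt / 100))
    expect_equal(pair$truth$true_percent_change,
                 100 * (ratio - 1), tolerance = 1e-12)
  }
  z <- phantom_pair(small_phantom_params(seed = 5, target_percent_change = 0))
  expect_identical(z$visits[[1]]$truth$drusen_mask, z$visits[[2]]$truth$drusen_mask)
  expect_error(phantom_params(seed = 1, target_percent_change = -150),
               class = "mspr_validation_error")
})

test_that("annotation covers the truth mask (grader-noise dilation)", {
  p <- small_phantom_params(seed = 9)
  v <- phantom_visit(p)
  expect_true(all(v$annotation[v$truth$drusen_mask]))
  expect_gt(sum(v$annotation), sum(v$truth$drusen_mask))
})

test_that("channel landmarks map the reference points through the planted jitter", {
  p <- small_phantom_params(seed = 12)
  v <- phantom_visit(p)
  for (ch in c("faf", "ir", "green")) {
    lm <- v$landmarks[[ch]]
    expect_equal(nrow(lm$moving), 8L)
    # fitting the landmarks recovers a transform with ~zero residual
    tr <- estimate_transform(lm)
    expect_lt(tr$residual_rmse, 1e-9)
  }
})

test_that("cohorts have the requested design and targets in the right bands", {
  co <- phantom_cohort(2, 2, 2, seed = 31,
                       base_params = small_phantom_params(seed = 1))
  expect_equal(nrow(co$manifest), 6L)
  expect_equal(as.vector(table(co$manifest$label)[c("progression", "stable", "regression")]),
               c(2L, 2L, 2L))
  prog <- co$manifest$true_pct_change[co$manifest$label == "progression"]
  reg <- co$manifest$true_pct_change[co$manifest$label == "regression"]
  stab <- co$manifest$true_pct_change[co$manifest$label == "stable"]
  expect_true(all(prog > 5) && all(reg < -5) && all(abs(stab) <= 5))
  # achieved area ratio within 1% (relative) of the target ratio
  ratio <- 1 + co$manifest$true_pct_change / 100
  target <- 1 + co$manifest$target_pct_change / 100
  expect_true(all(abs(ratio / target - 1) < 0.0101))
  # different seeds: same structure, different content
  co2 <- phantom_cohort(2, 2, 2, seed = 77,
                        base_params = small_phantom_params(seed = 1))
  expect_identical(names(co2$manifest), names(co$manifest))
  expect_false(identical(co$eyes[[1]]$pair$visits[[1]]$channels$faf,
                         co2$eyes[[1]]$pair$visits[[1]]$channels$faf))
  one <- phantom_cohort(1, 0, 0, seed = 3,
                        base_params = small_phantom_params(seed = 1))
  expect_equal(one$manifest$label, "progression")
})
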