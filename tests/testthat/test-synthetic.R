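test_that("landscape generation is seed-deterministic and spatially structured", {
  spec <- landscape_spec(rows = 60, cols = 60, n_covariates = 2,
                         smoothing_scale = 3, seed = 4)
  a <- generate_landscape(spec)
  b <- generate_landscape(spec)
  expect_identical(a$layers$cov1$values, b$layers$cov1$values)
  expect_named(a$layers, c("cov1", "cov2", "elevation", "slope", "aspect", "tri"))

  # unsmoothed noise has ~zero lag-1 autocorrelation; smoothed fields are high
  white <- generate_landscape(landscape_spec(rows = 100, cols = 100,
                                             n_covariates = 1,
                                             smoothing_scale = 0, seed = 9))
  expect_lt(abs(morans_i(white$layers$cov1$values)), 0.05)
  smooth <- generate_landscape(landscape_spec(rows = 100, cols = 100,
                                              n_covariates = 1,
                                              smoothing_scale = 5, seed = 9))
  expect_gt(morans_i(smooth$layers$cov1$values), 0.5)

  expect_error(landscape_spec(rows = 5), "at least 10")
})

test_that("true suitability implements the logistic linear-quadratic response", {
  st <- noise_stack(10, layers = 2, seed = 2)
  flat <- true_suitability(st, virtual_species(beta = c(cov1 = 0, cov2 = 0)))
  expect_true(all(flat$values == 0.5))  # logistic(0)

  sp <- virtual_species(beta0 = -2, beta = c(cov1 = 2), gamma = c(cov1 = 0))
  s <- true_suitability(st, sp)
  # spot-check a handful of cells against hand evaluation
  for (cell in list(c(1, 1), c(4, 7), c(10, 10))) {
    z <- st$layers$cov1$values[cell[1], cell[2]]
    expect_equal(s$values[cell[1], cell[2]], 1 / (1 + exp(-(-2 + 2 * z))))
  }
  # z = 1 gives logistic(0) = 0.5 under beta0 = -2, beta = 2
  st1 <- covariate_stack(list(cov1 = grid_from(matrix(1, 3, 3))))
  expect_equal(true_suitability(st1, sp)$values[2, 2], 0.5)

  expect_error(true_suitability(st, virtual_species(beta = c(missing = 1))),
               "lacks layer")
})

test_that("presences are drawn proportional to suitability with planted duplicates", {
  one <- grid_from(matrix(0, 5, 5)); one$values[3, 4] <- 1
  pts <- sample_presences(one, 20, seed = 6)
  idx <- cell_index(one, pts$lon, pts$lat)
  expect_true(all(idx$row == 3 & idx$col == 4))

  # duplicate_rate 0.3 on n = 100 emits 130 records that dedup back to 100
  suit <- noise_stack(10, layers = 1, seed = 3)$layers$cov1
  raw <- sample_presences(suit, 100, duplicate_rate = 0.3, seed = 8)
  expect_equal(nrow(raw), 130)
  expect_equal(nrow(suppressMessages(deduplicate(raw))), 100)

  # 4:1 suitability ratio across two cells draws ~4:1 points
  two <- grid_from(matrix(c(0.8, 0.2), 1, 2))
  draws <- sample_presences(two, 5000, seed = 10)
  counts <- table(cell_index(two, draws$lon, draws$lat)$col)
  expect_gt(stats::chisq.test(as.vector(counts), p = c(0.8, 0.2))$p.value, 0.01)

  zero <- grid_from(matrix(0, 3, 3))
  expect_error(sample_presences(zero, 5, seed = 1), "zero everywhere")
  expect_identical(sample_presences(suit, 50, 0.2, seed = 4),
                   sample_presences(suit, 50, 0.2, seed = 4))
})

test_that("true range thresholds the suitability field with boundary in", {
  suit <- noise_stack(12, layers = 1, seed = 5)$layers$cov1
  rng <- make_true_range(suit, 0.5)
  expect_equal(sum(rng$values), sum(suit$values >= 0.5))  # counting oracle

  all_half <- grid_from(matrix(0.5, 4, 4))
  expect_true(all(make_true_range(all_half, 0.5)$values == 1))

  tiny <- make_true_range(suit, 1e-9)
  expect_true(all(tiny$values == 1))

  expect_error(make_true_range(suit, 0), "strictly between")
  expect_error(make_true_range(suit, 1), "strictly between")
})

test_that("truth bundles are internally consistent and reproducible", {
  b1 <- simulate_truth_bundle(landscape_spec(rows = 30, cols = 30,
                                             n_covariates = 3),
                              n_presence = 40, n_background = 100, seed = 12)
  b2 <- simulate_truth_bundle(landscape_spec(rows = 30, cols = 30,
                                             n_covariates = 3),
                              n_presence = 40, n_background = 100, seed = 12)
  expect_identical(b1$presences, b2$presences)
  expect_identical(b1$background, b2$background)
  expect_identical(b1$stack$layers$cov2$values, b2$stack$layers$cov2$values)

  # presences come from cells with positive true suitability
  idx <- cell_index(b1$true_suitability, b1$presences$lon, b1$presences$lat)
  expect_true(all(b1$true_suitability$values[cbind(idx$row, idx$col)] > 0))

  # all components share geometry: features extract cleanly
  ft <- extract_features(normalize_stack(b1$stack), b1$presences)
  expect_equal(ncol(ft), 3 + length(b1$stack$layers))
  expect_equal(nrow(ft), nrow(b1$presences))
})
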