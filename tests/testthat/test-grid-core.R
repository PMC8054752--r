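test_that("min-max normalization maps layers onto [0,1] with the forced endpoints", {
  st <- covariate_stack(list(a = grid_from(matrix(c(2, 4, 6, 4), 2, 2))))
  out <- normalize_stack(st)
  expect_equal(sort(unique(as.vector(out$layers$a$values))), c(0, 0.5, 1))

  # any seeded random layer attains 0 and 1 exactly
  st2 <- noise_stack(12, layers = 3, seed = 99)
  out2 <- normalize_stack(st2)
  for (l in out2$layers) {
    expect_identical(min(l$values), 0)
    expect_identical(max(l$values), 1)
  }

  # idempotence: renormalizing changes nothing beyond floating tolerance
  out3 <- normalize_stack(out2)
  for (nm in names(out2$layers)) {
    expect_equal(out3$layers[[nm]]$values, out2$layers[[nm]]$values,
                 tolerance = 1e-12)
  }
})

test_that("constant layers normalize to all-0 with a warning, nodata survives", {
  v <- matrix(7, 3, 3); v[2, 2] <- NA
  st <- covariate_stack(list(flat = grid_from(v)))
  expect_warning(out <- normalize_stack(st), "constant")
  expect_equal(as.vector(out$layers$flat$values),
               c(0, 0, 0, 0, NA, 0, 0, 0, 0))
})

test_that("slope, aspect and TRI match analytic values on planes", {
  flat <- grid_from(matrix(5, 6, 6))
  tm <- terrain_metrics(flat)
  expect_true(all(tm$layers$slope$values == 0))
  expect_true(all(tm$layers$aspect$values == 0))
  expect_true(all(tm$layers$tri$values == 0))

  # inclined plane z = x (km) on 1-km cells: interior gradient magnitude 1
  n <- 8
  plane <- grid_from(outer(rep(1, n), seq_len(n)))  # z increases eastwards
  tm <- terrain_metrics(plane)
  interior <- tm$layers$slope$values[2:(n - 1), 2:(n - 1)]
  expect_equal(interior, matrix(45, n - 2, n - 2))
  # TRI on the same plane: six |dz| = 1 neighbours, two 0 -> 0.75
  expect_equal(tm$layers$tri$values[2:(n - 1), 2:(n - 1)],
               matrix(0.75, n - 2, n - 2))
  # downslope faces west on an east-rising plane
  expect_equal(tm$layers$aspect$values[4, 4], 270)

  expect_error(terrain_metrics(grid_from(matrix(1, 2, 5))), "3 x 3")
})

test_that("terrain metrics are invariant to constant elevation offsets", {
  withr::with_seed(5, {
    z <- matrix(cumsum(rnorm(100)), 10, 10)
  })
  a <- terrain_metrics(grid_from(z))
  b <- terrain_metrics(grid_from(z + 137.5))
  for (nm in c("slope", "aspect", "tri")) {
    expect_equal(a$layers[[nm]]$values, b$layers[[nm]]$values, tolerance = 1e-9)
  }
  # zero exactly where the 3x3 neighbourhood is constant
  z2 <- matrix(rnorm(100), 10, 10)
  z2[4:8, 4:8] <- 3
  tm <- terrain_metrics(grid_from(z2))
  expect_true(all(tm$layers$slope$values[6, 6] == 0))
  expect_true(all(tm$layers$tri$values[6, 6] == 0))
})

test_that("feature extraction maps points to their containing cells", {
  st <- noise_stack(6, layers = 2, seed = 3)
  # exact centre of cell (3, 2): x = 1.5, y = 2.5
  ft <- extract_features(st, tibble::tibble(lon = 1.5, lat = 2.5))
  expect_equal(ft$cov1, st$layers$cov1$values[3, 2])
  expect_equal(ft$cov2, st$layers$cov2$values[3, 2])
  expect_equal(names(ft), c("lon", "lat", "label", "cov1", "cov2"))

  # a nodata cell drops its row
  st$layers$cov2$values[3, 2] <- NA
  expect_message(
    ft2 <- extract_features(st, tibble::tibble(lon = c(1.5, 4.5),
                                               lat = c(2.5, 4.5))),
    "nodata")
  expect_equal(nrow(ft2), 1)
  expect_equal(ft2$lon, 4.5)

  # all points outside -> error; some outside -> warning
  expect_error(extract_features(st, tibble::tibble(lon = 99, lat = 99)),
               "outside")
  expect_warning(
    ft3 <- extract_features(st, tibble::tibble(lon = c(0.5, -3), lat = c(0.5, 2))),
    "outside")
  expect_equal(nrow(ft3), 1)
})

test_that("extraction agrees with a brute-force containment scan on random points", {
  st <- noise_stack(9, layers = 2, seed = 11)
  st$layers$cov1$values[2, 7] <- NA  # one nodata cell
  pts <- withr::with_seed(21, tibble::tibble(lon = runif(50, 0, 9),
                                             lat = runif(50, 0, 9)))
  ft <- suppressMessages(extract_features(st, pts))
  # oracle: loop every point, half-open rectangle containment
  expected <- list()
  for (r in seq_len(nrow(pts))) {
    i <- NA; j <- NA
    for (ii in 1:9) for (jj in 1:9) {
      if (pts$lon[r] >= jj - 1 && pts$lon[r] < jj &&
          pts$lat[r] >= ii - 1 && pts$lat[r] < ii) { i <- ii; j <- jj }
    }
    v1 <- st$layers$cov1$values[i, j]
    if (!is.na(v1)) {
      expected[[length(expected) + 1]] <-
        c(pts$lon[r], pts$lat[r], v1, st$layers$cov2$values[i, j])
    }
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(ft), nrow(expected))
  expect_equal(ft$cov1, expected[, 3])
  expect_equal(ft$cov2, expected[, 4])
})

test_that("stack construction rejects mismatched geometry and duplicate names", {
  a <- grid_from(matrix(1, 4, 4)); b <- grid_from(matrix(1, 5, 4))
  expect_error(covariate_stack(list(a = a, b = b)), "geometry")
  expect_error(covariate_stack(list(a = a, a = a)), "unique")
  expect_error(covariate_stack(list()), "at least one")
})
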