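test_that("deduplication keeps the first record per coordinate pair", {
  raw <- tibble::tibble(id = 1:3, lon = c(1, 1, 2), lat = c(1, 1, 2))
  out <- suppressMessages(deduplicate(raw))
  expect_equal(out$id, c(1L, 3L))

  # empty input passes through
  expect_equal(nrow(deduplicate(tibble::tibble(lon = numeric(0),
                                               lat = numeric(0)))), 0)

  # idempotence
  expect_identical(deduplicate(out), out)

  # non-numeric coordinates are rejected with a warning
  messy <- tibble::tibble(lon = c("1.5", "oops"), lat = c("2", "3"))
  expect_warning(kept <- deduplicate(messy), "non-numeric")
  expect_equal(nrow(kept), 1)
})

test_that("planted duplicates are removed exactly, against a set-based oracle", {
  withr::with_seed(17, {
    base <- tibble::tibble(lon = round(runif(70), 6), lat = round(runif(70), 6))
    dup_rows <- base[sample.int(70, 30, replace = TRUE), ]
    raw <- dplyr::bind_rows(base, dup_rows)[sample.int(100), ]
  })
  out <- suppressMessages(deduplicate(raw))
  distinct_oracle <- length(unique(paste(raw$lon, raw$lat)))
  expect_equal(nrow(out), distinct_oracle)
  expect_equal(nrow(out), 70)
})

test_that("region subsetting honours containment with boundary inside", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  occ <- tibble::tibble(id = 1:3, lon = c(0.5, 2, 1), lat = c(0.5, 2, 0.5))
  out <- subset_by_region(occ, square)
  expect_equal(out$id, c(1L, 3L))  # (1, 0.5) sits on the boundary

  expect_error(subset_by_region(occ, cbind(c(0, 1), c(0, 0))), "vertices")
})

test_that("region subsetting matches an independent ray-casting oracle", {
  hex <- cbind(cos(seq(0, 2 * pi, length.out = 7))[-7],
               sin(seq(0, 2 * pi, length.out = 7))[-7]) * 0.8
  pts <- withr::with_seed(31, tibble::tibble(id = 1:200,
                                             lon = runif(200, -1, 1),
                                             lat = runif(200, -1, 1)))
  got <- subset_by_region(pts, hex)
  want <- vapply(seq_len(200),
                 function(k) pip_oracle(pts$lon[k], pts$lat[k], hex),
                 logical(1))
  expect_equal(got$id, pts$id[want])
})

test_that("background sampling is uniform over the mask and reproducible", {
  mask <- grid_from(matrix(1, 2, 2))
  expect_equal(nrow(sample_background(mask, 0, seed = 1)), 0)

  # a single true cell forces every point into its rectangle
  m1 <- grid_from(matrix(c(0, 0, 1, 0), 2, 2))  # true cell at row 1, col 2
  pts <- sample_background(m1, 5, seed = 4)
  expect_true(all(pts$lon >= 1 & pts$lon < 2 & pts$lat >= 0 & pts$lat < 1))

  # reproducibility is bit-exact
  expect_identical(sample_background(mask, 100, seed = 9),
                   sample_background(mask, 100, seed = 9))
  expect_false(identical(sample_background(mask, 100, seed = 9),
                         sample_background(mask, 100, seed = 10)))

  # chi-square uniformity over a 4-cell mask
  pts <- sample_background(mask, 10000, seed = 2)
  idx <- cell_index(mask, pts$lon, pts$lat)
  counts <- table(factor(paste(idx$row, idx$col),
                         levels = c("1 1", "1 2", "2 1", "2 2")))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)

  # empty mask errors only when points are requested
  empty <- grid_from(matrix(0, 2, 2))
  expect_error(sample_background(empty, 3, seed = 1), "no true cells")
  expect_equal(nrow(sample_background(empty, 0, seed = 1)), 0)
})

test_that("fold assignment is a balanced partition", {
  occ10 <- tibble::tibble(id = 1:10, lon = 1:10, lat = 1:10)
  f <- kfold_split(occ10, k = 5, seed = 1)
  expect_equal(as.vector(table(f$fold)), rep(2L, 5))

  # 97 = 5*19 + 2 -> sizes {20, 20, 19, 19, 19}
  occ97 <- tibble::tibble(id = 1:97, lon = runif(97), lat = runif(97))
  f97 <- kfold_split(occ97, k = 5, seed = 3)
  expect_equal(sort(as.vector(table(f97$fold))), c(19L, 19L, 19L, 20L, 20L))

  # partition properties under several seeds
  for (s in 1:5) {
    f <- kfold_split(occ97, k = 5, seed = s)
    expect_setequal(f$id, occ97$id)
    expect_equal(anyDuplicated(f$id), 0)
    sizes <- table(f$fold)
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(kfold_split(occ10[1:3, ], k = 5), "at least")
})
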