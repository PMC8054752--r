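# small hyperparameters for desk-size fixtures; the algorithms and their
# contracts are unchanged
fast_hp <- list(ann = list(maxit = 200), gbm = list(nrounds = 150, eta = 0.1),
                maxent = list(), rf = list(ntree = 100), svm = list())

sep_data <- function(n = 60, seed = 5) {
  withr::with_seed(seed, list(
    pos = tibble::tibble(env = runif(n, 0.7, 1), noise = runif(n)),
    neg = tibble::tibble(env = runif(n, 0, 0.3), noise = runif(n))
  ))
}

test_that("every family separates linearly separable classes (training AUC >= 0.99)", {
  d <- sep_data()
  for (fam in c("ann", "gbm", "maxent", "rf", "svm")) {
    spec <- learner_spec(fam, fast_hp[[fam]], seed = 11)
    m <- fit_sdm(spec, d$pos, d$neg)
    expect_gte(auc(predict_sdm(m, d$pos), predict_sdm(m, d$neg)), 0.99)
    expect_true(all(predict_sdm(m, d$pos) >= 0 & predict_sdm(m, d$pos) <= 1))
  }
})

test_that("null-signal data yields chance-level held-out AUC for every family", {
  withr::with_seed(29, {
    train_pos <- tibble::tibble(a = runif(80), b = runif(80))
    train_neg <- tibble::tibble(a = runif(80), b = runif(80))
    test_pos <- tibble::tibble(a = runif(40), b = runif(40))
    test_neg <- tibble::tibble(a = runif(40), b = runif(40))
  })
  for (fam in c("ann", "gbm", "maxent", "rf", "svm")) {
    m <- fit_sdm(learner_spec(fam, fast_hp[[fam]], seed = 3),
                 train_pos, train_neg)
    a <- auc(predict_sdm(m, test_pos), predict_sdm(m, test_neg))
    expect_gte(a, 0.4)
    expect_lte(a, 0.75)
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  d <- sep_data(40, seed = 13)
  probe <- withr::with_seed(14, tibble::tibble(env = runif(30), noise = runif(30)))
  for (fam in c("ann", "gbm", "maxent", "rf", "svm")) {
    m1 <- fit_sdm(learner_spec(fam, fast_hp[[fam]], seed = 21), d$pos, d$neg)
    m2 <- fit_sdm(learner_spec(fam, fast_hp[[fam]], seed = 21), d$pos, d$neg)
    expect_identical(predict_sdm(m1, probe), predict_sdm(m2, probe))
  }
})

test_that("fit rejects degenerate and mismatched inputs", {
  d <- sep_data(20)
  spec <- learner_spec("rf", fast_hp$rf, seed = 1)
  expect_error(fit_sdm(spec, d$pos[0, ], d$neg), "non-empty")
  expect_error(fit_sdm(spec, d$pos, tibble::tibble(other = runif(5))),
               "columns differ")
  expect_error(learner_spec("cart"), "unknown learner")
})

test_that("map prediction equals pointwise prediction and propagates nodata", {
  st <- noise_stack(8, layers = 2, seed = 6, named = c("env", "noise"))
  st$layers$env$values[2, 5] <- NA
  d <- sep_data(30, seed = 7)
  m <- fit_sdm(learner_spec("maxent", seed = 2), d$pos, d$neg)
  smap <- predict_map(m, st)
  expect_true(is.na(smap$values[2, 5]))
  cells <- grid_cells(st$layers$env)
  ft <- tibble::tibble(env = as.vector(st$layers$env$values),
                       noise = as.vector(st$layers$noise$values))
  expect_equal(as.vector(smap$values), predict_sdm(m, ft))

  # stack rows at the training points reproduce the training scores
  ftr <- suppressWarnings(suppressMessages(extract_features(st, tibble::tibble(
    lon = cells$x[1:5], lat = cells$y[1:5]))))
  expect_equal(predict_sdm(m, ftr),
               as.vector(smap$values)[1:5])

  expect_error(predict_map(m, noise_stack(8, 1, named = "env")), "missing layer")

  allna <- covariate_stack(list(env = grid_from(matrix(NA_real_, 4, 4)),
                                noise = grid_from(matrix(NA_real_, 4, 4))))
  expect_true(all(is.na(predict_map(m, allna)$values)))
})

test_that("tree ensembles are monotone in a single informative covariate", {
  withr::with_seed(15, {
    pos <- tibble::tibble(z = runif(80, 0.6, 1))
    neg <- tibble::tibble(z = runif(80, 0, 0.4))
  })
  ramp <- covariate_stack(list(z = grid_from(matrix(seq(0, 1, length.out = 101),
                                                    1, 101))))
  for (fam in c("rf", "gbm")) {
    m <- fit_sdm(learner_spec(fam, fast_hp[[fam]], seed = 8), pos, neg)
    s <- as.vector(predict_map(m, ramp)$values)
    expect_true(all(diff(s) >= -1e-9))
    expect_gt(s[101], s[1])
  }
})

test_that("model serialization writes a readable artifact and manifest", {
  d <- sep_data(20, seed = 3)
  m <- fit_sdm(learner_spec("maxent", seed = 4), d$pos, d$neg, train_fold = 2L)
  path <- file.path(withr::local_tempdir(), "model")
  save_sdm_model(m, path)
  man <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(man$family, "maxent")
  expect_equal(man$train_fold, 2)
  expect_equal(man$feature_names, m$feature_names)
  m2 <- readRDS(paste0(path, ".rds"))
  expect_identical(predict_sdm(m2, d$pos), predict_sdm(m, d$pos))
})

test_that("tidy and glance expose the model's provenance", {
  d <- sep_data(20, seed = 9)
  m <- fit_sdm(learner_spec("rf", fast_hp$rf, seed = 5), d$pos, d$neg)
  g <- glance(m)
  expect_equal(g$family, "rf")
  expect_equal(g$n_presence, 20)
  expect_gte(g$train_auc, 0.9)
  expect_true("ntree" %in% tidy(m)$term)
})
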