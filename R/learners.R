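SDM_FAMILIES <- c("ann", "gbm", "maxent", "rf", "svm")

#' Specify a suitability learner
#'
#' One spec per model: an algorithm family, its hyperparameters, and a seed
#' (no unseeded fits — every model must be independently reproducible).
#' Defaults, none of which are sacred and all of which can be overridden:
#'
#' * `ann` — single-hidden-layer feed-forward network: `size = 8`,
#'   `decay = 0.01`, `maxit = 500`.
#' * `gbm` — gradient boosted trees, bernoulli loss: `nrounds = 1000`,
#'   `eta = 0.01`, `max_depth = 3`.
#' * `maxent` — L1-penalized logistic regression of presence vs background on
#'   an expanded feature set (linear + quadratic + pairwise products),
#'   following the equivalence of maximum-entropy presence-background models
#'   to penalized logistic regression; penalty chosen by BIC along the
#'   regularization path.
#' * `rf` — random forest: `ntree = 500`, default feature subsampling.
#' * `svm` — RBF-kernel support vector machine with probability calibration.
#'
#' No class reweighting is applied despite the presence:background imbalance
#' (set `weights = TRUE` in the hyperparameters to weight classes inversely
#' to their frequency).
#'
#' @param family One of `"ann"`, `"gbm"`, `"maxent"`, `"rf"`, `"svm"`
#'   (case-insensitive).
#' @param hyperparameters Named list of overrides for the family defaults.
#' @param seed Integer seed.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(family, hyperparameters = list(), seed = 1) {
  family <- tolower(family)
  if (!family %in% SDM_FAMILIES) {
    stop("unknown learner family '", family, "'; expected one of ",
         paste(SDM_FAMILIES, collapse = ", "), call. = FALSE)
  }
  if (is.null(seed) || is.na(seed)) stop("seed must be set", call. = FALSE)
  defaults <- switch(family,
    ann = list(size = 8, decay = 0.01, maxit = 500),
    gbm = list(nrounds = 1000, eta = 0.01, max_depth = 3),
    maxent = list(alpha = 1, expand = TRUE),
    rf = list(ntree = 500),
    svm = list(kernel = "radial", cost = 1)
  )
  defaults$weights <- FALSE
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

# linear + quadratic + pairwise-product expansion used by the maxent family
expand_features <- function(x) {
  p <- ncol(x)
  sq <- x^2
  colnames(sq) <- paste0(colnames(x), "^2")
  parts <- list(x, sq)
  if (p >= 2) {
    idx <- utils::combn(p, 2)
    prod <- x[, idx[1, ], drop = FALSE] * x[, idx[2, ], drop = FALSE]
    colnames(prod) <- paste0(colnames(x)[idx[1, ]], ":", colnames(x)[idx[2, ]])
    parts <- c(parts, list(prod))
  }
  do.call(cbind, parts)
}

feature_matrix <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  drop <- intersect(c("lon", "lat", "label", "id", "fold"), names(tbl))
  tbl <- tbl[, setdiff(names(tbl), drop), drop = FALSE]
  if (ncol(tbl) == 0) stop("no feature columns found", call. = FALSE)
  as.matrix(tbl)
}

#' Fit a presence-background suitability model
#'
#' Fits the family named in `spec` with presences as the positive class and
#' background points as the contrast class, returning a fitted scorer with a
#' uniform predict surface ([predict_sdm()], [predict_map()]). Fits are
#' deterministic given the spec's seed.
#'
#' @param spec A [learner_spec()].
#' @param presence,background Feature tables (e.g. from
#'   [extract_features()]); any `lon`/`lat`/`label` columns are ignored and
#'   the remaining columns must match between the two tables.
#' @param train_fold Optional fold index recorded for provenance.
#' @return An object of class `sdm_model`.
#' @export
fit_sdm <- function(spec, presence, background, train_fold = NA_integer_) {
  stopifnot(inherits(spec, "learner_spec"))
  xp <- feature_matrix(presence)
  xb <- feature_matrix(background)
  if (nrow(xp) == 0 || nrow(xb) == 0) {
    stop("both presence and background tables must be non-empty ",
         "(single-class input cannot be fitted)", call. = FALSE)
  }
  if (!identical(colnames(xp), colnames(xb))) {
    stop("presence and background feature columns differ", call. = FALSE)
  }
  x <- rbind(xp, xb)
  y <- c(rep(1, nrow(xp)), rep(0, nrow(xb)))
  hp <- spec$hyperparameters
  w <- if (isTRUE(hp$weights)) {
    ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
  } else {
    rep(1, length(y))
  }

  fit <- withr::with_seed(spec$seed, switch(spec$family,
    ann = nnet::nnet(x = x, y = y, size = hp$size, decay = hp$decay,
                     maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                     weights = w, MaxNWts = 10000),
    gbm = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1,
                      seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    },
    maxent = {
      xe <- if (isTRUE(hp$expand)) expand_features(x) else x
      path <- glmnet::glmnet(xe, y, family = "binomial", alpha = hp$alpha,
                             weights = w, standardize = TRUE)
      dev <- (1 - path$dev.ratio) * path$nulldev
      bic <- dev + log(nrow(xe)) * path$df
      list(path = path, lambda = path$lambda[which.min(bic)],
           expand = isTRUE(hp$expand))
    },
    rf = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)), ntree = hp$ntree,
      classwt = if (isTRUE(hp$weights)) c(`0` = mean(y == 1), `1` = mean(y == 0))),
    svm = e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                     kernel = hp$kernel, cost = hp$cost,
                     probability = TRUE,
                     class.weights = if (isTRUE(hp$weights))
                       c(`0` = 0.5 / mean(y == 0), `1` = 0.5 / mean(y == 1)))
  ))

  model <- structure(
    list(spec = spec, fit = fit, feature_names = colnames(x),
         train_fold = train_fold,
         n_presence = nrow(xp), n_background = nrow(xb)),
    class = "sdm_model")
  model$train_auc <- auc(predict_sdm(model, xp), predict_sdm(model, xb))
  model
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %s (seed %d, fold %s): %d presences vs %d background, training AUC %.4f\n",
              toupper(x$spec$family), x$spec$seed,
              ifelse(is.na(x$train_fold), "-", x$train_fold),
              x$n_presence, x$n_background, x$train_auc))
  invisible(x)
}

#' Score new feature rows with a fitted model
#'
#' @param model An [fit_sdm()] result.
#' @param newdata Feature table or matrix whose columns include the model's
#'   `feature_names`.
#' @return Numeric suitability scores clamped to `[0, 1]` (`NA` for rows with
#'   any missing feature).
#' @export
predict_sdm <- function(model, newdata) {
  stopifnot(inherits(model, "sdm_model"))
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[, model$feature_names, drop = FALSE]
  ok <- stats::complete.cases(x)
  out <- rep(NA_real_, nrow(x))
  if (any(ok)) {
    xi <- x[ok, , drop = FALSE]
    s <- switch(model$spec$family,
      ann = as.numeric(stats::predict(model$fit, xi)),
      gbm = stats::predict(model$fit,
                           xgboost::xgb.DMatrix(xi, nthread = 1)),
      maxent = {
        xe <- if (model$fit$expand) expand_features(xi) else xi
        as.numeric(stats::predict(model$fit$path, xe, s = model$fit$lambda,
                                  type = "response"))
      },
      rf = stats::predict(model$fit, xi, type = "prob")[, "1"],
      svm = {
        p <- stats::predict(model$fit, xi, probability = TRUE)
        attr(p, "probabilities")[, "1"]
      })
    out[ok] <- pmin(pmax(as.numeric(s), 0), 1)
  }
  out
}

#' Predict a suitability map over a covariate stack
#'
#' Applies the fitted scorer to every grid cell. A cell that is nodata in any
#' required layer is nodata in the map.
#'
#' @param model An [fit_sdm()] result.
#' @param stack A [covariate_stack()] whose layer names include the model's
#'   `feature_names`.
#' @return A `suitability_map`: a [raster_grid()] of scores in `[0, 1]` with
#'   a `model_id` attribute.
#' @export
predict_map <- function(model, stack) {
  stopifnot(inherits(model, "sdm_model"), inherits(stack, "covariate_stack"))
  missing <- setdiff(model$feature_names, names(stack$layers))
  if (length(missing)) {
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  g <- stack$layers[[1]]
  x <- vapply(model$feature_names,
              function(nm) as.vector(stack$layers[[nm]]$values),
              numeric(length(g$values)))
  x <- matrix(x, ncol = length(model$feature_names),
              dimnames = list(NULL, model$feature_names))
  scores <- predict_sdm(model, x)
  out <- g
  out$values <- matrix(scores, nrow = nrow(g$values), ncol = ncol(g$values))
  structure(out, class = c("suitability_map", "raster_grid"),
            model_id = sprintf("%s_fold%s_seed%d", model$spec$family,
                               ifelse(is.na(model$train_fold), "NA",
                                      model$train_fold),
                               model$spec$seed))
}

#' Serialize a fitted model with a JSON manifest
#'
#' Writes `<path>.rds` (the model) and `<path>.json` (family,
#' hyperparameters, seed, feature names, fold) so any single model can be
#' reloaded and audited.
#'
#' @param model An `sdm_model`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
save_sdm_model <- function(model, path) {
  stopifnot(inherits(model, "sdm_model"))
  saveRDS(model, paste0(path, ".rds"))
  jsonlite::write_json(
    list(format_version = 1L,
         family = model$spec$family,
         hyperparameters = model$spec$hyperparameters,
         seed = model$spec$seed,
         feature_names = model$feature_names,
         train_fold = model$train_fold),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
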