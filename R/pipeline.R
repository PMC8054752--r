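#' Configure an ensemble-election experiment
#'
#' Collects every tunable of the full experiment. The defaults mirror the
#' standard protocol: five algorithm families, 5-fold cross-validation with
#' the complete background attached to both sides of every fold, a 49-km
#' dispersal-buffer validation mask, simple-majority quorums (3 of 5 fold
#' maps per algorithm, 13 of 25 pooled models), and exclusion-style
#' unanimous decisions.
#'
#' @param algorithms Character vector of learner families (see
#'   [learner_spec()]).
#' @param k Number of cross-validation folds (`>= 2`).
#' @param n_background Background points to sample when the input provides
#'   none.
#' @param radius_km Dispersal-buffer radius for the validation range mask.
#' @param collective_quorum Votes required in the pooled election; default
#'   simple majority of `length(algorithms) * k` members.
#' @param fold_quorum Votes required in the per-algorithm election; default
#'   simple majority of `k`.
#' @param ud_forced_binary If `TRUE`, unanimous-decision ensembles class
#'   contested cells unsuitable instead of excluding them.
#' @param hyperparameters Named list of per-family hyperparameter overrides,
#'   e.g. `list(gbm = list(nrounds = 200))`.
#' @param subregion Polygon (two-column matrix) delimiting the second
#'   training configuration; `NULL` with a `truth_bundle` input uses the
#'   lower-left quadrant of the grid.
#' @param include_subregion Run the sub-region training configuration?
#' @param include_collective Build and evaluate the two pooled elections?
#' @param seed Master seed; fixes fold splits, background sampling and every
#'   learner seed.
#' @param output_dir If non-`NULL`, metrics and the manifest are written
#'   there.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(algorithms = SDM_FAMILIES, k = 5,
                              n_background = 10000, radius_km = 49,
                              collective_quorum = NULL, fold_quorum = NULL,
                              ud_forced_binary = FALSE,
                              hyperparameters = list(),
                              subregion = NULL, include_subregion = TRUE,
                              include_collective = TRUE,
                              seed = 1, output_dir = NULL) {
  algorithms <- tolower(algorithms)
  bad <- setdiff(algorithms, SDM_FAMILIES)
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (is.null(seed) || is.na(seed)) stop("seed must be set", call. = FALSE)
  structure(list(
    algorithms = algorithms, k = as.integer(k),
    n_background = n_background, radius_km = radius_km,
    fold_quorum = fold_quorum %||% ceiling((k + 1) / 2),
    collective_quorum = collective_quorum %||%
      ceiling((length(algorithms) * k + 1) / 2),
    ud_forced_binary = ud_forced_binary,
    hyperparameters = hyperparameters,
    subregion = subregion, include_subregion = include_subregion,
    include_collective = include_collective,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "experiment_config")
}

default_quadrant <- function(grid) {
  x0 <- grid$origin_x; y0 <- grid$origin_y
  x1 <- x0 + ncol(grid$values) * grid$cell_dx / 2
  y1 <- y0 + nrow(grid$values) * grid$cell_dy / 2
  cbind(lon = c(x0, x1, x1, x0), lat = c(y0, y0, y1, y1))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full ensemble-election experiment
#'
#' Executes the whole protocol: covariate normalization, occurrence
#' deduplication, background sampling, dispersal-buffer range estimation,
#' then — for each training configuration (all occurrences; occurrences
#' inside the sub-region polygon) — a k-fold cross-validation of every
#' algorithm family with per-fold thresholding and binarization, the three
#' per-algorithm ensembles (mean, majority vote, unanimous decision), and
#' the two collective elections pooling every fold model. Every
#' classification map is scored by confusion matrix against the buffer range
#' mask. With the defaults (2 configurations x 5 algorithms x 5 folds) this
#' evaluates `2 * (5*5 + 5*3 + 2) = 84` classification maps.
#'
#' @param x A `truth_bundle` from [simulate_truth_bundle()], or a list with
#'   elements `stack` (a [covariate_stack()]), `presences` (raw occurrence
#'   tibble), and optionally `background` (tibble) and `domain` (mask
#'   [raster_grid()]).
#' @param config An [experiment_config()].
#' @return An `sdm_experiment` manifest: `metrics` (tidy tibble), `maps`
#'   (named list of evaluated `binary_map`s), `fold_maps` (continuous fold
#'   `suitability_map`s), `mean_suitability` (pooled mean surface per
#'   training set), `range_mask`, `folds`, `occurrences`, `background`,
#'   `config`, and `counts`.
#' @export
run_experiment <- function(x, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  stack <- x$stack
  if (!inherits(stack, "covariate_stack")) stop("input lacks a covariate stack", call. = FALSE)
  grid <- stack$layers[[1]]

  stage_log("normalize", "normalizing %d layers", length(stack$layers))
  nstack <- normalize_stack(stack)

  occ <- deduplicate(x$presences)
  stage_log("dedup", "%d occurrence records retained", nrow(occ))

  background <- x$background
  if (is.null(background)) {
    domain <- x$domain
    if (is.null(domain)) {
      domain <- grid
      domain$values[] <- as.numeric(!is.na(grid$values))
    }
    background <- sample_background(domain, config$n_background,
                                    seed = derive_seed(config$seed, "background"))
  }
  stage_log("background", "%d background points", nrow(background))

  domain_mask <- x$domain
  range_mask <- buffer_range_mask(occ, config$radius_km, grid, domain_mask)
  stage_log("range", "radius %g km: %d in-range cells",
            config$radius_km, sum(range_mask$values == 1, na.rm = TRUE))

  bg_feat <- extract_features(nstack, background, label = "background")

  sets <- list(full = occ)
  if (config$include_subregion) {
    region <- config$subregion %||% default_quadrant(grid)
    sets$subregion <- subset_by_region(occ, region)
    stage_log("subregion", "%d of %d occurrences inside the sub-region",
              nrow(sets$subregion), nrow(occ))
  }

  metrics <- list()
  maps <- list()
  fold_maps <- list()
  mean_suit <- list()
  folds_out <- list()

  add_metric <- function(set, alg, unit, stat, value) {
    metrics[[length(metrics) + 1]] <<- tibble::tibble(
      training_set = set, algorithm = alg, unit = unit,
      statistic = stat, value = value)
  }
  add_confusion <- function(set, alg, unit, bmap) {
    # a unanimity ensemble may abstain on every cell; its confusion
    # statistics are then undefined and recorded as NA, not an abort
    cs <- tryCatch(confusion_stats(bmap, range_mask), error = function(e) {
      if (!grepl("no evaluable", conditionMessage(e))) stop(e)
      stage_log("evaluate", "%s/%s/%s: no evaluable cells, statistics NA",
                set, alg, unit)
      tibble::tibble(accuracy = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_)
    })
    for (stat in c("accuracy", "sensitivity", "specificity")) {
      add_metric(set, alg, unit, stat, cs[[stat]])
    }
    maps[[paste(set, alg, unit, sep = "/")]] <<- bmap
  }

  for (set in names(sets)) {
    socc <- sets[[set]]
    if (nrow(socc) < config$k) {
      stop("training set '", set, "' has fewer records than k", call. = FALSE)
    }
    folds <- kfold_split(socc, config$k,
                         seed = derive_seed(config$seed, paste0("folds_", set)))
    folds_out[[set]] <- folds
    pres_feat <- extract_features(nstack, socc, label = "presence")
    pres_fold <- folds$fold[match(socc$id, folds$id)]
    # extract_features may drop out-of-extent/nodata rows; realign by coords
    keep <- match(paste(pres_feat$lon, pres_feat$lat),
                  paste(socc$lon, socc$lat))
    pres_fold <- pres_fold[keep]

    all_binary <- list()
    for (alg in config$algorithms) {
      suit_maps <- list(); bin_maps <- list(); thresholds <- numeric(config$k)
      for (f in seq_len(config$k)) {
        spec <- learner_spec(
          alg, hyperparameters = config$hyperparameters[[alg]] %||% list(),
          seed = derive_seed(config$seed, paste(set, alg, f)))
        train <- pres_feat[pres_fold != f, , drop = FALSE]
        test <- pres_feat[pres_fold == f, , drop = FALSE]
        model <- fit_sdm(spec, train, bg_feat, train_fold = f)
        test_scores <- predict_sdm(model, test)
        bg_scores <- predict_sdm(model, bg_feat)
        th <- optimal_threshold(test_scores, bg_scores)
        add_metric(set, alg, paste0("fold", f), "auc",
                   auc(test_scores, bg_scores))
        add_metric(set, alg, paste0("fold", f), "threshold", th$threshold)
        smap <- predict_map(model, nstack)
        bmap <- binarize(smap, th$threshold)
        add_confusion(set, alg, paste0("fold", f), bmap)
        suit_maps[[f]] <- smap; bin_maps[[f]] <- bmap
        thresholds[f] <- th$threshold
      }
      fold_maps[[paste(set, alg, sep = "/")]] <- suit_maps
      add_confusion(set, alg, "mean_ens", mean_ensemble(suit_maps, thresholds))
      add_confusion(set, alg, "mv_ens",
                    vote_ensemble(bin_maps, config$fold_quorum))
      add_confusion(set, alg, "ud_ens",
                    unanimous_ensemble(bin_maps, config$ud_forced_binary))
      all_binary <- c(all_binary, bin_maps)
      stage_log("fit", "%s/%s: %d folds + 3 ensembles evaluated", set, alg,
                config$k)
    }
    if (config$include_collective) {
      add_confusion(set, "collective", "collective_mv",
                    vote_ensemble(all_binary, config$collective_quorum))
      add_confusion(set, "collective", "collective_ud",
                    unanimous_ensemble(all_binary, config$ud_forced_binary))
      stage_log("collective", "%s: pooled %d models, quorum %d", set,
                length(all_binary), config$collective_quorum)
    }
    mean_suit[[set]] <- mean_suitability(
      unlist(fold_maps[paste(set, config$algorithms, sep = "/")],
             recursive = FALSE))
  }

  metrics <- dplyr::bind_rows(metrics)
  n_sets <- length(sets); n_alg <- length(config$algorithms)
  counts <- list(
    n_evaluated_maps = length(maps),
    expected_maps = n_sets * (n_alg * config$k + n_alg * 3 +
                                if (config$include_collective) 2 else 0),
    n_training_sets = n_sets, n_algorithms = n_alg, k = config$k,
    collective_members = n_alg * config$k,
    collective_quorum = config$collective_quorum,
    n_occurrences = nrow(occ), n_background = nrow(background)
  )
  out <- structure(
    list(metrics = metrics, maps = maps, fold_maps = fold_maps,
         mean_suitability = mean_suit, range_mask = range_mask,
         folds = folds_out, occurrences = occ, background = background,
         config = config, counts = counts),
    class = "sdm_experiment")
  if (!is.null(config$output_dir)) write_experiment(out, config$output_dir)
  out
}

write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(exp$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  rep <- report(exp)
  utils::write.csv(rep$table, file.path(dir, "ensemble_table.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$fold_summaries, file.path(dir, "fold_summaries.csv"),
                   row.names = FALSE)
  write_range_mask(exp$range_mask, file.path(dir, "range_mask"))
  jsonlite::write_json(
    c(exp$counts, list(seed = exp$config$seed,
                       algorithms = exp$config$algorithms,
                       maps = names(exp$maps))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.sdm_experiment <- function(x, ...) {
  cat(sprintf(
    "<sdm_experiment> %d training set(s) x %d algorithms x %d folds: %d evaluated maps (seed %d)\n",
    x$counts$n_training_sets, x$counts$n_algorithms, x$counts$k,
    x$counts$n_evaluated_maps, x$config$seed))
  invisible(x)
}

#' Summary tables of a completed experiment
#'
#' Produces the ensemble results table — one row per training set x
#' algorithm x ensemble (mean, majority vote, unanimous decision) plus the
#' two collective elections, with accuracy, sensitivity and specificity —
#' and the per-fold summaries (mean and sample standard deviation of each
#' statistic across the k folds).
#'
#' @param x An `sdm_experiment` from [run_experiment()].
#' @return A list with tibbles `table` and `fold_summaries`.
#' @export
report <- function(x) {
  stopifnot(inherits(x, "sdm_experiment"))
  m <- x$metrics
  if (is.null(m) || nrow(m) == 0) stop("experiment manifest has no metrics", call. = FALSE)
  expected_units <- c("mean_ens", "mv_ens", "ud_ens")
  have <- unique(m[, c("training_set", "algorithm", "unit")])
  for (set in unique(m$training_set)) {
    alg_units <- have[have$training_set == set, ]
    missing <- character(0)
    for (alg in setdiff(unique(alg_units$algorithm), "collective")) {
      missing <- c(missing, setdiff(expected_units,
                                    alg_units$unit[alg_units$algorithm == alg]))
    }
    if (isTRUE(x$config$include_collective) &&
        !all(c("collective_mv", "collective_ud") %in% alg_units$unit)) {
      missing <- c(missing, "collective elections")
    }
    if (length(missing)) {
      stop("incomplete manifest for training set '", set, "': missing ",
           paste(unique(missing), collapse = ", "), call. = FALSE)
    }
  }
  ens_label <- c(mean_ens = "Mean", mv_ens = "MV", ud_ens = "UD",
                 collective_mv = "MV", collective_ud = "UD")
  tab <- m |>
    dplyr::filter(.data$unit %in% names(ens_label)) |>
    tidyr::pivot_wider(names_from = "statistic", values_from = "value") |>
    dplyr::mutate(ensemble = ens_label[.data$unit], .after = "algorithm") |>
    dplyr::select("training_set", "algorithm", "ensemble",
                  "accuracy", "sensitivity", "specificity")
  folds <- m |>
    dplyr::filter(grepl("^fold", .data$unit)) |>
    dplyr::group_by(.data$training_set, .data$algorithm, .data$statistic) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  list(table = tab, fold_summaries = folds)
}
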