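#' Tidy the metrics of an experiment
#'
#' @param x An `sdm_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return The tidy metrics tibble: one row per training set, algorithm,
#'   unit (fold or ensemble) and statistic.
#' @exportS3Method generics::tidy
tidy.sdm_experiment <- function(x, ...) x$metrics

#' One-row summary of an experiment
#'
#' @param x An `sdm_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: map counts, pooled-election settings, and the
#'   grand means of accuracy/sensitivity/specificity over every evaluated
#'   classification map.
#' @exportS3Method generics::glance
glance.sdm_experiment <- function(x, ...) {
  ens <- x$metrics
  grand <- function(stat) mean(ens$value[ens$statistic == stat], na.rm = TRUE)
  tibble::tibble(
    n_evaluated_maps = x$counts$n_evaluated_maps,
    n_training_sets = x$counts$n_training_sets,
    n_algorithms = x$counts$n_algorithms,
    k = x$counts$k,
    collective_members = x$counts$collective_members,
    collective_quorum = x$counts$collective_quorum,
    mean_accuracy = grand("accuracy"),
    mean_sensitivity = grand("sensitivity"),
    mean_specificity = grand("specificity")
  )
}

#' Tidy a fitted suitability model
#'
#' @param x An `sdm_model`.
#' @param ... Unused.
#' @return A tibble of the spec's hyperparameters (one row per setting).
#' @exportS3Method generics::tidy
tidy.sdm_model <- function(x, ...) {
  hp <- x$spec$hyperparameters
  tibble::tibble(term = names(hp),
                 value = vapply(hp, function(v) paste(format(v), collapse = ","),
                                character(1)))
}

#' One-row summary of a fitted suitability model
#'
#' @param x An `sdm_model`.
#' @param ... Unused.
#' @return A one-row tibble: family, seed, fold, class sizes, training AUC.
#' @exportS3Method generics::glance
glance.sdm_model <- function(x, ...) {
  tibble::tibble(
    family = x$spec$family, seed = x$spec$seed, train_fold = x$train_fold,
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$feature_names), train_auc = x$train_auc
  )
}
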