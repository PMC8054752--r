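#' Specify a synthetic landscape
#'
#' Parameters of the simulated study region: grid size, cell size, number of
#' bioclimate-like covariate layers, and the spatial correlation length of
#' the random fields. The defaults describe the package's standard recovery
#' scenario: a 100 x 100 planar grid of 1-km cells with six covariates and a
#' 5-cell smoothing scale, which gives the strong spatial autocorrelation
#' real climate surfaces show.
#'
#' @param rows,cols Grid dimensions (each at least 10).
#' @param cell_km Cell size in km.
#' @param n_covariates Number of covariate layers (besides elevation).
#' @param smoothing_scale Gaussian smoothing standard deviation in cells;
#'   0 gives spatially uncorrelated white noise.
#' @param seed Integer seed.
#' @return A `landscape_spec`.
#' @export
landscape_spec <- function(rows = 100, cols = 100, cell_km = 1,
                           n_covariates = 6, smoothing_scale = 5, seed = 1) {
  if (rows < 10 || cols < 10) stop("landscape must be at least 10 x 10", call. = FALSE)
  if (smoothing_scale < 0) stop("smoothing_scale must be >= 0", call. = FALSE)
  if (is.null(seed) || is.na(seed)) stop("seed must be set", call. = FALSE)
  structure(list(rows = rows, cols = cols, cell_km = cell_km,
                 n_covariates = n_covariates,
                 smoothing_scale = smoothing_scale, seed = as.integer(seed)),
            class = "landscape_spec")
}

# centred 1-D convolution with edge renormalization (kernel mass outside the
# field is dropped, not reflected)
conv1d <- function(x, k) {
  r <- (length(k) - 1) / 2
  n <- length(x)
  xp <- c(rep(0, r), x, rep(0, r))
  wp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- stats::filter(xp, k, sides = 2)
  den <- stats::filter(wp, k, sides = 2)
  as.numeric(num / den)[(r + 1):(r + n)]
}

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  m <- apply(m, 2, conv1d, k = k)
  t(apply(m, 1, conv1d, k = k))
}

#' Generate a spatially autocorrelated covariate landscape
#'
#' Draws seeded white noise per layer and smooths it with a Gaussian kernel
#' of the spec's `smoothing_scale` — a simple stationary random field that
#' reproduces the lag correlation structure of interpolated climate layers.
#' Covariate layers `cov1..covN` are min-max normalized to `[0, 1]`. An
#' `elevation` layer (same smoothing, scaled to 0-2 km of relief) is added,
#' and `slope`, `aspect` and `tri` are derived from it via
#' [terrain_metrics()].
#'
#' @param spec A [landscape_spec()].
#' @param relief_km Elevation range (max minus min) in km.
#' @return A [covariate_stack()] with layers `cov1..covN`, `elevation`,
#'   `slope`, `aspect`, `tri`.
#' @export
generate_landscape <- function(spec, relief_km = 2) {
  stopifnot(inherits(spec, "landscape_spec"))
  make_field <- function(sub) {
    withr::with_seed(derive_seed(spec$seed, sub), {
      m <- matrix(stats::rnorm(spec$rows * spec$cols), spec$rows, spec$cols)
      gaussian_smooth(m, spec$smoothing_scale)
    })
  }
  rescale01 <- function(m) (m - min(m)) / (max(m) - min(m))
  as_layer <- function(m) raster_grid(m, cell_dx = spec$cell_km,
                                      crs_kind = "planar_km")
  layers <- lapply(seq_len(spec$n_covariates), function(i) {
    as_layer(rescale01(make_field(paste0("cov", i))))
  })
  names(layers) <- paste0("cov", seq_len(spec$n_covariates))
  layers$elevation <- as_layer(rescale01(make_field("elevation")) * relief_km)
  terr <- terrain_metrics(layers$elevation, z_scale = 1)
  layers <- c(layers, terr$layers)
  covariate_stack(layers,
                  provenance = stats::setNames(
                    rep("simulated Gaussian random field", length(layers)),
                    names(layers)))
}

#' Define a virtual species response
#'
#' A known truth for parameter-recovery experiments: per-cell suitability is
#' `logistic(beta0 + sum(beta_i * z_i) + sum(gamma_i * z_i^2))` over named
#' covariate layers `z` in `[0, 1]`.
#'
#' @param beta0 Intercept.
#' @param beta Named numeric vector of linear coefficients (names must match
#'   stack layers).
#' @param gamma Named numeric vector of quadratic coefficients, same names
#'   as `beta`.
#' @return A `virtual_species`.
#' @export
virtual_species <- function(beta0 = 0, beta, gamma = 0 * beta) {
  if (is.null(names(beta)) || any(names(beta) == "")) {
    stop("beta must be a named vector of layer coefficients", call. = FALSE)
  }
  gamma <- gamma[names(beta)]
  if (any(is.na(gamma))) gamma[is.na(gamma)] <- 0
  names(gamma) <- names(beta)
  structure(list(beta0 = beta0, beta = beta, gamma = gamma),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' @param stack A [covariate_stack()] containing every layer named in the
#'   species coefficients.
#' @param species A [virtual_species()].
#' @return A `suitability_map` of true occupancy probabilities.
#' @export
true_suitability <- function(stack, species) {
  stopifnot(inherits(stack, "covariate_stack"),
            inherits(species, "virtual_species"))
  missing <- setdiff(names(species$beta), names(stack$layers))
  if (length(missing)) {
    stop("stack lacks layer(s) named in species coefficients: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- stack$layers[[1]]
  eta <- matrix(species$beta0, nrow(g$values), ncol(g$values))
  for (nm in names(species$beta)) {
    z <- stack$layers[[nm]]$values
    eta <- eta + species$beta[[nm]] * z + species$gamma[[nm]] * z^2
  }
  out <- g
  out$values <- logistic(eta)
  structure(out, class = c("suitability_map", "raster_grid"),
            model_id = "true_suitability")
}

#' Sample presence records proportional to suitability
#'
#' Emulates raw occurrence feeds: `n` cells are drawn with probability
#' proportional to the true suitability, each point is placed uniformly
#' within its cell, and `floor(n * duplicate_rate)` records are then
#' duplicated at their exact coordinates so downstream deduplication has
#' work to do.
#'
#' @param truth A `suitability_map` (from [true_suitability()]).
#' @param n Number of distinct presence draws (`>= 1`).
#' @param duplicate_rate Fraction of exact-coordinate duplicates to append,
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble with `id`, `lon`, `lat` (length `n + floor(n *
#'   duplicate_rate)`).
#' @export
sample_presences <- function(truth, n, duplicate_rate = 0, seed = 1) {
  stopifnot(inherits(truth, "raster_grid"), n >= 1,
            duplicate_rate >= 0, duplicate_rate < 1)
  w <- as.vector(truth$values)
  w[is.na(w)] <- 0
  if (all(w == 0)) stop("suitability is zero everywhere; nothing to sample", call. = FALSE)
  withr::with_seed(seed, {
    cells <- sample.int(length(w), n, replace = TRUE, prob = w)
    i <- ((cells - 1) %% nrow(truth$values)) + 1
    j <- ((cells - 1) %/% nrow(truth$values)) + 1
    lon <- truth$origin_x + (j - 1 + stats::runif(n)) * truth$cell_dx
    lat <- truth$origin_y + (i - 1 + stats::runif(n)) * truth$cell_dy
    ndup <- floor(n * duplicate_rate)
    if (ndup > 0) {
      pick <- sample.int(n, ndup, replace = FALSE)
      lon <- c(lon, lon[pick])
      lat <- c(lat, lat[pick])
    }
    tibble::tibble(id = seq_along(lon), lon = lon, lat = lat)
  })
}

#' Threshold the true suitability into a ground-truth range
#'
#' @param truth A `suitability_map`.
#' @param level Suitability cutoff in `(0, 1)`; cells with suitability at or
#'   above it are in range (boundary in).
#' @return A `range_mask` (1/0/NA grid).
#' @export
make_true_range <- function(truth, level = 0.5) {
  stopifnot(inherits(truth, "raster_grid"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  g <- truth
  g$values <- matrix(as.numeric(truth$values >= level),
                     nrow = nrow(truth$values), ncol = ncol(truth$values))
  structure(g, class = c("range_mask", "raster_grid"),
            radius_km = NA_real_, source_count = NA_integer_,
            level = level)
}

#' Simulate a complete virtual-species study
#'
#' Bundles everything one pipeline run needs, all deterministic under one
#' seed: a covariate landscape, the true suitability field, a ground-truth
#' range at `range_level`, raw presences (with planted duplicates), and
#' uniform background points. The defaults are the package's standard
#' recovery scenario: two informative covariates (`cov1` with `beta = +4`,
#' `cov2` with `beta = -4`, both with `gamma = -2`) among four pure-noise
#' covariates, 300 presence draws with 10% duplicates, and 2,000 background
#' points.
#'
#' @param landscape A [landscape_spec()]; its seed is overridden by `seed`.
#' @param species A [virtual_species()]; default as described above.
#' @param n_presence Distinct presence draws.
#' @param n_background Background points.
#' @param duplicate_rate Fraction of planted coordinate duplicates.
#' @param range_level Truth threshold for the ground-truth range.
#' @param seed Master seed.
#' @return A `truth_bundle`: list with `stack`, `true_suitability`,
#'   `true_range`, `presences`, `background`, `species`, `seed`.
#' @export
simulate_truth_bundle <- function(landscape = landscape_spec(),
                                  species = NULL,
                                  n_presence = 300, n_background = 2000,
                                  duplicate_rate = 0.1, range_level = 0.5,
                                  seed = 1) {
  landscape$seed <- derive_seed(seed, "landscape")
  stack <- generate_landscape(landscape)
  if (is.null(species)) {
    nm <- paste0("cov", seq_len(landscape$n_covariates))
    beta <- stats::setNames(rep(0, length(nm)), nm)
    gamma <- beta
    beta[1] <- 4; beta[2] <- -4
    gamma[1] <- -2; gamma[2] <- -2
    species <- virtual_species(beta0 = 0, beta = beta, gamma = gamma)
  }
  truth <- true_suitability(stack, species)
  domain <- stack$layers[[1]]
  domain$values[] <- 1
  structure(
    list(stack = stack,
         true_suitability = truth,
         true_range = make_true_range(truth, range_level),
         presences = sample_presences(truth, n_presence, duplicate_rate,
                                      seed = derive_seed(seed, "presences")),
         background = sample_background(domain, n_background,
                                        seed = derive_seed(seed, "background")),
         species = species,
         seed = seed),
    class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  g <- x$stack$layers[[1]]
  cat(sprintf(
    "<truth_bundle> %d x %d grid, %d layers, %d presence records, %d background points (seed %d)\n",
    nrow(g$values), ncol(g$values), length(x$stack$layers),
    nrow(x$presences), nrow(x$background), x$seed))
  invisible(x)
}
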