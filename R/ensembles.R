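#' Binary classification maps
#'
#' A `binary_map` is a [raster_grid()] whose cells take one of four states:
#' `1` suitable, `0` unsuitable, `2` no consensus (unanimity ensembles only;
#' excluded from confusion statistics), `NA` nodata. Provenance (member ids
#' and the rule that produced the map) travels in the `provenance` attribute.
#'
#' @param grid A [raster_grid()] with values in `{0, 1, 2, NA}`.
#' @param provenance A list describing members and rule.
#' @return A `binary_map`.
#' @keywords internal
new_binary_map <- function(grid, provenance = list()) {
  structure(grid, class = c("binary_map", "raster_grid"),
            provenance = provenance)
}

#' @export
print.binary_map <- function(x, ...) {
  v <- as.vector(x$values)
  cat(sprintf(
    "<binary_map> %d suitable / %d unsuitable / %d no-consensus / %d nodata [%s]\n",
    sum(v == 1, na.rm = TRUE), sum(v == 0, na.rm = TRUE),
    sum(v == 2, na.rm = TRUE), sum(is.na(v)),
    attr(x, "provenance")$rule %||% "binarize"))
  invisible(x)
}

#' Binarize a suitability map at a threshold
#'
#' A cell is suitable iff its score is at least the threshold (boundary
#' suitable); nodata is preserved.
#'
#' @param map A `suitability_map` (or any [raster_grid()] of scores).
#' @param threshold Cutoff in `[0, 1]`, typically from [optimal_threshold()].
#' @return A `binary_map`.
#' @export
binarize <- function(map, threshold) {
  stopifnot(inherits(map, "raster_grid"),
            is.numeric(threshold), threshold >= 0, threshold <= 1)
  g <- map
  g$values <- matrix(as.numeric(map$values >= threshold),
                     nrow = nrow(map$values), ncol = ncol(map$values))
  class(g) <- "raster_grid"
  new_binary_map(g, list(rule = "binarize", threshold = threshold,
                         members = attr(map, "model_id")))
}

member_values <- function(maps, forbid_no_consensus = FALSE) {
  stopifnot(length(maps) >= 1)
  ok <- vapply(maps, inherits, logical(1), what = "raster_grid")
  if (!all(ok)) stop("all members must be raster maps", call. = FALSE)
  stopifnot_same_geometry(maps, "ensemble members")
  v <- vapply(maps, function(m) as.vector(m$values),
              numeric(length(maps[[1]]$values)))
  v <- matrix(v, ncol = length(maps))
  if (forbid_no_consensus && any(v == 2, na.rm = TRUE)) {
    stop("vote members must be forced-binary (no no-consensus cells)",
         call. = FALSE)
  }
  v
}

#' Mean ensemble of suitability maps
#'
#' Averages the per-cell predicted value across the fold maps and binarizes
#' the averaged surface at the average of the fold thresholds. A cell that is
#' nodata in any member is nodata.
#'
#' @param maps List of `suitability_map`s on one geometry.
#' @param thresholds Numeric vector, one threshold per map.
#' @return A `binary_map`.
#' @export
mean_ensemble <- function(maps, thresholds) {
  if (length(thresholds) != length(maps)) {
    stop("need exactly one threshold per member map", call. = FALSE)
  }
  v <- member_values(maps)
  g <- maps[[1]]
  g$values <- matrix(rowMeans(v),  # rowMeans propagates any member NA
                     nrow = nrow(g$values), ncol = ncol(g$values))
  class(g) <- "raster_grid"
  out <- binarize(g, mean(thresholds))
  attr(out, "provenance") <- list(rule = "mean", threshold = mean(thresholds),
                                  n_members = length(maps))
  out
}

#' Mean suitability surface across fold maps
#'
#' The continuous counterpart of [mean_ensemble()]: the cellwise average of
#' the member suitability maps, useful for inspecting the pooled surface or
#' comparing it with a known truth.
#'
#' @param maps List of `suitability_map`s on one geometry.
#' @return A `suitability_map`.
#' @export
mean_suitability <- function(maps) {
  v <- member_values(maps)
  g <- maps[[1]]
  g$values <- matrix(rowMeans(v), nrow = nrow(g$values), ncol = ncol(g$values))
  structure(g, class = c("suitability_map", "raster_grid"),
            model_id = sprintf("mean_of_%d", length(maps)))
}

#' Majority-vote election ensemble
#'
#' Each member binary map casts one vote per cell; the cell is suitable iff
#' at least `quorum` members vote suitable, otherwise unsuitable. The default
#' quorum is a simple majority — 3 of 5 fold maps, 13 of 25 pooled models.
#' Nodata wherever any member is nodata.
#'
#' @param maps List of forced-binary `binary_map`s on one geometry.
#' @param quorum Votes required for suitability, in `1..m`.
#' @return A `binary_map`.
#' @export
vote_ensemble <- function(maps, quorum = ceiling((length(maps) + 1) / 2)) {
  m <- length(maps)
  if (quorum < 1 || quorum > m) {
    stop("quorum must lie in 1..", m, call. = FALSE)
  }
  v <- member_values(maps, forbid_no_consensus = TRUE)
  g <- maps[[1]]
  g$values <- matrix(as.numeric(rowSums(v) >= quorum),
                     nrow = nrow(g$values), ncol = ncol(g$values))
  class(g) <- "raster_grid"
  new_binary_map(g, list(rule = "majority_vote", quorum = quorum,
                         n_members = m))
}

#' Unanimous-decision election ensemble
#'
#' A cell is suitable only where every member votes suitable and unsuitable
#' only where every member votes unsuitable. By default contested cells are
#' assigned `no_consensus` (state 2) and excluded from confusion statistics
#' downstream — the reading under which a unanimity ensemble can be *more*
#' sensitive than a majority vote, because it is only ever scored on the
#' cells it is certain about. With `forced_binary = TRUE` contested cells
#' are classed unsuitable instead, which restores the strict nesting
#' UD-suitable \eqn{\subseteq} MV-suitable.
#'
#' @param maps List of forced-binary `binary_map`s on one geometry.
#' @param forced_binary If `TRUE`, contested cells become unsuitable rather
#'   than `no_consensus`.
#' @return A `binary_map`.
#' @export
unanimous_ensemble <- function(maps, forced_binary = FALSE) {
  v <- member_values(maps, forbid_no_consensus = TRUE)
  all1 <- rowSums(v == 1) == ncol(v)
  all0 <- rowSums(v == 0) == ncol(v)
  out <- rep(if (forced_binary) 0 else 2, nrow(v))
  out[all1] <- 1
  out[all0] <- 0
  out[rowSums(is.na(v)) > 0] <- NA
  g <- maps[[1]]
  g$values <- matrix(out, nrow = nrow(g$values), ncol = ncol(g$values))
  class(g) <- "raster_grid"
  new_binary_map(g, list(rule = "unanimous", forced_binary = forced_binary,
                         n_members = length(maps)))
}
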