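#' Remove exact coordinate duplicates from an occurrence table
#'
#' Citizen-science occurrence feeds routinely contain many records at the
#' identical longitude/latitude (repeat visits, checklist duplicates).
#' Exactly one record is kept per distinct coordinate pair — the first in
#' input order — matching the convention of filtering occurrences that share
#' coordinates before model building. Comparison is exact equality, no
#' rounding. Records with non-numeric or missing coordinates are rejected
#' with a warning.
#'
#' @param occ A data frame with columns `lon` and `lat` (an `id` column is
#'   created from row order when absent).
#' @return A tibble with columns `id`, `lon`, `lat`, deduplicated. The number
#'   of removed duplicates is reported via `message()`.
#' @export
deduplicate <- function(occ) {
  occ <- tibble::as_tibble(occ)
  if (!all(c("lon", "lat") %in% names(occ))) {
    stop("occurrence table must have 'lon' and 'lat' columns", call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(occ$lon))
  lat <- suppressWarnings(as.numeric(occ$lat))
  bad <- !is.finite(lon) | !is.finite(lat)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-numeric coordinates rejected",
            call. = FALSE)
  }
  id <- if ("id" %in% names(occ)) occ$id else seq_len(nrow(occ))
  out <- tibble::tibble(id = id[!bad], lon = lon[!bad], lat = lat[!bad])
  dup <- duplicated(out[, c("lon", "lat")])
  if (any(dup)) message(sum(dup), " duplicate coordinate pair(s) removed")
  out[!dup, ]
}

#' Test points against a polygon (boundary counts as inside)
#'
#' Even-odd crossing-number test with an explicit point-on-segment check so
#' boundary points are retained.
#'
#' @param lon,lat Point coordinates.
#' @param polygon Two-column matrix or data frame of vertex `lon`, `lat`
#'   (closed or open ring).
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(lon, lat, polygon) {
  polygon <- as.matrix(polygon[, 1:2])
  storage.mode(polygon) <- "double"
  if (nrow(polygon) >= 2 &&
      all(polygon[1, ] == polygon[nrow(polygon), ])) {
    polygon <- polygon[-nrow(polygon), , drop = FALSE]
  }
  if (nrow(polygon) < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  px <- polygon[, 1]; py <- polygon[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  if (any(px == qx & py == qy)) stop("polygon has zero-length edges", call. = FALSE)

  vapply(seq_along(lon), function(k) {
    x <- lon[k]; y <- lat[k]
    # on-boundary check
    cross <- (qx - px) * (y - py) - (qy - py) * (x - px)
    within <- pmin(px, qx) - 1e-12 <= x & x <= pmax(px, qx) + 1e-12 &
      pmin(py, qy) - 1e-12 <= y & y <= pmax(py, qy) + 1e-12
    if (any(abs(cross) < 1e-12 & within)) return(TRUE)
    # even-odd ray crossing to the right
    crosses <- ((py > y) != (qy > y)) &
      (x < px + (y - py) * (qx - px) / (qy - py))
    sum(crosses) %% 2 == 1
  }, logical(1))
}

#' Subset occurrences to a polygonal region
#'
#' Keeps exactly the records whose coordinates fall inside (or on the
#' boundary of) the polygon — the device used to build a sub-region training
#' set from one part of the naturalized range.
#'
#' @param occ Occurrence tibble with `lon`, `lat` (e.g. from
#'   [deduplicate()]).
#' @param region Polygon as a two-column matrix/data frame of vertices, or a
#'   region read by [read_region_geojson()].
#' @return The subset tibble, same columns as `occ`.
#' @export
subset_by_region <- function(occ, region) {
  occ <- tibble::as_tibble(occ)
  keep <- point_in_polygon(occ$lon, occ$lat, region)
  occ[keep, ]
}

#' Sample uniform background points over a domain mask
#'
#' Presence-background designs contrast occurrences against randomly placed
#' background (pseudo-absence) points. Cells where the mask is true are
#' sampled with equal probability and each point is placed uniformly within
#' its cell, so the points are uniform over the masked area. Background
#' points are not filtered against presence locations; collisions are
#' possible and harmless.
#'
#' @param domain A [raster_grid()] whose values are interpreted as a logical
#'   mask (`NA`/0 = excluded, non-zero = in-domain).
#' @param n Number of points (default 10,000, the scale typically used for
#'   continental presence-background models).
#' @param seed Integer seed; identical seeds give identical points.
#' @return A tibble with columns `lon`, `lat` and attributes `seed`,
#'   `n_requested`.
#' @export
sample_background <- function(domain, n = 10000, seed = 1) {
  stopifnot(inherits(domain, "raster_grid"), n >= 0)
  ok <- which(!is.na(domain$values) & domain$values != 0)
  if (n > 0 && length(ok) == 0) stop("domain mask has no true cells", call. = FALSE)
  pts <- withr::with_seed(seed, {
    if (n == 0) {
      tibble::tibble(lon = numeric(0), lat = numeric(0))
    } else {
      cells <- ok[sample.int(length(ok), n, replace = TRUE)]
      i <- ((cells - 1) %% nrow(domain$values)) + 1
      j <- ((cells - 1) %/% nrow(domain$values)) + 1
      tibble::tibble(
        lon = domain$origin_x + (j - 1 + stats::runif(n)) * domain$cell_dx,
        lat = domain$origin_y + (i - 1 + stats::runif(n)) * domain$cell_dy
      )
    }
  })
  attr(pts, "seed") <- seed
  attr(pts, "n_requested") <- n
  pts
}

#' Assign balanced cross-validation folds to presences
#'
#' Seeded random partition of the presence records into `k` folds whose sizes
#' differ by at most one. For each fold the training presences are every
#' record outside it and the test presences those inside it; the background
#' set is attached in full to both sides of every fold (backgrounds are never
#' held out in this design, which trades an optimistic evaluation for maximal
#' environmental coverage per fold).
#'
#' @param occ Occurrence tibble with an `id` column (see [deduplicate()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A tibble with columns `id` and `fold` (integer in `1..k`).
#' @export
kfold_split <- function(occ, k = 5, seed = 1) {
  occ <- tibble::as_tibble(occ)
  n <- nrow(occ)
  if (n < k) stop("need at least k = ", k, " records, got ", n, call. = FALSE)
  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  tibble::tibble(id = occ$id, fold = as.integer(fold))
}
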