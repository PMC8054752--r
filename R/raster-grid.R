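#' Construct a raster grid
#'
#' A `raster_grid` is the package's lightweight single-band raster: a numeric
#' matrix plus the geometry needed to place it. Row 1 of `values` is the
#' *southernmost* row, so `values[i, j]` sits at centre
#' `(origin_x + (j - 0.5) * cell_dx, origin_y + (i - 0.5) * cell_dy)`.
#' Missing cells are stored as `NA` (the nodata sentinel is only used at I/O
#' time).
#'
#' @param values Numeric matrix (rows x cols), row 1 = bottom row.
#' @param origin_x,origin_y Coordinates of the grid's lower-left corner.
#' @param cell_dx,cell_dy Positive cell sizes, in the units of `crs_kind`.
#' @param crs_kind Either `"planar_km"` (coordinates and cell sizes in km) or
#'   `"geographic_deg"` (degrees of longitude/latitude).
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin_x = 0, origin_y = 0,
                        cell_dx = 1, cell_dy = cell_dx,
                        crs_kind = c("planar_km", "geographic_deg")) {
  crs_kind <- match.arg(crs_kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("raster_grid needs at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(cell_dx) || !is.numeric(cell_dy) ||
      cell_dx <= 0 || cell_dy <= 0) {
    stop("cell sizes must be positive", call. = FALSE)
  }
  structure(
    list(values = values,
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_dx = as.numeric(cell_dx), cell_dy = as.numeric(cell_dy),
         crs_kind = crs_kind),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_grid> %d x %d cells (%s, dx=%g dy=%g)\n",
              nrow(x$values), ncol(x$values), x$crs_kind, x$cell_dx, x$cell_dy))
  if (length(v)) {
    cat(sprintf("  values: min %.4g  mean %.4g  max %.4g  (%d nodata)\n",
                min(v), mean(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_dx - b$cell_dx) < tol && abs(a$cell_dy - b$cell_dy) < tol &&
    identical(a$crs_kind, b$crs_kind)
}

stopifnot_same_geometry <- function(grids, what = "grids") {
  ok <- vapply(grids[-1], grid_same_geometry, logical(1), a = grids[[1]])
  if (!all(ok)) stop(what, " do not share grid geometry", call. = FALSE)
  invisible(TRUE)
}

#' Cell centre coordinates of a raster grid
#'
#' @param grid A [raster_grid()].
#' @return A tibble with `row`, `col`, `x`, `y`, `value`, one row per cell in
#'   column-major order.
#' @export
grid_cells <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    x = grid$origin_x + (rep(seq_len(nc), each = nr) - 0.5) * grid$cell_dx,
    y = grid$origin_y + (rep(seq_len(nr), times = nc) - 0.5) * grid$cell_dy,
    value = as.vector(grid$values)
  )
}

#' Locate the cell containing each point
#'
#' A point lies in cell `(i, j)` iff it falls in the half-open rectangle
#' `[x_left, x_right) x [y_bottom, y_top)`. Points outside the grid extent get
#' `NA` indices.
#'
#' @param grid A [raster_grid()].
#' @param x,y Point coordinates (same units as the grid).
#' @return A tibble with integer columns `row` and `col` (`NA` outside extent).
#' @export
cell_index <- function(grid, x, y) {
  j <- floor((x - grid$origin_x) / grid$cell_dx) + 1
  i <- floor((y - grid$origin_y) / grid$cell_dy) + 1
  bad <- i < 1 | i > nrow(grid$values) | j < 1 | j > ncol(grid$values) |
    is.na(x) | is.na(y)
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  tibble::tibble(row = as.integer(i), col = as.integer(j))
}

#' Build a covariate stack
#'
#' An ordered, named collection of [raster_grid()] layers sharing one
#' geometry: the feature source for every model in the pipeline. A
#' real-data stack typically holds the 19 bioclimatic layers plus elevation,
#' slope, aspect and terrain ruggedness.
#'
#' @param layers Named list of `raster_grid` objects (unique names).
#' @param provenance Optional named character vector of free-text provenance.
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers, provenance = NULL) {
  if (length(layers) == 0) stop("covariate_stack needs at least one layer", call. = FALSE)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layers must have unique, non-empty names", call. = FALSE)
  }
  ok <- vapply(layers, inherits, logical(1), what = "raster_grid")
  if (!all(ok)) stop("all layers must be raster_grid objects", call. = FALSE)
  stopifnot_same_geometry(layers, "stack layers")
  structure(list(layers = layers, provenance = provenance),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<covariate_stack> %d layers on a %d x %d grid (%s)\n",
              length(x$layers), nrow(g$values), ncol(g$values), g$crs_kind))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
names.covariate_stack <- function(x) names(x$layers)

#' Min-max normalize every layer of a stack to [0, 1]
#'
#' Each layer is rescaled as `(x - min) / (max - min)` over its non-nodata
#' cells, so covariates enter the learners with equal weight. Constant layers
#' cannot be rescaled and are set to all-0 with a warning rather than
#' erroring, so degenerate simulated layers do not abort a run. Nodata cells
#' are preserved.
#'
#' @param stack A [covariate_stack()] whose layers each have at least one
#'   non-nodata cell.
#' @return A `covariate_stack` with all non-nodata values in `[0, 1]`;
#'   non-constant layers attain 0 and 1 exactly.
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  out <- lapply(names(stack$layers), function(nm) {
    g <- stack$layers[[nm]]
    v <- g$values
    finite <- v[!is.na(v)]
    if (length(finite) == 0) {
      stop("layer '", nm, "' has no non-nodata cells", call. = FALSE)
    }
    lo <- min(finite); hi <- max(finite)
    if (hi == lo) {
      warning("layer '", nm, "' is constant; normalized to all-0", call. = FALSE)
      g$values[!is.na(v)] <- 0
    } else {
      g$values <- (v - lo) / (hi - lo)
    }
    g
  })
  names(out) <- names(stack$layers)
  covariate_stack(out, provenance = stack$provenance)
}

#' Extract per-point covariate features from a stack
#'
#' Maps each point to its containing cell (half-open cell rectangles, see
#' [cell_index()]) and reads every layer's value there. Points outside the
#' grid extent are dropped with a warning; rows that hit a nodata cell in any
#' layer are dropped and their count reported.
#'
#' @param stack A (typically normalized) [covariate_stack()].
#' @param points A data frame with numeric `lon` and `lat` columns (grid
#'   units: km for planar grids, degrees for geographic).
#' @param label Label attached to every retained row, e.g. `"presence"` or
#'   `"background"`.
#' @return A tibble with columns `lon`, `lat`, `label`, then one column per
#'   stack layer in stack order.
#' @export
extract_features <- function(stack, points, label = "presence") {
  stopifnot(inherits(stack, "covariate_stack"))
  points <- tibble::as_tibble(points)
  if (!all(c("lon", "lat") %in% names(points))) {
    stop("points must have 'lon' and 'lat' columns", call. = FALSE)
  }
  g <- stack$layers[[1]]
  idx <- cell_index(g, points$lon, points$lat)
  inside <- !is.na(idx$row)
  if (!any(inside)) stop("all points fall outside the grid extent", call. = FALSE)
  if (any(!inside)) {
    warning(sum(!inside), " point(s) outside the grid extent dropped", call. = FALSE)
  }
  keep <- which(inside)
  lin <- cbind(idx$row[keep], idx$col[keep])
  feats <- vapply(stack$layers, function(l) l$values[lin], numeric(length(keep)))
  feats <- matrix(feats, nrow = length(keep),
                  dimnames = list(NULL, names(stack$layers)))
  complete <- stats::complete.cases(feats)
  if (any(!complete)) {
    message(sum(!complete), " point(s) in nodata cells dropped")
  }
  dplyr::bind_cols(
    tibble::tibble(lon = points$lon[keep][complete],
                   lat = points$lat[keep][complete],
                   label = label),
    tibble::as_tibble(feats[complete, , drop = FALSE])
  )
}
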