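#' Read and write rasters as ESRI ASCII grids
#'
#' Layers travel as plain-text ESRI ASCII grid (`.asc`) files: a six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values, north row first. The
#' format requires square cells. Layer name = file stem.
#'
#' @param grid A [raster_grid()] with `cell_dx == cell_dy`.
#' @param path Output `.asc` path.
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  if (abs(grid$cell_dx - grid$cell_dy) > 1e-12) {
    stop("ASCII grid format requires square cells", call. = FALSE)
  }
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$origin_x, digits = 15)),
    paste("yllcorner", format(grid$origin_y, digits = 15)),
    paste("cellsize", format(grid$cell_dx, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  # rows are stored south-first internally, written north-first
  utils::write.table(v[rev(seq_len(nrow(v))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs_kind Coordinate interpretation of the file (the format itself
#'   does not record one).
#' @return For `read_ascii_grid`, a [raster_grid()].
#' @export
read_ascii_grid <- function(path, crs_kind = c("planar_km", "geographic_deg")) {
  crs_kind <- match.arg(crs_kind)
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  if (nrow(v) != h[["nrows"]] || ncol(v) != h[["ncols"]]) {
    stop("ASCII grid body does not match its header dimensions", call. = FALSE)
  }
  v[v == h[["nodata_value"]]] <- NA
  raster_grid(v[rev(seq_len(nrow(v))), , drop = FALSE],
              origin_x = h[["xllcorner"]], origin_y = h[["yllcorner"]],
              cell_dx = h[["cellsize"]], crs_kind = crs_kind)
}

#' Read or write a covariate stack as a directory of ASCII grids
#'
#' @param stack A [covariate_stack()].
#' @param dir Directory holding one `.asc` file per layer.
#' @return `write_stack` returns `dir` invisibly; `read_stack` returns a
#'   [covariate_stack()] with layers in alphabetical file order.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "covariate_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  invisible(dir)
}

#' @rdname write_stack
#' @inheritParams read_ascii_grid
#' @export
read_stack <- function(dir, crs_kind = c("planar_km", "geographic_deg")) {
  crs_kind <- match.arg(crs_kind)
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0) stop("no .asc layers found in ", dir, call. = FALSE)
  layers <- lapply(files, read_ascii_grid, crs_kind = crs_kind)
  names(layers) <- sub("\\.asc$", "", basename(files))
  covariate_stack(layers)
}

#' Read and write occurrence tables
#'
#' Occurrences are CSV files with a header and columns `id`, `lon`, `lat`
#' (`id` is created from row order when missing).
#'
#' @param path CSV path.
#' @return A tibble with `id`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("lon", "lat") %in% names(d))) {
    stop("occurrence CSV must have 'lon' and 'lat' columns", call. = FALSE)
  }
  if (!"id" %in% names(d)) d$id <- seq_len(nrow(d))
  d[, c("id", "lon", "lat")]
}

#' @rdname read_occurrences
#' @param occ Occurrence tibble.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' Read a polygonal region from GeoJSON
#'
#' Accepts a `Polygon` geometry, a `Feature` wrapping one, or a
#' `FeatureCollection` whose first feature is a polygon. Only the outer ring
#' is used; holes are ignored.
#'
#' @param path GeoJSON file path.
#' @return A two-column matrix of vertex `lon`, `lat`.
#' @export
read_region_geojson <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  geom <- switch(g$type %||% "",
                 FeatureCollection = g$features$geometry,
                 Feature = g$geometry,
                 Polygon = g,
                 stop("unsupported GeoJSON type: ", g$type, call. = FALSE))
  type <- geom$type[[1]]
  if (!identical(type, "Polygon")) {
    stop("region must be a Polygon geometry, got ", type, call. = FALSE)
  }
  coords <- geom$coordinates
  # fromJSON renders a single polygon's rings as an array [ring, vertex, xy]
  if (is.list(coords)) coords <- coords[[1]]
  ring <- if (length(dim(coords)) == 3) coords[1, , ] else coords
  ring <- matrix(as.numeric(ring), ncol = 2,
                 dimnames = list(NULL, c("lon", "lat")))
  if (nrow(ring) < 4) stop("polygon ring has too few vertices", call. = FALSE)
  ring
}

#' Write a range mask with its JSON sidecar
#'
#' The mask is written as an ASCII grid (1 = in range, 0 = out, nodata
#' elsewhere) together with `<path>.json` recording the buffer radius and
#' the number of source occurrences.
#'
#' @param mask A `range_mask`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_range_mask <- function(mask, path) {
  stopifnot(inherits(mask, "range_mask"))
  write_ascii_grid(mask, paste0(path, ".asc"))
  jsonlite::write_json(
    list(radius_km = attr(mask, "radius_km"),
         source_count = attr(mask, "source_count")),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
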