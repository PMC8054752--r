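#' Terrain derivatives: slope, aspect, and ruggedness
#'
#' Computes the three topographic covariates used alongside elevation:
#' * **slope** (degrees, `[0, 90)`) and **aspect** (degrees clockwise from
#'   north, `[0, 360)`, downslope direction; flat cells report 0) via Horn's
#'   8-neighbour finite-difference method;
#' * **tri**, the Terrain Ruggedness Index: the mean absolute elevation
#'   difference between a cell and its (available) 8 neighbours.
#'
#' Edge cells use the neighbours that exist: the TRI average runs over the
#' actual neighbours, and the Horn stencil is completed by edge replication,
#' so a locally constant 3x3 neighbourhood always yields slope = tri = 0.
#'
#' For `planar_km` grids the horizontal distances are the cell sizes in km
#' and elevation is expected in the same unit times `z_scale` (use
#' `z_scale = 1e-3` for metres). For `geographic_deg` grids cell sizes are
#' converted to km, with the east-west size scaled by `cos(latitude)` of each
#' cell row.
#'
#' @param elevation A [raster_grid()] of at least 3 x 3 cells.
#' @param z_scale Multiplier taking elevation values to kilometres
#'   (default 1, i.e. elevation already in km).
#' @return A [covariate_stack()] with layers `slope`, `aspect`, `tri` on the
#'   elevation grid's geometry.
#' @export
terrain_metrics <- function(elevation, z_scale = 1) {
  stopifnot(inherits(elevation, "raster_grid"))
  z <- elevation$values * z_scale
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("elevation grid must be at least 3 x 3", call. = FALSE)

  km_per_deg <- pi * 6371 / 180
  if (elevation$crs_kind == "geographic_deg") {
    lat <- elevation$origin_y + (seq_len(nr) - 0.5) * elevation$cell_dy
    dx_row <- elevation$cell_dx * km_per_deg * pmax(cos(lat * pi / 180), 1e-9)
    dy <- elevation$cell_dy * km_per_deg
  } else {
    dx_row <- rep(elevation$cell_dx, nr)
    dy <- elevation$cell_dy
  }

  # replicate-padded copy: pad[i+1, j+1] == z[i, j]
  pad <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(di, dj) pad[seq_len(nr) + 1 + di, seq_len(nc) + 1 + dj]
  zN <- sh(1, 0); zS <- sh(-1, 0); zE <- sh(0, 1); zW <- sh(0, -1)
  zNE <- sh(1, 1); zNW <- sh(1, -1); zSE <- sh(-1, 1); zSW <- sh(-1, -1)

  gx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * dx_row)
  gy <- ((zNE + 2 * zN + zNW) - (zSE + 2 * zS + zSW)) / (8 * dy)

  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[gx == 0 & gy == 0] <- 0

  # TRI over actual neighbours only
  absdiff <- function(m) { d <- abs(m - z); d }
  stackd <- array(c(absdiff(zN), absdiff(zS), absdiff(zE), absdiff(zW),
                    absdiff(zNE), absdiff(zNW), absdiff(zSE), absdiff(zSW)),
                  dim = c(nr, nc, 8))
  # mask padded (replicated) neighbours out of the TRI mean at the border
  avail <- array(1, dim = c(nr, nc, 8))
  has_n <- row(z) < nr; has_s <- row(z) > 1
  has_e <- col(z) < nc; has_w <- col(z) > 1
  avail[, , 1] <- has_n; avail[, , 2] <- has_s
  avail[, , 3] <- has_e; avail[, , 4] <- has_w
  avail[, , 5] <- has_n & has_e; avail[, , 6] <- has_n & has_w
  avail[, , 7] <- has_s & has_e; avail[, , 8] <- has_s & has_w
  tri <- apply(stackd * avail, c(1, 2), sum) / apply(avail, c(1, 2), sum)
  tri <- tri / z_scale  # report TRI in the input elevation unit

  na <- is.na(z)
  slope[na] <- NA; aspect[na] <- NA; tri[na] <- NA

  as_layer <- function(v) {
    g <- elevation
    g$values <- v
    g
  }
  covariate_stack(list(slope = as_layer(slope),
                       aspect = as_layer(aspect),
                       tri = as_layer(tri)))
}
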