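#' Define a regular analysis grid
#'
#' The pollution surfaces and the synthetic worlds live on a regular planar
#' grid of square cells (1 km by default, matching the spatial granularity of
#' hourly air-quality monitoring products). Cell `(0,0)` sits at the origin
#' corner; cells are indexed row-major with half-open extents
#' `[x0 + c*cell, x0 + (c+1)*cell)`.
#'
#' @param origin_x,origin_y planar coordinates (meters) of the grid's
#'   lower-left corner.
#' @param n_rows,n_cols number of rows (y direction) and columns (x direction).
#' @param cell_m cell edge length in meters (default 1000).
#' @return An object of class `mob_grid`.
#' @export
make_grid <- function(origin_x = 0, origin_y = 0, n_rows, n_cols,
                      cell_m = 1000) {
  if (n_rows < 1 || n_cols < 1 || cell_m <= 0)
    stop_param("grid must have positive dimensions and cell size")
  structure(list(origin_x = origin_x, origin_y = origin_y,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_m = cell_m),
            class = "mob_grid")
}

#' @export
print.mob_grid <- function(x, ...) {
  cat(sprintf("<mob_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_m, x$origin_x, x$origin_y))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Locate the grid cell containing a point
#'
#' Uses the half-open cell convention: a point exactly on a cell's upper
#' boundary belongs to the next cell. Points outside the grid are clamped to
#' the nearest boundary cell and counted via the `"n_outside"` attribute.
#'
#' @param x,y point coordinates (meters); vectors of equal length.
#' @param grid a [make_grid()] object.
#' @return Integer vector of 1-based row-major cell ids, with attribute
#'   `n_outside` giving the number of clamped points.
#' @export
locate_cell <- function(x, y, grid) {
  col <- floor((x - grid$origin_x) / grid$cell_m)
  row <- floor((y - grid$origin_y) / grid$cell_m)
  outside <- col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  col <- pmin(pmax(col, 0), grid$n_cols - 1)
  row <- pmin(pmax(row, 0), grid$n_rows - 1)
  ids <- as.integer(row * grid$n_cols + col + 1)
  attr(ids, "n_outside") <- sum(outside)
  ids
}

#' Coordinates of cell centers
#'
#' @param grid a [make_grid()] object.
#' @param cells optional integer cell ids (default: all cells in id order).
#' @return A data.frame with columns `cell`, `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(grid, cells = seq_len(n_cells(grid))) {
  idx <- as.integer(cells) - 1L
  row <- idx %/% grid$n_cols
  col <- idx %% grid$n_cols
  data.frame(cell = as.integer(cells), row = row, col = col,
             x = grid$origin_x + (col + 0.5) * grid$cell_m,
             y = grid$origin_y + (row + 0.5) * grid$cell_m)
}

# ---- zoning ----------------------------------------------------------------

#' Grid-block zones
#'
#' Fallback zoning when no subdistrict polygons are available: square blocks
#' of `block_cells` x `block_cells` grid cells act as zones, so the
#' Jaccard/clustering stage stays well-defined on purely synthetic worlds.
#'
#' @param grid a [make_grid()] object.
#' @param block_cells zone edge length in cells (default 1: each 1-km cell is
#'   its own zone).
#' @return A `mob_zones` object.
#' @export
make_grid_zones <- function(grid, block_cells = 1L) {
  if (block_cells < 1) stop_param("block_cells must be >= 1")
  structure(list(type = "grid", grid = grid,
                 block_cells = as.integer(block_cells)),
            class = "mob_zones")
}

#' Read subdistrict zones from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (or single-ring MultiPolygon)
#' features carrying a `zone_id` property. Only the outer ring of each
#' polygon is used.
#'
#' @param path path to a GeoJSON file.
#' @return A `mob_zones` object.
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0)
    stop_param("GeoJSON has no features: ", path)
  polys <- list(); ids <- integer(0)
  for (f in feats) {
    id <- f$properties$zone_id
    if (is.null(id)) stop_param("zone feature missing zone_id property")
    geom <- f$geometry
    ring <- switch(geom$type,
                   Polygon = geom$coordinates[[1]],
                   MultiPolygon = geom$coordinates[[1]][[1]],
                   stop_param("unsupported geometry type: ", geom$type))
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    polys[[length(polys) + 1L]] <- m
    ids <- c(ids, as.integer(id))
  }
  o <- order(ids)
  structure(list(type = "poly", ids = ids[o], polys = polys[o]),
            class = "mob_zones")
}

#' @export
print.mob_zones <- function(x, ...) {
  if (x$type == "grid")
    cat(sprintf("<mob_zones> grid blocks of %d cell(s)\n", x$block_cells))
  else
    cat(sprintf("<mob_zones> %d polygon zones\n", length(x$ids)))
  invisible(x)
}

# Even-odd (ray casting) point-in-polygon; points exactly on an edge count as
# inside, so boundary points resolve to the lowest-id zone containing them.
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j[i]]; yj <- ys[j[i]]
    # on-segment check
    dx <- xj - xi; dy <- yj - yi
    cross <- (px - xi) * dy - (py - yi) * dx
    if (abs(cross) < 1e-9 * max(1, abs(dx), abs(dy))) {
      if (px >= min(xi, xj) - 1e-12 && px <= max(xi, xj) + 1e-12 &&
          py >= min(yi, yj) - 1e-12 && py <= max(yi, yj) + 1e-12)
        return(TRUE)
    }
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Zone id of points
#'
#' For polygon zones, zones are tested in increasing `zone_id` order so a
#' point on a shared boundary is deterministically assigned to the zone with
#' the lowest id. Points in no polygon fall into the sentinel "outside" zone
#' `-1L`.
#'
#' @param x,y point coordinates (vectors).
#' @param zones a `mob_zones` object.
#' @return Integer vector of zone ids.
#' @export
zone_of <- function(x, y, zones) {
  if (zones$type == "grid") {
    g <- zones$grid
    cells <- locate_cell(x, y, g)
    idx <- cells - 1L
    brow <- (idx %/% g$n_cols) %/% zones$block_cells
    bcol <- (idx %% g$n_cols) %/% zones$block_cells
    nbc <- ceiling(g$n_cols / zones$block_cells)
    return(as.integer(brow * nbc + bcol + 1L))
  }
  vapply(seq_along(x), function(k) {
    for (i in seq_along(zones$ids))
      if (point_in_poly(x[k], y[k], zones$polys[[i]])) return(zones$ids[i])
    -1L
  }, integer(1))
}
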