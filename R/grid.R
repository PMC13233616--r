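## Equal-area grid system -----------------------------------------------------
##
## Cells are squares of cell_km x cell_km in a cylindrical equal-area
## projection configured from the data extent, so all cell areas are equal
## by construction. Cell ids are row-major starting at the south-west
## corner (row 1 = southernmost), stable across write/read round trips.

EARTH_RADIUS_KM <- 6371.0088

#' Cylindrical equal-area projection
#'
#' Forward/inverse Lambert cylindrical equal-area projection with a central
#' meridian `lon0` and standard parallel `lat_ts` (both degrees). Exactly
#' area-preserving, which is all the gridding needs; no named CRS registry
#' is involved.
#'
#' @param lon0 central meridian in degrees.
#' @param lat_ts standard parallel in degrees.
#' @return an object of class `div_projection` with `$forward(lon, lat)` and
#'   `$inverse(x, y)` (km in, km out).
#' @export
equal_area_projection <- function(lon0 = 0, lat_ts = 30) {
  k <- cos(lat_ts * pi / 180)
  if (k <= 0) stop_invalid("lat_ts must be strictly between -90 and 90")
  structure(list(
    lon0 = lon0, lat_ts = lat_ts,
    forward = function(lon, lat) {
      list(x = EARTH_RADIUS_KM * ((lon - lon0) * pi / 180) * k,
           y = EARTH_RADIUS_KM * sin(lat * pi / 180) / k)
    },
    inverse = function(x, y) {
      sy <- pmin(1, pmax(-1, y * k / EARTH_RADIUS_KM))
      list(lon = lon0 + (x / (EARTH_RADIUS_KM * k)) * 180 / pi,
           lat = asin(sy) * 180 / pi)
    }), class = "div_projection")
}

new_grid <- function(n_cols, n_rows, cell_km, x0, y0, proj, land) {
  structure(list(n_cols = n_cols, n_rows = n_rows, cell_km = cell_km,
                 x0 = x0, y0 = y0,
                 lon0 = proj$lon0, lat_ts = proj$lat_ts,
                 land = land),
            class = "div_grid")
}

grid_projection <- function(grid) equal_area_projection(grid$lon0, grid$lat_ts)

#' @export
print.div_grid <- function(x, ...) {
  cat(sprintf("<div_grid> %d x %d cells of %g km (%d land / %d total)\n",
              x$n_rows, x$n_cols, x$cell_km, sum(x$land), length(x$land)))
  invisible(x)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Land-cell ids of a grid
#' @param grid a `div_grid`.
#' @return integer vector of cell ids flagged as land.
#' @export
land_cells <- function(grid) which(grid$land)

cell_row <- function(grid, id) ((id - 1L) %/% grid$n_cols) + 1L
cell_col <- function(grid, id) ((id - 1L) %% grid$n_cols) + 1L
cell_id <- function(grid, row, col) (row - 1L) * grid$n_cols + col

#' Projected bounds of grid cells
#' @param grid a `div_grid`.
#' @param ids cell ids (default all).
#' @return data.frame with `id, xmin, xmax, ymin, ymax` in projected km.
#' @export
cell_bounds <- function(grid, ids = seq_len(n_cells(grid))) {
  col <- cell_col(grid, ids); row <- cell_row(grid, ids)
  data.frame(id = ids,
             xmin = grid$x0 + (col - 1L) * grid$cell_km,
             xmax = grid$x0 + col * grid$cell_km,
             ymin = grid$y0 + (row - 1L) * grid$cell_km,
             ymax = grid$y0 + row * grid$cell_km)
}

#' Cell centres in geographic coordinates
#' @param grid a `div_grid`.
#' @param ids cell ids (default all).
#' @return data.frame `id, lon, lat`.
#' @export
cell_centers <- function(grid, ids = seq_len(n_cells(grid))) {
  b <- cell_bounds(grid, ids)
  ll <- grid_projection(grid)$inverse((b$xmin + b$xmax) / 2, (b$ymin + b$ymax) / 2)
  data.frame(id = ids, lon = ll$lon, lat = ll$lat)
}

#' Locate points on the grid
#'
#' Maps geographic points to cell ids. Cells are half-open: a point lying
#' exactly on a shared edge belongs to the cell for which that edge is the
#' upper boundary, i.e. the cell with the lower id (ids grow with row and
#' column). Points on the outer west/south boundary fall in the first
#' column/row; points outside the grid return `NA`.
#'
#' @param grid a `div_grid`.
#' @param lon,lat numeric vectors in decimal degrees.
#' @return integer cell ids with `NA` for off-grid points.
#' @export
locate_cells <- function(grid, lon, lat) {
  xy <- grid_projection(grid)$forward(lon, lat)
  u <- (xy$x - grid$x0) / grid$cell_km
  v <- (xy$y - grid$y0) / grid$cell_km
  # snap to the lattice so projection round-trip jitter cannot move an
  # edge point across its cell boundary
  u <- ifelse(abs(u - round(u)) < 1e-9, round(u), u)
  v <- ifelse(abs(v - round(v)) < 1e-9, round(v), v)
  col <- ifelse(u == 0, 1L, ceiling(u))
  row <- ifelse(v == 0, 1L, ceiling(v))
  ok <- !is.na(col) & !is.na(row) &
    col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  out <- rep(NA_integer_, length(lon))
  out[ok] <- cell_id(grid, as.integer(row[ok]), as.integer(col[ok]))
  out
}

#' Build an equal-area analysis grid over a geographic extent
#'
#' Tiles the projected extent with square cells and flags the cells whose
#' centre falls on land. The land mask may be `NULL` (all land), a
#' predicate `function(lon, lat)` returning logical, or a polygon given as
#' a data.frame with `lon`/`lat` vertex columns (even-odd containment).
#'
#' @param extent named numeric: `lon_min, lon_max, lat_min, lat_max`.
#' @param cell_km cell edge length in km.
#' @param projection a `div_projection`, or `NULL` to configure one from
#'   the extent midpoint.
#' @param land_mask `NULL`, predicate function, or polygon data.frame.
#' @return a `div_grid`.
#' @export
build_grid <- function(extent, cell_km, projection = NULL, land_mask = NULL) {
  need <- c("lon_min", "lon_max", "lat_min", "lat_max")
  if (!all(need %in% names(extent))) stop_invalid("extent needs ", paste(need, collapse = ", "))
  if (extent["lon_max"] <= extent["lon_min"] || extent["lat_max"] <= extent["lat_min"])
    stop_invalid("extent is degenerate")
  if (!is.numeric(cell_km) || cell_km <= 0) stop_invalid("cell_km must be > 0")
  proj <- projection %||% equal_area_projection(
    lon0 = mean(extent[c("lon_min", "lon_max")]),
    lat_ts = mean(extent[c("lat_min", "lat_max")]))
  ll <- proj$forward(extent["lon_min"], extent["lat_min"])
  ur <- proj$forward(extent["lon_max"], extent["lat_max"])
  n_cols <- max(1L, as.integer(ceiling((ur$x - ll$x) / cell_km - 1e-9)))
  n_rows <- max(1L, as.integer(ceiling((ur$y - ll$y) / cell_km - 1e-9)))
  grid <- new_grid(n_cols, n_rows, cell_km, unname(ll$x), unname(ll$y), proj,
                   land = rep(TRUE, n_cols * n_rows))
  if (!is.null(land_mask)) {
    ctr <- cell_centers(grid)
    grid$land <- if (is.function(land_mask)) {
      as.logical(land_mask(ctr$lon, ctr$lat))
    } else {
      point_in_polygon(ctr$lon, ctr$lat, land_mask$lon, land_mask$lat)
    }
    if (!any(grid$land)) warning("grid has no land cells")
  }
  grid
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting containment for simple polygons; points exactly on an edge
#' count as inside. Stands in for a geometry library, which the runtime
#' environment does not provide.
#'
#' @param px,py point coordinates.
#' @param vx,vy polygon vertex coordinates (closed implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3L, length(vy) == n)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- (yi > py) != (yj > py)
    xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & !is.na(xint) & px < xint)
    # collinear-and-within-bbox points sit on the boundary
    d <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_edge <- on_edge | (abs(d) < 1e-12 &
                            px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
                            py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12)
    j <- i
  }
  inside | on_edge
}

## grid serialization (JSON keeps doubles at full precision) ------------------

#' Write / read a grid
#'
#' JSON serialization that round-trips the grid bit-exactly (full-precision
#' doubles), so cell ids and cell polygons are stable across runs.
#'
#' @param grid a `div_grid`.
#' @param path file path.
#' @return `read_grid` returns the `div_grid`; `write_grid` its path,
#'   invisibly.
#' @export
write_grid <- function(grid, path) {
  g <- unclass(grid)
  # doubles as %.17g strings so the round trip is bit-exact
  for (f in c("cell_km", "x0", "y0", "lon0", "lat_ts"))
    g[[f]] <- sprintf("%.17g", g[[f]])
  jsonlite::write_json(g, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_grid(as.integer(g$n_cols), as.integer(g$n_rows), as.numeric(g$cell_km),
           as.numeric(g$x0), as.numeric(g$y0),
           equal_area_projection(as.numeric(g$lon0), as.numeric(g$lat_ts)),
           as.logical(g$land))
}
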