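## Occurrence cleaning, thinning, and gridding --------------------------------

#' Read a delimited occurrence table
#'
#' @param path CSV/TSV path (UTF-8).
#' @param species_col,lat_col,lon_col,locality_col column names in the file.
#' @param sep field separator ("," default).
#' @return data.frame with columns `species, lat, lon, locality`.
#' @export
read_occurrences <- function(path, species_col = "species", lat_col = "lat",
                             lon_col = "lon", locality_col = "locality",
                             sep = ",") {
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                      stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("input-format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  for (col in c(species_col, lat_col, lon_col))
    if (!col %in% names(raw))
      stop("input-format error: column '", col, "' missing in ", path, call. = FALSE)
  out <- data.frame(species = as.character(raw[[species_col]]),
                    lat = suppressWarnings(as.numeric(raw[[lat_col]])),
                    lon = suppressWarnings(as.numeric(raw[[lon_col]])),
                    stringsAsFactors = FALSE)
  out$locality <- if (locality_col %in% names(raw)) as.character(raw[[locality_col]]) else ""
  out
}

FILTER_NAMES <- c("missing_locality", "identical_lat_lon", "zero_or_integer",
                  "in_sea", "outside_native_range")

#' Clean occurrence records
#'
#' Applies the five standard filters in a fixed order, attributing each
#' removed record to the first filter it violates:
#' \enumerate{
#'   \item missing or unparseable coordinates (and no usable locality);
#'   \item latitude numerically equal to longitude;
#'   \item either coordinate exactly zero, or both coordinates
#'     integer-valued;
#'   \item point not on land (off-grid or in a sea cell);
#'   \item point outside the species' native range (skipped, and logged,
#'     for species without a supplied range).
#' }
#'
#' @param table data.frame with `species, lat, lon` (optional `locality`).
#' @param grid a `div_grid` providing the land mask.
#' @param native_ranges optional data.frame of per-species geographic
#'   bounding boxes (`species, lon_min, lon_max, lat_min, lat_max`) or a
#'   named list of polygons (data.frames with `lon`, `lat`).
#' @return list with `cleaned` (retained records) and `report` (a
#'   `cleaning_report`: per-filter counts, retained count, per-record
#'   disposition, count of species skipped by filter 5).
#' @export
clean_records <- function(table, grid, native_ranges = NULL) {
  if (is.null(table) || nrow(table) == 0L) stop_invalid("occurrence table is empty")
  if (!inherits(grid, "div_grid")) stop_invalid("a land-mask grid is required")
  n <- nrow(table)
  lat <- suppressWarnings(as.numeric(table$lat))
  lon <- suppressWarnings(as.numeric(table$lon))
  disposition <- integer(n)  # 0 = retained, k = removed by filter k

  f1 <- is.na(lat) | is.na(lon)
  disposition[f1] <- 1L
  open <- disposition == 0L

  f2 <- open & (lat == lon)
  disposition[f2] <- 2L
  open <- disposition == 0L

  f3 <- open & (lat == 0 | lon == 0 | (lat %% 1 == 0 & lon %% 1 == 0))
  disposition[f3] <- 3L
  open <- disposition == 0L

  cell <- rep(NA_integer_, n)
  cell[open] <- locate_cells(grid, lon[open], lat[open])
  f4 <- open & (is.na(cell) | !grid$land[ifelse(is.na(cell), 1L, cell)])
  disposition[f4] <- 4L
  open <- disposition == 0L

  skipped5 <- length(unique(table$species[open]))  # skipped if no range supplied
  if (!is.null(native_ranges)) {
    sp_with_range <- if (is.data.frame(native_ranges)) native_ranges$species else names(native_ranges)
    skipped5 <- length(setdiff(unique(table$species[open]), sp_with_range))
    idx <- which(open & table$species %in% sp_with_range)
    if (length(idx)) {
      out_of_range <- vapply(idx, function(i) {
        sp <- table$species[i]
        if (is.data.frame(native_ranges)) {
          b <- native_ranges[native_ranges$species == sp, ][1, ]
          lon[i] < b$lon_min || lon[i] > b$lon_max ||
            lat[i] < b$lat_min || lat[i] > b$lat_max
        } else {
          poly <- native_ranges[[sp]]
          !point_in_polygon(lon[i], lat[i], poly$lon, poly$lat)
        }
      }, logical(1))
      disposition[idx[out_of_range]] <- 5L
    }
  }

  counts <- vapply(1:5, function(k) sum(disposition == k), integer(1))
  names(counts) <- FILTER_NAMES
  cleaned <- table[disposition == 0L, , drop = FALSE]
  cleaned$lat <- lat[disposition == 0L]
  cleaned$lon <- lon[disposition == 0L]
  rownames(cleaned) <- NULL
  report <- structure(list(n_input = n, removed = counts,
                           retained = nrow(cleaned),
                           disposition = disposition,
                           filter5_species_skipped = skipped5),
                      class = "cleaning_report")
  stopifnot(report$retained + sum(report$removed) == n)
  list(cleaned = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>", x$n_input, "records in,", x$retained, "retained\n")
  for (k in seq_along(x$removed))
    cat(sprintf("  filter %d (%s): %d removed\n", k, names(x$removed)[k], x$removed[k]))
  if (x$filter5_species_skipped > 0)
    cat("  filter 5 skipped for", x$filter5_species_skipped, "species without native range\n")
  invisible(x)
}

#' Write a cleaning report
#'
#' Machine-readable JSON summary plus a human-readable log.
#' @param report a `cleaning_report`.
#' @param path base path; writes `<path>.json` and `<path>.log`.
#' @return invisibly, the JSON path.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(list(n_input = report$n_input,
                            removed = as.list(report$removed),
                            retained = report$retained,
                            filter5_species_skipped = report$filter5_species_skipped),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  sink(paste0(path, ".log")); print(report); sink()
  invisible(paste0(path, ".json"))
}

## Presence matrix -------------------------------------------------------------

#' Construct a presence-absence matrix
#'
#' @param m integer matrix, species in rows (named), land cell ids in
#'   columns (named); entries 0/1.
#' @return a `presence_matrix`.
#' @export
presence_matrix <- function(m) {
  stopifnot(is.matrix(m), all(m %in% c(0L, 1L)),
            !is.null(rownames(m)), !is.null(colnames(m)))
  if (any(rowSums(m) == 0L))
    stop_invalid("presence matrix has species with range size 0: ",
                 paste(rownames(m)[rowSums(m) == 0L], collapse = ", "))
  structure(m, class = c("presence_matrix", class(m)))
}

#' Per-species range sizes (occupied-cell counts)
#' @param P a `presence_matrix`.
#' @return named integer vector.
#' @export
range_sizes <- function(P) rowSums(P)

#' Species present in a cell
#' @param P a `presence_matrix`.
#' @param cell cell id (column name).
#' @return character vector of species ids.
#' @export
cell_species <- function(P, cell) rownames(P)[P[, as.character(cell)] == 1L]

#' Rasterize cleaned records into a presence matrix
#'
#' Entry is 1 iff the species has at least one record in the cell. Cell
#' membership uses the grid's half-open convention (edge points go to the
#' lower-id cell). Records falling off-grid or in sea cells are not
#' silently dropped: they are returned in an overflow log attribute.
#'
#' @param cleaned cleaned occurrence table.
#' @param grid a `div_grid`.
#' @return a `presence_matrix` over all land cells of `grid`, with
#'   attributes `overflow` (row indices of off-land records) and
#'   `dropped_species` (species that ended with no on-land record).
#' @export
rasterize_presence <- function(cleaned, grid) {
  cells <- locate_cells(grid, cleaned$lon, cleaned$lat)
  on_land <- !is.na(cells) & grid$land[ifelse(is.na(cells), 1L, cells)]
  overflow <- which(!on_land)
  land <- land_cells(grid)
  species <- sort(unique(cleaned$species))
  m <- matrix(0L, length(species), length(land),
              dimnames = list(species, as.character(land)))
  if (any(on_land)) {
    ri <- match(cleaned$species[on_land], species)
    ci <- match(cells[on_land], land)
    m[cbind(ri, ci)] <- 1L
  }
  dropped <- rownames(m)[rowSums(m) == 0L]
  if (length(dropped)) m <- m[setdiff(rownames(m), dropped), , drop = FALSE]
  P <- presence_matrix(m)
  attr(P, "overflow") <- overflow
  attr(P, "dropped_species") <- dropped
  P
}

#' Thin records to one per species per cell
#'
#' For species-distribution modelling, retains exactly one record per
#' species per thinning cell, chosen uniformly at random under `seed`.
#'
#' @param cleaned cleaned occurrence table.
#' @param thin_grid a `div_grid`, or a single number taken as a thinning
#'   cell size in km on the same projection/origin as `grid`.
#' @param seed RNG seed.
#' @param grid required when `thin_grid` is a resolution, to supply
#'   projection and origin.
#' @return thinned occurrence table (row order: input order of the kept
#'   records).
#' @export
thin_per_cell <- function(cleaned, thin_grid, seed = 1, grid = NULL) {
  if (is.numeric(thin_grid) && length(thin_grid) == 1L) {
    if (is.null(grid)) stop_invalid("grid needed to derive a thinning grid from a resolution")
    f <- grid$cell_km / thin_grid
    thin_grid <- new_grid(as.integer(ceiling(grid$n_cols * f)),
                          as.integer(ceiling(grid$n_rows * f)),
                          thin_grid, grid$x0, grid$y0, grid_projection(grid),
                          land = TRUE)
    thin_grid$land <- rep(TRUE, n_cells(thin_grid))
  }
  cells <- locate_cells(thin_grid, cleaned$lon, cleaned$lat)
  keep_key <- !is.na(cells)
  if (any(!keep_key)) warning(sum(!keep_key), " records off the thinning grid were dropped")
  idx <- which(keep_key)
  key <- paste(cleaned$species[idx], cells[idx], sep = "\r")
  kept <- with_seed(seed, {
    vapply(split(idx, key), function(g) {
      if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
    }, integer(1))
  })
  out <- cleaned[sort(unname(kept)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## presence-matrix I/O: sparse triplets + range-size sidecar -------------------

#' Write / read a presence matrix
#'
#' Sparse triplet CSV (`species, cell, value`) plus a `<path>.ranges.csv`
#' sidecar of per-species range sizes. `read_presence_matrix` needs the
#' grid to restore the full land-cell column set.
#'
#' @param P a `presence_matrix`.
#' @param path triplet CSV path.
#' @param grid the `div_grid` the matrix is defined on.
#' @return `write_presence_matrix`: the path, invisibly.
#' @export
write_presence_matrix <- function(P, path) {
  idx <- which(P == 1L, arr.ind = TRUE)
  utils::write.csv(data.frame(species = rownames(P)[idx[, 1]],
                              cell = colnames(P)[idx[, 2]],
                              value = 1L),
                   path, row.names = FALSE)
  utils::write.csv(data.frame(species = rownames(P), range_size = rowSums(P)),
                   paste0(path, ".ranges.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path, grid) {
  trip <- utils::read.csv(path, stringsAsFactors = FALSE)
  land <- as.character(land_cells(grid))
  species <- sort(unique(trip$species))
  m <- matrix(0L, length(species), length(land), dimnames = list(species, land))
  m[cbind(match(trip$species, species), match(as.character(trip$cell), land))] <- 1L
  presence_matrix(m)
}
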