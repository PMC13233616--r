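## Conservation effectiveness and gap analysis --------------------------------

## cells (ids) intersected with positive area by any rectangle in rects;
## min_fraction > 0 demands that fraction of the cell's area be covered by
## at least one rectangle
cells_intersecting_rects <- function(grid, rects, ids = land_cells(grid),
                                     min_fraction = 0) {
  b <- cell_bounds(grid, ids)
  covered <- rep(FALSE, length(ids))
  cell_area <- grid$cell_km^2
  for (r in seq_len(nrow(rects))) {
    ox <- pmin(b$xmax, rects$xmax[r]) - pmax(b$xmin, rects$xmin[r])
    oy <- pmin(b$ymax, rects$ymax[r]) - pmax(b$ymin, rects$ymin[r])
    area <- pmax(0, ox) * pmax(0, oy)
    covered <- covered | (if (min_fraction > 0) area >= min_fraction * cell_area
                          else area > 0)
  }
  covered
}

#' Protection status of grid cells against a reserve layer
#'
#' A cell counts as covered by a reserve class iff at least one reserve of
#' that class intersects the cell with positive area (no minimum-fraction
#' rule by default; set `min_fraction` to demand one). Degenerate
#' rectangles are repaired by swapping inverted bounds where possible,
#' otherwise skipped with a warning.
#'
#' @param grid a `div_grid`.
#' @param reserves data.frame `class` (`"NNR"`/`"PNR"`), `xmin, xmax,
#'   ymin, ymax` in projected km.
#' @param min_fraction minimum covered fraction of the cell area, default 0
#'   (any positive overlap).
#' @return `protection_status`: data.frame over land cells with logical
#'   `nnr`, `pnr`, `either`.
#' @export
protection_status <- function(grid, reserves, min_fraction = 0) {
  land <- land_cells(grid)
  rects <- reserves
  if (nrow(rects) > 0) {
    swap_x <- !is.na(rects$xmin) & rects$xmin > rects$xmax
    rects[swap_x, c("xmin", "xmax")] <- rects[swap_x, c("xmax", "xmin")]
    swap_y <- !is.na(rects$ymin) & rects$ymin > rects$ymax
    rects[swap_y, c("ymin", "ymax")] <- rects[swap_y, c("ymax", "ymin")]
    bad <- is.na(rects$xmin) | is.na(rects$ymin) | is.na(rects$xmax) | is.na(rects$ymax) |
      rects$xmin == rects$xmax | rects$ymin == rects$ymax
    if (any(bad)) {
      warning(sum(bad), " invalid reserve geometries skipped")
      rects <- rects[!bad, , drop = FALSE]
    }
  }
  sub <- function(cls) rects[rects$class == cls, , drop = FALSE]
  nnr <- if (nrow(sub("NNR"))) cells_intersecting_rects(grid, sub("NNR"), land, min_fraction)
         else rep(FALSE, length(land))
  pnr <- if (nrow(sub("PNR"))) cells_intersecting_rects(grid, sub("PNR"), land, min_fraction)
         else rep(FALSE, length(land))
  structure(data.frame(cell = land, nnr = nnr, pnr = pnr, either = nnr | pnr),
            class = c("protection_status", "data.frame"))
}

scope_flags <- function(status, scope) {
  switch(scope,
         "NNR" = status$nnr, "PNR" = status$pnr, "NNR-PNR" = status$either,
         stop_invalid("scope must be one of NNR, PNR, NNR-PNR"))
}

species_in_cells <- function(P, cells) {
  inside <- colnames(P) %in% as.character(cells)
  rownames(P)[rowSums(P[, inside, drop = FALSE]) > 0L]
}

category_table <- function(traits) {
  list(all = traits$species,
       endemic = traits$species[traits$endemic],
       threatened = traits$species[traits$threat != "none"],
       protected = traits$species[traits$protected])
}

#' Conservation-effectiveness report for a hotspot set
#'
#' Grid-level effectiveness is the percentage of hotspot cells covered
#' under the reserve scope. A species counts as effectively conserved iff
#' it occurs in at least one *covered* hotspot cell; rates are reported
#' against the full trait-table category totals (printed as the
#' denominator).
#'
#' @param hotspots a `hotspot_set` or integer vector of hotspot cell ids.
#' @param status a `protection_status`.
#' @param P a `presence_matrix`.
#' @param traits trait table (`species, endemic, threat, protected`).
#' @param scope `"NNR"`, `"PNR"` or `"NNR-PNR"`.
#' @param digits decimals for printed percentages (half-up).
#' @param q optional threshold label carried into the report.
#' @return `effectiveness_report`: hotspot/covered/gap cell counts, grid
#'   effectiveness percentage, per-category species rates, gap cell set.
#' @export
effectiveness_report <- function(hotspots, status, P, traits,
                                 scope = "NNR-PNR", digits = 2, q = NULL) {
  cells <- if (inherits(hotspots, "hotspot_set")) hotspots$final else as.integer(hotspots)
  if (length(cells) == 0L) stop_invalid("hotspot set is empty")
  flags <- scope_flags(status, scope)
  covered_cells <- cells[cells %in% status$cell[flags]]
  gap_cells <- setdiff(cells, covered_cells)
  conserved <- species_in_cells(P, covered_cells)
  cats <- category_table(traits)
  rates <- do.call(rbind, lapply(names(cats), function(nm) {
    sp <- cats[[nm]]
    data.frame(category = nm, n_total = length(sp),
               n_conserved = sum(sp %in% conserved),
               rate_pct = if (length(sp) == 0L) NA_real_ else
                 round_half_up(100 * sum(sp %in% conserved) / length(sp), digits),
               stringsAsFactors = FALSE)
  }))
  structure(list(q = q %||% if (inherits(hotspots, "hotspot_set")) hotspots$q else NA_real_,
                 scope = scope,
                 n_hotspot = length(cells), n_covered = length(covered_cells),
                 n_gap = length(gap_cells),
                 grid_effectiveness_pct =
                   round_half_up(100 * length(covered_cells) / length(cells), digits),
                 species_rates = rates,
                 covered_cells = covered_cells, gap_cells = gap_cells),
            class = "effectiveness_report")
}

#' @export
print.effectiveness_report <- function(x, ...) {
  cat(sprintf("<effectiveness_report> scope %s: %s%% (%d/%d hotspot cells covered)\n",
              x$scope, format(x$grid_effectiveness_pct), x$n_covered, x$n_hotspot))
  for (i in seq_len(nrow(x$species_rates)))
    with(x$species_rates[i, ],
         cat(sprintf("  %s: %s%% (%d/%d species)\n", category,
                     format(rate_pct), n_conserved, n_total)))
  invisible(x)
}

#' Conservation-gap report
#'
#' Lists the hotspot cells uncovered under the scope, and the species
#' occurring in those gap cells with a per-category breakdown (percentages
#' against full category totals, as effectiveness rates are).
#'
#' @inheritParams effectiveness_report
#' @return `gap_report`: `gap_cells`, `n_gap`, `gap_species`, and a
#'   per-category count/percentage table.
#' @export
gap_report <- function(hotspots, status, P, traits, scope = "NNR-PNR",
                       digits = 2, q = NULL) {
  cells <- if (inherits(hotspots, "hotspot_set")) hotspots$final else as.integer(hotspots)
  flags <- scope_flags(status, scope)
  gap_cells <- cells[!cells %in% status$cell[flags]]
  gap_sp <- species_in_cells(P, gap_cells)
  cats <- category_table(traits)
  breakdown <- do.call(rbind, lapply(names(cats), function(nm) {
    sp <- cats[[nm]]
    data.frame(category = nm, n_total = length(sp),
               n_gap = sum(sp %in% gap_sp),
               gap_pct = if (length(sp) == 0L) NA_real_ else
                 round_half_up(100 * sum(sp %in% gap_sp) / length(sp), digits),
               stringsAsFactors = FALSE)
  }))
  structure(list(q = q %||% if (inherits(hotspots, "hotspot_set")) hotspots$q else NA_real_,
                 scope = scope, gap_cells = gap_cells, n_gap = length(gap_cells),
                 gap_species = gap_sp, breakdown = breakdown),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> scope %s: %d gap cells, %d gap species\n",
              x$scope, x$n_gap, length(x$gap_species)))
  invisible(x)
}

#' Write effectiveness/gap reports as JSON
#'
#' One block per (threshold, scope) combination.
#'
#' @param reports list of `effectiveness_report` and/or `gap_report`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_conservation_reports <- function(reports, path) {
  blocks <- lapply(reports, function(r) {
    if (inherits(r, "effectiveness_report"))
      list(type = "effectiveness", q = r$q, scope = r$scope,
           n_hotspot = r$n_hotspot, n_covered = r$n_covered, n_gap = r$n_gap,
           grid_effectiveness_pct = r$grid_effectiveness_pct,
           species_rates = r$species_rates)
    else
      list(type = "gap", q = r$q, scope = r$scope, n_gap = r$n_gap,
           breakdown = r$breakdown)
  })
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Deterministic protection worked-example fixture
#'
#' Builds a grid, presence matrix, trait table, reserve layer, and hotspot
#' cell set realizing a stated protection accounting exactly: counts of
#' hotspot cells covered by NNRs and by the NNR-PNR union, and per-category
#' species totals with their NNR-conserved, union-conserved, and
#' NNR-gap-occurring counts. Reserves are one shrunken rectangle per
#' covered cell, so coverage flags are exact. Useful for reproducing
#' published effectiveness ratios from their printed numerators and
#' denominators.
#'
#' @param n_hotspot number of hotspot cells (cells 1..n_hotspot).
#' @param n_nnr_covered hotspot cells covered by NNRs (cells 1..k).
#' @param n_union_covered hotspot cells covered by NNRs or PNRs.
#' @param n_pnr_covered hotspot cells covered by PNRs (must allow the
#'   stated union: `n_union_covered - n_nnr_covered <= n_pnr_covered <=
#'   n_union_covered`).
#' @param categories named list; each element
#'   `c(total, nnr, union, gap)`: category size, species conserved under
#'   NNR scope, under NNR-PNR scope, and species occurring in NNR-gap
#'   cells. Category "all" totals are derived as the across-category sums,
#'   so pass disjoint categories (e.g. endemic/threatened/protected/other).
#' @return list `grid, P, traits, reserves, status, hotspot_cells`.
#' @export
protection_fixture <- function(n_hotspot = 179, n_nnr_covered = 101,
                               n_union_covered = 147, n_pnr_covered = 96,
                               categories = list(
                                 endemic = c(1985, 1869, 1898, 1654),
                                 threatened = c(306, 276, 284, 239),
                                 protected = c(223, 199, 205, 188),
                                 other = c(3306, 2951, 3029, 2985))) {
  stopifnot(n_nnr_covered <= n_union_covered, n_union_covered <= n_hotspot,
            n_pnr_covered >= n_union_covered - n_nnr_covered,
            n_pnr_covered <= n_union_covered)
  n_extra <- 2L  # a gap-by-neither hotspot cell plus a non-hotspot cell
  n_needed <- n_hotspot + n_extra
  n_cols <- 20L
  n_rows <- as.integer(ceiling(n_needed / n_cols))
  grid <- make_landscape(n_cols, n_rows, cell_km = 50, sea_fraction = 0, seed = 1)
  pnr_only <- n_union_covered - n_nnr_covered  # PNR-only covered cells
  nnr_cells <- seq_len(n_nnr_covered)
  # PNRs: the cells after the NNR block up to the union count, plus the
  # stated amount of overlap taken from the back of the NNR block
  pnr_cells <- c(seq(n_nnr_covered + 1L, length.out = pnr_only),
                 seq(to = n_nnr_covered, length.out = n_pnr_covered - pnr_only))
  shrink <- grid$cell_km * 0.25
  rect_for <- function(ids, class) {
    b <- cell_bounds(grid, ids)
    data.frame(id = sprintf("%s%04d", class, seq_along(ids)), class = class,
               xmin = b$xmin + shrink, xmax = b$xmax - shrink,
               ymin = b$ymin + shrink, ymax = b$ymax - shrink,
               stringsAsFactors = FALSE)
  }
  reserves <- rbind(rect_for(nnr_cells, "NNR"), rect_for(pnr_cells, "PNR"))
  status <- protection_status(grid, reserves)

  gap_cell <- n_hotspot  # last hotspot cell: covered by neither
  stopifnot(gap_cell > n_union_covered)
  outside_cell <- n_hotspot + 1L
  union_only_cell <- n_nnr_covered + 1L

  sp_rows <- list(); traits_rows <- list()
  for (nm in names(categories)) {
    v <- categories[[nm]]
    total <- v[1]; a <- v[2]; b <- v[3]; g <- v[4]
    stopifnot(a <= b, b <= total, g >= b - a, g - (b - a) <= total)
    ids <- sprintf("%s_%04d", nm, seq_len(total))
    home <- c(rep(1L, a),                                   # NNR-covered
              rep(union_only_cell, b - a),                  # PNR-only covered
              rep(outside_cell, total - b))                 # outside hotspots
    in_gap <- c(rep(TRUE, g - (b - a)), rep(FALSE, total - g + (b - a)))
    # species a+1..b sit in an NNR-gap cell already; the remaining gap
    # species get an extra record in the neither-covered hotspot cell
    sp_rows[[nm]] <- data.frame(species = ids, cell = home, gap = in_gap)
    traits_rows[[nm]] <- data.frame(
      species = ids, endemic = nm == "endemic",
      threat = if (nm == "threatened") "VU" else "none",
      protected = nm == "protected", stringsAsFactors = FALSE)
  }
  sp <- do.call(rbind, sp_rows)
  traits <- do.call(rbind, traits_rows)
  rownames(sp) <- rownames(traits) <- NULL

  land <- as.character(land_cells(grid))
  P <- matrix(0L, nrow(sp), length(land), dimnames = list(sp$species, land))
  P[cbind(seq_len(nrow(sp)), match(as.character(sp$cell), land))] <- 1L
  P[sp$gap, as.character(gap_cell)] <- 1L
  P <- presence_matrix(P)
  list(grid = grid, P = P, traits = traits, reserves = reserves,
       status = status, hotspot_cells = seq_len(n_hotspot))
}
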