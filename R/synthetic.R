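## Synthetic world generator --------------------------------------------------
##
## Every input the pipeline consumes can be generated with known ground
## truth: a contiguous land mask, spreading-dye species ranges with a
## richness gradient and range-size skew, occurrence records with planted
## dirty rows (one cleaning filter each), a Yule phylogeny, a
## block-structured ethnic-use matrix, rectangular reserve layers of
## configurable coverage, and smooth climate surfaces with an engineered
## collinear pair and per-scenario offsets.

#' Generate a landscape grid with a contiguous land mask
#'
#' Land cells are grown from the grid centre by a spreading-dye process
#' (uniform frontier choice, 4-neighbourhood) until
#' `ceiling((1 - sea_fraction) * n)` cells are land, so the land mass is
#' always connected. The grid is placed on an equal-area projection
#' centred on a nominal study region.
#'
#' @param n_cols,n_rows grid dimensions (>= 2).
#' @param cell_km cell edge length in km.
#' @param sea_fraction fraction of cells left as sea, in [0, 1).
#' @param seed RNG seed.
#' @param lon0,lat0 geographic centre of the landscape.
#' @return a `div_grid`.
#' @export
make_landscape <- function(n_cols, n_rows, cell_km = 50, sea_fraction = 0,
                           seed = 1, lon0 = 105, lat0 = 32) {
  n_cols <- check_count(n_cols, "n_cols", 2L)
  n_rows <- check_count(n_rows, "n_rows", 2L)
  if (cell_km <= 0) stop_invalid("cell_km must be > 0")
  check_fraction(sea_fraction, "sea_fraction", 0, 1, hi_open = TRUE)
  proj <- equal_area_projection(lon0, lat0)
  ctr <- proj$forward(lon0, lat0)
  grid <- new_grid(n_cols, n_rows, cell_km,
                   x0 = ctr$x - n_cols * cell_km / 2,
                   y0 = ctr$y - n_rows * cell_km / 2,
                   proj, land = rep(FALSE, n_cols * n_rows))
  n <- n_cols * n_rows
  n_land <- as.integer(ceiling((1 - sea_fraction) * n))
  start <- cell_id(grid, as.integer(ceiling(n_rows / 2)), as.integer(ceiling(n_cols / 2)))
  land <- with_seed(seed, spread_dye(grid, start, n_land, allowed = rep(TRUE, n)))
  grid$land[land] <- TRUE
  grid
}

## connected cell set grown by uniform frontier choice
spread_dye <- function(grid, start, size, allowed) {
  n <- n_cells(grid)
  in_set <- logical(n)
  in_front <- logical(n)
  in_set[start] <- TRUE
  front <- integer(0)
  push_neighbors <- function(id, front) {
    r <- cell_row(grid, id); c <- cell_col(grid, id)
    nb <- c(if (r > 1L) id - grid$n_cols, if (r < grid$n_rows) id + grid$n_cols,
            if (c > 1L) id - 1L, if (c < grid$n_cols) id + 1L)
    nb <- nb[allowed[nb] & !in_set[nb] & !in_front[nb]]
    in_front[nb] <<- TRUE
    c(front, nb)
  }
  front <- push_neighbors(start, front)
  while (sum(in_set) < size && length(front) > 0L) {
    i <- if (length(front) == 1L) 1L else sample.int(length(front), 1L)
    id <- front[i]
    front <- front[-i]
    in_set[id] <- TRUE
    in_front[id] <- FALSE
    front <- push_neighbors(id, front)
  }
  which(in_set)
}

#' Simulate species ranges and occurrence records
#'
#' Ranges are connected cell sets grown by spreading dye from seed cells
#' placed along a richness gradient; range sizes follow the requested
#' distribution (lognormal by default, giving many narrow endemics and few
#' widespread species). Occurrence counts scale with range size. A stated
#' fraction of records is corrupted so that each dirty record violates one
#' cleaning filter, with the hidden validity label and intended filter
#' retained as ground truth. Species whose range lies wholly inside the
#' south-west quadrant of the land mass are flagged endemic; the smallest
#' ranged species receive threat categories (CR/EN/VU in roughly the
#' 24:94:188 proportions of the study system).
#'
#' @param grid a `div_grid` from [make_landscape()].
#' @param n_species number of species.
#' @param range_size_distribution list: `list(kind = "lognormal", meanlog,
#'   sdlog)`, `list(kind = "logseries", alpha)` or `list(kind = "fixed",
#'   size)`. Sizes are rounded and truncated to `[1, n_land]`.
#' @param richness_gradient list `list(direction, strength)`; direction one
#'   of "SW", "SE", "NW", "NE", "none".
#' @param endemic_fraction fraction of species grown inside the endemic
#'   subregion (the realized endemic flag is computed geometrically).
#' @param threatened_fraction fraction of species given a threat category.
#' @param protected_fraction fraction of species flagged protected.
#' @param records_per_cell expected valid records per occupied cell.
#' @param corrupt_fraction fraction of records corrupted to violate a
#'   cleaning filter.
#' @param seed RNG seed.
#' @return list with `species_table`, `occurrences` (with hidden `valid`
#'   label and `intended_filter`), and `native_ranges` (per-species
#'   geographic bounding boxes).
#' @export
simulate_species_ranges <- function(grid, n_species,
                                    range_size_distribution = list(kind = "lognormal", meanlog = 2, sdlog = 1),
                                    richness_gradient = list(direction = "SW", strength = 1),
                                    endemic_fraction = 0.34,
                                    threatened_fraction = 0.053,
                                    protected_fraction = 0.038,
                                    records_per_cell = 3,
                                    corrupt_fraction = 0.1,
                                    seed = 1) {
  n_species <- check_count(n_species, "n_species", 1L)
  check_fraction(endemic_fraction, "endemic_fraction")
  check_fraction(threatened_fraction, "threatened_fraction")
  check_fraction(protected_fraction, "protected_fraction")
  check_fraction(corrupt_fraction, "corrupt_fraction")
  land <- land_cells(grid)
  n_land <- length(land)
  if (n_land == 0L) stop_invalid("grid has no land cells")
  with_seed(seed, {
    sizes <- draw_range_sizes(range_size_distribution, n_species, n_land)
    ids <- sprintf("sp%03d", seq_len(n_species))

    # gradient weights over land cells
    w <- gradient_weights(grid, land, richness_gradient)
    # endemic subregion: south-west quadrant of the land bounding box
    rows <- cell_row(grid, land); cols <- cell_col(grid, land)
    sub <- land[rows <= stats::quantile(rows, 0.5) & cols <= stats::quantile(cols, 0.5)]
    n_end <- round(endemic_fraction * n_species)
    grow_in_sub <- seq_len(n_species) <= n_end

    allowed_all <- grid$land
    allowed_sub <- rep(FALSE, n_cells(grid)); allowed_sub[sub] <- TRUE

    ranges <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      if (grow_in_sub[i]) {
        size_i <- min(sizes[i], length(sub))
        seed_cell <- safe_sample(sub, 1L, prob = w[match(sub, land)])
        ranges[[i]] <- spread_dye(grid, seed_cell, size_i, allowed_sub)
      } else {
        seed_cell <- safe_sample(land, 1L, prob = w)
        ranges[[i]] <- spread_dye(grid, seed_cell, sizes[i], allowed_all)
      }
    }
    range_size <- lengths(ranges)
    endemic <- vapply(ranges, function(r) all(r %in% sub), logical(1))

    # threat categories go to the narrowest ranges
    n_thr <- round(threatened_fraction * n_species)
    threat <- rep("none", n_species)
    if (n_thr > 0L) {
      ord <- order(range_size, seq_len(n_species))
      picks <- ord[seq_len(n_thr)]
      cls <- rep(c("CR", "EN", "VU"), times = pmax(1L, round(n_thr * c(24, 94, 188) / 306)))
      threat[picks] <- cls[seq_len(n_thr)]
    }
    protected <- logical(n_species)
    n_pro <- round(protected_fraction * n_species)
    if (n_pro > 0L) protected[sample.int(n_species, n_pro)] <- TRUE

    species_table <- data.frame(
      species = ids, range_size = range_size, endemic = endemic,
      threat = threat, protected = protected, stringsAsFactors = FALSE)
    species_table$range_cells <- ranges

    occ <- place_occurrences(grid, ids, ranges, records_per_cell)
    native_ranges <- native_bboxes(grid, ids, ranges, buffer_km = grid$cell_km)
    occ <- corrupt_records(grid, occ, native_ranges, corrupt_fraction)
    list(species_table = species_table, occurrences = occ,
         native_ranges = native_ranges)
  })
}

draw_range_sizes <- function(spec, n, n_land) {
  kind <- spec$kind %||% "lognormal"
  raw <- switch(kind,
    lognormal = stats::rlnorm(n, spec$meanlog %||% 2, spec$sdlog %||% 1),
    logseries = {
      # inverse-cdf draw from Fisher's log-series with parameter theta
      theta <- spec$theta %||% 0.9
      k <- seq_len(n_land)
      p <- -theta^k / (k * log(1 - theta))
      safe_sample(k, n, replace = TRUE, prob = p)
    },
    fixed = {
      if ((spec$size %||% 1) > n_land)
        stop_invalid("range size ", spec$size, " exceeds land area ", n_land)
      rep(spec$size, n)
    },
    stop_invalid("unknown range size distribution kind: ", kind))
  pmin(pmax(1L, as.integer(round(raw))), n_land)
}

gradient_weights <- function(grid, land, gradient) {
  dirv <- switch(gradient$direction %||% "none",
                 SW = c(-1, -1), SE = c(1, -1), NW = c(-1, 1), NE = c(1, 1),
                 none = c(0, 0),
                 stop_invalid("unknown gradient direction"))
  s <- gradient$strength %||% 1
  cx <- (cell_col(grid, land) - 1) / max(1L, grid$n_cols - 1L) * 2 - 1
  cy <- (cell_row(grid, land) - 1) / max(1L, grid$n_rows - 1L) * 2 - 1
  w <- exp(s * (dirv[1] * cx + dirv[2] * cy))
  w / sum(w)
}

place_occurrences <- function(grid, ids, ranges, records_per_cell) {
  out <- vector("list", length(ids))
  proj <- grid_projection(grid)
  for (i in seq_along(ids)) {
    cells <- ranges[[i]]
    n_rec <- max(1L, stats::rpois(1L, records_per_cell * length(cells)))
    at <- c(cells[1L], safe_sample(cells, n_rec - 1L, replace = TRUE))
    b <- cell_bounds(grid, at)
    x <- stats::runif(n_rec, b$xmin + 1e-6, b$xmax - 1e-6)
    y <- stats::runif(n_rec, b$ymin + 1e-6, b$ymax - 1e-6)
    ll <- proj$inverse(x, y)
    out[[i]] <- data.frame(species = ids[i], lat = ll$lat, lon = ll$lon,
                           locality = sprintf("loc_%s_%d", ids[i], seq_len(n_rec)),
                           stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, out)
  occ$valid <- TRUE
  occ$intended_filter <- 0L
  rownames(occ) <- NULL
  occ
}

native_bboxes <- function(grid, ids, ranges, buffer_km) {
  proj <- grid_projection(grid)
  do.call(rbind, lapply(seq_along(ids), function(i) {
    b <- cell_bounds(grid, ranges[[i]])
    lo <- proj$inverse(min(b$xmin) - buffer_km, min(b$ymin) - buffer_km)
    hi <- proj$inverse(max(b$xmax) + buffer_km, max(b$ymax) + buffer_km)
    data.frame(species = ids[i], lon_min = lo$lon, lon_max = hi$lon,
               lat_min = lo$lat, lat_max = hi$lat, stringsAsFactors = FALSE)
  }))
}

## corrupt a fraction of records, each violating one cleaning filter; the
## record keeps a hidden validity label and the filter it was built to trip
corrupt_records <- function(grid, occ, native_ranges, corrupt_fraction) {
  n_dirty <- round(corrupt_fraction * nrow(occ))
  if (n_dirty == 0L) return(occ)
  # never corrupt the first (guaranteed in-range) record of a species
  first_of_species <- !duplicated(occ$species)
  eligible <- which(!first_of_species)
  n_dirty <- min(n_dirty, length(eligible))
  dirty <- safe_sample(eligible, n_dirty)
  sea <- which(!grid$land)
  proj <- grid_projection(grid)
  types <- rep_len(1:5, n_dirty)
  for (k in seq_len(n_dirty)) {
    i <- dirty[k]
    type <- types[k]
    if (type == 5L) {
      # relocate on land but outside the species' native bbox
      nb <- native_ranges[native_ranges$species == occ$species[i], ]
      ctr <- cell_centers(grid, land_cells(grid))
      outside <- ctr[ctr$lon < nb$lon_min | ctr$lon > nb$lon_max |
                       ctr$lat < nb$lat_min | ctr$lat > nb$lat_max, ]
      if (nrow(outside) == 0L) type <- 4L else {
        pick <- outside[sample.int(nrow(outside), 1L), ]
        occ$lat[i] <- pick$lat + 0.0123
        occ$lon[i] <- pick$lon + 0.0071
        if (occ$lat[i] == occ$lon[i]) occ$lon[i] <- occ$lon[i] + 0.003
      }
    }
    if (type == 4L) {
      # relocate into the sea (or off-grid when the world has no sea)
      if (length(sea) > 0L) {
        pick <- cell_centers(grid, safe_sample(sea, 1L))
        occ$lat[i] <- pick$lat + 0.0123
        occ$lon[i] <- pick$lon + 0.0071
      } else {
        edge <- proj$inverse(grid$x0 - 2 * grid$cell_km, grid$y0 - 2 * grid$cell_km)
        occ$lat[i] <- edge$lat - 0.0123
        occ$lon[i] <- edge$lon - 0.0071
      }
      if (occ$lat[i] == occ$lon[i]) occ$lon[i] <- occ$lon[i] + 0.003
    }
    if (type == 3L) {
      occ$lat[i] <- round(occ$lat[i])
      occ$lon[i] <- round(occ$lon[i])
      if (occ$lat[i] == occ$lon[i]) occ$lon[i] <- occ$lon[i] + 1
    }
    if (type == 2L) {
      a <- occ$lat[i]
      if (a == round(a)) a <- a + 0.123
      occ$lat[i] <- occ$lon[i] <- a
    }
    if (type == 1L) {
      occ$lat[i] <- NA_real_
      occ$locality[i] <- ""
    }
    occ$valid[i] <- FALSE
    occ$intended_filter[i] <- type
  }
  occ
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' @param species_ids character vector of >= 2 tip labels.
#' @param birth_rate speciation rate per unit time.
#' @param seed RNG seed.
#' @return a Newick string; binary rooted tree, tips = `species_ids`, all
#'   branch lengths > 0.
#' @export
simulate_phylogeny <- function(species_ids, birth_rate = 1, seed = 1) {
  n <- length(species_ids)
  if (n < 2L) stop_invalid("need >= 2 species for a phylogeny")
  if (birth_rate <= 0) stop_invalid("birth_rate must be > 0")
  tree <- with_seed(seed, ape::rphylo(n, birth = birth_rate, death = 0))
  tree$tip.label <- species_ids
  # rphylo can emit zero-length terminal edges at machine precision; floor them
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  ape::write.tree(tree)
}

#' Simulate a block-structured species-by-group use matrix
#'
#' Entries are independent Bernoulli draws with a background probability,
#' elevated inside planted (species set, group set) blocks. All-zero
#' species rows are resampled (the planted structure is ground truth for
#' clustering-recovery tests).
#'
#' @param species_ids character vector of species.
#' @param n_groups number of ethnic groups (columns).
#' @param block_plan list of `list(groups =, species =, p =)` with integer
#'   indices (or names) and a within-block use probability.
#' @param background_probability probability outside all blocks.
#' @param seed RNG seed.
#' @return binary matrix species x groups with attribute `block` (planted
#'   block id per species, 0 = background).
#' @export
simulate_use_matrix <- function(species_ids, n_groups, block_plan = list(),
                                background_probability = 0.03, seed = 1) {
  n_groups <- check_count(n_groups, "n_groups", 1L)
  check_fraction(background_probability, "background_probability")
  S <- length(species_ids)
  groups <- sprintf("grp%02d", seq_len(n_groups))
  prob <- matrix(background_probability, S, n_groups,
                 dimnames = list(species_ids, groups))
  block_of <- integer(S)
  for (b in seq_along(block_plan)) {
    bl <- block_plan[[b]]
    if (length(bl$groups) == 0L || length(bl$species) == 0L)
      stop_invalid("block ", b, " is empty")
    check_fraction(bl$p, "block probability")
    gi <- if (is.character(bl$groups)) match(bl$groups, groups) else as.integer(bl$groups)
    si <- if (is.character(bl$species)) match(bl$species, species_ids) else as.integer(bl$species)
    prob[si, gi] <- bl$p
    block_of[si] <- b
  }
  U <- with_seed(seed, {
    U <- matrix(stats::rbinom(S * n_groups, 1L, as.vector(prob)), S, n_groups,
                dimnames = dimnames(prob))
    for (i in which(rowSums(U) == 0L)) {
      if (all(prob[i, ] == 0)) next  # nothing to resample from; left zero
      tries <- 0L
      while (sum(U[i, ]) == 0L && tries < 1000L) {
        U[i, ] <- stats::rbinom(n_groups, 1L, prob[i, ])
        tries <- tries + 1L
      }
      if (sum(U[i, ]) == 0L) U[i, which.max(prob[i, ])] <- 1L
    }
    U
  })
  attr(U, "block") <- block_of
  U
}

#' Simulate a reserve layer of axis-aligned rectangles
#'
#' National (NNR) and provincial (PNR) reserves are rectangles dropped on
#' random land cells; a global size factor is tuned by bisection so the
#' realized land coverage lands within +/-20 percent (relative) of
#' `target_coverage`. NNRs are drawn twice the area of PNRs.
#'
#' @param grid a `div_grid`.
#' @param n_nnr,n_pnr reserve counts by class.
#' @param target_coverage desired covered fraction of land cells, [0, 1].
#' @param seed RNG seed.
#' @return data.frame `id, class, xmin, xmax, ymin, ymax` (projected km).
#' @export
simulate_reserves <- function(grid, n_nnr, n_pnr, target_coverage = 0.15, seed = 1) {
  n_nnr <- check_count(n_nnr, "n_nnr", 0L)
  n_pnr <- check_count(n_pnr, "n_pnr", 0L)
  check_fraction(target_coverage, "target_coverage")
  empty <- data.frame(id = character(0), class = character(0),
                      xmin = numeric(0), xmax = numeric(0),
                      ymin = numeric(0), ymax = numeric(0))
  n <- n_nnr + n_pnr
  if (target_coverage == 0 || n == 0L) return(empty)
  land <- land_cells(grid)
  with_seed(seed, {
    centers <- cell_bounds(grid, safe_sample(land, n, replace = TRUE))
    cx <- (centers$xmin + centers$xmax) / 2
    cy <- (centers$ymin + centers$ymax) / 2
    aspect <- stats::runif(n, 0.5, 2)
    rel_area <- c(rep(2, n_nnr), rep(1, n_pnr)) * stats::runif(n, 0.6, 1.4)
    base_area <- target_coverage * length(land) * grid$cell_km^2 / sum(rel_area)
    layer_at <- function(s) {
      a <- rel_area * base_area * s
      w <- sqrt(a * aspect); h <- a / w
      data.frame(id = sprintf("%s%03d", c(rep("NNR", n_nnr), rep("PNR", n_pnr)),
                              c(seq_len(n_nnr), seq_len(n_pnr))),
                 class = c(rep("NNR", n_nnr), rep("PNR", n_pnr)),
                 xmin = cx - w / 2, xmax = cx + w / 2,
                 ymin = cy - h / 2, ymax = cy + h / 2,
                 stringsAsFactors = FALSE)
    }
    realized <- function(s) {
      cov <- cells_intersecting_rects(grid, layer_at(s), ids = land)
      mean(cov)
    }
    lo <- 0.02; hi <- 50
    for (it in 1:40) {
      mid <- sqrt(lo * hi)
      if (realized(mid) < target_coverage) lo <- mid else hi <- mid
    }
    best <- if (abs(realized(lo) - target_coverage) < abs(realized(hi) - target_coverage)) lo else hi
    layer_at(best)
  })
}

#' Simulate climate predictor surfaces
#'
#' Each predictor is a linear spatial gradient (random direction) plus
#' spatially smoothed Gaussian noise, sampled at land cells. One engineered
#' collinear duplicate (`<first predictor>_dup` = first predictor + small
#' jitter) guarantees a pair with |r| > 0.85 for screening tests. Scenario
#' stacks apply the stated additive and/or multiplicative offsets to the
#' current surfaces.
#'
#' @param grid a `div_grid`.
#' @param predictor_names character; at least one.
#' @param scenario_offsets named list; each element a list with optional
#'   named numeric vectors `additive` and `multiplicative` (names =
#'   predictors).
#' @param gradient_strength amplitude of the deterministic gradient, in
#'   units of the predictor's natural scale.
#' @param noise_sd standard deviation of the noise field, in units of the
#'   predictor's natural scale.
#' @param noise_smooth number of 3x3 smoothing passes (0 = i.i.d. noise).
#' @param base_levels named list of `c(mean, sd)` natural scales per
#'   predictor (defaults approximate continental bioclimatic surfaces:
#'   bio1 in deg C, bio12 in mm, altitude in m, ...); unknown predictors
#'   default to mean 0, sd 1 so the scenario offsets stay commensurate
#'   with field variation.
#' @param collinear add the engineered duplicate predictor?
#' @param jitter_sd jitter of the duplicate, as a fraction of the parent's
#'   standard deviation.
#' @param seed RNG seed.
#' @return object of class `div_climate`: list with `predictors`,
#'   `scenarios` (named list of matrices, rows = land cell ids, columns =
#'   predictors), and `grid` dims for validation.
#' @export
simulate_climate <- function(grid,
                             predictor_names = c("altitude", "bio1", "bio2", "bio3", "bio4",
                                                 "bio12", "bio14", "bio15", "bio18"),
                             scenario_offsets = list(
                               "RCP2.6" = list(additive = c(bio1 = 1.0), multiplicative = c(bio12 = 1.03)),
                               "RCP4.5" = list(additive = c(bio1 = 1.8), multiplicative = c(bio12 = 1.00)),
                               "RCP6.0" = list(additive = c(bio1 = 2.2), multiplicative = c(bio12 = 0.97)),
                               "RCP8.5" = list(additive = c(bio1 = 3.7), multiplicative = c(bio12 = 0.94))),
                             gradient_strength = 1, noise_sd = 0.3,
                             noise_smooth = 2, collinear = TRUE,
                             jitter_sd = 0.02,
                             base_levels = list(
                               altitude = c(1500, 1000), bio1 = c(8, 7),
                               bio2 = c(10, 2), bio3 = c(30, 8),
                               bio4 = c(800, 250), bio12 = c(700, 450),
                               bio14 = c(10, 10), bio15 = c(70, 25),
                               bio18 = c(300, 180)),
                             seed = 1) {
  if (length(predictor_names) < 1L) stop_invalid("need >= 1 predictor")
  land <- land_cells(grid)
  with_seed(seed, {
    fields <- vapply(predictor_names, function(p) {
      lvl <- base_levels[[p]] %||% c(0, 1)
      lvl[1] + lvl[2] *
        smooth_field(grid, gradient_strength, noise_sd, noise_smooth)[land]
    }, numeric(length(land)))
    colnames(fields) <- predictor_names
    if (collinear) {
      parent <- fields[, 1L]
      dup <- parent + stats::rnorm(length(parent), 0, jitter_sd * max(stats::sd(parent), 1e-12))
      fields <- cbind(fields, dup)
      colnames(fields)[ncol(fields)] <- paste0(predictor_names[1L], "_dup")
    }
    rownames(fields) <- as.character(land)
    scenarios <- list(current = fields)
    for (sc in names(scenario_offsets)) {
      off <- scenario_offsets[[sc]]
      m <- fields
      for (p in names(off$additive %||% numeric(0)))
        if (p %in% colnames(m)) m[, p] <- m[, p] + off$additive[[p]]
      for (p in names(off$multiplicative %||% numeric(0)))
        if (p %in% colnames(m)) m[, p] <- m[, p] * off$multiplicative[[p]]
      scenarios[[sc]] <- m
    }
    structure(list(predictors = colnames(fields), scenarios = scenarios,
                   cell_ids = land),
              class = "div_climate")
  })
}

smooth_field <- function(grid, gradient_strength, noise_sd, noise_smooth) {
  nr <- grid$n_rows; nc <- grid$n_cols
  theta <- stats::runif(1, 0, 2 * pi)
  cx <- matrix(rep((seq_len(nc) - 1) / max(1, nc - 1) * 2 - 1, each = nr), nr, nc)
  cy <- matrix(rep((seq_len(nr) - 1) / max(1, nr - 1) * 2 - 1, nc), nr, nc)
  g <- gradient_strength * (cos(theta) * cx + sin(theta) * cy)
  eps <- matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  if (noise_smooth > 0) {
    for (k in seq_len(noise_smooth)) eps <- blur3(eps)
    # restore the requested marginal sd after smoothing
    s <- stats::sd(as.vector(eps))
    if (s > 0) eps <- eps * noise_sd / s
  }
  field <- g + eps
  # flatten so position (row-1)*n_cols+col holds field[row, col]
  as.vector(t(field))
}

blur3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + pad[dr + seq_len(nr), dc + seq_len(nc)]
  out / 9
}

#' Generate a complete synthetic world
#'
#' Bundles every generator with a single master seed (sub-seeds are derived
#' deterministically) into the stated default world: a 30 x 25 grid of
#' 50-km cells with 20 percent sea, 120 species with lognormal(2, 1) range
#' sizes and a south-west richness gradient, 34 percent endemics and 5.3
#' percent threatened species (the study system's proportions), 10 percent
#' planted dirty records, a Yule phylogeny, a 24-group use matrix with five
#' planted clade blocks, reserves covering 15 percent of land (8 NNR + 14
#' PNR), and nine climate predictors plus one engineered collinear
#' duplicate under four RCP scenarios.
#'
#' @param seed master seed.
#' @param n_cols,n_rows,cell_km,sea_fraction landscape parameters.
#' @param n_species species count.
#' @param n_groups ethnic-group count.
#' @param block_plan use-matrix block plan; `NULL` for the default five
#'   clade blocks.
#' @param background_probability background use probability.
#' @param n_nnr,n_pnr,target_coverage reserve parameters.
#' @param ... forwarded to [simulate_species_ranges()].
#' @return object of class `div_world`.
#' @export
synthetic_world <- function(seed = 1, n_cols = 30, n_rows = 25, cell_km = 50,
                            sea_fraction = 0.2, n_species = 120, n_groups = 24,
                            block_plan = NULL, background_probability = 0.03,
                            n_nnr = 8, n_pnr = 14, target_coverage = 0.15, ...) {
  seeds <- derive_seeds(seed, 6L)
  grid <- make_landscape(n_cols, n_rows, cell_km, sea_fraction, seed = seeds[1])
  sp <- simulate_species_ranges(grid, n_species, seed = seeds[2], ...)
  ids <- sp$species_table$species
  newick <- simulate_phylogeny(ids, birth_rate = 1, seed = seeds[3])
  if (is.null(block_plan)) {
    # five clade blocks mirroring group sizes 7/5/4/3/5 of the study system
    gsz <- c(7, 5, 4, 3, 5)
    gsz <- round(gsz / sum(gsz) * n_groups)
    gsz[length(gsz)] <- n_groups - sum(gsz[-length(gsz)])
    gcut <- cumsum(gsz)
    scut <- round(seq_along(gsz) / length(gsz) * n_species)
    block_plan <- lapply(seq_along(gsz), function(b) {
      list(groups = (c(0, gcut)[b] + 1L):gcut[b],
           species = (c(0, scut)[b] + 1L):scut[b], p = 0.35)
    })
    block_plan <- Filter(function(b) length(b$groups) > 0 && length(b$species) > 0, block_plan)
  }
  U <- simulate_use_matrix(ids, n_groups, block_plan, background_probability,
                           seed = seeds[4])
  reserves <- simulate_reserves(grid, n_nnr, n_pnr, target_coverage, seed = seeds[5])
  climate <- simulate_climate(grid, seed = seeds[6])
  structure(list(grid = grid, species_table = sp$species_table,
                 occurrences = sp$occurrences, native_ranges = sp$native_ranges,
                 phylogeny = newick, use_matrix = U, reserves = reserves,
                 climate = climate, rng_seed = seed),
            class = "div_world")
}

#' @export
print.div_world <- function(x, ...) {
  cat(sprintf("<div_world> seed %s: %d species, %d records (%d planted invalid), %d reserves\n",
              format(x$rng_seed), nrow(x$species_table), nrow(x$occurrences),
              sum(!x$occurrences$valid), nrow(x$reserves)))
  print(x$grid)
  invisible(x)
}

#' Write all world artifacts to a directory
#'
#' Occurrences (validity labels in a side file), phylogeny (Newick), use
#' matrix, reserves, climate tables, grid, and a manifest listing every
#' artifact with the master seed.
#'
#' @param world a `div_world`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  occ <- world$occurrences
  utils::write.csv(occ[c("species", "lat", "lon", "locality")], p("occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(occ[c("valid", "intended_filter")], p("occurrences_validity.csv"),
                   row.names = FALSE)
  writeLines(world$phylogeny, p("phylogeny.nwk"))
  utils::write.csv(as.data.frame(world$use_matrix), p("use_matrix.csv"))
  utils::write.csv(world$reserves, p("reserves.csv"), row.names = FALSE)
  write_grid(world$grid, p("grid.json"))
  dir.create(p("climate"), showWarnings = FALSE)
  files <- c("occurrences.csv", "occurrences_validity.csv", "phylogeny.nwk",
             "use_matrix.csv", "reserves.csv", "grid.json")
  for (sc in names(world$climate$scenarios)) {
    f <- file.path("climate", paste0(gsub("[^A-Za-z0-9._-]", "_", sc), ".csv"))
    m <- world$climate$scenarios[[sc]]
    utils::write.csv(data.frame(cell = rownames(m), m, check.names = FALSE),
                     p(f), row.names = FALSE)
    files <- c(files, f)
  }
  jsonlite::write_json(list(seed = world$rng_seed, artifacts = files),
                       p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(p("manifest.json"))
}
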