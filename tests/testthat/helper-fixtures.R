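# shared fixtures and independent oracles, built in code at test time

# a tiny all-land grid with ids 1..(nc*nr), row-major from the south-west
tiny_grid <- function(nc = 4, nr = 3, cell_km = 50) {
  make_landscape(nc, nr, cell_km = cell_km, sea_fraction = 0, seed = 1)
}

# presence matrix from a named list: cell id -> character species vector
pm_from_cells <- function(cells_list, grid = NULL) {
  species <- sort(unique(unlist(cells_list)))
  ids <- as.character(if (is.null(grid)) sort(as.integer(names(cells_list)))
                      else land_cells(grid))
  m <- matrix(0L, length(species), length(ids), dimnames = list(species, ids))
  for (cid in names(cells_list)) m[cells_list[[cid]], cid] <- 1L
  presence_matrix(m)
}

# independent PD/PE oracle: parent-pointer walking per tip (the package
# implementation accumulates descendant sets in postorder instead)
brute_pd_pe <- function(tree, P) {
  edges <- tree$edge
  parent_edge_of <- function(node) which(edges[, 2] == node)
  tip_edge_path <- function(tip) {
    path <- integer(0)
    node <- tip
    repeat {
      e <- parent_edge_of(node)
      if (length(e) == 0L) break
      path <- c(path, e)
      node <- edges[e, 1]
    }
    path
  }
  paths <- lapply(seq_along(tree$tip.label), tip_edge_path)
  names(paths) <- tree$tip.label
  # edge -> tips descending from it (tip has the edge on its root path)
  edge_tips <- lapply(seq_len(nrow(edges)), function(e)
    names(paths)[vapply(paths, function(p) e %in% p, logical(1))])
  cell_edge_union <- function(cell) {
    present <- rownames(P)[P[, cell] == 1L]
    present <- intersect(present, tree$tip.label)
    sort(unique(unlist(paths[present])))
  }
  edge_range <- vapply(seq_len(nrow(edges)), function(e) {
    tips <- intersect(edge_tips[[e]], rownames(P))
    if (length(tips) == 0L) return(0)
    sum(colSums(P[tips, , drop = FALSE]) > 0L)
  }, numeric(1))
  pd <- pe <- numeric(ncol(P))
  for (ci in seq_len(ncol(P))) {
    eu <- cell_edge_union(colnames(P)[ci])
    pd[ci] <- sum(tree$edge.length[eu])
    pe[ci] <- sum(tree$edge.length[eu] / edge_range[eu])
  }
  list(pd = pd, pe = pe)
}

# exhaustive minimum set cover for small instances (bitmask enumeration)
brute_min_cover <- function(P) {
  n_cell <- ncol(P); n_sp <- nrow(P)
  stopifnot(n_cell <= 12L, n_sp <= 30L)
  masks <- vapply(seq_len(n_cell), function(ci)
    sum(2^(which(P[, ci] == 1L) - 1L)), numeric(1))
  full <- sum(2^(seq_len(n_sp) - 1L))
  best <- n_cell
  for (s in seq_len(2^n_cell - 1L)) {
    sel <- which(bitwAnd(s, 2^(seq_len(n_cell) - 1L)) > 0)
    if (length(sel) >= best) next
    u <- 0
    for (ci in sel) u <- bitwOr(u, masks[ci])
    if (u == full) best <- length(sel)
  }
  best
}

# does an unrooted tree contain the split separating tip set A?
has_split <- function(tree, tips_a) {
  pp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(pp, "labels")
  a <- sort(tips_a)
  b <- sort(setdiff(labs, tips_a))
  any(vapply(pp, function(x) {
    s <- sort(labs[x])
    identical(s, a) || identical(s, b)
  }, logical(1)))
}

# 12-record cleaning fixture: one violator per filter + 7 clean records
cleaning_fixture <- function(grid) {
  ctr <- cell_centers(grid, land_cells(grid)[1:7])
  clean <- data.frame(species = sprintf("c%d", 1:7),
                      lat = ctr$lat + 0.011, lon = ctr$lon + 0.017,
                      locality = "ok", stringsAsFactors = FALSE)
  sea_or_off <- {
    sea <- which(!grid$land)
    if (length(sea)) cell_centers(grid, sea[1])
    else {
      ll <- grid_projection(grid)$inverse(grid$x0 - 2 * grid$cell_km, grid$y0)
      data.frame(lon = ll$lon, lat = ll$lat)
    }
  }
  bad <- data.frame(
    species = sprintf("d%d", 1:5),
    lat = c(NA, 34.56, 23, sea_or_off$lat + 0.013, clean$lat[1]),
    lon = c(100.5, 34.56, 112, sea_or_off$lon + 0.017, clean$lon[1]),
    locality = c("", rep("ok", 4)), stringsAsFactors = FALSE)
  # the filter-5 violator sits on land but outside its native bbox
  ranges <- data.frame(species = "d5",
                       lon_min = clean$lon[1] + 1, lon_max = clean$lon[1] + 2,
                       lat_min = clean$lat[1] + 1, lat_max = clean$lat[1] + 2)
  list(table = rbind(clean, bad), native_ranges = ranges)
}
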