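test_that("make_landscape honours the land-count contract and determinism", {
  g <- make_landscape(10, 10, 50, sea_fraction = 0, seed = 1)
  expect_equal(sum(g$land), 100L)
  g2 <- make_landscape(40, 40, 50, sea_fraction = 0.25, seed = 7)
  expect_equal(sum(g2$land), 1200L)
  g3 <- make_landscape(40, 40, 50, sea_fraction = 0.25, seed = 7)
  expect_identical(g2$land, g3$land)
  expect_error(make_landscape(1, 10, 50, 0, 1), "n_cols")
  # land mass is 4-connected: flood fill from one land cell reaches all
  land <- land_cells(g2)
  reached <- land[1]; frontier <- land[1]
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(id) {
      c(id - 1L, id + 1L, id - g2$n_cols, id + g2$n_cols)
    })))
    nb <- setdiff(intersect(nb, land), reached)
    reached <- c(reached, nb); frontier <- nb
  }
  expect_setequal(reached, land)
})

test_that("range-size draws match the truncated lognormal (Monte-Carlo oracle)", {
  g <- make_landscape(20, 15, 50, sea_fraction = 0.1, seed = 2)
  n_land <- sum(g$land)
  sp <- simulate_species_ranges(g, 200,
                                range_size_distribution = list(kind = "lognormal", meanlog = 2, sdlog = 1),
                                richness_gradient = list(direction = "none", strength = 0),
                                endemic_fraction = 0, corrupt_fraction = 0, seed = 3)
  set.seed(42)
  draws <- pmin(pmax(1, round(stats::rlnorm(1e6, 2, 1))), n_land)
  mu <- mean(draws); se <- stats::sd(draws) / sqrt(200)
  expect_lt(abs(mean(sp$species_table$range_size) - mu), 3 * se)
})

test_that("species/occurrence contracts hold", {
  g <- make_landscape(8, 8, 50, sea_fraction = 0.2, seed = 5)
  one <- simulate_species_ranges(g, 1,
                                 range_size_distribution = list(kind = "fixed", size = 1),
                                 corrupt_fraction = 0, seed = 2)
  cells <- locate_cells(g, one$occurrences$lon, one$occurrences$lat)
  expect_true(all(cells == one$species_table$range_cells[[1]]))
  expect_true(all(one$occurrences$valid))
  expect_error(simulate_species_ranges(g, 2,
                                       range_size_distribution = list(kind = "fixed", size = 10000)),
               "exceeds land area")
  # every species keeps >= 1 valid record inside its true range
  sp <- simulate_species_ranges(g, 30, corrupt_fraction = 0.3, seed = 9)
  for (i in seq_len(30)) {
    occ_i <- sp$occurrences[sp$occurrences$species == sp$species_table$species[i] &
                              sp$occurrences$valid, ]
    expect_gt(nrow(occ_i), 0)
    cells_i <- locate_cells(g, occ_i$lon, occ_i$lat)
    expect_true(any(cells_i %in% sp$species_table$range_cells[[i]]))
  }
})

test_that("hidden validity labels are consistent with the cleaning filters", {
  w <- synthetic_world(seed = 11, n_species = 60)
  res <- clean_records(w$occurrences, w$grid, w$native_ranges)
  expect_identical(res$report$disposition == 0L, w$occurrences$valid)
  # attributed filters equal the intended ones
  planted <- w$occurrences$intended_filter
  expect_identical(res$report$disposition[planted > 0L], planted[planted > 0L])
})

test_that("simulate_phylogeny produces binary Yule trees deterministically", {
  nwk <- simulate_phylogeny(c("a", "b"), seed = 1)
  tr <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(tr), 2L)
  nwk50 <- simulate_phylogeny(sprintf("s%02d", 1:50), seed = 2)
  tr50 <- ape::read.tree(text = nwk50)
  expect_equal(tr50$Nnode, 49L)
  expect_true(all(tr50$edge.length > 0))
  expect_setequal(tr50$tip.label, sprintf("s%02d", 1:50))
  expect_identical(nwk50, simulate_phylogeny(sprintf("s%02d", 1:50), seed = 2))
  expect_error(simulate_phylogeny("one", seed = 1), ">= 2")
})

test_that("use matrix planting matches its closed-form distance structure", {
  ids <- sprintf("s%03d", 1:40)
  # background 0, one block with p = 1 -> exact block indicator
  U <- simulate_use_matrix(ids, 4, list(list(groups = 1:2, species = 1:40, p = 1)),
                           background_probability = 0, seed = 1)
  expect_true(all(U[, 1:2] == 1L) && all(U[, 3:4] == 0L))
  expect_equal(ncol(simulate_use_matrix(ids, 24, background_probability = 0.2, seed = 1)), 24L)
  expect_error(simulate_use_matrix(ids, 4, list(list(groups = integer(0), species = 1, p = 1))),
               "empty")

  # two disjoint blocks: expected within/between p-distances from p and bg
  ids2 <- sprintf("t%03d", 1:300)
  p <- 0.95; bg <- 0.02
  U2 <- simulate_use_matrix(ids2, 24, list(
    list(groups = 1:12, species = 1:150, p = p),
    list(groups = 13:24, species = 151:300, p = p)), bg, seed = 4)
  D <- use_distance_matrix(encode_sequences(U2))
  within <- c(D[1:12, 1:12][upper.tri(D[1:12, 1:12])],
              D[13:24, 13:24][upper.tri(D[13:24, 13:24])])
  between <- as.vector(D[1:12, 13:24])
  e_within <- (150 * 2 * p * (1 - p) + 150 * 2 * bg * (1 - bg)) / 300
  e_between <- p * (1 - bg) + (1 - p) * bg
  expect_lt(max(within), min(between))
  expect_lt(abs(mean(within) - e_within), 0.05)
  expect_lt(abs(mean(between) - e_between), 0.05)
})

test_that("reserve layers hit the target coverage within tolerance", {
  g <- make_landscape(25, 20, 50, sea_fraction = 0.2, seed = 3)
  expect_equal(nrow(simulate_reserves(g, 3, 5, target_coverage = 0, seed = 1)), 0L)
  r1 <- simulate_reserves(g, 8, 14, target_coverage = 0.15, seed = 6)
  r2 <- simulate_reserves(g, 8, 14, target_coverage = 0.15, seed = 6)
  expect_identical(r1, r2)
  st <- protection_status(g, r1)
  expect_lt(abs(mean(st$either) - 0.15) / 0.15, 0.2)
})

test_that("climate scenarios, collinearity, and the i.i.d. limit behave", {
  g <- make_landscape(20, 20, 50, sea_fraction = 0, seed = 2)
  cl <- simulate_climate(g, predictor_names = c("bio1", "bio2"),
                         scenario_offsets = list(flat = list(additive = c(bio1 = 0))),
                         seed = 5)
  expect_equal(cl$scenarios$flat, cl$scenarios$current)
  r <- stats::cor(cl$scenarios$current[, "bio1"], cl$scenarios$current[, "bio1_dup"])
  expect_gt(abs(r), 0.85)
  # gradient 0, smoothing 0: i.i.d. noise, CLT bound on the mean
  cl2 <- simulate_climate(g, predictor_names = "x",
                          scenario_offsets = list(), gradient_strength = 0,
                          noise_sd = 1, noise_smooth = 0, collinear = FALSE,
                          base_levels = list(x = c(0, 1)), seed = 8)
  v <- cl2$scenarios$current[, "x"]
  expect_lt(abs(mean(v)), 4 / sqrt(length(v)))
})

test_that("world generation is a pure function of the seed, and writes a manifest", {
  w1 <- synthetic_world(seed = 21, n_species = 25, n_cols = 12, n_rows = 10)
  w2 <- synthetic_world(seed = 21, n_species = 25, n_cols = 12, n_rows = 10)
  expect_identical(w1$occurrences, w2$occurrences)
  expect_identical(w1$phylogeny, w2$phylogeny)
  expect_identical(unclass(w1$use_matrix), unclass(w2$use_matrix))
  expect_identical(w1$reserves, w2$reserves)
  expect_false(any(rowSums(w1$use_matrix) == 0L))
  dir <- withr::local_tempdir()
  write_world(w1, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$seed, 21)
  expect_true(all(file.exists(file.path(dir, man$artifacts))))
})
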