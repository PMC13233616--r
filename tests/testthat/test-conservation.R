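test_that("any positive-area intersection covers a cell", {
  g <- tiny_grid(4, 3)
  b <- cell_bounds(g, 1)
  sliver <- data.frame(id = "n1", class = "NNR",
                       xmin = b$xmax - 0.01 * g$cell_km, xmax = b$xmax + 5,
                       ymin = b$ymin, ymax = b$ymax)  # ~1% of cell 1
  st <- protection_status(g, sliver)
  expect_true(st$nnr[st$cell == 1])
  # empty layer covers nothing
  st0 <- protection_status(g, sliver[0, ])
  expect_false(any(st0$either))
  # one rectangle over the whole extent protects every land cell
  all_r <- data.frame(id = "n", class = "NNR", xmin = g$x0 - 1,
                      xmax = g$x0 + g$n_cols * g$cell_km + 1,
                      ymin = g$y0 - 1, ymax = g$y0 + g$n_rows * g$cell_km + 1)
  expect_true(all(protection_status(g, all_r)$nnr))
  # min_fraction screens out slivers
  stf <- protection_status(g, sliver, min_fraction = 0.5)
  expect_false(stf$nnr[stf$cell == 1])
})

test_that("coverage flags equal brute-force rectangle intersection", {
  g <- make_landscape(8, 6, 50, sea_fraction = 0.1, seed = 2)
  set.seed(12)
  n <- 50
  cx <- runif(n, g$x0, g$x0 + g$n_cols * g$cell_km)
  cy <- runif(n, g$y0, g$y0 + g$n_rows * g$cell_km)
  w <- runif(n, 5, 120); h <- runif(n, 5, 120)
  rects <- data.frame(id = sprintf("r%02d", 1:n),
                      class = sample(c("NNR", "PNR"), n, replace = TRUE),
                      xmin = cx - w / 2, xmax = cx + w / 2,
                      ymin = cy - h / 2, ymax = cy + h / 2)
  st <- protection_status(g, rects)
  b <- cell_bounds(g, st$cell)
  for (cls in c("NNR", "PNR")) {
    rr <- rects[rects$class == cls, ]
    brute <- vapply(seq_len(nrow(b)), function(i) {
      any(pmin(b$xmax[i], rr$xmax) > pmax(b$xmin[i], rr$xmin) &
            pmin(b$ymax[i], rr$ymax) > pmax(b$ymin[i], rr$ymin))
    }, logical(1))
    expect_identical(if (cls == "NNR") st$nnr else st$pnr, brute)
  }
  expect_identical(st$either, st$nnr | st$pnr)
})

test_that("invalid geometries are repaired or skipped with a warning", {
  g <- tiny_grid(4, 3)
  b <- cell_bounds(g, 5)
  rects <- data.frame(id = c("a", "b"), class = "NNR",
                      xmin = c(b$xmax, b$xmin), xmax = c(b$xmin, b$xmin),
                      ymin = c(b$ymin, b$ymin), ymax = c(b$ymax, b$ymax))
  expect_warning(st <- protection_status(g, rects), "invalid")
  expect_true(st$nnr[st$cell == 5])  # first rect repaired by swapping
})

test_that("effectiveness and gap accounting close on simple fixtures", {
  g <- tiny_grid(5, 4)  # 20 land cells
  hotspot <- 1:10
  b <- cell_bounds(g, 1:7)
  reserves <- data.frame(id = sprintf("n%d", 1:7), class = "NNR",
                         xmin = b$xmin + 5, xmax = b$xmax - 5,
                         ymin = b$ymin + 5, ymax = b$ymax - 5)
  # cell 8 covered by PNR only
  b8 <- cell_bounds(g, 8)
  reserves <- rbind(reserves, data.frame(id = "p1", class = "PNR",
                                         xmin = b8$xmin + 5, xmax = b8$xmax - 5,
                                         ymin = b8$ymin + 5, ymax = b8$ymax - 5))
  st <- protection_status(g, reserves)
  m <- matrix(0L, 30, 20, dimnames = list(sprintf("s%02d", 1:30), as.character(1:20)))
  m[cbind(1:30, rep(1:10, 3))] <- 1L  # 3 species per hotspot cell
  P <- presence_matrix(m)
  traits <- data.frame(species = rownames(m), endemic = rep(c(TRUE, FALSE), 15),
                       threat = "none", protected = FALSE)
  er <- effectiveness_report(hotspot, st, P, traits, "NNR")
  expect_equal(er$n_covered, 7L)
  expect_equal(er$grid_effectiveness_pct, 70)
  expect_equal(sort(c(er$covered_cells, er$gap_cells)), hotspot)  # accounting identity
  # PNR-only cell is a gap under NNR scope but not under NNR-PNR
  gp_nnr <- gap_report(hotspot, st, P, traits, "NNR")
  gp_both <- gap_report(hotspot, st, P, traits, "NNR-PNR")
  expect_true(8 %in% gp_nnr$gap_cells)
  expect_false(8 %in% gp_both$gap_cells)
  # 3 uncovered cells under NNR-PNR scope carry 9 of 30 species
  expect_equal(gp_both$n_gap, 2L)
  # fully covered world
  all_r <- data.frame(id = "n", class = "NNR", xmin = g$x0,
                      xmax = g$x0 + 999, ymin = g$y0, ymax = g$y0 + 999)
  st_all <- protection_status(g, all_r)
  er_all <- effectiveness_report(hotspot, st_all, P, traits, "NNR")
  expect_equal(er_all$grid_effectiveness_pct, 100)
  expect_length(er_all$gap_cells, 0)
  expect_error(effectiveness_report(integer(0), st, P, traits, "NNR"), "empty")
})

test_that("gap species are counted from occurrences in uncovered hotspot cells", {
  g <- tiny_grid(5, 4)
  hotspot <- 1:10
  b <- cell_bounds(g, 1:7)  # cover 7 of 10 hotspot cells
  reserves <- data.frame(id = sprintf("n%d", 1:7), class = "NNR",
                         xmin = b$xmin + 5, xmax = b$xmax - 5,
                         ymin = b$ymin + 5, ymax = b$ymax - 5)
  st <- protection_status(g, reserves)
  # 12 species confined to the 3 uncovered hotspot cells, 18 elsewhere
  m <- matrix(0L, 30, 20, dimnames = list(sprintf("s%02d", 1:30), as.character(1:20)))
  m[cbind(1:12, rep(8:10, 4))] <- 1L
  m[cbind(13:30, rep(1:6, 3))] <- 1L
  P <- presence_matrix(m)
  traits <- data.frame(species = rownames(m), endemic = FALSE, threat = "none",
                       protected = FALSE)
  gp <- gap_report(hotspot, st, P, traits, "NNR")
  expect_equal(gp$n_gap, 3L)
  expect_equal(length(gp$gap_species), 12L)
  expect_equal(gp$breakdown$n_gap[gp$breakdown$category == "all"], 12L)
})

test_that("scope monotonicity: union effectiveness dominates both parts", {
  for (seed in c(4, 9)) {
    w <- synthetic_world(seed = seed, n_species = 40, n_cols = 15, n_rows = 12)
    P <- rasterize_presence(clean_records(w$occurrences, w$grid)$cleaned, w$grid)
    traits <- w$species_table[c("species", "endemic", "threat", "protected")]
    surfaces <- compute_surfaces(P, w$phylogeny, c("sr", "sc", "we", "pa"))
    hs <- combine_rank_sum(surfaces, 0.17)
    st <- protection_status(w$grid, w$reserves)
    eff <- vapply(c("NNR", "PNR", "NNR-PNR"), function(sc)
      effectiveness_report(hs, st, P, traits, sc)$grid_effectiveness_pct, numeric(1))
    expect_gte(eff["NNR-PNR"], max(eff["NNR"], eff["PNR"]))
  }
})

test_that("the worked-example fixture reproduces its stated accounting", {
  fx <- protection_fixture(n_hotspot = 20, n_nnr_covered = 12, n_union_covered = 17,
                           n_pnr_covered = 9,
                           categories = list(other = c(40, 25, 30, 13)))
  er <- effectiveness_report(fx$hotspot_cells, fx$status, fx$P, fx$traits, "NNR")
  expect_equal(er$grid_effectiveness_pct, 60)
  expect_equal(er$species_rates$n_conserved[er$species_rates$category == "all"], 25L)
  gp <- gap_report(fx$hotspot_cells, fx$status, fx$P, fx$traits, "NNR")
  expect_equal(gp$breakdown$n_gap[gp$breakdown$category == "all"], 13L)
})
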