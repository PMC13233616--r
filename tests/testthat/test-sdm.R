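test_that("predictor screening matches an exhaustive policy check", {
  set.seed(5)
  n <- 200
  x <- rnorm(n)
  X <- cbind(a = x, b = rnorm(n), c = x + rnorm(n, 0, 0.01), d = rnorm(n))
  kept <- screen_predictors(X, 0.85)
  expect_true(all(abs(stats::cor(X[, kept])[upper.tri(diag(length(kept)))]) <= 0.85))
  expect_length(kept, 3L)  # exactly one of the duplicated pair dropped
  expect_true(xor("a" %in% kept, "c" %in% kept))
  # nothing to drop -> identity
  Y <- cbind(a = rnorm(n), b = rnorm(n))
  expect_equal(screen_predictors(Y, 0.85), c("a", "b"))
  # constant predictor dropped first with a warning
  expect_warning(k2 <- screen_predictors(cbind(X, e = rep(1, n)), 0.85), "constant")
  expect_false("e" %in% k2)

  # 4-predictor fixture vs brute force over all subsets under the policy
  set.seed(9)
  base <- rnorm(n)
  Z <- cbind(p1 = base, p2 = base + rnorm(n, 0, 0.3), p3 = rnorm(n),
             p4 = base + rnorm(n, 0, 0.35))
  kept_z <- screen_predictors(Z, 0.85)
  C <- abs(stats::cor(Z))
  ok_subsets <- Filter(function(s) all(C[s, s][upper.tri(C[s, s, drop = FALSE])] <= 0.85),
                       unlist(lapply(1:4, function(k)
                         utils::combn(colnames(Z), k, simplify = FALSE)), recursive = FALSE))
  # the retained set must be one of the constraint-satisfying subsets and
  # maximal (no superset also satisfies the constraint)
  expect_true(any(vapply(ok_subsets, function(s) setequal(s, kept_z), logical(1))))
  supersets <- Filter(function(s) all(kept_z %in% s) && length(s) > length(kept_z), ok_subsets)
  expect_length(supersets, 0L)
})

test_that("pseudo-absence sampling honours its contracts", {
  domain <- 1:100
  pres <- c(3, 14, 15, 92)
  sets <- sample_pseudo_absences(domain, 40, pres, n_sets = 2, seed = 6)
  expect_length(sets, 2L)
  for (s in sets) {
    expect_length(s, 40L)
    expect_length(intersect(s, pres), 0L)
    expect_false(any(duplicated(s)))
  }
  expect_false(identical(sets[[1]], sets[[2]]))
  expect_identical(sets, sample_pseudo_absences(domain, 40, pres, 2, seed = 6))
  # n = full availability returns the whole available set
  all_s <- sample_pseudo_absences(domain, 96, pres, 1, seed = 1)
  expect_setequal(all_s[[1]], setdiff(domain, pres))
  expect_error(sample_pseudo_absences(domain, 97, pres, 1, 1), "available")
})

test_that("stratified splits are exact, disjoint, exhaustive", {
  labels <- c(rep(1L, 10), rep(0L, 20))
  sp <- split_train_test(labels, 0.7, seed = 2)
  expect_equal(sum(labels[sp$train] == 1L), 7L)
  expect_equal(sum(labels[sp$test] == 1L), 3L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, split_train_test(labels, 0.7, seed = 2))
  expect_error(split_train_test(c(1L, 1L, 0L), 0.7, 1), ">= 2")
})

test_that("evaluation reproduces confusion-matrix arithmetic and AUC limits", {
  # TP=40 FN=10 TN=45 FP=5 at threshold 0.5
  scores <- c(rep(0.9, 40), rep(0.1, 10), rep(0.2, 45), rep(0.9, 5))
  labels <- c(rep(1L, 50), rep(0L, 50))
  st <- evaluate_predictions(scores, labels)
  expect_equal(st$sensitivity, 0.8)
  expect_equal(st$specificity, 0.9)
  expect_equal(st$tss, 0.7)
  expect_equal(st$tss, st$sensitivity + st$specificity - 1)
  # perfectly separating scores
  st2 <- evaluate_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(st2$auc, 1)
  expect_equal(st2$tss, 1)
  expect_error(evaluate_predictions(1:3, c(1, 1, 1)), "single class")
  # AUC is invariant under strictly monotone transforms
  set.seed(3)
  sc <- runif(300); lb <- rbinom(300, 1, 0.4)
  expect_equal(evaluate_predictions(sc, lb)$auc,
               evaluate_predictions(qlogis(sc / 1.0001 + 1e-5), lb)$auc)
  # label-independent scores: null AUC near 1/2
  set.seed(4)
  sc0 <- runif(10000); lb0 <- rbinom(10000, 1, 0.5)
  expect_lt(abs(evaluate_predictions(sc0, lb0)$auc - 0.5), 0.02)
})

test_that("TSS-weighted ensembling follows the weighted-mean arithmetic", {
  cells <- as.character(1:5)
  m1 <- stats::setNames(rep(0.2, 5), cells)
  m2 <- stats::setNames(rep(0.8, 5), cells)
  st1 <- structure(list(tss = 0.5, auc = 0.9), class = "eval_stats")
  st2 <- structure(list(tss = 0.75, auc = 0.9), class = "eval_stats")
  ens <- tss_weighted_ensemble(list(m1, m2), list(st1, st2))
  expect_equal(as.numeric(ens), rep((0.5 * 0.2 + 0.75 * 0.8) / 1.25, 5))
  # single passing model -> that map; failing ones ignored
  st_bad <- structure(list(tss = 0.2, auc = 0.9), class = "eval_stats")
  ens1 <- tss_weighted_ensemble(list(m1, m2), list(st1, st_bad))
  expect_equal(as.numeric(ens1), unname(m1))
  # ensemble bounded by member envelope cell-wise
  set.seed(8)
  mr1 <- stats::setNames(runif(5), cells); mr2 <- stats::setNames(runif(5), cells)
  ens2 <- tss_weighted_ensemble(list(mr1, mr2), list(st1, st2))
  expect_true(all(ens2 >= pmin(mr1, mr2) - 1e-12 & ens2 <= pmax(mr1, mr2) + 1e-12))
  expect_error(tss_weighted_ensemble(list(m1), list(st_bad)),
               class = "divprior_no_model")
})

test_that("binarization and stacking behave like their definitions", {
  m <- stats::setNames(c(0.1, 0.5, 0.9), as.character(1:3))
  expect_equal(unname(binarize(m, 0.5)), c(0L, 1L, 1L))
  expect_equal(unname(binarize(m, 0)), c(1L, 1L, 1L))
  expect_equal(unname(binarize(m, 0.95)), c(0L, 0L, 0L))
  bm <- binarize(m, 0.5)
  expect_equal(binarize(as.numeric(bm) + 0.0, 0.5), unname(bm))  # idempotent
  # stack equals independent accumulation
  set.seed(6)
  maps <- lapply(1:7, function(i)
    stats::setNames(rbinom(10, 1, 0.5), as.character(1:10)))
  stk <- stack_richness(maps, "current")
  brute <- numeric(10)
  for (m2 in maps) for (j in 1:10) brute[j] <- brute[j] + m2[[j]]
  expect_equal(unname(as.numeric(stk)), brute)
  # disjoint ranges: max SR 1, total = sum of areas
  dis <- list(stats::setNames(c(1, 0, 0), 1:3), stats::setNames(c(0, 1, 0), 1:3))
  sd2 <- stack_richness(dis)
  expect_equal(max(sd2), 1)
  expect_equal(sum(sd2), 2)
})

test_that("change assessment classifies growth, shrinkage, stasis", {
  cells <- as.character(1:12)
  mk <- function(k) stats::setNames(c(rep(1L, k), rep(0L, 12 - k)), cells)
  cur <- list(a = mk(10), b = mk(6), c = mk(4))
  fut <- list(a = mk(12), b = mk(3), c = mk(4))
  ca <- change_assessment(cur, fut)
  expect_equal(ca$species$pct_change, c(20, -50, 0))
  expect_equal(as.character(ca$species$class), c("increase", "decrease", "unchanged"))
  expect_equal(ca$class_fractions, rep(1/3, 3))
  # identical maps: no change anywhere
  ca0 <- change_assessment(cur, cur)
  expect_true(all(ca0$species$pct_change == 0))
  expect_true(all(ca0$delta_sr == 0))
  # zero current range handled explicitly
  ca1 <- change_assessment(list(x = mk(0)), list(x = mk(2)))
  expect_equal(as.character(ca1$species$class), "increase")
  expect_true(is.na(ca1$species$pct_change))
})

test_that("the envelope learner recovers a known envelope species", {
  w <- synthetic_world(seed = 19, n_cols = 20, n_rows = 16, n_species = 10)
  cl <- w$climate
  X <- cl$scenarios$current
  land <- as.integer(rownames(X))
  # true range: a box in (bio1, bio12) space
  lo <- apply(X[, c("bio1", "bio12")], 2, quantile, 0.25)
  hi <- apply(X[, c("bio1", "bio12")], 2, quantile, 0.85)
  truth <- land[X[, "bio1"] >= lo[1] & X[, "bio1"] <= hi[1] &
                  X[, "bio12"] >= lo[2] & X[, "bio12"] <= hi[2]]
  set.seed(2)
  train <- sample(truth, 100)
  suit <- reference_envelope_learner(train, X[, c("bio1", "bio12")], percentile = 0)
  expect_true(all(suit[as.character(train)] == 1))
  st <- evaluate_predictions(c(suit[as.character(truth)],
                               suit[as.character(setdiff(land, truth))]),
                             c(rep(1, length(truth)), rep(0, length(land) - length(truth))))
  bin <- binarize(suit, st$tss_max_threshold)
  recall <- mean(bin[as.character(truth)] == 1L)
  expect_gte(recall, 0.9)
  expect_error(reference_envelope_learner(train[1:3], X), ">= 5")
})

test_that("the pipeline runs end to end with scenario projections", {
  w <- synthetic_world(seed = 23, n_cols = 16, n_rows = 12, n_species = 10)
  cl <- w$climate
  X <- cl$scenarios$current
  land <- as.integer(rownames(X))
  set.seed(5)
  pres <- lapply(1:3, function(i) {
    v <- X[, "bio1"]
    cells <- land[v > quantile(v, 0.2 + 0.1 * i) & v < quantile(v, 0.7 + 0.08 * i)]
    sample(cells, min(60, length(cells)))
  })
  names(pres) <- paste0("sp", 1:3)
  res <- run_sdm_pipeline(pres, cl, n_pseudo = 150, n_rep = 2, seed = 7)
  expect_false("altitude_dup" %in% res$retained_predictors &&
                 "altitude" %in% res$retained_predictors)
  expect_setequal(names(res$stacks), names(cl$scenarios))
  expect_equal(length(res$changes), length(cl$scenarios) - 1L)
  # per-class species fractions sum to one
  for (ch in res$changes)
    expect_equal(sum(ch$class_fractions), 1)
  # reproducibility
  res2 <- run_sdm_pipeline(pres, cl, n_pseudo = 150, n_rep = 2, seed = 7)
  expect_identical(res$stacks, res2$stacks)
})
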