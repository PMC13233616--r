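## Ensemble SDM post-processing ------------------------------------------------
##
## Base statistical learners are pluggable behind a registry; the package
## ships a deterministic reference envelope learner so the machinery
## (screening, pseudo-absences, TSS/AUC evaluation, TSS-weighted
## ensembling, max-TSS binarization, stacking, change assessment) is
## testable without wrapping external model fitters.

#' Screen predictors for collinearity
#'
#' Iteratively, while any pair of predictors has |Pearson r| above
#' `r_max`, one member of the worst (largest |r|) pair is dropped: the one
#' with the larger mean absolute correlation to all other retained
#' predictors, ties resolved by dropping the later name in alphabetical
#' order. Constant predictors are dropped first with a warning.
#'
#' @param X numeric matrix, samples x named predictors (>= 3 samples).
#' @param r_max correlation bound (default 0.85).
#' @return character vector of retained predictor names (all pairwise
#'   |r| <= r_max).
#' @export
screen_predictors <- function(X, r_max = 0.85) {
  if (ncol(X) < 2L) return(colnames(X))
  if (nrow(X) < 3L) stop_invalid("need >= 3 samples to screen predictors")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant predictors dropped: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2L) break
    C <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(C) <- 0
    worst <- max(C)
    if (worst <= r_max) break
    idx <- which(C == worst, arr.ind = TRUE)[1L, ]
    pair <- keep[idx]
    mean_abs <- rowMeans(C)[idx]
    drop <- if (mean_abs[1L] > mean_abs[2L]) pair[1L]
      else if (mean_abs[2L] > mean_abs[1L]) pair[2L]
      else sort(pair)[2L]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Sample pseudo-absence sets
#'
#' `n_sets` independent uniform samples without replacement from the
#' domain cells minus the exclusion (presence) cells.
#'
#' @param domain_cells vector of candidate cell ids.
#' @param n points per set.
#' @param exclusion presence cell ids excluded from sampling.
#' @param n_sets number of independent sets (the study design uses 2).
#' @param seed master seed; each set gets a derived sub-seed.
#' @return list of integer vectors, one per set.
#' @export
sample_pseudo_absences <- function(domain_cells, n, exclusion = integer(0),
                                   n_sets = 2, seed = 1) {
  n <- check_count(n, "n", 1L)
  n_sets <- check_count(n_sets, "n_sets", 1L)
  avail <- setdiff(domain_cells, exclusion)
  if (length(avail) < n)
    stop_invalid("need ", n, " pseudo-absences but only ", length(avail),
                 " cells are available")
  seeds <- derive_seeds(seed, n_sets, salt = 7L)
  lapply(seq_len(n_sets), function(s)
    with_seed(seeds[s], sort(safe_sample(avail, n))))
}

#' Stratified train/test split
#'
#' `floor(train_fraction * n)` points of each label class go to training,
#' the rest to evaluation.
#'
#' @param labels 0/1 vector.
#' @param train_fraction training fraction (the study design uses 0.7).
#' @param seed RNG seed.
#' @return list of integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_train_test <- function(labels, train_fraction = 0.7, seed = 1) {
  check_fraction(train_fraction, "train_fraction", 0, 1, lo_open = TRUE, hi_open = TRUE)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop_invalid("need >= 2 points of each label to split")
  train <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(l) {
      idx <- which(labels == l)
      idx[sample.int(length(idx), floor(train_fraction * length(idx)))]
    }))
  })
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

#' Evaluate suitability scores against presence/absence labels
#'
#' AUC uses the rank (Mann-Whitney) statistic with midrank ties. The
#' threshold grid is the set of unique score values; predictions are
#' positive at `score >= threshold`; the reported threshold is the
#' smallest one attaining the maximal TSS, and sensitivity/specificity/TSS
#' are reported at that threshold (TSS = sensitivity + specificity - 1).
#'
#' @param scores numeric suitability per point.
#' @param labels 0/1 per point (both classes required).
#' @return `eval_stats`: list `sensitivity, specificity, tss, auc,
#'   tss_max_threshold`.
#' @export
evaluate_predictions <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_invalid("undefined metrics: labels contain a single class")
  r <- rank(scores)  # midranks for ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  # counts of points with score >= t via reverse cumulative sums over the
  # sorted scores (first occurrence of each threshold value)
  ord <- order(scores)
  s_sorted <- scores[ord]; l_sorted <- labels[ord]
  first_idx <- match(thr, s_sorted)
  tail_pos <- rev(cumsum(rev(l_sorted)))
  tail_all <- length(s_sorted) - seq_along(s_sorted) + 1L
  TP <- tail_pos[first_idx]
  FP <- tail_all[first_idx] - TP
  sens <- TP / n1
  spec <- (n0 - FP) / n0
  tss <- sens + spec - 1
  best <- max(tss)
  i <- which(tss == best)[1L]  # thresholds ascending: first = smallest
  structure(list(sensitivity = sens[i], specificity = spec[i], tss = tss[i],
                 auc = auc, tss_max_threshold = thr[i]),
            class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf("<eval_stats> TSS %.3f (sens %.3f, spec %.3f) AUC %.3f at threshold %.4g\n",
              x$tss, x$sensitivity, x$specificity, x$auc, x$tss_max_threshold))
  invisible(x)
}

#' TSS-weighted ensemble of suitability maps
#'
#' Members passing both bounds (TSS >= `tss_min` and AUC >= `auc_min`)
#' are averaged cell-wise with their TSS as weights. If no member passes,
#' a `divprior_no_model` error is signalled so callers can exclude the
#' species and log it.
#'
#' @param maps list of named numeric suitability vectors (same cells).
#' @param stats list of `eval_stats`, parallel to `maps`.
#' @param tss_min,auc_min retention bounds (study design: 0.5 and 0.7).
#' @return named numeric ensemble map with attribute `pass` (indices of
#'   retained members).
#' @export
tss_weighted_ensemble <- function(maps, stats, tss_min = 0.5, auc_min = 0.7) {
  stopifnot(length(maps) == length(stats))
  tss <- vapply(stats, `[[`, numeric(1), "tss")
  auc <- vapply(stats, `[[`, numeric(1), "auc")
  pass <- which(tss >= tss_min & auc >= auc_min)
  if (length(pass) == 0L)
    stop(structure(class = c("divprior_no_model", "error", "condition"),
                   list(message = "no model passed the TSS/AUC bounds",
                        call = sys.call(-1))))
  w <- tss[pass]
  ens <- Reduce(`+`, Map(function(m, wi) m * wi, maps[pass], w)) / sum(w)
  attr(ens, "pass") <- pass
  ens
}

#' Binarize a suitability map
#'
#' @param map named numeric suitability vector.
#' @param threshold cutoff in [0, 1]; presence iff suitability >=
#'   threshold.
#' @return named integer 0/1 vector.
#' @export
binarize <- function(map, threshold) {
  check_fraction(threshold, "threshold")
  out <- as.integer(map >= threshold)
  names(out) <- names(map)
  out
}

#' Stacked species richness from binary maps
#'
#' @param binary_maps list of named 0/1 vectors on identical cells.
#' @param scenario label recorded in provenance.
#' @return `metric_surface` "SR": per-cell sum of presences.
#' @export
stack_richness <- function(binary_maps, scenario = "current") {
  cells <- names(binary_maps[[1L]])
  for (m in binary_maps)
    if (!identical(names(m), cells)) stop_invalid("binary maps have mismatched geometry")
  metric_surface(Reduce(`+`, lapply(binary_maps, as.numeric)),
                 "SR", list(scenario = scenario, n_species = length(binary_maps))) -> s
  names(s) <- cells
  s
}

#' Range-change assessment between two scenarios
#'
#' Per species: current and future areas (cell counts), percent area
#' change (future - current) / current x 100, and a class by sign (exact
#' zero = "unchanged"; species with zero current area are classed
#' "increase" when the future area is positive, else "unchanged", with
#' `pct_change` = NA). Per cell: richness difference and its sign class.
#'
#' @param current_maps,future_maps named lists of binary maps (same
#'   species, same cells).
#' @return `change_assessment`: `species` table, `class_fractions`,
#'   `delta_sr` (named numeric), `delta_class` (factor).
#' @export
change_assessment <- function(current_maps, future_maps) {
  if (!identical(names(current_maps), names(future_maps)))
    stop_invalid("species sets differ between scenarios")
  sp <- names(current_maps)
  cur <- vapply(current_maps, sum, numeric(1))
  fut <- vapply(future_maps, sum, numeric(1))
  pct <- ifelse(cur > 0, (fut - cur) / cur * 100, NA_real_)
  cls <- ifelse(cur == 0, ifelse(fut > 0, "increase", "unchanged"),
                ifelse(fut > cur, "increase", ifelse(fut < cur, "decrease", "unchanged")))
  species <- data.frame(species = sp, current_area = cur, future_area = fut,
                        pct_change = pct,
                        class = factor(cls, levels = c("increase", "decrease", "unchanged")),
                        row.names = NULL, stringsAsFactors = FALSE)
  frac <- table(species$class) / length(sp)
  d_sr <- as.numeric(stack_richness(future_maps, "future")) -
    as.numeric(stack_richness(current_maps, "current"))
  names(d_sr) <- names(current_maps[[1L]])
  structure(list(species = species,
                 class_fractions = as.numeric(frac),
                 class_levels = names(frac),
                 delta_sr = d_sr,
                 delta_class = factor(ifelse(d_sr > 0, "increase",
                                             ifelse(d_sr < 0, "decrease", "unchanged")),
                                      levels = c("increase", "decrease", "unchanged"))),
            class = "change_assessment")
}

## reference envelope learner --------------------------------------------------

envelope_fit <- function(train_vals, percentile = 0) {
  lo <- apply(train_vals, 2L, stats::quantile, probs = percentile / 100, names = FALSE)
  hi <- apply(train_vals, 2L, stats::quantile, probs = 1 - percentile / 100, names = FALSE)
  list(lo = lo, hi = hi, predictors = colnames(train_vals))
}

envelope_predict <- function(model, predictors) {
  X <- predictors[, model$predictors, drop = FALSE]
  inside <- sweep(X, 2L, model$lo, ">=") & sweep(X, 2L, model$hi, "<=")
  out <- rowMeans(inside)
  names(out) <- rownames(predictors)
  out
}

#' Reference percentile-envelope learner
#'
#' The built-in, deterministic stand-in for external suitability models:
#' suitability of a cell is the fraction of predictors whose value lies
#' inside the [p, 100 - p] percentile window of the training presences.
#'
#' @param train_cells presence cell ids used for training (>= 5).
#' @param predictors numeric matrix, cells x predictors, rownames = cell
#'   ids.
#' @param percentile window trim p in percent (0 = min/max envelope).
#' @return named suitability vector over the rows of `predictors`, with
#'   the fitted model in attribute `model`.
#' @export
reference_envelope_learner <- function(train_cells, predictors, percentile = 0) {
  rows <- match(as.character(train_cells), rownames(predictors))
  if (sum(!is.na(rows)) < 5L) stop_invalid("need >= 5 training presences")
  model <- envelope_fit(predictors[rows[!is.na(rows)], , drop = FALSE], percentile)
  out <- envelope_predict(model, predictors)
  attr(out, "model") <- model
  out
}

## learner registry: name -> function(train_cells, predictors, ...) that
## returns a function(new_predictors) -> suitability vector
.learners <- new.env(parent = emptyenv())

#' Register / fetch suitability learners by name
#'
#' A learner factory takes `(train_cells, predictors, ...)` and returns a
#' prediction function over new predictor matrices, so fitted models can
#' be projected onto climate scenarios. The `"envelope"` learner is
#' pre-registered.
#'
#' @param name learner name.
#' @param factory learner factory function.
#' @return `get_learner` returns the factory.
#' @export
register_learner <- function(name, factory) {
  assign(name, factory, envir = .learners)
  invisible(name)
}

#' @rdname register_learner
#' @export
get_learner <- function(name) {
  if (!exists(name, envir = .learners)) stop_invalid("unknown learner: ", name)
  get(name, envir = .learners)
}

register_learner("envelope", function(train_cells, predictors, percentile = 0, ...) {
  rows <- match(as.character(train_cells), rownames(predictors))
  if (sum(!is.na(rows)) < 5L) stop_invalid("need >= 5 training presences")
  model <- envelope_fit(predictors[rows[!is.na(rows)], , drop = FALSE], percentile)
  function(new_predictors) envelope_predict(model, new_predictors)
})

#' Run the ensemble-SDM pipeline for a set of species
#'
#' For each species: sample `n_sets` pseudo-absence sets, run `n_rep`
#' replicate 70/30 stratified splits per set, fit the learner on each
#' training split, evaluate TSS/AUC on the held-out points, ensemble the
#' members passing the bounds with TSS weights, re-evaluate the ensemble
#' on all points to find its max-TSS threshold, binarize under every
#' scenario, and stack per-scenario richness. Species where no member
#' passes are excluded and logged, mirroring the retention rule.
#'
#' @param species_presences named list: per species, presence cell ids
#'   (already thinned).
#' @param climate a `div_climate` (scenario "current" required).
#' @param learner registered learner name.
#' @param n_pseudo pseudo-absences per set (capped at availability).
#' @param n_sets pseudo-absence sets (default 2).
#' @param n_rep replicate splits per set (default 10).
#' @param train_fraction training fraction (default 0.7).
#' @param tss_min,auc_min ensemble retention bounds.
#' @param r_max collinearity bound for predictor screening.
#' @param percentile envelope window for the reference learner.
#' @param seed master seed; all internal seeds derive from it.
#' @return list: `retained_predictors`, `species` (per-species list with
#'   eval stats, ensemble threshold, binary maps per scenario),
#'   `excluded`, `stacks` (per-scenario SR surfaces), `changes`
#'   (per-scenario `change_assessment` vs current), `manifest`.
#' @export
run_sdm_pipeline <- function(species_presences, climate, learner = "envelope",
                             n_pseudo = 10000, n_sets = 2, n_rep = 10,
                             train_fraction = 0.7, tss_min = 0.5, auc_min = 0.7,
                             r_max = 0.85, percentile = 0, seed = 1) {
  current <- climate$scenarios$current
  if (is.null(current)) stop_invalid("climate must include a 'current' scenario")
  retained <- screen_predictors(current, r_max)
  scen_names <- names(climate$scenarios)
  preds <- lapply(climate$scenarios, function(m) m[, retained, drop = FALSE])
  domain <- as.integer(rownames(current))
  factory <- get_learner(learner)
  sp_seeds <- derive_seeds(seed, length(species_presences), salt = 13L)

  fitted <- list(); excluded <- character(0)
  for (si in seq_along(species_presences)) {
    sp <- names(species_presences)[si]
    pres <- intersect(species_presences[[si]], domain)
    n_abs <- min(n_pseudo, length(domain) - length(pres))
    pa_sets <- sample_pseudo_absences(domain, n_abs, pres, n_sets, seed = sp_seeds[si])
    maps <- list(); stats <- list()
    rep_seeds <- derive_seeds(sp_seeds[si], n_sets * n_rep, salt = 29L)
    k <- 0L
    for (s in seq_len(n_sets)) for (rep in seq_len(n_rep)) {
      k <- k + 1L
      pts <- c(pres, pa_sets[[s]])
      labels <- c(rep(1L, length(pres)), rep(0L, length(pa_sets[[s]])))
      split <- split_train_test(labels, train_fraction, seed = rep_seeds[k])
      predict_fn <- factory(pts[split$train][labels[split$train] == 1L],
                            preds$current, percentile = percentile)
      map <- predict_fn(preds$current)
      test_scores <- map[as.character(pts[split$test])]
      st <- evaluate_predictions(test_scores, labels[split$test])
      maps[[k]] <- map; stats[[k]] <- st
      attr(maps[[k]], "predict_fn") <- predict_fn
    }
    ens <- tryCatch(tss_weighted_ensemble(maps, stats, tss_min, auc_min),
                    divprior_no_model = function(e) NULL)
    if (is.null(ens)) { excluded <- c(excluded, sp); next }
    pass <- attr(ens, "pass")
    # scenario ensembles from the same passing members and weights
    w <- vapply(stats[pass], `[[`, numeric(1), "tss")
    ens_by_scen <- lapply(scen_names, function(sc) {
      member_maps <- lapply(pass, function(j) attr(maps[[j]], "predict_fn")(preds[[sc]]))
      Reduce(`+`, Map(`*`, member_maps, w)) / sum(w)
    })
    names(ens_by_scen) <- scen_names
    all_pts <- c(pres, unique(unlist(pa_sets)))
    all_lab <- c(rep(1L, length(pres)), rep(0L, length(unique(unlist(pa_sets)))))
    ens_stats <- evaluate_predictions(ens[as.character(all_pts)], all_lab)
    bin <- lapply(ens_by_scen, binarize, threshold = ens_stats$tss_max_threshold)
    fitted[[sp]] <- list(stats = stats, pass = pass, ensemble_stats = ens_stats,
                         threshold = ens_stats$tss_max_threshold,
                         binary = bin)
  }
  if (length(fitted) == 0L) stop_invalid("no species could be modelled")
  stacks <- lapply(scen_names, function(sc)
    stack_richness(lapply(fitted, function(f) f$binary[[sc]]), sc))
  names(stacks) <- scen_names
  changes <- lapply(setdiff(scen_names, "current"), function(sc)
    change_assessment(lapply(fitted, function(f) f$binary$current),
                      lapply(fitted, function(f) f$binary[[sc]])))
  names(changes) <- setdiff(scen_names, "current")
  list(retained_predictors = retained, species = fitted, excluded = excluded,
       stacks = stacks, changes = changes,
       manifest = list(seed = seed, learner = learner, n_sets = n_sets,
                       n_rep = n_rep, n_pseudo = n_pseudo,
                       train_fraction = train_fraction,
                       tss_min = tss_min, auc_min = auc_min, r_max = r_max,
                       pa_mode = "separate"))
}
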