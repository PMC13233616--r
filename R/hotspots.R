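## Hotspot selection and overlay ----------------------------------------------

default_hotspot_thresholds <- c(0.05, 0.10, 0.17, 0.30)

#' Top-fraction cells of a surface
#'
#' Returns the k cells with the highest value, where k = `n_target`, or
#' `floor(q * n_land)` when `n_target = "auto"`. Ties at the cut are
#' broken by higher species richness (when an SR surface is supplied) and
#' then by lower cell id, so selection is deterministic.
#'
#' @param surface a `metric_surface`.
#' @param q fraction of land cells, in (0, 1).
#' @param n_target explicit cell count, or `"auto"`.
#' @param sr optional SR surface used for tie-breaking.
#' @return integer vector of selected cell ids.
#' @export
top_fraction_cells <- function(surface, q, n_target = "auto", sr = NULL) {
  if (length(surface) == 0L) stop_invalid("surface is empty")
  check_fraction(q, "q", 0, 1, lo_open = TRUE, hi_open = TRUE)
  k <- if (identical(n_target, "auto")) floor(q * length(surface)) else
    check_count(n_target, "n_target", 1L)
  if (k == 0L) stop_invalid("q = ", q, " selects 0 of ", length(surface), " cells")
  ids <- as.integer(names(surface))
  tie_sr <- if (is.null(sr)) numeric(length(surface)) else as.numeric(sr[names(surface)])
  ord <- order(-as.numeric(surface), -tie_sr, ids)
  ids[ord[seq_len(min(k, length(ids)))]]
}

dense_rank_desc <- function(v) match(v, sort(unique(v), decreasing = TRUE))

#' Merge per-metric hotspots by rank-sum overlay
#'
#' Candidate cells are the union of the per-metric top sets. Each
#' candidate is scored by the sum over metrics of its dense rank in that
#' metric's full surface (rank 1 = best, computed for every cell so
#' candidates missing from one metric's top set remain comparable). The
#' final set is the `n_target` candidates with the smallest rank-sum; ties
#' are broken by per-metric membership count (descending), SR
#' (descending), then cell id. Tier labels: cells in all four metric top
#' sets are Class I, three Class II, two Class III, one "unclassified".
#'
#' @param surfaces named list of `metric_surface`s (>= 2), e.g. SR,
#'   SC_rank, WE, PA.
#' @param q threshold fraction (records into the result; also sets the
#'   count when `n_target = "auto"`).
#' @param n_target final hotspot cell count, or `"auto"` for
#'   `floor(q * n_land)`.
#' @param sr SR surface for tie-breaks; defaults to `surfaces$SR`.
#' @return object of class `hotspot_set`: `q`, `n_target`, `final`
#'   (ordered cell ids), `rank_sum`, `membership` (per-final-cell count),
#'   `per_metric` (top sets), `tier` (factor I/II/III/unclassified).
#' @export
combine_rank_sum <- function(surfaces, q, n_target = "auto", sr = NULL) {
  if (length(surfaces) < 2L) stop_invalid("need >= 2 metric surfaces")
  sr <- sr %||% surfaces$SR
  k <- if (identical(n_target, "auto")) floor(q * length(surfaces[[1L]])) else
    check_count(n_target, "n_target", 1L)
  per_metric <- lapply(surfaces, top_fraction_cells, q = q, n_target = k, sr = sr)
  candidates <- sort(unique(unlist(per_metric)))
  ranks <- vapply(surfaces, function(s) {
    dr <- dense_rank_desc(as.numeric(s))
    dr[match(candidates, as.integer(names(s)))]
  }, numeric(length(candidates)))
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1L)
  memb <- vapply(per_metric, function(set) candidates %in% set,
                 logical(length(candidates)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1L)
  rank_sum <- rowSums(ranks)
  membership <- rowSums(memb)
  tie_sr <- if (is.null(sr)) numeric(length(candidates)) else
    as.numeric(sr[as.character(candidates)])
  ord <- order(rank_sum, -membership, -tie_sr, candidates)
  if (length(candidates) < k) {
    warning("union of per-metric top sets (", length(candidates),
            ") is smaller than the target (", k, "); returning all candidates")
    k <- length(candidates)
  }
  keep <- ord[seq_len(k)]
  hs <- structure(list(q = q, n_target = k,
                       final = candidates[keep],
                       rank_sum = rank_sum[keep],
                       membership = membership[keep],
                       per_metric = per_metric),
                  class = "hotspot_set")
  hs$tier <- classify_tiers(hs)
  hs
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> q = %g: %d cells (tiers: %s)\n", x$q,
              length(x$final), paste(names(table(x$tier)), table(x$tier),
                                     sep = "=", collapse = ", ")))
  invisible(x)
}

#' Tier labels from per-metric membership
#'
#' @param hotspot_set a `hotspot_set`.
#' @return factor over the final cells with levels
#'   `I`, `II`, `III`, `unclassified` (identified by 4/3/2/1 metrics).
#' @export
classify_tiers <- function(hotspot_set) {
  m <- hotspot_set$membership
  factor(ifelse(m >= 4, "I", ifelse(m == 3, "II", ifelse(m == 2, "III", "unclassified"))),
         levels = c("I", "II", "III", "unclassified"))
}

#' Species coverage of a hotspot set, by category
#'
#' For each category (all, endemic, threatened, protected), the percentage
#' of its species with at least one occupied cell inside the final hotspot
#' set. Percentages are rounded half-up.
#'
#' @param hotspot_set a `hotspot_set` (or integer vector of cell ids).
#' @param P a `presence_matrix`.
#' @param traits data.frame with `species`, logical `endemic`, `threat`
#'   (category or "none"), logical `protected`.
#' @param digits decimals for the printed percentage (default 2).
#' @return data.frame `category, n_total, n_covered, pct` (`pct` is `NA`
#'   for empty categories).
#' @export
species_coverage <- function(hotspot_set, P, traits, digits = 2) {
  cells <- if (inherits(hotspot_set, "hotspot_set")) hotspot_set$final else hotspot_set
  inside <- colnames(P) %in% as.character(cells)
  covered_sp <- rownames(P)[rowSums(P[, inside, drop = FALSE]) > 0L]
  cat_members <- list(
    all = traits$species,
    endemic = traits$species[traits$endemic],
    threatened = traits$species[traits$threat != "none"],
    protected = traits$species[traits$protected])
  do.call(rbind, lapply(names(cat_members), function(cat) {
    sp <- cat_members[[cat]]
    n <- length(sp); cov <- sum(sp %in% covered_sp)
    data.frame(category = cat, n_total = n, n_covered = cov,
               pct = if (n == 0L) NA_real_ else round_half_up(100 * cov / n, digits),
               stringsAsFactors = FALSE)
  }))
}

#' Hotspot table export
#'
#' One row per final hotspot cell: rank-sum score, per-metric membership
#' bits, and tier.
#'
#' @param hotspot_set a `hotspot_set`.
#' @param path CSV path (optional).
#' @return the data.frame, invisibly written to `path` when given.
#' @export
hotspot_table <- function(hotspot_set, path = NULL) {
  bits <- vapply(hotspot_set$per_metric,
                 function(set) hotspot_set$final %in% set,
                 logical(length(hotspot_set$final)))
  out <- data.frame(cell = hotspot_set$final, rank_sum = hotspot_set$rank_sum,
                    membership = hotspot_set$membership,
                    tier = as.character(hotspot_set$tier), bits)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
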