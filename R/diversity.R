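## Diversity surfaces ----------------------------------------------------------
##
## All metrics are computed per land cell from a presence_matrix; PD/PE
## additionally take a rooted phylogeny with branch lengths. Surfaces are
## named numeric vectors over cell ids with provenance recorded as
## attributes.

metric_surface <- function(values, metric, provenance = list()) {
  structure(values, metric = metric, provenance = provenance,
            class = "metric_surface")
}

#' @export
print.metric_surface <- function(x, ...) {
  cat(sprintf("<metric_surface> %s on %d cells; range [%g, %g]\n",
              attr(x, "metric"), length(x), min(x), max(x)))
  invisible(x)
}

#' Write a metric surface as a cell-id/value table
#' @param surface a `metric_surface`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_surface <- function(surface, path) {
  utils::write.csv(data.frame(cell = names(surface), value = as.numeric(surface)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Species richness per cell
#'
#' @param P a `presence_matrix`.
#' @return `metric_surface` "SR": count of species present per cell.
#' @export
species_richness <- function(P) {
  if (nrow(P) == 0L) stop_invalid("presence matrix is empty")
  metric_surface(colSums(P), "SR")
}

#' Weighted endemism (range-size rarity) per cell
#'
#' WE(cell) = sum over species present of 1 / range_size(species), so a
#' single-cell endemic contributes a full unit to its only cell and the
#' surface sums to the number of species.
#'
#' @param P a `presence_matrix`.
#' @return `metric_surface` "WE".
#' @export
weighted_endemism <- function(P) {
  rs <- range_sizes(P)
  if (any(rs < 1L)) stop_invalid("all species need range size >= 1")
  metric_surface(colSums(P / rs), "WE")
}

#' Greedy complementarity (minimum-set) cell selection
#'
#' Repeatedly selects the cell adding the most not-yet-represented species
#' until all species are covered. Ties are broken by higher total species
#' richness, then lower cell id. The `sc_rank` surface encodes selection
#' order as descending scores (first selected = highest), 0 for unselected
#' cells, so complementarity can enter top-fraction hotspot selection like
#' any other surface.
#'
#' @param P a `presence_matrix`.
#' @return list of class `complementarity_result`: `selected` (cell ids in
#'   order), `gains` (new species added by each), `cover_size`, and
#'   `sc_rank` (a `metric_surface`).
#' @export
complementarity <- function(P) {
  if (nrow(P) == 0L) stop_invalid("presence matrix is empty")
  remaining <- matrix(as.logical(P), nrow(P), ncol(P), dimnames = dimnames(P))
  sr <- colSums(P)
  cell_ids <- as.integer(colnames(P))
  selected <- integer(0)
  gains <- integer(0)
  uncovered <- rep(TRUE, nrow(P))
  while (any(uncovered)) {
    new_per_cell <- colSums(remaining[uncovered, , drop = FALSE])
    best <- max(new_per_cell)
    cand <- which(new_per_cell == best)
    cand <- cand[order(-sr[cand], cell_ids[cand])]
    pick <- cand[1L]
    selected <- c(selected, pick)
    gains <- c(gains, best)
    uncovered <- uncovered & !remaining[, pick]
  }
  score <- numeric(ncol(P))
  names(score) <- colnames(P)
  score[selected] <- rev(seq_along(selected))
  structure(list(selected = cell_ids[selected], gains = gains,
                 cover_size = length(selected),
                 sc_rank = metric_surface(score, "SC_rank",
                                          list(tie_break = "SR desc, cell id asc"))),
            class = "complementarity_result")
}

#' @export
print.complementarity_result <- function(x, ...) {
  cat("<complementarity_result> cover size", x$cover_size, "\n")
  invisible(x)
}

## phylogeny matching ----------------------------------------------------------

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree)) return(ape::read.tree(text = tree))
  stop_invalid("tree must be a phylo object or a Newick string")
}

## edge x species incidence: E[e, s] = 1 iff tip s descends from edge e
edge_tip_incidence <- function(tree, species) {
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # edges in postorder so children are resolved before parents
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  E <- matrix(0L, n_edge, length(species))
  tip_col <- match(tree$tip.label, species)
  for (e in seq_len(n_edge)) {
    tips <- desc[[tree$edge[e, 2]]]
    cols <- tip_col[tips]
    E[e, cols[!is.na(cols)]] <- 1L
  }
  E
}

match_tree <- function(P, tree) {
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length)) stop_invalid("tree has no branch lengths")
  matched <- intersect(rownames(P), tree$tip.label)
  if (length(matched) == 0L) stop_invalid("no species matched between matrix and tree")
  unmatched <- setdiff(rownames(P), tree$tip.label)
  # the supplied tree is used as-is (tips absent from the matrix keep the
  # root-path structure intact; their branches simply never enter a cell)
  list(tree = tree, matched = matched, unmatched = unmatched)
}

#' Faith's phylogenetic diversity per cell
#'
#' PD(cell) is the summed branch length of the minimal subtree connecting
#' the cell's species to the root (root path included). Species absent
#' from the tree are excluded from PD/PE only, and logged in the surface's
#' provenance; cells with no matched species get PD = 0.
#'
#' @param P a `presence_matrix`.
#' @param tree a `phylo` object or Newick string.
#' @return `metric_surface` "PD" with provenance recording the root-path
#'   convention and unmatched species.
#' @export
phylogenetic_diversity <- function(P, tree) {
  mt <- match_tree(P, tree)
  E <- edge_tip_incidence(mt$tree, rownames(P))
  B <- (E %*% P) > 0  # edge present in cell iff any descendant tip present
  pd <- colSums(B * mt$tree$edge.length)
  metric_surface(pd, "PD",
                 list(convention = "rooted; root path included",
                      unmatched_species = mt$unmatched))
}

#' Phylogenetic endemism per cell
#'
#' PE(cell) sums, over branches of the cell's rooted spanning subtree,
#' branch length divided by the branch's range: the number of grid cells
#' occupied by the union of its descendant tips. Summed over all cells PE
#' telescopes to the total tree length.
#'
#' @inheritParams phylogenetic_diversity
#' @return `metric_surface` "PE".
#' @export
phylogenetic_endemism <- function(P, tree) {
  mt <- match_tree(P, tree)
  E <- edge_tip_incidence(mt$tree, rownames(P))
  B <- (E %*% P) > 0
  branch_range <- rowSums(B)  # cells occupied by each branch's clade
  w <- ifelse(branch_range > 0, mt$tree$edge.length / branch_range, 0)
  pe <- colSums(B * w)
  metric_surface(pe, "PE",
                 list(convention = "rooted; branch range = occupied analysis-grid cells",
                      unmatched_species = mt$unmatched))
}

#' Composite phylogenetic index PA
#'
#' PA(cell) = PD(cell)/max(PD) + PE(cell)/max(PE), bounded in [0, 2].
#'
#' @param pd,pe `metric_surface`s on identical cell sets.
#' @return `metric_surface` "PA" with PD_max/PE_max in provenance.
#' @export
pa_index <- function(pd, pe) {
  if (!identical(names(pd), names(pe))) stop_invalid("pd and pe are on different cell sets")
  pd_max <- max(pd); pe_max <- max(pe)
  if (pd_max <= 0 || pe_max <= 0) stop_invalid("degenerate landscape: zero PD or PE maximum")
  metric_surface(as.numeric(pd) / pd_max + as.numeric(pe) / pe_max,
                 "PA", list(PD_max = pd_max, PE_max = pe_max)) -> s
  names(s) <- names(pd)
  s
}

#' Pearson correlation between two surfaces
#'
#' @param a,b `metric_surface`s (or named numeric vectors) on the same
#'   cells.
#' @return list `r`, `p` (two-sided, t transform), `n`.
#' @export
pattern_correlation <- function(a, b) {
  if (!identical(names(a), names(b))) stop_invalid("surfaces are on different cell sets")
  n <- length(a)
  if (n < 3L) stop_invalid("need >= 3 paired cells")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop_invalid("undefined correlation: zero variance surface")
  ct <- stats::cor.test(as.numeric(a), as.numeric(b), method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
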