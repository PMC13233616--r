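## Ethnic-use matrix analytics -------------------------------------------------
##
## The use matrix U is species x groups with 0/1 entries (1 = the group
## uses the species). Composition statistics follow the common/unique
## convention: species used by exactly one group are unique to it, species
## used by two or more groups are common.

subset_species <- function(U, traits, subset) {
  subset <- match.arg(subset, c("all", "endemic", "threatened"))
  if (subset == "all") return(U)
  if (is.null(traits)) stop_invalid("traits required for subset '", subset, "'")
  keep <- switch(subset,
                 endemic = traits$species[traits$endemic],
                 threatened = traits$species[traits$threat != "none"])
  U[rownames(U) %in% keep, , drop = FALSE]
}

#' Per-group species composition
#'
#' @param U binary use matrix, species x groups (dimnames required).
#' @param traits optional trait table for subsetting.
#' @param subset `"all"`, `"endemic"` or `"threatened"`.
#' @return data.frame `group, total, unique, shared` (shared = used by
#'   this group and at least one other), with attribute `n_common` = the
#'   number of species used by two or more groups overall.
#' @export
group_composition <- function(U, traits = NULL, subset = "all") {
  U <- subset_species(U, traits, subset)
  k <- rowSums(U)
  uni <- colSums(U[k == 1L, , drop = FALSE])
  tot <- colSums(U)
  out <- data.frame(group = colnames(U), total = as.integer(tot),
                    unique = as.integer(uni),
                    shared = as.integer(tot - uni), stringsAsFactors = FALSE)
  attr(out, "n_common") <- sum(k >= 2L)
  out
}

#' Use-frequency distribution
#'
#' Histogram of species by the number of groups using them.
#'
#' @inheritParams group_composition
#' @return data.frame `k, n_species` for k = 1..n_groups; counts sum to
#'   the number of species in the subset (all-zero rows, if any slipped
#'   in, are reported under k = 0).
#' @export
use_frequency_distribution <- function(U, traits = NULL, subset = "all") {
  U <- subset_species(U, traits, subset)
  k <- rowSums(U)
  kk <- 0:ncol(U)
  counts <- vapply(kk, function(x) sum(k == x), integer(1))
  out <- data.frame(k = kk, n_species = counts)
  out[out$k > 0L | out$n_species > 0L, ]
}

#' Encode the use matrix as binary sequences
#'
#' Each group becomes one character sequence over the alphabet {A, C} in a
#' fixed, recorded species order: position j is `A` iff the group uses
#' species j (1 = A, 0 = C). Optional outgroup rows (named binary vectors
#' over the same species) are appended.
#'
#' @param U binary use matrix, species x groups.
#' @param outgroups optional named list/matrix of extra binary rows
#'   (length = number of species).
#' @return object of class `coded_sequences`: named character vector of
#'   sequences with attribute `species` (the position order).
#' @export
encode_sequences <- function(U, outgroups = NULL) {
  species <- rownames(U)
  enc <- function(v) paste(ifelse(v == 1L, "A", "C"), collapse = "")
  seqs <- apply(U, 2L, enc)
  if (!is.null(outgroups)) {
    og <- if (is.matrix(outgroups) || is.data.frame(outgroups))
      as.list(as.data.frame(t(outgroups))) else outgroups
    if (is.null(names(og)) && (is.matrix(outgroups) || is.data.frame(outgroups)))
      names(og) <- rownames(outgroups)
    for (nm in names(og)) {
      if (length(og[[nm]]) != length(species))
        stop_invalid("outgroup '", nm, "' length != number of species")
      seqs[nm] <- enc(as.integer(og[[nm]]))
    }
  }
  structure(seqs, species = species, class = "coded_sequences")
}

#' Decode sequences back into a binary matrix
#' @param C a `coded_sequences`.
#' @return binary species x sequence matrix (the encode/decode round trip
#'   is exact).
#' @export
decode_sequences <- function(C) {
  m <- vapply(C, function(s) as.integer(strsplit(s, "")[[1]] == "A"),
              integer(nchar(C[[1]])))
  rownames(m) <- attr(C, "species")
  m
}

#' Export coded sequences
#'
#' FASTA and NEXUS writers so the coding can be fed to external
#' phylogenetics tools.
#'
#' @param C a `coded_sequences`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sequences_fasta <- function(C, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(C)) writeLines(c(paste0(">", nm), C[[nm]]), con)
  invisible(path)
}

#' @rdname write_sequences_fasta
#' @export
write_sequences_nexus <- function(C, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(C), nchar(C[[1]])),
               "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX"), con)
  for (nm in names(C)) writeLines(sprintf("%s  %s", nm, C[[nm]]), con)
  writeLines(c(";", "END;"), con)
  invisible(path)
}

#' Pairwise p-distance between coded sequences
#'
#' Hamming distance divided by sequence length; on this binary coding it
#' equals simple-matching dissimilarity of the use matrix columns.
#'
#' @param C a `coded_sequences` (equal lengths required).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
use_distance_matrix <- function(C) {
  if (length(C) < 2L) stop_invalid("need >= 2 sequences")
  L <- nchar(C[[1L]])
  if (any(nchar(C) != L)) stop_invalid("sequences have unequal lengths")
  M <- decode_sequences(C)
  n <- ncol(M)
  D <- matrix(0, n, n, dimnames = list(colnames(M), colnames(M)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- sum(M[, i] != M[, j]) / L
  D
}

#' Distance-based cluster tree of groups
#'
#' Neighbor joining (via ape) or average linkage (UPGMA, via hclust).
#' When an outgroup is given the tree is rooted on it. Deterministic for
#' fixed input.
#'
#' @param D symmetric distance matrix (e.g. from
#'   [use_distance_matrix()]).
#' @param method `"nj"` or `"average"`.
#' @param outgroup optional tip label(s) to root on (nj only; UPGMA trees
#'   are inherently rooted).
#' @return a `phylo` tree with attribute `method`.
#' @export
build_cluster_tree <- function(D, method = c("nj", "average"), outgroup = NULL) {
  method <- match.arg(method)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop_invalid("D must be a square matrix")
  if (method == "nj" && nrow(D) < 3L) stop_invalid("neighbor joining needs >= 3 taxa")
  tree <- if (method == "nj") ape::nj(stats::as.dist(D)) else
    ape::as.phylo(stats::hclust(stats::as.dist(D), method = "average"))
  if (!is.null(outgroup) && method == "nj")
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  attr(tree, "method") <- method
  tree
}
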