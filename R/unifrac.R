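#' Weighted UniFrac distance between two libraries
#'
#' For every branch b of the shared phylogeny, let A_b and B_b be the
#' fractions of each library's reads descending from b. The raw weighted
#' UniFrac distance is `sum_b l_b * |A_b - B_b|`; the normalized variant
#' (default) divides by `sum_b l_b * (A_b + B_b)` so values lie in [0, 1].
#' Branch masses are accumulated in a single postorder traversal.
#'
#' @param table An [asv_table()] with a tree covering all ASVs.
#' @param library_a,library_b Library ids (column names of the count matrix).
#' @param normalized Divide by the abundance-weighted total branch length?
#' @return A single non-negative number; 0 for libraries with identical
#'   relative-abundance vectors.
#' @export
weighted_unifrac <- function(table, library_a, library_b, normalized = TRUE) {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(table$tree)) stop("table has no tree", call. = FALSE)
  masses <- branch_masses(table, c(library_a, library_b))
  len <- table$tree$edge.length
  num <- sum(len * abs(masses[, 1] - masses[, 2]))
  if (!normalized) return(num)
  den <- sum(len * (masses[, 1] + masses[, 2]))
  if (den == 0) return(0)
  num / den
}

#' Pairwise weighted UniFrac distance matrix over all libraries
#'
#' @inheritParams weighted_unifrac
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
unifrac_matrix <- function(table, normalized = TRUE) {
  stopifnot(inherits(table, "asv_table"))
  if (is.null(table$tree)) stop("table has no tree", call. = FALSE)
  libs <- colnames(table$counts)
  masses <- branch_masses(table, libs)
  len <- table$tree$edge.length
  n <- length(libs)
  d <- matrix(0, n, n, dimnames = list(libs, libs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- sum(len * abs(masses[, i] - masses[, j]))
      if (normalized) {
        den <- sum(len * (masses[, i] + masses[, j]))
        num <- if (den == 0) 0 else num / den
      }
      d[i, j] <- d[j, i] <- num
    }
  }
  d
}

# fraction of each library's reads descending from every edge
# (edges in tree$edge order); one postorder pass
branch_masses <- function(table, libs) {
  tree <- table$tree
  bad <- setdiff(libs, colnames(table$counts))
  if (length(bad)) {
    stop(sprintf("unknown library id: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(rownames(table$counts), tree$tip.label)
  if (length(missing)) {
    stop(sprintf("ASV(s) missing from tree: %s",
                 paste(utils::head(missing, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  rel <- relative_abundance(table)[, libs, drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  node_mass <- matrix(0, nnode, length(libs))
  idx <- match(tree$tip.label, rownames(rel))
  has <- !is.na(idx)
  node_mass[seq_len(ntip)[has], ] <- rel[idx[has], , drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    child <- po$edge[e, 2]
    node_mass[parent, ] <- node_mass[parent, ] + node_mass[child, ]
  }
  # report per original edge order
  node_mass[tree$edge[, 2], , drop = FALSE]
}
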