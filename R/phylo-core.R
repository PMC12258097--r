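## Core branch-set algebra on ape "phylo" trees.
##
## A community's branch set is root-inclusive: every edge on the path from
## each present tip up to the root of the FULL tree. This makes deep shared
## branches count as shared in pairwise comparisons and makes the
## phylogenetic-endemism sum identity exact (sum of per-site PE equals the
## PD of the union of all occupied sites).

#' Validate a phylogenetic tree for branch-set computations
#'
#' Checks that `tree` is a rooted `phylo` object with non-negative branch
#' lengths on every edge and unique tip labels. An unrooted tree (basal
#' multifurcation) is accepted with a warning; its basal node is treated as
#' the root.
#'
#' @param tree an object of class `phylo`.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("`tree` must be an object of class \"phylo\"", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; branch lengths are required on all edges",
         call. = FALSE)
  if (anyNA(tree$edge.length))
    stop("tree has NA branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("tip labels are not unique", call. = FALSE)
  if (!ape::is.rooted(tree))
    warning("tree is unrooted (basal multifurcation); treating the basal node as the root",
            call. = FALSE)
  invisible(tree)
}

## Tip x edge descent matrix: D[t, e] is TRUE when tip t descends from the
## child node of edge e, i.e. edge e lies on tip t's path to the root.
tip_edge_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  nnode <- ntip + tree$Nnode
  D <- matrix(FALSE, nrow = ntip, ncol = nedge,
              dimnames = list(tree$tip.label, NULL))
  ## edge index leading into each node (0 for the root)
  edge_of <- integer(nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nedge)
  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  for (t in seq_len(ntip)) {
    node <- t
    while (edge_of[node] > 0L) {
      D[t, edge_of[node]] <- TRUE
      node <- parent_of[node]
    }
  }
  D
}

check_species_labels <- function(tree, species) {
  species <- unique(as.character(species))
  if (length(species) == 0L)
    stop("species set is empty", call. = FALSE)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown) > 0L)
    stop("species not found among tree tips: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  species
}

#' Spanning branch set of a species set
#'
#' Returns the union of all edges on the paths from each listed tip to the
#' root of the full tree, together with its total branch length (root-
#' inclusive Faith's PD).
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param species character vector of tip labels (non-empty, all present in
#'   the tree).
#' @return an object of class `branch_set`: a list with `edges` (integer
#'   indices into `tree$edge` rows), `lengths` (their branch lengths) and
#'   `total_length`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' spanning_branch_set(tr, c("A", "B"))$total_length  # 3
#' @export
spanning_branch_set <- function(tree, species) {
  validate_tree(tree)
  species <- check_species_labels(tree, species)
  D <- tip_edge_matrix(tree)
  inc <- colSums(D[species, , drop = FALSE]) > 0
  edges <- which(inc)
  structure(list(edges = edges,
                 lengths = tree$edge.length[edges],
                 total_length = sum(tree$edge.length[edges])),
            class = "branch_set")
}

#' @export
print.branch_set <- function(x, ...) {
  cat("Branch set:", length(x$edges), "edges, total length",
      format(x$total_length), "\n")
  invisible(x)
}

#' Faith's phylogenetic diversity of a species set
#'
#' Root-inclusive Faith's PD: the summed branch length of the union of
#' tip-to-root paths of the listed species. A single species therefore has
#' PD equal to its full path length to the root, and the complete tip set
#' has PD equal to the total tree length.
#'
#' @inheritParams spanning_branch_set
#' @return a non-negative number in the branch-length units of the tree.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' faith_pd(tr, c("A", "C"))  # 4
#' @export
faith_pd <- function(tree, species) {
  spanning_branch_set(tree, species)$total_length
}

#' Branch incidence matrix of a community matrix
#'
#' For each site (row of the community matrix), which edges of the tree are
#' in its root-inclusive branch set. This is the shared computational
#' substrate for dissimilarity, endemism and accumulation curves: a single
#' `sites x edges` logical incidence matrix makes all pairwise branch-set
#' intersections cheap matrix products.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param comm binary site-by-species matrix; column names must be tip
#'   labels of `tree`, row names are site ids.
#' @return a list with `incidence` (sites x edges logical matrix),
#'   `edge_lengths`, and `pd` (per-site root-inclusive Faith's PD).
#' @export
branch_incidence <- function(tree, comm) {
  validate_tree(tree)
  comm <- as_community_matrix(comm)
  unknown <- setdiff(colnames(comm), tree$tip.label)
  if (length(unknown) > 0L)
    stop("community matrix species not found among tree tips: ",
         paste(unknown, collapse = ", "),
         "; run reconcile_tree_matrix() first", call. = FALSE)
  D <- tip_edge_matrix(tree)
  inc <- (comm %*% D[colnames(comm), , drop = FALSE]) > 0
  list(incidence = inc,
       edge_lengths = tree$edge.length,
       pd = as.vector(inc %*% tree$edge.length))
}

## Coerce a community input (matrix or data.frame) to a binary matrix with
## site-id rownames, and validate it.
as_community_matrix <- function(comm) {
  if (is.data.frame(comm)) comm <- as.matrix(comm)
  if (!is.matrix(comm) || !is.numeric(comm))
    stop("community matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(comm)) || is.null(colnames(comm)))
    stop("community matrix needs site-id rownames and species colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(comm)))
    stop("duplicate site ids in community matrix", call. = FALSE)
  if (anyNA(comm) || any(comm != 0 & comm != 1))
    stop("community matrix must be binary (0/1)", call. = FALSE)
  storage.mode(comm) <- "double"
  comm
}

## Species sets per site from a community matrix (utility used by the
## per-pair operations and tests).
community_species <- function(comm, site) {
  comm <- as_community_matrix(comm)
  colnames(comm)[comm[site, ] > 0]
}
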