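## Asymmetric Ruggiero-type phylogenetic dissimilarity and the focal-row
## square matrix it lives in.
##
## The index is the proportion of the focal community's branch length that
## is NOT shared with the comparison community: PD_unique / PD_total. It is
## asymmetric by construction, so the matrix is square (rows = focal sites)
## rather than triangular, and the row mean (off-diagonal) is the site's
## phylogenetic uniqueness.

#' Ruggiero phylogenetic dissimilarity between two communities
#'
#' Proportion of the focal community's branch length (root-inclusive branch
#' set) not shared with the other community. 0 when the focal branch set is
#' contained in the other's; 1 when the two branch sets are disjoint.
#' Asymmetric: swapping `focal` and `other` generally changes the value.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param focal,other character vectors of tip labels (the two communities).
#' @return a number in \[0, 1\].
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' rug_pair_phylo(tr, c("A", "B"), c("A", "C"))  # 1/3
#' rug_pair_phylo(tr, c("A", "C"), c("A", "B"))  # 0.5
#' @export
rug_pair_phylo <- function(tree, focal, other) {
  bs_f <- spanning_branch_set(tree, focal)
  bs_o <- spanning_branch_set(tree, other)
  if (bs_f$total_length <= 0)
    stop("focal community has zero total branch length; dissimilarity undefined",
         call. = FALSE)
  shared <- intersect(bs_f$edges, bs_o$edges)
  unique_len <- bs_f$total_length - sum(tree$edge.length[shared])
  unique_len / bs_f$total_length
}

#' Taxonomic Ruggiero dissimilarity between two communities
#'
#' The species-level baseline of [rug_pair_phylo()]: the proportion of the
#' focal community's species absent from the other community. On a star
#' tree with equal tip branch lengths the phylogenetic index reduces to
#' this value exactly.
#'
#' @param focal,other character vectors of species names; `focal` non-empty.
#' @return a number in \[0, 1\].
#' @export
rug_pair_taxonomic <- function(focal, other) {
  focal <- unique(as.character(focal))
  other <- unique(as.character(other))
  if (length(focal) == 0L)
    stop("focal community is empty", call. = FALSE)
  length(setdiff(focal, other)) / length(focal)
}

#' Focal-row square matrix of phylogenetic dissimilarities
#'
#' Computes the full site-by-site matrix of Ruggiero phylogenetic
#' dissimilarities: entry \[i, j\] is the dissimilarity with site i as the
#' focal community and site j as the comparison. The diagonal is exactly 0
#' and the matrix is not symmetric. Shared branch length is computed from a
#' single per-edge site incidence matrix, so all n^2 pairs cost one matrix
#' product.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param comm binary site-by-species matrix (sites in rows); every site
#'   must have positive total branch length.
#' @return an n x n numeric matrix with site ids as dimnames, values in
#'   \[0, 1\], zero diagonal.
#' @export
rug_matrix <- function(tree, comm) {
  comm <- as_community_matrix(comm)
  if (nrow(comm) < 2L)
    stop("need at least 2 sites", call. = FALSE)
  bi <- branch_incidence(tree, comm)
  if (any(bi$pd <= 0))
    stop("sites with zero total branch length: ",
         paste(rownames(comm)[bi$pd <= 0], collapse = ", "), call. = FALSE)
  incL <- bi$incidence * rep(bi$edge_lengths, each = nrow(comm))
  shared <- tcrossprod(incL, bi$incidence)  # shared[i, j] = L(B_i intersect B_j)
  rug <- 1 - shared / bi$pd                 # rows are focal sites
  diag(rug) <- 0
  rug[rug < 0] <- 0                         # guard rounding at exact nestedness
  dimnames(rug) <- list(rownames(comm), rownames(comm))
  rug
}

#' Single focal row of the dissimilarity matrix
#'
#' Streaming alternative to materialising the full square matrix: computes
#' the dissimilarities of one focal site against all sites (its own entry
#' is 0). Useful when n^2 memory is the bottleneck; a distance-increase fit
#' can consume each row and discard it.
#'
#' @inheritParams rug_matrix
#' @param focal_site site id (rowname of `comm`).
#' @param incidence optional precomputed result of [branch_incidence()]
#'   for `tree` and `comm`, to amortise the per-edge setup across rows.
#' @return named numeric vector of length `nrow(comm)`.
#' @export
rug_row <- function(tree, comm, focal_site, incidence = NULL) {
  comm <- as_community_matrix(comm)
  if (!focal_site %in% rownames(comm))
    stop("unknown focal site: ", focal_site, call. = FALSE)
  bi <- if (is.null(incidence)) branch_incidence(tree, comm) else incidence
  i <- match(focal_site, rownames(comm))
  if (bi$pd[i] <= 0)
    stop("focal site has zero total branch length", call. = FALSE)
  focal_inc <- bi$incidence[i, ]
  shared <- as.vector(bi$incidence %*% (focal_inc * bi$edge_lengths))
  row <- 1 - shared / bi$pd[i]
  row[i] <- 0
  row[row < 0] <- 0
  names(row) <- rownames(comm)
  row
}

#' Phylogenetic uniqueness of each site
#'
#' Row means of the focal-row dissimilarity matrix, excluding the diagonal:
#' the average phylogenetic dissimilarity between each focal community and
#' all remaining communities.
#'
#' @param rug a square dissimilarity matrix from [rug_matrix()].
#' @return named numeric vector of per-site uniqueness values in \[0, 1\].
#' @export
phylo_uniqueness <- function(rug) {
  if (!is.matrix(rug) || nrow(rug) != ncol(rug))
    stop("`rug` must be a square matrix", call. = FALSE)
  n <- nrow(rug)
  if (n < 2L)
    stop("need at least 2 sites to compute uniqueness", call. = FALSE)
  u <- (rowSums(rug) - diag(rug)) / (n - 1)
  names(u) <- rownames(rug)
  u
}
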