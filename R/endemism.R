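## Rosauer phylogenetic endemism and its discrepancy with average
## phylogenetic uniqueness.

#' Phylogenetic endemism per site
#'
#' For each site, the sum over the edges of its root-inclusive branch set
#' of branch length divided by the edge's range size, where an edge's range
#' size is the number of sites whose branch set contains it (equivalently,
#' the number of sites holding at least one descendant tip). Each edge's
#' contributions across sites sum to its full length, so total PE over
#' sites equals the PD of the union of all occupied sites.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param comm binary site-by-species matrix.
#' @return named numeric vector of per-site PE values (branch-length units).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' cm <- rbind(S1 = c(A = 1, B = 1, C = 0, D = 0),
#'             S2 = c(A = 1, B = 0, C = 1, D = 0))
#' phylo_endemism(tr, cm)  # S1 = 2, S2 = 3
#' @export
phylo_endemism <- function(tree, comm) {
  comm <- as_community_matrix(comm)
  bi <- branch_incidence(tree, comm)
  range_size <- colSums(bi$incidence)
  w <- ifelse(range_size > 0, bi$edge_lengths / range_size, 0)
  pe <- as.vector(bi$incidence %*% w)
  names(pe) <- rownames(comm)
  pe
}

#' Discrepancy between phylogenetic endemism and uniqueness
#'
#' Min-max standardises PE and uniqueness to \[0, 1\] over the analysed
#' sites, takes the per-site difference (standardised PE minus standardised
#' uniqueness), and regresses that difference on log species richness by
#' ordinary least squares. A positive slope means the two measures diverge
#' more in species-rich sites.
#'
#' @param pe named numeric vector of per-site phylogenetic endemism.
#' @param uniqueness named numeric vector of per-site uniqueness; same sites.
#' @param richness named numeric vector of per-site species counts.
#' @return a list with `difference` (per-site standardised difference),
#'   `slope`, `intercept` and `r_squared` of the OLS fit on log richness.
#' @export
pe_discrepancy <- function(pe, uniqueness, richness) {
  ids <- names(pe)
  if (is.null(ids) || !setequal(ids, names(uniqueness)) ||
      !setequal(ids, names(richness)))
    stop("pe, uniqueness and richness must share the same site ids",
         call. = FALSE)
  if (length(ids) < 3L)
    stop("need at least 3 sites for the richness regression", call. = FALSE)
  uniqueness <- uniqueness[ids]
  richness <- richness[ids]

  minmax <- function(x, label) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning(label, " is constant across sites; standardisation degenerates to zeros",
              call. = FALSE)
      return(rep(0, length(x)))
    }
    (x - rng[1]) / diff(rng)
  }
  diff_std <- minmax(pe, "PE") - minmax(uniqueness, "uniqueness")
  names(diff_std) <- ids

  if (all(diff_std == diff_std[1])) {
    warning("discrepancy is constant; regression on log richness is degenerate",
            call. = FALSE)
    return(list(difference = diff_std, slope = 0, intercept = diff_std[[1]],
                r_squared = 0))
  }
  fit <- lm(diff_std ~ log(richness))
  list(difference = diff_std,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
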