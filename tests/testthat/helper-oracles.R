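# Shared fixtures and independent brute-force oracles. The oracles walk
# every tip-to-root path explicitly and do plain set arithmetic on edge
# ids; they never touch the incidence-matrix machinery they are used to
# check.

four_tip_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

four_tip_comm <- function() {
  rbind(S1 = c(A = 1, B = 1, C = 0, D = 0),
        S2 = c(A = 1, B = 0, C = 1, D = 0))
}

star_tree <- function(n, len = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}

# edge ids (rows of tree$edge) on the path from a tip to the root
path_edges_brute <- function(tree, tip) {
  node <- match(tip, tree$tip.label)
  edges <- integer(0)
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    edges <- c(edges, e)
    node <- tree$edge[e, 1]
  }
  edges
}

branch_set_brute <- function(tree, species) {
  sort(unique(unlist(lapply(species, path_edges_brute, tree = tree))))
}

faith_pd_brute <- function(tree, species) {
  sum(tree$edge.length[branch_set_brute(tree, species)])
}

rug_pair_brute <- function(tree, focal, other) {
  bf <- branch_set_brute(tree, focal)
  bo <- branch_set_brute(tree, other)
  sum(tree$edge.length[setdiff(bf, bo)]) / sum(tree$edge.length[bf])
}

phylo_endemism_brute <- function(tree, comm) {
  sets <- lapply(rownames(comm), function(s)
    branch_set_brute(tree, colnames(comm)[comm[s, ] > 0]))
  all_edges <- seq_len(nrow(tree$edge))
  range_size <- sapply(all_edges, function(e)
    sum(vapply(sets, function(bs) e %in% bs, logical(1))))
  pe <- vapply(sets, function(bs)
    sum(tree$edge.length[bs] / range_size[bs]), numeric(1))
  names(pe) <- rownames(comm)
  pe
}

community_species_of <- function(comm, i) colnames(comm)[comm[i, ] > 0]

# branch length of edges whose descendant tips all lie in `tips`
private_branch_length_brute <- function(tree, tips) {
  sets <- lapply(tree$tip.label, path_edges_brute, tree = tree)
  names(sets) <- tree$tip.label
  out <- 0
  for (e in seq_len(nrow(tree$edge))) {
    desc <- names(sets)[vapply(sets, function(p) e %in% p, logical(1))]
    if (length(desc) > 0 && all(desc %in% tips))
      out <- out + tree$edge.length[e]
  }
  out
}

random_community <- function(tips, min_size = 1) {
  size <- sample(min_size:length(tips), 1)
  sample(tips, size)
}

# small random landscape as a (tree, comm) pair; every site non-empty
random_landscape <- function(n_tips, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_tips)
  comm <- matrix(0, n_sites, n_tips,
                 dimnames = list(sprintf("s%02d", seq_len(n_sites)),
                                 tree$tip.label))
  for (i in seq_len(n_sites)) {
    comm[i, sample(n_tips, sample(1:n_tips, 1))] <- 1
  }
  list(tree = tree, comm = comm)
}
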