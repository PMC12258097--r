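## Synthetic landscape generators: a pure-birth tree, a site lattice with
## spatially autocorrelated circular species ranges (distance decay emerges
## from range overlap), a latitudinal range-size gradient (a turnover
## gradient producing "evolutionary hill" structure), and planted
## "evolutionary island" sites holding private endemic clades.

#' Landscape recipe
#'
#' Bundles the parameters of [generate_landscape()] with their defaults:
#' a 10 x 10 lattice of 100 sites over a 30-degree extent, 200 species on a
#' pure-birth tree, circular ranges with radii uniform on 5-15 degrees
#' shrinking northwards to 40% (the turnover gradient), 3 island sites with
#' private endemic clades of 8 tips at isolation 0.9, and the 5-species
#' minimum richness filter.
#'
#' @param n_side lattice side; the landscape has `n_side^2` sites.
#' @param extent lattice extent in decimal degrees (square, origin 0).
#' @param n_species number of tree tips / species.
#' @param birth_rate pure-birth speciation rate for the tree simulation.
#' @param range_radius length-2 vector: uniform bounds of range radii
#'   (degrees) before the gradient shrinkage.
#' @param hill_shrink multiplier applied to range radii at the far end of
#'   the latitudinal gradient (in (0, 1]; smaller = stronger turnover).
#' @param n_island_sites number of planted island sites.
#' @param endemic_clade_size minimum size of each island's private clade.
#' @param isolation isolation strength in \[0, 1\]: probability that a clade
#'   tip becomes exclusive to its island, and that a widespread species is
#'   thinned from the island site.
#' @param min_richness minimum species per retained site.
#' @param seed integer seed; all randomness flows from it.
#' @return a list of class `landscape_recipe`.
#' @export
landscape_recipe <- function(n_side = 10L, extent = 30, n_species = 200L,
                             birth_rate = 1, range_radius = c(5, 15),
                             hill_shrink = 0.4, n_island_sites = 3L,
                             endemic_clade_size = 8L, isolation = 0.9,
                             min_richness = 5L, seed = 1L) {
  stopifnot(n_side >= 2L, extent > 0, n_species >= 3L, birth_rate > 0,
            length(range_radius) == 2L, all(range_radius > 0),
            range_radius[1] <= range_radius[2],
            hill_shrink > 0, hill_shrink <= 1,
            n_island_sites >= 0L, endemic_clade_size >= 2L,
            isolation >= 0, isolation <= 1, min_richness >= 1L)
  structure(list(n_side = as.integer(n_side), extent = extent,
                 n_species = as.integer(n_species), birth_rate = birth_rate,
                 range_radius = range_radius, hill_shrink = hill_shrink,
                 n_island_sites = as.integer(n_island_sites),
                 endemic_clade_size = as.integer(endemic_clade_size),
                 isolation = isolation, min_richness = as.integer(min_richness),
                 seed = as.integer(seed)),
            class = "landscape_recipe")
}

#' Simulate a pure-birth ultrametric tree
#'
#' Reproducible pure-birth (Yule) tree with branch lengths; the same seed
#' yields a byte-identical newick string.
#'
#' @param n_tips number of tips (>= 3).
#' @param birth_rate speciation rate.
#' @param seed integer seed.
#' @return a rooted `phylo` tree with tips `t1 ... tn`.
#' @export
generate_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 3L) stop("need at least 3 tips", call. = FALSE)
  set.seed(seed)
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

## Branch length private to a tip set: total length of edges all of whose
## descendant tips lie in the set. These are exactly the edges no other
## community can share once the set is confined to one site.
private_branch_length <- function(tree, tips) {
  D <- tip_edge_matrix(tree)
  inside <- colSums(D[tips, , drop = FALSE])
  total <- colSums(D)
  sum(tree$edge.length[inside == total & total > 0])
}

## Endemic clade choice for an island: among clades of size `size` to
## 3 * size (bounded so one island cannot swallow the tree) disjoint from
## already-used tips, take the one with the greatest private branch length
## (crown plus stem) - an old, long-isolated lineage, which is the
## signature an evolutionary island is supposed to carry. Deterministic
## given tree and seed. Returns tip labels, or NULL when none is available.
deepest_free_clade <- function(tree, size, used) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  cands <- lapply(parts, function(idx) labs[idx])
  cands <- Filter(function(tips) length(tips) >= size &&
                    length(tips) <= 3L * size &&
                    !any(tips %in% used), cands)
  if (length(cands) == 0L) return(NULL)
  score <- vapply(cands, function(tips) private_branch_length(tree, tips),
                  numeric(1))
  cands[[which.max(score)]]
}

#' Generate a synthetic landscape with planted hills and islands
#'
#' Builds a pure-birth tree, a lattice of site centroids, and a binary
#' community matrix in which species occupy circular ranges in degree space
#' (so community similarity decays with distance), range radii shrink along
#' a latitudinal gradient (a turnover gradient: the small-range band
#' behaves like evolutionary hills), and a few island sites hold private
#' endemic clades whose tips are removed from everywhere else with
#' probability equal to the isolation strength; widespread species are
#' thinned from island sites with the same probability. Sites below the
#' minimum richness after planting are removed.
#'
#' @param recipe a [landscape_recipe()].
#' @return a list with `tree` (`phylo`), `coords` (site_id, lon, lat),
#'   `comm` (binary site x species matrix), `labels` (site_id, truth in
#'   hill / island / mainland), `endemics` (named list: island site id ->
#'   tips planted as exclusive to it), `recipe`.
#' @export
generate_landscape <- function(recipe = landscape_recipe()) {
  if (!inherits(recipe, "landscape_recipe"))
    stop("recipe must come from landscape_recipe()", call. = FALSE)
  r <- recipe
  tree <- generate_tree(r$n_species, r$birth_rate, r$seed)
  set.seed(r$seed + 1L)

  ## site lattice
  n_sites <- r$n_side^2
  step <- r$extent / r$n_side
  centres <- (seq_len(r$n_side) - 0.5) * step
  coords <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    lon = rep(centres, times = r$n_side),
    lat = rep(centres, each = r$n_side))

  ## island sites: sampled, kept mutually distant (>= a third of the extent)
  island_sites <- integer(0)
  if (r$n_island_sites > 0L) {
    for (tries in 1:200) {
      cand <- sample.int(n_sites, r$n_island_sites)
      dmin <- if (r$n_island_sites == 1L) Inf else
        min(dist(cbind(coords$lon[cand], coords$lat[cand])))
      if (dmin >= r$extent / 3) { island_sites <- cand; break }
    }
    if (length(island_sites) == 0L)
      stop("could not place ", r$n_island_sites,
           " mutually distant island sites on this lattice", call. = FALSE)
  }

  ## hill ground truth: the strongest-turnover latitudinal band (top 20%)
  lat_norm <- coords$lat / r$extent
  hill_sites <- setdiff(which(lat_norm >= 0.8), island_sites)

  ## endemic clades, one per island; each tip goes private with
  ## probability = isolation strength
  endemic_of <- setNames(rep(NA_integer_, r$n_species), tree$tip.label)
  used <- character(0)
  for (k in seq_along(island_sites)) {
    clade <- deepest_free_clade(tree, r$endemic_clade_size, used)
    if (is.null(clade))
      stop("tree has no free clade of size >= ", r$endemic_clade_size,
           " for island ", k, call. = FALSE)
    used <- c(used, clade)
    private <- clade[runif(length(clade)) < r$isolation]
    endemic_of[private] <- island_sites[k]
  }

  ## circular ranges for non-endemic species, radii shrunk along the
  ## latitudinal gradient at the range centre
  comm <- matrix(0, nrow = n_sites, ncol = r$n_species,
                 dimnames = list(coords$site_id, tree$tip.label))
  cx <- runif(r$n_species, 0, r$extent)
  cy <- runif(r$n_species, 0, r$extent)
  rad0 <- runif(r$n_species, r$range_radius[1], r$range_radius[2])
  shrink <- 1 - (1 - r$hill_shrink) * (cy / r$extent)
  rad <- rad0 * shrink
  for (sp in seq_len(r$n_species)) {
    if (!is.na(endemic_of[sp])) {
      comm[endemic_of[sp], sp] <- 1
      next
    }
    d2 <- (coords$lon - cx[sp])^2 + (coords$lat - cy[sp])^2
    inside <- d2 <= rad[sp]^2
    if (!any(inside)) inside[which.min(d2)] <- TRUE
    comm[inside, sp] <- 1
  }

  ## island thinning: widespread species drop out of island sites with
  ## probability = isolation, but never below the richness floor
  for (isl in island_sites) {
    shared <- which(comm[isl, ] == 1 & is.na(endemic_of))
    if (length(shared) > 0L) {
      drop <- shared[runif(length(shared)) < r$isolation]
      comm[isl, drop] <- 0
    }
    if (sum(comm[isl, ]) < r$min_richness && length(shared) > 0L) {
      short <- r$min_richness - sum(comm[isl, ])
      readd <- setdiff(shared, which(comm[isl, ] == 1))[seq_len(min(short,
                 length(setdiff(shared, which(comm[isl, ] == 1)))))]
      comm[isl, readd] <- 1
    }
  }

  ## minimum-richness filter
  keep <- rowSums(comm) >= r$min_richness
  if (any(!keep[island_sites]) || mean(keep) < 0.75)
    stop("recipe cannot satisfy min_richness = ", r$min_richness,
         " on enough sites; use larger range radii or more species",
         call. = FALSE)
  comm <- comm[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]

  truth <- rep("mainland", n_sites)
  truth[hill_sites] <- "hill"
  truth[island_sites] <- "island"
  labels <- data.frame(site_id = sprintf("S%03d", seq_len(n_sites)),
                       truth = truth)[keep, ]
  rownames(coords) <- rownames(labels) <- NULL
  endemics <- lapply(setNames(island_sites, sprintf("S%03d", island_sites)),
                     function(i) names(endemic_of)[!is.na(endemic_of) &
                                                     endemic_of == i])
  list(tree = tree, coords = coords, comm = comm, labels = labels,
       endemics = endemics, recipe = recipe)
}

#' Generate synthetic per-species conservation scores
#'
#' Non-negative scores correlated with terminal branch length (an
#' evolutionary-distinctiveness proxy) with multiplicative lognormal noise;
#' the top decile of species by score is flagged. Stands in for externally
#' supplied EDGE-style scores.
#'
#' @param tree a `phylo` tree.
#' @param seed integer seed.
#' @param noise_sd standard deviation of the lognormal noise on the log
#'   scale.
#' @return data frame: `species`, `score`, `edge_flag` (logical; exactly
#'   `ceiling(n/10)` species flagged).
#' @export
generate_species_scores <- function(tree, seed = 1L, noise_sd = 0.4) {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  term <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2])]
  score <- term * exp(rnorm(ntip, 0, noise_sd))
  n_flag <- ceiling(ntip / 10)
  flagged <- rank(-score, ties.method = "first") <= n_flag
  data.frame(species = tree$tip.label, score = score, edge_flag = flagged)
}
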