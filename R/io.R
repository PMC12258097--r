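## Readers and writers for the standard inputs and outputs, plus the
## tree/matrix reconciliation and richness filter.

#' Read a phylogenetic tree from a newick file
#'
#' Wrapper around [ape::read.tree()] that validates branch lengths and
#' rooting for downstream branch-set computations. Surrounding single
#' quotes on tip labels are stripped; no other normalisation is applied, so
#' labels must match community-matrix column headers exactly.
#'
#' @param path newick file path.
#' @return a `phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path, call. = FALSE)
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  validate_tree(tree)
  tree
}

#' Read a community matrix from CSV
#'
#' Accepts either a dense matrix (first column = site id, remaining columns
#' = species, binary cells) or a sparse triplet table with columns
#' `site_id, species, presence`. The layout is auto-detected from the
#' header.
#'
#' @param path CSV file path.
#' @return binary site-by-species matrix with site-id rownames.
#' @export
read_community_matrix <- function(path) {
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  if (length(header) == 3L &&
      all(tolower(header) == c("site_id", "species", "presence"))) {
    tr <- read.csv(path, check.names = FALSE, colClasses =
                     c("character", "character", "numeric"))
    sites <- unique(tr$site_id)
    species <- unique(tr$species)
    m <- matrix(0, length(sites), length(species),
                dimnames = list(sites, species))
    m[cbind(match(tr$site_id, sites), match(tr$species, species))] <-
      as.numeric(tr$presence > 0)
    return(as_community_matrix(m))
  }
  df <- read.csv(path, check.names = FALSE, row.names = 1)
  as_community_matrix(as.matrix(df))
}

#' Write a community matrix to dense CSV
#' @param comm binary site-by-species matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_community_matrix <- function(comm, path) {
  comm <- as_community_matrix(comm)
  df <- data.frame(site_id = rownames(comm), comm, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site coordinates from CSV (site_id, lon, lat)
#' @param path CSV file path.
#' @return validated coordinates data frame.
#' @export
read_coords <- function(path) {
  validate_coords(read.csv(path, colClasses = c(site_id = "character")))
}

#' Read per-species scores from CSV
#'
#' Expects columns `species` and `score`; an optional logical `edge_flag`
#' column marks flagged species.
#'
#' @param path CSV file path.
#' @return data frame with `species`, `score` and (possibly absent)
#'   `edge_flag`.
#' @export
read_species_scores <- function(path) {
  df <- read.csv(path, colClasses = c(species = "character"))
  if (!all(c("species", "score") %in% names(df)))
    stop("scores file needs columns species, score", call. = FALSE)
  df
}

#' Write a square (dissimilarity or distance) matrix to CSV
#'
#' Site ids in the first row and column; numeric fields are written at full
#' precision (15 significant digits) so a write/read round trip preserves
#' values exactly.
#'
#' @param m square matrix with site-id dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(site_id = rownames(m),
                   apply(m, 2, format_full), check.names = FALSE)
  colnames(df) <- c("site_id", colnames(m))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a square matrix written by [write_square_matrix()]
#' @param path CSV file path.
#' @return numeric matrix with site-id dimnames.
#' @export
read_square_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, row.names = 1,
                 colClasses = "character")
  m <- apply(as.matrix(df), c(1, 2), as.numeric)
  dimnames(m) <- list(rownames(df), colnames(df))
  m
}

#' Write a focal-row dissimilarity matrix in long format
#'
#' One row per (focal, other) pair: `focal_id, other_id, dissimilarity`.
#' Diagonal entries are omitted.
#'
#' @param rug square dissimilarity matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_rug_long <- function(rug, path) {
  ids <- rownames(rug)
  idx <- which(row(rug) != col(rug), arr.ind = TRUE)
  df <- data.frame(focal_id = ids[idx[, 1]], other_id = ids[idx[, 2]],
                   dissimilarity = format_full(rug[idx]))
  df <- df[order(df$focal_id, df$other_id), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## full-precision numeric formatting for CSV outputs
format_full <- function(x) {
  if (is.numeric(x)) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  else x
}

#' Write a data frame to CSV at full numeric precision
#' @param df data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table_full <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_full)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reconcile a community matrix with a tree
#'
#' Drops matrix species absent from the tree's tips and reports them. Tree
#' tips absent from the matrix are retained in the tree: under the
#' root-inclusive convention they only matter through deep edges that are
#' shared anyway.
#'
#' @param tree a `phylo` tree.
#' @param comm binary site-by-species matrix.
#' @return a list with `comm` (reconciled matrix), `dropped` (character
#'   vector of removed species), `n_dropped`.
#' @export
reconcile_tree_matrix <- function(tree, comm) {
  comm <- as_community_matrix(comm)
  dropped <- setdiff(colnames(comm), tree$tip.label)
  kept <- setdiff(colnames(comm), dropped)
  if (length(kept) == 0L)
    stop("no community species match the tree tips", call. = FALSE)
  list(comm = comm[, kept, drop = FALSE], dropped = dropped,
       n_dropped = length(dropped))
}

#' Filter sites by minimum species richness
#'
#' Removes sites holding fewer species than `min_richness` (extremely
#' species-poor cells distort proportion-based dissimilarities).
#' Idempotent.
#'
#' @param comm binary site-by-species matrix.
#' @param min_richness minimum species per retained site (default 5).
#' @return a list with `comm` (filtered matrix), `removed` (character
#'   vector of removed site ids), `n_removed`.
#' @export
filter_sites <- function(comm, min_richness = 5L) {
  comm <- as_community_matrix(comm)
  if (min_richness < 1L) stop("min_richness must be >= 1", call. = FALSE)
  keep <- rowSums(comm) >= min_richness
  if (!any(keep))
    stop("all sites removed by the richness filter (min_richness = ",
         min_richness, ")", call. = FALSE)
  list(comm = comm[keep, , drop = FALSE],
       removed = rownames(comm)[!keep],
       n_removed = sum(!keep))
}
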