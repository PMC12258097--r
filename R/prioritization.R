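## Area-accumulation curves of cumulative Faith's PD under descending
## per-site prioritisation criteria, plus the EDGE-based site metrics.

#' Per-site EDGE metrics
#'
#' For each site, the sum of EDGE scores over its species and the count of
#' present species in the EDGE flag set. Species missing from the score
#' table contribute 0 to the sum; their number is reported via a message.
#'
#' @param comm binary site-by-species matrix.
#' @param scores data frame with columns `species` and `score` (may omit
#'   species; missing species score 0).
#' @param edge_species character vector of species flagged as EDGE species.
#' @return data frame: `site_id`, `edge_sum`, `edge_richness`.
#' @export
edge_metrics <- function(comm, scores, edge_species = character()) {
  comm <- as_community_matrix(comm)
  scores <- as.data.frame(scores)
  if (!all(c("species", "score") %in% names(scores)))
    stop("scores need columns species, score", call. = FALSE)
  sp <- colnames(comm)
  score_vec <- setNames(rep(0, length(sp)), sp)
  known <- intersect(sp, scores$species)
  score_vec[known] <- scores$score[match(known, scores$species)]
  n_missing <- length(sp) - length(known)
  if (n_missing > 0)
    message(n_missing, " species without a score; scored as 0")
  flag_vec <- as.numeric(sp %in% edge_species)
  data.frame(site_id = rownames(comm),
             edge_sum = as.vector(comm %*% score_vec),
             edge_richness = as.vector(comm %*% flag_vec))
}

#' PD accumulation curve under a prioritisation ordering
#'
#' Sorts sites in descending order of a per-site criterion (ties broken by
#' ascending site id) and accumulates the root-inclusive branch-set union,
#' reporting at each step the fraction of sites included and the fraction of
#' total PD covered. The denominator is the PD of the union of all analysed
#' sites, so every curve ends at exactly 1.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param comm binary site-by-species matrix.
#' @param order_scores named numeric vector of the criterion, one value per
#'   site of `comm`.
#' @param criterion name recorded in the output.
#' @return data frame of class `accumulation_curve`: `criterion`, `step`,
#'   `site_id`, `area_fraction`, `cum_pd_fraction`.
#' @export
accumulation_curve <- function(tree, comm, order_scores, criterion = "score") {
  comm <- as_community_matrix(comm)
  ids <- rownames(comm)
  if (is.null(names(order_scores)) || !setequal(ids, names(order_scores)))
    stop("order_scores must be named with the community matrix site ids",
         call. = FALSE)
  order_scores <- order_scores[ids]
  ord <- order(-order_scores, ids)

  bi <- branch_incidence(tree, comm)
  total_pd <- sum(bi$edge_lengths[colSums(bi$incidence) > 0])
  if (total_pd <= 0)
    stop("union of all sites has zero branch length", call. = FALSE)

  n <- length(ids)
  covered <- rep(FALSE, ncol(bi$incidence))
  cum_pd <- numeric(n)
  running <- 0
  for (k in seq_len(n)) {
    new_edges <- bi$incidence[ord[k], ] & !covered
    running <- running + sum(bi$edge_lengths[new_edges])
    covered <- covered | new_edges
    cum_pd[k] <- running
  }
  out <- data.frame(criterion = criterion,
                    step = seq_len(n),
                    site_id = ids[ord],
                    area_fraction = seq_len(n) / n,
                    cum_pd_fraction = cum_pd / total_pd)
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

#' Accumulation curves for the standard criteria set
#'
#' Convenience wrapper computing one [accumulation_curve()] per column of a
#' site score table (typically richness, pd, pe, uniqueness, edge_sum,
#' edge_richness) and binding them.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param comm binary site-by-species matrix.
#' @param score_table data frame with a `site_id` column and one numeric
#'   column per criterion.
#' @return data frame of stacked curves.
#' @export
accumulation_curves <- function(tree, comm, score_table) {
  score_table <- as.data.frame(score_table)
  if (!"site_id" %in% names(score_table))
    stop("score_table needs a site_id column", call. = FALSE)
  criteria <- setdiff(names(score_table), "site_id")
  curves <- lapply(criteria, function(cr) {
    accumulation_curve(tree, comm,
                       setNames(score_table[[cr]], score_table$site_id),
                       criterion = cr)
  })
  out <- do.call(rbind, curves)
  rownames(out) <- NULL
  out
}

#' Plot PD accumulation curves
#'
#' Cumulative PD fraction against area fraction, one line per criterion.
#'
#' @param x stacked curves from [accumulation_curves()] or a single curve.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, `x`.
#' @export
plot_accumulation_curves <- function(x, ...) {
  crits <- unique(x$criterion)
  steps <- sort(unique(x$step))
  y <- sapply(crits, function(cr) x$cum_pd_fraction[x$criterion == cr])
  graphics::matplot(steps / max(steps), y, type = "l", lty = 1,
                    col = seq_along(crits),
                    xlab = "fraction of sites", ylab = "fraction of total PD", ...)
  graphics::legend("bottomright", legend = crits, col = seq_along(crits),
                   lty = 1, bty = "n")
  invisible(x)
}
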