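## Quartile-based classification of high-endemism sites into evolutionary
## hills and evolutionary islands, group contrasts, and multi-taxon
## top-quartile overlap.

#' Top-quartile flags
#'
#' Flags the sites whose value is at or above the 75th percentile (linear
#' interpolation between order statistics); ties at the threshold are
#' included, so between 25% and 100% of sites are flagged.
#'
#' @param values named numeric vector, length >= 4.
#' @return named logical vector.
#' @export
top_quartile_flags <- function(values) {
  if (length(values) < 4L)
    stop("need at least 4 sites to compute quartiles", call. = FALSE)
  if (anyNA(values))
    stop("values contain NA", call. = FALSE)
  thr <- quantile(values, 0.75, type = 7, names = FALSE)
  values >= thr
}

#' Classify high-endemism sites as evolutionary hills or islands
#'
#' Sites in the top quartile of phylogenetic endemism are labelled by the
#' spatial scaling of their uniqueness: `hill` if their distance-increase
#' slope (`slope_metric` = -b) is top-quartile, `island` if their
#' dissimilarity intercept (1 - a) is top-quartile, `both` if both, and
#' `neither` otherwise. Sites outside the top PE quartile are always
#' `neither`. Quartile thresholds for slope and intercept are computed over
#' the chosen reference population; unconverged fits are excluded from the
#' quartile computation and labelled `neither` with a warning.
#'
#' @param pe named numeric vector of per-site phylogenetic endemism.
#' @param fits fit table from [fit_all_sites()].
#' @param reference reference population for the slope/intercept quartiles:
#'   `"all"` (default) uses all analysed sites, `"top_pe"` restricts to the
#'   top PE quartile.
#' @return data frame: `site_id`, `in_top_pe_quartile`, `label`.
#' @export
classify_sites <- function(pe, fits, reference = c("all", "top_pe")) {
  reference <- match.arg(reference)
  ids <- names(pe)
  if (is.null(ids) || !setequal(ids, fits$site_id))
    stop("pe and fits must share site ids", call. = FALSE)
  fits <- fits[match(ids, fits$site_id), ]

  top_pe <- top_quartile_flags(pe)
  usable <- fits$converged & !is.na(fits$dissimilarity_intercept) &
    !is.na(fits$slope_metric)
  if (any(!usable))
    warning(sum(!usable), " site(s) with unconverged or failed fits excluded ",
            "from quartiles and labelled 'neither'", call. = FALSE)

  ref <- if (reference == "all") usable else usable & top_pe
  if (sum(ref) < 4L)
    stop("fewer than 4 usable fits in the quartile reference population",
         call. = FALSE)
  thr_slope <- quantile(fits$slope_metric[ref], 0.75, type = 7, names = FALSE)
  thr_int <- quantile(fits$dissimilarity_intercept[ref], 0.75, type = 7,
                      names = FALSE)

  hill <- usable & fits$slope_metric >= thr_slope
  island <- usable & fits$dissimilarity_intercept >= thr_int
  label <- rep("neither", length(ids))
  label[top_pe & hill & !island] <- "hill"
  label[top_pe & island & !hill] <- "island"
  label[top_pe & island & hill] <- "both"
  data.frame(site_id = ids, in_top_pe_quartile = top_pe, label = label,
             row.names = NULL)
}

#' Contrast evolutionary hills against evolutionary islands
#'
#' Compares the two classified groups on species richness, per-species
#' contribution to phylogenetic endemism (PE / richness) and per-species
#' EDGE score (edge_sum / richness), with two-sided Wilcoxon rank-sum tests
#' (normal approximation with tie and continuity correction). Sites
#' labelled `both` are excluded from the two groups by default.
#'
#' @param classification data frame from [classify_sites()].
#' @param score_table data frame with columns `site_id`, `richness`, `pe`,
#'   `edge_sum`.
#' @param include_both if `TRUE`, sites labelled `both` are pooled into
#'   both groups.
#' @return data frame: one row per (group, metric) with `n`, `median`,
#'   `mean`, plus a `p_value` shared by the two rows of each metric. Tests
#'   are skipped (NA p-value, warning) when a group has fewer than 2 sites.
#' @export
group_contrast <- function(classification, score_table, include_both = FALSE) {
  score_table <- as.data.frame(score_table)
  need <- c("site_id", "richness", "pe", "edge_sum")
  if (!all(need %in% names(score_table)))
    stop("score_table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  m <- merge(classification, score_table, by = "site_id")
  hills <- m[m$label == "hill" | (include_both & m$label == "both"), ]
  islands <- m[m$label == "island" | (include_both & m$label == "both"), ]
  if (nrow(hills) == 0L || nrow(islands) == 0L)
    stop("both groups must be non-empty", call. = FALSE)

  metrics <- list(
    richness = function(g) g$richness,
    pe_per_species = function(g) g$pe / g$richness,
    edge_per_species = function(g) g$edge_sum / g$richness)

  rows <- list()
  for (mn in names(metrics)) {
    x <- metrics[[mn]](hills)
    y <- metrics[[mn]](islands)
    p <- NA_real_
    if (length(x) >= 2L && length(y) >= 2L) {
      p <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    } else {
      warning("group with fewer than 2 sites: Wilcoxon test skipped for ", mn,
              call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = c("hill", "island"), metric = mn,
      n = c(length(x), length(y)),
      median = c(median(x), median(y)),
      mean = c(mean(x), mean(y)),
      p_value = p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-taxon overlap of top-endemism flags
#'
#' Given per-taxon logical flags over (possibly different) site sets, counts
#' for each site how many taxa flag it and summarises the fraction of sites
#' at each count and at "at least m" counts. Sites missing from a taxon's
#' vector count as unflagged for that taxon.
#'
#' @param flags named list (one element per taxon) of named logical vectors.
#' @return a list with `counts` (named integer vector over the site
#'   universe), `fraction_exact` (fraction of sites with count k, k = 0..K)
#'   and `fraction_at_least` (fraction with count >= m, m = 1..K).
#' @export
multi_taxon_overlap <- function(flags) {
  if (!is.list(flags) || length(flags) == 0L)
    stop("flags must be a non-empty list of named logical vectors", call. = FALSE)
  universe <- sort(unique(unlist(lapply(flags, names))))
  if (length(universe) == 0L)
    stop("flag vectors must be named by site id", call. = FALSE)
  k <- length(flags)
  counts <- setNames(integer(length(universe)), universe)
  for (f in flags) {
    present <- intersect(names(f), universe)
    counts[present] <- counts[present] + as.integer(f[present])
  }
  n <- length(universe)
  exact <- sapply(0:k, function(m) sum(counts == m) / n)
  names(exact) <- as.character(0:k)
  at_least <- sapply(1:k, function(m) sum(counts >= m) / n)
  names(at_least) <- as.character(1:k)
  list(counts = counts, fraction_exact = exact, fraction_at_least = at_least)
}
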