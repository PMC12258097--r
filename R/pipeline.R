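## End-to-end pipeline and the subcommand command-line interface.

#' Analysis configuration
#'
#' Collects input paths and analysis switches for [run_pipeline()] and the
#' CLI. All randomness downstream flows from `seed`.
#'
#' @param tree newick tree path.
#' @param matrix community-matrix CSV path (dense or sparse triplet).
#' @param coords site-coordinates CSV path.
#' @param scores optional per-species scores CSV path.
#' @param out_dir output directory (created if absent).
#' @param min_richness minimum species per retained site (>= 1; default 5).
#' @param distance_method `"haversine"` or `"ellipsoidal"`.
#' @param quartile_reference `"all"` or `"top_pe"` (see [classify_sites()]).
#' @param clip similarity clipping epsilon for fit initialisation,
#'   in (0, 1e-3].
#' @param seed integer seed recorded in outputs.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(tree, matrix, coords, scores = NULL,
                            out_dir = ".", min_richness = 5L,
                            distance_method = "haversine",
                            quartile_reference = "all",
                            clip = 1e-10, seed = 1L) {
  if (min_richness < 1L) stop("min_richness must be >= 1", call. = FALSE)
  if (clip <= 0 || clip > 1e-3) stop("clip must be in (0, 1e-3]", call. = FALSE)
  structure(list(tree = tree, matrix = matrix, coords = coords,
                 scores = scores, out_dir = out_dir,
                 min_richness = as.integer(min_richness),
                 distance_method = match.arg(distance_method,
                                             c("haversine", "ellipsoidal")),
                 quartile_reference = match.arg(quartile_reference,
                                                c("all", "top_pe")),
                 clip = clip, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Per-site score table
#'
#' Assembles the six prioritisation criteria per site: species richness,
#' Faith's PD, phylogenetic endemism, phylogenetic uniqueness, EDGE score
#' sum and EDGE richness. Without a score table the two EDGE columns are 0.
#'
#' @param tree a `phylo` tree.
#' @param comm reconciled binary site-by-species matrix.
#' @param rug optional precomputed dissimilarity matrix (recomputed if NULL).
#' @param scores optional data frame (`species`, `score`, optional
#'   `edge_flag`).
#' @return data frame: site_id, richness, pd, pe, uniqueness, edge_sum,
#'   edge_richness.
#' @export
site_score_table <- function(tree, comm, rug = NULL, scores = NULL) {
  comm <- as_community_matrix(comm)
  if (is.null(rug)) rug <- rug_matrix(tree, comm)
  bi <- branch_incidence(tree, comm)
  uniq <- phylo_uniqueness(rug)
  pe <- phylo_endemism(tree, comm)
  if (is.null(scores)) {
    em <- data.frame(site_id = rownames(comm), edge_sum = 0, edge_richness = 0)
  } else {
    flags <- if ("edge_flag" %in% names(scores))
      scores$species[as.logical(scores$edge_flag)] else character()
    em <- edge_metrics(comm, scores, flags)
  }
  data.frame(site_id = rownames(comm),
             richness = unname(rowSums(comm)),
             pd = bi$pd,
             pe = unname(pe[rownames(comm)]),
             uniqueness = unname(uniq[rownames(comm)]),
             edge_sum = em$edge_sum[match(rownames(comm), em$site_id)],
             edge_richness = em$edge_richness[match(rownames(comm), em$site_id)])
}

#' Run the full analysis pipeline
#'
#' Reads the configured inputs, reconciles the matrix with the tree,
#' applies the richness filter, and computes the dissimilarity matrix,
#' uniqueness, endemism, the per-site score table, geodesic distances,
#' per-site distance-increase fits, accumulation curves, the
#' hills-vs-islands classification and the group contrast. All outputs are
#' written to `config$out_dir` as CSV at full precision together with a
#' plain-text log of the configuration.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with every computed object.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_tree(config$tree)
  comm0 <- read_community_matrix(config$matrix)
  coords <- read_coords(config$coords)
  scores <- if (!is.null(config$scores) && nzchar(config$scores))
    read_species_scores(config$scores) else NULL

  rec <- reconcile_tree_matrix(tree, comm0)
  filt <- filter_sites(rec$comm, config$min_richness)
  comm <- filt$comm
  missing_coords <- setdiff(rownames(comm), coords$site_id)
  if (length(missing_coords) > 0L)
    stop("sites without coordinates: ",
         paste(missing_coords, collapse = ", "), call. = FALSE)
  coords <- coords[coords$site_id %in% rownames(comm), ]

  rug <- rug_matrix(tree, comm)
  st <- site_score_table(tree, comm, rug = rug, scores = scores)
  dmat <- geodesic_matrix(coords, method = config$distance_method)
  fits <- fit_all_sites(rug, dmat, clip = config$clip)
  curves <- accumulation_curves(tree, comm,
                                st[, c("site_id", "richness", "pd", "pe",
                                       "uniqueness", "edge_sum",
                                       "edge_richness")])
  pe <- setNames(st$pe, st$site_id)
  cls <- classify_sites(pe, fits, reference = config$quartile_reference)
  contrast <- tryCatch(group_contrast(cls, st),
                       error = function(e) {
                         warning("group contrast skipped: ",
                                 conditionMessage(e), call. = FALSE)
                         NULL
                       })
  disc <- pe_discrepancy(pe, setNames(st$uniqueness, st$site_id),
                         setNames(st$richness, st$site_id))

  out <- function(f) file.path(config$out_dir, f)
  write_square_matrix(rug, out("rug_matrix.csv"))
  write_rug_long(rug, out("rug_long.csv"))
  write_table_full(st, out("site_scores.csv"))
  write_square_matrix(dmat, out("distances.csv"))
  write_table_full(fits, out("scaling_fits.csv"))
  write_table_full(curves, out("accumulation_curves.csv"))
  write_table_full(cls, out("classification.csv"))
  if (!is.null(contrast)) write_table_full(contrast, out("group_contrast.csv"))
  write_table_full(
    data.frame(site_id = names(disc$difference),
               std_difference = unname(disc$difference)),
    out("pe_discrepancy.csv"))

  log_lines <- c(
    paste0("evoscape ", as.character(packageVersion("evoscape"))),
    paste0("seed: ", config$seed),
    paste0("min_richness: ", config$min_richness),
    paste0("distance_method: ", config$distance_method),
    paste0("quartile_reference: ", config$quartile_reference),
    paste0("clip: ", format_full(config$clip)),
    paste0("inputs: tree=", config$tree, " matrix=", config$matrix,
           " coords=", config$coords, " scores=",
           if (is.null(config$scores)) "<none>" else config$scores),
    paste0("species dropped in reconciliation: ", rec$n_dropped,
           if (rec$n_dropped > 0)
             paste0(" (", paste(rec$dropped, collapse = ", "), ")") else ""),
    paste0("sites removed by richness filter: ", filt$n_removed),
    paste0("sites analysed: ", nrow(comm)),
    paste0("discrepancy regression r2: ", format_full(disc$r_squared)))
  writeLines(log_lines, out("run_log.txt"))

  invisible(list(tree = tree, comm = comm, coords = coords, rug = rug,
                 site_scores = st, distances = dmat, fits = fits,
                 curves = curves, classification = cls, contrast = contrast,
                 discrepancy = disc, reconciliation = rec, filter = filt))
}

## ---- command-line interface ------------------------------------------

## exit codes: 0 ok, 1 usage, 2 input error, 3 reconciliation failure,
## 4 fit/precondition failure
CLI_OK <- 0L; CLI_USAGE <- 1L; CLI_INPUT <- 2L; CLI_RECONCILE <- 3L
CLI_FIT <- 4L

cli_usage <- function() {
  c("usage: evoscape <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  simulate    --out DIR [--seed N --n-side N --extent D --n-species N",
    "              --islands N --isolation X --min-richness N]",
    "  uniqueness  --tree F --matrix F --out DIR [--min-richness N]",
    "  endemism    --tree F --matrix F --out DIR [--min-richness N]",
    "  scaling     --tree F --matrix F --coords F --out DIR",
    "              [--min-richness N --distance-method haversine|ellipsoidal]",
    "  accumulate  --tree F --matrix F --out DIR [--scores F --min-richness N]",
    "  classify    --tree F --matrix F --coords F --out DIR [--scores F",
    "              --quartile-reference all|top_pe --min-richness N]",
    "  all         --tree F --matrix F --coords F --out DIR [--scores F ...]")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args))
      stop("malformed arguments near '", a, "'", call. = FALSE)
    flags[[sub("^--", "", a)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

flag_or <- function(flags, name, default) {
  if (!is.null(flags[[name]])) flags[[name]] else default
}

cli_config <- function(flags, need_coords = FALSE) {
  for (f in c("tree", "matrix")) {
    if (is.null(flags[[f]])) stop("--", f, " is required", call. = FALSE)
  }
  if (need_coords && is.null(flags[["coords"]]))
    stop("--coords is required", call. = FALSE)
  analysis_config(
    tree = flags[["tree"]], matrix = flags[["matrix"]],
    coords = flag_or(flags, "coords", ""),
    scores = flags[["scores"]],
    out_dir = flag_or(flags, "out", "."),
    min_richness = as.integer(flag_or(flags, "min-richness", 5L)),
    distance_method = flag_or(flags, "distance-method", "haversine"),
    quartile_reference = flag_or(flags, "quartile-reference", "all"),
    clip = as.numeric(flag_or(flags, "clip", 1e-10)),
    seed = as.integer(flag_or(flags, "seed", 1L)))
}

cli_load <- function(config, need_coords = FALSE) {
  tree <- read_tree(config$tree)
  comm0 <- read_community_matrix(config$matrix)
  rec <- reconcile_tree_matrix(tree, comm0)
  filt <- filter_sites(rec$comm, config$min_richness)
  coords <- NULL
  if (need_coords) {
    coords <- read_coords(config$coords)
    coords <- coords[coords$site_id %in% rownames(filt$comm), ]
  }
  list(tree = tree, comm = filt$comm, coords = coords, rec = rec, filt = filt)
}

#' Command-line entry point
#'
#' Subcommand dispatcher behind the `exec/evoscape` script. Returns an exit
#' status instead of quitting, so it is directly testable: 0 success, 1
#' usage error, 2 input error, 3 reconciliation failure, 4
#' fit/precondition failure.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` in the script).
#' @return integer exit status, invisibly.
#' @export
evoscape_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
    writeLines(cli_usage())
    return(invisible(CLI_USAGE))
  }
  sub <- args[1]
  status <- tryCatch({
    flags <- parse_cli_flags(args[-1])
    out_dir <- flag_or(flags, "out", ".")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    switch(sub,
      simulate = cli_simulate(flags, out_dir),
      uniqueness = cli_uniqueness(flags, out_dir),
      endemism = cli_endemism(flags, out_dir),
      scaling = cli_scaling(flags, out_dir),
      accumulate = cli_accumulate(flags, out_dir),
      classify = cli_classify(flags, out_dir),
      all = { run_pipeline(cli_config(flags, need_coords = TRUE)); CLI_OK },
      { message("unknown subcommand: ", sub); CLI_USAGE })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    msg <- conditionMessage(e)
    if (grepl("no community species match|not found among tree tips", msg))
      CLI_RECONCILE
    else if (grepl("at least 4 sites|at least 3 focal pairs|fit degenerate|fewer than 4 usable",
                   msg))
      CLI_FIT
    else CLI_INPUT
  })
  invisible(status)
}

cli_simulate <- function(flags, out_dir) {
  recipe <- landscape_recipe(
    n_side = as.integer(flag_or(flags, "n-side", 10L)),
    extent = as.numeric(flag_or(flags, "extent", 30)),
    n_species = as.integer(flag_or(flags, "n-species", 200L)),
    n_island_sites = as.integer(flag_or(flags, "islands", 3L)),
    isolation = as.numeric(flag_or(flags, "isolation", 0.9)),
    min_richness = as.integer(flag_or(flags, "min-richness", 5L)),
    seed = as.integer(flag_or(flags, "seed", 1L)))
  land <- generate_landscape(recipe)
  scores <- generate_species_scores(land$tree, seed = recipe$seed + 2L)
  ape::write.tree(land$tree, file.path(out_dir, "tree.nwk"))
  write_community_matrix(land$comm, file.path(out_dir, "matrix.csv"))
  write_table_full(land$coords, file.path(out_dir, "coords.csv"))
  write_table_full(scores, file.path(out_dir, "scores.csv"))
  write_table_full(land$labels, file.path(out_dir, "truth_labels.csv"))
  writeLines(c(paste0("evoscape ", as.character(packageVersion("evoscape"))),
               paste0("seed: ", recipe$seed),
               paste0("sites: ", nrow(land$comm)),
               paste0("species: ", ncol(land$comm))),
             file.path(out_dir, "simulate_log.txt"))
  CLI_OK
}

cli_uniqueness <- function(flags, out_dir) {
  config <- cli_config(flags)
  x <- cli_load(config)
  rug <- rug_matrix(x$tree, x$comm)
  uniq <- phylo_uniqueness(rug)
  write_square_matrix(rug, file.path(out_dir, "rug_matrix.csv"))
  write_rug_long(rug, file.path(out_dir, "rug_long.csv"))
  write_table_full(data.frame(site_id = names(uniq), uniqueness = unname(uniq)),
                   file.path(out_dir, "uniqueness.csv"))
  CLI_OK
}

cli_endemism <- function(flags, out_dir) {
  config <- cli_config(flags)
  x <- cli_load(config)
  pe <- phylo_endemism(x$tree, x$comm)
  bi <- branch_incidence(x$tree, x$comm)
  write_table_full(data.frame(site_id = rownames(x$comm),
                              richness = unname(rowSums(x$comm)),
                              pd = bi$pd, pe = unname(pe)),
                   file.path(out_dir, "endemism.csv"))
  CLI_OK
}

cli_scaling <- function(flags, out_dir) {
  config <- cli_config(flags, need_coords = TRUE)
  x <- cli_load(config, need_coords = TRUE)
  rug <- rug_matrix(x$tree, x$comm)
  dmat <- geodesic_matrix(x$coords, method = config$distance_method)
  fits <- fit_all_sites(rug, dmat, clip = config$clip)
  write_table_full(fits, file.path(out_dir, "scaling_fits.csv"))
  CLI_OK
}

cli_accumulate <- function(flags, out_dir) {
  config <- cli_config(flags)
  x <- cli_load(config)
  scores <- if (!is.null(config$scores)) read_species_scores(config$scores)
  rug <- rug_matrix(x$tree, x$comm)
  st <- site_score_table(x$tree, x$comm, rug = rug, scores = scores)
  curves <- accumulation_curves(x$tree, x$comm, st)
  write_table_full(curves, file.path(out_dir, "accumulation_curves.csv"))
  CLI_OK
}

cli_classify <- function(flags, out_dir) {
  config <- cli_config(flags, need_coords = TRUE)
  x <- cli_load(config, need_coords = TRUE)
  scores <- if (!is.null(config$scores)) read_species_scores(config$scores)
  rug <- rug_matrix(x$tree, x$comm)
  st <- site_score_table(x$tree, x$comm, rug = rug, scores = scores)
  dmat <- geodesic_matrix(x$coords, method = config$distance_method)
  fits <- fit_all_sites(rug, dmat, clip = config$clip)
  cls <- classify_sites(setNames(st$pe, st$site_id), fits,
                        reference = config$quartile_reference)
  write_table_full(cls, file.path(out_dir, "classification.csv"))
  contrast <- tryCatch(group_contrast(cls, st), error = function(e) NULL)
  if (!is.null(contrast))
    write_table_full(contrast, file.path(out_dir, "group_contrast.csv"))
  CLI_OK
}
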