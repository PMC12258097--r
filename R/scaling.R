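## Per-focal-site distance-increase models of phylogenetic dissimilarity.
##
## Model: d = 1 - a * exp(b * s), with d the Ruggiero phylogenetic
## dissimilarity of the focal site against each other site and s the
## geodesic distance in km. Equivalently the expected similarity
## E[1 - d] = exp(log a + b s), fitted as a Gaussian GLM with log link
## (IRLS). `a` is a similarity-scale multiplier; the dissimilarity
## intercept at s = 0 is 1 - a, and -b is the initial relative rate at
## which similarity decays (the "slope" of the dissimilarity increase).
## Both parameterisations are reported.

#' Fit a distance-increase model for one focal site
#'
#' Fits `d = 1 - a * exp(b * s)` to a vector of dissimilarities `d` in
#' \[0, 1\] and positive distances `s` (km) by a Gaussian GLM with log link
#' on the similarities `y = 1 - d`. Starting values come from an ordinary
#' least-squares fit of `log(y)` (clipped to `[clip, 1]`) on `s`; the IRLS
#' itself uses the unclipped similarities. Non-convergence is reported via
#' the `converged` flag, never as an error.
#'
#' @param d numeric vector of dissimilarities in \[0, 1\].
#' @param s numeric vector of distances in km, all > 0, same length as `d`.
#' @param site_id optional site identifier carried into the result.
#' @param clip lower clipping bound applied to similarities only for the
#'   log-scale initialisation (d = 1 pairs would otherwise destroy it).
#' @param epsilon relative deviance-change convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return a list of class `scaling_fit`: `site_id`, `a`, `b`,
#'   `dissimilarity_intercept` (= 1 - a), `slope_metric` (= -b),
#'   `pseudo_r2` (1 - residual deviance / null deviance), `n_pairs`,
#'   `converged`.
#' @examples
#' s <- seq(100, 5000, length.out = 50)
#' d <- 1 - 0.8 * exp(-0.002 * s)
#' fit <- fit_distance_increase(d, s)
#' c(fit$a, fit$b)  # 0.8, -0.002
#' @export
fit_distance_increase <- function(d, s, site_id = NA_character_,
                                  clip = 1e-10, epsilon = 1e-8, maxit = 100L) {
  if (length(d) != length(s))
    stop("d and s must have equal length", call. = FALSE)
  keep <- complete.cases(d, s)
  d <- d[keep]; s <- s[keep]
  if (length(d) < 3L)
    stop("need at least 3 focal pairs to fit the model", call. = FALSE)
  if (any(s <= 0))
    stop("all distances must be positive (exclude the self pair)", call. = FALSE)
  if (any(d < 0 | d > 1))
    stop("dissimilarities must lie in [0, 1]", call. = FALSE)
  if (clip <= 0 || clip > 1e-3)
    stop("clip must be in (0, 1e-3]", call. = FALSE)

  y <- 1 - d
  if (all(y == 0))
    stop("all dissimilarities equal 1: no similarity anywhere, fit degenerate",
         call. = FALSE)

  ## log-scale OLS initialisation on clipped similarities
  yc <- pmin(pmax(y, clip), 1)
  init <- coef(lm(log(yc) ~ s))
  if (anyNA(init)) init <- c(log(mean(yc)), 0)

  ## glm's own non-convergence chatter is muffled: the `converged` flag in
  ## the result is the contract
  fit <- tryCatch(
    withCallingHandlers(
      glm(y ~ s, family = gaussian(link = "log"),
          start = unname(init),
          control = glm.control(epsilon = epsilon, maxit = maxit)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)

  if (is.null(fit)) {
    ## IRLS failed to produce any iterate; report the initialisation as the
    ## last usable estimate, flagged unconverged.
    a <- exp(init[[1]]); b <- init[[2]]
    mu <- a * exp(b * s)
    dev <- sum((y - mu)^2); null_dev <- sum((y - mean(y))^2)
    pr2 <- if (null_dev > 0) 1 - dev / null_dev else 0
    converged <- FALSE
  } else {
    cf <- coef(fit)
    a <- exp(unname(cf[1])); b <- unname(cf[2])
    pr2 <- if (fit$null.deviance > 0) 1 - fit$deviance / fit$null.deviance else 0
    converged <- isTRUE(fit$converged)
  }

  structure(list(site_id = site_id, a = a, b = b,
                 dissimilarity_intercept = 1 - a,
                 slope_metric = -b,
                 pseudo_r2 = pr2,
                 n_pairs = length(d),
                 converged = converged),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Distance-increase fit%s: a = %.6g, b = %.6g (intercept 1-a = %.6g, slope -b = %.6g), pseudo-R2 = %.4f, n = %d, converged = %s\n",
              if (is.na(x$site_id)) "" else paste0(" [", x$site_id, "]"),
              x$a, x$b, x$dissimilarity_intercept, x$slope_metric,
              x$pseudo_r2, x$n_pairs, x$converged))
  invisible(x)
}

#' Fit distance-increase models for every focal site
#'
#' One model per row of the focal-row dissimilarity matrix, using that
#' row's off-diagonal entries against the corresponding geodesic distances.
#' Pairs at zero distance (duplicate coordinates) are dropped with a
#' warning. Per-site failures are recorded in the table (`converged =
#' FALSE`, NA parameters, a message), never raised.
#'
#' @param rug square focal-row dissimilarity matrix from [rug_matrix()].
#' @param dist symmetric distance matrix from [geodesic_matrix()], same
#'   site ids.
#' @param ... passed to [fit_distance_increase()].
#' @return data frame with one row per site: `site_id`, `a`, `b`,
#'   `dissimilarity_intercept`, `slope_metric`, `pseudo_r2`, `n_pairs`,
#'   `converged`, `message`.
#' @export
fit_all_sites <- function(rug, dist, ...) {
  ids <- rownames(rug)
  if (is.null(ids) || !setequal(ids, rownames(dist)))
    stop("dissimilarity and distance matrices must share site ids", call. = FALSE)
  dist <- dist[ids, ids]
  n <- length(ids)
  if (n < 4L)
    stop("need at least 4 sites (3 focal pairs per row)", call. = FALSE)
  zero_dropped <- FALSE
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- rug[i, -i]; s <- dist[i, -i]
    if (any(s == 0)) {
      zero_dropped <- TRUE
      d <- d[s > 0]; s <- s[s > 0]
    }
    res <- tryCatch(fit_distance_increase(d, s, site_id = ids[i], ...),
                    error = function(e) e)
    rows[[i]] <- if (inherits(res, "error")) {
      data.frame(site_id = ids[i], a = NA_real_, b = NA_real_,
                 dissimilarity_intercept = NA_real_, slope_metric = NA_real_,
                 pseudo_r2 = NA_real_, n_pairs = length(d), converged = FALSE,
                 message = conditionMessage(res))
    } else {
      data.frame(site_id = res$site_id, a = res$a, b = res$b,
                 dissimilarity_intercept = res$dissimilarity_intercept,
                 slope_metric = res$slope_metric, pseudo_r2 = res$pseudo_r2,
                 n_pairs = res$n_pairs, converged = res$converged,
                 message = "")
    }
  }
  if (zero_dropped)
    warning("pairs at zero distance (duplicate coordinates) were dropped from the fits",
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
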