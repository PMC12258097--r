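# Per-site negative-exponential distance-increase models.

test_that("noise-free exponential data are recovered exactly", {
  s <- seq(100, 5000, length.out = 100)
  for (pars in list(c(0.8, -0.002), c(0.3, -0.0005), c(1, -0.001))) {
    d <- 1 - pars[1] * exp(pars[2] * s)
    fit <- fit_distance_increase(d, s)
    expect_true(fit$converged)
    expect_equal(fit$a, pars[1], tolerance = 1e-6)
    expect_equal(fit$b, pars[2], tolerance = 1e-6)
    expect_equal(fit$dissimilarity_intercept, 1 - fit$a)
    expect_equal(fit$slope_metric, -fit$b)
    expect_equal(fit$pseudo_r2, 1, tolerance = 1e-8)
  }
})

test_that("constant dissimilarity gives a flat model with a = 1 - c", {
  s <- seq(10, 1000, length.out = 20)
  fit <- fit_distance_increase(rep(0.35, 20), s)
  expect_equal(fit$a, 0.65, tolerance = 1e-8)
  expect_equal(fit$b, 0, tolerance = 1e-10)
})

test_that("degenerate and malformed inputs are rejected", {
  s <- c(10, 20, 30)
  expect_error(fit_distance_increase(rep(1, 3), s), "degenerate")
  expect_error(fit_distance_increase(c(0.1, 0.2), s), "equal length")
  expect_error(fit_distance_increase(c(0.1, 0.2, 1.2), s), "\\[0, 1\\]")
  expect_error(fit_distance_increase(c(0.1, 0.2, 0.3), c(0, 20, 30)),
               "positive")
  expect_error(fit_distance_increase(c(0.1, 0.2), c(10, 20)), "at least 3")
})

test_that("parameters are recovered in the mean under Gaussian noise", {
  a_true <- 0.8; b_true <- -0.002
  n_pairs <- 500; n_seeds <- 200
  a_hat <- b_hat <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    set.seed(1000 + k)
    s <- runif(n_pairs, 100, 5000)
    d <- pmin(pmax(1 - a_true * exp(b_true * s) + rnorm(n_pairs, 0, 0.02), 0), 1)
    fit <- fit_distance_increase(d, s)
    a_hat[k] <- fit$a; b_hat[k] <- fit$b
  }
  expect_lt(abs(mean(a_hat) - a_true), 0.01)
  expect_lt(abs(mean(b_hat) - b_true) / abs(b_true), 0.10)
})

test_that("GLM fit agrees with independent nonlinear least squares", {
  skip_if_not_installed("minpack.lm")
  set.seed(55)
  for (rep in 1:10) {
    s <- runif(300, 50, 4000)
    a0 <- runif(1, 0.4, 0.95); b0 <- -runif(1, 2e-4, 2e-3)
    y <- pmin(pmax(a0 * exp(b0 * s) + rnorm(300, 0, 0.01), 0), 1)
    fit <- fit_distance_increase(1 - y, s)
    nls_fit <- minpack.lm::nlsLM(y ~ a * exp(b * s),
                                 start = list(a = a0, b = b0),
                                 control = minpack.lm::nls.lm.control(
                                   ftol = 1e-12, ptol = 1e-12))
    cf <- coef(nls_fit)
    expect_equal(fit$a, unname(cf["a"]), tolerance = 1e-4)
    expect_equal(fit$b, unname(cf["b"]), tolerance = 1e-4)
  }
})

test_that("pseudo-R2 decreases with noise in expectation", {
  s <- seq(50, 5000, length.out = 400)
  mean_r2 <- sapply(c(0.005, 0.05, 0.15), function(sd) {
    mean(sapply(1:20, function(k) {
      set.seed(200 + k)
      d <- pmin(pmax(1 - 0.8 * exp(-0.002 * s) + rnorm(400, 0, sd), 0), 1)
      fit_distance_increase(d, s)$pseudo_r2
    }))
  })
  expect_true(all(diff(mean_r2) < 0))
})

test_that("fit_all_sites fits one model per focal row and is order invariant", {
  land <- random_landscape(12, 8, seed = 61)
  coords <- data.frame(site_id = rownames(land$comm),
                       lon = runif(8, 0, 20), lat = runif(8, 0, 20))
  rug <- rug_matrix(land$tree, land$comm)
  dmat <- geodesic_matrix(coords)
  fits <- fit_all_sites(rug, dmat)
  expect_equal(nrow(fits), 8)
  expect_true(all(fits$n_pairs == 7))

  perm <- sample(8)
  fits_p <- fit_all_sites(rug[perm, perm], dmat)
  fits_p <- fits_p[match(fits$site_id, fits_p$site_id), ]
  expect_equal(fits_p$a, fits$a, tolerance = 1e-12)
  expect_equal(fits_p$b, fits$b, tolerance = 1e-12)
})

test_that("too few sites violate the per-row pair precondition", {
  m2 <- matrix(c(0, 0.4, 0.3, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  d2 <- matrix(c(0, 100, 100, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(fit_all_sites(m2, d2), "at least 4 sites")
})

test_that("zero-distance pairs are dropped with a warning, and per-site failures are recorded", {
  land <- random_landscape(10, 6, seed = 71)
  coords <- data.frame(site_id = rownames(land$comm),
                       lon = c(0, 0, 2, 4, 6, 8), lat = rep(0, 6))
  rug <- rug_matrix(land$tree, land$comm)
  dmat <- suppressWarnings(geodesic_matrix(coords))
  expect_warning(fits <- fit_all_sites(rug, dmat), "zero distance")
  expect_equal(fits$n_pairs[1], 4)   # the duplicate pair is dropped

  # a row of all-1 dissimilarities must be recorded as failed, not raised
  rug2 <- rug
  rug2[2, -2] <- 1
  expect_warning(fits2 <- fit_all_sites(rug2, dmat))
  expect_false(fits2$converged[2])
  expect_match(fits2$message[2], "degenerate")
  expect_equal(nrow(fits2), 6)  # other rows still present
})
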