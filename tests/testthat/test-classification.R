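# Top-quartile flags, hills/islands classification, group contrasts and
# multi-taxon overlap.

test_that("top-quartile flags use linear-interpolation percentiles with inclusive ties", {
  v <- setNames(1:8, letters[1:8])
  f <- top_quartile_flags(v)           # threshold 6.25 excludes 6
  expect_identical(names(which(f)), c("g", "h"))

  expect_true(all(top_quartile_flags(setNames(rep(3, 5), letters[1:5]))))

  v2 <- setNames(c(1, 2, 3, 100), letters[1:4])
  expect_identical(names(which(top_quartile_flags(v2))), "d")

  expect_error(top_quartile_flags(c(a = 1, b = 2, c = 3)), "at least 4")
})

test_that("labels follow the definitional implications", {
  ids <- sprintf("s%02d", 1:8)
  pe <- setNames(c(10, 10, 10, 1, 1, 1, 1, 1), ids)     # top PE: s01..s03
  fits <- data.frame(
    site_id = ids,
    a = 0.5, b = -0.001,
    dissimilarity_intercept = c(0.9, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1, 0.1),
    slope_metric           = c(0.001, 0.009, 0.009, 0.001, 0.001, 0.001,
                               0.001, 0.001),
    pseudo_r2 = 0.9, n_pairs = 7, converged = TRUE)
  cls <- classify_sites(pe, fits)
  got <- setNames(cls$label, cls$site_id)
  expect_equal(got[["s01"]], "island")
  expect_equal(got[["s02"]], "hill")
  expect_equal(got[["s03"]], "both")
  expect_true(all(got[4:8] == "neither"))
  expect_true(all(cls$label == "neither" | cls$in_top_pe_quartile))
})

test_that("unconverged fits are excluded from quartiles and labelled neither", {
  ids <- sprintf("s%02d", 1:8)
  pe <- setNames(8:1, ids)
  fits <- data.frame(site_id = ids, a = 0.5, b = -0.001,
                     dissimilarity_intercept = seq(0.1, 0.8, 0.1),
                     slope_metric = seq(0.001, 0.008, 0.001),
                     pseudo_r2 = 0.9, n_pairs = 7,
                     converged = c(TRUE, FALSE, rep(TRUE, 6)))
  expect_warning(cls <- classify_sites(pe, fits), "unconverged")
  expect_equal(cls$label[cls$site_id == "s02"], "neither")
})

test_that("labels on random inputs satisfy the invariants for both reference populations", {
  set.seed(121)
  for (rep in 1:10) {
    n <- 20
    ids <- sprintf("s%02d", 1:n)
    pe <- setNames(runif(n), ids)
    fits <- data.frame(site_id = ids, a = runif(n, 0.1, 1),
                       b = -runif(n, 1e-4, 5e-3),
                       pseudo_r2 = runif(n), n_pairs = n - 1, converged = TRUE)
    fits$dissimilarity_intercept <- 1 - fits$a
    fits$slope_metric <- -fits$b
    for (ref in c("all", "top_pe")) {
      cls <- classify_sites(pe, fits, reference = ref)
      top <- setNames(cls$in_top_pe_quartile, cls$site_id)
      expect_true(all(cls$label %in% c("hill", "island", "both", "neither")))
      expect_true(all(top[cls$site_id[cls$label != "neither"]]))
      n_top <- sum(top)
      expect_gte(n_top, floor(0.25 * n))
    }
  }
})

test_that("group contrast reports medians, means and Wilcoxon p-values", {
  cls <- data.frame(site_id = sprintf("s%02d", 1:10),
                    in_top_pe_quartile = TRUE,
                    label = rep(c("hill", "island"), each = 5))
  st <- data.frame(site_id = cls$site_id,
                   richness = c(30, 28, 26, 31, 29, 8, 9, 7, 10, 8),
                   pe = c(3, 2.8, 2.6, 3.1, 2.9, 4, 4.5, 3.8, 5, 4.2),
                   edge_sum = c(1, 1.1, 0.9, 1.2, 1, 2, 2.1, 1.9, 2.2, 2))
  ct <- group_contrast(cls, st)
  expect_equal(nrow(ct), 6)
  expect_true(all(ct$p_value > 0 & ct$p_value <= 1))
  med <- function(metric, group) ct$median[ct$metric == metric & ct$group == group]
  expect_gt(med("richness", "hill"), med("richness", "island"))
  expect_lt(med("pe_per_species", "hill"), med("pe_per_species", "island"))

  # two-sided test is invariant to group order
  cls_sw <- cls; cls_sw$label <- rev(cls$label)
  st_sw <- st[10:1, ]
  ct_sw <- group_contrast(cls_sw, st_sw)
  expect_equal(sort(unique(ct_sw$p_value)), sort(unique(ct$p_value)),
               tolerance = 1e-12)
})

test_that("identical groups give p near 1; separated groups give the extreme statistic", {
  cls <- data.frame(site_id = sprintf("s%02d", 1:6),
                    in_top_pe_quartile = TRUE,
                    label = rep(c("hill", "island"), each = 3))
  st <- data.frame(site_id = cls$site_id,
                   richness = c(1, 2, 3, 1, 2, 3),
                   pe = c(1, 2, 3, 1, 2, 3),
                   edge_sum = c(1, 2, 3, 1, 2, 3))
  ct <- group_contrast(cls, st)
  expect_true(all(ct$p_value[ct$metric == "richness"] > 0.9))

  st2 <- st; st2$richness <- c(1, 2, 3, 10, 11, 12)
  w <- wilcox.test(c(1, 2, 3), c(10, 11, 12), exact = FALSE)$statistic
  expect_equal(unname(w), 0)  # complete separation: extreme rank-sum value
  ct2 <- group_contrast(cls, st2)
  p_rich <- unique(ct2$p_value[ct2$metric == "richness"])
  expect_lt(p_rich, 0.1)
})

test_that("tiny groups skip the test with a warning but keep summaries", {
  cls <- data.frame(site_id = c("a", "b", "c"),
                    in_top_pe_quartile = TRUE,
                    label = c("hill", "island", "island"))
  st <- data.frame(site_id = c("a", "b", "c"), richness = c(5, 6, 7),
                   pe = c(1, 2, 3), edge_sum = c(0, 0, 0))
  expect_warning(ct <- group_contrast(cls, st), "fewer than 2")
  expect_true(all(is.na(ct$p_value)))
  expect_equal(ct$n[ct$group == "hill" & ct$metric == "richness"], 1)
})

test_that("multi-taxon overlap counts flags over the shared site universe", {
  ids <- sprintf("s%02d", 1:8)
  fa <- setNames(c(TRUE, TRUE, rep(FALSE, 6)), ids)
  fb <- setNames(c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, 4)), ids)
  ov <- multi_taxon_overlap(list(a = fa, b = fb))
  expect_true(all(ov$counts <= 1))                       # disjoint flags
  expect_equal(ov$fraction_at_least[["1"]], 4 / 8)

  ov2 <- multi_taxon_overlap(list(a = fa, b = fa, c = fa))
  expect_equal(sum(ov2$counts == 3), 2)
  expect_equal(ov2$fraction_exact[["3"]], 2 / 8)

  # sites missing from one taxon count as unflagged for it
  ov3 <- multi_taxon_overlap(list(a = fa, b = fb[1:4]))
  expect_equal(unname(ov3$counts[c("s03", "s04")]), c(1L, 1L))
})

test_that("independent flags at rate 1/4 give count-k fraction near (1/4)^k", {
  set.seed(33)
  n <- 20000
  ids <- sprintf("s%05d", 1:n)
  flags <- lapply(1:4, function(i) setNames(runif(n) < 0.25, ids))
  ov <- multi_taxon_overlap(flags)
  expect_equal(ov$fraction_exact[["4"]], 0.25^4, tolerance = 0.35)
  expect_equal(ov$fraction_at_least[["1"]], 1 - 0.75^4, tolerance = 0.02)
})
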