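toy_expr <- function() {
  heights <- matrix(c(8, 2, 4, 8), 1, 4,
                    dimnames = list("s1", c("G1", "ACTB", "GAPDH", "TFRC")))
  expression_table(heights,
                   c(G1 = "response", ACTB = "housekeeping",
                     GAPDH = "housekeeping", TFRC = "housekeeping"),
                   data.frame(subject_id = "s1", group = "HC"))
}

test_that("normalization matches the worked example and its invariances", {
  norm <- normalize_expression(toy_expr())
  expect_equal(norm[1, "G1"], 3 - (1 + 2 + 3) / 3) # = 1.0
  expect_equal(norm[1, "G1"], 1.0)

  # gene at the geometric mean of housekeeping normalizes to 0
  e <- toy_expr()
  e$heights[1, "G1"] <- (2 * 4 * 8)^(1 / 3)
  expect_equal(normalize_expression(e)[1, "G1"], 0)

  # per-subject global scaling cancels
  e2 <- toy_expr()
  e2$heights <- e2$heights * 17
  expect_equal(normalize_expression(e2), normalize_expression(toy_expr()))

  bad <- toy_expr()
  expect_error({
    bad$heights[1, "G1"] <- -1
    expression_table(bad$heights, bad$roles, bad$subjects)
  }, "G1")
})

test_that("expression tables survive the TSV round trip", {
  cfg <- cohort_config(n_hc = 3, n_sle = 3, n_ln = 1, seed = 19)
  e <- simulate_expression(cfg)
  hp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(e, hp, sp)
  back <- read_expression_table(hp, sp)
  expect_equal(back$heights, e$heights, tolerance = 1e-7)
  expect_identical(back$roles, e$roles)
  expect_equal(normalize_expression(back), normalize_expression(e),
               tolerance = 1e-7)
})

test_that("module scores are constituent means with the IFN-1 cutoff", {
  genes <- c("HERC5", "IFI27", "IFIT1", "RSAD2", "OTHER")
  norm <- matrix(c(1, 3, 0, 0, 5), 1, 5, dimnames = list("s1", genes))
  mods <- list(IFN_1 = list(name = "IFN_1", genes = genes[1:4],
                            is_ifn = TRUE),
               Single = list(name = "Single", genes = "OTHER",
                             is_ifn = FALSE),
               Two = list(name = "Two", genes = c("HERC5", "IFI27"),
                          is_ifn = TRUE))
  sc <- score_modules(norm, mods)
  expect_equal(unname(sc$scores[1, "Two"]), 2)       # mean(1, 3)
  expect_equal(unname(sc$scores[1, "Single"]), 5)    # identity
  expect_equal(unname(sc$ifn1[1]), 1)
  # score bounded by constituent extremes
  expect_true(all(sc$scores >= min(norm) & sc$scores <= max(norm)))
  # all-zero normalized values: score 0, classified high (0 > -0.5)
  sc0 <- score_modules(norm * 0, mods)
  expect_equal(unname(sc0$ifn1[1]), 0)
  expect_identical(unname(sc0$ifn_class[1]), "high")
  expect_equal(sc0$cutoff, -0.5)
  expect_error(score_modules(norm, list(E = list(name = "E",
                                                 genes = character(0)))),
               "empty")
})

test_that("IFN cutoff derivation is mean + 2 sd", {
  x <- c(-3.5, -2.5, -1.5) # mean -2.5, sd 1
  expect_equal(derive_ifn_cutoff(x), -0.5)
  expect_equal(derive_ifn_cutoff(rep(4, 10)), 4) # sd 0
  expect_error(derive_ifn_cutoff(1), "at least 2")
  # Monte-Carlo from N(-2.5, 1), n = 281 reference samples
  draws <- withr::with_seed(1, replicate(200, {
    derive_ifn_cutoff(rnorm(281, -2.5, 1))
  }))
  expect_lt(abs(mean(draws) - (-0.5)), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("Mann-Whitney agrees with exhaustive enumeration (n <= 8)", {
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(mwu_enum_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  withr::with_seed(99, {
    for (rep in 1:25) {
      n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
      x <- rnorm(n1); y <- rnorm(n2)
      expect_equal(mwu_test(x, y)$p.value, mwu_enum_p(x, y),
                   tolerance = 1e-12)
    }
  })
  # identical multisets give p = 1 (tie-corrected path)
  expect_equal(mwu_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # large-sample path is used beyond n = 30
  big <- mwu_test(rnorm(20), rnorm(20))
  expect_false(big$exact)
  expect_true(big$p.value > 0 && big$p.value <= 1)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.5, 0.9)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_true(all(adj <= 1))
  cmp <- compare_module_scores(
    matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("M", 1:4))),
    rep(c("HC", "SLE"), each = 5))
  expect_equal(cmp$p_adj, bh_adjust(cmp$p))
})

test_that("Ward clustering meets its contracts", {
  # two subjects merge once at their Euclidean distance
  x2 <- rbind(a = c(0, 0), b = c(3, 4))
  hc2 <- cluster_subjects(x2)
  expect_equal(nrow(hc2$merge), 1L)
  expect_equal(hc2$height, 5)

  # well-separated blobs are recovered exactly at k = 2
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 30), 20))
  })
  hc <- cluster_subjects(x)
  cl <- stats::cutree(hc, 2)
  expect_equal(length(unique(cl[1:20])), 1L)
  expect_equal(length(unique(cl[21:40])), 1L)
  expect_false(cl[1] == cl[21])
  # heights nondecreasing
  expect_true(all(diff(hc$height) >= -1e-12))
  # permuting subjects leaves merge heights unchanged
  perm <- withr::with_seed(5, sample(nrow(x)))
  hcp <- cluster_subjects(x[perm, ])
  expect_equal(sort(hcp$height), sort(hc$height), tolerance = 1e-12)
  expect_error(cluster_subjects(rbind(c(1, NaN), c(0, 1))), "finite")
})

test_that("branch enrichment reproduces the printed-scale example", {
  res_p <- hypergeom_tail(13, 16, 45, 17)
  expect_equal(res_p, 1.25e-5, tolerance = 0.01)

  # constructed dendrogram: 17 subjects in one branch carrying 13 of 16
  withr::with_seed(6, {
    x <- c(rnorm(17, 0, 0.1), rnorm(28, 10, 0.1))
    labels <- c(rep(TRUE, 13), rep(FALSE, 4), rep(TRUE, 3), rep(FALSE, 25))
  })
  hc <- cluster_subjects(matrix(x))
  enr <- branch_enrichment(hc, labels, level = 2)
  expect_equal(enr$k, 13); expect_equal(enr$n, 17)
  expect_equal(enr$p.value, res_p)

  # extreme case: all labels in one branch of a half/half split
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  lab2 <- rep(c(TRUE, FALSE), each = 10)
  enr2 <- branch_enrichment(cluster_subjects(matrix(y)), lab2, 2)
  expect_equal(enr2$p.value, 1 / choose(20, 10))
  expect_error(branch_enrichment(hc, labels, level = 100), "level")
})

test_that("branch enrichment p is calibrated under label permutation", {
  withr::with_seed(7, {
    x <- matrix(rnorm(30 * 4), 30)
    hc <- cluster_subjects(x)
    labels <- rep(c(TRUE, FALSE), 15)
    ps <- replicate(200, branch_enrichment(hc, sample(labels), 2)$p.value)
  })
  # conservative discrete test: rejection at 0.05 must not exceed nominal
  expect_lte(mean(ps <= 0.05), 0.09)
  expect_gt(mean(ps > 0.2), 0.5)
})
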