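test_that("compositions close to 1 with multiplicative zero replacement", {
  counts <- rbind(s1 = c(A = 50, B = 150), s2 = c(A = 0, B = 180))
  comp <- build_compositions(counts, c(200, 180), c("A", "B"))
  expect_equal(unname(comp$proportions["s1", ]), c(0.25, 0.75))
  expect_true(all(comp$proportions > 0))
  expect_equal(rowSums(comp$proportions), c(s1 = 1, s2 = 1),
               tolerance = 1e-9)
  expect_equal(unname(comp$proportions["s2", "A"]), 0.5 / 180)
  expect_error(build_compositions(counts, c(100, 100), c("A", "B")),
               "exceeds")
})

test_that("overlapping types are rejected", {
  x <- small_cohort()
  counts <- x$gated$counts
  expect_error(
    build_compositions(counts, counts[, "B_cells"], c("B_CD27neg", "DN2"),
                       tree = x$tree),
    "overlap")
  # mask-level overlap check fires even without a tree
  masks <- list(cbind(A = c(TRUE, TRUE), B = c(TRUE, FALSE)))
  expect_error(
    build_compositions(rbind(c(A = 2, B = 1)), 3, c("A", "B"),
                       masks = masks),
    "overlap")
})

test_that("Aitchison distance matches its closed form and axioms", {
  expect_equal(aitchison_distance(c(0.8, 0.2), c(0.2, 0.8)),
               2 * sqrt(2) * log(2))
  expect_equal(aitchison_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_error(aitchison_distance(c(0, 1), c(0.5, 0.5)), "positive")
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rexp(4); y <- rexp(4); z <- rexp(4)
      x <- x / sum(x); y <- y / sum(y); z <- z / sum(z)
      dxy <- aitchison_distance(x, y)
      expect_equal(dxy, aitchison_distance(y, x))
      expect_lte(dxy,
                 aitchison_distance(x, z) + aitchison_distance(z, y) + 1e-12)
      # scale invariance: closure is irrelevant
      expect_equal(aitchison_distance(x * 13, y), dxy)
    }
  })
})

test_that("HSIC statistic equals the brute-force double sum (n <= 12)", {
  withr::with_seed(9, {
    for (n in c(6, 12)) {
      P <- matrix(rexp(n * 4), n); P <- P / rowSums(P)
      lab <- rep(c("a", "b"), length.out = n)
      D <- as.matrix(stats::dist(t(apply(P, 1, function(z) {
        log(z) - mean(log(z))
      }))))
      bw <- median(D[lower.tri(D)])
      K <- exp(-D^2 / (2 * bw^2))
      L <- outer(lab, lab, `==`) * 1
      res <- codak_test(P, lab, B = 99, seed = 1)
      expect_equal(res$statistic, hsic_brute(K, L), tolerance = 1e-12)
    }
  })
})

test_that("codak degenerate and constructed cases behave as specified", {
  # identical compositions: statistic 0, p = 1
  P <- matrix(rep(c(0.2, 0.3, 0.5), each = 10), 10)
  res <- codak_test(P, rep(c("a", "b"), 5), B = 199, seed = 3)
  expect_equal(res$statistic, 0, tolerance = 1e-14)
  expect_equal(res$p.value, 1)

  # non-overlapping clusters: minimal attainable p = 1/(B+1)
  withr::with_seed(10, {
    P2 <- rbind(matrix(rexp(10 * 3, 1) + c(50, 0, 0), 10, 3, byrow = TRUE),
                matrix(rexp(10 * 3, 1) + c(0, 50, 0), 10, 3, byrow = TRUE))
  })
  P2 <- P2 / rowSums(P2)
  lab <- rep(c("a", "b"), each = 10)
  res2 <- codak_test(P2, lab, B = 999, seed = 4)
  expect_equal(res2$p.value, 1 / 1000)

  # invariance to group renaming and subject order
  res3 <- codak_test(P2, ifelse(lab == "a", "z", "w"), B = 999, seed = 4)
  expect_equal(res3$statistic, res2$statistic)
  expect_equal(res3$p.value, res2$p.value)
  expect_error(codak_test(P2, rep("a", 20), B = 999), "constant")
  expect_error(codak_test(P2, lab, B = 50), "99")
  # determinism
  expect_identical(codak_test(P2, lab, B = 199, seed = 9)$p.value,
                   codak_test(P2, lab, B = 199, seed = 9)$p.value)
})

test_that("logistic GLMM reduces to plain logistic with one obs/subject", {
  withr::with_seed(11, {
    n <- 30
    grp <- rep(c("A", "B"), each = n)
    tot <- rep(400, 2 * n)
    k <- rbinom(2 * n, tot, ifelse(grp == "A", 0.1, 0.15))
  })
  da <- differential_abundance_glmm(
    matrix(k, dimnames = list(NULL, "t1")), tot, grp,
    paste0("s", seq_along(k)))
  ref <- stats::glm(cbind(k, tot - k) ~ grp, family = stats::binomial())
  expect_lt(abs(da$estimate - unname(coef(ref)[2])), 1e-3)

  # null at large n: effect near 0, p clearly nonsignificant
  withr::with_seed(12, {
    k0 <- rbinom(2 * n, tot, 0.2)
  })
  da0 <- differential_abundance_glmm(
    matrix(k0, dimnames = list(NULL, "t1")), tot, grp,
    paste0("s", seq_along(k0)))
  expect_lt(abs(da0$estimate), 0.15)
  expect_gt(da0$p, 0.05)

  # separation is flagged, not fatal
  ks <- c(rep(0, 6), rep(380, 6))
  gs <- rep(c("A", "B"), each = 6)
  das <- differential_abundance_glmm(
    matrix(ks, dimnames = list(NULL, "t1")), rep(400, 12), gs,
    paste0("s", 1:12))
  expect_true(is.na(das$p) || nzchar(das$flag))
})

test_that("composition clustering separates disjoint composition groups", {
  withr::with_seed(13, {
    P <- rbind(matrix(abs(rnorm(8 * 3, c(100, 5, 5), 1)), 8, 3,
                      byrow = TRUE),
               matrix(abs(rnorm(8 * 3, c(5, 100, 5), 1)), 8, 3,
                      byrow = TRUE))
  })
  P <- P / rowSums(P)
  rownames(P) <- paste0("s", 1:16)
  lab <- rep(c(TRUE, FALSE), each = 8)
  cc <- cluster_compositions(
    structure(list(proportions = P), class = "composition_table"),
    lab, level = 2)
  expect_equal(cc$enrichment$k, 8)
  expect_equal(cc$enrichment$n, 8)
  expect_equal(cc$enrichment$p.value, 1 / choose(16, 8))
  # n = 2: a single merge
  cc2 <- cluster_subjects(aitchison_distance(P[1, ], P[9, ]) * stats::dist(
    rbind(0, 1)))
  expect_equal(nrow(cc2$merge), 1L)
})
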