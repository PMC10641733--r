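test_that("repeated-measures correlation meets its contracts", {
  # perfect line across visits
  subj <- rep(paste0("s", 1:6), each = 3)
  x <- rnorm(18)
  gc <- group_correlation(x, 2 * x + 5, subj)
  expect_equal(gc$r, 1, tolerance = 1e-10)
  expect_lt(gc$p.value, 1e-10)
  # sign follows the slope
  gcn <- group_correlation(x, -x, subj)
  expect_equal(gcn$r, -1, tolerance = 1e-10)

  # single visit per subject: exact Pearson reduction
  withr::with_seed(14, {
    x1 <- rnorm(12); y1 <- rnorm(12)
  })
  gc1 <- group_correlation(x1, y1, paste0("s", 1:12))
  ref <- stats::cor.test(x1, y1)
  expect_equal(gc1$r, unname(ref$estimate), tolerance = 1e-6)
  expect_equal(gc1$p.value, ref$p.value, tolerance = 1e-6)
  expect_identical(gc1$method, "pearson")

  expect_error(group_correlation(1:4, 1:4, c("a", "a", "b", "b")),
               "3 subjects")
  expect_warning(
    res <- group_correlation(rep(1, 9), rnorm(9), rep(paste0("s", 1:3), 3)),
    "variation")
  expect_true(is.na(res$r))
})

test_that("repeated-measures correlation p is calibrated under the null", {
  withr::with_seed(15, {
    ps <- replicate(400, {
      subj <- rep(paste0("s", 1:8), each = 3)
      u <- rep(rnorm(8), each = 3)
      group_correlation(rnorm(24), u + rnorm(24), subj)$p.value
    })
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
  # roughly uniform p-values
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.08)
})

test_that("differential correlation is symmetric and recovers slopes", {
  withr::with_seed(16, {
    subj <- rep(paste0("s", 1:20), each = 3)
    grp <- rep(rep(c("LN", "noLN"), each = 10), each = 3)
    x <- rnorm(60)
    y <- ifelse(grp == "LN", 0.8, 0.2) * x + rep(rnorm(20), each = 3) +
      rnorm(60, 0, 0.2)
  })
  dc <- differential_correlation(x, y, subj, grp)
  expect_lt(abs(dc$slopes[["LN"]] - 0.8), 3 * dc$se + 0.1)
  expect_lt(dc$interaction_p, 0.01)
  # swapping labels leaves the differential p unchanged
  grp2 <- ifelse(grp == "LN", "noLN", "LN")
  dc2 <- differential_correlation(x, y, subj, grp2)
  expect_equal(dc2$interaction_p, dc$interaction_p, tolerance = 1e-8)
  expect_equal(dc2$interaction_estimate, -dc$interaction_estimate,
               tolerance = 1e-8)
  # per-group r reported alongside
  expect_gt(dc$by_group[["LN"]]$r, 0.8)
  # LRT option produces a p-value of the same order
  dcl <- differential_correlation(x, y, subj, grp, test = "lrt")
  expect_lt(dcl$interaction_p, 0.01)
})

test_that("identical slopes give a null interaction on average", {
  withr::with_seed(17, {
    ps <- replicate(50, {
      subj <- rep(paste0("s", 1:16), each = 3)
      grp <- rep(rep(c("A", "B"), each = 8), each = 3)
      x <- rnorm(48)
      y <- 0.5 * x + rep(rnorm(16), each = 3) + rnorm(48, 0, 0.3)
      differential_correlation(x, y, subj, grp)$interaction_p
    })
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("marker-expression comparison is rank-invariant", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
                 dimnames = list(NULL, "CD38.CD8_TCM"))
  g <- rep(c("HC", "SLE"), each = 3)
  r1 <- compare_marker_expression(vals, g)
  expect_equal(r1$p, 0.1)
  # monotone transform leaves the p unchanged
  r2 <- compare_marker_expression(exp(vals), g)
  expect_equal(r2$p, r1$p)
})

test_that("LLDAS rule covers its boundary cases", {
  mk <- function(sledai, pred, new_act = FALSE, stable = TRUE) {
    list(sledai = sledai, prednisone = pred, new_activity = new_act,
         stable_maintenance = stable)
  }
  expect_true(classify_lldas(mk(4, 7.5)))     # both at the boundary
  expect_false(classify_lldas(mk(5, 7.5)))    # SLEDAI above
  expect_false(classify_lldas(mk(4, 10)))     # prednisone above
  expect_false(classify_lldas(mk(4, 7.5, new_act = TRUE)))
  expect_false(classify_lldas(mk(4, 7.5, stable = FALSE)))
  expect_true(is.na(classify_lldas(mk(NA, 5))))      # indeterminate
  expect_true(is.na(classify_lldas(list(sledai = 2)))) # missing fields
  # pure function: repeated evaluation identical
  expect_identical(classify_lldas(mk(3, 5)), classify_lldas(mk(3, 5)))
})

test_that("renal response rule covers its boundary cases", {
  mk <- function(egfr, upcr, wbc = 1, rbc = 1, casts = FALSE) {
    list(egfr = egfr, upcr = upcr, urine_wbc = wbc, urine_rbc = rbc,
         casts = casts)
  }
  # complete: all criteria inside their bounds
  expect_identical(
    classify_renal_response(mk(60, 3, 20, 15, TRUE), mk(100, 0.1, 2, 3)),
    "complete")
  # partial: UPCR 3 -> 1 (>=50%), sediment halved, eGFR normal and stable
  expect_identical(
    classify_renal_response(mk(100, 3, 20, 15), mk(100, 1, 10, 7)),
    "partial")
  # UPCR at 0.25 blocks complete even with everything else normal
  expect_identical(
    classify_renal_response(mk(60, 3, 20, 15), mk(100, 0.25, 1, 1)),
    "partial") # still partial via >=50% improvements
  expect_false(identical(
    classify_renal_response(mk(60, 3, 20, 15), mk(100, 0.25, 1, 1)),
    "complete"))
  # current UPCR above 1 blocks partial
  expect_identical(
    classify_renal_response(mk(100, 4, 20, 15), mk(100, 1.5, 5, 5)),
    "none")
  # worsening remaining parameter with abnormal baseline eGFR blocks partial
  expect_identical(
    classify_renal_response(mk(60, 3, 10, 10), mk(55, 1, 2, 2)),
    "none")
  expect_identical(
    classify_renal_response(mk(100, NA, 10, 10), mk(100, 0.1, 1, 1)),
    "indeterminate")
})
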