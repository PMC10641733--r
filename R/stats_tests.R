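#' Two-sample Mann-Whitney U test
#'
#' Exact two-sided test when the combined sample size is at most 30 and there
#' are no ties (null distribution from [stats::pwilcox()]); otherwise the
#' normal approximation with tie correction and continuity correction.
#' The U statistic is reported for the first sample.
#'
#' @param x,y numeric vectors, one per group.
#' @return list with `statistic` (U), `p.value`, `exact` (logical), `n1`, `n2`.
#' @export
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))$p.value # exact, 0.1
mwu_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (n1 + n2) <= 30L && !ties
  if (exact) {
    mu <- n1 * n2 / 2
    p <- if (u > mu) {
      2 * (1 - stats::pwilcox(u - 1, n1, n2))
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p.value = 1, exact = FALSE,
                                 n1 = n1, n2 = n2))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u, p.value = p, exact = exact, n1 = n1, n2 = n2)
}

#' Mann-Whitney tests across a feature family with BH correction
#'
#' Applies [mwu_test()] to each column of a feature matrix split by a
#' two-level group factor and adjusts p-values by Benjamini-Hochberg within
#' the family.
#'
#' @param values numeric matrix or data.frame (observations x features).
#' @param groups two-level factor/character of length `nrow(values)`.
#' @return data.frame with feature, U, p, p_adj.
#' @export
mwu_family <- function(values, groups) {
  values <- as.matrix(values)
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  lv <- levels(g)
  res <- lapply(colnames(values) %||% seq_len(ncol(values)), function(j) {
    t <- mwu_test(values[g == lv[1], j], values[g == lv[2], j])
    data.frame(feature = as.character(j), U = t$statistic, p = t$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}

# biased HSIC estimator tr(K H L H) / n^2 from precomputed kernel matrices
hsic_stat <- function(K, L) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  sum(Kc * L) / n^2
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Supremum of the absolute difference between the two empirical CDFs,
#' evaluated at the pooled sample points (handles ties exactly).
#'
#' @param x,y numeric vectors.
#' @return KS distance in \[0, 1\].
#' @export
ks_stat <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction, as used for cohort
#' demographic comparisons (sex 2x2, race/ethnicity 4x2).
#'
#' @param counts integer matrix of counts (groups in columns).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
demographic_chisq <- function(counts) {
  counts <- as.matrix(counts)
  # small expected counts trigger an approximation warning; the Pearson
  # statistic itself is what the study reports, so keep it quiet
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = unname(ht$p.value))
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of observing at least `k` labelled subjects in a branch of
#' size `n`, drawn from `K` labelled among `N` total.
#'
#' @param k labelled count in the branch.
#' @param K labelled count overall.
#' @param N total subjects.
#' @param n branch size.
#' @return upper-tail probability P(X >= k).
#' @export
hypergeom_tail <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
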