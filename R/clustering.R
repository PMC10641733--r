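#' Hierarchical clustering of subjects
#'
#' Agglomerative clustering of a subjects x features matrix using Ward's
#' minimum-variance criterion (the Lance-Williams update family) on
#' Euclidean distances, as implemented by [stats::hclust()] with method
#' `"ward.D2"`. Merge heights are nondecreasing and invariant to subject
#' order (up to exact ties).
#'
#' @param x numeric matrix (subjects x features) with finite entries, or a
#'   `dist` object.
#' @param distance "euclidean" (matrix input) — Aitchison-distance
#'   clustering passes a precomputed `dist`.
#' @return an `hclust` object.
#' @export
cluster_subjects <- function(x, distance = "euclidean") {
  d <- if (inherits(x, "dist")) x else {
    x <- as.matrix(x)
    if (any(!is.finite(x))) stop("non-finite values in clustering input")
    if (nrow(x) < 2) stop("need at least 2 subjects")
    stats::dist(x, method = distance)
  }
  stats::hclust(d, method = "ward.D2")
}

# cut into two branches by removing the top (level - 1) merges and keeping
# the two largest resulting clusters
cut_two_branches <- function(hc, level = 2) {
  n_merge <- nrow(hc$merge)
  if (level > n_merge) stop("level exceeds the number of merges")
  cl <- stats::cutree(hc, k = level)
  sizes <- sort(table(cl), decreasing = TRUE)
  top2 <- names(sizes)[1:2]
  branch <- ifelse(cl == top2[1], 1L, ifelse(cl == top2[2], 2L, NA_integer_))
  names(branch) <- hc$labels %||% seq_along(cl)
  branch
}

#' Branch enrichment of a binary label in a dendrogram
#'
#' Cuts the dendrogram at the stated branch level (removing the top
#' `level - 1` merges and keeping the two largest clusters) and tests
#' whether the branch holding the larger share of labelled subjects is
#' enriched, using the one-sided hypergeometric tail.
#'
#' @param hc an `hclust` from [cluster_subjects()].
#' @param labels logical (or 0/1) vector in dendrogram label order.
#' @param level branch level (2 = the top split).
#' @return list with `branch` (1/2/NA per subject), `enriched_branch`,
#'   `k` labelled in the enriched branch, `n` branch size, and `p.value`.
#' @export
branch_enrichment <- function(hc, labels, level = 2) {
  labels <- as.logical(labels)
  branch <- cut_two_branches(hc, level)
  if (length(labels) != length(branch)) {
    stop("labels must cover every clustered subject")
  }
  keep <- !is.na(branch)
  b <- branch[keep]; l <- labels[keep]
  N <- length(l); K <- sum(l)
  frac <- c(mean(l[b == 1L]), mean(l[b == 2L]))
  eb <- which.max(frac)
  k <- sum(l[b == eb]); n <- sum(b == eb)
  list(branch = branch, enriched_branch = eb, k = k, n = n, N = N, K = K,
       p.value = hypergeom_tail(k, K, N, n))
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` object.
#' @return a Newick string with merge heights as branch depths.
#' @export
hclust_newick <- function(hc) {
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  node <- function(i, h) {
    if (i < 0) {
      sprintf("%s:%.6g", lab[-i], h)
    } else {
      sprintf("(%s,%s):%.6g", node(hc$merge[i, 1], hc$height[i]),
              node(hc$merge[i, 2], hc$height[i]), h - hc$height[i])
    }
  }
  paste0(node(nrow(hc$merge), hc$height[nrow(hc$merge)]), ";")
}
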