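#' Build a composition table from gated counts
#'
#' Closes per-sample counts of mutually exclusive cell types under a
#' declared denominator population into proportions summing to 1. Zero
#' counts are handled by multiplicative replacement: a zero proportion is
#' replaced by `delta / denominator_count` and the nonzero proportions are
#' rescaled so the row re-closes to 1.
#'
#' @param counts samples x types matrix of cell counts (e.g. from
#'   [gate_cohort()]`$counts`), or a `population_table` list.
#' @param denominator_counts per-sample denominator counts (same order).
#' @param types columns of `counts` to use.
#' @param delta zero-replacement pseudo-count (default 0.5).
#' @param tree optional gating tree; when supplied, `types` must be
#'   exclusive (non-overlapping) nodes, or an error is raised.
#' @param masks optional list of per-sample membership mask matrices; when
#'   supplied, any cell belonging to two requested types raises an error.
#' @return a `composition_table`: list with `proportions` (rows sum to 1,
#'   strictly positive), `denominator`, `delta`.
#' @export
build_compositions <- function(counts, denominator_counts, types,
                               delta = 0.5, tree = NULL, masks = NULL) {
  counts <- as.matrix(counts)
  stop_missing(setdiff(types, colnames(counts)), "cell types")
  if (!is.null(tree)) {
    names(tree) <- vapply(tree, `[[`, character(1), "name")
    nonexcl <- types[vapply(types, function(t) {
      !isTRUE(tree[[t]]$exclusive)
    }, logical(1))]
    if (length(nonexcl)) {
      stop("types overlap other populations and cannot enter a composition: ",
           paste(nonexcl, collapse = ", "))
    }
    # structural disjointness: no type may be an ancestor of another, and
    # each pair must diverge at distinct exclusive children of their
    # deepest common ancestor
    path_to_root <- function(t) {
      p <- t
      while (!is.na(tree[[p[1]]]$parent)) p <- c(tree[[p[1]]]$parent, p)
      p
    }
    paths <- lapply(types, path_to_root)
    names(paths) <- types
    for (i in seq_along(types)) {
      for (j in seq_len(i - 1)) {
        a <- paths[[i]]; b <- paths[[j]]
        if (types[i] %in% b || types[j] %in% a) {
          stop("types overlap (nested populations): ", types[j], ", ",
               types[i])
        }
        depth <- max(which(a[seq_len(min(length(a), length(b)))] ==
                             b[seq_len(min(length(a), length(b)))]))
        ca <- a[depth + 1]; cb <- b[depth + 1]
        if (!isTRUE(tree[[ca]]$exclusive) || !isTRUE(tree[[cb]]$exclusive)) {
          stop("types overlap via non-exclusive branches: ", types[j],
               ", ", types[i])
        }
      }
    }
  }
  if (!is.null(masks)) {
    for (m in masks) {
      if (any(rowSums(m[, types, drop = FALSE]) > 1)) {
        stop("requested types overlap at the cell level")
      }
    }
  }
  x <- counts[, types, drop = FALSE]
  if (any(x > denominator_counts)) {
    stop("type count exceeds denominator count")
  }
  p <- x / denominator_counts
  # multiplicative zero replacement, then re-closure
  for (i in seq_len(nrow(p))) {
    z <- p[i, ] == 0
    if (any(z)) {
      repl <- delta / denominator_counts[i]
      p[i, z] <- repl
      p[i, !z] <- p[i, !z] * (1 - sum(z) * repl) / sum(p[i, !z])
    } else {
      p[i, ] <- p[i, ] / sum(p[i, ])
    }
  }
  structure(list(proportions = p, denominator = denominator_counts,
                 delta = delta, types = types),
            class = "composition_table")
}

clr <- function(z) log(z) - mean(log(z))

#' Aitchison distance between two compositions
#'
#' Euclidean distance between centered-log-ratio transforms,
#' `clr(z) = log z - mean(log z)` (natural log). Scale-invariant: closure
#' of raw counts does not change it.
#'
#' @param x,y strictly positive compositions of equal length.
#' @return nonnegative distance.
#' @export
aitchison_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x <= 0) || any(y <= 0)) stop("compositions must be strictly positive")
  sqrt(sum((clr(x) - clr(y))^2))
}

aitchison_dist_matrix <- function(p) {
  lc <- t(apply(p, 1, clr))
  stats::dist(lc, method = "euclidean")
}

#' Kernel distance-covariance test for composition-predictor association
#'
#' A CODAK-style permutation test: Gaussian kernel on Aitchison distances
#' (bandwidth = median pairwise distance), delta kernel on the group
#' labels, and the biased HSIC statistic `tr(K H L H) / n^2`. The p-value
#' is `(1 + #\{permuted >= observed\}) / (B + 1)` over B label
#' permutations, fully determined by `seed`.
#'
#' @param comp a `composition_table` (or strictly positive matrix).
#' @param labels group label per sample (>= 2 per group).
#' @param B number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return list with `statistic`, `p.value`, `B`, `bandwidth`, `seed`.
#' @export
codak_test <- function(comp, labels, B = 10000, seed = 1L) {
  p <- if (inherits(comp, "composition_table")) comp$proportions else
    as.matrix(comp)
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) stop("labels must not be constant")
  if (any(table(labels) < 2)) stop("need at least 2 samples per group")
  if (B < 99) stop("B must be at least 99")
  D <- as.matrix(aitchison_dist_matrix(p))
  n <- nrow(D)
  bw <- stats::median(D[lower.tri(D)])
  K <- if (bw > 0) exp(-D^2 / (2 * bw^2)) else (D == 0) * 1
  L <- outer(labels, labels, `==`) * 1
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  obs <- sum(Kc * L) / n^2
  perm <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n)
      sum(Kc * L[idx, idx]) / n^2
    }, numeric(1))
  })
  # ties at floating-point resolution count as >= (keeps the degenerate
  # all-equal case at p = 1)
  tol <- 1e-12 * max(1, abs(obs))
  list(statistic = obs, p.value = (1 + sum(perm >= obs - tol)) / (B + 1),
       B = B,
       bandwidth = bw, seed = seed,
       kernel = "gaussian/median-heuristic on Aitchison distances")
}

#' Per-type differential abundance via logistic mixed models
#'
#' For each cell type, fits a binomial logistic GLMM of count/total on
#' group with a subject random intercept ([lme4::glmer()]) and reports the
#' Wald p-value for the group effect, BH-adjusted across types. With one
#' observation per subject the random-intercept variance is estimated at
#' the boundary (0) and the fit reduces to ordinary logistic regression.
#' Complete separation or non-convergence is flagged, not fatal.
#'
#' @param counts observations x types matrix of cell counts.
#' @param totals per-observation denominator counts.
#' @param groups two-level factor per observation.
#' @param subjects subject id per observation (repeated measures allowed).
#' @return data.frame type, estimate (log-OR), se, z, p, p_adj, flag.
#' @export
differential_abundance_glmm <- function(counts, totals, groups, subjects) {
  counts <- as.matrix(counts)
  stopifnot(all(totals >= counts), length(totals) == nrow(counts))
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("groups must have exactly two levels")
  res <- lapply(colnames(counts) %||% seq_len(ncol(counts)), function(j) {
    df <- data.frame(k = counts[, j], n = totals, group = g,
                     subject = as.factor(subjects))
    flag <- ""
    fit <- withCallingHandlers(
      tryCatch(
        lme4::glmer(cbind(k, n - k) ~ group + (1 | subject), data = df,
                    family = stats::binomial()),
        error = function(e) e),
      warning = function(w) {
        flag <<- paste(flag, conditionMessage(w), sep = ";")
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    if (inherits(fit, "error")) {
      return(data.frame(type = as.character(j), estimate = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        flag = paste0("error:", conditionMessage(fit)),
                        stringsAsFactors = FALSE))
    }
    co <- suppressWarnings(summary(fit))$coefficients
    est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
    if (abs(est) > 10 || se > 10) {
      flag <- paste(flag, "possible separation", sep = ";")
    }
    data.frame(type = as.character(j), estimate = est, se = se,
               z = est / se, p = 2 * stats::pnorm(-abs(est / se)),
               flag = sub("^;", "", flag), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Cluster subjects by cell-type composition
#'
#' Ward clustering on Aitchison distances between compositions, with the
#' same branch-enrichment test as the expression-module clustering.
#'
#' @param comp a `composition_table`.
#' @param labels logical disease labels in row order.
#' @param level branch level for the enrichment cut (default 3).
#' @return list with `hclust` and `enrichment` (see [branch_enrichment()]).
#' @export
cluster_compositions <- function(comp, labels, level = 3) {
  p <- if (inherits(comp, "composition_table")) comp$proportions else
    as.matrix(comp)
  hc <- cluster_subjects(aitchison_dist_matrix(p))
  hc$labels <- rownames(p) %||% as.character(seq_len(nrow(p)))
  list(hclust = hc, enrichment = branch_enrichment(hc, labels, level))
}
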