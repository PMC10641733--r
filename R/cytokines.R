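#' Anchor-referenced cytokine positivity threshold
#'
#' The positivity threshold for a cytokine is the q-quantile (default 95th
#' percentile, linear-interpolation convention, quantile type 7) of the
#' cytokine's intensity over the anchor sample's cells in the scored
#' population at T0. Thresholds are batch-local: each barcode set carries
#' its own anchor aliquot.
#'
#' @param anchor_events anchor `event_table` at condition T0.
#' @param population logical membership mask (NULL = all anchor cells).
#' @param cytokine marker name.
#' @param q quantile level.
#' @param scale "raw" (default) or "arcsinh".
#' @return threshold intensity on the requested scale.
#' @export
anchor_threshold <- function(anchor_events, population = NULL, cytokine,
                             q = 0.95, scale = c("raw", "arcsinh")) {
  scale <- match.arg(scale)
  if (!identical(anchor_events$condition, "T0")) {
    stop("anchor thresholds are defined at condition T0")
  }
  mat <- if (scale == "raw") anchor_events$intensities else {
    if (is.null(anchor_events$transformed)) {
      stop("events are not arcsinh transformed")
    }
    anchor_events$transformed
  }
  if (!cytokine %in% colnames(mat)) stop("unknown cytokine: ", cytokine)
  v <- mat[, cytokine]
  if (!is.null(population)) v <- v[population]
  if (length(v) == 0) stop("anchor population is empty")
  stats::quantile(v, q, names = FALSE, type = 7)
}

#' Percent of population cells above a threshold
#'
#' `100 * #\{intensity > threshold\} / #population`; ties with the threshold
#' count as negative (strict inequality).
#'
#' @param events an `event_table`.
#' @param population logical mask (NULL = all cells).
#' @param cytokine marker name.
#' @param threshold intensity threshold (same scale as `scale`).
#' @param scale "raw" or "arcsinh".
#' @return percent in \[0, 100\]; `NA` for an empty population.
#' @export
percent_positive <- function(events, population = NULL, cytokine, threshold,
                             scale = c("raw", "arcsinh")) {
  scale <- match.arg(scale)
  mat <- if (scale == "raw") events$intensities else events$transformed
  if (!cytokine %in% colnames(mat)) stop("unknown cytokine: ", cytokine)
  v <- mat[, cytokine]
  if (!is.null(population)) v <- v[population]
  if (length(v) == 0) return(NA_real_)
  100 * mean(v > threshold)
}

#' T6 - T0 change in percent-positive
#'
#' For one subject and one population/cytokine, the percentage of cells
#' above the batch anchor threshold after the 6-hour incubation minus the
#' baseline percentage at T0. Negative values mean fewer above-threshold
#' cells at T6 than at T0 and are preserved.
#'
#' @param events_t0,events_t6 paired `event_table`s of the same subject.
#' @param population_t0,population_t6 membership masks in each sample.
#' @param cytokine marker name.
#' @param threshold the batch-local anchor threshold.
#' @param scale "raw" or "arcsinh".
#' @return delta in percentage points, in \[-100, 100\].
#' @export
delta_percent_positive <- function(events_t0, events_t6, population_t0 = NULL,
                                   population_t6 = NULL, cytokine, threshold,
                                   scale = "raw") {
  if (!identical(events_t0$subject_id, events_t6$subject_id)) {
    stop("T0/T6 samples belong to different subjects")
  }
  p0 <- percent_positive(events_t0, population_t0, cytokine, threshold, scale)
  p6 <- percent_positive(events_t6, population_t6, cytokine, threshold, scale)
  p6 - p0
}

#' Cohort-level cytokine positivity deltas
#'
#' Computes batch-local anchor thresholds and per-subject T6 - T0 positivity
#' deltas for one gated population across a cytokine family.
#'
#' @param events named list of `event_table`s (anchors included).
#' @param gated output of [gate_cohort()] over the same samples.
#' @param population gated population to score (threshold population
#'   defaults to the same one).
#' @param cytokines character vector of cytokine markers.
#' @param q anchor quantile (default 0.95).
#' @return list with `thresholds` (batch x cytokine matrix) and `deltas`
#'   (data.frame subject x cytokine with delta percentage points).
#' @export
cytokine_deltas <- function(events, gated, population, cytokines, q = 0.95) {
  is_anchor <- vapply(events, function(e) isTRUE(e$is_anchor), logical(1))
  anchors <- events[is_anchor &
                      vapply(events, function(e) e$condition == "T0",
                             logical(1))]
  if (!length(anchors)) stop("no anchor T0 samples found")
  batches <- unname(vapply(anchors, `[[`, character(1), "batch_id"))
  thresholds <- t(vapply(anchors, function(a) {
    mask <- gated$tables[[a$sample_id]]$masks[, population]
    vapply(cytokines, function(cy) {
      anchor_threshold(a, mask, cy, q)
    }, numeric(1))
  }, numeric(length(cytokines))))
  rownames(thresholds) <- batches
  if (length(cytokines) == 1L) colnames(thresholds) <- cytokines

  subj <- vapply(events, `[[`, character(1), "subject_id")
  cond <- vapply(events, `[[`, character(1), "condition")
  visit <- vapply(events, function(e) as.integer(e$visit_id), integer(1))
  keep <- !is_anchor & visit == 1L
  ids0 <- names(events)[keep & cond == "T0"]
  rows <- lapply(ids0, function(id0) {
    e0 <- events[[id0]]
    id6 <- names(events)[keep & cond == "T6" & subj == e0$subject_id]
    if (length(id6) != 1L) stop("unpaired T0 sample: ", id0)
    e6 <- events[[id6]]
    m0 <- gated$tables[[id0]]$masks[, population]
    m6 <- gated$tables[[id6]]$masks[, population]
    d <- vapply(cytokines, function(cy) {
      delta_percent_positive(e0, e6, m0, m6, cy,
                             thresholds[e0$batch_id, cy])
    }, numeric(1))
    cbind(data.frame(subject_id = e0$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(d)))
  })
  list(thresholds = thresholds, deltas = do.call(rbind, rows))
}

#' Group comparison of positivity deltas
#'
#' Two-sample test per cytokine (Welch t-test by default, with pooled-
#' variance and Mann-Whitney alternatives since the source analyses cite
#' both), Benjamini-Hochberg adjusted across the family.
#'
#' @param deltas numeric matrix/data.frame (subjects x cytokines).
#' @param groups two-level factor over subjects.
#' @param method "welch", "student" or "mwu".
#' @return data.frame cytokine, statistic, p, p_adj.
#' @export
compare_delta <- function(deltas, groups, method = c("welch", "student",
                                                     "mwu")) {
  method <- match.arg(method)
  deltas <- as.matrix(deltas)
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (any(table(g) < 2)) stop("both groups need at least 2 values")
  lv <- levels(g)
  res <- lapply(colnames(deltas) %||% seq_len(ncol(deltas)), function(j) {
    x <- deltas[g == lv[1], j]; y <- deltas[g == lv[2], j]
    if (method == "mwu") {
      t <- mwu_test(x, y)
      data.frame(cytokine = as.character(j), statistic = t$statistic,
                 p = t$p.value, stringsAsFactors = FALSE)
    } else {
      if (stats::var(x) + stats::var(y) == 0) {
        # degenerate: zero variance in both groups
        eq <- isTRUE(all.equal(mean(x), mean(y)))
        data.frame(cytokine = as.character(j),
                   statistic = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                   p = if (eq) 1 else 0, stringsAsFactors = FALSE)
      } else {
        ht <- stats::t.test(x, y, var.equal = (method == "student"))
        data.frame(cytokine = as.character(j),
                   statistic = unname(ht$statistic), p = ht$p.value,
                   stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}
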