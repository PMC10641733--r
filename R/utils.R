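`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as a named surface so that the
#' FDR family used by each analysis stage is explicit and testable.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, same length/names as `p`.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

relu <- function(x) pmax(x, 0)

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score for a binary truth label.
#' Ties in scores are handled by midranks.
#'
#' @param score numeric scores, higher = more positive.
#' @param truth logical (or 0/1) ground-truth labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(score, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score) == length(truth), any(truth), any(!truth))
  r <- rank(score)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic child seed, kept under 2^31 for R's 32-bit integers
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

stop_missing <- function(missing, what) {
  if (length(missing)) {
    stop(sprintf("missing required %s: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}
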