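#' Construct an expression table
#'
#' Subjects x genes raw heights from a targeted capillary-electrophoresis
#' panel: 51 response genes plus the 3 housekeeping normalizer genes ACTB,
#' GAPDH and TFRC. Heights are any positive abundance scale; normalization
#' only uses ratios.
#'
#' @param heights positive numeric matrix, subjects x genes.
#' @param roles named character vector over genes, "response" or
#'   "housekeeping".
#' @param subjects data.frame with at least `subject_id` and `group`.
#' @return an `expression_table`.
#' @export
expression_table <- function(heights, roles, subjects) {
  heights <- as.matrix(heights)
  if (any(heights <= 0)) {
    bad <- which(heights <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive height for subject %s, gene %s",
                 rownames(heights)[bad[1]], colnames(heights)[bad[2]]))
  }
  stopifnot(all(colnames(heights) %in% names(roles)),
            all(roles %in% c("response", "housekeeping")))
  hk <- names(roles)[roles == "housekeeping"]
  if (!setequal(intersect(hk, colnames(heights)), hk) || length(hk) < 1) {
    stop("housekeeping genes absent from the height matrix")
  }
  structure(list(heights = heights, roles = roles[colnames(heights)],
                 subjects = subjects),
            class = "expression_table")
}

#' Default gene-module map (synthetic stand-in)
#'
#' The 10 modules of the targeted immune-profiling panel with a synthetic
#' stand-in gene membership: the commercial panel's full 51-gene list is not
#' public, so genes other than the four printed IFN-1 genes (HERC5, IFI27,
#' IFIT1, RSAD2) are plausible, documented placeholders with the correct
#' module count and total (51 response genes). The three interferon modules
#' are flagged `is_ifn`.
#'
#' @return named list of modules, each `list(name, genes, is_ifn)`.
#' @export
default_module_defs <- function() {
  mk <- function(name, genes, is_ifn = FALSE) {
    list(name = name, genes = genes, is_ifn = is_ifn)
  }
  mods <- list(
    mk("IFN_1", c("HERC5", "IFI27", "IFIT1", "RSAD2"), TRUE),
    mk("IFN_Beta", c("IFI44", "IFI44L", "IFI6", "MX1", "OAS1"), TRUE),
    mk("IFN_Gamma", c("GBP1", "GBP5", "STAT1", "CXCL10", "IDO1"), TRUE),
    mk("B_Cell", c("MS4A1", "CD79A", "CD79B", "TNFRSF13B", "FCRL1")),
    mk("Plasmablast", c("MZB1", "JCHAIN", "TNFRSF17", "TXNDC5", "XBP1")),
    mk("T_Cell", c("CD3E", "CD2", "IL7R", "TRAC", "LCK")),
    mk("Neutrophil", c("ELANE", "DEFA4", "MPO", "CEACAM8", "MMP8")),
    mk("pDC", c("LILRA4", "CLEC4C", "IRF7", "GZMB")),
    mk("Energy", c("ATP5F1A", "NDUFA4", "COX5A", "SDHB", "UQCRC1")),
    mk("mRNA_Translation", c("RPL13A", "RPS6", "EEF1A1", "EIF4E", "RPL37",
                             "RPS24", "RPL11", "RPS15")))
  names(mods) <- vapply(mods, `[[`, character(1), "name")
  mods
}

#' Read / write an expression table as TSV
#'
#' Layout: one row per gene with columns `gene`, `role` and one column per
#' subject (genes x subjects); the `role` column marks the orientation.
#' Subject metadata (subject_id, group) travels as a separate plain TSV,
#' written alongside the heights when `subjects_path` is given.
#'
#' @param path TSV of gene heights.
#' @param subjects data.frame with `subject_id`, `group` (reader), or path
#'   to a two-column TSV with those columns.
#' @return an [expression_table()].
#' @export
read_expression_table <- function(path, subjects) {
  df <- utils::read.csv(path, sep = "\t", check.names = FALSE)
  if (!all(c("gene", "role") %in% names(df))) {
    stop("expected 'gene' and 'role' columns")
  }
  if (is.character(subjects)) {
    subjects <- utils::read.csv(subjects, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  heights <- t(as.matrix(df[, setdiff(names(df), c("gene", "role")),
                            drop = FALSE]))
  colnames(heights) <- df$gene
  roles <- stats::setNames(df$role, df$gene)
  expression_table(heights[subjects$subject_id, , drop = FALSE], roles,
                   subjects)
}

#' @rdname read_expression_table
#' @param tbl an `expression_table` to write.
#' @param subjects_path optional TSV path for the subject metadata.
#' @export
write_expression_table <- function(tbl, path, subjects_path = NULL) {
  df <- data.frame(gene = colnames(tbl$heights),
                   role = unname(tbl$roles[colnames(tbl$heights)]),
                   t(tbl$heights), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(subjects_path)) {
    utils::write.table(tbl$subjects, subjects_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Housekeeping-normalized expression
#'
#' `norm[s, g] = log2(height[s, g]) - mean_h log2(height[s, h])` over the
#' housekeeping genes h; returned for response genes only. Invariant to a
#' global per-subject scaling of heights.
#'
#' @param tbl an [expression_table()].
#' @return numeric matrix subjects x response genes (log2 scale).
#' @export
normalize_expression <- function(tbl) {
  stopifnot(inherits(tbl, "expression_table"))
  hk <- names(tbl$roles)[tbl$roles == "housekeeping"]
  resp <- names(tbl$roles)[tbl$roles == "response"]
  l2 <- log2(tbl$heights)
  l2[, resp, drop = FALSE] - rowMeans(l2[, hk, drop = FALSE])
}

#' Module scores and IFN-1 classification
#'
#' Each module score is the arithmetic mean of its constituent genes'
#' normalized values; the IFN-1 score is the mean of the normalized HERC5,
#' IFI27, IFIT1 and RSAD2 values, classified high when it exceeds the
#' cutoff (default -0.5, the fixed panel constant).
#'
#' @param norm normalized matrix from [normalize_expression()].
#' @param modules module list as from [default_module_defs()].
#' @param ifn_cutoff high/low cutoff on the IFN-1 score.
#' @return list with `scores` (subjects x modules matrix), `ifn1` (numeric),
#'   `ifn_class` ("high"/"low"), `cutoff`.
#' @export
score_modules <- function(norm, modules = default_module_defs(),
                          ifn_cutoff = IFN1_CUTOFF) {
  scores <- sapply(modules, function(m) {
    if (length(m$genes) == 0) stop("empty module: ", m$name)
    stop_missing(setdiff(m$genes, colnames(norm)), "module genes")
    rowMeans(norm[, m$genes, drop = FALSE])
  })
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1,
                     dimnames = list(rownames(norm), names(modules)))
  }
  ifn1 <- if ("IFN_1" %in% colnames(scores)) scores[, "IFN_1"] else
    stop("no IFN_1 module defined")
  list(scores = scores, ifn1 = ifn1,
       ifn_class = ifelse(ifn1 > ifn_cutoff, "high", "low"),
       cutoff = ifn_cutoff)
}

#' Fixed IFN-1 high/low cutoff
#'
#' The panel constant -0.5: two healthy standard deviations (95th
#' percentile) above the mean IFN-1 score of 281 healthy reference samples.
#' @export
IFN1_CUTOFF <- -0.5

#' Derive an IFN-1 cutoff from healthy reference scores
#'
#' Mean plus two sample standard deviations of the healthy scores.
#'
#' @param healthy_scores numeric vector (length >= 2).
#' @return the cutoff.
#' @export
derive_ifn_cutoff <- function(healthy_scores) {
  healthy_scores <- healthy_scores[!is.na(healthy_scores)]
  if (length(healthy_scores) < 2) stop("need at least 2 healthy scores")
  mean(healthy_scores) + 2 * stats::sd(healthy_scores)
}

#' Group comparison of module scores
#'
#' Two-sided Mann-Whitney U test per module (exact for small untied
#' samples, otherwise tie-corrected normal approximation) with
#' Benjamini-Hochberg adjustment across the module family.
#'
#' @param scores subjects x modules matrix.
#' @param groups two-level factor over subjects.
#' @return data.frame module, U, p, p_adj.
#' @export
compare_module_scores <- function(scores, groups) {
  out <- mwu_family(scores, groups)
  names(out)[names(out) == "feature"] <- "module"
  out
}
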