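#' Default CyTOF marker panel
#'
#' The marker panel assumed by [default_gating_tree()] and emulated by the
#' synthetic-cohort generator: lineage markers for the gating hierarchy,
#' activation markers (CD38, PD1, HLADR) and intracellular cytokines.
#'
#' @return data.frame with columns `marker`, `role`
#'   (lineage/activation/cytokine).
#' @export
default_panel <- function() {
  data.frame(
    marker = c("CD66", "CD3", "CD4", "CD8", "CD45RA", "CD27", "CD19", "IgM",
               "IgD", "CD21", "CD11c", "CXCR5", "CD56", "CD16", "CD14",
               "CD38", "PD1", "HLADR", "MCP1", "MIP1B", "IL1RA", "IFNG"),
    role = c(rep("lineage", 15), rep("activation", 3), rep("cytokine", 4)),
    stringsAsFactors = FALSE)
}

#' Construct a gate node
#'
#' A node of the manual gating hierarchy. Its predicate is a conjunction of
#' threshold comparisons on arcsinh-transformed markers; `complement = TRUE`
#' instead defines the node as the parent cells not captured by any already
#' defined exclusive sibling (the "other"/ungated remainder), which
#' guarantees that exclusive siblings partition their parent.
#'
#' @param name population name.
#' @param parent parent population name (`NA` for the root).
#' @param predicate list of triples `list(marker, op, ref)` with `op` one of
#'   `">"`, `"<="` and `ref` the name of a threshold (see
#'   [estimate_gate_thresholds()]) or a numeric constant.
#' @param exclusive logical; exclusive siblings must not overlap.
#' @param complement logical; see above.
#' @return a `gate_node` list.
#' @export
gate_node <- function(name, parent = NA_character_, predicate = list(),
                      exclusive = TRUE, complement = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  for (p in predicate) {
    stopifnot(all(c("marker", "op", "ref") %in% names(p)),
              p$op %in% c(">", "<="))
  }
  structure(list(name = name, parent = parent, predicate = predicate,
                 exclusive = exclusive, complement = complement),
            class = "gate_node")
}

cmp <- function(marker, op, ref) list(marker = marker, op = op, ref = ref)

#' Built-in gating hierarchy
#'
#' The manual gating tree used throughout: leukocytes split into CD66+
#' neutrophils and lymphocytes; lymphocytes into T, B, NK, CD14hi monocytes
#' (plus a complement remainder); T cells into CD4/CD8 and CD45RA/CD27
#' memory quadrants; CD4 cells additionally into PD-1hi cTfh (CXCR5+) and
#' cTph (CXCR5-); B cells into CD27-/CD27+ IgM/IgD quadrants, plasmablasts
#' (CD27+CD38+), the double-negative family (DN1/DN2/activated DN), anergic
#' naive Bnd with its activated Bnd2 subset, aNAV and CD21lo B cells; NK
#' into CD56dim CD16+.
#'
#' @param panel data.frame as from [default_panel()].
#' @param memory_convention `"as_printed"` keeps the memory-quadrant naming
#'   used in the source study (TCM = CD45RA+CD27-, TEM = CD45RA-CD27+);
#'   `"conventional"` swaps to the textbook assignment.
#' @param bnd_igm_ref threshold reference used for the IgM-low/negative cut
#'   of the anergic Bnd gate (defaults to the shared `"IgM"` threshold).
#' @return list of [gate_node()] objects in evaluation order.
#' @export
default_gating_tree <- function(panel = default_panel(),
                                memory_convention = c("as_printed",
                                                      "conventional"),
                                bnd_igm_ref = "IgM") {
  memory_convention <- match.arg(memory_convention)
  need <- c("CD66", "CD3", "CD4", "CD8", "CD45RA", "CD27", "CD19", "IgM",
            "IgD", "CD21", "CD11c", "CXCR5", "CD56", "CD16", "CD14", "CD38",
            "PD1")
  stop_missing(setdiff(need, panel$marker), "markers")

  # memory quadrant naming: RA+27+ / RA+27- / RA-27+ / RA-27-
  qnames <- if (memory_convention == "as_printed") {
    c("TN", "TCM", "TEM", "TEMRA")
  } else {
    c("TN", "TEMRA", "TCM", "TEM")
  }
  tquads <- function(lineage) {
    pp <- paste0(lineage, "_T")
    list(
      gate_node(paste0(lineage, "_", qnames[1]), pp,
                list(cmp("CD45RA", ">", "CD45RA"), cmp("CD27", ">", "CD27"))),
      gate_node(paste0(lineage, "_", qnames[2]), pp,
                list(cmp("CD45RA", ">", "CD45RA"), cmp("CD27", "<=", "CD27"))),
      gate_node(paste0(lineage, "_", qnames[3]), pp,
                list(cmp("CD45RA", "<=", "CD45RA"), cmp("CD27", ">", "CD27"))),
      gate_node(paste0(lineage, "_", qnames[4]), pp,
                list(cmp("CD45RA", "<=", "CD45RA"), cmp("CD27", "<=", "CD27"))))
  }

  c(list(
    gate_node("leukocytes"),
    gate_node("neutrophils", "leukocytes", list(cmp("CD66", ">", "CD66"))),
    gate_node("lymphocytes", "leukocytes", list(cmp("CD66", "<=", "CD66"))),
    gate_node("T_cells", "lymphocytes", list(cmp("CD3", ">", "CD3"))),
    gate_node("B_cells", "lymphocytes",
              list(cmp("CD3", "<=", "CD3"), cmp("CD19", ">", "CD19"))),
    gate_node("NK", "lymphocytes",
              list(cmp("CD3", "<=", "CD3"), cmp("CD19", "<=", "CD19"),
                   cmp("CD56", ">", "CD56"))),
    gate_node("Monocytes_CD14hi", "lymphocytes",
              list(cmp("CD3", "<=", "CD3"), cmp("CD19", "<=", "CD19"),
                   cmp("CD56", "<=", "CD56"), cmp("CD14", ">", "CD14"))),
    gate_node("Lymphocytes_other", "lymphocytes", complement = TRUE),
    gate_node("CD4_T", "T_cells",
              list(cmp("CD4", ">", "CD4"), cmp("CD8", "<=", "CD8"))),
    gate_node("CD8_T", "T_cells",
              list(cmp("CD8", ">", "CD8"), cmp("CD4", "<=", "CD4"))),
    gate_node("T_other", "T_cells", complement = TRUE)),
    tquads("CD4"), tquads("CD8"),
    list(
      gate_node("cTfh", "CD4_T",
                list(cmp("PD1", ">", "PD1.hi"), cmp("CXCR5", ">", "CXCR5")),
                exclusive = FALSE),
      gate_node("cTph", "CD4_T",
                list(cmp("PD1", ">", "PD1.hi"), cmp("CXCR5", "<=", "CXCR5")),
                exclusive = FALSE),
      gate_node("B_CD27neg", "B_cells", list(cmp("CD27", "<=", "CD27"))),
      gate_node("B_CD27pos", "B_cells", list(cmp("CD27", ">", "CD27"))),
      # CD27- quadrants
      gate_node("DN_B", "B_CD27neg",
                list(cmp("IgM", "<=", "IgM"), cmp("IgD", "<=", "IgD"))),
      gate_node("AnergicNaive", "B_CD27neg",
                list(cmp("IgM", "<=", "IgM"), cmp("IgD", ">", "IgD"))),
      gate_node("ImmatureNaive", "B_CD27neg",
                list(cmp("IgM", ">", "IgM"), cmp("IgD", "<=", "IgD"))),
      gate_node("MatureNaive", "B_CD27neg",
                list(cmp("IgM", ">", "IgM"), cmp("IgD", ">", "IgD"))),
      # CD27+ quadrants
      gate_node("SwitchedMemory", "B_CD27pos",
                list(cmp("IgM", "<=", "IgM"), cmp("IgD", "<=", "IgD"))),
      gate_node("CdeltaSwitched", "B_CD27pos",
                list(cmp("IgM", "<=", "IgM"), cmp("IgD", ">", "IgD"))),
      gate_node("IgMMemory", "B_CD27pos",
                list(cmp("IgM", ">", "IgM"), cmp("IgD", "<=", "IgD"))),
      gate_node("PreSwitched", "B_CD27pos",
                list(cmp("IgM", ">", "IgM"), cmp("IgD", ">", "IgD"))),
      # double-negative B family
      gate_node("DN1", "DN_B",
                list(cmp("CXCR5", ">", "CXCR5"), cmp("CD11c", "<=", "CD11c"))),
      gate_node("DN2", "DN_B",
                list(cmp("CXCR5", "<=", "CXCR5"), cmp("CD11c", ">", "CD11c"),
                     cmp("CD21", "<=", "CD21"))),
      gate_node("ActivatedDN", "DN_B", complement = TRUE),
      # anergic naive and its activated CD21lo CXCR5- subset
      gate_node("Bnd", "B_CD27neg",
                list(cmp("IgM", "<=", bnd_igm_ref), cmp("IgD", ">", "IgD")),
                exclusive = FALSE),
      gate_node("Bnd2", "Bnd",
                list(cmp("CD21", "<=", "CD21"), cmp("CXCR5", "<=", "CXCR5"))),
      gate_node("Bnd1", "Bnd", complement = TRUE),
      gate_node("Plasmablasts", "B_cells",
                list(cmp("CD27", ">", "CD27"), cmp("CD38", ">", "CD38")),
                exclusive = FALSE),
      gate_node("aNAV", "B_CD27neg",
                list(cmp("CD38", "<=", "CD38"), cmp("CD21", "<=", "CD21"),
                     cmp("CXCR5", "<=", "CXCR5"), cmp("IgD", ">", "IgD"),
                     cmp("CD11c", ">", "CD11c")),
                exclusive = FALSE),
      gate_node("B_CD21lo", "B_cells", list(cmp("CD21", "<=", "CD21")),
                exclusive = FALSE),
      gate_node("NK_CD56dim_CD16pos", "NK", list(cmp("CD16", ">", "CD16"))),
      gate_node("NK_other", "NK", complement = TRUE)))
}

#' Data-driven gate thresholds
#'
#' The study gates manually from supplementary plots; as machine-readable
#' defaults, each lineage-marker threshold is derived from the pooled
#' (typically healthy-control) arcsinh-transformed intensities. Two methods
#' are offered: `"midpoint"` (default) places the threshold halfway between
#' a low and a high quantile (default 2nd and 98th percentiles), which lands
#' in the valley of a bimodal negative/positive marker even when the
#' positive mode is a small minority; `"quantile"` uses the stated quantile
#' `q` directly. "hi" gates use the 90th percentile of the relevant parent
#' population (PD-1hi over CD4 T cells). Every threshold can be overridden.
#'
#' @param events_list list of transformed `event_table`s to pool (typically
#'   healthy controls).
#' @param method "midpoint" or "quantile".
#' @param q quantile for base thresholds (method "quantile").
#' @param lo,hi bracketing quantiles (method "midpoint").
#' @param hi_q quantile for "hi" thresholds.
#' @param overrides named numeric vector of thresholds to force.
#' @return named numeric vector of thresholds on the arcsinh scale.
#' @export
estimate_gate_thresholds <- function(events_list,
                                     method = c("midpoint", "quantile"),
                                     q = 0.5, lo = 0.02, hi = 0.98,
                                     hi_q = 0.9, overrides = NULL) {
  method <- match.arg(method)
  if (inherits(events_list, "event_table")) events_list <- list(events_list)
  for (e in events_list) {
    if (is.null(e$transformed)) stop("events must be arcsinh transformed")
  }
  pooled <- do.call(rbind, lapply(events_list, function(e) e$transformed))
  base_markers <- c("CD66", "CD3", "CD4", "CD8", "CD45RA", "CD27", "CD19",
                    "IgM", "IgD", "CD21", "CD11c", "CXCR5", "CD56", "CD16",
                    "CD14", "CD38")
  base_markers <- intersect(base_markers, colnames(pooled))
  thr <- vapply(base_markers, function(m) {
    if (method == "quantile") {
      stats::quantile(pooled[, m], q, names = FALSE, type = 7)
    } else {
      mean(stats::quantile(pooled[, m], c(lo, hi), names = FALSE, type = 7))
    }
  }, numeric(1))
  names(thr) <- base_markers
  if (all(c("CD3", "CD4", "PD1") %in% colnames(pooled))) {
    cd4 <- pooled[, "CD3"] > thr["CD3"] & pooled[, "CD4"] > thr["CD4"]
    ref <- if (any(cd4)) pooled[cd4, "PD1"] else pooled[, "PD1"]
    thr <- c(thr, PD1.hi = stats::quantile(ref, hi_q, names = FALSE, type = 7))
  }
  if (!is.null(overrides)) thr[names(overrides)] <- overrides
  thr
}

resolve_ref <- function(ref, thresholds) {
  if (is.numeric(ref)) return(ref)
  if (!ref %in% names(thresholds)) stop("no threshold named ", ref)
  unname(thresholds[ref])
}

#' Apply a gating tree to transformed events
#'
#' Evaluates each node's predicate on the arcsinh-transformed intensities,
#' intersected with its parent's membership; complement nodes receive the
#' parent cells not captured by any exclusive sibling. Child membership
#' therefore always implies parent membership.
#'
#' @param events a transformed `event_table`.
#' @param tree list of [gate_node()]s (parents before children).
#' @param thresholds named numeric vector (see [estimate_gate_thresholds()]).
#' @return a `population_table`: list with `sample_id`, logical `masks`
#'   (cells x populations), integer `counts`, and the `tree`.
#' @export
apply_gating <- function(events, tree, thresholds) {
  if (is.null(events$transformed)) stop("events must be arcsinh transformed")
  mat <- events$transformed
  n <- nrow(mat)
  names(tree) <- vapply(tree, `[[`, character(1), "name")
  masks <- matrix(FALSE, n, length(tree), dimnames = list(NULL, names(tree)))
  for (nd in tree) {
    parent_mask <- if (is.na(nd$parent)) rep(TRUE, n) else {
      if (!nd$parent %in% colnames(masks)) {
        stop("parent not yet gated: ", nd$parent)
      }
      masks[, nd$parent]
    }
    if (isTRUE(nd$complement)) {
      sibs <- Filter(function(z) identical(z$parent, nd$parent) &&
                       z$exclusive && !isTRUE(z$complement), tree)
      covered <- rep(FALSE, n)
      for (s in sibs) covered <- covered | masks[, s$name]
      masks[, nd$name] <- parent_mask & !covered
      next
    }
    m <- parent_mask
    for (p in nd$predicate) {
      if (!p$marker %in% colnames(mat)) {
        stop("gating predicate references absent marker: ", p$marker)
      }
      t <- resolve_ref(p$ref, thresholds)
      m <- m & (if (p$op == ">") mat[, p$marker] > t else mat[, p$marker] <= t)
    }
    masks[, nd$name] <- m
  }
  structure(list(sample_id = events$sample_id, masks = masks,
                 counts = colSums(masks), tree = tree),
            class = "population_table")
}

#' Population frequencies relative to a declared denominator
#'
#' @param pt a `population_table` from [apply_gating()].
#' @param denominator population name whose count is the denominator
#'   (e.g. "lymphocytes", "B_cells", "CD4_T").
#' @param populations populations to report (default: all).
#' @return data.frame with population, count, denominator count, `freq` in
#'   \[0, 1\] (`NA` with a warning if the denominator is empty).
#' @export
population_frequencies <- function(pt, denominator,
                                   populations = names(pt$counts)) {
  if (!denominator %in% names(pt$counts)) {
    stop("unknown denominator population: ", denominator)
  }
  den <- pt$counts[[denominator]]
  freq <- if (den > 0) unname(pt$counts[populations]) / den else {
    warning("denominator '", denominator, "' has zero cells in sample ",
            pt$sample_id, "; frequencies are NA")
    rep(NA_real_, length(populations))
  }
  data.frame(sample_id = pt$sample_id, population = populations,
             count = unname(pt$counts[populations]),
             denominator = denominator, denominator_count = den,
             freq = freq, row.names = NULL, stringsAsFactors = FALSE)
}

#' Gate a cohort of samples
#'
#' Convenience wrapper: applies one tree and threshold set to every sample.
#'
#' @param events_list list of transformed `event_table`s.
#' @param tree,thresholds as in [apply_gating()].
#' @return list with `tables` (per-sample `population_table`s, named by
#'   sample id) and `counts` (samples x populations integer matrix).
#' @export
gate_cohort <- function(events_list, tree, thresholds) {
  tables <- lapply(events_list, apply_gating, tree = tree,
                   thresholds = thresholds)
  names(tables) <- vapply(events_list, `[[`, character(1), "sample_id")
  counts <- do.call(rbind, lapply(tables, `[[`, "counts"))
  rownames(counts) <- names(tables)
  list(tables = tables, counts = counts)
}

#' Serialize / read a gating tree as JSON
#'
#' @param tree list of [gate_node()]s.
#' @param path file path.
#' @return `read_gating_tree` returns the tree; `write_gating_tree` the path.
#' @export
write_gating_tree <- function(tree, path) {
  jsonlite::write_json(lapply(tree, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gating_tree
#' @export
read_gating_tree <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(nd) {
    gate_node(nd$name, nd$parent %||% NA_character_,
              lapply(nd$predicate, function(p) {
                cmp(p$marker, p$op,
                    if (is.numeric(p$ref)) p$ref else as.character(p$ref))
              }),
              exclusive = isTRUE(nd$exclusive),
              complement = isTRUE(nd$complement))
  })
}
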