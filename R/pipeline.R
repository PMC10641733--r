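write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Five-number box summary (median, Q1, Q3)
#'
#' Quartiles use the linear-interpolation convention (quantile type 7).
#'
#' @param x numeric vector.
#' @return named vector with n, median, q1, q3.
#' @export
boxplot_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7,
                       na.rm = TRUE)
  c(n = sum(!is.na(x)), median = q[2], q1 = q[1], q3 = q[3])
}

default_run_config <- function() {
  list(
    outdir = "cytoimmune_run",
    seed = 1L,
    stages = c("simulate", "gate", "modules", "cytokines", "composition",
               "longitudinal", "signature"),
    cohort = list(),
    composition_types = c("CD4_TN", "CD4_TCM", "CD4_TEM", "CD4_TEMRA",
                          "CD8_TN", "CD8_TCM", "CD8_TEM", "CD8_TEMRA",
                          "T_other", "B_CD27neg", "B_CD27pos",
                          "NK_CD56dim_CD16pos", "NK_other",
                          "Monocytes_CD14hi", "Lymphocytes_other"),
    cytokine_population = "Monocytes_CD14hi",
    codak_B = 999L,
    signature = list(bag_size = 100L, n_bags_per_sample = 10L,
                     search_iters = 2L, epochs = 8L, percentile = 85))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order on a freshly simulated
#' cohort, writes one TSV/JSON per result family under `config$outdir`, and
#' finishes with a provenance manifest (package version, config, seeds, and
#' an MD5 checksum per output) from which a re-run is bit-reproducible.
#'
#' @param config a named list (or path to a JSON file) overriding the
#'   defaults: `outdir`, `seed`, `stages`, `cohort` (arguments to
#'   [cohort_config()]), `composition_types`, `cytokine_population`,
#'   `codak_B`, `signature` (budget for [train()]).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- utils::modifyList(default_run_config(), config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out_files <- character(0)
  results <- list()
  stages <- config$stages
  need <- function(stage, dep) {
    if (!dep %in% names(results)) {
      stop(sprintf("stage '%s' requires missing upstream stage '%s'",
                   stage, dep), call. = FALSE)
    }
  }

  if ("simulate" %in% stages) {
    cfg <- do.call(cohort_config,
                   utils::modifyList(list(seed = config$seed),
                                     as.list(config$cohort)))
    sim <- simulate_cohort(cfg)
    sim$events <- lapply(sim$events, arcsinh_transform, cofactor = cfg$cofactor)
    results$simulate <- list(cfg = cfg, sim = sim)
    out_files <- c(out_files,
                   write_tsv(sim$visits, file.path(config$outdir,
                                                   "visits.tsv")))
  }

  if ("gate" %in% stages) {
    need("gate", "simulate")
    sim <- results$simulate$sim
    tree <- default_gating_tree()
    hc_t0 <- Filter(function(e) {
      grepl("^HC", e$subject_id) && e$condition == "T0" && !e$is_anchor
    }, sim$events)
    thresholds <- estimate_gate_thresholds(hc_t0)
    gated <- gate_cohort(sim$events, tree, thresholds)
    results$gate <- list(tree = tree, thresholds = thresholds, gated = gated)
    counts_df <- data.frame(sample_id = rownames(gated$counts),
                            gated$counts, check.names = FALSE)
    out_files <- c(out_files,
                   write_tsv(counts_df,
                             file.path(config$outdir, "population_counts.tsv")))
  }

  if ("modules" %in% stages) {
    need("modules", "simulate")
    cfg <- results$simulate$cfg
    expr <- simulate_expression(cfg)
    norm <- normalize_expression(expr)
    sc <- score_modules(norm)
    cmpr <- compare_module_scores(sc$scores, expr$subjects$group)
    hc <- cluster_subjects(sc$scores)
    hc$labels <- rownames(sc$scores)
    enr <- branch_enrichment(hc, expr$subjects$group == "SLE", level = 2)
    results$modules <- list(expr = expr, scores = sc, compare = cmpr,
                            hclust = hc, enrichment = enr)
    mod_df <- data.frame(subject_id = rownames(sc$scores), sc$scores,
                         ifn1 = sc$ifn1, ifn_class = sc$ifn_class,
                         check.names = FALSE)
    out_files <- c(out_files,
                   write_tsv(mod_df, file.path(config$outdir,
                                               "module_scores.tsv")),
                   write_tsv(cmpr, file.path(config$outdir,
                                             "module_tests.tsv")))
    writeLines(hclust_newick(hc),
               fp <- file.path(config$outdir, "module_dendrogram.nwk"))
    out_files <- c(out_files, fp)
  }

  if ("cytokines" %in% stages) {
    need("cytokines", "gate")
    sim <- results$simulate$sim
    cyt <- results$simulate$cfg$marker_panel$marker[
      results$simulate$cfg$marker_panel$role == "cytokine"]
    cd <- cytokine_deltas(sim$events, results$gate$gated,
                          config$cytokine_population, cyt)
    grp <- ifelse(grepl("^HC", cd$deltas$subject_id), "HC", "SLE")
    cmpd <- compare_delta(cd$deltas[, cyt, drop = FALSE], grp)
    results$cytokines <- list(deltas = cd, compare = cmpd)
    out_files <- c(out_files,
                   write_tsv(cd$deltas, file.path(config$outdir,
                                                  "cytokine_deltas.tsv")),
                   write_tsv(cmpd, file.path(config$outdir,
                                             "cytokine_tests.tsv")))
  }

  if ("composition" %in% stages) {
    need("composition", "gate")
    sim <- results$simulate$sim
    gated <- results$gate$gated
    base_ids <- names(sim$events)[vapply(sim$events, function(e) {
      !e$is_anchor && e$condition == "T0" && e$visit_id == 1L
    }, logical(1))]
    counts <- gated$counts[base_ids, , drop = FALSE]
    types <- intersect(config$composition_types, colnames(counts))
    comp <- build_compositions(counts, counts[, "lymphocytes"], types,
                               tree = results$gate$tree)
    grp <- ifelse(grepl("^HC", base_ids), "HC", "SLE")
    ck <- codak_test(comp, grp, B = config$codak_B,
                     seed = derive_seed(config$seed, 11L))
    subj <- sub("_v.*", "", base_ids)
    da <- differential_abundance_glmm(counts[, types],
                                      counts[, "lymphocytes"], grp, subj)
    cc <- cluster_compositions(comp, grp == "SLE", level = 3)
    results$composition <- list(comp = comp, codak = ck, glmm = da,
                                clustering = cc)
    out_files <- c(out_files,
                   write_tsv(da, file.path(config$outdir,
                                           "differential_abundance.tsv")))
    jsonlite::write_json(ck[c("statistic", "p.value", "B", "bandwidth",
                              "seed", "kernel")],
                         fp <- file.path(config$outdir, "codak.json"),
                         auto_unbox = TRUE, digits = NA)
    out_files <- c(out_files, fp)
  }

  if ("longitudinal" %in% stages) {
    need("longitudinal", "simulate")
    v <- results$simulate$sim$visits
    sle <- v[v$group == "SLE", ]
    dc <- differential_correlation(sle$spiked_pct, sle$sledai,
                                   sle$subject_id,
                                   ifelse(sle$ln, "LN", "noLN"))
    lldas <- vapply(seq_len(nrow(v)), function(i) {
      as.logical(classify_lldas(v[i, ]))
    }, logical(1))
    renal <- vapply(split(seq_len(nrow(sle)), sle$subject_id), function(ix) {
      d <- sle[ix, ][order(sle$visit[ix]), ]
      if (nrow(d) < 2) return("indeterminate")
      classify_renal_response(d[1, ], d[nrow(d), ])
    }, character(1))
    results$longitudinal <- list(diffcorr = dc, lldas = lldas, renal = renal)
    out_files <- c(out_files,
                   write_tsv(data.frame(subject_id = names(renal),
                                        renal_response = renal),
                             file.path(config$outdir, "renal_response.tsv")))
    jsonlite::write_json(
      list(interaction_p = dc$interaction_p,
           interaction_estimate = dc$interaction_estimate,
           r_by_group = lapply(dc$by_group, `[[`, "r"), flag = dc$flag),
      fp <- file.path(config$outdir, "differential_correlation.json"),
      auto_unbox = TRUE, digits = NA)
    out_files <- c(out_files, fp)
  }

  if ("signature" %in% stages) {
    need("signature", "gate")
    sim <- results$simulate$sim
    gated <- results$gate$gated
    sg <- config$signature
    base_ids <- names(sim$events)[vapply(sim$events, function(e) {
      !e$is_anchor && e$condition == "T0" && e$visit_id == 1L &&
        grepl("^SLE", e$subject_id)
    }, logical(1))]
    labels <- ifelse(sim$truth$subjects$ln[match(sub("_v.*", "", base_ids),
                                                 sim$truth$subjects$subject_id)],
                     "LN", "noLN")
    pregate <- lapply(base_ids, function(id) {
      gated$tables[[id]]$masks[, "B_cells"]
    })
    bags <- make_bags(sim$events[base_ids], labels, pregate,
                      bag_size = sg$bag_size,
                      n_bags_per_sample = sg$n_bags_per_sample,
                      seed = derive_seed(config$seed, 21L))
    model <- train(bags, search_iters = sg$search_iters,
                   seed = derive_seed(config$seed, 22L),
                   epochs = sg$epochs)
    scores <- lapply(base_ids, function(id) {
      m <- gated$tables[[id]]$masks[, "B_cells"]
      s <- rep(0, nrow(sim$events[[id]]$transformed))
      if (any(m)) {
        s[m] <- score_cells(model, sim$events[[id]]$transformed[m, ,
                                                                drop = FALSE],
                            positive_class = "LN")
      }
      s[m]
    })
    names(scores) <- base_ids
    sel <- select_cells(scores, percentile = sg$percentile)
    freq_df <- data.frame(sample_id = base_ids, label = labels,
                          selected_pct = sel$frequency)
    results$signature <- list(model = model, selection = sel,
                              frequency = freq_df)
    out_files <- c(out_files,
                   write_tsv(freq_df,
                             file.path(config$outdir,
                                       "signature_frequencies.tsv")))
  }

  manifest <- list(
    package = "cytoimmune",
    version = as.character(utils::packageVersion("cytoimmune")),
    seed = config$seed,
    stages = stages,
    config = config[setdiff(names(config), "stages")],
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(out_files)), basename(out_files))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest,
                 outdir = config$outdir))
}

#' Figure-style summary tables from a pipeline run
#'
#' Collapses a [run_pipeline()] result into per-figure-family tables: box
#' summaries of module scores and population frequencies by group, cytokine
#' deltas, composition test results, differential correlations and
#' signature frequencies. Comparisons with an empty group are flagged
#' "insufficient data" rather than failing. BH correction is applied within
#' each family, never across families.
#'
#' @param bundle result of [run_pipeline()].
#' @return named list of data.frames.
#' @export
summarize_results <- function(bundle) {
  res <- bundle$results
  out <- list()
  if (!is.null(res$modules)) {
    sc <- res$modules$scores$scores
    grp <- res$modules$expr$subjects$group
    rows <- lapply(colnames(sc), function(m) {
      cbind(data.frame(module = m),
            t(boxplot_summary(sc[grp == "HC", m])),
            t(boxplot_summary(sc[grp == "SLE", m]) |>
                stats::setNames(c("n_sle", "median_sle", "q1_sle", "q3_sle"))))
    })
    tab <- do.call(rbind, rows)
    tab <- merge(tab, res$modules$compare, by = "module")
    out$module_scores <- tab
  }
  if (!is.null(res$cytokines)) out$cytokine_tests <- res$cytokines$compare
  if (!is.null(res$composition)) {
    out$composition <- data.frame(
      statistic = res$composition$codak$statistic,
      p = res$composition$codak$p.value,
      branch_p = res$composition$clustering$enrichment$p.value)
    out$differential_abundance <- res$composition$glmm
  }
  if (!is.null(res$longitudinal)) {
    dc <- res$longitudinal$diffcorr
    out$differential_correlation <- data.frame(
      interaction_p = dc$interaction_p,
      r_ln = dc$by_group[["LN"]]$r %||% NA_real_,
      r_noln = dc$by_group[["noLN"]]$r %||% NA_real_,
      flag = dc$flag)
  }
  if (!is.null(res$signature)) {
    f <- res$signature$frequency
    if (length(unique(f$label)) < 2 || any(table(f$label) < 1)) {
      out$signature <- data.frame(note = "insufficient data")
    } else {
      out$signature <- f
    }
  }
  out
}
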