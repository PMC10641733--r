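#' Default generative population specifications
#'
#' Mixture components of the synthetic cohort on the arcsinh (cofactor 5)
#' scale. Each population has a per-marker Gaussian location (baseline 0.3
#' for "negative" markers) and scale, baseline mixing weights shared by all
#' groups, and a `spiked` flag marking the disease-associated populations
#' (plasmablast-like and DN2-like B cells) whose total abundance is set by
#' the `spike_frac_*` effect sizes in SLE subjects.
#'
#' @param panel marker panel data.frame (see [default_panel()]).
#' @return list of population specs (name, mu, sd, weight, spiked).
#' @export
default_population_specs <- function(panel = default_panel()) {
  markers <- panel$marker
  base <- function(name, weight, spiked = FALSE, ...) {
    mu <- stats::setNames(rep(0.3, length(markers)), markers)
    hi <- c(...)
    mu[names(hi)] <- hi
    list(name = name, mu = mu,
         sd = stats::setNames(rep(0.35, length(markers)), markers),
         weight = weight, spiked = spiked)
  }
  list(
    base("neutrophil", 0.30, CD66 = 3.2, CD16 = 2.0),
    base("mono", 0.10, CD14 = 3.2, CD11c = 3.0, HLADR = 2.5,
         MCP1 = 0.5, MIP1B = 0.5, IL1RA = 0.5),
    base("cd4_tn", 0.13, CD3 = 3.2, CD4 = 3.0, CD45RA = 3.0, CD27 = 3.0,
         PD1 = 0.5),
    base("cd4_tem", 0.09, CD3 = 3.2, CD4 = 3.0, CD27 = 3.0, PD1 = 1.2,
         CXCR5 = 1.0, CD38 = 0.8),
    base("cd8_tn", 0.08, CD3 = 3.2, CD8 = 3.0, CD45RA = 3.0, CD27 = 3.0),
    base("cd8_tem", 0.06, CD3 = 3.2, CD8 = 3.0, CD27 = 3.0, PD1 = 1.2,
         CD38 = 1.5, HLADR = 1.5),
    base("b_naive", 0.08, CD19 = 3.0, IgM = 2.8, IgD = 2.8, CD21 = 2.8,
         CXCR5 = 2.5, HLADR = 2.5),
    base("b_anergic", 0.015, CD19 = 3.0, IgM = 0.4, IgD = 2.8, CD21 = 2.6,
         CXCR5 = 2.4, HLADR = 2.5),
    base("b_switched_mem", 0.035, CD19 = 3.0, CD27 = 2.8, IgM = 0.4,
         IgD = 0.4, CD21 = 2.6, CXCR5 = 2.3, HLADR = 2.5),
    base("nk", 0.08, CD56 = 2.6, CD16 = 3.0),
    base("pb", 0.002, spiked = TRUE, CD19 = 2.2, CD27 = 3.2, CD38 = 4.0,
         CD21 = 0.4, CXCR5 = 0.4, HLADR = 3.0, IFNG = 0.8),
    base("dn2", 0.002, spiked = TRUE, CD19 = 3.0, CD11c = 3.0, CD21 = 0.4,
         CD38 = 1.8, IFNG = 0.8))
}

#' All-zero effect sizes (the null world)
#'
#' @return named list with every cohort effect set to 0; with this, HC and
#'   SLE samples are drawn from an identical generative law.
#' @export
null_effects <- function() {
  list(spike_frac_ln = 0, spike_frac_noln = 0, ifn_shift = 0,
       cytokine_shift_t6 = 0, diffcorr_slope_ln = 0, diffcorr_slope_noln = 0)
}

#' Cohort configuration
#'
#' Describes the synthetic cohort: group sizes (defaults mirror the study:
#' 30 HC, 24 SLE of whom 7 have lupus nephritis), visit structure (3 visits
#' per SLE subject, cross-sectional HC), per-sample cell counts, batch
#' structure with an anchor pseudo-subject replicated per batch, the marker
#' panel and generative populations, and named effect sizes. A single
#' integer seed fully determines all outputs.
#'
#' @param n_hc,n_sle,n_ln group sizes; `n_ln <= n_sle`.
#' @param visits_per_subject visits per SLE subject (HC always have 1).
#' @param cells_per_sample cells per event table.
#' @param batches number of processing batches.
#' @param anchor_per_batch include anchor T0/T6 event tables per batch.
#' @param marker_panel data.frame of markers and roles.
#' @param population_specs list from [default_population_specs()].
#' @param effect_sizes named list; missing entries filled with defaults
#'   `spike_frac_ln = 0.05`, `spike_frac_noln = 0.005`, `ifn_shift = 2`,
#'   `cytokine_shift_t6 = 1.5`, `diffcorr_slope_ln = 0.5`,
#'   `diffcorr_slope_noln = 0`.
#' @param noise_sd residual noise sd of the clinical-score generator.
#' @param subject_intercept_sd sd of subject random intercepts in the
#'   clinical-score generator (0 disables them).
#' @param weight_concentration Dirichlet concentration for subject- and
#'   visit-level mixing-weight variation (larger = less variation).
#' @param batch_sd sd of the per-batch per-marker arcsinh-scale offset.
#' @param cofactor arcsinh cofactor used for the inverse transform.
#' @param cytokine_t6_pops populations whose cytokine channels shift at T6
#'   in SLE subjects.
#' @param seed integer master seed.
#' @return a validated `cohort_config` object.
#' @export
cohort_config <- function(n_hc = 30, n_sle = 24, n_ln = 7,
                          visits_per_subject = 3, cells_per_sample = 1000,
                          batches = 4, anchor_per_batch = TRUE,
                          marker_panel = default_panel(),
                          population_specs =
                            default_population_specs(marker_panel),
                          effect_sizes = list(), noise_sd = 0.3,
                          subject_intercept_sd = 1,
                          weight_concentration = 200, batch_sd = 0.05,
                          cofactor = 5, cytokine_t6_pops = "mono",
                          seed = 1L) {
  defaults <- list(spike_frac_ln = 0.05, spike_frac_noln = 0.005,
                   ifn_shift = 2, cytokine_shift_t6 = 1.5,
                   diffcorr_slope_ln = 0.5, diffcorr_slope_noln = 0)
  effect_sizes <- utils::modifyList(defaults, as.list(effect_sizes))
  if (n_ln > n_sle) stop("n_ln must not exceed n_sle")
  if (cells_per_sample <= 0) stop("cells_per_sample must be positive")
  for (f in c("spike_frac_ln", "spike_frac_noln")) {
    if (effect_sizes[[f]] < 0 || effect_sizes[[f]] > 1) {
      stop(f, " must lie in [0, 1]")
    }
  }
  w <- vapply(population_specs, `[[`, numeric(1), "weight")
  if (any(w < 0) || sum(w) <= 0) stop("population weights not normalizable")
  for (s in population_specs) {
    if (any(s$sd <= 0)) stop("population scales must be positive")
  }
  structure(
    list(n_hc = n_hc, n_sle = n_sle, n_ln = n_ln,
         visits_per_subject = visits_per_subject,
         cells_per_sample = as.integer(cells_per_sample), batches = batches,
         anchor_per_batch = anchor_per_batch, marker_panel = marker_panel,
         population_specs = population_specs, effect_sizes = effect_sizes,
         noise_sd = noise_sd, subject_intercept_sd = subject_intercept_sd,
         weight_concentration = weight_concentration, batch_sd = batch_sd,
         cofactor = cofactor, cytokine_t6_pops = cytokine_t6_pops,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# group-level mixing weights: spiked populations get spike_frac in total
# (split equally) when the group's spike fraction is positive, otherwise the
# baseline weight; remaining mass rescaled over the other populations.
group_mixing_weights <- function(cfg, group3) {
  w <- vapply(cfg$population_specs, `[[`, numeric(1), "weight")
  names(w) <- vapply(cfg$population_specs, `[[`, character(1), "name")
  spiked <- vapply(cfg$population_specs, `[[`, logical(1), "spiked")
  w <- w / sum(w)
  sf <- switch(group3, SLE_LN = cfg$effect_sizes$spike_frac_ln,
               SLE_noLN = cfg$effect_sizes$spike_frac_noln, 0)
  if (sf > 0 && any(spiked)) {
    w[spiked] <- sf / sum(spiked)
    w[!spiked] <- w[!spiked] * (1 - sf) / sum(w[!spiked])
  }
  w / sum(w)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha # degenerate protection
  g / sum(g)
}

# draw one event table worth of cells; returns list(raw, labels)
draw_cells <- function(cfg, weights, shift_cytokines, batch_offset) {
  specs <- cfg$population_specs
  pop_names <- vapply(specs, `[[`, character(1), "name")
  markers <- cfg$marker_panel$marker
  counts <- as.vector(stats::rmultinom(1, cfg$cells_per_sample, weights))
  labels <- rep(pop_names, counts)
  mu_tab <- do.call(rbind, lapply(specs, `[[`, "mu"))[, markers, drop = FALSE]
  sd_tab <- do.call(rbind, lapply(specs, `[[`, "sd"))[, markers, drop = FALSE]
  rownames(mu_tab) <- rownames(sd_tab) <- pop_names
  idx <- match(labels, pop_names)
  n <- length(labels)
  z <- matrix(stats::rnorm(n * length(markers)), n, length(markers),
              dimnames = list(NULL, markers))
  z <- z * sd_tab[idx, , drop = FALSE] + mu_tab[idx, , drop = FALSE]
  if (shift_cytokines != 0) {
    cyt <- cfg$marker_panel$marker[cfg$marker_panel$role == "cytokine"]
    hit <- labels %in% cfg$cytokine_t6_pops
    if (any(hit) && length(cyt)) {
      z[hit, cyt] <- z[hit, cyt] + shift_cytokines
    }
  }
  z <- sweep(z, 2, batch_offset, "+")
  ord <- sample.int(n) # shuffle so cell order carries no population signal
  raw <- pmax(sinh(z[ord, , drop = FALSE]) * cfg$cofactor, 0)
  list(raw = raw, labels = labels[ord])
}

#' Simulate a full synthetic cohort
#'
#' Generates one event table per subject x visit x condition (T0 and T6),
#' plus anchor event tables (a fixed pseudo-subject) per batch, with known
#' per-cell population labels. SLE subjects receive the spiked
#' (plasmablast-like / DN2-like) populations at the configured fractions;
#' cytokine channels of the designated populations are shifted at T6 in SLE
#' subjects; every batch applies a small common arcsinh-scale offset that
#' the anchor samples share. All randomness derives from `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return list with `events` (named list of `event_table`s), `visits`
#'   (SubjectVisitTable data.frame, see [simulate_longitudinal_scores()]),
#'   and `truth` (a `ground_truth` list: per-cell labels per sample, subject
#'   table, sample table, group mixing weights, effects used).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  truth <- withr::with_seed(derive_seed(cfg$seed, 1L), {
    subjects <- data.frame(
      subject_id = c(sprintf("HC%02d", seq_len(cfg$n_hc)),
                     sprintf("SLE%02d", seq_len(cfg$n_sle))),
      group = rep(c("HC", "SLE"), c(cfg$n_hc, cfg$n_sle)),
      ln = c(rep(FALSE, cfg$n_hc),
             seq_len(cfg$n_sle) <= cfg$n_ln),
      stringsAsFactors = FALSE)
    subjects$group3 <- ifelse(subjects$group == "HC", "HC",
                              ifelse(subjects$ln, "SLE_LN", "SLE_noLN"))
    subjects$batch <- sprintf("B%d", (seq_len(nrow(subjects)) - 1L) %%
                                cfg$batches + 1L)
    gw <- sapply(unique(subjects$group3), function(g) {
      group_mixing_weights(cfg, g)
    })
    batch_offsets <- matrix(
      stats::rnorm(cfg$batches * nrow(cfg$marker_panel), 0, cfg$batch_sd),
      cfg$batches, nrow(cfg$marker_panel),
      dimnames = list(sprintf("B%d", seq_len(cfg$batches)),
                      cfg$marker_panel$marker))

    samples <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
      nv <- if (subjects$group[i] == "SLE") cfg$visits_per_subject else 1L
      expand.grid(subject_id = subjects$subject_id[i], visit = seq_len(nv),
                  condition = c("T0", "T6"), stringsAsFactors = FALSE)
    }))
    samples$sample_id <- sprintf("%s_v%d_%s", samples$subject_id,
                                 samples$visit, samples$condition)
    samples <- merge(samples, subjects, by = "subject_id", sort = FALSE)
    samples <- samples[order(samples$subject_id, samples$visit,
                             samples$condition), ]
    rownames(samples) <- NULL

    subject_w <- list()
    visit_w <- list()
    events <- list()
    labels <- list()
    for (i in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[i]
      base_w <- gw[, subjects$group3[i]]
      subject_w[[sid]] <- rdirichlet1(cfg$weight_concentration * base_w)
      names(subject_w[[sid]]) <- names(base_w)
      nv <- if (subjects$group[i] == "SLE") cfg$visits_per_subject else 1L
      for (v in seq_len(nv)) {
        wv <- rdirichlet1(cfg$weight_concentration * subject_w[[sid]])
        names(wv) <- names(base_w)
        visit_w[[sprintf("%s_v%d", sid, v)]] <- wv
        for (cond in c("T0", "T6")) {
          shift <- if (cond == "T6" && subjects$group[i] == "SLE") {
            cfg$effect_sizes$cytokine_shift_t6
          } else 0
          cells <- draw_cells(cfg, wv, shift,
                              batch_offsets[subjects$batch[i], ])
          id <- sprintf("%s_v%d_%s", sid, v, cond)
          events[[id]] <- event_table(
            cells$raw, markers = cfg$marker_panel$marker, sample_id = id,
            subject_id = sid, visit_id = v, condition = cond,
            batch_id = subjects$batch[i], is_anchor = FALSE)
          labels[[id]] <- cells$labels
        }
      }
    }
    if (isTRUE(cfg$anchor_per_batch)) {
      anchor_w <- gw[, "HC"]
      for (b in seq_len(cfg$batches)) {
        for (cond in c("T0", "T6")) {
          cells <- draw_cells(cfg, anchor_w, 0, batch_offsets[b, ])
          id <- sprintf("ANCHOR_B%d_%s", b, cond)
          events[[id]] <- event_table(
            cells$raw, markers = cfg$marker_panel$marker, sample_id = id,
            subject_id = "ANCHOR", visit_id = 1L, condition = cond,
            batch_id = sprintf("B%d", b), is_anchor = TRUE)
          labels[[id]] <- cells$labels
        }
      }
    }
    structure(
      list(subjects = subjects, samples = samples, labels = labels,
           subject_weights = subject_w, visit_weights = visit_w,
           group_weights = gw, effects = cfg$effect_sizes,
           events = events),
      class = "ground_truth")
  })
  events <- truth$events
  truth$events <- NULL
  visits <- simulate_longitudinal_scores(cfg, truth)
  list(events = events, visits = visits, truth = truth)
}

#' Realized spiked-cell fraction per sample
#'
#' Fraction of cells in each sample whose ground-truth label is a spiked
#' population.
#'
#' @param truth a `ground_truth` object.
#' @param cfg the matching [cohort_config()].
#' @return named numeric vector over samples.
#' @export
spiked_fraction <- function(truth, cfg) {
  spiked <- vapply(cfg$population_specs, `[[`, logical(1), "spiked")
  spiked_names <- vapply(cfg$population_specs, `[[`,
                         character(1), "name")[spiked]
  vapply(truth$labels, function(l) mean(l %in% spiked_names), numeric(1))
}

#' Simulate longitudinal clinical scores
#'
#' Per-visit SLEDAI-2K and complement C3 are linear functions of each
#' subject-visit's realized spiked-cell percentage, with LN-status-specific
#' slopes (`diffcorr_slope_ln` / `diffcorr_slope_noln` for SLEDAI; -5 times
#' those for C3), a subject random intercept and Gaussian noise. With
#' `noise_sd = 0` and `subject_intercept_sd = 0` the scores are exact linear
#' functions of the frequency. Other clinical fields (prednisone, UPCR,
#' eGFR, urine sediment, activity flags) follow simple improving
#' trajectories so the clinical rule classifiers have realistic inputs.
#'
#' @param cfg a [cohort_config()].
#' @param truth the `ground_truth` from [simulate_cohort()] (same cfg/seed).
#' @return SubjectVisitTable data.frame keyed by subject x visit.
#' @export
simulate_longitudinal_scores <- function(cfg, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    subjects <- truth$subjects
    sv <- unique(truth$samples[truth$samples$condition == "T0" &
                                 !grepl("^ANCHOR", truth$samples$subject_id),
                               c("subject_id", "visit", "group", "ln",
                                 "group3")])
    sv <- sv[order(sv$subject_id, sv$visit), ]
    rownames(sv) <- NULL
    sv$week <- (sv$visit - 1L) * 12
    x <- 100 * spiked_fraction(truth, cfg)[
      sprintf("%s_v%d_T0", sv$subject_id, sv$visit)]
    sv$spiked_pct <- unname(x)
    u <- stats::rnorm(nrow(subjects), 0, cfg$subject_intercept_sd)
    names(u) <- subjects$subject_id
    slope <- ifelse(sv$group == "HC", 0,
                    ifelse(sv$ln, cfg$effect_sizes$diffcorr_slope_ln,
                           cfg$effect_sizes$diffcorr_slope_noln))
    base_sledai <- ifelse(sv$group == "HC", 0, 8)
    sv$sledai <- pmax(0, base_sledai + u[sv$subject_id] + slope * x +
                        stats::rnorm(nrow(sv), 0, cfg$noise_sd))
    sv$c3 <- 110 - 5 * slope * x + u[sv$subject_id] * 2 +
      stats::rnorm(nrow(sv), 0, 5 * max(cfg$noise_sd, 0))
    sle <- sv$group == "SLE"
    sv$prednisone <- ifelse(sle, pmax(0, 30 - 10 * (sv$visit - 1L)), 0)
    sv$upcr <- ifelse(sv$ln, pmax(0.05, 3 * 0.5^(sv$visit - 1L) *
                                    exp(stats::rnorm(nrow(sv), 0, 0.2))),
                      ifelse(sle, 0.15, 0.05))
    sv$egfr <- pmax(30, 110 + stats::rnorm(nrow(sv), 0, 8))
    sv$urine_wbc <- ifelse(sv$ln, pmax(0, round(20 * 0.5^(sv$visit - 1L))), 1)
    sv$urine_rbc <- ifelse(sv$ln, pmax(0, round(15 * 0.5^(sv$visit - 1L))), 1)
    sv$casts <- sv$ln & sv$visit == 1L
    sv$new_activity <- FALSE
    sv$stable_maintenance <- TRUE
    sv
  })
}

#' Simulate the targeted gene-expression table
#'
#' Positive capillary-electrophoresis-like heights for 51 response genes and
#' 3 housekeeping genes (ACTB, GAPDH, TFRC) per subject. Interferon-module
#' genes are multiplied by `2^ifn_shift` in SLE subjects; housekeeping
#' heights are group-independent. The IFN-1 genes sit 2.5 log2 units below
#' the housekeeping mean in healthy subjects, so the healthy IFN-1 score is
#' centred at -2.5 (consistent with a high/low cutoff of -0.5 at two healthy
#' standard deviations above the mean).
#'
#' @param cfg a [cohort_config()].
#' @param modules module definitions (see [default_module_defs()]).
#' @return an `expression_table` (see [expression_table()]).
#' @export
simulate_expression <- function(cfg, modules = default_module_defs()) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(derive_seed(cfg$seed, 3L), {
    subjects <- data.frame(
      subject_id = c(sprintf("HC%02d", seq_len(cfg$n_hc)),
                     sprintf("SLE%02d", seq_len(cfg$n_sle))),
      group = rep(c("HC", "SLE"), c(cfg$n_hc, cfg$n_sle)),
      stringsAsFactors = FALSE)
    hk <- c("ACTB", "GAPDH", "TFRC")
    response <- unique(unlist(lapply(modules, `[[`, "genes")))
    ifn_genes <- unique(unlist(lapply(
      Filter(function(m) isTRUE(m$is_ifn), modules), `[[`, "genes")))
    offsets <- stats::setNames(rep(0, length(response)), response)
    offsets[intersect(names(offsets),
                      modules[["IFN_1"]]$genes)] <- -2.5
    n <- nrow(subjects)
    log2h_hk <- matrix(stats::rnorm(n * 3, 12, 0.2), n, 3,
                       dimnames = list(subjects$subject_id, hk))
    log2h_resp <- matrix(stats::rnorm(n * length(response), 0, 1), n,
                         length(response),
                         dimnames = list(subjects$subject_id, response))
    log2h_resp <- sweep(log2h_resp, 2, 12 + offsets, "+")
    is_sle <- subjects$group == "SLE"
    shift_cols <- colnames(log2h_resp) %in% ifn_genes
    log2h_resp[is_sle, shift_cols] <- log2h_resp[is_sle, shift_cols] +
      cfg$effect_sizes$ifn_shift
    heights <- 2^cbind(log2h_resp, log2h_hk)
    roles <- stats::setNames(c(rep("response", length(response)),
                               rep("housekeeping", 3)),
                             c(response, hk))
    expression_table(heights, roles, subjects)
  })
}
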