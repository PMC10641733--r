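# Independent oracles used against the package implementations. These stay
# deliberately naive (enumeration, double loops, finite differences) so they
# share no code path with the functions they check.

# exact two-sided Mann-Whitney p by exhaustive enumeration of labelings
mwu_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# biased HSIC by explicit double loop over the centered kernel
hsic_brute <- function(K, L) {
  n <- nrow(K)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      kc <- K[i, j] - mean(K[i, ]) - mean(K[, j]) + mean(K)
      s <- s + kc * L[i, j]
    }
  }
  s / n^2
}

# central finite-difference gradient of the bag cross-entropy loss w.r.t.
# one flat parameter vector
numeric_bag_grad <- function(model, x, y_onehot, par_name, eps = 1e-5) {
  f <- function(p) {
    m <- model
    m[[par_name]][] <- p
    pr <- forward(m, x)
    -log(pr[which.max(y_onehot)])
  }
  p0 <- as.vector(model[[par_name]])
  g <- numeric(length(p0))
  for (i in seq_along(p0)) {
    up <- p0; up[i] <- up[i] + eps
    dn <- p0; dn[i] <- dn[i] - eps
    g[i] <- (f(up) - f(dn)) / (2 * eps)
  }
  array(g, dim = dim(model[[par_name]]) %||% length(p0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small transformed event table from a raw matrix
make_events <- function(raw, markers = colnames(raw), ...) {
  arcsinh_transform(event_table(as.matrix(raw), markers = markers, ...))
}

# compact synthetic cohort used by several suites (memoised per session)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_hc = 8, n_sle = 8, n_ln = 4,
                           visits_per_subject = 2, cells_per_sample = 500,
                           batches = 2, seed = 42)
      sim <- simulate_cohort(cfg)
      sim$events <- lapply(sim$events, arcsinh_transform)
      hc_t0 <- Filter(function(e) {
        grepl("^HC", e$subject_id) && e$condition == "T0" && !e$is_anchor
      }, sim$events)
      thresholds <- estimate_gate_thresholds(hc_t0)
      tree <- default_gating_tree()
      gated <- gate_cohort(sim$events, tree, thresholds)
      cache <<- list(cfg = cfg, sim = sim, tree = tree,
                     thresholds = thresholds, gated = gated)
    }
    cache
  }
})
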