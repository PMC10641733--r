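#' Build multi-cell bags from gated samples
#'
#' Draws fixed-size multi-cell inputs ("bags") uniformly with replacement
#' from each sample's pre-gated parent population (e.g. CD19+ B cells);
#' every bag inherits its sample's class label. Sampling with replacement
#' also fills bags from samples smaller than the bag size.
#'
#' @param events list of transformed `event_table`s.
#' @param labels class label per sample (same order/names as `events`).
#' @param pregate optional list of logical masks selecting the parent
#'   population per sample (NULL = all cells).
#' @param bag_size cells per bag (default 200).
#' @param n_bags_per_sample bags drawn per sample (default 100).
#' @param seed integer seed; the bag set is seed-deterministic.
#' @return a `bag_set`: list with `bags` (each `list(x, label, sample_id,
#'   cell_idx)`), `bag_size`, `markers`, `classes`.
#' @export
make_bags <- function(events, labels, pregate = NULL, bag_size = 200,
                      n_bags_per_sample = 100, seed = 1L) {
  stopifnot(length(labels) == length(events))
  markers <- events[[1]]$markers
  classes <- sort(unique(as.character(labels)))
  bags <- withr::with_seed(seed, {
    out <- list()
    for (i in seq_along(events)) {
      e <- events[[i]]
      if (is.null(e$transformed)) stop("events must be arcsinh transformed")
      idx_pool <- if (is.null(pregate)) seq_len(nrow(e$transformed)) else
        which(pregate[[i]])
      if (length(idx_pool) == 0) stop("empty sample: ", e$sample_id)
      for (b in seq_len(n_bags_per_sample)) {
        ci <- sample(idx_pool, bag_size, replace = TRUE)
        out[[length(out) + 1L]] <- list(
          x = e$transformed[ci, , drop = FALSE],
          label = as.character(labels[[i]]), sample_id = e$sample_id,
          cell_idx = ci)
      }
    }
    out
  })
  structure(list(bags = bags, bag_size = bag_size, markers = markers,
                 classes = classes),
            class = "bag_set")
}

new_signature_model <- function(n_filters, markers, classes, k_frac,
                                learning_rate, dropout) {
  m <- length(markers)
  structure(
    list(W = matrix(stats::runif(n_filters * m, -0.05, 0.05), n_filters, m,
                    dimnames = list(NULL, markers)),
         b = rep(0, n_filters),
         V = matrix(stats::runif(2 * n_filters, -0.05, 0.05), 2, n_filters),
         c = rep(0, 2),
         n_filters = n_filters, k_frac = k_frac,
         learning_rate = learning_rate, dropout = dropout,
         markers = markers, classes = classes, trained = FALSE),
    class = "signature_model")
}

# forward pass for one bag; returns cache for backprop
forward_bag <- function(model, x, dropout_mask = NULL) {
  Z <- x %*% t(model$W) + matrix(model$b, nrow(x), length(model$b),
                                 byrow = TRUE)
  R <- relu(Z)
  k <- max(1L, ceiling(model$k_frac * nrow(x)))
  topk <- lapply(seq_len(ncol(R)), function(f) {
    order(R[, f], decreasing = TRUE)[seq_len(k)]
  })
  pooled <- vapply(seq_len(ncol(R)), function(f) mean(R[topk[[f]], f]),
                   numeric(1))
  pooled_d <- if (is.null(dropout_mask)) pooled else pooled * dropout_mask
  logits <- drop(model$V %*% pooled_d + model$c)
  list(probs = softmax(logits), Z = Z, R = R, topk = topk, k = k,
       pooled = pooled, pooled_d = pooled_d)
}

#' Class probabilities for one bag
#'
#' Per cell and filter, response = relu(w . x + b); the pooled response per
#' filter is the mean of the top ceiling(k% x bag size) cell responses; the
#' output layer applies a weighted sum and softmax.
#'
#' @param model a `signature_model`.
#' @param bag cells x markers numeric matrix on the arcsinh scale.
#' @return named probability vector over classes (sums to 1).
#' @export
forward <- function(model, bag) {
  bag <- as.matrix(bag)
  if (ncol(bag) != ncol(model$W)) stop("bag marker dimension mismatch")
  stats::setNames(forward_bag(model, bag)$probs, model$classes)
}

# analytic gradient of the categorical cross-entropy for one bag
bag_gradient <- function(model, x, y_onehot, dropout_mask = NULL) {
  fw <- forward_bag(model, x, dropout_mask)
  dlogits <- fw$probs - y_onehot
  dV <- outer(dlogits, fw$pooled_d)
  dc <- dlogits
  dpooled <- drop(t(model$V) %*% dlogits)
  if (!is.null(dropout_mask)) dpooled <- dpooled * dropout_mask
  h <- ncol(fw$R)
  dZ <- matrix(0, nrow(x), h)
  for (f in seq_len(h)) {
    idx <- fw$topk[[f]]
    dZ[idx, f] <- (dpooled[f] / fw$k) * (fw$Z[idx, f] > 0)
  }
  list(dW = t(dZ) %*% x, db = colSums(dZ), dV = dV, dc = dc,
       loss = -log(max(fw$probs[which.max(y_onehot)], 1e-12)))
}

bag_loss <- function(model, bags, classes) {
  mean(vapply(bags, function(bg) {
    p <- forward_bag(model, bg$x)$probs
    -log(max(p[match(bg$label, classes)], 1e-12))
  }, numeric(1)))
}

adam_init <- function(par) lapply(par, function(p) list(m = p * 0, v = p * 0))

adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(par)) {
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * grad[[nm]]
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * grad[[nm]]^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

train_one <- function(model, train_bags, val_bags, classes, epochs,
                      batch_bags, patience) {
  par <- model[c("W", "b", "V", "c")]
  state <- adam_init(par)
  t <- 0
  best <- list(loss = Inf, par = par)
  stall <- 0
  log <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(train_bags))
    for (start in seq(1, length(ord), by = batch_bags)) {
      idx <- ord[start:min(start + batch_bags - 1, length(ord))]
      grad <- NULL
      for (i in idx) {
        bg <- train_bags[[i]]
        y <- as.numeric(classes == bg$label)
        dm <- if (model$dropout > 0) {
          stats::rbinom(model$n_filters, 1, 1 - model$dropout) /
            (1 - model$dropout)
        } else NULL
        mtmp <- model; mtmp[c("W", "b", "V", "c")] <- par
        g <- bag_gradient(mtmp, bg$x, y, dm)
        grad <- if (is.null(grad)) g[c("dW", "db", "dV", "dc")] else
          Map(`+`, grad, g[c("dW", "db", "dV", "dc")])
      }
      grad <- lapply(grad, `/`, length(idx))
      names(grad) <- c("W", "b", "V", "c")
      t <- t + 1
      st <- adam_step(par, grad, state, model$learning_rate, t)
      par <- st$par; state <- st$state
    }
    mtmp <- model; mtmp[c("W", "b", "V", "c")] <- par
    vl <- bag_loss(mtmp, val_bags, classes)
    log <- c(log, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, par = par)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
  }
  model[c("W", "b", "V", "c")] <- best$par
  model$val_loss <- best$loss
  model$val_log <- log
  model
}

#' Train the multiple-instance signature model
#'
#' Random search over the hyperparameters (number of filters 3-10, top-k
#' fraction from \{0.1, 1, 5, 20, 100\}%, learning rate, dropout), each
#' candidate evaluated by 5-fold cross-validation with folds split at the
#' source-sample level to prevent leakage of cells between folds. Filters
#' and output weights are initialized from U\[-0.05, 0.05\] and trained by
#' mini-batch Adam on the categorical cross-entropy with early stopping on
#' validation loss. The trained (candidate, fold) model with the lowest
#' validation loss is returned. The whole procedure is seed-deterministic.
#'
#' @param bags a `bag_set` from [make_bags()].
#' @param search_iters random-search candidates (default 5).
#' @param seed integer seed.
#' @param epochs maximum epochs per fit.
#' @param batch_bags bags per Adam mini-batch.
#' @param n_folds cross-validation folds (default 5).
#' @param patience early-stopping patience in epochs.
#' @param k_grid candidate top-k fractions.
#' @param n_filter_range candidate filter counts.
#' @param dropout_choices candidate dropout rates.
#' @return a trained `signature_model` with `$val_loss`, `$search_log`.
#' @export
train <- function(bags, search_iters = 5, seed = 1L, epochs = 20,
                  batch_bags = 16, n_folds = 5, patience = 5,
                  k_grid = c(0.001, 0.01, 0.05, 0.20, 1.00),
                  n_filter_range = 3:10,
                  dropout_choices = c(0, 0.25, 0.5)) {
  stopifnot(inherits(bags, "bag_set"))
  classes <- bags$classes
  if (length(classes) < 2) stop("need at least 2 classes")
  sample_ids <- unique(vapply(bags$bags, `[[`, character(1), "sample_id"))
  if (length(sample_ids) < n_folds) {
    stop("need at least ", n_folds, " samples for ", n_folds,
         "-fold splitting")
  }
  withr::with_seed(seed, {
    # sample-level folds, stratified by the sample's class
    sample_class <- vapply(sample_ids, function(s) {
      bags$bags[[match(s, vapply(bags$bags, `[[`, character(1),
                                 "sample_id"))]]$label
    }, character(1))
    fold_of <- stats::setNames(integer(length(sample_ids)), sample_ids)
    for (cl in classes) {
      ids <- sample(sample_ids[sample_class == cl])
      fold_of[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
    bag_fold <- fold_of[vapply(bags$bags, `[[`, character(1), "sample_id")]

    best <- NULL
    search_log <- list()
    for (it in seq_len(search_iters)) {
      hyper <- list(
        n_filters = sample(n_filter_range, 1),
        k_frac = sample(k_grid, 1),
        learning_rate = 10^stats::runif(1, -3, -1.7),
        dropout = sample(dropout_choices, 1))
      fold_losses <- rep(NA_real_, n_folds)
      for (fd in seq_len(n_folds)) {
        train_bags <- bags$bags[bag_fold != fd]
        val_bags <- bags$bags[bag_fold == fd]
        # a fold can be empty when a class has fewer samples than folds
        if (length(val_bags) == 0 || length(train_bags) == 0) next
        model <- new_signature_model(hyper$n_filters, bags$markers, classes,
                                     hyper$k_frac, hyper$learning_rate,
                                     hyper$dropout)
        fit <- train_one(model, train_bags, val_bags, classes, epochs,
                         batch_bags, patience)
        fold_losses[fd] <- fit$val_loss
        if (is.null(best) || fit$val_loss < best$val_loss) best <- fit
      }
      if (all(is.na(fold_losses))) stop("degenerate folds: no usable split")
      search_log[[it]] <- c(hyper,
                            list(mean_val_loss = mean(fold_losses,
                                                      na.rm = TRUE)))
    }
    best$trained <- TRUE
    best$search_log <- search_log
    best$seed <- seed
    best
  })
}

#' Serialize / read a signature model as JSON
#'
#' Weights, biases, hyperparameters, classes and the search log are stored
#' as plain JSON arrays; numeric precision is preserved (`digits = NA`).
#'
#' @param model a `signature_model`.
#' @param path file path.
#' @return `read_signature_model` returns the model; the writer its path.
#' @export
write_signature_model <- function(model, path) {
  obj <- unclass(model)
  obj$W <- list(dim = dim(model$W), data = as.vector(model$W),
                markers = colnames(model$W))
  obj$V <- list(dim = dim(model$V), data = as.vector(model$V))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W <- matrix(obj$W$data, obj$W$dim[1], obj$W$dim[2],
                  dimnames = list(NULL, obj$W$markers))
  obj$V <- matrix(obj$V$data, obj$V$dim[1], obj$V$dim[2])
  structure(obj, class = "signature_model")
}

#' Per-cell signature (CellCnn-style) scores
#'
#' Response of the disease-associated filter(s) for every cell of a sample,
#' computed on the full sample independently of bag membership. The
#' disease-associated filters are those whose output weight favours the
#' positive class; `mode = "max"` (default) takes the maximum response
#' across them, `mode = "best"` uses only the single strongest filter.
#'
#' @param model trained `signature_model`.
#' @param events a transformed `event_table`, or a cells x markers matrix
#'   on the arcsinh scale.
#' @param positive_class class treated as disease (default: last class).
#' @param mode "max" or "best".
#' @return numeric vector of nonnegative per-cell scores.
#' @export
score_cells <- function(model, events, positive_class = NULL,
                        mode = c("max", "best")) {
  mode <- match.arg(mode)
  if (!isTRUE(model$trained)) stop("model is not trained")
  x <- if (inherits(events, "event_table")) {
    if (is.null(events$transformed)) stop("events must be arcsinh transformed")
    events$transformed
  } else as.matrix(events)
  positive_class <- positive_class %||% model$classes[length(model$classes)]
  pos <- match(positive_class, model$classes)
  if (is.na(pos)) stop("unknown positive class: ", positive_class)
  w_pos <- model$V[pos, ] - model$V[-pos, , drop = FALSE][1, ]
  filters <- if (mode == "best" || !any(w_pos > 0)) which.max(w_pos) else
    which(w_pos > 0)
  R <- relu(x %*% t(model$W[filters, , drop = FALSE]) +
              matrix(model$b[filters], nrow(x), length(filters),
                     byrow = TRUE))
  apply(R, 1, max)
}

#' Select high-scoring cells by pooled percentile
#'
#' The selection threshold is the stated percentile (default 85) of the
#' scores pooled over all samples; cells strictly above it are selected.
#' Per-sample selected frequency is reported as a percentage of each
#' sample's parent-population cell count.
#'
#' @param scores list of per-sample numeric score vectors (or one vector).
#' @param percentile pooled percentile in (0, 100).
#' @param per_sample if TRUE, thresholds are computed within each sample
#'   instead of pooled.
#' @return list with `threshold` (pooled, or per-sample vector), `masks`
#'   (list of logical vectors), `frequency` (% selected per sample).
#' @export
select_cells <- function(scores, percentile = 85, per_sample = FALSE) {
  if (!is.list(scores)) scores <- list(scores)
  pooled <- unlist(scores, use.names = FALSE)
  if (!all(is.finite(pooled))) stop("scores must be finite")
  if (length(unique(pooled)) == 1L) {
    warning("all scores identical; nothing selected under strict inequality")
  }
  if (per_sample) {
    thr <- vapply(scores, function(s) {
      stats::quantile(s, percentile / 100, names = FALSE, type = 7)
    }, numeric(1))
    masks <- Map(function(s, t) s > t, scores, thr)
  } else {
    thr <- stats::quantile(pooled, percentile / 100, names = FALSE, type = 7)
    masks <- lapply(scores, function(s) s > thr)
  }
  freq <- vapply(masks, function(m) 100 * mean(m), numeric(1))
  names(freq) <- names(scores)
  list(threshold = thr, masks = masks, frequency = freq)
}

#' Marker-wise KS characterization of selected cells
#'
#' Two-sample Kolmogorov-Smirnov distance per marker between the selected
#' cells and the whole cell population they came from.
#'
#' @param events transformed `event_table` or cells x markers matrix.
#' @param mask logical selection mask (nonempty, not full).
#' @return named numeric vector of KS distances in \[0, 1\].
#' @export
ks_characterize <- function(events, mask) {
  x <- if (inherits(events, "event_table")) events$transformed else
    as.matrix(events)
  if (!any(mask)) stop("empty selection")
  if (all(mask)) stop("selection covers every cell")
  vapply(colnames(x), function(m) ks_stat(x[mask, m], x[, m]), numeric(1))
}

#' Map selected cells onto gated populations
#'
#' For each gated population, the fraction of the selected set Sc whose
#' events also fall in the gate (So), i.e. |So| / |Sc|, sharing the stable
#' event index space of the source sample.
#'
#' @param sc_mask logical selection mask over a sample's cells.
#' @param pop_masks logical cells x populations matrix from
#'   [apply_gating()].
#' @param populations populations to report (default: all columns).
#' @return named numeric vector of overlap fractions in \[0, 1\].
#' @export
map_selection_to_gates <- function(sc_mask, pop_masks,
                                   populations = colnames(pop_masks)) {
  if (!any(sc_mask)) stop("empty selection Sc")
  stopifnot(length(sc_mask) == nrow(pop_masks))
  vapply(populations, function(p) {
    sum(sc_mask & pop_masks[, p]) / sum(sc_mask)
  }, numeric(1))
}
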