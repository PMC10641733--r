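# tiny separable two-class world shared by the training tests
toy_world <- function(n_samples = 10, n_cells = 300, spike = 15,
                      seed = 21) {
  withr::with_seed(seed, {
    evs <- list(); labs <- character(0)
    for (i in seq_len(n_samples)) {
      raw <- pmax(sinh(matrix(rnorm(n_cells * 3, 0.3, 0.35), n_cells, 3,
                              dimnames = list(NULL, c("m1", "m2", "m3")))) *
                    5, 0)
      e <- make_events(raw, sample_id = paste0("S", i),
                       subject_id = paste0("S", i))
      lab <- if (i <= n_samples / 2) "A" else "B"
      if (lab == "B") {
        e$transformed[seq_len(spike), ] <-
          e$transformed[seq_len(spike), ] + 2.5
      }
      evs[[i]] <- e; labs <- c(labs, lab)
    }
    list(events = evs, labels = labs)
  })
}

test_that("bags have the declared shape, labels and determinism", {
  w <- toy_world(4, n_cells = 50)
  b1 <- make_bags(w$events, w$labels, bag_size = 30, n_bags_per_sample = 3,
                  seed = 5)
  expect_length(b1$bags, 12)
  for (bg in b1$bags) {
    expect_equal(dim(bg$x), c(30L, 3L))
    expect_true(all(bg$cell_idx >= 1 & bg$cell_idx <= 50))
  }
  expect_identical(
    b1$bags[[1]]$x,
    make_bags(w$events, w$labels, bag_size = 30, n_bags_per_sample = 3,
              seed = 5)$bags[[1]]$x)
  # sample smaller than the bag: replacement fills it
  small <- list(make_events(matrix(1:6, 2, 3,
                                   dimnames = list(NULL,
                                                   c("m1", "m2", "m3"))),
                            sample_id = "tiny"))
  b2 <- make_bags(small, "A", bag_size = 10, n_bags_per_sample = 1, seed = 1)
  expect_equal(nrow(b2$bags[[1]]$x), 10L)
})

test_that("forward pass matches its closed forms", {
  m <- cytoimmune:::new_signature_model(1, c("m1", "m2", "m3"),
                                        c("A", "B"), 1.0, 0.01, 0)
  m$W[] <- c(1, 0, 0); m$b[] <- 0
  bag <- matrix(c(-1, 2, 5, 0, 0, 0, 0, 0, 0), 3, 3,
                dimnames = list(NULL, c("m1", "m2", "m3")))
  fw <- cytoimmune:::forward_bag(m, bag)
  expect_equal(fw$pooled, mean(pmax(bag[, 1], 0))) # mean relu over marker 1

  # top-1 pooling picks the maximum response
  m$k_frac <- 1e-9
  expect_equal(cytoimmune:::forward_bag(m, bag)$pooled, 5)

  # zero output weights give uniform class probabilities
  m$V[] <- 0; m$c[] <- 0
  expect_equal(unname(forward(m, bag)), c(0.5, 0.5))
  expect_error(forward(m, bag[, 1:2]), "dimension")
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(22, {
    m <- cytoimmune:::new_signature_model(3, paste0("m", 1:4),
                                          c("A", "B"), 0.3, 0.01, 0)
    m$W[] <- rnorm(12, 0, 0.5); m$b[] <- rnorm(3, 0, 0.1)
    m$V[] <- rnorm(6, 0, 0.5); m$c[] <- rnorm(2, 0, 0.1)
    x <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("m", 1:4)))
  })
  y <- c(0, 1)
  g <- cytoimmune:::bag_gradient(m, x, y)
  for (nm in c("W", "b", "V", "c")) {
    num <- numeric_bag_grad(m, x, y, nm)
    den <- pmax(abs(num), 1e-4)
    expect_lt(max(abs(g[[paste0("d", nm)]] - num) / den), 1e-4)
  }
})

test_that("training solves a separable problem and is deterministic", {
  w <- toy_world()
  bags <- make_bags(w$events, w$labels, bag_size = 100,
                    n_bags_per_sample = 10, seed = 2)
  m <- train(bags, search_iters = 2, seed = 3, epochs = 10)
  acc <- mean(vapply(bags$bags, function(b) {
    names(which.max(forward(m, b$x))) == b$label
  }, logical(1)))
  expect_equal(acc, 1)
  m2 <- train(bags, search_iters = 2, seed = 3, epochs = 10)
  expect_identical(m$W, m2$W)
  expect_identical(m$val_loss, m2$val_loss)
  expect_error(train(make_bags(w$events[1:4], rep("A", 4), bag_size = 50,
                               n_bags_per_sample = 2, seed = 1)),
               "2 classes")
})

test_that("permuted labels stay near chance-level validation loss", {
  w <- toy_world()
  perm <- withr::with_seed(30, sample(w$labels))
  bags <- make_bags(w$events, perm, bag_size = 100, n_bags_per_sample = 10,
                    seed = 4)
  m <- train(bags, search_iters = 2, seed = 5, epochs = 10)
  mean_losses <- vapply(m$search_log, `[[`, numeric(1), "mean_val_loss")
  expect_gt(min(mean_losses), log(2) - 0.15)
})

test_that("cell scores follow the relu closed form and ignore bags", {
  m <- cytoimmune:::new_signature_model(2, c("m1", "m2"), c("A", "B"),
                                        0.5, 0.01, 0)
  m$trained <- TRUE
  m$W[] <- rbind(c(1, 0), c(0, 1)); m$b[] <- c(0, -1)
  m$V[] <- rbind(c(0, 1), c(2, 0)) # filter 1 favours B, filter 2 favours A
  x <- matrix(c(2, -1, 0.5, 3), 2, 2, dimnames = list(NULL, c("m1", "m2")))
  s <- score_cells(m, x, positive_class = "B")
  # disease filter = filter 1 (w . x + b = m1): relu(2) and relu(-1)
  expect_equal(unname(s), c(2, 0))
  # "best" mode picks the same single filter here
  expect_equal(score_cells(m, x, positive_class = "B", mode = "best"), s)
  expect_error(score_cells(cytoimmune:::new_signature_model(
    2, c("m1", "m2"), c("A", "B"), 0.5, 0.01, 0), x), "not trained")
})

test_that("selection thresholds and tie conventions are honoured", {
  s <- withr::with_seed(23, list(sample(1:60), sample(61:100)))
  sel <- select_cells(s, percentile = 85)
  expect_equal(sum(unlist(sel$masks)), 15L) # 100 distinct scores -> 15
  expect_true(all(unlist(s)[unlist(sel$masks)] > sel$threshold))
  expect_warning(sel0 <- select_cells(list(rep(1, 50)), 85), "identical")
  expect_equal(sum(unlist(sel0$masks)), 0L)
  # per-sample option thresholds within each sample
  selp <- select_cells(s, percentile = 90, per_sample = TRUE)
  expect_equal(vapply(selp$masks, sum, integer(1)), c(6L, 4L))
})

test_that("KS characterization matches hand-computed ECDFs", {
  x <- matrix(c(1, 1, 1, 5, 5, 5), 6, 1, dimnames = list(NULL, "m1"))
  ks <- ks_characterize(x, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(ks["m1"]), 0.5)
  # identical selected distribution: KS 0
  ks0 <- ks_characterize(matrix(rep(2, 6), 6, 1,
                                dimnames = list(NULL, "m1")),
                         c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(ks0["m1"]), 0)
  withr::with_seed(24, {
    xx <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  })
  kk <- ks_characterize(xx, c(rep(TRUE, 30), rep(FALSE, 70)))
  expect_true(all(kk >= 0 & kk <= 1))
  expect_error(ks_characterize(xx, rep(FALSE, 100)), "empty")
  expect_error(ks_characterize(xx, rep(TRUE, 100)), "every cell")
})

test_that("signature models survive the JSON round trip", {
  w <- toy_world(4, n_cells = 60)
  bags <- make_bags(w$events, w$labels, bag_size = 30,
                    n_bags_per_sample = 4, seed = 6)
  m <- train(bags, search_iters = 1, seed = 7, epochs = 3, n_folds = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_model(m, path)
  m2 <- read_signature_model(path)
  expect_equal(m2$W, m$W)
  expect_equal(m2$V, m$V)
  x <- w$events[[1]]$transformed
  expect_equal(score_cells(m2, x, positive_class = "B"),
               score_cells(m, x, positive_class = "B"))
})

test_that("gate mapping fractions behave as set ratios", {
  pop <- cbind(PB = c(TRUE, TRUE, FALSE, FALSE),
               DN2 = c(FALSE, FALSE, TRUE, FALSE))
  sc <- c(TRUE, TRUE, FALSE, FALSE)
  fr <- map_selection_to_gates(sc, pop)
  expect_equal(unname(fr), c(1, 0)) # Sc equals the PB gate
  sc2 <- c(TRUE, TRUE, TRUE, TRUE)
  fr2 <- map_selection_to_gates(sc2, pop)
  expect_lte(sum(fr2), 1) # exclusive gates
  expect_error(map_selection_to_gates(rep(FALSE, 4), pop), "empty")
})
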