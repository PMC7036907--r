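test_that("focal loss matches direct evaluation of the piecewise form", {
  expect_equal(focal_loss(1, 0.5, gamma = 0, alpha = 0.5), 0.5 * log(2),
               tolerance = 1e-12)
  expect_equal(focal_loss(1, 1 - 1e-9), 0, tolerance = 1e-6)
  expect_equal(focal_loss(1, 0.9, gamma = 2, alpha = 0.5),
               0.5 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_equal(focal_loss(0, 0.9, gamma = 2, alpha = 0.5),
               0.5 * 0.9^2 * (-log(0.1)), tolerance = 1e-12)
  expect_error(focal_loss(2, 0.5), "binary")
})

test_that("focal loss with gamma 0 halves the cross entropy everywhere", {
  p <- seq(0.01, 0.99, length.out = 50)
  grid <- expand.grid(y = c(0, 1), p = p)
  fl <- focal_loss(grid$y, grid$p, gamma = 0, alpha = 0.5)
  bce <- ifelse(grid$y == 1, -log(grid$p), -log(1 - grid$p))
  expect_equal(fl, 0.5 * bce, tolerance = 1e-10)
})

test_that("focal loss is monotone in the prediction and in gamma", {
  p <- seq(0.02, 0.98, length.out = 40)
  lp <- focal_loss(rep(1, 40), p)
  expect_true(all(diff(lp) < 0))          # decreasing for positives
  ln <- focal_loss(rep(0, 40), p)
  expect_true(all(diff(ln) > 0))          # increasing for negatives
  for (ph in c(0.2, 0.6, 0.9)) {
    lg <- sapply(c(0, 0.5, 1, 2, 5), function(g) focal_loss(1, ph, gamma = g))
    expect_true(all(diff(lg) <= 1e-15))   # non-increasing in gamma
  }
})

test_that("batch loss is the mean over all cells", {
  y <- matrix(c(1, 0, 1, 0), 2)
  p <- matrix(c(0.8, 0.3, 0.6, 0.1), 2)
  expect_equal(batch_loss(y[1, 1, drop = FALSE], p[1, 1, drop = FALSE]),
               focal_loss(1, 0.8))
  hand <- mean(mapply(focal_loss, as.vector(y), as.vector(p)))
  expect_equal(batch_loss(y, p), hand, tolerance = 1e-12)
  expect_lt(batch_loss(y, abs(y - 1e-6)), 1e-8)
  expect_error(batch_loss(y, p[, 1, drop = FALSE]), "shape")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  graphs <- parse_molecules(c("CCO", "CC=O", "CCC(C)O"))
  y <- matrix(c(1, 0, 0, 1, 1, 1), nrow = 3)
  params <- gcn_params(atom_feature_spec()$feature_dim, 2, depth = 2,
                       width = 5, seed = 3)
  batch <- graph_batch(graphs)
  loss_at <- function(p) {
    batch_loss(y, molgcn:::.gcn_forward_impl(p, batch, "train", TRUE)$probs,
               2, 0.5)
  }
  cache <- molgcn:::.gcn_forward_impl(params, batch, "train", TRUE)
  grads <- molgcn:::.gcn_backward(
    cache, molgcn:::.focal_loss_grad(y, cache$probs, 2, 0.5))
  h <- 1e-5
  for (leaf in molgcn:::.grad_leaves(params)) {
    g <- molgcn:::.pluck(grads, leaf)
    v <- molgcn:::.pluck(params, leaf)
    for (ii in sample(length(v), min(2, length(v)))) {
      vp <- v; vp[ii] <- vp[ii] + h
      vm <- v; vm[ii] <- vm[ii] - h
      fd <- (loss_at(molgcn:::.poke(params, leaf, vp)) -
               loss_at(molgcn:::.poke(params, leaf, vm))) / (2 * h)
      if (abs(fd) < 1e-10 && abs(g[ii]) < 1e-10) next
      expect_lt(abs(g[ii] - fd) / max(abs(fd), abs(g[ii])), 1e-4)
    }
  }
})

test_that("fit is deterministic, improves on a separable task, and handles epochs 0", {
  spec <- synth_spec(n_molecules = 80, n_tasks = 1, positive_fraction = 0.3,
                     motifs = task_motifs(1), seed = 5)
  ds <- simulate_dataset(spec)
  sp <- stratified_split(ds$labels, seed = 1)
  cfg <- fit_config(depth = 1, width = 8, epochs = 5, batch_size = 16,
                    seed = 11)
  f1 <- fit_gcn(ds$graphs, ds$labels, sp, cfg)
  f2 <- fit_gcn(ds$graphs, ds$labels, sp, cfg)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_lte(f1$history$train_loss[5], f1$history$train_loss[1])
  cfg0 <- fit_config(depth = 1, width = 8, epochs = 0, seed = 11)
  f0 <- fit_gcn(ds$graphs, ds$labels, sp, cfg0)
  expect_equal(nrow(f0$history), 0)
  expect_s3_class(f0$params, "gcn_params")
})

test_that("a task without training positives warns but training proceeds", {
  spec <- synth_spec(n_molecules = 40, n_tasks = 1, positive_fraction = 0.3,
                     motifs = task_motifs(1), seed = 6)
  ds <- simulate_dataset(spec)
  y2 <- cbind(ds$labels$labels, dead = 0L)
  y2[1, 2] <- 1L                           # lone positive, forced into train
  lm <- label_matrix(ds$labels$compound_ids, ds$labels$smiles, y2)
  sp <- index_split(40)
  sp$train <- setdiff(sp$train, 1L)        # drop its only positive
  sp$test <- c(sp$test, 1L)
  cfg <- fit_config(depth = 1, width = 4, epochs = 1, batch_size = 20,
                    seed = 1)
  expect_warning(fit_gcn(ds$graphs, lm, sp, cfg), "zero training positives")
})
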