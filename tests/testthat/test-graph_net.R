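test_that("graph convolution reproduces hand-computed values", {
  # 2-node path, scalar features [1, 2], W_1 = 1, b_1 = 0 -> [3, 3]
  g <- make_graph(list(2L, 1L), matrix(c(1, 2), 2, 1))
  lp <- list(W = lapply(1:7, function(d) matrix(1, 1, 1)),
             b = lapply(1:7, function(d) 0))
  expect_equal(as.vector(graph_conv(matrix(c(1, 2), 2, 1), g, lp)), c(3, 3))
  # all-zero parameters give all-zero output
  lp0 <- list(W = lapply(1:7, function(d) matrix(0, 2, 1)),
              b = lapply(1:7, function(d) c(0, 0)))
  expect_true(all(graph_conv(matrix(c(1, 2), 2, 1), g, lp0) == 0))
  # isolated atom uses the degree-0 weights and no neighbour term
  iso <- make_graph(list(integer(0)), matrix(2, 1, 1))
  lp_iso <- list(W = lapply(1:7, function(d) matrix(d, 1, 1)),
                 b = lapply(1:7, function(d) 0.5))
  expect_equal(as.vector(graph_conv(matrix(2, 1, 1), iso, lp_iso)),
               1 * 2 + 0.5)
  expect_error(graph_conv(matrix(1, 2, 3), g, lp), "width")
})

test_that("node batch norm normalizes channels and handles edge cases", {
  bn <- list(gamma = 1, beta = 0, running_mean = 0, running_var = 1)
  out <- node_batch_norm(matrix(c(1, 3), 2, 1), bn, "train")
  expect_equal(as.vector(out$state), c(-1, 1), tolerance = 1e-4)
  # constant channel collapses to zero, guarded by epsilon
  out2 <- node_batch_norm(matrix(c(5, 5, 5), 3, 1), bn, "train")
  expect_equal(as.vector(out2$state), c(0, 0, 0))
  # eval mode with unit running stats is the identity
  out3 <- node_batch_norm(matrix(c(1, 3), 2, 1), bn, "eval")
  expect_equal(as.vector(out3$state), c(1, 3), tolerance = 1e-4)
  expect_error(node_batch_norm(matrix(1, 1, 1), bn, "train"), "degenerate")
  # running statistics move toward the batch statistics
  expect_gt(out$bn_params$running_mean, 0)
})

test_that("max pooling takes the closed-neighbourhood maximum", {
  g <- make_graph(list(2L, 1L), matrix(0, 2, 2))
  h <- rbind(c(1, 5), c(3, 2))
  out <- graph_max_pool(h, g)
  expect_equal(out, rbind(c(3, 5), c(3, 5)))
  iso <- make_graph(list(integer(0)), matrix(0, 1, 2))
  expect_equal(graph_max_pool(rbind(c(7, -1)), iso), rbind(c(7, -1)))
  # constant state is a fixed point
  hc <- matrix(4, 2, 3)
  expect_equal(graph_max_pool(hc, make_graph(list(2L, 1L), hc)), hc)
})

test_that("graph gather produces the tanh-squashed weighted sum", {
  gp0 <- list(Phi = lapply(1:7, function(d) matrix(0, 2, 2)),
              beta = c(0, 0))
  g <- make_graph(list(2L, 1L), matrix(1, 2, 2))
  expect_equal(as.vector(graph_gather(matrix(1, 2, 2), g, gp0)), c(0, 0))
  gpI <- list(Phi = lapply(1:7, function(d) diag(1)), beta = 0)
  iso <- make_graph(list(integer(0)), matrix(0.5, 1, 1))
  expect_equal(as.vector(graph_gather(matrix(0.5, 1, 1), iso, gpI)),
               tanh(0.5))
})

test_that("each layer op matches its naive per-node oracle", {
  set.seed(11)
  for (trial in 1:60) {
    g <- random_graph(max_n = 6, dim = 3)
    h <- g$atom_features
    lp <- random_layer_params(3, 4)
    expect_equal(graph_conv(h, g, lp), oracle_conv(h, g, lp),
                 tolerance = 1e-12)
    expect_equal(graph_max_pool(h, g), oracle_max_pool(h, g),
                 tolerance = 1e-12)
    gp <- random_gather_params(3, 4)
    expect_equal(as.vector(graph_gather(h, g, gp)),
                 oracle_gather(h, g, gp), tolerance = 1e-12)
  }
})

test_that("forward matches a hand-computed single-layer chain", {
  # 3-atom path, 1 conv layer, BN forced to identity via eval mode
  g <- make_graph(list(2L, c(1L, 3L), 2L), matrix(c(0.1, 0.2, 0.3), 3, 1))
  params <- gcn_params(1, 1, depth = 1, width = 1, seed = 5)
  W1 <- 0.7; W2 <- -0.4; b1 <- 0.05; b2 <- 0.1
  # list slot d+1 holds the degree-d parameters
  params$conv[[1]]$W <- lapply(0:6, function(d) matrix(c(W1, W2)[min(max(d, 1), 2)], 1, 1))
  params$conv[[1]]$b <- lapply(0:6, function(d) c(b1, b2)[min(max(d, 1), 2)])
  params$gather$Phi <- lapply(1:7, function(d) matrix(1.3, 1, 1))
  params$gather$beta <- -0.2
  params$head$W <- matrix(2, 1, 1); params$head$b <- 0.3
  probs <- gcn_forward(params, list(g), mode = "eval")
  # hand chain: conv (degree-indexed), eval BN with unit running stats
  # (scale 1/sqrt(1 + eps)), pool, gather, head
  conv <- c(max(W1 * (0.1 + 0.2) + b1, 0),
            max(W2 * (0.2 + 0.1 + 0.3) + b2, 0),
            max(W1 * (0.3 + 0.2) + b1, 0)) / sqrt(1 + 1e-5)
  pool <- c(max(conv[1:2]), max(conv), max(conv[2:3]))
  emb <- tanh(1.3 * sum(pool) - 0.2)
  expect_equal(as.vector(probs), 1 / (1 + exp(-(2 * emb + 0.3))),
               tolerance = 1e-10)
})

test_that("forward output shape and head-only degenerate case", {
  graphs <- parse_molecules(c("CCO", "c1ccccc1", "CC(C)C"))
  params <- gcn_params(atom_feature_spec()$feature_dim, 4, depth = 2,
                       width = 6, seed = 2)
  probs <- gcn_forward(params, graphs, mode = "eval")
  expect_equal(dim(probs), c(3, 4))
  expect_true(all(probs > 0 & probs < 1))
  params$head$W[] <- 0
  params$head$b <- c(-1, 0, 1, 2)
  probs0 <- gcn_forward(params, graphs, mode = "eval")
  for (m in 1:3) {
    expect_equal(as.vector(probs0[m, ]), 1 / (1 + exp(-params$head$b)),
                 tolerance = 1e-12)
  }
})

test_that("outputs are invariant to atom relabeling", {
  set.seed(21)
  smis <- generate_molecules(synth_spec(n_molecules = 10, n_tasks = 1,
                                        positive_fraction = 0.3,
                                        motifs = task_motifs(1), seed = 9))
  graphs <- parse_molecules(as.character(smis))
  params <- gcn_params(atom_feature_spec()$feature_dim, 2, depth = 2,
                       width = 8, seed = 3)
  for (g in graphs) {
    perm <- sample(g$n_atoms)
    p1 <- gcn_forward(params, list(g), mode = "eval")
    p2 <- gcn_forward(params, list(permute_graph(g, perm)), mode = "eval")
    expect_equal(p1, p2, tolerance = 1e-6)
  }
})

test_that("batched evaluation equals one-by-one evaluation", {
  graphs <- parse_molecules(c("CCO", "CC(=O)OC", "c1ccncc1", "C"))
  params <- gcn_params(atom_feature_spec()$feature_dim, 3, depth = 2,
                       width = 5, seed = 7)
  together <- gcn_forward(params, graphs, mode = "eval")
  singly <- do.call(rbind, lapply(graphs, function(g) {
    gcn_forward(params, list(g), mode = "eval")
  }))
  expect_equal(together, singly, tolerance = 1e-6)
})

test_that("checkpoints round-trip bit-exactly", {
  params <- gcn_params(atom_feature_spec()$feature_dim, 3, depth = 2,
                       width = 4, seed = 13)
  path <- tempfile(fileext = ".json")
  write_checkpoint(params, path)
  back <- read_checkpoint(path)
  expect_identical(back$conv[[1]]$W[[2]], params$conv[[1]]$W[[2]])
  expect_identical(back$gather$Phi[[7]], params$gather$Phi[[7]])
  expect_identical(back$head$W, params$head$W)
  expect_equal(back$bn[[1]], params$bn[[1]])
  probs1 <- gcn_forward(params, parse_molecules("CC(=O)OC")[1], "eval")
  probs2 <- gcn_forward(back, parse_molecules("CC(=O)OC")[1], "eval")
  expect_identical(probs1, probs2)
})
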