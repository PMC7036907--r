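split_is_partition <- function(sp, n) {
  all_idx <- sort(c(sp$train, sp$valid, sp$test))
  identical(all_idx, seq_len(n)) &&
    !length(intersect(sp$train, sp$valid)) &&
    !length(intersect(sp$train, sp$test)) &&
    !length(intersect(sp$valid, sp$test))
}

test_that("index split takes the first 80/10/10 in order", {
  sp <- index_split(10)
  expect_equal(sp$train, 1:8)
  expect_equal(sp$valid, 9L)
  expect_equal(sp$test, 10L)
  sp100 <- index_split(100)
  expect_equal(lengths(sp100[c("train", "valid", "test")]),
               c(train = 80L, valid = 10L, test = 10L))
  expect_equal(sp100$train, sort(sp100$train))   # input order preserved
  expect_error(index_split(9), "n >= 10")
})

test_that("random split is a seeded permutation with 80/10/10 sizes", {
  expect_identical(random_split(50, seed = 3), random_split(50, seed = 3))
  expect_false(identical(random_split(50, seed = 3)$train,
                         random_split(50, seed = 4)$train))
  for (n in c(10, 23, 100)) {
    sp <- random_split(n, seed = 1)
    expect_true(split_is_partition(sp, n))
    expect_lte(abs(length(sp$train) - 0.8 * n), 1)
    expect_lte(abs(length(sp$valid) - 0.1 * n), 1)
  }
})

test_that("stratified split distributes positives 8/1/1 for a 10-positive task", {
  set.seed(1)
  y <- matrix(0L, 100, 1)
  y[sample(100, 10), 1] <- 1L
  lm <- label_matrix(sprintf("c%03d", 1:100), rep("C", 100), y, "t1")
  for (s in 1:5) {
    sp <- stratified_split(lm, seed = s)
    expect_true(split_is_partition(sp, 100))
    expect_equal(sum(y[sp$train, 1]), 8)
    expect_equal(sum(y[sp$valid, 1]), 1)
    expect_equal(sum(y[sp$test, 1]), 1)
  }
})

test_that("stratified split keeps train ratios near global for common tasks", {
  set.seed(7)
  y <- cbind(rbinom(200, 1, 0.3), rbinom(200, 1, 0.15))
  lm <- label_matrix(sprintf("c%03d", 1:200), rep("C", 200), y)
  devs <- sapply(1:10, function(s) {
    sp <- stratified_split(lm, seed = s)
    abs(colMeans(y[sp$train, , drop = FALSE]) - colMeans(y))
  })
  expect_lte(median(devs[1, ]), 0.02)
  expect_lte(median(devs[2, ]), 0.02)
})

test_that("stratified split warns on degenerate tasks and fills folds", {
  y <- cbind(a = c(1L, 1L, rep(0L, 18)), b = rep(0L, 20))
  lm <- label_matrix(sprintf("c%02d", 1:20), rep("C", 20), y)
  expect_warning(
    expect_warning(sp <- stratified_split(lm, seed = 2), "fewer than 3"),
    "no positives")
  expect_true(split_is_partition(sp, 20))
  expect_equal(sum(y[sp$train, "a"]), 2)   # 1-2 positives go to train
  expect_gt(length(sp$test), 0)
})

test_that("scaffold split keeps scaffolds within one fold", {
  # toluene/ethylbenzene share the benzene scaffold
  smis <- c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1", "Cc1ccncc1",
            "C1CCCCC1", "CC1CCCCC1", "CCC1CCCCC1", "CCCC", "CCCCC",
            "CCOCC", "CC(C)C", "C1CC1")
  sp <- scaffold_split(smis, seed = 1)
  expect_true(split_is_partition(sp, length(smis)))
  keys <- scaffold_keys(smis)
  folds <- list(sp$train, sp$valid, sp$test)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_length(intersect(keys[folds[[a]]], keys[folds[[b]]]), 0)
  }
  benz <- which(keys == keys[1])
  fold_of <- function(i) which(sapply(folds, function(f) i %in% f))
  expect_length(unique(sapply(benz, fold_of)), 1)
})

test_that("scaffold groups are allocated greedily by size", {
  # 4 scaffold groups of sizes 5/3/1/1 over 10 molecules
  smis <- c(rep("Cc1ccccc1", 5), rep("CC1CCCCC1", 3), "Cc1ccncc1",
            "CC1CCCC1")
  smis <- paste0(smis, c("", "C", "CC", "CCC", "CCCC")[c(1:5, 1:3, 1, 1)])
  keys <- scaffold_keys(smis)
  expect_equal(as.integer(sort(table(keys), decreasing = TRUE)),
               c(5L, 3L, 1L, 1L))
  sp <- scaffold_split(smis, seed = 1)
  expect_equal(sort(sp$train), 1:8)       # size-5 then size-3 group
  expect_length(sp$valid, 1)
  expect_length(sp$test, 1)
})

test_that("all strategies produce valid partitions on randomized inputs", {
  set.seed(99)
  pool <- generate_molecules(synth_spec(n_molecules = 50, n_tasks = 2,
                                        positive_fraction = c(0.3, 0.1),
                                        motifs = task_motifs(2), seed = 42))
  pool_graphs <- parse_molecules(as.character(pool))
  for (trial in 1:20) {
    n <- sample(10:50, 1)
    y <- matrix(rbinom(n * 3, 1, runif(1, 0.1, 0.4)), n, 3)
    if (!any(y == 1)) y[1, 1] <- 1L
    lm <- label_matrix(sprintf("c%03d", seq_len(n)),
                       rep("C", n), y)
    expect_true(split_is_partition(index_split(n), n))
    expect_true(split_is_partition(random_split(n, trial), n))
    sp <- suppressWarnings(stratified_split(lm, trial))
    expect_true(split_is_partition(sp, n))
    expect_gt(length(sp$test), 0)
    idx <- sample(50, n)
    expect_true(split_is_partition(scaffold_split(pool_graphs[idx], trial),
                                   n))
  }
})
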