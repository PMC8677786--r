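# Multi-target tree induction: split criterion, tree growth, bagging.

test_that("target_variance is the normalized population variance sum", {
  expect_equal(target_variance(matrix(c(1, 1), 1, 2)), 0)
  y <- rbind(c(0, 0), c(2, 0))
  expect_equal(target_variance(y, c(1, 1)), 1)
  # scaling targets and scale together leaves the value unchanged
  expect_equal(target_variance(3 * y, 3 * c(1, 1)),
               target_variance(y, c(1, 1)))
})

test_that("evaluate_split matches the brute-force oracle on a fixture", {
  set.seed(3)
  X <- matrix(rbinom(6 * 8, 1, 0.5), 6, 8)
  y <- cbind(runif(6), runif(6))
  scale <- c(0.7, 1.3)
  for (bit in 0:7) {
    expect_equal(evaluate_split(X, y, bit, scale),
                 oracle_reduction(X, y, bit, scale))
  }
  # a bit separating two constant groups recovers the whole variance
  Xp <- cbind(rep(c(0L, 1L), each = 3), matrix(0L, 6, 3))
  yp <- cbind(rep(c(1, 0.5), each = 3), rep(c(1, 0.6), each = 3))
  expect_equal(evaluate_split(Xp, yp, 0, c(1, 1)),
               target_variance(yp, c(1, 1)))
  # a constant bit gives an empty branch: sentinel
  expect_identical(evaluate_split(Xp, yp, 1, c(1, 1)), -Inf)
  expect_error(evaluate_split(Xp, yp, 99, c(1, 1)), "invalid bit")
})

test_that("the chosen root split equals exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:60) {
    n <- sample(3:8, 1)
    X <- matrix(rbinom(n * 8, 1, 0.5), n, 8)
    y <- cbind(runif(n), runif(n))
    reds <- vapply(0:7, function(b)
      oracle_reduction(X, y, b, c(1, 1)), numeric(1))
    if (!any(is.finite(reds))) next
    tr <- grow_tree(X, y, tree_params(min_leaf = 1), c(1, 1))
    # the chosen bit attains the exhaustive maximum; when that maximum is
    # unique the index matches exactly (ties arise from duplicate or
    # complementary bit columns, which induce the same partition)
    expect_lt(max(reds) - reds[tr$split[1] + 1L], 1e-10)
    tied <- which(reds > max(reds) - 1e-10)
    if (length(tied) == 1) expect_equal(tr$split[1], tied - 1L)
  }
})

test_that("tree growth recovers representable target structures", {
  # constant targets: a single leaf predicting the pair
  Xc <- matrix(rbinom(40, 1, 0.5), 10, 4)
  yc <- cbind(rep(0.8, 10), rep(1.2, 10))
  trc <- grow_tree(Xc, yc, tree_params(min_leaf = 1), c(1, 1))
  expect_length(trc$split, 1)
  expect_equal(unname(predict_tree(trc, Xc)[1, ]), c(0.8, 1.2))

  # targets equal to bit 5: depth-1 tree splitting on bit 5, zero error
  set.seed(5)
  X <- matrix(rbinom(20 * 8, 1, 0.5), 20, 8)
  X[, 6] <- rep(c(0L, 1L), each = 10)
  y <- cbind(X[, 6], X[, 6])
  tr <- grow_tree(X, y, tree_params(min_leaf = 1), c(1, 1))
  expect_equal(tr$split[1], 5)
  expect_equal(predict_tree(tr, X)[, 1], y[, 1])

  # XOR of two bits needs (and gets) depth 2 with four pure leaves
  Xx <- cbind(as.matrix(expand.grid(0:1, 0:1)), 0L)
  storage.mode(Xx) <- "integer"
  yx <- cbind(as.numeric(xor(Xx[, 1], Xx[, 2])),
              as.numeric(xor(Xx[, 1], Xx[, 2])))
  trx <- grow_tree(Xx, yx, tree_params(min_leaf = 1), c(1, 1))
  expect_equal(sum(trx$split < 0), 4)
  expect_equal(predict_tree(trx, Xx)[, 1], yx[, 1])
})

test_that("leaf counts partition the training sample", {
  set.seed(9)
  X <- matrix(rbinom(200 * 16, 1, 0.4), 200, 16)
  y <- cbind(runif(200), runif(200))
  tr <- grow_tree(X, y, tree_params(min_leaf = 5), c(1, 1))
  expect_equal(sum(tr$n[tr$split < 0]), 200)
  # routing every record reaches a leaf whose prototype is finite
  p <- predict_tree(tr, X)
  expect_true(all(is.finite(p)))
  # split bits are distinct along every root-to-leaf path
  walk <- function(node, seen) {
    if (tr$split[node] < 0) return(invisible())
    expect_false(tr$split[node] %in% seen)
    walk(tr$left[node], c(seen, tr$split[node]))
    walk(tr$right[node], c(seen, tr$split[node]))
  }
  walk(1, integer(0))
})

test_that("ensembles are seeded, deterministic, and reduce to one tree", {
  ts <- random_training_set(40, 32, seed = 2)
  e1 <- fit_ensemble(ts, tree_params(n_trees = 10), seed = 99)
  e2 <- fit_ensemble(ts, tree_params(n_trees = 10), seed = 99)
  expect_identical(e1$trees, e2$trees)
  expect_identical(e1$boot_idx, e2$boot_idx)

  es <- fit_ensemble(ts, tree_params(n_trees = 1, bootstrap = FALSE), seed = 1)
  tr <- grow_tree(ts$X, ts$y, tree_params(), ts$scale)
  pe <- predict_ensemble(es, ts$X)
  pt <- predict_tree(tr, ts$X)
  expect_equal(pe$rfp_mean, pt[, 1])
  expect_equal(pe$rfp_sd, rep(0, 40))

  # constant targets: every tree is one leaf with that prototype
  tsc <- suppressWarnings(
    training_set(ts$ids, ts$fps, rep(0.9, 40), rep(1.1, 40)))
  ec <- fit_ensemble(tsc, tree_params(n_trees = 5), seed = 3)
  expect_true(all(vapply(ec$trees, function(t) length(t$split) == 1,
                         logical(1))))
  pc <- predict_ensemble(ec, ts$X[1:3, , drop = FALSE])
  expect_equal(pc$rfp_mean, rep(0.9, 3))
  expect_equal(pc$egfp_sd, rep(0, 3))
})

test_that("ensemble prediction averages trees and scores disagreement", {
  leaf <- function(r, g) {
    tr <- list(split = -1L, left = 0L, right = 0L, n = 1L,
               pred = cbind(r, g), nbits = 8L)
    class(tr) <- "pct_tree"
    tr
  }
  ens <- structure(list(trees = list(leaf(0.6, 1), leaf(0.8, 1)),
                        params = tree_params(n_trees = 2), seed = 0L,
                        scale = c(1, 1), nbits = 8L, radius = 2L,
                        boot_idx = list(1L, 1L)),
                   class = "pct_ensemble")
  p <- predict_ensemble(ens, make_fp(c(0, 3), nbits = 8))
  expect_equal(p$rfp_mean, 0.7)
  expect_equal(p$rfp_sd, 0.1) # population sd of {0.6, 0.8}
  expect_equal(p$egfp_sd, 0)
  expect_error(predict_ensemble(ens, make_fp(1, nbits = 16)), "nbits")
})

test_that("bagging does not underperform the worst constituent tree", {
  worse <- 0
  for (s in 1:20) {
    scen <- simulate_scenario("paper-like", seed = 100 + s, n = 80,
                              nbits = 128)
    ens <- fit_ensemble(scen$train, tree_params(n_trees = 15), seed = s)
    pe <- predict_ensemble(ens, scen$train$X)
    ens_mae <- mae(pe$rfp_mean, scen$train$y[, 1]) +
      mae(pe$egfp_mean, scen$train$y[, 2])
    tree_maes <- vapply(ens$trees, function(tr) {
      pt <- predict_tree(tr, scen$train$X)
      mae(pt[, 1], scen$train$y[, 1]) + mae(pt[, 2], scen$train$y[, 2])
    }, numeric(1))
    if (ens_mae > max(tree_maes)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("root splits concentrate on the causal bits of a noise-free screen", {
  scen <- simulate_scenario("noise-free", seed = 31, n = 300, nbits = 512)
  ens <- fit_ensemble(scen$train, tree_params(n_trees = 50), seed = 31)
  roots <- vapply(ens$trees, function(t) t$split[1], integer(1))
  expect_gte(mean(roots %in% scen$gt$effect_bits), 0.8)
})

test_that("ensembles survive a JSON round trip", {
  ts <- random_training_set(30, 32, seed = 4)
  ens <- fit_ensemble(ts, tree_params(n_trees = 5, max_depth = 4), seed = 12)
  path <- tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$params, ens$params)
  expect_equal(back$scale, ens$scale)
  p1 <- predict_ensemble(ens, ts$X)
  p2 <- predict_ensemble(back, ts$X)
  expect_equal(p2, p1)
})
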