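# The synthetic screen generator: ground truth, library assembly, and the
# generative formula.

test_that("ground truths are seeded, sparse, and respect their pool", {
  g0 <- make_ground_truth(nbits = 64, k_effects = 0, seed = 1)
  expect_length(g0$effect_bits, 0)
  g1 <- make_ground_truth(nbits = 64, k_effects = 5, seed = 9)
  g2 <- make_ground_truth(nbits = 64, k_effects = 5, seed = 9)
  expect_identical(g1, g2)
  expect_false(anyDuplicated(g1$effect_bits) > 0)
  expect_true(all(g1$effect_bits >= 0 & g1$effect_bits < 64))
  g3 <- make_ground_truth(nbits = 64, k_effects = 2, seed = 3,
                          candidate_bits = c(10L, 20L, 30L))
  expect_true(all(g3$effect_bits %in% c(10L, 20L, 30L)))
  expect_error(make_ground_truth(nbits = 64, k_effects = 4,
                                 candidate_bits = 1:3), "exceeds")
  # RFP and EGFP effects share a latent draw: positively coupled
  gbig <- make_ground_truth(nbits = 2048, k_effects = 50, seed = 5)
  expect_gt(cor(gbig$rfp_effect, gbig$egfp_effect), 0.5)
})

test_that("sampled libraries parse, are diverse, and are reproducible", {
  mols <- sample_library(40, seed = 3)
  expect_length(mols, 40)
  expect_equal(mols[[1]]$id, "SYN-000001")
  expect_true(all(vapply(mols, inherits, logical(1), "molecule")))
  mols2 <- sample_library(40, seed = 3)
  expect_identical(vapply(mols, function(m) m$source_text, character(1)),
                   vapply(mols2, function(m) m$source_text, character(1)))
  fps <- fingerprint_library(mols[1:10], nbits = 512)
  keys <- vapply(fps, compound_key, character(1))
  expect_gte(length(unique(keys)), 2)
  expect_error(sample_library(5, structure(list(fragments = character(0),
                                                linkers = "", max_fragments = 1L),
                                           class = "fragment_grammar")),
               "no fragments")
})

test_that("the screen formula is exact when noise is absent", {
  mols <- sample_library(30, seed = 4)
  g0 <- make_ground_truth(nbits = 256, k_effects = 0, noise_sd = 0, seed = 1)
  # a constant screen triggers the degenerate-scale fallback on both targets
  w <- capture_warnings(ts <- simulate_screen(mols, g0, seed = 2))
  expect_length(w, 2)
  expect_match(w, "zero variance", all = TRUE)
  expect_true(all(ts$y == 1))

  # one causal bit with a known effect subtracts exactly
  fps <- fingerprint_library(mols, nbits = 256)
  X <- fingerprint_matrix(fps)
  freq <- colMeans(X)
  bit <- which(freq > 0.2 & freq < 0.9)[1] - 1L
  g1 <- make_ground_truth(nbits = 256, k_effects = 1, noise_sd = 0, seed = 1,
                          candidate_bits = bit)
  ts1 <- simulate_screen(mols, g1, seed = 2)
  carrier <- X[, bit + 1L] == 1
  expect_equal(ts1$y[carrier, 1], rep(1 - g1$rfp_effect, sum(carrier)))
  expect_equal(ts1$y[!carrier, 1], rep(1, sum(!carrier)))

  # intensities clip at zero when effects exceed the baseline
  g2 <- make_ground_truth(nbits = 256, k_effects = 1, noise_sd = 0, seed = 1,
                          candidate_bits = bit)
  g2$rfp_effect <- 5
  ts2 <- simulate_screen(mols, g2, seed = 2)
  expect_true(all(ts2$y[carrier, 1] == 0))
  expect_true(all(ts2$y[, 1] >= 0))
})

test_that("scenarios are deterministic under the root seed", {
  s1 <- simulate_scenario("paper-like", seed = 77, n = 60, nbits = 256)
  s2 <- simulate_scenario("paper-like", seed = 77, n = 60, nbits = 256)
  expect_identical(s1$train$y, s2$train$y)
  expect_identical(s1$gt$effect_bits, s2$gt$effect_bits)
  het <- simulate_scenario("heteroscedastic", seed = 77, n = 60, nbits = 256)
  expect_true(het$gt$noise_bit %in% het$gt$effect_bits)
  expect_equal(het$gt$noise_sd_high, c(0.2, 0.2))
})

test_that("the packaged reference panel is well formed", {
  refs <- fixture_references(nbits = 1024)
  expect_gt(nrow(refs$table), 5)
  expect_false(anyDuplicated(refs$table$name) > 0)
  dop <- refs$fps[[which(refs$table$name == "dopamine")]]
  zan <- refs$fps[[which(refs$table$name == "zanamivir")]]
  expect_equal(tanimoto(dop, dop), 1)
  expect_lt(tanimoto(dop, zan), 1)
  # frozen regression value at the default 2048-bit length
  refs2048 <- fixture_references()
  d <- refs2048$fps[[which(refs2048$table$name == "dopamine")]]
  z <- refs2048$fps[[which(refs2048$table$name == "zanamivir")]]
  expect_equal(tanimoto(d, z), 5 / 73, tolerance = 1e-12)
  expect_true(any(refs$table$in_training))
  expect_true(any(!refs$table$in_training))
})
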