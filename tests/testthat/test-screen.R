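# Hit calling: activity threshold, reliability quantile, novelty exclusion,
# and nearest-reference grouping.

# assemble a screen_predictions object from raw prediction rows
make_sp <- function(ids, rfp_mean, rfp_sd, egfp_mean = NULL, egfp_sd = NULL,
                    fps = NULL, nbits = 64) {
  n <- length(ids)
  if (is.null(egfp_mean)) egfp_mean <- rfp_mean
  if (is.null(egfp_sd)) egfp_sd <- rfp_sd
  if (is.null(fps))
    fps <- lapply(seq_len(n), function(i)
      make_fp(c(i %% 32, 32 + i %/% 32), nbits))
  structure(list(
    table = tibble::tibble(id = ids, rfp_mean = rfp_mean,
                           egfp_mean = egfp_mean, rfp_sd = rfp_sd,
                           egfp_sd = egfp_sd,
                           key = vapply(fps, compound_key, character(1))),
    fps = fps, skipped = character(0)), class = "screen_predictions")
}

test_that("the activity filter applies the 25% reduction rule inclusively", {
  sp <- make_sp(c("a", "b", "c"), rfp_mean = c(0.74, 0.75, 0.76),
                rfp_sd = c(0.1, 0.1, 0.1))
  out <- filter_hits(sp, screen_config())
  expect_equal(out$table$passed_activity, c(TRUE, TRUE, FALSE))
  # threshold scales with the control level
  out2 <- filter_hits(sp, screen_config(control_level = 2))
  expect_true(all(out2$table$passed_activity))
})

test_that("the reliability quantile keeps the agreeing half, degenerately all", {
  sp <- make_sp(sprintf("c%d", 1:4), rfp_mean = rep(0.5, 4),
                rfp_sd = c(0.01, 0.02, 0.03, 0.04))
  out <- filter_hits(sp, screen_config(reliability_quantile = 0.5))
  expect_equal(sum(out$table$passed_reliability), 2)
  spc <- make_sp(sprintf("c%d", 1:4), rfp_mean = rep(0.5, 4),
                 rfp_sd = rep(0.02, 4))
  outc <- filter_hits(spc, screen_config())
  expect_true(all(outc$table$passed_reliability))
})

test_that("a hand-enumerated 10-compound table yields the hand-counted hits", {
  # activity (<= 0.75): c01 c02 c03 c05 c07 c10
  # sd quantile 0.5 over all ten sds (median 0.05): c01 c03 c04 c06 c08
  # dual pass, by hand: c01, c03
  sp <- make_sp(sprintf("c%02d", 1:10),
                rfp_mean = c(0.50, 0.75, 0.60, 0.90, 0.74, 1.00, 0.70, 0.80,
                             0.95, 0.30),
                rfp_sd = c(0.01, 0.09, 0.02, 0.03, 0.08, 0.04, 0.07, 0.04,
                           0.10, 0.06))
  out <- filter_hits(sp, screen_config(reliability_quantile = 0.5))
  expect_equal(sum(out$table$passed_activity), 6)
  h <- hits(out)
  expect_setequal(h$id, c("c01", "c03"))
})

test_that("training compounds and duplicate candidates are excluded", {
  fps <- list(make_fp(c(1, 2)), make_fp(c(3, 4)), make_fp(c(1, 2)),
              make_fp(c(5, 6)))
  sp <- make_sp(sprintf("c%d", 1:4), rfp_mean = rep(0.5, 4),
                rfp_sd = rep(0.01, 4), fps = fps)
  sp <- filter_hits(sp, screen_config())
  ts <- suppressWarnings(
    training_set(c("t1", "t2"), list(make_fp(c(5, 6)), make_fp(c(7, 8))),
                 c(1, 1), c(1, 1)))
  expect_message(out <- remove_training_overlap(sp, ts), "duplicate")
  # duplicate of c1 dropped, training twin c4 flagged
  expect_equal(nrow(out$table), 3)
  expect_equal(out$table$passed_novelty, c(TRUE, TRUE, FALSE))
  # with an empty training comparison all candidates are retained
  sp2 <- filter_hits(make_sp(c("a", "b"), c(0.5, 0.5), c(0.01, 0.02)),
                     screen_config())
  out2 <- remove_training_overlap(sp2, NULL)
  expect_true(all(out2$table$passed_novelty))
})

test_that("grouping assigns the nearest reference with panel-order ties", {
  refs <- reference_set(c("ref1", "ref2", "ref3"),
                        c("CCO", "c1ccccc1", "CCN"),
                        in_training = c(TRUE, FALSE, FALSE),
                        nbits = 256)
  hit_fps <- list(ecfp(parse_smiles("CCO"), nbits = 256),     # = ref1
                  ecfp(parse_smiles("ClC(Cl)(Cl)Cl"), nbits = 256)) # dissimilar
  sp <- make_sp(c("h1", "h2"), rfp_mean = c(0.5, 0.5),
                rfp_sd = c(0.01, 0.01), fps = hit_fps, nbits = 256)
  sp <- filter_hits(sp, screen_config())
  asg <- group_by_reference(sp, refs, tau = 0.4)
  expect_equal(asg$group, c("ref1", "other"))
  expect_equal(asg$best_tanimoto[1], 1)
  expect_lt(asg$best_tanimoto[2], 0.4)

  # an exact tie goes to the earlier panel entry
  refs2 <- reference_set(c("first", "second"), c("CCO", "OCC"), nbits = 256)
  asg2 <- group_by_reference(sp, refs2, tau = 0.4)
  expect_equal(asg2$group[1], "first")
  expect_error(group_by_reference(sp, structure(list(
    table = tibble::tibble()), class = "reference_set")), "empty")
})

test_that("screening the training library against itself leaves no hits", {
  scen <- simulate_scenario("noise-free", seed = 17, n = 100, nbits = 256)
  ens <- fit_ensemble(scen$train, tree_params(n_trees = 20), seed = 17)
  sp <- screen_library(ens, scen$train$ids, scen$train$fps)
  sp <- filter_hits(sp, screen_config())
  sp <- suppressMessages(remove_training_overlap(sp, scen$train))
  expect_false(any(sp$table$passed_novelty))
  expect_equal(nrow(hits(sp)), 0)
})

test_that("summaries count groups and expose panel-level fractions", {
  empty <- summarize_screen(tibble::tibble(id = character(0),
                                           group = character(0),
                                           best_tanimoto = numeric(0)))
  expect_equal(empty$n_hits, 0)
  expect_equal(nrow(empty$groups), 0)

  # the 19-of-44 dopamine bin
  asg <- tibble::tibble(
    id = sprintf("h%02d", 1:44),
    group = c(rep("dopamine", 19), rep("zanamivir", 8), rep("topiramate", 2),
              rep("other", 15)),
    best_tanimoto = 0.5)
  rep44 <- summarize_screen(asg)
  dop <- rep44$groups$fraction[rep44$groups$group == "dopamine"]
  expect_equal(dop, 19 / 44, tolerance = 1e-12)
  expect_equal(round(dop, 2), 0.43)
  named <- rep44$groups$fraction[rep44$groups$group != "other"]
  expect_lte(sum(named), 1)
})

test_that("filters are monotone in their thresholds", {
  set.seed(23)
  sp <- make_sp(sprintf("m%03d", 1:100), rfp_mean = runif(100, 0.4, 1.2),
                rfp_sd = runif(100, 0, 0.1))
  counts <- vapply(c(0.4, 0.3, 0.2, 0.1), function(thr)
    sum(filter_hits(sp, screen_config(reduction_threshold = thr))$
          table$passed_activity), numeric(1))
  expect_true(all(diff(counts) >= 0))

  refs <- fixture_references(nbits = 64)
  spf <- filter_hits(make_sp(sprintf("m%03d", 1:30),
                             rfp_mean = runif(30, 0.3, 0.7),
                             rfp_sd = runif(30, 0, 0.1),
                             fps = lapply(1:30, function(i)
                               make_fp(sample(0:63, 12), 64))),
                     screen_config())
  others <- vapply(c(0.1, 0.3, 0.5, 0.7), function(tau)
    sum(group_by_reference(spf, refs, tau)$group == "other"), numeric(1))
  expect_true(all(diff(others) >= 0))
})
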