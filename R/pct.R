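# Multi-target predictive clustering trees and their bagging ensemble.
#
# A tree node splits the training records on a fingerprint bit so as to
# maximize the variance reduction summed over the two targets (RFP, EGFP),
# each target's variance normalized by its full-training-set standard
# deviation so both phenotypes contribute comparably. Variances are
# population variances (divide by n) throughout, which keeps the brute-force
# oracle tests exact. Leaves predict the per-target mean of their records.
# Per-prediction reliability is the population sd of the individual trees'
# predictions.

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Training set of screened compounds
#'
#' Bundles compound ids, fingerprints and the two fold-over-control
#' intensities (RFP = alpha-SMA reporter, EGFP = collagen reporter) into the
#' container the learners operate on. The per-target normalization scale
#' (population sd over the full set) is computed here; a degenerate
#' (zero-variance) target falls back to scale 1 with a warning.
#'
#' @param ids Character vector of compound identifiers.
#' @param fps List of `ecfp` fingerprints (equal `nbits`).
#' @param rfp,egfp Non-negative fold-over-control intensities.
#' @return An object of class `training_set` with elements `ids`, `fps`,
#'   `X` (binary matrix), `y` (n x 2 matrix, columns rfp/egfp), `scale`,
#'   `nbits`, `radius`.
#' @export
training_set <- function(ids, fps, rfp, egfp) {
  n <- length(ids)
  stopifnot(n >= 2, length(fps) == n, length(rfp) == n, length(egfp) == n,
            all(rfp >= 0), all(egfp >= 0))
  X <- fingerprint_matrix(fps)
  y <- cbind(rfp = as.numeric(rfp), egfp = as.numeric(egfp))
  scale <- c(.pop_sd(y[, 1]), .pop_sd(y[, 2]))
  for (j in 1:2) {
    if (scale[j] <= 0) {
      warning(sprintf("target '%s' has zero variance; using scale 1",
                      colnames(y)[j]), call. = FALSE)
      scale[j] <- 1
    }
  }
  structure(list(ids = as.character(ids), fps = fps, X = X, y = y,
                 scale = scale, nbits = fps[[1]]$nbits,
                 radius = fps[[1]]$radius),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set: %d compounds, %d fingerprint bits>\n",
              nrow(x$y), x$nbits))
  invisible(x)
}

#' @export
as.data.frame.training_set <- function(x, ...) {
  data.frame(id = x$ids, rfp = x$y[, 1], egfp = x$y[, 2],
             stringsAsFactors = FALSE)
}

#' Normalized multi-target variance of a set of records
#'
#' Sum over the two targets of the population variance divided by the squared
#' normalization scale. This is the quantity a tree split reduces.
#'
#' @param y Numeric n x 2 target matrix.
#' @param scale Length-2 positive normalization scale.
#' @return A non-negative number.
#' @export
target_variance <- function(y, scale = c(1, 1)) {
  y <- rbind(y)
  stopifnot(nrow(y) >= 1, ncol(y) == 2, all(scale > 0))
  v <- apply(y, 2, function(col) mean((col - mean(col))^2))
  sum(v / scale^2)
}

#' Variance reduction of splitting on one fingerprint bit
#'
#' `V(records) - sum_branch (n_b / n) V(branch)` for the partition induced by
#' the bit. Returns `-Inf` when either branch is empty or smaller than
#' `min_leaf`.
#'
#' @param X Binary record x bit matrix.
#' @param y Numeric n x 2 target matrix.
#' @param bit 0-based bit position to split on.
#' @param scale Length-2 normalization scale.
#' @param min_leaf Minimum records per branch.
#' @return The variance reduction, or `-Inf` if the split is inadmissible.
#' @export
evaluate_split <- function(X, y, bit, scale = c(1, 1), min_leaf = 1) {
  stopifnot(nrow(X) >= 2, nrow(X) == nrow(y))
  if (bit < 0 || bit >= ncol(X)) stop("invalid bit index ", bit, call. = FALSE)
  storage.mode(X) <- "integer"
  red <- cpp_eval_all_splits(X, cbind(y[, 1], y[, 2]), seq_len(nrow(X)),
                             as.numeric(scale), as.integer(min_leaf))
  red[bit + 1L]
}

#' Tree hyperparameters
#'
#' @param n_trees Number of bagged trees (default 100).
#' @param min_leaf Minimum records per leaf (default 5).
#' @param max_depth Maximum tree depth, `Inf` for unlimited (default).
#' @param bootstrap Draw a bootstrap sample per tree (default `TRUE`).
#' @return A `tree_params` list.
#' @export
tree_params <- function(n_trees = 100, min_leaf = 5, max_depth = Inf,
                        bootstrap = TRUE) {
  stopifnot(n_trees >= 1, min_leaf >= 1, max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees), min_leaf = as.integer(min_leaf),
                 max_depth = max_depth, bootstrap = isTRUE(bootstrap)),
            class = "tree_params")
}

#' Grow a single predictive clustering tree
#'
#' Recursive top-down induction: each node takes the bit with the maximal
#' variance reduction (ties broken toward the lowest bit index) among splits
#' leaving at least `min_leaf` records per branch; a node becomes a leaf when
#' its targets are constant within tolerance, no admissible split exists, the
#' best reduction is negative (floating point), or `max_depth` is reached.
#'
#' @param X Binary record x bit matrix (rows may repeat for bootstrap
#'   samples).
#' @param y Numeric n x 2 target matrix.
#' @param params A [tree_params()] (only `min_leaf` and `max_depth` are used).
#' @param scale Length-2 normalization scale.
#' @return An object of class `pct_tree`: parallel node vectors `split`
#'   (0-based bit, -1 at leaves), `left`, `right` (1-based node ids, 0 at
#'   leaves), `n` (record counts) and an n_nodes x 2 `pred` prototype matrix.
#' @export
grow_tree <- function(X, y, params = tree_params(), scale = c(1, 1)) {
  stopifnot(nrow(X) >= 1, nrow(X) == nrow(y))
  storage.mode(X) <- "integer"
  md <- if (is.finite(params$max_depth)) as.integer(params$max_depth) else -1L
  tr <- cpp_grow_tree(X, cbind(y[, 1], y[, 2]), seq_len(nrow(X)),
                      as.numeric(scale), params$min_leaf, md)
  tr$nbits <- ncol(X)
  class(tr) <- "pct_tree"
  tr
}

#' @export
print.pct_tree <- function(x, ...) {
  cat(sprintf("<pct_tree: %d nodes, %d leaves, %d training records>\n",
              length(x$split), sum(x$split < 0), x$n[1]))
  invisible(x)
}

.as_bit_matrix <- function(fps, nbits) {
  if (is.matrix(fps)) {
    storage.mode(fps) <- "integer"
    return(fps)
  }
  if (inherits(fps, "ecfp")) fps <- list(fps)
  bad <- vapply(fps, function(f) f$nbits != nbits, logical(1))
  if (any(bad))
    stop("fingerprint nbits does not match the model (", nbits, ")",
         call. = FALSE)
  fingerprint_matrix(fps)
}

#' Predict targets with a single tree
#'
#' Routes each compound by the split bits to a leaf and returns its
#' prototype.
#'
#' @param tree A `pct_tree`.
#' @param fps An `ecfp`, a list of them, or a binary matrix with matching
#'   number of columns.
#' @return A numeric matrix with columns `rfp`, `egfp`.
#' @export
predict_tree <- function(tree, fps) {
  X <- .as_bit_matrix(fps, tree$nbits)
  if (ncol(X) != tree$nbits)
    stop("fingerprint nbits does not match the model", call. = FALSE)
  out <- cpp_predict_tree(unclass(tree), X)
  colnames(out) <- c("rfp", "egfp")
  out
}

#' Fit a bagging ensemble of predictive clustering trees
#'
#' Draws `n_trees` bootstrap samples (size n, with replacement) from a seeded
#' generator and grows one tree per sample. Per-tree seeds are drawn up front
#' from the root seed, so the result does not depend on evaluation order;
#' identical seeds give bit-identical ensembles. With `bootstrap = FALSE`
#' every tree sees the full training set.
#'
#' @param ts A [training_set()].
#' @param params A [tree_params()].
#' @param seed Integer root seed.
#' @return An object of class `pct_ensemble`: `trees`, `params`, `seed`,
#'   `scale`, `nbits`, `radius`, and the retained per-tree bootstrap
#'   indices `boot_idx`.
#' @export
fit_ensemble <- function(ts, params = tree_params(), seed = 1) {
  stopifnot(inherits(ts, "training_set"))
  n <- nrow(ts$y)
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, params$n_trees)
  trees <- vector("list", params$n_trees)
  boot <- vector("list", params$n_trees)
  for (t in seq_len(params$n_trees)) {
    set.seed(tree_seeds[t])
    idx <- if (params$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    boot[[t]] <- idx
    trees[[t]] <- grow_tree(ts$X[idx, , drop = FALSE],
                            ts$y[idx, , drop = FALSE], params, ts$scale)
  }
  structure(list(trees = trees, params = params, seed = as.integer(seed),
                 scale = ts$scale, nbits = ts$nbits, radius = ts$radius,
                 boot_idx = boot),
            class = "pct_ensemble")
}

#' @export
print.pct_ensemble <- function(x, ...) {
  cat(sprintf("<pct_ensemble: %d trees over %d bits (seed %d)>\n",
              length(x$trees), x$nbits, x$seed))
  invisible(x)
}

#' Ensemble prediction with reliability scores
#'
#' Per-target mean and population standard deviation of the individual
#' trees' predictions; the sd is the per-prediction reliability score (a
#' one-tree ensemble has sd 0).
#'
#' @param ens A `pct_ensemble`.
#' @param fps An `ecfp`, a list of them, or a binary matrix.
#' @return A tibble with columns `rfp_mean`, `egfp_mean`, `rfp_sd`,
#'   `egfp_sd`, one row per compound.
#' @export
predict_ensemble <- function(ens, fps) {
  stopifnot(inherits(ens, "pct_ensemble"))
  X <- .as_bit_matrix(fps, ens$nbits)
  if (ncol(X) != ens$nbits)
    stop("fingerprint nbits does not match the model (", ens$nbits, ")",
         call. = FALSE)
  out <- cpp_predict_forest(lapply(ens$trees, unclass), X)
  tibble::tibble(rfp_mean = out$mean[, 1], egfp_mean = out$mean[, 2],
                 rfp_sd = out$sd[, 1], egfp_sd = out$sd[, 2])
}

# --- JSON serialization ----------------------------------------------------

#' Write an ensemble to JSON
#'
#' The schema stores each tree as parallel node arrays (`split`, `left`,
#' `right`, `n`, `pred_rfp`, `pred_egfp`) plus the ensemble's parameters,
#' scale, seed and bootstrap indices, so trained models can be reloaded by
#' the screening CLI.
#'
#' @param ens A `pct_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "pct_ensemble"))
  obj <- list(
    format = "phenoscreen-ensemble-1",
    nbits = ens$nbits, radius = ens$radius, seed = ens$seed,
    scale = as.numeric(ens$scale),
    params = unclass(ens$params),
    trees = lapply(ens$trees, function(tr) list(
      split = tr$split, left = tr$left, right = tr$right, n = tr$n,
      pred_rfp = tr$pred[, 1], pred_egfp = tr$pred[, 2])),
    boot_idx = ens$boot_idx
  )
  obj$params$max_depth <- if (is.finite(obj$params$max_depth))
    obj$params$max_depth else "unlimited"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param path JSON file path.
#' @return A `pct_ensemble`.
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "phenoscreen-ensemble-1"))
    stop("not a phenoscreen ensemble file: ", path, call. = FALSE)
  md <- obj$params$max_depth
  params <- tree_params(obj$params$n_trees, obj$params$min_leaf,
                        if (identical(md, "unlimited")) Inf else md,
                        obj$params$bootstrap)
  trees <- lapply(seq_len(nrow(obj$trees)), function(i) {
    tr <- list(split = as.integer(obj$trees$split[[i]]),
               left = as.integer(obj$trees$left[[i]]),
               right = as.integer(obj$trees$right[[i]]),
               n = as.integer(obj$trees$n[[i]]),
               pred = cbind(obj$trees$pred_rfp[[i]], obj$trees$pred_egfp[[i]]))
    tr$nbits <- obj$nbits
    class(tr) <- "pct_tree"
    tr
  })
  structure(list(trees = trees, params = params, seed = as.integer(obj$seed),
                 scale = as.numeric(obj$scale), nbits = as.integer(obj$nbits),
                 radius = as.integer(obj$radius),
                 boot_idx = lapply(obj$boot_idx, as.integer)),
            class = "pct_ensemble")
}
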