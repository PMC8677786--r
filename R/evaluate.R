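# Cross-validated performance estimation and reliability diagnostics.

#' Mean absolute error
#'
#' @param predictions,truths Equal-length numeric vectors.
#' @return Mean of `|prediction - truth|`.
#' @export
mae <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths))
    stop("predictions and truths must be non-empty and of equal length",
         call. = FALSE)
  mean(abs(predictions - truths))
}

# seeded shuffle, then contiguous blocks; the remainder is spread one record
# per fold starting from the first fold (folds differ in size by at most 1)
.fold_assignment <- function(n, k, perm) {
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), times = sizes)
  folds
}

#' k-fold cross-validated mean absolute error
#'
#' Records are shuffled with a seeded permutation and assigned to contiguous
#' folds; for each fold an ensemble is fitted on the remainder and the
#' held-out compounds are predicted. The aggregate MAE per target pools the
#' absolute errors of all held-out predictions (fold-level MAEs are reported
#' alongside). Identical seeds give bit-identical reports.
#'
#' @param ts A [training_set()].
#' @param params A [tree_params()].
#' @param k Number of folds (default 10).
#' @param seed Integer root seed; per-fold model seeds are derived from it.
#' @return An object of class `cv_report`: `k`, integer fold assignment
#'   `folds`, tibble `per_fold` (fold, n, mae_rfp, mae_egfp), named vector
#'   `mae` (pooled, per target), and tibble `per_compound` with predictions,
#'   truths, absolute errors and per-target reliability sds.
#' @export
kfold_mae <- function(ts, params = tree_params(), k = 10, seed = 1) {
  stopifnot(inherits(ts, "training_set"), k >= 2)
  n <- nrow(ts$y)
  if (k > n) stop("k = ", k, " exceeds the number of records (", n, ")",
                  call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  fold_seeds <- sample.int(.Machine$integer.max, k)
  folds <- .fold_assignment(n, k, perm)

  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    sub <- training_set(ts$ids[train], ts$fps[train],
                        ts$y[train, 1], ts$y[train, 2])
    ens <- fit_ensemble(sub, params, seed = fold_seeds[f])
    pr <- predict_ensemble(ens, ts$X[test, , drop = FALSE])
    rows[[f]] <- tibble::tibble(
      id = ts$ids[test], fold = f,
      rfp_pred = pr$rfp_mean, egfp_pred = pr$egfp_mean,
      rfp_true = ts$y[test, 1], egfp_true = ts$y[test, 2],
      rfp_sd = pr$rfp_sd, egfp_sd = pr$egfp_sd,
      rfp_abs_err = abs(pr$rfp_mean - ts$y[test, 1]),
      egfp_abs_err = abs(pr$egfp_mean - ts$y[test, 2]))
  }
  per_compound <- do.call(rbind, rows)
  per_fold <- tibble::tibble(
    fold = seq_len(k),
    n = vapply(seq_len(k), function(f) sum(per_compound$fold == f), integer(1)),
    mae_rfp = vapply(seq_len(k), function(f)
      mean(per_compound$rfp_abs_err[per_compound$fold == f]), numeric(1)),
    mae_egfp = vapply(seq_len(k), function(f)
      mean(per_compound$egfp_abs_err[per_compound$fold == f]), numeric(1)))
  structure(list(
    k = as.integer(k), folds = folds, per_fold = per_fold,
    mae = c(rfp = mean(per_compound$rfp_abs_err),
            egfp = mean(per_compound$egfp_abs_err)),
    per_compound = per_compound, seed = as.integer(seed)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("MAE RFP=%.4f EGFP=%.4f\n", x$mae["rfp"], x$mae["egfp"]))
  cat(sprintf("  (%d-fold cross-validation, %d held-out predictions)\n",
              x$k, nrow(x$per_compound)))
  invisible(x)
}

#' Rank correlation between reliability score and prediction error
#'
#' Spearman correlation between the per-prediction tree-disagreement sd and
#' the absolute prediction error across held-out compounds. A positive
#' coefficient means less-reliable predictions (higher sd) tend to have
#' larger errors; ties are handled by mid-ranks.
#'
#' @param report A `cv_report`.
#' @param target `"rfp"` or `"egfp"`.
#' @return A list with `target`, the Spearman coefficient `rho`, and the
#'   number of pairs `n`.
#' @export
reliability_error_correlation <- function(report, target = c("rfp", "egfp")) {
  stopifnot(inherits(report, "cv_report"))
  target <- match.arg(target)
  sd <- report$per_compound[[paste0(target, "_sd")]]
  err <- report$per_compound[[paste0(target, "_abs_err")]]
  if (length(sd) < 3)
    stop("need at least 3 held-out predictions", call. = FALSE)
  if (max(sd) - min(sd) <= 0)
    stop("reliability sd is constant; the rank correlation is undefined",
         call. = FALSE)
  list(target = target,
       rho = stats::cor(sd, err, method = "spearman"),
       n = length(sd))
}

#' Write a cross-validation report to CSV
#'
#' One row per held-out compound, plus the pooled MAEs echoed in a JSON
#' sidecar when `json_path` is given.
#'
#' @param report A `cv_report`.
#' @param path CSV output path.
#' @param json_path Optional JSON summary path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  utils::write.csv(as.data.frame(report$per_compound), path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      k = report$k, seed = report$seed,
      mae_rfp = unname(report$mae["rfp"]),
      mae_egfp = unname(report$mae["egfp"]),
      per_fold = report$per_fold), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
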