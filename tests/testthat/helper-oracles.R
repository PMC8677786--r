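# Brute-force oracles and small constructed fixtures, independent of the
# package's computation paths.

# bit-by-bit Tanimoto over logical vectors
oracle_tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# population variance
pvar <- function(x) mean((x - mean(x))^2)

# normalized multi-target variance of a record set, straight from the formula
oracle_variance <- function(y, scale) {
  sum(apply(y, 2, pvar) / scale^2)
}

# variance reduction of splitting on a 0-based bit, by explicit partition
oracle_reduction <- function(X, y, bit, scale, min_leaf = 1) {
  on <- X[, bit + 1L] == 1
  n1 <- sum(on); n0 <- sum(!on); n <- nrow(X)
  if (n1 < min_leaf || n0 < min_leaf) return(-Inf)
  oracle_variance(y, scale) -
    (n1 / n) * oracle_variance(y[on, , drop = FALSE], scale) -
    (n0 / n) * oracle_variance(y[!on, , drop = FALSE], scale)
}

# forge an ecfp object directly from 0-based bit positions
make_fp <- function(bits, nbits = 64, radius = 2) {
  structure(list(nbits = as.integer(nbits),
                 bits = sort(unique(as.integer(bits))),
                 radius = as.integer(radius)),
            class = "ecfp")
}

# random fingerprint list + training set over `nbits` bits
random_training_set <- function(n, nbits, seed, rfp = NULL, egfp = NULL) {
  set.seed(seed)
  fps <- lapply(seq_len(n), function(i)
    make_fp(sample(0:(nbits - 1), rbinom(1, nbits, 0.3)), nbits))
  if (is.null(rfp)) rfp <- runif(n, 0.4, 1.4)
  if (is.null(egfp)) egfp <- runif(n, 0.4, 1.4)
  training_set(sprintf("T%03d", seq_len(n)), fps, rfp, egfp)
}

# forge a minimal cv_report for the reliability diagnostic
make_cv_report <- function(sd, err, target = "rfp") {
  pc <- tibble::tibble(id = sprintf("c%d", seq_along(sd)), fold = 1L)
  pc[[paste0(target, "_sd")]] <- sd
  pc[[paste0(target, "_abs_err")]] <- err
  other <- setdiff(c("rfp", "egfp"), target)
  pc[[paste0(other, "_sd")]] <- rep(0, length(sd))
  pc[[paste0(other, "_abs_err")]] <- rep(0, length(sd))
  structure(list(k = 1L, folds = rep(1L, length(sd)), per_fold = NULL,
                 mae = c(rfp = mean(err), egfp = 0), per_compound = pc,
                 seed = 0L),
            class = "cv_report")
}
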