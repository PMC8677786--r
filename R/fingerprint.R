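# Extended connectivity fingerprints (Morgan-style iterative neighbourhood
# hashing), Tanimoto similarity, and stable compound identity keys.
#
# All identifiers are 32-bit FNV-1a hashes (computed in C++), so fingerprints
# are deterministic across platforms and process runs. Identical substructure
# environments arising in the same iteration are not deduplicated before
# folding: folding into a binary vector collapses them anyway.

#' Initial-iteration atom identifier
#'
#' Hash of the tuple (atomic number, heavy-atom degree, attached-H count,
#' formal charge, in-ring flag). Atoms with equal tuples receive equal
#' identifiers; this is the iteration-0 identifier of the fingerprint
#' algorithm.
#'
#' @param mol A `molecule`.
#' @param atom_index 1-based atom index.
#' @return A numeric scalar holding an unsigned 32-bit hash.
#' @export
atom_invariant <- function(mol, atom_index) {
  stopifnot(atom_index >= 1, atom_index <= mol$natoms)
  i <- atom_index
  cpp_fnv1a(c(mol$anum[i], mol$degree[i], mol$hcount[i],
              mol$charge[i] %% 4294967296, as.integer(mol$in_ring[i])))
}

.ecfp_iterations <- function(mol, radius) {
  init <- vapply(seq_len(mol$natoms), function(i) atom_invariant(mol, i),
                 numeric(1))
  edges <- cbind(mol$bond_from, mol$bond_to)
  storage.mode(edges) <- "integer"
  cpp_ecfp_iterations(mol$natoms, init, edges, as.integer(mol$bond_order),
                      as.integer(radius))
}

#' Unfolded fingerprint identifiers per iteration
#'
#' Returns the raw 32-bit substructure identifiers produced at each
#' neighbourhood iteration 0..radius, before folding. The cumulative
#' identifier set is monotone in the radius.
#'
#' @inheritParams ecfp
#' @return A list of numeric vectors, one per iteration (length `radius + 1`).
#' @export
ecfp_identifiers <- function(mol, radius = 2) {
  stopifnot(inherits(mol, "molecule"), radius >= 0)
  if (mol$natoms == 0) stop("empty molecule", call. = FALSE)
  .ecfp_iterations(mol, radius)
}

#' Extended connectivity fingerprint
#'
#' Iteration 0 assigns each atom its [atom_invariant()]; iteration r hashes
#' the atom's previous identifier together with the sorted list of
#' (bond order, neighbour's previous identifier) pairs. All identifiers from
#' iterations 0..radius are folded into `[0, nbits)` by modulo and the
#' corresponding bits set. The result is invariant under atom relabelling.
#'
#' @param mol A `molecule`.
#' @param radius Number of neighbourhood iterations (default 2, ECFP4-style).
#' @param nbits Folded vector length (default 2048).
#' @return An object of class `ecfp`: list with `nbits`, sorted 0-based
#'   set-bit positions `bits`, and `radius`.
#' @examples
#' fp <- ecfp(parse_smiles("CCO"))
#' tanimoto(fp, fp)
#' @export
ecfp <- function(mol, radius = 2, nbits = 2048) {
  stopifnot(inherits(mol, "molecule"), radius >= 0, nbits >= 2)
  if (mol$natoms == 0) stop("empty molecule", call. = FALSE)
  ids <- unlist(.ecfp_iterations(mol, radius), use.names = FALSE)
  structure(list(nbits = as.integer(nbits),
                 bits = sort(unique(as.integer(ids %% nbits))),
                 radius = as.integer(radius)),
            class = "ecfp")
}

#' @export
print.ecfp <- function(x, ...) {
  cat(sprintf("<ecfp radius %d, %d/%d bits set>\n", x$radius, length(x$bits),
              x$nbits))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|` over set-bit positions. When both
#' fingerprints are empty the similarity is 0 by convention.
#'
#' @param a,b `ecfp` fingerprints with equal `nbits`.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "ecfp"), inherits(b, "ecfp"))
  if (a$nbits != b$nbits)
    stop("fingerprint lengths differ: ", a$nbits, " vs ", b$nbits,
         call. = FALSE)
  u <- length(union(a$bits, b$bits))
  if (u == 0) return(0)
  length(intersect(a$bits, b$bits)) / u
}

#' Hex encoding of a fingerprint bit vector
#'
#' @param fp An `ecfp`.
#' @return A lowercase hex string of the packed bit vector (bit 0 is the
#'   lowest bit of the first byte).
#' @export
fp_hex <- function(fp) {
  stopifnot(inherits(fp, "ecfp"), all(fp$bits >= 0), all(fp$bits < fp$nbits))
  nbytes <- ceiling(fp$nbits / 8)
  v <- logical(nbytes * 8)
  v[fp$bits + 1L] <- TRUE
  paste(as.character(packBits(v, type = "raw")), collapse = "")
}

#' Canonical identity key of a fingerprint
#'
#' Equal fingerprints (same radius, length, and bit set) map to equal keys;
#' the key is stable across runs and platforms. Used to exclude training
#' compounds from candidate lists.
#'
#' @param fp An `ecfp`.
#' @return A character scalar.
#' @export
compound_key <- function(fp) {
  stopifnot(inherits(fp, "ecfp"))
  paste0("r", fp$radius, ":", fp$nbits, ":", fp_hex(fp))
}

#' Stack fingerprints into a binary matrix
#'
#' @param fps A list of `ecfp` with identical `nbits`.
#' @return An integer 0/1 matrix with one row per fingerprint.
#' @export
fingerprint_matrix <- function(fps) {
  stopifnot(length(fps) >= 1)
  nbits <- fps[[1]]$nbits
  ok <- vapply(fps, function(f) f$nbits == nbits, logical(1))
  if (!all(ok)) stop("fingerprints have differing nbits", call. = FALSE)
  X <- matrix(0L, nrow = length(fps), ncol = nbits)
  for (i in seq_along(fps)) X[i, fps[[i]]$bits + 1L] <- 1L
  X
}
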