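# SMILES ingestion and the heavy-atom molecular graph.
#
# The supported dialect covers the organic subset (B C N O P S F Cl Br I),
# aromatic lowercase atoms, branches, ring-closure digits 1-9 and %nn (with
# reuse after closure), bracket atoms with explicit H counts and charges, and
# explicit bonds - = # :. Stereo tokens (/ \ @ @@) are accepted and ignored:
# the fingerprint iterations are achiral. Dot-disconnected inputs are
# rejected.

.organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_organic <- c("b", "c", "n", "o", "p", "s")

# smallest admissible valence(s) used to resolve implicit hydrogens on bare
# organic-subset atoms (bracket atoms carry explicit H counts)
.valences <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                  S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Si = 14,
  P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29, Zn = 30,
  As = 33, Se = 34, Br = 35, I = 53
)

#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph: elements, formal charges, attached-hydrogen
#' counts (explicit in brackets, otherwise resolved by standard valence
#' rules), bond orders (1, 2, 3, or aromatic) and ring-membership flags
#' (an atom is ring-flagged when it is incident to a bond that lies on a
#' cycle).
#'
#' @param text A single SMILES string (restricted dialect, see Details).
#' @param id Compound identifier carried on the molecule; defaults to `text`.
#'
#' @details Bonds between two aromatic atoms default to the aromatic order
#'   token; aromatic bond orders count 1.5 toward the valence sum when
#'   resolving implicit hydrogens. Stereochemistry tokens are ignored.
#'   Malformed input (unclosed ring bond or branch, unknown element, dangling
#'   bond) raises an error naming the offending position.
#'
#' @return An object of class `molecule`: a list with `id`, `natoms`,
#'   per-atom vectors `element`, `anum`, `charge`, `hcount`, `aromatic`,
#'   `in_ring`, `degree`, bond vectors `bond_from`, `bond_to`, `bond_order`
#'   (order 4 codes aromatic), and `source_text`.
#' @examples
#' m <- parse_smiles("CCO")
#' m$hcount # 3 2 1
#' @export
parse_smiles <- function(text, id = text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty SMILES string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  nch <- length(chars)

  perr <- function(pos, msg)
    stop(sprintf("SMILES parse error at position %d in \"%s\": %s",
                 pos, text, msg), call. = FALSE)

  element <- character(0); charge <- integer(0); hexp <- integer(0)
  arom <- logical(0); bracket <- logical(0)
  bond_from <- integer(0); bond_to <- integer(0); bond_order <- integer(0)

  prev <- NA_integer_       # atom the next bond attaches to
  branch <- integer(0)      # stack of prev atoms at '('
  pend <- NA_integer_       # explicit order of the next bond
  pend_pos <- NA_integer_
  ring_open <- list()       # ring number -> list(atom, order, pos)

  add_bond <- function(a, b, ord, pos) {
    if (a == b) perr(pos, "ring bond closes onto its own atom")
    if (any((bond_from == a & bond_to == b) | (bond_from == b & bond_to == a)))
      perr(pos, "duplicate bond between the same atoms")
    if (is.na(ord)) ord <- if (arom[a] && arom[b]) 4L else 1L
    bond_from <<- c(bond_from, a)
    bond_to <<- c(bond_to, b)
    bond_order <<- c(bond_order, ord)
  }

  add_atom <- function(el, is_arom, ch, hh, is_bracket, pos) {
    element <<- c(element, el)
    arom <<- c(arom, is_arom)
    charge <<- c(charge, ch)
    hexp <<- c(hexp, hh)
    bracket <<- c(bracket, is_bracket)
    idx <- length(element)
    if (!is.na(prev)) {
      add_bond(prev, idx, pend, pos)
      pend <<- NA_integer_
    } else if (!is.na(pend)) {
      perr(pend_pos, "bond symbol with no preceding atom")
    }
    prev <<- idx
  }

  close_ring <- function(num, pos) {
    key <- as.character(num)
    if (is.na(prev)) perr(pos, "ring-closure digit before any atom")
    if (is.null(ring_open[[key]])) {
      ring_open[[key]] <<- list(atom = prev, order = pend, pos = pos)
    } else {
      op <- ring_open[[key]]
      ord <- pend
      if (!is.na(op$order)) {
        if (!is.na(ord) && ord != op$order)
          perr(pos, "conflicting bond orders on ring closure")
        ord <- op$order
      }
      add_bond(op$atom, prev, ord, pos)
      ring_open[[key]] <<- NULL
    }
    pend <<- NA_integer_
  }

  i <- 1L
  while (i <= nch) {
    ch <- chars[i]
    two <- if (i < nch) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE, 0L, NA_integer_, FALSE, i); i <- i + 2L
    } else if (ch %in% .organic) {
      add_atom(ch, FALSE, 0L, NA_integer_, FALSE, i); i <- i + 1L
    } else if (ch %in% .aromatic_organic) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, FALSE, i); i <- i + 1L
    } else if (ch == "[") {
      res <- .parse_bracket(chars, i, perr)
      add_atom(res$el, res$arom, res$charge, res$h, TRUE, i)
      i <- res$next_i
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.na(pend)) perr(i, "two consecutive bond symbols")
      pend <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L,
                     "/" = 1L, "\\" = 1L)
      pend_pos <- i
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nch || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        perr(i, "'%' must be followed by two digits")
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == "(") {
      if (is.na(prev)) perr(i, "branch opened before any atom")
      branch <- c(branch, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(branch) == 0L) perr(i, "unmatched ')'")
      if (!is.na(pend)) perr(i, "dangling bond before ')'")
      prev <- branch[length(branch)]
      branch <- branch[-length(branch)]
      i <- i + 1L
    } else if (ch == ".") {
      perr(i, "disconnected components ('.') are not supported")
    } else {
      perr(i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(branch) > 0L) perr(nch, "unclosed branch '('")
  if (!is.na(pend)) perr(pend_pos, "dangling bond at end of input")
  if (length(ring_open) > 0L) {
    op <- ring_open[[1L]]
    perr(op$pos, "unclosed ring bond")
  }
  if (length(element) == 0L) perr(1L, "no atoms")

  natoms <- length(element)
  degree <- tabulate(c(bond_from, bond_to), nbins = natoms)

  # implicit hydrogens for bare organic-subset atoms; aromatic orders count 1.5
  ordval <- c(1, 2, 3, 1.5)
  bondsum <- numeric(natoms)
  if (length(bond_from)) {
    bs <- ordval[bond_order]
    bondsum <- vapply(seq_len(natoms), function(a)
      sum(bs[bond_from == a | bond_to == a]), numeric(1))
  }
  hcount <- hexp
  for (a in seq_len(natoms)) {
    if (!is.na(hcount[a])) next
    vals <- .valences[[element[a]]]
    need <- ceiling(bondsum[a] - 1e-9)
    # aromatic atoms stay at their default valence (no hypervalent promotion)
    if (arom[a]) vals <- vals[1]
    fit <- vals[vals >= need]
    hcount[a] <- if (length(fit)) as.integer(fit[1] - need) else 0L
  }

  anum <- .atomic_numbers[element]
  if (anyNA(anum)) perr(1L, sprintf("unknown element '%s'",
                                    element[which(is.na(anum))[1]]))

  structure(list(
    id = id, natoms = natoms, element = element,
    anum = unname(as.integer(anum)), charge = charge, hcount = hcount,
    aromatic = arom, in_ring = .ring_atoms(natoms, bond_from, bond_to),
    degree = degree, bond_from = bond_from, bond_to = bond_to,
    bond_order = bond_order, source_text = text
  ), class = "molecule")
}

# bracket atom: [isotope? symbol chiral? H(count)? charge? :class?]
.parse_bracket <- function(chars, start, perr) {
  i <- start + 1L
  nch <- length(chars)
  take_digits <- function(i) {
    j <- i
    while (j <= nch && grepl("^[0-9]$", chars[j])) j <- j + 1L
    list(num = if (j > i) as.integer(paste(chars[i:(j - 1L)], collapse = "")) else NA_integer_,
         next_i = j)
  }
  i <- take_digits(i)$next_i  # isotope label ignored
  if (i > nch) perr(start, "unterminated bracket atom")
  el <- NULL; is_arom <- FALSE
  ch <- chars[i]
  if (grepl("^[A-Z]$", ch)) {
    two <- if (i < nch) paste0(ch, chars[i + 1L]) else ""
    if (two %in% names(.atomic_numbers)) {
      el <- two; i <- i + 2L
    } else {
      el <- ch; i <- i + 1L
    }
  } else if (ch %in% .aromatic_organic) {
    el <- toupper(ch); is_arom <- TRUE; i <- i + 1L
  } else {
    perr(i, sprintf("unknown element '%s' in bracket", ch))
  }
  if (!el %in% names(.atomic_numbers))
    perr(i - 1L, sprintf("unknown element '%s' in bracket", el))
  while (i <= nch && chars[i] == "@") i <- i + 1L  # chirality ignored
  h <- 0L
  if (i <= nch && chars[i] == "H") {
    d <- take_digits(i + 1L)
    h <- if (is.na(d$num)) 1L else d$num
    i <- d$next_i
  }
  chg <- 0L
  if (i <= nch && chars[i] %in% c("+", "-")) {
    sign <- if (chars[i] == "+") 1L else -1L
    reps <- 1L
    j <- i + 1L
    while (j <= nch && chars[j] == chars[i]) { reps <- reps + 1L; j <- j + 1L }
    d <- take_digits(j)
    chg <- if (!is.na(d$num)) sign * d$num else sign * reps
    i <- d$next_i
  }
  if (i <= nch && chars[i] == ":") i <- take_digits(i + 1L)$next_i
  if (i > nch || chars[i] != "]") perr(start, "unterminated bracket atom")
  list(el = el, arom = is_arom, charge = chg, h = h, next_i = i + 1L)
}

# an atom is in a ring iff it is an endpoint of a non-bridge edge
.ring_atoms <- function(natoms, from, to) {
  flags <- rep(FALSE, natoms)
  if (length(from) == 0L) return(flags)
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = natoms,
                          directed = FALSE)
  cyc <- setdiff(seq_along(from), as.integer(igraph::bridges(g)))
  flags[unique(c(from[cyc], to[cyc]))] <- TRUE
  flags
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d heavy atoms, %d bonds, %d in rings>\n",
              x$id, x$natoms, length(x$bond_from), sum(x$in_ring)))
  invisible(x)
}

#' Reorder the atoms of a molecule
#'
#' Relabels atoms by a permutation while preserving the graph; used to check
#' that fingerprints are invariant under atom input order.
#'
#' @param mol A `molecule`.
#' @param perm A permutation of `seq_len(mol$natoms)`.
#' @return A `molecule` with atoms reordered.
#' @export
permute_molecule <- function(mol, perm) {
  stopifnot(sort(perm) == seq_len(mol$natoms))
  inv <- order(perm)
  out <- mol
  for (f in c("element", "anum", "charge", "hcount", "aromatic", "in_ring",
              "degree"))
    out[[f]] <- mol[[f]][perm]
  out$bond_from <- inv[mol$bond_from]
  out$bond_to <- inv[mol$bond_to]
  out$source_text <- NULL
  out
}
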