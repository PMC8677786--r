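# Virtual screening and hit prioritization: predict over a candidate
# library, apply the activity (>= 25% predicted alpha-SMA reduction) and
# reliability filters, exclude training compounds, and group surviving hits
# by nearest reference drug.

#' Screening configuration
#'
#' @param reduction_threshold Minimum predicted fractional RFP reduction for
#'   a hit (default 0.25, i.e. predicted RFP <= 0.75 of control); boundary
#'   inclusive.
#' @param control_level Untreated-control intensity (default 1, fold-over-
#'   control scale).
#' @param reliability_quantile A compound passes the reliability filter when
#'   the configured target's tree-sd is at or below this quantile of the sd
#'   distribution over the whole prediction set (default 0.5: keep the more
#'   reliable half).
#' @param similarity_cutoff Tanimoto cutoff below which a hit is labelled
#'   `"other"` in the grouping step (default 0.4).
#' @param reliability_target Which sd the reliability filter uses: `"rfp"`
#'   (default, the thresholded phenotype), `"egfp"`, or `"both"` (must pass
#'   on each).
#' @param exclude_labels Optional reference-group labels to drop from the
#'   final hit list on pharmacological grounds (e.g. corticosteroids); empty
#'   by default.
#' @return A `screen_config` list.
#' @export
screen_config <- function(reduction_threshold = 0.25, control_level = 1,
                          reliability_quantile = 0.5, similarity_cutoff = 0.4,
                          reliability_target = c("rfp", "egfp", "both"),
                          exclude_labels = character(0)) {
  stopifnot(reduction_threshold > 0, reduction_threshold < 1,
            reliability_quantile > 0, reliability_quantile <= 1,
            similarity_cutoff >= 0, similarity_cutoff <= 1)
  structure(list(reduction_threshold = reduction_threshold,
                 control_level = control_level,
                 reliability_quantile = reliability_quantile,
                 similarity_cutoff = similarity_cutoff,
                 reliability_target = match.arg(reliability_target),
                 exclude_labels = as.character(exclude_labels)),
            class = "screen_config")
}

#' Reference drug panel
#'
#' An ordered panel of named drugs used to group hits by structural
#' similarity; the order is the tie-break for equal similarities.
#'
#' @param names Unique drug names.
#' @param smiles SMILES strings (parsed with the package dialect).
#' @param approved Logical: reference has reached clinical approval.
#' @param in_training Logical: reference was part of the training screen
#'   library.
#' @param radius,nbits Fingerprint parameters.
#' @return An object of class `reference_set`: tibble `table` (name, smiles,
#'   approved, in_training) plus parallel `mols` and `fps` lists.
#' @export
reference_set <- function(names, smiles, approved = TRUE,
                          in_training = FALSE, radius = 2, nbits = 2048) {
  stopifnot(length(names) >= 1, length(smiles) == length(names))
  if (anyDuplicated(names)) stop("reference names must be unique", call. = FALSE)
  n <- length(names)
  approved <- rep_len(as.logical(approved), n)
  in_training <- rep_len(as.logical(in_training), n)
  mols <- mapply(parse_smiles, smiles, names, SIMPLIFY = FALSE)
  fps <- lapply(mols, ecfp, radius = radius, nbits = nbits)
  structure(list(table = tibble::tibble(name = as.character(names),
                                        smiles = as.character(smiles),
                                        approved = approved,
                                        in_training = in_training),
                 mols = unname(mols), fps = unname(fps)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set: %d drugs (%d approved, %d in training library)>\n",
              nrow(x$table), sum(x$table$approved), sum(x$table$in_training)))
  invisible(x)
}

#' Predict a candidate library with a trained ensemble
#'
#' One prediction per library compound, in input order. Compounds whose
#' fingerprint length does not match the model are skipped (collected in the
#' `skipped` field and reported via a warning); duplicate ids are predicted
#' but flagged with a warning.
#'
#' @param ens A `pct_ensemble`.
#' @param ids Compound identifiers.
#' @param fps List of `ecfp` fingerprints, parallel to `ids`.
#' @return An object of class `screen_predictions`: tibble `table` with
#'   columns `id`, `rfp_mean`, `egfp_mean`, `rfp_sd`, `egfp_sd`, `key`
#'   (compound identity key); list `fps` parallel to the rows; character
#'   vector `skipped`.
#' @export
screen_library <- function(ens, ids, fps) {
  stopifnot(inherits(ens, "pct_ensemble"), length(ids) == length(fps))
  ids <- as.character(ids)
  ok <- vapply(fps, function(f) f$nbits == ens$nbits, logical(1))
  skipped <- ids[!ok]
  if (length(skipped) > 0)
    warning(length(skipped), " compound(s) skipped: fingerprint length ",
            "does not match the model", call. = FALSE)
  if (anyDuplicated(ids[ok]))
    warning("duplicate compound ids in the library; all are predicted",
            call. = FALSE)
  if (!any(ok)) {
    tab <- tibble::tibble(id = character(0), rfp_mean = numeric(0),
                          egfp_mean = numeric(0), rfp_sd = numeric(0),
                          egfp_sd = numeric(0), key = character(0))
    return(structure(list(table = tab, fps = list(), skipped = skipped),
                     class = "screen_predictions"))
  }
  fps_ok <- fps[ok]
  pr <- predict_ensemble(ens, fps_ok)
  tab <- tibble::tibble(id = ids[ok], pr,
                        key = vapply(fps_ok, compound_key, character(1)))
  structure(list(table = tab, fps = fps_ok, skipped = skipped),
            class = "screen_predictions")
}

#' @export
print.screen_predictions <- function(x, ...) {
  cat(sprintf("<screen_predictions: %d compounds (%d skipped)>\n",
              nrow(x$table), length(x$skipped)))
  invisible(x)
}

#' Apply activity and reliability filters to screen predictions
#'
#' A compound passes activity when its predicted RFP mean is at or below
#' `(1 - reduction_threshold) * control_level` (the paper's ">= 25% alpha-SMA
#' reduction" rule, boundary inclusive). It passes reliability when the
#' configured target's tree-sd is at or below the configured quantile of
#' that sd over the full prediction set; with all sds equal every compound
#' passes. All compounds are retained with audit flags (`passed_novelty`
#' starts `TRUE` and is refined by [remove_training_overlap()]); [hits()]
#' returns the passing subset.
#'
#' @param sp A `screen_predictions`.
#' @param cfg A [screen_config()].
#' @return A `screen_predictions` with logical columns `passed_activity`,
#'   `passed_reliability`, `passed_novelty` added to `table`.
#' @export
filter_hits <- function(sp, cfg = screen_config()) {
  stopifnot(inherits(sp, "screen_predictions"), inherits(cfg, "screen_config"))
  tab <- sp$table
  if (nrow(tab) == 0) stop("no predictions to filter", call. = FALSE)
  tab$passed_activity <-
    tab$rfp_mean <= (1 - cfg$reduction_threshold) * cfg$control_level
  pass_q <- function(sds)
    sds <= stats::quantile(sds, cfg$reliability_quantile, names = FALSE)
  tab$passed_reliability <- switch(cfg$reliability_target,
    rfp = pass_q(tab$rfp_sd),
    egfp = pass_q(tab$egfp_sd),
    both = pass_q(tab$rfp_sd) & pass_q(tab$egfp_sd))
  tab$passed_novelty <- TRUE
  sp$table <- tab
  sp$config <- cfg
  sp
}

#' Compounds passing every filter
#'
#' @param sp A filtered `screen_predictions`.
#' @return The rows of `sp$table` with all of `passed_activity`,
#'   `passed_reliability` and `passed_novelty` `TRUE`.
#' @export
hits <- function(sp) {
  stopifnot(inherits(sp, "screen_predictions"),
            "passed_activity" %in% names(sp$table))
  tab <- sp$table
  tab[tab$passed_activity & tab$passed_reliability & tab$passed_novelty, ,
      drop = FALSE]
}

#' Exclude training compounds from the candidate list
#'
#' Marks `passed_novelty = FALSE` for any candidate whose compound identity
#' key equals a training compound's key, and drops candidate-internal key
#' duplicates (first occurrence kept; a message reports the count).
#'
#' @param sp A filtered `screen_predictions`.
#' @param ts A [training_set()] with comparable fingerprints.
#' @return The updated `screen_predictions`.
#' @export
remove_training_overlap <- function(sp, ts) {
  stopifnot(inherits(sp, "screen_predictions"))
  dup <- duplicated(sp$table$key)
  if (any(dup)) {
    message(sum(dup), " duplicate candidate fingerprint(s) dropped ",
            "(first occurrence kept)")
    sp$table <- sp$table[!dup, , drop = FALSE]
    sp$fps <- sp$fps[!dup]
  }
  train_keys <- if (inherits(ts, "training_set") && length(ts$fps))
    vapply(ts$fps, compound_key, character(1)) else character(0)
  sp$table$passed_novelty <- !(sp$table$key %in% train_keys)
  sp
}

#' Group hits by their nearest reference drug
#'
#' For each hit, the best Tanimoto similarity over the panel is computed;
#' the hit is labelled with the maximizing reference's name when the best
#' similarity reaches the cutoff, else `"other"`. Ties are broken by panel
#' order.
#'
#' @param sp A filtered `screen_predictions` (grouping operates on [hits()]).
#' @param refs A [reference_set()].
#' @param tau Tanimoto cutoff (defaults to the config's `similarity_cutoff`,
#'   else 0.4).
#' @return A tibble with columns `id`, `group`, `best_tanimoto`,
#'   `reference_approved` (NA for `"other"`).
#' @export
group_by_reference <- function(sp, refs, tau = NULL) {
  stopifnot(inherits(sp, "screen_predictions"), inherits(refs, "reference_set"),
            "passed_activity" %in% names(sp$table))
  if (nrow(refs$table) == 0) stop("empty reference set", call. = FALSE)
  if (is.null(tau))
    tau <- if (!is.null(sp$config)) sp$config$similarity_cutoff else 0.4
  tab <- sp$table
  keep <- tab$passed_activity & tab$passed_reliability & tab$passed_novelty
  fps <- sp$fps[keep]
  ids <- tab$id[keep]
  if (length(fps) == 0) {
    return(tibble::tibble(id = character(0), group = character(0),
                          best_tanimoto = numeric(0),
                          reference_approved = logical(0)))
  }
  sims <- vapply(fps, function(f)
    vapply(refs$fps, tanimoto, numeric(1), a = f),
    numeric(nrow(refs$table)))
  sims <- matrix(sims, nrow = nrow(refs$table))
  best_i <- apply(sims, 2, which.max)  # first max: earlier panel entry wins ties
  best <- sims[cbind(best_i, seq_along(best_i))]
  label <- ifelse(best >= tau, refs$table$name[best_i], "other")
  tibble::tibble(id = ids, group = label, best_tanimoto = best,
                 reference_approved = ifelse(label == "other", NA,
                                             refs$table$approved[best_i]))
}

#' Summarize a screening run
#'
#' Counts and fractions of hits per reference-group label, stage counts, and
#' the labels whose reference drug was absent from the training library (the
#' genuinely novel pharmacology the screen surfaces).
#'
#' @param assignments A tibble from [group_by_reference()].
#' @param refs Optional [reference_set()] used to flag training-library
#'   membership of the assigned labels.
#' @param stage_counts Optional named list/vector of pipeline stage counts,
#'   echoed into the report.
#' @return An object of class `screen_report`: `n_hits`, tibble `groups`
#'   (group, n, fraction), `novel_labels`, `stage_counts`.
#' @export
summarize_screen <- function(assignments, refs = NULL, stage_counts = NULL) {
  n <- nrow(assignments)
  if (n == 0) {
    groups <- tibble::tibble(group = character(0), n = integer(0),
                             fraction = numeric(0))
  } else {
    counts <- table(assignments$group)
    n_total <- n
    groups <- tibble::tibble(group = names(counts),
                             n = as.integer(counts),
                             fraction = as.integer(counts) / n_total)
    groups <- groups[order(-groups$n, groups$group), ]
  }
  novel <- character(0)
  if (!is.null(refs)) {
    assigned <- setdiff(unique(assignments$group), "other")
    novel <- assigned[!refs$table$in_training[match(assigned, refs$table$name)]]
  }
  structure(list(n_hits = n, groups = groups, novel_labels = sort(novel),
                 stage_counts = stage_counts),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report: %d hits in %d groups>\n", x$n_hits,
              nrow(x$groups)))
  if (nrow(x$groups)) print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}
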