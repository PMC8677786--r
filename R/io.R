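# Readers/writers, run configuration, and the end-to-end pipeline.

#' Read a compound table (CSV with `id` and `smiles` columns)
#'
#' Rows whose SMILES fail to parse are collected into an error sidecar CSV
#' (`<path>.errors.csv` by default); the run aborts only when more than half
#' of the rows fail.
#'
#' @param path CSV path; the header must contain `id` and `smiles`.
#' @param sidecar Path for the error sidecar (only written when failures
#'   occur).
#' @return A list with `mols` (list of `molecule`), `n_failed`, `sidecar`
#'   (path or `NA`).
#' @export
read_compound_table <- function(path, sidecar = paste0(path, ".errors.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("id", "smiles"), names(tab))
  if (length(missing))
    stop("compound table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  mols <- vector("list", nrow(tab))
  errs <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    m <- tryCatch(parse_smiles(tab$smiles[i], id = as.character(tab$id[i])),
                  error = function(e) conditionMessage(e))
    if (is.character(m)) errs[i] <- m else mols[[i]] <- m
  }
  failed <- nzchar(errs)
  if (any(failed)) {
    utils::write.csv(data.frame(id = tab$id[failed], smiles = tab$smiles[failed],
                                error = errs[failed]),
                     sidecar, row.names = FALSE)
    if (mean(failed) > 0.5)
      stop(sum(failed), "/", nrow(tab), " rows failed to parse (see ",
           sidecar, ")", call. = FALSE)
    warning(sum(failed), " row(s) failed to parse; written to ", sidecar,
            call. = FALSE)
  }
  list(mols = mols[!failed], n_failed = sum(failed),
       sidecar = if (any(failed)) sidecar else NA_character_)
}

#' Write a compound table
#'
#' @param ids,smiles Parallel vectors.
#' @param path Output CSV path.
#' @param extra Optional data frame of extra columns (e.g. rfp/egfp).
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(ids, smiles, path, extra = NULL) {
  tab <- data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
  if (!is.null(extra)) tab <- cbind(tab, extra)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference drug panel CSV
#'
#' Columns: `name,smiles,approved(0/1),in_training(0/1)`.
#'
#' @param path CSV path.
#' @param radius,nbits Fingerprint parameters.
#' @return A [reference_set()].
#' @export
read_reference_table <- function(path, radius = 2, nbits = 2048) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("name", "smiles", "approved", "in_training"), names(tab))
  if (length(missing))
    stop("reference table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  reference_set(tab$name, tab$smiles, approved = tab$approved > 0,
                in_training = tab$in_training > 0, radius = radius,
                nbits = nbits)
}

#' Write the final hit list
#'
#' Joins filter flags with group assignments for the compounds passing every
#' filter, ordered by descending predicted RFP reduction (i.e. ascending
#' predicted RFP), ties broken by id. Numeric columns are written with
#' full precision so the file round-trips through [read_hits()] without
#' loss.
#'
#' @param sp A filtered `screen_predictions`.
#' @param assignments Tibble from [group_by_reference()] (ids must match the
#'   hits of `sp`).
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_hits <- function(sp, assignments, path) {
  h <- hits(sp)
  if (!setequal(h$id, assignments$id))
    stop("hit ids and assignment ids do not match", call. = FALSE)
  tab <- merge(as.data.frame(h), as.data.frame(assignments), by = "id")
  tab <- tab[order(tab$rfp_mean, tab$id), , drop = FALSE]
  cols <- c("id", "rfp_mean", "egfp_mean", "rfp_sd", "egfp_sd",
            "passed_activity", "passed_reliability", "passed_novelty",
            "group", "best_tanimoto")
  tab <- tab[, cols]
  fmt <- tab
  for (col in c("rfp_mean", "egfp_mean", "rfp_sd", "egfp_sd", "best_tanimoto"))
    fmt[[col]] <- sprintf("%.17g", tab[[col]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(tibble::as_tibble(tab))
}

#' Read a hit list written by [write_hits()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_hits <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tab)
}

# --- run configuration -----------------------------------------------------

.default_config <- function() {
  list(
    seed = 1,
    fingerprint = list(radius = 2, nbits = 2048),
    trees = list(n_trees = 100, min_leaf = 5, max_depth = "unlimited",
                 bootstrap = TRUE),
    screen = list(reduction_threshold = 0.25, control_level = 1,
                  reliability_quantile = 0.5, similarity_cutoff = 0.4,
                  reliability_target = "rfp",
                  exclude_labels = character(0)),
    cv = list(k = 10),
    scenario = list(name = "paper-like", n_train = 640, n_library = 5000),
    paths = list(training_csv = NULL, library_csv = NULL, refs_csv = NULL,
                 model_json = NULL, out_dir = "phenoscreen-out")
  )
}

.check_keys <- function(cfg, template, where = "config") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra))
    stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      .check_keys(cfg[[k]], template[[k]], paste0(where, "$", k))
  }
  invisible(TRUE)
}

#' Build a validated run configuration
#'
#' Defaults mirror the screening study's settings (radius-2 2048-bit
#' fingerprints, 100 bagged trees with min_leaf 5, 25% reduction threshold,
#' 10-fold CV). Unknown keys are rejected.
#'
#' @param ... Named overrides, nested as in the defaults (e.g.
#'   `trees = list(n_trees = 50)`).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  over <- list(...)
  cfg <- .default_config()
  .check_keys(over, cfg)
  merge_in <- function(base, over) {
    for (k in names(over)) {
      if (is.null(over[[k]])) base[k] <- list(NULL)
      else if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
               is.list(over[[k]]))
        base[[k]] <- merge_in(base[[k]], over[[k]])
      else base[[k]] <- over[[k]]
    }
    base
  }
  cfg <- merge_in(cfg, over)
  cfg$screen$exclude_labels <- as.character(unlist(cfg$screen$exclude_labels))
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys must match the [run_config()] schema.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' Save a run configuration as YAML
#'
#' `read_run_config(save_run_config(cfg, path))` reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.cfg_tree_params <- function(cfg) {
  md <- cfg$trees$max_depth
  tree_params(cfg$trees$n_trees, cfg$trees$min_leaf,
              if (identical(md, "unlimited")) Inf else md,
              cfg$trees$bootstrap)
}

.cfg_screen_config <- function(cfg) {
  screen_config(cfg$screen$reduction_threshold, cfg$screen$control_level,
                cfg$screen$reliability_quantile, cfg$screen$similarity_cutoff,
                cfg$screen$reliability_target,
                as.character(cfg$screen$exclude_labels))
}

# --- pipeline --------------------------------------------------------------

#' Run the full virtual-screening pipeline
#'
#' Stages: load or simulate the training screen, candidate library and
#' reference panel; fit the bagging ensemble; estimate CV performance;
#' predict and filter the library; exclude training compounds; group hits by
#' nearest reference; summarize. Writes `report.json`, `hits.csv`, `cv.csv`
#' and `log.txt` under the configured output directory. Identical config and
#' seed reproduce every output byte-identically.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage messages (default `TRUE`).
#' @return The report list (stage counts, group summary, MAEs, config echo),
#'   invisibly.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_stage <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  radius <- cfg$fingerprint$radius
  nbits <- cfg$fingerprint$nbits
  seed <- cfg$seed

  t0 <- Sys.time()
  # -- data stage
  if (!is.null(cfg$paths$training_csv)) {
    raw <- utils::read.csv(cfg$paths$training_csv, stringsAsFactors = FALSE)
    missing <- setdiff(c("id", "smiles", "rfp", "egfp"), names(raw))
    if (length(missing))
      stop("training table is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    cmp <- read_compound_table(cfg$paths$training_csv)
    keep <- vapply(cmp$mols, function(m) m$id, character(1))
    raw <- raw[match(keep, as.character(raw$id)), ]
    fps <- fingerprint_library(cmp$mols, radius, nbits)
    train <- training_set(raw$id, fps, raw$rfp, raw$egfp)
    gt <- NULL
    scen_mols <- NULL
  } else {
    scen <- simulate_scenario(cfg$scenario$name, seed = seed,
                              n = cfg$scenario$n_train, nbits = nbits,
                              radius = radius)
    train <- scen$train
    gt <- scen$gt
    scen_mols <- scen$mols
  }
  if (!is.null(cfg$paths$library_csv)) {
    cmp <- read_compound_table(cfg$paths$library_csv)
    lib_mols <- cmp$mols
  } else {
    lib_mols <- sample_library(cfg$scenario$n_library,
                               default_fragment_grammar(), seed = seed + 10,
                               prefix = "LIB")
  }
  lib_fps <- fingerprint_library(lib_mols, radius, nbits)
  lib_ids <- vapply(lib_mols, function(m) m$id, character(1))
  refs <- if (!is.null(cfg$paths$refs_csv))
    read_reference_table(cfg$paths$refs_csv, radius, nbits)
  else fixture_references(radius, nbits)
  log_stage("data: %d training compounds, %d library compounds, %d references",
            nrow(train$y), length(lib_mols), nrow(refs$table))

  # -- train stage
  params <- .cfg_tree_params(cfg)
  ens <- if (!is.null(cfg$paths$model_json) && file.exists(cfg$paths$model_json))
    read_ensemble(cfg$paths$model_json)
  else fit_ensemble(train, params, seed = seed)
  if (!is.null(cfg$paths$model_json) && !file.exists(cfg$paths$model_json))
    write_ensemble(ens, cfg$paths$model_json)
  log_stage("train: %d trees over %d bits", length(ens$trees), ens$nbits)

  # -- cv stage
  cv <- kfold_mae(train, params, k = cfg$cv$k, seed = seed)
  write_cv_report(cv, file.path(out_dir, "cv.csv"))
  log_stage("cv: MAE RFP=%.4f EGFP=%.4f over %d folds", cv$mae["rfp"],
            cv$mae["egfp"], cv$k)

  # -- screen stage
  scfg <- .cfg_screen_config(cfg)
  sp <- screen_library(ens, lib_ids, lib_fps)
  sp <- filter_hits(sp, scfg)
  n_activity <- sum(sp$table$passed_activity)
  n_reliability <- sum(sp$table$passed_activity & sp$table$passed_reliability)
  log_stage("screen: %d/%d pass activity, %d also pass reliability",
            n_activity, nrow(sp$table), n_reliability)

  # -- novelty stage
  sp <- remove_training_overlap(sp, train)
  n_novel <- nrow(hits(sp))
  log_stage("novelty: %d hits after excluding training compounds", n_novel)

  # -- group stage
  assignments <- group_by_reference(sp, refs)
  if (length(scfg$exclude_labels)) {
    drop <- assignments$group %in% scfg$exclude_labels
    if (any(drop)) {
      excluded <- assignments$id[drop]
      assignments <- assignments[!drop, , drop = FALSE]
      sp$table$passed_novelty[sp$table$id %in% excluded] <- FALSE
      log_stage("group: %d hit(s) excluded by label", length(excluded))
    }
  }
  stage_counts <- list(library = nrow(sp$table) + length(sp$skipped),
                       predicted = nrow(sp$table),
                       activity_pass = n_activity,
                       reliability_pass = n_reliability,
                       novelty_pass = n_novel,
                       final = nrow(assignments))
  report <- summarize_screen(assignments, refs, stage_counts)
  log_stage("report: %d hits in %d groups", report$n_hits, nrow(report$groups))

  # -- outputs
  write_hits(sp, assignments, file.path(out_dir, "hits.csv"))
  full <- list(
    software = paste0("phenoscreen ",
                      as.character(utils::packageVersion("phenoscreen"))),
    seed = seed,
    config = unclass(cfg),
    stage_counts = stage_counts,
    cv = list(k = cv$k, mae_rfp = unname(cv$mae["rfp"]),
              mae_egfp = unname(cv$mae["egfp"])),
    groups = report$groups,
    novel_labels = report$novel_labels
  )
  jsonlite::write_json(full, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_lines <- c(log_lines, sprintf("elapsed: %.1f s",
                                    as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(report = report, cv = cv, ensemble = ens, predictions = sp,
                 assignments = assignments, ground_truth = gt,
                 library_fps = lib_fps, train = train, json = full))
}
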