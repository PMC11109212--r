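#' Write a multimodal cohort as delimited text
#'
#' One CSV per modality (first column `subject_id`, remaining columns
#' the feature labels) plus `labels.csv` (`subject_id,label`). Values
#' are printed with 17 significant digits so a write/read round trip
#' reproduces every matrix exactly. A `manifest.json` records the
#' modality file names and the hash of any configuration supplied.
#'
#' @param dataset a [multimodal_dataset()].
#' @param dir output directory (created if absent).
#' @param config optional configuration list whose hash is embedded in
#'   the manifest.
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(dataset, dir, config = NULL) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(dataset$modalities)) {
    m <- dataset$modalities[[nm]]
    p <- file.path(dir, paste0(nm, ".csv"))
    lines <- c(paste(c("subject_id", colnames(m)), collapse = ","),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(dataset$subject_ids[i], sprintf("%.17g", m[i, ])),
                       collapse = ","), ""))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.csv")
  writeLines(c("subject_id,label",
               paste(dataset$subject_ids, dataset$labels, sep = ",")), lp)
  paths <- c(paths, lp)
  manifest <- list(modalities = names(dataset$modalities),
                   n_subjects = length(dataset$subject_ids),
                   config_hash = if (is.null(config)) NA else config_hash(config))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read a multimodal cohort from delimited text
#'
#' Reads one feature table per modality (header row of feature labels,
#' first column the subject ID) and a two-column label file, and aligns
#' all modalities by subject ID. Only subjects present in every modality
#' file and the label file are kept (the complete-case rule); the
#' subjects dropped from each file are recorded in the
#' `alignment_report` attribute and messaged. Labels may be coded
#' `-1/1` or `0/1`; anything else is an error naming the offending
#' values.
#'
#' @param modality_files named character vector of CSV paths; names
#'   become modality names.
#' @param label_file path of the label CSV.
#' @return a [multimodal_dataset()] with an `alignment_report` attribute.
#' @export
read_multimodal <- function(modality_files, label_file) {
  if (is.null(names(modality_files)) || any(names(modality_files) == ""))
    stop("modality_files must be a named vector of paths", call. = FALSE)
  for (p in c(modality_files, label_file))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  lab_df <- utils::read.csv(label_file, check.names = FALSE,
                            colClasses = c("character", "numeric"))
  if (anyDuplicated(lab_df[[1]]))
    stop("duplicate subject IDs in label file", call. = FALSE)
  vals <- sort(unique(lab_df[[2]]))
  if (identical(vals, c(0, 1))) {
    lab_df[[2]] <- ifelse(lab_df[[2]] > 0, 1, -1)
  } else if (!identical(vals, c(-1, 1))) {
    stop("labels must be binary (-1/1 or 0/1); found values: ",
         paste(vals, collapse = ", "), call. = FALSE)
  }

  tables <- lapply(modality_files, function(p) {
    df <- utils::read.csv(p, check.names = FALSE)
    if (anyDuplicated(df[[1]]))
      stop("duplicate subject IDs in ", p, call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
  })

  keep <- Reduce(intersect, c(list(lab_df[[1]]), lapply(tables, rownames)))
  if (length(keep) == 0L)
    stop("empty subject-ID intersection across input files", call. = FALSE)
  keep <- lab_df[[1]][lab_df[[1]] %in% keep]  # label-file order
  report <- c(
    stats::setNames(lapply(tables, function(m) setdiff(rownames(m), keep)),
                    names(tables)),
    list(labels = setdiff(lab_df[[1]], keep)))
  dropped <- length(unique(unlist(report)))
  if (dropped > 0L)
    message(sprintf("alignment dropped %d subject(s) not shared by all files",
                    dropped))

  ds <- multimodal_dataset(
    subject_ids = keep,
    labels = lab_df[[2]][match(keep, lab_df[[1]])],
    modalities = lapply(tables, function(m) m[keep, , drop = FALSE]))
  attr(ds, "alignment_report") <- report
  ds
}

#' Read and validate a run configuration file
#'
#' YAML configuration for the pipeline: data location or synthetic
#' preset, modality inclusion/exclusion, model hyperparameters
#' (`lambda_reg`, `cost`), cross-validation design (`n_splits`,
#' `train_frac`, `n_permutations`), preprocessing switches and
#' `master_seed`. Unknown fields are an error; constraints on counts
#' and fractions are validated at load time.
#'
#' @param path YAML file path.
#' @return a validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(data_dir = NULL, preset = NULL, dims = NULL,
                   modalities = NULL, exclude_multimodal = character(0),
                   models = c("unimodal", "early_fusion", "mkl", "stacking"),
                   lambda_reg = 0.95, cost = 1,
                   n_splits = 100L, train_frac = 0.75,
                   n_permutations = 1000L, standardize = FALSE,
                   inner_folds = 5L, master_seed = 1L, out_dir = ".")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$data_dir) && is.null(cfg$preset))
    stop("config must name either data_dir or preset", call. = FALSE)
  if (!is.null(cfg$data_dir) && !dir.exists(cfg$data_dir))
    stop("data_dir does not exist: ", cfg$data_dir, call. = FALSE)
  assert_count(cfg$n_splits, "n_splits", min = 2L)
  assert_count(cfg$n_permutations, "n_permutations")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("train_frac must be strictly between 0 and 1", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Persist experiment results and archives as text artifacts
#'
#' Writes `results.csv` (one row per model family: median AUC, median
#' PR-AUC, permutation p-value, config hash), `archive.json` (per-split
#' AUCs, split seeds and the full configuration) and, when the
#' experiment collected weights, one `weights_<model>_<modality>.csv`
#' per archived panel. Every artifact embeds the configuration hash.
#'
#' @param experiment a [run_experiment()] result.
#' @param dir output directory.
#' @param save_weights write the per-split weight matrices too.
#' @return invisibly, the written paths.
#' @export
write_experiment <- function(experiment, dir, save_weights = TRUE) {
  stopifnot(inherits(experiment, "mkl_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- results_table(experiment)
  tab$config_hash <- experiment$config_hash
  rp <- file.path(dir, "results.csv")
  lines <- c(paste(colnames(tab), collapse = ","),
             vapply(seq_len(nrow(tab)), function(i)
               paste(c(tab$model[i], sprintf("%.17g", tab$median_auc[i]),
                       sprintf("%.17g", tab$pr_auc_median[i]),
                       sprintf("%.17g", tab$p_value[i]), tab$config_hash[i]),
                     collapse = ","), ""))
  writeLines(lines, rp)
  paths <- rp

  archive <- list(
    config = experiment$config,
    config_hash = experiment$config_hash,
    split_seeds = vapply(experiment$archive$splits, `[[`, 0L, "seed"),
    per_split_auc = lapply(experiment$archive$per_model, function(m)
      vapply(m$per_split, `[[`, 0.0, "auc")))
  ap <- file.path(dir, "archive.json")
  jsonlite::write_json(archive, ap, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, ap)

  if (save_weights) {
    for (key in names(experiment$archive$per_model)) {
      ws <- experiment$archive$per_model[[key]]$weights
      for (nm in names(ws)) {
        wp <- file.path(dir, sprintf("weights_%s_%s.csv", key, nm))
        m <- ws[[nm]]
        wl <- c(paste(colnames(m), collapse = ","),
                vapply(seq_len(nrow(m)), function(i)
                  paste(sprintf("%.17g", m[i, ]), collapse = ","), ""))
        writeLines(wl, wp)
        paths <- c(paths, wp)
      }
    }
  }
  invisible(paths)
}
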