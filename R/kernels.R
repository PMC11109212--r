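#' Gram (kernel) matrix with subject bookkeeping
#'
#' A subject-by-subject similarity block. Square train-train blocks are
#' validated to be symmetric and positive semidefinite (minimum
#' eigenvalue no smaller than -1e-8 times the maximum); rectangular
#' test-train blocks are not. `scale_factor` records the cumulative
#' normalization constant applied to the block, which
#' [extract_primal_weights()] needs to map dual coefficients back to
#' feature space.
#'
#' @param values numeric matrix of kernel values.
#' @param row_subjects,col_subjects subject IDs for rows / columns.
#' @param modality modality name the kernel was computed from.
#' @param scale_factor positive normalization constant already applied.
#' @return an object of class `gram_matrix`.
#' @export
gram_matrix <- function(values, row_subjects, col_subjects,
                        modality = "modality", scale_factor = 1) {
  stopifnot(is.matrix(values), is.numeric(values))
  row_subjects <- as.character(row_subjects)
  col_subjects <- as.character(col_subjects)
  if (nrow(values) != length(row_subjects) || ncol(values) != length(col_subjects))
    stop("gram matrix dimensions do not match subject lists", call. = FALSE)
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L || scale_factor <= 0)
    stop("scale_factor must be a single positive number", call. = FALSE)
  square <- length(row_subjects) == length(col_subjects) &&
    all(row_subjects == col_subjects)
  if (square) {
    if (max(abs(values - t(values))) > 1e-10)
      stop(sprintf("train kernel for '%s' is not symmetric", modality), call. = FALSE)
    ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1e-12))
      stop(sprintf("train kernel for '%s' is not positive semidefinite (min eigenvalue %.3e)",
                   modality, min(ev)), call. = FALSE)
  }
  dimnames(values) <- list(row_subjects, col_subjects)
  structure(list(values = values, row_subjects = row_subjects,
                 col_subjects = col_subjects, modality = modality,
                 scale_factor = scale_factor),
            class = "gram_matrix")
}

#' Linear kernel between subjects
#'
#' Builds the train-train Gram matrix of dot products between subjects'
#' feature vectors and, when test features are supplied, the test-train
#' cross block (test rows against train columns). `scale_factor` starts
#' at 1; apply [normalize_kernel()] afterwards.
#'
#' @param train_features subjects x features numeric matrix.
#' @param test_features optional matrix with the same feature count.
#' @param modality modality name recorded on the output.
#' @return list with elements `train` ([gram_matrix()]) and `test`
#'   (`gram_matrix` or `NULL`).
#' @export
linear_kernel <- function(train_features, test_features = NULL,
                          modality = "modality") {
  if (!is.matrix(train_features)) train_features <- as.matrix(train_features)
  if (nrow(train_features) < 1L) stop("empty train set", call. = FALSE)
  if (anyNA(train_features)) stop("train features contain missing values", call. = FALSE)
  tr_ids <- rownames(train_features)
  if (is.null(tr_ids)) tr_ids <- paste0("train_", seq_len(nrow(train_features)))
  ktr <- tcrossprod(train_features)
  ktr <- (ktr + t(ktr)) / 2  # kill floating-point asymmetry
  out <- list(train = gram_matrix(ktr, tr_ids, tr_ids, modality), test = NULL)
  if (!is.null(test_features)) {
    if (!is.matrix(test_features)) test_features <- as.matrix(test_features)
    if (ncol(test_features) != ncol(train_features))
      stop(sprintf("feature width mismatch: train %d vs test %d",
                   ncol(train_features), ncol(test_features)), call. = FALSE)
    if (anyNA(test_features)) stop("test features contain missing values", call. = FALSE)
    te_ids <- rownames(test_features)
    if (is.null(te_ids)) te_ids <- paste0("test_", seq_len(nrow(test_features)))
    out$test <- gram_matrix(tcrossprod(test_features, train_features),
                            te_ids, tr_ids, modality)
  }
  out
}

#' Trace-normalize a kernel
#'
#' Rescales a train-train Gram matrix so its trace equals the number of
#' train subjects (the convention of the EasyMKL literature, ensuring
#' modalities of very different dimensionality contribute on a common
#' scale when combined). The same constant `c = n / trace` is applied to
#' the test-train block and accumulated into `scale_factor`, which makes
#' the operation idempotent and keeps primal-weight reconstruction exact.
#' The constant is computed from the train block only, so test subjects
#' can never leak into it.
#'
#' @param train_gram square [gram_matrix()] on the train subjects.
#' @param test_gram optional test-train [gram_matrix()].
#' @return list with normalized `train` and `test` blocks.
#' @export
normalize_kernel <- function(train_gram, test_gram = NULL) {
  stopifnot(inherits(train_gram, "gram_matrix"))
  tr <- sum(diag(train_gram$values))
  if (tr <= 0)
    stop(sprintf("degenerate kernel for modality '%s': trace %.3e <= 0",
                 train_gram$modality, tr), call. = FALSE)
  n <- nrow(train_gram$values)
  cst <- n / tr
  train_gram$values <- train_gram$values * cst
  train_gram$scale_factor <- train_gram$scale_factor * cst
  if (!is.null(test_gram)) {
    stopifnot(inherits(test_gram, "gram_matrix"))
    test_gram$values <- test_gram$values * cst
    test_gram$scale_factor <- test_gram$scale_factor * cst
  }
  list(train = train_gram, test = test_gram)
}

#' Build a per-modality kernel set for one train/test split
#'
#' For each included modality, computes the linear kernel from the train
#' rows and (when test indices are given) the test-train cross block,
#' then normalizes both using constants derived from the train block
#' only. Optional per-feature standardization uses train means and SDs,
#' applied identically to test rows (constant features map to zero).
#' Modality exclusion — e.g. dropping a modality whose unimodal
#' performance is at chance, as done for mean diffusivity in the original
#' analysis — is expressed through `include_modalities`.
#'
#' @param dataset a [multimodal_dataset()].
#' @param train_idx,test_idx disjoint integer subject indices; `test_idx`
#'   may be `NULL` for a train-only kernel set.
#' @param include_modalities modality names to keep (default: all).
#' @param standardize z-score features by train statistics first.
#' @param normalization `"trace"` (default) or `"cosine"` (unit-norm
#'   feature rows, giving a unit-diagonal kernel).
#' @param keep_features also store the (possibly transformed) feature
#'   matrices, needed for primal-weight extraction under standardization.
#' @return an object of class `kernel_set`.
#' @export
build_kernel_set <- function(dataset, train_idx, test_idx = NULL,
                             include_modalities = names(dataset$modalities),
                             standardize = FALSE,
                             normalization = c("trace", "cosine"),
                             keep_features = FALSE) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  normalization <- match.arg(normalization)
  n <- length(dataset$subject_ids)
  train_idx <- as.integer(train_idx)
  if (length(train_idx) < 1L || any(train_idx < 1L) || any(train_idx > n))
    stop("train_idx out of range", call. = FALSE)
  if (!is.null(test_idx)) {
    test_idx <- as.integer(test_idx)
    if (any(test_idx < 1L) || any(test_idx > n))
      stop("test_idx out of range", call. = FALSE)
    if (length(intersect(train_idx, test_idx)) > 0L)
      stop("leakage: train and test indices overlap", call. = FALSE)
  }
  unknown <- setdiff(include_modalities, names(dataset$modalities))
  if (length(unknown) > 0L)
    stop("unknown modalities: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(include_modalities) < 1L)
    stop("include_modalities must name at least one modality", call. = FALSE)

  mods <- vector("list", length(include_modalities))
  names(mods) <- include_modalities
  feats <- if (keep_features) list() else NULL
  for (nm in include_modalities) {
    xtr <- dataset$modalities[[nm]][train_idx, , drop = FALSE]
    xte <- if (!is.null(test_idx))
      dataset$modalities[[nm]][test_idx, , drop = FALSE] else NULL
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- Inf  # constant features -> zero after scaling
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      if (!is.null(xte)) xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    if (normalization == "cosine") {
      rn <- function(m) {
        nr <- sqrt(rowSums(m^2))
        nr[nr == 0] <- 1
        m / nr
      }
      xtr <- rn(xtr)
      if (!is.null(xte)) xte <- rn(xte)
    }
    kk <- linear_kernel(xtr, xte, modality = nm)
    if (normalization == "trace") kk <- normalize_kernel(kk$train, kk$test)
    mods[[nm]] <- kk
    if (keep_features) feats[[nm]] <- list(train = xtr, test = xte)
  }
  structure(list(
    modalities = mods,
    train_subjects = dataset$subject_ids[train_idx],
    test_subjects = if (is.null(test_idx)) NULL else dataset$subject_ids[test_idx],
    normalization = normalization,
    standardize = standardize,
    features = feats
  ), class = "kernel_set")
}

#' Write kernel blocks as delimited text for inspection
#'
#' @param kernel_set a [build_kernel_set()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_kernels <- function(kernel_set, dir) {
  stopifnot(inherits(kernel_set, "kernel_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(kernel_set$modalities)) {
    for (block in c("train", "test")) {
      g <- kernel_set$modalities[[nm]][[block]]
      if (is.null(g)) next
      p <- file.path(dir, sprintf("kernel_%s_%s.csv", nm, block))
      utils::write.csv(as.data.frame(g$values), p, row.names = TRUE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
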