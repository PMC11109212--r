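#' Collect per-split primal weight vectors into a panel
#'
#' Stacks the weight vectors one model family learned for one modality
#' across all CV splits, in split order, and normalizes each vector to
#' unit Euclidean norm. Splits whose weight vector is identically zero
#' (possible when a modality's kernel weight is zero) have no direction
#' and are excluded with a warning; the count is recorded.
#'
#' @param experiment a [run_experiment()] result (run with
#'   `collect_weights = TRUE`).
#' @param modality modality name.
#' @param model_name archived model key, e.g. `"mkl"` or
#'   `"unimodal_fmri"`.
#' @return an object of class `weight_panel`.
#' @export
collect_weights <- function(experiment, modality, model_name) {
  stopifnot(inherits(experiment, "mkl_experiment"))
  pm <- experiment$archive$per_model
  if (!model_name %in% names(pm))
    stop(sprintf("model '%s' not in archive (have: %s)", model_name,
                 paste(names(pm), collapse = ", ")), call. = FALSE)
  w <- pm[[model_name]]$weights[[modality]]
  if (is.null(w))
    stop(sprintf("no archived weights for modality '%s' under model '%s'",
                 modality, model_name), call. = FALSE)
  make_weight_panel(w, modality, model_name,
                    vapply(experiment$archive$splits, `[[`, 0L, "seed"))
}

# Shared panel constructor: unit-normalizes rows, drops zero-norm rows
# (no direction) with a warning.
make_weight_panel <- function(w, modality, model_name, seeds = NULL) {
  w <- as.matrix(w)
  if (is.null(seeds)) seeds <- rep(NA_integer_, nrow(w))
  norms <- sqrt(rowSums(w^2))
  zero <- norms == 0
  if (any(zero))
    warning(sprintf("%d zero-norm weight vector(s) excluded for %s/%s",
                    sum(zero), model_name, modality))
  keep <- !zero
  structure(list(modality = modality, model_name = model_name,
                 matrix = w[keep, , drop = FALSE] / norms[keep],
                 feature_labels = colnames(w),
                 split_seeds = seeds[keep], n_dropped = sum(zero)),
            class = "weight_panel")
}

#' Project weight panels to two dimensions by PCA
#'
#' Fits one PCA on the row-stacked union of all supplied panels (which
#' must share a feature space), so that panels from different model
#' families — say the unimodal SVM and MKL weights for the same
#' modality — are projected onto common axes and their spreads are
#' directly comparable. Each panel's rows are returned as scores on the
#' top two components, with explained-variance fractions from the joint
#' fit. Zero-variance input (all rows identical) reports coordinates at
#' the origin and explained-variance fractions of 0.
#'
#' @param panels a `weight_panel` or list of them, sharing feature labels.
#' @return a list of `stability_result` objects (one per panel), each
#'   with `coordinates` (rows x 2), `explained_variance_fractions`,
#'   `dispersion` and `fitted_on`.
#' @export
pca_project <- function(panels) {
  if (inherits(panels, "weight_panel")) panels <- list(panels)
  stopifnot(length(panels) >= 1L,
            all(vapply(panels, inherits, TRUE, "weight_panel")))
  labs <- panels[[1]]$feature_labels
  for (p in panels)
    if (!identical(p$feature_labels, labs))
      stop("panels do not share a feature space", call. = FALSE)
  stacked <- do.call(rbind, lapply(panels, `[[`, "matrix"))
  if (nrow(stacked) < 3L)
    stop("need at least 3 weight vectors for a PCA projection", call. = FALSE)
  centered <- sweep(stacked, 2, colMeans(stacked))
  total_var <- sum(centered^2) / (nrow(stacked) - 1)
  if (total_var <= 1e-24) {
    coords <- matrix(0, nrow(stacked), 2)
    evf <- c(0, 0)
  } else {
    pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE, rank. = 2)
    coords <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
    if (ncol(coords) < 2L) coords <- cbind(coords, 0)
    evf <- (pc$sdev[1:2]^2) / total_var
    evf[is.na(evf)] <- 0
  }
  colnames(coords) <- c("PC1", "PC2")
  fitted_on <- vapply(panels, `[[`, "", "model_name")
  offsets <- c(0L, cumsum(vapply(panels, function(p) nrow(p$matrix), 0L)))
  out <- lapply(seq_along(panels), function(i) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    structure(list(model_name = panels[[i]]$model_name,
                   modality = panels[[i]]$modality,
                   coordinates = coords[rows, , drop = FALSE],
                   explained_variance_fractions = evf,
                   dispersion = dispersion(panels[[i]]),
                   fitted_on = fitted_on),
              class = "stability_result")
  })
  names(out) <- fitted_on
  out
}

#' Dispersion of a weight panel: mean pairwise cosine similarity
#'
#' Averages the cosine similarity over all pairs of unit-normalized
#' weight vectors in the panel. 1 means every split learned the same
#' direction (perfectly stable); values near 0 mean unrelated
#' directions. This scalar summarizes what the two-dimensional PCA
#' projection shows visually. Weight vectors are not sign-aligned
#' before comparison: labels are fixed across splits, so `w` and `-w`
#' are genuinely different classifiers.
#'
#' @param panel a [collect_weights()] panel with at least 2 rows.
#' @return a number in `[-1, 1]`.
#' @export
dispersion <- function(panel) {
  stopifnot(inherits(panel, "weight_panel"))
  m <- panel$matrix
  n <- nrow(m)
  if (n < 2L) stop("dispersion needs at least 2 weight vectors", call. = FALSE)
  s <- tcrossprod(m)
  (sum(s) - sum(diag(s))) / (n * (n - 1))
}

#' Features with the highest mean absolute weight across splits
#'
#' Ranks a panel's features by the mean absolute (unit-normalized)
#' weight across splits, descending, reporting the signed mean
#' alongside: a positive mean weight tilts predictions toward the
#' positive class. Ties in mean absolute weight are broken by
#' lexicographic feature label so the ranking is total and
#' deterministic.
#'
#' @param panel a [collect_weights()] panel.
#' @param k number of features to report, `1 <= k <= feature count`.
#' @return data.frame with `feature`, `mean_weight`, `mean_abs_weight`.
#' @export
top_features <- function(panel, k) {
  stopifnot(inherits(panel, "weight_panel"))
  p <- length(panel$feature_labels)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > p || k != floor(k))
    stop(sprintf("k must be an integer in [1, %d]", p), call. = FALSE)
  mean_w <- colMeans(panel$matrix)
  mean_abs <- colMeans(abs(panel$matrix))
  ord <- order(-mean_abs, panel$feature_labels)
  data.frame(feature = panel$feature_labels[ord][seq_len(k)],
             mean_weight = unname(mean_w[ord][seq_len(k)]),
             mean_abs_weight = unname(mean_abs[ord][seq_len(k)]),
             row.names = NULL)
}
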