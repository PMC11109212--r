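#' Fit a soft-margin linear SVM
#'
#' Thin wrapper around libsvm (via e1071) that returns an explicit
#' primal weight vector and bias, oriented so that a higher decision
#' score favors the +1 class regardless of the label order libsvm saw.
#' Features are passed through unscaled; any standardization is the
#' caller's responsibility so that train statistics never leak into
#' test rows.
#'
#' @param features subjects x features numeric matrix.
#' @param labels +1/-1 vector.
#' @param cost soft-margin cost parameter C (default 1).
#' @return an object of class `linear_model` with elements `weights`,
#'   `bias`, `model_family`, `regularization`, `train_subjects`.
#' @export
fit_linear_svm <- function(features, labels, cost = 1) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  y <- as.numeric(labels)
  assert_binary_labels(y)
  if (nrow(features) != length(y))
    stop("feature rows must match label length", call. = FALSE)
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0)
    stop("cost must be a single positive number", call. = FALSE)
  fit <- e1071::svm(features, factor(y, levels = c(-1, 1)),
                    kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = 1e-6)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm's decision value is positive for the first training label it
  # saw; re-orient to the fixed convention higher score == class +1.
  dv <- attr(stats::predict(fit, features, decision.values = TRUE),
             "decision.values")
  pos_class <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (pos_class == "-1") { w <- -w; b <- -b }
  names(w) <- colnames(features)
  structure(list(weights = w, bias = b, model_family = "svm",
                 regularization = cost,
                 train_subjects = rownames(features)),
            class = "linear_model")
}

#' Decision scores of a linear model
#'
#' @param model a `linear_model`.
#' @param features matrix with the model's feature width.
#' @return numeric scores, higher favoring class +1.
#' @export
predict_linear <- function(model, features) {
  stopifnot(inherits(model, "linear_model"))
  if (!is.matrix(features)) features <- as.matrix(features)
  if (ncol(features) != length(model$weights))
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(features), length(model$weights)), call. = FALSE)
  drop(features %*% model$weights) + model$bias
}

#' Concatenate modalities into one early-fusion feature matrix
#'
#' Horizontal concatenation in the declared modality order. By default
#' each feature is z-scored using train-row statistics before
#' concatenation so low-dimensional modalities are not drowned by
#' high-dimensional ones; the same transform is applied to all rows.
#' Features constant on the train rows map to all-zeros (never NaN).
#'
#' @param dataset a [multimodal_dataset()].
#' @param include_modalities modality names to concatenate.
#' @param train_idx rows whose statistics drive the scaling (default:
#'   all rows).
#' @param scale z-score by train statistics (default `TRUE`); `FALSE`
#'   gives raw concatenation.
#' @return list with `features` (all subjects x total width, columns
#'   named `<modality>_<feature>`) and `feature_labels`.
#' @export
concat_features <- function(dataset, include_modalities,
                            train_idx = seq_along(dataset$subject_ids),
                            scale = TRUE) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  if (length(include_modalities) < 1L)
    stop("include_modalities must name at least one modality", call. = FALSE)
  unknown <- setdiff(include_modalities, names(dataset$modalities))
  if (length(unknown) > 0L)
    stop("unknown modalities: ", paste(unknown, collapse = ", "), call. = FALSE)
  blocks <- lapply(include_modalities, function(nm) {
    x <- dataset$modalities[[nm]]
    if (scale) {
      mu <- colMeans(x[train_idx, , drop = FALSE])
      sdv <- apply(x[train_idx, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- Inf
      x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    }
    x
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- dataset$subject_ids
  list(features = out, feature_labels = colnames(out))
}

# Ridge-penalized logistic regression by IRLS (penalty off the intercept).
# Used as the stacking meta-learner; the ridge keeps the fit defined for
# collinear or separable meta-features.
ridge_logistic <- function(x, y01, ridge = 1e-2, max_iter = 100L, tol = 1e-10) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(x)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(x, y01 - mu)) - drop(pen %*% beta)
    hess <- crossprod(x * w, x) + pen
    delta <- solve(hess, grad)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  list(bias = beta[1], weights = beta[-1])
}

#' Stacked-generalization (late fusion) classifier
#'
#' Per modality, a unimodal linear SVM produces out-of-fold decision
#' scores on the train set via stratified inner folds; these scores are
#' the meta-features of a ridge-penalized logistic meta-learner. For
#' test scoring, the base SVMs are refit on the full train set and the
#' meta-learner's linear predictor is the decision score. Fully seeded.
#'
#' @param dataset a [multimodal_dataset()].
#' @param train_idx integer train-row indices.
#' @param include_modalities modality names used as base learners.
#' @param inner_folds number of stratified inner folds (default 5).
#' @param cost base-SVM cost.
#' @param ridge meta-learner ridge penalty.
#' @param seed integer seed for the fold assignment.
#' @return an object of class `stacked_model`.
#' @export
stacked_generalization_fit <- function(dataset, train_idx, include_modalities,
                                       inner_folds = 5L, cost = 1,
                                       ridge = 1e-2, seed = 1L) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  inner_folds <- assert_count(inner_folds, "inner_folds", min = 2L)
  y <- dataset$labels[train_idx]
  assert_binary_labels(y)
  if (min(sum(y > 0), sum(y < 0)) < inner_folds)
    stop(sprintf("stratification error: smallest class (%d) cannot fill %d inner folds",
                 min(sum(y > 0), sum(y < 0)), inner_folds), call. = FALSE)
  set.seed(derive_seed(seed, "stacking_folds"))
  fold <- integer(length(y))
  for (cls in c(1, -1)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(inner_folds), length(idx)))
  }
  meta_x <- matrix(NA_real_, length(y), length(include_modalities),
                   dimnames = list(NULL, include_modalities))
  for (nm in include_modalities) {
    x <- dataset$modalities[[nm]][train_idx, , drop = FALSE]
    for (f in seq_len(inner_folds)) {
      inn <- which(fold != f)
      out <- which(fold == f)
      m <- fit_linear_svm(x[inn, , drop = FALSE], y[inn], cost = cost)
      meta_x[out, nm] <- predict_linear(m, x[out, , drop = FALSE])
    }
  }
  meta <- ridge_logistic(meta_x, (y + 1) / 2, ridge = ridge)
  base_models <- lapply(include_modalities, function(nm)
    fit_linear_svm(dataset$modalities[[nm]][train_idx, , drop = FALSE], y,
                   cost = cost))
  names(base_models) <- include_modalities
  structure(list(meta = meta, base_models = base_models,
                 modalities = include_modalities,
                 train_subjects = dataset$subject_ids[train_idx]),
            class = "stacked_model")
}

#' @rdname stacked_generalization_fit
#' @param model a `stacked_model`.
#' @param test_idx integer test-row indices.
#' @return `predict_stacked`: numeric decision scores (meta linear
#'   predictor; higher favors class +1).
#' @export
predict_stacked <- function(model, dataset, test_idx) {
  stopifnot(inherits(model, "stacked_model"))
  meta_x <- vapply(model$modalities, function(nm)
    predict_linear(model$base_models[[nm]],
                   dataset$modalities[[nm]][test_idx, , drop = FALSE]),
    numeric(length(test_idx)))
  if (length(test_idx) == 1L) meta_x <- matrix(meta_x, nrow = 1L)
  drop(meta_x %*% model$meta$weights) + model$meta$bias
}

#' Serialize a linear model as JSON
#'
#' Shares the layout of [write_mkl_model()] with a `model_family` tag.
#'
#' @param model a `linear_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_linear_model <- function(model, path) {
  stopifnot(inherits(model, "linear_model"))
  jsonlite::write_json(list(
    model_family = model$model_family,
    weights = as.list(model$weights),
    bias = model$bias,
    regularization = model$regularization,
    train_subjects = model$train_subjects
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
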