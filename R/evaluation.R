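#' Monte-Carlo stratified train/test splits
#'
#' Draws `n_splits` independent random splits. Within each split, each
#' class contributes `round_half_up(train_frac * class size)` subjects
#' to the train set (sampled without replacement), so train and test
#' label proportions track the cohort's within one subject. Per-split
#' seeds are derived deterministically from the master seed, making the
#' whole plan reproducible.
#'
#' @param labels +1/-1 vector for the full cohort.
#' @param n_splits number of random splits (the study design uses 100).
#' @param train_frac fraction of each class assigned to train (default 0.75).
#' @param master_seed integer master seed.
#' @return list of split plans, each with `split_id`, `seed`,
#'   `train_idx`, `test_idx`, `stratified`.
#' @export
make_splits <- function(labels, n_splits = 100L, train_frac = 0.75,
                        master_seed = 1L) {
  y <- as.numeric(labels)
  assert_binary_labels(y)
  n_splits <- assert_count(n_splits, "n_splits")
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be strictly between 0 and 1", call. = FALSE)
  pos <- which(y > 0); neg <- which(y < 0)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each class needs at least 2 subjects to split", call. = FALSE)
  n_tr_pos <- round_half_up(train_frac * length(pos))
  n_tr_neg <- round_half_up(train_frac * length(neg))
  if (n_tr_pos < 1L || n_tr_neg < 1L ||
      n_tr_pos >= length(pos) || n_tr_neg >= length(neg))
    stop("a class would get an empty train or test set at this train_frac",
         call. = FALSE)
  set.seed(derive_seed(master_seed, "splits"))
  seeds <- sample.int(2147483646L, n_splits)
  lapply(seq_len(n_splits), function(s) {
    set.seed(seeds[s])
    tr <- c(sample(pos, n_tr_pos), sample(neg, n_tr_neg))
    tr <- sort(tr)
    list(split_id = s, seed = seeds[s], train_idx = tr,
         test_idx = sort(setdiff(seq_along(y), tr)), stratified = TRUE)
  })
}

#' ROC AUC by the Mann-Whitney statistic
#'
#' Probability that a random positive outranks a random negative, with
#' ties given half credit: (concordant + 0.5 * tied) / (n_pos * n_neg),
#' computed from midranks.
#'
#' @param scores numeric decision scores (higher favors +1).
#' @param labels +1/-1 vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC
#'
#' Walks the ranking from the highest score down (tied scores move as a
#' block) and accumulates area under the precision-recall curve. The
#' default `"step"` rule uses the interpolated precision envelope
#' (maximum precision at any recall at least as large), matching the
#' usual step-wise PR-AUC; `"trapezoid"` integrates raw precision
#' linearly between recall steps. A perfect ranking scores 1; random
#' scores approach the positive-class prevalence.
#'
#' @param scores numeric decision scores.
#' @param labels +1/-1 vector with at least one positive.
#' @param method `"step"` (default) or `"trapezoid"`.
#' @return PR-AUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels, method = c("step", "trapezoid")) {
  method <- match.arg(method)
  y <- as.numeric(labels)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1", call. = FALSE)
  n_pos <- sum(y > 0)
  if (n_pos == 0L) stop("PR-AUC needs at least one positive label", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord] > 0
  # cut points after each block of tied scores
  block_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(yy)[block_end]
  npred <- block_end
  recall <- tp / n_pos
  precision <- tp / npred
  r_prev <- c(0, recall[-length(recall)])
  if (method == "step") {
    # precision envelope: running max from the high-recall end
    prec_env <- rev(cummax(rev(precision)))
    sum((recall - r_prev) * prec_env)
  } else {
    p_prev <- c(precision[1], precision[-length(precision)])
    sum((recall - r_prev) * (precision + p_prev) / 2)
  }
}

#' Permutation-null p-value for a median-AUC statistic
#'
#' Builds the null distribution by relabeling test subjects: for each of
#' `B` replicates one random permutation of the full cohort label vector
#' is drawn, every split's test labels are replaced by the permuted
#' values at that split's test positions, each split's AUC is recomputed
#' from the stored scores, and the median across splits is one null
#' value. Drawing a single cohort-level permutation per replicate keeps
#' the dependence between overlapping test sets identical to the
#' observed statistic's, which makes the test exact: under a label-free
#' cohort the labels are exchangeable given the scores, so the observed
#' median AUC is one draw from exactly this permutation distribution.
#' (Permuting each split independently instead narrows the null and
#' inflates the type-I error; see the methods vignette.)
#'
#' The p-value uses the add-one estimator
#' `p = (1 + #{null >= observed}) / (B + 1)`, so it is never exactly
#' zero and its floor is `1/(B+1)`. Since score ranks within a split are
#' fixed, each permuted AUC reduces to a rank-sum over the relabeled
#' positives, which keeps large B cheap. In the rare event that a
#' permutation leaves some split's test set single-class, that split
#' drops out of that replicate's median.
#'
#' @param observed_median_auc the observed median AUC across splits.
#' @param per_split list with one element per split, each holding the
#'   numeric test `scores` and the cohort `test_idx` they belong to.
#' @param labels +1/-1 label vector for the full cohort.
#' @param n_permutations number of replicates B (the study used 1000).
#' @param seed integer seed.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed_median_auc, per_split, labels,
                               n_permutations = 1000L, seed = 1L) {
  n_permutations <- assert_count(n_permutations, "n_permutations")
  stopifnot(is.list(per_split), length(per_split) >= 1L)
  y <- as.numeric(labels)
  assert_binary_labels(y)
  pre <- lapply(per_split, function(sp) {
    if (is.null(sp$test_idx))
      stop("each per_split element needs scores and test_idx", call. = FALSE)
    list(r = rank(sp$scores, ties.method = "average"),
         idx = as.integer(sp$test_idx), n = length(sp$scores))
  })
  set.seed(derive_seed(seed, "permutation"))
  null_medians <- vapply(seq_len(n_permutations), function(b) {
    perm <- sample(y)
    stats::median(vapply(pre, function(p) {
      yt <- perm[p$idx]
      n_pos <- sum(yt > 0)
      if (n_pos == 0L || n_pos == p$n) return(NA_real_)
      (sum(p$r[yt > 0]) - n_pos * (n_pos + 1) / 2) /
        (n_pos * (p$n - n_pos))
    }, 0.0), na.rm = TRUE)
  }, 0.0)
  (1 + sum(null_medians >= observed_median_auc)) / (n_permutations + 1)
}

#' Run the full model-comparison experiment
#'
#' The machinery behind a Table-2-style comparison: one shared set of
#' Monte-Carlo stratified splits is used for every model family (paired
#' comparison). Per split, each requested model is fit on the train
#' rows, scored on the test rows, and its ROC AUC, PR-AUC and — for the
#' unimodal SVMs and MKL — per-modality primal weight vectors are
#' recorded. Aggregates are the median AUC across splits, the median
#' PR-AUC, and a permutation-null p-value for the median AUC.
#'
#' Model families: `"unimodal"` (one linear SVM per modality in
#' `modalities`), `"early_fusion"` (SVM on the z-scored concatenation of
#' `multimodal_modalities`), `"mkl"` (EasyMKL on the normalized linear
#' kernels of `multimodal_modalities`), `"stacking"` (late fusion over
#' `multimodal_modalities`). A modality excluded from
#' `multimodal_modalities` (e.g. one at chance unimodally, as mean
#' diffusivity was in the original analysis) still gets its unimodal
#' evaluation.
#'
#' @param dataset a [multimodal_dataset()].
#' @param models subset of `c("unimodal", "early_fusion", "mkl", "stacking")`.
#' @param modalities modalities evaluated unimodally (default: all).
#' @param multimodal_modalities modalities entering the fusion models
#'   (default: all).
#' @param n_splits,train_frac Monte-Carlo CV design (defaults 100, 0.75).
#' @param n_permutations permutation replicates for the p-values.
#' @param lambda_reg EasyMKL regularization.
#' @param cost SVM cost parameter.
#' @param standardize standardize features before kernel computation.
#' @param inner_folds stacked-generalization inner folds.
#' @param collect_weights record per-split primal weights (needed by the
#'   stability analysis).
#' @param master_seed integer master seed driving splits, permutations
#'   and inner folds.
#' @return an object of class `mkl_experiment`: `results` (named list of
#'   `eval_result`), `archive` (splits, per-split scores/labels/AUCs,
#'   weight matrices), `config`, `config_hash`.
#' @export
run_experiment <- function(dataset,
                           models = c("unimodal", "early_fusion", "mkl", "stacking"),
                           modalities = names(dataset$modalities),
                           multimodal_modalities = names(dataset$modalities),
                           n_splits = 100L, train_frac = 0.75,
                           n_permutations = 1000L,
                           lambda_reg = 0.95, cost = 1,
                           final_classifier = c("komd", "svm"),
                           standardize = FALSE,
                           inner_folds = 5L,
                           collect_weights = TRUE,
                           master_seed = 1L) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  models <- match.arg(models, several.ok = TRUE)
  final_classifier <- match.arg(final_classifier)
  unknown <- setdiff(union(modalities, multimodal_modalities),
                     names(dataset$modalities))
  if (length(unknown) > 0L)
    stop("unknown modalities: ", paste(unknown, collapse = ", "), call. = FALSE)

  config <- list(models = models, modalities = modalities,
                 multimodal_modalities = multimodal_modalities,
                 n_splits = n_splits, train_frac = train_frac,
                 n_permutations = n_permutations, lambda_reg = lambda_reg,
                 cost = cost, final_classifier = final_classifier,
                 standardize = standardize,
                 inner_folds = inner_folds, master_seed = master_seed)
  chash <- config_hash(config)

  splits <- make_splits(dataset$labels, n_splits, train_frac, master_seed)
  model_names <- character(0)
  if ("unimodal" %in% models)
    model_names <- c(model_names, paste0("unimodal_", modalities))
  model_names <- c(model_names, intersect(models, c("early_fusion", "mkl", "stacking")))

  per_model <- lapply(model_names, function(nm)
    list(per_split = vector("list", n_splits), weights = NULL))
  names(per_model) <- model_names
  wt_store <- list()  # model -> modality -> list of split weight vectors

  record <- function(store, model, split_id, scores, test_labels, test_idx) {
    store[[model]]$per_split[[split_id]] <- list(
      scores = unname(scores), labels = test_labels, test_idx = test_idx,
      auc = roc_auc(scores, test_labels),
      pr_auc = pr_auc(scores, test_labels))
    store
  }

  for (sp in splits) {
    tr <- sp$train_idx; te <- sp$test_idx
    y_tr <- dataset$labels[tr]; y_te <- dataset$labels[te]
    s <- sp$split_id

    if ("unimodal" %in% models) {
      for (nm in modalities) {
        x_tr <- dataset$modalities[[nm]][tr, , drop = FALSE]
        fit <- fit_linear_svm(x_tr, y_tr, cost = cost)
        sc <- predict_linear(fit, dataset$modalities[[nm]][te, , drop = FALSE])
        key <- paste0("unimodal_", nm)
        per_model <- record(per_model, key, s, sc, y_te, te)
        if (collect_weights)
          wt_store[[key]][[nm]][[s]] <- fit$weights
      }
    }
    if ("early_fusion" %in% models) {
      cc <- concat_features(dataset, multimodal_modalities, train_idx = tr)
      fit <- fit_linear_svm(cc$features[tr, , drop = FALSE], y_tr, cost = cost)
      sc <- predict_linear(fit, cc$features[te, , drop = FALSE])
      per_model <- record(per_model, "early_fusion", s, sc, y_te, te)
      if (collect_weights) {
        offset <- 0L
        for (nm in multimodal_modalities) {
          p <- ncol(dataset$modalities[[nm]])
          wt_store[["early_fusion"]][[nm]][[s]] <-
            fit$weights[(offset + 1L):(offset + p)]
          offset <- offset + p
        }
      }
    }
    if ("mkl" %in% models) {
      ks <- build_kernel_set(dataset, tr, te,
                             include_modalities = multimodal_modalities,
                             standardize = standardize,
                             keep_features = collect_weights || standardize)
      fit <- easymkl_fit(ks, y_tr, lambda_reg = lambda_reg,
                         final_classifier = final_classifier, svm_cost = cost)
      sc <- mkl_decision_scores(fit, ks)
      per_model <- record(per_model, "mkl", s, sc, y_te, te)
      if (collect_weights) {
        tf <- lapply(ks$features, `[[`, "train")
        ws <- extract_primal_weights(fit, tf)
        for (nm in multimodal_modalities)
          wt_store[["mkl"]][[nm]][[s]] <- ws[[nm]]
      }
    }
    if ("stacking" %in% models) {
      fit <- stacked_generalization_fit(dataset, tr, multimodal_modalities,
                                        inner_folds = inner_folds, cost = cost,
                                        seed = derive_seed(master_seed,
                                                           paste0("stack_", s)))
      sc <- predict_stacked(fit, dataset, te)
      per_model <- record(per_model, "stacking", s, sc, y_te, te)
    }
  }

  # weight panels: splits x features matrices
  for (key in names(wt_store))
    for (nm in names(wt_store[[key]]))
      per_model[[key]]$weights[[nm]] <- do.call(rbind, wt_store[[key]][[nm]])

  results <- lapply(model_names, function(key) {
    aucs <- vapply(per_model[[key]]$per_split, `[[`, 0.0, "auc")
    praucs <- vapply(per_model[[key]]$per_split, `[[`, 0.0, "pr_auc")
    med <- stats::median(aucs)
    p <- permutation_pvalue(med, per_model[[key]]$per_split, dataset$labels,
                            n_permutations = n_permutations,
                            seed = derive_seed(master_seed, paste0("perm_", key)))
    structure(list(model_name = key, per_split_auc = aucs, median_auc = med,
                   pr_auc_median = stats::median(praucs), perm_pvalue = p,
                   n_permutations = n_permutations, config_hash = chash),
              class = "eval_result")
  })
  names(results) <- model_names

  structure(list(results = results,
                 archive = list(splits = splits, per_model = per_model),
                 config = config, config_hash = chash,
                 subject_ids = dataset$subject_ids,
                 labels = dataset$labels),
            class = "mkl_experiment")
}

#' Tabulate experiment results
#'
#' One row per model family: median ROC AUC, median PR-AUC, permutation
#' p-value — the layout of the study's performance table.
#'
#' @param experiment a [run_experiment()] result.
#' @return a data.frame.
#' @export
results_table <- function(experiment) {
  stopifnot(inherits(experiment, "mkl_experiment"))
  do.call(rbind, lapply(experiment$results, function(r)
    data.frame(model = r$model_name, median_auc = r$median_auc,
               pr_auc_median = r$pr_auc_median, p_value = r$perm_pvalue,
               row.names = NULL)))
}

#' @export
print.mkl_experiment <- function(x, ...) {
  cat(sprintf("mkl_experiment: %d splits, %d permutations, config %s\n",
              x$config$n_splits, x$config$n_permutations,
              substr(x$config_hash, 1, 8)))
  print(results_table(x), digits = 3)
  invisible(x)
}
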