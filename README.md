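# mklfusion

Multimodal multiple kernel learning for small-cohort binary
classification, built for the neuroimaging setting where each subject
carries several high-dimensional feature blocks — cortical structure
summaries, functional-connectivity edges, diffusion statistics — and
the scientific questions are (a) whether combining modalities predicts
a clinical label better than the best single modality and (b) whether
fusion stabilizes the multivariate patterns the classifier learns.

## What it implements

**EasyMKL intermediate fusion.** One linear kernel per modality
(`K_r = X_r X_r'`, trace-normalized so `tr(K_r) = n`), combined as
`K = Σ_r η_r K_r` with weights learned by EasyMKL: solve the KOMD
margin-distribution problem

```
min_{γ ∈ Γ}  (1−λ) γ' Ŷ (Σ_r K_r) Ŷ γ + λ‖γ‖²,
Γ = {γ ≥ 0, Σ_{y_i=+1} γ_i = 1, Σ_{y_i=−1} γ_i = 1}
```

on the kernel sum, set `η_r ∝ γ' Ŷ K_r Ŷ γ` (each kernel's
contribution to separating the γ-weighted class hulls), then train the
final classifier on the composite kernel. The QP solver (accelerated
projected gradient over the bi-simplex, exact simplex projections) is
implemented in-package and verified against exhaustive grid search and
an interior-point solver. For linear kernels the fitted model's exact
per-modality primal weights `w_r = η_r c_r Σ_i γ_i y_i x_i^{(r)}` are
recovered for interpretation.

**Baselines.** Unimodal linear SVMs, early fusion (z-scored feature
concatenation + SVM), and stacked-generalization late fusion (per-
modality SVMs + ridge-logistic meta-learner).

**Evaluation.** Monte-Carlo cross-validation (100 stratified 75/25
splits shared across all models), median ROC AUC and PR-AUC across
splits, and an exact permutation-null p-value (cohort-level label
permutations, add-one estimator).

**Stability analysis.** Per-split primal weight vectors per modality,
unit-normalized, projected to 2-D by a joint PCA across model families,
summarized by the mean pairwise cosine similarity ("dispersion") and by
top-feature rankings.

**Synthetic cohorts.** A latent-factor generator (shared, private, and
label-independent factors per modality) emulating the study's cohort
layout — 43 clinical-high-risk vs 31 controls, 11 converters vs 32
nonconverters, feature widths 84/4851/4304 plus a pure-noise
modality — so the entire pipeline is testable without restricted
clinical data.

## Worked example

```r
library(mklfusion)

spec <- synergy_spec(seed = 2024)     # 11 vs 32, four modalities, one weak
ds <- generate_cohort(spec)
exp <- run_experiment(ds, models = c("unimodal", "early_fusion", "mkl"),
                      n_splits = 100, n_permutations = 999, master_seed = 1)
results_table(exp)
```

```
                                  model median_auc pr_auc_median p_value
unimodal_structural unimodal_structural      0.750         0.667   0.009
unimodal_fmri             unimodal_fmri      0.854         0.767   0.001
unimodal_fa                 unimodal_fa      0.917         0.833   0.001
unimodal_dwi               unimodal_dwi      0.667         0.556   0.069
early_fusion               early_fusion      0.917         0.867   0.001
mkl                                 mkl      0.917         0.867   0.001
```

Each row is one model family evaluated on the same 100 random
stratified splits: `median_auc` is the median test ROC AUC across
splits, `pr_auc_median` the median precision–recall AUC, and `p_value`
the permutation-null p-value of the median AUC (floor 1/1000 at
B = 999). On this synthetic cohort the multimodal models match the best
unimodal model while every individual modality varies more widely.

The stability question — does fusion steady the pattern a weak modality
learns? — is answered from the archived per-split weights:

```r
p_mkl <- collect_weights(exp, "fa", "mkl")
p_svm <- collect_weights(exp, "fa", "unimodal_fa")
round(c(mkl = dispersion(p_mkl), svm = dispersion(p_svm)), 3)
#>   mkl   svm
#> 0.886 0.773
top_features(p_mkl, 3)
#>   feature mean_weight mean_abs_weight
#> 1  fa_318      -0.157           0.157
#> 2  fa_238       0.148           0.148
#> 3  fa_298       0.129           0.129
```

Dispersion is the mean pairwise cosine similarity of the unit-
normalized weight vectors across splits (1 = identical direction every
split): the MKL weights for the weak `fa` modality are noticeably more
stable (0.886) than the unimodal SVM's (0.773). `pca_project()` returns
the corresponding 2-D coordinates for plotting.

A shell interface covers the same pipeline
(`inst/cli/mklfusion simulate|fit|evaluate|stability|report`); see
`?pipeline_cli`.

## Package layout

- `R/synthetic-cohort.R` — latent-factor cohort generator and presets
- `R/kernels.R` — Gram matrices, normalization, per-split kernel sets
- `R/easymkl.R` — KOMD solver, EasyMKL fit, scoring, primal weights
- `R/baselines.R` — linear SVM, early fusion, stacked generalization
- `R/evaluation.R` — splits, AUC/PR-AUC, permutation test, experiment runner
- `R/stability.R` — weight panels, joint PCA, dispersion, top features
- `R/io.R`, `R/cli.R` — delimited-text readers/writers, YAML config, CLI
- `vignettes/multimodal-mkl.Rmd` — the methods vignette (model details,
  design choices, what the synthetic benchmarks do and do not show)
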