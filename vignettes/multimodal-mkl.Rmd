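---
title: "Multimodal multiple kernel learning: models, choices, and what the synthetic benchmarks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal multiple kernel learning: models, choices, and what the synthetic benchmarks show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mklfusion)
```

## The problem

Small clinical-imaging cohorts routinely carry several feature
modalities per subject — cortical structure summaries, functional
connectivity edges, diffusion tract statistics — each high-dimensional
relative to the handful of subjects available. The question `mklfusion`
addresses is how to combine such modalities to predict a binary label
(for instance, clinical-high-risk status, or later conversion to
psychosis) and how to tell whether the combination genuinely helps over
the best single modality.

Three fusion strategies are implemented behind one evaluation harness:

* **Early fusion** — concatenate all feature blocks and train one
  linear SVM.
* **Intermediate fusion (MKL)** — build one linear kernel per modality,
  learn a convex combination of the kernels jointly with the
  classifier (EasyMKL).
* **Late fusion (stacking)** — train one SVM per modality, combine
  their out-of-fold decision scores with a logistic meta-learner.

## The kernel pipeline

For modality $r$ with train feature matrix $X_r$, the kernel is the
plain Gram matrix of dot products, $K_r = X_r X_r^\top$. Each kernel is
trace-normalized, $K_r \leftarrow c_r K_r$ with $c_r = n/\mathrm{tr}(K_r)$,
so that modalities of wildly different dimensionality enter the
combination on a common scale. The constant is computed from train rows
only and applied unchanged to the test–train block, so no information
about test subjects flows backwards. $c_r$ is retained on the kernel
object because the primal weights need it (below).

Two switches exist because the convention is genuinely open:
unit-diagonal ("cosine") normalization, implemented as unit-norm
scaling of each subject's feature row, and per-feature z-scoring by
train statistics. Both default to off: raw dot products with trace
normalization are the simplest contract, and the package makes no claim
that the original analysis standardized features.

## EasyMKL and the KOMD problem

The inner problem is the kernel method for optimizing the margin
distribution (KOMD): with $\hat Y = \mathrm{diag}(y)$,

$$\min_{\gamma \in \Gamma} \; (1-\lambda)\, \gamma^\top \hat Y K \hat Y \gamma
   \;+\; \lambda \lVert\gamma\rVert^2,$$

where $\Gamma$ is the bi-simplex ($\gamma \ge 0$, coefficients summing
to one within each class). The quadratic term is the squared distance
between the $\gamma$-weighted convex hulls of the two classes in kernel
feature space. The solver is an accelerated projected-gradient method
with exact sort-based simplex projections, run to a relative objective
change of $10^{-12}$; the problem is convex, so this reaches the global
optimum, and the whole path is deterministic. The test suite checks the
solution against a step-0.01 exhaustive grid over the bi-simplex and
against an interior-point QP solver.

EasyMKL then proceeds in three steps: solve KOMD once on the unweighted
kernel sum $\sum_r K_r$ to get $\gamma_0$; score each modality by its
contribution to the hull separation,
$d_r = \gamma_0^\top \hat Y K_r \hat Y \gamma_0$, and set
$\eta = d / \sum_r d_r$; finally train the classifier on the composite
kernel $\sum_r \eta_r K_r$. By default the final classifier is KOMD
re-solved on the composite; a hinge-loss SVM on the precomputed
composite kernel is available through `final_classifier = "svm"`.

### Why $\lambda$ defaults to 0.95

$\lambda$ is exposed and genuinely matters, and the default deserves a
paragraph. At small $\lambda$ the optimizer concentrates $\gamma$ on a
few hull points and *actively minimizes* the separation the kernels
achieve. On cohorts of 30–60 subjects with trace-normalized kernels
this has a perverse consequence: every $d_r$ is compressed toward the
floor $\approx \lambda$-independent $\lVert\gamma\rVert^2$ that even a
pure-noise kernel attains (a trace-normalized noise kernel is close to
the identity, for which $d_r = \lVert\gamma\rVert^2$ exactly). In
simulation, a modality with *no* label information then receives a
kernel weight near $0.19$ — indistinguishable from weakly informative
signal modalities. Near the other extreme, $\gamma$ approaches the
per-class uniform vector and $d_r$ becomes the squared distance between
the class centroids in each kernel's feature space — exactly the
quantity that separates informative from uninformative kernels. With
$\lambda = 0.95$ the same noise modality's mean weight drops to
$\approx 0.11$ while informative modalities keep theirs, and the final
dual vector (nearly uniform, data-informed) is markedly more stable
across resampled train sets. The default is therefore 0.95; users who
want the sparse, hard-margin-like regime can set $\lambda$ freely.

### Bias and primal weights

The decision score for a new subject $z$ is
$f(z) = \sum_i \gamma_i y_i \sum_r \eta_r K_r(z, x_i) + b$ with
$b = -(s_+ + s_-)/2$, the midpoint of the $\gamma$-weighted class-hull
images. The bias shifts every score equally and can never change AUC;
it only fixes the zero of the decision axis.

Because all kernels are linear, the dual solution has an exact primal
counterpart per modality,
$w_r = \eta_r\, c_r \sum_i \gamma_i y_i\, x_i^{(r)}$, where $c_r$ is
the stored normalization constant. The identity
$f(z) = \sum_r w_r^\top z^{(r)} + b$ is enforced to $10^{-8}$ by tests;
it is what makes the weight-stability analysis possible.

## Evaluation design

Performance is assessed by Monte-Carlo cross-validation: 100 random
stratified 75/25 splits, each class contributing
`round_half_up(0.75 × class size)` subjects to train (round-half-up is
pinned down so the rule is platform-stable; 11 positives yield 8 train,
3 test). All model families are evaluated on the *same* splits, so
comparisons are paired. The headline statistic is the median test ROC
AUC across splits (Mann–Whitney form, ties at half credit), with the
median precision–recall AUC alongside; PR-AUC uses the interpolated
precision envelope by default, trapezoidal integration behind a switch.

Significance comes from a permutation null: for each of $B$ replicates
(default 1000) one random permutation of the cohort label vector is
drawn, every split's test labels are replaced by the permuted values at
that split's test positions, and the median AUC across splits is
recomputed from the stored scores. The p-value is
$(1 + \#\{\text{null} \ge \text{observed}\})/(B+1)$.

One subtlety is worth recording. An alternative reading — permute each
split's test labels *independently* within each replicate — looks
equivalent but is not: the observed median is computed over splits
whose test sets share subjects and are therefore correlated, and
independent per-split permutation destroys that correlation, narrowing
the null and inflating the type-I error (measured at 0.17 for nominal
0.05 in the package's calibration simulation). With one cohort-level
permutation per replicate the test is exact: under a label-free cohort
the labels are exchangeable given the scores, and the observed
statistic is one draw from precisely the permutation distribution
sampled. The calibration simulation (200 label-free cohorts, $B = 99$)
holds the empirical rate at $p \le 0.05$ inside $[0.02, 0.09]$.

## Weight-vector stability

For each CV split the per-modality primal weight vectors of the
unimodal SVMs and of MKL are archived. Each panel (splits × features)
is row-normalized to unit norm; identically zero vectors (a modality
whose kernel weight vanished) carry no direction and are dropped with a
warning. Panels being compared — say the unimodal SVM and MKL weights
for the same modality — are projected by a *joint* PCA fit on their
stacked rows, so both live on common axes and their spreads are
directly comparable; fitting separate PCAs would make the panels'
coordinates incommensurable, and nothing in the original figure's
description settles which was done. Weight vectors are not sign-aligned
before comparison: the labels are fixed across splits, so $w$ and $-w$
are different classifiers and conflating them would overstate
stability. Zero-variance panels report explained-variance fractions of
0 rather than erroring.

The scalar summary is the **dispersion**: the mean pairwise cosine
similarity across a panel's rows (1 = every split learned the same
direction; ≈0 = unrelated directions). This statistic is this package's
own addition — a quantitative rendering of what the two-dimensional
projections show visually — and is labeled as such in reports. Top
features are ranked by mean absolute weight across splits, ties broken
lexicographically by feature label so the ranking is total.

## The synthetic cohort generator

Real scans for this problem are restricted, so the package ships a
latent-factor generator that every downstream stage is tested against.
Each subject carries unit-variance Gaussian latent factors whose class
means differ by `effect_size`: *shared* factors loading into every
modality (redundancy), *private* factors per modality
(complementarity), and *label-independent* factors per modality
(structured nuisance variation — the way scanner, motion or anatomical
variation spreads across many extracted features). A modality's matrix
is the latent matrix times a fixed random loading matrix scaled by
`modality_snr` (label factors) and `noise_structure` (nuisance
factors), plus isotropic Gaussian noise. `modality_snr = 0` gives a
modality that provably carries no label information. Subject order is
shuffled after generation so splitting code can never exploit
label-sorted rows.

The label-independent factors are not decoration: without them, every
linear classifier's weight vector collapses onto the train-split
class-centroid direction (empirically at cosine ≈ 0.96), all methods
become equally stable, and the stability analysis has nothing to
measure. Correlated nuisance directions are what let a unimodal SVM
latch onto different noise components depending on the train sample —
the multi-stability the analysis quantifies — while MKL's dual
coefficients, anchored by the other modalities, average over them.

Two presets mirror the study's analyses: `chr_vs_control` (43 vs 31)
and `converter_vs_nonconverter` (11 vs 32), both with signal widths
84 / 4851 / 4304 plus one pure-noise modality (the mean-diffusivity
analogue; its width, unstated in the source material, is set to match
the diffusion width). Defaults: 3 shared, 2 private, 2 nuisance
factors, effect size 1.0 latent SD, unit loading scales, unit noise.
An `effect_size` of 1.0 puts unimodal test AUCs in the 0.6–0.9 band —
above chance but below ceiling — which is the regime where model
comparisons are informative.

The `synergy_spec()` preset is the condition for the fusion-advantage
and stability claims: four modalities (84/500/400/300 features), one
shared + two private label factors, `modality_snr = (1, 1, 0.5, 1)` so
the third modality is the weak one, two nuisance factors at unit scale.
These values were fixed once, by pilot simulation, to realize the
regime the claims are about: genuinely complementary signal (without
it, fusion has nothing to add over the best single modality) and no
single modality at ceiling (a modality whose median AUC hits 1.0 makes
"fusion at least matches the best unimodal model" unattainable by
construction). They were not revisited afterwards.

What passing tests on this generator do **not** show: robustness to
non-Gaussian feature distributions, site or batch effects, missing
modalities, label noise, or any spatial structure of real images — the
simulation lives entirely at the extracted-feature level.

## Problem sizes used by the test suite

The full-width cohorts (4851-feature connectivity blocks) are generated
in seconds, but the suite exercises the claims at reduced widths so the
whole battery stays fast: the noise-modality and model-comparison
checks use widths 84/500/400/100 at the study's 11-vs-32 class split
with 50–100 CV splits; the fusion-advantage check runs 10 cohorts × 100
splits; the stability check 20 cohorts × 50 splits; the permutation
calibration 200 label-free cohorts of 24 subjects at $B = 99$. Cohort
size, class imbalance and the full design are never reduced — only
feature widths and replicate counts.

At $n = 43$ a test set holds 3 positives and 8 negatives, so a single
split's AUC moves in steps of $1/24$ and medians over splits remain
coarse; across independent cohorts the fusion margin fluctuates
accordingly. This is why the package states the fusion-advantage and
stability claims as *rates over seeded repetitions* rather than as
single-cohort facts, and why `scripts/acceptance.R` reports them the
same way.

## A worked example

```{r example, eval = FALSE}
spec <- synergy_spec(seed = 2024)
ds <- generate_cohort(spec)
exp <- run_experiment(ds, models = c("unimodal", "early_fusion", "mkl"),
                      n_splits = 100, n_permutations = 999,
                      master_seed = 1)
results_table(exp)

# weight stability of the weak modality
p_mkl <- collect_weights(exp, "fa", "mkl")
p_svm <- collect_weights(exp, "fa", "unimodal_fa")
c(mkl = dispersion(p_mkl), svm = dispersion(p_svm))
pca_project(list(p_mkl, p_svm))
```

## Known limitations

* The final-classifier convention ("KOMD re-solve" vs "SVM on the
  composite kernel") is an unresolved ambiguity of the method's usual
  description; both are implemented, the KOMD re-solve is the default,
  and on the synthetic benchmarks the two agree closely.
* The stacking meta-learner is a ridge-penalized logistic regression
  fit by IRLS in-package (a plain GLM cannot carry the ridge, and the
  single-modality stacking case needs a one-column design); it is this
  package's rendering of stacked generalization, not a claim about the
  original.
* Only linear kernels are provided: the dot-product kernel is what the
  primal-weight reconstruction and the stability analysis rely on.
* Hyperparameters are deliberately flat (one $\lambda$, one SVM cost,
  no inner tuning loops), mirroring the simplicity of the design the
  package reproduces; nested model selection is out of scope.
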