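---
title: "Sparse linear and multikernel multitask regression with mkmtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse linear and multikernel multitask regression with mkmtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkmtl)
```

## The multitask setting

We observe a feature matrix $X \in \mathbb{R}^{m \times p}$ and $T$ related
continuous outcomes $y_1, \dots, y_T$ (tasks), possibly each on its own
subset of the samples (an `observed` mask in `multitask_dataset`). The premise
of multitask learning is that the tasks share structure — typically, the same
small set of features or the same combination of similarity measures drives
all of them — so fitting them jointly beats fitting each alone.

`mkmtl` implements three estimators around this idea, plus the kernel,
evaluation and simulation infrastructure to use them.

## Linear $\ell_q,\ell_1$ multitask learning

`fit_lq1_mtl` minimizes

$$\tfrac12 \lVert Y - X\Theta \rVert_F^2 \;+\;
  \lambda \sum_{i=1}^{p} \lVert \Theta_{i\cdot} \rVert_q,$$

where $\Theta_{i\cdot}$ is the row of coefficients of feature $i$ across all
tasks. The row-wise $\ell_q$ norm couples the tasks: a feature is either kept
(for all tasks) or its whole row is zeroed, with $q$ controlling how the
within-row magnitudes are traded off ($q=2$ is the classic group penalty,
$q=\infty$ encourages equal magnitudes, $q=1$ decouples into per-task lasso).

The solver is FISTA with backtracking: the step size is found by doubling the
Lipschitz estimate until the majorization holds (with a mild shrink between
iterations), a monotone safeguard keeps the recorded objective non-increasing,
and convergence is declared on the relative objective change and the proximal
fixed-point residual.

The proximal map is applied row by row (`project_row_lq`):

* $q = 1$: soft thresholding;
* $q = 2$: radial shrinkage;
* $q = \infty$: an exact sorted-segment scan;
* general $q > 1$: a two-level bisection on the dual-scaling root, vectorized
  across rows (`project_matrix_lq1`).

In all cases the row is exactly zero if and only if
$\lambda \ge \lVert v \rVert_{\bar q}$ with $1/q + 1/\bar q = 1$, so fitted
supports are exact, not thresholded.

```{r linear}
sim <- gen_linear(synthetic_spec(m = 200, p = 50, n_tasks = 5, s = 5,
                                 snr = 10, seed = 1))
fit <- fit_lq1_mtl(sim$dataset, q = 2, lam = 10)
identical(which(rowSums(abs(fit$theta)) > 0), sim$support)
```

## Kernel pools

`build_pool` evaluates a list of `kernel_spec`s (linear, polynomial,
Gaussian) on the training samples and normalizes every Gram matrix to unit
trace, so base kernels enter the learners on a common scale. With
`per_modality = TRUE`, each kernel is also evaluated separately on each
feature modality (column block), which is how heterogeneous sources are fused.

Two consequences of unit-trace normalization are worth keeping in mind:

* Gram eigenvalues sit near $1/m$, so the useful $\lambda$ range of the kernel
  learners is much larger than the linear learner's (think `10^(1:5)`).
* For z-scored features, squared distances concentrate around $2p$, so
  Gaussian bandwidths should scale like $\sqrt{p}$ — a fixed bandwidth of 1 is
  effectively a delta kernel in high dimension.

## $\ell_q,\ell_1$ multikernel multitask learning

`fit_mkmtl` performs kernel ridge regression per task on the effective kernel

$$\tilde K_t \;=\; \sum_{j=1}^{k} \mu_j\, \nu_{jt}\, K_j,$$

with the kernel weights $\mu$ on the simplex (shared by all tasks) and the
task weights $\nu_{j\cdot}$ on the dual-norm ball
$\{\nu \ge 0 : \sum_t \nu_{jt}^{\bar q} \le 1\}$. Given the dual variables
$\alpha_t = -(\tilde K_t + I/\lambda)^{-1} y_t$, both weight blocks have
closed-form optimality conditions: $\nu$ by a Hölder argument
(`update_nu`; $q = 2$ degenerates to $\nu \equiv 1$, $q = \infty$ to a
vertex), and $\mu_j \propto \sqrt{b_j}$ with
$b_j = \sum_t \nu_{jt}\, \alpha_t^\top K_j \alpha_t$ (`update_mu`, an instance
of the quotient-minimization lemma implemented in `lemma1_minimizer`).

Because those closed forms are derived holding $\alpha$ at the previous
sweep's value, applying them at full length can overshoot and cycle. The
solver therefore treats each closed-form update as a *step target* and
backtracks over step lengths $1, \tfrac12, \tfrac14, \dots$, accepting the
longest step that does not increase the exactly re-solved objective
$\tfrac12 \sum_t y_t^\top (\tilde K_t + I/\lambda)^{-1} y_t$. Both feasible
sets are convex, so interpolated steps stay feasible, and the recorded
`objective_trace` is non-increasing by construction. A feasibility check runs
after every sweep (`feasibility_trace`).

Note the regularization convention: $\lambda$ multiplies the *loss*, so the
ridge in the dual is $1/\lambda$ and training residuals shrink as $\lambda$
grows — the opposite direction from the linear learner's penalty $\lambda$.

```{r mkmtl}
ds <- sim$dataset
pool <- build_pool(ds, specs = list(kernel_spec("linear"),
                                    kernel_spec("gaussian", sqrt(2 * 50))))
kfit <- fit_mkmtl(ds, pool, q = 3, lam = 100)
kfit$mu                      # simplex kernel weights
all(diff(kfit$objective_trace) <= 0)
```

With a single kernel and a single task the weights pin at 1 and the fit is
exactly kernel ridge regression — a useful correctness anchor that the test
suite checks to $10^{-8}$.

## $\ell_{2,1}\ell_q$ multikernel multitask learning

`fit_l21lq` couples the tasks through a symmetric PSD matrix $Q_j$ acting in
each kernel's feature space, under the mixed trace constraint
$\sum_j \operatorname{tr}(Q_j)^{\bar q} \le 1$, $\bar q = q/(2-q)$,
$q \in [1, 2)$. Everything is kernelized through the eigendecomposition
$G_j = V S^2 V^\top$ of the pooled Gram: the maps
$M_{tj} = S V^\top[\cdot, \text{task-}t\ \text{columns}]$ satisfy
$M_{tj}^\top M_{t'j} = G_j[t, t']$, so $Q_j$ lives in the (at most
$m$-dimensional) factor space and no explicit features are formed
(`factor_kernels`). The identity between this kernelized objective and the
explicit-feature objective is verified in the tests on a polynomial feature
map.

For fixed $Q$, the inner problem is a per-task SPD solve
(`solve_alpha_q`); the outer objective $f(Q)$ has Danskin subgradient
$-\tfrac12 \sum_t M_{tj}\alpha_t\alpha_t^\top M_{tj}^\top$
(`objective_and_gradient`) and is minimized by projected subgradient descent
with step $\eta_0/\sqrt{l}$, best-iterate tracking, and a total projection
(PSD clip plus closed-form trace rescale, `project_Q`). An entropic
mirror-descent variant is available via `mirror = "entropic"`.

One geometric fact guides expectations here: $f$ is non-increasing in $Q$ in
the PSD order, so the minimizer always sits on the trace boundary — relaxing
the bound keeps improving the objective rather than converging to any fixed
interior point such as $Q = I$.

## Evaluation and experiments

`nested_cv` runs nested cross-validation: hyperparameters (λ, and q where
applicable) are selected on inner folds by validation nMSE, the model is
refitted on the outer training fold, and features (optionally targets,
`scale_y = TRUE`) are z-scored inside each training fold to avoid leakage.
`compare_methods` runs several methods on a shared fold plan. Metrics are
per-task rMSE and correlation (`rmse_per_task`, `cc_per_task`), pooled nMSE
(`nmse`, residual sum scaled by the per-task target spread), and the
sample-size-weighted mean correlation (`weighted_r`).

```{r cv, eval = FALSE}
tab <- compare_methods(ds, c("ridge", "lq1-mtl"), seed = 1,
                       outer = 5, inner = 3)
tab
```

The synthetic generators cover the regimes the methods are designed for:
`gen_linear` (row-sparse shared support with a target SNR),
`gen_kernel_nonlinear` (targets drawn from the RKHS of a source kernel), and
`gen_multimodal` (signal split evenly across feature blocks, where a
per-modality kernel pool outperforms any single block). All are seeded,
restore the caller's RNG state, and round-trip to CSV/JSON via
`write_simulation`/`load_dataset`.

## Scope and limitations

* Experiment sizes in the tests and acceptance script (hundreds of samples,
  tens of features) are package choices for fast, deterministic verification,
  not claims about the methods' limits.
* The kernel learners assume fully dense per-task Gram blocks; very large $m$
  (beyond a few thousand) will be dominated by the $O(m^3)$ factorizations.
* The linear learner has no intercept; center the targets (or use
  `scale_y = TRUE` in `nested_cv`) when task means are nonzero.
* `fit_l21lq` uses a subgradient outer loop; objectives are accurate to the
  best-iterate tolerance, not machine precision.
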