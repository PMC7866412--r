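---
title: "Stochastic decision fusion of multi-view ripeness classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic decision fusion of multi-view ripeness classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdfuse)
```

## The problem

Fruit ripeness staging from images is an ordinal, fine-grained
classification problem: a tomato passes through five USDA color stages —
Turning, Pink, Light Red, Red, Deep Red — and the visual difference between
consecutive stages is small, while tomatoes within one stage vary a lot.
A single camera viewpoint compounds the difficulty: the stem end and the
flower end of the same fruit often color at different rates, so a classifier
looking at one end can call a different stage than a classifier looking at
the other. `sdfuse` implements decision-level (late) fusion of such per-view
classifier outputs: each view's detector produces a multi-label score vector
$P_n \in \mathbb{R}^{1 \times M}$ (independent logistic scores, non-negative,
not constrained to sum to one), and the fusion step combines the $P_n$ into
one final stage call per fruit.

## The two fusion rules

**Equal weighting.** The baseline averages the views,
$P = \sum_{n=1}^{N} \tfrac{1}{N} P_n$ (weights of $0.5$ each for two views).
Every view counts the same regardless of how good it is.

**Stochastic decision fusion (SDF).** The package's core rule weights each
view by its demonstrated reliability *for the class it is currently
calling*. Each view $n$ carries a column-normalized confusion matrix $A_n$
(rows = true class, columns = predicted class; each column divided by its
total, so the diagonal entry of column $m$ is the precision of class $m$).
If view $n$'s winning class is $m_n = \arg\max P_n$, the $m_n$-th column is
selected from *every* view's matrix, and view $n$'s weight vector is the
element-wise ratio

$$\alpha_n \;=\; a_{n,m_n} \oslash \sum_k a_{k,m_n},$$

which for two views reduces to
$\alpha_1 = a_{1 m_1} / (a_{1 m_1} + a_{2 m_1})$ and
$\alpha_2 = a_{2 m_2} / (a_{1 m_2} + a_{2 m_2})$. The fused vector is
$P = \sum_n \alpha_n \otimes P_n$ with $\otimes$ element-wise
multiplication. Both rules L2-normalize the result and decide the stage by
argmax. Precision is the right reliability notion here: on a sorting line a
false positive (calling fruit riper than it is) is the costly error.

The worked example shipped with the package makes the difference concrete.
With the stem end calling Turning at score 0.8 and the flower end calling
Pink at 0.8, equal weighting produces an *exact tie* (0.45 vs 0.45) and the
decision degenerates to the tie-break; SDF consults the matrices, finds the
stem end's Turning column far more precise, and decides Turning with a clear
margin:

```{r worked}
P_stem   <- c(0.8, 0.1, 0.05, 0.025, 0.025)
P_flower <- c(0.1, 0.8, 0.1, 0, 0)
cms <- tomato_confusion_fixtures()
sdf_fuse(list(stem = P_stem, flower = P_flower), cms)
equal_weight_fuse(list(stem = P_stem, flower = P_flower))
```

## Numerical conventions

Several corner cases are undefined in the bare formulas; the package fixes
them as follows.

* **Argmax ties** resolve to the lowest class index, i.e. the earliest
  ripeness stage. The rule is deterministic and conservative — under-calling
  ripeness is the recoverable error when sorting for shipment.
* **0/0 coordinates in $\alpha_n$** (no view has any precision mass at that
  row of the selected columns) get weight 0 by default: no evidence, no
  weight. `zero_over_zero = "half"` switches to $1/N$ for users who prefer
  the agnostic reading. Note that the denominators are per selected column,
  so the weight vectors of views that call *different* classes are not
  complements of each other — only the weights derived from one fixed
  column partition unity coordinate-by-coordinate (or sum to 0 where no
  view has mass).
* **All-zero fused vectors** are flagged `degenerate` with an undefined
  stage rather than silently mapped to class 1.
* **Confusion columns for never-predicted classes** are kept as all-zero
  columns with a degeneracy flag, so matrix dimensions never depend on the
  calibration sample.
* **Classification loss** clips scores to $[10^{-12}, 1 - 10^{-12}]$ before
  logs. The box and confidence losses use the plain Euclidean distance
  $d(u, v)$ (weighted by $\lambda_{bbox} = 5$ and, on empty cells,
  $\lambda_{nobj} = 0.1$); a `squared = TRUE` flag provides the squared-error
  variant common in the one-stage detector literature.
* **PR curve area** is the step sum $\sum_i (R_i - R_{i-1})\,P_i$ over the
  descending-threshold sweep, anchored at recall 0 (the average-precision
  convention). At tied scores all tied samples enter together; the
  monotonicity of the area under score improvements is therefore guaranteed
  only for distinct scores.
* **Metric 0/0** (class never predicted, or never true) is reported as 0
  with a flag, and macro averages always divide by the full class count M,
  matching how per-stage tables are usually averaged.

## The detector-side operations

The package does not train or run a neural detector. It implements the
surrounding, exactly specified pieces — the $S \times S \times B \times
(5+M)$ output-tensor contract, center-format IoU, greedy class-aware NMS,
and the three-part loss (localization, objectness, multi-label
cross-entropy) evaluated on toy tensors — so that every stated formula is
executable and testable. NMS thresholds default to IoU 0.45 and score 0.25,
the conventional operating point for this detector family; both are
arguments. Grid-cell/box assignment is the caller's responsibility via
`assignment_mask()`, since assignment policy (all boxes vs the responsible
box) is a training-time choice the fusion layer never sees.

## What the simulator emulates — and what it does not

Real paired-view image data for this problem is not publicly deposited, so
the package ships a score-space simulator. Each view $v$ is a row-stochastic
*kernel* $K_v$: row $c$ is the view's expected score profile when the truth
is stage $c$, built by `make_view_kernel(M, accuracy, spill)` with
`accuracy` on the diagonal, `spill` on the ordinal neighbors $c \pm 1$, and
the remainder spread uniformly — adjacent-stage confusion is exactly what
per-view confusion matrices of ripeness classifiers show. A sample's scores
are drawn as $\mathrm{Dirichlet}\!\big(\kappa (K_v[c,]+\varepsilon)\big)$
with smoothing $\varepsilon = 10^{-3}$ (exact kernel zeros stay drawable)
and concentration $\kappa$ controlling noise; the Dirichlet mean is the
smoothed, renormalized kernel row, which makes the generator's calibration
directly testable. Per-view draws are conditionally independent given the
true stage.

The default two-view configuration uses kernels
`make_view_kernel(5, 0.90, 0.04)` (stem end) and
`make_view_kernel(5, 0.78, 0.10)` (flower end) with $\kappa = 50$ — a
stronger and a weaker view with ordinal spill, echoing the asymmetry of the
shipped fixture matrices. Two caveats matter when reading test results:

* At $\kappa = 50$ the draws are tight enough that per-view argmax is
  essentially always correct, so the fusion-vs-single-view comparison at
  this operating point is an equality of (near-)perfect scores. The
  regression suite therefore also exercises a noisy operating point,
  $\kappa = 4$, where per-view macro-F1 lands in the low/mid 0.9s — the
  quality regime well-trained per-view detectors actually reach — and there
  fused decisions measurably beat the best single view.
* Simulated scores live on the simplex, whereas real multi-label logistic
  scores need not sum to one; the fusion functions accept both, and the
  simplex choice is what makes the kernel-mean property exact. The
  simulator also does not model view correlation induced by shared lighting
  or occlusion, nor localization errors — passing simulation tests shows
  the *fusion arithmetic and its calibration pipeline* behave as designed,
  not that any particular accuracy transfers to field data.

## Evaluation choices

Metrics are one-vs-rest per class (precision, recall, F1) with unweighted
macro averages over all M classes. Cross-validation (`crossval_fusion()`)
uses a seeded shuffle into k folds of sizes differing by at most one
(k = 5 by default), calibrating the confusion matrices on each training
split and fusing the held-out split — confusion matrices are *learned
parameters* and never see test data. Stratified splitting is available but
off by default.

Problem sizes in the shipped checks — 5000 evaluation samples with 2000
calibration samples for the headline comparison, 25 000 draws for the
kernel-mean calibration, 10 000 per concentration level for the
monotonicity check, and 100–1000 randomized instances per property — were
chosen so that Monte-Carlo error is well below the asserted tolerances
(e.g. the per-class mean check at $n \approx 5000$ per class has standard
errors an order of magnitude under its 0.02 bound).

## Known limitations

* Fusion operates on pre-matched samples: it assumes the per-view
  detections already refer to the same fruit. Spatial reconciliation of
  disagreeing boxes across views is out of scope.
* The generalization of the weight rule to $N > 2$ views
  ($\alpha_n = a_{n,m_n} \oslash \sum_k a_{k,m_n}$) reduces to the two-view
  formula but has no empirical validation beyond the simulator.
* The Dirichlet family is a modeling choice for the unknown class-conditional
  score distribution of real detectors; heavier-tailed or multimodal score
  behavior is not represented.
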