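---
title: "Weight imprinting for one-shot class addition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight imprinting for one-shot class addition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintr)
```

## The model

A linear classifier head scores an activation vector $x \in \mathbb{R}^M$
against $N$ classes:

$$y_i = x \cdot w_i + b_i = \lVert x\rVert\,\lVert w_i\rVert\cos\theta_i + b_i,$$

and classification is the arg-max of the raw logits (no softmax is needed
for top-1 decisions; ties break to the lowest row index so results are
reproducible). Weight imprinting adds class $N\!+\!1$ by writing a new row
$w_j$ computed directly from the activation of a training example — the
machine-learning analogue of a fast Hebbian synaptic write, where the
presynaptic activity pattern $x$ and a binary postsynaptic teaching signal
(represented here simply by *which* row is written) strengthen one row of
synapses in a single event.

Because neural activity and synaptic weights live on different scales, the
raw activation cannot serve as a weight row directly; it must be
transformed so its statistics match the original weights $W_{\mathrm{ori}}$.
The five imprints differ only in that transformation (all act on the
element-wise mean of the $K$ training activations):

* **done1** — shift so the mean equals the mean of the flattened
  $W_{\mathrm{ori}}$.
* **done2** — rescale about the activation's own mean so the population
  variance matches; the mean is deliberately left untouched, which makes
  this the affine analogue of a pure cosine head (both normalize scale but
  not location).
* **done3** — the full affine map: mean and variance both matched.
* **done4** (default) — quantile normalization: the $r$-th largest
  activation element receives the $r$-th element of the reference multiset
  $W_{\mathrm{typical}}$, so the new row's empirical distribution equals
  the reference *exactly* (all moments, not just the first two), while the
  activation's neuron ranking is preserved.
* **qi** — the cosine-classifier baseline: $w_j = x/\lVert x\rVert$, all
  original rows rescaled to unit norm, biases zeroed, and queries
  L2-normalized at prediction time. Original row *directions* are
  preserved but magnitudes and biases are not.

$W_{\mathrm{typical}}$ is built from the flattened $n_{\mathrm{ori}} \times M$
original weight block: sort all elements descending, partition into $M$
consecutive rank groups of $n_{\mathrm{ori}}$ elements, and take each
group's median. Every DONE row receives the median of the original biases
(midpoint convention for even counts; an all-zero bias vector gives 0).

## Choices where the design was open

* **Tie handling in quantile normalization.** Tied activation elements are
  ranked by ascending index (a stable descending sort). The alternative —
  averaging the reference values across tied ranks, as bioinformatics
  pipelines often do — would break the exact multiset-equality property
  that is the whole point of the method, and would not be idempotent. The
  stable rule is deterministic, idempotent, and keeps multiset equality
  exact.
* **Which elements define the moments.** For done1–done3 the mean and
  variance are taken over *all* flattened original weight elements, not
  per row, consistent with $W_{\mathrm{typical}}$ being built from the
  flattened block. Population (divide-by-$n$) variance is used throughout
  so independent oracles can agree bit-for-bit.
* **K-shot averaging order.** The $K$ training activations are averaged
  raw, before any normalization, for every method including qi
  (mean-then-normalize). Normalize-then-mean is a defensible alternative
  for qi; raw-mean is the simpler reading and is applied uniformly.
* **Sequential additions.** The reference multiset, weight moments and
  bias median always derive from rows $1..n_{\mathrm{ori}}$ only, so the
  order in which classes are added can never change any imprinted row.
* **Qi misuse guard.** A qi-imprinted head is a pure cosine classifier;
  evaluating it with un-normalized queries silently inflates logits of
  long queries. Heads carry their imprinting method as metadata and the
  prediction/evaluation functions auto-enable query L2 normalization for
  qi heads (with a warning if the caller explicitly disabled it).

## Evaluation metrics

`evaluate_classification()` reports, with the raw counts retained so every
fraction is auditable:

* per-new-class top-1 accuracy;
* original-class top-1 accuracy;
* the **interference fraction**: the share of original-class evaluation
  items whose top-1 prediction lands on *any* imprinted class — the
  practical cost class addition imposes on stored knowledge. Its
  denominator is all original-class evaluation items.

`pca_weight_scores()` projects weight rows onto principal axes fitted to
the *original* rows only (centered by their mean); imprinted or probe rows
are projected passively so they are located relative to the original
cloud without deforming it. Each axis is oriented so its
largest-magnitude loading is positive, fixing the sign indeterminacy of
eigenvectors. "In-distribution" is operationalized as membership in the
minimum-volume enclosing ellipsoid of the original rows' 2-D scores — an
exact geometric criterion rather than a Mahalanobis/χ² threshold.

## Numerical choices

* **MVEE.** Khachiyan's barycentric coordinate-ascent, default tolerance
  $10^{-6}$, at most 10,000 iterations. The ascent is stopped when the
  maximum lifted Mahalanobis score satisfies
  $m_{\max} - d - 1 \le d\,\mathrm{tol}/2$ (by the block-inverse identity
  the membership value of a point is $(m-1)/d$, so this bounds every
  defining point's membership by $1 + \mathrm{tol}/2$). Because the ascent
  converges only linearly, the returned shape matrix is additionally
  rescaled so the farthest defining point lies exactly on the boundary —
  enclosure then holds even if the iteration cap is reached first.
  Membership tests use $(q-c)^\top A (q-c) \le 1 + \mathrm{tol}$.
  Rank-deficient point sets are rejected as degenerate.
* **Exactness.** The qi self-logit (a training activation scored against
  its own imprinted class) is 1 in exact arithmetic; floating point
  reproduces it to within a few ulp, so tests assert $10^{-12}$ except in
  cases (the 3-4-5 vector) where the arithmetic is exactly representable.
* **Zero-variance activations** cannot be scale-matched (done2/done3) and
  raise an error; zero-norm activations or weight rows likewise for qi.
* **Archives.** HDF5 stores doubles natively (bit-exact round trip); the
  CSV pair prints 17 significant digits, which also round-trips IEEE
  doubles exactly. Overwrites require `force = TRUE`.

## The synthetic generator

Real backbones and image datasets are deliberately out of scope; the
generator provides the *distributional* conditions under which the
methods' behaviour differs, at desk scale.

`make_backbone()` draws latent class prototypes from a standard normal in
$M$ dimensions. Each original weight row is its prototype standardized to
sample mean `weight_mean` and population sd `weight_sd` exactly — so
pooled weight elements are bell-shaped around zero, like trained heads,
and the head classifies its own prototypes without a training loop.
Activations for a class are its prototype plus i.i.d. Gaussian noise:
returned as-is in `bell` mode (transformer-like: symmetric, near-zero
mean) or rectified at zero element-wise in `right_tailed` mode (CNN-like:
non-negative, positively skewed, positive mean). Rectification of a
Gaussian latent is the simplest mechanism producing exactly the
non-negativity-plus-positive-mean property that makes cosine imprinting
interfere. All draws come from named, counter-based RNG substreams (one
per class per purpose), so adding classes or resampling one stream never
perturbs another's values and every experiment is a pure function of its
seed.

Default study configuration: 50 original classes, 64 features,
`noise_sd = 0.5`, `weight_mean = 0`, `weight_sd = 1`, `bias_sd = 0.1`,
8 new classes, 25 evaluation items per class, seeds 0–9 for sweeps. At
this separability the interference contrast is visible but small (median
qi interference ≈ 1.6% vs 0% for done4 in right-tailed mode, and no
systematic difference in bell mode); K-shot sweeps use `noise_sd = 2`,
where one-shot accuracy is far from ceiling and the improvement from
averaging 1 → 10 → 100 training activations is clearly visible.

**What passing these tests does and does not show.** The generator
reproduces the *mechanism* — the statistical mismatch between right-tailed
activations and bell-shaped weights and its repair by
distribution-matching — not the magnitudes of any real backbone. Real
activation distributions are heavier-tailed and correlated across
features, real class structure is hierarchical, and real evaluation sets
are orders of magnitude larger; absolute accuracies and interference
fractions here say nothing about ImageNet-scale behaviour. Shifted
rectification (negative values with a small positive mean, as some
efficiency-oriented CNNs show) is not emulated.

## Problem sizes

Tests and the acceptance sweep use heads up to $1000 \times 768$ for the
quantile-normalization multiset property, the 50-class canonical
configuration for experiment sweeps (10–20 seeds), and $10^5$ pooled
samples for distribution-shape checks. The full suite runs in well under
a minute of CPU; the acceptance script in a few seconds.

## Known limitations

* Only dense classifier heads are supported; there is no feature
  extraction, fine-tuning, or calibration of logits.
* Statistical significance machinery (paired tests, outlier tests) is out
  of scope; the evaluation reports carry raw counts so users can apply
  their own.
* `mvee()` is exact only up to its iteration budget; for pathological
  point sets the returned ellipsoid is a slightly-larger-than-minimal
  enclosure (enclosure itself is guaranteed by the final rescaling).
* Checkpoint formats of deep-learning frameworks are not parsed; users
  export arrays to the documented CSV/HDF5 layout.
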