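---
title: "Hyperbolic logistic matrix factorization: model, geometry, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperbolic logistic matrix factorization: model, geometry, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lorentzMF)
```

## The problem

Drug–target interaction (DTI) prediction asks: given a binary matrix
$R = (r_{ij})$ recording which of $m$ drugs are known to bind which of
$n$ protein targets, rank the unobserved pairs by their probability of
interacting. Matrix factorization attacks this by giving every drug and
every target a latent vector and modeling the interaction probability
from the pair's compatibility. Classical factorizations embed in flat
Euclidean space; biological interaction networks, however, are
scale-free and hierarchical, and such networks embed with far less
distortion in negatively curved (hyperbolic) space. `lorentzMF`
implements logistic matrix factorization whose latent space is the
Lorentz (hyperboloid) model of hyperbolic geometry, together with the
Euclidean variant as a baseline, so the two geometries can be compared
on identical data with identical protocols.

## Geometry: the Lorentz model

Ambient space is $\mathbb{R}^{d,1}$ with the Lorentzian bilinear form
$$\langle x,y\rangle_{\mathcal{L}} = \sum_{k=1}^{d} x_k y_k - x_{d+1}y_{d+1},$$
and the latent space is the upper sheet of the unit hyperboloid
$\mathbb{H}^d = \{x : \langle x,x\rangle_{\mathcal{L}} = -1,\ x_{d+1} > 0\}$
(curvature fixed at $-1$; no curvature parameter is exposed). The
geodesic distance is
$d_{\mathbb{H}}(x,y) = \operatorname{arccosh}(-\langle x,y\rangle_{\mathcal{L}})$,
and the squared Lorentzian distance
$d_{\mathcal{L}}^2(x,y) = -2-2\langle x,y\rangle_{\mathcal{L}} = 2(\cosh d_{\mathbb{H}} - 1)$
is its monotone surrogate. The package exposes the exact primitives —
`lorentz_inner()`, `hyperbolic_distance()`, `sq_lorentz_distance()`,
`exp_map()`, `log_map()`, `parallel_transport()`,
`project_to_tangent()`, `lift_to_hyperboloid()` — and every operation
that returns a point re-establishes the constraint to machine
precision.

## The probabilistic model

The interaction probability for drug $i$ and target $j$ with embeddings
$u^i, v^j \in \mathbb{H}^d$ is the logistic link on the squared
Lorentzian distance,
$$p_{ij} = \frac{e^{-d_{\mathcal{L}}^2(u^i,v^j)}}{1+e^{-d_{\mathcal{L}}^2(u^i,v^j)}},$$
so coincident points give $p = 1/2$ (the model's maximum) and
probability decays with distance. The likelihood is Bernoulli with
confidence weights $w_{ij} = c$ for observed interactions and $1$ for
zeros (zeros mean "no interaction *or unobserved*", hence the lower
confidence). The prior on every latent row is the wrapped
(pseudo-hyperbolic Gaussian) normal $\mathcal{G}(\mu_0, \sigma^2 I)$ at
the vertex $\mu_0 = (0,\dots,0,1)$: a tangent Gaussian pushed onto the
manifold by parallel transport and the exponential map
(`rwrapped_normal()`), with the closed-form log density
$$\ln p(z) = \ln \mathcal{N}(\bar{x}\,|\,0,\sigma^2 I) - (d-1)\ln\frac{\sinh r}{r},
\qquad r = d_{\mathbb{H}}(\mu_0, z)$$
(`dwrapped_normal()`; the correction term accounts for the volume
expansion of the manifold and makes the density integrate to one, which
the test suite verifies by polar quadrature).

The negative log posterior, dropping additive constants, is the loss
minimized by `hmf_fit()` (see `hmf_loss()`): the weighted Bernoulli
term, a prior penalty
$\alpha\operatorname{arccosh}^2(x_{d+1}) + (d-1)\ln\bigl(\sqrt{x_{d+1}^2-1}/\operatorname{arccosh}(x_{d+1})\bigr)$
per row with $\alpha = 1/(2\sigma^2)$, and, when similarity matrices
are supplied, the hyperbolic neighborhood regularization
$\beta_U\sum_{ij} s_{ij}\, d_{\mathcal{L}}^2(u^i,u^j) + \beta_V\sum_{ij} t_{ij}\, d_{\mathcal{L}}^2(v^i,v^j)$,
which pulls the embeddings of similar drugs (targets) together.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `d` | latent dimension | 5 | hyperbolic embeddings saturate at much smaller `d` than Euclidean ones |
| `c` | confidence weight of observed interactions | 5 | `c = 1` gives the unweighted likelihood |
| `alpha_U`, `alpha_V` | prior precisions $1/(2\sigma^2)$ | 0.1 | `0` disables the prior entirely, including its volume-correction term |
| `beta_U`, `beta_V` | neighborhood-regularization weights | 0 | require similarity matrices |
| `eta` | initial step size | 0.05 | annealed by `lr_decay` between phases |
| `epochs_per_phase`, `phases` | schedule | 60, 3 | three phases with `lr_decay = 0.1` |
| `clip_norm` | tangent-gradient clip | 1 | guards against gradient blow-up far from the origin |
| `init_sigma2` | initialization spread | 0.01 | near-origin start avoids the unstable rim |

All quantities are dimensionless (latent coordinates on a unit-curvature
manifold).

## Optimization

`hmf_fit()` performs alternating full-batch Riemannian gradient
descent: per epoch, all drug rows are updated with targets fixed, then
all target rows with drugs fixed. Each row update is the textbook
three-step scheme — ambient gradient (with the sign of the time-like
component flipped, which converts partial derivatives into the
Lorentzian gradient representation), orthogonal projection onto the
tangent space, exponential-map step — followed by re-projection onto
the hyperboloid by recomputing the last coordinate, which is cheap,
exact, and prevents floating-point drift from accumulating. Analytic
ambient gradients are verified against central finite differences of
the loss (relative error below $10^{-5}$ on dozens of random instances
spanning all regularization regimes); this finite-difference oracle is
the package's core correctness check, because the
neighborhood-regularization gradients (derived by differentiating the
penalty with symmetrized coefficients $s_{ij}+s_{ji}$) and the
small-$r$ series limits of the prior gradient are easy to get subtly
wrong.

Numerical choices: `arccosh` arguments are clamped to $\ge 1$;
$\sinh(t)/t$-type ratios switch to series below $t = 10^{-6}$
($10^{-4}$ for the density correction); prior terms at $x_{d+1} = 1$
use their finite limits; the loss evaluates stably slightly
off-manifold so the finite-difference oracle is well posed. Learning
follows the annealing-plus-clipping heuristic standard for hyperbolic
descent: three phases, step size multiplied by 0.1 between phases,
tangent gradients rescaled to Lorentzian norm 1 when they exceed it.
A `converged` flag records whether the relative loss change across the
final phase fell below $10^{-6}$.

## Cold start and similarity handling

An entity with an empty interaction profile gets its latent vector from
the weighted-profile rule: the similarity-weighted Lorentzian center of
mass of its $J$ (default 5) most similar warm neighbors
(`weighted_profile()`). The centroid under the squared Lorentzian
distance has a closed form — the weighted Euclidean sum rescaled onto
the hyperboloid (`lorentz_centroid()`) — which the tests validate
against direct numerical minimization of the Fréchet objective; the
numerical oracle, not the formula, is the source of truth. Because the
closed form is invariant to positive rescaling of the weights, it does
not matter whether the similarity weights are normalized before or
after projection. During cross-validation, rows or columns whose
training profile becomes empty are re-embedded this way when
similarities are available, and fall back to the origin (hyperbolic) or
the zero vector (Euclidean) otherwise.

Similarity matrices may optionally be restricted to each row's $K$
strongest neighbors with `knn_sparsify()` (the usual
neighborhood-regularization practice); dense similarity matrices with
heavy tails tend to collapse the embedding into a single clump, and in
our recovery experiments $K$-NN restriction was decisively better than
dense use, so the examples and the acceptance experiments use
`knn_sparsify(S, 3)`.

## Evaluation harness

`make_folds()` implements two protocols: `pair_kfold` (the CVP test —
each round partitions all $m \times n$ cells into $k$ groups, each
group held out once with its cells zeroed in training) and `loocv_drug`
(one fold per drug, the whole row hidden — the new-compound scenario).
Metrics are AUC (midrank form, ties counted one half), AUPR (step-wise
PR interpolation, which avoids the over-optimism of linear
interpolation), average precision, and PREC@k computed over the pooled
test cells of a round (`k = 10` by default); ranking ties are broken by
a fixed seeded permutation so every reported number is reproducible.
All four metrics are checked exactly against brute-force
enumeration oracles. `run_cv()` assembles per-round metrics with mean
and standard deviation; `run_benchmark()` adds nested model selection
over a hyperparameter grid, choosing the configuration with the best
inner-split AUPR (AUPR rather than AUC, because precision-recall
metrics are the ones that matter for sparse interaction matrices) and
guaranteeing both geometries see identical folds under a shared seed.

## Synthetic data: what it emulates and what it does not

`generate_synthetic()` draws planted embeddings from the wrapped normal
at the vertex, samples interactions from the logistic link, and derives
within-domain similarity matrices by a Gaussian kernel on squared
hyperbolic distances (bandwidth = median squared distance; the kernel
is a generator choice, not part of the model). It reproduces the
model's own sampling distribution — ideal for calibration and
parameter-recovery experiments — but not several features of real DTI
data: block structure from protein families, hub drugs, curated
(non-random) missingness, and similarity matrices computed from
chemistry or sequence rather than from the latent geometry itself.
Passing recovery tests therefore demonstrates the correctness of the
machinery, not performance on any real benchmark.
`generate_tree_synthetic()` embeds a regular tree in the hyperbolic
plane with unit geodesic edges (children fanned around the parent's
outgoing geodesic), placing drugs at leaves and targets at internal
nodes: data with an explicit hierarchy, where a low-dimensional
hyperbolic embedding has a representational edge over a flat one.
`generate_synthetic_euclidean()` is the flat-space analogue for testing
the baseline against its own generative model; its default spread
(`sigma2 = 6`) is chosen so the planted labels are nearly
deterministic, making the recovery experiment a test of the fitting
machinery rather than of the Bernoulli noise floor.

## Problem sizes and known limitations

The test suite and the acceptance script use desk-scale experiments:
$60 \times 50$ matrices for recovery (five generator seeds, fivefold
CVP), $32 \times 31$ tree data (ten seeds), $10^5$ draws for sampler
moments, and $10^4$-segment discretizations for the geodesic-length
oracle. Two limitations are worth stating plainly. First, the logistic
link caps every interaction probability at $1/2$, so planted labels are
intrinsically noisy; at $60 \times 50$ with unit prior variance the
held-out AUC of the exact posterior mode sits near 0.8 — we verified
that descending the loss *from the planted truth itself* lands there —
so recovery numbers at this scale reflect an information limit of the
generative setting, not an optimizer deficiency (the same code exceeds
0.83 at $200 \times 150$ without tuning). Second, the optimizer is
plain full-batch descent with annealing; no stochastic sampling,
adaptivity, or second-order geometry is implemented, which is adequate
at these scales but not tuned for very large matrices.
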