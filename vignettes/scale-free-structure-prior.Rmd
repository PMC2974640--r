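---
title: "A scale-free structure prior for decomposable Gaussian graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A scale-free structure prior for decomposable Gaussian graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Gene association networks are estimated here as Gaussian graphical models
(GGMs): genes are the coordinates of a zero-mean multivariate Gaussian, and a
missing edge between two genes means they are conditionally independent given
all the others, equivalently that the corresponding precision-matrix entry is
zero. With `n` expression profiles on `p` genes (typically `n` much smaller
than `p`), inference is Bayesian model selection over networks:

    p(G | X)  ∝  p(X | G) P(G).

**Likelihood.** For a *decomposable* (chordal) network the covariance matrix
is given a hyper-inverse Wishart prior with hyperparameters `delta` (degrees
of freedom) and dispersion `D = tau I`, and the marginal likelihood
`p(X | G)` factorizes over the maximal cliques `C` and separators `S` of any
perfect ordering:

    log p(X | G) = sum_C log m(X_C) - sum_S log m(X_S),

where `m(X_A)` is the closed-form marginal of a saturated Gaussian on the
complete set `A`. We adopt the shape convention in which the precision matrix
of a complete set of size `k` is Wishart with `delta + k - 1` degrees of
freedom; marginally each variance is then inverse-gamma(`delta/2`, `tau/2`)
with prior mode `tau / (delta + 2)`. Because textbook conventions differ, the
convention here is pinned not by citation but by two convention-free oracles
in the test suite: 1-D quadrature of the defining integral, and Monte-Carlo
integration over covariance matrices drawn from the prior by its hyper-Markov
construction.

**Structure priors.** The baseline random prior is the Erdős–Rényi measure
`P_ER(G | beta) = beta^|E| (1-beta)^(M-|E|)`, `M = p(p-1)/2`. The scale-free
prior is the network probability under the *static model*: label the nodes
`1..p` through a permutation `pi`, give label `i` the Zipf weight
`w_i ∝ i^(-alpha)` with `alpha` in `[0, 1)`, and connect the pair with labels
`(i, j)` independently with probability `f_ij = 1 - exp(-2 K w_i w_j)`. The
ensemble has a power-law degree distribution with exponent
`gamma = 1 + 1/alpha`, and `alpha = 0` recovers the Erdős–Rényi model with
`beta = 1 - exp(-2K/p^2)` exactly (a tested identity). Because the nodes are
not exchangeable under this prior, the labeling `pi` is a genuine unknown; it
is included in the sampler state rather than marginalized, with a uniform
prior over the `p!` labelings.

**Hyperpriors.** `beta ~ U(0, 1)`, `alpha ~ U[0, 1)`, and
`K ~ U(0, K_max]` with `K_max = p(p-1)/2`. The bound on `K` is the package's
own choice: `K` is an expected attempt count whose useful range ends when the
expected edge count saturates the graph, and a bounded domain keeps the flat
hyperprior proper. (The source literature ties `K`'s domain to `alpha`
through a constraint that is not recoverable from the available text; this
substitution is documented, not inherited.)

## The sampler

A Metropolis–Hastings sweep updates the joint state `(G, theta, pi)`:

1. **Edge kernel.** A coin flip chooses add or delete; the edge is drawn
   uniformly from the non-edges or edges. Candidates outside the decomposable
   class — and boundary draws such as a delete on the empty graph — are
   immediate, counted rejections. The Hastings ratio uses the candidate
   counts of both graphs, `(M - e)/(e + 1)` for an add and `e/(M - e + 1)`
   for a delete. Whether the original implementations carried this count
   correction is not documented anywhere we can check; including it is what
   makes the chain's stationary law provably the posterior, and the
   enumeration oracle below verifies exactly that.
2. **Hyperparameter kernel.** Each component in turn receives a symmetric
   uniform perturbation of half-width `xi` (defaults: 0.05 for `alpha` and
   `beta`, `0.05 K_max` for `K`); values outside the domain are rejected
   outright.
3. **Label kernel** (scale-free prior only). A label `k` is drawn uniformly
   from `1..p-1` and the nodes carrying labels `k` and `k+1` swap them. The
   proposal is symmetric, the likelihood unaffected; only the prior ratio
   enters, and it reduces to a sum over the neighbours of the two nodes.

The likelihood of each candidate graph is assembled from per-node-set terms
memoized across the whole run, so an edge move only ever computes the few
clique/separator terms it actually changes; a cold recomputation is asserted
to agree to 1e-8 in the tests.

**Sweep schedule.** One edge move, one update per hyperparameter, and
`p - 1` label-swap proposals per sweep. The single-swap-per-sweep schedule
one might read off the kernel description is a design choice we rejected
after measurement: adjacent transpositions mix the labeling by a random walk
needing order `p^2` accepted swaps, and with one proposal per sweep the
labeling cannot sort hubs toward label 1 within realistic chain lengths. The
symptom is not subtle — `alpha` collapses toward its Erdős–Rényi corner and
the exponent estimate diverges. With `p - 1` proposals per sweep (each
`O(deg)` work) the labeling equilibrates orders of magnitude faster at
negligible cost. The schedule is configurable (`label_moves`), and a random
scan is available.

**Defaults.** 110,000 iterations, 10,000 burn-in, thinning 100, empty
initial network, identity initial labeling, `delta = 3`,
`tau = tau_for_unit_mode(3) = 5` on column-standardized data, initial
`beta = 0.5` and `(alpha, K) = (0.5, p - 1)` — `p - 1` being a tree's edge
count, the sparsity regime the simulations inhabit. Chain-length and
step-size values are workflow-shaped defaults, not reproductions: the
source text redacts the original numbers.

## The enumeration oracle

For `p <= 5` the posterior is computed exactly: every decomposable graph is
enumerated; the flat `beta` hyperprior integrates in closed form through the
Beta function; the `(alpha, K)` hyperprior is integrated by Gauss–Legendre
quadrature; and the labeling is summed over all `p!` permutations. Chain
edge marginals at `p = 3, 4` are required to sit within three batch-means
standard errors of these exact values for both priors — this is the primary
correctness gate for the sampler, and it is sensitive to any error in the
Hastings accounting.

## The synthetic world

Simulated truths are labeled trees, because a tree's conditional-independence
structure can be realized exactly by a linear Gaussian cascade: the root is
standard normal and each child is `r` times its parent plus
`sqrt(1 - r^2)` fresh noise, giving unit variances, correlation `r` along
every edge and `r^d` at tree distance `d`. The default `r = 0.7` is a
package choice (the original value is redacted): strong enough that single
edges are detectable at `n = 100`, weak enough that the problem is not
trivial.

Tree ensembles span a spectrum of degree distributions:

* **binomial** — uniform random labeled trees via Prüfer sequences (degree =
  1 + Binomial(p-2, 1/p));
* **ba** — preferential-attachment trees, asymptotic exponent 3;
* **sf(gamma)** — the weighted ensemble `P(T) ∝ prod_v w(deg v)` with
  `w(d) = (d-1)! d^(-gamma)`, sampled by a Metropolis chain whose move
  detaches a uniform leaf and reattaches it to a uniform other node, with a
  leaf-count Hastings correction. The `(d-1)!` factor cancels the Prüfer
  multiplicity of a degree sequence, so the degree-sequence law is
  `∝ prod d^(-gamma)` — a power law with exponent `gamma`. `w ≡ 1` is the
  uniform labeled-tree law, verified against the Prüfer ensemble by
  enumeration on 5 nodes;
* **crumple** — the same family in its *condensed* phase. Under the fixed
  total degree `2(p-1)` of a tree, the grand-canonical mean degree of the
  `d^(-gamma)` law is `zeta(gamma-1)/zeta(gamma)`; once `gamma` exceeds the
  point where this drops below 2 (about 2.48), the surplus degree condenses
  onto a single macroscopic hub over a power-law bulk — heavier degree
  concentration than any power law, intermediate between scale-free and
  star. The preset uses `gamma = 3`, for which the predicted hub degree at
  `p = 100` is about 61, matching what the chain equilibrates to. Note this
  *contradicts* the naive reading that small `gamma` means heavy tails: for
  `gamma < 2` the constraint is met with a strong exponential cutoff and the
  ensemble is *lighter*-tailed than at `gamma = 2.3` (we verified both
  directions empirically). Crumple chains are started at the star — inside
  the condensed phase — so the slow hub nucleation is a relaxation rather
  than a barrier crossing;
* **star** — the deterministic extreme.

**Tail-exponent estimation.** Plain log–log regression on these ensembles is
biased steep by the exponential finite-size cutoff the degree constraint
imposes. `fit_degree_exponent()` therefore fits the grand-canonical form
itself, a Poisson regression `log E[count_d] = c - gamma log d - mu d`,
which recovers `gamma` exactly on theoretical count curves. For the
preferential-attachment check the fit starts at `d_min = 8` and uses
`p = 1000`: the closed-form attachment law `4/(d(d+1)(d+2))` only nears its
asymptotic slope of 3 beyond `d ≈ 8`, and a tree's maximum degree grows like
`sqrt(p)`, so smaller trees simply contain no asymptotic regime to measure.
These choices were computed from the closed-form law, not fitted to our
samples.

## What a green test does and does not establish

The generator reproduces exactly the second-order structure of a
tree-Markov Gaussian. Real expression data differ in every inconvenient way:
non-Gaussian margins, non-tree truths, hidden confounders, measurement batch
structure. Green acceptance tests therefore establish correctness of the
machinery (priors normalize, the chain targets the right law, estimators
recover known truths at the stated scale) — not biological validity of any
estimated network.

Scaled-down settings are used throughout the stochastic tests (p = 25–50,
20,000 sweeps, 2–3 replicates) because the full-scale simulation costs hours
per table row; the reduced scale is the documented compromise and its
tolerances (±0.1 on proportions, ±0.4 on exponents) are inherited, not
retuned. At this scale the `gamma = 2.3` ensemble occasionally realizes a
tree with no real hub; its fitted exponent is then legitimately large, which
is why the exponent-recovery check averages over replicate trees exactly as
the full simulation's tables average over chains.

## Numerical choices

* `log(1 - f) = -2 K w_i w_j` is exact in this parameterization; `log f`
  uses `log(-expm1(.))`. No clamping is ever needed.
* Determinants are Cholesky factorizations of `tau I + X_A' X_A`, which is
  positive definite for every `tau > 0`.
* Chordality testing is maximum cardinality search plus a zero-fill-in
  verification; MCS ties break toward the lowest node index so clique
  orderings are deterministic.
* Labeling marginalization and graph enumeration are guarded (`p <= 9` and
  `p <= 5`) rather than silently slow.
* The per-set likelihood cache is keyed by node sets only and is therefore
  valid for exactly one `(X, hiw)` pair; `run_chain()` owns one cache per
  run.

## Known limitations

* Only decomposable graphs are visited; edge marginals are with respect to
  the decomposable-restricted posterior. Disconnected graphs are allowed —
  nothing in the model requires connectivity.
* `estimate_gamma()`'s per-record average of `1 + 1/alpha` is heavy-tailed
  when the posterior puts mass near `alpha = 0`; the alternative
  `from_mean_alpha = TRUE` transform is provided, and a diffuse exponent
  estimate should be read as "no scale-free signal", not as a precise value.
* The exact `(delta, tau)` and chain-schedule values used in the original
  analyses are unrecoverable; defaults are documented substitutes.
* Pure R throughput is roughly 2 ms per sweep at `p = 40`; hundreds of
  variables want longer patience or a compiled port of the edge kernel.
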