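---
title: "Methods: Bayesian variable selection for regulatory network inference"
author: "bvsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian variable selection for regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvsnet)
```

## The inference problem

A gene regulatory network (GRN) is a directed graph of transcriptional
influences. Perturbing one gene (with siRNA, an inhibitor, or a natural
genetic variant) shifts the steady state of the whole network, so observed
responses mix direct and indirect effects. The classical resolution is that
*at steady state, a gene's responses across perturbations are a linear
function of the responses of its direct regulators*: if $x_{ij}$ is the
response of gene $i$ to perturbation $j$ and $X^i$ collects the responses
of the candidate regulators of gene $i$,

$$x^i = X^{iT}\beta^i + \epsilon^i, \qquad \epsilon_{ij} \sim N(0, \sigma^2),$$

where $\beta^i$ holds the interaction strengths and the Gaussian residual
summarizes measurement error. Network inference is then per-gene variable
selection: decide which candidate rows of $X^i$ enter the model. With
fewer perturbations than genes — the usual case — the system is
under-determined, which motivates (a) Bayesian model averaging instead of a
single least-squares solution, and (b) informative priors built from
external evidence.

### Important caveat: a gene's own perturbation

The linear relation above has no perturbation term: it holds for
perturbations that act *elsewhere* in the network. A gene's response to a
perturbation that targets the gene itself (e.g. its own knockdown) is
dominated by the intervention, not by regulation, and behaves as one large
unmodeled residual. Left in the regression, it systematically rewards
regressors that merely co-respond to that intervention — typically the
gene's *downstream targets*, i.e. reverse edges. `expression_dataset()`
therefore carries an optional per-column annotation of the directly
perturbed gene (parsed automatically from column names of the form
`kd_<gene>`), and `infer_network()` drops, for each target gene, the
columns annotated with that gene (`exclude_self_perturbations = TRUE`).
On the package's own synthetic benchmark (20 genes, 20 knockdowns, noise
SD 0.05), this choice is the difference between mediocre and near-perfect
recovery; the test suite pins the latter. Datasets without the annotation
are used as-is.

## The configuration score

The regulators of gene $i$ are encoded by a binary vector $A^i$ over the
$n_r$ candidates ($n_i$ = number of ones). Interaction strengths get a
Zellner $g$-prior, $V_\beta = c\,\sigma^2 (X^i X^{iT})^{-1}$ with
$c = \max(n_p, n_i^2)$, and $\sigma^2$ a Jeffreys prior
$p(\sigma^2) \propto 1/\sigma^2$. Integrating both out leaves a score that
depends on the data only through the coefficient of determination $R^2$:

$$P(A^i \mid x^i, X^i) \;\propto\; (1+c)^{-\frac{n_i+1}{2}}
  \left(1 - \tfrac{c}{1+c}R^2\right)^{-\frac{n_p-1}{2}} P(A^i).$$

Conventions the implementation fixes:

* **Centering.** The response and every candidate row are mean-centered
  once at problem construction (`build_problem()`), the equivalent of an
  unpenalized intercept; $R^2$ is taken about the response mean, which is
  what makes the formula well defined. A useful consequence, asserted in
  the tests, is that rescaling any row or the response leaves $R^2$ and
  the marginal unchanged.
* **Empty model.** For $n_i = 0$ the score is evaluated with $R^2 = 0$
  (the intercept-only limit), giving $-\tfrac12\log(1+c)$ with $c = n_p$.
* **$c$ per configuration.** $c = \max(n_p, n_i^2)$ is recomputed for
  every scored configuration; it is not a global constant.
* **Identifiability.** Configurations whose Gram matrix has reciprocal
  condition number below $10^{-10}$ (collinear candidates) score
  $-\infty$ and are simply never accepted; no diagonal loading is applied.
* **Log space.** All scores are natural logs; only acceptance ratios are
  exponentiated. $(1+c)$ powers overflow otherwise for large $n_p$.
* A hand-checkable anchor, frozen in the tests: $n_p = 3$, $n_i = 1$,
  $R^2 = 1$ gives $c = 3$ and a log marginal of exactly $0$.

## Priors over configurations

* **Flat**: $P(A^i) = \gamma$; implemented as log-prior 0 (normalization
  cancels in Metropolis–Hastings ratios).
* **Sparse**: beta-binomial
  $P(A^i) = \binom{n_r}{n_i} B(n_i+\alpha,\, n_r-n_i+\beta)/B(\alpha,\beta)$
  with defaults $\alpha = 1$, $\beta = 2$. As printed the expression
  already contains the binomial coefficient, so summed over one
  representative per size it normalizes to 1 (tested to $n_r = 20$); it is
  used as an unnormalized per-configuration score, which is all the
  sampler needs.
* **Network**: $P(A^i) \propto \exp(\Gamma^i \cdot A^i)$ on the restricted
  space. Including a supported edge multiplies the prior odds by
  $e^{\alpha_c}$; including an unsupported edge changes nothing, so novel
  interactions are never penalized — they must simply earn their place
  through the likelihood.

### Building the prior network

$\Gamma$ is assembled from two evidence types. TFBS edges
(regulator → target binding-site evidence) become *direct* entries
$\Gamma_{\text{target, regulator}} = \alpha_c$. Undirected TF–TF physical
interactions extend them: if TF $b$ has a direct edge to gene $g$ and TF
$a$ physically binds $b$, then $a$ is credited with $g$ as an *indirect*
entry (and symmetrically). The expansion is deliberately depth-1 — built
from direct edges only, so partner-of-partner chains create nothing — and
an edge supported both ways is stored once as direct. All supported edges
share one confidence $\alpha_c$ (default 2, the value used in the
reference case studies); multiple supporting sources do not accumulate
weight. Autoregulatory evidence is dropped (the model class excludes
self-edges) and self-interacting PPI pairs are ignored with a warning.

### The restriction parameter k

Sampling is restricted to $\zeta_k$: configurations with fewer than $k$
regulators, $k \le n_p$. This guarantees identifiable fits without
diagonal loading and shrinks the search space. When a prior network is
available, `restriction_parameter()` sets $k$ to its average in-degree
(total edges / targets, rounded half away from zero, capped at $n_p$):
217 edges over 21 genes give $k = 10$, and 16,372 over 1,317 give
$k = 12$. Without prior knowledge the default is $k = n_p$ (the weakest
admissible restriction). In the package's under-determined benchmark the
corrupted prior's average in-degree (≈2) would cap models at one
regulator, below the generating network's typical in-degree, so the
benchmark fixes $k = 5$ for *both* priors — large enough to hold any true
regulator set there, small enough to keep the space well explored — and
attributes performance differences to the priors alone.

## The sampler

Per target gene, a Metropolis–Hastings chain on $\zeta_k$:

* **Start**: each candidate included independently with probability
  $\min(0.5,\, (k-1)/(2 n_r))$, resampled until the size is below $k$ — a
  sparse start that avoids immediate trapping at the size boundary.
* **Proposal**: uniform over the single-bit-flip neighborhood
  $\eta(A^i) \subseteq \zeta_k$. Removals are always legal; additions only
  below the boundary, so $|\eta| = n_r$ when $n_i \le k-2$ and
  $|\eta| = n_i$ when $n_i = k-1$.
* **Acceptance**: $\min\{1, \exp(s' - s)\cdot |\eta(A)|/|\eta(A')|\}$.
  The Hastings factor matters: neighborhoods are asymmetric at the
  boundary, and omitting it would bias the chain there. A rejected
  proposal re-records the current state, as the standard estimator
  requires.
* **Defaults**: 50,000 iterations, 10% burn-in, no thinning. These are
  engineering choices (the method's origin does not fix them); acceptance
  rates are reported per gene, and the tests verify the estimator against
  exhaustive enumeration rather than trusting convergence heuristics.
* **Estimator**: edge probability = inclusion frequency $n_{ij}/n_s$.
  No Rao–Blackwellization, by design.
* **Determinism**: every random draw comes from R's RNG. One master seed;
  per-gene seeds are derived by a multiplicative congruential fold of
  (seed, gene index), and per-replicate seeds of (seed, constant,
  replicate), so per-gene chains are independent, reproducible and
  order-independent; replicate $r$ reuses the same seed under every prior
  setting so that prior comparisons are paired.

The hot loop is compiled (Rcpp/RcppArmadillo) with per-configuration score
memoization; an exhaustive-enumeration reference (`exact_posterior()`,
log-sum-exp normalized) provides the independent check on small spaces.
The tests require sampled marginals within 0.02 of enumeration at 50,000
iterations on 6-gene problems, verify detailed balance empirically, and
confirm that sampled model-size distributions match enumeration under the
sparse prior.

## Synthetic data

`generate_network()` draws each off-diagonal edge independently with
probability `mean_degree/(n-1)`, magnitudes uniform on $[0.5, 1.5]$ and
repressive with probability 0.25 — effect sizes of order one on
knockdown-scale perturbations, a plausible regime for strong
transcriptional regulators. The strength matrix is rescaled to spectral
radius ≤ 0.8 so the steady-state map $x = (I-B)^{-1}p$ exists and is well
conditioned; fixture instability should never masquerade as method
failure. `simulate_perturbations()` applies that map column-wise (default
design: single-gene knockdowns encoded as −1, mimicking siRNA panels) and
adds i.i.d. Gaussian noise. `corrupt_prior()` keeps true edges with a
given recall and adds false ones at a given rate, emulating incomplete,
imprecise external evidence.

What the simulator does *not* emulate: nonlinear or dynamic (time-course)
regulation, perturbation off-target effects, correlated measurement error,
and the combinatorial logic of transcription-factor complexes beyond the
prior-network construction. Passing benchmarks on these fixtures therefore
demonstrates correctness of the inference machinery under the model's own
assumptions, not performance on any particular real dataset.

Reference study conditions used by the test suite and the acceptance
script, chosen once: recovery at $n = 20$ genes, mean degree 2, 20
knockdowns, noise SD 0.05, flat prior, 3 seeds; prior benefit at
$n_p = 10 < n = 20$, prior recall 0.8 / false rate 0.05, 10 replicates,
$k = 5$; oracle agreement on ten 6-gene, 10-perturbation problems at
$k = 3$. Each complete acceptance run is well under a minute of CPU.

## Evaluation conventions

* An edge is *called* when its posterior probability is strictly greater
  than the threshold.
* The evaluation universe is every ordered (target, regulator) pair with a
  defined posterior entry and the regulator inside the gold standard's
  regulator mask (benchmarks typically assay only a TF subset);
  self-pairs are excluded, and gold edges outside the universe are dropped
  with a notice. Directed (ordered) pairs are used throughout, matching
  the directed model.
* TPR = called true / all true; FPR = called false / all non-edges;
  precision = called true / called, defined as 1 for an empty call set
  (needed to anchor PR curves).
* AUROC and AUPR are trapezoidal integrals over the threshold sweep (all
  observed probabilities plus one value below the minimum); the PR curve
  is anchored at recall 0 with the most stringent non-empty precision.
  AUROC is cross-checked in the tests against an independent ROC
  implementation and is invariant under monotone transforms of the
  probabilities.
* Replicate comparisons use the two-sided Mann–Whitney rank-sum test
  (normal approximation with tie correction); averaged curves are vertical
  averages on a fixed 101-point grid; network similarity is Pearson
  correlation over shared defined pairs.

## Known limitations

* Linear, steady-state model: feedback through time, saturation and
  synergistic TF logic are outside the model class; inferred edges can
  reflect acausal dependence rather than causal regulation.
* Only edge *probabilities* are reported; interaction strengths $\beta$
  are integrated out and not estimated with uncertainty.
* One confidence level $\alpha_c$ for all prior edges; evidence sources
  are not differentially weighted, and heavily-connected PPI hubs can
  inflate the indirect prior.
* The restriction to $\zeta_k$ makes $k$ consequential when prior
  knowledge is poor; the average in-degree rule is a heuristic, not an
  optimum.
* Chains are fixed-length with no automatic convergence control;
  reproducibility was preferred over adaptivity. For large candidate sets,
  inspect the reported acceptance rates and increase iterations as needed.
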