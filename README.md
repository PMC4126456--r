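# bvsnet

Bayesian variable selection for inferring gene regulatory networks (GRNs)
from steady-state perturbation-response expression data, with optional
integration of prior knowledge from transcription-factor binding sites
(TFBS) and protein–protein interactions (PPI) among transcription factors.

## Who this is for

Systems biologists with a genes × perturbations response matrix — e.g.
matrix-RNAi knockdown panels, or observational expression across samples
whose genetic variation acts as "natural" perturbations — who want a
probabilistic, directed regulatory network rather than a correlation
network, and who may hold partial prior knowledge about which regulators
can bind which promoters.

## The model

At steady state, the responses `x^i = (x_i1, …, x_inp)` of gene *i* to
`n_p` perturbations are modeled as a linear combination of the responses of
its direct regulators:

    x^i = X^iᵀ β^i + ε^i,   ε_ij ~ N(0, σ²)

Which regulators enter the model is encoded by a binary configuration
vector `A^i`; finding the network means inferring these vectors. Each
configuration is scored by its posterior under a Zellner *g*-prior on the
interaction strengths (`V_β = c σ² (X^i X^iᵀ)⁻¹`, `c = max(n_p, n_i²)`)
and a Jeffreys prior on σ², which integrates to

    P(A^i | x^i, X^i) ∝ (1+c)^{-(n_i+1)/2} · (1 − c/(1+c) · R²)^{-(n_p−1)/2} · P(A^i)

where `R²` is the coefficient of determination of the least-squares fit
and `n_i` the number of selected regulators. A Metropolis–Hastings sampler
explores the space `ζ_k` of configurations with fewer than `k` regulators
(single-bit-flip proposals with the exact Hastings correction at the size
boundary); the posterior probability of edge *j → i* is estimated as the
inclusion frequency `n_ij / n_s` across samples.

Three configuration priors `P(A^i)` are available:

* **flat** — all admissible configurations equally likely;
* **sparse** — beta-binomial on the model size (α = 1, β = 2), favoring
  few regulators;
* **network** — `P(A^i) ∝ exp(Γ^i · A^i)`, where the prior weight matrix Γ
  is built from TFBS edges (direct evidence) expanded by TF–TF physical
  interactions (a TF in complex with a promoter-binding TF is credited
  with the same target, one hop only). Supported edges get a uniform
  confidence `α_c`; unsupported edges are not penalized, so novel
  interactions can still be inferred. The restriction parameter `k` can be
  set from the prior network's average in-degree (e.g. 217 edges over 21
  genes → k = 10; 16,372 over 1,317 → k = 12).

A synthetic-data module generates stability-constrained linear GRNs,
simulates knockdown responses through the steady-state map
`x = (I − B)⁻¹ p`, and degrades true networks into imperfect priors, so
the whole pipeline can be exercised and benchmarked without any external
data. Evaluation against a gold-standard edge set uses threshold-swept
ROC and precision–recall curves (AUROC/AUPR), Mann–Whitney rank-sum
comparisons across replicate runs, and Pearson network similarity.

## Worked example

Infer a 20-gene network from only 10 knockdowns (an under-determined
design) with an imperfect informative prior:

```r
library(bvsnet)

net   <- generate_network(20, mean_degree = 2, seed = 1)   # ground truth
data  <- simulate_perturbations(net, noise_sd = 0.05, seed = 2, n_p = 10)
prior <- corrupt_prior(net, recall = 0.8, false_rate = 0.05, seed = 3)

post <- infer_network(data, prior = network_prior(prior),
                      settings = chain_settings(iterations = 50000,
                                                seed = 4, k = 5))
post
#> posterior_network: 20 genes, 20 candidate regulators, k = 5
#> mean acceptance rate 0.34 over 20 chains

gold <- gold_standard(network_edges(net), regulator_mask = data$gene_ids)
roc_pr_curves(post, gold)
#> evaluation_result: AUROC = 0.975, AUPR = 0.798 (376 thresholds)
```

Each row of `post$probabilities` holds `P(A_ij = 1 | data)` for one target
gene; the top-ranked edges here (`g11 ← g1` at 1.00, `g19 ← g7` at 0.98,
`g9 ← g2` at 0.97, …) are true edges of the generating network, and an
AUROC of 0.975 means true edges are ranked above non-edges 97.5% of the
time even though the linear system is under-determined. Running the same
data with `prior = flat_prior()` drops the AUROC to about 0.90 — that gap
is the value of the prior knowledge.

The same pipeline is scriptable from a shell via the thin CLI installed
with the package (symlink it onto your PATH if you use it often):

```sh
bvsnet=$(Rscript -e 'cat(system.file("exec", "bvsnet", package = "bvsnet"))')
Rscript $bvsnet simulate --genes 20 --seed 1 --out-dir run/
Rscript $bvsnet infer --expr run/expression.tsv --iterations 50000 --k 5 --seed 4 --out-dir run/
Rscript $bvsnet evaluate --posterior run/posterior.tsv --gold run/truth_edges.tsv --out-dir run/
```

All artifacts are plain TSV/CSV plus a JSON metadata sidecar recording
seed, k, iteration count and per-gene acceptance rates.

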