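---
title: "A phylogeny-explicit Bayesian logistic model for taxon occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A phylogeny-explicit Bayesian logistic model for taxon occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`phylobeta` models the presence/absence `O[i, j]` of taxon `j` at site `i`
as a Bernoulli draw with a logit-linear dependence on one per-site
covariate `x` (in the motivating survey, stream pH):

    logit(P[i, j]) = alpha_j + beta_j * x_i

What distinguishes the model from a stack of independent logistic
regressions is the prior on the slopes. Every node of a rooted phylogeny
over the taxa — leaves and internal nodes alike — carries a slope `beta`
and a precision `tau`, and each slope is drawn around its parent's:

    beta_node ~ Normal(mean = beta_parent, precision = tau_node)
    beta_root ~ Normal(mean = 0,           precision = tau_root)
    tau_node  ~ Gamma(0.001, 0.001)
    alpha_j   ~ Normal(0, precision = 1e-6)     (leaves only)

This is a Brownian-motion-style cascade on the topology: related taxa
borrow strength from one another, so a genus seen at two sites out of a
hundred is pulled towards the environmental response of its relatives
instead of being estimated from two data points. The derived quantity
`sigma = 1/tau` is reported as the per-edge variance.

Assumptions worth stating plainly:

* **Precision parameterization.** All Normal distributions are specified
  by precision, the BUGS convention. The pairing of a Gamma(0.001, 0.001)
  prior with `sigma = 1/tau` only makes sense in this convention, and the
  intercept prior described as high-variance corresponds to precision
  1e-6 (variance 1e6). A standard-deviation reading of the same symbols
  would make that prior nearly a point mass, contradicting its purpose.
* **Topology only.** Branch lengths are discarded everywhere. Each edge
  has its own precision, estimated from the data, which partially absorbs
  what branch lengths would have encoded. Weighting the cascade by branch
  lengths is an explicit non-goal.
* **One covariate, no interactions.** The model is deliberately the
  simplest occurrence regression with a phylogenetic prior.
* **Polytomies are legal**: every child of a multifurcation draws from the
  same parent slope.
* `alpha` exists only for leaves; internal nodes have no likelihood terms.

## Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `alpha_precision` | 1e-6 | logit^-2 | diffuse intercepts |
| `tau_shape`, `tau_rate` | 0.001, 0.001 | — | near-uninformative edge precisions |
| `root_beta_mean` | 0 | logit per covariate unit | agnostic root slope |
| `n_chains` | 5 | — | study schedule |
| `burn_in`, `kept_per_chain`, `thin` | 1000, 1000, 5 | sweeps | study schedule |
| `proposal_sd_init` | 0.5 | logit | starting random-walk scale |
| `holdout_fraction` | 0.05 | fraction of taxa | preserves the topology |
| `n_rounds` | 1000 | — | study schedule |

## Sampling: what is exact and what is Metropolis

The tree interior is conditionally conjugate and is exploited exactly:

* `tau_node | rest ~ Gamma(shape + 1/2, rate + (beta_node - beta_parent)^2 / 2)` —
  one Normal increment per edge.
* An internal `beta_node | rest` is Gaussian with precision
  `tau_node + sum(tau_children)` and mean the precision-weighted average
  of the parent's and children's slopes.

Leaf `(alpha, beta)` pairs face the Bernoulli likelihood and are updated
by componentwise Gaussian random walks, with scales adapted during
burn-in (Robbins–Monro on the log scale towards 0.44 acceptance) and
frozen afterwards so the stationary distribution is untouched. One sweep
updates every `tau`, every internal `beta` in preorder, and every leaf.

Numerical choices:

* **Initialization** is deterministic and data-informed: `alpha` at the
  logit of observed occupancy clamped to [-3, 3], `beta = 0`, `tau = 1`.
* **Reparameterized leaf updates.** With a covariate centred far from zero
  (pH ~ 7.3) the intercept and slope are almost perfectly anticorrelated,
  and literal componentwise walks on `(alpha, beta)` mix an order of
  magnitude slower. Internally the chain therefore walks in
  `(gamma, beta)` with `gamma = alpha + beta * mean(x)` — a unit-Jacobian
  rotation that leaves the posterior unchanged — and transforms back when
  storing draws. This is an implementation detail of the sampler, not a
  change of model; the covariate itself is used as given. An optional
  `center_covariate` flag instead centres `x` up front, which changes
  what the reported intercepts mean and is therefore off by default.
* **Precision cap.** Gamma(0.001, 0.001) is nearly improper; `tau` draws
  are capped at 1e12 to avoid overflow. The cap sits so far in the tail
  that its posterior effect is negligible.
* **Reproducibility** is a hard contract: per-chain seeds derive
  deterministically from the configuration seed, and a fixed seed gives
  bit-identical output.
* Chains with non-finite initial posteriors error immediately; the
  deterministic initialization makes this unreachable for valid data.

Convergence is monitored with the classic Gelman–Rubin ratio over chains
(floored at 1, so identical chains report exactly 1), and
`effective_size()` provides autocorrelation-corrected Monte-Carlo sample
sizes for standard-error arguments.

## Decision bands

Evidence that a slope is real is summarized by the posterior minority-sign
mass `p = min(Pr(beta > 0), Pr(beta < 0))` (draws at zero split evenly) —
the two-sided Bayesian analogue of rejecting "no effect". A one-sided
variant is available behind a flag. The four bands are fixed:
`p < 0.05` very strong, `0.05 <= p < 0.15` strong, `0.15 <= p < 0.30`
acceptable, `p >= 0.30` little evidence. Band edges are closed on the
left because the source bands are phrased as "lower than 0.05" and
"exceeds 0.30"; exact-boundary values are measure-zero but the convention
is fixed and tested.

The no-phylogeny comparator is the same sampler run on a star topology
with the root slope frozen at its prior mean, which makes every taxon an
independent Bayesian logistic regression with the same prior family —
so any difference between the two reports is attributable to the
phylogeny, not to different machinery.

## Cross-validation

Each round holds out `max(1, round(0.05 * n_taxa))` taxa, prunes them
from tree and data, refits, and scores each held-out taxon at every site
as `logistic(alpha_bar + beta_anc * x_i)`, where `beta_anc` is the
posterior mean slope of the taxon's nearest surviving ancestor and
`alpha_bar` is the pooled mean of fitted leaf intercepts. The held-out
taxon has no intercept of its own; any constant would give the same
per-taxon AUC, and the pooled mean is a neutral, documented choice. When
every true ancestor of a held-out leaf was suppressed by pruning (a leaf
hanging directly off a root that became unary), the pruned root is used.

One AUC is computed per round, pooling the (site, taxon) pairs of all
held-out taxa; a per-taxon-averaged variant exists behind the `pooling`
option. AUC uses the Mann–Whitney pair formulation with ties counted
half. Rounds whose pooled labels are single-class have no defined AUC and
are recorded as skipped rather than imputed. The interval over rounds is
a simple percentile interval (2.5%, 97.5% by default); the rounds are not
independent replicates of the data, so the interval describes procedure
variability, not sampling error of a population parameter.

## The supertree heuristic

The package combines source topologies by collecting every rooted cluster
(descendant leaf set of an internal node) from every input, ranking
clusters by frequency across inputs, then by size, then lexically, and
greedily accepting each cluster compatible (nested or disjoint) with
those already accepted. The tree assembled from the accepted clusters is
returned. The procedure is deterministic, reproduces its inputs when they
agree, never fails on conflict (it simply leaves the conflicting region
unresolved), and on the tested examples is at least as close in
Robinson–Foulds terms to the inputs as any single input used alone. No
optimality is claimed: published analyses rarely state their supertree
algorithm, and this construction is our own, chosen for transparency.

## What the generator emulates — and what it does not

`sim_config()` defaults mirror the motivating survey's printed marginals:
24 taxa, 101 sites, covariate from Normal(7.29, 0.92) truncated to
[3.72, 8.80]. Trees are grown by sequential random leaf attachment;
slopes follow the model's own cascade with `root_beta = 1` and
`diffusion_tau = 4` (moderate, mostly-positive phylogenetic signal);
occurrence is Bernoulli at the model probabilities.

Intercepts need care. The slope cascade combined with a covariate centred
at 7.3 moves `beta * x` over many logits across taxa, so intercepts drawn
blindly from one Normal would make most taxa all-absent or all-present.
The generator instead draws
`alpha_j = alpha_mean - beta_j * env_mean + Normal(0, alpha_sd)`, i.e. it
controls each taxon's logit-occupancy at the mean environment
(`alpha_mean = -2.5`, `alpha_sd = 1.5`). This yields the strongly skewed
occupancy spectrum seen in the real survey — a few widespread taxa, many
rare ones, typically 1–50 presences out of 101 — while keeping the
generative slope structure exactly the model's own. Datasets with an
all-absent taxon are redrawn (intercept stage only, bounded retries) so
the output is always valid model input.

Because the generator reuses the model's own prior as the truth, fitting
the model to its output is a *self-consistency* exercise: calibration
and recovery results show the implementation is correct, not that the
model describes real streams. Features of real data the generator does
not emulate: spatial autocorrelation among sites, observation/detection
error beyond Bernoulli sampling, covariate measurement error, abundance,
and any misfit between the true niche structure and a logit-linear pH
response.

## Scales used by the shipped checks

The test-suite and acceptance-script experiments run at deliberately
modest scales chosen to make their conclusions stable: recovery,
calibration and shrinkage use 20 simulated surveys at full study size
(24 taxa, 101 sites) with 2 chains of 500 kept sweeps; cross-validation
checks use 30–50 rounds with single short chains. At these scales the
measured quantities sit comfortably away from their decision boundaries
(rank correlation ~0.8 vs the 0.7 line; interval coverage ~93% within
[85, 100]; strong-signal mean AUC ~0.85 with chance excluded, shuffled
null within 0.05 of 0.5).

## Known limitations

* The per-node Gamma(0.001, 0.001) precisions make rare-taxon slope
  posteriors heavy-tailed (the classic funnel); posterior *means* for
  taxa with one or two presences are volatile in both the phylogenetic
  and the star-tree fit, and the phylogenetic advantage for such taxa,
  while real on average, is not guaranteed replicate by replicate.
* A single environmental covariate; no multi-predictor support.
* The supertree heuristic is a stated construction, not an optimizer of
  any published criterion.
* Percentile CIs over cross-validation rounds understate uncertainty
  about generalization to new surveys, as all rounds share one dataset.
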