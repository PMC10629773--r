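---
title: "Network community models of glioma genetic panels and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network community models of glioma genetic panels and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Routine neuro-oncology molecular panels record, per patient, a handful of
coarse genetic domains — IDH, ATRX, TERT, histone, BRAF, 1p/19q, MGMT
methylation, EGFR amplification — each at a finer granularity (specific
point mutations, methylation bands, amplification grades).  Diagnostic
labels compress this panel into a few categories, discarding the
combinatorial structure of feature interactions.  `gliomanet` models that
structure explicitly, two ways:

1. **Feature mapping** — a directed graph over the fine-grained feature
   indicators, with edges weighted by conditional probabilities of
   co-occurrence, whose hierarchical community structure exposes groups of
   features with similar roles in the genetic landscape.
2. **Patient mapping** — a complete graph over patients, with edges
   carrying shared-feature counts, whose communities stratify patients
   into signature-defined subpopulations that can be scored for prognostic
   value against diagnosis and raw features.

Clinical panel data of this kind are not shareable, so the package also
ships a synthetic-cohort generator that plants the statistical structure
the analysis assumes; every stage is tested against that planted truth.

## Feature barcodes and the conditional-probability graph

Each domain result is fractionated into mutually exclusive indicator
columns — wildtype states included, which is what produces a 37-node
feature vocabulary from the default taxonomy.  Missingness propagates:
an unassayed domain yields missing indicators, never zeros.

For features $a, b$ the directed weight is the Bayes-rule conditional
$$W_{ab} = P(a \mid b) = \frac{P(b \mid a)\,P(a)}{P(b)},$$
estimated pairwise-complete (denominators restricted to patients with both
domains assayed).  Pairwise-complete estimation uses all available data,
and the co-assay frequencies themselves form a second, symmetric layer
$S_{ab}$, so clinically driven sampling and biologically driven
co-occurrence can be modelled separately and compared formally.  Pairs
whose conditioning feature never occurs among co-assayed patients get
weight zero and a flag, keeping the node set fixed.  With $N$ nodes there
are $2\binom{N}{2}$ possible directed edges (1332 at $N = 37$).  On exact
counts the identity $W_{ab}\,p_b = W_{ba}\,p_a = P(a \cap b)$ holds to
machine precision, and the test suite asserts it.

Conditional weights spread over a far wider range than intersection
weights (the package reports both histograms and their population
variances), which is why the directed conditional graph, not a
covariance-style graph, is carried forward.

Centralities use the directed weighted adjacency: eigenvector, hub and
authority scores by deterministic power iteration (uniform start,
tolerance $10^{-10}$, at most $10^4$ iterations); pagerank and betweenness
via igraph, betweenness on the distance transform $d = -\ln w$ floored at
$10^{-12}$ so higher conditional probability means a shorter path; the
floored distances are then divided by their minimum, which leaves every
shortest path unchanged but keeps the values away from the path solver's
absolute epsilon.  A symmetric weight matrix is treated as an undirected
graph, so unordered node pairs are counted once.

## The microcanonical stochastic block model

Community structure is inferred with a nonparametric microcanonical
stochastic block model.  The description length
$\Sigma = -\ln P(\text{data}, \text{partition})$, in nats, scores a
hierarchy of memberships $\{b_i\}$; minimizing $\Sigma$ balances fit
against complexity, and differences of $\Sigma$ convert to posterior odds
$\Lambda = e^{-\Delta\Sigma}\,P(H_a)/P(H_b)$.

All terms are documented in `?description_length` and unit-tested
term-by-term against hand evaluation.  The fixed prior choices are:

* partition prior $P(b) = \frac{\prod_r n_r!}{N!}\binom{N-1}{B-1}^{-1}N^{-1}$;
* plain adjacency likelihood
  $P(A\mid e,b) = \frac{\prod_{r<s} e_{rs}!\,\prod_r e_{rr}!!}{\prod_r n_r^{e_r}\,\prod_{i<j}A_{ij}!}$,
  and its degree-corrected form conditioning on the degree sequence with a
  uniform per-block degree prior
  $P(k\mid e,b)=\prod_r \binom{n_r + e_r - 1}{e_r}^{-1}$ (the simpler of
  the standard combinatorial forms; the restricted-partition hyperprior is
  not implemented);
* nested levels price the block multigraph uniformly,
  $\prod_{R<S}\binom{m_R m_S + E_{RS} - 1}{E_{RS}}^{-1}
   \prod_R \binom{\binom{m_R+1}{2} + E_{RR}/2 - 1}{E_{RR}/2}^{-1}$,
  with the top level forced to one block;
* edge covariates enter through conjugate marginal likelihoods per block
  pair: exponential weights with a Gamma(1,1) rate prior, normal weights
  with a normal-inverse-gamma prior ($\mu_0=0,\kappa_0=1,\alpha_0=1,
  \beta_0=1$), binomial shared counts with a Beta(1,1) prior;
* layered graphs contribute one adjacency/degree/covariate/multigraph term
  per layer with shared partitions, plus a uniform composition prior over
  the split of edges among layers.  This is an independent-layers
  formulation: an empty second layer changes $\Sigma$ by a constant only,
  and duplicated layers double the data terms but not the partition terms
  (both are asserted in tests).

The graph container is an undirected multigraph.  A directed graph is
encoded by giving each orientation its own parallel edge carrying its own
conditional weight — the block structure is then inferred from the
symmetrized multigraph.  A genuinely directed likelihood (separate in/out
group memberships) is out of scope; for the feature graphs modelled here
the two orientations carry closely related weights and the encoding
preserves both.

### Search

Inference is stochastic minimization of $\Sigma$:

1. greedy agglomerative collapse from singletons (each node moves to its
   best neighbouring block while $\Sigma$ falls);
2. an agglomerative merge exploration that folds block pairs all the way
   to a single block using block-level statistics only, recording every
   state passed — this is what lets the search cross the merge barriers
   single-node moves cannot;
3. Metropolis–Hastings sweeps: one proposed move per node per sweep in a
   seeded random order, target blocks drawn from a random neighbour's
   block mixed with a uniform block (including a fresh one) at rate
   $\varepsilon = 0.1$, accepted with probability
   $\min(1, e^{-\Delta\Sigma})$.  The proposal-ratio correction is
   deliberately omitted: the chain is used as a stochastic optimizer whose
   record (minimum-$\Sigma$) state is returned, not as an unbiased
   posterior sampler.  No burn-in is used — the chain starts from the
   state the initialization generates.
4. stopping by the record-breaking rule: terminate after `patience`
   (default 100) sweeps without a new minimum; a final greedy merge pass
   polishes the result.

Hierarchies are grown greedily: after the flat fit, the block multigraph
is recursively partitioned with the same machinery (full recompute per
move; the upper problems are tiny), levels are kept while total $\Sigma$
falls, and a bounded refinement pass revisits node-level memberships under
the fixed upper levels.  Ties in $\Sigma$ break toward fewer blocks.

On every graph with at most 8 nodes in the test fixture set, the search
attains the exhaustive minimum over all 4140 partitions, for both the
plain and degree-corrected variants.  One caution from that oracle: at
very small sizes the minimum-description-length principle under-resolves —
two disconnected 4-cliques are best described by a *single* block (23.68
vs 25.27 nats), and only from 5-cliques upward does the two-block split
win.  This is the familiar resolution limit, not a search failure; tests
that need resolvable structure use 5-cliques or larger planted graphs.

### Nulls

Two permutation nulls are built in: shuffling edge weights across edges
within each layer (topology kept), and shuffling layer labels across edges
(per-layer totals kept).  The layered feature model is compared against
the layer-shuffled null by $\Delta\Sigma$; on planted two-layer graphs the
layer-respecting fit wins in at least 9 of 10 seeded replicates, and the
package reports the posterior odds in log space because the odds
themselves overflow (the evidence is typically hundreds of nats).

## The patient graph

Patients form a complete graph; the edge between two patients carries one
binary covariate per feature (1 when both carry the indicator) and the
collapsed shared count, modelled as a binomial($K$) covariate.  Sharing
requires indicator agreement at 1 — wildtype agreement counts by default
because wildtype states are explicit indicators, and a missing result
never matches; `wildtype_agreement = FALSE` restricts sharing to
non-wildtype states, since either convention is defensible.  The collapsed
binomial model is the default for tractability; a per-feature layered
encoding is available behind a flag.

The minimum spanning tree uses distance $K - \text{shared}$ (more sharing
= closer); PCA on the zero-imputed barcode is the linear baseline, with
component signs fixed by the largest-loading-positive rule.

Community genetic loadings come from a Bayesian multinomial logistic
regression of membership on the indicators: weakly informative
Normal(0, 2.5²) priors, random-walk Metropolis-within-Gibbs (per-category
proposals, scales adapted during burn-in only), posterior means with
central 95% credibility intervals.  Near-separated data are flagged; the
prior then does the regularizing.

## Survival models

Three representations compete: community one-hots at a chosen hierarchy
level, diagnosis one-hots, and raw non-wildtype indicators — each with
standardized age and a binary sex indicator as nuisance covariates, rows
with missing time/event/age/sex dropped, survival days clamped at the 1st
and 99th percentiles (linear-interpolation quantiles), and any
community/diagnosis level with fewer than five patients removed by an
iterated filter run to a fixed point (non-iterated filtering can strand
new sub-threshold levels).

The Cox model maximizes the Breslow-tie partial log-likelihood minus
$(\lambda/2)\lVert\beta\rVert^2$ (default $\lambda = 0.1$) by Newton
iterations to gradient norm $10^{-8}$; the gradient is verified against
finite differences and the maximizer against a dense grid search and
against an independent implementation.  Performance is median out-of-fold
Harrell concordance over 5 folds stratified by event status.  Fixed-
horizon outcomes at 12/24/36 months (30.44 days/month) exclude patients
censored before the horizon — they carry no information about it, and
imputation would manufacture some.  The Bayesian logits implement ridge
and horseshoe shrinkage priors natively; the other four named schemes
alias to the nearest implemented prior with a warning, a documented
simplification.  Fits are scored by McFadden's pseudo-$R^2$ at the
posterior-mean coefficients (the pseudo-$R^2$ definition is a declared
choice) and by WAIC $= -2(\mathrm{lppd} - p_{\mathrm{waic}})$ computed
from pointwise posterior predictive densities.

## The synthetic cohort

`default_synthetic_config()` plants six subtypes with deterministic
signature profiles mapped onto four diagnosis labels; two pairs share a
diagnosis while differing in signature and hazard (medians 250/700 days
within the glioblastoma-like label, 1100/2600 within the astrocytoma-like
label), so survival-relevant structure is deliberately sub-diagnostic.
Whole domains go missing with configured probabilities (ATRX 20% by
default); survival is Weibull per subtype — shapes equal across subtypes
(all 1, i.e. exponential) so proportional hazards holds by construction —
censored by the minimum of an exponential dropout (rate set so the
configured `censor_rate` is the probability of dropout within follow-up)
and the administrative horizon; survival availability defaults to one
third of patients.  The within-diagnosis hazard contrasts were sized by a
prospective power check so that the planted community advantage in
cross-validated concordance is detectable (≥ 0.02) at cohorts of a few
hundred patients.

What the generator deliberately does **not** emulate: within-subtype
panel heterogeneity (profiles are deterministic; a block model correctly
resolves any systematically shared extra state into its own sub-community,
which would make "the" planted truth ill-defined for recovery tests),
intra-tumoural heterogeneity, variant allele frequencies, copy-number
mechanics, assay error, and any dependence of censoring or missingness on
the genotype.  Passing recovery tests on this generator therefore shows
the machinery finds identifiable planted structure at realistic marginal
rates; it does not show that real cohorts decompose as cleanly, and on
real data the fitted hierarchy should be expected to refine clinical
labels rather than reproduce them.

## Numerical and design notes

* All randomness flows through one seeded generator per entry point;
  sweep orders are seeded permutations; identical seeds reproduce fits
  bit-for-bit, and the caller's RNG state is restored on exit.
* $\Sigma$ evaluation during search uses cached block-level sufficient
  statistics; a transiently empty block is evaluated as the compacted
  partition (an empty block must not contribute prior mass).  The final
  $\Sigma$ is recomputed from scratch and asserted equal in tests.
* Weight models validate their support (non-negative for exponential,
  integers in $0..K$ for binomial); requesting a weight model on an
  unweighted graph is an error, not a silent default.
* Constant weight vectors rescale to all zeros with a warning; zero rows
  in power iteration yield zero centrality; identical ANOVA groups report
  $F = 0, p = 1$ by convention.
* Degenerate cross-validation folds (no events) are redrawn with the next
  seed, with a warning.
* Desk-scale problem sizes used by the shipped analyses and tests: feature
  graphs of 37 nodes; patient graphs up to 200 nodes (the dense builder
  refuses beyond a configurable limit of 2000); planted-recovery
  experiments at $n = 80$; survival comparisons at 700–800 patients;
  logit samplers at a few thousand iterations (the 100&nbsp;000-sample
  schedule remains the documented default for final analyses).

## Limitations

* The SBM is undirected-multigraph only; directed structure is encoded,
  not modelled with separate in/out memberships.
* The layered formulation treats layers as independent given the shared
  partition; correlated-layer models are out of scope.
* The greedy nested construction can miss hierarchies that only a joint
  multi-level move would find; the refinement pass mitigates but does not
  eliminate this.
* Horseshoe sampling uses random-walk updates, adequate at the moderate
  dimensions used here but slower-mixing than specialized samplers at
  high dimension.
* No overlapping communities, dynamic graphs, time-varying covariates,
  competing risks, or frailty terms.
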