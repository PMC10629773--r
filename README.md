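# gliomanet

Graph community models of brain-tumour genetic panels and survival.

Routine glioma molecular panels record a small set of genetic domains —
IDH, ATRX, TERT, histone, BRAF, 1p/19q, MGMT methylation, EGFR
amplification — each at finer granularity (specific point mutations,
methylation bands, amplification grades).  Diagnostic labels compress
this panel into a few categories and discard the combinatorial structure
of feature interactions.  `gliomanet` is for researchers who want to model
that structure explicitly:

* **Feature mapping.**  Panel results are fractionated into per-patient
  binary *barcodes* over fine-grained indicators (wildtype states
  included; 37 indicators under the default taxonomy).  Features become
  nodes of a directed graph with Bayes-rule conditional-probability
  weights `W[a,b] = P(a | b)` estimated pairwise-complete, a symmetric
  co-assay (sampling-frequency) layer, and `2·C(N,2)` possible directed
  edges (1332 at N = 37).
* **Hierarchical community inference.**  A nonparametric microcanonical
  stochastic block model — flat or nested, plain or degree-corrected,
  single- or multi-layer, with normal / exponential / binomial edge
  covariates under conjugate marginal likelihoods — is fitted by
  Metropolis–Hastings description-length minimization with agglomerative
  initialization and record-breaking stopping (no new minimum Σ for
  `patience` sweeps).  Model variants and permutation nulls are compared
  by description length Σ (nats) and posterior odds
  `Λ = exp(−ΔΣ)·P(H_a)/P(H_b)`.
* **Patient mapping.**  Patients form a complete graph whose edges count
  shared fine-grained features (binomial edge covariates); its block-model
  communities stratify patients into signature subpopulations, summarized
  by median survival and Bayesian multinomial genetic loadings.
* **Prognostic comparison.**  Penalized Cox proportional-hazards models
  (Breslow ties, L2 penalty 0.1, Newton solver) and Bayesian fixed-horizon
  survival logits (ridge / horseshoe shrinkage priors) are fitted on three
  competing representations — network communities, diagnosis, raw genetic
  features — and scored by 5-fold cross-validated Harrell concordance,
  McFadden pseudo-R², and WAIC.
* **Synthetic cohorts.**  Clinical panel data of this kind are not
  shareable, so the package generates cohorts with planted genetic
  subtypes, domain-level panel missingness and subtype-linked censored
  survival; every stage is validated against the planted truth.

The methods vignette
(`vignettes/network-models-of-glioma-genetics.Rmd`) documents the model,
every prior, the search, the generator's assumptions, and limitations.

## Worked example

```r
library(gliomanet)

cfg <- default_synthetic_config(n_patients = 200, survival_available = 1)
sim <- sample_cohort(cfg, seed = 1)
barcode <- fractionate_features(sim$records)

graph <- conditional_probability_graph(barcode)
pg  <- build_patient_graph(barcode)
fit <- fit_patient_communities(pg, seed = 1, patience = 60)
comm <- hierarchy_membership(fit, 1)

st <- survival_table(sim$records, barcode = barcode, community = comm)
cv_concordance(st$time, st$event, st$designs$communities, seed = 1)
```

Output (abridged):

```
nodes: 37 | possible directed edges: 1332 | nonzero: 210
weight variance, conditional vs intersection: 0.1128 vs 0.0294
block_hierarchy: 200 nodes; block counts 7 -> 1
  sigma = 52986.41274 nats; degree-corrected; weights: binomial ; nested
ARI vs planted subtypes: 0.939
median CV concordance, communities: 0.710
median CV concordance, diagnosis:   0.701
median CV concordance, raw:         0.714
```

Reading it: the 200-patient cohort yields the 37-node feature vocabulary;
conditional weights spread ~4× wider than intersection weights, which is
why the directed conditional graph is the one worth modelling.  The
patient block model compresses the complete shared-feature graph to
Σ ≈ 52,986 nats with 7 level-1 communities that recover the planted
subtypes almost exactly (ARI 0.94), and the community representation
out-predicts the coarser diagnosis labels in cross-validated concordance
(0.710 vs 0.701) because two pairs of planted subtypes share a diagnosis
while differing in hazard.

## The analysis workflow

The `analysis/` scripts run the full study end to end, writing tables
under `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate.R` | draw the default synthetic cohort + truth |
| `analysis/02_feature_graph.R` | barcodes, conditional graph, centralities, ANOVA, diagnostics |
| `analysis/03_feature_sbm.R` | layered nested SBM, model selection, layer-shuffled null, posterior odds |
| `analysis/04_patient_graph.R` | patient graph, MST/PCA baselines, communities, survival summary, loadings |
| `analysis/05_survival.R` | three-way Cox + horizon-logit comparison |

`run_pipeline(run_config(...))` performs the same stages programmatically
with one master seed and a machine-readable manifest.

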