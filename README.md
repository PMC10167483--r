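# mechassembly

Large-scale text mining of the biomedical literature produces millions of
redundant, partially overlapping, and error-prone statements about molecular
mechanisms ("MAP2K1 phosphorylates MAPK1 on T185", "MEK activates ERK",
"TP53 binds MDM2"). Multiple reading systems and curated pathway databases
describe the same underlying mechanism at different levels of specificity
and with different mistakes. `mechassembly` is an R implementation of a
knowledge-assembly engine for such corpora, aimed at computational
biologists who want to turn raw multi-source extractions into a
deduplicated, hierarchically organized, reliability-scored mechanism
network — and then use that network, e.g. to prioritize uncurated
protein–protein interactions or to explain gene codependencies observed in
perturbation screens.

## What it does

* **Statement model** — typed statements over `Agent`s carrying
  multi-namespace groundings (HGNC, UP, FPLX, ...) and molecular state
  (modifications, mutations, activity, bound partners, location), with
  evidence provenance, canonical equivalence keys, and lossless JSON
  round-tripping.
* **Normalization pipeline** — configurable filter stages: hypothesis /
  negation filtering, grounding standardization over an ontology's `xref`
  edges with a manual override table, grounded-only / genes-only /
  human-only filters, and modification-site mapping against a site table.
* **Assembly** — duplicate collapse by equivalence key, and a refinement
  graph in which an edge points from a more specific statement to each
  statement it subsumes (same type, every element equal or more specific
  via the ontology's `isa`/`partof` hierarchy, at least one strictly so).
  Evidence for specific statements is propagated to the generic statements
  they refine ("extended evidence").
* **Belief models** — the probability that a statement is correctly
  extracted given its per-source mention counts `N_k`:
  - binomial: `B = 1 − ∏_k e_rand,k^{N_k}`
  - beta-binomial: `B = 1 − ∏_k Beta(α_k, N_k + β_k) / Beta(α_k, β_k)`
  - two-parameter systematic/random model:
    `B = 1 − ∏_k (e_syst,k + e_rand,k^{N_k} (1 − e_syst,k))` for `N_k ≥ 1`

  fit to curated statements by an affine-invariant ensemble MCMC sampler
  (100 walkers, 100 + 100 steps) or deterministic L-BFGS-B maximum
  likelihood, plus feature-based classifiers (logistic, kNN, SVC, random
  forest) evaluated by cross-validated AUPRC.
* **Corpus statistics** — mention-count distributions with discrete
  power-law fitting (exact zeta MLE, log-CCDF regression, likelihood-ratio
  tests against exponential and positive lognormal), multi-source overlap
  (upset) tables, source count correlations, and empirical precision by
  mention count.
* **Applications** — comparison of complex-forming statements against a
  reference PPI list with belief-binned counts and an expected-yield curve;
  gene codependency detection from paired effect matrices (Fisher z,
  Stouffer combination, Bonferroni/BH/BY control, optional network prior)
  and single-edge explanation against the assembled network
  (direct / family-complex / parent-link).
* **Synthetic data** — generators for toy ontologies, multi-source corpora
  with power-law mention counts and per-source systematic/random errors,
  stratified curation samples, and paired dependency matrices with planted
  correlations, so the whole pipeline is testable offline.

## Worked example

```r
library(mechassembly)

cfg  <- sim_config(seed = 42, n_mechanisms = 200)
sim  <- simulate_corpus(cfg)
piped <- run_pipeline(sim$statements,
                      stages = c("hypothesis", "grounding", "grounded",
                                 "genes"),
                      ontology = sim$ontology)
corpus <- assemble_corpus(piped$statements, sim$ontology)
corpus
#> <assembled_corpus> 280 unique statements, 4 sources, 112 refinement edges
```

346 raw extractions collapse to 280 unique statements; 112 refinement
edges link specific statements (member-level, site-bearing) to the generic
ones they subsume. Fit error rates to curated statements and score the
corpus:

```r
dat <- simulate_curated_statements(2000, e_syst = 0.1, e_rand = 0.35,
                                   seed = 42)
fit <- fit_belief(dat, model = "indra", method = "mcmc", seed = 42)
fit
#> Belief model: indra (fit by MCMC, n = 2000 statements)
#> Parameters:
#>   reader1: e_syst = 0.0894, e_rand = 0.3375
#> Negative log-likelihood: 745.12
```

The sampler recovers the generating rates (0.1 / 0.35) to within 0.015.
`e_syst` is the probability the source is wrong about a statement in a way
repeated across all its mentions (so reliability plateaus at
`1 − e_syst`); `e_rand` is the per-mention error probability. Attach
beliefs (using refinement-extended evidence) and flatten to a network:

```r
beliefs <- belief_with_refinements(
  corpus, list(`__default__` = fit$params$reader1), "indra")
net <- flatten_to_network(set_beliefs(corpus, beliefs)$statements)
head(net[order(-net$belief),
         c("subject", "object", "type", "belief", "n_evidence")], 3)
#>     subject object            type    belief n_evidence
#> 18     FAM2   FAM4         Complex 0.9997797          1
#> 46     FAM4   FAM2         Complex 0.9997797          1
#> 55     FAM5   FAM3      Activation 0.9988157          1
```

Family-level statements with a single direct mention reach high belief
because many specific member-level statements refine them and contribute
their evidence. Mention-count statistics:

```r
fit_power_law(corpus)
#> Discrete power-law fit (xmin = 1, n_tail = 280)
#>   MLE exponent alpha = 3.200 (SE 0.1315)
#>   log-CCDF regression: exponent 3.676, r^2 = 0.9970
#>   LR vs exponential: 5.1 (p = 0.43); vs lognormal: 4.1 (p = 0.45)
```

(At 280 statements the likelihood-ratio tests are inconclusive, as the
p-values say; on 1e5 samples they separate decisively.)

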