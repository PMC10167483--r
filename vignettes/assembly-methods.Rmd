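---
title: "Assembling and scoring mechanistic statement corpora: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and scoring mechanistic statement corpora: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechassembly)
```

This vignette explains the models and procedures behind `mechassembly`,
the assumptions they rest on, the tunable parameters that matter, and the
design decisions taken where several reasonable choices existed.

## The statement model

A *statement* is a typed claim about a mechanism — `Phosphorylation`,
`Activation`, `Complex`, and so on — whose arguments are *agents*:
biological entities with a display name, a set of namespace groundings
(`HGNC` gene ids, `UP` UniProt accessions, `FPLX` family/complex ids,
`CHEBI` chemicals, ...), and molecular state (modification conditions,
mutations, activity, bound partners, cellular location). Each statement
carries a list of *evidence* records: one mention extracted from one
sentence of one publication by one source, or one database entry, with
epistemic flags for hypothetical and negated phrasing.

Two conventions matter downstream:

* **Unspecified slots.** "CREB1 is phosphorylated" has no enzyme. The
  missing argument is an explicit empty slot (`NULL`), which participates
  in equivalence keys and ranks below every specified agent in the
  refinement order. Treating absence as "least specific" rather than as a
  wildcard keeps the refinement relation a partial order.
* **Equivalence keys.** Duplicates are detected by a canonical string over
  the statement type, each agent's canonical grounding (chosen by a
  configurable namespace priority, `FPLX > HGNC > UP > CHEBI > GO > MESH`,
  with the bare name as fallback), all agent states, and the remaining
  arguments (e.g. residue/position). Families outrank member namespaces so
  that family-level agents canonicalize stably. The key is an explicit
  string, not a language hash, so it is identical across platforms and
  sessions. Evidence never enters the key; `Complex` members are sorted
  before keying.

Evidence identity is the tuple (source, publication id, sentence text,
record id): the same sentence processed by two readers yields two distinct
evidences, which is exactly the multi-source accounting the belief models
need.

## Normalization pipeline

`run_pipeline()` applies an ordered list of stages and reports per-stage
input/output counts (the counts always satisfy `kept + removed = input`).
The default order runs epistemic filtering first (hypotheses and negated
assertions are dropped together, each flag individually switchable),
then grounding normalization — so that the grounded-only filter that
follows sees standardized groundings — then the genes-only and human-only
filters, site mapping, and deduplication.

Grounding normalization traverses the ontology's directed `xref` paths
from every input grounding and unions everything reached; when two paths
reach the same namespace with different identifiers, the first identifier
in breadth-first order wins (the ontology is expected to be consistent;
this rule only breaks ties). A manually curated override table maps raw
entity strings to replacement groundings, or to the explicit marker
`ungrounded` for strings known to be unresolvable; this table is the
only disambiguation mechanism — no context-based disambiguation model is
included, but the override interface is where one would plug in.

Site mapping is a table-driven stand-in for reference-sequence
validation: each claimed (protein, residue, position) is `valid`,
`mapped` to corrected coordinates, or `invalid`, in which case the
statement is removed (non-reference positions are usually reading
errors). Sites absent from the table are treated as valid — a permissive
default appropriate for a partial table. The human filter keeps
family-level (FPLX) agents: families of human genes are in scope.

## Refinement

Statement `a` *refines* statement `b` when they have the same type and
every element of `a` is equal to or more specific than the corresponding
element of `b`, with at least one strictly more specific — and no element
of `b` is strictly more specific than its counterpart in `a` (mixed
directions mean no relation). Entity specificity follows directed
`isa`/`partof` paths in the ontology; both edge types participate by
default (`use_partof = FALSE` restricts to `isa`). Agent states compare
by set inclusion with per-element refinement (a site-bearing
phosphorylation condition refines a bare one); bound conditions compare
their entities through the ontology as well, which is an interpretation —
one could argue bound-partner context should compare by equality only.
`Complex` members are matched by the best correspondence over
permutations, which is exact and cheap at realistic member counts.

The refinement graph connects **all** ordered pairs in the relation (the
transitive closure); `transitive_reduction()` provides the display view.
Building it all-pairs is quadratic, so candidate pairs are generated from
an index over (type, arity, slot, entity-or-ancestor key): a statement
can only refine statements whose slot entities lie in its own slots'
ancestor closures (or are unspecified). The indexed construction is
verified against the brute-force oracle in the test suite, exactly, at
n = 200.

*Extended evidence* `E'(T)` is the union of `T`'s own evidence with the
evidence of everything that refines it, deduplicated by evidence
identity. Because the graph stores the full closure, this is a single
union per statement rather than a recursion. Extended counts dominate
direct counts componentwise by construction.

## Belief models

All three models give the probability that a statement is correctly
extracted as one minus a product of per-source joint-error terms over
sources with at least one mention; a source with zero mentions
contributes nothing.

* **Binomial**: the source's joint error on `N` mentions is
  `e_rand^N` — every mention an independent Bernoulli error. This model
  has no mechanism for a statement that stays wrong no matter how often
  it is mentioned.
* **Two-parameter systematic/random model**: with probability `e_syst`
  the source is wrong about this statement *as such* (misgrounding, a
  systematically misread construction), regardless of mention count;
  otherwise mentions fail independently at rate `e_rand`. Joint error
  `e_syst + e_rand^N (1 − e_syst)`; reliability plateaus at `1 − e_syst`.
* **Beta-binomial**: the per-mention success probability is itself drawn
  from `Beta(α, β)` per statement; the joint error is
  `Beta(α, N + β) / Beta(α, β)` (computed on the log scale via
  `lbeta` for numerical stability).

The binomial model is the `e_syst = 0` special case of the two-parameter
model — asserted numerically in the tests. The likelihood is
statement-level Bernoulli in `B(T)` over curated statements, where a
statement is *correct* if at least one of its curated mentions is correct
(and incorrect if all curated mentions are incorrect — incomplete
curation is allowed under that rule; multi-curator conflicts at the
evidence level resolve to "correct", consistent with the statement rule).
Identical count profiles are grouped before evaluation, which makes a
likelihood call O(distinct profiles) instead of O(statements).

### Fitting

`fit_belief()` samples the posterior under uniform priors — on `[0, 1]`
for error rates and log-uniform on `[1e-2, 1e2]` for `α` and `β` — with
an affine-invariant ensemble sampler (Goodman–Weare stretch moves,
`a = 2`, two alternating half-ensembles). The defaults are 100 walkers,
100 burn-in and 100 retained steps; the point estimate is the
maximum-posterior sample. On 2,000 curated statements this recovers
generating rates (0.1, 0.35) within ±0.05 in at least 9 of 10 seeds (one
seed landing just outside is consistent with the sampling noise of a
2,000-statement sample). A deterministic L-BFGS-B maximum-likelihood path
(`method = "ml"`, small multistart) gives reproducible fits without
sampling noise and is used wherever only the optimum matters, e.g. the
likelihood comparison of the three models. Beliefs of exactly 0/1 against
a contradicting label are clamped at `eps` so likelihoods stay finite;
degenerate all-one-label data yields a boundary estimate with a warning.

### Feature-based classifiers

`encode_features()` produces a deterministic matrix: per-source direct
mention counts, optional refinement-extended counts in *separate*
columns, unique-publication counts, one-hot statement type, mean mention
token length (whitespace split), and the fraction of mention texts
containing "promoter" (a marker for transcription-context sentences that
readers frequently misinterpret). `train_and_evaluate()` runs stratified
k-fold cross-validation (default 10) and reports AUPRC (step-wise average
precision; equal to prevalence for uninformative scores). Random-forest
probabilities are averaged leaf frequencies (a regression forest on the
0/1 labels) rather than tree-vote shares — vote shares are sharpened
toward 0/1 and would not be calibrated.

## Corpus statistics

Mention counts in assembled corpora are heavily long-tailed. The
power-law exponent is estimated by exact discrete maximum likelihood
(`p(x) = x^{-α}/ζ(α, xmin)`, with the generalized zeta evaluated by
direct summation plus an integral tail correction); the closed-form
continuous approximation `1 + n [Σ ln(x_i/(xmin − ½))]^{-1}` is reported
alongside as `alpha_approx` but is visibly biased for `xmin = 1` and not
used as the primary estimate. The quoted standard error is the standard
asymptotic `(α − 1)/√n`. A second, regression-based estimate fits
`log P(X > x)` against `log(x + ½)` (continuity correction), weighted by
the number of observations at each value; `exponent = 1 − slope`. On pure
power-law samples the two estimates agree within ~0.05 and the regression
r² exceeds 0.999. Model comparison against a discrete exponential
(geometric tail, closed-form MLE) and a discrete *positive* lognormal
(location constrained non-negative, numerically normalized over the
integers) uses the Vuong normalized likelihood-ratio statistic; positive
ratios favor the power law. `xmin` defaults to 1; an optional scan picks
the `xmin` minimizing the Kolmogorov–Smirnov distance of the fitted tail.
The regression fits all points as-is — no high-count trimming — and
reports r² unadjusted.

Empirical precision by mention count is a plain stratified proportion,
optionally restricted to statements supported by a single source;
monotonicity in the count is deliberately *not* assumed anywhere —
systematic errors produce plateaus.

## Codependency analysis

Per gene pair, Pearson correlations are computed in each of two replicate
effect matrices on pairwise-complete observations (minimum overlap 4
samples; smaller overlaps are skipped and logged), converted to signed
z-scores by the Fisher transform `z = atanh(r) √(n − 3)` — the
transform is the standard variance-stabilizing choice and preserves
sign — and combined across the two datasets by Stouffer's method,
`(z₁ + z₂)/√2`. Two-sided p-values feed Bonferroni, Benjamini–Hochberg or
Benjamini–Yekutieli control via `stats::p.adjust`; a network prior
restricts the hypothesis set, and pairs significant only under the prior
are reported separately. Pairs where *both* genes are mitochondrial are
excluded before testing (pervasive co-variation of mitochondrial genes in
screens would otherwise dominate); pairs with exactly one mitochondrial
gene are retained.

Explanations are single network edges only — multi-step paths never
count — in priority order `direct` (edge between the genes), then
`family_complex` (shared `isa`/`partof` ancestor), then `parent_link`
(edge touching a gene's family parent), most to least specific, so the
labels are exclusive and deterministic.

For reference-PPI comparison, binary `Complex` statements are binned by
belief (width 0.1); the sum of beliefs over statements absent from the
reference estimates the number of correct-but-uncurated interactions, and
the cumulative sum in descending belief order is the expected curation
yield curve. The estimate is accurate exactly to the extent the beliefs
are calibrated, which the test suite checks on synthetic data.

## The synthetic-data generator

The generator emulates the statistical structure the methods are designed
for, with defaults chosen once as the reference study conditions:

* ontology of 6 families × 4 member genes, with `isa` membership and
  UP-alias `xref` edges;
* 300 true mechanisms over those genes (type mix weighted toward
  phosphorylation; 70% of phosphorylations carry a site);
* mention counts drawn from a discrete power law with exponent 2.38 — the
  long-tailed regime a literature-scale corpus exhibits — capped at 1,000;
* three reader sources at `e_syst = 0.1`, `e_rand = 0.35` (a mid-range
  reader profile, matching the parameter-recovery reference point) and
  one database source at `0.01/0.05` (curated databases are
  high-reliability);
* systematic errors modeled as one coin flip per (mechanism, source)
  that replaces *all* of that source's mentions by one fixed corrupted
  variant — the generative story behind the `e_syst` parameter — while
  random errors corrupt mentions independently;
* per-mention specificity degradation (30% site drop, 20% member→family
  generalization) so generic and specific variants coexist and the
  refinement graph is non-trivial;
* codependency block: 40 genes × 500 samples, 20 planted pairs at
  `ρ = 0.5`, unit noise, two independent replicates.

Everything is deterministic given the seed. What the generator does *not*
emulate: real sentence text (only token counts and the "promoter"
keyword), reader-specific error signatures, citation structure
(publications are sampled uniformly), and corpus-scale statement counts.
Passing tests therefore demonstrate the correctness and calibration of
the machinery under the model's own assumptions, not the empirical error
rates of any particular reading system.

The curation-style generator used for fitting draws mention counts
uniformly over 1–10 (mirroring stratified curation sampling) and labels
statements by the same systematic/random process, so `P(correct | n)`
equals the two-parameter model's `B(n)` exactly; this is what makes the
calibration bands in the test suite (±0.05 per belief bin at n ≥ 5,000)
meaningful.

## Numerical choices and limitations

* Beta functions on the log scale; beliefs clamped to `[eps, 1 − eps]`
  (`eps = 1e-12` in the public likelihood, `1e-9` inside the grouped
  fitting objective) only where a 0/1 belief meets a contradicting label.
* The ensemble sampler uses the standard `z^{d−1}` stretch-move
  acceptance factor; chains are initialized uniformly over the prior box.
* `findInterval` on a tabulated CDF samples the discrete power law
  exactly up to the table cap (1e6 when untruncated); the neglected tail
  mass is < 1e-9 at the exponents used.
* Refinement candidate generation assumes canonicalized groundings; two
  statements about the same entity grounded in different namespaces
  without ontology links will not be related.
* Problem sizes in the tests — 200-statement oracle comparisons,
  2,000-statement fits, 1e5-sample exponent recovery, 40×500 dependency
  matrices — were chosen as the smallest sizes at which the statistical
  assertions are stable across seeds.
* `Complex` refinement requires equal member counts; a three-way complex
  does not refine its binary sub-complexes. Multi-step causal reasoning
  over the flattened network is out of scope.
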