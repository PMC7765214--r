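---
title: "Sons-and-Spouses Bayesian networks: models, search, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sons-and-Spouses Bayesian networks: models, search, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbn)
```

## The modelling problem

Health-survey extracts are tables of categorical answers — demographics,
diagnoses, binned laboratory values — with one rare binary outcome of
interest, such as a depression indicator derived from a quality-of-life
instrument. Clinically useful analysis of such data needs more than a
predictive score: it needs an explicit, inspectable model of which factors
bear on the outcome, how strongly, and what a hypothetical change in a
subject's profile would do to their risk.

`ssbn` models such a table as a discrete Bayesian network: a directed
acyclic graph whose nodes are the variables and whose joint distribution
factorises as

$$P(x_1, \dots, x_n) = \prod_i P(x_i \mid \mathrm{pa}_i),$$

one conditional probability table (CPT) per node. All inference is exact:
posteriors and marginal likelihoods are computed by variable elimination
with a min-degree elimination order, which is entirely adequate at the
scale the package targets (tens of nodes, cardinalities 2–5). A
brute-force enumeration (`posterior_enumerate()`) is kept as an in-package
cross-check; the test suite also verifies the engine against an
independently written full-joint oracle.

## Supervised structures

Three classifier structures are learned from data, all keeping the target
parentless:

* **Naive Bayes** (`learn_naive_bayes()`): every feature is a child of the
  target. No feature selection — irrelevant variables stay in the model.
* **TAN** (`learn_tan()`): the classical tree augmentation. Feature–feature
  edges are weighted by conditional mutual information given the target
  (base 2), a maximum-weight spanning tree is built, and the tree is
  directed outward from the feature with the highest mutual information
  with the target. Every feature ends up with the target plus at most one
  feature parent.
* **Sons and Spouses** (`learn_sons_and_spouses()`): a supervised
  neighbourhood around the target consisting of its children ("sons") and
  the other parents of those children ("spouses"). Spouses never carry an
  arc to or from the target, and variables that end up connected to
  nothing are dropped, so the learned network doubles as feature
  selection — `select_features()` returns children(target) ∪
  parents(children) − target.

The original description of the Sons-and-Spouses method names the output
topology but not the learning algorithm, so the search here is a
reconstruction, documented as such: (1) features whose *relative binary
mutual information* with the target — $100 \cdot I(X; T) / H(T)$ percent —
exceeds `mi_threshold` (default 0.1%) become candidate sons; (2) arcs are
added greedily from the legal set {target→candidate son, feature→son},
each step taking the largest BIC improvement, with ties broken
lexicographically by child then parent, subject to acyclicity and
`max_parents` (default 3, the target included); (3) unconnected variables
are pruned. The procedure is a deterministic function of the data.

Counting is available-case — a record contributes to a family if it is
complete for that family — but each candidate arc's BIC improvement is
evaluated with both the extended and the current model counted on the
*same* records (those complete for child, current parents, and the
candidate parent). This matters: if the two likelihoods were taken on
different available-case subsets, merely dropping a few incomplete rows
would register as a likelihood gain and pull arbitrary variables into the
model. Records missing more than 20% of their columns are excluded up
front, mirroring the record-exclusion step such surveys require.

Parameters are maximum-a-posteriori estimates with a symmetric Dirichlet
pseudo-count (`smoothing`, default 1 — Laplace). Smoothing 1 keeps every
CPT entry strictly positive, which matters downstream: classification and
explanation scoring never meet a hard zero from sampling accidents.

## Strength and relevance metrics

All information quantities are base-2 (bits), matching the explicit log2
of the divergence the method family is built on.

* `kl_divergence(p, q)`: $\sum_s p_s \log_2 (p_s/q_s)$, with $0\log 0 = 0$
  and an `Inf` sentinel (not an error) when `q` lacks support.
* `mutual_information()` / `conditional_mutual_information()`: empirical,
  on rows complete for the columns involved.
* `arc_force()`: the KL divergence between the network's joint and the
  joint of the same network with one arc deleted and the child refit on
  the data — "how much of the distribution does this arc carry?". For a
  two-node network fit by maximum likelihood this equals the empirical
  mutual information of the pair, which the tests exploit as a closed-form
  identity.
* `state_bayes_factor()`: $P(x = s \mid T = t) / P(x = s \mid T = \bar t)$,
  the single-evidence likelihood ratio. `target_report()` tabulates, per
  node: relative binary MI, the posterior mean of zero-based state codes
  (a compact location summary for ordered states; a convention, since the
  quantity is not otherwise pinned down), and the extreme Bayes factors
  for *both* target directions. Reporting both directions explicitly is
  deliberate: a single two-column max/min layout is ambiguous because the
  two directions are exact reciprocals of each other.

## Explanations: the generalized Bayes factor

For a partial assignment $x$ (the explanation) and evidence $e$ on
disjoint variables,

$$\mathrm{GBF}(x; e) = \frac{P(e \mid x)}{P(e \mid \bar x)},
\qquad
P(e \mid \bar x) = \frac{P(e) - P(e, x)}{1 - P(x)}.$$

The complement is handled by total probability — never by enumerating the
complement set. GBF > 1 means the explanation makes the evidence more
likely; the measure is deliberately asymmetric in $x$ and $e$ (it is a
likelihood ratio, not an odds ratio), and `gbf_chain()` verifies the
chain-rule decomposition $\mathrm{GBF}(x; e_1,\dots,e_n) =
\mathrm{GBF}(x; e_1)\prod_i \mathrm{GBF}(x; e_i \mid e_{<i})$, which is
algebraically exact for every ordering and is asserted to 1e-9 in the
tests. $P(x) \in \{0, 1\}$ leaves no complement to compare against and is
an error; a zero denominator with a positive numerator returns the `Inf`
sentinel, because a caller searching explanations must be able to keep
going.

### Genetic-algorithm search

The *most relevant explanation* task — maximise GBF over partial
assignments of a candidate set — has a search space of
$\prod_j (k_j + 1)$ configurations, so `run_ga()` searches it with a
plain generational GA: chromosomes with one gene per candidate (a state
index or "unset"), tournament selection (size 3), one-point crossover
(rate 0.8), per-gene mutation (rate 1/L), elitism (2). The source method
names the operators but none of the run parameters; the defaults here
(population 100, 50 generations) were chosen once for desk-scale
determinism and are documented as a reconstruction. Elitism makes the
best fitness per generation non-decreasing, which the implementation
asserts on every run at the resolution the ranking uses (10 significant
digits — ties below that are interchangeable under the deterministic
tie-break: GBF descending, then fewer bound variables, then the
lexicographic gene string). The all-unset chromosome scores exactly 1 and
an ill-defined GBF scores 0, so fitness is total. `allow_unset = FALSE`
restricts the search to full profiles, mirroring published risk-profile
tables.

`exhaustive_mre()` enumerates the whole space (vectorised over an
augmented-margin array) under the same fitness and tie-break and serves as
the optimality reference: on 8–10 binary candidates the GA with defaults
matches it in at least 18 of 20 seeded runs in the acceptance checks, and
can never exceed it.

Repeated GBF queries share an inference cache: one variable-elimination
pass computes the exact joint over (candidates, target), and each query
becomes a slice sum. Past 2^19 joint cells the engine switches to
per-query variable elimination instead — both routes are exact; the cap
only trades memory for per-query time.

`whatif()` is the deployment-facing query: the posterior of the target's
positive state under a hypothetical profile, with its change from the
prior.

## Evaluation protocol

`evaluate_cv()` runs stratified k-fold cross-validation (default 10) of
the NB/TAN/SS classifiers. Records are scored with the target posterior;
prediction is the argmax with ties toward the negative (majority) class;
a record whose profile is impossible under the fold's network falls back
to the prior and is counted. Two protocol choices are worth stating
because the source protocol leaves them open, and both were made for
stability under a ~5% positive class: folds are stratified, and the
confusion matrix is pooled across folds (micro-averaged) rather than
averaged per fold — per-fold averages are noisy when a fold holds only a
handful of positives. AUC is the midrank Mann–Whitney statistic, so it is
invariant to monotone transformations of the scores. A classifier that
never predicts the positive class has no defined precision or F-measure;
both are reported as missing with a `degenerate` flag rather than as 0,
mirroring the "N/A" convention of published benchmark tables.

## The synthetic cohort

Because the original survey data cannot be redistributed, the package
ships a generator whose defaults are the study conditions the rest of the
package is tested under: a binary `depression` target with prevalence
0.055, seven sons (children of the target) with cardinalities 2–5 and
survey-flavoured names, six spouses (parents of distinct sons, no arc to
the target) with cardinalities 2–3, six isolated noise variables, and
completely-at-random cell masking to exercise the record-exclusion step.
An optional three-level instrument rendering of the target
(`eq5d = TRUE`) makes the none/some/extreme → binary merge itself
testable via `merge_states()`.

Son CPTs concentrate a randomly chosen risk state: probability `risk_lo`
(0.15) in the target-negative baseline, modulated by up to
`spouse_effect` (0.25) across the spouse's states, and `risk_hi` (0.93)
in the target-positive rows. Two deliberate choices:

* The target-positive risk mass is high and the spouse modulation lives in
  the target-negative rows. With 5.5% prevalence, the positive rows of a
  son's CPT are informed by a small fraction of records (further split by
  spouse states), so weak positive-row contrasts would be unestimable at
  realistic cohort sizes; the strong separation also matches the large
  explanation Bayes factors and what-if posterior jumps this kind of risk
  model is built to surface.
* Spouse cardinalities stay at 2–3 (sons and noise span 2–5) for the same
  reason: each spouse state partitions its son's rare positive rows.

The stored `high_risk_profile` attribute is the single-state-per-son
assignment with maximal target posterior. Because spouses are assigned to
distinct sons, sons are conditionally independent given the target and
the per-son likelihood-ratio argmax is exactly the joint argmax; the test
suite confirms this by enumeration on a small cohort.

What passing tests on this cohort do *not* show: faithfulness to any real
survey's marginals, survey weights, informative missingness (masking is
MCAR), ordinal structure in the answer scales, or continuous laboratory
values. The generator emulates the *shape* of the problem — rare target,
dependent categorical covariates, distractors, missingness — not its
content.

## Numerical conventions and degenerate inputs

* CPT rows are validated to sum to 1 within 1e-9; parent configurations
  are enumerated in odometer order over the (lexicographically canonical)
  parent list, last parent fastest, so serialization is bit-stable.
* Impossible evidence is a classed error (`ssbn_impossible_evidence`),
  distinct from unknown-variable/state errors; callers that need totality
  (classification, GA fitness) catch it explicitly.
* All randomness flows through caller-supplied integer seeds; no function
  reads or perturbs the session RNG state.
* JSON serialization writes probabilities at 17 significant digits and
  XMLBIF at `%.17g`, so round-trips preserve posteriors beyond 1e-12.
* Exact enumeration (arc force, exhaustive explanation search, the
  brute-force posterior) refuses state spaces beyond an explicit cap with
  a `too_large` error rather than thrashing.

## Problem sizes used in the checks

The bundled checks run at the scales the methods are designed for:
structure recovery at 20,000 records (10 seeds for the TAN tree, 5 for
the sons-and-spouses selection), parameter recovery at 100,000 records
(maximum absolute CPT error ≤ 0.02), generator calibration at 50,000
records (prevalence within ±0.5 points of 5.5%), inference and GBF
identities on 100 random networks of up to 8 nodes, and the GA–oracle
comparison on 20 networks with 8–10 binary candidates.

## Known limitations

* Exact inference only: no conditional-Gaussian nodes, no dynamic
  networks, no approximate inference — out of scope by design.
* The Sons-and-Spouses search is a greedy BIC reconstruction of a method
  whose published description names only the output topology; whether the
  original constrained spouses per son, or optimised a different score, is
  unknowable from the description.
* The GA returns the top-k of its final population; with strong ties
  (e.g. several profiles at the same GBF) the set it surfaces depends on
  the seed, though the optimum itself does not in the tested regimes.
* Available-case counting is unbiased only under MCAR missingness, which
  is what the generator produces; informatively missing surveys need
  upstream care.
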