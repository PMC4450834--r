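---
title: "Ontological patient similarity: model, weighting, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontological patient similarity: model, weighting, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosim)
```

## The model

`ontosim` measures how similar two clinical reports are when each report is
reduced to a set of concept ids from an is-a terminology. The measure has
three ingredients.

**Semantic distance.** The terminology is a rooted DAG whose edges point
from a child concept to its parents. The distance from an extracted term
`d` to a feature concept `f` is 0 if they are the same concept, the minimum
number of is-a edges on an upward path if `d` descends from `f`, and
unreachable otherwise. Unreachability is represented by R's `Inf`: it is a
typed IEEE value, not a magic number, and the only arithmetic ever applied
to it is the vector formula below, where `1 / (1 + Inf)` correctly yields 0.
The distance is deliberately asymmetric — it is defined walking *up* the
hierarchy only — and the test suite asserts that the reverse direction is
unreachable whenever the forward one is not.

**Feature vectors.** Feature concepts are all concepts at one hierarchy
level; each defines a vector dimension, ordered lexicographically by
concept id (C locale) so the dimension order never depends on session
settings. For a report with terms `d_1 … d_n`, element `i` is

$$a_i = \frac{\sqrt{p_i}}{1 + \min_{j = 1 \dots n} s_{ij}},$$

and the vector is closed with a regularization element `δ = 10^-k`. An
empty report, or a feature concept that none of the report's terms descends
from, gives `a_i = 0` exactly (no epsilon flooring; `sqrt(0) = 0`). The
weight `p_i` is the conditional probability of the feature concept given
the disease of interest; it modulates how much each dimension can
contribute.

**Modified direction cosine.** Similarity is the cosine of the two
δ-augmented vectors. Because both norms are at least `δ > 0`, the score is
defined for every pair — including two empty reports, which score exactly 1
— and lies in (0, 1]. Without the augmentation the cosine would be 0/0 for
an empty report.

## Weighting schemes

* **equal** — `p_i = 1` everywhere: the unweighted baseline.
* **generic** — `p_i` is estimated once per feature concept as the fraction
  of disease-mentioning abstracts that also mention the feature concept or
  one of its synonyms. Weights are shared by all reports.
* **specific** — each extracted term `t` gets
  `q_t = #(term ∧ disease) / #(disease)`; a report's weight for feature `f`
  is the plain mean of `q_t` over the report's terms that descend from (or
  equal) `f`. Weights therefore differ between reports. When a report has
  no term under `f` the weight is set to 0 — an inert choice, since `a_i`
  is already 0 there, but it keeps the weight table total. The mean is
  unweighted by term frequency: reports carry term *sets*, so a frequency
  weighting has no natural source.

Counts come from a `count_provider`, which is the seam where a live
literature index could be plugged in. Two implementations ship: a local
corpus provider (case-insensitive whole-phrase matching with word-boundary
anchoring, each abstract counted at most once per group — an approximation
of a search engine's phrase query) and a recorded count-table provider that
replays numbers captured from any external index. Recorded tables key each
query group by its first (preferred) name, lower-cased, with `*` as the
reserved marginal key, and reject joint counts exceeding a recorded
marginal. A live remote client is intentionally out of scope: a
time-varying external service cannot anchor reproducible tests.

## Evaluation

Every unordered report pair is labeled `match` (same diagnosis) or
`mismatch`. The similarity score is evaluated as a classifier of that label
with:

* AUROC by the rank (Mann–Whitney) formulation, midranks for ties; the
  threshold-sweep curve collapses tied scores so its trapezoidal area
  equals the rank statistic to 1e-9 (asserted in tests);
* a Hanley–McNeil standard error for the single-curve 95% interval;
* DeLong's covariance of placement values for comparing two AUROCs computed
  on the same pairs, with a two-sided p-value (the sidedness is a package
  choice; both score tables must cover the identical pair set, and
  identical tables give difference 0, p = 1).

Pairs sharing a report are statistically dependent; the primary analysis
treats pairs as exchangeable, which is the convention of full-cohort
pairwise designs.
`cluster_bootstrap_auroc()` is provided as a labeled sensitivity analysis
that resamples *reports* rather than pairs; it is not part of the primary
pipeline.

`sweep_k()` recomputes the AUROC across `k = 0 … 12` (default). Small `k`
lets δ dominate: with `k = 0` the unit δ makes scores sensitive to vector
norms and inflates the similarity of term-poor reports regardless of
content, which degrades the ranking; as `k` grows the score converges
monotonically to the plain cosine of the raw vectors and the AUROC
saturates. The chosen `k` is the smallest one within a plateau tolerance
(1e-3) of the maximum — a deliberately conservative reading of "the curve
has flattened". Only the feature part of the matrix is rebuilt once per
sweep; δ is swapped per `k`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `level` | 4 | hierarchy level of the feature concepts |
| `root_level` | 0 | level assigned to the root; set 1 for one-based conventions |
| `k` | 10 | regularization exponent, `δ = 10^-k` |
| `plateau_tol` | 1e-3 | AUROC tolerance defining the k-sweep plateau |
| `conf_level` | 0.95 | confidence level of the AUROC interval |

The root-level convention is exposed because published level numbers depend
on whether the root counts as level 0 or 1; both conventions reach the same
feature sets via the offset. With multiple parents, both concept levels and
semantic distances take the minimum over upward paths — the standard
edge-counting convention, and consistent with the minimum over terms inside
the vector formula. A term that descends from several feature concepts
scores against each of them independently.

## The synthetic-data generators

The generators exist so that every stage has testable ground truth.

**Ontology.** Levels grow under a Poisson branching model (mean `branching`
children per concept), each concept takes one uniform parent on the level
above and, with probability `multi_parent_prob` (default 0.1), a second
parent on the same level — keeping levels exact while making the graph a
true DAG. Level sizes are floored at 2 because a real terminology never
pinches to a single concept mid-hierarchy, and a one-concept level would
make that level unusable as a feature slice. Concepts carry 0–3 synthetic
synonyms.

**Cohorts.** Reports sample their terms from a per-label panel. Because
reports are compared after projection to feature concepts, label signal
only exists when labels differ in which *feature subtrees* their terms
occupy; `make_panels()` therefore partitions the feature concepts between
labels (dropping terms whose ancestors span labels) with a controllable
shared fraction: overlap 0 plants a near-perfect signal, overlap 1 plants
none. Within a panel, terms are drawn with Zipf weights
(`rank^-panel_concentration`, default exponent 1.5): clinical finding
frequencies are heavy-tailed — a few common findings recur in most
same-diagnosis reports — and uniform panel use would understate how often
two same-diagnosis patients share a finding. Non-empty reports carry
`max(1, Poisson(terms_per_report))` terms (default mean 3) and a fraction
`empty_report_prob` (default 0.1) of reports has no terms at all, the case
the δ regularization exists for.

**Corpora.** Abstracts follow an abstract-level Bernoulli co-mention model:
each abstract mentions the disease with probability `disease_prob`, and
conditional on disease status each vocabulary term is mentioned
independently with its planted probability. This is the simplest model
under which the count-ratio estimators are consistent, with binomial
standard error `sqrt(p(1-p)/n_disease)`; the recovery tests assert
agreement within three standard errors. Mentions are embedded as whole
phrases, randomly choosing the preferred name or a synonym so that synonym
expansion is exercised.

What the generators do **not** emulate: real radiology language (no
free-text realism beyond phrase embedding), correlated findings within a
report, term-extraction noise, polysemy between concept names, or the
query semantics of an actual literature index. Passing tests therefore
demonstrate the correctness and calibration of the computational pipeline
under a known model — not the clinical performance that would be obtained
on real reports against a live index.

## Numerical and degenerate-input choices

* Ties in term ranking break lexicographically by term id; ties in scores
  use midranks throughout the ROC machinery.
* `sim(x, x) = 1` is asserted to 1e-12 relative tolerance (pure
  floating-point cosine); similarity tables are emitted at full precision
  and rounded only for display.
* Vectors built over different feature spaces or different `k` raise a
  contract error rather than being silently reconciled, as are
  report-specific weight tables applied to the wrong report.
* A cohort with a single diagnosis label yields a warning at pair-labeling
  time and a hard error at ROC time; a disease group matching zero
  abstracts raises an undefined-denominator error.
* A degenerate DeLong variance (identical score tables) returns z = 0,
  p = 1 when the difference is 0.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to exercise
the design realistically while staying quick: the pair-formation check uses
the full 112-report (59 + 53) two-label design; distance oracles enumerate
all pairs on random DAGs of up to 20 nodes; weight recovery uses 5000
disease abstracts; DeLong calibration uses 1000 null replicates of 100 + 100
scores; the end-to-end synthetic study uses 80 reports over a ~200-concept,
depth-6 hierarchy and a 5000-abstract corpus, run separately with disjoint
and identical panels.

## Known limitations

* Only is-a relationships are modeled; other relationship types, and
  release-format parsing of real terminologies, are out of scope.
* Generic and specific weights are point estimates of count ratios; no
  shrinkage or smoothing is applied to rare terms (a term with a tiny
  marginal count gets a noisy weight).
* The corpus matcher is a phrase matcher, not a tokenizer: punctuation
  boundaries follow regex word boundaries, and hyphenated variants of a
  name are distinct phrases unless listed as synonyms.
* AUROC confidence intervals treat pairs as independent; use the cluster
  bootstrap to gauge the effect of shared-report dependence.
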