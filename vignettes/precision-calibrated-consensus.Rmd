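---
title: "Precision-calibrated consensus ranking for pharmacophore screening"
author: "pharmscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-calibrated consensus ranking for pharmacophore screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

A ligand-based pharmacophore model $x_i$ is a one-class classifier: a
compound is retrieved when at least one of its conformers presents the
model's typed feature points in the required geometry.  `pharmscreen`
treats each model probabilistically.  On a calibration set of known
actives and inactives, the probability that a compound matching $x_i$ is
active is estimated by the model's precision,

$$P(Y \mid x_i) \;=\; \frac{N_{Y \cap x_i}}{N_{x_i}},$$

where $N_{x_i}$ counts the labelled compounds the model retrieves and
$N_{Y \cap x_i}$ the actives among them.  For a compound matching the
set $X$ of models, two consensus estimates of $P(Y \mid X)$ are
provided:

* **Max scheme** — $P(Y\mid X) = \max_{x_i \in X} P(Y \mid x_i)$;
* **Mean scheme** — $P(Y\mid X) = \sum_{x_i \in X} P(Y\mid x_i) / S$,
  with $S$ the total number of models in the set.

Both reduce to classical baselines when every probability is forced to
one: Max becomes the OR-consensus (any match is a hit, no ranking) and
Mean becomes the common-hits approach (CHA, the matched fraction).
Unlike those baselines, the calibrated schemes rank compounds, and both
are insensitive to poorly performing models, whose precisions — and
therefore contributions — are near zero.  Geometric or harmonic pooling
and plain products of $P(Y\mid x_i)$ lack this robustness (one poor
model collapses the score); they exist only as the comparison utility
`score_pooled()` and are never used for ranking.

### The Mean denominator

The reduction of Mean to CHA forces $S$ to be the total number of
models, and that is the default.  Reading $S$ as the number of *matched*
models is also defensible and is available as
`denominator = "matched"`; the two coincide for compounds matching
everything and differ most for sparsely matched compounds.

### Undefined precisions

Precision is undefined for a model that retrieves no calibration
compound ($N_{x_i} = 0$).  Such models carry an explicit `NA`, contribute
probability zero to every consensus score (no evidence of precision is
treated as no evidence of activity — the conservative choice), and are
dropped by `filter_models()` whenever a precision threshold is active.

## Calibration conventions

Activity classes come from the conventional potency cut-off: a compound
is active when its affinity on the $-\log_{10}$ molar scale is at least
6 log units (1 µM).  The boundary belongs to the active class, and the
threshold is a parameter (`assign_activity_class(threshold = )`), not a
constant.  Structures recorded as both active and inactive (after
whatever structure standardisation produced the caller's structure
keys) are removed outright by `remove_conflicting_duplicates()`;
within-class duplicates collapse to one record.  Because each model is
typically trained on a subset of the labelled corpus, calibration
accepts per-model exclusion sets so that every model is scored only on
compounds outside its own training data.

Model complexity is measured as the number of features with *distinct
coordinates*: features closer than 0.01 Å are merged (single linkage)
before counting, separating genuinely co-located features from
numerical noise.  Precision filtering is strict ("larger than"): a
model at exactly the threshold is dropped, and an empty retained set is
legal — selection is then empty and enrichment is zero.

## The simplified 3D matcher

The matcher answers one question: does any conformer of a compound
admit an injective, type-compatible assignment of the model's features
such that every pairwise inter-feature distance is reproduced within a
tolerance (default 1.0 Å)?  Pairwise-distance correspondence needs no
explicit superposition, is invariant under rigid motion, and is
monotone in the tolerance.  It is deliberately simpler than production
matchers that bin distances or optimise overlays; it exists so that the
probabilistic pipeline can be exercised end to end from structures, and
it is checked against exhaustive assignment enumeration in the test
suite.  Users with an external matcher can skip it entirely and supply
match matrices as CSV/TSV.

Feature perception uses an editable rule table (`feature_rules()`)
covering the standard six-type alphabet (donor, acceptor, aromatic,
hydrophobic, anion, cation).  Group features sit at the centroid of the
matched atoms.  The rules are intentionally compact — e.g. hydrophobic
points require a connected cluster of at least three heteroatom-free,
non-aromatic carbons — and are data, so they can be aligned with an
external tool's definitions by editing rows.  Conformers of enumerated
stereoisomers are pooled under one compound identifier: a compound
matches if *any* conformer of *any* stereoisomer matches.  Tautomer
grouping is the caller's responsibility via identifier assignment.

## Evaluation battery and universe conventions

Rankings are evaluated the way virtual-screening benchmarks report
them:

* **EF, precision, recall** are computed over the *selected* universe —
  compounds matching at least one model — at retrieved fractions
  0.25%, 0.5%, 1%, 2%, 5% and 10% by default.  The top slice holds
  $\lceil f N_\mathrm{sel} \rceil$ compounds (never empty, so small
  fractions remain well defined).  The enrichment baseline rate is
  always the *full* test set's active rate, which makes EF at 100% of
  the selected set ("EF$_{100\%}$") a non-trivial baseline shared by
  Max, Mean and CHA.
* **ROC AUC and BEDROC** consider the full test set, with unselected
  compounds assigned probability zero.  AUC uses the Mann–Whitney
  convention (ties count one half).  BEDROC's decay parameter is
  derived from a fraction by the exponential weight-share rule
  $(1-e^{-\alpha f}) = 0.8\,(1-e^{-\alpha})$, which gives the familiar
  $\alpha \approx \ln(5)/f$ for small fractions (160.9 at 1%, 32.2 at
  5%, 16.1 at 10%) and degenerates to $\alpha = 0$ at 100%, where
  BEDROC is therefore refused.

Ties are resolved deterministically by input order (stable sort)
everywhere; an optional `ties = "expected"` mode reports EF, precision
and recall averaged analytically over permutations of the tie group cut
by a slice boundary.  BEDROC always assigns tie-group-average ranks, so
coarse score sets (e.g. the single-model case) are scored independently
of input order.  Note that with very few distinct score values, heavy
score ties place actives at deep average ranks and early-weighted
BEDROC values are legitimately small even when EF at the same fraction
is maximal — the metric is answering a different question (how sure is
the *within-list order*), and this shows most at the smallest
fractions.

## The synthetic benchmark generator

`synthetic_design()` + `generate_match_benchmark()` stand in for a
labelled screening corpus: each model matches actives with probability
$s_i$ (its sensitivity) and inactives with probability $b_i$ (its
false-positive rate), independently across models and compounds, for
$n_A$ actives and $n_I$ inactives per split.  The expected precision of
model $i$ is then analytically

$$\pi_i = \frac{s_i\,n_A}{s_i\,n_A + b_i\,n_I},$$

so estimated precisions, their ranking, and downstream enrichment can
be verified against ground truth.  Calibration and test splits are
independent draws from the same design, reproducible per seed (R's
default Mersenne-Twister generator; seeds are recorded in the emitted
manifest).

Independence across models is the generator's main idealisation — real
pharmacophores share features and overlap in their hit lists.  A
shared-latent-factor mode (`latent_sd > 0` shifts each compound's match
logits by a common normal draw) induces correlation for sensitivity
analyses.  The generator also does not imitate property-matched decoy
selection; passing tests therefore demonstrate correctness of the
calibration/consensus/metric machinery, not transferability of
calibration precisions to structurally divergent libraries, which
remains the method's main applicability-domain caveat.

Geometric fixtures for the matcher are built with guarantees rather
than realism: every model gets a distinct feature-type set (so
cross-model matches are impossible by type), "actives" embed a model's
geometry under rigid motion with per-point displacement below half the
tolerance (the triangle inequality then bounds every pairwise-distance
deviation below the tolerance), and "decoys" stretch one inter-feature
distance by 2.5 tolerances, which makes the type-forced assignment
infeasible.

## Worked example

```{r example}
library(pharmscreen)

design <- synthetic_design(n_active = 500, n_inactive = 1500,
                           sensitivity = c(0.6, 0.6), fpr = c(0.01, 0.6))
analytic_precision(design)

bench <- generate_match_benchmark(design, seed = 1)
fit <- pcc(bench$calibration$matches, bench$calibration$labels)
coef(fit)

report <- evaluate_ranking(bench$test$matches, fit$precision_table,
                           scheme = "max", labels = bench$test$labels)
report
```

The high-precision model dominates the Max ranking; early enrichment
(`1%` column) far exceeds the EF$_{100\%}$ baseline, which is what
calibration buys over the uncalibrated OR-consensus.

## Numerical and design notes

* **Problem sizes.** The shipped tests calibrate on splits of 2 000 to
  4 000 compounds, recover designed precisions over 200 seeds, and
  verify metrics exhaustively at $N = 8$; these sizes give binomial
  standard errors well below the asserted tolerances while keeping the
  default check quick.
* **BEDROC stability.** The closed form is evaluated with `expm1` and
  the identity $\cosh u - \cosh v = 2\sinh\frac{u+v}{2}\sinh\frac{u-v}{2}$,
  so $\alpha = 10^{-6}$ reproduces the AUC to $10^{-3}$ without
  catastrophic cancellation.  The closed form is algebraically
  identical to normalising the empirical RIE between its best- and
  worst-case placements, which is how the test oracle computes it.
* **Matcher search order.** Backtracking assigns the model feature with
  the fewest type-compatible candidates first; the visit order affects
  speed only, never the decision.
* **Degenerate inputs.** Zero-conformer compounds match nothing;
  all-active or all-inactive test sets make AUC/BEDROC meaningless and
  raise a degenerate-input error (exit code 3 in the CLI); an empty
  selected universe yields EF 0 by convention.

## Limitations

The matcher is a simplified pairwise-distance implementation, not a
re-creation of any production tool, so hit lists will not reproduce an
external matcher's exactly; the intended interchange point is the match
matrix.  Calibration-set precision transfers to a new library only to
the extent that the library resembles the calibration corpus — the
method's honest dependency, inherited by this implementation.  No
significance testing between schemes is provided.
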