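# pharmscreen

Precision-calibrated consensus ranking for pharmacophore-based virtual
screening.

## What problem this solves

A ligand-based pharmacophore model retrieves a compound when at least
one of its conformers presents the model's typed 3D feature points
(donor, acceptor, aromatic, hydrophobic, anion, cation) in the right
geometry.  Screening campaigns usually have *many* such models per
target and combine them crudely: OR-consensus (hit = matches any model;
no ranking, and one promiscuous model floods the hit list) or the
common-hits approach (CHA; rank by the fraction of models matched, all
models weighted equally).

`pharmscreen` treats every model as a probabilistic one-class
classifier instead.  On a labelled calibration set, the probability
that a compound matching model *x<sub>i</sub>* is active is estimated
by the model's **precision**

> P(Y | x<sub>i</sub>) = N<sub>Y∩x<sub>i</sub></sub> / N<sub>x<sub>i</sub></sub>

(actives retrieved over total retrieved).  A screened compound matching
the model set *X* is then scored by either

* **Max scheme**: P(Y | X) = max<sub>i</sub> P(Y | x<sub>i</sub>), or
* **Mean scheme**: P(Y | X) = Σ<sub>i∈X</sub> P(Y | x<sub>i</sub>) / S,
  with S the total number of models,

which rank the library, degrade gracefully to OR-consensus / CHA when
all probabilities are 1, and are insensitive to poor models (their
precisions are near zero).  The package is aimed at cheminformaticians
who already produce pharmacophore match data (any matcher that can emit
a compound × model boolean matrix works) and want calibrated, rankable
consensus scores plus the standard virtual-screening evaluation
battery.

Included:

* `pcc()` — the fitting function: calibrate a model set on a labelled
  match matrix; methods `print`, `summary`, `coef`, `predict`,
  `simulate`, `plot`.
* A simplified 3D matcher (`match_model()`, `build_match_matrix()`)
  with feature perception from SDF input via an editable rule table,
  for running the pipeline straight from structures.
* Calibration utilities: activity-class assignment at a log-affinity
  threshold, conflicting-duplicate removal, per-model calibration
  exclusions, precision/complexity model filters.
* Metrics under benchmark conventions: enrichment factors at fixed
  fractions with the EF<sub>100%</sub> baseline, BEDROC with
  fraction-derived alpha, ROC AUC, precision/recall.
* A synthetic benchmark generator with analytically known model
  precisions, and a command-line interface
  (`inst/scripts/pharmscreen`) with subcommands
  `match | calibrate | rank | evaluate | simulate`.

## Worked example

Two models screen a library: one precise, one promiscuous.  The
synthetic design makes the truth known (analytic precisions 0.952 and
0.250):

```r
library(pharmscreen)

design <- synthetic_design(n_active = 500, n_inactive = 1500,
                           sensitivity = c(0.6, 0.6), fpr = c(0.01, 0.6))
bench  <- generate_match_benchmark(design, seed = 1)

fit <- pcc(bench$calibration$matches, bench$calibration$labels)
coef(fit)
#>       M01       M02
#> 0.9369369 0.2540717

report <- evaluate_ranking(bench$test$matches, fit$precision_table,
                           scheme = "max", labels = bench$test$labels)
report
#> Screening report -- scheme 'max'
#> Test set: 2000 compounds (500 active), 1336 selected by >=1 model
#>
#>  fraction EF precision recall BEDROC
#>     0.25%  4         1  0.008  0.000
#>      0.5%  4         1  0.014  0.000
#>        1%  4         1  0.028  0.000
#>        2%  4         1  0.054  0.018
#>        5%  4         1  0.134  0.363
#>       10%  4         1  0.268  0.688
#>
#> EF_100%: 1.26   AUC ROC: 0.801
```

Reading the numbers: calibration recovered the designed precisions
(0.937 ≈ 0.952, 0.254 ≈ 0.250).  Ranking by the Max scheme puts
compounds matched by the precise model first, so the top 1% of the
selected set is all active — EF = 4, the maximum possible at a 25%
base rate — while selecting everything any model retrieves
(EF<sub>100%</sub>, what OR-consensus gives you) only enriches 1.26-
fold.  That gap is what precision calibration buys.  The small BEDROC
values at the tightest fractions reflect the coarse score set of a
two-model consensus: large tie groups get average ranks, and the
early-weighted metric does not credit an order it cannot see.

The methods vignette
(`vignettes/precision-calibrated-consensus.Rmd`) documents the model,
the universe conventions behind each metric, tie handling, the
generator's assumptions, and known limitations.

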