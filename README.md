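# qsarens

QSAR ensemble modelling and virtual screening for enzyme-inhibition
discovery, built as a tidyverse-native R package.

## The problem

Medicinal chemists screening for inhibitors of a protein target (the
motivating case is dipeptidyl peptidase 4, DPP4, a type-2-diabetes target)
need two things from a QSAR model: a *qualitative* call — will this molecule
inhibit the enzyme at lead-like potency (IC50 ≤ 50 nM)? — and a
*quantitative* estimate of the potency itself (pIC50 = −log10 IC50 [M]),
together with an honest statement of when either prediction should not be
trusted. `qsarens` implements the full model-construction and deployment
pipeline for that workflow:

1. **Curation** of raw SMILES + IC50 tables: salt/water stripping and
   canonicalization (Open Babel), relation-qualifier filtering, duplicate
   resolution — concordant replicate measurements (sd/mean < 0.2) collapse
   to their geometric mean, discordant ones are rejected — and labelling by
   the ≤ 50 nM activity rule or the pIC50 transform.
2. **Descriptors** through a pluggable provider (built-in:
   ChemmineR/Open Babel 2D descriptors organized in a 20-category
   registry); any backend that returns named numeric columns plugs in.
3. **Preprocessing**: constant/non-finite column removal, |r| > 0.90
   Pearson correlation filter, kNN imputation (k = 3, uniform weights),
   standard scaling — all fitted on training data and re-applied
   bit-reproducibly at prediction time; k-means cluster-stratified 75/25
   train/validation splitting.
4. **Feature selection** by a genetic algorithm over descriptor subsets:
   penalized five-fold cross-validated fitness (F1 or R²), top-50% parent
   selection, half-and-half recombination, 30% mutation and 30% deletion,
   elitist survival over up to 200 generations.
5. **Models**: random forest, extra trees (both via `ranger`) and discrete
   AdaBoost (in-package, over `rpart` trees), tuned by exhaustive
   grid search with cross-validated F1; an extra-trees regressor for
   pIC50. Classifiers combine by hard (majority) or weighted soft voting
   P = Σwᵢpᵢ/Σwᵢ, with deployed weights (0.1, 0.7, 0.2) for
   (RF, ET, AdaBoost) and an exhaustive 0–2.0 weight-lattice optimizer.
6. **Applicability domain**: per-model kNN-density thresholds (each
   training compound's mean distance to its k nearest neighbours, capped
   at the median of that distribution); a query is inside a model's domain
   if it sits within any training compound's threshold, and inside the
   *ensemble's* domain when at least two of three models cover it
   (0.33 per model, inside iff the sum exceeds 0.6).
7. **Assay analysis** for single-point fluorogenic screens: kinetic slope
   over minutes 10–20, % inhibition = 100·(slope_ctrl − slope_cmpd)/slope_ctrl,
   hit calling at > 15% inhibition, and confusion-matrix scoring of
   predictions against experiment (PPV/NPV/TPR/TNR/ACC).

Classification metrics (accuracy, recall, precision, specificity, FPR,
FNR, MCC with the four-factor denominator, F1) propagate zero-denominator
cases as `NA`, never as silent zeros.

## Worked example

Weighted soft voting with the deployed weights over three base-model
probabilities:

```r
library(qsarens)
soft_vote(c(0.9, 0.4, 0.6), weights = c(0.1, 0.7, 0.2))
#> # A tibble: 1 × 2
#>   probability label
#>         <dbl> <chr>
#> 1        0.49 inactive
```

0.1·0.9 + 0.7·0.4 + 0.2·0.6 = 0.49 < 0.5, so despite one confident base
model the ensemble withholds the active call — exactly the cautious
behaviour that makes weighted soft voting useful for ranking borderline
candidates.

Scoring a 29-compound single-point screen in which 19 compounds were
experimental hits, 17 were predicted active and 14 of those were confirmed
(tp = 14, fp = 3, fn = 5, tn = 7):

```r
classification_metrics(tibble::tibble(tp = 14, fp = 3, fn = 5, tn = 7))
#> # A tibble: 1 × 5 (selected columns)
#>   accuracy recall precision    f1   mcc
#> 1    0.724  0.737     0.824 0.778 0.422
```

i.e. a hit-identification rate (PPV) of 82%, a true-positive rate of 74%
and 72% overall accuracy. The ensemble applicability-domain rule for a
compound covered by two of three base models:

```r
ensemble_ad(c(TRUE, TRUE, FALSE))
#>   ensemble_score inside_ensemble
#> 1           0.66 TRUE
```

Curating the bundled toy molecule set (synthetic IC50 assignments; see
`?toy_molecule_set`) for regression:

```r
curate_activities(toy_molecule_set(), "regression") |>
  dplyr::select(compound_id, standard_smiles, ic50, pic50) |> head(4)
#>   compound_id standard_smiles              ic50 pic50
#> 1 TOY001      CC(=O)Oc1ccccc1C(=O)O        12.5  7.90
#> 2 TOY002      Cn1cnc2c1c(=O)n(C)c(=O)n2C  850    6.07
#> 3 TOY003      CC(=O)Nc1ccc(cc1)O         3200    5.49
#> 4 TOY004      CC(Cc1ccc(cc1)C(C(=O)O)C)C   45    7.35
```

TOY001's IC50 of 12.5 nM is the geometric mean of a planted duplicate pair
(12 and 13 nM); a discordant pair and an invalid SMILES in the fixture are
rejected with logged reasons (`curation_rejections()`).

End-to-end: `train_qsar_bundle()` takes an activity table to a serializable
bundle (preprocessing + three tuned classifiers + soft-vote weights +
regressor + applicability domains), and `predict_batch()` applies it to any
SMILES list, emitting one row per input — including per-row error flags for
invalid structures — with class probability, label, predicted pIC50/IC50
and all AD verdicts. A thin command-line wrapper over these functions ships
in `inst/scripts/qsarens-cli.R`.

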