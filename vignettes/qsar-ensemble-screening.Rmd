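---
title: "Ensemble QSAR screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble QSAR screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the assumptions behind them, the defaults and
their units, and the places where the design was genuinely open and a
choice had to be made.

## The modelling problem

Given a table of compounds with measured half-maximal inhibitory
concentrations (IC50, nM) against an enzyme target, the package builds two
complementary QSAR models: a binary classifier ("active" = IC50 ≤ 50 nM, a
stringent lead-likeness cutoff for high-affinity inhibitors) and a
regressor on the pIC50 scale (−log10 of the molar IC50, so 1 nM ↦ 9.0).
Both operate on molecular descriptors — numeric features computed from the
2D structure — and both carry an applicability domain (AD) that flags
query compounds too far from the training chemistry for the prediction to
be trusted.

## Curation

Structures are canonicalized with Open Babel; disconnected fragments are
split, waters always removed, and the largest organic (carbon-containing)
fragment retained, so salt forms and co-crystallized solvent collapse onto
the parent compound. The canonical SMILES of that fragment is the identity
key for duplicate detection — after salt stripping it is the only stable
key available, and it is invariant to input atom ordering.

Duplicate groups resolve as follows. Identical response values keep one
entry. For regression, groups whose IC50 coefficient of variation
(sd/mean) is below 0.2 are replaced by the geometric mean — the natural
average for a log-normally distributed potency — while groups at or above
0.2 are discarded entirely as irreconcilable measurements. The sd is the
sample (n−1) standard deviation by default; the choice is exposed as an
argument because either convention is defensible and the boundary cases
differ. For classification, a group whose members straddle the 50 nM line
is rejected outright: averaging across a label boundary would manufacture
a label no experiment supports. Classification admits all relation
qualifiers (>, <, ≥, ≤, =) since a censored measurement still bounds the
label in most cases; regression admits only exact ("=") values.

## Descriptors

Descriptor computation is deliberately pluggable: the pipeline's
algorithms never depend on specific descriptor names, only on a named
numeric matrix plus a map from each column to one of twenty registry
categories (autocorrelations, functional groups, topological, atom
centered, physicochemical, …). The built-in provider uses
ChemmineR/Open Babel and produces ~54 2D descriptors: physicochemical
properties (MW, logP, molar refractivity, TPSA), hydrogen-bond counts,
element/bond/ring counts, twelve functional-group counts, and a SMARTS
fragment panel. It populates only the 2D categories; conformer-dependent
families (3D autocorrelations, charged-partial-surface-area descriptors)
are left to richer backends. Per-structure failures yield `NA` cells — a
batch never aborts because one molecule resists one descriptor.

## Preprocessing

The unsupervised reduction chain runs in a fixed order: drop
constant/non-finite columns, filter correlated pairs, impute, scale.
`NA` means "missing, imputable"; `NaN`/`Inf` mean "broken descriptor,
drop the column".

* **Correlation filter.** Pairwise Pearson r on pairwise-complete
  observations; in any pair with |r| > 0.90 one member is removed. The
  retained member is the earlier column in matrix order (greedy
  left-to-right) — deterministic, order-dependent, and verified post hoc
  in the tests by recomputing the correlation matrix of the survivors.
* **kNN imputation.** k = 3, uniform weights: a missing cell takes the
  mean of its column over the 3 nearest rows, with row distance the root
  mean squared difference over mutually observed columns (normalizing by
  the count keeps rows with different missingness comparable). The fitted
  preprocessing model stores the *raw* training rows, so a training
  compound re-presented at prediction time reproduces its fit-time
  imputation exactly.
* **Scaling.** Centre/scale to mean 0, unit variance with the population
  (n) standard deviation — the convention of the common StandardScaler —
  using training statistics only. Scaling statistics are fitted on the
  training split, never the full dataset, to avoid information leakage
  into validation metrics; this is the conservative reading where
  practice is often laxer.

The train/validation split (default 75/25) is cluster-stratified: k-means
in descriptor space, then largest-remainder allocation of each cluster to
both sets at the global fraction, so every region of the represented
chemical space appears on both sides. The number of clusters defaults to
round(√(n/2)) — a standard rule of thumb — and is overridable; singleton
clusters go to training.

## Genetic-algorithm feature selection

The GA is a wrapper selector: the fitness of a descriptor subset is the
mean five-fold cross-validated score (F1 for classification, R² for
regression) of a model trained on exactly those columns, minus a linear
penalty of 0.001 per descriptor. Linearity is the simplest monotone
penalty consistent with "prefer smaller subsets at equal performance";
the coefficient is configurable and the tests verify strict monotonicity
in subset size. One fold split is drawn per run so fitnesses are
comparable across generations, and fitness values are cached by member
set.

Generational scheme: initialize each subset by including each pool
descriptor independently with probability 0.5 (an alternative reading —
restricting the whole run to a random half of the pool — is available as
`init_mode = "restricted_pool"`); each generation, keep the top 50% by
fitness as parents (ties prefer smaller subsets), pair them in rank
order, produce two children per pair by taking a random half of each
parent (set union collapses duplicates), then apply mutation (probability
0.3: swap one member for a random non-member) and deletion (probability
0.3: remove one member, floored at size 1), independently and in that
order. The next generation is parents + children truncated to the
population size — parents survive, making the scheme elitist, which is
what guarantees the non-decreasing best-fitness trace asserted in the
tests. Default stopping criterion: 200 generations; population size
defaults to 50 (not externally fixed; chosen as a conventional GA
population).

Inside the GA loop the default cross-validation learner is a logistic
model (classification) or ordinary least squares (regression), fitted on
raw matrices. This is a deliberate speed/fidelity trade-off: a wrapper GA
evaluates thousands of subsets, and a linear probe is a cheap, unbiased
detector of informative columns; the `builder` argument accepts any model
factory when tree-based fitness is wanted. The GA is run once per
ensemble algorithm, so each base classifier gets its own subset — the
reading consistent with the three base models carrying distinct
descriptor sets.

The planted-signal validation runs the GA on synthetic 60-descriptor
problems (8 informative columns, logistic effect size 1.0, 300 rows — a
realistic desk-scale dataset, fixed before any tuning), population 24, 30
generations: across 10 independent runs at least 70% must recover ≥ 6 of
the 8 planted descriptors.

## Base learners, tuning and the voting ensemble

Random forest and extra trees are fitted with `ranger` (split rules
"gini" vs "extratrees" with one random split; bootstrap resampling for
the forest, full-sample draws for extra trees), single-threaded with a
fixed seed for bit-reproducibility. AdaBoost is implemented in-package as
the classic discrete two-class algorithm over `rpart` trees (exponential
reweighting; ensemble probability = α-weighted vote share), since no
boosting implementation ships in the supported dependency set. The
extra-trees regressor handles pIC50.

Hyperparameters are tuned by exhaustive grid search under k-fold
cross-validation (F1 / R²; stratified folds for classification; ties go
to the first combination in grid order). Default grids are small and
documented in `default_grid()`; 10 folds is the reference setting, and
the toy-scale examples use fewer because 28 compounds cannot stratify 10
folds.

Classifiers combine by hard (majority) or soft voting. The soft-vote
probability is the weight-normalized average Σwᵢpᵢ/Σwᵢ — invariant to
positive rescaling of the weights — with the decision threshold fixed at
0.5 (no probability cutoff is externally specified; 0.5 is the symmetric
default). The deployed weight triple is (0.1, 0.7, 0.2) for
(random forest, extra trees, AdaBoost); `optimize_weights()` reproduces
the selection procedure, scanning the full 0–2.0 lattice at step 0.1
(9,260 triples after excluding all-zero) and breaking ties toward the
lowest total weight, then lexicographically. When the pipeline optimizes
weights it scores candidates on out-of-fold probabilities (each base
model refitted per fold), not on resubstitution predictions, to keep the
weight selection honest; which partition the original deployment used is
not documented, so the leakage-free choice is the default here.

## Applicability domain

Per model, the AD follows the kNN-density scheme: for each training
compound compute the mean Euclidean distance (in the model's scaled
descriptor subspace) to its k nearest training neighbours (k = 5 by
default; self excluded); take the median of those means as the global
reference width; give each compound the threshold
min(own mean kNN distance, reference width), floored at a tiny positive
fraction of the reference so duplicated training points keep usable
neighbourhoods. Compounds in dense regions therefore carry tighter
thresholds — the adaptive-kernel idea in its simplest robust form. A
query is inside the domain if it lies within any training compound's
threshold. The percentile and k are configuration parameters recorded in
the model manifest; the exact values used by any particular deployment of
this scheme are not externally fixed, so the defaults are stated as this
package's own.

For the three-model ensemble, each covering model contributes a score of
0.33 and the compound is inside the ensemble AD iff the sum exceeds 0.6 —
equivalently, two or more models. The regression model uses the identical
single-model rule without aggregation.

## Single-point assay analysis

Fluorogenic kinetics are reduced to a slope over the minute 10–20 window,
(FLU₂₀ − FLU₁₀)/10 in fluorescence units per minute, linearly
interpolating when readings do not fall exactly on those minutes (read
intervals vary by plate reader; interpolation is exact for linear
segments). Percent inhibition is 100·(slope_control − slope_sample)/slope_control,
computed against the mean control slope; replicate slopes are averaged
per compound. Negative inhibition (activation) is reported as-is. A
compound is an experimental hit when inhibition strictly exceeds 15% at
the single 1.5 µM test concentration — the boundary value is a miss. The
screen scorer treats these calls as ground truth and reports
PPV/NPV/TPR/TNR/ACC from the confusion matrix.

## Synthetic data: what it does and does not emulate

`make_synthetic_classification()` / `make_synthetic_regression()` generate
iid standard-normal features with a planted linear/logistic signal,
optional near-duplicate columns (r ≈ 0.99, to exercise the correlation
filter) and optional missing cells (to exercise imputation). They emulate
the *statistical* structure the pipeline must handle — informative vs
noise columns, redundancy, missingness, a known R² ceiling
var(signal)/var(total) — but not the *chemical* structure of real
descriptor matrices: heavy-tailed and discrete descriptor distributions,
block correlation by descriptor family, activity cliffs, or scaffold
clustering. Passing the planted-signal tests therefore demonstrates that
the machinery (selection, tuning, voting, AD) behaves correctly, not that
any particular real-data accuracy will be achieved; real-data performance
depends on the curated dataset and descriptor backend supplied by the
user.

The toy molecule set is a ~30-compound hand-built fixture with synthetic
IC50 assignments and deliberately planted pathologies (duplicate notation
pair, salt form, water adduct, discordant duplicates, one invalid
SMILES). It exists to exercise the full curate→train→predict path in
seconds; its IC50 values are labels for plumbing tests, not measured
potencies.

## Numerical and degenerate-input choices

* Undefined metrics (zero denominators) are `NA`, never 0, and aggregation
  uses `na.rm` so folds with undefined precision do not fabricate zeros.
* `soft_vote` rejects an all-zero weight triple; `hard_vote` over three
  voters cannot tie.
* The GA never lets a subset shrink below one member; mutation is skipped
  (and only deletion can act) when the subset already spans the pool.
* k-means split: clusters smaller than 2 go wholesale to training;
  largest-remainder rounding makes the global train count exact.
* Scaling refuses zero-variance columns (they should have been dropped),
  and AD fitting refuses k ≥ n.
* All stochastic steps (fold draws, k-means, GA, tree learners) derive
  sub-seeds from one master seed via a fixed-seed stream, so every result
  in the package is bit-reproducible given (data, config, seed), and
  `ranger` runs single-threaded to keep tree fitting deterministic.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run at desk scale, chosen so the
full battery completes in minutes on a single CPU while still giving each
statistical claim room to fail: 10 GA recovery runs at n = 300 × 60
descriptors; brute-force metric recounts on 100 random instances up to
n = 200; imputation oracles on 20 × 10 matrices; the end-to-end path on
the ~30-molecule fixture with a population-8, 3-generation GA and
single-point grids. The reference defaults (200 generations, population
50, 10-fold tuning) remain the recommended settings for real datasets.

## Known limitations

* The built-in descriptor provider is intentionally small (~54 2D
  descriptors); serious modelling should register a richer backend
  (e.g. an external descriptor tool exported to CSV and joined as a
  custom provider).
* No probability calibration (Platt/isotonic) and no stacking beyond
  hard/soft voting.
* No stereochemistry enumeration or tautomer canonicalization beyond the
  standardizer's defaults; no dose–response curve fitting in the assay
  module (single-point calls only).
* The AD is a distance-based heuristic: it flags extrapolation in
  descriptor space, not mechanistic novelty.
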