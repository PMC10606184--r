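---
title: "Ancestry-informative panel selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-informative panel selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aimpanel)
```

This vignette is the package's own account of the science it implements:
the binary genotype encoding, the distinctiveness ranking, the
genetic-algorithm (GA) panel search and its fitness, the classifier
benchmark, and the synthetic cohort generator used to validate the whole
chain. It also records the design decisions that were genuinely open and
why they were resolved the way they were.

## The classification problem

Given per-sample exome variant calls (VCF) and population labels, we want a
small panel of ancestry-informative markers (AIMs) and a classifier that
assign each sample to its population of origin. Two properties of real
cohorts drive the design:

* **Weak differentiation.** Closely related populations (e.g. Western,
  Eastern and Southern Slavs) differ little at most sites; informative
  markers are a small minority.
* **Class imbalance.** Reference cohorts are lopsided — the default
  configuration here mirrors a realistic study: 127 + 28 + 20 samples for
  three Slavic populations against 503 non-Slavic European samples
  (678 total). Overall accuracy is then dominated by the majority class,
  which is why the package optimizes and reports the **minimum per-class
  one-vs-all F1-score** instead.

## Binary encoding of variant calls

Each VCF record contributes one feature per alternate allele, keyed as
`chrom:pos ref/alt|gstate`. Two encoding modes exist:

* **genotype** (default): heterozygous and homozygous-alternate calls are
  distinct features (`HET`, `HOM_ALT`), the finer-grained reading of a
  "(polymorphism, genotype) pair".
* **presence**: any non-reference dose collapses to one `PRESENT` feature
  per site.

A record absent from a per-sample VCF is interpreted as homozygous
reference (cell 0). This assumption is sound for per-sample calls over a
*shared capture target* — absence then means "observed reference", not
"not sequenced" — and it is the one prominent data assumption a user must
be aware of when mixing call sets from different capture designs.
Multiallelic records are split per alternate allele (`GT 1/2` yields one
heterozygous feature for each allele); fully missing genotypes (`./.`) are
skipped; indel records are encoded exactly like SNPs and can be excluded
with `snps_only = TRUE`. Coordinates stay 1-based as in VCF; no left
alignment or normalization is attempted (calls must come from one
reference build and caller convention). Feature columns are sorted by the
total order (chrom, pos, ref, alt, gstate), which makes the matrix
invariant to input-file order. Known low-quality samples are dropped by an
explicit exclusion list rather than by quality logic, which belongs
upstream.

## Distinctiveness ranking

For feature $f$ and class $c$ with carrier rate
$r(f,c)$ (fraction of class-$c$ samples carrying $f$), the score is the
one-vs-rest differential

$$s(f,c) = r(f,c) - \max_{c' \ne c} r(f,c').$$

A feature private to class $c$ scores $+1$; a universal feature scores 0.
"Carrier percentage within a population" admits several rankings; the
differential was chosen because it yields a *per-class* ranking directly
comparable across features and is maximal exactly for the
population-specific markers the panel should contain. Ties are broken by
canonical feature order, so pools are fully deterministic. The top
`pool_size_per_class` features per class (default 50) form the GA's
candidate pools; pools may overlap between classes.

## The genetic algorithm

A candidate solution ("chromosome") is one size-$k$ feature subset per
class. The assembled classifier input is the concatenation over classes —
with four classes and $k = 300$, a 1200-element binary vector per sample.
Concatenation keeps duplicates by default so the assembled length is
exactly $k \times n_\text{classes}$; deduplication is available
(`dedupe_assembled`).

**Fitness** is the minimum over classes of the mean per-class one-vs-all
F1 under stratified `inner_cv_folds`-fold cross-validation (default 3) of
the designated fitness classifier (default: linear SVM, the
best-performing preset). Fitness values are cached by the canonical panel
rendering; the cache makes GA-vs-exhaustive comparisons exact and repeated
evaluations free.

**Operators and defaults** (all in `ga_config()`):

| parameter | default | rationale |
|---|---|---|
| population_size | 50 | standard size for subset-selection GAs at these pool sizes |
| generations | 100 | upper bound; stagnation usually stops earlier |
| tournament_size | 3 | mild, scale-free selection pressure |
| crossover_rate | 0.9 | children mostly recombine; 10% clones preserve building blocks |
| mutation_rate | 1/(k · n_classes) | one expected swap per *panel*; see below |
| stagnation_patience | 20 | stop after 20 generations without improvement |
| elitism | 1 (fixed) | guarantees monotone best fitness |

Two decisions deserve their reasoning spelled out:

* **Mutation rate.** The textbook "1/k per gene" choice gives one expected
  swap per *class*, i.e. ~4 swaps per child in a 4-class panel. Measured on
  a frozen separable fitness, that rate stalls the search in a
  mutation–selection balance: every child of a good panel is disturbed in
  several classes at once, improvements stop after ~16 generations, and no
  run out of 20 reaches the enumerable optimum. With one expected swap per
  chromosome ($1/(k \cdot n_\text{classes})$), 20 of 20 seeded runs reach
  the exact optimum. The minimum-over-classes fitness is what makes the
  difference: progress requires improving the bottleneck class *without*
  touching the already-optimal ones.
* **Greedy seeding.** The initial population holds one greedy chromosome —
  the top $k$ of each class's score-ordered pool — alongside uniform
  random subsets. On strongly separable cohorts the fitness saturates at
  1.0 early, after which a purely random initialization leaves the
  returned panel an arbitrary fitness-tied subset; with greedy seeding and
  strict-improvement elitism, ties resolve toward the most individually
  distinctive markers. This is what makes planted-marker recovery a
  property of the design rather than of luck.

**Panel-size sweep.** `sweep_panel_size()` runs the GA across a grid of
$k$ and selects the smallest $k$ whose best fitness is within
$\varepsilon$ of the grid-wide maximum. No principled tolerance exists for
"minimum number sufficient"; $\varepsilon = 0.005$ (half an F1 percentage
point) is the package default and is exposed as a parameter.

## Classifier presets

Six frozen presets (in `classifier_presets()`): SVM with linear /
polynomial / RBF / sigmoid kernels at $C = 1$, `gamma = "scale"`
($1/(p \cdot \mathrm{Var}(X))$), degree 3; random forest with 100 trees,
Gini splits, unlimited depth, minimum node size 1; gradient-boosted trees
(gbtree booster, learning rate 0.3, depth 6, $\lambda = 1$, $\alpha = 0$,
minimum child weight 1, 100 rounds — the round count is an ecosystem
default, not a tuned value, and is recorded in provenance). Class
weighting stays at each family's unweighted default: the imbalance is a
property of the study design and rebalancing would mask exactly the
minority-class behaviour the F1 report is meant to expose.

Implementation notes: SVMs run through `e1071` (libsvm, one-vs-one
voting), boosted trees through `xgboost` (single-threaded for
determinism). The random forest runs through `ranger` as a *probability*
forest with predictions taken as the argmax of averaged class
probabilities (first-max tie-break): majority voting with stochastic tie
breaking would violate the package's determinism and row-order-equivariance
contracts, and the classical `randomForest` implementation does not
terminate on an all-constant feature matrix, a degenerate input the
contract covers.

## Evaluation

`one_vs_all_counts()` uses the convention in which, scoring class $c$:
TP = class-$c$ samples predicted $c$; FN = class-$c$ samples predicted
otherwise; FP = other-class samples predicted $c$; **TN = correctly
classified other-class samples** (the sum of the other diagonal entries).
This differs from the textbook binarized convention ("any non-$c$ sample
predicted non-$c$"): a class-$a$ sample misclassified as class $b$ (both
$\ne c$) counts in *neither* cell for class $c$, so the four counts need
not sum to the test-fold size. The textbook convention is available via
`convention = "standard"`; the function documentation carries a worked
example where the two differ. Consequently the headline accuracy reported
in benchmark tables is the overall multiclass accuracy (trace over total),
which equals the one-vs-all accuracy of every class only when
off-diagonal mass is symmetric; both are emitted per fold.

F1 is $TP / (TP + 0.5(FP + FN))$, equal to the harmonic mean of precision
and recall; it is 0 when $TP = 0$ with errors present, and *undefined* —
an error, not a silent 0 or 1 — when $TP = FP = FN = 0$ (a class absent
from both truth and predictions, which stratification should have
prevented).

**Splitting.** "A 70/30 split with five-fold cross-validation" admits two
readings, and both are implemented: mode `kfold5` (default) is stratified
5-fold cross-validation (each fold tests 20%; the aggregated confusion
matrix then covers every sample exactly once), and mode `shuffle70` is
five repeated stratified 70/30 shuffle splits. The mode is recorded in
every report. Stratified folds are built with balanced remainder
allocation (each class's leftover samples go to the currently smallest
folds), so per-class counts differ by at most one across folds *and*
total fold sizes are the balanced partition — 678 samples always split
136/136/136/135/135.

**Selection leakage.** Selecting markers on the full data set and then
cross-validating the classifier lets test samples inform the selection and
inflates scores. The pipeline default is therefore leakage-safe: the
candidate pools and GA re-run inside each training fold
(`nested_cross_validate()`). The single-panel protocol is available as
`whole_data_selection = TRUE`, and the package's tests demonstrate the inflation on
near-null cohorts (whole-data selection beats leakage-safe selection in
all five paired seeds).

## The synthetic cohort generator

The generator exists because the pipeline's claims need a ground truth.
It emulates:

* **Background differentiation** — Balding–Nichols: ancestral frequency
  $p \sim U(\text{range})$, per-population frequency
  $\sim \mathrm{Beta}\!\big(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\big)$,
  giving mean $p$ and variance $p(1-p)F$. `estimate_fst()` (the
  variance-of-frequencies estimator) recovers $F$ from the emitted table;
  $F < 10^{-12}$ is treated as the exact zero-divergence limit.
* **Planted AIMs** — for each class, sites whose class frequency exceeds
  every other class's by at least `aim_delta`: the target frequency is
  drawn from $U(\text{lo} + \delta, \text{hi})$ and the others from
  $U(\text{lo}, q - \delta)$, which satisfies the constraint by
  construction over the feasible region; an infeasible `aim_delta`
  (wider than the frequency range) fails loudly naming the site rather
  than silently relaxing the differential.
* **Genotypes** — Binomial(2, p) per sample and site (Hardy–Weinberg).
* **Output** — per-sample VCFs listing only non-reference genotypes
  (matching real variant-call semantics; a multi-sample writer with
  explicit `0/0` calls is a flag), a labels TSV, and a truth JSON
  (planted site ids + the full frequency table).

Defaults are the study conditions: class sizes 127/28/20/503, 5000
background sites at $F_{ST} = 0.005$, 10 AIMs per class at
$\delta = 0.6$, ancestral frequencies in (0.05, 0.95).

**What it does not emulate** — linkage disequilibrium, demographic
history and admixture, genotyping or sequencing error, indels and
multiallelic sites (those are exercised by hand-written fixture VCFs in
the tests). Passing tests on this generator therefore show that the
pipeline recovers *planted, LD-free, error-free* signal under realistic
imbalance and differentiation levels; they do not certify performance on
real exomes, where correlated markers and batch effects can make panels
redundant or optimistic.

## Numerical choices and degenerate inputs

* All randomness is seed-scoped (`with_seed` saves and restores the
  caller's RNG state); a pipeline's global seed fans out to fixed
  per-stage offsets so stages are independently reproducible.
* Ties: feature ranking and pool construction break ties by canonical
  feature order; random-forest prediction breaks probability ties by
  first class level; GA tournament ties resolve by the sampled order.
* Degenerate inputs: single-class training labels, non-binary matrices,
  feature-list mismatches at prediction, empty classes, a class absent
  from a training fold, and undefined F1 all raise errors naming the
  offender; an all-zero feature matrix yields a constant (majority-class)
  prediction rather than an error.
* Validation problem sizes: the test suite exercises the full 678-sample,
  5000-site cohort once for the recovery/benchmark claims and smaller
  cohorts (tens of samples, hundreds of sites) for properties where scale
  adds nothing; the GA-vs-exhaustive comparison uses pools of 12 and
  $k = 3$, the largest size where per-class enumeration ($\binom{12}{3}
  = 220$ subsets) stays exact. The GA-optimality fixture's fitness is a
  frozen *separable* function (minimum over classes of mean frozen
  per-feature weights) precisely so that the global optimum is enumerable
  per class; a CV-based fitness would make exhaustive enumeration over
  the joint space ($220^4 \approx 2.3 \times 10^9$ panels) infeasible.

## Known limitations

* The homozygous-reference interpretation of absent records requires a
  shared capture design across samples.
* Distinctiveness is a marginal (per-feature) score: the greedy pool can
  in principle miss markers informative only jointly; the GA can combine
  them only if they enter the pools.
* `whole_data_selection` reproduces the optimistic single-panel protocol and should
  be used for comparison, not for reported performance.
* The generator's independence assumptions (no LD) make panel sizes
  optimistic relative to real data, where correlated markers carry
  redundant information.
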