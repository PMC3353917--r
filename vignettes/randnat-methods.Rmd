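---
title: "Classifying natural versus random proteins from structural descriptors"
author: "randnat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying natural versus random proteins from structural descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randnat)
```

## The question and the approach

Are folded natural proteins distinguishable from polypeptides whose sequence
is pure chance? `randnat` implements a structural answer to that question: it
describes each protein by eleven structure-related variables — net charge,
residue volume, solvent-accessible surface area, counts of alpha-helix,
beta-sheet and coil residues, their percentages of chain length, the
percentage of secondary structure, and surface hydrophobicity — and trains an
evolutionary neural network to tell the two classes apart.

The classifier, here called ENNA (Evolutionary Neural Network Algorithm),
couples two standard pieces of machinery:

* a **genetic algorithm** over binary chromosomes, one bit per structural
  variable, where a chromosome switches input variables on or off;
* a **two-hidden-layer sigmoid multilayer perceptron** whose 10-fold
  cross-validated misclassification rate on the selected variables is the
  chromosome's fitness.

After the final generation, the per-variable *occurrence probability* (the
fraction of chromosomes carrying a variable) identifies the variables that
are robustly required for classification, and a final network on those
variables yields the headline correct-classification rate.

## Structural descriptors

`extract_features()` computes all eleven variables from a PDB coordinate
file, via `parse_structure()` (first MODEL, one chain, highest-occupancy
altLoc, hydrogens and HETATM ignored; parsing itself is delegated to
`bio3d::read.pdb()`).

**Secondary structure** is assigned by `assign_secondary_structure()` with a
Kabsch–Sander style hydrogen-bond analysis: the backbone amide hydrogen is
placed on N along the direction anti-parallel to the preceding carbonyl, the
electrostatic bond energy is
$E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, and a bond is called below −0.5 kcal/mol. Two consecutive
i → i+4 turns make a helix (H); parallel/antiparallel bridge patterns make
sheet (E); turn interiors and bends (CA virtual angle above 70°) are a
fourth state, `other`; the remainder is coil (C). The four states are
mutually exclusive, so `alpha + beta + coil` can be below the chain length —
consistent with the per-class means of the packaged reference moments, where
the three counts sum to about 56 of 70 residues. Percentages are counts over
chain length and `% secondary structure` is exactly `%alpha + %beta`.

**Surface area** uses `compute_sasa()`, an in-package Shrake–Rupley
implementation: each heavy atom carries a standard van der Waals radius
(C 1.70, N 1.55, O 1.52, S 1.80 Å), a 1.4 Å probe is added, and the exposed
fraction of a deterministic golden-spiral point set (default 960 points per
atom, accurate to well under 1% on an isolated sphere) gives the atomic
area. Tests compare it against an independent Monte-Carlo point oracle.

**Net charge** uses the simplest pH ≈ 7 convention: +1 for Lys/Arg, −1 for
Asp/Glu, histidine and termini neutral. This is the convention consistent
with a near-zero mean charge for uniform-composition random 70-mers
(expected 70·(2−2)/20 = 0). **Volume** is the composition sum of Zamyatnin
mean residue volumes, identical for experimental structures and models by
construction. **Surface hydrophobicity** is the fraction of total
solvent-accessible area contributed by residues in
{A, V, L, I, M, F, W, C, P}.

Because the original study does not name the software used for these
descriptors, absolute values may differ from other tools by a method offset;
all comparisons inside the package are internally consistent.

## Random sequences

`generate_random_sequence()` draws residues i.i.d. uniformly over the 20
standard amino acids (integers 0–19 mapped alphabetically), default length
70 — the length of a short single-domain protein. `generate_library()`
filters draws through a pluggable novelty predicate standing in for a
database-similarity screen; the default accepts everything, and
`kmer_novelty_filter()` provides an offline k-mer overlap screen against a
reference FASTA. Running an actual BLAST search is intentionally out of
scope.

## Synthetic feature tables

The original feature sets (762 experimentally solved natural proteins and
762 modelled random 70-mers, drawn from 902 and 20,494 candidates) cannot be
regenerated on a desk: they require structure determination and large-scale
ab initio modelling. The package therefore ships the published per-class
mean and standard deviation of every variable (`table1_params()`) and a
simulator, `simulate_feature_table()`, that draws independent per-variable
samples matching those moments.

Three shapes are available: `gaussian` (default), `flat-wide` (uniform with
matched moments, mimicking the broad plateau-like spread described for
natural proteins), and `skewed` (standardized gamma, skewness 1). Values
are clipped to physical ranges — percentages to [0, 100], the
hydrophobicity fraction to [0, 1], counts and areas to ≥ 0 — and the number
of clipped values is recorded. Clipping necessarily biases the moments of
variables whose mean sits within a few SDs of a bound (the beta-sheet count
of the random class, most visibly), so `clip = FALSE` exposes the raw
draws; the moment-recovery tests use raw draws, while analyses use the
physical (clipped) tables.

What the simulator deliberately does **not** reproduce: cross-variable
correlations (the published correlation structure is not numerically
available; an independent-variable model is the neutral choice), the exact
empirical shapes of the real data, and the deterministic identity
`%secondary = %alpha + %beta` between columns (each is drawn from its own
marginal). Passing tests on synthetic data therefore demonstrate that the
pipeline recovers the statistical structure it assumes — not that the
original biological conclusion is re-derived from raw structures.

## Outlier filtering and balancing

`flag_outliers()` reproduces the tail filter: a record is removed when any
variable falls strictly outside the 0.5% or 99.5% empirical quantile of its
class (linear interpolation between order statistics, R type 7). Quantiles
are estimated per class because the study reports separate per-class removal
counts. With 11 independent variables the expected removal fraction is
1 − 0.99¹¹ ≈ 10.4%, matching the reported 2029/20,494 ≈ 9.9% random-class
removals to within correlation effects. `balance_classes()` then subsamples
the majority class without replacement to the minority size.

## Statistical battery

Gaussianity is tested per variable with Shapiro–Wilk, location differences
with the two-sided Wilcoxon rank-sum test (exact for small tie-free
samples, tie-corrected normal approximation otherwise), and dispersion
differences with Fligner–Killeen — all via the corresponding `stats`
functions, at the study's significance level of 0.01 and with no
multiple-testing correction (none was applied originally). The original
description calls the rank-sum comparison a test "for the mean"; the
implementation is the standard location-shift rank test, which tracks the
mean difference under finite variance. Printed p-values of the original
table are not assertion targets — the exact continuity/tie conventions of
the original environment are unknowable — so the tests assert calibration
(type-I error ≈ α) and power properties instead.

## ENNA settings

Defaults follow the described evolutionary run: population 30, 10
generations, single-point crossover, per-bit mutation probability 0.01,
roulette-wheel selection, fitness = 10-fold cross-validated
misclassification; the network has two sigmoid hidden layers and learning
rate 0.3. Where the description is silent the package documents its own
choices:

* **Selection weights.** Read literally, selection probability
  "proportional to the misclassification rate" would favour the *worst*
  networks; the package uses weight = 1 − misclassification and keeps the
  literal variant behind `literal_fitness_weights = TRUE`.
* **Hidden sizes.** `⌈(m + 2)/2⌉` units per hidden layer for `m` selected
  inputs — the `(attributes + classes)/2` convention of common MLP toolkits.
* **Epochs 500, momentum 0.2** (unstated originally; common toolkit
  defaults).
* **Elitism 1**, so the best chromosome is never lost and the best-fitness
  trace is monotone.
* **All-zero chromosomes** are redrawn at initialization; if mutation
  creates one it is assigned worst fitness (1.0) rather than evaluated.
* **Ties at output 0.5** classify as `random` (arbitrary, documented).
* **Determinism.** Every stochastic step — fold assignment, weight
  initialization, epoch shuffling, all GA operators — derives from one
  master seed; network training runs on its own `std::mt19937` stream, so
  results are reproducible across platforms. Fitness values are cached per
  chromosome, and fold assignment canonicalizes record order by `id`, so a
  mask's fitness is independent of row order and of when the GA re-visits
  it.

The reported 94.36% correct classification is ambiguous between a
cross-validated and a whole-data rate, so `final_classifier()` reports
three numbers: holdout accuracy (default 30% stratified split),
cross-validated accuracy, and the apparent accuracy of a single fit to all
records.

## Problem sizes and numerical choices

The test-suite and acceptance computations run at the study's scales where
that is cheap (tables of 20,494 + 902 simulated records; moment recovery at
n = 18,465 and n = 10,000) and at reduced scales where the full computation
adds nothing (toy 4-variable GA-versus-enumeration checks at n = 60 with
200 training epochs; pipeline determinism at a few hundred records). The
full evolutionary run used for the headline property — 30 chromosomes, 10
generations, 10-fold cross-validation on 762 + 762 records with 500-epoch
networks — takes on the order of five minutes on one CPU thanks to the
compiled training loop and fitness caching.

Degenerate inputs are handled explicitly: constant samples are rejected by
the Gaussianity test, classes too small for 0.5% tail estimation produce a
warning and no flags, single-class training data yields a constant
predictor with a warning, and empty masks are refused.

## Known limitations

* Descriptor values carry method offsets relative to whichever tools the
  original study used; only within-package comparisons are meaningful.
* The secondary-structure assignment is a simplified Kabsch–Sander variant
  (no full ladder/sheet bookkeeping, no pi-helix state); it is accurate on
  canonical geometry but not a drop-in DSSP replacement.
* The synthetic generator models marginals only; any analysis that depends
  on the real cross-variable correlation structure is outside its reach.
* The novelty filter abstracts the database-similarity screen; no sequence
  database is queried.
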