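---
title: "Grammatical evolution decision trees for gene-gene interaction detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammatical evolution decision trees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(gedt)
```

## The problem

Case-control association studies code each bi-allelic SNP as 0, 1 or 2
copies of the minor allele. Hierarchical tree learners (CART, C4.5) pick one
marginally informative SNP at a time, so a *purely epistatic* pair — two loci
whose joint genotype predicts disease while neither locus has any
single-locus effect — is invisible to them: no first split ever looks
worthwhile. `gedt` searches the space of ternary decision trees *globally*
with grammatical evolution (GE), so variable selection and tree structure
are optimized together and a pure interaction can be discovered as a unit.

## Genotype-to-phenotype mapping

A candidate solution is a variable-length binary genome read in 8-bit codons.
Codons are transcribed to integers and translated into a decision tree by a
context-free grammar whose recursive production

```
pseudoV := <v> <val_0> <pseudoV> <val_1> <pseudoV> <val_2> <pseudoV> | <class>
```

either opens an internal node (a SNP test with one subtree per genotype
value) or closes a branch with a class leaf (`+` case / `-` control). Each
expansion of a non-terminal with `k >= 2` alternatives consumes one codon and
selects alternative `codon mod k`; non-terminals with a single alternative
(`S`, `val_0`, `val_1`, `val_2`) consume nothing, since `mod 1` is always 0.
Derivation is leftmost. When codons run out, the genome is reused from the
start ("wrapping") at most `max_wraps = 2` times; a still-incomplete
derivation marks the individual invalid, and invalid individuals simply
receive fitness 0 so selection removes them — no resampling.

Useful consequences, all covered by tests:

* mapping is a pure function of (codons, grammar, wrap budget);
* congruent codons (`c + k * n_alternatives`) map identically, giving the
  neutral genetic variation GE is known for;
* encoding a tree as bare alternative indices and re-mapping reproduces it
  exactly, which is how sensible initialization guarantees a population with
  zero invalid individuals.

The grammar requires `n_snps <= 2^codon_size_bits` (256 at the default codon
width) so the MOD rule can address every variable; wider codons would be
needed for larger maps.

## Fitness

Fitness is balanced accuracy, `(sensitivity + specificity) / 2`, computed on
the training split. It equals plain accuracy on the balanced designs
simulated here but stays meaningful under class imbalance. A tree that
ignores the data (a bare leaf) scores exactly 0.5 on two-class data, a
convenient null anchor.

## The genetic algorithm

The population (default 500) is split across 4 islands. Each generation,
every individual is mapped and scored; the next generation of identical size
is then formed from three disjoint operator groups, mirroring the usual
duplication / crossover / mutation split of generational GE systems:

* **duplication** — the top `duplication_rate` (default 5%) of each island
  is copied unchanged. This elitism makes best-ever fitness monotone.
* **crossover** — `crossover_rate` (default 90%) of the next generation are
  offspring of tournament-selected parents (`k = 2`) recombined by one-point
  crossover at codon boundaries, with the cut point drawn independently in
  each parent; this is what lets genome lengths vary. Cut pairs violating
  the chromosome-size limits are re-drawn, and after 10 failures the parents
  pass through unchanged.
* **mutation** — the remaining slots are tournament-selected copies whose
  bits flip independently with probability `mutation_rate = 0.01`.

Mutating every crossover offspring instead was tried and rejected: at 0.01
per bit a few-hundred-bit genome takes ~8 codon hits per generation, the
population never converges (mean fitness stays at the 0.5 anchor even after
1000 generations) and the search finds nothing. Keeping the operator groups
disjoint preserves building blocks and matches the behaviour the published
power levels imply.

Every 25 generations the best individual of each island is broadcast to
every other island, replacing its worst residents. The run stops at balanced
accuracy 1.0 or at the generation limit, returning the best-ever tree (ties
resolved toward the earliest generation, then the smaller tree, for
reproducibility and parsimony).

**Chromosome limits are bits, not codons.** The 50–1000 chromosome-size
bounds are interpreted as bits, i.e. 7–125 eight-bit codons, capping mapped
trees at roughly 60 nodes. This matters more than it looks: with limits read
as codon counts (up to 1000 codons) evolved trees bloat into full depth-5
trees carrying ~60 distinct SNPs each, cross-validation consistency
saturates with noise loci, and the exact-two-loci final model becomes
unreachable at any search budget. Under the bit reading, trees stay small
enough to be interpretable and the cross-validation filter works as
intended. `sensible_init_max_depth` defaults to 3, the deepest full ternary
tree (80 codons) that fits the cap.

Sensible initialization builds trees directly from the grammar — half
"full" trees that choose the recursive rule until the depth limit forces
leaves, half "grow" trees of a random depth up to the limit with a fair
coin at each node — then encodes them into codons and pads to the minimum
chromosome size with random (unused) codons.

## Cross-validation and the final model

The data are split into 10 stratified folds (each holds ~1/10 of the cases
and ~1/10 of the controls, so balanced accuracy is always defined; remainder
individuals are spread from opposite ends of the fold sequence, keeping
totals within one). Each fold's search trains on the other nine tenths and
is scored once on the held-out tenth. *Cross-validation consistency* counts,
per SNP, the folds whose best tree contains it; the final model is every SNP
with majority support (consistency strictly above `k/2`). A threshold rather
than an argmax is used deliberately: a two-locus interaction needs both
partners in the final model, which an argmax cannot represent when their
counts differ (e.g. 10 and 9). The threshold is configurable.

## The baselines

*Random search* re-runs sensible initialization at every generation and
keeps the single best tree, with no selection, crossover or mutation — a
negative control that spends exactly the same number of fitness evaluations
as the GA under the same configuration.

*Greedy trees* re-implement the C4.5 recipe: 3-way categorical genotype
splits chosen by maximum positive gain ratio (information gain over split
information), recursion stopping on purity, fewer than `min_leaf = 2`
individuals, or no positive gain; then bottom-up subtree-replacement pruning
under the pessimistic confidence-bound error estimate at confidence 0.25 (a
node becomes a majority leaf whenever the leaf's pessimistic error does not
exceed the sum over its subtree's leaves). Subtree *raising* is not
implemented; replacement alone preserves the property the comparison turns
on — a hierarchical learner cannot enter a purely epistatic pair because no
single-locus split ever looks good. The greedy pipeline runs under the same
folds, consistency and final-model rule as the GE searches.

## The simulator

Two-locus penetrance models assign a disease probability `f(g1, g2)` to each
of the 9 genotype combinations; three published symbol patterns are
supported. `XOR` is pure epistasis: low risk on exactly one heterozygous
locus, with *flat* single-locus marginal penetrances. `BOX` places low risk
on the AA column and BB row (main effects at both loci). `MOD` is an
asymmetric modified-XOR with a main effect.

The papers in this literature print symbol placements, not numbers, so the
solver recovers tables from `(pattern, maf, h2)`. Penetrances are written as
`f = K + s * d`: the deviation direction `d` is prevalence-neutral under the
Hardy-Weinberg cell masses (and, for XOR, additionally lies in the null
space of the flat-marginal constraint, so purity of epistasis is exact, not
approximate), and the scale follows in closed form from the broad-sense
heritability on the penetrance scale,

```
h2 = sum_g P(g) (f(g) - K)^2 / (K (1 - K)),   K = sum_g P(g) f(g),
```

with `P(g)` the Hardy-Weinberg genotype probabilities at the model's minor
allele frequency. The prevalence is fixed at `K = 1/2`. This is the
distinctive design choice of the generator and deserves its rationale: `K`
is not identified by `(pattern, maf, h2)`, and the extreme choice — baseline
penetrance 0 — makes every case carry a risk genotype, so even a 1%
heritability model hands any classifier a balanced accuracy near 0.75 and
*every* search method trivially saturates, contradicting the basic
qualitative behaviour of such experiments (power should rise with effect
size, and blind random search should stay near zero). Fixing `K = 1/2`
maximizes the phenotypic variance `K(1 - K)`, so the target heritability is
the sole knob controlling association strength, phenocopies exist at every
effect size, and the balanced 125/125 case-control draw matches the
population. Solved tables reproduce their targets to `1e-6` and XOR
marginal spreads stay below `1e-8` across the whole 1–10% × {0.25, 0.5}
grid (asserted in the test suite).

Datasets are drawn by rejection sampling: functional-locus genotypes from
Hardy-Weinberg proportions, disease status as a Bernoulli draw from the
penetrance table, accumulation until the case and control quotas (default
125 + 125 over 100 SNPs) are exactly met. Noise SNPs are independent of
status, so they are drawn only for retained individuals — the joint
distribution is identical to drawing full rows and rejecting. Noise SNPs
share the functional MAF by default (configurable).

What the generator does **not** emulate: linkage disequilibrium, genotyping
error, missingness, locus heterogeneity, phenocopy *structure* beyond the
flat baseline, covariates, or more than two functional loci. Passing power
checks on these data therefore says nothing about robustness to any of
those features of real data.

## Power estimation

For each grid point the full CV pipeline runs on `n` replicate datasets and
each final model is classified: **conservative** success means the final
model is exactly the two functional loci; **liberal** success requires both
functional loci but tolerates false positives (conservative successes are a
subset, so conservative power never exceeds liberal power — asserted on
every output row). Tables report percentages with exact binomial 95%
confidence intervals so that scaled-down runs carry their Monte-Carlo
uncertainty with them.

## Problem sizes and numerical choices

The experiments in the test suite run at desk scale, chosen as the package's
own verification budget: 20 replicates with 200 generations × population 200
for the GE power checks (compared to printed values through two-sided exact
binomial tests), 100 replicates for the deterministic greedy baseline, and
10⁵-individual draws for the distributional checks of the simulator
(chi-square goodness of fit at α = 0.001). Full published scale (population
500 × 1000 generations × 100 replicates) is reachable through the same API
and the `power` CLI subcommand, at hours rather than minutes.

Other numerical conventions: solver tolerance 1e-6 on heritability
(closed-form, so achieved to machine precision); gain ratios below 1e-12
treated as zero; pessimistic error for a zero-error leaf of size `n` is
`n (1 - 0.25^{1/n})`; ties in tournament selection are broken uniformly at
random; ties for the best-ever tree prefer the earlier generation, then the
smaller tree; per-bit mutation is realised as a Binomial(bits, rate) flip
count at distinct uniform positions, which is the same distribution with
far fewer RNG draws. All randomness flows from R's RNG, so `set.seed()`
makes every pipeline — including the C++ core — exactly reproducible.

## Known limitations

* The grammar is fixed to the ternary SNP tree language; no user grammars.
* No missing genotypes (validation rejects them), no continuous phenotypes,
  no covariates, and no VCF/PLINK readers — input is the package's own
  tab-delimited format.
* Islands run sequentially in one process; the island model is used for its
  search dynamics, not for wall-clock parallelism.
* Greedy pruning implements subtree replacement only (no raising, no
  Laplace smoothing).
* Power at genome-wide SNP counts is untested; the codon width bounds the
  addressable variable count at 256 by default.

## A worked example

```{r example, eval = FALSE}
model <- solve_penetrance("XOR", maf = 0.25, target_h2 = 0.10)
model
ds <- simulate_dataset(model, n_cases = 250, n_controls = 250)
cfg <- gedt_config(generations = 200, population_size = 200)
cv <- run_cv(ds, cfg)
cv                       # consistency table and final loci
run_c45_cv(ds)           # the greedy baseline on the same data
```
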