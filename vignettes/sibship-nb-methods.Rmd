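---
title: "Estimating the effective number of breeders from sibship reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the effective number of breeders from sibship reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibnb)
```

## Scope and model

`sibnb` evaluates two single-sample estimators of the effective number of
breeders (Nb) that work from the sibling structure of one offspring cohort,
genotyped at a modest biallelic SNP panel, with no parental genotypes:

* the **sibship-assignment (SA)** estimator, a function of the sample
  frequencies of paternal half-sib (Q1), maternal half-sib (Q2) and
  full-sib (Q3) dyads with a nonrandom-mating correction `alpha`
  (Wright's F_IS), and
* **parentage without parents (PwoP)**, the Crow–Denniston inbreeding
  effective size computed from the vector of per-parent offspring counts
  `ki`, which needs nothing from parents that contributed no offspring:
  `Nb = (2S - 1) / (sum(ki^2)/(2S) - 1)` for `S` offspring.

Both require a sibship partition. The package supplies every stage:
simulation of hatchery-style cohorts with known truth, maximum-likelihood
sibship reconstruction, the two estimators, and the evaluation designs
(confusion matrices, subsampling bias, concordance).

Within the SA formula the parental sex counts N1 and N2 are not observable
from offspring alone; we substitute their sibship-implied values
`1/(Q1+Q3)` and `1/(Q2+Q3)`, dropping the term when `alpha = 0` or the
sharing probability is zero. The Q definitions are exclusive (Q1 excludes
full-sibs), which makes `Q1 + Q3` exactly the probability of sharing a
sire and keeps that substitution coherent. With these choices the SA and
PwoP estimates from the same monogamous partition obey the exact identity
`SA / PwoP = 2(n-1) / (2n-1)` when `alpha = 0` — the basis of the
concordance results: the two methods can never differ by more than
`100/(2n-1)` percent in that regime, under 0.7% for `n >= 80`.
`alpha` itself is estimated as one minus the ratio of mean observed to mean
expected heterozygosity, pooled over loci as a ratio of averages, which is
considerably more stable across ~100 SNPs than averaging per-locus ratios.

Infinity is a first-class estimate throughout (a sample with no inferred
sibs has `Q1 = Q2 = Q3 = 0` and an infinite SA estimate); evaluation
summaries exclude infinite estimates and report their count rather than
failing.

## The synthetic cohort generator

The generator emulates the spawning structure of five Snake River
steelhead hatcheries that serve as the package's benchmark populations
(`hatchery_populations()`): broodstock counts split by sex, cohort sizes
from 80 to 1,516 offspring, and Nb/NC ratios near 0.27–0.34.

* **Crosses.** One cross per female. Males are drawn fresh while any
  remain; with probability `male_reuse_rate` — and always once fresh males
  run out, as happens when females outnumber males — an already-used male
  takes a second cross. No male serves more than two crosses, which is why
  a configuration needing more than `2 * n_males` crosses errors. With
  probability `contamination_rate` a cross is merged with another into a
  2-male-by-2-female matrix whose offspring draw both parents uniformly;
  this models egg batches pooled while fertilisation is still under way.
  These two mechanisms are the only sources of true half-sib dyads.
* **Family sizes.** Offspring are allocated to cross units by a
  Dirichlet-multinomial with a single concentration `theta` per cross.
  Small `theta` produces the long zero tail (most broodstock leaving no
  returning adult) and the family-size skew that real hatchery returns
  show; `theta = Inf` is the deterministic equal-allocation limit.
  `calibrate_dispersion()` bisects on `log(theta)` so that the mean PwoP
  Nb/NC over at least 20 replicate pedigrees matches a target; the
  per-population defaults in `hatchery_populations()` were set this way
  against each population's ratio (40 replicates, 2% tolerance), giving
  `theta` between 0.33 and 0.50. A target ratio of 1 is the
  ideal-population limit, approached only as `theta` grows without bound,
  so such targets return the search ceiling with a warning flag.
* **Genotypes.** Per-locus minor-allele frequencies are uniform on
  `[maf_low, maf_high]`; the real panel's frequency spectrum is not
  published, so the default `[0.1, 0.5]` covers informative SNPs and both
  bounds are user-tunable. Founders are Hardy–Weinberg, transmission is
  fair Mendelian segregation, and genotyping error is a uniform class-II
  miscall: with probability `e` the observed code becomes one of the other
  two codes. A single catch-all rate mirrors how sibship software lumps
  allelic dropout with other errors. The error and missingness stages use
  RNG substreams separate from transmission, so the same seed with a
  different `e` perturbs only the miscalled cells — which is also how the
  tests verify the realised miscall fraction.
* **What it does not model.** No linkage, no age structure, no
  iteroparity, no sex-biased survival, no cohort/year structure (the two
  return years of the benchmark populations are pooled, and so are we).
  Passing tests therefore demonstrate estimator behaviour under the
  hatchery mating structure, not under wild mating systems with resident
  males or real marker ascertainment.

## Sibship reconstruction

The reconstructor maximises an exact configuration likelihood over
partitions of the sample into latent-parent assignments. Per locus, latent
parental genotypes carry Hardy–Weinberg priors at the sample allele
frequencies (clamped to `[1/(4n), 1-1/(4n)]`, frequencies held fixed during
the search), offspring follow Mendelian transmission, observations pass
through the miscall model with the *assumed* error rate (deliberately
crossable with the simulated rate), missing genotypes contribute
probability one, and loci multiply. Latent parents shared across crosses
are marginalised jointly over each connected component of the parent–cross
graph: exactly (full summation over parental genotype combinations) up to
`max_component_parents = 12`, beyond which a structured mean-field
approximation takes over — coordinate-ascent updates of one parent's
per-locus genotype distribution at a time, returning the variational lower
bound so an approximated component can never outscore an exactly summed
one. Approximated components are flagged.

The search is simulated annealing from the all-singleton configuration:
moves are move-one-offspring, merge two families, split a family, and —
under polygamous assumptions — independent reassignment of an offspring's
latent sire or dam; Metropolis acceptance with geometric cooling (factor
0.95 every `n` proposals), an initial temperature chosen by a pilot so a
typical uphill-cost move accepts with ~50% probability, `50 n` proposals
per restart, 20 restarts by default, ties broken by first-found, and a
greedy hill-climbing polish after each restart. The returned configuration
never scores below the all-singleton start, and everything is
deterministic given the seed. The monogamy search (one latent sire–dam
pair per family, so components stay at two parents) is implemented in
compiled code and handles cohorts of several hundred offspring in seconds;
the polygamous searches run in R with a component-level likelihood cache,
bounding search-time components (exact to 8 parents, mean-field to 16,
larger proposals rejected) and re-scoring the final configuration at the
full cap. This is a re-implementation of the full-likelihood approach, not
a port of any existing program: no bit-compatibility is attempted, and
accuracy is judged by truth recovery on synthetic data.

Two open choices were resolved as follows. The sibship prior is uniform
over configurations (no penalty on family number or size); a prior flag
exists but only the uniform option is implemented, since the benchmark
results were produced under default settings whose internal prior is not
documented. And the assumed error rate enters only the likelihood, so
assuming 0.01 while simulating 0.0001 is a legitimate (and tested)
crossing.

## Evaluation designs

* **Confusion matrices** (`confusion()`): exhaustive 3x3 cross-tabulation
  of true versus inferred full-sib / half-sib / unrelated labels over all
  `choose(n, 2)` pairs, with type-I (unrelated called sib) and type-II
  (sib called unrelated) totals. Under an assumed monogamous system the
  inferred half-sib column is structurally zero.
* **Subsampling** (`subsample_design()`, `subsample_experiment()`):
  fractions 10%–90% of the cohort, draw size `floor(fraction * n)`
  (which reproduces every published draw-size table the design is checked
  against), 10 draws per fraction, sampling without replacement within a
  draw and full replacement between draws. Per fraction: average bias,
  average percent bias, absolute average percent bias, percent RMSB
  `100 * sqrt(mean(((est - true)/true)^2))` over finite estimates, the
  standard deviation of estimates, and the count of infinite estimates
  excluded.
* **Concordance** (`sa_pwop_concordance()`): per run, SA and PwoP from the
  identical partition, their ratio and percent difference
  `100 * |SA - PwoP| / PwoP` (the published comparison reports differences
  relative to the estimates; the exact convention is unstated, so this
  choice is documented rather than claimed), a ratio histogram, and the
  count of runs excluded for infinite PwoP.

## Numerical choices and degenerate inputs

Allele frequencies are clamped so no observable genotype has zero prior
mass; a locus with fewer than two calls is an error naming the locus. With
an assumed error rate of zero the likelihood can reach `-Inf` only if a
family's genotypes cannot be explained by any parent pair — with
Hardy–Weinberg priors this does not occur for biallelic markers, but the
annealer tolerates `-Inf` moves anyway. Individuals with no non-missing
genotypes are excluded from fitting with a warning. `pwop_nb()` validates
`sum(ki) = 2S` and returns `Inf` (not an error) on a non-positive
denominator. Cluster relabelling is dense and in order of first
appearance, so identical seeds give byte-identical partitions.

## Problem sizes used by the test suite and acceptance script

The packaged checks run on one core in a few minutes, using cohorts of
80–400 offspring at 95 SNPs for reconstruction-based checks (20 restarts
at `n = 80`, 10–15 where many runs are batched), 500 loci for the
perfect-information recovery check, and the full 1,516-offspring design of
the largest benchmark population for the small-sample bias direction check
(10% draws, twelve seeds, sign test). The full-sib accuracy figure pools
five 80-offspring cohorts so the percentage rests on several hundred true
full-sib dyads rather than ~75. Polygamous-assumption checks use cohorts
of 24–30 offspring, where the R search is exact for every component that
arises.

## Known limitations

* Half-sib recovery under polygamous assumptions is poor at 95 SNPs — as
  expected from the information content of half-sib dyads — and the
  package reproduces that qualitative ordering rather than any particular
  half-sib accuracy figure.
* The reconstructor's likelihood matches the simulator's genotype model
  exactly; on real data, model misspecification (allele-frequency error,
  non-uniform miscalls, linkage) would lower accuracy relative to what
  these simulations show.
* No confidence intervals are produced for Nb estimates; the published
  interval method is not described in our sources and a dyad bootstrap,
  while straightforward, is deliberately out of scope.
* `calibrate_dispersion()` matches the mean Nb/NC ratio, not the full
  family-size distribution; simulated cohorts are somewhat richer in
  full-sib and poorer in half-sib dyads than the real populations they are
  scaled to.
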