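---
title: "Parsimony phasing with uncertain genotypes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony phasing with uncertain genotypes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmphase)
```

## The phasing problem

A genotype is a string over `{0, 1, 2}`: `0` and `2` are homozygous sites
(wild and mutant type), `1` is heterozygous. A pair of binary haplotypes
$(h, h')$ resolves genotype $g$ when $g_j = h_j + h'_j$ at every SNP $j$. A
genotype with $k$ heterozygous sites admits $2^{k-1}$ resolving pairs, so a
criterion is needed to pick among them; the pure parsimony criterion selects
the smallest set of distinct haplotypes that resolves every genotype
simultaneously. Inputs must be non-degenerate (at least one heterozygous
site per genotype — a degenerate input row is rejected) and duplicated rows
are removed with a warning, since identical genotypes carry no extra
information and would break the subset structure described below.

With uncertain data, a binary error mask $M$ flags entries that may be
missing or wrong. At a masked cell the observed value may be corrected by an
integer $\delta$ keeping the corrected value in `{0, 1, 2}`: an observed `0`
admits $\delta \in \{+1, +2\}$, a `2` admits $\{-1, -2\}$, a `1` admits
$\{+1, -1\}$, and "no correction" is always allowed. The resolution
condition becomes $g_{pj} + \delta_{pj} = h_j + h'_j$. Two bounds $L \le U$
constrain the **number of corrected cells** (not the total magnitude of the
deltas — each masked cell contributes 0 or 1; this is the package's reading
of the correction budget, with defaults $L = 0$ and $U$ equal to the number
of masked cells). A corrected row is allowed to become degenerate; such a
row can only be resolved by a doubled haplotype $h + h$, a case the model
below handles explicitly.

## The class-representative integer program

Any phasing solution induces a family of genotype subsets, one per distinct
haplotype, where a subset collects the genotypes carrying that haplotype:
each genotype lies in exactly two subsets (or one, taken twice, in the
doubled case). Each subset is named by its smallest member $q$; because a
genotype has two haplotypes, the same $q$ can name at most two subsets, and
a *dummy* companion index $n + q$ hosts the second one. Genotype $p$ can
therefore only sit in classes $\{1..p\} \cup \{n+1..n+p\}$, and at most $2n$
classes are ever needed.

Binary variables:

* $x_q$, $q = 1..2n$ — class $q$ is used;
* $y_{pq}$ — genotype $p$ belongs to class $q$, defined for candidate
  classes with $q \ne p, n+p$; membership in a genotype's own classes is
  identified with the use variables themselves ($y_{pp} \equiv x_p$,
  $y_{p,n+p} \equiv x_{n+p}$), which also realizes the special
  representative/dummy linkage: the representative belongs to every class it
  names;
* $z_{qj}$ — allele of class $q$'s haplotype at SNP $j$;
* $e_{pj\delta}$ — correction $\delta$ applied at masked cell $(p, j)$;
* $d_p$ — genotype $p$ is resolved by a doubled haplotype (defined only
  when every unmasked entry of row $p$ is homozygous, the only rows whose
  corrected version can be degenerate).

Constraints, with objective $\min \sum_q x_q$:

* dummy gating $x_{n+q} \le x_q$ — the second class of $q$ exists only if
  the first does;
* exactly two memberships: $\sum_q y_{pq} + d_p = 2$ over $p$'s candidate
  classes (so a doubled genotype occupies a single class);
* linkage $y_{pq} \le x_q$;
* certain homozygous entries pin member classes' alleles:
  $z_{qj} \le 1 - y_{pq}$ when $g_{pj} = 0$ is unmasked, $z_{qj} \ge y_{pq}$
  when $g_{pj} = 2$;
* certain heterozygous entries couple the two member classes, linearized
  pairwise over candidate classes $q \ne q'$:
  $z_{qj} + z_{q'j} \ge y_{pq} + y_{pq'} - 1$ and
  $z_{qj} + z_{q'j} \le 3 - y_{pq} - y_{pq'}$;
* masked entries use the corrected value
  $c_{pj} = g_{pj} + \sum_\delta \delta\, e_{pj\delta}$ with the same
  pairwise pattern and a big-M of 2 (sufficient since
  $|z_{qj} + z_{q'j} - c_{pj}| \le 2$ always):
  $|z_{qj} + z_{q'j} - c_{pj}| \le 2\,(2 - y_{pq} - y_{pq'})$;
* doubling: $|2 z_{qj} - c_{pj}| \le 2\,(2 - d_p - y_{pq})$ for all $j$,
  which also makes $d_p$ infeasible unless every corrected entry of row $p$
  is even;
* at most one correction per masked cell, and
  $L \le \sum e_{pj\delta} \le U$.

At the optimum no two used classes carry the same haplotype (merging them
would be feasible and strictly improving, with the doubled case absorbed by
$d_p$), so the objective equals the number of distinct haplotypes; the
extractor nevertheless deduplicates defensively and the verifier checks the
count. The doubling variable is the one place the package deliberately goes
beyond a literal two-subsets-per-genotype reading: without it, a corrected
row collapsing to all-homozygous would be charged two classes for one
haplotype and the model could exceed the true optimum, breaking equivalence
with the exhaustive oracle.

### Model-size reduction

Three sound, polynomial preprocessing rules shrink the model without
touching the optimum (`reduction_plan()`):

1. **conflict removals** — if genotypes $p$ and $q < p$ show an unmasked `0`
   facing an unmasked `2` at some SNP, no haplotype can be shared and the
   memberships of $p$ in classes $q$ and $n+q$ are dropped; a mask on either
   cell lifts the conflict because a correction could reconcile it;
2. **site fixings** — class $q$'s allele is pinned to 0 (resp. 1) wherever
   its representative has an unmasked `0` (resp. `2`), applied to the dummy
   companion as well, since the representative belongs to both;
3. **triplet cuts** — a genotype with an unmasked `1` at SNP $j$ cannot
   belong to two classes whose representatives both pin the same allele at
   $j$: $y_{pq} + y_{pq'} \le 1$.

After the site fixings are substituted into the heterozygous coupling rows,
those rows reduce exactly to the triplet cuts, so rule 3 is implied by rules
1–2 plus substitution; the cuts are kept explicit because they are cheap and
document the reduction. Fixed alleles and removed memberships are
substituted out of the variable set, so the reduced model never has more
variables than the unreduced one, and a dedicated acceptance property checks
that reduced and unreduced optima coincide with the oracle across a
randomized suite.

## The exhaustive oracle

`oracle_solve()` is an independent implementation used as ground truth: it
enumerates every correction profile (per masked cell, "none" plus each
permitted delta, kept when the correction count lies in $[L, U]$), and for
each corrected matrix searches the Cartesian product of the genotypes'
resolving pairs depth-first — genotypes with fewer pairs first, pruning a
branch as soon as the running distinct-haplotype count reaches the best
found. Degenerate corrected rows contribute the single doubled pair. The
oracle shares no code with the model builder, and is guarded to $n \le 6$,
$m \le 8$ so the full randomized comparison runs in minutes.

## What the simulator emulates — and what it does not

`sim_instance()` reproduces the construction of the classic
uniform/nonuniform phasing benchmarks: a pool of `pool_size` distinct
haplotypes, genotypes formed by summing two pool members, and an error mask
of exact density. Choices and defaults:

* **pool** — i.i.d. Bernoulli(1/2) sites with duplicate rejection. A
  coalescent simulator would add realistic linkage and frequency spectra;
  solver correctness does not depend on either, so the simpler generator is
  used and the pool plays the coalescent collection's role.
* **pairing** — `uniform` samples both parents uniformly from the distinct
  pool; `nonuniform` draws a frequency vector once per call from a symmetric
  Gamma(`concentration`) law (a Dirichlet up to normalization), so smaller
  `concentration` (default 0.5) concentrates mass on few haplotypes, as in
  a collection where haplotypes recur with unequal frequency. Degenerate or
  duplicated genotypes are rejected and resampled under a bounded retry
  budget, since the problem statement requires distinct non-degenerate
  input.
* **mask** — exactly `round(ratio * n * m)` ones placed uniformly without
  replacement, so a stated error ratio (the benchmark ratios are 1%, 5%,
  10%, 15%) is realized exactly rather than in expectation; whether the
  original benchmark masks were exact-count or per-entry Bernoulli is not
  stated anywhere, and exact-count is this package's choice because it
  matches the ratio's definition.
* **`inject_errors()`** — replaces each masked entry by a uniformly chosen
  different value; the benchmark masks flag entries without corrupting them,
  so this operation exists purely to support recovery experiments where the
  mask marks genuinely wrong observations.

Passing tests on these instances demonstrates correctness of the
optimization — the optimum matches an exhaustive search under every tested
correction budget — not biological fidelity: real panels have linkage
disequilibrium, recombination and genotyping-error structure the generator
does not model, and parsimony phasing accuracy on real data is a separate
question outside the package's scope.

## Accuracy metric and experiment

`haplotype_accuracy()` is the recovered fraction of a reference haplotype
set: $|R \cap E| / |R|$ over exact binary vectors, no partial credit.
`accuracy_experiment()` phases each simulated instance without uncertainty,
takes that optimum's haplotype set as the "correct set", then re-phases
under masks of increasing density and reports per-ratio mean/max/min
accuracy. Parsimony optima need not be unique, so the reference is whichever
optimal set the fixed deterministic backend returns and accuracies are
reported rather than asserted per instance; the tested property is the
aggregate trend that denser masks make the correct set harder to recover.
The experiment defaults (10 genotypes × 8 SNPs, pool of 6, uniform pairing,
20 replicates, ratios 1–15%) keep every solve exact while exercising all
four benchmark ratios; these are the package's study conditions for the
scaled-down recovery experiment.

## Numerical choices and degenerate inputs

* All variables are binary; the backend solves to zero MIP gap, and
  incumbents are accepted at an integrality tolerance of $10^{-6}$ and
  rounded before extraction.
* The default backend (HiGHS through SciPy, one batched subprocess per
  `solve_crm_batch()` call) is deterministic for a fixed model, so
  objectives are reproducible; the haplotype set itself may differ between
  backends when optima are non-unique, and tests never pin a specific
  optimal set unless it is unique.
* A `seed` argument is accepted throughout the solving path for interface
  symmetry; all actual randomness lives in the simulator, which isolates its
  RNG use via `withr`.
* Big-M constants are all 2, the tightest valid value for site sums and
  corrected values.
* `L > U` and entries outside the alphabet raise immediately; an infeasible
  correction window (e.g. $L$ exceeding the number of masked cells) is
  reported as solver status `"infeasible"`, not an error.
* Duplicate genotype rows are removed with a warning at validation;
  degenerate input rows are an error; degenerate *corrected* rows are legal
  and handled by the doubling mechanism.

## Bounds on the optimum

For $n'$ distinct genotypes, $k$ haplotypes supply $k(k-1)/2$ unordered
pairs of distinct haplotypes, and each genotype consumes one pair, giving
$\lceil (1 + \sqrt{1 + 8n'})/2 \rceil \le \mathrm{opt} \le 2n'$. Two
caveats apply under uncertainty, and the test suite accounts for both:
corrections can merge two distinct input genotypes into the same corrected
row (which then share one pair), so the counting argument applies to the
number of distinct *corrected* rows; and a doubled haplotype enlarges the
pair budget to $k(k+1)/2$. With an empty mask (or $U = 0$) neither occurs
and the plain bound holds as stated.

## Problem sizes and limitations

The randomized acceptance suite uses 70 base instances with $n \le 5$,
$m \le 6$, mask ratios up to 15% and correction budgets $U \le 2$, solved
with and without the reduction plan (490 integer programs in one backend
batch) against the oracle; the recovery experiment uses 20 replicates of
10 × 8 instances. These sizes are chosen so the whole suite solves every
model to proven optimality in a few minutes on a single core.

Known limitations:

* the heterozygous/masked coupling is linearized pairwise over candidate
  classes, so constraint count grows as $O(n^3 m)$ — adequate for the
  benchmark-style sizes above, but the model builder is not intended for
  hundreds of genotypes;
* the default backend requires a Python interpreter with SciPy on the PATH;
  any MILP solver can be substituted through the backend contract;
* accuracy values depend on which optimum the solver returns when optima
  are non-unique; only aggregate trends are meaningful;
* multi-allelic sites and real nucleotide encodings are out of scope — the
  input is already the 0/1/2 abstraction.
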