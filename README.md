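# crmphase

Exact haplotype phasing under the **pure parsimony criterion**, with support
for uncertain (missing or erroneous) SNP entries.

## The problem

Sequencing an individual yields, at each SNP, the *conflation* of the two
chromosome copies: a genotype entry is `0` (homozygous wild type), `2`
(homozygous mutant type) or `1` (heterozygous). A pair of haplotypes
`h, h'` (binary allele vectors) *resolves* genotype `g` when

```
g_j = h_j + h'_j   for every SNP j.
```

A genotype with `k` heterozygous sites is resolved by `2^(k-1)` different
pairs, so phasing needs a selection criterion. The pure parsimony criterion
asks for the **minimum number of distinct haplotypes** resolving all `n`
genotypes at once — an NP-hard combinatorial problem once genotypes carry
three or more heterozygous sites.

Real genotype matrices also contain *uncertain* entries. Given a binary
error mask `M` flagging those cells, the uncertain-data variant allows an
integer correction `delta in {-2,...,2}` at each masked cell (so the
corrected value stays in `{0,1,2}`), with the total number of corrected
entries bounded in `[L, U]`:

```
g_pj + delta_pj = h_j + h'_j   for every SNP j of every genotype p.
```

## The model

`crmphase` builds a **class-representative integer linear program**: a
solution partitions genotypes into subsets ("classes"), one per distinct
haplotype, each genotype belonging to the two classes carrying its pair and
each class named by its smallest member (a dummy index hosts a
representative's second class). Binary variables encode class use (`x_q`),
membership (`y_pq`), per-class allele values (`z_qj`) and per-cell correction
choices; the objective `sum_q x_q` counts the classes used, which at the
optimum equals the number of distinct haplotypes. A polynomial model-size
reduction removes memberships excluded by certain 0-vs-2 conflicts, pins
class alleles at certain homozygous entries of their representatives, and
adds joint-membership cuts, without changing the optimum. An independent
exhaustive oracle (`oracle_solve()`) provides ground truth on small
instances, and every randomized check in the test suite gates the integer
program on oracle equivalence.

The MILP is solved through a pluggable backend; the default delegates to the
HiGHS solver via SciPy (`python` on the PATH with `scipy >= 1.9`). Any
function implementing the documented backend contract can be passed instead.

## Worked example

The classic 5-genotype, 4-SNP instance shipped with the package:

```r
library(crmphase)
g <- read_genotypes(system.file("extdata", "table1.gen", package = "crmphase"))
sol <- phase_genotypes(g, relax = TRUE)
sol
#> Pure-parsimony phasing solution (optimal)
#>   genotypes: 5   SNPs: 4
#>   distinct haplotypes: 4
#>   corrections applied: 0
#>   LP-relaxation gap: 25.000%
#> haplotypes:
#>   1: 1101
#>   2: 1011
#>   3: 1000
#>   4: 0011
```

Four haplotypes suffice for the five genotypes (ten haplotypes would be the
trivial worst case); the LP-relaxation value at the root was 3, hence the
25% gap. `tidy()` shows the per-genotype assignment:

```r
tidy(sol)
#> # A tibble: 5 × 6
#>   genotype hap_a hap_b haplotype_a haplotype_b n_corrections
#>      <int> <int> <int> <chr>       <chr>               <int>
#> 1        1     1     2 1101        1011                    0
#> 2        2     3     4 1000        0011                    0
#> 3        3     2     4 1011        0011                    0
#> 4        4     2     3 1011        1000                    0
#> 5        5     1     3 1101        1000                    0
```

Each row sums to its genotype, e.g. genotype 1 = `2112` = `1101` + `1011`.

With uncertainty, a single correction can repair an apparent conflict. The
genotypes `12` and `10` disagree at SNP 2 (a certain `2` facing a certain
`0`) and would need four haplotypes; masking cell (2, 2) and allowing one
correction drops the optimum to two:

```r
gg <- validate_genotypes(rbind(c(1, 2), c(1, 0)))
mask <- rbind(c(0L, 0L), c(0L, 1L))
phase_genotypes(gg, mask, upper = 1)
#> Pure-parsimony phasing solution (optimal)
#>   genotypes: 2   SNPs: 2
#>   distinct haplotypes: 2
#>   corrections applied: 1
#> haplotypes:
#>   1: 11
#>   2: 01
```

The applied correction (`$corrections`) sets the masked `0` to `2`, after
which both genotypes are resolved by `01` + `11`.

A shell interface wrapping the same functions lives at
`inst/cli/crmphase.R` (subcommands `solve`, `simulate`, `eval`,
`experiment`); see `?run_cli`.

## Solution file format

`write_solution()` emits a line-oriented ASCII report: a `key value` header
(`n`, `m`, `objective`, `corrections`, `status`), a `HAPLOTYPES` section
(one binary string per line), an `ASSIGNMENT` section (`genotype hap_a
hap_b`, 1-based indices into the haplotype section) and a `CORRECTIONS`
section (`genotype snp original corrected`). `read_solution()` inverts it
byte-for-byte, so reports can be diffed directly.
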