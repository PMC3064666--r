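Package: crmphase
Title: Pure Parsimony Haplotype Phasing with Uncertain Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact haplotype phasing under the pure parsimony criterion, with
    support for uncertain (missing or erroneous) SNP entries. Builds a
    class-representative integer linear program whose optimum is the minimum
    number of distinct haplotypes resolving a set of genotypes, optionally
    allowing a bounded number of corrections at entries flagged by an error
    mask. Includes a polynomial model-size reduction, an exhaustive oracle for
    small instances, a benchmark-style instance simulator, a haplotype-set
    recovery accuracy metric, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with SciPy (>= 1.9) for the default
    MILP backend.
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
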