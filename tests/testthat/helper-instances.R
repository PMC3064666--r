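# shared fixtures and tiny independent oracles, built in code

table1_genotypes <- function() {
  validate_genotypes(rbind(
    c(2, 1, 1, 2),
    c(1, 0, 1, 1),
    c(1, 0, 2, 2),
    c(2, 0, 1, 1),
    c(2, 1, 0, 1)
  ))
}

# independent enumeration of resolving pairs: all 2^m x 2^m binary pairs
brute_force_pairs <- function(g) {
  m <- length(g)
  haps <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
  found <- character(0)
  for (a in seq_len(nrow(haps))) {
    for (b in a:nrow(haps)) {
      if (all(haps[a, ] + haps[b, ] == g)) {
        key <- paste(
          sort(c(
            paste0(haps[a, ], collapse = ""),
            paste0(haps[b, ], collapse = "")
          )),
          collapse = "|"
        )
        found <- c(found, key)
      }
    }
  }
  sort(unique(found))
}

pair_keys <- function(pairs) {
  sort(vapply(pairs, function(p) {
    paste(sort(c(
      paste0(p[[1]], collapse = ""),
      paste0(p[[2]], collapse = "")
    )), collapse = "|")
  }, character(1)))
}

# pair-counting lower bound on the haplotype count: k haplotypes yield
# k(k-1)/2 unordered pairs of distinct haplotypes, or k(k+1)/2 pairs when a
# haplotype may be doubled, and each distinct (corrected) genotype consumes
# one pair
pair_counting_lower_bound <- function(n_distinct, doubled = FALSE) {
  if (doubled) {
    ceiling((-1 + sqrt(1 + 8 * n_distinct)) / 2)
  } else {
    ceiling((1 + sqrt(1 + 8 * n_distinct)) / 2)
  }
}
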