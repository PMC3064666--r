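#' Generate a pool of distinct haplotypes
#'
#' Sites are i.i.d. Bernoulli(1/2); duplicate haplotypes are rejected and
#' redrawn so the pool contains `pool_size` distinct binary vectors. For short
#' haplotypes (m <= 20) the pool is drawn directly without replacement from the
#' 2^m possible vectors.
#'
#' @param pool_size Number of distinct haplotypes (>= 2, <= 2^m).
#' @param m Number of SNP sites.
#' @param seed Optional integer seed; the draw is deterministic per seed.
#' @return Integer 0/1 matrix with `pool_size` rows.
#' @export
sim_haplotype_pool <- function(pool_size, m, seed = NULL) {
  if (pool_size < 2L) stop("pool_size must be at least 2", call. = FALSE)
  if (m <= 30L && pool_size > 2^m) {
    stop("pool_size (", pool_size, ") exceeds the 2^m = ", 2^m, " possible haplotypes",
      call. = FALSE
    )
  }
  if (!is.null(seed)) withr::local_seed(seed)
  if (m <= 20L) {
    codes <- sample.int(2^m, pool_size) - 1L
    pool <- t(vapply(codes, function(cd) as.integer(intToBits(cd))[seq_len(m)], integer(m)))
  } else {
    pool <- matrix(integer(0), 0L, m)
    while (nrow(pool) < pool_size) {
      cand <- matrix(stats::rbinom((pool_size - nrow(pool)) * m, 1L, 0.5), ncol = m)
      pool <- rbind(pool, cand)
      pool <- pool[!duplicated(apply(pool, 1L, hap_key)), , drop = FALSE]
    }
  }
  storage.mode(pool) <- "integer"
  dimnames(pool) <- NULL
  pool
}

#' Generate genotypes by randomly pairing pool haplotypes
#'
#' Emulates the benchmark construction for parsimony phasing: each genotype is
#' the componentwise sum of two haplotypes drawn from the pool. In `uniform`
#' mode both parents are sampled uniformly from the distinct pool members; in
#' `nonuniform` mode a fixed frequency vector is drawn once per call from a
#' symmetric Gamma (Dirichlet) law whose shape is `concentration` — smaller
#' values give more skewed haplotype frequencies, mimicking a coalescent
#' collection in which some haplotypes recur much more often than others.
#' Degenerate or duplicated genotypes are rejected and resampled.
#'
#' @param pool Haplotype pool matrix from [sim_haplotype_pool()].
#' @param n Number of genotypes to generate.
#' @param mode `"uniform"` or `"nonuniform"`.
#' @param concentration Positive shape of the frequency law (nonuniform mode).
#' @param seed Optional integer seed.
#' @param max_tries Retry budget for the rejection loop.
#' @return Validated genotype matrix with `n` distinct non-degenerate rows.
#' @export
sim_genotypes <- function(pool, n, mode = c("uniform", "nonuniform"),
                          concentration = 0.5, seed = NULL, max_tries = 200L * n) {
  mode <- match.arg(mode)
  if (!is.null(seed)) withr::local_seed(seed)
  P <- nrow(pool)
  w <- if (mode == "uniform") {
    rep(1 / P, P)
  } else {
    f <- stats::rgamma(P, shape = concentration)
    if (sum(f) == 0) f <- rep(1, P)
    f / sum(f)
  }
  rows <- matrix(integer(0), 0L, ncol(pool))
  keys <- character(0)
  parents <- matrix(integer(0), 0L, 2L)
  tries <- 0L
  while (nrow(rows) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not generate ", n, " distinct non-degenerate genotypes from this pool",
        call. = FALSE
      )
    }
    ab <- sample.int(P, 2L, replace = TRUE, prob = w)
    g <- pool[ab[1L], ] + pool[ab[2L], ]
    if (!any(g == 1L)) next
    key <- paste0(g, collapse = "")
    if (key %in% keys) next
    rows <- rbind(rows, g)
    keys <- c(keys, key)
    parents <- rbind(parents, sort(ab))
  }
  dimnames(rows) <- NULL
  storage.mode(rows) <- "integer"
  attr(rows, "parents") <- parents
  rows
}

#' Generate an error mask with an exact error ratio
#'
#' Places exactly `round(error_ratio * n * m)` ones, sampled uniformly without
#' replacement over the n x m cells, so the realized error ratio (ones divided
#' by n*m) equals the requested one exactly rather than in expectation.
#'
#' @param n,m Mask dimensions.
#' @param error_ratio Fraction of uncertain entries in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Integer 0/1 matrix.
#' @export
sim_error_mask <- function(n, m, error_ratio, seed = NULL) {
  if (error_ratio < 0 || error_ratio > 1) stop("error_ratio must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  k <- round(error_ratio * n * m)
  mask <- matrix(0L, n, m)
  if (k > 0L) mask[sample.int(n * m, k)] <- 1L
  mask
}

#' Corrupt masked entries of a genotype matrix
#'
#' Each masked entry is replaced by a uniformly chosen *different* value in
#' \{0,1,2\}; unmasked entries are untouched. Supports recovery experiments in
#' which the mask marks genuinely erroneous observations.
#'
#' @param genotypes Genotype matrix.
#' @param mask Error mask of the same shape.
#' @param seed Optional integer seed.
#' @return Corrupted matrix (rows may become degenerate or duplicated).
#' @export
inject_errors <- function(genotypes, mask, seed = NULL) {
  mask <- validate_mask(mask, genotypes)
  if (!is.null(seed)) withr::local_seed(seed)
  out <- genotypes
  idx <- which(mask == 1L)
  for (i in idx) {
    out[i] <- sample(setdiff(0:2, out[i]), 1L)
  }
  out
}

#' Simulate a complete phasing instance
#'
#' Draws a haplotype pool, pairs haplotypes into genotypes and places an error
#' mask, reproducing the study conditions of the uniform/nonuniform benchmark
#' families (pool + random pairing, mask ratios such as 1%, 5%, 10%, 15%).
#'
#' @inheritParams sim_genotypes
#' @inheritParams sim_error_mask
#' @param m Number of SNPs.
#' @param pool_size Distinct haplotypes in the pool.
#' @param seed Integer seed driving the whole instance.
#' @return A list with elements `genotypes`, `mask`, `pool` and `config`.
#' @export
sim_instance <- function(n, m, pool_size = 10L, mode = c("uniform", "nonuniform"),
                         concentration = 0.5, error_ratio = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) withr::local_seed(seed)
  pool <- sim_haplotype_pool(pool_size, m)
  genotypes <- sim_genotypes(pool, n, mode = mode, concentration = concentration)
  mask <- sim_error_mask(n, m, error_ratio)
  list(
    genotypes = genotypes,
    mask = mask,
    pool = pool,
    config = list(
      n = n, m = m, pool_size = pool_size, mode = mode,
      concentration = concentration, error_ratio = error_ratio, seed = seed
    )
  )
}
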