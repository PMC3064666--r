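#' Brute-force exact solver for tiny phasing instances
#'
#' Independent ground truth for the integer-programming model: enumerates, for
#' every masked cell, "no correction" plus each permitted delta, keeps
#' correction profiles whose total count lies in `[lower, upper]`, and for each
#' corrected matrix searches the Cartesian product of every genotype's
#' resolving pairs for the smallest set of distinct haplotypes. A corrected row
#' that became degenerate (all homozygous) is resolvable only by a doubled
#' haplotype h + h. The search branches over genotypes and prunes on the
#' current distinct-haplotype count; it shares no code with the model builder.
#'
#' @param genotypes Validated genotype matrix (n <= 6, m <= 8 guardrail).
#' @param mask Error mask or `NULL`.
#' @param lower,upper Bounds on the number of corrected entries.
#' @return An `oracle_result` list: `optimum`, `witness` (a `pph_solution`),
#'   `explored` (number of enumerated configurations).
#' @examples
#' oracle_solve(validate_genotypes(rbind(c(1, 1))))$optimum # 2
#' @export
oracle_solve <- function(genotypes, mask = NULL, lower = 0L, upper = NULL) {
  g0 <- genotypes
  mask <- validate_mask(mask, g0)
  n <- nrow(g0)
  m <- ncol(g0)
  if (n > 6L || m > 8L) {
    stop("oracle guardrail: n <= 6 and m <= 8 (got ", n, "x", m, ")", call. = FALSE)
  }
  n_masked <- sum(mask)
  if (is.null(upper)) upper <- n_masked
  lower <- as.integer(lower)
  upper <- as.integer(upper)
  if (lower > upper) stop("lower bound exceeds upper bound", call. = FALSE)

  cells <- which(mask == 1L, arr.ind = TRUE)
  explored <- 0L
  best <- list(optimum = 2L * n + 1L, witness = NULL)

  # enumerate correction profiles: per masked cell, NA (none) or a delta
  profile_deltas <- vector("list", nrow(cells))
  if (nrow(cells) > 0L) {
    for (i in seq_len(nrow(cells))) {
      profile_deltas[[i]] <- allowed_corrections(g0[cells[i, 1L], cells[i, 2L]])
    }
  }

  consider <- function(deltas) {
    k <- sum(!is.na(deltas))
    if (k < lower || k > upper) {
      return(invisible(NULL))
    }
    gc <- g0
    if (length(deltas)) {
      for (i in seq_along(deltas)) {
        if (!is.na(deltas[i])) gc[cells[i, 1L], cells[i, 2L]] <- gc[cells[i, 1L], cells[i, 2L]] + deltas[i]
      }
    }
    res <- min_distinct_haplotypes(gc, best$optimum)
    explored <<- explored + res$explored
    if (res$optimum < best$optimum) {
      best <<- list(
        optimum = res$optimum, witness_pairs = res$pairs,
        corrected = gc, deltas = deltas
      )
    }
    invisible(NULL)
  }

  recurse_profiles <- function(i, deltas, count) {
    if (count > upper) {
      return(invisible(NULL))
    }
    if (i > nrow(cells)) {
      consider(deltas)
      return(invisible(NULL))
    }
    recurse_profiles(i + 1L, c(deltas, NA_integer_), count)
    for (d in profile_deltas[[i]]) {
      recurse_profiles(i + 1L, c(deltas, d), count + 1L)
    }
    invisible(NULL)
  }
  recurse_profiles(1L, integer(0), 0L)

  if (is.null(best$witness_pairs)) {
    return(structure(
      list(optimum = NA_integer_, witness = NULL, explored = explored, status = "infeasible"),
      class = "oracle_result"
    ))
  }

  deltas <- best$deltas
  corr <- if (length(deltas) && any(!is.na(deltas))) {
    used <- which(!is.na(deltas))
    tibble::tibble(
      genotype = as.integer(cells[used, 1L]),
      snp = as.integer(cells[used, 2L]),
      original = g0[cells[used, , drop = FALSE]],
      delta = as.integer(deltas[used]),
      corrected = g0[cells[used, , drop = FALSE]] + as.integer(deltas[used])
    )
  } else {
    empty_corrections()
  }
  witness <- pairs_to_solution(best$witness_pairs, n, m, corr, status = "optimal")
  structure(
    list(optimum = best$optimum, witness = witness, explored = explored, status = "optimal"),
    class = "oracle_result"
  )
}

empty_corrections <- function() {
  tibble::tibble(
    genotype = integer(0), snp = integer(0), original = integer(0),
    delta = integer(0), corrected = integer(0)
  )
}

# minimum number of distinct haplotypes resolving all rows of gc,
# depth-first over genotypes, bounded by `cutoff` (exclusive).
min_distinct_haplotypes <- function(gc, cutoff) {
  n <- nrow(gc)
  options <- vector("list", n)
  for (p in seq_len(n)) {
    row <- gc[p, ]
    options[[p]] <- if (any(row == 1L)) {
      resolving_pairs(row)
    } else {
      h <- as.integer(row / 2L)
      list(list(h, h))
    }
  }
  # visit constrained genotypes first: fewer resolving pairs
  ord <- order(lengths(options))
  best <- cutoff
  best_pairs <- NULL
  explored <- 0L

  dfs <- function(i, used, chosen) {
    if (length(used) >= best) {
      return(invisible(NULL))
    }
    if (i > n) {
      best <<- length(used)
      best_pairs <<- chosen
      return(invisible(NULL))
    }
    p <- ord[i]
    for (pair in options[[p]]) {
      explored <<- explored + 1L
      k1 <- hap_key(pair[[1L]])
      k2 <- hap_key(pair[[2L]])
      add <- setdiff(c(k1, k2), names(used))
      if (length(used) + length(add) >= best) next
      new_used <- used
      for (k in add) new_used[[k]] <- if (k == k1) pair[[1L]] else pair[[2L]]
      new_chosen <- chosen
      new_chosen[[p]] <- pair
      dfs(i + 1L, new_used, new_chosen)
    }
    invisible(NULL)
  }
  dfs(1L, stats::setNames(list(), character(0)), vector("list", n))
  list(optimum = if (is.null(best_pairs)) cutoff else best, pairs = best_pairs, explored = explored)
}

# build a pph_solution from per-genotype haplotype pairs
pairs_to_solution <- function(pairs, n, m, corrections, status) {
  keys <- character(0)
  haps <- list()
  idx_of <- function(h) {
    k <- hap_key(h)
    i <- match(k, keys)
    if (is.na(i)) {
      keys <<- c(keys, k)
      haps[[length(haps) + 1L]] <<- as.integer(h)
      i <- length(keys)
    }
    i
  }
  asg <- matrix(0L, n, 2L)
  for (p in seq_len(n)) {
    asg[p, ] <- sort(c(idx_of(pairs[[p]][[1L]]), idx_of(pairs[[p]][[2L]])))
  }
  hap_mat <- do.call(rbind, haps)
  new_pph_solution(
    haplotypes = hap_mat,
    assignment = tibble::tibble(
      genotype = seq_len(n),
      hap_a = asg[, 1L], hap_b = asg[, 2L]
    ),
    corrections = corrections,
    objective = nrow(hap_mat),
    status = status,
    n = n, m = m
  )
}

#' @export
print.oracle_result <- function(x, ...) {
  cat("Exhaustive phasing oracle: optimum =", x$optimum,
    "(", x$explored, "configurations explored )\n"
  )
  invisible(x)
}
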