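#' Certain conflict between two genotypes at a SNP
#'
#' Two genotypes certainly conflict at a site when one is homozygous wild type
#' (0) and the other homozygous mutant type (2) and neither cell is masked: the
#' 0 forces both haplotypes of its genotype to carry allele 0 there, the 2
#' forces allele 1, so no haplotype can be shared. A mask on either cell lifts
#' the conflict, since a correction could reconcile the two values.
#'
#' @param p,q Genotype rows (integer vectors over \{0,1,2\}).
#' @param mask_p,mask_q Mask rows (0/1) for `p` and `q`; `NULL` means unmasked.
#' @param j SNP index to test, or `NULL` to test whether a conflict exists at
#'   any site.
#' @return Logical.
#' @export
certain_conflict <- function(p, q, mask_p = NULL, mask_q = NULL, j = NULL) {
  if (length(p) != length(q)) stop("genotype rows must have equal length", call. = FALSE)
  if (is.null(mask_p)) mask_p <- rep(0L, length(p))
  if (is.null(mask_q)) mask_q <- rep(0L, length(q))
  conflict <- (abs(p - q) == 2L) & (p + q == 2L) & mask_p == 0L & mask_q == 0L
  if (is.null(j)) any(conflict) else conflict[j]
}

#' Compute a model-size reduction plan
#'
#' Identifies, before the integer program is assembled, variables that can be
#' removed or fixed without changing the optimal number of haplotypes:
#'
#' * **conflict removals** — genotype `p` can never share a haplotype with a
#'   representative genotype `q < p` if the two certainly conflict (an
#'   unmasked 0 facing an unmasked 2) at some site, so the membership of `p`
#'   in class `q` and in its dummy companion is dropped;
#' * **site fixings** — the haplotype of class `q` is pinned to allele 0 at
#'   every site where its representative has an unmasked 0, and to allele 1
#'   where it has an unmasked 2 (applied to the class and its dummy);
#' * **pair cuts** — for a genotype `p` with an unmasked heterozygous site `j`
#'   and two candidate classes whose representatives both pin allele 0 (or
#'   both allele 1) at `j`, joint membership is forbidden: the two class
#'   haplotypes must sum to 1 at `j`.
#'
#' All three rules are sound (they only discard provably infeasible
#' assignments), so the optimum with the plan applied equals the optimum
#' without it; the whole computation is polynomial in `n * m`.
#'
#' @param genotypes Validated genotype matrix.
#' @param mask Error mask or `NULL`.
#' @return A `crm_reduction_plan` with tibbles `removed` (genotype, class),
#'   `fixed_sites` (class, snp, value) and `pair_cuts` (genotype, class_a,
#'   class_b).
#' @export
reduction_plan <- function(genotypes, mask = NULL) {
  g <- genotypes
  mask <- validate_mask(mask, g)
  n <- nrow(g)
  m <- ncol(g)

  # site fixings from certain homozygous entries of each representative
  fix <- which(mask == 0L & (g == 0L | g == 2L), arr.ind = TRUE)
  fixed_sites <- if (nrow(fix) > 0L) {
    q <- fix[, 1L]
    j <- fix[, 2L]
    v <- as.integer(g[fix] == 2L)
    tibble::tibble(
      class = c(q, n + q), snp = c(j, j), value = c(v, v)
    )
  } else {
    tibble::tibble(class = integer(0), snp = integer(0), value = integer(0))
  }

  # pairwise certain conflicts: p cannot join class q (or its dummy) for q < p
  removed <- list()
  for (p in seq_len(n)) {
    for (q in seq_len(p - 1L)) {
      if (certain_conflict(g[p, ], g[q, ], mask[p, ], mask[q, ])) {
        removed[[length(removed) + 1L]] <- c(p, q)
        removed[[length(removed) + 1L]] <- c(p, n + q)
      }
    }
  }
  removed <- if (length(removed)) {
    rm <- do.call(rbind, removed)
    tibble::tibble(genotype = rm[, 1L], class = rm[, 2L])
  } else {
    tibble::tibble(genotype = integer(0), class = integer(0))
  }

  # triplet rule: certain heterozygote p at j cannot sit in two classes whose
  # representatives both pin the same allele at j
  cuts <- list()
  fixed_key <- paste(fixed_sites$class, fixed_sites$snp)
  fixed_val <- stats::setNames(fixed_sites$value, fixed_key)
  for (p in seq_len(n)) {
    cand <- c(seq_len(p), n + seq_len(p))
    het <- which(g[p, ] == 1L & mask[p, ] == 0L)
    for (j in het) {
      vals <- fixed_val[paste(cand, j)]
      for (allele in c(0L, 1L)) {
        same <- cand[!is.na(vals) & vals == allele]
        if (length(same) >= 2L) {
          cuts[[length(cuts) + 1L]] <- cbind(p, t(utils::combn(same, 2L)))
        }
      }
    }
  }
  pair_cuts <- if (length(cuts)) {
    cm <- unique(do.call(rbind, cuts))
    tibble::tibble(
      genotype = as.integer(cm[, 1L]),
      class_a = as.integer(cm[, 2L]), class_b = as.integer(cm[, 3L])
    )
  } else {
    tibble::tibble(genotype = integer(0), class_a = integer(0), class_b = integer(0))
  }

  structure(
    list(removed = removed, fixed_sites = fixed_sites, pair_cuts = pair_cuts, n = n, m = m),
    class = "crm_reduction_plan"
  )
}

#' @export
print.crm_reduction_plan <- function(x, ...) {
  cat(
    "CRM reduction plan: ",
    nrow(x$removed), " membership removals, ",
    nrow(x$fixed_sites), " fixed sites, ",
    nrow(x$pair_cuts), " pair cuts\n",
    sep = ""
  )
  invisible(x)
}
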