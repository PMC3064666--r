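#' Validate a genotype matrix
#'
#' Checks an integer matrix against the genotype encoding used throughout the
#' package: rows are genotypes, columns are SNP sites, and entries are 0
#' (homozygous wild type), 2 (homozygous mutant type) or 1 (heterozygous).
#' Degenerate rows (no heterozygous site) are rejected, and duplicated rows are
#' dropped with a warning, because the class-representative phasing model
#' presumes distinct non-degenerate genotypes.
#'
#' @param raw An integer matrix (or something coercible to one) with entries in
#'   \{0, 1, 2\}.
#' @return The validated integer matrix, with duplicate rows removed.
#' @examples
#' g <- validate_genotypes(rbind(c(2, 1, 1, 2), c(1, 0, 1, 1)))
#' @export
validate_genotypes <- function(raw) {
  g <- as_int_matrix(raw, what = "genotype matrix")
  if (nrow(g) < 1L || ncol(g) < 1L) {
    stop("genotype matrix must have at least one row and one column", call. = FALSE)
  }
  bad <- !(g %in% c(0L, 1L, 2L))
  if (any(bad)) {
    stop("genotype entries must be 0, 1 or 2; found ", g[which(bad)[1L]], call. = FALSE)
  }
  degenerate <- rowSums(g == 1L) == 0L
  if (any(degenerate)) {
    stop(
      "degenerate genotype (no heterozygous site) in row ",
      paste(which(degenerate), collapse = ", "),
      call. = FALSE
    )
  }
  keys <- apply(g, 1L, paste0, collapse = "")
  if (anyDuplicated(keys)) {
    dup <- which(duplicated(keys))
    warning(
      "removing ", length(dup), " duplicated genotype row(s): ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
    g <- g[!duplicated(keys), , drop = FALSE]
  }
  dimnames(g) <- NULL
  g
}

#' Validate an error mask
#'
#' An error mask is a binary matrix with the same shape as its genotype matrix;
#' a 1 marks a SNP entry as uncertain (missing or possibly erroneous).
#'
#' @param mask Binary matrix, or `NULL` for an all-certain mask.
#' @param genotypes Validated genotype matrix the mask belongs to.
#' @return An integer 0/1 matrix of the same shape as `genotypes`.
#' @export
validate_mask <- function(mask, genotypes) {
  if (is.null(mask)) {
    return(matrix(0L, nrow(genotypes), ncol(genotypes)))
  }
  m <- as_int_matrix(mask, what = "error mask")
  if (!identical(dim(m), dim(genotypes))) {
    stop("error mask shape (", nrow(m), "x", ncol(m), ") does not match genotypes (",
      nrow(genotypes), "x", ncol(genotypes), ")",
      call. = FALSE
    )
  }
  if (!all(m %in% c(0L, 1L))) stop("error mask entries must be 0 or 1", call. = FALSE)
  dimnames(m) <- NULL
  m
}

as_int_matrix <- function(x, what = "matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop(what, " must be a matrix", call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x)) stop(what, " contains missing values", call. = FALSE)
  x
}

#' Enumerate the haplotype pairs resolving a genotype
#'
#' A genotype row with k heterozygous sites is resolved by exactly 2^(k-1)
#' unordered pairs of haplotypes: both haplotypes carry 0 where the genotype is
#' 0 and 1 where it is 2, and are complementary at heterozygous sites.
#'
#' @param g Genotype row (integer vector over \{0,1,2\}) with at least one 1.
#' @return A list of `2^(k-1)` unordered pairs; each element is a list of two
#'   binary site vectors summing componentwise to `g`.
#' @examples
#' resolving_pairs(c(0, 2, 1))
#' @export
resolving_pairs <- function(g) {
  g <- as.integer(g)
  if (!all(g %in% c(0L, 1L, 2L))) stop("genotype entries must be 0, 1 or 2", call. = FALSE)
  het <- which(g == 1L)
  k <- length(het)
  if (k == 0L) stop("degenerate genotype: no heterozygous site", call. = FALSE)
  base <- ifelse(g == 2L, 1L, 0L)
  # fix the first heterozygous site to 0 in haplotype a: kills the a/b symmetry
  free <- het[-1L]
  n_pairs <- 2L^(k - 1L)
  lapply(seq_len(n_pairs) - 1L, function(code) {
    ha <- base
    ha[het[1L]] <- 0L
    if (length(free)) {
      bits <- as.integer(intToBits(code))[seq_along(free)]
      ha[free] <- bits
    }
    hb <- g - ha
    list(ha, hb)
  })
}

#' Test whether a haplotype pair resolves a genotype
#'
#' @param g Genotype row over \{0,1,2\}.
#' @param ha,hb Binary haplotype vectors of the same length as `g`.
#' @return `TRUE` iff `g == ha + hb` componentwise.
#' @export
is_resolved <- function(g, ha, hb) {
  if (length(g) != length(ha) || length(g) != length(hb)) {
    stop("genotype and haplotypes must have equal length", call. = FALSE)
  }
  all(as.integer(g) == as.integer(ha) + as.integer(hb))
}

#' Corrections permitted at an uncertain genotype entry
#'
#' At a masked entry the observed value may be corrected by an integer delta so
#' that the corrected value is again a valid genotype symbol: an observed 0 can
#' become 1 or 2 (deltas +1, +2), an observed 2 can become 1 or 0 (deltas -1,
#' -2), and an observed 1 can become 2 or 0 (deltas +1, -1). Leaving the entry
#' unchanged (no delta) is always permitted in addition.
#'
#' @param entry Observed genotype value, one of 0, 1, 2.
#' @return Integer vector of permitted non-zero deltas.
#' @export
allowed_corrections <- function(entry) {
  entry <- as.integer(entry)
  if (length(entry) != 1L || !entry %in% c(0L, 1L, 2L)) {
    stop("genotype entry must be a single value in {0, 1, 2}", call. = FALSE)
  }
  switch(as.character(entry),
    "0" = c(1L, 2L),
    "1" = c(-1L, 1L),
    "2" = c(-2L, -1L)
  )
}

#' Apply corrections to a genotype matrix
#'
#' @param genotypes Validated genotype matrix.
#' @param corrections A data frame with columns `genotype` (row index), `snp`
#'   (column index) and `delta`; at most one correction per cell, each at a
#'   masked cell with a delta permitted for the observed entry.
#' @param mask Error mask (binary matrix of the same shape), or `NULL` for no
#'   uncertainty (in which case `corrections` must be empty).
#' @return The corrected matrix. Corrected rows are allowed to become
#'   degenerate; such rows are resolvable only by a doubled haplotype.
#' @export
apply_corrections <- function(genotypes, corrections, mask = NULL) {
  m <- validate_mask(mask, genotypes)
  out <- genotypes
  if (is.null(corrections) || nrow(corrections) == 0L) {
    return(out)
  }
  cell <- cbind(corrections$genotype, corrections$snp)
  if (anyDuplicated(cell)) stop("more than one correction at a single cell", call. = FALSE)
  for (i in seq_len(nrow(corrections))) {
    p <- corrections$genotype[i]
    j <- corrections$snp[i]
    d <- as.integer(corrections$delta[i])
    if (p < 1L || p > nrow(out) || j < 1L || j > ncol(out)) {
      stop("correction index (", p, ", ", j, ") out of range", call. = FALSE)
    }
    if (m[p, j] != 1L) {
      stop("correction at unmasked cell (", p, ", ", j, ")", call. = FALSE)
    }
    if (!d %in% allowed_corrections(out[p, j])) {
      stop(
        "delta ", d, " not allowed for entry ", out[p, j],
        " at (", p, ", ", j, ")",
        call. = FALSE
      )
    }
    out[p, j] <- out[p, j] + d
  }
  out
}

hap_key <- function(h) paste0(as.integer(h), collapse = "")
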