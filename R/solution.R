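#' @keywords internal
new_pph_solution <- function(haplotypes, assignment, corrections, objective,
                             status, n, m, bound = NA_real_, lp_value = NA_real_,
                             gap = NA_real_, nodes = NA_integer_) {
  structure(
    list(
      haplotypes = haplotypes,
      assignment = assignment,
      corrections = corrections,
      objective = objective,
      status = status,
      n = n,
      m = m,
      bound = bound,
      lp_value = lp_value,
      gap = gap,
      nodes = nodes
    ),
    class = "pph_solution"
  )
}

#' @export
print.pph_solution <- function(x, ...) {
  cat(
    "Pure-parsimony phasing solution (", x$status, ")\n",
    "  genotypes: ", x$n, "   SNPs: ", x$m, "\n",
    "  distinct haplotypes: ", x$objective, "\n",
    "  corrections applied: ", nrow(x$corrections), "\n",
    sep = ""
  )
  if (is.finite(x$gap)) {
    cat("  LP-relaxation gap: ", sprintf("%.3f%%", 100 * x$gap), "\n", sep = "")
  }
  cat("haplotypes:\n")
  cat(paste0("  ", seq_len(nrow(x$haplotypes)), ": ",
    apply(x$haplotypes, 1L, paste0, collapse = "")
  ), sep = "\n")
  invisible(x)
}

#' Tidy a phasing solution into a per-genotype tibble
#'
#' One row per genotype with the indices and site strings of its two assigned
#' haplotypes and the number of corrections applied to it.
#'
#' @param x A `pph_solution`.
#' @param ... Unused.
#' @export
tidy.pph_solution <- function(x, ...) {
  hap_str <- apply(x$haplotypes, 1L, paste0, collapse = "")
  dplyr::mutate(
    x$assignment,
    haplotype_a = hap_str[.data$hap_a],
    haplotype_b = hap_str[.data$hap_b],
    n_corrections = vapply(
      .data$genotype,
      function(p) sum(x$corrections$genotype == p), integer(1)
    )
  )
}

#' Glance at a phasing solution
#'
#' @param x A `pph_solution`.
#' @param ... Unused.
#' @return A one-row tibble with the objective and solver diagnostics.
#' @export
glance.pph_solution <- function(x, ...) {
  tibble::tibble(
    n = x$n, m = x$m,
    objective = x$objective,
    n_corrections = nrow(x$corrections),
    status = x$status,
    bound = x$bound,
    lp_value = x$lp_value,
    gap = x$gap,
    nodes = x$nodes
  )
}

#' Plot the haplotypes of a solution as an allele map
#'
#' @param object A `pph_solution`.
#' @param ... Unused.
#' @export
autoplot.pph_solution <- function(object, ...) {
  df <- tidyr::expand_grid(
    haplotype = seq_len(nrow(object$haplotypes)),
    snp = seq_len(ncol(object$haplotypes))
  )
  df$allele <- factor(object$haplotypes[cbind(df$haplotype, df$snp)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snp, y = factor(.data$haplotype), fill = .data$allele)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey92", `1` = "grey25")) +
    ggplot2::labs(x = "SNP", y = "haplotype", fill = "allele") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
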