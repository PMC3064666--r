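#' Verify a phasing solution against its instance
#'
#' Checks, without raising, that: every genotype's assigned haplotype pair
#' sums componentwise to its corrected row; corrections sit only at masked
#' cells, at most one per cell, each with a permitted delta; the number of
#' corrections lies in `[lower, upper]`; listed haplotypes are pairwise
#' distinct; and the recorded objective equals the number of listed
#' haplotypes.
#'
#' @param sol A `pph_solution`.
#' @param genotypes Genotype matrix of the instance.
#' @param mask Error mask or `NULL`.
#' @param lower,upper Correction-count bounds the solution must respect;
#'   `upper` defaults to the number of masked cells.
#' @return Character vector of violations; `character(0)` means valid.
#' @export
verify_solution <- function(sol, genotypes, mask = NULL, lower = 0L, upper = NULL) {
  mask <- validate_mask(mask, genotypes)
  if (is.null(upper)) upper <- sum(mask)
  v <- character(0)
  n <- nrow(genotypes)

  if (nrow(sol$assignment) != n) {
    v <- c(v, sprintf("assignment covers %d genotypes, instance has %d", nrow(sol$assignment), n))
  }

  corr <- sol$corrections
  if (nrow(corr) > 0L) {
    cellkey <- paste(corr$genotype, corr$snp)
    if (anyDuplicated(cellkey)) v <- c(v, "more than one correction at a single cell")
    for (i in seq_len(nrow(corr))) {
      p <- corr$genotype[i]
      j <- corr$snp[i]
      if (mask[p, j] != 1L) {
        v <- c(v, sprintf("correction at unmasked cell (%d, %d)", p, j))
      } else if (!corr$delta[i] %in% allowed_corrections(genotypes[p, j])) {
        v <- c(v, sprintf("disallowed delta %d at cell (%d, %d)", corr$delta[i], p, j))
      }
    }
  }
  if (nrow(corr) < lower || nrow(corr) > upper) {
    v <- c(v, sprintf("correction count %d outside [%d, %d]", nrow(corr), lower, upper))
  }

  corrected <- genotypes
  if (nrow(corr) > 0L) {
    for (i in seq_len(nrow(corr))) {
      corrected[corr$genotype[i], corr$snp[i]] <-
        corrected[corr$genotype[i], corr$snp[i]] + corr$delta[i]
    }
  }

  for (i in seq_len(nrow(sol$assignment))) {
    p <- sol$assignment$genotype[i]
    ha <- sol$haplotypes[sol$assignment$hap_a[i], ]
    hb <- sol$haplotypes[sol$assignment$hap_b[i], ]
    if (!all(corrected[p, ] == ha + hb)) {
      v <- c(v, sprintf("genotype %d: assigned pair does not sum to its corrected row", p))
    }
  }

  keys <- apply(sol$haplotypes, 1L, paste0, collapse = "")
  if (anyDuplicated(keys)) v <- c(v, "listed haplotypes are not pairwise distinct")
  if (!is.na(sol$objective) && sol$objective != nrow(sol$haplotypes)) {
    v <- c(v, sprintf(
      "objective %d differs from the number of listed haplotypes (%d)",
      sol$objective, nrow(sol$haplotypes)
    ))
  }
  v
}

#' Haplotype-set recovery accuracy
#'
#' The fraction of the reference haplotypes that also appear in the estimated
#' set: `|reference intersect estimated| / |reference|`, comparing exact
#' binary site vectors with no partial credit. A value of 1 means the
#' reference set was fully recovered.
#'
#' @param reference,estimated Haplotype matrices (rows are haplotypes) or
#'   character vectors of site strings; `pph_solution` objects are accepted
#'   and their haplotype blocks used.
#' @return A number in `[0, 1]`.
#' @export
haplotype_accuracy <- function(reference, estimated) {
  ref <- unique(hap_set(reference))
  est <- unique(hap_set(estimated))
  if (length(ref) == 0L) stop("reference haplotype set is empty", call. = FALSE)
  length(intersect(ref, est)) / length(ref)
}

hap_set <- function(x) {
  if (inherits(x, "pph_solution")) x <- x$haplotypes
  if (is.matrix(x)) {
    return(apply(x, 1L, paste0, collapse = ""))
  }
  as.character(x)
}

#' Accuracy of uncertain-data phasing under increasing error ratios
#'
#' Replicates, at package scale, the recovery experiment of the uncertain-data
#' model: for each replicate an instance is simulated, phased without
#' uncertainty to obtain the reference ("correct") haplotype set, then an
#' error mask is drawn at each requested ratio and the instance is re-phased
#' under uncertainty; the accuracy is the fraction of reference haplotypes
#' recovered. Because parsimony optima need not be unique, the reference is
#' whichever optimal set the fixed backend returns, and per-instance
#' accuracies are reported, never asserted.
#'
#' @inheritParams sim_instance
#' @param ratios Error ratios to test.
#' @param replicates Number of simulated instances.
#' @param seed Integer seed driving all replicates.
#' @param backend,time_limit Passed to the solver.
#' @return A `pph_accuracy` object; `tidy()` gives per-replicate accuracies,
#'   `summary()`/`glance()` the per-ratio mean/max/min table.
#' @export
accuracy_experiment <- function(n = 10L, m = 8L, pool_size = 6L,
                                mode = c("uniform", "nonuniform"),
                                concentration = 0.5,
                                ratios = c(0.01, 0.05, 0.10, 0.15),
                                replicates = 20L, seed = NULL,
                                backend = "highs", time_limit = 600) {
  mode <- match.arg(mode)
  if (!is.null(seed)) withr::local_seed(seed)
  inst_seeds <- sample.int(.Machine$integer.max, replicates)
  mask_seeds <- matrix(sample.int(.Machine$integer.max, replicates * length(ratios)),
    nrow = replicates
  )

  rows <- list()
  for (r in seq_len(replicates)) {
    inst <- sim_instance(n, m,
      pool_size = pool_size, mode = mode,
      concentration = concentration, error_ratio = 0, seed = inst_seeds[r]
    )
    g <- inst$genotypes
    plan0 <- reduction_plan(g, NULL)
    models <- list(build_crm(g, NULL, plan = plan0))
    masks <- vector("list", length(ratios))
    for (i in seq_along(ratios)) {
      masks[[i]] <- sim_error_mask(n, m, ratios[i], seed = mask_seeds[r, i])
      models[[i + 1L]] <- build_crm(g, masks[[i]],
        plan = reduction_plan(g, masks[[i]])
      )
    }
    sols <- solve_crm_batch(models, backend = backend, time_limit = time_limit)
    failed <- vapply(sols, function(s) !s$status %in% c("optimal"), logical(1))
    if (failed[1L]) {
      warning("replicate ", r, ": reference solve did not reach optimality; replicate skipped")
      next
    }
    ref <- sols[[1L]]
    for (i in seq_along(ratios)) {
      if (failed[i + 1L]) {
        warning(
          "replicate ", r, ", ratio ", ratios[i],
          ": solve did not reach optimality; excluded from aggregates"
        )
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = r,
        error_ratio = ratios[i],
        reference_count = ref$objective,
        estimated_count = sols[[i + 1L]]$objective,
        shared_count = round(haplotype_accuracy(ref, sols[[i + 1L]]) * ref$objective),
        accuracy = haplotype_accuracy(ref, sols[[i + 1L]])
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  structure(
    list(
      results = results,
      config = list(
        n = n, m = m, pool_size = pool_size, mode = mode,
        concentration = concentration, ratios = ratios,
        replicates = replicates, seed = seed
      )
    ),
    class = "pph_accuracy"
  )
}

#' @export
tidy.pph_accuracy <- function(x, ...) x$results

#' @export
glance.pph_accuracy <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$error_ratio),
    mean_accuracy = mean(.data$accuracy),
    max_accuracy = max(.data$accuracy),
    min_accuracy = min(.data$accuracy),
    replicates = dplyr::n(),
    .groups = "drop"
  )
}

#' @export
summary.pph_accuracy <- function(object, ...) glance(object)

#' @export
print.pph_accuracy <- function(x, ...) {
  cfg <- x$config
  cat(
    "Haplotype-recovery experiment: ", cfg$replicates, " replicates of ",
    cfg$n, "x", cfg$m, " ", cfg$mode, " instances (pool of ", cfg$pool_size, ")\n",
    sep = ""
  )
  print(glance(x))
  invisible(x)
}

#' Plot recovery accuracy against the error ratio
#'
#' @param object A `pph_accuracy` object.
#' @param ... Unused.
#' @export
autoplot.pph_accuracy <- function(object, ...) {
  agg <- glance(object)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$error_ratio, y = .data$mean_accuracy)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$min_accuracy, ymax = .data$max_accuracy),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "error ratio", y = "haplotype-set recovery accuracy",
      title = "Recovery of the uncertainty-free haplotype set"
    ) +
    ggplot2::theme_minimal()
}
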