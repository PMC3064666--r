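# Class-representative formulation of pure-parsimony phasing.
#
# Classes are indexed 1..2n: class q is the subset of genotypes sharing one
# haplotype whose smallest member is genotype q; class n+q is the "dummy"
# companion hosting genotype q's second haplotype when q is the smallest
# member of both its subsets.  Genotype p can only sit in classes
# {1..p} u {n+1..n+p}, and its membership in its own classes p and n+p is
# identified with the class-use variables themselves (the representative
# belongs to every class it represents).

candidate_classes <- function(p, n) c(seq_len(p), n + seq_len(p))

# growing accumulator for sparse constraint rows
acc_new <- function() {
  e <- new.env(parent = emptyenv())
  e$ri <- integer(2048L)
  e$rj <- integer(2048L)
  e$rx <- numeric(2048L)
  e$nnz <- 0L
  e$lo <- numeric(512L)
  e$hi <- numeric(512L)
  e$nr <- 0L
  e
}

# terms: list of c(id, coef, const); id NA means the variable was eliminated
# and contributes coef * const to the row's constant part.
acc_row <- function(e, ids, coefs, consts, lo, hi) {
  fixed <- is.na(ids)
  const <- sum(coefs[fixed] * consts[fixed])
  ids <- ids[!fixed]
  coefs <- coefs[!fixed]
  e$nr <- e$nr + 1L
  if (e$nr > length(e$lo)) {
    e$lo <- c(e$lo, numeric(length(e$lo)))
    e$hi <- c(e$hi, numeric(length(e$hi)))
  }
  e$lo[e$nr] <- lo - const
  e$hi[e$nr] <- hi - const
  k <- length(ids)
  if (k > 0L) {
    while (e$nnz + k > length(e$ri)) {
      e$ri <- c(e$ri, integer(length(e$ri)))
      e$rj <- c(e$rj, integer(length(e$rj)))
      e$rx <- c(e$rx, numeric(length(e$rx)))
    }
    at <- e$nnz + seq_len(k)
    e$ri[at] <- e$nr
    e$rj[at] <- ids
    e$rx[at] <- coefs
    e$nnz <- e$nnz + k
  }
  invisible(e)
}

#' Build the class-representative integer program
#'
#' Assembles the 0/1 linear program whose optimum is the minimum number of
#' distinct haplotypes resolving the genotypes, allowing between `lower` and
#' `upper` corrections at masked entries. Variables: class-use `x_q`
#' (q = 1..2n), memberships `y_pq` for candidate classes of each genotype,
#' per-class site values `z_qj`, one binary per permitted correction delta at
#' each masked cell, and a doubling indicator for genotypes whose corrected
#' row can become fully homozygous (such a row is resolved by one haplotype
#' taken twice). The objective is the number of used classes; at the optimum
#' used classes carry pairwise-distinct haplotypes, so it equals the distinct
#' haplotype count.
#'
#' @param genotypes Validated genotype matrix.
#' @param mask Error mask or `NULL` (plain parsimony phasing).
#' @param lower,upper Bounds on the number of corrected entries; `upper`
#'   defaults to the number of masked cells.
#' @param plan Optional [reduction_plan()]; `NULL` builds the unreduced model.
#' @return A `crm_model` object.
#' @export
build_crm <- function(genotypes, mask = NULL, lower = 0L, upper = NULL, plan = NULL) {
  g <- genotypes
  mask <- validate_mask(mask, g)
  n <- nrow(g)
  m <- ncol(g)
  n_masked <- sum(mask)
  if (is.null(upper)) upper <- n_masked
  lower <- as.integer(lower)
  upper <- as.integer(upper)
  if (lower < 0L) stop("lower bound must be non-negative", call. = FALSE)
  if (lower > upper) stop("lower bound exceeds upper bound", call. = FALSE)

  removed_key <- if (!is.null(plan)) paste(plan$removed$genotype, plan$removed$class) else character(0)
  zfix <- matrix(NA_integer_, 2L * n, m)
  if (!is.null(plan) && nrow(plan$fixed_sites) > 0L) {
    zfix[cbind(plan$fixed_sites$class, plan$fixed_sites$snp)] <- plan$fixed_sites$value
  }

  nvar <- 0L
  var_name <- character(0)
  newv <- function(nm) {
    nvar <<- nvar + 1L
    var_name[nvar] <<- nm
    nvar
  }

  xid <- integer(2L * n)
  for (q in seq_len(2L * n)) xid[q] <- newv(paste0("x", q))

  # doubling indicators: only rows whose unmasked entries are all homozygous
  # can be corrected into a degenerate row
  did <- rep(NA_integer_, n)
  for (p in seq_len(n)) {
    if (all(g[p, mask[p, ] == 0L] != 1L)) did[p] <- newv(paste0("d", p))
  }

  yid <- matrix(NA_integer_, n, 2L * n)
  for (p in seq_len(n)) {
    for (q in setdiff(candidate_classes(p, n), c(p, n + p))) {
      if (!(paste(p, q) %in% removed_key)) yid[p, q] <- newv(paste0("y", p, "_", q))
    }
  }

  zid <- matrix(NA_integer_, 2L * n, m)
  for (q in seq_len(2L * n)) {
    for (j in seq_len(m)) {
      if (is.na(zfix[q, j])) zid[q, j] <- newv(paste0("z", q, "_", j))
    }
  }

  cells <- which(mask == 1L, arr.ind = TRUE)
  dimnames(cells) <- NULL
  einfo <- vector("list", nrow(cells))
  if (nrow(cells) > 0L) {
    for (k in seq_len(nrow(cells))) {
      deltas <- allowed_corrections(g[cells[k, 1L], cells[k, 2L]])
      ids <- vapply(
        deltas,
        function(d) newv(paste0("e", cells[k, 1L], "_", cells[k, 2L], "_", d)),
        integer(1)
      )
      einfo[[k]] <- list(ids = ids, deltas = deltas)
    }
  }
  # masked cell lookup: (p, j) -> index into einfo
  cell_idx <- matrix(NA_integer_, n, m)
  if (nrow(cells) > 0L) cell_idx[cells] <- seq_len(nrow(cells))

  # membership term of genotype p in class q: id (or NA) + constant
  yterm <- function(p, q) {
    if (q == p) {
      return(c(xid[p], 0L))
    }
    if (q == n + p) {
      return(c(xid[n + p], 0L))
    }
    c(yid[p, q], 0L)
  }
  zterm <- function(q, j) {
    if (is.na(zid[q, j])) c(NA_integer_, zfix[q, j]) else c(zid[q, j], 0L)
  }

  e <- acc_new()

  # dummy gating: x_{n+q} <= x_q
  for (q in seq_len(n)) {
    acc_row(e, c(xid[n + q], xid[q]), c(1, -1), c(0, 0), -Inf, 0)
  }

  # each genotype in exactly two subsets (one when doubled)
  for (p in seq_len(n)) {
    ids <- c(xid[p], xid[n + p], yid[p, ][!is.na(yid[p, ])])
    coefs <- rep(1, length(ids))
    if (!is.na(did[p])) {
      ids <- c(ids, did[p])
      coefs <- c(coefs, 1)
    }
    acc_row(e, ids, coefs, numeric(length(ids)), 2, 2)
  }

  # membership implies class use: y_pq <= x_q
  for (p in seq_len(n)) {
    for (q in which(!is.na(yid[p, ]))) {
      acc_row(e, c(yid[p, q], xid[q]), c(1, -1), c(0, 0), -Inf, 0)
    }
  }

  # joint-membership cuts from the triplet rule
  if (!is.null(plan) && nrow(plan$pair_cuts) > 0L) {
    for (k in seq_len(nrow(plan$pair_cuts))) {
      ya <- yterm(plan$pair_cuts$genotype[k], plan$pair_cuts$class_a[k])
      yb <- yterm(plan$pair_cuts$genotype[k], plan$pair_cuts$class_b[k])
      if (is.na(ya[1L]) || is.na(yb[1L])) next
      acc_row(e, c(ya[1L], yb[1L]), c(1, 1), c(0, 0), -Inf, 1)
    }
  }

  # resolution constraints
  for (p in seq_len(n)) {
    cand <- candidate_classes(p, n)
    yt <- lapply(cand, function(q) yterm(p, q))
    present <- !vapply(yt, function(v) is.na(v[1L]), logical(1))
    for (j in seq_len(m)) {
      gpj <- g[p, j]
      if (mask[p, j] == 0L) {
        if (gpj == 0L || gpj == 2L) {
          # homozygous certain entry pins the member class's site
          for (qi in which(present)) {
            q <- cand[qi]
            zt <- zterm(q, j)
            yv <- yt[[qi]][1L]
            if (is.na(zt[1L])) {
              # site already fixed: conflicting fix forbids membership
              if ((gpj == 0L && zt[2L] == 1L) || (gpj == 2L && zt[2L] == 0L)) {
                acc_row(e, yv, 1, 0, -Inf, 0)
              }
            } else if (gpj == 0L) {
              acc_row(e, c(zt[1L], yv), c(1, 1), c(0, 0), -Inf, 1)
            } else {
              acc_row(e, c(zt[1L], yv), c(1, -1), c(0, 0), 0, Inf)
            }
          }
        } else {
          # heterozygous certain entry: the two member classes sum to 1
          pres <- which(present)
          if (length(pres) >= 2L) {
            for (ai in seq_len(length(pres) - 1L)) {
              for (bi in seq((ai + 1L), length(pres))) {
                qa <- cand[pres[ai]]
                qb <- cand[pres[bi]]
                ya <- yt[[pres[ai]]][1L]
                yb <- yt[[pres[bi]]][1L]
                za <- zterm(qa, j)
                zb <- zterm(qb, j)
                ids <- c(za[1L], zb[1L], ya, yb)
                consts <- c(za[2L], zb[2L], 0, 0)
                acc_row(e, ids, c(1, 1, -1, -1), consts, -1, Inf)
                acc_row(e, ids, c(1, 1, 1, 1), consts, -Inf, 3)
              }
            }
          }
        }
      } else {
        # masked entry: corrected value equals the member classes' site sum
        ec <- einfo[[cell_idx[p, j]]]
        pres <- which(present)
        if (length(pres) >= 2L) {
          for (ai in seq_len(length(pres) - 1L)) {
            for (bi in seq((ai + 1L), length(pres))) {
              qa <- cand[pres[ai]]
              qb <- cand[pres[bi]]
              ya <- yt[[pres[ai]]][1L]
              yb <- yt[[pres[bi]]][1L]
              za <- zterm(qa, j)
              zb <- zterm(qb, j)
              ids <- c(za[1L], zb[1L], ec$ids, ya, yb)
              zc <- c(za[2L], zb[2L], numeric(length(ec$ids)), 0, 0)
              acc_row(
                e, ids, c(1, 1, -ec$deltas, 2, 2), zc,
                -Inf, 4 + gpj
              )
              acc_row(
                e, ids, c(1, 1, -ec$deltas, -2, -2), zc,
                gpj - 4, Inf
              )
            }
          }
        }
      }
    }
    # doubled resolution: 2 z_qj equals the corrected value when d_p = 1
    if (!is.na(did[p])) {
      for (qi in which(present)) {
        q <- cand[qi]
        yv <- yt[[qi]][1L]
        for (j in seq_len(m)) {
          zt <- zterm(q, j)
          gpj <- g[p, j]
          if (mask[p, j] == 1L) {
            ec <- einfo[[cell_idx[p, j]]]
            ids <- c(zt[1L], ec$ids, did[p], yv)
            consts <- c(zt[2L], numeric(length(ec$ids)), 0, 0)
            acc_row(e, ids, c(2, -ec$deltas, 2, 2), consts, -Inf, 4 + gpj)
            acc_row(e, ids, c(2, -ec$deltas, -2, -2), consts, gpj - 4, Inf)
          } else {
            ids <- c(zt[1L], did[p], yv)
            consts <- c(zt[2L], 0, 0)
            acc_row(e, ids, c(2, 2, 2), consts, -Inf, 4 + gpj)
            acc_row(e, ids, c(2, -2, -2), consts, gpj - 4, Inf)
          }
        }
      }
    }
  }

  # at most one correction per masked cell
  for (k in seq_along(einfo)) {
    acc_row(e, einfo[[k]]$ids, rep(1, length(einfo[[k]]$ids)), numeric(length(einfo[[k]]$ids)), -Inf, 1)
  }
  # correction-count window [lower, upper]
  all_e <- unlist(lapply(einfo, `[[`, "ids"))
  acc_row(e, all_e, rep(1, length(all_e)), numeric(length(all_e)), lower, upper)

  obj <- numeric(nvar)
  obj[xid] <- 1

  structure(
    list(
      n = n, m = m, genotypes = g, mask = mask, lower = lower, upper = upper,
      nvar = nvar, var_name = var_name, obj = obj,
      ai = e$ri[seq_len(e$nnz)], aj = e$rj[seq_len(e$nnz)], ax = e$rx[seq_len(e$nnz)],
      clo = e$lo[seq_len(e$nr)], chi = e$hi[seq_len(e$nr)], nrow = e$nr,
      xid = xid, yid = yid, zid = zid, zfix = zfix, did = did,
      cells = cells, einfo = einfo,
      reduced = !is.null(plan), plan = plan
    ),
    class = "crm_model"
  )
}

#' @export
print.crm_model <- function(x, ...) {
  cat(
    "Class-representative phasing model (", if (x$reduced) "reduced" else "unreduced", ")\n",
    "  genotypes: ", x$n, "   SNPs: ", x$m, "   masked cells: ", nrow(x$cells), "\n",
    "  binary variables: ", x$nvar, "   constraints: ", x$nrow, "\n",
    "  correction window: [", x$lower, ", ", x$upper, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Number of decision variables in a model
#' @param model A `crm_model`.
#' @export
n_variables <- function(model) model$nvar

model_to_problem <- function(model, relax = FALSE) {
  list(
    ncol = model$nvar, nrow = model$nrow, obj = model$obj,
    ai = model$ai, aj = model$aj, ax = model$ax,
    clo = model$clo, chi = model$chi, relax = relax
  )
}

#' Solve class-representative phasing models
#'
#' `solve_crm()` solves one assembled model; `solve_crm_batch()` solves a list
#' of models in a single backend invocation (the default backend launches one
#' Python/HiGHS subprocess per call, so batching amortizes its startup).
#'
#' @param model A `crm_model` from [build_crm()].
#' @param models List of `crm_model` objects.
#' @param backend `"highs"` (the bundled SciPy/HiGHS backend) or a function
#'   implementing the backend contract (see [milp_highs()]).
#' @param time_limit Per-model limit in seconds.
#' @param seed Accepted for interface symmetry; the bundled backend is
#'   deterministic for a fixed model, so the objective never depends on it.
#' @param relax Also solve the LP relaxation and report the relative gap
#'   `(objective - lp_value) / objective`.
#' @return A `pph_solution` (status `"optimal"`, `"time_limit"`,
#'   `"infeasible"`, ...); for the batch version, a list of them.
#' @export
solve_crm <- function(model, backend = "highs", time_limit = 600, seed = NULL, relax = FALSE) {
  solve_crm_batch(list(model), backend = backend, time_limit = time_limit, relax = relax)[[1L]]
}

#' @rdname solve_crm
#' @export
solve_crm_batch <- function(models, backend = "highs", time_limit = 600, seed = NULL, relax = FALSE) {
  fn <- resolve_backend(backend)
  probs <- lapply(models, model_to_problem, relax = relax)
  res <- fn(probs, time_limit)
  purrr::map2(models, res, crm_result)
}

crm_result <- function(model, r) {
  if (is.null(r$x)) {
    return(new_pph_solution(
      haplotypes = matrix(integer(0), 0L, model$m),
      assignment = tibble::tibble(genotype = integer(0), hap_a = integer(0), hap_b = integer(0)),
      corrections = empty_corrections(),
      objective = NA_integer_, status = r$status, n = model$n, m = model$m,
      bound = if (is.null(r$bound)) NA_real_ else r$bound
    ))
  }
  sol <- extract_solution(model, unlist(r$x), status = r$status)
  sol$bound <- if (is.null(r$bound)) NA_real_ else r$bound
  sol$nodes <- if (is.null(r$nodes)) NA_integer_ else r$nodes
  if (!is.null(r$lp_value)) {
    sol$lp_value <- r$lp_value
    obj <- sum(model$obj * round(unlist(r$x)))
    sol$gap <- if (obj > 0) (obj - r$lp_value) / obj else NA_real_
  }
  sol
}

#' Extract a phasing solution from solver variable values
#'
#' Recovers the haplotype set, the per-genotype class pair and the applied
#' corrections from an integral incumbent. Values farther than 1e-6 from an
#' integer raise an error.
#'
#' @param model A `crm_model`.
#' @param values Numeric vector of variable values (length `n_variables(model)`).
#' @param status Status string recorded on the solution.
#' @return A `pph_solution`; its `objective` is the number of distinct
#'   haplotypes among the used classes.
#' @export
extract_solution <- function(model, values, status = "optimal") {
  if (length(values) != model$nvar) stop("value vector has the wrong length", call. = FALSE)
  if (max(abs(values - round(values))) > 1e-6) {
    stop("incumbent violates the integrality tolerance (1e-6)", call. = FALSE)
  }
  v <- as.integer(round(values))
  n <- model$n
  m <- model$m

  class_hap <- function(q) {
    ifelse(is.na(model$zid[q, ]), model$zfix[q, ], v[model$zid[q, ]])
  }

  # memberships per genotype
  hap_keys <- character(0)
  hap_rows <- list()
  hap_index <- function(h) {
    k <- hap_key(h)
    i <- match(k, hap_keys)
    if (is.na(i)) {
      hap_keys <<- c(hap_keys, k)
      hap_rows[[length(hap_rows) + 1L]] <<- as.integer(h)
      i <- length(hap_keys)
    }
    i
  }

  asg <- matrix(0L, n, 2L)
  for (p in seq_len(n)) {
    cand <- candidate_classes(p, n)
    member <- cand[vapply(cand, function(q) {
      id <- if (q == p) model$xid[p] else if (q == n + p) model$xid[n + p] else model$yid[p, q]
      !is.na(id) && v[id] == 1L
    }, logical(1))]
    doubled <- !is.na(model$did[p]) && v[model$did[p]] == 1L
    if (doubled) {
      if (length(member) != 1L) {
        stop("doubled genotype ", p, " is a member of ", length(member), " classes", call. = FALSE)
      }
      i <- hap_index(class_hap(member))
      asg[p, ] <- c(i, i)
    } else {
      if (length(member) != 2L) {
        stop("genotype ", p, " is a member of ", length(member), " classes", call. = FALSE)
      }
      asg[p, ] <- sort(c(hap_index(class_hap(member[1L])), hap_index(class_hap(member[2L]))))
    }
  }

  corr <- empty_corrections()
  if (length(model$einfo) > 0L) {
    recs <- list()
    for (k in seq_along(model$einfo)) {
      on <- which(v[model$einfo[[k]]$ids] == 1L)
      if (length(on) == 1L) {
        p <- model$cells[k, 1L]
        j <- model$cells[k, 2L]
        d <- model$einfo[[k]]$deltas[on]
        recs[[length(recs) + 1L]] <- c(p, j, model$genotypes[p, j], d)
      }
    }
    if (length(recs)) {
      rm <- do.call(rbind, recs)
      corr <- tibble::tibble(
        genotype = as.integer(rm[, 1L]), snp = as.integer(rm[, 2L]),
        original = as.integer(rm[, 3L]), delta = as.integer(rm[, 4L]),
        corrected = as.integer(rm[, 3L] + rm[, 4L])
      )
    }
  }

  hap_mat <- if (length(hap_rows)) do.call(rbind, hap_rows) else matrix(integer(0), 0L, m)
  new_pph_solution(
    haplotypes = hap_mat,
    assignment = tibble::tibble(genotype = seq_len(n), hap_a = asg[, 1L], hap_b = asg[, 2L]),
    corrections = corr,
    objective = nrow(hap_mat),
    status = status,
    n = n, m = m
  )
}

#' Phase genotypes under the pure parsimony criterion
#'
#' One-call interface: validates the inputs, computes the model-size reduction
#' plan, assembles the class-representative integer program and solves it.
#' With `mask = NULL` (or an all-zero mask) this is plain pure-parsimony
#' phasing; with a mask it allows between `lower` and `upper` corrections at
#' the uncertain entries.
#'
#' @inheritParams build_crm
#' @inheritParams solve_crm
#' @param reduce Apply the [reduction_plan()] before building the model.
#' @param oracle_check Cross-check the objective against the exhaustive
#'   oracle; refused for instances beyond the oracle guardrail (n > 6 or
#'   m > 8).
#' @return A `pph_solution`.
#' @examples
#' \donttest{
#' g <- validate_genotypes(rbind(c(1, 2), c(1, 0)))
#' phase_genotypes(g)$objective # 4: the two genotypes conflict at SNP 2
#' }
#' @export
phase_genotypes <- function(genotypes, mask = NULL, lower = 0L, upper = NULL,
                            reduce = TRUE, backend = "highs", time_limit = 600,
                            seed = NULL, relax = FALSE, oracle_check = FALSE) {
  g <- validate_genotypes(genotypes)
  mask <- validate_mask(mask, g)
  plan <- if (reduce) reduction_plan(g, mask) else NULL
  model <- build_crm(g, mask, lower = lower, upper = upper, plan = plan)
  sol <- solve_crm(model, backend = backend, time_limit = time_limit, seed = seed, relax = relax)
  if (oracle_check) {
    if (nrow(g) > 6L || ncol(g) > 8L) {
      stop("oracle check refused for instances larger than 6 genotypes x 8 SNPs", call. = FALSE)
    }
    ora <- oracle_solve(g, mask, lower = lower, upper = if (is.null(upper)) sum(mask) else upper)
    ok <- (is.na(sol$objective) && is.na(ora$optimum)) ||
      (!is.na(sol$objective) && !is.na(ora$optimum) && sol$objective == ora$optimum)
    if (!ok) {
      stop(
        "model objective (", sol$objective, ") disagrees with the oracle (",
        ora$optimum, ")",
        call. = FALSE
      )
    }
  }
  sol
}
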