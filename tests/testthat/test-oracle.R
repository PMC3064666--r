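test_that("oracle solves canonical instances exactly", {
  # one heterozygous genotype always needs two distinct haplotypes
  expect_identical(oracle_solve(validate_genotypes(rbind(c(1, 1))))$optimum, 2L)

  res <- oracle_solve(table1_genotypes())
  expect_identical(res$optimum, 4L)
  expect_length(verify_solution(res$witness, table1_genotypes()), 0L)
  expect_identical(res$witness$objective, 4L)
  expect_gt(res$explored, 0L)

  # conflicting pair: no haplotype can be shared
  g2 <- validate_genotypes(rbind(c(1, 2), c(1, 0)))
  expect_identical(oracle_solve(g2)$optimum, 4L)
  # one correction at the masked cell reconciles them
  mask <- rbind(c(0L, 0L), c(0L, 1L))
  res2 <- oracle_solve(g2, mask, lower = 0, upper = 1)
  expect_identical(res2$optimum, 2L)
  expect_length(verify_solution(res2$witness, g2, mask, upper = 1), 0L)
})

test_that("oracle respects its guardrail and bound arguments", {
  g7 <- validate_genotypes(rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
    c(0, 1, 1), c(1, 0, 1), c(1, 1, 1)
  ))
  expect_error(oracle_solve(g7), "guardrail")
  expect_error(oracle_solve(table1_genotypes(), lower = 2, upper = 1), "exceeds")
})

test_that("a lower bound above the masked-cell count is infeasible", {
  g <- validate_genotypes(rbind(c(1, 1)))
  res <- oracle_solve(g, lower = 1, upper = 2)
  expect_identical(res$status, "infeasible")
  expect_true(is.na(res$optimum))
})

test_that("oracle optimum is invariant under row and column permutation", {
  set.seed(17)
  for (i in 1:5) {
    inst <- sim_instance(4, 5, pool_size = 4, error_ratio = 0.15, seed = 300 + i)
    base <- oracle_solve(inst$genotypes, inst$mask, upper = 2)$optimum
    rp <- sample(nrow(inst$genotypes))
    cp <- sample(ncol(inst$genotypes))
    perm <- oracle_solve(
      inst$genotypes[rp, cp, drop = FALSE],
      inst$mask[rp, cp, drop = FALSE],
      upper = 2
    )$optimum
    expect_identical(perm, base)
  }
})

test_that("an all-zero mask with no corrections reduces to plain parsimony", {
  set.seed(23)
  for (i in 1:4) {
    inst <- sim_instance(4, 5, pool_size = 4, error_ratio = 0.1, seed = 400 + i)
    plain <- oracle_solve(inst$genotypes)$optimum
    masked_u0 <- oracle_solve(inst$genotypes, inst$mask, lower = 0, upper = 0)$optimum
    zero_mask <- oracle_solve(inst$genotypes, matrix(0L, 4, 5))$optimum
    expect_identical(masked_u0, plain)
    expect_identical(zero_mask, plain)
  }
})

test_that("pairwise certain conflicts force the 2n upper bound to be tight", {
  g <- validate_genotypes(rbind(
    c(1, 0, 0, 2),
    c(1, 2, 0, 0),
    c(1, 0, 2, 0)
  ))
  expect_identical(oracle_solve(g)$optimum, 6L)

  # and 2n is never exceeded
  set.seed(29)
  for (i in 1:4) {
    inst <- sim_instance(3, 4, pool_size = 3, error_ratio = 0, seed = 500 + i)
    expect_lte(oracle_solve(inst$genotypes)$optimum, 2L * nrow(inst$genotypes))
  }
})

test_that("degenerate corrected rows are resolved by a doubled haplotype", {
  # masking both heterozygous entries of (1,1) lets corrections reconcile the
  # two genotypes: optimum 2 instead of 3
  g <- validate_genotypes(rbind(c(1, 1), c(1, 2)))
  mask <- rbind(c(1L, 1L), c(0L, 0L))
  res <- oracle_solve(g, mask, lower = 0, upper = 2)
  expect_identical(res$optimum, 2L)
  expect_length(verify_solution(res$witness, g, mask, upper = 2), 0L)

  # forcing two corrections on a lone heterozygous pair makes the corrected
  # row fully homozygous: a single doubled haplotype suffices
  g1 <- validate_genotypes(rbind(c(1, 1)))
  m1 <- rbind(c(1L, 1L))
  res1 <- oracle_solve(g1, m1, lower = 2, upper = 2)
  expect_identical(res1$optimum, 1L)
  w <- res1$witness
  expect_identical(w$assignment$hap_a, w$assignment$hap_b)
  expect_length(verify_solution(w, g1, m1, lower = 2, upper = 2), 0L)
})
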