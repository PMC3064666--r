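test_that("certain conflicts require an unmasked 0 facing an unmasked 2", {
  expect_true(certain_conflict(c(0, 1), c(2, 1), j = 1))
  expect_false(certain_conflict(c(0, 1), c(2, 1), mask_p = c(1, 0), j = 1))
  expect_false(certain_conflict(c(0, 1), c(2, 1), mask_q = c(1, 0), j = 1))
  expect_false(certain_conflict(c(0, 1), c(0, 1), j = 1))
  expect_false(certain_conflict(c(0, 1), c(1, 1), j = 1))
  g <- c(0, 1, 2)
  expect_false(any(vapply(1:3, function(j) certain_conflict(g, g, j = j), logical(1))))
  expect_error(certain_conflict(c(0, 1), c(0, 1, 2)), "equal length")
})

test_that("conflicting genotypes lose membership in each other's classes", {
  g <- validate_genotypes(rbind(c(0, 1), c(2, 1)))
  plan <- reduction_plan(g)
  # genotype 2 cannot join genotype 1's class or its dummy companion (n=2)
  expect_true(all(c(1, 3) %in% plan$removed$class[plan$removed$genotype == 2]))

  mask <- rbind(c(1L, 0L), c(0L, 0L))
  plan2 <- reduction_plan(g, mask)
  expect_identical(nrow(plan2$removed), 0L)
})

test_that("site fixings pin class haplotypes at certain homozygous entries", {
  g <- validate_genotypes(rbind(c(0, 1, 2)))
  plan <- reduction_plan(g)
  fx <- plan$fixed_sites
  expect_identical(fx$value[fx$class == 1 & fx$snp == 1], 0L)
  expect_identical(fx$value[fx$class == 1 & fx$snp == 3], 1L)
  expect_identical(fx$value[fx$class == 2 & fx$snp == 1], 0L) # dummy companion
  expect_false(any(fx$snp == 2)) # heterozygous site never fixed

  # masking the homozygous entry lifts the fixing
  plan2 <- reduction_plan(g, rbind(c(1L, 0L, 0L)))
  expect_false(any(plan2$fixed_sites$snp == 1))
})

test_that("triplet cuts forbid joint membership in same-allele classes", {
  # genotypes 1 and 2 pin allele 0 at SNP 1; genotype 3 is heterozygous there
  g <- validate_genotypes(rbind(c(0, 1, 1), c(0, 1, 2), c(1, 1, 0)))
  plan <- reduction_plan(g)
  cuts <- plan$pair_cuts
  hit <- cuts$genotype == 3 & cuts$class_a == 1 & cuts$class_b == 2
  expect_true(any(hit))
})

test_that("the plan never increases the variable count", {
  set.seed(31)
  for (i in 1:6) {
    inst <- sim_instance(4, 5, pool_size = 4, error_ratio = 0.1, seed = 600 + i)
    with_plan <- build_crm(inst$genotypes, inst$mask,
      plan = reduction_plan(inst$genotypes, inst$mask)
    )
    without <- build_crm(inst$genotypes, inst$mask)
    expect_lte(n_variables(with_plan), n_variables(without))
  }
})

test_that("the plan is computed by scanning, not enumeration, and scales", {
  inst <- sim_instance(30, 20, pool_size = 12, error_ratio = 0.05, seed = 888)
  t0 <- Sys.time()
  plan <- reduction_plan(inst$genotypes, inst$mask)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_s3_class(plan, "crm_reduction_plan")
})

test_that("applying the plan preserves the optimum on random instances", {
  set.seed(37)
  models <- list()
  oracles <- integer(0)
  insts <- list()
  for (i in 1:6) {
    inst <- sim_instance(4, 4, pool_size = 4, error_ratio = 0.15, seed = 700 + i)
    U <- (i %% 3)
    insts[[length(insts) + 1L]] <- list(inst = inst, U = U)
    models <- c(models, list(
      build_crm(inst$genotypes, inst$mask,
        upper = U,
        plan = reduction_plan(inst$genotypes, inst$mask)
      ),
      build_crm(inst$genotypes, inst$mask, upper = U)
    ))
    oracles <- c(oracles, oracle_solve(inst$genotypes, inst$mask, upper = U)$optimum)
  }
  sols <- solve_crm_batch(models)
  for (k in seq_along(oracles)) {
    expect_identical(sols[[2 * k - 1]]$objective, oracles[k])
    expect_identical(sols[[2 * k]]$objective, oracles[k])
  }
})
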