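test_that("model structure follows the class-representative layout", {
  g <- validate_genotypes(rbind(c(1, 2), c(1, 0)))
  model <- build_crm(g)
  # 2n class-use variables, no correction variables without a mask
  expect_identical(sum(startsWith(model$var_name, "x")), 4L)
  expect_identical(sum(startsWith(model$var_name, "e")), 0L)

  mask <- rbind(c(0L, 0L), c(0L, 1L))
  model2 <- build_crm(g, mask)
  # masked entry 0 admits deltas +1 and +2
  expect_identical(sum(startsWith(model2$var_name, "e")), 2L)

  expect_error(build_crm(g, mask, lower = 1, upper = 0), "exceeds")
  expect_error(build_crm(g, lower = -1), "non-negative")
})

test_that("the worked 5x4 example solves to four haplotypes", {
  g <- table1_genotypes()
  sol <- phase_genotypes(g)
  expect_identical(sol$status, "optimal")
  expect_identical(sol$objective, 4L)
  expect_length(verify_solution(sol, g), 0L)
  expect_identical(nrow(sol$assignment), 5L)

  # uncertain-data model with an all-zero mask gives the same optimum
  sol_ud <- phase_genotypes(g, matrix(0L, 5, 4))
  expect_identical(sol_ud$objective, 4L)
})

test_that("masked corrections can reconcile conflicting genotypes", {
  g <- validate_genotypes(rbind(c(1, 2), c(1, 0)))
  expect_identical(phase_genotypes(g)$objective, 4L)
  mask <- rbind(c(0L, 0L), c(0L, 1L))
  sol <- phase_genotypes(g, mask, lower = 0, upper = 1)
  expect_identical(sol$objective, 2L)
  expect_identical(nrow(sol$corrections), 1L)
  expect_identical(sol$corrections$snp, 2L)
  expect_length(verify_solution(sol, g, mask, upper = 1), 0L)
})

test_that("a correction lower bound without masked cells is infeasible", {
  g <- validate_genotypes(rbind(c(1, 1)))
  model <- build_crm(g, lower = 1, upper = 2)
  sol <- solve_crm(model)
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective))
})

test_that("degenerate corrected rows cost a single doubled haplotype", {
  g <- validate_genotypes(rbind(c(1, 1), c(1, 2)))
  mask <- rbind(c(1L, 1L), c(0L, 0L))
  sol <- phase_genotypes(g, mask, lower = 0, upper = 2)
  expect_identical(sol$objective, 2L)
  expect_identical(sol$objective, oracle_solve(g, mask, upper = 2)$optimum)
  expect_length(verify_solution(sol, g, mask, upper = 2), 0L)

  # forced corrections collapse a lone heterozygous pair to h + h
  g1 <- validate_genotypes(rbind(c(1, 1)))
  m1 <- rbind(c(1L, 1L))
  sol1 <- phase_genotypes(g1, m1, lower = 2, upper = 2)
  expect_identical(sol1$objective, 1L)
  expect_identical(sol1$assignment$hap_a, sol1$assignment$hap_b)
  expect_length(verify_solution(sol1, g1, m1, lower = 2, upper = 2), 0L)
})

test_that("solver diagnostics expose the LP-relaxation gap", {
  sol <- phase_genotypes(table1_genotypes(), relax = TRUE)
  expect_true(is.finite(sol$lp_value))
  expect_lte(sol$lp_value, sol$objective + 1e-9)
  expect_equal(sol$gap, (sol$objective - sol$lp_value) / sol$objective)
})

test_that("solving is deterministic and backend-pluggable", {
  g <- table1_genotypes()
  model <- build_crm(g, plan = reduction_plan(g, NULL))
  s1 <- solve_crm(model)
  s2 <- solve_crm(model, seed = 123)
  expect_identical(s1$objective, s2$objective)
  expect_identical(s1$haplotypes, s2$haplotypes)

  # a backend is just a function over the problem contract
  logging_backend <- function(problems, time_limit) {
    calls <<- calls + length(problems)
    milp_highs(problems, time_limit)
  }
  calls <- 0L
  s3 <- solve_crm(model, backend = logging_backend)
  expect_identical(calls, 1L)
  expect_identical(s3$objective, s1$objective)
  expect_error(solve_crm(model, backend = "nonexistent"), "unknown backend")
})

test_that("extraction enforces the integrality tolerance", {
  g <- validate_genotypes(rbind(c(1, 1)))
  model <- build_crm(g)
  expect_error(extract_solution(model, rep(0.4, n_variables(model))), "integrality")
  expect_error(extract_solution(model, numeric(2)), "wrong length")
})

test_that("oracle_check flags nothing on agreeing instances and refuses big ones", {
  g <- validate_genotypes(rbind(c(1, 2), c(1, 0)))
  expect_identical(phase_genotypes(g, oracle_check = TRUE)$objective, 4L)
  big <- sim_instance(7, 4, pool_size = 6, seed = 3)$genotypes
  expect_error(phase_genotypes(big, oracle_check = TRUE), "refused")
})
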