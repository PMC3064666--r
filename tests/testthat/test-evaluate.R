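test_that("verify_solution reports each class of violation", {
  g <- table1_genotypes()
  good <- oracle_solve(g)$witness
  expect_length(verify_solution(good, g), 0L)

  # same haplotype twice cannot resolve a genotype with heterozygous sites
  bad <- good
  bad$assignment$hap_b <- bad$assignment$hap_a
  expect_true(any(grepl("does not sum", verify_solution(bad, g))))

  # a correction at an unmasked cell
  bad2 <- good
  bad2$corrections <- tibble::tibble(
    genotype = 1L, snp = 1L, original = 2L, delta = -1L, corrected = 1L
  )
  v <- verify_solution(bad2, g)
  expect_true(any(grepl("unmasked", v)))

  # objective out of step with the haplotype block
  bad3 <- good
  bad3$objective <- 3L
  expect_true(any(grepl("differs from the number", verify_solution(bad3, g))))

  # correction count outside the window: an uncorrected solution cannot
  # satisfy a correction lower bound of one
  mask <- matrix(0L, 5, 4)
  mask[1, 1] <- 1L
  expect_true(any(grepl("outside", verify_solution(good, g, mask, lower = 1, upper = 1))))
})

test_that("accuracy is the recovered fraction of the reference set", {
  ref <- c("1011", "0011", "1101", "1000")
  expect_identical(haplotype_accuracy(ref, ref), 1)
  expect_identical(haplotype_accuracy(ref, c("1011", "0011", "0000", "1111")), 0.5)
  expect_identical(haplotype_accuracy(ref, c("0000", "1111")), 0)
  # superset of the reference still scores 1
  expect_identical(haplotype_accuracy(ref, c(ref, "0101")), 1)
  expect_error(haplotype_accuracy(character(0), ref), "empty")
  # matrices and solutions are accepted
  sol <- oracle_solve(table1_genotypes())$witness
  expect_identical(haplotype_accuracy(sol, sol$haplotypes), 1)
})

exp_small <- accuracy_experiment(
  n = 6, m = 5, pool_size = 4, ratios = c(0, 0.1), replicates = 3, seed = 505
)

test_that("the recovery experiment aggregates per-ratio accuracies", {
  res <- tidy(exp_small)
  expect_identical(nrow(res), 6L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  # a zero error ratio yields an empty mask, hence the identical model and
  # objective as the uncertainty-free reference solve
  expect_true(all(res$estimated_count[res$error_ratio == 0] ==
    res$reference_count[res$error_ratio == 0]))

  agg <- glance(exp_small)
  expect_identical(nrow(agg), 2L)
  expect_named(
    agg,
    c("error_ratio", "mean_accuracy", "max_accuracy", "min_accuracy", "replicates")
  )
  expect_true(all(agg$min_accuracy <= agg$mean_accuracy &
    agg$mean_accuracy <= agg$max_accuracy))
  expect_identical(summary(exp_small), agg)
})

test_that("experiments are reproducible for a fixed seed", {
  again <- accuracy_experiment(
    n = 6, m = 5, pool_size = 4, ratios = c(0, 0.1), replicates = 3, seed = 505
  )
  expect_identical(tidy(again), tidy(exp_small))
})

test_that("tidiers and autoplot expose solutions as tables and figures", {
  sol <- phase_genotypes(table1_genotypes())
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 5L)
  expect_true(all(nchar(td$haplotype_a) == 4L))

  gl <- glance(sol)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$objective, 4L)
  expect_identical(gl$status, "optimal")

  expect_s3_class(autoplot(sol), "ggplot")
  expect_s3_class(autoplot(exp_small), "ggplot")
})
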