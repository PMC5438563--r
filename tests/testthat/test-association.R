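test_that("nCpG depletion resampling test: degenerate subset, extreme subset, reproducibility", {
  set.seed(1)
  pool <- rnorm(400, 0.3, 0.08)
  # DM set = entire methylated set: every null draw equals the observed
  r_all <- ncpg_depletion_test(pool, pool, B = 99, seed = 1)
  expect_equal(r_all$p_value, 1)
  # DM set = the k lowest values: minimum attainable p
  low <- sort(pool)[1:50]
  r_low <- ncpg_depletion_test(low, pool, B = 99, seed = 1)
  expect_equal(r_low$p_value, 1 / 100)
  # bit-exact reproducibility under a fixed seed
  r1 <- ncpg_depletion_test(low, pool, B = 199, seed = 7)
  r2 <- ncpg_depletion_test(low, pool, B = 199, seed = 7)
  expect_identical(r1, r2)
  expect_error(ncpg_depletion_test(numeric(0), pool), "empty")
  expect_error(ncpg_depletion_test(rep(0.1, 500), pool), "larger")
})

test_that("KS comparison equals a brute-force ECDF gap", {
  same <- rnorm(50)
  r <- ks_compare(same, same)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
  expect_equal(ks_compare(1:10, 101:110)$D, 1)   # disjoint supports
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(sample(20:100, 1))
    b <- rnorm(sample(20:100, 1), mean = runif(1, -1, 1))
    grid <- sort(c(a, b))
    d_brute <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
    expect_equal(ks_compare(a, b)$D, d_brute, tolerance = 1e-12)
  }
})

test_that("proximity permutation test: extremes, symmetry and coarse-B warning", {
  set.seed(3)
  # perfectly separated classes reach the floor
  lab <- rep(c(TRUE, FALSE), each = 100)
  ind <- lab
  r <- proximity_permutation_test(lab, ind, B = 199, seed = 1)
  expect_equal(r$p_value, 1 / 200)
  # swapping class labels leaves the two-sided p unchanged
  r2 <- proximity_permutation_test(!lab, ind, B = 199, seed = 1)
  expect_equal(r$p_value, r2$p_value)
  expect_warning(
    proximity_permutation_test(lab, ind, B = 49, seed = 1), "coarse")
  expect_error(proximity_permutation_test(rep(TRUE, 10), rep(1, 10)),
               "two classes")
})

test_that("Fisher methylation-by-expression test matches hypergeometric enumeration", {
  # [[5,0],[0,5]]: p = 2 / C(10,5) = 2/252
  gt <- data.frame(dm = rep(c(TRUE, FALSE), each = 5),
                   de = rep(c(TRUE, FALSE), each = 5))
  r <- methylation_expression_fisher(gt)
  expect_equal(r$p_value, 2 / 252, tolerance = 1e-12)
  # [[1,1],[1,1]]: no association
  gt2 <- data.frame(dm = c(TRUE, TRUE, FALSE, FALSE),
                    de = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(methylation_expression_fisher(gt2)$p_value, 1)
  # zero margin flagged with p = 1
  gt3 <- data.frame(dm = c(TRUE, TRUE, FALSE), de = rep(FALSE, 3))
  r3 <- methylation_expression_fisher(gt3)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$flag, "zero_margin")
  # de_class interface counts anything but "none" as DE
  gt4 <- data.frame(dm = rep(c(TRUE, FALSE), each = 5),
                    de_class = rep(c("male_up", "none"), each = 5))
  expect_equal(methylation_expression_fisher(gt4)$p_value, 2 / 252,
               tolerance = 1e-12)
})

test_that("repeat abundance statistics: KW identity case and closed-form OLS", {
  x <- c(CR1 = 0.05, HAT = 0.04, DIRS = 0.02, Gypsy = 0.01)
  r <- suppressWarnings(repeat_abundance_stats(x, x, x))
  expect_true(all(r$kruskal$H == 0))
  expect_true(all(r$kruskal$p_value == 1))

  y <- 2 * x
  r2 <- suppressWarnings(repeat_abundance_stats(x, x, y))
  expect_equal(r2$regressions$on_genome$slope, 2)
  expect_equal(r2$regressions$on_genome$r2, 1)

  # OLS equals the normal-equations oracle on noisy data
  set.seed(4)
  g <- setNames(runif(30, 0, 0.1), paste0("c", 1:30))
  t_ <- 0.5 * g + rnorm(30, 0, 0.01)
  names(t_) <- names(g)
  m <- setNames(runif(30, 0, 0.1), names(g))
  fit <- repeat_abundance_stats(g, m, t_)
  X <- cbind(1, g)
  beta <- solve(t(X) %*% X, t(X) %*% t_)
  expect_equal(fit$regressions$on_genome$slope, unname(beta[2, 1]),
               tolerance = 1e-10)
  expect_error(repeat_abundance_stats(x[1:2], x[1:2], x[1:2]), ">= 3")
})

test_that("repeat proximity: counts monotone in distance, chi-square hand-checked, concordance reported", {
  sim <- simulate_genome(sim_config(seed = 11, n_scaffolds = 1L,
                                    scaffold_length = 5e5, n_genes = 80L,
                                    gene_length = c(1500L, 2500L),
                                    intergenic_gap = c(500L, 2500L),
                                    n_dm_genes = 12L,
                                    libraries = data.frame(
                                      library_id = c("m1", "m2", "f1", "f2"),
                                      sex = c("male", "male",
                                              "female", "female"),
                                      size = c(12000L, 12500L,
                                               12200L, 13000L),
                                      stringsAsFactors = FALSE)))
  wc <- simulate_medip_counts(sim$bundle, sim$truth)
  calls <- call_methylated(wc, sim$bundle)
  dm <- diffmeth_windows(wc, calls)
  gs <- summarize_genes(dm, sim$bundle)
  prox <- repeat_proximity(sim$bundle, calls, dm, gs)

  # nested distances give monotone counts within every set
  for (s in unique(prox$table$set)) {
    d <- prox$table[prox$table$set == s, ]
    d <- d[order(d$distance), ]
    expect_true(all(diff(d$n_with_repeat) >= 0))
  }
  expect_true(all(prox$table$fraction >= 0 & prox$table$fraction <= 1,
                  na.rm = TRUE))
  expect_true(all(prox$table$n_with_repeat <= prox$table$n_genes))

  # chi-square statistic equals the hand formula on the same 2x2 table
  row_m <- prox$table[prox$table$set == "methylated" &
                        prox$table$distance == 10000, ]
  row_n <- prox$table[prox$table$set == "non_methylated" &
                        prox$table$distance == 10000, ]
  O <- rbind(c(row_m$n_with_repeat, row_m$n_genes - row_m$n_with_repeat),
             c(row_n$n_with_repeat, row_n$n_genes - row_n$n_with_repeat))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(row_m$chisq_stat, sum((O - E)^2 / E), tolerance = 1e-10)

  # the documented example value for the chi-square convention in use
  ex <- suppressWarnings(chisq.test(rbind(c(90, 10), c(10, 90)),
                                    correct = FALSE))
  expect_equal(unname(ex$statistic), 128)

  # concordance fractions are proportions
  if (!is.null(prox$concordance) && nrow(prox$concordance)) {
    expect_true(all(prox$concordance$fraction >= 0 &
                      prox$concordance$fraction <= 1))
    expect_true(all(prox$concordance$matched <= prox$concordance$total))
  }
})
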