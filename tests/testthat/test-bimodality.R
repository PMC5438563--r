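test_that("G = 1 fit equals the closed-form MLE and G = 2 never fits worse", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(200 + i * 50, runif(1), runif(1, 0.02, 0.2))
    f1 <- fit_gmm(x, 1)
    expect_equal(f1$means, mean(x), tolerance = 1e-6)
    expect_equal(f1$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
    f2 <- fit_gmm(x, 2, seed = i)
    expect_gte(f2$loglik, f1$loglik - 1e-6)
    expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
    expect_true(all(diff(f2$means) >= 0))
  }
})

test_that("well-separated mixture parameters are recovered", {
  set.seed(6)
  x <- c(rnorm(1000, 0.25, 0.04), rnorm(1000, 0.60, 0.05))
  f <- fit_gmm(x, 2, seed = 1)
  expect_lt(abs(f$means[1] - 0.25), 0.02)
  expect_lt(abs(f$means[2] - 0.60), 0.02)
  expect_lt(abs(f$weights[1] - 0.5), 0.05)
})

test_that("fit agrees with mclust's unequal-variance model as an independent check", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(7)
  x <- c(rnorm(600, 0.3, 0.05), rnorm(400, 0.7, 0.08))
  ours <- fit_gmm(x, 2, seed = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(ours$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(ours$means), sort(unname(mc$parameters$mean)),
               tolerance = 1e-3)
})

test_that("EM is deterministic given the seed and invariant to input order", {
  set.seed(8)
  x <- c(rnorm(300, 0.3, 0.05), rnorm(300, 0.6, 0.05))
  f1 <- fit_gmm(x, 2, seed = 9)
  f2 <- fit_gmm(x, 2, seed = 9)
  expect_identical(f1, f2)
  f3 <- fit_gmm(rev(x), 2, seed = 9)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-6)
  # monotone likelihood assertion active in debug mode
  expect_silent(fit_gmm(x, 2, seed = 3, debug = TRUE))
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(fit_gmm(rep(0.5, 100), 2), "degenerate")
  expect_error(fit_gmm(rnorm(5), 1), "insufficient")
})

test_that("bootstrap LRT respects its floor and selects G = 2 only on bimodal data", {
  set.seed(9)
  xb <- c(rnorm(500, 0.25, 0.04), rnorm(500, 0.60, 0.05))
  bt <- lrt_bimodality(xb, B = 39, seed = 2)
  expect_equal(bt$p_value, 1 / 40)        # minimum attainable
  expect_equal(bt$chosen_G, 2L)
  expect_equal(length(bt$peaks), 2L)
  expect_gte(bt$lrt_stat, 0)

  xu <- rnorm(800, 0.3, 0.05)
  bu <- lrt_bimodality(xu, B = 49, seed = 3)
  expect_gte(bu$p_value, 1 / 50)
  # chi-square variant gives a p-value without simulation
  bc <- lrt_bimodality(xu, seed = 3, method = "chi2")
  expect_true(bc$p_value > 0 && bc$p_value <= 1)
})
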