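#' Fit a univariate Gaussian mixture by EM
#'
#' Fits a `G`-component normal mixture with free component variances.
#' `G = 1` uses the closed-form maximum likelihood solution (sample mean,
#' MLE standard deviation). For `G >= 2`, EM is run from several random
#' restarts (k-means++-style initial means, equal weights, pooled sd) and
#' the best log-likelihood is kept. Standard deviations are floored at
#' `1e-4` times the data range to avoid likelihood singularities.
#'
#' @param values numeric vector (at least 10 finite values).
#' @param G number of components (1 or 2 in this pipeline; larger G works).
#' @param seed integer seed controlling the restarts.
#' @param restarts number of random restarts for `G >= 2`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum EM iterations per restart.
#' @param debug if `TRUE`, assert that EM never decreased the
#'   log-likelihood across iterations.
#' @return object of class `mixture_fit`: list with `G`, `weights`,
#'   `means` (ascending), `sds`, `loglik`, `n`, `converged`,
#'   `n_iterations`.
#' @export
fit_gmm <- function(values, G, seed = 1L, restarts = 5L, tol = 1e-8,
                    maxit = 1000L, debug = FALSE) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 10) .stopf("insufficient data: need >= 10 finite values, got %d", n)
  rng <- diff(range(x))
  if (rng == 0) .stopf("degenerate data: all values identical")
  sd_floor <- 1e-4 * rng

  if (G == 1) {
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))  # MLE (divides by n)
    ll <- sum(dnorm(x, mu, s, log = TRUE))
    return(structure(list(G = 1L, weights = 1, means = mu, sds = s,
                          loglik = ll, n = n, converged = TRUE,
                          n_iterations = 0L),
                     class = "mixture_fit"))
  }

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  best <- NULL
  pooled_sd <- sd(x)
  for (r in seq_len(restarts)) {
    mu0 <- .kmeanspp_means(x, G)
    fit <- .em_gmm_cpp(x, mu0, rep(pooled_sd, G), rep(1 / G, G),
                       tol, as.integer(maxit), sd_floor, debug)
    if (debug && !fit$monotone)
      .stopf("EM log-likelihood decreased across iterations")
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$means)
  structure(list(G = as.integer(G),
                 weights = best$weights[ord],
                 means = best$means[ord],
                 sds = best$sds[ord],
                 loglik = best$loglik, n = n,
                 converged = best$converged,
                 n_iterations = best$n_iterations),
            class = "mixture_fit")
}

# k-means++ style seeding of initial component means
.kmeanspp_means <- function(x, G) {
  mu <- numeric(G)
  mu[1] <- x[sample.int(length(x), 1L)]
  if (G > 1) {
    for (g in 2:G) {
      d2 <- vapply(x, function(v) min((v - mu[1:(g - 1)])^2), numeric(1))
      if (all(d2 == 0)) {
        mu[g] <- x[sample.int(length(x), 1L)]
      } else {
        mu[g] <- x[sample.int(length(x), 1L, prob = d2)]
      }
    }
  }
  mu
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit, G = %d (n = %d)\n", x$G, x$n))
  for (g in seq_len(x$G))
    cat(sprintf("  comp %d: weight %.3f, mean %.4f, sd %.4f\n",
                g, x$weights[g], x$means[g], x$sds[g]))
  cat(sprintf("  loglik %.3f, %s in %d iteration(s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' Mixture density evaluated on a grid
#' @param fit a `mixture_fit`.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of densities.
#' @export
mixture_density <- function(fit, x) {
  rowSums(vapply(seq_len(fit$G), function(g)
    fit$weights[g] * dnorm(x, fit$means[g], fit$sds[g]),
    numeric(length(x))))
}

# density modes of a mixture by fine grid search + local refinement
.density_modes <- function(fit, grid_n = 2048L) {
  lo <- min(fit$means) - 4 * max(fit$sds)
  hi <- max(fit$means) + 4 * max(fit$sds)
  xs <- seq(lo, hi, length.out = grid_n)
  d <- mixture_density(fit, xs)
  idx <- which(d > c(-Inf, d[-grid_n]) & d >= c(d[-1], -Inf))
  sort(xs[idx])
}

#' Bimodality likelihood-ratio test for an nCpG distribution
#'
#' Fits one- and two-component Gaussian mixtures and tests `G = 1` against
#' `G = 2` with a likelihood-ratio statistic. Because the one-component
#' model sits on the boundary of the two-component parameter space, the
#' usual chi-square asymptotics are unreliable; the default reference
#' distribution is therefore a parametric bootstrap (simulate from the
#' fitted `G = 1` model, refit both models, tally statistics at least as
#' large as observed). A `chi2` method with 3 degrees of freedom is
#' offered as a fast, approximate alternative.
#'
#' @param values numeric vector of (capped, defined) nCpG values.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param alpha significance level used to choose `G`.
#' @param method `"bootstrap"` (default) or `"chi2"`.
#' @param restarts restarts for the observed-data fits.
#' @param boot_restarts restarts used inside bootstrap refits (fewer, for
#'   speed; the test statistic is a maximum over restarts so this is
#'   slightly conservative for the null fits).
#' @return object of class `bimodality_test`: list with `lrt_stat`,
#'   `p_value`, `method`, `B`, `chosen_G`, `fit1`, `fit2`, `peaks`
#'   (component means of the winning model) and `modes` (density modes of
#'   the winning model).
#' @export
lrt_bimodality <- function(values, B = 199L, seed = 1L, alpha = 0.05,
                           method = c("bootstrap", "chi2"),
                           restarts = 5L, boot_restarts = 2L) {
  method <- match.arg(method)
  x <- values[is.finite(values)]
  fit1 <- fit_gmm(x, 1L, seed = seed)
  fit2 <- fit_gmm(x, 2L, seed = seed, restarts = restarts)
  lrt <- max(0, 2 * (fit2$loglik - fit1$loglik))

  if (method == "chi2") {
    p <- stats::pchisq(lrt, df = 3, lower.tail = FALSE)
    B <- NA_integer_
  } else {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(.sub_seed(seed, 17L))
    n <- fit1$n
    exceed <- 0L
    for (b in seq_len(B)) {
      xb <- rnorm(n, fit1$means, fit1$sds)
      f1 <- fit_gmm(xb, 1L)
      f2 <- fit_gmm(xb, 2L, seed = .sub_seed(seed, 1000L + b),
                    restarts = boot_restarts, tol = 1e-6)
      if (max(0, 2 * (f2$loglik - f1$loglik)) >= lrt) exceed <- exceed + 1L
    }
    p <- .empirical_p(exceed, B)
  }

  chosen <- if (p < alpha) 2L else 1L
  win <- if (chosen == 2L) fit2 else fit1
  structure(list(lrt_stat = lrt, p_value = p, method = method,
                 B = B, alpha = alpha, chosen_G = chosen,
                 fit1 = fit1, fit2 = fit2,
                 peaks = win$means, modes = .density_modes(win)),
            class = "bimodality_test")
}

#' @export
print.bimodality_test <- function(x, ...) {
  cat(sprintf("Bimodality LRT (G=1 vs G=2), %s\n", x$method))
  cat(sprintf("  lrt = %.3f, p = %.4g, chosen G = %d\n",
              x$lrt_stat, x$p_value, x$chosen_G))
  cat(sprintf("  peaks (component means): %s\n",
              paste(sprintf("%.3f", x$peaks), collapse = ", ")))
  invisible(x)
}
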