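test_that("common dispersion estimation recovers the generative value and its limits", {
  set.seed(1)
  n <- 10000
  # NB with phi = 0.1 at depth 20
  counts <- matrix(rnbinom(n * 4, size = 10, mu = 20), n, 4)
  wc <- wc_from_matrix(counts)
  phi <- estimate_dispersion(wc)
  expect_gte(phi, 0.07)
  expect_lte(phi, 0.13)

  # Poisson limit
  wcp <- wc_from_matrix(matrix(rpois(n * 4, 20), n, 4))
  expect_lte(estimate_dispersion(wcp), 0.01)

  # constant counts: zero within-group variance floors the estimate
  wcc <- wc_from_matrix(matrix(20L, 100, 4))
  expect_equal(estimate_dispersion(wcc), 1e-4)

  # a single library per group is rejected
  wc1 <- wc_from_matrix(counts[, 1:2], sex = c("male", "female"))
  expect_error(estimate_dispersion(wc1), "2 replicate")
})

test_that("NB exact test matches full enumeration and its symmetries", {
  # independent oracle: log-space NB pmf from lgamma, explicit loop
  oracle <- function(a, b, phi, nA = 2, nB = 2) {
    tot <- a + b
    if (tot == 0) return(1)
    nb_lpmf <- function(k, size, mu) {
      lgamma(k + size) - lgamma(size) - lgamma(k + 1) +
        size * log(size / (size + mu)) + k * log(mu / (size + mu))
    }
    lp <- numeric(tot + 1)
    for (k in 0:tot)
      lp[k + 1] <- nb_lpmf(k, nA / phi, tot * nA / (nA + nB)) +
        nb_lpmf(tot - k, nB / phi, tot * nB / (nA + nB))
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    min(1, sum(pr[pr <= pr[a + 1] * (1 + 1e-7)]))
  }
  set.seed(2)
  for (i in 1:60) {
    tot <- sample(1:200, 1)
    a <- sample(0:tot, 1)
    expect_equal(nb_exact_test(a, tot - a, 0.1)$p_value,
                 oracle(a, tot - a, 0.1), tolerance = 1e-12)
  }
  # the example split checked at strict precision
  expect_equal(nb_exact_test(30, 2, 0.1)$p_value, oracle(30, 2, 0.1),
               tolerance = 1e-12)
  # balanced designs sit at the mode
  for (a in c(1, 7, 30, 100)) {
    expect_equal(nb_exact_test(a, a, 0.1)$p_value, 1)
  }
  # exchangeability
  expect_equal(nb_exact_test(30, 2, 0.1)$p_value,
               nb_exact_test(2, 30, 0.1)$p_value)
  # zero total flagged
  z <- nb_exact_test(0, 0, 0.1)
  expect_equal(z$p_value, 1)
  expect_equal(z$flag, "zero_total")
})

test_that("Benjamini-Hochberg q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  # agreement with a hand-rolled step-up on random input
  set.seed(3)
  p <- runif(50)
  o <- order(p)
  q_hand <- numeric(50)
  prev <- 1
  for (i in 50:1) {
    prev <- min(prev, p[o[i]] * 50 / i)
    q_hand[o[i]] <- prev
  }
  expect_equal(bh_fdr(p), q_hand)
})

test_that("book-ended same-direction windows merge and coverage is conserved", {
  mk_dm <- function(df) {
    w <- data.frame(window_id = sprintf("w%d", seq_len(nrow(df))),
                    scaffold = df$scaffold, start = df$start,
                    end = df$end, tested = TRUE,
                    mean_female = 2, mean_male = 1,
                    logFC = df$logFC, p_value = df$p, q_value = df$p,
                    significant = df$p < 0.05,
                    direction = ifelse(df$p >= 0.05, "none",
                                       ifelse(df$logFC > 0, "female_hyper",
                                              "male_hyper")),
                    stringsAsFactors = FALSE)
    structure(list(windows = w, phi = 0.1, q_cutoff = 0.05,
                   n_tested = nrow(w), female = "female", male = "male"),
              class = "diffmeth_result")
  }
  dm <- mk_dm(data.frame(scaffold = "s1", start = c(0, 500, 1500),
                         end = c(500, 1000, 2000),
                         logFC = c(2, 2, 2), p = c(0.01, 0.01, 0.01)))
  m <- merge_dm_windows(dm)
  expect_equal(nrow(m), 2L)
  expect_equal(m$end[1] - m$start[1], 1000)     # two adjacent merge
  expect_equal(m$n_windows, c(2L, 1L))

  # opposite directions never merge
  dm2 <- mk_dm(data.frame(scaffold = "s1", start = c(0, 500),
                          end = c(500, 1000),
                          logFC = c(2, -2), p = c(0.01, 0.01)))
  expect_equal(nrow(merge_dm_windows(dm2)), 2L)

  # merged coverage equals the union of the significant windows
  set.seed(4)
  st <- sort(sample(0:200, 40)) * 500L
  dm3 <- mk_dm(data.frame(scaffold = "s1", start = st, end = st + 500L,
                          logFC = 2, p = 0.01))
  m3 <- merge_dm_windows(dm3)
  ir <- IRanges::reduce(IRanges::IRanges(st + 1L, st + 500L))
  expect_equal(sum(m3$end - m3$start), sum(IRanges::width(ir)))
})

test_that("gene summaries tag regions, flag DM and contrasting genes", {
  sim <- simulate_genome(small_cfg(seed = 9))
  wc <- simulate_medip_counts(sim$bundle, sim$truth)
  calls <- call_methylated(wc, sim$bundle)
  dm <- diffmeth_windows(wc, calls)
  gs <- summarize_genes(dm, sim$bundle)

  sig <- dm$windows[dm$windows$significant, ]
  expect_equal(sum(gs$genes$dm), length(unique(
    gs$window_tags$gene_id[gs$window_tags$tag %in%
                             c("gene_body", "promoter")])))
  # every exon-tagged window also carries the gene_body tag
  tags <- gs$window_tags
  ex_w <- unique(tags$window_id[tags$tag == "exon"])
  gb_w <- unique(tags$window_id[tags$tag == "gene_body"])
  expect_true(all(ex_w %in% gb_w))
  # contrasting genes have at least one window of each direction
  cg <- gs$genes[gs$genes$contrasting, ]
  if (nrow(cg)) {
    expect_true(all(cg$n_female_hyper >= 1 & cg$n_male_hyper >= 1))
  }
  # direction convention: positive logFC pairs with female_hyper
  expect_true(all(sig$logFC[sig$direction == "female_hyper"] > 0))
  expect_true(all(sig$logFC[sig$direction == "male_hyper"] < 0))
})
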