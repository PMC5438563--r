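test_that("the generator is deterministic and hits its methylated-window target", {
  cfg <- small_cfg(seed = 3)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$bundle$seqs, s2$bundle$seqs)
  expect_identical(s1$truth, s2$truth)
  c1 <- simulate_medip_counts(s1$bundle, s1$truth)
  c2 <- simulate_medip_counts(s2$bundle, s2$truth)
  expect_identical(c1$counts, c2$counts)

  tw <- s1$truth$windows
  expect_lt(abs(mean(tw$methylated) - cfg$methylated_fraction), 0.02)
  # DM windows are a subset of methylated windows
  expect_true(all(tw$methylated[tw$dm]))
  # designated non-methylated genes end up without methylated windows
  tg <- s1$truth$genes
  expect_true(all(!tg$methylated[tg$designated_unmethylated]))
})

test_that("simulated files validate through the io readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_genome(small_cfg(seed = 5))
  wc <- simulate_medip_counts(sim$bundle, sim$truth)

  write_genome(sim$bundle$seqs, file.path(dir, "g.fa"))
  expect_identical(read_genome(file.path(dir, "g.fa")), sim$bundle$seqs)

  write_gff3(sim$bundle$genes, sim$bundle$exons, file.path(dir, "g.gff3"))
  ann <- read_gff3(file.path(dir, "g.gff3"))
  expect_identical(ann$genes, sim$bundle$genes)
  expect_identical(ann$exons, sim$bundle$exons)

  write_repeats_bed(sim$bundle$repeats, file.path(dir, "r.bed"))
  expect_identical(read_repeats_bed(file.path(dir, "r.bed")),
                   sim$bundle$repeats)

  # fragment realization conserves the count matrix exactly
  beds <- simulate_fragment_beds(wc, file.path(dir, "frags"), seed = 5)
  fsets <- lapply(seq_along(beds), function(j)
    read_fragments(beds[j], library_id = wc$libraries$library_id[j],
                   sex = wc$libraries$sex[j],
                   known_scaffolds = names(sim$bundle$seqs)))
  wc2 <- count_fragments(window_grid(sim$bundle, 500L), fsets)
  expect_true(all(wc2$counts == wc$counts))
})

test_that("count expectations are reconstructible from the truth ledger (NB moments)", {
  cfg <- small_cfg(seed = 6)
  sim <- simulate_genome(cfg)
  wc <- simulate_medip_counts(sim$bundle, sim$truth)

  # rebuild the per-library means independently from bundle + truth
  tw <- sim$truth$windows
  segs <- substring(sim$bundle$seqs[tw$scaffold], tw$start + 1L, tw$end)
  cpg <- vapply(segs, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  }, numeric(1))
  base_w <- ifelse(tw$methylated, cpg, 0)
  z <- NULL
  for (j in seq_len(nrow(cfg$libraries))) {
    w <- base_w
    hyper <- !is.na(tw$direction) &
      tw$direction == paste0(cfg$libraries$sex[j], "_hyper")
    w[hyper] <- w[hyper] * cfg$dm_fold_change
    mu <- cfg$libraries$size[j] * w / sum(w)
    keep <- mu > 3
    z <- c(z, (wc$counts[keep, j] - mu[keep]) /
             sqrt(mu[keep] + cfg$nb_dispersion * mu[keep]^2))
  }
  # standardized residuals against the generative NB moments
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(var(z) - 1), 0.1)
  # unmethylated windows get no fragments at all
  expect_true(all(wc$counts[!tw$methylated, ] == 0))
})

test_that("Poisson limit and zero-weight guard", {
  cfg <- small_cfg(seed = 7, nb_dispersion = 0)
  sim <- simulate_genome(cfg)
  wc <- simulate_medip_counts(sim$bundle, sim$truth, cfg)
  tw <- sim$truth$windows
  segs <- substring(sim$bundle$seqs[tw$scaffold], tw$start + 1L, tw$end)
  cpg <- vapply(segs, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch[-length(ch)] == "C" & ch[-1] == "G")
  }, numeric(1))
  z <- NULL
  for (j in seq_len(nrow(cfg$libraries))) {
    w <- ifelse(tw$methylated, cpg, 0)
    hyper <- !is.na(tw$direction) &
      tw$direction == paste0(cfg$libraries$sex[j], "_hyper")
    w[hyper] <- w[hyper] * cfg$dm_fold_change
    mu <- cfg$libraries$size[j] * w / sum(w)
    keep <- mu > 5
    z <- c(z, (wc$counts[keep, j] - mu[keep]) / sqrt(mu[keep]))
  }
  expect_true(all(abs(z) < 5.5))     # Poisson tails at ~900 windows
  expect_lt(abs(var(z) - 1), 0.15)

  # no methylated window anywhere: zero total weight errors out
  truth0 <- sim$truth
  truth0$windows$methylated <- FALSE
  truth0$windows$dm <- FALSE
  expect_error(simulate_medip_counts(sim$bundle, truth0, cfg),
               "zero total weight")
})

test_that("expression labels track DM status exactly as the association dial says", {
  sim <- simulate_genome(small_cfg(seed = 8))
  # maximal association: DE iff DM, class opposite to the direction
  cfg1 <- sim$truth$config
  cfg1$expression_association <- 1
  e1 <- simulate_expression_labels(sim$truth, cfg1)
  tg <- sim$truth$genes
  expect_true(all((e1$de_class != "none") == tg$dm))
  opp <- c(female_hyper = "male_up", male_hyper = "female_up")
  has_dir <- tg$dm & !is.na(tg$direction)
  expect_true(all(e1$de_class[has_dir] == opp[tg$direction[has_dir]]))
  gt <- data.frame(dm = tg$dm, de = e1$de_class != "none")
  expect_lt(methylation_expression_fisher(gt)$p_value, 0.001)

  # zero association: DE rate near the base rate regardless of DM
  cfg0 <- sim$truth$config
  cfg0$expression_association <- 0
  e0 <- simulate_expression_labels(sim$truth, cfg0)
  expect_gt(mean(e0$de_class != "none"), 0.05)
})
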