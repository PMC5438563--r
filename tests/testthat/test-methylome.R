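test_that("window grid tiles scaffolds exhaustively with a true-length terminal window", {
  gb <- genome_bundle(c(s1 = rand_seq(1234, seed = 1)))
  g <- window_grid(gb, 500L)
  expect_equal(g$start, c(0L, 500L, 1000L))
  expect_equal(g$end, c(500L, 1000L, 1234L))
  expect_equal(sum(g$end - g$start), 1234L)
})

test_that("midpoint counting assigns boundary ties leftward and conserves totals", {
  gb <- genome_bundle(c(s1 = rand_seq(2000, seed = 2)))
  g <- window_grid(gb, 500L)
  fs <- fragment_set("L1", "male", data.frame(
    scaffold = "s1",
    start = c(100L, 400L), end = c(350L, 600L)))  # midpoints 225, 500
  wc <- count_fragments(g, list(fs))
  expect_equal(unname(wc$counts[, 1]), c(2L, 0L, 0L, 0L))

  set.seed(3)
  s <- sample(0:1800, 1000, replace = TRUE)
  fr <- fragment_set("L1", "male",
                     data.frame(scaffold = "s1", start = s, end = s + 150L))
  wc2 <- count_fragments(g, list(fr))
  expect_equal(sum(wc2$counts), 1000L)
  # overlap mode counts boundary-spanning fragments once per window
  wc3 <- count_fragments(g, list(fr), mode = "overlap")
  expect_gte(sum(wc3$counts), 1000L)
})

test_that("RPKM follows its formula and is invariant to depth scaling", {
  counts <- matrix(c(10L, 0L, 30L, 40L), ncol = 1)
  wc <- wc_from_matrix(counts, sex = "male")
  wc$libraries$total <- 1e6L          # fix depth for the hand example
  r <- rpkm(wc)
  expect_equal(r[1, 1], 20, ignore_attr = TRUE)  # 10 / (0.5 kb * 1 M/1e6)
  expect_equal(r[2, 1], 0, ignore_attr = TRUE)

  wc2 <- wc_from_matrix(counts * 2L, sex = "male")
  wc2$libraries$total <- 2e6L
  expect_equal(rpkm(wc2), r, ignore_attr = TRUE)
})

test_that("methylation calls use group-mean RPKM and flag genes by window overlap", {
  sim <- simulate_genome(small_cfg(seed = 5))
  wc <- simulate_medip_counts(sim$bundle, sim$truth)
  calls <- call_methylated(wc, sim$bundle)
  # all-zero windows are never methylated
  zero <- rowSums(wc$counts) == 0
  expect_false(any(calls$windows$methylated[zero]))

  # raising the threshold never increases the methylated fraction
  fr <- sapply(c(0.5, 1, 2, 5), function(th) {
    cl <- call_methylated(wc, sim$bundle, threshold = th)
    c(mean(cl$windows$methylated), sum(cl$genes$methylated))
  })
  expect_true(all(diff(fr[1, ]) <= 0))
  expect_true(all(diff(fr[2, ]) <= 0))

  # a gene overlapped by exactly one methylated window is methylated
  g1 <- calls$genes[calls$genes$n_meth_windows == 1, ]
  if (nrow(g1)) expect_true(all(g1$methylated))
})

test_that("methylome fractions equal a brute-force base and CpG tally", {
  sim <- simulate_genome(small_cfg(seed = 6))
  wc <- simulate_medip_counts(sim$bundle, sim$truth)
  calls <- call_methylated(wc, sim$bundle)
  fr <- methylome_fractions(calls, sim$bundle)

  mw <- calls$windows[calls$windows$methylated, ]
  expect_equal(fr$genome_fraction,
               sum(mw$end - mw$start) / sim$bundle$assembly_length)
  # brute-force per-position scan: a CpG belongs to a window iff its C
  # position lies inside it
  total <- 0
  pos_scan <- 0
  for (sc in names(sim$bundle$seqs)) {
    ch <- strsplit(sim$bundle$seqs[[sc]], "")[[1]]
    cpg_c <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
    total <- total + length(cpg_c)
    msc <- mw[mw$scaffold == sc, ]
    if (nrow(msc)) {
      inside <- rep(FALSE, length(ch))
      for (i in seq_len(nrow(msc)))
        inside[(msc$start[i] + 1L):msc$end[i]] <- TRUE
      pos_scan <- pos_scan + sum(inside[cpg_c])
    }
  }
  expect_equal(fr$cpg_fraction, pos_scan / total)
})

test_that("context classification partitions methylated windows with gene-body precedence", {
  # two genes: w inside gA's body also lies upstream of gB
  seqs <- c(s1 = rand_seq(60000, seed = 7), s2 = rand_seq(5000, seed = 8))
  genes <- data.frame(gene_id = c("gA", "gB"), scaffold = "s1",
                      strand = "+", start = c(1000L, 30000L),
                      end = c(5000L, 35000L), stringsAsFactors = FALSE)
  gb <- genome_bundle(seqs, genes)
  wc <- wc_from_matrix(matrix(1000L, nrow = 130, ncol = 4))
  wc$grid$scaffold <- c(rep("s1", 120), rep("s2", 10))
  wc$grid$start <- c(0:119 * 500L, 0:9 * 500L)
  wc$grid$end <- wc$grid$start + 500L
  calls <- call_methylated(wc, gb)
  ctx <- classify_context(calls, gb)
  expect_equal(sum(ctx$proportions), 1)
  w_in_gA <- ctx$windows$context[ctx$windows$start >= 1000 &
                                   ctx$windows$end <= 5000 &
                                   ctx$windows$scaffold == "s1"]
  expect_true(all(w_in_gA == "gene_body"))
  # gene-free scaffold: everything intergenic beyond 50 kb of any TSS
  s2ctx <- ctx$windows$context[ctx$windows$scaffold == "s2"]
  expect_true(all(s2ctx == "intergenic"))
  # gA body windows lie within 50 kb upstream of gB, so the pre-precedence
  # upstream-in-gene fraction must be positive
  expect_gt(ctx$upstream_in_gene_fraction, 0)
})
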