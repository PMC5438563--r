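test_that("compute_ncpg matches hand counts and handles degenerate input", {
  r <- compute_ncpg("CGCGCG")
  expect_equal(r[c("l", "c", "g", "cg")], list(l = 6L, c = 3L, g = 3L,
                                               cg = 3L))
  expect_equal(r$ncpg, 2)              # (3/6) / ((3/6)(3/6))
  expect_equal(compute_ncpg("GGGCCC")$ncpg, 0)
  expect_true(is.na(compute_ncpg("ATATAT")$ncpg))   # c = 0
  expect_error(compute_ncpg(""), "empty")
  # N contributes to length only
  rn <- compute_ncpg("CGNNCG")
  expect_equal(rn[c("l", "c", "g", "cg")], list(l = 6L, c = 2L, g = 2L,
                                                cg = 2L))
})

test_that("compute_ncpg equals an independent Biostrings counter on random sequences", {
  set.seed(11)
  for (i in 1:200) {
    s <- rand_seq(sample(10:300, 1), gc = runif(1, 0.2, 0.7))
    if (i %% 5 == 0) {  # sprinkle Ns
      ch <- strsplit(s, "")[[1]]
      ch[sample(length(ch), max(1, length(ch) %/% 20))] <- "N"
      s <- paste(ch, collapse = "")
    }
    a <- compute_ncpg(s)
    b <- biostrings_counts(s)
    expect_identical(a[c("l", "c", "g", "cg")],
                     lapply(b, as.integer))
  }
})

test_that("region extraction obeys strand arithmetic, set algebra and nesting", {
  gb <- tiny_bundle()
  # single-exon genes yield no intron record
  one <- genome_bundle(c(s1 = rand_seq(1000, seed = 2)),
                       data.frame(gene_id = "g", scaffold = "s1",
                                  strand = "+", start = 100L, end = 400L,
                                  stringsAsFactors = FALSE),
                       data.frame(gene_id = "g", start = 100L, end = 400L,
                                  stringsAsFactors = FALSE))
  expect_equal(nrow(extract_regions(one, "intron")), 0L)

  # minus-strand gene ending at 500: promoter_150 is [500, 650)
  mb <- genome_bundle(c(s1 = rand_seq(1000, seed = 3)),
                      data.frame(gene_id = "m", scaffold = "s1",
                                 strand = "-", start = 100L, end = 500L,
                                 stringsAsFactors = FALSE))
  p150 <- extract_regions(mb, "promoter_150")
  expect_equal(c(p150$start, p150$end), c(500L, 650L))

  # exon + intron bases equal gene-body bases for every gene
  sim <- simulate_genome(small_cfg(seed = 7))
  ex <- extract_regions(sim$bundle, "exon")
  inx <- extract_regions(sim$bundle, "intron")
  per_gene <- function(df, suffix)
    tapply(df$end - df$start, sub(suffix, "", df$region_id), sum)
  exl <- per_gene(ex, ":exon$")
  inl <- per_gene(inx, ":intron$")
  body <- with(sim$bundle$genes, setNames(end - start, gene_id))
  inl_full <- setNames(rep(0, length(body)), names(body))
  inl_full[names(inl)] <- inl
  expect_equal(as.vector(exl[names(body)]) +
                 as.vector(inl_full[names(body)]), unname(body))

  # promoters nested per gene
  for (w in c(300, 600, 3000)) {
    inner <- extract_regions(sim$bundle, "promoter_150")
    outer <- extract_regions(sim$bundle, paste0("promoter_", w))
    m <- match(sub(":promoter_150", "", inner$region_id),
               sub(paste0(":promoter_", w), "", outer$region_id))
    expect_true(all(inner$start >= outer$start[m] &
                      inner$end <= outer$end[m]))
  }

  # intergenic blocks complement gene bodies exactly
  ig <- extract_regions(sim$bundle, "intergenic")
  expect_equal(sum(ig$end - ig$start) + sum(body),
               unname(sim$bundle$assembly_length))
})

test_that("ncpg_table flags unusable records and recounts match a brute-force scan", {
  sim <- simulate_genome(small_cfg(seed = 8))
  tab <- ncpg_table(sim$bundle)
  expect_true(all(!tab$usable[is.na(tab$ncpg)]))
  expect_true(all(tab$cg <= pmin(tab$c, tab$g)))
  expect_true(all(tab$c + tab$g <= tab$l))

  # independent recount of 50 random single-interval records
  set.seed(20)
  single <- tab[tab$class %in% c("gene_body", "promoter_600",
                                 "intergenic"), ]
  pick <- single[sample(nrow(single), 50), ]
  for (i in seq_len(nrow(pick))) {
    s <- substring(sim$bundle$seqs[[pick$scaffold[i]]],
                   pick$start[i] + 1L, pick$end[i])
    b <- biostrings_counts(s)
    expect_equal(pick$l[i], b$l)
    expect_equal(pick$c[i], b$c)
    expect_equal(pick$g[i], b$g)
    expect_equal(pick$cg[i], as.integer(b$cg))
  }
})

test_that("i.i.d. sequence has nCpG near 1 at large length for any GC content", {
  set.seed(30)
  for (gc in c(0.3, 0.42, 0.6)) {
    v <- compute_ncpg(rand_seq(1e5, gc = gc))$ncpg
    expect_lt(abs(v - 1), 0.03)
  }
})

test_that("deplete_cpg multiplies expected nCpG by (1 - d)", {
  set.seed(31)
  s <- rand_seq(2e5)
  base <- compute_ncpg(s)$ncpg
  for (d in c(0.3, 0.7)) {
    v <- compute_ncpg(deplete_cpg(s, d))$ncpg
    expect_lt(abs(v - (1 - d) * base), 0.1 * (1 - d) * base)
  }
  expect_identical(deplete_cpg(s, 0), s)
})
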