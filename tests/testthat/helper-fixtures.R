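# Shared fixtures, all built in code at test time.

# deterministic i.i.d. sequence
rand_seq <- function(n, gc = 0.42, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# tiny hand-laid genome bundle: two genes on one 2-kb scaffold
tiny_bundle <- function(seed = 42) {
  set.seed(seed)
  seqs <- c(s1 = rand_seq(2000), s2 = rand_seq(800))
  genes <- data.frame(
    gene_id = c("gA", "gB"), scaffold = "s1", strand = c("+", "-"),
    start = c(200L, 1200L), end = c(700L, 1700L), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    start = c(200L, 500L, 1200L), end = c(350L, 700L, 1700L),
    stringsAsFactors = FALSE)
  repeats <- data.frame(scaffold = "s1", start = 50L, end = 150L,
                        category = "CR1", stringsAsFactors = FALSE)
  genome_bundle(seqs, genes, exons, repeats)
}

# scaled-down simulation scenario for fast unit tests
small_cfg <- function(seed = 1L, ...) {
  sim_config(n_scaffolds = 1L, scaffold_length = 2e5, n_genes = 40L,
             gene_length = c(1500L, 2500L), intergenic_gap = c(500L, 2000L),
             n_dm_genes = 8L, dm_windows_per_gene = c(1L, 3L),
             libraries = data.frame(
               library_id = c("male_1", "male_2", "female_1", "female_2"),
               sex = c("male", "male", "female", "female"),
               size = c(6000L, 6500L, 6200L, 7000L),
               stringsAsFactors = FALSE),
             seed = seed, ...)
}

# independent dinucleotide counter built on Biostrings (oracle)
biostrings_counts <- function(seq) {
  d <- Biostrings::BString(seq)
  lf <- Biostrings::letterFrequency(d, c("C", "G"))
  list(l = nchar(seq), c = unname(lf[["C"]]), g = unname(lf[["G"]]),
       cg = Biostrings::countPattern("CG", d))
}

# build a window_counts object from a plain matrix
wc_from_matrix <- function(counts, size = 500L,
                           sex = c("male", "male", "female", "female")) {
  n <- nrow(counts)
  grid <- data.frame(window_id = sprintf("s:%d", seq_len(n) - 1L),
                     scaffold = "s", start = (seq_len(n) - 1L) * size,
                     end = seq_len(n) * size, stringsAsFactors = FALSE)
  class(grid) <- c("window_grid", "data.frame")
  window_counts(grid, counts,
                data.frame(library_id = paste0("L", seq_len(ncol(counts))),
                           sex = sex, stringsAsFactors = FALSE))
}

# minimal SAM text with header
write_sam <- function(path, records, sq = c(chr1 = 10000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, records), path)
  path
}
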