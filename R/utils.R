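# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based half-open
# [start, end); GFF3 (1-based closed) and the 1-based IRanges/GRanges
# world are converted at the boundary.

# 0-based half-open data.frame -> GRanges (1-based closed)
.as_granges0 <- function(df, seqlens = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    seqlengths = seqlens
  )
}

# raw codes for the bases we care about
.RAW_C <- charToRaw("C")
.RAW_G <- charToRaw("G")

# Count C, G and overlapping CpG dinucleotides in an uppercase sequence.
# N (or any non-C/G byte) contributes to length only.
.cg_counts <- function(seq) {
  r <- charToRaw(seq)
  l <- length(r)
  is_c <- r == .RAW_C
  is_g <- r == .RAW_G
  cg <- if (l >= 2L) sum(is_c[-l] & is_g[-1L]) else 0L
  list(l = l, c = sum(is_c), g = sum(is_g), cg = as.integer(cg))
}

# nCpG from raw counts: (cg/l) / ((c/l)(g/l)) = cg * l / (c * g).
# Undefined (NA) when c == 0, g == 0 or l < 2.
.ncpg_from_counts <- function(l, c, g, cg) {
  out <- as.numeric(cg) * as.numeric(l) / (as.numeric(c) * as.numeric(g))
  out[c == 0 | g == 0 | l < 2] <- NA_real_
  out
}

# empirical p-value with the +1 correction; `exceed` counts null draws at
# least as extreme as the observed statistic (ties included)
.empirical_p <- function(exceed, B) (1 + exceed) / (B + 1)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# derive a stream-specific 32-bit seed from a master seed
.sub_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset) %% 2147483647
}
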