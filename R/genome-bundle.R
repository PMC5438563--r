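#' Genomic data bundle
#'
#' Container holding everything the pipeline needs about one assembly:
#' scaffold sequences, gene models (gene table plus exon table) and repeat
#' intervals, under a single coordinate convention (0-based half-open).
#'
#' @param seqs named character vector of uppercase scaffold sequences
#'   (alphabet A, C, G, T, N).
#' @param genes data.frame with columns `gene_id`, `scaffold`, `strand`
#'   (`"+"` or `"-"`), `start`, `end` (0-based half-open).
#' @param exons data.frame with columns `gene_id`, `start`, `end`; exons of
#'   a gene must be sorted, disjoint and contained in the gene span.
#' @param repeats data.frame with columns `scaffold`, `start`, `end`,
#'   `category`.
#'
#' @return An object of class `genome_bundle`: a list with elements `seqs`,
#'   `seqlen`, `genes`, `exons`, `repeats` and `assembly_length`.
#' @export
genome_bundle <- function(seqs,
                          genes = .empty_genes(),
                          exons = .empty_exons(),
                          repeats = .empty_repeats()) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    .stopf("scaffold sequences must have unique names")
  seqs <- vapply(seqs, toupper, character(1))
  seqlen <- vapply(seqs, nchar, integer(1))

  .check_intervals(genes, seqlen, "gene")
  if (nrow(genes) && any(genes$end <= genes$start))
    .stopf("gene intervals must satisfy end > start")
  if (nrow(genes) && !all(genes$strand %in% c("+", "-")))
    .stopf("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id))
    .stopf("gene ids must be unique")

  # exon invariants per gene
  if (nrow(exons)) {
    if (!all(exons$gene_id %in% genes$gene_id))
      .stopf("exons reference unknown gene ids")
    sp <- split(exons, exons$gene_id)
    for (gid in names(sp)) {
      e <- sp[[gid]][order(sp[[gid]]$start), ]
      g <- genes[genes$gene_id == gid, ]
      if (any(e$start < g$start) || any(e$end > g$end))
        .stopf("exon outside parent gene '%s'", gid)
      if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
        .stopf("overlapping exons in gene '%s'", gid)
    }
    exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
    rownames(exons) <- NULL
  }

  .check_intervals(repeats, seqlen, "repeat")
  if (nrow(repeats) && any(repeats$end <= repeats$start))
    .stopf("repeat intervals must satisfy end > start")
  if (nrow(repeats) && any(!nzchar(repeats$category)))
    .stopf("repeat categories must be non-empty")

  structure(list(
    seqs = seqs, seqlen = seqlen,
    genes = genes, exons = exons, repeats = repeats,
    assembly_length = sum(as.numeric(seqlen))
  ), class = "genome_bundle")
}

.empty_genes <- function() data.frame(
  gene_id = character(), scaffold = character(), strand = character(),
  start = integer(), end = integer(), stringsAsFactors = FALSE)

.empty_exons <- function() data.frame(
  gene_id = character(), start = integer(), end = integer(),
  stringsAsFactors = FALSE)

.empty_repeats <- function() data.frame(
  scaffold = character(), start = integer(), end = integer(),
  category = character(), stringsAsFactors = FALSE)

.check_intervals <- function(df, seqlen, what) {
  if (!nrow(df)) return(invisible())
  bad <- !(df$scaffold %in% names(seqlen))
  if (any(bad))
    .stopf("%s intervals on unknown scaffolds: %s", what,
           paste(unique(df$scaffold[bad]), collapse = ", "))
  if (any(df$start < 0) || any(df$end > seqlen[df$scaffold]))
    .stopf("%s interval outside scaffold bounds", what)
  invisible()
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf(
    "genome_bundle: %d scaffold(s), %s bp, %d gene(s), %d repeat(s)\n",
    length(x$seqs), format(x$assembly_length, big.mark = ","),
    nrow(x$genes), nrow(x$repeats)))
  invisible(x)
}

#' Transcription start sites
#'
#' Strand-aware TSS of each gene: the 5' edge of the gene span (`start` on
#' the plus strand, `end` on the minus strand), as a 0-based coordinate.
#'
#' @param genes gene table of a [genome_bundle()].
#' @return integer vector of TSS positions, named by gene id.
#' @export
gene_tss <- function(genes) {
  setNames(ifelse(genes$strand == "+", genes$start, genes$end),
           genes$gene_id)
}

#' Set of aligned MeDIP fragments for one library
#'
#' @param library_id library identifier.
#' @param sex group label (e.g. `"male"`, `"female"`).
#' @param fragments data.frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open).
#' @param skipped number of unmapped records skipped while reading.
#' @return Object of class `fragment_set` with fields `library_id`, `sex`,
#'   `fragments`, `total_count`, `skipped`.
#' @export
fragment_set <- function(library_id, sex, fragments, skipped = 0L) {
  stopifnot(all(c("scaffold", "start", "end") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$end <= fragments$start))
    .stopf("fragment intervals must satisfy end > start")
  structure(list(
    library_id = library_id, sex = sex,
    fragments = fragments[order(fragments$scaffold, fragments$start), ,
                          drop = FALSE],
    total_count = nrow(fragments), skipped = as.integer(skipped)
  ), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set '%s' (%s): %d fragments (%d records skipped)\n",
              x$library_id, x$sex, x$total_count, x$skipped))
  invisible(x)
}
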