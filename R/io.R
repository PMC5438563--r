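#' Read a genome FASTA
#'
#' Reads scaffold sequences, uppercases them and maps any IUPAC ambiguity
#' code other than A/C/G/T/N to N (with a warning giving the substitution
#' count).
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, suitable for the
#'   `seqs` argument of [genome_bundle()].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) .stopf("missing input: genome ('%s')", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) .stopf("malformed FASTA '%s': %s", path,
                               conditionMessage(e)))
  if (length(set) == 0) .stopf("empty FASTA '%s'", path)
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) .stopf("malformed FASTA header in '%s'", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  n_sub <- 0L
  cleaned <- vapply(seqs, function(s) {
    bad <- gsub("[ACGTN]", "", s)
    n_sub <<- n_sub + nchar(bad)
    if (nchar(bad)) gsub("[^ACGTN]", "N", s) else s
  }, character(1))
  if (n_sub > 0)
    .warnf("%d non-ACGTN base(s) replaced with N", n_sub)
  cleaned
}

#' Write a genome FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features linked by `ID`/`Parent` (one level of
#' `mRNA` indirection is followed). GFF3 1-based closed coordinates are
#' converted to the package's 0-based half-open convention. Genes without
#' exon children become single-exon genes spanning the whole gene.
#'
#' @param path path to a GFF3 file.
#' @return list with data.frames `genes` and `exons` as used by
#'   [genome_bundle()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) .stopf("missing input: annotation ('%s')", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(list(genes = .empty_genes(), exons = .empty_exons()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) .stopf("malformed GFF3 line in '%s'", path)
  m <- do.call(rbind, f)
  attr_field <- function(attrs, key) {
    m <- regexec(paste0("(^|;)", key, "=([^;]*)"), attrs)
    vapply(regmatches(attrs, m),
           function(g) if (length(g) >= 3) g[3] else NA_character_,
           character(1))
  }
  type <- m[, 3]
  start1 <- as.integer(m[, 4])
  end1 <- as.integer(m[, 5])
  ids <- attr_field(m[, 9], "ID")
  parents <- attr_field(m[, 9], "Parent")

  gsel <- type == "gene"
  genes <- data.frame(
    gene_id = ids[gsel], scaffold = m[gsel, 1], strand = m[gsel, 7],
    start = start1[gsel] - 1L, end = end1[gsel],
    stringsAsFactors = FALSE)
  if (anyNA(genes$gene_id)) .stopf("gene feature without ID in '%s'", path)

  # transcript indirection: map mRNA id -> gene id
  tsel <- type %in% c("mRNA", "transcript")
  tx2gene <- setNames(parents[tsel], ids[tsel])

  esel <- type == "exon"
  epar <- parents[esel]
  resolved <- ifelse(epar %in% genes$gene_id, epar,
                     unname(tx2gene[epar]))
  if (any(is.na(resolved) & esel[esel]))
    .stopf("exon with unresolvable Parent in '%s'", path)
  exons <- data.frame(
    gene_id = resolved, start = start1[esel] - 1L, end = end1[esel],
    stringsAsFactors = FALSE)
  exons <- unique(exons)

  # exon containment check with gene named in the error
  if (nrow(exons)) {
    g <- genes[match(exons$gene_id, genes$gene_id), ]
    bad <- which(exons$start < g$start | exons$end > g$end)
    if (length(bad))
      .stopf("exon outside parent gene '%s'", exons$gene_id[bad[1]])
  }

  # genes lacking exons: single exon spanning the gene
  orphan <- setdiff(genes$gene_id, exons$gene_id)
  if (length(orphan)) {
    og <- genes[genes$gene_id %in% orphan, ]
    exons <- rbind(exons, data.frame(
      gene_id = og$gene_id, start = og$start, end = og$end,
      stringsAsFactors = FALSE))
  }
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based closed GFF3 records (gene rows plus exon rows
#' with `Parent` attributes).
#'
#' @param genes,exons gene and exon tables of a [genome_bundle()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tmedipcpg\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$scaffold, g$start + 1L, g$end, g$strand, g$gene_id),
               con)
    e <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(e))
      writeLines(sprintf(
        "%s\tmedipcpg\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        g$scaffold, e$start + 1L, e$end, g$strand, g$gene_id), con)
  }
  invisible(path)
}

#' Read repeat intervals from BED
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Column 4, when present, is the repeat category; otherwise the category
#' defaults to `"repeat"`.
#'
#' @param path path to a BED3+ file.
#' @return repeat data.frame as used by [genome_bundle()].
#' @export
read_repeats_bed <- function(path) {
  if (!file.exists(path)) .stopf("missing input: repeats ('%s')", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  out <- data.frame(scaffold = df[[1]], start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    category = if (ncol(df) >= 4) as.character(df[[4]])
                               else "repeat",
                    stringsAsFactors = FALSE)
  out
}

#' Write repeat intervals to BED
#' @param repeats repeat table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(repeats, path) {
  write.table(repeats[, c("scaffold", "start", "end", "category")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read aligned MeDIP fragments
#'
#' Accepts SAM (via on-the-fly conversion to BAM) or BED3. Each mapped
#' fragment yields one interval: the outer span for a proper pair, the read
#' span extended to `fragment_length` for single-end reads. Unmapped
#' records are skipped and counted.
#'
#' @param path SAM or BED path (dialect chosen by file extension; override
#'   with `format`).
#' @param library_id,sex metadata attached to the returned set.
#' @param format `"auto"`, `"sam"` or `"bed"`.
#' @param fragment_length extension length for single-end reads (bp). MeDIP
#'   libraries are size-selected to roughly 100-300 bp, so the default is
#'   200.
#' @param known_scaffolds optional character vector; fragments on other
#'   scaffolds raise an error listing the offenders.
#' @return a [fragment_set()].
#' @export
read_fragments <- function(path, library_id = basename(path), sex = NA,
                           format = c("auto", "sam", "bed"),
                           fragment_length = 200L,
                           known_scaffolds = NULL) {
  if (!file.exists(path)) .stopf("missing input: fragments ('%s')", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam"
              else "bed"
  }
  if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    frags <- data.frame(scaffold = df[[1]], start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]), stringsAsFactors = FALSE)
    skipped <- 0L
  } else {
    parsed <- .read_sam_fragments(path, fragment_length)
    frags <- parsed$fragments
    skipped <- parsed$skipped
  }
  if (!is.null(known_scaffolds)) {
    bad <- setdiff(unique(frags$scaffold), known_scaffolds)
    if (length(bad))
      .stopf("fragments on unknown scaffold(s): %s",
             paste(bad, collapse = ", "))
  }
  fragment_set(library_id, sex, frags, skipped)
}

# SAM -> fragment intervals using Rsamtools/GenomicAlignments.
.read_sam_fragments <- function(path, fragment_length) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  # unmapped records are excluded from alignments; count them via flagstat
  flag_unmapped <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  skipped <- Rsamtools::countBam(bam, param = flag_unmapped)$records

  prm <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isPaired = FALSE)))
  pairs <- GenomicAlignments::readGAlignmentPairs(
    bam, param = prm)

  rows <- list()
  if (length(pairs)) {
    gr <- GenomicRanges::granges(pairs)   # outer span of each pair
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  }
  if (length(aln)) {
    gr <- GenomicRanges::granges(aln)
    # extend single-end reads to the library fragment length, strand-aware
    gr <- GenomicRanges::resize(gr, width = pmax(
      GenomicRanges::width(gr), fragment_length), fix = "start")
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  }
  frags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  list(fragments = frags, skipped = skipped)
}

#' Write fragments to BED3
#' @param fs a [fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fs, path) {
  write.table(fs$fragments[, c("scaffold", "start", "end")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene expression label table
#'
#' @param path TSV with columns `gene_id` and `de_class` (one of
#'   `male_up`, `female_up`, `none`).
#' @return data.frame with those two columns.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) .stopf("missing input: expression ('%s')", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "de_class") %in% names(df)))
  bad <- setdiff(unique(df$de_class), c("male_up", "female_up", "none"))
  if (length(bad))
    .stopf("unknown de_class value(s): %s", paste(bad, collapse = ", "))
  df[, c("gene_id", "de_class")]
}
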