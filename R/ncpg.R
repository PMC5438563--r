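#' Normalized CpG content of a sequence
#'
#' Computes the observed/expected CpG ratio
#' \deqn{nCpG = (cg/l) / ((c/l)(g/l))}
#' for a sequence of length `l` with `c` cytosines, `g` guanines and `cg`
#' CpG dinucleotides (overlapping scan on the forward strand; CpG is its
#' own reverse complement as a motif, so a forward-only scan suffices).
#' N bases count toward `l` but never toward `c`, `g` or `cg`. The ratio is
#' undefined (`NA`) when `c == 0`, `g == 0` or `l < 2`.
#'
#' @param seq a single uppercase nucleotide string.
#' @return list with elements `l`, `c`, `g`, `cg`, `ncpg`.
#' @export
#' @examples
#' compute_ncpg("CGCGCG")  # ncpg = 2
compute_ncpg <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (!nzchar(seq)) .stopf("empty sequence")
  cnt <- .cg_counts(seq)
  cnt$ncpg <- .ncpg_from_counts(cnt$l, cnt$c, cnt$g, cnt$cg)
  cnt
}

# region classes understood by extract_regions()
.REGION_CLASSES <- c("exon", "intron", "gene_body", "promoter_3000",
                     "promoter_600", "promoter_300", "promoter_150",
                     "intergenic")

#' Extract region coordinates by class
#'
#' Returns one record per region; a record may span several intervals
#' (per-gene exon and intron classes are concatenations of the gene's
#' features). Classes:
#' \describe{
#'   \item{exon / intron}{one record per gene, all its exons (introns)
#'     concatenated; single-exon genes yield no intron record.}
#'   \item{gene_body}{the full gene span.}
#'   \item{promoter_W}{the W bases strand-upstream of the TSS, truncated at
#'     scaffold edges (W in 3000, 600, 300, 150).}
#'   \item{intergenic}{complement of all gene bodies per scaffold, one
#'     record per contiguous block.}
#' }
#'
#' @param gb a [genome_bundle()].
#' @param class one of `r paste0('"', .REGION_CLASSES, '"', collapse = ", ")`.
#' @return data.frame with columns `region_id`, `class`, `scaffold`,
#'   `start`, `end` (interval; several rows may share a `region_id`).
#' @export
extract_regions <- function(gb, class) {
  class <- match.arg(class, .REGION_CLASSES)
  genes <- gb$genes
  empty <- data.frame(region_id = character(), class = character(),
                      scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  mk <- function(region_id, scaffold, start, end) {
    if (!length(region_id)) return(empty)
    data.frame(region_id = region_id, class = class, scaffold = scaffold,
               start = as.integer(start), end = as.integer(end),
               stringsAsFactors = FALSE)
  }

  if (class == "exon") {
    e <- gb$exons
    if (!nrow(e)) return(empty)
    sc <- genes$scaffold[match(e$gene_id, genes$gene_id)]
    return(mk(paste0(e$gene_id, ":exon"), sc, e$start, e$end))
  }

  if (class == "intron") {
    out <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      e <- gb$exons[gb$exons$gene_id == g$gene_id, , drop = FALSE]
      e <- e[order(e$start), ]
      if (nrow(e) < 2) return(NULL)
      data.frame(region_id = paste0(g$gene_id, ":intron"), class = class,
                 scaffold = g$scaffold,
                 start = e$end[-nrow(e)], end = e$start[-1],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) return(empty)
    out <- out[out$end > out$start, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }

  if (class == "gene_body") {
    if (!nrow(genes)) return(empty)
    return(mk(paste0(genes$gene_id, ":body"), genes$scaffold,
              genes$start, genes$end))
  }

  if (grepl("^promoter_", class)) {
    if (!nrow(genes)) return(empty)
    w <- as.integer(sub("promoter_", "", class))
    tss <- gene_tss(genes)
    plus <- genes$strand == "+"
    start <- ifelse(plus, pmax(0L, tss - w), tss)
    end <- ifelse(plus, tss,
                  pmin(unname(gb$seqlen[genes$scaffold]), tss + w))
    keep <- end > start
    return(mk(paste0(genes$gene_id, ":", class)[keep],
              genes$scaffold[keep], start[keep], end[keep]))
  }

  # intergenic: per-scaffold complement of the union of gene bodies
  out <- lapply(names(gb$seqs), function(sc) {
    len <- unname(gb$seqlen[[sc]])
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    if (!nrow(g)) {
      iv <- data.frame(start = 0L, end = len)
    } else {
      ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
      gap <- IRanges::gaps(ir, start = 1L, end = len)
      iv <- data.frame(start = IRanges::start(gap) - 1L,
                       end = IRanges::end(gap))
    }
    iv <- iv[iv$end > iv$start, , drop = FALSE]
    if (!nrow(iv)) return(NULL)
    data.frame(region_id = sprintf("%s:intergenic_%d", sc,
                                   seq_len(nrow(iv))),
               class = class, scaffold = sc, start = iv$start, end = iv$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Per-region normalized CpG content table
#'
#' Computes `l`, `c`, `g`, `cg` and nCpG for every region of the requested
#' classes. Multi-interval regions (concatenated exons/introns) are counted
#' per interval and summed, so no artificial CpG is created at junctions.
#' Records with undefined nCpG, or shorter than `min_length`, are retained
#' but flagged unusable (`usable = FALSE`) so that distribution summaries
#' can exclude them.
#'
#' @param gb a [genome_bundle()].
#' @param classes character vector of region classes
#'   (default: all of them).
#' @param min_length minimum region length (bp) for inclusion in
#'   distribution summaries; shorter records are flagged.
#' @param per_feature if `TRUE`, exon and intron classes yield one record
#'   per feature instead of one concatenated record per gene (individual
#'   short features make the ratio noisier; the per-gene default is what
#'   the distribution analyses use).
#' @return data.frame with one row per region: `region_id`, `class`,
#'   `scaffold`, `start`, `end` (envelope), `l`, `c`, `g`, `cg`, `ncpg`,
#'   `usable`.
#' @export
ncpg_table <- function(gb, classes = .REGION_CLASSES, min_length = 50L,
                       per_feature = FALSE) {
  classes <- match.arg(classes, .REGION_CLASSES, several.ok = TRUE)
  out <- lapply(classes, function(cl) {
    reg <- extract_regions(gb, cl)
    if (!nrow(reg)) return(NULL)
    if (per_feature && cl %in% c("exon", "intron"))
      reg$region_id <- sprintf("%s_%d", reg$region_id,
                               stats::ave(seq_len(nrow(reg)),
                                          reg$region_id,
                                          FUN = seq_along))
    segs <- substring(gb$seqs[reg$scaffold], reg$start + 1L, reg$end)
    cnt <- lapply(segs, .cg_counts)
    per <- data.frame(region_id = reg$region_id,
                      l = vapply(cnt, `[[`, integer(1), "l"),
                      c = vapply(cnt, `[[`, integer(1), "c"),
                      g = vapply(cnt, `[[`, integer(1), "g"),
                      cg = vapply(cnt, `[[`, integer(1), "cg"),
                      stringsAsFactors = FALSE)
    agg <- do.call(rbind, lapply(split(seq_len(nrow(per)), per$region_id),
      function(ix) {
        data.frame(region_id = per$region_id[ix[1]],
                   l = sum(per$l[ix]), c = sum(per$c[ix]),
                   g = sum(per$g[ix]), cg = sum(per$cg[ix]),
                   stringsAsFactors = FALSE)
      }))
    first <- reg[!duplicated(reg$region_id), ]
    env_start <- tapply(reg$start, reg$region_id, min)[agg$region_id]
    env_end <- tapply(reg$end, reg$region_id, max)[agg$region_id]
    data.frame(region_id = agg$region_id, class = cl,
               scaffold = first$scaffold[match(agg$region_id,
                                               first$region_id)],
               start = as.integer(env_start), end = as.integer(env_end),
               l = agg$l, c = agg$c, g = agg$g, cg = agg$cg,
               ncpg = .ncpg_from_counts(agg$l, agg$c, agg$g, agg$cg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(cbind(.empty_ncpg_table(), usable = logical()))
  out$usable <- !is.na(out$ncpg) & out$l >= min_length
  rownames(out) <- NULL
  out
}

.empty_ncpg_table <- function() data.frame(
  region_id = character(), class = character(), scaffold = character(),
  start = integer(), end = integer(), l = integer(), c = integer(),
  g = integer(), cg = integer(), ncpg = numeric(), stringsAsFactors = FALSE)

#' Usable nCpG values of one class, capped for mixture fitting
#'
#' Filters an [ncpg_table()] to one class, keeps defined values in
#' `(0, cap]` and returns them as a numeric vector. Empirically nCpG has an
#' upper limit between 2 and 2.5 in animal genomes, so values above `cap`
#' (default 3) are treated as outliers and dropped.
#'
#' @param tab an [ncpg_table()].
#' @param class region class to keep.
#' @param cap upper cap on nCpG.
#' @return numeric vector of nCpG values.
#' @export
ncpg_values <- function(tab, class, cap = 3) {
  v <- tab$ncpg[tab$class == class & tab$usable]
  v[is.finite(v) & v > 0 & v <= cap]
}
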