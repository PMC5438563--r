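#' Fixed-step window grid over a genome
#'
#' Tiles every scaffold with non-overlapping windows of `size` bp; the
#' final partial window of each scaffold is retained with its true length.
#'
#' @param gb a [genome_bundle()] (only scaffold lengths are used).
#' @param size window size in bp (default 500).
#' @return data.frame of class `window_grid` with columns `window_id`,
#'   `scaffold`, `start`, `end` (0-based half-open).
#' @export
window_grid <- function(gb, size = 500L) {
  out <- lapply(names(gb$seqlen), function(sc) {
    len <- unname(gb$seqlen[[sc]])
    starts <- seq.int(0L, len - 1L, by = size)
    data.frame(scaffold = sc, start = starts,
               end = pmin(starts + size, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- cbind(window_id = sprintf("%s:%d-%d", out$scaffold, out$start,
                                   out$end), out, stringsAsFactors = FALSE)
  class(out) <- c("window_grid", "data.frame")
  out
}

#' Count fragments per window
#'
#' Default `midpoint` mode assigns each fragment to the single window
#' containing its midpoint; a midpoint falling exactly on a window boundary
#' goes to the left window, so library totals are conserved exactly.
#' `overlap` mode counts a fragment once in every window it overlaps
#' (column sums then exceed fragment totals, and the matrix carries an
#' attribute flagging this).
#'
#' @param grid a [window_grid()].
#' @param fragsets list of [fragment_set()] objects (one per library).
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return object of class `window_counts`: list with `grid`, integer
#'   matrix `counts` (windows x libraries), and data.frame `libraries`
#'   (`library_id`, `sex`, `total`).
#' @export
count_fragments <- function(grid, fragsets, mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  if (inherits(fragsets, "fragment_set")) fragsets <- list(fragsets)
  scaffs <- unique(grid$scaffold)
  size <- max(grid$end - grid$start)
  # per-scaffold window index offsets (grid is ordered per scaffold)
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(fragsets))
  lib_meta <- data.frame(library_id = character(0), sex = character(0),
                         total = integer(0), stringsAsFactors = FALSE)
  row_key <- paste0(grid$scaffold, ":", grid$start %/% size)

  for (j in seq_along(fragsets)) {
    fs <- fragsets[[j]]
    fr <- fs$fragments
    bad <- setdiff(unique(fr$scaffold), scaffs)
    if (length(bad))
      .stopf("fragments on scaffold(s) absent from grid: %s",
             paste(bad, collapse = ", "))
    if (mode == "midpoint") {
      mid <- (fr$start + fr$end) / 2
      idx <- floor((mid - 0.5) / size)            # boundary ties go left
      idx[idx < 0] <- 0
      key <- paste0(fr$scaffold, ":", idx)
      # clamp beyond-last-window midpoints onto the terminal window
      miss <- !(key %in% row_key)
      if (any(miss)) {
        last_idx <- tapply(grid$start %/% size, grid$scaffold, max)
        key[miss] <- paste0(fr$scaffold[miss], ":",
                            last_idx[fr$scaffold[miss]])
      }
      tb <- table(factor(key, levels = row_key))
      counts[, j] <- as.integer(tb)
    } else {
      gr_w <- .as_granges0(grid)
      gr_f <- .as_granges0(fr)
      hits <- GenomicRanges::findOverlaps(gr_w, gr_f)
      tb <- table(factor(S4Vectors::queryHits(hits),
                         levels = seq_len(nrow(grid))))
      counts[, j] <- as.integer(tb)
    }
    lib_meta <- rbind(lib_meta, data.frame(
      library_id = fs$library_id, sex = as.character(fs$sex),
      total = sum(counts[, j]), stringsAsFactors = FALSE))
  }
  colnames(counts) <- lib_meta$library_id
  structure(list(grid = grid, counts = counts, libraries = lib_meta,
                 mode = mode),
            class = "window_counts")
}

#' Build a window_counts object from a pre-computed count matrix
#'
#' Used by the simulator, which draws counts directly rather than placing
#' fragments.
#'
#' @param grid a [window_grid()].
#' @param counts integer matrix, windows x libraries.
#' @param libraries data.frame with `library_id` and `sex`.
#' @return a `window_counts` object.
#' @export
window_counts <- function(grid, counts, libraries) {
  stopifnot(nrow(counts) == nrow(grid),
            ncol(counts) == nrow(libraries),
            all(counts >= 0))
  libraries$total <- as.integer(colSums(counts))
  colnames(counts) <- libraries$library_id
  structure(list(grid = grid, counts = counts, libraries = libraries,
                 mode = "simulated"),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d windows x %d libraries (%s mode)\n",
              nrow(x$counts), ncol(x$counts), x$mode))
  print(x$libraries, row.names = FALSE)
  invisible(x)
}

#' RPKM per window and library
#'
#' `rpkm = count / ((window_length/1000) * (library_total/1e6))` — reads
#' per kilobase per million mapped fragments, using each window's true
#' length (partial terminal windows keep their shorter length).
#'
#' @param wc a `window_counts` object.
#' @return numeric matrix, windows x libraries.
#' @export
rpkm <- function(wc) {
  totals <- wc$libraries$total
  if (any(totals <= 0)) .stopf("library with zero assigned fragments")
  len_kb <- (wc$grid$end - wc$grid$start) / 1000
  sweep(wc$counts / len_kb, 2, totals / 1e6, "/")
}

#' Call methylated windows and genes
#'
#' A window is methylated within a group (sex) when its group-mean RPKM
#' (average over that group's replicate libraries) reaches `threshold`;
#' methylated overall when methylated in at least one group. A gene is
#' methylated when one or more methylated windows intersect its
#' `[start, end)` span.
#'
#' @param wc a `window_counts` object.
#' @param gb a [genome_bundle()] (for gene-level calls); optional.
#' @param threshold group-mean RPKM threshold (default 1).
#' @return object of class `methylation_calls`: list with `windows`
#'   (data.frame: grid columns + per-group mean RPKM + pooled mean +
#'   per-group and overall methylated flags), `genes` (data.frame:
#'   `gene_id`, `methylated`, `n_meth_windows`), `threshold`, `groups`.
#' @export
call_methylated <- function(wc, gb = NULL, threshold = 1) {
  r <- rpkm(wc)
  groups <- unique(wc$libraries$sex)
  win <- wc$grid
  meth_any <- rep(FALSE, nrow(win))
  for (g in groups) {
    cols <- which(wc$libraries$sex == g)
    gm <- rowMeans(r[, cols, drop = FALSE])
    win[[paste0("mean_rpkm_", g)]] <- gm
    win[[paste0("methylated_", g)]] <- gm >= threshold
    meth_any <- meth_any | (gm >= threshold)
  }
  win$mean_rpkm <- rowMeans(r)
  win$methylated <- meth_any

  genes <- NULL
  if (!is.null(gb) && nrow(gb$genes)) {
    mw <- win[win$methylated, c("scaffold", "start", "end")]
    ov <- if (nrow(mw)) GenomicRanges::countOverlaps(
      .as_granges0(gb$genes), .as_granges0(mw)) else
        rep(0L, nrow(gb$genes))
    genes <- data.frame(gene_id = gb$genes$gene_id,
                        methylated = ov > 0,
                        n_meth_windows = as.integer(ov),
                        stringsAsFactors = FALSE)
  }
  structure(list(windows = win, genes = genes, threshold = threshold,
                 groups = groups),
            class = "methylation_calls")
}

#' @export
print.methylation_calls <- function(x, ...) {
  cat(sprintf(
    "methylation_calls: %d/%d windows methylated (threshold %.2f RPKM)\n",
    sum(x$windows$methylated), nrow(x$windows), x$threshold))
  if (!is.null(x$genes))
    cat(sprintf("  %d/%d genes methylated\n", sum(x$genes$methylated),
                nrow(x$genes)))
  invisible(x)
}

#' Genome and CpG fractions covered by the methylome
#'
#' @param calls a `methylation_calls` object.
#' @param gb the matching [genome_bundle()].
#' @return list with `genome_fraction` (methylated-window bases /
#'   assembly length), `cpg_fraction` (CpGs whose C lies inside a
#'   methylated window / all genome CpGs), `n_methylated_windows`,
#'   `n_methylated_genes`.
#' @export
methylome_fractions <- function(calls, gb) {
  w <- calls$windows
  mw <- w[w$methylated, , drop = FALSE]
  genome_fraction <- sum(as.numeric(mw$end - mw$start)) / gb$assembly_length

  total_cpg <- 0; meth_cpg <- 0
  for (sc in names(gb$seqs)) {
    r <- charToRaw(gb$seqs[[sc]])
    l <- length(r)
    if (l < 2) next
    cpg_pos <- which(r[-l] == .RAW_C & r[-1] == .RAW_G)  # 1-based C position
    total_cpg <- total_cpg + length(cpg_pos)
    msc <- mw[mw$scaffold == sc, , drop = FALSE]
    if (nrow(msc) && length(cpg_pos)) {
      inside <- rep(FALSE, l)
      for (i in seq_len(nrow(msc)))
        inside[(msc$start[i] + 1L):msc$end[i]] <- TRUE
      meth_cpg <- meth_cpg + sum(inside[cpg_pos])
    }
  }
  list(genome_fraction = genome_fraction,
       cpg_fraction = if (total_cpg > 0) meth_cpg / total_cpg else NA_real_,
       n_methylated_windows = nrow(mw),
       n_methylated_genes = if (!is.null(calls$genes))
         sum(calls$genes$methylated) else NA_integer_)
}

#' Genomic context of methylated windows
#'
#' Partitions methylated windows into `gene_body`, `upstream_50kb` and
#' `intergenic` with precedence gene_body > upstream > intergenic: a
#' window intersecting any gene body is `gene_body`; otherwise, if it
#' intersects the strand-aware `upstream_bp` region upstream of any TSS it
#' is `upstream_50kb`; otherwise `intergenic`. Also reports, among windows
#' that intersect an upstream region *before* precedence, the fraction
#' lying inside another gene's body.
#'
#' @param calls a `methylation_calls` object.
#' @param gb the matching [genome_bundle()].
#' @param upstream_bp upstream span (default 50000).
#' @return list with `windows` (methylated windows + `context` column),
#'   `proportions` (named fractions summing to 1),
#'   `upstream_in_gene_fraction`.
#' @export
classify_context <- function(calls, gb, upstream_bp = 50000L) {
  mw <- calls$windows[calls$windows$methylated, , drop = FALSE]
  if (!nrow(mw))
    return(list(windows = mw,
                proportions = c(gene_body = NA_real_,
                                upstream_50kb = NA_real_,
                                intergenic = NA_real_),
                upstream_in_gene_fraction = NA_real_))
  gr_w <- .as_granges0(mw[, c("scaffold", "start", "end")])

  in_body <- rep(FALSE, nrow(mw))
  if (nrow(gb$genes))
    in_body <- GenomicRanges::countOverlaps(
      gr_w, .as_granges0(gb$genes)) > 0

  in_up <- rep(FALSE, nrow(mw))
  if (nrow(gb$genes)) {
    tss <- gene_tss(gb$genes)
    plus <- gb$genes$strand == "+"
    up <- data.frame(
      scaffold = gb$genes$scaffold,
      start = ifelse(plus, pmax(0, tss - upstream_bp), tss),
      end = ifelse(plus, tss,
                   pmin(unname(gb$seqlen[gb$genes$scaffold]),
                        tss + upstream_bp)))
    up <- up[up$end > up$start, , drop = FALSE]
    if (nrow(up))
      in_up <- GenomicRanges::countOverlaps(gr_w, .as_granges0(up)) > 0
  }

  context <- ifelse(in_body, "gene_body",
                    ifelse(in_up, "upstream_50kb", "intergenic"))
  mw$context <- context
  props <- c(gene_body = mean(context == "gene_body"),
             upstream_50kb = mean(context == "upstream_50kb"),
             intergenic = mean(context == "intergenic"))
  up_in_gene <- if (any(in_up)) mean(in_body[in_up]) else NA_real_
  list(windows = mw, proportions = props,
       upstream_in_gene_fraction = up_in_gene)
}
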