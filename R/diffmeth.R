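# Differential methylation between two groups (sexes) under a negative
# binomial model with a common dispersion, window by window, followed by
# Benjamini-Hochberg FDR control, merging of adjacent significant windows
# and gene-level summaries.
#
# NB parameterization throughout: variance = mean + phi * mean^2
# (size = 1/phi in dnbinom/rnbinom terms).

#' Library-size factors to the geometric-mean depth
#' @param totals per-library totals.
#' @return numeric vector of size factors (divide counts by these).
#' @export
size_factors <- function(totals) {
  totals / exp(mean(log(totals)))
}

#' Estimate a common NB dispersion
#'
#' Counts are first normalized to the geometric-mean library depth. For
#' each window the within-group moments give a dispersion estimate; with
#' only two replicates per group these are individually very noisy, so
#' they are pooled across windows with a moment identity: summing
#' `variance - mean = phi * mean^2` over windows with mean at least
#' `min_mean` and solving for `phi`. The estimate is floored at `1e-4`.
#'
#' @param wc a `window_counts` object (at least 2 libraries per group).
#' @param min_mean minimum normalized mean for a window to contribute.
#' @param floor lower bound for the estimate.
#' @return common dispersion estimate (scalar).
#' @export
estimate_dispersion <- function(wc, min_mean = 5, floor = 1e-4) {
  sexes <- wc$libraries$sex
  tab <- table(sexes)
  if (any(tab < 2))
    .stopf("need >= 2 replicate libraries per group to estimate dispersion")
  sf <- size_factors(wc$libraries$total)
  norm <- sweep(wc$counts, 2, sf, "/")

  groups <- names(tab)
  gmeans <- sapply(groups, function(g)
    rowMeans(norm[, sexes == g, drop = FALSE]))
  gvars <- sapply(groups, function(g)
    apply(norm[, sexes == g, drop = FALSE], 1, var))
  m <- rowMeans(gmeans)          # overall normalized mean per window
  v <- rowMeans(gvars)           # pooled within-group variance

  keep <- is.finite(v) & m >= min_mean
  if (!any(keep)) return(floor)
  phi <- sum(v[keep] - m[keep]) / sum(m[keep]^2)
  max(phi, floor)
}

#' Conditional NB exact test for two group sums
#'
#' Given normalized pseudo-count sums `a` (group A, `n_a` libraries) and
#' `b` (group B, `n_b` libraries) and a common per-library dispersion
#' `phi`, conditions on the total `T = a + b` and enumerates every split
#' `(k, T - k)`. Under the null of equal per-library means, the group sums
#' are NB with means proportional to library numbers and sizes
#' `n_a / phi`, `n_b / phi`; each split has probability proportional to
#' the product of the two NB masses. The two-sided p-value sums the
#' probabilities of all splits no more probable than the observed one.
#'
#' @param a,b non-negative group sums (rounded internally to integers).
#' @param phi common NB dispersion (per library).
#' @param n_a,n_b number of libraries in each group.
#' @return list with `p_value`, `total`, and `flag` (`"zero_total"` when
#'   `T = 0`, otherwise `NA`).
#' @export
nb_exact_test <- function(a, b, phi, n_a = 2L, n_b = 2L) {
  a <- round(a); b <- round(b)
  tot <- a + b
  if (tot == 0)
    return(list(p_value = 1, total = 0L, flag = "zero_total"))
  k <- 0:tot
  mu_a <- tot * n_a / (n_a + n_b)
  mu_b <- tot * n_b / (n_a + n_b)
  size_a <- n_a / phi
  size_b <- n_b / phi
  logp <- dnbinom(k, size = size_a, mu = mu_a, log = TRUE) +
    dnbinom(tot - k, size = size_b, mu = mu_b, log = TRUE)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[a + 1L]
  # tolerance for ties in floating point, as in fisher.test
  p <- sum(pr[pr <= obs * (1 + 1e-7)])
  list(p_value = min(1, p), total = as.integer(tot), flag = NA_character_)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (monotone minimum of `p * n / rank` from the
#' largest p downward, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p)) .stopf("NA p-value passed to bh_fdr")
  if (any(p < 0 | p > 1)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Window-level differential methylation between sexes
#'
#' Tests every window methylated in at least one group with the
#' conditional NB exact test at the common dispersion, controls FDR over
#' the tested windows with Benjamini-Hochberg, and annotates direction.
#' `logFC` is log2(female / male) of normalized group means with a 0.5
#' pseudocount, so positive values mean female-hypermethylated.
#'
#' @param wc a `window_counts` object.
#' @param calls matching `methylation_calls` (defines which windows are
#'   tested); `NULL` tests every window with a positive total.
#' @param phi common dispersion; `NULL` estimates it with
#'   [estimate_dispersion()].
#' @param female,male the two group labels in `wc$libraries$sex`.
#' @param q_cutoff FDR cutoff defining significance (default 0.05).
#' @return object of class `diffmeth_result`: data.frame `windows` with
#'   `window_id`, `scaffold`, `start`, `end`, `mean_female`, `mean_male`,
#'   `logFC`, `p_value`, `q_value`, `significant`, `direction`
#'   (`female_hyper` / `male_hyper` / `none`), plus fields `phi`,
#'   `q_cutoff`, `n_tested`.
#' @export
diffmeth_windows <- function(wc, calls = NULL, phi = NULL,
                             female = "female", male = "male",
                             q_cutoff = 0.05) {
  sexes <- wc$libraries$sex
  if (!all(c(female, male) %in% sexes))
    .stopf("groups '%s' and '%s' not both present", female, male)
  if (is.null(phi)) phi <- estimate_dispersion(wc)
  sf <- size_factors(wc$libraries$total)
  norm <- sweep(wc$counts, 2, sf, "/")
  f_cols <- which(sexes == female)
  m_cols <- which(sexes == male)

  tested <- if (is.null(calls)) rowSums(wc$counts) > 0 else
    calls$windows$methylated
  idx <- which(tested)

  a <- round(rowSums(norm[, f_cols, drop = FALSE]))
  b <- round(rowSums(norm[, m_cols, drop = FALSE]))
  pv <- rep(NA_real_, nrow(norm))
  for (i in idx)
    pv[i] <- nb_exact_test(a[i], b[i], phi,
                           n_a = length(f_cols),
                           n_b = length(m_cols))$p_value

  qv <- rep(NA_real_, nrow(norm))
  qv[idx] <- bh_fdr(pv[idx])

  mean_f <- rowMeans(norm[, f_cols, drop = FALSE])
  mean_m <- rowMeans(norm[, m_cols, drop = FALSE])
  lfc <- log2((mean_f + 0.5) / (mean_m + 0.5))
  sig <- !is.na(qv) & qv < q_cutoff
  direction <- ifelse(!sig, "none",
                      ifelse(lfc > 0, "female_hyper", "male_hyper"))

  win <- data.frame(window_id = wc$grid$window_id,
                    scaffold = wc$grid$scaffold,
                    start = wc$grid$start, end = wc$grid$end,
                    tested = tested,
                    mean_female = mean_f, mean_male = mean_m,
                    logFC = lfc, p_value = pv, q_value = qv,
                    significant = sig, direction = direction,
                    stringsAsFactors = FALSE)
  structure(list(windows = win, phi = phi, q_cutoff = q_cutoff,
                 n_tested = length(idx),
                 female = female, male = male),
            class = "diffmeth_result")
}

#' @export
print.diffmeth_result <- function(x, ...) {
  w <- x$windows
  cat(sprintf(
    "diffmeth_result: %d windows tested (phi = %.4g), %d significant at q < %.2f\n",
    x$n_tested, x$phi, sum(w$significant), x$q_cutoff))
  cat(sprintf("  female-hyper %d, male-hyper %d\n",
              sum(w$direction == "female_hyper"),
              sum(w$direction == "male_hyper")))
  invisible(x)
}

#' Merge adjacent significant windows into regions
#'
#' Book-ended (zero-gap) significant windows on the same scaffold with the
#' same direction merge into one region carrying the minimum q-value and
#' the length-weighted mean logFC of its windows.
#'
#' @param dm a `diffmeth_result`.
#' @return data.frame with `scaffold`, `start`, `end`, `direction`,
#'   `n_windows`, `q_min`, `logFC` per merged region.
#' @export
merge_dm_windows <- function(dm) {
  w <- dm$windows[dm$windows$significant, , drop = FALSE]
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), direction = character(),
                      n_windows = integer(), q_min = numeric(),
                      logFC = numeric(), stringsAsFactors = FALSE)
  if (!nrow(w)) return(empty)
  w <- w[order(w$scaffold, w$start), ]
  new_run <- c(TRUE, w$scaffold[-1] != w$scaffold[-nrow(w)] |
                 w$start[-1] != w$end[-nrow(w)] |
                 w$direction[-1] != w$direction[-nrow(w)])
  run <- cumsum(new_run)
  out <- lapply(split(seq_len(nrow(w)), run), function(ix) {
    len <- w$end[ix] - w$start[ix]
    data.frame(scaffold = w$scaffold[ix[1]],
               start = min(w$start[ix]), end = max(w$end[ix]),
               direction = w$direction[ix[1]],
               n_windows = length(ix),
               q_min = min(w$q_value[ix]),
               logFC = sum(w$logFC[ix] * len) / sum(len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gene-level differential-methylation summary and region tagging
#'
#' Tags every significant window with each genic region class it
#' intersects (`promoter` = `promoter_bp` upstream of the TSS, `exon`,
#' `intron`, `downstream` = `downstream_bp` past the gene 3' end,
#' `gene_body`), flags a gene as differentially methylated when at least
#' one significant window intersects its footprint (gene body plus
#' promoter), and marks genes carrying windows of both directions as
#' `contrasting`.
#'
#' @param dm a `diffmeth_result`.
#' @param gb the matching [genome_bundle()].
#' @param promoter_bp promoter width upstream of the TSS (default 3000).
#' @param downstream_bp span past the gene 3' end (default 1000).
#' @return list with data.frames `genes` (`gene_id`, `dm`, `n_female_hyper`,
#'   `n_male_hyper`, `contrasting`, `q_min`), `window_tags` (one row per
#'   significant window x region tag), and `region_summary` (per tag:
#'   `n_windows`, `mean_abs_logFC`, `median_abs_logFC`).
#' @export
summarize_genes <- function(dm, gb, promoter_bp = 3000L,
                            downstream_bp = 1000L) {
  sig <- dm$windows[dm$windows$significant, , drop = FALSE]
  genes <- gb$genes
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"

  region_ivs <- list(
    gene_body = data.frame(gene_id = genes$gene_id,
                           scaffold = genes$scaffold,
                           start = genes$start, end = genes$end),
    exon = data.frame(gene_id = gb$exons$gene_id,
                      scaffold = genes$scaffold[
                        match(gb$exons$gene_id, genes$gene_id)],
                      start = gb$exons$start, end = gb$exons$end),
    intron = {
      ii <- extract_regions(gb, "intron")
      data.frame(gene_id = sub(":intron$", "", ii$region_id),
                 scaffold = ii$scaffold, start = ii$start, end = ii$end)
    },
    promoter = data.frame(
      gene_id = genes$gene_id, scaffold = genes$scaffold,
      start = ifelse(plus, pmax(0, tss - promoter_bp), tss),
      end = ifelse(plus, tss,
                   pmin(unname(gb$seqlen[genes$scaffold]),
                        tss + promoter_bp))),
    downstream = data.frame(
      gene_id = genes$gene_id, scaffold = genes$scaffold,
      start = ifelse(plus, genes$end,
                     pmax(0, genes$start - downstream_bp)),
      end = ifelse(plus,
                   pmin(unname(gb$seqlen[genes$scaffold]),
                        genes$end + downstream_bp),
                   genes$start))
  )

  tags <- NULL
  if (nrow(sig)) {
    gr_w <- .as_granges0(sig[, c("scaffold", "start", "end")])
    tags <- do.call(rbind, lapply(names(region_ivs), function(tag) {
      iv <- region_ivs[[tag]]
      iv <- iv[iv$end > iv$start, , drop = FALSE]
      if (!nrow(iv)) return(NULL)
      hits <- GenomicRanges::findOverlaps(gr_w, .as_granges0(iv))
      if (!length(hits)) return(NULL)
      data.frame(window_id = sig$window_id[S4Vectors::queryHits(hits)],
                 gene_id = iv$gene_id[S4Vectors::subjectHits(hits)],
                 tag = tag,
                 direction = sig$direction[S4Vectors::queryHits(hits)],
                 logFC = sig$logFC[S4Vectors::queryHits(hits)],
                 q_value = sig$q_value[S4Vectors::queryHits(hits)],
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(tags))
    tags <- data.frame(window_id = character(), gene_id = character(),
                       tag = character(), direction = character(),
                       logFC = numeric(), q_value = numeric(),
                       stringsAsFactors = FALSE)

  # gene footprint = gene body + promoter
  foot <- tags[tags$tag %in% c("gene_body", "promoter"), , drop = FALSE]
  per_gene <- lapply(split(foot, foot$gene_id), function(d) {
    d <- d[!duplicated(d$window_id), ]
    data.frame(gene_id = d$gene_id[1], dm = TRUE,
               n_female_hyper = sum(d$direction == "female_hyper"),
               n_male_hyper = sum(d$direction == "male_hyper"),
               contrasting = any(d$direction == "female_hyper") &&
                 any(d$direction == "male_hyper"),
               q_min = min(d$q_value), stringsAsFactors = FALSE)
  })
  dm_genes <- if (length(per_gene)) do.call(rbind, per_gene) else NULL
  gene_tab <- data.frame(gene_id = genes$gene_id, dm = FALSE,
                         n_female_hyper = 0L, n_male_hyper = 0L,
                         contrasting = FALSE, q_min = NA_real_,
                         stringsAsFactors = FALSE)
  if (!is.null(dm_genes)) {
    i <- match(dm_genes$gene_id, gene_tab$gene_id)
    gene_tab[i, c("dm", "contrasting")] <-
      dm_genes[, c("dm", "contrasting")]
    gene_tab$n_female_hyper[i] <- dm_genes$n_female_hyper
    gene_tab$n_male_hyper[i] <- dm_genes$n_male_hyper
    gene_tab$q_min[i] <- dm_genes$q_min
  }
  rownames(gene_tab) <- NULL

  region_summary <- do.call(rbind, lapply(split(tags, tags$tag),
    function(d) data.frame(tag = d$tag[1],
                           n_windows = length(unique(d$window_id)),
                           mean_abs_logFC = mean(abs(d$logFC)),
                           median_abs_logFC = median(abs(d$logFC)),
                           stringsAsFactors = FALSE)))
  if (is.null(region_summary))
    region_summary <- data.frame(tag = character(), n_windows = integer(),
                                 mean_abs_logFC = numeric(),
                                 median_abs_logFC = numeric(),
                                 stringsAsFactors = FALSE)
  rownames(region_summary) <- NULL
  list(genes = gene_tab, window_tags = tags,
       region_summary = region_summary)
}
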