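# Cross-cutting statistics linking nCpG, methylation, repeats and
# expression: resampling and permutation nulls, proximity tables and the
# standard closed-form tests.

.new_resampling_result <- function(observed, null_draws, B, p, direction,
                                   seed) {
  structure(list(observed = observed, B = as.integer(B),
                 null_mean = mean(null_draws), null_sd = sd(null_draws),
                 p_value = p, direction = direction, seed = seed),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "resampling/permutation test (%s tail): observed %.4f, null %.4f +/- %.4f, p = %.4g (B = %d)\n",
    x$direction, x$observed, x$null_mean, x$null_sd, x$p_value, x$B))
  invisible(x)
}

#' Resampling test for CpG depletion of differentially methylated genes
#'
#' Tests whether the mean nCpG of differentially methylated genes is lower
#' than expected for a random subset of methylated genes of the same size:
#' the null distribution is built by repeatedly drawing (without
#' replacement) subsets from the full methylated set. The default tail is
#' one-sided lower (the alternative is that DM genes are *more* CpG
#' depleted); use `direction = "two_sided"` for a two-sided version.
#'
#' @param dm_ncpg nCpG values of the differentially methylated genes
#'   (defined values only).
#' @param methylated_ncpg nCpG values of all methylated genes (must
#'   contain the DM set).
#' @param B number of resampling draws (default 999).
#' @param seed integer seed.
#' @param direction `"lower"`, `"higher"` or `"two_sided"`.
#' @return a `resampling_result` with the observed mean, null summary and
#'   empirical p-value `(1 + exceedances) / (B + 1)`.
#' @export
ncpg_depletion_test <- function(dm_ncpg, methylated_ncpg, B = 999L,
                                seed = 1L,
                                direction = c("lower", "higher",
                                              "two_sided")) {
  direction <- match.arg(direction)
  dm_ncpg <- dm_ncpg[is.finite(dm_ncpg)]
  methylated_ncpg <- methylated_ncpg[is.finite(methylated_ncpg)]
  k <- length(dm_ncpg)
  if (k == 0) .stopf("empty DM gene set")
  if (k > length(methylated_ncpg))
    .stopf("DM set larger than the methylated set")
  obs <- mean(dm_ncpg)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null <- vapply(seq_len(B), function(b)
    mean(sample(methylated_ncpg, k, replace = FALSE)), numeric(1))
  exceed <- switch(direction,
    lower = sum(null <= obs),
    higher = sum(null >= obs),
    two_sided = sum(abs(null - mean(null)) >= abs(obs - mean(null))))
  .new_resampling_result(obs, null, B, .empirical_p(exceed, B),
                         direction, seed)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] returning the maximum ECDF gap
#' `D` and its p-value; used to compare nCpG distributions between gene
#' sets.
#'
#' @param sample1,sample2 numeric vectors.
#' @return list with `D` and `p_value`.
#' @export
ks_compare <- function(sample1, sample2) {
  stopifnot(length(sample1) > 0, length(sample2) > 0)
  kt <- suppressWarnings(stats::ks.test(sample1, sample2))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Methylated-repeat proximity table
#'
#' For each gene set (all methylated, non-methylated, male-hypermethylated,
#' female-hypermethylated and an optional interest list) and each upstream
#' distance, counts genes having at least one *methylated repeat* (a
#' repeat interval intersecting a methylated window) within the
#' strand-aware upstream distance of the gene anchor (TSS). Each
#' methylated-gene set is compared to the non-methylated set with a 2x2
#' chi-square test (no Yates correction by default). Also reports, per
#' distance, the direction concordance between differentially methylated
#' repeat windows and the nearest differentially methylated genes they sit
#' upstream of.
#'
#' @param gb a [genome_bundle()] (genes and repeats).
#' @param calls a `methylation_calls` object (with gene calls).
#' @param dm a `diffmeth_result`; `gene_summary` its [summarize_genes()]
#'   output.
#' @param gene_summary output of [summarize_genes()] (for gene DM
#'   direction).
#' @param distances upstream distances in bp.
#' @param interest_genes optional character vector of gene ids.
#' @param yates logical; apply Yates continuity correction.
#' @return object of class `proximity_table`: list with `table`
#'   (data.frame: set, distance, n_genes, n_with_repeat, fraction,
#'   chisq_stat, chisq_p), `concordance` (data.frame per direction and
#'   distance: matched, total, fraction), and the per-gene indicator
#'   matrix used (`indicator`, genes x distances, for permutation tests).
#' @export
repeat_proximity <- function(gb, calls, dm = NULL, gene_summary = NULL,
                             distances = c(1000L, 5000L, 10000L),
                             interest_genes = NULL, yates = FALSE) {
  genes <- gb$genes
  if (!nrow(genes)) .stopf("no genes in the bundle")
  if (!nrow(gb$repeats)) .stopf("no repeats in the bundle")

  # methylated repeats: repeat intervals intersecting a methylated window
  mw <- calls$windows[calls$windows$methylated,
                      c("scaffold", "start", "end"), drop = FALSE]
  rep_meth <- rep(FALSE, nrow(gb$repeats))
  if (nrow(mw))
    rep_meth <- GenomicRanges::countOverlaps(
      .as_granges0(gb$repeats), .as_granges0(mw)) > 0
  mrep <- gb$repeats[rep_meth, , drop = FALSE]

  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  indicator <- matrix(FALSE, nrow(genes), length(distances),
                      dimnames = list(genes$gene_id, as.character(distances)))
  for (di in seq_along(distances)) {
    d <- distances[di]
    up <- data.frame(
      scaffold = genes$scaffold,
      start = ifelse(plus, pmax(0, tss - d), tss),
      end = ifelse(plus, tss,
                   pmin(unname(gb$seqlen[genes$scaffold]), tss + d)))
    ok <- up$end > up$start
    if (any(ok) && nrow(mrep)) {
      cnt <- GenomicRanges::countOverlaps(
        .as_granges0(up[ok, , drop = FALSE]), .as_granges0(mrep))
      indicator[ok, di] <- cnt > 0
    }
  }

  gm <- calls$genes
  sets <- list(methylated = gm$gene_id[gm$methylated],
               non_methylated = gm$gene_id[!gm$methylated])
  if (!is.null(gene_summary)) {
    gs <- gene_summary$genes
    sets$male_hyper <- gs$gene_id[gs$dm & gs$n_male_hyper > 0]
    sets$female_hyper <- gs$gene_id[gs$dm & gs$n_female_hyper > 0]
  }
  if (!is.null(interest_genes))
    sets$interest <- intersect(interest_genes, genes$gene_id)

  nm_ids <- sets$non_methylated
  rows <- list()
  for (set_name in names(sets)) {
    ids <- sets[[set_name]]
    for (di in seq_along(distances)) {
      n_with <- sum(indicator[ids, di])
      stat <- p <- NA_real_
      if (set_name != "non_methylated") {
        if (!length(nm_ids)) {
          .warnf("empty non-methylated set; chi-square skipped")
        } else if (length(ids)) {
          tab <- rbind(c(n_with, length(ids) - n_with),
                       c(sum(indicator[nm_ids, di]),
                         length(nm_ids) - sum(indicator[nm_ids, di])))
          ct <- suppressWarnings(chisq.test(tab, correct = yates))
          stat <- unname(ct$statistic); p <- ct$p.value
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, distance = distances[di],
        n_genes = length(ids), n_with_repeat = n_with,
        fraction = if (length(ids)) n_with / length(ids) else NA_real_,
        chisq_stat = stat, chisq_p = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  concord <- NULL
  if (!is.null(dm) && !is.null(gene_summary)) {
    concord <- .repeat_gene_concordance(gb, dm, gene_summary, distances)
  }
  structure(list(table = tab, concordance = concord,
                 indicator = indicator, distances = distances,
                 methylated_repeats = mrep),
            class = "proximity_table")
}

# Direction concordance between DM repeat windows and the DM genes they
# sit upstream of: a DM repeat window (significant window intersecting a
# repeat) within distance d upstream of a DM gene matches when its
# direction equals the gene's dominant direction.
.repeat_gene_concordance <- function(gb, dm, gene_summary, distances) {
  sig <- dm$windows[dm$windows$significant, , drop = FALSE]
  gs <- gene_summary$genes
  gs <- gs[gs$dm, , drop = FALSE]
  empty <- data.frame(distance = integer(), direction = character(),
                      matched = integer(), total = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  if (!nrow(sig) || !nrow(gs) || !nrow(gb$repeats)) return(empty)

  in_rep <- GenomicRanges::countOverlaps(
    .as_granges0(sig[, c("scaffold", "start", "end")]),
    .as_granges0(gb$repeats)) > 0
  rw <- sig[in_rep, , drop = FALSE]
  if (!nrow(rw)) return(empty)

  genes <- gb$genes[gb$genes$gene_id %in% gs$gene_id, , drop = FALSE]
  gdir <- ifelse(gs$n_female_hyper >= gs$n_male_hyper, "female_hyper",
                 "male_hyper")
  names(gdir) <- gs$gene_id
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"

  out <- list()
  for (d in distances) {
    up <- data.frame(
      scaffold = genes$scaffold,
      start = ifelse(plus, pmax(0, tss - d), tss),
      end = ifelse(plus, tss,
                   pmin(unname(gb$seqlen[genes$scaffold]), tss + d)))
    ok <- up$end > up$start
    hits <- GenomicRanges::findOverlaps(
      .as_granges0(rw[, c("scaffold", "start", "end")]),
      .as_granges0(up[ok, , drop = FALSE]))
    if (!length(hits)) next
    wdir <- rw$direction[S4Vectors::queryHits(hits)]
    gid <- genes$gene_id[ok][S4Vectors::subjectHits(hits)]
    for (dir in c("male_hyper", "female_hyper")) {
      sel <- wdir == dir
      tot <- sum(sel)
      if (!tot) next
      matched <- sum(gdir[gid[sel]] == dir)
      out[[length(out) + 1L]] <- data.frame(
        distance = d, direction = dir, matched = matched, total = tot,
        fraction = matched / tot, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Permutation test for proximity enrichment
#'
#' Tests whether the proportion of genes with a proximal methylated repeat
#' differs between two label classes, by shuffling the labels across genes
#' `B` times. Two-sided by construction (absolute difference in
#' proportions).
#'
#' @param labels logical or two-level vector over genes (e.g. methylated
#'   vs not).
#' @param indicator logical vector over the same genes (has a proximal
#'   methylated repeat).
#' @param B number of permutations (default 999; below 99 a warning flags
#'   the coarse resolution).
#' @param seed integer seed.
#' @return a `resampling_result` (observed = difference in proportions).
#' @export
proximity_permutation_test <- function(labels, indicator, B = 999L,
                                       seed = 1L) {
  if (B < 99) .warnf("B = %d gives coarse p-value resolution", B)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2)
    .stopf("labels must have exactly two classes")
  indicator <- as.logical(indicator)
  stopifnot(length(labels) == length(indicator))
  lev <- levels(labels)
  prop_diff <- function(lab) {
    mean(indicator[lab == lev[1]]) - mean(indicator[lab == lev[2]])
  }
  obs <- prop_diff(labels)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null <- vapply(seq_len(B), function(b)
    prop_diff(sample(labels)), numeric(1))
  exceed <- sum(abs(null) >= abs(obs))
  .new_resampling_result(obs, null, B, .empirical_p(exceed, B),
                         "two_sided", seed)
}

#' Fisher exact test of methylation status against expression status
#'
#' Builds the 2x2 contingency table of genes differentially expressed (or
#' not) by differentially methylated (or not) and computes the two-sided
#' Fisher exact p-value (sum of hypergeometric probabilities of tables no
#' more probable than the observed one). The sample odds ratio
#' `(ad)/(bc)` is reported alongside.
#'
#' @param gene_table data.frame with logical columns `dm` and `de` (or a
#'   `de_class` column, where anything other than `"none"` counts as DE).
#' @return list with `odds_ratio` (sample OR), `p_value`, `table`, and
#'   `flag` (`"zero_margin"` when a margin is empty, p is then 1).
#' @export
methylation_expression_fisher <- function(gene_table) {
  dm <- as.logical(gene_table$dm)
  de <- if ("de" %in% names(gene_table)) as.logical(gene_table$de)
        else gene_table$de_class != "none"
  if (anyNA(dm) || anyNA(de)) .stopf("every gene needs both labels")
  tab <- table(factor(de, c(TRUE, FALSE)), factor(dm, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab,
                flag = "zero_margin"))
  ft <- fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value, table = tab,
       flag = NA_character_)
}

#' Repeat-abundance comparisons across genome, methylome and transcriptome
#'
#' Given per-category repeat abundances (fractions of bases by default) in
#' the genome, the methylome and the transcriptome, runs pairwise
#' Kruskal-Wallis tests on the category-wise abundances and ordinary
#' least-squares regressions of transcriptome abundance on genome
#' abundance, on methylome abundance, and on both together.
#'
#' @param genome,methylome,transcriptome named numeric vectors over the
#'   same repeat categories (at least 3).
#' @return list with `kruskal` (data.frame: comparison, H, p) and
#'   `regressions` (list of `lm` summaries: slope(s), p, r2 per model).
#' @export
repeat_abundance_stats <- function(genome, methylome, transcriptome) {
  cats <- names(genome)
  if (length(cats) < 3) .stopf("need >= 3 repeat categories")
  if (!identical(sort(cats), sort(names(methylome))) ||
      !identical(sort(cats), sort(names(transcriptome))))
    .stopf("the three vectors must share the same category set")
  methylome <- methylome[cats]
  transcriptome <- transcriptome[cats]

  pairs <- list(genome_vs_methylome = list(genome, methylome),
                genome_vs_transcriptome = list(genome, transcriptome),
                methylome_vs_transcriptome = list(methylome, transcriptome))
  kw <- do.call(rbind, lapply(names(pairs), function(nm) {
    a <- pairs[[nm]][[1]]; b <- pairs[[nm]][[2]]
    kt <- kruskal.test(list(a, b))
    data.frame(comparison = nm, H = unname(kt$statistic),
               p_value = kt$p.value, stringsAsFactors = FALSE)
  }))

  reg_one <- function(y, x) {
    fit <- lm(y ~ x)
    sm <- summary(fit)
    list(slope = unname(coef(fit)[2]),
         p_value = sm$coefficients[2, 4],
         r2 = sm$r.squared)
  }
  fit_both <- lm(transcriptome ~ genome + methylome)
  smb <- summary(fit_both)
  regressions <- list(
    on_genome = reg_one(transcriptome, genome),
    on_methylome = reg_one(transcriptome, methylome),
    on_both = list(slopes = coef(fit_both)[-1],
                   p_values = smb$coefficients[-1, 4],
                   r2 = smb$r.squared))
  list(kruskal = kw, regressions = regressions)
}

#' Per-category repeat abundance as a fraction of the genome
#'
#' Abundance of each repeat category as total repeat bases divided by the
#' assembly length, optionally restricted to repeats intersecting a set of
#' intervals (e.g. methylated windows), in which case only the overlapping
#' bases count.
#'
#' @param gb a [genome_bundle()].
#' @param within optional data.frame of intervals (`scaffold`, `start`,
#'   `end`) to intersect with (e.g. methylated windows).
#' @param mode `"fraction"` (of assembly bases) or `"count"` (number of
#'   repeat intervals).
#' @return named numeric vector over repeat categories.
#' @export
repeat_abundance <- function(gb, within = NULL,
                             mode = c("fraction", "count")) {
  mode <- match.arg(mode)
  reps <- gb$repeats
  cats <- sort(unique(reps$category))
  out <- setNames(numeric(length(cats)), cats)
  gr_r <- .as_granges0(reps)
  if (is.null(within)) {
    kept <- gr_r
    cat_of <- reps$category
  } else {
    gr_w <- GenomicRanges::reduce(.as_granges0(within))
    hits <- GenomicRanges::findOverlaps(gr_r, gr_w)
    kept <- IRanges::pintersect(gr_r[S4Vectors::queryHits(hits)],
                                gr_w[S4Vectors::subjectHits(hits)])
    cat_of <- reps$category[S4Vectors::queryHits(hits)]
  }
  if (length(kept)) {
    if (mode == "count") {
      tb <- table(factor(cat_of, levels = cats))
      out[] <- as.numeric(tb)
    } else {
      wsum <- tapply(GenomicRanges::width(kept),
                     factor(cat_of, levels = cats), sum)
      wsum[is.na(wsum)] <- 0
      out[] <- as.numeric(wsum) / gb$assembly_length
    }
  }
  out
}
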