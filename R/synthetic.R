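# Synthetic genome, annotation, repeat, expression and MeDIP-count
# generator with a ground-truth ledger. The generator reproduces the
# statistical structure the analysis assumes: region-specific CpG
# depletion (bimodal promoter nCpG from a low/high-CpG promoter class
# mixture), a fixed 500-bp methylation landscape covering a target genome
# fraction, two sexes x two replicate libraries of NB-distributed window
# counts with truly differentially methylated windows, repeats clustered
# upstream of methylated genes with direction-concordant differential
# methylation, and gene expression labels with tunable association to DM
# status.

#' Simulation configuration
#'
#' Defaults define the package's reference scenario: a 2 x 1-Mb toy
#' genome, 200 genes, promoter nCpG forced bimodal through a 60/40
#' mixture of heavily (d = 0.75) and lightly (d = 0.2) deaminated promoter
#' classes, 57% of 500-bp windows methylated, 2 + 2 libraries of
#' NB(phi = 0.1) counts with mean methylated-window depth above 20
#' fragments, and 30 differentially methylated genes at 4-fold change.
#'
#' @param n_scaffolds,scaffold_length genome shape.
#' @param n_genes genes placed (non-overlapping, split across scaffolds).
#' @param exons_per_gene integer range (min, max).
#' @param gene_length,intergenic_gap bp ranges (min, max) for gene spans
#'   and inter-gene gaps.
#' @param gc_content base composition of the i.i.d. background sequence.
#' @param depletion_rates named per-CpG deamination probabilities for
#'   `exon`, `intron`, `intergenic`.
#' @param promoter_width bp upstream of the TSS treated as promoter for
#'   depletion.
#' @param lcg_weight mixing weight of the low-CpG promoter class.
#' @param lcg_depletion,hcg_depletion per-CpG deamination probability of
#'   the two promoter classes.
#' @param dm_extra_depletion additional deamination applied to the gene
#'   bodies of DM genes (creates the lower nCpG of DM genes).
#' @param methylated_fraction target fraction of windows methylated.
#' @param gene_unmethylated_fraction fraction of genes designated
#'   non-methylated (their bodies and 10-kb flanks are kept free of
#'   methylated windows).
#' @param n_dm_genes,dm_windows_per_gene,dm_fold_change differential
#'   methylation design.
#' @param contrast_fraction probability that a DM gene carries one window
#'   of the opposite direction.
#' @param repeat_concordance probability that a DM repeat window upstream
#'   of a DM gene shares the gene's direction.
#' @param window_size bp.
#' @param libraries data.frame with `library_id`, `sex`, `size` (expected
#'   fragments).
#' @param nb_dispersion NB dispersion phi (variance = mean + phi mean^2).
#' @param repeats_per_methylated_gene,repeats_per_unmethylated_gene mean
#'   number of repeats placed 1-10 kb upstream.
#' @param repeat_length bp range.
#' @param repeat_categories named sampling weights.
#' @param expression_association strength in `[0, 1]` of the DM-DE link
#'   (0 = independent, 1 = DE iff DM with the opposite-sex class).
#' @param de_base_rate baseline probability a gene is DE.
#' @param seed master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_scaffolds = 2L,
                       scaffold_length = 1e6,
                       n_genes = 200L,
                       exons_per_gene = c(2L, 8L),
                       gene_length = c(2000L, 5000L),
                       intergenic_gap = c(1000L, 8000L),
                       gc_content = 0.42,
                       depletion_rates = c(exon = 0.65, intron = 0.75,
                                           intergenic = 0.75),
                       promoter_width = 3000L,
                       lcg_weight = 0.6,
                       lcg_depletion = 0.75,
                       hcg_depletion = 0.2,
                       dm_extra_depletion = 0.1,
                       methylated_fraction = 0.57,
                       gene_unmethylated_fraction = 0.10,
                       n_dm_genes = 30L,
                       dm_windows_per_gene = c(2L, 5L),
                       dm_fold_change = 4,
                       contrast_fraction = 0.2,
                       repeat_concordance = 0.75,
                       window_size = 500L,
                       libraries = data.frame(
                         library_id = c("male_1", "male_2",
                                        "female_1", "female_2"),
                         sex = c("male", "male", "female", "female"),
                         size = c(50000L, 52000L, 48000L, 56000L),
                         stringsAsFactors = FALSE),
                       nb_dispersion = 0.1,
                       repeats_per_methylated_gene = 3,
                       repeats_per_unmethylated_gene = 0.3,
                       repeat_length = c(200L, 800L),
                       repeat_categories = c(CR1 = 0.35, HAT = 0.30,
                                             DIRS = 0.15, Gypsy = 0.12,
                                             Harbinger = 0.08),
                       expression_association = 0.8,
                       de_base_rate = 0.2,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$depletion_rates, cfg$lcg_depletion, cfg$hcg_depletion,
             cfg$dm_extra_depletion, cfg$methylated_fraction,
             cfg$gene_unmethylated_fraction, cfg$lcg_weight,
             cfg$gc_content, cfg$contrast_fraction,
             cfg$repeat_concordance, cfg$expression_association,
             cfg$de_base_rate)
  if (any(probs < 0 | probs > 1))
    .stopf("all probabilities must lie in [0, 1]")
  if (cfg$dm_fold_change <= 1) .stopf("dm_fold_change must exceed 1")
  if (any(table(cfg$libraries$sex) < 2))
    .stopf("need >= 2 libraries per sex for the DM stage")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with known depletion, methylation and DM structure
#'
#' Builds the synthetic genome in stages: (1) i.i.d. bases at the given GC
#' content; (2) non-overlapping genes with exon/intron structure, random
#' strand and a low/high-CpG promoter class per gene; (3) a fixed 500-bp
#' methylation landscape hitting the target methylated fraction, with
#' designated non-methylated genes kept methylation-free (body plus 10-kb
#' flanks); (4) per-CpG C-to-T deamination at the class-specific rates
#' (precedence exon > intron > promoter > intergenic), plus extra
#' deamination on DM gene bodies, so a class with prior nCpG0 has expected
#' nCpG of about `(1 - d) * nCpG0`; (5) repeats placed 1-10 kb upstream of
#' genes at a density depending on the gene's methylation label; (6) true
#' DM windows inside DM gene bodies and on repeats upstream of DM genes,
#' with direction-concordance as configured.
#'
#' Deamination is bookkept on the forward strand only, which keeps the
#' closed-form expectation exact.
#'
#' @param cfg a [sim_config()].
#' @return list with `bundle` (a [genome_bundle()]) and `truth` (the
#'   ground-truth ledger: `windows`, `genes`, `repeats` data.frames and
#'   the config).
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$seed)

  ## (1) background sequence
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  scaff_names <- sprintf("scaffold_%d", seq_len(cfg$n_scaffolds))
  base_mat <- lapply(scaff_names, function(s)
    sample(names(p), cfg$scaffold_length, replace = TRUE, prob = p))
  names(base_mat) <- scaff_names

  ## (2) gene placement
  per_scaffold <- diff(round(seq(0, cfg$n_genes,
                                 length.out = cfg$n_scaffolds + 1)))
  genes_l <- list(); exons_l <- list()
  gi <- 0L
  for (si in seq_len(cfg$n_scaffolds)) {
    pos <- 0L
    for (k in seq_len(per_scaffold[si])) {
      gap <- sample(cfg$intergenic_gap[1]:cfg$intergenic_gap[2], 1L)
      len <- sample(cfg$gene_length[1]:cfg$gene_length[2], 1L)
      start <- pos + gap
      if (start + len > cfg$scaffold_length)
        .stopf(paste("cannot place %d genes on scaffold %d without",
                     "overlap; increase scaffold_length"),
               per_scaffold[si], si)
      gi <- gi + 1L
      gid <- sprintf("gene_%03d", gi)
      genes_l[[gi]] <- data.frame(
        gene_id = gid, scaffold = scaff_names[si],
        strand = sample(c("+", "-"), 1L),
        start = start, end = start + len, stringsAsFactors = FALSE)
      exons_l[[gi]] <- .simulate_exons(gid, start, start + len,
                                       cfg$exons_per_gene)
      pos <- start + len
    }
  }
  genes <- do.call(rbind, genes_l)
  exons <- do.call(rbind, exons_l)
  rownames(genes) <- rownames(exons) <- NULL

  promoter_class <- sample(c("LCG", "HCG"), nrow(genes), replace = TRUE,
                           prob = c(cfg$lcg_weight, 1 - cfg$lcg_weight))

  ## (3) methylation landscape on the window grid
  seqlen <- setNames(rep(cfg$scaffold_length, cfg$n_scaffolds),
                     scaff_names)
  grid <- local({
    gb0 <- structure(list(seqlen = seqlen, seqs = setNames(
      rep("", cfg$n_scaffolds), scaff_names)), class = "genome_bundle")
    window_grid(gb0, cfg$window_size)
  })
  nw <- nrow(grid)
  gr_grid <- .as_granges0(grid)

  n_unmeth <- round(cfg$gene_unmethylated_fraction * nrow(genes))
  unmeth_ids <- sample(genes$gene_id, n_unmeth)
  dm_ids <- sample(setdiff(genes$gene_id, unmeth_ids), cfg$n_dm_genes)

  # desert: designated non-methylated genes sit in hypomethylated
  # neighborhoods -- methylation is regional -- so no methylated window may
  # touch their body (plus 2-kb flanks) or their strand-aware 10-kb
  # upstream region, keeping upstream repeats unmethylated as well
  ug <- genes[genes$gene_id %in% unmeth_ids, , drop = FALSE]
  desert <- rep(FALSE, nw)
  if (nrow(ug)) {
    up_plus <- ug$strand == "+"
    utss <- ifelse(up_plus, ug$start, ug$end)
    flank <- rbind(
      data.frame(scaffold = ug$scaffold,
                 start = pmax(0, ug$start - 2000L),
                 end = pmin(unname(seqlen[ug$scaffold]), ug$end + 2000L)),
      data.frame(scaffold = ug$scaffold,
                 start = pmax(0, ifelse(up_plus, utss - 10000L, utss)),
                 end = pmin(unname(seqlen[ug$scaffold]),
                            ifelse(up_plus, utss, utss + 10000L))))
    desert <- GenomicRanges::countOverlaps(gr_grid,
                                           .as_granges0(flank)) > 0
  }

  # forced: one body window per methylated gene, all DM-gene body windows
  # eligible for DM selection later
  mg <- genes[!(genes$gene_id %in% unmeth_ids), , drop = FALSE]
  body_hits <- GenomicRanges::findOverlaps(gr_grid, .as_granges0(mg))
  body_win_by_gene <- split(S4Vectors::queryHits(body_hits),
                            mg$gene_id[S4Vectors::subjectHits(body_hits)])
  forced <- integer(0)
  for (gid in names(body_win_by_gene)) {
    cand <- setdiff(body_win_by_gene[[gid]], which(desert))
    if (length(cand))
      forced <- c(forced, cand[sample.int(length(cand), 1L)])
  }
  forced <- unique(forced)

  target_m <- round(cfg$methylated_fraction * nw)
  pool <- setdiff(which(!desert), forced)
  n_fill <- max(0L, target_m - length(forced))
  fill <- if (n_fill > 0)
    pool[sample.int(length(pool), min(n_fill, length(pool)))] else
    integer(0)
  meth <- rep(FALSE, nw)
  meth[c(forced, fill)] <- TRUE

  ## (4) deamination
  # per-base class painting: intergenic < promoter < intron < exon
  tss <- setNames(ifelse(genes$strand == "+", genes$start, genes$end),
                  genes$gene_id)
  class_codes <- c(intergenic = 1L, promoter_LCG = 2L, promoter_HCG = 3L,
                   intron = 4L, exon = 5L)
  d_of_code <- c(cfg$depletion_rates[["intergenic"]],
                 cfg$lcg_depletion, cfg$hcg_depletion,
                 cfg$depletion_rates[["intron"]],
                 cfg$depletion_rates[["exon"]])
  paint <- lapply(seqlen, function(len) rep(1L, len))
  paint_iv <- function(paint, sc, s, e, code) {
    if (e > s) paint[[sc]][(s + 1L):e] <- code
    paint
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    pw <- cfg$promoter_width
    if (g$strand == "+") {
      ps <- max(0L, g$start - pw); pe <- g$start
    } else {
      ps <- g$end; pe <- min(unname(seqlen[[g$scaffold]]), g$end + pw)
    }
    code <- if (promoter_class[i] == "LCG") 2L else 3L
    paint <- paint_iv(paint, g$scaffold, ps, pe, code)
  }
  for (i in seq_len(nrow(genes)))
    paint <- paint_iv(paint, genes$scaffold[i], genes$start[i],
                      genes$end[i], 4L)
  for (i in seq_len(nrow(exons))) {
    sc <- genes$scaffold[match(exons$gene_id[i], genes$gene_id)]
    paint <- paint_iv(paint, sc, exons$start[i], exons$end[i], 5L)
  }
  dm_body <- lapply(seqlen, function(len) rep(FALSE, len))
  for (i in which(genes$gene_id %in% dm_ids))
    dm_body[[genes$scaffold[i]]][
      (genes$start[i] + 1L):genes$end[i]] <- TRUE

  # Deamination with compositional repair: each CpG's C deaminates to T
  # with its class rate d; an equal number of T -> C back-mutations is then
  # applied per class, at T sites where the new C cannot form a CpG (next
  # base not G). Mononucleotide composition therefore stays at its
  # equilibrium -- as in real genomes, where substitution re-equilibrates
  # composition over evolutionary time -- and the expected class nCpG is
  # exactly (1 - d) times the undepleted value.
  seqs <- character(cfg$n_scaffolds)
  names(seqs) <- scaff_names
  for (sc in scaff_names) {
    b <- base_mat[[sc]]
    n <- length(b)
    cpos <- which(b[-n] == "C" & b[-1] == "G")  # 1-based C position
    if (length(cpos)) {
      d <- d_of_code[paint[[sc]][cpos]]
      hit <- runif(length(cpos)) < d
      extra <- !hit & dm_body[[sc]][cpos] &
        runif(length(cpos)) < cfg$dm_extra_depletion
      conv <- cpos[hit | extra]
      b[conv] <- "T"
      # repair pool: T sites (pre-existing, not freshly deaminated) whose
      # next base is not G, grouped by the same class stratification the
      # conversions used (region class, refined by DM-body membership)
      tpos <- setdiff(which(b == "T" & c(b[-1], "N") != "G"), conv)
      strat_of <- function(pos)
        paste0(paint[[sc]][pos], ifelse(dm_body[[sc]][pos], "d", ""))
      conv_strat <- strat_of(conv)
      pool_strat <- strat_of(tpos)
      for (st in unique(conv_strat)) {
        need <- sum(conv_strat == st)
        pool <- tpos[pool_strat == st]
        take <- min(need, length(pool))
        if (take > 0)
          b[pool[sample.int(length(pool), take)]] <- "C"
      }
    }
    seqs[[sc]] <- paste(b, collapse = "")
  }

  ## gene truth labels from the realized window states
  mw <- grid[meth, c("scaffold", "start", "end"), drop = FALSE]
  gene_meth <- GenomicRanges::countOverlaps(
    .as_granges0(genes), .as_granges0(mw)) > 0

  ## (5) repeats
  reps_l <- list()
  for (i in seq_len(nrow(genes))) {
    lam <- if (gene_meth[i]) cfg$repeats_per_methylated_gene else
      cfg$repeats_per_unmethylated_gene
    nr <- stats::rpois(1, lam)
    if (!nr) next
    g <- genes[i, ]
    for (k in seq_len(nr)) {
      off <- sample(1000L:10000L, 1L)
      rl <- sample(cfg$repeat_length[1]:cfg$repeat_length[2], 1L)
      if (g$strand == "+") {
        s <- g$start - off; e <- s + rl
      } else {
        e <- g$end + off; s <- e - rl
      }
      s <- max(0L, s); e <- min(unname(seqlen[[g$scaffold]]), e)
      if (e <= s) next
      reps_l[[length(reps_l) + 1L]] <- data.frame(
        scaffold = g$scaffold, start = as.integer(s), end = as.integer(e),
        category = sample(names(cfg$repeat_categories), 1L,
                          prob = cfg$repeat_categories),
        near_gene = g$gene_id, stringsAsFactors = FALSE)
    }
  }
  repeats <- if (length(reps_l)) do.call(rbind, reps_l) else
    cbind(.empty_repeats(), near_gene = character(0))
  rownames(repeats) <- NULL

  ## (6) true DM windows
  dm_flag <- rep(FALSE, nw)
  dm_dir <- rep(NA_character_, nw)
  gene_dir <- setNames(rep(NA_character_, nrow(genes)), genes$gene_id)
  swap_pool <- setdiff(fill, integer(0))
  for (gid in dm_ids) {
    gdir <- sample(c("female_hyper", "male_hyper"), 1L)
    gene_dir[gid] <- gdir
    body <- intersect(body_win_by_gene[[gid]], which(meth))
    if (!length(body)) next
    k <- sample(cfg$dm_windows_per_gene[1]:cfg$dm_windows_per_gene[2], 1L)
    pick <- body[sample.int(length(body), min(k, length(body)))]
    dm_flag[pick] <- TRUE
    dm_dir[pick] <- gdir
    if (length(pick) >= 2 && runif(1) < cfg$contrast_fraction)
      dm_dir[pick[1]] <- setdiff(c("female_hyper", "male_hyper"), gdir)

    # one upstream repeat window shares (or contradicts) the direction
    rup <- repeats[repeats$near_gene == gid, , drop = FALSE]
    if (nrow(rup)) {
      r <- rup[sample.int(nrow(rup), 1L), ]
      mid <- floor((r$start + r$end) / 2)
      widx <- which(grid$scaffold == r$scaffold & grid$start <= mid &
                      grid$end > mid)
      if (length(widx) == 1 && !desert[widx]) {
        if (!meth[widx]) {
          # keep the realized methylated fraction on target by swapping
          # one randomly filled window out
          spool <- setdiff(swap_pool, c(which(dm_flag), widx, forced))
          if (length(spool)) {
            drop1 <- spool[sample.int(length(spool), 1L)]
            meth[drop1] <- FALSE
            swap_pool <- setdiff(swap_pool, drop1)
          }
          meth[widx] <- TRUE
        }
        if (!dm_flag[widx]) {
          dm_flag[widx] <- TRUE
          dm_dir[widx] <- if (runif(1) < cfg$repeat_concordance) gdir else
            setdiff(c("female_hyper", "male_hyper"), gdir)
        }
      }
    }
  }

  # recompute gene methylation after swaps, then guard: forced windows
  # guarantee every non-designated gene stays methylated
  mw <- grid[meth, c("scaffold", "start", "end"), drop = FALSE]
  gene_meth <- GenomicRanges::countOverlaps(
    .as_granges0(genes), .as_granges0(mw)) > 0

  bundle <- genome_bundle(
    seqs, genes, exons,
    repeats[, c("scaffold", "start", "end", "category"), drop = FALSE])

  win_truth <- data.frame(
    window_id = grid$window_id, scaffold = grid$scaffold,
    start = grid$start, end = grid$end,
    methylated = meth, dm = dm_flag, direction = dm_dir,
    stringsAsFactors = FALSE)
  gene_truth <- data.frame(
    gene_id = genes$gene_id, promoter_class = promoter_class,
    designated_unmethylated = genes$gene_id %in% unmeth_ids,
    methylated = gene_meth,
    dm = genes$gene_id %in% dm_ids,
    direction = unname(gene_dir),
    stringsAsFactors = FALSE)

  truth <- list(windows = win_truth, genes = gene_truth,
                repeats = repeats,
                depletion = list(rates = cfg$depletion_rates,
                                 lcg = cfg$lcg_depletion,
                                 hcg = cfg$hcg_depletion,
                                 dm_extra = cfg$dm_extra_depletion),
                config = cfg)
  list(bundle = bundle, truth = truth)
}

# random exon structure: k exons with >= 100-bp exons and introns
.simulate_exons <- function(gid, start, end, k_range) {
  len <- end - start
  k_max <- max(1L, min(k_range[2], (len - 100L) %/% 200L))
  k <- if (k_max <= k_range[1]) k_max else
    sample(k_range[1]:k_max, 1L)
  n_seg <- 2L * k - 1L
  # random composition of len into n_seg parts of >= 100 bp
  extra <- len - 100L * n_seg
  cuts <- if (n_seg > 1) sort(sample.int(extra + 1L, n_seg - 1L,
                                         replace = TRUE) - 1L) else integer(0)
  parts <- diff(c(0L, cuts, extra)) + 100L
  bounds <- start + cumsum(c(0L, parts))
  idx <- seq(1L, n_seg, by = 2L)
  data.frame(gene_id = gid, start = bounds[idx], end = bounds[idx + 1L],
             stringsAsFactors = FALSE)
}

#' Apply CpG deamination to a single sequence
#'
#' The same depletion model the genome simulator uses, for one sequence:
#' each CpG's C converts to T with probability `d`; with `repair = TRUE`
#' an equal number of T sites whose next base is not G back-mutate to C,
#' keeping mononucleotide composition at equilibrium so that the expected
#' nCpG is exactly `(1 - d)` times the input's.
#'
#' @param seq uppercase nucleotide string.
#' @param d per-CpG deamination probability in `[0, 1]`.
#' @param repair keep base composition constant (default `TRUE`).
#' @return the depleted sequence string.
#' @export
deplete_cpg <- function(seq, d, repair = TRUE) {
  stopifnot(length(seq) == 1, d >= 0, d <= 1)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  if (n < 2 || d == 0) return(seq)
  cpos <- which(b[-n] == "C" & b[-1] == "G")
  if (!length(cpos)) return(seq)
  conv <- cpos[runif(length(cpos)) < d]
  b[conv] <- "T"
  if (repair && length(conv)) {
    pool <- setdiff(which(b == "T" & c(b[-1], "N") != "G"), conv)
    take <- min(length(conv), length(pool))
    if (take > 0)
      b[pool[sample.int(length(pool), take)]] <- "C"
  }
  paste(b, collapse = "")
}

#' Simulate MeDIP window counts from the truth ledger
#'
#' For every library, window weights are proportional to (methylation
#' state x CpG count in the window), renormalized to sum to one per
#' library; true DM windows multiply the weight of the hypermethylated
#' sex by the configured fold change. Counts are drawn
#' `NB(mean = library_size x weight, variance = mean + phi mean^2)`
#' (Poisson when `phi = 0`).
#'
#' @param bundle the simulated [genome_bundle()].
#' @param truth the matching truth ledger.
#' @param cfg the [sim_config()] used.
#' @return a `window_counts` object.
#' @export
simulate_medip_counts <- function(bundle, truth, cfg = truth$config) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.sub_seed(cfg$seed, 101L))

  wt <- truth$windows
  segs <- substring(bundle$seqs[wt$scaffold], wt$start + 1L, wt$end)
  cpg <- vapply(lapply(segs, .cg_counts), `[[`, integer(1), "cg")
  base_w <- ifelse(wt$methylated, as.numeric(cpg), 0)
  if (sum(base_w) <= 0)
    .stopf("no methylated windows: zero total weight")

  libs <- cfg$libraries
  counts <- matrix(0L, nrow(wt), nrow(libs))
  for (j in seq_len(nrow(libs))) {
    w <- base_w
    hyper <- !is.na(wt$direction) &
      wt$direction == paste0(libs$sex[j], "_hyper")
    w[hyper] <- w[hyper] * cfg$dm_fold_change
    w <- w / sum(w)
    mu <- libs$size[j] * w
    counts[, j] <- if (cfg$nb_dispersion <= 0)
      stats::rpois(length(mu), mu) else
      rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu)
  }
  grid <- truth$windows[, c("window_id", "scaffold", "start", "end")]
  class(grid) <- c("window_grid", "data.frame")
  window_counts(grid, counts,
                libs[, c("library_id", "sex"), drop = FALSE])
}

#' Write per-library fragment BED files realizing a count matrix
#'
#' Places `count` fragments of fixed length uniformly within each window
#' (fragments stay inside their window, so midpoint counting recovers the
#' matrix exactly).
#'
#' @param wc a `window_counts` object.
#' @param dir output directory.
#' @param fragment_length bp (must not exceed the window size).
#' @param seed integer seed.
#' @return named character vector of BED paths, one per library.
#' @export
simulate_fragment_beds <- function(wc, dir, fragment_length = 200L,
                                   seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.sub_seed(seed, 202L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (j in seq_len(ncol(wc$counts))) {
    n <- wc$counts[, j]
    idx <- rep.int(seq_along(n), n)
    slack <- pmax(0L, (wc$grid$end - wc$grid$start)[idx] - fragment_length)
    s <- wc$grid$start[idx] +
      floor(runif(length(idx)) * (slack + 1L))
    e <- pmin(s + fragment_length, wc$grid$end[idx])
    df <- data.frame(scaffold = wc$grid$scaffold[idx], start = s, end = e)
    df <- df[order(df$scaffold, df$start), ]
    path <- file.path(dir, paste0(wc$libraries$library_id[j], ".bed"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    out[wc$libraries$library_id[j]] <- path
  }
  out
}

#' Simulate gene expression labels with tunable DM association
#'
#' Assigns each gene `male_up`, `female_up` or `none`. With association
#' `a = 0` labels are independent of DM status; with `a = 1` a gene is DE
#' if and only if it is DM, with the class opposite to its methylation
#' direction (hypermethylation in one sex pairing with overexpression in
#' the other).
#'
#' @param truth a truth ledger from [simulate_genome()].
#' @param cfg the [sim_config()] used.
#' @return data.frame with `gene_id`, `de_class`.
#' @export
simulate_expression_labels <- function(truth, cfg = truth$config) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.sub_seed(cfg$seed, 303L))
  g <- truth$genes
  a <- cfg$expression_association
  base <- cfg$de_base_rate
  de_class <- character(nrow(g))
  opp <- c(female_hyper = "male_up", male_hyper = "female_up")
  for (i in seq_len(nrow(g))) {
    if (g$dm[i]) {
      p_de <- base + a * (1 - base)
      if (runif(1) < p_de) {
        dir <- g$direction[i]
        if (!is.na(dir) && runif(1) < 0.5 + a / 2) {
          de_class[i] <- opp[[dir]]
        } else {
          de_class[i] <- sample(c("male_up", "female_up"), 1L)
        }
      } else de_class[i] <- "none"
    } else {
      p_de <- base * (1 - a)
      de_class[i] <- if (runif(1) < p_de)
        sample(c("male_up", "female_up"), 1L) else "none"
    }
  }
  if (!any(de_class != "none"))
    .warnf("no DE genes simulated; association tests will be degenerate")
  data.frame(gene_id = g$gene_id, de_class = de_class,
             stringsAsFactors = FALSE)
}

#' Write an expression label table
#' @param expr data.frame with `gene_id`, `de_class`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
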