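# End-to-end pipeline: ncpg -> bimodality -> methylome -> diffmeth ->
# association, from files or from the built-in simulator, writing TSV
# tables, a machine-readable JSON summary and a parameter log.

.default_params <- function() list(
  window_size = 500L, rpkm_threshold = 1, q_cutoff = 0.05,
  promoter_bp = 3000L, downstream_bp = 1000L, upstream_bp = 50000L,
  ncpg_cap = 3, min_region_length = 50L,
  bimodality_B = 199L, bimodality_classes = c(
    "exon", "intron", "gene_body", "intergenic", "promoter_3000",
    "promoter_600", "promoter_300", "promoter_150"),
  resampling_B = 999L, proximity_distances = c(1000L, 5000L, 10000L),
  fragment_length = 200L, count_mode = "midpoint",
  realize_fragments = TRUE)

#' Run the full analysis pipeline
#'
#' Executes the five analysis stages on either user-supplied files or the
#' built-in simulator, writes per-stage TSV tables plus a machine-readable
#' `summary.json` and a `run.log` into `out_dir`, and returns the summary
#' invisibly. The whole run is a pure function of (inputs, config, seed):
#' re-running with the same configuration produces byte-identical
#' summaries.
#'
#' @param config a list, or the path to a YAML file, with entries:
#'   \describe{
#'     \item{mode}{`"simulate"` (default) or `"files"`.}
#'     \item{seed}{integer master seed.}
#'     \item{out_dir}{output directory.}
#'     \item{sim}{(simulate mode) named overrides for [sim_config()].}
#'     \item{inputs}{(files mode) list with `genome` (FASTA),
#'       `annotation` (GFF3), `repeats` (BED), `fragments` (list of
#'       `list(path, library_id, sex)`), optional `expression` (TSV) and
#'       `interest_genes` (one id per line).}
#'     \item{params}{named overrides for thresholds and sizes; see
#'       Details.}
#'   }
#' @details Default parameters: 500-bp windows, group-mean RPKM threshold
#'   1.0, q-cutoff 0.05, promoter 3000 bp, downstream 1000 bp, 50-kb
#'   upstream context span, nCpG cap 3, bootstrap B = 199 for bimodality,
#'   B = 999 for resampling/permutation tests, midpoint fragment counting.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- config$mode %||% "simulate"
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% .stopf("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- utils::modifyList(.default_params(), config$params %||% list())

  log_lines <- c("medipcpg pipeline run",
                 sprintf("mode: %s", mode), sprintf("seed: %d", seed),
                 "parameters:",
                 vapply(names(params), function(k)
                   sprintf("  %s: %s", k,
                           paste(params[[k]], collapse = ",")),
                   character(1)))
  fail <- function(stage, e)
    .stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))

  ## ---- inputs ----
  truth <- NULL
  interest <- NULL
  if (mode == "simulate") {
    cfg <- do.call(sim_config,
                   utils::modifyList(config$sim %||% list(),
                                     list(seed = seed)))
    sim <- tryCatch(simulate_genome(cfg), error = function(e)
      fail("simulate", e))
    bundle <- sim$bundle
    truth <- sim$truth
    wc_true <- tryCatch(simulate_medip_counts(bundle, truth, cfg),
                        error = function(e) fail("simulate", e))
    if (isTRUE(params$realize_fragments)) {
      beds <- simulate_fragment_beds(
        wc_true, file.path(out_dir, "fragments"),
        fragment_length = min(params$fragment_length, cfg$window_size),
        seed = seed)
      fragsets <- lapply(seq_along(beds), function(j)
        read_fragments(beds[j],
                       library_id = wc_true$libraries$library_id[j],
                       sex = wc_true$libraries$sex[j], format = "bed",
                       known_scaffolds = names(bundle$seqs)))
      wc <- count_fragments(window_grid(bundle, cfg$window_size),
                            fragsets, mode = params$count_mode)
    } else {
      wc <- wc_true
    }
    expr <- simulate_expression_labels(truth, cfg)
  } else {
    inp <- config$inputs %||% list()
    if (is.null(inp$genome)) .stopf("missing input: genome")
    if (is.null(inp$annotation)) .stopf("missing input: annotation")
    seqs <- tryCatch(read_genome(inp$genome),
                     error = function(e) fail("io", e))
    ann <- tryCatch(read_gff3(inp$annotation),
                    error = function(e) fail("io", e))
    repeats <- if (!is.null(inp$repeats))
      read_repeats_bed(inp$repeats) else .empty_repeats()
    bundle <- genome_bundle(seqs, ann$genes, ann$exons, repeats)
    if (is.null(inp$fragments) || !length(inp$fragments))
      .stopf("missing input: fragments")
    fragsets <- lapply(inp$fragments, function(f)
      read_fragments(f$path, library_id = f$library_id, sex = f$sex,
                     fragment_length = params$fragment_length,
                     known_scaffolds = names(bundle$seqs)))
    wc <- count_fragments(window_grid(bundle, params$window_size),
                          fragsets, mode = params$count_mode)
    expr <- if (!is.null(inp$expression))
      read_expression_table(inp$expression) else NULL
    if (!is.null(inp$interest_genes))
      interest <- readLines(inp$interest_genes)
  }

  ## ---- ncpg stage ----
  tab <- tryCatch(
    ncpg_table(bundle, min_length = params$min_region_length),
    error = function(e) fail("ncpg", e))
  write.table(tab, file.path(out_dir, "ncpg.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ncpg_summary <- lapply(split(tab[tab$usable, ], tab$class[tab$usable]),
    function(d) list(n = nrow(d), mean = mean(d$ncpg),
                     median = median(d$ncpg)))

  ## ---- bimodality stage ----
  bim <- list()
  bim_rows <- list()
  for (cl in params$bimodality_classes) {
    v <- ncpg_values(tab, cl, cap = params$ncpg_cap)
    if (length(v) < 20) next
    bt <- tryCatch(
      lrt_bimodality(v, B = params$bimodality_B,
                     seed = .sub_seed(seed, 11L + match(
                       cl, params$bimodality_classes))),
      error = function(e) fail("bimodality", e))
    bim[[cl]] <- list(n = length(v), lrt_stat = bt$lrt_stat,
                      p_value = bt$p_value, chosen_G = bt$chosen_G,
                      peaks = bt$peaks, modes = bt$modes)
    bim_rows[[cl]] <- data.frame(
      class = cl, n = length(v),
      g1_mean = bt$fit1$means, g1_sd = bt$fit1$sds,
      g2_mean1 = bt$fit2$means[1], g2_mean2 = bt$fit2$means[2],
      g2_sd1 = bt$fit2$sds[1], g2_sd2 = bt$fit2$sds[2],
      g2_w1 = bt$fit2$weights[1],
      lrt_stat = bt$lrt_stat, p_value = bt$p_value,
      chosen_G = bt$chosen_G,
      peaks = paste(sprintf("%.4f", bt$peaks), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(bim_rows))
    write.table(do.call(rbind, bim_rows),
                file.path(out_dir, "bimodality.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  ## ---- methylome stage ----
  calls <- tryCatch(
    call_methylated(wc, bundle, threshold = params$rpkm_threshold),
    error = function(e) fail("methylome", e))
  fr <- methylome_fractions(calls, bundle)
  ctx <- classify_context(calls, bundle, upstream_bp = params$upstream_bp)
  write.table(calls$windows, file.path(out_dir, "windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(calls$genes, file.path(out_dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- diffmeth stage ----
  dm <- tryCatch(
    diffmeth_windows(wc, calls, q_cutoff = params$q_cutoff),
    error = function(e) fail("diffmeth", e))
  merged <- merge_dm_windows(dm)
  gsum <- summarize_genes(dm, bundle, promoter_bp = params$promoter_bp,
                          downstream_bp = params$downstream_bp)
  write.table(dm$windows, file.path(out_dir, "dm_windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(merged, file.path(out_dir, "dm_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gsum$genes, file.path(out_dir, "dm_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- association stage ----
  assoc <- tryCatch({
    body_tab <- tab[tab$class == "gene_body" & tab$usable, ]
    body_ncpg <- setNames(body_tab$ncpg,
                          sub(":body$", "", body_tab$region_id))
    meth_ids <- calls$genes$gene_id[calls$genes$methylated]
    dm_ids <- gsum$genes$gene_id[gsum$genes$dm]
    dm_ids <- intersect(dm_ids, meth_ids)
    meth_ncpg <- body_ncpg[intersect(meth_ids, names(body_ncpg))]
    dm_ncpg <- body_ncpg[intersect(dm_ids, names(body_ncpg))]

    depl <- if (length(dm_ncpg))
      ncpg_depletion_test(dm_ncpg, meth_ncpg, B = params$resampling_B,
                          seed = .sub_seed(seed, 31L)) else NULL
    ks <- if (length(meth_ncpg))
      ks_compare(body_ncpg, meth_ncpg) else NULL

    prox <- perm <- NULL
    if (nrow(bundle$repeats)) {
      prox <- repeat_proximity(bundle, calls, dm, gsum,
                               distances = params$proximity_distances,
                               interest_genes = interest)
      dmax <- as.character(max(params$proximity_distances))
      perm <- proximity_permutation_test(
        calls$genes$methylated, prox$indicator[, dmax],
        B = params$resampling_B, seed = .sub_seed(seed, 37L))
      write.table(prox$table, file.path(out_dir, "proximity.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(prox$concordance) && nrow(prox$concordance))
        write.table(prox$concordance,
                    file.path(out_dir, "concordance.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    fish <- abund <- NULL
    if (!is.null(expr) && nrow(expr)) {
      gt <- data.frame(gene_id = gsum$genes$gene_id, dm = gsum$genes$dm,
                       stringsAsFactors = FALSE)
      gt$de_class <- expr$de_class[match(gt$gene_id, expr$gene_id)]
      gt$de_class[is.na(gt$de_class)] <- "none"
      fish <- methylation_expression_fisher(gt)
      if (nrow(bundle$repeats)) {
        mwin <- calls$windows[calls$windows$methylated,
                              c("scaffold", "start", "end")]
        de_g <- bundle$genes[bundle$genes$gene_id %in%
                               gt$gene_id[gt$de_class != "none"], ,
                             drop = FALSE]
        tss <- gene_tss(de_g)
        plus <- de_g$strand == "+"
        de_up <- data.frame(
          scaffold = de_g$scaffold,
          start = ifelse(plus, pmax(0, tss - 5000L), tss),
          end = ifelse(plus, tss,
                       pmin(unname(bundle$seqlen[de_g$scaffold]),
                            tss + 5000L)))
        ab_g <- repeat_abundance(bundle)
        ab_m <- repeat_abundance(bundle, within = mwin)
        ab_t <- repeat_abundance(bundle, within = de_up)
        if (length(ab_g) >= 3)
          abund <- repeat_abundance_stats(ab_g, ab_m, ab_t)
      }
    }
    list(depletion = depl, ks = ks, proximity = prox, permutation = perm,
         fisher = fish, abundance = abund)
  }, error = function(e) fail("association", e))

  ## ---- summary ----
  summary <- list(
    seed = seed, mode = mode, parameters = params,
    ncpg = ncpg_summary,
    bimodality = bim,
    methylome = list(
      genome_fraction = fr$genome_fraction,
      cpg_fraction = fr$cpg_fraction,
      n_methylated_windows = fr$n_methylated_windows,
      n_methylated_genes = fr$n_methylated_genes,
      context_proportions = as.list(ctx$proportions),
      upstream_in_gene_fraction = ctx$upstream_in_gene_fraction),
    diffmeth = list(
      phi = dm$phi, n_tested = dm$n_tested,
      n_significant = sum(dm$windows$significant),
      n_female_hyper = sum(dm$windows$direction == "female_hyper"),
      n_male_hyper = sum(dm$windows$direction == "male_hyper"),
      n_merged_regions = nrow(merged),
      n_dm_genes = sum(gsum$genes$dm),
      n_contrasting_genes = sum(gsum$genes$contrasting)),
    association = list(
      depletion_p = if (!is.null(assoc$depletion))
        assoc$depletion$p_value else NULL,
      depletion_observed = if (!is.null(assoc$depletion))
        assoc$depletion$observed else NULL,
      depletion_null_mean = if (!is.null(assoc$depletion))
        assoc$depletion$null_mean else NULL,
      ks_D = if (!is.null(assoc$ks)) assoc$ks$D else NULL,
      ks_p = if (!is.null(assoc$ks)) assoc$ks$p_value else NULL,
      proximity_permutation_p = if (!is.null(assoc$permutation))
        assoc$permutation$p_value else NULL,
      fisher_p = if (!is.null(assoc$fisher))
        assoc$fisher$p_value else NULL,
      fisher_odds_ratio = if (!is.null(assoc$fisher))
        assoc$fisher$odds_ratio else NULL)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
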