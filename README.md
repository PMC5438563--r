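# medipcpg

Window-based MeDIP-seq methylome analysis and normalized CpG content
statistics for non-model vertebrate genomes.

## The problem

DNA methylation leaves two complementary records in a genome. Current
methylation can be measured by MeDIP-seq (methylated-DNA
immunoprecipitation sequencing), whose read density over ~500-bp windows
reflects regional methylation. Historic methylation leaves a sequence
footprint: methylated CpGs deaminate to TpG over evolutionary time, so
long-methylated regions are CpG depleted. The normalized CpG content of
a region of length *l* with *c* cytosines, *g* guanines and *cg* CpG
dinucleotides,

    nCpG = (cg/l) / ((c/l) (g/l)),

is 1 under random expectation and below 1 where methylation has eroded
CpGs. `medipcpg` is for researchers who want to connect the two records
in a genome with only an assembly, a GFF3 annotation, repeat intervals
and a handful of MeDIP libraries — e.g. comparing male and female
gonadal methylomes in a species with temperature-dependent sex
determination — and who need every statistic auditable and testable on
synthetic data with known truth.

## What it implements

- per-region nCpG (exons, introns, gene bodies, promoters of
  3000/600/300/150 bp, intergenic blocks), with Gaussian-mixture fits
  (G = 1 vs G = 2, free variances) and a parametric-bootstrap
  likelihood-ratio test for bimodality — the low-CpG/high-CpG promoter
  class structure;
- 500-bp window quantification of MeDIP fragments in RPKM, methylation
  calls at a fixed group-mean threshold, genome/CpG fraction summaries
  and genomic-context partition (gene body > 50-kb upstream >
  intergenic);
- sex-differential methylation per window under a negative-binomial
  model (conditional exact test at a pooled common dispersion,
  Benjamini–Hochberg FDR, merging of book-ended significant windows,
  gene-level summaries with contrasting-direction flags);
- resampling and permutation statistics: CpG depletion of
  differentially methylated genes, methylated-repeat proximity and
  direction concordance, methylation × expression Fisher test,
  Kruskal–Wallis and OLS comparisons of repeat abundances;
- a synthetic-genome simulator (`sim_config()`, `simulate_genome()`,
  `simulate_medip_counts()`, `simulate_expression_labels()`) with a
  ground-truth ledger that drives the package's recovery and
  calibration tests;
- `run_pipeline()` and a thin `exec/medipcpg` command-line wrapper that
  execute everything from a YAML config and write TSV tables plus a
  machine-readable JSON summary, byte-identical under a fixed seed.

## Worked example

Simulate the default scenario (2 × 1 Mb genome, 200 genes, 57% of
windows methylated, 2 + 2 MeDIP libraries) and run the core analyses:

```r
library(medipcpg)

cfg  <- sim_config(seed = 1)
sim  <- simulate_genome(cfg)
sim$bundle
#> genome_bundle: 2 scaffold(s), 2,000,000 bp, 200 gene(s), 485 repeat(s)

wc    <- simulate_medip_counts(sim$bundle, sim$truth, cfg)
calls <- call_methylated(wc, sim$bundle)
calls
#> methylation_calls: 2272/4000 windows methylated (threshold 1.00 RPKM)
#>   164/200 genes methylated

tab <- ncpg_table(sim$bundle)
lrt_bimodality(ncpg_values(tab, "promoter_600"), B = 199, seed = 1)
#> Bimodality LRT (G=1 vs G=2), bootstrap
#>   lrt = 143.835, p = 0.005, chosen G = 2
#>   peaks (component means): 0.237, 0.787

dm <- diffmeth_windows(wc, calls)
dm
#> diffmeth_result: 2272 windows tested (phi = 0.09881), 84 significant at q < 0.05
#>   female-hyper 43, male-hyper 41

gs   <- summarize_genes(dm, sim$bundle)
body <- tab[tab$class == "gene_body" & tab$usable, ]
ncpg <- setNames(body$ncpg, sub(":body$", "", body$region_id))
meth <- intersect(calls$genes$gene_id[calls$genes$methylated], names(ncpg))
dmg  <- intersect(gs$genes$gene_id[gs$genes$dm], meth)
ncpg_depletion_test(ncpg[dmg], ncpg[meth], B = 999, seed = 1)
#> resampling/permutation test (lower tail): observed 0.2720, null 0.2963 +/- 0.0057, p = 0.001 (B = 999)
```

Reading the output: 57% of windows exceed the 1-RPKM call threshold
(the simulated landscape), promoter nCpG is decisively bimodal with a
low-CpG mode at 0.24 and a high-CpG mode at 0.79, 84 windows differ
between the sexes at q < 0.05 with both directions represented, and the
differentially methylated genes are more CpG depleted (mean nCpG 0.272)
than random subsets of methylated genes (0.296 ± 0.006) — the signature
of higher historic methylation, at the resampling floor p = 0.001.

The same run end-to-end, writing all tables and a summary:

```r
run_pipeline(list(mode = "simulate", seed = 1, out_dir = "run1"))
```

or from the shell: `exec/medipcpg run-all --seed 1 --out-dir run1`.

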