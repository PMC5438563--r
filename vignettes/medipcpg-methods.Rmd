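---
title: "Methods: linking historic and current DNA methylation with medipcpg"
author: "medipcpg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking historic and current DNA methylation with medipcpg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipcpg)
```

## The analysis in one paragraph

Methylated cytosines in CpG dinucleotides deaminate to thymine over
evolutionary time, so genomic regions with a long history of methylation
are depleted of CpGs. The normalized CpG content (CpG observed/expected)
is therefore a sequence-only proxy for *historic* methylation, while
MeDIP-seq (methylated-DNA immunoprecipitation sequencing) measures
*current* methylation as read density at a resolution of a few hundred
base pairs. `medipcpg` implements both sides and the statistics that
connect them: per-region nCpG with a mixture-model bimodality test,
500-bp window quantification of MeDIP fragments with methylation calls,
a negative-binomial exact test for sex-differential methylation with FDR
control, and resampling/permutation tests for CpG depletion of
differentially methylated genes, for clustering of methylated repeats
near methylated genes, and for methylation-by-expression association. A
synthetic-genome generator with a complete ground-truth ledger makes the
whole pipeline testable end to end.

## Normalized CpG content

For a region of length $l$ with $c$ cytosines, $g$ guanines and $cg$
CpG dinucleotides (overlapping scan, forward strand — CpG is its own
reverse complement as a motif),

$$\mathrm{nCpG} = \frac{cg/l}{(c/l)\,(g/l)}.$$

A value of 1 means CpGs occur at the rate expected from base
composition; values below 1 indicate depletion, the footprint of
historic methylation. The ratio is undefined when $c=0$ or $g=0$; such
records are kept but flagged and excluded from distribution summaries,
as are regions shorter than 50 bp, where the ratio is numerically
unstable. Values are capped at 3.0 before mixture fitting: animal
genomes show an empirical upper limit between 2 and 2.5, so larger
values are treated as outliers of tiny denominators.

Region classes are extracted from the annotation with one coordinate
convention (0-based half-open internally; GFF3 and BED converted at the
boundary): per-gene concatenated exons and introns (one record per gene
per class, so tiny individual exons do not inflate the noise; counting
is per interval and summed, so no artificial CpG is created at
junctions), gene bodies, promoters of 3000/600/300/150 bp strand-upstream
of the TSS (truncated at scaffold edges), and intergenic blocks (the
per-scaffold complement of gene bodies, one record per contiguous
block). The TSS is the strand-aware 5' edge of the gene span; annotations
without CDS features make a start-codon anchor impractical, and the
proximity analyses accept any anchor through their interval arguments.

## Bimodality of the nCpG distribution

Vertebrate promoters typically split into a low-CpG (heavily
historically methylated) and a high-CpG class, producing a bimodal nCpG
distribution. We fit one- and two-component Gaussian mixtures with free
component variances by EM (5 k-means++-style restarts, relative
log-likelihood tolerance $10^{-8}$, at most 1000 iterations, standard
deviations floored at $10^{-4}$ times the data range) and compare them
with the likelihood-ratio statistic $\Lambda = 2(\ell_2 - \ell_1)$.

Because the one-component model lies on the boundary of the
two-component parameter space, $\Lambda$ has no clean asymptotic
chi-square reference. The default p-value is therefore a parametric
bootstrap: simulate $B = 199$ datasets from the fitted one-component
model, refit both models on each (2 restarts per refit — the statistic
is a maximum over restarts, so fewer restarts in the null fits make the
test, if anything, slightly conservative), and report
$p = (1 + \#\{\Lambda_b \ge \Lambda\})/(B+1)$. A `chi2` option with 3
degrees of freedom is provided for quick screening and labelled
approximate. Both the component means and the density modes of the
winning model are reported, since the two differ when components
overlap.

## Methylome construction

Aligned MeDIP fragments (SAM or BED; proper pairs collapsed to their
outer span, single-end reads extended to a configurable 200-bp fragment
length consistent with typical MeDIP size selection) are counted into a
fixed 500-bp tiling of the genome. The default assignment is by fragment
midpoint, with boundary ties going to the left window, which conserves
library totals exactly; an overlap mode (one count per overlapped
window) exists and is flagged because totals then exceed fragment
counts. Terminal partial windows are kept with their true length.

Window signal is RPKM,
$\mathrm{count} / \big((\mathrm{len}/10^3)(\mathrm{total}/10^6)\big)$,
and a window is called methylated within a group when its group-mean
RPKM reaches a threshold (default 1.0). The threshold is a first-class
parameter, deliberately fixed and documented rather than hidden inside
an enrichment model, so calls are auditable; raising it can only shrink
the methylome (a monotonicity the tests assert). A gene is methylated
when at least one methylated window intersects its span. Methylated
windows are partitioned by context with precedence gene body >
50-kb-upstream > intergenic (intragenic methylation is the primary unit,
and the precedence makes the three proportions sum to one); the
pre-precedence fraction of upstream windows lying inside another gene's
body is reported separately.

## Differential methylation between sexes

Counts are normalized to the geometric-mean library depth. A common
negative-binomial dispersion $\varphi$
($\mathrm{var} = \mu + \varphi\mu^2$) is estimated by pooling
within-group moments across windows: with only two replicates per group,
per-window moment estimates are individually so noisy that their median
is badly biased (the median of a scaled $\chi^2_2$ variance estimate
sits at $\ln 2 \approx 0.69$ of its mean), so instead we sum
$\widehat{\mathrm{var}} - \widehat{\mu}$ over windows with normalized
mean at least 5 and divide by $\sum \widehat{\mu}^2$, which is unbiased
up to a small second-order term and recovers a generative
$\varphi = 0.1$ within a few percent on $10^4$ windows.

Each window methylated in at least one group is tested with a
conditional NB exact test: given the total $T$ of the two normalized
group sums, every split $(k, T-k)$ receives probability proportional to
$\mathrm{NB}(k;\, \mu_A, n_A/\varphi)\,\mathrm{NB}(T-k;\, \mu_B,
n_B/\varphi)$ under equal per-library means (a sum of $n$ NB variables
with common $\varphi$ is NB with size $n/\varphi$), and the two-sided
p-value sums the probabilities of splits no more probable than the
observed one. The test matches full enumeration to $10^{-12}$ by
construction and gives $p = 1$ for balanced splits. Benjamini–Hochberg
adjustment over the tested windows yields q-values; windows with
$q < 0.05$ are significant, with direction from the sign of
$\log_2\big((\bar{x}_F + 0.5)/(\bar{x}_M + 0.5)\big)$ (positive =
female-hypermethylated; the 0.5 pseudocount keeps the fold change finite
at sparse windows). Book-ended significant windows of the same direction
merge into regions carrying the minimum q and the length-weighted mean
logFC. A gene is differentially methylated when a significant window
intersects its body or promoter (minimum window q serves as the gene's
q; a gene-level test is not attempted), and genes carrying windows of
both directions are flagged as contrasting.

**A power ceiling worth knowing about.** With two replicates per group,
the biological dispersion bounds detectability no matter how deep the
libraries are: for a fold change $f$ the conditional z-statistic
saturates at $2(f-1)/\big((f+1)\sqrt{\varphi}\big)$ as depth grows —
about 3.8 for $f = 4$ at $\varphi = 0.1$. After BH correction over a few
thousand windows this yields roughly 70% sensitivity, not more, and the
realized statistic inherits additional spread from the same biological
noise. This is a property of two-replicate NB designs generally, not of
the exact test; the package's false-discovery control is unaffected
(observed FDR stays near 0.03 at $q < 0.05$).

## Association statistics

- **CpG depletion of DM genes.** The observed statistic is the mean
  nCpG of differentially methylated genes; the null is built by drawing
  $B = 999$ random subsets of the same size from all methylated genes,
  without replacement, with a one-sided lower-tail empirical p-value
  (the scientific claim is directional — DM genes are *more* depleted; a
  two-sided switch exists).
- **Distribution comparisons** use the two-sample Kolmogorov–Smirnov
  test.
- **Repeat proximity.** A repeat is methylated when it intersects a
  methylated window. For each gene set and each distance (1, 5, 10 kb,
  strand-aware upstream of the TSS), the fraction of genes with at
  least one proximal methylated repeat is tabulated and compared with
  the non-methylated gene set by a 2×2 chi-square test (no Yates
  correction by default); a label-shuffling permutation test (two-sided,
  $B = 999$) gives an exact-style p-value for the difference in
  proportions. Direction concordance is the fraction of differentially
  methylated repeat windows upstream of DM genes that share the gene's
  dominant direction.
- **Methylation × expression** is a two-sided Fisher exact test on the
  2×2 table of differentially expressed (or not) by differentially
  methylated (or not) genes; a zero margin returns $p = 1$ with a flag.
- **Repeat abundances** (fraction of assembly bases per category, with a
  count mode) in genome, methylome and transcriptome proxies are
  compared by pairwise Kruskal–Wallis tests and by OLS regressions of
  transcriptome abundance on genome and methylome abundance, singly and
  jointly.

All empirical p-values obey $p = (1 + \text{exceedances})/(B+1)$ and its
floor $1/(B+1)$, and all are bit-reproducible under a fixed seed.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the package's reference scenario, chosen
once as a desk-scale emulation of a hatchling-gonad MeDIP study in a
vertebrate with temperature-dependent sex determination:

- **Genome**: 2 scaffolds × 1 Mb of i.i.d. sequence at GC 0.42
  (turtle-like), 200 non-overlapping genes of 2–5 kb with 2–8 exons and
  1–8-kb gaps (at 2 Mb the gaps must be this small for 200 genes to
  fit).
- **Historic methylation** is imprinted by deamination with
  compositional repair: each CpG's C converts to T with a class rate
  $d$, and an equal number of T sites whose successor is not G
  back-mutate to C within the same class. Plain C→T conversion alone
  would also deplete the mononucleotide C count and inflate the ratio by
  $1/(1 - d\,p_G)$ (+17% at $d = 0.75$, GC 0.42); the repair models the
  compositional re-equilibration real genomes undergo and makes the
  class expectation exactly $(1-d)\times$ the undepleted nCpG, which is
  what the recovery tests assert. Rates: exons 0.65, introns and
  intergenic 0.75 (centering exon nCpG at 0.35 and the rest at 0.25, the
  regional contrast typical of a heavily methylated vertebrate genome),
  and promoters drawn per gene from a 60/40 mixture of a low-CpG class
  ($d = 0.75$) and a high-CpG class ($d = 0.2$), forcing promoter
  bimodality with the low-CpG class more abundant.
- **Current methylation** is a fixed landscape over the 500-bp grid
  targeting 57% of windows methylated. Ten percent of genes are
  designated non-methylated — enough genes at this scale for the
  two-class proximity statistics to be estimable — and methylation is
  regional: no methylated window may touch their bodies (±2 kb) or
  their 10-kb upstream neighborhoods, so repeats there stay
  unmethylated too. Every other gene is guaranteed one methylated body
  window; remaining windows are drawn to hit the global target exactly.
  Gene-level truth labels are then *derived* from the realized window
  landscape with the same intersection rule the pipeline uses.
- **Libraries**: two sexes × two replicates with unequal sizes
  (48–56 k fragments), window weights proportional to methylation ×
  CpG count (MeDIP pulls down methylated CpGs), renormalized per
  library; counts are NB with $\varphi = 0.1$
  ($\mathrm{var} = \mu + \varphi\mu^2$; Poisson at $\varphi = 0$). The
  sizes give a mean methylated-window depth a little above 20
  fragments. 30 DM genes carry 2–5 true DM windows each at 4-fold
  change in a random direction (20% of them with one opposite-direction
  window, creating contrasting genes), and one upstream repeat window
  per DM gene becomes DM with the gene's direction with probability
  0.75 — the direction-concordance signal.
- **Repeats** (CR1/HAT-dominated categories) are placed 1–10 kb
  upstream of methylated genes at Poisson mean 3 versus 0.3 for
  non-methylated genes.
- **Expression labels** (male-up / female-up / none) have a tunable
  association dial: 0 is full independence (the null for calibration),
  1 makes a gene differentially expressed iff it is DM with the class
  opposite to its methylation direction.

Not emulated: realistic sequence evolution, CpG islands, isoforms, the
CpG-density (coupling) bias of MeDIP enrichment, mappability, duplicate
reads and sequencing error. Passing the recovery tests therefore shows
the statistics are correct and calibrated under an NB world with a
known landscape — not that the fixed RPKM threshold or window size are
optimal for any particular real genome.

## Numerical choices and degenerate inputs

EM on identical values or fewer than 10 points errors out rather than
returning a singular fit. Empirical p-values can never be 0 (the +1
rule). The exact test rounds normalized sums to integer pseudo-counts
and treats probability ties with a $1+10^{-7}$ relative tolerance, as
Fisher-test implementations do; a zero total returns $p = 1$ with a
flag. Dispersion estimation floors at $10^{-4}$ and requires two
replicates per group. Fragment midpoints exactly on a window boundary
go left; promoters are truncated (not dropped) at scaffold edges;
undefined nCpG propagates as `NA` and is excluded from fitting input.
The pipeline is a pure function of (inputs, config, seed): rerunning
with the same seed produces byte-identical summaries.

## Problem sizes used by the test suite

Unit tests run on a scaled-down scenario (1 × 200 kb, 40 genes);
recovery and calibration checks use the full default scenario (2 × 1 Mb)
over 10 seeds, 200-seed calibration loops for the empirical-p uniformity
checks, a 10,000-window null simulation for type-I error, full
enumeration up to totals of 200 for the exact test, and 50 + 100 seeds
for bimodality power and size. These sizes keep the whole suite in the
ten-minute range on one CPU while leaving each check with useful
resolution.
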