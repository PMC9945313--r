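---
title: "Statistical methods for paired pre/post probiotic microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for paired pre/post probiotic microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volemicrobiome)
```

## The study design this package serves

The package implements the statistical machinery for a paired probiotic
intervention study in a small rodent cohort: each animal contributes a
pre-treatment and a post-treatment stool sample, animals are crossed by sex
(F/M) and treatment arm (live probiotic vs. a heat-killed, "HK", control
preparation), with 8 animals per sex-by-treatment cell by default. The
defining statistical obstacle in such cohorts is very large inter-individual
variation in microbiome composition: group-mean methods drown true
treatment responses in between-animal noise, which is why the centerpiece
here is a *per-animal* paired selection procedure rather than a group test
alone.

## Normalization

Sequencing depth differs per sample, so raw counts are divided by
median-of-ratios size factors: reference taxa are those with nonzero counts
in every sample, each taxon gets a geometric-mean pseudo-sample across
samples, and a sample's factor is the median ratio of its counts to that
reference. Size factors are computed **once on the full table** and the
normalized table is then subset into groups, not recomputed per subset —
this matches the order of operations the procedure was designed around.
When no taxon is ubiquitous the code falls back to a +0.5 pseudo-reference
on all counts and says so; the classical estimator is simply undefined on
such sparse tables and the fallback is the standard remedy.

## The vole-by-vole (VBV) selection procedure

For every animal with both timepoints, the per-taxon paired log2 fold
change is

$$ l_{a,i} = \log_2\frac{\mathrm{post}_{a,i} + c}{\mathrm{pre}_{a,i} + c} $$

on normalized counts, with pseudocount $c = 0.5$ (the source procedure
never states its zero handling; $c$ is a logged, configurable knob). A
taxon is selected in a sex-by-treatment cell when

1. at least 5 of the 8 animals individually satisfy $l \ge 0.693$
   (a supermajority, rescaled as $\lceil 5n/8 \rceil$ for other group
   sizes), **in the same direction**, and
2. the mean of $l$ over **all** animals in the cell is $\ge 1.25$,

mirrored for decreases. Animals crossing the individual threshold in the
direction opposite the group mean do not count toward the supermajority.
The per-animal threshold is kept at the printed value 0.693 (numerically
$\ln 2$, almost surely a natural-log slip for "2-fold", but fidelity to the
printed rule wins; set `theta_ind = 1` for a strict 2-fold rule).
Family-level reporting applies a stricter group-average threshold of 1.8.
Selected taxa carry an abundance-quartile annotation computed from mean
raw pre-treatment counts (quartile 4 = most abundant).

The whole-group companion test is a deliberately simplified per-taxon
negative-binomial Wald test: moment-based dispersion shrunk halfway toward
a fitted mean-dispersion trend, delta-method standard error on the log2
ratio of group means, t reference distribution with $n_1 + n_2 - 2$ df,
Benjamini-Hochberg adjustment, and a passing rule of padj < 0.1 **and**
|log2fc| ≥ 0.693. It is *not* a reimplementation of any specific
differential-abundance tool's empirical-Bayes machinery; its contract is
calibration (empty passing sets on null cohorts) and power (recovery of
strong planted effects), both of which are tested directly.

## Diversity

Alpha diversity: bias-corrected Chao1
($S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$, safe at $F_2 = 0$), Shannon
effective number of species $\exp(H)$, and inverse Simpson $1/\sum p_i^2$.
Beta diversity: Bray-Curtis, unweighted UniFrac (fraction of branch length
unique to one community), and weighted UniFrac, normalized by default by
$\sum_b \ell_b (A_b + B_b)$ so it lives on [0, 1]. Trees are used as
rooted as parsed; no midpoint re-rooting is performed.

PERMANOVA is single-factor, computed from the stated sums-of-squares
decomposition with free label permutation and the $(1 + \#\{F^* \ge
F\})/(1 + n_{perm})$ p-value convention (999 permutations by default, seed
mandatory). Paired pre/post structure is *not* used to restrict
permutations — a documented simplification. Dispersion homogeneity
(betadisper-style) embeds samples by PCoA, keeps negative-eigenvalue axes
as imaginary components (their squared distances subtract), measures
distance to group **centroids** (not spatial medians, for testability),
and permutes labels for significance.

A degenerate but real corner: when every taxon is present in every sample
— common in small synthetic communities at realistic depths — unweighted
UniFrac is identically zero and PERMANOVA on it is undefined; the
functions return `NA` with a warning rather than fabricating a statistic.

## Rank tests and the effect size r

Mann-Whitney U is reported under the min convention with the effect size

$$ r = \frac{|n_1 n_2 / 2 - U - 0.5|}{\sigma_U \sqrt{n_1 + n_2}},
   \qquad \sigma_U = \sqrt{n_1 n_2 (n_1 + n_2 + 1)/12}. $$

This continuity-corrected $|Z|/\sqrt{N}$ convention was chosen because it
reproduces the published (U, n, r) triples exactly — (0, 8, 8) → 0.83,
(28, 8, 8) → 0.09, (121, 16, 16) → 0.04, (68, 16, 16) → 0.40, and four
more — which neither the uncorrected Z nor the rank-biserial convention
does. One published triple (U = 10.5 → r = 0.56) involves tied ranks and
is excluded from exact checks. Exact p-values come from the exact U
distribution (n ≤ 20, no ties); the Wilcoxon signed-rank test is exact for
n ≤ 25 by the signed-rank null distribution. The normal approximation and
the exact p agree within 0.02 for $n_1 = n_2 = 8$ everywhere except the
two central U values, where capping the two-sided exact p at 1 opens a gap
of up to 0.04 — an inherent property, documented in the tests.

## qPCR quantification

Relative quantification is delta-delta-Ct with a universal 16S reference
assay: $\Delta Ct = Ct_{target} - Ct_{ref}$ per (animal, timepoint),
$\Delta\Delta Ct = \Delta Ct_{post} - \Delta Ct_{pre}$, fold change
$= 2^{-\Delta\Delta Ct}$. The orientation (a *drop* in dCt is a fold
*increase*) is the one that makes live-treatment enrichment come out as a
positive fold change. Group summaries are **arithmetic** means of
per-animal fold changes — the procedure's own convention, kept despite the
geometric mean being more usual for ratios.

## Gated correlations

Taxon-phenotype association uses Spearman's rho (Pearson on mid-ranks,
pairwise-complete deletion) between each phenotype and two per-taxon
features: post-treatment normalized abundance and paired log2fc. Taxa are
prevalence-filtered first (nonzero in ≥ 10% of samples). Confidence
intervals are Bonett-Wright: Fisher transform with
$SE = \sqrt{(1 + \rho^2/2)/(n - 3)}$, at the 0.95 and 0.99 levels.

The community gate is the central interpretive decision of this module:
a phenotype is declared community-associated only when the *fraction* of
taxa whose CI excludes zero exceeds the level's alpha (0.05 at 0.95; 0.01
at 0.99) — i.e. more taxa correlate than chance alone would flag. When
the gate fails, individual flags are rejected wholesale. The source
wording ("a percentage … proportionate to the confidence interval alpha")
cannot be pinned down exactly; this operationalization is isolated behind
`community_gate()` so alternatives can be swapped. Perfect correlations
(|rho| = 1, outside the Fisher transform's domain) are treated as point
intervals and flagged.

## Behavioral composites and ANOVA

The anxiety composite averages the per-animal z-scores of percent open-arm
time (elevated plus maze) and center duration (open field). Two-way ANOVA
(sex × treatment) uses Type II sums of squares (the original analysis tool
does not state its type; Type II is the defensible default for unbalanced
data and equals the sequential decomposition when balanced). The
Student-Newman-Keuls post hoc uses stepwise studentized-range comparisons
on ordered means with containment blocking, reporting compact letter
displays; letter assignment is invariant to group input order.

## The synthetic cohort generator

The generator is first-class, tested code — the stated world every
downstream stage is exercised against:

* a log-normal community profile (sdlog 1.5) shared by all animals —
  heavy-tailed rank abundance;
* per-animal, per-taxon log-normal multiplicative effects with sdlog 1.0 —
  the "large inter-individual dispersion" regime;
* planted treatment effects: per-animal log2fc draws
  $N(\mu_e, \sigma_e)$ applied to a chosen fraction of a target cell's
  animals;
* multinomial resampling at per-sample depths drawn uniformly from
  20,000-60,000 reads, forcing unequal size factors;
* phenotypes tied to a taxon's *realized* per-animal log2fc through a
  Gaussian copula targeting a requested Spearman rho;
* qPCR Ct tables built by inverting the delta-delta-Ct model, with
  Gaussian noise on the target-assay Ct (reference noise cancels within a
  timepoint's dCt, so one knob controls recovery error: recovered log2
  fold change has SD `noise_sd * sqrt(2)`).

Everything derives from one integer seed with fixed substream splits, so
any single stage is reproducible in isolation.

What the generator does **not** emulate: amplicon-vs-shotgun detection
bias (reported in the source system but never quantified), chimeras,
contamination, compositional artifacts of extraction, or taxa absent from
most samples at these depths — hence a green test establishes procedural
correctness under the stated model, not robustness to every real-data
pathology.

## Numerical choices and degenerate inputs

* Pseudocounts: 0.5 throughout (paired log2fc, group-test means,
  size-factor fallback).
* Quartile ties break by stable taxon order, making the partition
  deterministic.
* Permutation p-values always use the +1 convention, so p is never 0 and
  its resolution is $1/(n_{perm} + 1)$.
* All-zero samples are errors for alpha diversity and weighted UniFrac;
  all-zero distance matrices return `NA` statistics with warnings.
* Constant vectors in Spearman correlation return flagged `NA`, excluded
  from gating denominators only when undefined.
* 32-bit seed discipline: derived stream seeds stay below $2^{31}$.

## Known limitations

* The group test is a calibrated approximation, not tool-equivalent to any
  named differential-abundance package.
* PERMANOVA ignores the paired structure in pre/post contrasts (free
  permutation).
* The community gate's decision rule is one defensible reading of an
  ambiguous description; it is deliberately swappable.
* Family-level display thresholds assume the lineage strings carry a
  family rank; unclassified ranks propagate the deepest classified label.
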