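---
title: "Methods: population structure, outlier scans and transcriptome plasticity from mRNA data"
author: "plastisel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, outlier scans and transcriptome plasticity from mRNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

Messenger-RNA sequencing of a two-population experiment yields two kinds of
information at once: genetic variation (SNPs called from the transcribed
sequence) and phenotypic plasticity (expression responses to the
treatment). `plastisel` implements the downstream arm of such a study for a
design with two populations sampled at three timepoints of an environmental
challenge: SNP quality control, population-genetic estimation with bootstrap
confidence intervals, two independent outlier-SNP scans, three
transcriptome plasticity tests, and a gene-level contingency analysis
asking whether signatures of selection and plasticity co-occur in the same
genes.

Because the interesting properties of every stage are statistical
(unbiasedness, type-I error, power), the package ships a synthetic-data
module with known truth; all validation below refers to it.

## Genotype simulation: the Balding–Nichols model

Each locus draws an ancestral allele frequency $p$ uniformly on a
configurable interval (default $(0.1, 0.9)$, avoiding near-fixed loci that
a minor-allele-frequency filter would discard anyway). Population $k$ then
draws its own frequency

$$p_k \sim \mathrm{Beta}\!\left(p\,\frac{1-\theta_k}{\theta_k},\;
  (1-p)\,\frac{1-\theta_k}{\theta_k}\right),$$

so that $\mathrm{Var}(p_k) = \theta_k\,p(1-p)$: $\theta$ is the divergence
on the FST scale. Genotypes are drawn with heterozygote probability
$2p_k(1-p_k)(1-F)$, where $F$ is the within-population inbreeding
coefficient (negative $F$, heterozygote excess, is allowed). Microsatellites
use the Dirichlet generalization with symmetric Dirichlet(1) ancestral
frequencies. The model is the standard FST-parameterized divergence model;
it was chosen because it makes parameter-recovery tests well defined: the
Weir–Cockerham estimator, Nei's $F_{IS}$ and the allele-matching
$\beta_i$ all have expectation (approximately) equal to the simulated
parameter, which the test suite and the acceptance script verify by
replicate simulation (100–200 replicates of 5000 loci, $n = 16$ per
population — the scale at which Monte-Carlo error is far below the
recovery tolerances while a full run stays under a minute).

Defaults mirror the study design the package targets: two populations of
16 individuals, background $\theta = 0.023$, no inbreeding, loci grouped
into transcript clusters of 5 (the "chromosome" unit for LD pruning).
`theta_background` may be a per-population vector, which simulates
population-specific drift for validating the $\beta_i$ estimator.

What the generator does *not* emulate: read-level noise (no FASTQ, no
sequencing error, genotype qualities are decorative draws), linkage beyond
the cluster labels, selection as an allele-frequency trajectory (planted
outliers are simply loci with a larger $\theta$), and site-frequency
spectra of real transcriptomes. Passing recovery tests therefore shows the
estimators are correct for their model, not that real mRNA-derived SNPs
are unbiased samples of the genome — the motivating study argues they are
not (purifying selection depresses diversity in transcribed sequence).

## The SNP filter cascade

`apply_site_filters()` applies, in order: genotype-quality masking
(calls with GQ ≤ 30 become missing — masking rather than site removal,
so a few bad calls do not discard an otherwise clean site), site quality
(QUAL strictly > 30), biallelic-only, minor allele frequency ≥ 0.05
(inclusive), and per-site missingness ≤ 20%. Two panels are built by
`snp_panels()`:

* **overall** — the cascade above;
* **neutral** — additionally no missing data, Hardy–Weinberg exact-test
  p ≥ 0.005 (loci *incompatible* with HWE are removed), and
  within-cluster LD pruning at $r^2 > 0.20$.

The HWE test is the exact conditional test (heterozygote-count
enumeration); the exact test is the standard choice for SNP QC and is
verifiable against full enumeration, which the suite does for every table
with up to 30 individuals. It is applied to the pooled sample; pooling
makes the neutral panel conservative in the presence of a Wahlund effect.
LD pruning is a greedy left-to-right pass within each cluster with a
strictly-greater-than threshold and first-kept-wins tie-breaking; loci in
different clusters are never compared. A zero-variance locus has
undefined correlation; it is treated as $r^2 = 0$ and never triggers a
removal. Individual-level filtering removes individuals with ≥ 3 missing
loci (the 20%-of-19-markers rule) and anything on an external exclusion
list (e.g. full-siblings identified by a sibship analysis, which is out
of scope here).

## Population-genetic estimators

Per locus and population, observed heterozygosity $H_O$ is the
heterozygote fraction among genotyped individuals and gene diversity uses
Nei's unbiased form
$H_S = \tfrac{n}{n-1}\bigl(1 - \sum_k \hat p_k^2 - H_O/2n\bigr)$.
The inbreeding coefficient is $F_{IS} = 1 - \bar H_O / \bar H_S$ with
multi-locus means; monomorphic loci contribute zeros to both means and
cancel from the ratio.

Pairwise FST is Weir & Cockerham's $\hat\theta$: variance components
$a$ (among populations), $b$ (among individuals) and $c$ (within
individuals) computed per allele and locus from sample sizes, allele
frequencies and heterozygote frequencies, aggregated as the **ratio of
sums** $\sum a / \sum(a+b+c)$ — not the mean of per-locus ratios, which
is a different (worse) estimator; a test constructs a two-locus example
where the two aggregations disagree and pins the implemented one.
Multi-allelic loci contribute one term per allele.

Population-specific FST uses allele-matching proportions: $M_i$ is the
sample-size-corrected probability that two distinct alleles drawn within
population $i$ match, $M_B$ the mean between-population matching, and
$\beta_i = (M_i - M_B)/(1 - M_B)$, with matching proportions averaged
over loci before the ratio. Under the divergence model above,
$E[M_i] - M_B \approx \theta_i (1 - M_B)$, so $\beta_i$ recovers
population-specific drift; the acceptance benchmark verifies this at the
study's published values.

Confidence intervals come from a percentile bootstrap over loci (1000
iterations by default), re-aggregating stored per-locus components rather
than refitting; the seed is a required argument and resampling is
deterministic under it. Replicates on which a statistic is undefined are
skipped and counted; more than 10% skipped is an error rather than a
silently narrowed interval.

PCA mean-imputes missing dosages, centers but does not scale columns
(the convention of the population-genetics PCA tools this mirrors), and
k-means reassignment runs on the leading 75 components (clamped to what
is available, with a warning) with 25 restarts, labels renumbered so
cluster 1 is the largest.

## Outlier scans

**PC scan.** Dosages are centered and scaled; each SNP is regressed on
the first $K = 2$ orthonormal principal-component score vectors, giving a
vector of $K$ z-statistics per SNP. Its squared Mahalanobis distance
$D^2$ — with a minimum-covariance-determinant (robust) estimate of the
z covariance, falling back to the classical covariance for small panels —
is divided by the genomic inflation factor
$\lambda = \mathrm{median}(D^2)/\chi^2_{K,0.5}$ and referred to a
$\chi^2_K$ distribution. A SNP is *flagged* when its BH q-value is below
0.05 **and** its largest squared z lies on component 1 — the axis that
separates the populations ("varied along PC1" is operationalized as the
argmax of the squared per-component z, which the published analysis left
undefined). Zero-variance SNPs get p = 1.

**Permutation FST scan.** The second detector in the original analysis
was a reversible-jump MCMC model; that is out of scope here and is
replaced by a distribution-free scan: per-locus Weir–Cockerham
$\hat\theta$ against its null distribution under random permutation of
the population labels, with $p = (1+b)/(1+n_{\mathrm{perm}})$ so p is
never zero. One property of this scan deserves emphasis: with equal
group sizes, the only permutation-varying ingredient of the per-locus
$\hat\theta$ is $(\hat p_1 - \hat p_2)^2$, a heavily tied discrete
statistic, so the empirical p-values are conservative (observed type-I
≈ 0.015–0.03 at nominal 0.05) rather than uniform. The test suite
asserts validity (type-I ≤ 0.06), not exact nominal attainment.

A SNP is a **joint outlier** when significant in both scans (with each
scan's own axis restriction); a gene is selection-flagged when it
contains at least one joint outlier, and the retained gene-level value is
the minimum $-\log_{10} q$ among the gene's significant values — the
least significant of the significant, matching how the published analysis
summarized genes for plotting.

## Transcriptome plasticity tests

The expression filter keeps a gene only if *every* sample of at least one
population-by-timepoint cell has a nonzero count. Normalization is TMM;
the nine contrasts are between-population at each timepoint and
within-population between timepoint pairs.

**DGE** fits negative-binomial log-linear models over the six cells with
TMM offsets and tests contrasts with quasi-likelihood F-tests (edgeR).
Null calibration (type-I within [0.03, 0.08] at p < 0.05 on a
2000-gene null simulation) and power (> 0.8 at q < 0.05 for planted
two-fold log2 changes at 5–6 samples per cell) are asserted in the suite,
and reported log2 fold changes are checked against unshrunk per-gene NB
maximum-likelihood fits on high-count data.

**DEU** uses exon-level log-CPM with voom precision weights, per-exon
linear models, and limma's `diffSplice`: each exon's contrast coefficient
is compared with the precision-weighted average of the gene's other
exons, and gene-level p-values apply the Simes procedure to the $E-1$
smallest exon p-values with penalty $i/(E-1)$ (the per-exon relative
contrasts sum to zero within a gene, so the largest p-value is
redundant; a two-exon gene's p is its smaller exon p). Single-exon genes
are excluded and counted. Two calibration facts are documented rather
than wished away: (i) because exon counts share their gene's biological
(NB) noise, which the relative contrast cancels but the per-exon variance
estimate retains, null gene p-values are *conservative*, increasingly so
as gene dispersion grows; (ii) even with exact per-exon p-values, the
within-gene negative correlation of the relative contrasts
($\approx -1/(E-1)$) makes the Simes aggregate detectably non-uniform at
a 2000-gene Kolmogorov–Smirnov resolution. The suite therefore asserts
type-I control (never anti-conservative; no BH discoveries under the
null) and power on planted usage switches (0.5 → 0.1 on one exon is
detected in well over half of planted genes), not exact uniformity.

**GEV** (gene expression variability) asks whether count overdispersion
— not the mean — differs between groups. For each gene the package fits
two NB models by maximum likelihood with the offset
$\log(\text{library size} \times \text{TMM factor})$ on the mean: a full
model with group factors on both the log-mean and the log-dispersion
(fitted per group), and a reduced model with group on the mean only
(common dispersion); the statistic $2(\ell_{\mathrm{full}} -
\ell_{\mathrm{reduced}})$ is referred to $\chi^2_{G-1}$. Of the several
model pairs the source description admits, this contrast — group effect
on dispersion *given* group on mean — is the one that isolates
variability from abundance, and it is the package's documented choice.
Genes must exceed 1 count per million on average, and genes whose fitted
coefficient of variation $\sqrt{\phi + 1/\mu}$ (with $\mu$ the mean
count and $\phi$ the reduced-model dispersion — the operational reading
of "CV of mRNA copy number") falls outside $(10^{-3}, 3)$ are removed
before testing, which excises near-Poisson and pathologically inflated
genes. Optimization is bounded L-BFGS-B on $(\eta, \log\phi)$ with
moment starts; bounds $\eta \in [-40, 40]$, $\log\phi \in [-12, 6]$ keep
the likelihood finite; non-convergent genes are excluded and counted.
Calibration at $n = 16$ per group is within [0.03, 0.08]; power for a
4-fold dispersion ratio at equal means is about 0.65–0.75 per gene at
p < 0.05 (and modest after BH at a few hundred genes — dispersion
differences at these sample sizes are genuinely hard to detect, which is
consistent with the published analysis reporting no significant GEV genes).

## Combining selection and plasticity

A gene is *plastic* when any DGE/DEU/GEV q-value in any contrast is below
0.05; the retained plasticity value is the lowest $-\log_{10} q$ among
the significant ones (a deliberate, documented reading: the least
significant of the significant, used for plotting; `retain = "max"`
offers the conventional most-significant alternative for sensitivity
analysis). Selection flags come from the joint-outlier mapping. The gene
universe is the full transcript-cluster list, not just
expression-filtered genes, so the "neither" cell of the table counts
untestable genes too — matching how the published analysis reports its totals.
Independence is tested with the closed-form 2×2 chi-square
$N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ without the Yates
correction by default (the correction is available and does not change
the study-scale conclusion); a zero margin is an error, not a silent 0.

On the published category counts (8 / 67 / 4880 / 244021 over 248976
genes) this gives $\chi^2 \approx 29.5$, $p \approx 5.5\times10^{-8}$.
The chi-square statistics printed in the published analysis (in the tens of
millions) exceed the algebraic maximum for a 2×2 table ($\chi^2 \le N$)
and are mutually inconsistent between text and figure; the package
reports the closed-form value and treats only the published significance
bound ($p < 10^{-5}$) as reproducible.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit integer seed; one master seed is
expanded into per-stage substreams so stages can be re-run independently,
and identical configuration plus seed reproduces byte-identical tables.
Validation problem sizes were chosen so the whole suite runs in well
under a minute per module: 5000 loci × 32 individuals for recovery
benchmarks (Monte-Carlo SE ≈ 1×10⁻⁴ for FST over 100 replicates, an
order of magnitude below the tolerance), 19 loci × 8 alleles × (528, 191)
individuals for the microsatellite benchmark, and 500–2000 genes for
expression calibration. The study-scale marker counts (hundreds of
thousands of SNPs, a quarter-million transcript clusters) depend on raw
read data and are not reproduced here; published per-dataset counts are
treated as context, not targets.
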