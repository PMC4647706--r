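---
title: "Methods: germplasm diversity from SNP panels and transcript variation"
author: "germdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germplasm diversity from SNP panels and transcript variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germdiv)
```

## What the package models

Germplasm collections of clonally propagated fruit trees — the motivating
system is a mango collection of a few dozen accessions genotyped on a
Fluidigm-style panel of a few hundred biallelic SNPs — are surveyed for
diversity with a small, fixed toolbox: per-locus summary statistics,
distance-based clustering with bootstrap confidence, and model-based
ancestry inference. `germdiv` implements that toolbox end to end, together
with transcript-level variation classifiers (joint SNP genotype categories
for two resequenced accessions, longest-ORF assignment, microsatellite
scanning) and a synthetic-data generator so every stage can be exercised
with known ground truth on a desk machine.

## Genotype representation and quality control

Genotypes are unordered diploid allele pairs at biallelic loci, stored
internally as reference-allele dosages 0/1/2 with `NA` for a no-call.
Heterogeneous call spellings ("AG", "A/G", "G:A") normalize to one pair at
read time; loci observed with a single allele are kept and flagged so
downstream statistics can exclude them explicitly.

QC removes samples whose no-call fraction *strictly exceeds* 10%, then
assays whose no-call fraction — recomputed on the surviving samples —
strictly exceeds 30% (both thresholds are arguments). Samples are filtered
first, in a single pass, which avoids oscillating iterative removal. A
consequence worth knowing: the single pass is idempotent when failed
samples/assays are clearly separated from the thresholds (the intended use
case), but a grid in which many rows sit exactly at the boundary can shift
across the threshold once high-missing columns are dropped. `apply_qc`
reports every removal with its missing fraction so such cases are visible.

## Per-locus statistics

For allele frequencies $p_i$ estimated from the called genotypes of the
chosen sample set:

* polymorphism information content, $\mathrm{PIC} = 1 - \sum_i p_i^2$ —
  for a biallelic locus identical to the expected heterozygosity
  $H_{exp} = 2p(1-p)$, maximal at 0.5;
* observed heterozygosity $H_{obs}$, the fraction of called genotypes that
  are heterozygous;
* the within-population fixation index
  $F_S = (H_{exp} - H_{obs}) / H_{exp}$, negative under heterozygote
  excess; monomorphic loci ($H_{exp}=0$) are excluded from its summaries;
* differentiation $F_{ST} = (H_T - H_S) / H_T$, where $H_S$ is the average
  within-subpopulation expected heterozygosity weighted by called-genotype
  counts and $H_T$ the expected heterozygosity of the pooled allele
  frequencies. With these definitions $H_S \le H_T$ (Wahlund), so the
  per-locus $F_{ST}$ is non-negative. The sign convention is the standard
  $G_{ST}$ orientation: positive under differentiation.

The plug-in $H_{exp}$ estimator is biased low by a factor $(2n-1)/2n$; an
`unbiased = TRUE` switch applies the correction. It is off by default —
the plain frequency formulas above are the defaults the field reports —
but the Hardy–Weinberg checks in the test suite use it, because with a few
dozen samples the $-1/(2n)$ bias in $F_S$ is comparable to the effects
being tested.

Two estimator properties matter when interpreting recoveries on synthetic
data, and we document them rather than hide them. First, with only two
subpopulations the pooled-frequency $H_T$ is shrunk by the
between-subpopulation variance itself, so the per-locus $G_{ST}$ has
expectation near $F/2$, not $F$, under a Balding–Nichols model with
parameter $F$; with $K$ demes the factor is $(1-1/K)$. Second, the
per-locus ratio is strongly right-skewed (the numerator is essentially a
scaled $\chi^2_1$ for $K=2$), so its *median* sits near $0.46 \cdot F/2$.
Finite samples add roughly $1/(2n_s)$ of apparent differentiation. The
many-deme recovery test in the suite runs at $K=8$, where the deme factor
and the skew factor nearly cancel and the median tracks $F$ closely; at
$K=2$ no parameter-free agreement between the median statistic and the
generative $F$ should be expected, and the package does not pretend one.

Association helpers wrap the standard machinery: a two-sided Fisher exact
test implemented by full enumeration of the hypergeometric support (all
tables no more probable than the observed one; a zero margin returns
$p = 1$ with a flag), and the Pearson chi-square for goodness-of-fit or
two-vector homogeneity. Wilcoxon tests in `summarize_partition` use the
exact distribution up to 25 informative values and the normal
approximation with continuity correction above; zero differences are
dropped, and a fully degenerate signed-rank test reports $p = 1$ with a
degeneracy flag.

## Shared-allele distance, Ward trees, bootstrap

The kinship distance is $D = 1 - \mathrm{PSA}$, where per pair the
proportion of shared alleles is $\sum_l PS_l / (2L)$ and $PS_l \in
\{0,1,2\}$ is the multiset intersection of the two diploid genotypes
(equivalently $2 - |g_i - g_j|$ on dosages). Loci missing in either sample
are deleted pairwise and $L$ reduced, which preserves panel scale under
scattered no-calls; a pair with no jointly called locus is an error, not a
silent zero.

Clustering is Ward's minimum-variance method in the `ward.D2` convention —
the Lance–Williams recursion on squared dissimilarities, heights reported
on the original scale — implemented in the package so the tie-break is
pinned: among minimal-cost merges the smallest pair of cluster slot
indices wins, making trees reproducible across platforms. On tie-free
input the result is identical to `stats::hclust(method = "ward.D2")`, and
an exhaustive greedy minimum-variance oracle verifies every merge at small
$n$ in the tests.

Branch confidence comes from resampling loci with replacement (default
1000 replicates), rebuilding the tree, and scoring each internal
bipartition of the reference tree by the percentage of replicate trees
containing the same unordered leaf split — heights ignored,
root-invariant. One master seed pre-draws a per-replicate seed stream, so
runs are reproducible and replicates independent of ordering; replicates
that lose all jointly called loci for some pair are redrawn and counted.
`cut_partitions` cuts at the height giving exactly $k$ groups and labels
clusters by decreasing size (ties by smallest member index) — stable, but
with no claim about which group corresponds to any published one.

## Admixture model and choice of K

The ancestry model is the standard admixture likelihood: sample $i$ has
mixing proportions $q_{ik}$ over $K$ ancestral populations with
reference-allele frequencies $p_{kl}$, and each called dosage contributes
$g \log f_{il} + (2-g) \log (1-f_{il})$ with $f_{il} = \sum_k q_{ik}
p_{kl}$. Inference is maximum likelihood by EM — the E-step splits each
allele copy over ancestries, the M-step renormalizes — rather than the
Bayesian MCMC of the classical structure-inference programs. This is a
deliberate substitution, not a reproduction: EM on the same likelihood is
deterministic given its start, testable (the log-likelihood is
monotone, asserted in the suite), and fast enough that 20 random restarts
per $K$ play the role that repeated MCMC runs play elsewhere, with the
restart spread feeding the selection statistic.

Defaults: restarts draw $Q$ rows from Dirichlet(1) and $P$ from
Uniform(0.05, 0.95) with per-restart seeds derived from one master seed;
$P$ is clamped to $[10^{-6}, 1-10^{-6}]$ each M-step to keep the
likelihood finite; convergence is declared when the per-iteration gain
drops below `tol` (default $10^{-6}$, cap 2000 iterations). $K=1$ is
solved in closed form (observed frequencies). The full $K$ scans in the
acceptance path run at `tol = 0.01`: on a 74 × 239 panel the
log-likelihood is of order $-2\times10^4$, so a 0.01 gain is a relative
change of $5\times10^{-7}$, far below the between-restart spread that the
selection statistic consumes, and the selected $K$ is unchanged while the
scan fits roughly twice as fast.

The number of subpopulations is chosen by the Evanno second-difference
statistic $\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| /
\mathrm{sd}(L(K))$ across restarts (sample standard deviation), defined
only at interior $K$ with positive spread; ties break to the smaller $K$.
A practical note: restarts that all reach the same optimum make
$\mathrm{sd}(L(K))$ tiny and $\Delta K$ at the true $K$ enormous — that is
the statistic working as intended, not an instability.

## Transcript variation

For two resequenced accessions, each SNP site falls into HoHo, HeHo, HoHe
or HeHe by the heterozygosity of the two calls; two identical homozygous
calls describe a monomorphic site and are rejected. ORFs are scanned in
all six frames (both strands by default, configurable): a candidate runs
from ATG to the next in-frame stop, the stop codon lies inside the
reported 1-based forward-strand span, and the amino-acid length counts the
codons strictly between start and stop — the default minimum is 67 aa, so
`ATG` + 66 codons + `TAA` is rejected at the default and accepted at
`min_aa = 66`. SNPs are inORF iff `start <= pos <= end` (inclusive,
strand-agnostic); contigs without a qualifying ORF yield `no_orf`.

Microsatellite scanning reports all maximal perfect tandem repeats of unit
length 1–6 meeting the published MISA default minima (10, 6, 5, 5, 5, 5
repeats for mono- through hexanucleotides). A run is reported once, at its
smallest unit (a poly-A stretch is `(A)n`, never `(AA)n`), cannot be
extended by a whole unit in either direction, and never crosses an `N`.
Compound or interrupted repeats are out of scope — the summaries tabulate
simple motifs. Motifs pair with their reverse complements for reporting
("GA/TC"), lexicographically smaller member first; rotational variants
stay distinct, matching how motif spectra are usually plotted.

## Synthetic data: what it emulates and what it does not

`simulate_collection` draws ancestral frequencies from Uniform(0.05,
0.95), subpopulation frequencies from the Balding–Nichols Beta with
parameter $F$ (so the expected differentiation of the *frequencies* is
$F$), ancestries either pure or Dirichlet-admixed, dosages
Binomial(2, $QP$), and an i.i.d. missingness mask; optional planted
high-missingness samples/loci give QC tests exact ground truth. The
shipped `paper_like` scenario fixes the collection-survey conditions used
throughout the recovery checks: 74 accessions × 239 loci, two
subpopulations at $F = 0.03$, 20% of samples admixed with
Dirichlet(0.5, 0.5) ancestries, and a 5% no-call rate — chosen once as a
typical residual rate for a post-QC panel. Balding–Nichols is the simplest
generator whose single parameter is a differentiation level; it is a
modeling convenience, not a claim about mango demography. It omits
linkage, ascertainment bias of panel SNPs, clonal duplicates and
genotyping-error structure, so passing recovery tests demonstrates the
estimators and the inference machinery, not field performance on real
panels.

`simulate_transcripts` plants one ORF (either strand), one SSR and a set
of category-labelled SNP sites per contig in i.i.d. background sequence,
then rejection-samples the background until the planted features are
exactly what the scanners report (rejection counts are returned), keeping
the ground-truth GFF-style tables exact.

## Numerical and design choices

* Thresholds in QC are strict inequalities ("more than"), matching the
  stated filtering rules.
* Allele order within a call never carries information; the lexicographic
  normalization happens at parse time.
* `ward.D2` is the default (and only) agglomeration because it is the
  variant that implements Ward's criterion on raw dissimilarities; the
  historical `ward.D` ambiguity is resolved by construction.
* Problem sizes in the test suite — e.g. 20 replicates of the 74 × 239
  scenario for the recovery checks, 500 random kilobase sequences for the
  repeat-scanner equivalence, $n \le 8$ for the exhaustive Ward oracle —
  were chosen so the whole suite runs comfortably on a single CPU while
  keeping each property statistically meaningful.
* All randomness flows from explicit seeds; equal seeds give
  byte-identical simulations.

## Known limitations

The admixture fit is a point estimate; no posterior uncertainty on $Q$ is
provided, and label switching across independent fits is resolved only by
greedy matching when a reference is supplied. The bootstrap supports
inherit Ward's sensitivity to distance noise for very small clusters. The
two-deme $F_{ST}$ median issue discussed above means collection-level
differentiation numbers from two-group surveys should be compared between
datasets analysed identically, not read as estimates of a generative $F$.
VCF ingestion handles biallelic GT-style records only, and variant calling
itself is out of scope: variant tables are inputs.
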