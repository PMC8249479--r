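---
title: "Methods behind popkit: from filtered SNPs to diversity, structure, ROH and haplotype networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind popkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popkit implements the analysis stages that follow joint variant calling in a
small-population conservation-genomics study: a filtering cascade that turns
a raw multi-sample SNP call set into an analysis-ready genotype matrix, and,
on top of it, windowed nucleotide diversity, individual heterozygosity,
polymorphism proportions, windowed Weir–Cockerham F~ST~ with a subsampling
null, PCA and model-based ancestry with cross-validation, PLINK-semantics
runs-of-homozygosity (ROH) calling with coverage-normalised F~ROH~, and
minimum spanning networks for aligned mitochondrial haplotypes. A
Balding–Nichols simulator with recorded ground truth makes every stage
testable without sequence data. This vignette describes each model, its
assumptions, the tunable parameters, and the design decisions where the
field leaves room for choice.

## The genotype matrix and the filtering cascade

All statistics operate on a `genotype_matrix`: diploid alt-allele dosages
(0/1/2, `NA` for missing) for samples × biallelic SNPs, with per-site
scaffold, 1-based position, aggregate depth and variant-caller annotations.
Multiallelic records are dropped, not split, and any GT containing `.`
(including half-calls) is treated as missing — half-call handling is not
standardised across callers, and discarding the partial information is the
conservative choice.

The cascade mirrors standard GATK-era practice, each step separately logged
so the site-count telescope is auditable:

1. **Hard filters** — retain a site iff every *present* annotation passes
   QD > 2, QUAL > 30, SOR < 3, FS < 60, MQ > 40, MQRankSum > −12.5,
   ReadPosRankSum > −8.0. Absent annotations pass: the rank-sum statistics
   are undefined without heterozygotes, and failing such sites would discard
   legitimate fixed differences.
2. **Aggregate depth** — with mean per-sample coverage `c` over `n` samples,
   the aggregate mean is `A = c·n`; sites outside `[round(A/3), round(2A)]`
   are removed (inclusive bounds, integer thresholds — e.g. 16.9× over 60
   samples gives 338–2028×). The lower bound removes poorly covered sites,
   the upper bound collapsed repeats and organelle contamination.
3. **Mappability mask** — BED intervals (0-based half-open) are merged on
   read; a site at VCF position `p` is excluded iff `start ≤ p−1 < end`.
4. **MAF ≥ 0.01**, computed on non-missing alleles; **call rate ≥ 0.90**;
   **scaffold length ≥ 10 kb**. All bounds keep the site when it sits
   exactly at the threshold ("lower than" / "shorter than" semantics).

The narrative order (hard → depth → mask → MAF → call rate → scaffold) is
fixed; whether MAF/call-rate run before or after the mask is immaterial to
the final set but changes per-step counts, which the report makes explicit.

**LD pruning** follows `indep-pairwise` semantics: windows of 50 SNPs
stepping by 5; within a window, ordered pairs with dosage-correlation
r² > 0.5 (Pearson over samples non-missing at both sites) cause removal of
the *later* site. Because removal shifts window composition, a single sweep
can leave a correlated pair that never shared a window; popkit iterates the
sweep to a fixed point, which makes pruning idempotent — a property worth
more to downstream reproducibility than one-pass fidelity.

## Diversity statistics

Per site and population, nucleotide diversity is the mean pairwise allele
difference: with `c_ref`/`c_alt` called alleles (`n = c_ref + c_alt`),
`π = c_ref·c_alt / C(n,2)`, the unbiased per-site estimator of expected
heterozygosity. Windows of 10 kb tile each scaffold from position 1; the
window value is the π-sum divided by the *full* window length (VCFtools
`--window-pi` semantics), which reproduces the familiar per-bp magnitudes
(~2×10⁻⁴ for the systems this package targets). Windows containing no SNP
are excluded from the genome-wide mean: a SNP-only input cannot distinguish
"invariant" from "uncallable" there, and treating them as zeros would
deflate the average by the callability fraction. Anchoring windows at
position 1 rather than 0 is arbitrary; it is fixed by decision and affects
only window labels, not the mean.

Individual heterozygosity `H` is the count of heterozygous calls divided by
the **joint** (all-population) SNP count; missing sites stay in the
denominator, so H is comparable across individuals with different call
rates under the assumption that missingness is random with respect to
heterozygosity (an option divides by called sites instead). The proportion
of polymorphic sites `P` likewise uses the joint denominator, so P measures
each population's share of the total variation.

Because all three statistics grow with sample size (more sampled
chromosomes segregate more variants), populations of unequal size are
compared by resampling: `resample_equal_n()` draws six individuals per
population (without replacement), rebuilds the joint matrix from the drawn
individuals so denominators shrink consistently, recomputes the statistic,
and repeats 100×, reporting mean ± sd. Replicate seeds derive from one user
seed; the same seed reproduces the replicate vector bit for bit.

## Weir–Cockerham F~ST~ and the substructure null

Differentiation uses the Weir & Cockerham (1984) variance components for
two populations — `a` (among populations), `b` (among individuals within
populations), `c` (within individuals) — computed from per-population
called sample sizes, allele frequencies and observed heterozygote
fractions, so genotyping error that inflates heterozygosity propagates
correctly rather than through a Hardy–Weinberg shortcut. Individuals
missing at a site are dropped from that site's sample sizes
(pairwise-complete, as VCFtools does). A window's "weighted" value is the
ratio of sums `Σa / Σ(a+b+c)` over informative sites; negative estimates
are retained, since clipping would bias every downstream average upward.

Two genome-wide summaries exist in the wild: the unweighted mean of
windowed weighted values, and the single ratio-of-sums over all sites.
popkit returns both (`mean_fst`, `overall_weighted_fst`) and defaults to
the window mean. The two differ by a small Jensen-type bias of the window
mean when windows hold few sites (~7 SNPs per 10-kb window at the default
simulated density, bias ≈ −0.01 at F~ST~ ≈ 0.2); at either summary the
simulator's divergence parameter is recovered within ±0.02.

`substructure_null()` asks whether a *suggested* split of one population
(say, the two subgroups an admixture fit hints at) is better differentiated
than chance: the population is resplit at random into groups of the same
sizes 100 times, windowed weighted F~ST~ computed each time, and the
observed value located in that null. Under panmixia the observed quantile
is uniform; a true two-deme structure of F~ST~ ≈ 0.04 at n = 10+10 with a
few thousand SNPs essentially always exceeds the null maximum.

## PCA and admixture

PCA standardizes each dosage column by its sample allele frequency (center
`2p̂`, scale `√(2p̂(1−p̂))` — the variance of a binomial allele count),
mean-imputes missing entries (0 after centering), and eigendecomposes the
sample covariance. Mean imputation shrinks scores of high-missingness
samples toward the origin; that is visible, not hidden, and preferable to
dropping samples. Monomorphic columns carry no information and are dropped
with a message.

The admixture model is the standard binomial mixture: individual `i`
carries ancestry fractions `q_i` (summing to 1) over `K` clusters with
allele frequencies `f_k`, and the genotype likelihood is
`ℓ = Σ_ij [ g_ij log(Σ_k q_ik f_kj) + (2−g_ij) log(1 − Σ_k q_ik f_kj) ]`,
missing entries skipped. popkit fits it with multiplicative EM updates —
simpler than the quasi-Newton block relaxation of the reference software,
provably monotone in ℓ, and entirely adequate at desk scale. Defaults:
convergence when the ℓ gain drops below 10⁻⁴, at most 2000 iterations,
frequencies clamped to [10⁻⁶, 1−10⁻⁶], 5 random restarts (best ℓ kept)
with restart seeds derived from the user seed. `K = 1` reaches its
closed-form solution (Q ≡ 1, F = sample frequencies) in one step, a useful
internal check. Cluster labels are arbitrary; `align_q()` matches columns
across runs by greedy maximal correlation.

`K` is chosen by masking cross-validation in the style described by the
ADMIXTURE manual: genotype *entries* (not whole individuals) are
partitioned into 5 folds; each fold is masked, the model refit, and masked
entries predicted as dosage `2·(QF)_ij`; the error is mean binomial
deviance over masked entries (sites left with no observation in a training
fold are skipped for that fold). The CV minimum over K = 1..6 recovers the
simulated number of sources; under panmixia the curve is flat-to-rising
beyond K = 1. CV refits default to 2 restarts — fold error differences
dwarf restart-to-restart likelihood differences, so extra restarts buy
nothing measurable.

## Runs of homozygosity

`detect_roh()` reproduces PLINK `--homozyg` scanning semantics: windows of
50 consecutive SNPs slide one SNP at a time; a window is homozygous iff it
holds ≤ 1 heterozygous and ≤ 5 missing calls; a SNP is a *hit* iff ≥ 5% of
the windows overlapping it are homozygous (edge SNPs use only the windows
that exist, as PLINK does at chromosome ends); maximal runs of hits, split
wherever consecutive SNPs lie > 1000 kb apart, become candidate segments;
candidates pass with span ≥ 100 kb (first to last SNP position, PLINK
convention — not window borders), ≥ 50 SNPs, and ≤ 50 kb per SNP (the
density condition applied per segment, matching `--homozyg-density`). The
window size and 5% hit fraction are the PLINK 1.9 defaults; the package
treats them as explicit parameters. There is no segment-level heterozygote
cap: the window caps do that work. The implementation is validated by
exhaustive equivalence against a literal-loop oracle on hundreds of random
chromosomes.

Because a sparse SNP map cannot reveal ROH anywhere, F~ROH~ is normalised
by *analysis coverage* (after Meyermans et al.'s recommendation): an
artificial sample homozygous at every site is scanned with the same
parameters once per length threshold (100 kb, 1000 kb), and its aggregate
segment length is the denominator. The artificial sample itself therefore
has F~ROH~ = 1 exactly, and `coverage(1000 kb) ≤ coverage(100 kb)` always.

## Mitochondrial haplotype networks

Aligned sequences are collapsed to unique haplotypes with per-population
carrier counts. Alignment columns containing a gap in any sequence are
excluded before comparison — in the indel-free data this package targets,
gaps can only be alignment padding. Distances are Hamming counts
(case-insensitive; ambiguity codes are compared literally with a warning).
The network is the ε = 0 minimum spanning network: Kruskal-style growth
where, at each distance level, *every* edge joining two distinct components
at that level is admitted — exactly the union of all minimum spanning
trees, verified against exhaustive spanning-tree enumeration on small
cases. Edges present in every MST are flagged `essential`; the rest are tie
alternatives. Median-joining networks (inferred intermediate haplotypes)
are out of scope; for star-like, few-step data a plain MSN carries the same
information.

## The simulator and what it does (not) emulate

`simulate_populations()` draws ancestral frequencies uniformly on
[0.05, 0.95] (avoiding near-fixed sites whose Beta parameters degenerate at
small F), per-population frequencies from the Balding–Nichols Beta
`(p(1−F)/F, (1−p)(1−F)/F)`, and genotypes as Binomial(2, p_pop). For two
populations with divergence parameters F₁, F₂ the expected pairwise
Weir–Cockerham estimate is ≈ (F₁+F₂)/2; the default per-population values
(0.221, 0.171, 0.169) were solved from the three pairwise targets
0.196/0.195/0.170 that characterise the strongly drifted river populations
this design emulates. Defaults: 3 populations × 20 diploids + 6 admixed
individuals at mean ancestry (0.746, 0.135, 0.119); 50,000 SNPs placed
uniformly over 10 scaffolds totalling 73 Mb, a layout chosen so per-bp π
lands at the empirical ~2×10⁻⁴ given E[2pq] ≈ 0.29 under the ancestral law;
per-sample depth 16.9× with negative-binomial site noise (dispersion 10),
whose heavy tails exercise both depth bounds; 2% missingness and 0.5%
heterozygote miscall inside implanted tracts.

Admixed genotypes draw each allele copy's source population from the
individual's Q row, then the allele from that source's frequency — the
exact generative model the admixture fit assumes. `implant_roh()` forces
tracts homozygous (one allele drawn per site from the population frequency)
with the het-error overlay; `degrade()` adds i.i.d. missingness, redraws
depths, and can flip heterozygotes to homozygotes to mimic allelic dropout
at low coverage — the failure mode that inflates ROH in downsampled data.

The simulator deliberately omits: linkage disequilibrium (sites are
unlinked, so LD-pruning tests use literally duplicated or resampled
columns rather than realistic decay), ascertainment of SNPs through a
caller, base-level sequencing error outside tracts, selection, and any
spatial/pedigree structure. Passing tests therefore demonstrate estimator
correctness under the stated generative model — not robustness to the full
messiness of real resequencing data.

## Problem sizes and numerical notes

The test-suite and the acceptance script run at sizes a laptop handles in
minutes, chosen as the package's own validation design: 50k sites × 40
samples for F~ST~ and π recovery; 10k sites × 66 samples for the ancestry
sweep (CV refits at a relaxed tolerance of 10⁻², 150 iterations — CV ranks
K by differences orders of magnitude larger than the residual likelihood
drift); hundreds of ≤ 500-SNP chromosomes for the ROH oracle; ≤ 7-node
exhaustive enumeration for the MSN oracle. The structure stage of the
acceptance script runs on an 8k-SNP thinned subset of the pruned matrix;
ancestry estimates stabilise well below that density. All stochastic
entry points take a single integer seed and derive their internal streams
from it; identical seeds give bit-identical outputs, including across the
two pipeline arms.

Known limitations: the EM fit finds local maxima (mitigated by restarts,
not eliminated); window-mean F~ST~ carries the small-window bias described
above; H's fixed joint denominator assumes missingness unrelated to
heterozygosity; and the ROH caller, like PLINK's, is a heuristic scan, not
an HMM — tract endpoints are SNP positions, so recovery precision is bounded
by marker density.
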