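---
title: "Methods: island/continental population structure, AIM panels and hybrid indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: island/continental population structure, AIM panels and hybrid indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`goshawkpop` implements a two-step population-genomic workflow for a system
with one strongly differentiated island population (Haida Gwaii, `HG`) and a
weakly structured continental cluster of sampling regions. Step one operates
on a genome-wide SNP matrix from high-quality samples: filtering, PCA,
maximum-likelihood admixture clustering, F_ST and divergence statistics, f3
admixture tests, and the design of a small ancestry-informative marker (AIM)
panel. Step two takes that panel to low-quality samples (shed feathers,
museum toe pads) and estimates, per individual, the ancestry index S — the
proportion of the genome from the island reference — and the interclass
heterozygosity H — the proportion of loci with one allele copy from each
source — in a maximum-likelihood framework that does not require diagnostic
markers.

All computation lives in package functions; the numbered scripts under
`analysis/` are thin narrative drivers over them, and `scripts/acceptance.R`
recomputes the headline quantities from scratch.

# The synthetic-data generator

No external download is needed to exercise the pipeline: the generator in
`sim_config()` / `simulate_dataset()` produces data with the statistical
structure the analyses assume.

**Allele frequencies.** Ancestral frequencies are Uniform(0.05, 0.95) —
bounded away from fixation so sites stay informative and Beta parameters
stay defined. Each region draws site frequencies from the Balding–Nichols
distribution `Beta(p(1-F)/F, (1-p)(1-F)/F)`; `F = 0` copies the ancestral
frequency exactly. Under this model the expected pairwise Weir–Cockerham
F_ST between two regions is approximately the mean of their drift
parameters. The defaults — island `F = 0.15` against continental
`F = 0.003`, at the nuclear-dataset sample sizes (HG = 12, AA = 17,
AK = 26, BC = 11, BCc = 5, East = 29, VI = 6, WA = 13) — therefore put
island-vs-continent F_ST in the observed 0.06–0.09 band and continental
pairs at or below 0.01.

**Admixed individuals.** A planted individual with parameters (S, H) assigns
each locus independently to one of three ancestry classes — both copies from
parent 1, one from each, both from parent 2 — with probabilities
`(S - H/2, H, 1 - S - H/2)`, then draws each allele copy from the
corresponding parent's frequency. Feasibility requires
`H <= 2 min(S, 1 - S)`. Loci are unlinked, which matches the downstream
analyses' assumption of approximately independent SNPs after pruning; the
generator cannot be used to study local-ancestry blocks.

**Missingness and quality.** Each sample has a tissue source; genotypes are
masked independently at the source's rate (defaults: tissue 0.10, blood
0.12, toepad 0.50, feather 0.85) and retained genotypes get qualities from a
per-source discretised gamma. Only the ordering of qualities against the GQ
threshold matters downstream. The feather rate is deliberately above the
80%-missing sample filter so that feather attrition emerges end-to-end; the
underlying quantitative missingness-by-source distribution is a free
parameter of the generator, not an observed quantity.

**mtDNA.** Sequences come from a per-group star-like coalescent
approximation: each continental sequence carries Poisson(theta/2) private
mutations on a shared ancestor, giving mean pairwise difference theta
(default 4); the island group is constrained to a small number of haplotypes
(default 2, one mutational step apart) on an ancestor several steps from the
continental one. This reproduces the low island haplotype diversity and the
strong island/continent mtDNA differentiation (Hudson F_ST ~ 0.7 under the
defaults), but the star approximation makes continental haplotype richness
higher than real control-region data shows — nearly every simulated
continental sequence is unique. Tests therefore assert summary properties
(mean pairwise differences, island constraint), never haplotype counts of
the continental group.

**Determinism.** A configuration's `seed` fixes everything; the stage
functions use fixed offsets (`seed`, `seed + 1`, ...) so each stage is
independently reproducible and repeated runs are bit-identical, including
the written VCF/FASTA/TSV.

# Filtering semantics

The filter chain order is fixed: biallelic SNPs, excess heterozygosity,
sample missingness, genotype-quality masking, site missingness, rare
alleles, LD pruning. The boundary conventions are deliberate and asymmetric,
and encoded exactly:

* excess heterozygosity: remove at observed het **>= 0.6** (collapsed
  paralogues);
* sample missingness: drop at **> 80%** missing (strict; a sample at
  exactly 80% stays);
* genotype quality: keep **GQ >= 10**;
* site missingness: keep **< 30%** missing (strict), computed after GQ
  masking;
* rare alleles: either drop singletons (minor allele observed exactly once)
  or keep **MAF >= 0.05** (inclusive).

All-missing sites are removed by the first filter that computes a per-site
statistic, with a report entry. Every filter is monotone and idempotent, and
the `FilterReport` chain composes: each step's input counts equal the
previous step's output counts, so total attrition is reproducible
arithmetic (the basis of the feather-attrition bookkeeping in
`attrition_by_source()`).

LD pruning is a greedy scan in `(scaffold, position)` order dropping any
site whose squared genotype correlation with a retained site within 500 kb
exceeds 0.2; threshold and window are conventional defaults for this style
of pruning and are configurable, since no single published value governs
them.

Two screens are principled stand-ins, implemented from first principles
because their published procedures are not available in accessible form:
sex-linkage flags (per-site Fisher exact test on heterozygote counts
between known-sex groups, expecting the avian Z pattern of heterozygotes
confined to males, default level 1e-3) and close-kin detection (the robust
between-family moment kinship estimator on shared dosages; duplicates score
~0.5, first-degree pairs ~0.25, flagged above 0.177, the conventional
first/second-degree midpoint). Both are labelled as stand-ins in their help
pages.

# Structure inference

**PCA.** Sites are centred; missing dosages are imputed by three rounds of
rank-`min(10, n-1)` SVD reconstruction seeded with per-site means. Three
rounds suffice because the reconstruction changes little afterwards at the
missingness levels the filters admit (< 30% per site). Axis signs are fixed
by making the largest-magnitude score on each axis positive, so results are
reproducible across BLAS implementations.

**Admixture model.** The binomial likelihood
`L(Q, P) = sum_ij [ g_ij log sum_k q_ik p_kj + (2 - g_ij) log sum_k q_ik (1 - p_kj) ]`
is maximised by plain EM (the accelerated quasi-Newton optimiser of the
standard tool is intentionally not reproduced; EM keeps the monotonicity
property that the tests assert). Convergence is declared when successive
log-likelihoods differ by less than 1e-9, with a 10,000-iteration guard.
Samples with zero observed genotypes get uniform ancestry (they carry no
information). K is chosen by cross-validation: random folds of non-missing
genotype *cells* are masked, the model refit, and masked dosages scored by
squared error against `2 sum_k q_ik p_kj`; the K minimising the mean error
wins. Cell-level masking and squared-error loss are this package's choices —
the reference tool's exact CV loss is not published prose — and fold count
(default 5) is configurable.

**DAPC-style assignment.** For each axis count `a = 1..10` and each of 20
replicates: stratified 60/40 split, PCA on the training matrix (missing
cells filled with training site means), linear discriminant classifier
(`MASS::lda`) on the first `a` axes, accuracy on the held-out samples;
the reported accuracy averages the whole grid. Chance level for two equal
groups is 0.5. Splits are seeded per replicate for reproducibility.

# Differentiation and divergence

**Weir–Cockerham F_ST** uses the 1984 diploid two-level variance components
`a`, `b`, `c` with observed heterozygosity; the weighted estimate is
`sum(a) / sum(a+b+c)` over sites with at least two non-missing genotypes per
group — a ratio of sums, never a mean of per-site ratios. The estimator is
not clamped: identical groups legitimately produce small negative values.
Sites with `a + b + c <= 0` have undefined ratios and are excluded from the
outlier distribution, whose threshold is the empirical 0.99 quantile with
linear interpolation between order statistics (`quantile(..., type = 7)`,
fixed and documented).

**Hudson's F_ST** on sequence alignments is `1 - Hw/Hb` with `Hw` the
unweighted mean of the two within-group mean pairwise difference rates and
`Hb` the between-group rate, pairwise-deleting ambiguous columns.

**Windowed divergence.** Sites with more than 60% missing genotypes are
excluded; windows accumulate the next 5,000 retained positions per scaffold
("sequenced bp"), a terminal window keeps at least half that and smaller
remainders are discarded (the source convention is silent; this choice is
fixed here). Per site, `D_XY = pX(1-pY) + pY(1-pX)` and the within-group
diversities use the sample-size-unbiased `2p(1-p) * 2n/(2n-1)`. The genome
estimate is the unweighted mean over windows, matching the
"average the windows together" convention rather than weighting by window
span. Net divergence is `D_A = D_XY - 0.5 (D_X + D_Y)`, and the
divergence-time reading is the neutral approximation `t = D_A / (2 mu)`
(nuclear rate 2.30e-9, mtDNA rate 2.9e-7 per year per bp). These times are
rough by construction — rate transfer across taxa, saturation and gene flow
all bias them — and negative `D_A` is reported non-estimable rather than
clamped. Note that on simulated SNP-only matrices `D_A` is per SNP site,
not per bp; per-bp interpretation requires a callset with invariant sites.

**mtDNA distances** use Tamura–Nei (1993) with gamma rate variation at
shape 0.05 via `ape::dist.dna`. This is a documented substitute for the
maximum-composite-likelihood, composition-bias-aware distance of the
original toolchain, which no available package implements; at
control-region divergences the numerical difference is small (at one
difference per 400 bp the correction is under 5%).

**Inbreeding** is the method-of-moments
`F = (O_hom - E_hom) / (L - E_hom)` with `E_hom` from group allele
frequencies with the `2n/(2n-1)` small-sample correction; individual values
may be negative.

# f3 admixture tests

Per site, `f3_j = (x - y)(x - z) - x(1 - x)/(n_X - 1)` with sample ALT
frequencies of target X and sources Y, Z and `n_X` the non-missing
chromosome count in X; the statistic is the mean over sites. The
bias-correction term uses only the target population, the convention of the
admixture-test literature; no heterozygosity normalisation is applied.
Standard errors come from a delete-one-block jackknife over 50 consecutive
SNPs in matrix order, with a short terminal block retained at equal weight
(simple jackknife; a weighted jackknife would be the refinement). All
ordered triples of n regions give `n(n-1)(n-2)` tests — 336 for eight
regions; because the statistic is symmetric in (Y, Z) a `dedup` flag can
halve the enumeration.

# AIM panel design and concordance

Candidates are per-site F_ST ratios between the island group and all other
samples, with pooled MAF < 0.05 removed, sorted descending (ties by
coordinate). Design filters accept top candidates greedily: at least 30 bp
of flanking sequence on both sides, no non-rare variant within the flanks
("rare" interpreted as pooled MAF < 0.05 across the whole dataset, the
reading best supported by the design description), and one site per
scaffold; selection stops at the target panel size (default 11 selected,
any size accepted downstream). Reference allele frequencies are then
attached from the two reference groups (the study used 12 island and 28
eastern reference individuals).

Cross-platform concordance compares shared (sample, site) calls non-missing
in both datasets, classifying discrepancies as het-vs-hom or
opposite-homozygote, and reports the percentage rounded half-up to two
decimals (the convention of the printed 0.79% figure).

# Ancestry index and interclass heterozygosity

With class weights `pi11 = S - H/2`, `pi12 = H`, `pi22 = 1 - S - H/2` and
per-locus reference frequencies `p1, p2`, the genotype likelihood is the
three-class mixture given in `hi_loglik()`; over dosages {0, 1, 2} the
per-locus probabilities sum to one for any feasible (S, H). Estimation is
an exhaustive grid over the feasible triangle at step 0.005 followed by
Nelder–Mead refinement in the reparameterisation `H = h * 2 min(S, 1 - S)`
with `h` in [0, 1], which cannot leave the triangle; the grid optimum is
kept if refinement fails to improve it. Zero-probability genotypes
(possible with plug-in frequencies and a genotyping error) are floored at
`log(1e-300)` instead of `-Inf` — a documented softening of the strict
likelihood that stops one incompatible call from destroying an estimate.
Samples with fewer than 7 non-missing panel genotypes are skipped.

Two behaviours to know about: reference frequencies are treated as known
(no uncertainty propagated from the reference samples), and for individuals
near the triangle's apex (an F1 has H at its feasible maximum) small panels
bias H downward, because noise in S tightens the feasible cap
`2 min(S, 1-S)`. The parameter-recovery tests quantify this: at 500 loci
with |p1 - p2| = 0.8 mean recovery is within 0.03 (S) and 0.06 (H); at 10
loci the tolerances widen to 0.15 and 0.25, and a single F1's H can land
well below 1. Classification uses H >= 0.5 ("high", early-generation
hybrids), 0.25 <= H < 0.5 ("intermediate"), both boundaries inclusive at
the lower edge, plus an S > 0.5 cluster flag.

# mtDNA haplotype analyses

Uncorrected p-distances use pairwise deletion; the Neighbor-Joining tree is
`ape::nj` with negative branch lengths clamped to zero. Haplotype collapsing
treats N as incompatible — two sequences differing only at an N are *not*
merged, the conservative choice since the true base is unknown; trimming to
a well-covered interval (half-open `[start, end)` columns) is an explicit
preprocessing step with user-supplied bounds. The haplotype network is a
minimum spanning tree over Hamming distances with deterministic label-order
tie-breaks — an honest substitute for median-joining networks, which
additionally infer unobserved intermediate haplotypes and are out of scope.

# Coordinates, degenerate inputs, numerics

Coordinates are 1-based as in VCF; every internal interval is half-open
`[start, end)` (under which the control-region segment 1,169–1,747 spans
578 bp). Degenerate inputs have defined behaviour throughout: all-missing
sites are filtered with a report entry, zero-variance matrices and
empty groups raise errors, saturated TN93 pairs warn and return undefined,
`Hb = 0` makes Hudson's F_ST undefined by construction. Percentages that
mirror printed conventions round half-up (`round_half_up()`), since base
R rounds half to even.

# Problem sizes in the test suite

The suite exercises the estimators at sizes chosen to balance statistical
resolution against quick iteration: F_ST recovery at 5,000 SNPs with the
12-vs-107 island/continent sample sizes; f3 on 20,000 SNPs; (S, H) recovery
at 500 and 10 loci; cross-validated K and DAPC on 40-sample, 500–5,000-SNP
matrices; oracle comparisons on fixtures of at most ten samples or eight
sequences, where brute-force pair enumeration is exact. Passing these shows
the estimators recover parameters under the generator's assumptions —
unlinked loci, Balding–Nichols drift, missingness independent of genotype.
Real GBS data violate all three mildly (linkage, complex demography,
genotype-dependent dropout), so simulated recovery bounds are necessary,
not sufficient, evidence of field performance.

# Known limitations

* Median-joining networks, SplitsTree-style splits graphs, and the
  composition-bias MCL distance are substituted or omitted, as noted above.
* The admixture EM is slower than quasi-Newton-accelerated implementations
  near convergence; for exploratory runs a tolerance of 1e-7 is usually
  indistinguishable.
* Divergence times are point readings of `D_A / (2 mu)`; no uncertainty
  intervals are attached, deliberately.
* The sex-linkage and kinship screens are stand-ins for unpublished
  procedures and should be tuned before use on real data.
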