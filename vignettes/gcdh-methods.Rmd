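---
title: "Methods: collapsed double-heterozygosity scanning"
author: "gcdhscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapsed double-heterozygosity scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the defaults and why they were chosen, and
the limits of what the synthetic-data tests can show.

## The model

A compound heterozygote (CH) carries two different minor alleles at two
nearby variants, one on each parental haplotype (trans). A double
heterozygote (DH) carries them on the same haplotype (cis). Single-variant
GWAS regression can be blind to a CH effect because each allele's marginal
association is diluted, while the *joint* carrier state is what matters.

The GCDH test therefore collapses a pair of SNP genotypes
$(g_1, g_2) \in \{0,1,2\}^2$ into a pseudo-genotype through a total map over
the nine genotype combinations (the *collapsing matrix*). Two matrices are
built in:

* additive (alternative): $\min(g_1+g_2,\,2)$ — categories 0, 1, "2 or
  more" minor alleles. Used throughout for quantitative traits under a
  joint additive minor-allele model.
* recessive (default in the original software's nomenclature):
  $\mathbf{1}[g_1+g_2 \ge 2]$ — two categories.

The pseudo-marker is tested like a single variant: ordinary least squares of
the trait on the numeric pseudo-genotype dose plus covariates, with a
two-sided $t$ reference for the dose coefficient. The numeric (not
categorical) coding is the default because the assumed model is additive in
minor-allele count; a categorical option exists (`fitPseudoMarker(...,
categorical = TRUE)`) for completeness. CH and cis-DH land in the same
pseudo-genotype on purpose; they are separated only later, at significant
pairs.

### Window scheme and threshold

The scan slides one SNP per step over the (chromosome, position)-sorted
map. For index SNP $i$, pairing SNPs are the *downstream* SNPs on the same
chromosome within $d$ bp, pre-screened by the marginal p-filter, truncated
to at most $k$; pairs are never double-counted as $(i,j)$ and $(j,i)$ and
never span chromosomes. The minimum pseudo-marker P value in the window is
assigned to the index SNP; ties break to the smallest partner position so
results are deterministic. Since at most $k$ tests occur per window, the
genome-wide significance threshold is derived (never hard-coded) as
$\alpha/k$; the defaults $\alpha = 5\times10^{-8}$, $k = 300$ give
$1.67\times10^{-10}$.

Defaults, with units:

| parameter | default | meaning |
|---|---|---|
| `k` | 300 | max pairing SNPs (= tests) per window |
| `d` | 500000 bp | max index-partner distance |
| `pFilter` | 0.1 | marginal single-SNP P inclusion threshold |
| `rule` | `"either"` | which pair member must pass the filter |
| `alpha` | 5e-8 | genome-wide level before the per-window correction |
| `minN` | 30 | minimum complete-case n per pair |

**p-filter semantics.** Published descriptions of the filter do not pin
down whether *both* members, *either* member, or only the index SNP must
pass. Empirically, genome-wide significant pairs are reported whose first
member has a marginal P well above 0.1, which rules the "both" reading out
as the operative one. We therefore default to the weakest rule consistent
with the method's description and its reported output — a pair is eligible
when at least one member passes — and expose `both` and `index` as options.

**Missing data.** A missing call in either member yields a missing
pseudo-genotype; each test is complete-case. Pairs with fewer than two
observed pseudo-categories or complete-case n below `minN` are skipped and
counted.

### Empirical null

The distribution of window minima is strongly inflated relative to the
single-test null: each window reports the minimum of up to $k$ correlated
tests, and the p-filter preferentially admits SNPs with some marginal
signal. The genomic-inflation factor of the scan minima is therefore
expected to be far above 1 even on a null cohort — this is a property of
the statistic, not evidence of confounding. The calibrated reference is the
permutation null: the *entire* procedure (marginal GWAS, p-filter, scan) is
re-run on phenotype tables whose rows are shuffled against the sample ids
(height, sex, age and PCs move together, so the covariate structure is
preserved while the genotype-phenotype link is broken). Replicate $r$ uses
seed $+ r$; with identical seeds the pipeline is bit-reproducible.

## Diplotype inference and CH validation

At a significant pair, the four haplotype frequencies
$(f_{AB}, f_{Ab}, f_{aB}, f_{ab})$ (capitals = major alleles) are estimated
by EM on the 3×3 genotype table. Only the (1,1) class is phase-ambiguous;
the E-step splits it between cis ($AB/ab$) and trans ($Ab/aB$) proportional
to $2f_{AB}f_{ab}$ vs. $2f_{Ab}f_{aB}$, and the M-step recounts haplotypes.
Numerical choices: initialization at linkage equilibrium (products of
observed allele frequencies — the standard, well-behaved start for the
two-locus problem), tolerance $10^{-8}$ on the log-likelihood, at most 1000
iterations, monotonicity asserted at every step. Because per-locus allele
counts are observed exactly, the estimated haplotype marginals equal the
sample allele frequencies after every M-step; the tests exploit this by
checking EM against an independent profile grid search over the single free
parameter $f_{ab}$.

Each double heterozygote's posterior trans probability is
$P(\text{trans}) = 2f_{Ab}f_{aB} / (2f_{Ab}f_{aB} + 2f_{AB}f_{ab})$; the
MAP rule at 0.5 defines the CH group (the posterior itself is reported so
users can re-threshold). The validation verdict compares the CH group's
mean covariate-adjusted height to the reference group: `CH_supported` when
the difference has the sign of the GCDH effect, `no_CH_group` when no
carrier is classified trans, `other_mechanism` otherwise; CH groups smaller
than 5 carry a low-confidence flag. The reference group is taken as
pseudo-genotype 0 (no minor allele at either SNP): the published rule
mentions "the group with reference alleles" without spelling it out, and
the pseudo-0 group is the only choice that is a pure reference under both
collapsing matrices. Heights are adjusted by regressing out sex and age
(optionally PCs) before group means.

## Variance accounting

The iterative ledger reproduces the multivariable bookkeeping exactly: fit
the full joint model of sex- and age-regressed height residuals on all
predictors; record each term's $-\log_{10}P$; order terms by ascending
full-model P (ties by input order; a marginal-P ordering exists but is
non-default since the procedure is defined on the joint model); refit
nested models adding one term at a time; report each increment as that
term's R². The increments telescope to the full-model R² by construction —
the suite asserts this to $10^{-10}$ relative — and near-collinear
predictors (e.g. a pseudo-marker alongside its member SNPs) simply
contribute near-zero increments late in the order. R² is reported in
percent of the covariate-adjusted variance (the dependent variable is the
adjusted residual, so "adjusted" is the only coherent base). Polygenic
scores are weighted effect-allele sums; missing genotypes contribute the
SNP's mean dosage (standard allele-score practice). Replication is exact:
discovery-defined pairs, effect alleles and matrix are frozen, tested with
sex and age adjustment, flagged at nominal P < 0.05 with sign agreement
reported separately.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
population-genetic history:

* **LD**: Markov allele-copying within blocks — all SNPs of a block share
  one frequency drawn from `mafRange`; along the block each haplotype
  copies its previous allele with probability $\rho$ (default 0.8), else
  redraws. This is frequency-preserving and gives adjacent-site haplotype
  correlation $\rho$; blocks and chromosomes are independent. Only local
  pairwise LD matters to the scan, so no coalescent realism, recombination
  maps or admixture are attempted.
* **Positions**: cumulative $1+\text{Exponential}$ gaps (mean 5 kb), so
  distance windowing is exercised.
* **Planted pair effects** act on the collapsed additive pseudo-genotype
  $\min(g_1+g_2,2)$, so the planted and detected models coincide. A
  `chOnly` variant confines the effect to trans carriers; it is an
  extension used to exercise the diplotype stage, not a claim about any
  published analysis.
* **Phase planting**: `plantPairEffect(phase = "trans")` rearranges the
  partner locus's minor alleles across the haplotype pool so that
  both-minor haplotypes are eliminated (repulsion LD, $f_{ab}\to 0$),
  preserving both allele frequencies; `"cis"` concentrates them on
  minor-carrying haplotypes. The population-level rearrangement matters:
  merely re-phasing double-heterozygous individuals would leave the
  genotype table — the only thing EM ever sees — unchanged, and in a
  linkage-equilibrium background the trans posterior would sit at 0.5
  identically. A detectable CH locus *is* a locus whose alleles reside on
  different haplotype backgrounds, and that is what the generator creates.
* **Covariates and noise**: sex Bernoulli(0.5) with a 13 cm effect, age
  Uniform(45, 90) years at −0.05 cm/year (an elderly-cohort recruitment
  range), four standard-normal PCs at 0.3 cm each, Gaussian residual SD
  6.5 cm — a realistic covariate-adjusted adult-height residual scale.
* **Tall ascertainment**: optional appending of individuals with
  within-sex standard deviation score above 1.88 (the upper ~3% tail),
  sampled from a larger simulated pool.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: genotyping/imputation error, missingness
patterns, long-range LD and population structure (PCs here are pure noise,
not ancestry), relatedness, non-Gaussian trait tails, and real effect-size
architectures. The pipeline's statistical calibration on these cohorts is a
necessary, not sufficient, condition for validity on a real cohort.

## A note on the GCDH-vs-GWAS power contrast

With the additive planted model, the pseudo-marker of two *independent*
rare SNPs is essentially $g_1+g_2$, so its non-centrality is close to the
sum of the members' marginal non-centralities: each member's expected
association $z$-statistic is about $z_{\text{pseudo}}/\sqrt{2}$. The GCDH
threshold ($1.67\times10^{-10}$, $|z|\approx6.4$) is stricter than the
single-SNP one ($5\times10^{-8}$, $|z|\approx5.45$), so the corridor in
which a pair is a GCDH discovery while *neither* member is a single-SNP
discovery is narrow under this generative model, and maximum repulsion LD
between rare alleles is too weak to widen it. The joint event "GCDH hit and
no marginal hit" therefore has bounded probability under additive planting
at any noise level, and is rare at the generator's realistic residual SD.
The acceptance script measures this rate, together with its two components,
rather than assuming it. Strong real-data versions of the contrast (pair
$P\sim10^{-13}$ with one member at $P\sim0.4$) involve common partner
alleles and LD configurations in which the collapsing truncation is far
from linear — a regime outside the generator's planted additive model.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in a few CPU-minutes while keeping Monte-Carlo noise well
inside the asserted tolerances: null calibration at 2000 SNPs × 2000
samples with 5 permutation replicates; EM accuracy at n = 5000 against
phased truth (tolerance 0.02) and a 50-sample profile-grid oracle
(tolerance $10^{-6}$ on the log-likelihood); scan-vs-brute-force equality
on a 20-SNP × 500-sample genome; power-contrast measurement over 50
replicates at n = 4000. A median-based genomic-lambda estimate at 2000
tests has sampling SD ≈ 0.05, so the asserted [0.95, 1.05] band is a
±1-SD check at a fixed seed, not a population guarantee.

Other conventions: dosages from VCF DS fields are hard-called by
round-half-to-even (the analysis semantics need hard calls; the boundary
convention is ours, as upstream pipelines do not state one); variant
records are re-oriented at load so calls always count the minor allele,
with a lexicographic tie-break at frequency exactly 0.5; coordinates are
1-based bp; monomorphic SNPs report P = 1 with a flag; P values are
serialized in scientific notation at full precision so written tables
re-parse value-identically.

## Known limitations

Only biallelic SNPs and a single quantitative trait are supported; the GLM
layer is linear-model only (no binary traits, mixed models or relatedness
correction). Collapsing is pairwise — no >2-SNP pseudo-markers and no
exhaustive epistasis outside the d-window. Phasing is statistical and
two-locus only; pedigree or long-range phasing information is not used.
Genotype QC (call rate, HWE, imputation quality) is assumed done upstream.
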