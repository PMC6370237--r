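---
title: "Methods: mapping and characterising a recessive lethal under balancing selection"
author: "lethalmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and characterising a recessive lethal under balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lethalmap)
```

# The scientific problem

A recessive lethal allele can persist at moderate frequency in a closed
breeding population when heterozygous carriers are favoured by the
selection applied to the herd — balancing selection through heterozygote
advantage. The canonical livestock example is a premature stop codon in
*myostatin* (*MSTN*), a negative regulator of muscle growth: carriers show
more muscle and less fat (traits under index selection), while homozygous
mutants suffer a lethal leg-weakness syndrome as piglets.

`lethalmap` implements the complete inference chain used to discover and
characterise such an allele from herd data, together with a forward
simulator that generates populations with the same statistical structure,
so that every stage of the chain is testable without access to the
original animals:

1. segregation analysis of the binary syndrome (within-litter ratio test
   and Bayesian monogenic segregation analysis by Gibbs sampling);
2. variance components and heritability for the binary trait, with the
   Dempster–Lerner liability transformation;
3. case/control homozygosity mapping of the shared autozygous segment;
4. recessive candidate-variant filtering from a multi-sample VCF, with
   GATK-style site hard filters and stop-gain consequence annotation;
5. Hardy–Weinberg distortion analysis across life stages (the
   $\alpha$ statistic);
6. pedigree mixed-model association of carrier status with performance
   traits.

# The forward simulator

`simulatePopulation()` generates a closed nucleus herd:

* **Pedigree and mating.** `n_founders` unrelated founders; each later
  generation selects `n_sires` males and `n_dams` females from the
  survivors of the previous generation, mates each dam to one random
  selected sire, and draws litter sizes from a Poisson truncated at one.
  The defaults (80 founders, 9 generations, 15 sires and 35 dams per
  generation, mean litter 8) give populations of roughly 2,000–2,500
  individuals — a deliberately reduced image of the study herd
  (27,501 pedigree records over 9 generations) chosen so the whole test
  suite runs in minutes; all sizes are configurable upwards.
* **The lethal allele.** The T allele starts at founder frequency
  `q0 = 0.22` (the frequency observed in the motivating herd at birth),
  carried heterozygously by distinct founders. Every founder copy of T
  sits on one shared marker haplotype across the `ibd_window_bp` window
  (default 8.3 Mbp) around the causal position — a single-origin,
  identical-by-descent segment. Within that window recombination is
  suppressed, modelling a young mutation whose surrounding haplotype is
  effectively unrecombined at the timescale of the pedigree; this makes
  "every TT individual is homozygous across the window" an exact
  invariant rather than an approximate one. Outside the window, gametes
  recombine under a uniform 1 cM/Mbp Haldane map without interference.
* **Survival.** Genotype-dependent: by default TT piglets survive to the
  40 kg stage with probability 0.02 and never reach 110 kg (in the study,
  all but one TT died shortly after birth and none completed the test);
  GG and GT survival is equal, so any other loss is random with respect
  to genotype.
* **Phenotypes.** Leg weakness is monogenic: affected with probability
  `leg_penetrance` (default 1) iff TT, with optional polygenic, litter,
  maternal and residual components on the observed 0/1 scale.
  Muscle depth, fat depth and live weight have genotype means taken from
  the published carrier effects (GT − GG of about +4.8 mm muscle,
  −1.8 mm fat, −2.2 kg weight), and polygenic values bred down the
  pedigree as midparent plus a Mendelian-sampling deviation
  $N(0, \tfrac{1}{2}\sigma^2_a(1-\bar F_{par}))$; the inbreeding
  correction matters because the pedigree closes. Default variance
  partitions give phenotypic SDs near 5.95 mm, 2.72 mm and 7.96 kg with
  heritabilities around 0.35 — ordinary values for these traits.
* **Selection.** By default, truncation on the phenotypic index
  $I = w_m \cdot \text{muscle} - w_f \cdot \text{fat}$ with equal
  weights. Because the whole index is scale-free in the weights, the
  realised carrier advantage is governed by the genotype effect relative
  to the index noise; with the default intense truncation it exceeds the
  advantage implied by the herd's standing frequency, and the allele
  equilibrates near $q \approx 0.4$ over nine generations rather than
  holding at 0.22. This is an honest property of selecting directly on
  an individual phenotypic index: the real herd selected on smoothed
  estimated breeding values in which the single-locus effect is diluted
  by family information. Runs that need the stationary balanced state use
  `selection = "random"` together with explicit per-genotype viabilities,
  which reproduces the deterministic recursion below; the index weights
  themselves are free parameters, not calibrated claims.

Separate generators cover designs the analyses need: carrier-by-carrier
litters (`simulateCarrierLitters()`, the design behind the within-litter
ratio and the segregation sampler) and balanced half-sib designs with
litter structure (`simulateHalfSib()`, for variance-component parameter
recovery).

**What the simulator does not emulate.** Linkage-disequilibrium-realistic
genome-wide haplotype panels (founder marker alleles are drawn
independently per locus); EBV-based selection with family information;
read-level sequence data (the emitted VCF contains constructed site
records, not re-called genotypes); genotyping error (genotypes are exact
unless degraded by the caller). Passing tests therefore demonstrate that
the analysis chain recovers structure of this statistical form; they do
not validate behaviour under chip-level artefacts or real LD.

## The deterministic recursion

`deterministicRecursion()` iterates one-locus viability selection with
heterozygote-referenced fitnesses $w_{GG} = 1 - s_1$, $w_{GT} = 1$,
$w_{TT} = 1 - s_2$: $s_1$ is the carrier advantage over wildtype and
$s_2$ the homozygote disadvantage ($s_2 = 1$ for a lethal). This is the
classical overdominance parameterisation, with internal equilibrium

$$q^\ast = \frac{s_1}{s_1 + s_2},$$

so a lethal maintained at $q^\ast = 0.22$ implies
$s_1 = q^\ast/(1-q^\ast) \approx 0.28$. With $s_1 = s_2 = 0$ the
trajectory is constant and no selective equilibrium exists; the function
returns the starting frequency with a `neutral` flag.

# Segregation analysis

## Within-litter ratio test

`litterRatioTest()` pools the offspring of all litters containing at
least one affected individual and tests the pooled proportion against
0.25 (1 df $\chi^2$). Conditioning on litters with an affected case is
how the analysis is run in practice (unaffected carrier matings are not
identifiable in the herd), but it carries a small upward ascertainment
bias of roughly $0.25 \cdot P(\text{no affected in litter})$ — about
+1.5 percentage points at litter size 10 — because all-normal litters
from carrier matings are excluded. The tests therefore check the exact
Mendelian convergence on the unconditional pool, and the conditional
estimate at the two-percentage-point precision at which 23–25% is read
as consistent with a recessive.

## Bayesian monogenic model by Gibbs sampling

`gibbsSegregation()` fits a single biallelic major locus with
environmental variation. The published analysis cites its segregation
method without equations, so this package fixes a concrete model:

* founders carry genotypes in Hardy–Weinberg proportions at frequency
  $q$; transmission down the pedigree is Mendelian, and an unknown single
  parent is integrated over HWE at the current $q$;
* the phenotype (the 0/1 record, or any numeric trait) has Gaussian
  penetrance with genotype means $\mu - a$ (GG), $\mu + d$ (GT),
  $\mu + a$ (TT) and residual variance $\sigma^2_e$ — the scale on which
  a fully penetrant recessive has $a = 0.5$, $d = -0.5$. A probit
  penetrance would be a natural extension but is not the default, as the
  published effects are reported on the 0/1 scale.

The sampler is a single-site Gibbs scheme: each individual's genotype is
drawn from its full conditional (parent transmission × transmission to
offspring with current mates × phenotype likelihood; implemented in
compiled code), $q$ from its conjugate Beta update on founder allele
counts (prior Beta(1,1)), $(\mu, a, d)$ jointly through the saturated
genotype-class means with improper flat priors, and $\sigma^2_e$ from
the flat scaled-inverse-$\chi^2$ ($\nu = -2$). Defaults: 20,000
iterations, 5,000 burn-in, thinning 5, mandatory seed.

Numerical and degenerate-case rules:

* **Identifiability.** The likelihood is invariant to relabelling the
  alleles ($q \leftrightarrow 1-q$, $a \to -a$, genotype classes
  mirrored). Retained draws are mapped to the $a \ge 0$ orientation, so
  mirrored data give mirrored summaries — verified as a test property.
* **Empty genotype classes.** Under the flat prior the full conditional
  of an unoccupied class mean is improper; the sampler retains the
  current value until the class is repopulated. On monomorphic data the
  chain therefore reports $q$ near a boundary and an `a` draw that never
  updates, without error.
* **Residual floor.** $\sigma^2_e$ is floored at $10^{-10}$ to keep the
  likelihood finite on noise-free data.
* **Initialization.** Single-site updates cannot escape a state in which
  both parents of a clearly affected offspring are homozygous wildtype:
  the offspring's full conditional is then degenerate at GG whatever its
  phenotype says. The chain therefore starts from a likelihood-aware,
  Mendelian-consistent configuration — a provisional three-class split
  of the phenotype range, repaired upward (parents of carriers and
  homozygotes are made carriers) and downward (children incompatible
  with their parents are moved to the nearest legal dosage) — which
  places it in the phenotype-supported mode before sampling begins.
* **Oracle mode.** `fix_params` holds $(q, \mu, a, d, \sigma^2_e)$ fixed
  and samples genotypes only, making the genotype posteriors directly
  comparable with the exact-enumeration oracle
  `exactSegregationPosterior()` (brute-force sum over all $3^n$
  configurations, $n \le 10$), which is itself cross-checked against a
  second, independently coded enumeration in the tests.

The posterior summary includes the share of phenotypic variance
attributable to the locus (frequency-weighted variance of the class
means against $\sigma^2_e$); on pure-noise phenotypes this share sits
near zero, which is the package's operational reading of "almost all
variation explained by a single locus" — no published statistic exists
for it, so no numeric claim is attached.

# Variance components and heritability

`gibbsVarComp()` fits the observed-scale linear mixed model
$y = X\beta + Z_1 u + Z_2 v + Z_3 w + e$ for the 0/1 record by a blocked
conjugate Gibbs sampler: fixed effects and each random term from their
multivariate-normal full conditionals via the mixed-model equations,
variances from scaled-inverse-$\chi^2$ full conditionals (flat,
$\nu = -2$). Genetic terms (sire, dam, or animal) carry
$A\sigma^2$ covariance with $A$ the pedigree numerator relationship
matrix; litter and maternal-environment terms are identity-structured.
Identity-structured blocks have diagonal normal equations and are drawn
in vectorised form; A-structured blocks use a dense Cholesky (the study
scale keeps these small). Variances are floored at $10^{-8}\,
\mathrm{var}(y)$ instead of truncating at zero; posterior mass near the
floor is the boundary diagnostic.

The published liability-scale analysis used a logit threshold model in
proprietary software; that route is deliberately **not** reimplemented.
The supported path is the observed-scale model plus the Dempster–Lerner
transformation
$h^2_{liab} = h^2_{obs}\, p(1-p)/z^2$ with $z$ the standard normal
density at the threshold $\Phi^{-1}(1-p)$ (`liabilityTransform()`); the
published study reports both routes, and its printed variance-component
table serves here only as a worked example for the heritability
formulas. `heritability()` uses $4\sigma^2_s/\sigma^2_p$ for sire
models and $2(\sigma^2_s + \sigma^2_d)/\sigma^2_p$ for sire-and-dam
models; the sire-only convention is implied by the printed 0.71 rather
than stated, and estimates above 1 (possible in small samples) are
flagged, not truncated.

# Homozygosity mapping

`filterInformative()` retains autosomal SNPs that are neither fixed nor
completely heterozygous. `longestSharedSegment()` then finds, per
chromosome, maximal runs of consecutive SNPs at which all non-missing
cases are homozygous for the same allele, ranking runs by SNP count
(ties: bp span, then chromosome and position). Conventions:

* missing case genotypes do not break a run (the chip-data source is
  silent on missingness) but are counted and reported;
* coordinates are 1-based inclusive; the bp span is `last − first`,
  the convention under which the mapped interval
  86,745,668–95,062,143 reads as 8.3 Mbp;
* `allow_case_het` tolerates a configurable number of discordant cases
  per SNP (default 0, the strict headline analysis); the knob exists
  because one unaffected control shared the mapped segment in the study,
  so borderline sample classification is a realistic concern;
* the count of SNPs in the maximal run after the global informativeness
  filter is reported as the segment's SNP content; no additional
  per-segment informativeness criterion is applied (whether the original
  55-SNP count used one is not stated).

`summaryRows()` renders the per-group consensus rows (any heterozygote
→ heterozygous; all homozygous for one allele → that allele), the rule
used for the summary lines of the published mapping figure.

# Candidate-variant filtering and consequence annotation

`siteHardFilter()` applies the standard site-level hard filters with the
printed operators taken literally as strict inequalities — a site at
exactly QD = 2.0, FS = 60.0, MQ = 40.0, MQRankSum = −12.5,
ReadPosRankSum = −8.0 passes. Missing metrics cannot fail their clause
and are flagged. `candidateFilter()` implements the recessive
segregation pattern — cases homozygous for one shared allele, obligate
carriers heterozygous, controls homozygous for the other allele — with
the relaxed variants (one heterozygous case, or one carrier homozygous
for the non-case allele) motivated by low sequencing depth limiting
heterozygote detection. Missing genotypes never count against a clause
but are tallied per group. Multi-allelic records are decomposed to
biallelic sites on reading (`readVcfVariants()`, via `vcfR`). InDels
pass through the candidate filter but `annotateConsequence()` rejects
them: consequence annotation supports SNVs only.

`annotateConsequence()` maps a genomic SNV onto a `GeneModel` (CDS exon
intervals plus the genomic sequence of the gene span), honouring strand,
and translates the affected codon with the standard genetic code,
emitting HGVS-like `c.` and `p.` strings. The bundled
`syntheticMstnModel()` is a fully synthetic three-exon, 376-codon gene
model emulating the structure of the porcine myostatin locus (codon 274
= GAA, so `c.820G>T` yields `p.E274*`); it is a structural stand-in
labelled as synthetic — the real sequence is not redistributed. The
candidate count of the original sequence analysis (40 SNPs in the mapped
interval) depends on raw read data that this package does not consume,
and is replaced by structural tests on simulator-emitted VCFs with
planted truth.

# Hardy–Weinberg distortion across life stages

For genotype counts $(n_{GG}, n_{GT}, n_{TT})$, `cohortStats()` computes
$q$ by counting, $H_{obs} = n_{GT}/n$, $H_{exp} = 2q(1-q)$,
$\alpha = 1 - H_{obs}/H_{exp}$, and the 3-class HWE $\chi^2$ with the
allele frequency estimated from the data (1 df, no continuity
correction) — the convention under which $\chi^2 = n\alpha^2$ holds as
an algebraic identity, consistent with the published values
($486 \times 0.019^2 \approx 0.18$). Two documentation notes: random
mating in a dioecious population gives a slightly negative expected
$\alpha$ of order $-1/(2N)$, which reports surface but do not test
against; and the published "P > 0.001" at the distorted 110 kg stage is
treated as a typographical artifact, since $\chi^2 = 11.45$ on 1 df has
$p < 0.001$.

The per-stage table distributed with the package
(`syntheticCohortCounts()`) is a synthetic reconstruction: integer
counts found by search so that every printed per-stage statistic is
reproduced exactly at printed precision; the original per-genotype
supplement is not redistributed, and the reconstructed totals differ
slightly from the narrative cohort sizes (485 vs 486 at birth, 259 at
110 kg). `genotypeChangeTest()` runs the contingency $\chi^2$ on the GG
and GT classes only — no change there, combined with HWE distortion
driven by TT, is the signature of selective loss of homozygotes rather
than selection against the allele.

# Association analysis

`fitAssociation()` estimates the carrier effect (GT vs GG; 1 df because
no mutant homozygote completes the test) under
$y = X\beta + gb + Zu + e$, $u \sim MVN(0, A\sigma^2_a)$. The variance
ratio $\lambda = \sigma^2_e/\sigma^2_a$ is profiled out of the residual
(REML) likelihood on a 50-point log grid over $[10^{-3}, 10^3]$ with
local refinement at the maximiser (via an eigendecomposition of $A$, so
each $\lambda$ costs a weighted least squares, not a new factorisation).
Wald tests, the effect standardised by the phenotypic SD
($\sigma_P = \sqrt{\sigma^2_a + \sigma^2_e}$), and least-squares
genotype means at covariate means are reported; whether the published
genotype means are raw or adjusted is not stated, so the adjusted-means
convention is documented here. Two deviations from the original
analysis: the cubic smoothing splines for test start date are replaced
by categorical batch covariates (splines are an extension hook), and
`locusVarianceShare()` implements an explicit convention — locus
variance = frequency-weighted variance of genotype means, share =
locus/(locus + background polygenic) — because the formula behind the
published "31% / 18% of genetic variance" is not given; those figures
are therefore not directly verifiable and are not asserted anywhere.

# Reproducibility and problem sizes

All stochastic stages draw their seeds from one master seed through a
named-stream splitter, so each stage is independently reproducible and
pipeline reruns are byte-identical. The test suite and the acceptance
script use deliberately reduced problem sizes chosen as the package's
own testing conditions: populations of a few thousand individuals,
500–800 carrier litters (about 4,000–8,000 offspring) for segregation
checks, marker panels of 60–700 SNPs, and chains of 20,000 iterations
for headline posterior summaries (shorter chains for smoke tests).
Under these conditions the segregation sampler's posterior means of
$(a, d)$ on a fully penetrant recessive land within 0.02 of
$(0.5, -0.5)$.

# Known limitations

* Single-site genotype updates can mix slowly through extended loops of
  related, unphenotyped individuals, and switch only slowly between the
  near-symmetric labellings of two phenotypically overlapping genotype
  classes (for the recessive 0/1 trait, GG and GT both sit at zero), so
  posterior means of class contrasts carry a small extra Monte-Carlo
  wobble of order 0.01 at the tested scales. Blocked peeling updates are
  the standard remedy and are out of scope here. Mixing at the tested
  scales is verified against exact enumeration.
* The small-sample posterior of the monogenic model is genuinely
  multimodal (a monomorphic-locus mode explains anything as noise);
  parameter summaries are meaningful at the data sizes the tests use,
  not on ten-individual pedigrees.
* Dense relationship matrices cap practical pedigree sizes at a few tens
  of thousands; the sparse-inverse (Henderson) machinery is a listed
  extension, not implemented.
* The variance-component sampler is for the observed scale; no
  generalized linear mixed model with logit link is provided, so the
  published threshold-model components are not reproducible here by
  design.
* Consequence annotation handles SNVs against a single gene model; it is
  not a general-purpose annotator (no InDels, no splice-site classes,
  no transcript databases).
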