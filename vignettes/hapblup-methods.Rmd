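---
title: "Comparing SNP, pseudo-SNP and high-LD SNP information in single-step genomic evaluation"
author: "hapblup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing SNP, pseudo-SNP and high-LD SNP information in single-step genomic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question the package addresses

Genomic evaluation of dairy cattle usually treats each SNP as an
independent marker. Because selection moves whole chromosome segments
rather than single loci, markers in strong linkage disequilibrium (LD)
carry correlated signal, and that correlation can be exploited in at
least three ways:

* **SNP_ALL** — use every SNP that survives quality control;
* **HAP_PSEUDOSNP** — detect haplotype blocks of contiguous SNPs in high
  LD, enumerate the haplotype alleles of each block, and recode every
  common allele as one biallelic *pseudo-SNP* whose dosage is the number
  of copies an animal carries;
* **SNP_HAP** — keep only the individual SNPs that form those blocks,
  discarding markers outside high-LD regions.

`hapblup` implements all three marker constructions behind one shared
evaluation pipeline — single-step GBLUP breeding values, back-solved
marker effects with p-values, explained genetic variance, and
prediction-error-variance reliabilities — so that the only difference
between analyses is the marker matrix. A synthetic-population generator
with the same record structure makes every stage testable without any
external data.

## The evaluation model

Each lactation record is modelled as

$$y_{ijklmn} = \mu + HYS_i + AGE_j + PE_k + SH_l + ANI_m + e_{ijklmn}$$

with fixed herd-year-season contemporary groups ($HYS$; two six-month
seasons per year) and calving-age classes ($AGE$; classes 1–9, three per
lactation with cut-offs 23.4/25.5, 35.9/39.5 and 48.7/53.3 months), and
random permanent-environment ($PE$), sire-herd interaction ($SH$), animal
additive ($ANI$) and residual terms. Variance components are user inputs
(`simConfig(variance_components = ...)`); no REML estimation is
performed, because in the intended use the simulator knows the truth and
in real use the components come from the routine evaluation.

The animal effect is correlated across animals through the single-step
relationship structure

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & \tau G^{-1} - \omega A_{22}^{-1} \end{bmatrix},$$

where $A$ is the pedigree numerator relationship matrix (tabular method;
sparse inverse by Henderson's rules with Meuwissen–Luo inbreeding), $G$
is the VanRaden method-1 genomic matrix $M M' / (2\sum p_i q_i)$ built
from the analysis' marker set (columns centred at $2p_i$, missing
dosages mean-imputed), and $A_{22}$ is the pedigree block of the
genotyped animals. By default $G$ is tuned so its mean diagonal and
off-diagonal match $A_{22}$ and blended as $0.95\,G + 0.05\,A_{22}$, with
$\tau = \omega = 1$; all four knobs are exposed. Tuning and blending are
standard conditioning of ssGBLUP systems (the observed-frequency $G$ is
singular by construction), and the defaults follow common practice.

Mixed-model equations are assembled with effect order (fixed, PE, SH,
animal) and solved by dense factorization — the package targets desk
scale, where an exact solve and exact inverse are affordable.
Reliability uses the inverse coefficient matrix:

$$\mathrm{PEV}_i = (C^{-1})_{ii}\,\sigma^2_E, \qquad
  \mathrm{Rel}_i = 1 - \frac{\mathrm{PEV}_i}{\sigma^2_A (1 + F_i)},$$

where $\sigma^2_A$ is the additive genetic variance only and $F_i$ the
pedigree inbreeding coefficient. Reliabilities outside $[0,1]$ (possible
under blending mismatches) are clamped and counted, not errors.

## ssGWAS back-solving

Marker effects are recovered from the genotyped animals' breeding values
as

$$\hat a = k\, D\, Z' G^{-1} \hat u, \qquad k = \frac{1}{2\sum p_i q_i},$$

with $Z$ the centred marker matrix and $D$ a diagonal weight matrix —
identity by default (a single pass, the common default of
post-evaluation GWAS tools), or VanRaden weights
$d_i \propto \hat a_i^2\, 2 p_i q_i$ normalised to trace $m$ and iterated
on request. Standard errors use exact error propagation of the
prediction-error covariance of $\hat u$ through $B = k D Z' G^{-1}$,
p-values are the two-sided normal scores
$2(1 - \Phi(|\hat a_i| / \mathrm{sd}(\hat a_i)))$, and the genome-wide
threshold is Bonferroni, $-\log_{10}(\alpha/m)$ with $\alpha = 0.01$,
applied with strict inequality. Explained genetic variance is
$2 p_i q_i \hat a_i^2$ per marker, summed for the total; the formula
assumes Hardy–Weinberg equilibrium and ignores LD covariance between
markers, so totals can be inflated in dense high-LD sets — it is
reported as defined, without de-correlation.

With identity weights and an unblended, invertible $G$, back-solving is
algebraically identical to the ridge (SNP-BLUP) solution of the
equivalent marker-effects model; the test-suite verifies this
equivalence to $10^{-6}$ on fully genotyped instances.

## Haplotype blocks and pseudo-SNPs

LD is measured as $r^2$ from phased haplotype counts:
$D = p_{AB} - p_A p_B$, $r^2 = D^2 / (p_A q_A p_B q_B)$. The simulator
provides phase; real unphased data must be phased upstream, since
EM-based unphased estimation is out of scope.

A block is a run of contiguous markers in which **every pair** satisfies
$r^2 \ge 0.80$, the run spans at most 200 kb, and at least two SNPs
participate. Detection is a greedy left-to-right scan that extends the
current run until the first failing marker, emits the block, and
restarts at that marker, so blocks form a disjoint partition into
maximal runs favouring the earlier start. The all-pairs rule was chosen
over an adjacent-pair rule because it makes the quantitative threshold
statement exact for every marker pair inside a block; the adjacent-pair
variant is available (`pair_mode = "adjacent"`). The 200 kb cap matches
the span scale at which pairwise LD in cattle decays well below the
threshold. Monomorphic markers, whose $r^2$ is undefined, never join or
start a block. A confidence-interval (Gabriel/Taliun-style) block
definition is deliberately not implemented.

Every haplotype allele of a block with population frequency above 1% is
recoded as a biallelic carrier-versus-rest pseudo-marker. This framing
lets the pseudo-SNP set flow through the same QC, $G$ construction and
GWAS code as real SNPs. With no frequency filtering the per-animal
per-block dosages sum to exactly 2 (two chromosomes), and each retained
column's allele frequency equals its haplotype-allele frequency —
both are tested invariants. Pseudo-marker map positions are the block
midpoint (offset by 1 bp per extra allele of the same block); the
original pipeline's mapping rule is unreported, and the midpoint keeps
block-to-position provenance invertible, which the overlap reports use.

## Quality control

Animals are screened first (call rate < 0.95 on the full marker set, or
an opposing-homozygote conflict rate ≥ 1% with any genotyped parent,
taken per parent), then markers on the surviving animals (monomorphic,
MAF < 0.05, call rate < 0.95, Hardy–Weinberg screen). The order is fixed
but reversible via a flag, since reversing it can change the result. The
HWE screen removes a marker when the 1-df chi-square p-value falls
below 0.15, even though QC tools conventionally threshold
the heterozygote-frequency deviation instead; both semantics are
implemented behind `hwe_mode`, with the p-value rule as default. QC is
idempotent once the animal set is stable (e.g. complete calls); with
missingness, a second pass can only shrink the kept set, because marker
removal re-weights animal call rates.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not cattle population history:

* **Pedigree** — founders plus `n_generations` cohorts of constant size;
  dams from the previous cohort, sires from a restricted pool
  (`sire_ratio`, default 0.25 of available males), emulating narrow sire
  usage. Mating is random; no selection.
* **Founder LD** — markers come in ancestral blocks (sizes
  $1 + \mathrm{Poisson}$, mean ≈ 3.5 SNPs) with tight within-block
  spacing (5–25 kb) and wide between-block gaps; each block carries a
  small pool of ancestral haplotype alleles (default 4) from which
  founder gametes draw independently per block. Markers following the
  block's primary pool bipartition (probability 0.85) are in complete
  mutual LD; the remainder follow an alternative split, so detected
  blocks have realistically imperfect $r^2$ structure. This gives direct
  control of block LD without a coalescent simulator.
* **Meiosis** — Haldane model: Poisson crossover counts in the
  chromosome map length (1 cM/Mb), uniform positions, no interference.
  Independent assortment across chromosomes.
* **QTL** — sampled among markers, by default only inside multi-SNP
  blocks (`qtl_in_blocks`); effects i.i.d. normal. When
  `qtl_effect_sd = NULL` (default) the draw is rescaled by one common
  factor so the Hardy–Weinberg additive variance $2\sum p q \beta^2$
  equals `sigma2_A` — this anchors the variance components of the record
  model to the simulated genome, which the reliability formula requires
  to be meaningful. A numeric `qtl_effect_sd` is honoured untouched.
* **Records** — every female gets lactations 1–3 with herd-year-season
  and age-class fixed effects drawn once per level
  (SDs `hys_effect_sd` = 0.5, `age_effect_sd` = 0.2 trait units),
  a PE deviation constant within cow, an SH deviation constant within
  sire-herd pair, and i.i.d. residuals. Default variance components
  (0.30, 0.15, 0.05, 0.50) give heritability 0.30 and repeatability 0.45
  — a plausible regime for yield traits.
* **Genotyping** — the youngest two generations are genotyped; dosage
  entries can be masked missing uniformly at random. The phased panel is
  never masked.

All randomness derives from one master seed (`simConfig(seed = )`);
child streams are fixed draws from it, so every artefact is reproducible
bit for bit.

What the generator does **not** emulate: selection history and the LD it
creates between unlinked loci, non-random mating, genotyping-array
ascertainment bias, imputation errors, age/parity trends in variance,
heterogeneous herd sizes, or multi-trait covariance. Passing tests
therefore demonstrate internal correctness of the machinery and the
qualitative mechanism (high-LD marker subsets concentrate signal), not
quantitative transferability to any real population.

## Numerical and design choices

* Dense linear algebra throughout; sparse storage only for incidence
  matrices and $A^{-1}$. Problem sizes used by the test-suite: pedigrees
  of 1500 animals (300 founders, five cohorts), 2000 markers on five
  chromosomes, 600 genotyped animals, 40 QTL, ten replicate seeds —
  sizes at which exact solves and exact inverses are comfortable on a
  single core.
* Fixed effects use drop-first-level reference coding; columns that
  remain aliased (e.g. sparse herd-year-season cells nested in an age
  class) are detected by pivoted QR and dropped with a message, the
  standard estimability handling of evaluation software.
* Rounding of the somatic cell score is half-up before clamping to 0–9;
  the published scale gives anchors only (0 = 12.5, doubling to
  9 = 6400 thousand cells/mL).
* `blendTuneG` verifies invertibility (Cholesky) only when blending is
  actually applied ($\alpha < 1$); $\alpha = 1$ returns $G$ untouched.
* Markers with zero effect-standard-deviation are excluded from testing
  but retained in explained-variance totals with zero contribution.
* Significant pseudo-SNPs are reported as their block span
  (start–end bp) so overlap with individual-SNP results is well defined;
  each pseudo-SNP column counts once.
* The reliability ANOVA treats animals as independent units, as is
  customary in comparisons of this kind; with relatives this is
  anti-conservative, and it is documented rather than "fixed".

## Limitations

The explained-genetic-variance totals ignore LD covariance and can
exceed the simulated additive variance in dense high-LD marker sets.
Reliabilities are exact for the model as specified but inherit any
mismatch between the blended $H$ and the true genetic covariance.
The command-line surface is the R API plus `scripts/acceptance.R`;
there is no standalone shell tool. Genotype imputation, REML,
metafounders, APY inverses and multi-trait models are out of scope.
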