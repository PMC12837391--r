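# hapblup

Single-step genomic evaluation and association analysis in dairy cattle,
comparing three sources of genomic information on one shared pipeline:

* **SNP_ALL** — all quality-controlled SNPs;
* **HAP_PSEUDOSNP** — haplotype blocks of contiguous SNPs in high linkage
  disequilibrium (all pairwise r² ≥ 0.80, span ≤ 200 kb, ≥ 2 SNPs), with
  every common haplotype allele (frequency > 1%) recoded as a biallelic
  *pseudo-SNP* counting copies carried (0/1/2);
* **SNP_HAP** — only the individual SNPs that form those blocks.

The question the package operationalises: does concentrating the marker
set on high-LD regions increase the explained genetic variance and the
reliability of genomic breeding values, relative to using all SNPs?

## The model

Breeding values come from single-step GBLUP on a repeatability animal
model for lactation records,

y = μ + HYS + AGE + PE + SH + ANI + e,

with fixed herd-year-season and calving-age classes and random
permanent-environment, sire-herd, animal and residual effects. The
animal effect uses the single-step relationship inverse

H⁻¹ = A⁻¹ + [0 0; 0 τG⁻¹ − ωA₂₂⁻¹],

where G is the VanRaden genomic matrix MM′/(2Σpᵢqᵢ) of the analysis'
marker set (tuned and blended against A₂₂ by default). Marker effects
are back-solved from the genotyped animals' GBVs,

â = k D Z′ G⁻¹ û,  k = 1/(2Σpᵢqᵢ),

with exact standard errors from the prediction-error covariance,
two-sided normal p-values 2(1 − Φ(|âᵢ|/sd(âᵢ))), Bonferroni thresholds
−log₁₀(α/m), per-marker explained genetic variance EXGVᵢ = 2pᵢqᵢâᵢ², and
per-animal reliability 1 − PEVᵢ/(σ²A(1 + Fᵢ)). A synthetic-population
generator (block-structured founder haplotypes, gene dropping, additive
QTL, repeated lactation records) exercises everything end to end; see
`vignettes/hapblup-methods.Rmd` for the methods account.

## Worked example

```r
library(hapblup)

cfg <- simConfig(n_founders = 100, n_generations = 3, n_chromosomes = 3,
                 markers_per_chromosome = 150, n_qtl = 20, seed = 2024)
ds <- simulateDataset(cfg)

blocks <- detectBlocks(ds$genotyped_panel)
blockSummary(blocks)$overall
#>   n_blocks snps_mean  snps_sd snps_min snps_max span_kb_mean span_kb_min span_kb_max
#> 1      119  3.092437 1.193141        2        7     31.28024       5.166      93.323

cmp <- runComparison(ds)
cmp$report
#> Explained genetic variance:
#>        analysis marker_count       exgv
#> 1       SNP_ALL          362 0.02487446
#> 2 HAP_PSEUDOSNP          193 0.04146133
#> 3       SNP_HAP          300 0.02586570
#> Reliability of GBVs:
#>        analysis   n      mean          se letters
#> 1       SNP_ALL 200 0.4936107 0.007069303       b
#> 2 HAP_PSEUDOSNP 200 0.5067673 0.007128092      ab
#> 3       SNP_HAP 200 0.5173641 0.006806358       a
#> ANOVA: F = 2.888, p = 0.0565
```

Reading the output: 119 LD blocks were detected (about 3.1 SNPs and
31 kb each). The haplotype-informed marker sets explain more genetic
variance than the full SNP set despite containing fewer markers, and
mean GBV reliability rises from SNP_ALL through HAP_PSEUDOSNP to
SNP_HAP; the letters are Tukey groupings from a one-way ANOVA across
the three analyses. Per-marker effect tables (`cmp$results[[i]]$gwas$table`)
carry id, position, allele frequencies, â, sd(â), p-value, −log₁₀ p and
EXGVᵢ for Manhattan plots and significance reports.

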