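# vcqtl

Genome-wide mapping of QTL that control trait **variances** and trait
**covariance structure** in biparental recombinant inbred line (RIL)
populations — for quantitative geneticists asking not *"which locus shifts
the mean?"* but *"which locus canalizes the trait, reshapes the G matrix, or
drives genotype-by-environment interaction?"*

The package grew out of flowering-time phenology in a selfing crucifer: 178
F6 RIL families from a cross between two homozygous parents (`CO` x `MT`),
genotyped at 164 markers on 7 linkage groups and phenotyped as family means
in six growth-chamber environments, plus heterogeneous inbred family (HIF)
greenhouse experiments that test the focal locus against fixed genomic
backgrounds.

## What it computes

**Single-trait variance QTL (genetic canalization).** Per marker, the
Brown–Forsythe statistic contrasting the two homozygote classes — the Levene
one-way F on absolute deviations from the class medians,

    F = (N − 2) · Σᵢ nᵢ(z̄ᵢ − z̄)² / Σᵢⱼ(zᵢⱼ − z̄ᵢ)²,  zᵢⱼ = |yᵢⱼ − median(yᵢ)|

with genome-wide significance from maximum-statistic permutations
(whole trait vectors shuffled against the genotype matrix; `perm_p` =
fraction of permutation genome-wide maxima at or above the observed value).
Markers with minor class frequency < 0.33 are excluded. For significant
markers the pooled variance decomposes exactly as
`Vp = pq(μ_CO − μ_MT)² + pq(σ_CO − σ_MT)² + (pσ_CO + qσ_MT)²`, giving the
shares `Vm/Vp` (mean difference) and `Vv/Vp` (variance difference).

**Covariance-structure QTL (constraint and GxE).** Per marker, the two
class G matrices of family means are compared by: trace-form Box's M
(`M = N ln S − Σ Vᵢ ln Sᵢ`, size), the angle between leading eigenvectors
reflected into [0, π/2] (orientation), and the Krzanowski common-subspace
index (sum of eigenvalues of AᵀBBᵀA over the first k ≤ p/2 axes; the scan
statistic is the negative index). Same permutation machinery.

**HIF mixed models.** REML fits of
`response ~ genotype * HIF + (1|Family) + (1|Block)` with Type III F tests,
containment denominator df, and likelihood-ratio chi-squared tests for the
random terms; delta-Ct expression analysis (`ΔCt = Ct_reference − Ct_target`)
and the bud–expression association test.

**Threshold-model simulator.** Because the original RIL phenotypes are not
deposited, a tested generative model reproduces the structure the scans
assume: selfing descent under the Haldane map function, and flowering gated
by a sigmoid signal integrator `y = 1/(1 + exp(a(−x + b_G)))` whose threshold
depends on the focal genotype, producing bimodal season-1/season-2 flowering
around a 180-day boundary, environment-dependent and *reversible*
canalization, and HIF designs with controllable epistasis. See the methods
vignette (`vignettes/variance-qtl-mapping.Rmd`) for every model parameter and
calibration decision.

## A worked example

```r
library(vcqtl)
library(dplyr)

map   <- sim_genetic_map()                      # 164 markers, 7 linkage groups
geno  <- sim_ril_genotypes(map, seed = 11)      # 178 F6 families
model <- threshold_model(map)
pheno <- sim_threshold_phenotypes(geno, model, seed = 12) |>
  standardize_phenotypes()

scan <- scan_variance(geno, pheno, "flowering_time@12h18C4w",
                      map = map, n_perm = 1000, seed = 13)
glance(scan)
#> # A tibble: 1 × 6
#>   method         trait                   n_markers n_perm top_marker min_perm_p
#> 1 brown_forsythe flowering_time@12h18C4w       164   1000 m01_012             0

tidy(scan) |> arrange(perm_p, desc(statistic)) |> head(3)
#>   marker  linkage_group    cM statistic perm_p  n_CO  n_MT
#> 1 m01_012             1  60.5      48.5      0    86    87
#> 2 m01_011             1  55        23.4      0    88    84
#> 3 m01_009             1  44        22.1      0    89    81
```

The genome-wide top hit is `m01_012` — the simulator's focal threshold locus.
Its Brown–Forsythe F of 48.5 beats all 1000 permutation maxima (`perm_p = 0`;
use `correction = TRUE` for a never-zero estimate). In this slightly
inhibiting environment the high-threshold `CO` class splits between the two
flowering seasons while `MT` is saturated, so the marker controls variance,
not just the mean. The decomposition of the pooled variance at that marker:

```r
v   <- pheno |> filter(trait_id == "flowering_time@12h18C4w")
cls <- geno$m01_012
decompose_variance(v$value[cls == "CO"], v$value[cls == "MT"]) |>
  select(Vm_over_Vp, Vv_over_Vp)
#>   Vm_over_Vp Vv_over_Vp
#> 1      0.186      0.289
```

— 19% of the trait variance comes from the class mean difference and 29%
from the class variance difference. The same objects feed the covariance
scans (`scan_covariance(..., method = "boxm" | "gmax_angle" | "krzanowski")`)
and `autoplot(scan)` draws the genome scan. A HIF analysis of the bundled
*synthetic* example data:

```r
d <- read_hif_table(system.file("extdata", "synthetic_hif_phenotypes.tsv",
                                package = "vcqtl"))
fit_hif_mixed_model(d, "Flowering_time")
#> Mixed-model ANOVA (Flowering_time, 72 observations, containment df)
#>   nFT_genotype           F_1,44 =   107.47   p = <0.001
#>   HIF                    F_3,16 =    66.96   p = <0.001
#>   nFT_genotype:HIF       F_3,44 =    25.05   p = <0.001
#>   Family                 chi2_1 =     0.0   p = 0.886  (random)
#>   Block                  chi2_1 =     0.0   p = 1  (random)
```

The significant genotype-by-HIF interaction is the epistasis signature: the
focal locus's effect depends on the genomic background. A thin command-line
wrapper covers the same pipeline
(`Rscript inst/cli/vcqtl.R simulate|scan-var|scan-cov|hif-anova ...`).

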