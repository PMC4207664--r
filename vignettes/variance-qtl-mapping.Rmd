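---
title: "Mapping variance- and covariance-controlling QTL: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping variance- and covariance-controlling QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcqtl)
library(dplyr)
options(vcqtl.verbose = FALSE)
```

## The problem

Most QTL mapping targets loci that shift a trait's *mean*. This package maps
loci that control a trait's *variance* and the *covariance structure* among
traits — three faces of the same phenomenon:

* **Genetic canalization** — one locus's genotype suppresses (or releases) the
  phenotypic variance contributed by the rest of the segregating genome. In a
  biparental RIL population it shows up as unequal among-family variance
  between the two homozygote classes at a marker.
* **Genetic constraint** — the genetic covariance between different traits in
  the same environment (the **G** matrix), which shapes how multivariate
  selection can move the population.
* **Genotype-by-environment interaction (GxE)** — treating the same trait in
  different environments as separate traits, GxE is the off-diagonal structure
  of their G matrix, so the same machinery applies.

The motivating system is flowering phenology in a selfing crucifer: a
biparental RIL cross between two homozygous parents (labelled `CO` and `MT`
throughout), phenotyped as family means for flowering time and leaf number at
flowering in six growth-chamber environments (three ambient regimes x two
vernalization lengths), with a major phenology QTL segregating alongside many
small-effect flowering-time loci.

## Single-trait variance scan

At each marker the families are split by homozygote class (heterozygous and
missing calls dropped) and compared with the **Brown–Forsythe** statistic —
the Levene one-way F computed on absolute deviations from each class median:

$$
z_{ij} = |y_{ij} - \tilde y_i|, \qquad
F \;=\; \frac{(N-2)\sum_i n_i(\bar z_i - \bar z)^2}{\sum_{ij}(z_{ij}-\bar z_i)^2 }.
$$

Median centring makes the test robust to non-normal, skewed family-mean
distributions — essential here, where the interesting signal *is* a bimodal
mixture. `brown_forsythe()` is location-invariant and is verified in the test
suite against an independently implemented Levene-median oracle to 1e-10.

**Genome-wide significance** uses the maximum-statistic permutation method:
whole trait vectors are shuffled against the genotype matrix (family genotype
vectors and trait values are never broken apart), the genome-wide maximum
statistic of each permuted data set forms the null, and

$$\text{perm\_p}(m) = \frac{\#\{\text{permutation maxima} \ge F_m\}}{n_\text{perm}}.$$

Design choices:

* p-values are reported **without** the add-one correction, so a marker that
  beats all permutation maxima reports `p = 0`; `correction = TRUE` gives the
  never-zero `(k+1)/(n+1)` estimate instead.
* Ties (`>=`) count against the observed marker — the conservative direction.
* One shared null per scan (trait x environment), as the family-wise
  max-statistic method requires.
* Markers with minor genotype-class frequency below `maf_min = 0.33` are
  removed before scanning (`filter_maf()`), mirroring the exclusion of
  distorted markers whose class variances would rest on few families.
* Missing genotype calls are dropped per marker (family means exist for all
  families; only calls are missing). Missing phenotypes are kept by the
  readers and dropped pairwise by each analysis — the upstream study does not
  state its policy, so the package documents this one rather than guessing.

For a significant marker, `decompose_variance()` splits the pooled two-class
variance with the exact identity for a biallelic homozygous locus

$$
V_p = \underbrace{pq(\mu_{CO}-\mu_{MT})^2}_{V_m}
    + \underbrace{pq(\sigma_{CO}-\sigma_{MT})^2}_{V_v}
    + \underbrace{(p\,\sigma_{CO}+q\,\sigma_{MT})^2}_{V_r},
$$

so `Vm/Vp` and `Vv/Vp` are the shares attributable to the class mean
difference and the class SD difference; each is zero exactly when the
corresponding moments are equal.

## Covariance-structure scan

`estimate_g_pair()` computes the two class G matrices from family means
(complete-case per marker and trait set, at least 3 families per class — a
deliberately cheap estimator, since each scan recomputes ~160 pairs for each
of 1000 permutations). Three comparison statistics:

* **Box's M, trace form** (`boxs_m()`): with \(S_i = \mathrm{tr}(G_i)\),
  \(V_i\) the class df, \(N = \sum V_i\), pooled \(S = \sum V_i S_i / N\),
  \(M = N\ln S - \sum V_i \ln S_i \ge 0\). The trace is the total variance
  ("multivariate volume"), so M compares overall *size* and is invariant to
  common rescaling. This trace form is intentionally not the classical
  determinant-based Box's M; a `form = "determinant"` variant is available,
  but the scan's validity comes from the permutation null either way, and the
  trace form is robust to near-singular G estimates from family means.
* **Gmax angle** (`gmax_angle()`): the angle between leading eigenvectors,
  reflected into \([0, \pi/2]\) because eigenvectors are non-directional —
  *orientation* of the major axis.
* **Krzanowski subspace index** (`krzanowski_index()`): eigenvector matrices
  \(A, B\) of the first \(k \le \lfloor p/2 \rfloor\) axes (unit-normalized);
  the index is the sum of eigenvalues of \(A^{\top}BB^{\top}A\), from 0
  (orthogonal subspaces) to \(k\) (identical). Because the scan hunts for
  *dissimilarity*, the permutation maxima are taken over the negative index;
  the reported `statistic` column is the index itself. With two traits the
  Gmax angle already captures all orientation difference, so the Krzanowski
  scan refuses two-trait sets. Default `k = floor(p/2)`.

Numerical conventions: eigenvectors are ordered by decreasing eigenvalue and
signed so the largest-magnitude component is positive (a deterministic
tie-break that makes scans reproducible); permutations shuffle whole family
trait *vectors*, preserving inter-trait correlation under the null.

The usual trait groupings run off one configuration: all 12
trait-by-environment combinations, the 6 flowering-time traits, the 6
leaf-number traits (joint structure), per-environment {flowering time, leaf
number} pairs (constraint), and cross-environment same-trait pairs (GxE).
`plot_g_ellipses()` draws the per-class 95% ellipses (chi-squared quantile,
2 df) for any pair; presentation only.

## The threshold/sigmoid simulator

The original RIL phenotype data are not deposited, so the package carries a
generative model reproducing the statistical structure the scans assume —
first-class, tested code, and the source of every scan-level acceptance
check.

**Genotypes.** `sim_ril_genotypes()` simulates diploid descent from a fully
heterozygous F1 through 5 rounds of selfing with single-seed descent
(F6 lines), crossovers drawn per meiosis under the **Haldane** map function
(no interference — the simplest standard choice; the upstream study is silent
on interference). Defaults: 178 families, 164 markers on 7 linkage groups at
5.5 cM. Residual heterozygosity is \(2^{-5} = 3.1\%\) in expectation
(~96.9% homozygous calls) and is stored as missing, matching how
heterozygous calls are treated on reading real data.

**Phenotypes.** Flowering is gated by a sigmoid signal integrator
(`sigmoid_response()`):

$$y = \frac{1}{1 + e^{a(-x + b_G)}},$$

where \(x\) is the input signal — the sum of 12 equal-effect background loci
(two per non-focal linkage group, `beta = 0.5` per MT allele), an environment
offset \(E_e\), and Gaussian noise — and \(b_G\) is the threshold of the
focal genotype, \(b_{MT} = 1.8 < b_{CO} = 4.2\) (the MT genotype needs less
signal to flower). With probability \(y\) the individual flowers in season 1
at `season1_base - slope_c * x` days (truncated below the 180-day season
boundary), otherwise in season 2 around `season2_base = 244` days (truncated
above 180). Leaf number is coupled to flowering time
(`leaf_coupling = 0.3` leaves/day). Family means are taken over `n_reps = 5`
individuals. Steepness `a = 4` puts the sigmoid's logistic width well inside
the background-signal spread, so the integrator behaves like a soft
threshold.

**Environment calibration.** The six offsets are a packaged configuration,
chosen once:

| environment | offset | regime |
|---|---|---|
| 16h18C 4w/6w | +4.6 / +8.9 | promoting: both genotypes saturated, all season 1 |
| 12h18C 4w/6w | +2.1 / +2.5 | slightly inhibiting: MT saturated, ~15–20% of CO families in season 2 |
| 16h25C 4w/6w | −1.5 / −0.6 | strongly inhibiting: CO nearly all season 2, MT straddling |

The promoting and strongly-inhibiting offsets reproduce the reported
grand-mean flowering times for those regimes (about 141/122 and 229 days).
In the slightly-inhibiting regime the two published facts — a grand mean near
147 days *and* a substantial Colorado season-2 tail — cannot both hold under
this model's single-offset-per-environment contract (the season-2 tail
necessarily drags the mixture mean up). The offsets above preserve the
regime's defining mixture structure, which is what the variance phenomenology
and all downstream checks rest on; the simulated grand means there run
roughly 10–15 days high. This is a structural simplification, not a tuning
knob: chamber-specific growth rates, the mid-experiment chamber move, and the
excluded second vernalization period are all deliberately not modelled
(season-2 times come from a single distribution).

Under these defaults the package's acceptance suite verifies the headline
phenomenology: among-family flowering-time variance is larger in the CO class
in the slightly-inhibiting environment and larger in the MT class in the
strongly-inhibiting one (reversible canalization), and the focal marker is
the genome-wide top variance hit in both inhibiting regimes but not the
promoting one.

What the simulator does **not** emulate: crossover interference, segregation
distortion (so the MAF filter rarely triggers on simulated data),
environment-specific within-season growth curves, phenotyping error
correlated across environments, and lines that never flower (every simulated
individual flowers by season 2). Passing tests therefore demonstrate the
statistical machinery, not field realism.

**HIF designs.** `sim_hif()` builds a heterogeneous-inbred-family experiment:
each HIF is a sibling group with a fixed background signal, segregating only
at the focal locus, with family and block random intercepts (defaults 4 HIFs
x 20 families x 9 sibs over 9 blocks, family SD 3 days, block SD 2 days). A
true focal-by-background interaction exists exactly when the HIF backgrounds
straddle one of the two thresholds; backgrounds above \(b_{CO}\) give none.
`sim_expression()` generates delta-Ct values and bud presence from the same
activation probability, coupling phenology to expression.

## HIF mixed models

`fit_hif_mixed_model()` fits, by REML via `lme4`/`lmerTest`,

```
response ~ nFT_genotype * HIF + (1 | Family) + (1 | Block)
```

with marginal (Type III) F tests for fixed terms and REML likelihood-ratio
chi-squared tests (1 df) for the random intercepts; a variance component
estimated at zero is reported (chi-squared 0, p 1), not an error. The LRT
reference is the plain 1-df chi-squared without the boundary 50:50 mixture
correction — anticonservative at the boundary, but it matches how such tables
are conventionally reported; treat borderline random-term p-values
accordingly.

**Denominator df** default to the containment method. The family (sibling
group) stratum carries `n_families - n_cells` df; the residual stratum
carries `N - n_families - n_blocks - 1`. Which stratum tests which fixed term
is set by `family_contains`: for the phenotype experiment the default is
`"HIF"` — HIF lineages are between-family groupings, so HIF is tested at the
family stratum while the genotype contrast and the interaction, which
distinguish sibling families within a lineage, are tested at the residual
stratum. For the small expression experiment (`fit_expression_model()`,
no block term) the family is the unit of biological replication for *all*
design factors, so every fixed term is tested at the family stratum. These
choices reproduce the df structure of the original SAS containment analyses
of both designs. The F statistics themselves do not depend on the denominator
df; `ddf = "satterthwaite"` is available when an approximation-based p-value
is preferred. `holm_adjust()` applies sequential Bonferroni across the
univariate responses.

`test_bud_association()` asks whether the phenological state (visible buds)
predicts expression: `delta_Ct ~ Visible_bud + (1 | Family)`. The delta-Ct
(reference-gene Ct minus target Ct) is used directly as the response — it is
proportional to log relative expression, whereas `2^delta_Ct` is heavily
skewed.

The three-trait MANOVA of the original greenhouse analysis is out of scope;
only its univariate components are implemented.

## Problem sizes and reproducibility

Every generator and scan takes a single integer seed; identical seeds give
identical output, and permutation streams are drawn from R's RNG so scans are
reproducible end to end. The test suite and `scripts/acceptance.R` run at the
study scale the methods were designed for: 178 families x 164 markers with
1000 permutations per scan; 200 replicate null scans for the type-I
calibration of each scan family; 100 seeds for power, canalization-reversal
and top-hit rates; 100–200 seeds for the HIF mixed-model recovery and
calibration properties. A full variance scan takes well under a second, a
covariance scan a few seconds.

## A worked scan

```{r example, fig.width = 7, fig.height = 3}
map <- sim_genetic_map()
geno <- sim_ril_genotypes(map, seed = 11)
model <- threshold_model(map)
pheno <- sim_threshold_phenotypes(geno, model, seed = 12) |>
  standardize_phenotypes()

scan <- scan_variance(geno, pheno, "flowering_time@12h18C4w",
                      map = map, n_perm = 1000, seed = 13)
glance(scan)
tidy(scan) |> arrange(perm_p, desc(statistic)) |> head(3)
```

The focal locus (`r threshold_model()$focal_marker`) should top the scan in
this slightly-inhibiting environment; `autoplot(scan)` draws the genome-wide
picture, and

```{r cov, eval = FALSE}
scan_covariance(geno, pheno,
                paste0("flowering_time@", names(model$env_offsets)),
                method = "krzanowski", n_perm = 1000, seed = 14)
```

runs the GxE-flavoured subspace scan over the six flowering-time traits.
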