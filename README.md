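# mppme — multi-parent, multi-environment QTL mapping

`mppme` detects and characterises QTLs in multi-parent populations (MPPs)
phenotyped in several environments — for example a nested association
mapping (NAM) panel of doubled-haploid maize lines, one central parent
crossed to many peripheral parents, grown at multiple locations. It is
aimed at quantitative geneticists and breeders who want environment-
specific allelic effects, not just effects averaged across trials.

## The models

Four detection strategies share one REML machinery, each scanning the
genome with a Wald test on the QTL term:

| method | data | model | QTL df |
|---|---|---|---|
| M1 | BLUEs across environments | `blue_ic = mu + C_c + x_ia b_a + e_ic`, cross-specific `var(e)` | `n_a - 1` |
| M2 | BLUEs per environment | M1 fitted separately in each environment | `n_a - 1` each |
| M3 | stacked within-env BLUEs | `blue_ice = mu + E_e + C_ce + x_ia b_ae + GE_ice + e_ice` | `N_e (n_a - 1)` |
| M4 | plot data | M3 plus random replicate/block terms (one stage) | `N_e (n_a - 1)` |

M3 and M4 use a compound-symmetry genotypic covariance with environment-
cross-specific error variances (CS + ECSE): observations of the same
genotype in different environments covary by `sigma2_g`, and each
(environment, cross) stratum keeps its own residual variance.

The QTL dosage matrix `x_ia` comes in three codings — `parental`
(expected parental allele copies from a 2-state identity-by-descent HMM
for DH progeny, Haldane map function), `ancestral` (parental alleles
merged by windowed identity-by-state clustering), and `biallelic` (SNP
minor-allele dosage) — always with the central parent's allele as the
reference, so estimates are allelic substitution effects.

Detection follows simple interval mapping for cofactor selection
(threshold `-log10 p = 4`, 50 cM spacing), composite interval mapping
conditioned on cofactors outside an exclusion window, QTL selection at
20 cM spacing, and backward elimination. Environment-specific QTL effects
can be decomposed against an environmental covariate `Z_e` (e.g. mm of
precipitation) as `b_ae = b_a + Z_e g_a + d_ae`: a main effect at the
reference environment and a sensitivity per covariate unit, with
homozygous contrasts `-2 (b_a + Z g_a)`.

## Worked example

Simulate a NAM panel with a QTL active only in the second environment,
then recover it with the two-stage joint analysis:

```r
library(mppme)
set.seed(11)

map  <- sim_map(n_chr = 2, length_cM = 90, n_markers = 11)
sim  <- sim_nam_genotypes(map, n_peripheral = 4, n_per_cross = 80)
truth <- tibble::tibble(marker = "c1_m06",
                        parent = rep(paste0("P", 1:4), 2),
                        env = rep(c("E1", "E2"), each = 4),
                        beta = rep(c(0, -3), each = 4))
ph   <- sim_phenotypes(sim, qtl = truth, n_env = 2)

geno    <- dedupe_positions(qc_markers(sim$geno))
ibd     <- compute_ibd_dh(geno, sim$crosses)
designs <- qtl_designs(geno, sim$crosses, "parental", ibd = ibd)

blues <- fit_blues_within(ph$plots)
cim   <- cim_scan(blues, designs, "M3",
                  cofactors = select_cofactors(sim_scan(blues, designs, "M3")))
qtls  <- backward_elimination(blues, designs, select_qtls(cim), "M3")
qtls
#> qtl_model (M3, parental): 1 QTL(s)
#>   marker chr pos_cM     W df         p neglog10p
#> 1 c1_m06   1     45 249.9  8 1.794e-49     48.75

tidy(qtls)
#> # A tibble: 8 x 5
#>   marker allele env   estimate std.error
#>   <chr>  <chr>  <chr>    <dbl>     <dbl>
#> 1 c1_m06 P1     E1       0.235     0.371
#> 2 c1_m06 P2     E1       0.461     0.461
#> 3 c1_m06 P3     E1      -0.292     0.386
#> # ... with 5 more rows
```

The scan peaks at the planted position (45 cM on chromosome 1) and the
Wald test uses `N_e (n_a - 1) = 8` degrees of freedom. `tidy(qtls)` lists
the per-allele, per-environment substitution effects — close to the
planted −3 dt/ha in E2 and near zero in E1 — and `autoplot(cim)` /
`autoplot(qtls)` draw the profile and the allelic effect series.

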