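---
title: "Joint QTL mapping in multi-parent, multi-environment trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint QTL mapping in multi-parent, multi-environment trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mppme)
```

## The problem

Nested association mapping (NAM) populations cross one central parent to a
set of peripheral parents and phenotype the doubled-haploid (DH) progeny in
field trials. When the same population is grown in several environments,
the interesting genetic signal lives at two levels: variation of a QTL's
allelic effects *between crosses* (different peripheral parents carry
different alleles) and *between environments* (QTL-by-environment
interaction, QTLxE). The common practice of scanning genotype means
averaged across environments hides the second level entirely; scanning each
environment separately recovers it but ignores that the same genotype was
measured repeatedly, which distorts the tests.

`mppme` implements four detection strategies over a common machinery:

* **M1** — QTL scan on genotype BLUEs computed *across* environments:
  `blue_ic = mu + C_c + x_ia beta_a + e_ic`, with a cross-specific residual
  variance `sigma2_e(c)`. One substitution effect per allele; Wald df
  `n_a - 1`.
* **M2** — the same model fitted separately on each environment's BLUEs.
* **M3** — a joint two-stage model on the stacked within-environment BLUEs:
  `blue_ice = mu + E_e + C_ce + x_ia beta_ae + GE_ice + e_ice`, with
  environment-specific cross and allelic effects; Wald df `N_e (n_a - 1)`.
* **M4** — the one-stage version of M3 on plot data, adding the trial
  design terms (replicate, incomplete block) as random effects.

M3 and M4 share the covariance structure that makes the joint analysis
honest: a **compound-symmetry (CS)** genotypic term (`sigma2_g` links the
same genotype across environments) combined with **environment
cross-specific errors (ECSE)** — one residual variance per
(environment, cross) stratum. For one genotype per cross observed in two
environments the observation covariance is block-diagonal by cross, with
`sigma2_g` on the off-diagonal linking environments and
`sigma2_g + sigma2_e(ce)` on the diagonal; `build_vcov()` materialises
exactly this pattern.

## Allele codings

The QTL term is built from one of three codings of expected allele dosage
`x_ia` (rows sum to two expected copies; effects are deviations from the
reference allele, always the central parent's):

* **parental** — one allele per parent; dosages are expected parental
  allele copies from identity-by-descent (IBD) probabilities. For DH
  progeny we use a two-state hidden Markov chain along each chromosome
  (origin = parent 1 or parent 2; no heterozygous state — residual
  heterozygous calls are treated as missing). Transition probabilities
  between adjacent markers are Haldane recombination fractions
  `r = (1 - exp(-2d/100))/2`; markers where the parents agree emit no
  information. Haldane (no interference) is used consistently here and in
  the simulator.
* **ancestral** — parental alleles merged within local ancestral classes.
  Classes come from windowed identity-by-state similarity (default ±2 cM)
  followed by single-linkage clustering at a user-set similarity threshold
  (default 0.8). This is a deliberately simple stand-in for kernel-based
  haplotype clustering tools: it defines sensible allele classes but does
  not reproduce any particular published clustering, so the threshold is
  exposed rather than fixed.
* **biallelic** — SNP minor-allele dosage, one column, the major allele as
  reference.

Quality control mirrors standard practice: markers with minor-allele
frequency below 0.05 or more than 10% missing calls are dropped
(`qc_markers()`), co-located markers keep the most polymorphic
representative with ties resolved by map order (`dedupe_positions()`), and
remaining missing biallelic calls are imputed from within-cross allele
frequencies under a fixed seed (`impute_biallelic()`). Monomorphic allele
columns are removed before model fitting to keep designs non-singular.

## Detection procedure

A scan (`sim_scan()`) fits the method's model at every marker position and
records the Wald `-log10(p)` of the QTL term. Cofactors are then chosen
greedily at a threshold of 4 with a minimum spacing of 50 cM
(`select_cofactors()`), and a composite interval mapping scan
(`cim_scan()`) conditions each position on all cofactors except those
within an exclusion window on the same chromosome. The window defaults to
50 cM (matching the cofactor spacing) — published analyses of this kind do
not state the window they used, so it is a documented, adjustable default.
QTLs are selected from the CIM profile at the same threshold with 20 cM
spacing and pruned by backward elimination (`backward_elimination()`):
repeatedly refit the multi-QTL model and drop the weakest QTL while it
falls below the threshold. Ties in the greedy selections go to the
smallest chromosome, then the smallest position, making every selection
deterministic and order-invariant. Positions whose REML fit fails are
reported as `NA` rather than aborting a scan.

The fixed threshold `-log10(p) = 4` avoids permutation testing; a
Bonferroni alternative is available (`bonferroni_threshold()`). QTLs found
by different methods are merged into unique positions by single-linkage
clustering at 10 cM (`consolidate_qtls()`); note that single linkage
chains, so positions 0, 8 and 16 cM form one cluster.

Wald tests here are *marginal*: each term is tested given all other terms
in the final model. Sequential (conditional) Wald tests, as some mixed
model software reports, depend on the order terms enter the model; we
prefer the order-invariant version and document the divergence.

## REML engine

All models are fitted by restricted maximum likelihood in a single engine
(`reml_fit()`). The covariance is `V = sum_k sigma2_k Z_k Z_k' + R`, with
`R` diagonal carrying one variance per residual stratum. `V^{-1}` uses the
Woodbury identity with a sparse Cholesky factorisation of
`G^{-1} + Z'R^{-1}Z` (the factorisation is symbolic-analysed once and
updated numerically); the common case of a single indicator random term
(the CS genotype effect) reduces to closed-form diagonal updates.

Numerical choices, stated once:

* The overall variance scale is profiled out analytically, so the search
  runs over log variance *ratios* (one dimension fewer, no scale ridge);
  single-variance models are closed form.
* Optimisation is Nelder-Mead on the log scale (bounded quasi-Newton
  behaves poorly on these small, occasionally boundary-bound problems),
  with two deterministic starts; inside a scan each position warm-starts
  from the previous optimum and keeps one start.
* Convergence: relative change of the REML criterion below `1e-9`
  (tighter than the `1e-6` accuracy we rely on in tests).
* Non-negativity is automatic on the log scale; components driven to the
  boundary are reported as exactly zero. Variance ratios are clamped at
  `exp(±18)` inside the objective: degenerate (noise-free) fits otherwise
  push ratios into ranges where the Woodbury algebra loses precision.
* Saturated fixed designs (zero residual degrees of freedom, as in
  noise-free toys) fall back to an exact least-squares solve.
* Rank-deficient fixed designs are repaired by pivoted-QR column dropping;
  dropped columns are recorded on the fit.
* p-values come from the chi-square reference distribution, computed on
  the log scale so `-log10(p)` is stable far beyond double-precision
  underflow.

The restricted log-likelihood includes the `(n - p) log(2 pi)` constant,
so values are directly comparable with `lme4` (which serves as an
independent oracle in the test suite, never as the implementation — it
cannot express the cross-specific or CS+ECSE structures these models
need).

## Environmental sensitivity

For a QTL with environment-specific effects, `fit_sensitivity()` rewrites
the QTL term as `x_ia (beta_a + Z_e gamma_a + delta_ae)`: a main effect at
the reference covariate level, a sensitivity per covariate unit, and a
random residual QTLxE term. The covariate is centred on a reference
environment (by default the smallest raw value — e.g. the driest site —
sits at `Z = 0`; `center_covariate()`). With only two environments `delta`
is inestimable next to `beta` and `gamma` and is dropped; with two
environments the decomposition is an exact reparameterisation of the
saturated per-environment effects, which the tests verify. Homozygous
contrasts between the reference allele and allele `a` at covariate level
`Z` are `-2 (beta_a + Z gamma_a)` — positive when the reference allele
confers the larger trait value — with delta-method standard errors from
the joint coefficient covariance. Low-frequency alleles are retained but
flagged (`carriers < min_carriers`), since their effects carry large
standard errors. `allele_contrast()` also accepts a plain coefficient
table, so published estimates can be turned into contrasts directly.

## The simulator

`sim_map()`, `sim_nam_genotypes()` and `sim_phenotypes()` generate a NAM
multi-environment experiment with known truth. DH progeny are single
recombinant gametes (Poisson crossovers, Haldane, no interference),
doubled; peripheral parents descend from a configurable number of founder
haplotypes with per-marker mutation, so ancestral classes are a real
feature of the simulated data. Phenotypes follow the one-stage generative
model: environment main effects, random replicate and block effects, fixed
cross-by-environment shifts, QTL effects (per-environment, or
`beta + Z gamma` against a covariate), a CS genotype term drawn once per
genotype, and plot errors with (optionally) environment-cross-specific
variances. Trials are augmented p-rep layouts: one third of the entries
replicated twice by default, incomplete blocks of eight entry plots, and
check genotypes repeated once per block.

Defaults (`sigma2_g = 4`, `sigma2_e = 8`, replicate and block variances 1,
`mu = 100`) put the line-mean heritability near 0.5 and the
between-environment genotype correlation near `sigma2_g / (sigma2_g +
sigma2_e) = 1/3` — the same moderate-heritability, strong-GxE regime the
method is designed for. What the simulator does *not* emulate: linkage
disequilibrium among founder genomes, spatial field trends, segregation
distortion, or non-Gaussian error; passing tests therefore demonstrate
correctness of the machinery under the stated generative model, not
robustness to those real-data features.

## Worked example

```{r example, eval = FALSE}
library(mppme)

set.seed(11)
map <- sim_map(n_chr = 2, length_cM = 90, n_markers = 11)
sim <- sim_nam_genotypes(map, n_peripheral = 4, n_per_cross = 80)
truth <- tibble::tibble(marker = "c1_m06",
                        parent = rep(paste0("P", 1:4), 2),
                        env = rep(c("E1", "E2"), each = 4),
                        beta = rep(c(0, -3), each = 4))
ph <- sim_phenotypes(sim, qtl = truth, n_env = 2)

geno <- dedupe_positions(qc_markers(sim$geno))
ibd <- compute_ibd_dh(geno, sim$crosses)
designs <- qtl_designs(geno, sim$crosses, "parental", ibd = ibd)

blues <- fit_blues_within(ph$plots)
prof <- sim_scan(blues, designs, "M3")
cof <- select_cofactors(prof)
cim <- cim_scan(blues, designs, "M3", cofactors = cof)
qtls <- backward_elimination(blues, designs, select_qtls(cim), "M3")
qtls
autoplot(cim)
autoplot(qtls)
```

## Problem sizes, interfaces and limitations

The validation suites run on deliberately scaled-down experiments — two
chromosomes of about a dozen markers, three to four crosses of 30–80 DH
lines, two to four environments, fifty replicates for the
planted-QTL-recovery property — sizes at which every property can be
checked against brute-force or closed-form oracles. The same code runs
unchanged on realistically sized panels; the one-stage M4 scan is the
expensive path (a full mixed model per position on plot data), which is
exactly why the two-stage M3 exists.

The package is driven from R, like the mapping packages this field already
uses: readers/writers for the plain-CSV schemas (`read_mpp_inputs()`,
`write_mpp_inputs()`, `write_scan_profile()`, `write_qtl_model()`,
`write_run_manifest()`) replace a shell interface, and the run manifest
records config, seed and package version for exact reruns.

Known limitations, intentionally out of scope: unstructured or
cross-specific genotypic covariances between environments (the CS+ECSE
structure is the point here), permutation-based thresholds, pseudo-marker
grids between markers (the scan evaluates marker positions), spatial field
models in stage one, weighting of stage-one BLUEs when carried to stage
two (no weighting is applied), multi-trait extensions, and
physical-coordinate handling.
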