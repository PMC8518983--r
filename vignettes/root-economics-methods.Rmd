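---
title: "Root economics phenomics: models, assumptions and design choices"
author: "rootEconomics maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root economics phenomics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootEconomics)
```

# Scope

`rootEconomics` turns raw seedling phenotyping measurements — closed-chamber
CO~2~ accumulation traces, image-analysis root-architecture feature tables
and dry masses — into a root economics trait table, and then asks the
quantitative-genetic questions a diversity panel is grown for: how heritable
each trait is, how the traits relate as a network, and which markers
associate with them. Every stage is exercised end-to-end on synthetic data
with known ground truth, so the statistical machinery is testable without
any external download.

# Respiration flux from chamber traces

A root sample respires inside a closed chamber of nominal volume 19 ml
while the analyzer logs the water-corrected CO~2~ molar fraction once per
second for 90 s. The CO~2~ flux is

$$F = \frac{P\,V}{R\,T}\,\frac{dC}{dt},$$

with pressure $P$ (kPa), corrected chamber volume $V$ (the nominal volume
minus the sample's total root volume), gas constant
$R = 8.31446$ L kPa K$^{-1}$ mol$^{-1}$, temperature $T$ (K), and $dC/dt$
the OLS slope of CO~2~ on time. $F$ is reported in nmol CO~2~ s$^{-1}$.

Two windowing parameters matter. The *dead band* (default 20 s) discards
the initial chamber-equilibration transient; the window end (default 90 s)
closes the fit. Both endpoints are inclusive, so the default window holds
71 of the 91 readings. The synthetic trace generator models the transient
as an additive exponential decay whose half-life (default 4 s) confines it
almost entirely to the dead band; its functional form is a modelling choice
of this package — the instrument literature motivates discarding the early
readings without prescribing a shape.

Defaults of 101.325 kPa and 301.15 K are used when pressure and
temperature are not supplied per sample; whether these were logged or
assumed during any particular campaign is instrument-configuration
dependent, so both are exposed on `ChamberConfig`. Negative fluxes are
retained and flagged rather than clipped: clipping would bias panel-level
statistics and hide unsealed-chamber failures.

# The trait table

Traits are derived at the plant level and averaged to genotype means.
Axial and lateral tissue is split at a root diameter of 0.3 mm (axial
> 0.3 mm). The derived quantities keep the conventional units: SRL in
m g$^{-1}$, SRR_M in nmol g$^{-1}$ s$^{-1}$, SRR_L in nmol m$^{-1}$
s$^{-1}$, RMF in percent, RTD in g cm$^{-3}$, branching density in tips
cm$^{-1}$ of axial root. Samples with a zero denominator (root mass,
length or volume) are rejected with a reason rather than propagating
infinities; no other outlier policy is applied. Fold variation (max/min
over genotype means, reported to one decimal) is undefined for traits
whose range spans zero, such as the partition residual below.

# Partitioning respiration among tissue types

Total respiration is regressed on three tissue-compartment volumes: axial
root volume, lateral-axis volume and lateral-tip volume. The tip
compartment is constructed, not measured: lateral tip count = total tips
minus the assumed four seminal roots (floored at zero), each tip assigned
a nominal 0.01 mm^3^. Lateral-axis volume is total lateral volume minus
tip volume, floored at zero with the clamping counted and reported.

Respiration is the *response* and the volumes are predictors — only this
orientation makes "variance in respiration explained" and slope-ratio
statements meaningful — and the model includes an intercept so the
residual trait below is exactly mean-zero on the fitting set. The fitted
slopes are average specific respiration rates (nmol s$^{-1}$ mm$^{-3}$)
per tissue class; their ratios (tip over axial, tip over lateral axis)
summarize how concentrated metabolic activity is in the tips. Bidirectional
stepwise AIC over the three terms is available to confirm the full model is
parsimonious. The residual, SRR_R = observed − predicted respiration, is
appended to the trait table: it is the respiration a root system performs
beyond what its architecture predicts, and is treated as a trait in its own
right downstream. It is computed per plant and then averaged to genotype
means, like every other trait.

# Heritability

Each trait is fit with the randomized-complete-block mixed model (genotype
random, block fixed) by REML via `lme4`, and broad-sense heritability on a
genotype-mean basis is

$$H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / r},$$

with $r$ the number of blocks (the harmonic-mean replicate count when
unbalanced). On balanced data the REML solution coincides with the ANOVA
moment estimator $(\mathrm{MS}_g - \mathrm{MS}_e)/r$ truncated at zero,
which the test suite uses as an independent oracle. The model is fit on
plant-level values, matching the $r$ in the denominator; residuals are
assumed i.i.d. across plants within genotype, which is the simplest error
structure consistent with a complete-block design.

# Trait space: correlations, PCA, Gaussian graphical model

PCA is computed on centred, unit-scaled genotype means by default — the
traits carry incommensurate units, so unscaled PCA would be dominated by
the large-magnitude length traits; a `scale. = FALSE` switch exists for
sensitivity analysis. Variable contributions are squared unit loadings in
percent, so each component's contributions sum to 100.

The trait network is a Gaussian graphical model: partial correlations
from the inverse correlation matrix,
$\rho_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$, i.e. pairwise dependence
conditional on all other traits. Because total = axial + lateral
identities make volume and surface-area traits collinear with the length
traits, the default network excludes the volume, surface-area and
length-ratio traits, leaving 17; the subset is configurable. A
near-singular correlation matrix is ridge-jittered with a message, and a
matrix that stays singular raises an error naming the collinear traits.
Edges are kept where $|\rho| \ge 0.15$; on the resulting unweighted graph
outdegree is the retained connection count and betweenness is Brandes
shortest-path centrality with fractional counting over ties (both
count-based definitions, hence the unweighted graph).

# Association scans

Marker QC drops markers with missing-call fraction above 0.5 or minor
allele frequency below 0.05 (both strict inequalities); MAF is computed on
non-missing calls with heterozygotes counted once. Missing dosages are
mean-imputed per marker for kinship and scanning. Kinship is the centered
relatedness matrix $K = WW^\top/p$ over the $p$ filtered, column-centered
markers.

The univariate scan is the standard eigendecomposition mixed model: with
$K = UDU^\top$, the rotated model has independent errors with variances
$\sigma_e^2(\lambda d_i + 1)$, and the REML profile in
$\lambda = \sigma_g^2/\sigma_e^2$ is maximized by Brent search over
$\log_{10}\lambda \in [-5, 5]$. By default $\lambda$ is estimated once
under the no-marker null and reused across markers, with the residual
scale re-estimated per marker from the weighted residual sum of squares —
the widely used approximation that makes panel-scale scans fast; an exact
mode re-optimizes $\lambda$ per marker and is tested to differ negligibly
at this scale. Each marker is tested by Wald $\chi^2_1$. With identity
kinship the scan reduces exactly to plain linear-regression Wald tests.

The multivariate scan models $d \le 6$ traits jointly with genetic
covariance $V_g \otimes K$ and residual $V_e \otimes I$. After the kinship
rotation, all row covariances $d_i V_g + V_e$ are simultaneously
diagonalized through $V_e$'s Cholesky factor, which reduces both the REML
likelihood and every per-marker GLS fit to independent weighted
regressions per transformed coordinate. $V_g$ and $V_e$ are estimated
once under the null by direct REML maximization over their Cholesky
factors (so both stay positive semi-definite by construction; a
near-singular $V_e$, e.g. from duplicated traits, triggers a warning).
Per-marker effects are tested by Wald $\chi^2_d$, with the residual scale
re-estimated per marker so that $d = 1$ reduces exactly to the univariate
statistic. PC-GWAS simply runs the univariate scan on each leading
principal-component score vector.

Significance is flagged two ways per marker: the raw threshold
$-\log_{10} p \ge 3.5$ (inclusive), and Benjamini–Hochberg FDR at 0.05
applied within each scan — BH being the canonical step-up "stepwise" FDR
procedure. Candidate genes are genes overlapping ±250 kb around each
flagged marker (inclusive boundaries, same chromosome), computed with
GenomicRanges; coordinates are 1-based inclusive in files.

# The synthetic study

The generator emulates the study design the analysis is built for: 276
genotypes in 4 complete blocks (1104 plants), a diploid biallelic array
(default MAF uniform on [0.05, 0.5], 2% missing calls, markers in
ascending positions over 21 chromosomes), and optional two-subpopulation
Balding–Nichols structure so the kinship correction has something to
absorb; the fixture uses a mild $F_{st} = 0.05$, while the calibration
tests use 0.15 to create strong confounding.

Plant size is lognormal: block effect plus a genotype effect
($\sigma_g^2 = 0.04$ on the log scale) plus plant noise
($\sigma_e^2 = 0.12$), giving a latent $H^2$ near 0.57 before a planted
size QTL — chosen to sit in the middle of the 0.25–0.57 range typical of
seedling root traits. Architecture features scale allometrically with size
with lognormal noise (sd 0.20): large enough that the three tissue
compartments are not collinear, matching the wide independent ranges seen
in real panels. True respiration is the volume-weighted sum over tissue
classes with the tip rate 30.5 times the axial rate and 8.1 times the
lateral-axis rate, scaled so panel-mean respiration is ~0.54 nmol
s$^{-1}$; a heritable metabolic offset (with its own planted QTL) rides on
top, which is what makes SRR_R heritable. Traces are then generated by
inverting the flux equation, with 0.05 µmol mol$^{-1}$ instrument noise
and a 5 µmol mol$^{-1}$ transient. QTL effect sizes are set to explain
15% (size) and 25% (metabolic) of genotype-mean variance — comfortably
detectable at panel scale without dominating the polygenic background.

What the generator does *not* emulate: linkage disequilibrium decay
(marker positions are independent within chromosome), genotype-by-block
interaction, non-Gaussian trait residuals, image-analysis artifacts, and
spatially structured chamber drift. Passing tests therefore demonstrate
that the statistical machinery is correct under the stated model, not that
real data meet the model.

Because the trait surface is lognormal, the ground truth recorded for the
end-to-end check converts the log-scale components to the observed scale:
for $Y = C e^{g + e}$, the genotypic variance is
$(e^{\sigma_g^2}-1)e^{\sigma_g^2}e^{\sigma_e^2}$ and the residual variance
$e^{2\sigma_g^2} e^{\sigma_e^2}(e^{\sigma_e^2}-1)$, which gives the
observed-scale $H^2$ the pipeline should recover.

# Numerical choices and degenerate inputs

* Kinship eigenvalues are floored at zero; a kinship matrix with
  eigenvalues below $-10^{-6}$ (relative) is rejected.
* The REML profile search range $\log_{10}\lambda \in [-5, 5]$ covers
  heritabilities from effectively 0 to effectively 1 at panel scale.
* Monomorphic or collinear markers yield `NA` test results rather than
  aborting a scan.
* Correlation-matrix inversion for the GGM starts ridge jitter at
  $10^{-8}$ and gives up at $10^{-2}$.
* Tip-count and lateral-axis-volume clamping is flagged per sample and
  counted in the partition report; zero clamping is expected on
  well-formed data.
* All generators are seeded; identical configuration and seed give
  bit-identical outputs, and the pipeline itself is deterministic given
  its inputs.

# Problem sizes used in the checks

The shipped checks run the full pipeline on the tiny preset (50 genotypes
× 4 blocks, 500 markers) and once at panel scale (276 × 4, 5000 markers);
calibration uses 3000–5000 markers at $n = 276$, power uses 25 panels of
2000 markers, and variance-component recovery uses 200 replicates of the
balanced 276 × 4 design via the ANOVA form of the REML estimator. These
sizes make the whole suite run in a few minutes on one CPU while keeping
every Monte-Carlo bound comfortably away from its threshold.

# Known limitations

* The EMMAX-style null-$\lambda$ reuse slightly misestimates standard
  errors for markers with very large effects; the exact mode exists for
  final candidate reporting.
* The multivariate REML optimizer is quasi-Newton on a non-convex
  surface; with near-duplicated traits it converges to a boundary and
  warns rather than refusing.
* Heritability assumes the complete-block error structure; spatial or
  temporal measurement-order effects are not modelled.
* The candidate-window lookup is purely positional; functional annotation
  and literature curation are out of scope.
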