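---
title: "Models and methods behind breedgain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind breedgain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedgain)
```

breedgain quantifies what a breeding program gains from different ways of
choosing its best lines.  The deliverable of every analysis is a response to
selection,

$$R = H^2 \, S, \qquad S = \mu_\text{selected} - \mu_\text{unselected},
\qquad H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e},$$

computed for phenotypic (PS), marker-based (MS), genomic (GS1/GS2) and
combined (PS+GS) truncation selection, both in the environment the selection
used and in an independent validation environment.  This vignette documents
the statistical models, the simulator the test suite runs against, the
numerical choices, and the limits of what passing tests demonstrate.

## Field-trial adjustment

Unreplicated breeding trials are laid out as an augmented complete block
design: every block carries the same small set of replicated check cultivars
plus a batch of test lines that each appear once per environment.  Two
models are fit.

**Single environment (BLUEs).** The fixed-effect model
$Y = \mu + B_i + G + C + I + \varepsilon$, where $B_i$ is the block, $G$
the unreplicated test genotype, $C$ the check-versus-test contrast and $I$
the identifier of the individual checks.  We encode $G$, $C$ and $I$ with
pooled levels ($I$ has one level per named check plus one pooled level for
all tests; $G$ pools all checks), which makes $(G, C, I)$ a partition of a
single *entry* factor; the model is therefore fit as
`yield ~ block + entry` — the identical column space, always estimable when
every block contains a check.  A line's BLUE is its entry mean evaluated at
the average block effect, and all BLUEs are re-centered so the mean of the
check BLUEs equals the raw check mean.  Degenerate layouts are handled
explicitly: one single block returns raw values (nothing is estimable to
adjust), and a block with no check is an error naming the block.

**Combined environments (BLUPs).** The same structure with environment
$E_i$, the interactions $G{\times}E$, $C{\times}E$ ($I{\times}E$), and
blocks nested in environments, all random; REML via `lme4::lmer`.  The
genotype variance $\sigma^2_g$ and residual $\sigma^2_e$ feed $H^2$, and
genotype BLUPs are shrunken toward the grand mean.  A multi-component model
cannot be profiled over a single variance ratio, so lme4's general REML is
the right tool here; the single-ratio spectral REML described below is
reserved for the kinship models where it is exact.  Negative variance
estimates are clamped at $10^{-10}$ (with a warning) so $H^2$ stays in
$[0,1]$; missing plots are dropped listwise, which augmented designs
tolerate by construction.

**What $H^2$ means under G×E.** The simulator calibrates *within-
environment plot* heritability.  When the genetic correlation between
environments is 1, the combined-analysis $\sigma^2_g/(\sigma^2_g +
\sigma^2_e)$ estimates exactly that target — the parameter-recovery checks
(targets 0.15 and 0.56, 500 lines, 50 seeds) are run under that setting.
With genetic correlation $< 1$ part of the genetic variance moves into the
$G{\times}E$ component and the combined-fit $H^2$ is smaller than the plot
target; that is a property of the estimand, not an estimation error, and it
only rescales $R$ within a population without affecting strategy orderings.

## Kinship and relatedness

The additive relationship matrix uses VanRaden scaling: dosages (minor-
allele counts, 0/1/2) are centered by $2\hat p$ per marker and
$K = WW'/c$ with $c = 2\sum \hat p(1-\hat p)$.  For fully inbred panels the
mean diagonal sits near $1 + f = 2$.  Missing dosages are mean-imputed per
marker before centering — a deliberately simple replacement for LD-based
imputation, defensible because the A-matrix is robust to it and the
simulator produces missing-free data; a k-nearest-line imputer was judged
not worth its complexity here.

Rogers distance between two populations is, per biallelic marker, the
Euclidean distance between allele-frequency vectors divided by $\sqrt 2$
(which reduces to $|p_A - p_B|$), averaged over the markers in scope.
Because the field reports this quantity both ways, the package emits it
averaged over chromosomes and averaged over line pairs (each line treated
as a two-allele population), labelled as such — the line-pair mean is
always at least the frequency-profile distance by convexity.

## RRBLUP prediction

The prediction model is $y = X\beta + Zu + \varepsilon$ with $Z = I$,
$u \sim N(0, K\sigma^2_u)$.  One spectral decomposition $K = UDU'$ turns
REML into a one-dimensional profile over $\lambda = \sigma^2_e/\sigma^2_u$,
maximized by Brent search on $\log\lambda \in [-10, 10]$ at tolerance
$10^{-8}$.  Marker effects come from the ridge identity
$a = W'(WW' + \lambda_m I)^{-1} r = (W'W + \lambda_m I)^{-1} W' r$ with
$\lambda_m = c\,\lambda$, so the marker parameterization and the K (GBLUP)
parameterization give identical GEBVs; the test suite enforces the
equivalence at $10^{-6}$ and checks the ridge solution against the explicit
normal equations at $10^{-8}$.  A fixed $\lambda$ can be supplied to bypass
REML (used by the oracle tests).

GS2 adds the top GWAS markers as fixed-effect dosage columns next to the
intercept; they also remain in the polygenic background, matching common
GWAS-assisted prediction practice and keeping GS1 and GS2 nested.  Reports
distinguish the **GEBV** $u$ (deviation scale, mean ~0) from the
**predicted yield** $X\beta + u$ (t/ha): published mean breeding values of
several t/ha only make sense with the intercept included, so both are
always emitted and no consumer needs to guess.

Predictive ability is the Pearson correlation between GEBV and adjusted
yield over the overlapping lines.  Cross-validation uses a uniform random
permutation split into k folds (no stratification — nothing in the design
calls for it); each line is predicted exactly once by a model that never
saw it.

## Association scan

Marker–trait association uses a kinship-only mixed linear model per marker,
$y = \mu + m g + u + \varepsilon$, with the P3D/EMMAX device: variance
components are estimated once on the marker-free null model and the
rotation $U'$ is reused for every marker, so the scan is a vectorized
weighted least-squares sweep.  The residual scale is re-estimated per
marker from the weighted RSS, which makes the scan collapse *exactly* to
per-marker OLS t-tests when $K = I$ and $\sigma^2_u = 0$ — a property the
tests exploit as an oracle.  The phenotype is centered and standardized
internally (t statistics are invariant; effects are rescaled back), which
avoids catastrophic cancellation when an input dataset is nearly constant,
e.g. BLUPs fully shrunken at a zero-variance boundary.  This single-marker
scan deliberately replaces multi-locus iterative methods (FarmCPU-style
pseudo-QTN loops): downstream stages consume only a ranked significant-SNP
list, and calibration and power are verifiable against simulated truth.
Every result records `engine = "MLM-P3D"`.

Markers are pre-filtered to MAF > 0.05 and ≤ 10% missing.  Significance is
Benjamini–Hochberg FDR at q ≤ 0.05 (`stats::p.adjust`).  The top-k set
"across datasets" ranks markers by their *best* q over all datasets,
requiring significance in at least one — the natural reading of a bolded
shortlist drawn from different environments — with ties broken by absolute
effect then marker ID.  The favorable allele is the dosage direction with
positive yield effect in the best dataset; because the material is inbred,
MS requires the *homozygous* favorable dosage (2 or 0), and residual F5
heterozygotes fail the requirement.  Per-SNP variance explained is the
drop-one $R^2$ from a joint OLS fit of all significant markers (collinear
markers pruned, later-ordered first), which can legitimately be near zero
for correlated hits.

## Selection and response accounting

Truncation keeps $\lfloor qN \rfloor$ lines (minimum 1), ties broken
lexicographically by line ID, with $q = 0.20$ by default — this reproduces
91 of 456 and 12 of 61; published counts for some populations (90 of 447,
150 of 759) are inconsistent with any single rounding rule, so one
deterministic rule is fixed and documented rather than guessed per table.
An empty selection (MS with no qualifying line, PS+GS with a disjoint
intersection) is a *not-applicable* sentinel (NA), never zero, and is
dropped pairwise from strategy comparisons.  $S$ can be evaluated on the
same environment's adjusted values or on a validation environment's; a
check-relative variant replaces $\mu_\text{unselected}$ by the check mean.
Paired t-tests compare strategies over shared (population × training
dataset) cells, with two degenerate-case conventions: an all-zero
difference vector reports $p = 1$, a constant non-zero one reports
$|t| = \infty$, $p = 0$, flagged `degenerate`.

## The simulator and what it does (not) emulate

The generator reproduces the *structure* the analysis assumes, with these
fixed conventions:

* founders are fully inbred (dosage 0/2), MAF uniform in the configured
  range with the empirical floor enforced per column; markers round-robin
  across the 21 wheat chromosomes with positions encoded in
  `S1A_497083519`-style IDs;
* biparental progeny arise from simulated meioses — crossovers Poisson
  with mean L/100 per chromosome (default L = 150 cM, no interference,
  uniform marker spacing); DH doubles one F1 gamete, F5 is four rounds of
  selfing (≈ 1/16 residual heterozygosity at segregating loci);
* QTL effects are drawn per environment from a multivariate normal whose
  correlation is the G×E knob (`gxe_corr`, default 0.3 — strong
  interaction); the residual SD is calibrated from the realized genetic
  variance so plot $H^2$ hits its target exactly;
* plot value = grand mean (default 4.5 t/ha, a mid-range regional yield) +
  block effect + genetic value + residual; block effects are normal with
  SD = 20% of the residual SD (the literature gives plot counts, not block
  magnitudes, so this is a fixed package convention exposed in
  `sim_config`); checks are average performers (genetic value 0 on the
  centered scale) replicated once per block; default blocks hold 40 plots
  with 3 checks, matching ~37–45-plot practice;
* all randomness flows from one seed through pre-drawn stage seeds:
  identical seed, identical field book, byte-identical report bundle.

Default study scenario: a 456-line training panel with 2000 markers and 30
QTL at plot $H^2 = 0.5$ in two environments, predicting a 500-line DH
population ($H^2 = 0.56$) and a 500-line F5 population ($H^2 = 0.13$) —
the panel size, the population-size order of magnitude and the two $H^2$
extremes mirror the study design the package emulates.

Not emulated: linkage-disequilibrium decay with physical distance,
selection during line development, dominance and epistasis, spatial field
trends, and missing genotype patterns.  Passing tests therefore demonstrate
that the *methods* behave correctly under the stated stochastic structure —
they do not certify performance numbers on real populations, where
relatedness, LD and non-additive variation will move predictive abilities
and responses.

## Numerical conventions and problem sizes

Degenerate inputs are handled by explicit convention rather than chance:
monomorphic-only panels error (kinship scale $c = 0$); rank-deficient
fixed-effect designs error naming the offending column; constant phenotypes
error; eigenvalues are clipped at 0; kinship must be PSD to $-10^{-6}$.
Acceptance-grade checks run at the study's own sizes: heritability recovery
at 500 lines × 2 environments × 50 seeds per target; GWAS calibration on a
456 × 2000 panel (200 null replicates, 100 power replicates, the panel and
its eigendecomposition reused across replicates since only the phenotype
changes); the truncated-normal check at N = 5000 × 50 seeds against the
closed form $i = \phi(\Phi^{-1}(0.8))/0.2 = 1.3998$; and the full-study
Monte Carlo at 20 seeds.  The end-to-end worked analysis in `analysis/`
runs one seed of everything in about a minute.

## Known limitations

The MS strategy is brittle by construction — favorable alleles found in a
diverse panel often do not segregate (or segregate unfavorably) in a given
biparental cross, so empty selections and near-zero responses are expected
and are reported as not-applicable rather than smoothed over.  GEBV-only
selection of weakly related progeny has predictive ability near zero; the
package reports it honestly rather than stratifying the simulator toward
prettier numbers.  The single-marker scan shares power limitations of all
P3D methods when a marker is strongly confounded with kinship structure.
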