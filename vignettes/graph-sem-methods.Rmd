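---
title: "Graph-specified SEM for multi-omics cohorts: models and methods"
author: "GraphSEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-specified SEM for multi-omics cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GraphSEM)
```

## The problem

Cancer cohorts measure the same tumors on several scales at once: mRNA (and
miRNA/protein) expression, somatic mutation status, thresholded copy-number
codes, clinical covariates and right-censored overall survival. Mechanistic
questions about such data — does a driver mutation worsen outcome *through*
proliferation? is an apparent survival effect explained by a co-occurring
alteration? — are questions about a *network* of relations, not a single
regression. GraphSEM lets the analyst state the hypothesized network as a
graph and evaluates it by structural equation modeling (SEM), with survival
endpoints handled by proportional-hazards regression.

A hypothesis graph contains:

* **observed nodes**, each resolving to a cohort variable;
* **latent factors**, defined only through loading edges onto observed
  indicators (e.g. a proliferation factor measured by CCNB1, PCNA and MKI67
  expression);
* **regression edges** (directed causal claims), **loading edges** (factor
  definitions) and **covariance edges** (undirected associations).

There is no restriction to simple structures: chains, multiple components
and even cycles are allowed (cycles require the stability check described
below).

## The covariance model

The non-survival part of the graph is compiled to the RAM (reticular action
model) parameterization. With all modeled variables (observed manifest
variables first, then latents) collected in one vector, two square matrices
describe the model: $A$ holds the directed-path coefficients ($A_{ij}$ is
the coefficient on the edge $j \to i$; loadings are paths from a latent to
its indicator) and $S$ the symmetric disturbance (co)variances. The filter
$F$ selects the observed rows. The implied covariance of the observed
variables is

$$\Sigma(\theta) = F\,(I - A)^{-1} S\, (I - A)^{-T} F^T.$$

Numeric coding is deliberately simple, mirroring common practice for
level-3 tumor data: mutations enter as 0/1 indicators, copy-number as its
$-2..2$ code, $k$-level categoricals as $k-1$ dummy columns (and may only
be predictors). Treating these coded variables as part of a covariance
model is an approximation — no polychoric machinery is used — and is
documented as such.

Identification conventions: each latent factor's scale is fixed by setting
its first loading to 1; every variable receives a free disturbance
variance; covariances among all pairs of *exogenous* observed variables
are free by default (`autoCovaryExogenous = FALSE` disables this). Missing
data are handled by listwise deletion for the fitted variable set.

## Estimation

Fitting minimizes the normal-theory maximum-likelihood discrepancy between
the sample covariance $S_{obs}$ (computed with the $n-1$ denominator) and
$\Sigma(\theta)$:

$$F_{ML}(\theta) = \ln|\Sigma| + \mathrm{tr}(S_{obs}\Sigma^{-1})
  - \ln|S_{obs}| - p,$$

which is nonnegative and zero exactly at a perfect fit. The gradient is
analytic: with $E = \Sigma^{-1} - \Sigma^{-1} S_{obs} \Sigma^{-1}$,
$B = (I-A)^{-1}$ and $C = B S B^T$, the derivative for an $A$-parameter at
$(i,j)$ is $2\,(C\,G\,B)_{ji}$ and for an $S$-parameter $(B^T G B)_{ij}$
(doubled off-diagonal), where $G$ embeds $E$ in the full variable order.

Numerical choices, in order of importance:

* **Start values are scale-equivariant**: variances start at half the
  sample variances, loadings at the ratio of the indicator's sd to the
  scale indicator's sd, paths at $0.1\times$ the sd ratio. This makes the
  optimization behave identically when a variable is rescaled.
* **BFGS with parameter scaling**, restarted from each optimum (restarts
  reset the curvature approximation), followed by a damped **Newton
  polish** using a finite-difference Hessian of the analytic gradient.
  The polish gives machine-precision agreement with closed-form solutions
  (e.g. least-squares coefficients for just-identified regressions).
* **Convergence** is declared on a scale-invariant gradient norm
  $\max_j |g_j|\cdot\max(|\theta_j|, 10^{-3}) < 10^{-6}$; off the
  positive-definite region the objective returns a large penalty so the
  line search backtracks.
* **Cyclic graphs** are fitted like any other; the spectral radius of
  $\hat A$ is reported, and effect decomposition refuses unstable
  ($\rho \ge 1$) solutions.

Standard errors come from the observed information: the Hessian of
$F_{ML}$ at the optimum scaled by $2/(n-1)$; $z =$ estimate/SE with
two-sided normal p-values. The $(n-1)$ constant is used consistently
($\chi^2 = (n-1)F_{ML}$, RMSEA, SE scaling).

## Global fit

The baseline (independence) model has the closed form
$F_b = -\ln|R|$ with $R$ the sample correlation matrix, giving
$\chi^2_b = (n-1)F_b$ on $p(p-1)/2$ df. From model and baseline
chi-squares the usual indices follow: TLI (reported unclipped), CFI,
RMSEA, and SRMR computed on correlation-scale residuals. The conventional
reading — comparative indices high (TLI $> 0.9$–$0.95$), absolute residual
measures low (SRMR $< 0.1$) — is a guideline, not a hard threshold. The
model chi-square *p-value* is intentionally absent from the parameter
table: at cohort sample sizes it tracks $n$ more than misfit. With zero
model df TLI and RMSEA are undefined and reported as `NA`.

## Survival endpoints

How to place a censored endpoint inside a covariance SEM is genuinely
open; a naive "survival time as a continuous variable" treatment ignores
censoring. GraphSEM adopts a hybrid: the non-survival structure is fitted
as above, and each survival node is estimated by one Cox
proportional-hazards model (Breslow ties) containing **all** of its graph
parents as simultaneous covariates. Latent parents enter as
regression-method factor scores

$$\hat\eta = C_{\eta y}\,\hat\Sigma_{yy}^{-1} (y - \bar y),$$

where $C_{\eta y}$ is the model-implied latent–observed covariance block
(this generalizes $\Psi\Lambda^T\Sigma^{-1}$ to latents with structural
parents). The payoff is that "controlling for" semantics are exact: adding
a mediator or confounder parent to a survival node changes the direct
edge's z precisely as a multivariable Cox adjustment, which reproduces the
mediation-attenuation and confounder-correction patterns the tool is
designed to probe. Two limitations are accepted knowingly: factor-score
uncertainty is not propagated into the Cox stage, and survival nodes must
be sinks (the validator rejects outgoing edges).

Kaplan–Meier estimation, log-rank comparison and median splits (≤ median =
"low") support the stratified-survival views; the positive-coefficient =
worse-outcome sign convention is used throughout.

## Direct, indirect and total effects

On the fitted path matrix, the total effect of source $s$ on target $t$ is
$((I-A)^{-1} - I)_{ts}$ — the sum over all directed paths, including
through stable cycles — the direct effect is $A_{ts}$, and the indirect
effect is the difference, so direct + indirect = total holds exactly.

## The exploratory screen

Variable selection is served by an all-against-one scan whose statistic
dispatches on the data-type pair: Pearson $r$ (continuous/continuous,
with ordinal codes treated numerically), point-biserial $r$
(binary/continuous, positive = higher in the altered group), Haldane–
Anscombe-corrected log odds ratio with Woolf SE (binary/binary, positive =
co-occurrence, negative = mutual exclusivity), and the Cox Wald $z$
against survival. $|z|$ is capped at 38 — beyond double-precision p-value
underflow — so perfect associations remain rankable. Benjamini–Hochberg
q-values are computed over the whole run, with degenerate (zero-variance)
candidates kept in the denominator as the conservative choice. Compound
queries ("associated with A and B but not C") intersect screens at a
q threshold. The precompute store writes every unordered pair once as
chunked TSV columns plus a JSON manifest; a query reconstructs the seed's
screen (recomputing q over exactly the records a direct screen would
test), so store-backed and on-the-fly results are identical. Which
statistic a production all-against-all resource should use per type pair
is not standardized anywhere; this dispatch table is our reconstruction
and is documented as such.

## The cohort simulator

Every statistical claim in the test suite is exercised on cohorts drawn
from a known ground truth, so the generator is part of the package proper.
Continuous and latent nodes follow the linear structural model
$x = (I-A)^{-1}(\Gamma u + e)$ with Gaussian disturbances; mutations are
Bernoulli, either marginal or logistic in parent nodes (with the intercept
recentered so the requested marginal prevalence is respected); CNV codes
quantile-threshold a Gaussian copy signal to target code frequencies
(marginally — adequate for co-occurrence fixtures); survival times are
exponential with hazard $h_0\exp(\sum\beta_k\,\text{parent}_k)$ and an
independent uniform-horizon censoring time whose horizon is solved
numerically to hit the requested censoring fraction. Exponential hazards
and covariate-independent censoring keep Cox estimation unbiased, which is
what the recovery tests require.

Default conditions are chosen once to resemble a mid-size adult cancer
cohort: $n = 500$ per cohort for comparative fits (TCGA cohorts with
usable survival mostly span a few hundred to ~1000 tumors), driver
prevalence 0.3 (the order of TP53 mutation rates in high-burden cancers),
factor loadings $(1, 0.8, 0.6)$, structural effects around 0.5, censoring
fraction 0.4–0.5. Validation problem sizes: $n = 2000$ with 50 seeded
replicates for SE calibration, $n = 1000$ for the mediation and
confounding patterns (the confounding attenuation is asserted across 12
seeded replicates, because a single draw can fail to materialize the
confounded association at all), $n = 300$ with 200 candidates for
false-discovery control.

What the simulator does *not* emulate — and hence what passing tests do
not establish about real tumors: expression is Gaussian (no heavy tails,
no normalization artifacts), mutations within a gene are exchangeable (no
hotspot/truncating distinction beyond the non-silent filter), copy number
is marginal (no arm-level correlation structure), hazards are exactly
proportional, and missingness is injected only by the file round-trip, not
by informative dropout.

## Input conventions and derived variables

Readers accept gene×sample expression TSVs, MAF mutation tables (a gene is
"mutant" in a sample if it carries ≥ 1 variant in the conventional
non-silent classes — missense, nonsense, frameshifts, in-frame indels,
splice site, translation start, nonstop; which classes a given resource
counts is rarely stated, so this default is explicit and overridable),
GISTIC by-gene integer codes ($-2$ deep loss … $+2$ amplification) and
clinical tables with a time/event pair (dead/alive synonyms accepted).
Samples present in a cohort but absent from a MAF are wild-type zeros,
not missing, because MAFs list only variant-bearing samples. Cohorts
align samples by sorted intersection (union with a missing mask on
request).

Derived variables cover the two manipulations analysts actually perform:
binarization of numeric/ordinal variables (threshold or explicit
code→label map, e.g. Diploid vs Copy Gain) and grouping of binary
variables (WT/Mutant by any- or all-member logic, e.g. a Ras/MAPK group
over NF1/KRAS/NRAS/BRAF mutations). For grouping with missing members the
rule is: one observed positive member decides "Mutant" under any-logic;
the output is missing only when the observed members cannot decide the
call. Both record their rule as provenance, and rules embedded in a model
JSON are materialized automatically before fitting.

For co-occurrence tables against copy number, the default collapse counts
codes $< 0$ as "loss" (shallow loss/monosomy included), matching how
arm-level losses are usually read. Heatmap ordering uses average-linkage
hierarchical clustering on Euclidean distances (no method is standard for
such displays; average linkage is a stable middle ground), with row
z-scaling (sample sd) on request; leaf order is deterministic given the
input order.

## Known limitations

* Normal-theory ML on coded categorical/ordinal variables; no WLS or
  polychoric estimators, no FIML, no bootstrap SEs, no multi-group
  constrained fits.
* Factor-score uncertainty ignored in the Cox stage; no time-varying
  covariates or competing risks.
* The z-scores in the unified table are on the unstandardized scale;
  standardized path coefficients are not reported.
* The precompute store is size-agnostic but single-machine; it is chunked
  so the same code serves a test fixture and a full cohort, not to
  distribute computation.
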