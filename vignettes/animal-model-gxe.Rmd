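---
title: "Animal-model BLUP, REML and genotype-by-environment analysis for a closed fish breeding program"
author: "AquaBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Animal-model BLUP, REML and genotype-by-environment analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AquaBLUP)
```

## The setting

AquaBLUP implements the quantitative-genetic analysis of a closed
aquaculture nucleus selected for harvest body weight. The program it
models mates each selected male to two females (nested design), rears
each full-sib family separately in hapas until the fingerlings are large
enough to tag, then grow-out-tests the tagged sibs of every family
communally in two environments: an earthen **pond** (the selection
environment) and a freshwater **cage** (a production environment).
Selection acts on pond-weight estimated breeding values, with at most two
males and four females kept per family to restrain inbreeding.

Two features of that design drive everything in the package:

* separate early rearing induces a **common full-sib environmental
  effect**: full sibs resemble each other beyond their shared genes, and
  that resemblance (denoted `c2` as a fraction of phenotypic variance) is
  large and must be separated from additive variance;
* sibs tested in pond and cage are *relatives* but no fish is ever
  measured in both environments, so pond and cage expression of a trait
  can be treated as **two genetically correlated traits**. A genetic
  correlation below one is re-ranking genotype-by-environment
  interaction; it erodes the gain realized in cages from selection done
  in ponds.

## The model

For one trait in one environment the package fits the animal model

$$y = Xb + Za + Wc + e$$

with fixed effects $b$ (generation, sex, generation-by-sex, a linear
age-at-harvest covariate nested within sex-by-generation subclass, and a
stocking-weight covariate), additive genetic values
$a \sim N(0, A\sigma^2_a)$ over *every* pedigree member, family effects
$c \sim N(0, I\sigma^2_c)$ and residuals $e \sim N(0, I\sigma^2_e)$. $A$
is the numerator relationship matrix. BLUE/BLUP solutions come from
Henderson's mixed-model equations; the coefficient matrix uses the sparse
$A^{-1}$ built directly from the pedigree by Henderson's rules with
inbreeding (Mendelian-sampling variances from Meuwissen-Luo inbreeding
coefficients). The source material never states whether inbreeding
entered $A^{-1}$; we include it by default — a closed nucleus with family
caps accumulates measurable $F$ by the third generation — and expose
`use_inbreeding = FALSE` for sensitivity checks.

Heritability and the common full-sib fraction are ratios of the REML
components, $h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_c+\sigma^2_e)$ and
$c^2 = \sigma^2_c/(\sigma^2_a+\sigma^2_c+\sigma^2_e)$. The family effect
is tested by a likelihood-ratio statistic referred to the 50:50 mixture
of $\chi^2_0$ and $\chi^2_1$, because the null value sits on the boundary
of the parameter space.

For the cross-environment analysis the same trait in pond and cage forms
a bivariate animal model with full $2\times 2$ additive and family
covariance matrices and the **residual covariance fixed at zero** — it is
structurally absent, since no animal carries records in both
environments. The additive correlation
$r_g = \sigma_{a,12}/\sqrt{\sigma^2_{a,1}\sigma^2_{a,2}}$ is the G-by-E
summary. Within one environment, pairs of traits are fitted bivariately
with a free residual covariance; each pair includes harvest weight, the
selection criterion, which limits selection-induced bias in the
components.

### Binary survival

Survival (1 = present at harvest) is analyzed two ways. On the observed
scale it goes through the same linear animal model. On the logit scale it
is a sire GLMM — logit link, random sire and family intercepts, the same
fixed effects — estimated by Laplace approximation (`lme4::glmer`), with

$$h^2 = \frac{4\sigma^2_s}{\sigma^2_s + \sigma^2_c + \pi^2/3}$$

the sire variance capturing a quarter of the additive variance and
$\pi^2/3$ the logistic residual. `observedLiabilityTransform()` converts
between observed and liability scales through $z$, the normal density at
the threshold cutting off incidence $p$. Both algebraic directions are
exposed: `as_printed` multiplies by $p(1-p)/z^2$ (the classical
observed-to-liability form) and `as_applied` multiplies by the reciprocal
$z^2/(p(1-p))$. They are exact inverses; the default is `as_applied`,
the direction consistent with the converted survival heritabilities this
package is checked against. The `as_applied` factor never exceeds
$2/\pi$, so that direction can only shrink an estimate.

### Genetic trend

Response to selection is measured as cohort means of EBVs: per
generation, per trait, per environment, expressed as change from the base
cohort (or from the first selected cohort, under a flag) in trait units
and in genetic standard deviations $\sigma_A = \sqrt{\sigma^2_a}$.
Whether cohort means are taken over the animals tested in the given
environment or over all pedigree animals is not decidable from the
source design; `trend_animals = c("tested", "all")` exposes both, with
"tested" the default since trends are reported per test environment.

## REML estimation: the choices that matter

The restricted log-likelihood is evaluated exactly through one sparse
Cholesky factorization of the variance-form mixed-model equations per
parameter point, using the identity
$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$. The default
estimator maximizes this directly — univariately over variance *ratios*
with the residual variance profiled out in closed form, bivariately over
log-variances and `atanh`-transformed correlations (so every iterate is
positive definite) — using Nelder-Mead with a convergence-tightening
restart. We chose direct maximization over the EM/average-information
hybrid that is traditional in this field because the AI trace terms
require a selected inverse of the sparse coefficient matrix, which would
have to be computed densely here; the likelihood itself needs no traces.
EM-REML (`method = "em"`) is nevertheless implemented with dense trace
computation: it is the reference implementation on small problems, and
its guaranteed monotone likelihood ascent is a standing invariant of the
test suite. Standard errors come from a numerically differentiated
Hessian of the REML log-likelihood at the optimum — asymptotically the
same information matrix AI-REML would supply — with delta-method SEs for
$h^2$, $c^2$ and correlations.

Numerical conventions:

* variance floor $10^{-8}\times$ the phenotypic variance; an estimate at
  the floor is flagged as a boundary solution and SEs are not reported
  there;
* convergence at relative log-likelihood change below `tol` (default
  `1e-8`), tightened tenfold in a restart;
* the bivariate likelihood can be multimodal in the correlation
  parameters when an additive variance is weakly identified (small
  heritability, few sire families). The engine therefore probes several
  correlation starting values coarsely and polishes only the best basin.
  Start-point independence of the converged correlation is itself a test;
* equations are ordered fixed, animal, family, and the symbolic Cholesky
  analysis is computed once and reused across all likelihood evaluations;
* aliased fixed-effect columns are dropped by pivoted QR (zero
  constraints) and reported, so fixed-effect solutions are estimable
  contrasts under reference-level coding. Covariates are centered within
  their subclass, which changes only the intercept's meaning.

## The simulator

`simulateBreedingProgram()` generates pedigrees and phenotypes with the
program's statistical structure, so that every analysis stage can be
verified by parameter recovery. Its defaults are the study conditions:
79 + 79 founder parents, three selection generations, 100-150 tagged
offspring per family, nested one-male-two-female matings that fail with
probability 0.15, per-family splitting across pond and cage (base cohort
pond-only), EBV selection with the 2-male/4-female family caps, and true
components, correlations, means and survival incidences taken from the
reported tables.

Genetics are simulated on the trait-by-environment expression vector:
founders draw additive values from $\Sigma_a$; offspring receive
mid-parent plus Mendelian sampling
$N(0, \tfrac12(1-\bar F_{par})\Sigma_a)$; each full-sib group draws one
family deviate from $\Sigma_c$; residuals are per-individual. Survival is
a liability threshold at the configured incidence, with the liability's
additive and family components on the logistic-residual scale. G-by-E
is encoded exactly as the estimation model assumes: pond and cage
expression of a trait are two coordinates of the additive vector with
correlation below one.

Choices the source design leaves open (stated here once; they are
package defaults, not reported facts):

* the reported within-environment and cross-environment additive
  correlation tables are not jointly positive semi-definite, and
  cross-environment correlations between *different* traits are not
  reported at all. Missing cells are filled by composing the
  within-environment and cross-environment correlations, and the whole
  matrix is projected to the nearest PSD correlation matrix by eigenvalue
  clipping. The projection distance is attached to the truth report
  rather than hidden — with all five traits it is substantial, so
  recovery harnesses use trait subsets (e.g. weight only) for which the
  configured correlations pass through unchanged;
* family-effect correlations: 0.8 among body traits, 0.3 with survival,
  0.9 across environments (shared pre-tagging rearing); residual
  correlations 0.5 among body traits within an animal. None of these are
  reported; they only shape the joint distribution, not the
  single-trait truths;
* fixed-effect magnitudes default to modest fractions of a phenotypic
  SD (sex 0.5, per-generation 0.25, age 0.02/day, stocking weight
  0.1/g), enough to exercise BLUE estimation; harvest age
  $\sim N(120, 10)$ days and stocking weight $\sim N(7.5, 1.5)$ g are
  assumptions consistent with the described rearing;
* `founder_mating = "nested"` optionally applies the one-male-two-female
  design already in the base cohort. The emulated program paired founders
  1:1 (the default), but base-generation half-sib families substantially
  sharpen the separation of additive from family variance, so recovery
  studies at reduced scale use the nested option.

Body traits are recorded only on survivors; survival is recorded for all
stocked fish. That convention resolves an ambiguity in the source
material (identical record counts were reported for survival and body
traits despite ~55% survival); we follow the stated coding rule rather
than the table.

## What the tests do and do not show

The closed loop — simulate at known truth, estimate, compare — is the
package's acceptance surface. Test problem sizes are deliberately
reduced: pedigrees of 2,000-5,000 animals with 100-300 families, against
roughly 20,000 in the emulated program. At that scale the additive
variance in the low-heritability cage environment ($h^2 \approx 0.08$
for weight, against a large $c^2$) is weakly identified in any single
replicate, so the cross-environment genetic correlation is recovered *on
average over replicate seeds* with a Monte-Carlo SE of a few hundredths,
not per-replicate. Recovery bands in the tests are two Monte-Carlo SEs
(plus a small allowance for the SE itself being estimated from five
replicates). Passing these tests shows the estimation machinery is
consistent with its own generating model at realistic parameter values;
it does not validate the model against real fish, and it cannot detect
model misspecification (e.g. maternal genetic effects distinct from the
common-environment term, which the single `c` term deliberately
absorbs).

Known limitations:

* "multivariate" analyses are pairwise bivariate fits, as in the
  emulated analysis chain; a full five-trait REML is out of scope;
* no genetic groups for unknown parents — all unknowns are one base
  population;
* the liability-scale survival rows of the reported component table
  cannot be reconciled with the stated sire-model formula under any one
  convention, so they are not used as check points; the two transform
  directions are both exposed instead;
* the LRT mixture reference is asymptotic; at a few hundred families its
  realized type-I error is checked to be near, not exactly, 5%.
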