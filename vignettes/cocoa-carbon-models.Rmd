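---
title: "Modelling carbon stocks and tree growth in cocoa agroforestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling carbon stocks and tree growth in cocoa agroforestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadecarbon)
```

## The problem

Cocoa fields across the West African cocoa belt are not treeless: they
hold shade and companion trees of three origins, or *cohorts* — remnant
trees spared at land clearing, spontaneous trees recruited by natural
regeneration, and trees deliberately planted by farmers. The questions
this package addresses are (i) how much aboveground carbon each cohort
stores per hectare of cocoa field, (ii) how fast individual planted and
spontaneous trees accumulate carbon as they age, and (iii) how both
quantities respond to the social, field, soil and climate context of
the plot. The data are standard multi-site inventories: one table of
trees (diameter at breast height above a 10 cm threshold, height,
species, cohort, and a farmer-reported age for planted and spontaneous
trees) and one table of plots (area and eight socio-environmental
covariates).

## From tree measurements to carbon

Per-tree aboveground biomass uses the height-inclusive pantropical
allometry `AGB = 0.0673 (rho D^2 H)^0.976` (kg), appropriate because
heights are measured in the field with a dendrometer rather than
imputed; the bioclimatic height-free variant of the same family is
deliberately out of scope. Wood density `rho` is resolved by species,
then by the mean of the genus' entries, then by a dataset-mean default
tier so no tree is silently dropped; the default tier warns, and each
estimate records which tier fired. An explicit per-record density
measurement overrides the table. Biomass converts to carbon with the
0.47 fraction for tropical angiosperms, applied exactly.

Stocks are expressed per hectare: within each (plot, cohort) cell, tree
carbon (kg) is summed, divided by 1,000 and by the plot area (ha). Cells
with no trees yield *no observation* rather than a zero — the stock
model below is lognormal with strictly positive support, and cohort
absence is a presence/absence fact the model does not describe. The
number of absent cells is visible to the caller, and the aggregation
conserves mass: `stock * area * 1000` sums back to the plot's tree
carbon exactly.

## The plot-level stock model

Observed stocks `Cs[coh, p]` (Mg/ha) are modelled as

$$Cs_{coh,p} \sim \mathrm{LN}\!\left(\log\!\big(\theta_{coh}\,
e^{\sum_{se} \theta_{X,se} X_{se,p}}\big),\ \sigma^2\right)$$

with one baseline `theta_coh` per cohort and a single set of eight
covariate effects shared across cohorts (no cohort-by-covariate
interactions). Because covariates are centred and scaled to unit sample
standard deviation (n − 1; binary covariates standardized like
continuous ones), `theta_coh` is the median stock of the cohort in a
plot in average conditions, and the `theta_X` are directly comparable
standardized effects on the log scale. The exponential link keeps
predictions positive and makes the effects multiplicative.

## The tree-level growth model

Tree carbon over age is well approximated by a power law — growth rates
scale with size under geometric and metabolic constraints — so for
planted and spontaneous trees (remnant ages are unknowable):

$$Cf_{i} \sim \mathrm{LN}\!\left(\log\!\big(\theta_{coh}\,\theta_{sp}\,
Age_i^{\beta_{coh}}\, e^{\sum_{se} \theta_{X,se} X_{se,p}}\big),\
\sigma^2\right), \qquad
\theta_{sp} \sim \mathrm{LN}(\log 1,\ \sigma_{sp}^2)$$

`theta_coh` is the cohort's median first-year carbon (kg at age 1),
`beta_coh` the cohort-specific exponent (`beta > 1`: accelerating
gains; `beta < 1`: decelerating), and `theta_sp` a multiplicative
species effect with lognormal distribution centred at 1, partially
pooling the long tail of rare species toward the population. Covariates
enter at plot level only and do not interact with age or cohort.

**Gains.** The reported quantity "annual carbon gain" is operationalized
as the one-year finite difference of the median trajectory of a
population-average tree (`theta_sp = 1`, covariates at their means),
with `C(0) = 0`. Window means over the young (ages 1–7) and older
(7–40) windows telescope exactly to `(C(b) − C(a))/(b − a)`, which is
also how posterior draws of the window-mean gain are computed. The
instantaneous derivative `theta * beta * t^(beta-1)` is available as an
alternative (`annual_gain_curve(..., method = "derivative")`); the two
differ at small ages, and the finite difference is the default because
it matches how per-year accumulation is read off yearly trajectories.
Ages are positive integers; age-0 trees are not admitted (a tree
recorded at age 0 has no growth history to model), and ages above 40
years are retained with a warning since farmer recall degrades there —
ages above 60 are rejected outright.

## Inference

Both models are fit by MCMC with JAGS. Two implementation choices
matter:

* **Log-scale sampling.** A lognormal observation model is a normal
  linear model on the log of the response, and the Jacobian of that
  transform does not involve the parameters, so the posterior is
  unchanged. Written this way, JAGS's `glm` module block-samples the
  entire linear structure (cohort baselines, exponents, species
  effects, covariate effects) instead of updating node by node, which
  removes the slow random-walk behaviour between correlated parameters
  (notably the baseline/species-mean and baseline/exponent pairs). The
  package's own `stock_loglik()` / `growth_loglik()` stay on the
  lognormal scale and serve as an independent check of the density.
* **Untruncated exponent prior.** `beta_coh` carries a normal(1, 0.5)
  prior *without* positivity truncation: truncation would exclude the
  exponent from the conjugate block update and cost an order of
  magnitude in effective sample size, while with trees of age >= 1 the
  likelihood leaves no practical posterior mass below zero at study
  scale. Positivity of all multiplicative parameters is enforced where
  it matters — in the parameter containers used for simulation and
  prediction.

Priors are weakly informative on the observed scale and overridable:
lognormal(log 5, 1.5) on cohort baselines (both models), normal(0, 1)
on standardized covariate effects, half-normal(0, 1) on `sigma` and
`sigma_sp`. Baselines are sampled as unconstrained logs and reported on
the natural scale; `sigma` is the sampled scale parameter and `sigma2`
is reported alongside it.

Sampler defaults are 4 chains of 1,000 warmup + 1,000 retained draws
with chain RNGs seeded deterministically from a single integer seed.
Convergence is gated, not merely reported: any split-R-hat above
`rhat_max` (default 1.01) or effective sample size below `min_ess`
(default 100) aborts with a structured error that carries the full
diagnostics, so a non-converged fit can never flow silently into
reporting. Split-R-hat halves each chain before computing the potential
scale reduction factor, which also catches within-chain drift.
Divergence-style diagnostics specific to gradient-based samplers have
no analogue here; the gate rests on R-hat and ESS.

## The synthetic-study generator

The generator emulates the study design the models were built for, and
its defaults are fixed once:

* 15 sites x 10 fields; plot areas uniform on 0.3–5 ha; site-level
  climate spanning 22.6–26.2 °C and 1,100–1,900 mm (shared within a
  site up to small local jitter, as raster-extracted covariates would
  be); the other covariates drawn independently from plausible field
  distributions (Bernoulli(0.5) binaries, Beta(2, 2)-scaled knowledge
  percentages, lognormal cocoa density, bulk density and soil organic
  carbon around 1,100 ind/ha, 1.4 kg/dm3 and 15 g/kg).
* Cohort shares proportional to the observed cohort counts
  (spontaneous most numerous, then planted, then remnant); per-cohort
  truncated-lognormal diameters calibrated so the expected share of
  trees above 50 cm dbh is 25% / 15% / 4% for remnant / spontaneous /
  planted; heights `1.5 dbh^0.7` with lognormal noise; integer ages
  1–40 for the two aged cohorts; a 60-species pool over 25 genera with
  geometric abundance skew; wood densities normal(0.55, 0.08) truncated
  to (0.2, 0.9).
* Stock-study truth defaults: cohort medians 6.33 / 2.06 / 1.53 Mg/ha,
  the three large reported plot-level effects (ownership −0.39,
  previous forest +0.41, cocoa density −0.34) and `sigma = 1.1`, chosen
  to match the spread of observed per-cohort stock quantiles.
* Growth-study truth defaults are a *constructed* divergence scenario,
  not a reproduction of any fitted values: exponents 0.75 (planted) vs
  1.35 (spontaneous) with baselines 18 and 3.2 kg place the crossing of
  the two annual-gain curves around year 7 (finite-difference crossing
  between ages 7 and 8), after which spontaneous trees pull away — the
  qualitative regime the models must be able to distinguish. Species
  scale 0.3, tree-level effects ownership +0.19, previous forest +0.13,
  cocoa density −0.13, temperature −0.08, residual scale 0.5.

Every generator output is a pure function of (design, truth, seed).
What the generator does *not* emulate — and therefore what passing
recovery tests cannot certify about real data — includes: correlations
among covariates (temperature and precipitation, in particular, are
negatively associated along real climatic gradients; a correlation hook
is the natural extension), spatial structure beyond the site level,
measurement error in farmer-reported ages (explicitly not modelled),
species–cohort associations, and any model misspecification, since the
synthetic carbon is drawn from the very lognormal forms being fit.

## Numerical choices and degenerate inputs

Quantile tables use the linear-interpolation definition (R type 7)
throughout. Standardization requires at least two plots and every
covariate to vary; a zero-variance covariate is a named error, not a
silent drop. Presence/absence of cohorts is respected end to end:
empty cells never enter the likelihood. Single-species growth data
leave `sigma_sp` prior-dominated (warned); a single growth cohort
drops the cohort contrast (warned). Remnant trees carrying an age have
the age discarded with a warning at validation; planted or spontaneous
trees without an age are kept for stocks and excluded from growth
modelling, and the exclusion list is reported.

## Problem sizes used by the automated checks

The test suite and the acceptance script run reduced-but-realistic
sizes chosen to exercise the full hierarchy: stock-model recovery uses
20 replicate 150-plot studies at 2 chains x (300 + 400) iterations with
a 1.05 R-hat gate; growth-model recovery uses a ~3,000-tree, 40-species
study at 2 chains x (400 + 600); the analytic lognormal-median check
uses 30,000 draws per cohort so its 2% tolerance sits at ~2.5 Monte
Carlo standard errors given `sigma = 1.1`. The full default sampler
(4 x 2,000) is reserved for interactive analyses.

## Known limitations

Allometric uncertainty is not propagated into the Bayesian models: the
power-law coefficients are treated as exact, so posterior intervals
reflect sampling and ecological variability only. Farmer-reported age
error is unmodelled and likely widens true uncertainty on growth
parameters. The stock model shares covariate effects across cohorts by
construction; cohort-specific effects would require interactions the
models deliberately omit. There is no mortality or population dynamics:
"gain" is growth of surviving trees, not a net stand-level flux. And
the genus tier of the wood-density lookup is an unweighted mean of the
genus' entries — adequate for a reference table, but not a
phylogenetically informed imputation.
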