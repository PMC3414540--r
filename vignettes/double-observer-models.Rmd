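---
title: "Hierarchical double-observer line-transect models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical double-observer line-transect models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rjds)
```

## The estimation problem

Line-transect surveys count groups of animals along strips of known area,
but some groups go undetected, and single-observer protocols can only
estimate relative detectability unless detection on the line is assumed
perfect. With two observers (or pooled observer teams) recording independent
detection histories for every group either of them saw, detection on the
line becomes estimable, and the survey supports absolute abundance
estimation without that assumption.

`rjds` fits a hierarchical Bayesian model to such data. The joint model has
three conditional layers:

1. **Observation model.** For group $i$ on transect $j$, each observer $k$
   records $Y_{ijk} \in \{0, 1\}$. Latent variables
   $\tilde Y_{ijk} = X^{det}_{ijk} \beta^{det} + \epsilon_{ijk}$ drive
   detections through a probit link: $Y_{ijk} = 1$ iff
   $\tilde Y_{ijk} > 0$. The pair $(\epsilon_{ij1}, \epsilon_{ij2})$ is
   standard bivariate normal with correlation that is **zero on the
   transect line and grows linearly with distance** ("point independence"):
   $\rho \, d$ for continuous distance $d \in [0, 1]$ (scaled to the
   half-width) and $\rho (b - 1)/(B - 1)$ for distance bins
   $b = 1, \dots, B$. The probit link admits the Albert–Chib data
   augmentation, so $\beta^{det}$ has a closed-form Gibbs update and the
   latent variables are truncated-normal draws.

2. **Covariate model.** Individual covariates (distance, group size,
   species, exposure, ...) of never-detected groups are latent, so each is
   given a population model $g(z \mid \theta)$: uniform (distance),
   categorical, Poisson, zero-truncated Poisson, or overdispersed variants
   in which $z \sim \text{Poisson}(e^{\theta + \epsilon})$ with a per-group
   random effect $\epsilon \sim N(0, \sigma^2)$. Zero truncation matters
   for group size, which is at least 1 by definition.

3. **Process model.** The number of groups in cell $j$ is
   $G_j \sim \text{Poisson}(A_j \lambda_j)$ with
   $\log \lambda_j = v_j \sim N(x_j'\beta^{hab}, 1/\tau_v)$, a lognormal
   layer that both carries habitat covariates and absorbs overdispersion
   relative to the Poisson. Cell areas are scaled to their mean so the
   intercept is interpretable on the mean-cell scale; the Poisson's
   proportional scaling makes unequal transect areas unproblematic.

Posterior predictions follow the same hierarchy: in sampled cells, group
and individual abundance are read off the augmented state (sum of group
sizes over observed plus latent groups); in unsampled cells, $G_j$ is drawn
from its Poisson law at the current $v_j$ and sizes from the current size
model, so all parameter uncertainty propagates.

## Posterior computation

Unknown abundance makes the parameter space trans-dimensional. Each sampled
cell (or cell-by-species unit, see below) owns a slot array of size
$G^{max}_j$: slots $1..c_j$ hold the observed groups, $c_j+1..G_j$ the
active latent groups (all-zero detection histories, sampled covariates),
and $G_j+1..G^{max}_j$ inactive *pseudo-groups* whose covariates are
refreshed from the current $g(\cdot \mid \theta)$ every sweep. A
reversible-jump move proposes $G' $ uniformly on
$\{G-\psi, \dots, G+\psi\} \setminus \{G\}$; because pseudo-group
covariates are proposals from $g$, the covariate densities cancel and the
one-step acceptance ratio for an addition reduces to
$\lambda_j A_j (1 - p^*_{new}) / (G + 1 - c_j)$, where $p^*$ is the
probability of detection by at least one observer (a bivariate-normal
orthant mass). Deletions use the reciprocal; multi-step jumps multiply
one-step factors and activate/deactivate the lowest/highest slots (slot
labels are non-identifiable, so this stack discipline is a pure
relabeling).

A full sweep updates, in order: pseudo-group refresh, the detection linear
predictors and $p^*$, the reversible-jump count move (newly added groups
receive exact latent probit pairs conditioned on double non-detection),
latent-covariate resampling (Metropolis–Hastings with prior proposals,
ratio $(1-p^*(z'))/(1-p^*(z))$), the truncated-normal probit Gibbs pass,
the $\beta^{det}$ GLS Gibbs draw, a Metropolis step for $\rho$, covariate
hyperparameter updates (conjugate Dirichlet for categorical marks;
random-walk Metropolis for log rates, overdispersion SDs and random
effects), and the process updates ($v_j$ by Metropolis for sampled cells
and directly from the prior for unsampled ones, then conjugate draws for
$\beta^{hab}$ and $\tau_v$).

Two ordering decisions deserve note:

* **Pseudo-group refresh runs at the start of the sweep**, immediately
  after the previous sweep's $\theta$ update. The reversible-jump ratio is
  exact only if activation proposals are draws from $g(\cdot \mid \theta)$
  at the *current* $\theta$; refreshing before the jump step guarantees
  this.
* **Unsampled cells do not enter the $\beta^{hab}$ / $\tau_v$ full
  conditionals.** They carry no count information, so including their
  prior-sampled $v_j$ would only inject noise; they are redrawn each
  iteration for prediction. The marginal law is unchanged and mixing is
  better.

Proposal widths (the jump window $\psi$, and the $\rho$, $\theta$,
$\sigma$, random-effect and $v$ walks) are tuned during a pilot phase
(default 1000 iterations, discarded) toward a 0.3–0.4 acceptance band and
then frozen; continuing adaptation after the pilot would perturb the
invariant law, so it is deliberately not done.

The per-sweep inner loop is implemented in compiled code (`src/sweep.cpp`)
with the detection design flattened into static (observer, species,
unit-level) and dynamic (modeled covariate) column factors; the parameter
blocks stay in R. All random numbers come from R's generator, so runs are
bit-reproducible given `sampler_config(seed = )`; chain $c$ seeds with
`seed + c - 1`.

## Species handling

The package supports two treatments of a species mark:

* `partitioned` (default when species are recorded): one joint sampler
  over cell-by-species units. Each species gets its own abundance columns
  in the habitat design and its own clones of the non-fixed covariate
  models (so group-size and exposure parameters are species-specific),
  while the detection model is shared, with species available as a fixed
  covariate. This matches fitting separate intensity models per species
  but estimates the shared detection function once. $\tau_v$ is shared
  across species.
* `joint_latent`: a single intensity per cell, with species a latent
  categorical covariate of never-detected groups (conjugate Dirichlet
  updates). This is the right mode when per-species intensities are not of
  interest, or when species of a latent group should be inferred.

## Defaults and tunables

| Parameter | Default | Why |
|---|---|---|
| $\beta$ priors (detection, habitat) | $N(0, 10^2)$ | vague on the probit / log scales |
| $\tau_v$ prior | $\text{Gamma}(1, 0.01)$ | weak; conjugate Gibbs draw |
| $\rho$ prior | uniform on $(-0.99, 0.99)$ | keeps every implied correlation inside $(-1,1)$ |
| categorical concentration | $\text{Dirichlet}(10, \dots)$ | moderately informative, as used for species/exposure marks in the motivating analyses |
| size hyperpriors | $\theta \sim N(0,1)$ (log scale), $\sigma \sim U(0,2)$ | covers group sizes up to $\sim e^3$; the normal prior is placed on the log rate |
| $G^{max}_j$ | $\max(20,\ 5 c_j + 20)$ | generous headroom; a run warns if the count sits at the bound in more than 1% of iterations, and the bound is configurable |
| pilot / adaptation | 1000 iterations, target 0.3–0.4 | frozen afterwards (see above) |
| credible intervals | equal-tailed, linear-interpolation quantiles | the default sample-quantile rule; documented because quantile conventions differ |

Numerical choices: orthant probabilities use a deterministic
bivariate-normal CDF (a 6/12/20-point Gauss–Legendre scheme with a
tail-asymptotic branch for $|r| \ge 0.925$; absolute error well below
$10^{-10}$), not Monte Carlo, for reproducibility. Truncated normals use
rejection sampling where the truncated region holds appreciable mass and a
tail-safe inverse-CDF otherwise. Zero-truncated Poisson draws are exact
inverse-CDF. Detection-curve diagnostics guard the conditional and
dependence ratios against underflowing individual probabilities (emitting
`NA`). Degenerate inputs: all-zero design columns and rank-deficient
habitat designs are rejected with errors; a proposal moving $G$ below
$c_j$ or above $G^{max}_j$ counts as a rejection.

## The simulator and what passing tests mean

`simulate_survey(sim_design())` generates the reference validation design:
25 transects, each surveyed by two observers drawn from a pool of three
with different detective abilities; a shared probit detection function of
observer, distance, group size and species; observer correlation growing
linearly to 0.5 at the farthest distance; zero-truncated Poisson group
sizes with species means 4 and 2; species-1 log-intensity linear in a
scaled transect-number covariate $x \in [-1, 1]$ (true slope 1.0) and
species-2 quadratic. Intensity intercepts (2.4) and $\tau_v = 20$ were
chosen once so expected per-transect group counts fall in a realistic 5–30
range; all are arguments of `sim_design()`.

`golf_tee_fixture()` builds a known-truth population in the style of the
classic golf-tee double-observer experiment: exactly 250 groups with the
printed composition (108 green / 142 yellow overall; 44 green / 86 yellow
in the northern stratum), sizes 1–8 from a declared zero-truncated Poisson
law conditioned to that range, color-specific unexposed proportions 0.56
and 0.53, uniform distances over 11 full-coverage transects, and two
pooled observer teams. **It is a synthetic stand-in, not the published
dataset**: detections are simulated from a declared probit model, so
analyses of the fixture validate the estimation pipeline against known
truth rather than reproduce published point estimates.

The simulator draws distances uniformly (random line placement), places
groups independently between cells, and has no animal movement, responsive
behavior, availability bias, or species misidentification. Passing
recovery tests therefore demonstrates correctness of the estimator under
its own assumptions — not robustness to their violation in field data.

The test suite validates the sampler against independent oracles rather
than against itself: the group-count law on a fixed-parameter transect has
a closed form (thinned Poisson); a one-transect toy with a binary latent
mark is enumerable by brute force; orthant probabilities are checked
against $10^7$-draw Monte Carlo; and the full model must recover its
generating parameters across 20 replicate surveys with nominal-95%
interval coverage of at least 80%. Test problem sizes (chains of 20,000
for the replicate study; $10^5$ sweeps for the oracle laws) were chosen as
the smallest runs at which these checks are stable.

## Known limitations

* At most two observers (or pooled teams) per transect; the bivariate
  formulation does not extend to three simultaneous histories.
* Correlation is a function of distance only.
* Missing covariate values on *detected* groups are rejected; augmentation
  covers fully undetected groups only.
* No spatial autocorrelation between cell intensities (no CAR layer), and
  no model-selection machinery; compare candidate habitat structures by
  examining credible intervals.
* Species-specific covariate models are cloned per species in partitioned
  mode; covariate distributions cannot vary by cell.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_survey(sim_design(), seed = 1)
fit <- fit_hds(sim$detections, sim$cells, sim$model,
               sampler = sampler_config(n_iter = 20000, burn_in = 2000,
                                        thin = 10, n_chains = 2, seed = 1))
summarize_draws(fit, c("rho", "hab.speciessp1:x", "G.total"))
truth_report(sim$truth, fit)
diagnose(fit, c("rho", "G.total"))
report(fit, "rjds-report", truth = sim$truth)
```
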