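---
title: "Bayesian functional regression for curve predictors: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian functional regression for curve predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfr)
```

## The problem and the model

High-throughput phenotyping platforms produce curve-valued predictors: a
hyperspectral camera measures reflectance at hundreds of narrow wavelength
bands per plot, an NIR spectrometer returns an absorbance spectrum per milk
sample. Treating each band as an unrelated covariate ignores that the
underlying object is a smooth function of wavelength, and it leaves a
regression with more columns than samples. Scalar-on-function regression
treats the whole curve as one predictor:

$$y_i = \int x_i(t)\,\beta(t)\,dt + e_i, \qquad e_i \sim N(0, \sigma^2),$$

where $y_i$ is a scalar trait (say, grain yield) and $x_i(t)$ the sample's
curve over the continuum $t$ (wavelength, time). In practice the curve is
observed only at $m$ discrete points $t_1 < \dots < t_m$, contaminated by
measurement noise: $x_i(t_j) = f_i(t_j) + \epsilon_{ij}$. Both the curves and
the coefficient function are represented in a truncated basis expansion
$x_i(t) \approx \sum_{l=1}^{L} c_{il}\phi_l(t)$,
$\beta(t) = \sum_{s=1}^{S} d_s \psi_s(t)$; throughout the package the
default is $\psi = \phi$ and $S = L$.

## Basis systems

Two families are provided.

**B-splines** of degree $q$ with $K$ interior knots give
$L = q + 1 + K$ basis functions. The construction is the clamped (open
uniform) one — boundary knots at the domain endpoints with multiplicity
$q+1$ — which guarantees the partition-of-unity property
$\sum_l \phi_l(t) = 1$ and local support. Evaluation is delegated to
`splines::splineDesign()`. Interior knots are placed either equally spaced
(`uniform`) or at empirical quantiles of the measurement points
(`quantile`), with probabilities $k/(K+1)$ and linear-interpolation
quantiles, so the two rules coincide on equispaced grids. Degree 3 is the
default: cubic splines balance fit quality against cost and are the
near-universal choice.

**Fourier systems** are the constant followed by sine/cosine pairs of
periods $T/r$: $1, \sin(2\pi t/T), \cos(2\pi t/T), \sin(4\pi t/T), \dots$
An even $L$ truncates after the last sine (a complete system has odd
length); the constructor warns. The default period is the domain width
$T = t_{\max} - t_{\min}$, the conventional fallback when no cyclic
structure is known. Basis functions are evaluated at raw $t$ without
rescaling to $[0, T]$: a shift of origin only changes the phase of each
pair, not its span, so fits are unaffected. The period matters a great
deal for smoothing quality (see the sine experiment below), much less for
prediction accuracy in our cross-validation experience.

## Smoothing and knot selection

Each curve's coefficients are the least-squares projection
$\hat c_i = (\Phi'\Phi)^{-1}\Phi' x_i$, i.e. the raw values times the
smoother (hat) matrix. The solver uses a QR factorisation of $\Phi$ rather
than forming the normal equations; the two are algebraically identical and
the tests assert agreement to $10^{-8}$ against a literal normal-equations
oracle. Before solving, the singular values of $\Phi$ are checked and the
fit aborts with a named configuration when the smallest falls below
$10^{-10}$ of the largest — the typical trigger is a Fourier system whose
high frequencies alias on a coarse grid. Duplicated grid points are
rejected at construction, since they would silently double-weight rows of
$\Phi$.

The number of interior knots is chosen by one of two criteria over an
explicit candidate list:

* **GCV**: $\mathrm{GCV}(K) = \frac{\mathrm{RSS}/N}{(1 - L/m)^2}$,
  minimised; $N$ is the total number of residuals scored.
* **$R^2$**: the smallest candidate reaching a target coefficient of
  determination; if none does, the largest candidate is returned with a
  warning.

Ties break toward the smaller candidate, and the full score table is always
returned so an alternate rule can be applied externally. When several
curves are smoothed at once, residual and total sums of squares are pooled
over curves and a single shared basis is selected — selecting per-curve
bases is deliberately out of scope, because the regression stage requires
one common coordinate system.

## The seven design constructions

All methods reduce to a linear model $y = \mu + Z\theta + e$ with a fixed
linear map $Z = XM$ of the band matrix; the map is learned from the basis
alone, so it can be re-applied to held-out curves without refitting:

| method | $Z$ | columns | basis |
|---|---|---|---|
| M1 | $X$ (raw bands) | $m$ | none |
| M2 / M3 | $W = X\Phi(\Phi'\Phi)^{-1}J$ | $S$ | B-spline / Fourier |
| M4 / M5 | $X^* = X\Phi(\Phi'\Phi)^{-1}\Phi'$ | $m$ | B-spline / Fourier |
| M6 / M7 | $X^{**} = X\Phi$ | $L$ | B-spline / Fourier |

$J_{ls} = \int\phi_l(t)\psi_s(t)\,dt$ is the cross-basis integral. Two
quadrature conventions are offered. The default, `grid_sum`, drops the
$dt$ factor so that $J = \Phi'\Psi$ holds exactly on the observation grid;
with identical bases this makes $\Phi(\Phi'\Phi)^{-1}J$ collapse to $\Phi$
and hence $W = X^{**}$ exactly, which the code exploits (the collapse is
carried out symbolically, not numerically). The `trapezoid` rule carries
physical units on a grid refined tenfold per interval; it rescales the
design, the scaling is absorbed by the coefficients, and least-squares or
shrinkage fits are unchanged — an identity the test suite asserts. $X^*$
is the row-wise smoothed band matrix: same size as $X$ but of column rank
$L$, so it costs as much as M1 to fit while being as constrained as M6.
M6/M7 are the recommended constructions: $L \ll m$ columns, full column
rank, and the functional coefficient is recovered directly as
$\hat\beta(t) = \sum_s \hat\theta_s \phi_s(t)$ (`beta_curve()`). M1/M4/M5
fits carry one coefficient per band instead (`pointwise_coefficients()`).

## Shrinkage priors and the Gibbs sampler

The regression is fit by Gibbs sampling under five standard shrinkage
priors: Bayesian ridge (common Gaussian), BayesA (per-coefficient
scaled-inverse-$\chi^2$ variances, marginally scaled-$t$), BayesB (spike at
zero plus the BayesA slab, Beta-updated inclusion probability), BayesC
(spike plus common-variance slab) and the Bayesian lasso (double
exponential via its exponential scale mixture). The intercept has a flat
prior; design columns are centered by default (means stored and re-applied
at prediction), with optional unit-variance standardisation off by default.

Hyperparameters follow the variance-partition convention of
whole-genome-regression software: a proportion `R2` (default 0.5) of
`var(y)` is attributed a priori to the linear term. Residual variance is
scaled-inv-$\chi^2$ with 5 degrees of freedom and scale
$S_e = (1-R2)\,\mathrm{var}(y)\,(df+2)$ (prior mode at
$(1-R2)\mathrm{var}(y)$); coefficient variances are scaled analogously
from $R2\cdot\mathrm{var}(y)$ divided by the summed column variances of
$Z$, additionally divided by the prior inclusion probability $\pi_0 = 0.5$
for BayesB/C, whose $\pi$ carries a Beta prior with 10 prior counts. The
lasso rate gets a Gamma prior with shape 1.1 and rate solved so the prior
mode of $\lambda^2$ matches the `R2` partition; BayesA's scale is held
fixed rather than given a hyperprior — a simpler hierarchy with the same
conjugate limit. Every one of these is overridable through `hyper`.

Chain defaults are 6000 iterations, 1000 burn-in, thinning 5 — adequate
for designs with tens of columns; sweep-style analyses in the tests use
shorter chains (600–2000 iterations) after checking that conclusions do
not move. Coefficients are updated in fixed column order from a single RNG
stream keyed by `seed`, so every fit is bitwise reproducible. A diagnostic
mode (`fix =`) pins any part of the hierarchy; with both variances fixed,
every family's conditional collapses to the conjugate Bayesian-ridge
posterior, which the tests compare against the closed-form ridge mean
within Monte-Carlo error — the standard correctness check for samplers of
this family.

## Cross-validation protocol

`run_cv()` mirrors the evaluation protocol of hyperspectral yield studies:
threefold cross-validation (two folds train, one tests; fold sizes differ
by at most one), Pearson correlation per held-out fold, and per
configuration the fold mean with standard error $\mathrm{sd}(r)/\sqrt{k}$.
Designs for test curves are rebuilt from the training map and centering
means only; the test suite corrupts held-out rows and asserts the training
draws are bitwise unchanged. Each cell derives its sampler seed
deterministically from the base seed and cell index, so the sweep is
reproducible and cells are independent. M1 appears once per basis-count
column of the report, exactly as published accuracy tables repeat it. A
single CV partition is the default; the fold vector is exposed so
replicated partitions can be averaged externally.

## What the synthetic generators emulate — and what they do not

`simulate_sine()` reproduces the classic one-curve smoothing benchmark:
100 points uniform on $[10, 20]$, $x = \sin(1+t)$ plus Gaussian noise of
sd 0.5. Points are stored sorted with the original draw order kept as
metadata (basis evaluation and plotting want monotone grids; sorting does
not change a least-squares fit).

`simulate_curves()` emulates a hyperspectral campaign: an equispaced grid
(default 250 points on 392–851 nm), per-sample smooth truth
$f_i = \Phi_{\mathrm{truth}} c_i$ with $c_i \sim N(0, \mathrm{coef\_sd}^2 I)$,
plus i.i.d. measurement noise. Defaults — cubic B-spline truth basis with
$L = 15$, unit coefficient sd, noise sd 0.1 — give centered curves of
roughly unit variance with features a few tens of nm wide, visually akin
to centered reflectance spectra. `simulate_phenotypes()` then applies the
functional linear model literally: trapezoid quadrature of
$f_i(t)\beta(t)$ over the grid using the *noise-free* truth curves, plus
Gaussian residual noise, by default scaled to a 3:1 signal-to-noise ratio.

Real reflectance data differ in ways these generators do not imitate:
bands are correlated through physics rather than a fixed spline space,
noise is heteroscedastic across wavelengths, responses are BLUEs carrying
their own estimation error, and samples are genetically related. Passing
tests therefore demonstrate the machinery — identities, oracles, recovery
under the stated generative model — not field-level predictive claims.

One identifiability point matters when interpreting recovery experiments:
coefficients in a basis space are only as well determined as the design's
column space. If curves live in a 15-dimensional smooth space and the
model projects onto 23 basis functions, the extra directions are
unidentified and no estimator recovers them; recovery experiments
therefore draw curves from the same basis that the design projects onto.
Recovery correlations remain stochastic — a drawn coefficient vector can
align with the design's weakest singular directions — so the package's
recovery checks report the median over a handful of seeded replicates.

## Numerical choices, in one place

* Least squares via QR of $\Phi$; singular-value guard at $10^{-10}$
  relative; `kappa` guard at $10^{12}$ when forming $(\Phi'\Phi)^{-1}$ in
  designs.
* `grid_sum` quadrature as default (makes the $J \approx \Phi'\Phi$
  approximation an identity); trapezoid with tenfold refinement when
  physical units are wanted.
* Knot-selection ties break toward fewer knots; an unattainable $R^2$
  target returns the largest candidate with a warning rather than an
  error, so sweeps keep running.
* CSV I/O writes doubles with 17 significant digits and reads through
  `strtod`, so band tables round-trip bitwise.
* Test-scale problem sizes: identity and oracle checks run at
  $n \le 50, m \le 150$; recovery at $n = 500, m = 250$; the full
  7-method × 9-basis CV sweep at $n = 150, m = 250$ with shortened
  chains. These sizes were chosen to exercise the wheat-campaign geometry
  (250 bands, $L$ up to 51) at desk scale.

## Limitations

Gaussian responses only; binary/ordinal traits, multi-trait models,
environment and genotype-by-environment terms, and genomic or pedigree
kernels are out of scope. Roughness-penalty (P-spline) smoothing and
mixed-model spline reformulations are not implemented — the smoother here
is the unpenalised least-squares projection. Wavelet, polynomial and
radial bases are not provided. The standard error reported by the CV
harness is over $k$ folds of a single partition and should be read as the
published tables' convention, not as a calibrated uncertainty interval.
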