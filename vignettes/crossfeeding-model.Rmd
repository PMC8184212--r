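---
title: "Modeling and measuring obligate metabolite cross-feeding"
author: "crossfeed package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring obligate metabolite cross-feeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeed)
```

# The system and the model

The package models a two-strain obligate mutualism of the kind built in
engineered yeast communities: strain 1 cannot synthesize metabolite A
(e.g. lysine) but overproduces and releases metabolite B (e.g.
hypoxanthine); strain 2 is the mirror image. Live cells of strain *i*
release their product at a per-cell rate $r_i$ (fmol/cell/hr) and consume
$c_i$ fmol of the partner-supplied metabolite per cell birth. Growth on
the consumed metabolite at concentration $L$ follows Moser kinetics, a
Hill-type generalization of Monod's law,

$$b(L) = b_{max} \frac{L^n}{K_L^n + L^n},$$

with $b_{max}$ the birth rate in excess nutrient (1/hr), $K_L$ the
half-saturation concentration (µM), and $n$ the cooperativity exponent
($n = 1$ recovers Monod). Death is a per-capita rate $d$, default 0: dead
cells are tracked in the data but no death model is asserted by the
measurements the package emulates, so death is configurable plumbing
rather than an estimated quantity.

**Units.** Concentrations are µM at every interface and fmol/ml
internally (1 µM = 10^6 fmol/ml); densities are cells/ml, rates 1/hr,
times hr. This convention makes the exchange-ratio arithmetic
dimensionally transparent: $r/c$ has units 1/hr, directly comparable to
growth and dilution rates.

## Steady-state theory

A strain's **exchange ratio** $r_i/c_i$ is its benefit supply rate per
intake benefit. When both metabolite pools are supply-limited (pools graze
zero, so every released molecule is promptly consumed), births of strain 1
are limited by strain 2's supply and vice versa, giving the linear system

$$\dot N_1 = \frac{r_2}{c_1} N_2, \qquad \dot N_2 = \frac{r_1}{c_2} N_1.$$

Its dominant eigenvalue is the common steady-state growth rate

$$g = \sqrt{\left(\frac{r_1}{c_1}\right)\left(\frac{r_2}{c_2}\right)},$$

the geometric mean of the two exchange ratios (the two cross-feeding
coefficients' product regroups into the product of exchange ratios), and
the eigenvector fixes the strain composition
$N_1/N_2 = \sqrt{(r_2/c_1)/(r_1/c_2)}$. `communitySteadyGrowth()` and
`communitySteadyRatio()` implement these closed forms; the test suite
checks them against brute-force eigen-decomposition for random phenotypes
and against the late-time log-slope of the full nonlinear simulation.

Two consequences carry the package's inferential weight:

* Multiplying one strain's exchange ratio by a factor $f$ (the partner
  unchanged) multiplies $g$ by $\sqrt f$; the predicted relative change in
  the partner's steady-state growth rate is $\sqrt f - 1$
  (`predictPartnerGrowthChange()`). A 1.6-fold improvement predicts +26%.
* In a chemostat at dilution rate $dil$ with inflow concentration $L_0$,
  the product balance $\dot H = r N u - dil\, H$ and the nutrient balance
  give, at steady state with near-complete depletion,
  $dil \cdot H_{ss} / L_0 = r/c$: the population-level measurement equals
  the individual-level phenotype (`exchangeRatio()`).

## The ODE models

`simulateChemostat()` integrates live cells, dead cells, residual
nutrient and released product under dilution; `simulateCommunity()` a
closed well-mixed patch of both strains and both pools (the
spatially structured patch experiments are treated as well-mixed closed
patches, since only total abundances are analyzed); and
`simulateCompetition()` two genotypes sharing one nutrient pool under
dilution, for self-serving (competitive) phenotypes. All use a
stiff-capable LSODA integrator at relative tolerance 1e-8 and absolute
tolerance 1e-10, with metabolite states clipped at zero after integration
because supply-limited pools legitimately graze zero and can overshoot
negative by integrator error. Mass-balance identities (nutrient in =
nutrient out + consumption at steady state) are asserted in the tests at
integrator tolerance.

Consumption is tied to births ($c\, b(L) N$), not biomass maintenance,
matching the per-birth definition of $c$. Release is proportional to live
cells regardless of growth status — the data motivating the model say
products are released by live cells, but whether starving cells keep
releasing is an assumption, made here in the affirmative.

# Estimators

**Growth rate from a signal time course.**
`growthRateFromTimeseries()` normalizes intensities to time zero and takes
the maximal OLS slope of log signal over overlapping windows of 3
(default) or 4 consecutive points; if no window slope is positive the
series is flagged "no growth" and the rate is 0 (matching how zero-growth
points at very low nutrient are treated). The max-over-windows rule makes
the estimator robust to lags and late saturation but gives it an upward
noise bias of roughly the window-slope standard error times the expected
maximum of correlated standardized noise terms: with multiplicative noise
of coefficient of variation $cv$, the window-slope error scales as
$cv/\sqrt{S_{tt}}$ with $S_{tt}$ the window's time sum of squares. The
bias therefore shrinks with wider windows, longer sampling intervals and
faster true rates. The synthetic-data validation runs the recovery
experiment in the fast-growth regime (0.44/hr, 2-hourly imaging, 12
frames, window 4), where the median recovery error at 5% noise is below
5%; at slow rates the same noise produces proportionally larger upward
errors, which is a property users should expect on real data as well.

**Moser fits.** `fitMoser()` is Levenberg–Marquardt least squares with
box constraints ($b_{max} \in (0, 10]$, $K_L \in (0, 10^4]$ µM,
$n \in [0.5, 10]$) and data-driven starts: $b_{max}$ at 1.1× the largest
observed rate, $K_L$ interpolated at half-max, $n = 2$. These choices give
robust convergence on saturating data; non-convergence is reported with
the starting point, and under-determined (< 4 distinct concentrations) or
degenerate (flat) inputs are rejected.

**Steady-state detection.** `detectSteadyState()` takes the trailing 30%
of points as the candidate plateau, requires every value from the onset
onward to lie within `relTol` (default 0.10) of the plateau mean, and
additionally bounds the *drift* — OLS slope times segment duration —
by the same tolerance. The drift guard is what rejects slow monotone ramps
whose local fluctuations are individually small; without it, any
sufficiently slow ramp would be declared steady by a finite window. The
tolerance should be sized to the observation noise (roughly 3–4× the
multiplicative cv) so that plateau points stay inside the band while the
trailing-window mean averages the noise away. Experimental practice
declares steady state by eye; this criterion is the package's
operationalization, not a community standard.

**Community growth rate.** `communityGrowthRate()` excludes the initial
lag by finding the longest trailing run of points whose consecutive
log-slopes agree with their mean within `relTol` (default 0.15), then fits
one OLS slope over that run. With noisy samplings the band should again be
widened to about twice the consecutive-slope noise
($cv\sqrt{2}/\Delta t$ relative to the rate); the defaults suit smooth or
lightly noisy series.

**Cytometry and bioassay.** `cytometryDensities()` applies the bead-ratio
arithmetic (cells per bead × beads added per sample volume);
`fitStandardCurve()`/`bioassayConcentration()` fit and invert the linear
yield-based bioassay, warning on — but still returning — values outside
the calibrated range, since plate behavior outside calibration is
uncharacterized. `generationsFromOD()` accumulates density as OD times
the running product of fold-dilutions and converts to generations with
log2; this accumulation convention is the package's reading of standard
serial-dilution bookkeeping and is documented rather than asserted as
canonical.

# Inference

`foldChangeCI()` reports the ratio of group means with a Welch t-interval
on the difference of log-means, exponentiated. The log scale respects the
positivity and multiplicative error structure of exchange ratios; when
group variances vanish the interval degenerates to the point (where
geometric and arithmetic means coincide). Because $\sqrt{\cdot}$ is
monotone, a CI for the predicted partner speed-up is obtained by mapping
the interval endpoints through `predictPartnerGrowthChange()`. The CI
construction is the package's own choice — the experimental literature
this machinery serves reports such intervals without specifying their
construction — so downstream comparisons should treat the interval method
as part of the analysis, not as ground truth. With skewed replicate sets
the log-scale interval can sit asymmetrically around the mean-ratio point
estimate; the interval is widened minimally to bracket it.

`compareGroups()` reproduces the F-test-gated t-test convention: a
two-sided variance F-test at 0.05 selects pooled or Welch two-tailed
t-tests. Under the equal-variance null the pooled branch's p-values are
uniform (checked by KS test over 1000 simulated nulls). No
multiple-testing correction is applied, matching the practice the
package mirrors.

# Synthetic data and what passing tests show

The generators (`genMicroscopySeries()`, `genChemostatSeries()`,
`genCommunitySeries()`, `genCytometryEvents()`, `genBioassayCurve()`)
produce every input the estimators consume with known ground truth in a
machine-readable sidecar, deterministic given a seed (a local RNG scope
leaves the session RNG untouched). Noise models are conventional for the
instruments: lognormal multiplicative noise for intensities,
concentrations and densities; Poisson noise for cytometry event counts.
The default phenotypes use an ancestor-like exchange ratio of 0.10/hr
(consistent with the ~0.1/hr steady-state growth rate of the ancestral
community), a mutant-like 1.6-fold increase in release rate, and
$c = 3$ fmol/cell, back-computed from the design pairing of a 21 µM
reservoir with a 7 × 10^6 cells/ml steady state. The partner strain's
absolute $r$ and $c$ are synthetic stand-ins with a realistic exchange
ratio; only the ratio matters to the steady-state theory.

What the round-trip tests establish: the estimators are unbiased enough,
at the stated noise levels and sampling designs, to recover the
generating parameters at the stated tolerances, and the full pipeline
(simulate → sample → estimate → predict) is internally consistent with
the closed-form theory. What they do not establish: that real instruments
have lognormal/Poisson noise of these magnitudes, that real communities
satisfy the supply-limited assumptions (pools near zero, rates below
$b_{max} - d$), or that release is growth-independent. On real data the
user should check the supply-limited preconditions (residual nutrient
under ~1% of inflow before trusting the exchange-ratio identity; a clean
exponential regime before trusting the community rate).

# Problem sizes and numerical choices

Simulations in the tests and the acceptance script use grids of 100–250
output points over 120–400 hr, enough for plateaus to converge well below
estimator tolerances at the LSODA settings above. Parameter-recovery
experiments use 20 seeds per estimator; the coverage check for the
fold-change interval uses 1000 replicates; the eigen-decomposition oracle
runs 100 random phenotype draws. Tie-breaks and degenerate inputs:
identical groups compare with p = 1 on the pooled branch; all-flat growth
series return rate 0 with a no-growth flag rather than a negative maximum;
washed-out chemostats (dilution above $b_{max} - d$) have no finite
steady state and `chemostatSteadyState()` returns NULL.

# Known limitations

* Spatial structure is not modeled; patch experiments are approximated as
  well-mixed closed systems.
* No evolutionary dynamics: genotypes do not mutate into existence during
  a simulation; competition is between fixed phenotypes.
* The death model is a constant per-capita rate with default 0; dead-cell
  data constrain it only weakly.
* The max-slope growth-rate estimator is intentionally simple and carries
  the noise bias described above; rates well below the sampling design's
  resolving power will be overestimated in noise.
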