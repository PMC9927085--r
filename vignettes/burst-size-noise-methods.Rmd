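---
title: "Methods: single-cell burst-size distributions and noise decomposition"
author: "phageburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell burst-size distributions and noise decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageburst)
```

## The measurement this package models

A lysis-deficient phage lambda lysogen can be induced so that every cell
starts its lytic cycle at the same moment but never lyses on its own;
virions accumulate until the experimenter lyses the cell chemically at a
chosen time. Diluting induced cells into 96-well plates at far less than
one cell per well (limiting dilution) makes most occupied wells
single-cell, so a plaque assay of a well's contents counts the progeny of
one cell: a single-cell burst size. Repeating this over a schedule of
lysis times yields, per time point, a distribution of burst sizes across
~100 cells — mean, CV, CV², and skewness — rather than the single
population average a one-step growth curve provides.

`phageburst` implements the statistical machinery around that design: the
Poisson occupancy mathematics of the plates, the per-time-point
distribution summaries, a saturating model of mean burst size versus lysis
time, a first-order decomposition of burst-size noise into parameter-level
sources, tests for CV equality between groups, and a synthetic generator
for the complete assay.

## The burst-size model

Mean burst size $BS$ as a function of lysis time $LT$ is modelled
phenomenologically as

$$
BS(LT) \;=\; k_{\max}\,
\frac{e^{r(LT-D)} - 1}{e^{r(LT_{50}-D)} + e^{r(LT-D)} - 2},
\qquad LT > D,
$$

with $BS = 0$ for $LT \le D$. The four parameters have direct
interpretations: $D$ (min) is the delay before progeny start to
accumulate, $r$ (min⁻¹) the exponential accumulation rate, $LT_{50}$
(min) the lysis time of half-maximal burst, and $k_{\max}$ (PFU/cell) the
asymptotic burst size — the cell's capacity to produce phage. The form is
exactly half-maximal at $LT_{50}$, monotone, and saturates at $k_{\max}$;
it is deliberately phenomenological, not a mechanistic model of holin
kinetics or ribosome budgets.

Numerically, `burst_size()` evaluates the exponentials scaled by
$e^{-\max(a,b,0)}$ (with $a = r(LT-D)$, $b = r(LT_{50}-D)$) so that
arguments far beyond the double-precision overflow point (~709 on the
natural-log scale) remain finite; in that regime the function returns the
algebraic limit $k_{\max}$.

## Noise decomposition

Writing $BS = f(LT; k_{\max}, LT_{50}, r)$ and expanding $f$ to first
order in small cell-to-cell parameter deviations around the population
means gives, after squaring and taking expectations,

$$
CV^2_{BS} \;=\; S_{k_{\max}}^2\,CV^2_{k_{\max}}
  + S_{LT_{50}}^2\,CV^2_{LT_{50}}
  + S_{r}^2\,CV^2_{r},
$$

where $S_x = (\hat x/f)\,\partial f/\partial x$ are dimensionless
log-sensitivities (elasticities) and the $CV^2_x$ are the squared
coefficients of variation of each parameter across cells. Parameters are
taken as independent across cells, so no covariance terms appear. The
delay $D$ is treated as fixed.

The decisive structural fact is that $f$ is linear in $k_{\max}$, so
$S_{k_{\max}} \equiv 1$ at every lysis time, while $S_{LT_{50}}$ and
$S_r$ decay to zero as $LT$ grows. Consequently:

* capacity heterogeneity alone predicts a burst-size CV² that is
  *constant* in lysis time, equal to $CV^2_{k_{\max}}$;
* heterogeneity in $LT_{50}$ or $r$ alone predicts a CV² that *decays
  toward zero* as the mean burst size saturates.

An observed CV² profile that stays flat as the mean rises by an order of
magnitude therefore points to cell-to-cell differences in production
capacity, not in lysis kinetics. `burst_sensitivities()` implements the
elasticities analytically (they are cross-checked against central finite
differences of $\log f$ in $\log x$ in the test suite), and `cv2_burst()`
assembles the decomposition. `decompose_noise()` confronts data with the
three single-source hypotheses, calibrating each hypothesis's one free
scalar by least squares of the observed CV² profile on the squared
sensitivity profile.

The finite-difference cross-check uses a 1e-6 relative tolerance with a
1e-9 absolute floor: in the deep decay regime the elasticities fall below
1e-9, where central differences of $\log f$ are dominated by roundoff and
no finite-difference oracle can resolve a relative comparison.

## Poisson occupancy

Under limiting dilution the cell count per well is Poisson with mean
occupancy $\lambda$. The package exposes the pmf (`p_cells()`), the
expected empty-well count $n e^{-\lambda}$ (`expected_empty()`), and the
zero-class estimator $\hat\lambda = -\log(n_{\rm empty}/n)$
(`occupancy_from_empty()`). Whole-well planning numbers take the *floor*
of the expectation — the convention that reproduces both printed planning
values at 96 wells (74 empty at $\lambda = 0.25$, 52 at $0.61$), where
nearest rounding would give 75 at $\lambda = 0.25$. Percent-of-wells
quantities are reported both as raw probabilities and nearest-integer
percents (`occupancy_table()`). The design math is exposed in both
directions (forward expectation and zero-class inversion) without forcing
them to agree: 74/96 empty inverts to 0.260, slightly above the forward
design value 0.25, and both are reported as-is.

A consequence the analysis must live with: a well whose cell produced
zero countable virions is indistinguishable from an empty well, so wells
with zero plaques are treated as empty. At short lysis times this
conditions the observed sample on producing at least one plaque; the
generator keeps the latent cell count so the size of this bias can be
examined, but the package does not correct for it.

## Distribution summaries, trimming, bootstrap

`summarize_bursts()` reports mean, sample SD, CV = SD/mean, CV², and the
moment skewness $g_1 = m_3/m_2^{3/2}$ computed with $1/n$-normalised
central moments (the convention of the R **moments** package; not the
adjusted Fisher–Pearson form). A zero-variance sample has $g_1 = 0$ by
convention. Multi-cell wells place probability mass at roughly integer
multiples of the single-cell mean, which right-skews the occupied-well
distribution; `trim_outliers()` removes values *strictly greater* than
twice the untrimmed mean, in one pass (the threshold is not recomputed),
keeping ties. The strict reading keeps boundary values and makes the rule
deterministic.

Bootstrap intervals (`bootstrap_ci()`) are percentile intervals over
resamples with replacement — endpoints are the
$\lceil B\alpha/2 \rceil$-th and $\lceil B(1-\alpha/2) \rceil$-th order
statistics of the $B$ resampled statistics. Percentile rather than BCa is
the minimal-assumption choice; for the skewed samples here it
under-covers slightly (the test suite measures ~90–95% at nominal 95% on
lognormal samples of 100), which is acceptable for the descriptive error
bars it provides.

## Fitting the model

`fit_burst_model()` minimises least squares of per-lysis-time mean burst
sizes against the model, using Levenberg–Marquardt on the transformed
parameters $(\log k_{\max}, \log(LT_{50} - D), \log r, D)$ — the log
transforms keep the optimizer inside the valid domain and enforce
$LT_{50} > D$ by construction; $D$ is box-bounded to $[0, 0.95\max LT)$.
Because the $LT \le D$ zero clause kinks the objective in $D$, the fit
multi-starts from a fixed design of ten perturbations around an automatic
initialisation (capacity from the largest mean, $LT_{50}$ from the
half-maximum crossing, $D$ from the first positive time point minus one
sampling interval, $r$ from the log-linear rising phase). The
perturbation design is deterministic rather than random so that fits are
reproducible without consuming RNG state and invariant to point ordering.

Least squares is unweighted by default (no loss function is canonical for
these means); an inverse-variance-weighted option is available and
matters for the delay: plateau-scale residuals otherwise drown the early,
low-burst points that are the only ones informative about $D$. There is a
genuine near-flat ridge between $r$ and $D$ when only mid-rise points are
available — at 10% mean-level noise on an 11-point 20-minute grid the
kinetic pair is not reliably recoverable even though the fitted curve is.
With the assay's actual precision (means of ~100 cells with burst CV
~0.4, so ~4% noise), a 10-minute schedule starting at 30 min, and
inverse-variance weights, all four parameters are recovered within 10% in
≥90% of replicate simulations; that is the configuration the package's
recovery study uses, with full virion viability so that the capacity
estimate is not confounded by the known counting loss (see below).
Bootstrap parameter intervals (`bootstrap_fit_cis()`, resampling wells
within lysis times) are a package addition: the underlying assay reports
no fit uncertainty, and the output labels them accordingly.

## CV-equality tests

Two k-sample tests of equal CVs are implemented from the primary
statistical literature (Feltz & Miller 1996; Krishnamoorthy & Lee 2014)
rather than called from a wrapper package. The asymptotic test compares
the degrees-of-freedom-weighted dispersion of group CVs to
$\chi^2_{k-1}$. The modified signed-likelihood-ratio test profiles the
normal likelihood over a common CV (group means have a closed-form
solution at fixed CV, leaving a one-dimensional profile), then rescales
the likelihood-ratio statistic by a Monte-Carlo estimate of its null mean
— a Bartlett-type correction that markedly improves small-sample
calibration; `n_mc = 0` gives the plain asymptotic LRT. Both tests hold
their nominal 5% size at $n = 100$ per group in the package's simulation
checks, and both are scale invariant, as any CV test must be.

## The synthetic generator

`simulate_experiment()` builds the full assay: Poisson cell counts per
well, per-cell parameters, per-cell lysis times, integer virion counts,
binomial thinning, and the well-level CSV the analysis consumes (latent
truth is kept in a separate sidecar and never enters the analysis-facing
columns). Defaults are the study conditions:

| setting | default | why |
|---|---|---|
| plates × wells per time point | 5 × 96 | ~500 plaque assays per time point, ~100 occupied |
| mean occupancy | 0.25 cells/well | the design's dilution target (0.25–0.61 observed) |
| lysis schedule | 40–240 min, 20-min steps | spans the rise and the ~3 h plateau |
| population parameters | $k_{\max} = 1430$, $LT_{50} = 119$, $r = 0.027$, $D = 25$ | the fitted values for this system |
| heterogeneity | $CV^2_{k_{\max}} = 0.16$, others 0 | capacity CV 0.4, the level consistent with flat observed noise |
| parameter family | lognormal (gamma optional) | positive support and right skew; no family is prescribed by the data, so moments are matched instead |
| viability | 0.81 | chloroform handling removes ~19% of countable phage |
| natural lysis | mean 40.89 min, CV 0.05, truncated normal $> D$ | the naturally lysing comparison strain's mean; lysis-time noise an order of magnitude below burst noise |

Per-cell parameters are drawn independently of each other and of
occupancy, matching the no-covariance assumption of the decomposition.
Each cell's burst is rounded to whole virions before binomial thinning,
since plaque counts are integers of viable particles. An optional
cell-volume covariate scaling capacity exists but is off by default.

With heterogeneity and thinning off and occupancy small, observed means
equal the model curve up to rounding and the whole pipeline inverts —
fits recover the generating parameters to rounding error. That closure
property is what makes the generator usable as a test harness.

What the generator deliberately does *not* emulate: mechanistic
intracellular kinetics, cell-cycle structure, pipetting bias or clumped
(non-Poisson) occupancy, and adsorption losses. Passing tests on
synthetic data therefore demonstrate that the statistical machinery is
correct and internally consistent under the stated stochastic structure —
not that real assays satisfy that structure.

One quantitative consequence of the structure deserves emphasis: at
occupancy 0.25–0.61, a nontrivial fraction of occupied wells hold two or
more cells (13% of occupied wells at $\lambda = 0.3$). Pooled multi-cell
bursts inflate the observed mean by the factor
$\lambda/(1-e^{-\lambda})$ and add a lysis-time-independent occupancy
term (~0.12 at $\lambda = 0.3$) to the observed well-level CV². The flat
capacity signature survives this (the added term is itself flat), but a
decaying single-cell CV² decays to the occupancy floor, not to zero; the
package's discrimination checks therefore read the decay on single-cell
wells identified from the generator's latent truth, while slope checks
use the analysis-facing occupied wells as a real analysis would.

## Numerical and design choices collected

* Overflow-guarded exponentials throughout the model and sensitivities.
* Sensitivities analytic, finite differences only as a cross-check, so
  the structural identity $S_{k_{\max}} \equiv 1$ holds exactly.
* The third term of the decomposition is the symmetric $S_r^2 CV_r^2$
  form forced by the derivation.
* Floor convention for expected whole-well counts.
* Strictly-greater-than trimming threshold, one pass, ties kept.
* $1/n$ central moments for skewness.
* Percentile bootstrap with order-statistic endpoints.
* Deterministic multi-start for fitting; $LT_{50} > D$ by
  reparameterisation.
* Model fits default to untrimmed means (the original data including
  outliers); trimmed summaries are always reported alongside.
* The viability correction (×1/0.81) exists but defaults off: the
  headline mean-burst curve describes counted plaques, and the fitted
  capacity is correspondingly an underestimate of true capacity by ~19%.
* Simulation sizes in the test suite (2000 null replicates for test
  calibration, 50 replicate studies for recovery, 400-replicate
  bootstraps) are chosen to keep Monte-Carlo error well below the margins
  being asserted.

## Limitations

The decomposition is first-order: at capacity CV 0.4 the linearisation is
accurate because $f$ is exactly linear in $k_{\max}$, but for large
$LT_{50}$ or $r$ heterogeneity the predicted CV² is an approximation and
the simulated profiles deviate from it quantitatively (the qualitative
flat-versus-decaying distinction is robust). Zero-plaque occupied wells
are unidentifiable and silently dropped, biasing short-lysis-time samples
upward. The CV tests assume roughly normal within-group variation for
their stated size; on strongly skewed burst distributions their size is
approximate. Bootstrap intervals are percentile and mildly anti-
conservative on skewed samples.
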