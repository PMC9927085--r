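# phageburst

Single-cell bacteriophage burst-size analysis: distributions, a saturating
burst-size/lysis-time model, and a noise decomposition that asks *where*
cell-to-cell variability in phage output comes from.

## The problem

A phage-infected bacterium releases a burst of progeny virions when it
lyses. Classical one-step growth curves measure only the *average* burst
size of a population. With a lysis-deficient lysogen, induced cells keep
assembling phage until they are lysed chemically at a chosen time, and
limiting dilution into 96-well plates (≈0.25 cells/well, Poisson
occupancy) isolates single cells whose progeny can be counted by plaque
assay. Repeating this across lysis times gives the full single-cell
burst-size distribution — mean, CV², skewness — as a function of lysis
time.

`phageburst` is for researchers analysing such assays (or designing
them). It implements:

* **Occupancy math** — Poisson well statistics, expected empty wells,
  the zero-class occupancy estimator (`p_cells`, `expected_empty`,
  `occupancy_from_empty`).
* **Distribution summaries** — per-lysis-time mean/CV/CV²/moment
  skewness, one-pass outlier trimming at twice the mean (multi-cell
  wells), percentile bootstrap CIs (`summarize_assay`, `trim_outliers`,
  `bootstrap_ci`).
* **The burst-size model** — mean burst size vs lysis time
  (`burst_size`, `fit_burst_model`):

  $$BS(LT) = k_{\max}\,\frac{e^{r(LT-D)}-1}{e^{r(LT_{50}-D)}+e^{r(LT-D)}-2},
  \qquad LT > D,$$

  with delay $D$, accumulation rate $r$, half-maximal lysis time
  $LT_{50}$, and cellular capacity $k_{\max}$.
* **Noise decomposition** — first-order propagation of parameter
  heterogeneity into burst-size noise,
  $CV^2_{BS}=\sum_x S_x^2\,CV^2_x$ with log-sensitivities
  $S_x=(\hat x/f)\,\partial f/\partial x$. Since $S_{k_{\max}}\equiv 1$
  while $S_{LT_{50}},S_r\to 0$ at long lysis times, a *flat* CV² profile
  identifies capacity heterogeneity as the noise source
  (`burst_sensitivities`, `cv2_burst`, `decompose_noise`, `noise_trend`).
* **CV-equality tests** — Feltz–Miller asymptotic and modified
  signed-likelihood-ratio tests for equal CVs across groups
  (`cv_test_asymptotic`, `cv_test_mslr`), e.g. natural vs chemical lysis.
* **A synthetic assay generator** — complete plate experiments with
  Poisson occupancy, lognormal per-cell parameter heterogeneity, optional
  natural-lysis timing noise, and binomial virion-viability thinning
  (`assay_config`, `simulate_experiment`), so every stage runs and is
  testable without any external data.
* **An end-to-end pipeline** — `run_pipeline()` plus a thin CLI wrapper
  in `inst/scripts/phageburst-pipeline.R`.

## Worked example

Simulate a full assay at the default study conditions (5 × 96-well
plates per lysis time at 0.25 cells/well, capacity heterogeneity
CV² = 0.16, 19% virion counting loss), summarise it, fit the model, and
decompose the noise:

```r
library(phageburst)

cfg <- assay_config(seed = 42)
sim <- simulate_experiment(cfg)
#> Simulated assay: 5280 wells (1173 occupied by plaque count) at 11 lysis times

summ <- summarize_assay(sim$wells, n_boot = 1000)
summ[c(1, 5, 11), c("lysis_time_min", "n", "mean", "ci_lo", "ci_hi",
                    "cv2", "skewness", "frac_removed")]
#>    lysis_time_min   n     mean    ci_lo    ci_hi   cv2 skewness frac_removed
#> 1              40 110   51.136   46.764   55.864 0.212    1.142        0.045
#> 5             120 111  713.162  651.144  770.937 0.207    1.312        0.045
#> 11            240 105 1355.000 1227.533 1482.571 0.253    1.526        0.048

fit <- fit_burst_model(summ$lysis_time_min, summ$mean)
fit
#> Burst-size model fit (nonlinear least squares)
#> Burst-size model parameters:
#>   k_max = 1469.12 PFU/cell
#>   LT50  = 128.362 min
#>   r     = 0.0177445 /min
#>   D     = 35.1041 min
#>   RSS = 1.484e+04 on 11 points; converged: TRUE (10 starts)

dec <- decompose_noise(sim$wells, fit$params)
dec$calibrated_cv2["kmax"]   # capacity CV^2 implied by the flat profile
#> 0.241
tr <- noise_trend(sim$wells, n_boot = 400)
c(tr$slope, tr$ci)
#> slope 1.98e-05, 95% CI -4.10e-05 .. 8.10e-05
```

Reading the output: burst size rises ~25-fold from 40 to 240 min while
CV² stays in a narrow band (~0.21–0.25) — the slope of CV² against mean
burst size is statistically indistinguishable from zero. Under the
decomposition only capacity heterogeneity predicts that flat profile, and
its calibrated CV² (0.24 here) is the capacity CV² 0.16 plus the
lysis-time-independent Poisson multi-cell occupancy term that well-level
counts carry. The distributions are right-skewed (g₁ ≈ 1–1.5, multi-cell
wells in the right tail), and trimming at twice the mean removes ~5% of
wells. The fitted means describe *counted* plaques: with 19% of virions
lost to handling, the fitted $k_{\max}$ underestimates true capacity
accordingly.

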