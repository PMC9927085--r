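test_that("noiseless data return the generating parameters to high precision", {
  p <- ref_params()
  lt <- seq(40, 240, 20)
  fit <- fit_burst_model(lt, burst_size(lt, p))
  expect_true(fit$converged)
  rel <- abs(coef(fit) - unlist(p)) / unlist(p)
  expect_true(all(rel < 1e-6))
  expect_lt(fit$residual_sum_of_squares, 1e-10)
})

test_that("exact recovery holds across random true parameters", {
  set.seed(44)
  for (i in 1:20) {
    p <- rand_params()
    # sample the rise and the plateau of this particular curve
    lt <- p$D + seq(0.2, 4, length.out = 12) * (p$LT50 - p$D)
    fit <- fit_burst_model(lt, burst_size(lt, p))
    # relative errors, with an absolute floor of 1 minute on the delay so
    # near-zero true delays do not inflate the ratio
    denom <- unlist(p)
    denom["D"] <- max(denom["D"], 1)
    rel <- abs(coef(fit) - unlist(p)) / denom
    expect_true(all(rel < 1e-4))
  }
})

test_that("fit is invariant to point ordering", {
  set.seed(45)
  p <- ref_params()
  lt <- seq(40, 240, 20)
  y <- burst_size(lt, p) * exp(rnorm(length(lt), 0, 0.05))
  o <- sample(length(lt))
  f1 <- fit_burst_model(lt, y)
  f2 <- fit_burst_model(lt[o], y[o])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-3)
})

test_that("multiplicative noise on means still recovers parameters roughly", {
  # CV 0.1 noise on the per-lysis-time means; tolerances calibrated from
  # repeated draws. The capacity and half-maximum parameters are well
  # identified at this noise level, while the rate/delay pair trades off
  # along a near-flat ridge (the delay only enters through the earliest
  # points), so the kinetic pair is checked through the fitted curve, the
  # quantity the ridge leaves identified.
  set.seed(55)
  p <- ref_params()
  lt <- seq(40, 240, 20)
  f0 <- burst_size(lt, p)
  res <- replicate(20, {
    y <- f0 * exp(rnorm(length(lt), 0, sqrt(log(1 + 0.01))))
    fit <- fit_burst_model(lt, y)
    rel <- abs(coef(fit) - unlist(p)) / unlist(p)
    curve_err <- sqrt(mean((predict(fit, lt) / f0 - 1)^2))
    c(rel, curve = curve_err)
  })
  med <- apply(res, 1, median)
  expect_lt(med[["k_max"]], 0.15)
  expect_lt(med[["LT50"]], 0.12)
  expect_lt(med[["curve"]], 0.15)
})

test_that("fitting refuses unidentifiable designs", {
  p <- ref_params()
  lt <- c(60, 120, 180, 240)
  expect_error(fit_burst_model(lt, burst_size(lt, p)), "5 distinct")
  expect_error(fit_burst_model(c(60, 60, 60, 120, 180),
                               rep(c(100, 500, 900), c(3, 1, 1))),
               "5 distinct")
})

test_that("inverse-variance weights are honoured", {
  p <- ref_params()
  lt <- seq(30, 240, 15)
  y <- burst_size(lt, p)
  y[1] <- y[1] * 3  # corrupt the first point
  w <- rep(1, length(lt))
  w[1] <- 1e-10
  fw <- fit_burst_model(lt, y, weights = w)
  rel <- abs(coef(fw) - unlist(p)) / unlist(p)
  expect_true(all(rel < 1e-3))
})

test_that("predicted curves inherit the model anchors", {
  p <- ref_params()
  lt <- seq(40, 240, 20)
  fit <- fit_burst_model(lt, burst_size(lt, p))
  grid <- c(fit$params$D, fit$params$LT50, 180)
  curve <- predict_curve(fit, grid)
  expect_identical(curve$mean_burst[1], 0)
  expect_equal(curve$mean_burst[2], fit$params$k_max / 2, tolerance = 1e-12)
  expect_equal(curve$mean_burst[3], 1211.71350584357, tolerance = 1e-6)
  expect_equal(predict(fit, grid), curve$mean_burst)
})

test_that("the fitted rising phase is near-linear on the log scale", {
  p <- ref_params()
  lt_rise <- seq(45, 100, 5)
  logbs <- log(burst_size(lt_rise, p))
  fit_lin <- lm(logbs ~ lt_rise)
  expect_gt(summary(fit_lin)$r.squared, 0.97)
})

test_that("bootstrap parameter intervals cover the point estimate", {
  cfg <- assay_config(n_plates_per_timepoint = 3,
                      lysis_times = seq(40, 240, 25), viability = 1,
                      seed = 66)
  sim <- simulate_experiment(cfg)
  summ <- summarize_assay(sim$wells, n_boot = 0)
  fit <- fit_burst_model(summ$lysis_time_min, summ$mean)
  set.seed(67)
  fit <- bootstrap_fit_cis(fit, sim$wells, n_boot = 60)
  expect_true(all(rownames(fit$param_cis) == c("k_max", "LT50", "r", "D")))
  est <- coef(fit)
  expect_true(all(fit$param_cis$lo <= est & est <= fit$param_cis$hi))
})
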