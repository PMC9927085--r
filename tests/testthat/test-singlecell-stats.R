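test_that("summary statistics match hand-computed moments", {
  # counts {1,2,3,4,10}: mean 4, m2 = 10, m3 = 36, g1 = 36/10^1.5
  s <- summarize_bursts(c(1, 2, 3, 4, 10))
  expect_identical(s$n, 5L)
  expect_identical(s$mean, 4)
  expect_equal(s$sd, sd(c(1, 2, 3, 4, 10)))
  expect_equal(s$cv2, s$cv^2)
  expect_equal(s$skewness, 36 / 10^1.5, tolerance = 1e-12)
  expect_gt(s$skewness, 0)
})

test_that("degenerate samples are handled by convention or error", {
  s <- summarize_bursts(c(7, 7, 7))
  expect_identical(s$sd, 0)
  expect_identical(s$cv, 0)
  expect_identical(s$skewness, 0)  # zero variance -> no asymmetry
  expect_error(summarize_bursts(5), "at least two")
  expect_error(summarize_bursts(c(0, 0, 0)), "zero mean")
  expect_error(summarize_bursts(c(-1, 2, 3)), "nonnegative")
})

test_that("summaries are location-free in scale: CV and skewness invariant", {
  set.seed(11)
  x <- rlnorm(200, meanlog = 4, sdlog = 0.4)
  for (a in c(0.5, 3, 100)) {
    s1 <- summarize_bursts(x)
    s2 <- summarize_bursts(a * x)
    expect_equal(s2$mean, a * s1$mean)
    expect_equal(s2$sd, a * s1$sd)
    expect_equal(s2$cv, s1$cv, tolerance = 1e-12)
    expect_equal(s2$cv2, s1$cv2, tolerance = 1e-12)
    expect_equal(s2$skewness, s1$skewness, tolerance = 1e-12)
  }
})

test_that("trimming removes exactly the values above twice the mean, once", {
  tr <- trim_outliers(c(10, 10, 10, 50))
  expect_identical(tr$kept, c(10, 10, 10))
  expect_identical(tr$n_removed, 1L)
  expect_identical(tr$threshold, 40)
  expect_identical(tr$mean_before, 20)
  expect_identical(tr$mean_after, 10)
  # ties at the threshold are kept (strictly greater than 2x mean)
  tr2 <- trim_outliers(c(10, 10, 20))
  expect_identical(tr2$n_removed, 0L)
  expect_identical(tr2$kept, c(10, 10, 20))
  # single pass: the threshold is not recomputed after removal
  x <- c(rep(10, 8), 25, 60)
  thr <- 2 * mean(x)
  expect_identical(trim_outliers(x)$kept, x[x <= thr])
})

test_that("trimming right-skewed samples reduces mean and skewness", {
  set.seed(22)
  for (i in 1:20) {
    x <- rlnorm(150, meanlog = 5, sdlog = 0.5)
    tr <- trim_outliers(x)
    expect_lte(tr$mean_after, tr$mean_before)
    if (tr$n_removed > 0) expect_lte(tr$skew_after, tr$skew_before)
  }
})

test_that("bootstrap intervals are reproducible order statistics", {
  x <- c(12, 40, 7, 33, 21)
  ci1 <- bootstrap_ci(x, "mean", n_boot = 250, seed = 99)
  ci2 <- bootstrap_ci(x, "mean", n_boot = 250, seed = 99)
  expect_identical(ci1, ci2)
  # brute-force re-implementation: same RNG stream, explicit loops
  set.seed(99)
  idx <- sample.int(5, 5 * 250, replace = TRUE)
  mat <- matrix(x[idx], nrow = 250, ncol = 5)
  stats <- sort(apply(mat, 1, mean))
  expect_identical(unname(ci1),
                   c(stats[ceiling(250 * 0.025)], stats[ceiling(250 * 0.975)]))
  # cv statistic against brute force too
  ci_cv <- bootstrap_ci(x, "cv", n_boot = 250, seed = 7)
  set.seed(7)
  idx <- sample.int(5, 5 * 250, replace = TRUE)
  mat <- matrix(x[idx], nrow = 250, ncol = 5)
  stats <- sort(apply(mat, 1, function(r) sd(r) / mean(r)))
  expect_equal(unname(ci_cv),
               c(stats[ceiling(250 * 0.025)], stats[ceiling(250 * 0.975)]),
               tolerance = 1e-12)
  # constant sample collapses to a point
  expect_identical(unname(bootstrap_ci(rep(5, 10), "mean", n_boot = 50,
                                       seed = 1)), c(5, 5))
})

test_that("bootstrap mean interval attains near-nominal coverage", {
  set.seed(33)
  true_mean <- exp(4 + 0.4^2 / 2)  # lognormal(4, 0.4) mean
  hits <- 0
  reps <- 400
  for (i in 1:reps) {
    x <- rlnorm(100, 4, 0.4)
    ci <- bootstrap_ci(x, "mean", n_boot = 400)
    hits <- hits + (ci["lo"] <= true_mean && true_mean <= ci["hi"])
  }
  # percentile bootstrap slightly under-covers for skewed data; allow
  # [0.88, 0.99] around the nominal 0.95
  expect_gte(hits / reps, 0.88)
  expect_lte(hits / reps, 0.99)
})

test_that("assay CSV round-trips and malformed tables fail with row diagnostics", {
  cfg <- assay_config(n_plates_per_timepoint = 1, lysis_times = c(60, 120),
                      seed = 4)
  sim <- simulate_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(sim$wells, path)
  back <- read_assay_csv(path)
  expect_identical(back$plaque_count, sim$wells$plaque_count)
  expect_false("n_cells" %in% names(back))  # latent truth never leaks
  bad <- back
  bad$plaque_count[c(3, 8)] <- -1
  expect_error(validate_wells(bad), "row\\(s\\): 3, 8")
  expect_error(validate_wells(back[, -4]), "missing column")
})

test_that("per-lysis-time assay summary reports trimmed and untrimmed stats", {
  cfg <- assay_config(n_plates_per_timepoint = 3, seed = 8)
  sim <- simulate_experiment(cfg)
  summ <- summarize_assay(sim$wells, n_boot = 200)
  expect_true(all(diff(summ$lysis_time_min) > 0))
  expect_true(all(summ$ci_lo <= summ$mean & summ$mean <= summ$ci_hi))
  expect_true(all(summ$n_trimmed <= summ$n))
  expect_true(all(summ$mean_trimmed <= summ$mean))
  # correction rescales means but leaves the scale-free statistics alone
  summ_c <- summarize_assay(sim$wells, n_boot = 0, correction = 1 / 0.81)
  expect_equal(summ_c$mean, summ$mean / 0.81, tolerance = 1e-12)
  expect_equal(summ_c$cv2, summ$cv2, tolerance = 1e-12)
  expect_equal(summ_c$skewness, summ$skewness, tolerance = 1e-12)
})
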