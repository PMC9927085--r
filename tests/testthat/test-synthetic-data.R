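test_that("zero heterogeneity returns the population parameters exactly", {
  cfg <- assay_config(heterogeneity = noise_budget(), seed = 1)
  cp <- draw_cell_params(50, cfg)
  expect_identical(cp$k_max, rep(1430, 50))
  expect_identical(cp$LT50, rep(119, 50))
  expect_identical(cp$r, rep(0.027, 50))
  expect_identical(cp$D, rep(25, 50))
})

test_that("lognormal parameter draws are moment-matched", {
  set.seed(10)
  cfg <- assay_config(heterogeneity = noise_budget(cv2_kmax = 0.16))
  k <- draw_cell_params(1e4, cfg)$k_max
  # CV within 5% of 0.4, mean within 2 standard errors of 1430
  expect_lt(abs(sd(k) / mean(k) - 0.4), 0.02)
  expect_lt(abs(mean(k) - 1430), 2 * sd(k) / sqrt(1e4))
  # gamma alternative matches the same moments
  cfg_g <- assay_config(heterogeneity = noise_budget(cv2_kmax = 0.16),
                        parameter_family = "gamma")
  kg <- draw_cell_params(1e4, cfg_g)$k_max
  expect_lt(abs(sd(kg) / mean(kg) - 0.4), 0.02)
  expect_lt(abs(mean(kg) - 1430), 2 * sd(kg) / sqrt(1e4))
})

test_that("empty wells produce no plaques and singles at LT50 give half capacity", {
  cfg <- assay_config(heterogeneity = noise_budget(), viability = 1,
                      mean_occupancy = 0.2, lysis_times = 119,
                      n_plates_per_timepoint = 3, seed = 12)
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$wells$plaque_count[sim$wells$n_cells == 0] == 0))
  singles <- sim$wells[sim$wells$n_cells == 1, ]
  expect_true(all(singles$plaque_count == round(1430 / 2)))
  doubles <- sim$wells[sim$wells$n_cells == 2, ]
  expect_true(all(doubles$plaque_count == 2 * round(1430 / 2)))
})

test_that("simulation is bit-identical given the seed", {
  cfg <- assay_config(n_plates_per_timepoint = 2, seed = 77)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(simulate_experiment(cfg)$wells, p1)
  write_assay_csv(simulate_experiment(cfg)$wells, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("multi-cell fraction among occupied wells follows the Poisson conditional", {
  cfg <- assay_config(mean_occupancy = 0.61, lysis_times = 180,
                      n_plates_per_timepoint = 40, seed = 13)
  sim <- simulate_experiment(cfg)
  occ <- sim$wells[sim$wells$n_cells >= 1, ]
  frac <- mean(occ$n_cells >= 2)
  expected <- p_multicell_given_occupied(0.61)
  se <- sqrt(expected * (1 - expected) / nrow(occ))
  expect_lt(abs(frac - expected), 3.5 * se)
})

test_that("the generator inverts cleanly through the full analysis pipeline", {
  # no heterogeneity, full viability, very low occupancy: observed means
  # equal the model curve up to integer rounding, so the fit recovers the
  # generating parameters to rounding error
  cfg <- assay_config(heterogeneity = noise_budget(), viability = 1,
                      mean_occupancy = 0.08, n_plates_per_timepoint = 2,
                      lysis_times = seq(40, 240, 20), seed = 14)
  sim <- simulate_experiment(cfg)
  singles_only <- sim$wells[sim$wells$n_cells <= 1, ]
  summ <- summarize_assay(singles_only, n_boot = 0)
  expect_true(all(abs(summ$mean - burst_size(summ$lysis_time_min,
                                             cfg$true_params)) <= 0.5))
  fit <- fit_burst_model(summ$lysis_time_min, summ$mean)
  rel <- abs(coef(fit) - unlist(cfg$true_params)) / unlist(cfg$true_params)
  expect_true(all(rel < 0.02))
})

test_that("viability thinning scales means by the survival probability", {
  base <- list(heterogeneity = noise_budget(), mean_occupancy = 0.3,
               lysis_times = 180, n_plates_per_timepoint = 25)
  cfg1 <- do.call(assay_config, c(base, viability = 1, seed = 15))
  cfg2 <- do.call(assay_config, c(base, viability = 0.81, seed = 15))
  w1 <- simulate_experiment(cfg1)$wells
  w2 <- simulate_experiment(cfg2)$wells
  # condition on single-cell wells: each has exactly round(BS(180)) virions,
  # so the mean plaque count estimates the survival probability directly
  m1 <- mean(w1$plaque_count[w1$n_cells == 1])
  m2 <- mean(w2$plaque_count[w2$n_cells == 1])
  expect_equal(m2 / m1, 0.81, tolerance = 0.005)
})

test_that("natural lysis draws truncated per-cell lysis times", {
  cfg <- assay_config(lysis_mode = "natural", natural_lt_mean = 40.89,
                      natural_lt_cv = 0.3, lysis_times = 60,
                      heterogeneity = noise_budget(), viability = 1,
                      mean_occupancy = 0.3, n_plates_per_timepoint = 30,
                      seed = 16)
  sim <- simulate_experiment(cfg)
  singles <- sim$wells[sim$wells$n_cells == 1, ]
  # with no parameter heterogeneity, all burst variation among single-cell
  # wells comes from the per-cell lysis times; wide lysis-time noise must
  # therefore spread the distribution well beyond rounding error
  expect_gt(sd(singles$plaque_count) / mean(singles$plaque_count), 0.2)
  # chemical lysis at the same schedule is deterministic by contrast
  cfg_chem <- assay_config(lysis_times = 60, heterogeneity = noise_budget(),
                           viability = 1, mean_occupancy = 0.3,
                           n_plates_per_timepoint = 5, seed = 16)
  chem <- simulate_experiment(cfg_chem)
  chem_singles <- chem$wells[chem$wells$n_cells == 1, ]
  expect_identical(unique(chem_singles$plaque_count),
                   as.integer(round(burst_size(60, cfg_chem$true_params))))
})

test_that("truth sidecar records config and model-implied moments", {
  cfg <- assay_config(n_plates_per_timepoint = 1, lysis_times = c(60, 180),
                      seed = 17)
  sim <- simulate_experiment(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim, path)
  truth <- jsonlite::fromJSON(path)
  expect_equal(truth$config$true_params$k_max, 1430)
  expect_equal(truth$per_timepoint$predicted_cv2, c(0.16, 0.16))
  expect_equal(truth$per_timepoint$true_mean_counted,
               burst_size(c(60, 180), cfg$true_params) * 0.81,
               tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(assay_config(viability = 0), "viability")
  expect_error(assay_config(mean_occupancy = -1), "mean_occupancy")
  expect_error(assay_config(lysis_times = numeric(0)), "lysis_times")
  expect_error(assay_config(n_plates_per_timepoint = 0), "at least 1")
  expect_error(assay_config(lysis_mode = "natural", natural_lt_mean = 10),
               "natural lysis")
})
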