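# Shared fixtures: the reference parameter set and random valid draws for
# property-style tests.

ref_params <- function() burst_params(k_max = 1430, LT50 = 119, r = 0.027, D = 25)

# one random parameter set satisfying all invariants (uses current RNG)
rand_params <- function() {
  D <- runif(1, 0, 40)
  burst_params(
    k_max = exp(runif(1, log(50), log(5000))),
    LT50 = D + runif(1, 20, 150),
    r = runif(1, 0.005, 0.08),
    D = D)
}

# a lysis time strictly above the delay of p
rand_lt <- function(p) p$D + runif(1, 5, 400)

# central finite differences of log f in log x: independent numerical
# oracle for the analytic log-sensitivities
fd_sensitivity <- function(lt, p, which, h = 1e-6) {
  perturb <- function(fac) {
    q <- unclass(p)
    q[[which]] <- q[[which]] * fac
    burst_size(lt, burst_params(q$k_max, q$LT50, q$r, q$D))
  }
  (log(perturb(exp(h))) - log(perturb(exp(-h)))) / (2 * h)
}

# check an analytic log-sensitivity against the finite-difference oracle:
# 1e-6 relative, with a 1e-9 absolute floor because central differences of
# log f cannot resolve elasticities below roundoff (~1e-10) in the deep
# decay regime
expect_fd_match <- function(analytic, lt, p, which) {
  fd <- fd_sensitivity(lt, p, which)
  expect_lt(abs(analytic - fd), max(1e-6 * abs(fd), 1e-9))
}

# 100 single-cell bursts at each lysis time under capacity-only lognormal
# heterogeneity; exploits the model's exact linearity in k_max
capacity_only_means <- function(lt, p, cv2 = 0.16, n_cells = 100) {
  cfg <- assay_config(true_params = p,
                      heterogeneity = noise_budget(cv2_kmax = cv2),
                      viability = 1)
  shape <- burst_size(lt, p) / p$k_max
  dat <- lapply(shape, function(s)
    round(draw_cell_params(n_cells, cfg)$k_max * s))
  list(means = vapply(dat, mean, numeric(1)),
       se2 = vapply(dat, function(x) stats::var(x) / length(x), numeric(1)))
}
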