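test_that("noiseless data are recovered essentially exactly", {
  d <- noiseless_design()
  p <- cmpd1_params()
  ds <- simulate_dataset(d, p, "1")
  f <- fit_operational_global(ds, assess = FALSE)
  expect_identical(f$status, "converged")
  expect_equal(unname(f$estimates[c("pkb", "log_alpha_beta", "log_tau_b")]),
               c(5.47, 1.63, 0.12), tolerance = 1e-4)
  expect_equal(unname(f$estimates[["em"]]), 100, tolerance = 1e-4)
  expect_lt(f$rss, 1e-10)
})

test_that("fit preconditions are enforced", {
  d <- small_design()
  ds <- simulate_dataset(d, cmpd1_params(), "1")
  no_veh <- ds[ds$conc_B_M > 0, ]
  expect_error(fit_operational_global(no_veh), "vehicle")
  one_b <- ds[ds$conc_B_M %in% c(0, 1e-6), ]
  expect_error(fit_operational_global(one_b), "two non-zero")
})

test_that("noisy compound-1 panel is recovered within reporting tolerance", {
  d <- default_design()
  ds <- simulate_dataset(d, cmpd1_params(), "1", seed = 11)
  f <- fit_operational_global(ds)
  expect_identical(f$status, "converged")
  expect_lt(abs(f$estimates[["pkb"]] - 5.47), 0.2)
  expect_lt(abs(f$estimates[["log_alpha_beta"]] - 1.63), 0.3)
  expect_true(all(f$se[c("pkb", "log_alpha_beta", "log_tau_b")] > 0))
})

f_converged <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ds <- simulate_dataset(small_design(), cmpd1_params(), "1", seed = 2)
      memo <<- fit_operational_global(ds)
    }
    memo
  }
})

test_that("near-neutral interaction is flagged ambiguous; flat data too", {
  d <- default_design()
  flat <- operational_params(5.0, 0.02, -5)
  ds <- simulate_dataset(d, flat, "8", seed = 3)
  f <- fit_operational_global(ds)
  expect_identical(f$status, "ambiguous")
  expect_true(length(f$identifiability$flags) > 0)
  # constant responses: nothing identifiable
  dc <- ds
  dc$response_pct <- 50
  fc <- fit_operational_global(dc)
  expect_identical(fc$status, "ambiguous")
  # coef() withholds estimates for non-converged fits
  expect_true(all(is.na(coef(fc))))
  expect_false(any(is.na(coef(f_converged()))))
})

test_that("identifiability rules fire on constructed fits", {
  f <- f_converged()
  cfg <- fit_config()
  # rule (i): inflate one SE
  f1 <- f; f1$se[["pkb"]] <- 2.3; f1$data <- NULL
  expect_identical(as.character(assess_identifiability(f1, cfg)), "ambiguous")
  # rule (ii): push an estimate to a bound
  f2 <- f; f2$estimates[["pkb"]] <- cfg$upper[["pkb"]]
  f2$data <- NULL
  expect_identical(as.character(assess_identifiability(f2, cfg)), "ambiguous")
  # exception: tauB reported ND (no apparent agonism) is not an ambiguity
  f3 <- f
  f3$estimates[["log_tau_b"]] <- NA_real_
  f3$se[["log_tau_b"]] <- NA_real_
  f3$data <- NULL
  expect_identical(as.character(assess_identifiability(f3, cfg)), "converged")
  # a healthy fit stays converged
  expect_identical(as.character(assess_identifiability(f, cfg)), "converged")
})

test_that("a compound devoid of intrinsic agonism converges with tauB not determined", {
  # epoxide-like profile: real affinity and cooperativity, tauB ~ 0; needs
  # the full modulator range (up to 30 uM) because KB is ~29 uM
  d <- default_design()
  d$n_experiments <- 4L
  ds <- simulate_dataset(d, operational_params(4.54, 1.45, -5), "6",
                         seed = 13)
  f <- fit_operational_global(ds)
  expect_identical(f$status, "converged")
  expect_true(is.na(f$estimates[["log_tau_b"]]))
  expect_false(is.na(f$estimates[["pkb"]]))
  expect_identical(classify_profile(f), "pure PAM")
  fp <- fit_operational_per_experiment(ds)
  expect_identical(fp$status, "converged")
  expect_identical(classify_profile(fp), "pure PAM")
})

test_that("per-experiment mode summarises across experiments", {
  # identical noiseless experiments: SEM exactly zero
  d0 <- noiseless_design(n_experiments = 3)
  ds0 <- simulate_dataset(d0, cmpd1_params(), "1")
  f0 <- fit_operational_per_experiment(ds0, assess = FALSE)
  expect_identical(f0$status, "converged")
  expect_equal(unname(f0$se), rep(0, 6), tolerance = 1e-6)
  expect_equal(f0$n, 3)
  # noisy experiments differ and SEMs are sub-log-unit
  d <- small_design(n_experiments = 4, seed = 21)
  ds <- simulate_dataset(d, operational_params(5.09, 2.24, 0.58), "7b")
  f <- fit_operational_per_experiment(ds, assess = FALSE)
  expect_identical(f$status, "converged")
  per <- f$per_experiment
  expect_equal(nrow(per), 4)
  expect_gt(sd(per$pkb), 0)
  expect_lt(f$se[["pkb"]], 1.0)
  expect_lt(f$se[["log_alpha_beta"]], 1.0)
  expect_lt(f$se[["log_tau_b"]], 1.0)
  # too few experiments is an input error
  one <- ds[ds$experiment == 1, ]
  expect_error(fit_operational_per_experiment(one), "at least 3")
})

test_that("global optimum matches an exhaustive grid search on a noiseless toy", {
  d <- assay_design(agonist_concs = c(0, 10^seq(-4.5, -2, length.out = 7)),
                    modulator_concs = c(0, 3e-6, 3e-5),
                    replicates_per_point = 1, n_experiments = 1,
                    noise_sd = 0)
  truth <- operational_params(5, 1.5, 0, em = 100, pec50 = 3.3, nb = 2)
  ds <- simulate_dataset(d, truth, "toy")
  f <- fit_operational_global(ds, assess = FALSE)
  # independent oracle: exhaustive 0.05-log grid over the allosteric
  # parameters with the shared curve shape held at its generating values
  grid <- expand.grid(pkb = seq(4, 6, by = 0.05),
                      log_ab = seq(0.5, 2.5, by = 0.05),
                      log_tau = seq(-1, 1, by = 0.05))
  A <- ds$conc_A_M; B <- ds$conc_B_M; y <- ds$response_pct
  ssr <- vapply(seq_len(nrow(grid)), function(i) {
    mu <- naive_operational(A, B, 100, 3.3, 2, grid$pkb[i], grid$log_ab[i],
                            grid$log_tau[i], 1e-4)
    sum((y - mu)^2)
  }, numeric(1))
  best <- grid[which.min(ssr), ]
  expect_equal(best$pkb, 5)
  expect_equal(best$log_ab, 1.5)
  expect_equal(best$log_tau, 0)
  expect_lte(f$rss, min(ssr) + 1e-8)
  expect_lt(abs(f$estimates[["pkb"]] - best$pkb), 0.05)
  expect_lt(abs(f$estimates[["log_alpha_beta"]] - best$log_ab), 0.05)
  expect_lt(abs(f$estimates[["log_tau_b"]] - best$log_tau), 0.05)
})

test_that("estimates are invariant to rescaling responses and Em", {
  ds <- simulate_dataset(small_design(seed = 9), cmpd1_params(), "1")
  f1 <- fit_operational_global(ds, assess = FALSE)
  ds2 <- ds
  ds2$response_pct <- ds$response_pct * 0.5
  f2 <- fit_operational_global(ds2, assess = FALSE)
  expect_equal(f2$estimates[["em"]], f1$estimates[["em"]] * 0.5,
               tolerance = 1e-3)
  for (par in c("pkb", "log_alpha_beta", "log_tau_b"))
    expect_equal(f2$estimates[[par]], f1$estimates[[par]], tolerance = 0.01)
})

test_that("parameter recovery is unbiased with calibrated intervals", {
  d <- small_design(n_experiments = 5)
  p <- cmpd1_params()
  true <- c(pkb = 5.47, log_alpha_beta = 1.63, log_tau_b = 0.12)
  n_panels <- 60
  est <- se <- matrix(NA_real_, n_panels, 3,
                      dimnames = list(NULL, names(true)))
  for (i in seq_len(n_panels)) {
    ds <- simulate_dataset(d, p, "1", seed = 5000 + i)
    f <- fit_operational_global(ds, assess = FALSE)
    est[i, ] <- f$estimates[names(true)]
    se[i, ] <- f$se[names(true)]
  }
  bias <- colMeans(est) - true
  expect_true(all(abs(bias) < 0.1))
  covered <- abs(est - rep(true, each = n_panels)) < 1.96 * se
  cov_rate <- colMeans(covered)
  expect_true(all(cov_rate >= 0.85 & cov_rate <= 0.99))
})

test_that("more experiments shrink the standard errors", {
  p <- cmpd1_params()
  f5 <- fit_operational_global(
    simulate_dataset(small_design(n_experiments = 5, seed = 31), p, "1"),
    assess = FALSE)
  f20 <- fit_operational_global(
    simulate_dataset(small_design(n_experiments = 20, seed = 31), p, "1"),
    assess = FALSE)
  for (par in c("pkb", "log_alpha_beta", "log_tau_b"))
    expect_lt(f20$se[[par]], f5$se[[par]])
})

test_that("shared-slope sigmoid fit recovers curve families", {
  # noiseless family: exact recovery
  hf0 <- simulate_hill_family(noise_sd = 0, n_experiments = 1, seed = 1)
  f0 <- fit_hill_shared_slope(hf0)
  expect_identical(f0$status, "converged")
  expect_equal(f0$shared_slope, 3.5, tolerance = 1e-6)
  expect_equal(f0$curves$pec50[f0$curves$conc_B_M == 0], 3.55,
               tolerance = 1e-6)
  # noisy family: slope within +/-0.5 of the generating 3.5
  hf <- simulate_hill_family(seed = 7)
  f <- fit_hill_shared_slope(hf)
  expect_lt(abs(f$shared_slope - 3.5), 0.5)
  expect_true(all(is.finite(f$curves$pec50)))
  expect_true(is.finite(f$shared_slope_se) && f$shared_slope_se >= 0)
  # genuinely different slopes: the shared-slope model fits worse than
  # free-slope fits
  mixed <- rbind(
    as.data.frame(simulate_hill_family(
      pec50 = 3.5, hill_slope = 2, modulator_concs = 0,
      n_experiments = 2, seed = 4)),
    as.data.frame(simulate_hill_family(
      pec50 = 3.5, hill_slope = 5, modulator_concs = 1e-6,
      n_experiments = 2, seed = 5)))
  fshared <- fit_hill_shared_slope(mixed)
  free_rss <- sum(vapply(unique(mixed$conc_B_M), function(b) {
    sub <- mixed[mixed$conc_B_M == b, ]
    g <- stats::nls(response_pct ~ bot + (top - bot) /
                      (1 + 10^(sl * (-pec - log10(conc_A_M + 1e-15)))),
                    data = sub,
                    start = list(bot = 0, top = 100, pec = 3.5, sl = 3))
    sum(residuals(g)^2)
  }, numeric(1)))
  expect_gt(fshared$rss, free_rss)
  expect_error(fit_hill_shared_slope(
    simulate_hill_family(pec50 = 3.55, modulator_concs = 0, seed = 1)),
    "two curves")
})
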