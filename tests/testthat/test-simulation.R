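test_that("true_clinical_rates implements the law of total probability", {
  r <- true_clinical_rates(0.15, 0.9999, 0.2, 0.3)
  expect_equal(r$pi_xt, 0.03008, tolerance = 1e-12)
  expect_equal(r$pi_xc, 0.04507, tolerance = 1e-12)
  expect_equal(r$rr_true, 0.03008 / 0.04507, tolerance = 1e-12)
  # perfect concordance, equal biomarker rates -> null RR
  expect_equal(true_clinical_rates(1, 1, 0.3, 0.3)$rr_true, 1)
  # PPV = NPV = 0.5: biomarker uninformative, clinical rate 0.5 everywhere
  r5 <- true_clinical_rates(0.5, 0.5, 0.123, 0.3)
  expect_equal(r5$pi_xt, 0.5)
  expect_equal(r5$rr_true, 1)
})

test_that("modified bias and RMSE take their hand-computed values", {
  expect_equal(as.numeric(modified_bias(c(2, 0.5), 1)), 0)
  expect_equal(as.numeric(modified_bias(c(1, 4), 2)), 0)
  expect_equal(as.numeric(modified_bias(rep(3.7, 5), 3.7)), 0)
  expect_equal(as.numeric(modified_rmse(c(1, 4), 2)), log10(2))
  expect_equal(as.numeric(modified_rmse(c(1, 4), 2, base = exp(1))), log(2))
  expect_equal(as.numeric(modified_rmse(5, 2)), abs(log10(5 / 2)))
  expect_equal(as.numeric(modified_rmse(rep(2, 3), 2)), 0)
  # non-positive estimates are excluded and counted
  b <- modified_bias(c(1, 4, -1, 0), 2)
  expect_equal(as.numeric(b), 0)
  expect_equal(attr(b, "n_excluded"), 2L)
  expect_error(modified_bias(c(-1, 0), 2), "no positive finite")
})

test_that("modified_rmse >= |modified_bias| on random inputs", {
  set.seed(4)
  for (i in 1:200) {
    rr <- rlnorm(sample(1:30, 1), 0, 1)
    truth <- rlnorm(1, 0, 0.5)
    expect_gte(as.numeric(modified_rmse(rr, truth)) + 1e-12,
               abs(as.numeric(modified_bias(rr, truth))))
  }
})

test_that("avg_ci_width is the mean lower/upper ratio and antitone in width", {
  expect_equal(avg_ci_width(0.5, 1), 0.5)
  expect_equal(avg_ci_width(c(0.2, 0.5), c(0.8, 1)), 0.375)
  expect_equal(avg_ci_width(c(2, 3), c(2, 3)), 1)
  expect_error(avg_ci_width(1, 0.5), "lower <= upper")
  expect_error(avg_ci_width(-1, 1), "lower <= upper")
  # widening any interval on the ratio scale lowers the measure
  lo <- c(0.3, 0.6); up <- c(0.9, 1.2)
  expect_lt(avg_ci_width(lo / 1.5, up), avg_ci_width(lo, up))
  expect_lt(avg_ci_width(lo, up * 1.5), avg_ci_width(lo, up))
})

test_that("perfect concordance makes clinical counts copy biomarker counts", {
  cfg <- scenario_config(ppv = 1, npv = 1, n_trials = 30, phi_bj = 0.3,
                         k_reps = 1, seed = 8)
  set.seed(8)
  tr <- generate_historical_trials(cfg)
  expect_identical(tr$x_t, tr$b_t)
  expect_identical(tr$x_c, tr$b_c)
  # and the patient-level generator agrees
  set.seed(8)
  arm <- simulate_patients(500, 0.3, 1, 1)
  expect_identical(arm$c, arm$d)
})

test_that("generated clinical rates match the total-probability truth at n = 1e5", {
  set.seed(15)
  ppv <- 0.7; npv <- 0.85; pi_b <- 0.25; n <- 1e5
  truth <- ppv * pi_b + (1 - npv) * (1 - pi_b)
  # patient-level generator
  arm <- simulate_patients(n, pi_b, ppv, npv)
  se <- sqrt(truth * (1 - truth) / n)
  expect_lt(abs(mean(arm$c) - truth), 3 * se)
  expect_lt(abs(mean(arm$d) - pi_b), 3 * sqrt(pi_b * (1 - pi_b) / n))
  # count-level shortcut used by the scenario engine (one big trial)
  cfg <- scenario_config(ppv = ppv, npv = npv, n_trials = 2, phi_bj = 0.3,
                         k_reps = 1, patients_per_trial = 2 * n,
                         pi_bc = pi_b, seed = 1)
  tr <- generate_historical_trials(cfg, phi_b = c(0.5, 0.5))
  expect_lt(abs(tr$x_c[1] / n - truth), 3 * se)
})

test_that("generator validates the implied treatment-arm rate", {
  cfg <- scenario_config(ppv = 0.8, npv = 0.8, n_trials = 2, phi_bj = 0.3,
                         k_reps = 1, seed = 1)
  expect_error(generate_historical_trials(cfg, phi_b = c(0.8, 0.5)),
               "outside \\(0, 1\\)")
  tr <- generate_historical_trials(cfg, phi_b = c(0.1, 0.6))
  expect_equal(nrow(tr), 2L)
  expect_true(all(tr$n_t == 200L & tr$n_c == 200L))
})

test_that("run_scenario is deterministic given the seed and reports K_effective", {
  cfg <- scenario_config(ppv = 0.9, npv = 0.9, n_trials = 4, phi_bj = 0.3,
                         k_reps = 5, seed = 99,
                         mcmc = mcmc_control(1, 200, 500, 1))
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_equal(r1$modified_bias, r2$modified_bias)
  expect_equal(r1$modified_rmse, r2$modified_rmse)
  expect_equal(r1$avg_ci_width, r2$avg_ci_width)
  expect_identical(r1$rr_hat, r2$rr_hat)
  expect_lte(r1$k_effective, cfg$k_reps)
  expect_equal(r1$rr_true,
               true_clinical_rates(0.9, 0.9, 0.3 * 0.3 / 0.7, 0.3)$rr_true)
})

test_that("predictive intervals cover the truth in a near-linear world", {
  # PPV = NPV = 0.99 makes the logit-scale association almost exactly
  # linear, so the 95% interval should cover the true RR at (at least) the
  # nominal rate; the intervals are in fact conservative here, matching the
  # reference account of the interval estimate.
  cfg <- scenario_config(ppv = 0.99, npv = 0.99, n_trials = 10,
                         phi_bj = 0.3, k_reps = 150, seed = 44)
  r <- run_scenario(cfg)
  cov <- mean(r$rr_lo <= r$rr_true & r$rr_true <= r$rr_up)
  expect_gte(cov, 0.95 - 3 * sqrt(0.95 * 0.05 / r$k_effective))
})

test_that("scenario grids cross parameters and derive per-cell seeds", {
  g <- run_scenario_grid(ppv = c(0.9, 0.95), npv = c(0.9, 0.95),
                         n_trials = 4, phi_bj = 0.3, k_reps = 3,
                         paired = TRUE, seed = 5,
                         mcmc = mcmc_control(1, 200, 400, 1))
  expect_equal(nrow(g), 2L)
  expect_equal(g$ppv, g$npv)
  g2 <- run_scenario_grid(ppv = 0.9, npv = 0.9, n_trials = c(4, 6),
                          phi_bj = c(0.1, 0.3), k_reps = 2, seed = 5,
                          mcmc = mcmc_control(1, 200, 400, 1))
  expect_equal(nrow(g2), 4L)
  expect_true(all(c("modified_bias", "modified_rmse", "avg_ci_width",
                    "k_effective") %in% names(g2)))
})

test_that("reference grids match their stated designs", {
  expect_equal(equal_ppv_npv_grid(), c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99))
  g <- high_npv_grid()
  expect_true(all(g$ppv + g$npv >= 1))
  expect_true(all(g$ppv <= 0.5))
  expect_setequal(unique(g$npv), c(0.9, 0.95, 0.99))
})

test_that("scenario_config rejects invalid designs", {
  expect_error(scenario_config(0.8, 0.8, 10, phi_bj = 0.8, k_reps = 1),
               "phi_bj")
  expect_error(scenario_config(1.2, 0.8, 10, k_reps = 1))
  expect_error(scenario_config(0.8, 0.8, 1, k_reps = 1))
})
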