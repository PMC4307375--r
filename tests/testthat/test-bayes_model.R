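test_that("log_likelihood equals direct binomial-pmf evaluation", {
  toy <- toy_trials()
  # identity association (logit, beta0 = 0, beta = 1): phi_X = phi_B
  phi <- c(0.5, 0.5)
  expect_equal(log_likelihood(toy, 0, 1, phi),
               sum(dbinom(toy$b_t, toy$b, phi, log = TRUE)) +
                 sum(dbinom(toy$x_t, toy$x, phi, log = TRUE)))
  # general states, all three links, against the independent oracle
  set.seed(42)
  for (lk in link_names()) {
    spec <- model_spec(link = lk)
    for (i in 1:20) {
      b0 <- rnorm(1); b1 <- rnorm(1, 1); ph <- runif(2, 0.05, 0.95)
      expect_equal(log_likelihood(toy, b0, b1, ph, spec),
                   oracle_loglik(toy, b0, b1, ph, lk))
    }
  }
})

test_that("odds link assigns -Inf outside the invertible domain", {
  toy <- toy_trials()
  spec <- model_spec(link = "odds")
  # beta0 + beta * odds(phi) <= 0 has no valid inverse
  expect_identical(log_likelihood(toy, -2, 1, c(0.5, 0.5), spec), -Inf)
  expect_true(is.finite(log_likelihood(toy, 0.5, 1, c(0.5, 0.5), spec)))
})

test_that("fit-time rejections are informative", {
  toy <- toy_trials()
  expect_error(fit_bayes(toy[1, ]), "at least two")
  zero <- trial_set("z", 10, 10, 0, 0, 1, 1)
  expect_error(fit_bayes(rbind(toy, zero)), "zero biomarker.*z")
  new_tr <- trial_set("n", 10, 10, 2, 3)
  expect_error(log_likelihood(rbind(toy, new_tr), 0, 1, c(0.5, 0.5, 0.5)),
               "without observed endpoint")
  expect_error(log_likelihood(toy, 0, 1, c(0.5, 1.5)), "inside \\(0, 1\\)")
})

test_that("same data and seed give identical draws", {
  toy <- toy_trials()
  ctl <- quick_ctl(n_chains = 1, n_burnin = 200, n_iter = 500)
  f1 <- fit_bayes(toy, toy_spec(), ctl, seed = 7, diagnostics = FALSE)
  f2 <- fit_bayes(toy, toy_spec(), ctl, seed = 7, diagnostics = FALSE)
  expect_identical(f1$beta0, f2$beta0)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$phi_b, f2$phi_b)
})

test_that("every kept draw has finite log-likelihood (posterior support)", {
  toy <- toy_trials()
  for (lk in c("logit", "odds")) {
    f <- fit_bayes(toy, model_spec(link = lk), quick_ctl(1, 500, 1000),
                   seed = 3, diagnostics = FALSE)
    idx <- seq(1, length(f$beta0), by = 20)
    ll <- vapply(idx, function(i)
      log_likelihood(toy, f$beta0[i], f$beta[i], f$phi_b[i, ],
                     model_spec(link = lk)), numeric(1))
    expect_true(all(is.finite(ll)))
  }
})

test_that("with beta degenerate at 0 the phi_B posterior is conjugate Beta", {
  toy <- toy_trials()
  spec <- model_spec(beta_bounds = c(0, 0))
  f <- fit_bayes(toy, spec, mcmc_control(2, 2000, 10000, 2), seed = 11)
  expect_true(all(f$beta == 0))
  for (i in 1:2) {
    a <- 1 + toy$b_t[i]
    b <- 1 + toy$b[i] - toy$b_t[i]
    qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
    expect_equal(unname(quantile(f$phi_b[, i], qs)), qbeta(qs, a, b),
                 tolerance = 0.02)
    expect_equal(mean(f$phi_b[, i]), a / (a + b), tolerance = 0.01)
  }
})

test_that("trial order does not change the (beta0, beta) posterior", {
  toy <- rbind(toy_trials(),
               trial_set("t3", 20, 20, 8, 4, 6, 3))
  ctl <- mcmc_control(2, 2000, 8000, 2)
  f1 <- fit_bayes(toy, toy_spec(), ctl, seed = 5)
  f2 <- fit_bayes(toy[c(3, 1, 2), ], toy_spec(), ctl, seed = 6)
  se <- function(f, p) {
    d <- if (p == "beta0") f$beta0 else f$beta
    e <- f$diagnostics$ess[f$diagnostics$parameter == p]
    sd(d) / sqrt(e)
  }
  for (p in c("beta0", "beta")) {
    d1 <- if (p == "beta0") f1$beta0 else f1$beta
    d2 <- if (p == "beta0") f2$beta0 else f2$beta
    tol <- 3 * sqrt(se(f1, p)^2 + se(f2, p)^2)
    expect_lt(abs(mean(d1) - mean(d2)), tol)
  }
})

test_that("summary and draw export expose all parameters", {
  toy <- toy_trials()
  f <- fit_bayes(toy, toy_spec(), quick_ctl(1, 200, 400), seed = 2,
                 diagnostics = FALSE)
  s <- summary(f)
  expect_setequal(s$parameter, c("beta0", "beta", "phi_b[t1]", "phi_b[t2]"))
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
  df <- as.data.frame(f)
  expect_equal(dim(df), c(400L, 4L))
})
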