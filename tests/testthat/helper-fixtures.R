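# Shared fixtures, built in code.

# 2-trial toy with moderate counts: small enough for brute-force oracles.
toy_trials <- function() {
  trial_set(trial_id = c("t1", "t2"), n_t = c(10, 10), n_c = c(10, 10),
            b_t = c(2, 3), b_c = c(2, 3), x_t = c(2, 3), x_c = c(2, 3))
}

# narrow-prior spec used when comparing MCMC against the grid oracle (both
# sides use the same spec, so the comparison is prior-independent)
toy_spec <- function(link = "logit") {
  model_spec(link = link, beta0_sd = 2, beta_bounds = c(-4, 4))
}

# short sampler schedule for fast unit tests
quick_ctl <- function(n_chains = 2, n_burnin = 1000, n_iter = 3000,
                      thin = 1) {
  mcmc_control(n_chains, n_burnin, n_iter, thin)
}

# independent full-likelihood oracle: direct dbinom evaluation
oracle_loglik <- function(trials, beta0, beta, phi_b, link) {
  g <- function(p) switch(link, odds = p / (1 - p), logit = qlogis(p),
                          cloglog = log(-log(1 - p)))
  ginv <- function(y) switch(link,
                             odds = ifelse(y > 0, y / (1 + y), NaN),
                             logit = plogis(y),
                             cloglog = 1 - exp(-exp(y)))
  phi_x <- ginv(beta0 + beta * g(phi_b))
  if (any(!is.finite(phi_x) | phi_x <= 0 | phi_x >= 1)) return(-Inf)
  sum(dbinom(trials$b_t, trials$b, phi_b, log = TRUE)) +
    sum(dbinom(trials$x_t, trials$x, phi_x, log = TRUE))
}

# brute-force grid-integration posterior for the 2-trial toy under toy_spec()
# (logit link); returns posterior means of (beta0, beta, phi_b1, phi_b2).
# Midpoint rule over a 4-D grid, vectorized over the coefficient plane.
grid_posterior_means <- function(trials, spec, n_coef = 60, n_phi = 30) {
  stopifnot(spec$link == "logit", nrow(trials) == 2L)
  b0g <- seq(-6, 6, length.out = n_coef)
  bg <- seq(spec$beta_bounds[1], spec$beta_bounds[2], length.out = n_coef)
  phig <- (seq_len(n_phi) - 0.5) / n_phi
  coef_grid <- expand.grid(beta0 = b0g, beta = bg)
  lp_coef <- dnorm(coef_grid$beta0, 0, spec$beta0_sd, log = TRUE)
  s <- c(beta0 = 0, beta = 0, phi1 = 0, phi2 = 0)
  z <- 0
  for (p1 in phig) for (p2 in phig) {
    bterm <- dbinom(trials$b_t[1], trials$b[1], p1, log = TRUE) +
      dbinom(trials$b_t[2], trials$b[2], p2, log = TRUE)
    px1 <- plogis(coef_grid$beta0 + coef_grid$beta * qlogis(p1))
    px2 <- plogis(coef_grid$beta0 + coef_grid$beta * qlogis(p2))
    ll <- bterm + dbinom(trials$x_t[1], trials$x[1], px1, log = TRUE) +
      dbinom(trials$x_t[2], trials$x[2], px2, log = TRUE)
    w <- exp(ll + lp_coef)
    z <- z + sum(w)
    s <- s + c(sum(w * coef_grid$beta0), sum(w * coef_grid$beta),
               sum(w) * p1, sum(w) * p2)
  }
  s / z
}
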