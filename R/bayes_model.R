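#' Specify the Bayesian association model
#'
#' The model links the treatment-arm responder shares of the biomarker and
#' the clinical endpoint at the trial level:
#' \deqn{B_{Ti} \sim \mathrm{Bin}(B_i, \phi_{Bi}), \quad
#'       X_{Ti} \sim \mathrm{Bin}(X_i, \phi_{Xi}), \quad
#'       g(\phi_{Xi}) = \beta_0 + \beta\, g(\phi_{Bi}),}
#' with `g` one of the three link functions (see [link_fun()]). Default
#' priors: `beta ~ Uniform(beta_bounds)` with the diffuse bounds (-100, 100);
#' each `phi_Bi ~ Beta(a_B, b_B)` with the flat `Beta(1, 1)`; and
#' `beta0 ~ Normal(0, beta0_sd^2)` with the weakly-informative unit scale
#' `beta0_sd = 1`. The intercept is the log rate ratio (logit link) of the
#' clinical endpoint in a trial whose biomarker shows no treatment effect
#' (`phi_B = 0.5`), so the unit-scale prior encodes, softly, that no
#' biomarker effect should mean no clinical effect; it also keeps the
#' posterior away from the separation ridge that arises with fully diffuse
#' intercepts when several historical trials have zero treatment-arm
#' endpoint counts (common with rare endpoints). Set `beta0_sd = 100` for a
#' fully diffuse intercept. Setting `beta_bounds = c(v, v)` fixes the slope
#' at `v` (useful for conjugacy checks: with `beta` fixed at 0 the `phi_Bi`
#' posterior is exactly `Beta(a_B + B_Ti, b_B + B_i - B_Ti)`).
#'
#' @param link link function name, default `"logit"`.
#' @param beta0_sd prior standard deviation of the intercept (> 0).
#' @param beta_bounds length-2 numeric, support of the uniform prior on the
#'   slope; equal endpoints fix the slope.
#' @param phi_b_prior length-2 positive numeric `(a_B, b_B)`, the Beta prior
#'   shared by every trial's `phi_Bi`.
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(link = "logit", beta0_sd = 1,
                       beta_bounds = c(-100, 100), phi_b_prior = c(1, 1)) {
  link <- match.arg(link, link_names())
  stopifnot(is.numeric(beta0_sd), length(beta0_sd) == 1L, beta0_sd > 0,
            is.numeric(beta_bounds), length(beta_bounds) == 2L,
            beta_bounds[1] <= beta_bounds[2],
            is.numeric(phi_b_prior), length(phi_b_prior) == 2L,
            all(phi_b_prior > 0))
  structure(list(link = link, beta0_sd = beta0_sd,
                 beta_bounds = as.numeric(beta_bounds),
                 phi_b_prior = as.numeric(phi_b_prior)),
            class = "model_spec")
}

#' MCMC sampler settings
#'
#' Defaults give 4 chains of 10,000 burn-in plus 20,000 post-burn-in
#' iterations thinned by 4, i.e. 5,000 kept draws per chain and 20,000 in
#' total. The simulation engine uses a much shorter schedule (see
#' [scenario_config()]).
#'
#' @param n_chains number of independent chains.
#' @param n_burnin burn-in iterations per chain (adaptation happens here).
#' @param n_iter post-burn-in iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return An object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_chains = 4, n_burnin = 10000, n_iter = 20000,
                         thin = 4) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_iter >= thin, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_iter = as.integer(n_iter), thin = as.integer(thin)),
            class = "mcmc_control")
}

# internal: trials usable for model fitting (positive responder totals in
# both endpoints); errors name the offenders
usable_for_fit <- function(trials) {
  trials <- validate_trials(trials)
  if (any(is.na(trials$x))) {
    stop("trial(s) without observed endpoint counts cannot enter the fit: ",
         paste(trials$trial_id[is.na(trials$x)], collapse = ", "),
         call. = FALSE)
  }
  bad <- trials$b == 0L | trials$x == 0L
  if (any(bad)) {
    stop("trial(s) with zero biomarker or endpoint responders carry no ",
         "information on the association and are rejected at fit time: ",
         paste(trials$trial_id[bad], collapse = ", "), call. = FALSE)
  }
  trials
}

#' Log-likelihood of the association model
#'
#' The sum over trials of the two binomial log-probabilities
#' `log P(B_Ti | B_i, phi_Bi) + log P(X_Ti | X_i, phi_Xi)` with
#' `phi_Xi = g^{-1}(beta0 + beta * g(phi_Bi))`. Returns `-Inf` when any
#' `phi_Xi` falls outside (0,1) or the inverse link is undefined (odds link
#' with non-positive predictor).
#'
#' @param trials a `"trial_set"` with observed endpoint counts.
#' @param beta0,beta intercept and slope of the linear predictor.
#' @param phi_b numeric vector, one `phi_Bi` in (0,1) per trial.
#' @param spec a [model_spec()] (only the link is used here).
#' @return A single numeric value (possibly `-Inf`).
#' @export
log_likelihood <- function(trials, beta0, beta, phi_b, spec = model_spec()) {
  trials <- usable_for_fit(trials)
  stopifnot(length(phi_b) == nrow(trials))
  if (any(phi_b <= 0 | phi_b >= 1)) {
    stop("phi_b must lie strictly inside (0, 1)", call. = FALSE)
  }
  eta <- beta0 + beta * link_fun(phi_b, spec$link)
  phi_x <- inverse_link(eta, spec$link)
  if (any(!is.finite(phi_x)) || any(phi_x <= 0 | phi_x >= 1)) return(-Inf)
  sum(stats::dbinom(trials$b_t, trials$b, phi_b, log = TRUE)) +
    sum(stats::dbinom(trials$x_t, trials$x, phi_x, log = TRUE))
}

#' Fit the Bayesian association model by MCMC
#'
#' Runs a Metropolis-within-Gibbs sampler (random-walk updates on the
#' intercept, a centred slope move, and logit-scale random walks on each
#' trial's `phi_Bi`; step sizes adapt during burn-in only). Results are
#' reproducible: given the same data, spec, control and seed the draws are
#' identical.
#'
#' @param trials a `"trial_set"` of at least two historical trials, each with
#'   positive biomarker and endpoint responder totals.
#' @param spec a [model_spec()].
#' @param control an [mcmc_control()].
#' @param seed integer seed, or `NULL` to continue the current RNG stream
#'   (used by the simulation engine).
#' @param diagnostics compute split-chain Rhat and effective sample sizes
#'   (default `TRUE`; the simulation engine disables this for speed).
#' @return An object of class `"bayes_fit"`: posterior draws of `beta0`,
#'   `beta` and the `phi_B` matrix (stacked chains), sampler metadata, and
#'   per-parameter split-chain scale reduction (`rhat`) and effective sample
#'   size diagnostics. A warning (not an error) is raised when any `rhat`
#'   exceeds 1.1.
#' @examples
#' fit <- fit_bayes(example_trials(), seed = 1,
#'                  control = mcmc_control(n_chains = 2, n_burnin = 500,
#'                                         n_iter = 1000, thin = 1))
#' summary(fit)
#' @export
fit_bayes <- function(trials, spec = model_spec(), control = mcmc_control(),
                      seed = NULL, diagnostics = TRUE) {
  trials <- usable_for_fit(trials)
  if (nrow(trials) < 2L) {
    stop("at least two usable trials are required to identify the ",
         "two-coefficient association model", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(trials)
  phi_init <- (trials$b_t + 0.5) / (trials$b + 1)
  beta_fixed <- spec$beta_bounds[1] == spec$beta_bounds[2]
  beta_init <- if (beta_fixed) spec$beta_bounds[1] else
    min(max(1, spec$beta_bounds[1]), spec$beta_bounds[2])

  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    chains[[ch]] <- .mcmc_chain_cpp(
      trials$b, trials$b_t, trials$x, trials$x_t,
      link_code(spec$link), spec$beta0_sd,
      spec$beta_bounds[1], spec$beta_bounds[2],
      rep(spec$phi_b_prior[1], n), rep(spec$phi_b_prior[2], n),
      control$n_burnin, control$n_iter, control$thin,
      0, beta_init, phi_init)
  }

  beta0 <- unlist(lapply(chains, `[[`, "beta0"))
  beta <- unlist(lapply(chains, `[[`, "beta"))
  phi_b <- do.call(rbind, lapply(chains, `[[`, "phi_b"))
  colnames(phi_b) <- paste0("phi_b[", trials$trial_id, "]")

  n_kept <- length(chains[[1L]]$beta0)
  diag <- NULL
  if (diagnostics) {
    draws <- cbind(beta0 = beta0, beta = beta, phi_b)
    keep_for_diag <- if (beta_fixed) setdiff(colnames(draws), "beta") else
      colnames(draws)
    diag <- data.frame(
      parameter = keep_for_diag,
      rhat = vapply(keep_for_diag, function(p)
        split_rhat(draws[, p], control$n_chains), numeric(1)),
      ess = vapply(keep_for_diag, function(p)
        effective_size(draws[, p], control$n_chains), numeric(1)),
      row.names = NULL)
    if (any(is.finite(diag$rhat) & diag$rhat > 1.1)) {
      warning("possible non-convergence: split-chain Rhat > 1.1 for ",
              paste(diag$parameter[is.finite(diag$rhat) & diag$rhat > 1.1],
                    collapse = ", "), call. = FALSE)
    }
  }

  structure(list(beta0 = beta0, beta = beta, phi_b = phi_b,
                 trials = trials, spec = spec, control = control,
                 n_chains = control$n_chains, n_kept = n_kept,
                 seed = seed, diagnostics = diag,
                 accept = c(beta0 = mean(vapply(chains, `[[`, 0,
                                                "accept_beta0")),
                            beta = mean(vapply(chains, `[[`, 0,
                                               "accept_beta")))),
            class = "bayes_fit")
}

#' Assemble posterior draws by hand
#'
#' Builds a minimal `"bayes_fit"` object from given draw vectors, mainly for
#' constructing degenerate posteriors in tests and worked examples (e.g. a
#' posterior concentrated at a single `(beta0, beta)` point to check
#' closed-form predictions).
#'
#' @param beta0,beta numeric draw vectors of equal length.
#' @param phi_b optional draw matrix (draws in rows, trials in columns).
#' @param spec a [model_spec()].
#' @return A `"bayes_fit"` object usable with [predict.bayes_fit()].
#' @export
posterior_draws <- function(beta0, beta, phi_b = NULL, spec = model_spec()) {
  stopifnot(length(beta0) == length(beta))
  structure(list(beta0 = beta0, beta = beta, phi_b = phi_b, trials = NULL,
                 spec = spec, control = NULL, n_chains = 1L,
                 n_kept = length(beta0), seed = NULL, diagnostics = NULL,
                 accept = NULL),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat("Bayesian biomarker-endpoint association model\n")
  cat(sprintf("  link: %s; trials: %s; draws: %d (%d chain%s)\n",
              x$spec$link,
              if (is.null(x$trials)) "(external draws)" else nrow(x$trials),
              length(x$beta0), x$n_chains, if (x$n_chains > 1) "s" else ""))
  cat(sprintf("  beta0: %.3f [%.3f, %.3f];  beta: %.3f [%.3f, %.3f]\n",
              stats::median(x$beta0),
              stats::quantile(x$beta0, 0.025, names = FALSE),
              stats::quantile(x$beta0, 0.975, names = FALSE),
              stats::median(x$beta),
              stats::quantile(x$beta, 0.025, names = FALSE),
              stats::quantile(x$beta, 0.975, names = FALSE)))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("  max Rhat: %.3f; min ESS: %.0f\n",
                max(x$diagnostics$rhat, na.rm = TRUE),
                min(x$diagnostics$ess, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.bayes_fit <- function(object, ...) {
  draws <- cbind(beta0 = object$beta0, beta = object$beta, object$phi_b)
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    median = apply(draws, 2, stats::median),
    q2.5 = apply(draws, 2, stats::quantile, 0.025, names = FALSE),
    q97.5 = apply(draws, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL)
  if (!is.null(object$diagnostics)) {
    out <- merge(out, object$diagnostics, by = "parameter", all.x = TRUE,
                 sort = FALSE)
  }
  out
}

#' Export posterior draws as a data frame
#'
#' @param x a `"bayes_fit"`.
#' @param row.names,optional,... standard [as.data.frame()] arguments,
#'   ignored.
#' @return A data frame with one column per parameter (`beta0`, `beta`, one
#'   `phi_b[...]` per trial), suitable for `write.csv()`.
#' @export
as.data.frame.bayes_fit <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  as.data.frame(cbind(beta0 = x$beta0, beta = x$beta, x$phi_b))
}
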