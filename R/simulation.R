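#' Simulation scenario configuration
#'
#' Describes one cell of the predictive-ability evaluation: historical trials
#' are generated at patient level with a biomarker control-arm rate of
#' `pi_bc` (default 0.3) and a per-trial biomarker share
#' `phi_Bi ~ Uniform(0, 0.76)` (the upper bound implied by `pi_bc = 0.3`);
#' each patient's clinical response copies the biomarker response with
#' probability PPV when biomarker-positive and NPV when biomarker-negative.
#' The model is fitted to the generated trial summaries and the rate ratio of
#' a new trial with observed biomarker share `phi_bj` is predicted; this is
#' repeated `k_reps` times.
#'
#' @param ppv,npv positive and negative predictive value of the biomarker for
#'   the clinical endpoint, in (0,1]; 1 means perfect concordance.
#' @param n_trials number of historical trials per repetition.
#' @param phi_bj the new trial's observed biomarker share; by convention one
#'   of 0.1, 0.3, 0.5. Must stay below the bound implied by `pi_bc` so the
#'   implied treatment-arm rate is below 1.
#' @param k_reps number of repetitions (the reference design uses 5,000; the
#'   packaged defaults are scaled down, see Details).
#' @param patients_per_trial patients completing each trial (default 400,
#'   split 1:1).
#' @param pi_bc control-arm biomarker response rate (default 0.3).
#' @param link link function for model fitting (default `"logit"`).
#' @param seed integer master seed; mandatory for reproducibility.
#' @param new_trial `"given"` (default): the new trial's `phi_Bj` enters
#'   prediction as the stated observed value; `"sampled"`: patient-level data
#'   for the new trial are generated at the implied rates and its observed
#'   counts are used instead.
#' @param mcmc an [mcmc_control()]; the default is a short single-chain
#'   schedule (1,000 burn-in, 2,000 kept draws) sized for thousands of
#'   repeated fits.
#' @param spec optional [model_spec()] overriding the default priors; its
#'   link must match `link`.
#'
#' @details With `pi_bc = 0.3`, a biomarker share `phi` implies a
#'   treatment-arm rate `pi_bt = pi_bc * phi / (1 - phi)`, which stays below
#'   1 exactly when `phi < 0.76`... more precisely `phi < 1/(1 + pi_bc)` =
#'   0.769; the generator draws from Uniform(0, 0.76).
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(ppv, npv, n_trials, phi_bj = 0.1, k_reps = 200,
                            patients_per_trial = 400, pi_bc = 0.3,
                            link = "logit", seed = 1,
                            new_trial = c("given", "sampled"),
                            mcmc = mcmc_control(n_chains = 1, n_burnin = 1000,
                                                n_iter = 2000, thin = 1),
                            spec = NULL) {
  new_trial <- match.arg(new_trial)
  link <- match.arg(link, link_names())
  if (!is.null(spec)) stopifnot(inherits(spec, "model_spec"),
                                spec$link == link)
  stopifnot(ppv > 0, ppv <= 1, npv > 0, npv <= 1,
            n_trials >= 2, k_reps >= 1,
            patients_per_trial >= 2, patients_per_trial %% 2 == 0,
            pi_bc > 0, pi_bc < 1,
            phi_bj > 0, phi_bj < 1 / (1 + pi_bc),
            is.numeric(seed), length(seed) == 1L)
  structure(list(ppv = ppv, npv = npv, n_trials = as.integer(n_trials),
                 phi_bj = phi_bj, k_reps = as.integer(k_reps),
                 patients_per_trial = as.integer(patients_per_trial),
                 pi_bc = pi_bc, link = link, seed = as.integer(seed),
                 new_trial = new_trial, mcmc = mcmc, spec = spec),
            class = "scenario_config")
}

#' Patient-level trial simulation
#'
#' Simulates one trial arm at patient level: the biomarker indicator
#' `D ~ Bernoulli(pi_b)` per patient, and the clinical indicator `C` copying
#' `D` with probability PPV when `D = 1` and probability NPV when `D = 0`
#' (the concordance construction), i.e. `P(C=1|D=1) = PPV` and
#' `P(C=1|D=0) = 1 - NPV`.
#'
#' @param n number of patients in the arm.
#' @param pi_b biomarker response rate of the arm.
#' @param ppv,npv predictive values of the biomarker.
#' @return A `data.frame` with logical-0/1 columns `d` (biomarker response)
#'   and `c` (clinical response), one row per patient.
#' @export
simulate_patients <- function(n, pi_b, ppv, npv) {
  d <- stats::rbinom(n, 1L, pi_b)
  concord <- ifelse(d == 1L, stats::rbinom(n, 1L, ppv),
                    stats::rbinom(n, 1L, npv))
  c_ <- ifelse(concord == 1L, d, 1L - d)
  data.frame(d = d, c = c_)
}

# internal: count-level equivalent of one arm (sufficient statistics of the
# patient-level process; B ~ Bin(n, pi_b), X | B ~ Bin(B, PPV) + Bin(n-B,
# 1-NPV))
sim_arm_counts <- function(n, pi_b, ppv, npv) {
  b <- stats::rbinom(length(pi_b), n, pi_b)
  x <- stats::rbinom(length(pi_b), b, ppv) +
    stats::rbinom(length(pi_b), n - b, 1 - npv)
  cbind(b = b, x = x)
}

#' Generate historical trials for a scenario
#'
#' For each trial, a biomarker share `phi_Bi` is drawn from Uniform(0, 0.76),
#' the treatment-arm biomarker rate `pi_BTi = pi_bc * phi_Bi / (1 - phi_Bi)`
#' is derived, and both arms are simulated under the concordance construction
#' (see [simulate_patients()]). Counts are generated from the exact binomial
#' distributions of the patient-level sums, which is distributionally
#' identical to summing individual Bernoulli patients.
#'
#' @param cfg a [scenario_config()].
#' @param phi_b optional vector of biomarker shares (one per trial) to use
#'   instead of the uniform draws.
#' @return A `"trial_set"` with `cfg$n_trials` rows.
#' @export
generate_historical_trials <- function(cfg, phi_b = NULL) {
  n_arm <- cfg$patients_per_trial %/% 2L
  if (is.null(phi_b)) {
    phi_b <- stats::runif(cfg$n_trials, 0, 0.76)
  }
  stopifnot(length(phi_b) == cfg$n_trials)
  pi_bt <- cfg$pi_bc * phi_b / (1 - phi_b)
  if (any(pi_bt <= 0 | pi_bt >= 1)) {
    stop("phi_B implies a treatment-arm biomarker rate outside (0, 1)",
         call. = FALSE)
  }
  trt <- sim_arm_counts(n_arm, pi_bt, cfg$ppv, cfg$npv)
  ctl <- sim_arm_counts(n_arm, rep(cfg$pi_bc, cfg$n_trials), cfg$ppv, cfg$npv)
  out <- data.frame(trial_id = seq_len(cfg$n_trials),
                    n_t = n_arm, n_c = n_arm,
                    b_t = trt[, "b"], b_c = ctl[, "b"],
                    x_t = trt[, "x"], x_c = ctl[, "x"])
  class(out) <- c("trial_set", "data.frame")
  out$b <- out$b_t + out$b_c
  out$x <- out$x_t + out$x_c
  out
}

#' True clinical response rates implied by PPV/NPV
#'
#' By the law of total probability, an arm with biomarker rate `pi_B` has
#' clinical rate `pi_X = PPV * pi_B + (1 - NPV) * (1 - pi_B)`; the true rate
#' ratio is the ratio of the two arms' clinical rates.
#'
#' @param ppv,npv predictive values, in (0,1).
#' @param pi_bt,pi_bc biomarker rates of the treatment and control arm.
#' @return A list with `pi_xt`, `pi_xc` and `rr_true`.
#' @examples
#' true_clinical_rates(0.15, 0.9999, 0.2, 0.3)
#' @export
true_clinical_rates <- function(ppv, npv, pi_bt, pi_bc) {
  stopifnot(ppv > 0, ppv <= 1, npv > 0, npv <= 1,
            pi_bt > 0, pi_bt < 1, pi_bc > 0, pi_bc < 1)
  pi_xt <- ppv * pi_bt + (1 - npv) * (1 - pi_bt)
  pi_xc <- ppv * pi_bc + (1 - npv) * (1 - pi_bc)
  if (pi_xc == 0) stop("control clinical rate is zero; RR undefined",
                       call. = FALSE)
  list(pi_xt = pi_xt, pi_xc = pi_xc, rr_true = pi_xt / pi_xc)
}

#' Predictive-ability metrics on the log rate-ratio scale
#'
#' Because the rate ratio is a positive ratio, accuracy is measured after a
#' log transformation. Over `K` repeated predictions with point estimates
#' `rr_hats` of a common truth `rr_true`:
#'
#' * `modified_bias`: mean of `log(rr_hat / rr_true)`;
#' * `modified_rmse`: root mean square of the same residuals, so
#'   `modified_rmse >= |modified_bias|` always;
#'
#' The common (base-10) logarithm is the default scale: it is the scale on
#' which the reference evaluation's reported accuracy bounds are expressed
#' (see the methods vignette); set `base = exp(1)` for natural-log
#' residuals, which simply multiplies both metrics by `log(10) ~ 2.303`.
#' * `avg_ci_width`: mean of the lower/upper 95%-CI bound ratios -- 1 for a
#'   degenerate interval, approaching 0 as intervals widen on the ratio
#'   scale, so *larger is more precise*.
#'
#' Non-positive or non-finite point estimates are excluded from the mean
#' (the count of exclusions is available via `attr(, "n_excluded")`),
#' mirroring repetitions whose prediction fails.
#'
#' @param rr_hats vector of predicted rate ratios.
#' @param rr_true the true rate ratio (positive scalar).
#' @param base base of the logarithm (default 10).
#' @return A numeric scalar (with attribute `n_excluded` for the two
#'   accuracy metrics).
#' @examples
#' modified_bias(c(1, 4), 2)    # 0 (log-symmetric errors)
#' modified_rmse(c(1, 4), 2)    # log10(2)
#' avg_ci_width(c(0.2, 0.5), c(0.8, 1.0))  # 0.375
#' @export
modified_bias <- function(rr_hats, rr_true, base = 10) {
  r <- log_residuals(rr_hats, rr_true, base)
  structure(mean(r$resid), n_excluded = r$n_excluded)
}

#' @rdname modified_bias
#' @export
modified_rmse <- function(rr_hats, rr_true, base = 10) {
  r <- log_residuals(rr_hats, rr_true, base)
  structure(sqrt(mean(r$resid^2)), n_excluded = r$n_excluded)
}

log_residuals <- function(rr_hats, rr_true, base = 10) {
  stopifnot(length(rr_true) == 1L, is.finite(rr_true), rr_true > 0,
            is.numeric(base), length(base) == 1L, base > 1)
  ok <- is.finite(rr_hats) & rr_hats > 0
  if (!any(ok)) stop("no positive finite rate-ratio estimates", call. = FALSE)
  list(resid = (log(rr_hats[ok]) - log(rr_true)) / log(base),
       n_excluded = sum(!ok))
}

#' @rdname modified_bias
#' @param lower,upper vectors of 95%-CI bounds, `0 < lower <= upper`.
#' @export
avg_ci_width <- function(lower, upper) {
  stopifnot(length(lower) == length(upper))
  if (any(!is.finite(lower) | !is.finite(upper) | lower <= 0 |
          lower > upper)) {
    stop("CI bounds must satisfy 0 < lower <= upper", call. = FALSE)
  }
  mean(lower / upper)
}

#' Run one simulation scenario
#'
#' Repeats `cfg$k_reps` times: generate `cfg$n_trials` historical trials at
#' patient level, fit the Bayesian association model, predict the rate ratio
#' of a new trial with biomarker share `cfg$phi_bj`, and record the median
#' point estimate and 95% credible interval. Repetitions whose fit or
#' prediction fails (e.g. a generated trial set with fewer than two usable
#' trials) are dropped and counted. The truth is computed from the scenario's
#' PPV/NPV and the implied treatment-arm biomarker rate via
#' [true_clinical_rates()]. Fully reproducible given `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return An object of class `"metric_report"`: `modified_bias`,
#'   `modified_rmse`, `avg_ci_width`, `k_effective`, `rr_true`, the per-
#'   repetition estimates, and the configuration.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  spec <- if (is.null(cfg$spec)) model_spec(link = cfg$link) else cfg$spec
  pi_btj <- cfg$pi_bc * cfg$phi_bj / (1 - cfg$phi_bj)
  truth <- true_clinical_rates(cfg$ppv, cfg$npv, pi_btj, cfg$pi_bc)
  n_arm <- cfg$patients_per_trial %/% 2L

  rr_hat <- rr_lo <- rr_up <- rep(NA_real_, cfg$k_reps)
  n_failed <- 0L
  for (k in seq_len(cfg$k_reps)) {
    res <- tryCatch(suppressWarnings({
      trials <- generate_historical_trials(cfg)
      trials <- trials[trials$b > 0L & trials$x > 0L, , drop = FALSE]
      fit <- fit_bayes(trials, spec = spec, control = cfg$mcmc, seed = NULL,
                       diagnostics = FALSE)
      pred <- if (cfg$new_trial == "given") {
        predict(fit, phi_bj = cfg$phi_bj)
      } else {
        counts <- sim_arm_counts(n_arm, c(pi_btj, cfg$pi_bc),
                                 cfg$ppv, cfg$npv)
        if (sum(counts[, "b"]) == 0L) stop("no biomarker responders")
        predict(fit, b_t = counts[1, "b"], b_c = counts[2, "b"])
      }
      c(pred$rr_point, pred$rr_ci)
    }), error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    rr_hat[k] <- res[1]; rr_lo[k] <- res[2]; rr_up[k] <- res[3]
  }

  ok <- !is.na(rr_hat)
  if (!any(ok)) stop("all repetitions failed", call. = FALSE)
  structure(list(
    modified_bias = as.numeric(modified_bias(rr_hat[ok], truth$rr_true)),
    modified_rmse = as.numeric(modified_rmse(rr_hat[ok], truth$rr_true)),
    avg_ci_width = avg_ci_width(rr_lo[ok], rr_up[ok]),
    k_effective = sum(ok), k_reps = cfg$k_reps,
    rr_true = truth$rr_true,
    rr_hat = rr_hat[ok], rr_lo = rr_lo[ok], rr_up = rr_up[ok],
    config = cfg), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Scenario: PPV=%.2f NPV=%.2f N=%d phi_Bj=%.2f link=%s K=%d\n",
    cfg$ppv, cfg$npv, cfg$n_trials, cfg$phi_bj, cfg$link, cfg$k_reps))
  cat(sprintf("  RR_true = %.4f; successful repetitions: %d/%d\n",
              x$rr_true, x$k_effective, x$k_reps))
  cat(sprintf(
    "  modified bias = %.4f; modified RMSE = %.4f; avg CI width = %.4f\n",
    x$modified_bias, x$modified_rmse, x$avg_ci_width))
  invisible(x)
}

#' Run a grid of simulation scenarios
#'
#' Convenience wrapper expanding vectors of scenario parameters into cells
#' and running [run_scenario()] on each. Per-cell seeds are derived from
#' `seed` (seed + cell index), keeping cells independent and the grid
#' reproducible and order-insensitive.
#'
#' @param ppv,npv,n_trials,phi_bj vectors; the grid is their full crossing
#'   unless `paired = TRUE`, in which case `ppv` and `npv` are advanced in
#'   lockstep (for equal-PPV/NPV designs).
#' @param k_reps,link,new_trial,mcmc,... passed to [scenario_config()].
#' @param seed master seed.
#' @param paired cross (`FALSE`, default) or pair `ppv`/`npv`.
#' @param verbose print one line per completed cell.
#' @return A `data.frame` with one row per cell: the scenario parameters and
#'   the three metrics plus `k_effective`.
#' @export
run_scenario_grid <- function(ppv, npv, n_trials, phi_bj, k_reps = 200,
                              link = "logit", seed = 1, paired = FALSE,
                              new_trial = "given",
                              mcmc = mcmc_control(n_chains = 1,
                                                  n_burnin = 1000,
                                                  n_iter = 2000, thin = 1),
                              verbose = FALSE, ...) {
  pv <- if (paired) data.frame(ppv = ppv, npv = npv) else
    expand.grid(ppv = ppv, npv = npv)
  cells <- merge(merge(pv, data.frame(n_trials = n_trials)),
                 data.frame(phi_bj = phi_bj))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- scenario_config(ppv = cells$ppv[i], npv = cells$npv[i],
                           n_trials = cells$n_trials[i],
                           phi_bj = cells$phi_bj[i], k_reps = k_reps,
                           link = link, seed = seed + i,
                           new_trial = new_trial, mcmc = mcmc, ...)
    rep <- run_scenario(cfg)
    out[[i]] <- data.frame(
      ppv = cfg$ppv, npv = cfg$npv, n_trials = cfg$n_trials,
      phi_bj = cfg$phi_bj, link = cfg$link,
      modified_bias = rep$modified_bias,
      modified_rmse = rep$modified_rmse,
      avg_ci_width = rep$avg_ci_width,
      k_effective = rep$k_effective)
    if (verbose) {
      message(sprintf(
        "[%d/%d] PPV=%.2f NPV=%.2f N=%d phi_Bj=%.1f: bias=%+.3f rmse=%.3f width=%.3f",
        i, nrow(cells), cfg$ppv, cfg$npv, cfg$n_trials, cfg$phi_bj,
        rep$modified_bias, rep$modified_rmse, rep$avg_ci_width))
    }
  }
  do.call(rbind, out)
}

#' Reference PPV/NPV grids
#'
#' `equal_ppv_npv_grid()` returns the equal-PPV/NPV values at or above the
#' applicability bound 0.5: 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99.
#' `high_npv_grid()` returns the high-NPV/low-PPV design: NPV in
#' \{0.9, 0.95, 0.99\} crossed with PPV in \{0.05, 0.1, 0.15, 0.2, 0.3, 0.4,
#' 0.5\}, keeping cells with `PPV + NPV >= 1`.
#'
#' @return A numeric vector (`equal_ppv_npv_grid`) or a `data.frame` with
#'   columns `ppv`, `npv` (`high_npv_grid`).
#' @export
equal_ppv_npv_grid <- function() c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99)

#' @rdname equal_ppv_npv_grid
#' @export
high_npv_grid <- function() {
  g <- expand.grid(ppv = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5),
                   npv = c(0.9, 0.95, 0.99))
  g[g$ppv + g$npv >= 1, , drop = FALSE]
}
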