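#' Rate ratio from a responder-share proportion
#'
#' Under allocation ratio `R = n_t / n_c`, the treatment:control rate ratio
#' and the treatment-arm responder share `phi` are linked by
#' `RR = phi / (R * (1 - phi))`. For 1:1 allocation this is the plain odds of
#' `phi`, and `rr_from_phi(phi_hat(a, b))` equals `a / b` exactly.
#'
#' @param phi_x proportion(s) strictly inside (0, 1).
#' @param R sample-size ratio treatment:control (default 1).
#' @return Positive rate ratio(s), strictly increasing in `phi_x`.
#' @examples
#' rr_from_phi(1/3)          # 0.5
#' rr_from_phi(phi_hat(7, 29))  # 7/29
#' @export
rr_from_phi <- function(phi_x, R = 1) {
  stopifnot(length(R) == 1L, R > 0)
  if (any(phi_x <= 0 | phi_x >= 1, na.rm = TRUE)) {
    stop("phi_x must lie strictly inside (0, 1)", call. = FALSE)
  }
  phi_x / (R * (1 - phi_x))
}

#' Predict the clinical rate ratio of a new trial
#'
#' For every posterior draw `(beta0, beta)` the new trial's endpoint share is
#' `phi_Xj = g^{-1}(beta0 + beta * g(phi_Bj))`, turned into a rate ratio
#' `RR_j = phi_Xj / (R (1 - phi_Xj))` and vaccine efficacy `VE_j = 1 - RR_j`.
#' The biomarker share `phi_Bj` is taken per draw either as
#'
#' * the plug-in estimate `B_Tj / (B_Tj + R B_Cj)` (`propagate = FALSE`,
#'   the default -- the prediction treats the observed biomarker share as
#'   given), or
#' * a fresh draw from the conjugate posterior
#'   `Beta(a_B + B_Tj, b_B + B_j - B_Tj)` given the observed counts
#'   (`propagate = TRUE`, a sensitivity analysis consistent with the
#'   model's treatment of the historical `phi_Bi`), or
#' * a value supplied directly via `phi_bj` (no counts needed; used by the
#'   simulation engine where the new trial's observed share is a design
#'   quantity).
#'
#' The point estimate is the median of the predictive `RR` draws and the 95%
#' credible interval its 2.5/97.5 percentiles (type-7 quantiles). Under the
#' odds link, draws whose linear predictor has no valid inverse are dropped
#' and counted; a warning is emitted when more than 1% are dropped.
#'
#' @param object a `"bayes_fit"`.
#' @param new_trial optional one-row `"trial_set"` carrying the new trial's
#'   biomarker counts (endpoint counts may be `NA`); alternative to
#'   `b_t`/`b_c`.
#' @param b_t,b_c biomarker responder counts of the new trial.
#' @param phi_bj directly supplied biomarker share in (0,1); overrides the
#'   counts and implies plug-in treatment.
#' @param R sample-size ratio treatment:control of the new trial.
#' @param propagate propagate Beta-binomial uncertainty in `phi_Bj`
#'   (default `FALSE`; ignored when `phi_bj` is given).
#' @param ... unused.
#' @return An object of class `"rr_prediction"`: predictive draw vectors
#'   (`phi_x_draws`, `rr_draws`), summaries `rr_point`, `rr_ci`, `ve_point`,
#'   `ve_ci`, and bookkeeping (`n_dropped`, `propagate`).
#' @examples
#' post <- posterior_draws(beta0 = rep(0, 100), beta = rep(1, 100))
#' predict(post, phi_bj = 0.25)  # phi_X = 0.25, RR = 1/3
#' @export
predict.bayes_fit <- function(object, new_trial = NULL, b_t = NULL,
                              b_c = NULL, phi_bj = NULL, R = 1,
                              propagate = FALSE, ...) {
  spec <- object$spec
  n_draws <- length(object$beta0)
  if (n_draws == 0L) stop("posterior contains no draws", call. = FALSE)

  if (!is.null(new_trial)) {
    new_trial <- validate_trials(new_trial)
    if (nrow(new_trial) != 1L) {
      stop("new_trial must have exactly one row", call. = FALSE)
    }
    b_t <- new_trial$b_t
    b_c <- new_trial$b_c
  }

  if (is.null(phi_bj)) {
    if (is.null(b_t) || is.null(b_c)) {
      stop("supply either biomarker counts (b_t, b_c / new_trial) or phi_bj",
           call. = FALSE)
    }
    if (b_t + b_c == 0) {
      stop("new trial has no biomarker responders; phi_Bj is undefined",
           call. = FALSE)
    }
    if (propagate) {
      a <- spec$phi_b_prior[1] + b_t
      b <- spec$phi_b_prior[2] + b_c   # b_B + B_j - B_Tj
      phi_b_draws <- stats::rbeta(n_draws, a, b)
    } else {
      phi_b_draws <- rep(phi_hat(b_t, b_c, R), n_draws)
    }
  } else {
    stopifnot(length(phi_bj) == 1L, phi_bj > 0, phi_bj < 1)
    propagate <- FALSE
    phi_b_draws <- rep(phi_bj, n_draws)
  }

  eta <- object$beta0 + object$beta * link_fun(phi_b_draws, spec$link)
  phi_x <- inverse_link(eta, spec$link)
  valid <- is.finite(phi_x) & phi_x > 0 & phi_x < 1
  n_dropped <- sum(!valid)
  if (n_dropped == n_draws) {
    stop("no predictive draw has a valid inverse link", call. = FALSE)
  }
  if (n_dropped > 0.01 * n_draws) {
    warning(sprintf("%d of %d predictive draws (%.1f%%) had no valid %s ",
                    n_dropped, n_draws, 100 * n_dropped / n_draws,
                    spec$link),
            "inverse and were dropped", call. = FALSE)
  }
  phi_x <- phi_x[valid]
  rr <- rr_from_phi(phi_x, R)

  rr_point <- stats::median(rr)
  rr_ci <- stats::quantile(rr, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(phi_x_draws = phi_x, rr_draws = rr,
                 rr_point = rr_point, rr_ci = rr_ci,
                 ve_point = 1 - rr_point, ve_ci = rev(1 - rr_ci),
                 n_draws = n_draws, n_dropped = n_dropped,
                 propagate = propagate, link = spec$link, R = R),
            class = "rr_prediction")
}

#' @export
print.rr_prediction <- function(x, ...) {
  cat("Predictive rate-ratio summary (new trial)\n")
  cat(sprintf("  link: %s; draws used: %d of %d; phi_Bj uncertainty: %s\n",
              x$link, x$n_draws - x$n_dropped, x$n_draws,
              if (x$propagate) "propagated (Beta-binomial)" else "plug-in"))
  cat(sprintf("  RR: %.4f  (95%% CI %.4f, %.4f)\n",
              x$rr_point, x$rr_ci[1], x$rr_ci[2]))
  cat(sprintf("  VE: %.2f%% (95%% CI %.2f%%, %.2f%%)\n",
              100 * x$ve_point, 100 * x$ve_ci[1], 100 * x$ve_ci[2]))
  invisible(x)
}
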