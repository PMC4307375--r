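#' Link functions for the association model
#'
#' The association model relates the treatment-arm share of biomarker
#' responders, `phi_B`, to that of endpoint responders, `phi_X`, on a
#' transformed scale: `g(phi_X) = beta0 + beta * g(phi_B)`. Three candidate
#' transforms `g` are supported:
#'
#' * `odds`: `p / (1 - p)`, mapping (0,1) to (0, Inf);
#' * `logit`: `log(p / (1 - p))`, the package default;
#' * `cloglog`: `log(-log(1 - p))`.
#'
#' All three are strictly increasing on (0,1). Because the odds transform
#' maps onto the positive half-line only, a linear predictor `y <= 0` has no
#' valid inverse under the odds link; `inverse_link()` then returns `NaN` and
#' the MCMC sampler assigns such states zero likelihood rather than clipping
#' them.
#'
#' @param p proportion(s) strictly inside (0, 1).
#' @param link one of `"odds"`, `"logit"`, `"cloglog"`.
#' @return `link_fun()`: the transformed value(s); `inverse_link()`: the
#'   proportion(s), `NaN` where the inverse is undefined (odds link with
#'   `y <= 0`).
#' @examples
#' link_fun(0.5, "logit")                   # 0
#' inverse_link(1, "odds")                  # 0.5
#' inverse_link(link_fun(0.1944, "cloglog"), "cloglog")
#' @export
link_fun <- function(p, link = c("logit", "odds", "cloglog")) {
  link <- match.arg(link)
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("link functions are defined for proportions strictly inside (0, 1)",
         call. = FALSE)
  }
  switch(link,
         odds    = p / (1 - p),
         logit   = stats::qlogis(p),
         cloglog = log(-log1p(-p)))
}

#' @rdname link_fun
#' @param y value(s) on the linear-predictor scale; for the odds link only
#'   `y > 0` is invertible.
#' @export
inverse_link <- function(y, link = c("logit", "odds", "cloglog")) {
  link <- match.arg(link)
  switch(link,
         odds    = ifelse(y > 0, y / (1 + y), NaN),
         logit   = stats::plogis(y),
         cloglog = -expm1(-exp(y)))
}

#' @rdname link_fun
#' @export
link_names <- function() c("logit", "odds", "cloglog")

# internal: map a link name to the code used by the C++ sampler
link_code <- function(link) {
  match(match.arg(link, link_names()), c("odds", "logit", "cloglog")) - 1L
}
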