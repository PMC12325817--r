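#' Brute-force marginal log-likelihood of the logistic random-intercept model
#'
#' Independent check of the logistic mixed-model likelihood: for each region
#' the Bernoulli likelihood is integrated over the regional intercept
#' `u ~ N(0, tau2)` by non-adaptive Gauss-Hermite quadrature with a high
#' node count (default 101), accumulated with log-sum-exp for stability, and
#' summed over regions. At `tau2 = 0` it reduces to the ordinary logistic
#' log-likelihood. Intended for small instances (tens of regions, a few
#' thousand persons) as a test oracle; it shares no code with the model
#' fitter.
#'
#' @param y 0/1 outcome vector.
#' @param eta fixed-effect linear predictor per person (logit scale,
#'   excluding the regional intercept).
#' @param region region label per person.
#' @param tau2 regional intercept variance (>= 0).
#' @param nodes number of Gauss-Hermite nodes (default 101).
#' @return The marginal log-likelihood (a single number).
#' @export
marginal_loglik_oracle <- function(y, eta, region, tau2, nodes = 101L) {
  stopifnot(length(y) == length(eta), length(y) == length(region),
            all(y %in% c(0, 1)), tau2 >= 0, nodes >= 2L)
  if (tau2 == 0)
    return(sum(stats::dbinom(y, 1L, stats::plogis(eta), log = TRUE)))
  gh <- pracma::gaussHermite(nodes)
  u <- sqrt(2 * tau2) * gh$x
  log_w <- log(gh$w) - 0.5 * log(pi)
  total <- 0
  for (r in unique(region)) {
    sel <- region == r
    yr <- y[sel]; er <- eta[sel]
    # log Bernoulli likelihood of the region at each quadrature point
    ls <- vapply(u, function(uk)
      sum(stats::dbinom(yr, 1L, stats::plogis(er + uk), log = TRUE)),
      numeric(1L))
    m <- max(log_w + ls)
    total <- total + m + log(sum(exp(log_w + ls - m)))
  }
  total
}

#' Oracle log-likelihood at a fitted model's optimum
#'
#' Convenience wrapper evaluating [marginal_loglik_oracle()] at the
#' parameters of a fitted binary `multilevel_fit`, for comparison with the
#' fitter's reported log-likelihood.
#'
#' @param fit a binary `multilevel_fit`.
#' @param nodes Gauss-Hermite node count (default 101).
#' @return The oracle marginal log-likelihood at the fitted parameters.
#' @export
oracle_loglik <- function(fit, nodes = 101L) {
  stopifnot(inherits(fit, "multilevel_fit"))
  if (fit$type != "binary")
    stop("oracle applies to binary fits", call. = FALSE)
  y <- lme4::getME(fit$model, "y")
  eta <- stats::predict(fit$model, re.form = NA)
  region <- as.character(fit$model@frame$region_id)
  marginal_loglik_oracle(y, eta, region, fit$tau2, nodes = nodes)
}
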