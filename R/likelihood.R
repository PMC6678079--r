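#' Simulated log-likelihood of the random-parameters model
#'
#' For each crash the joint rectangle probability of the observed outcome
#' pair is averaged over `R` realizations of the random coefficients
#' (\eqn{\beta + \sigma \cdot d} with quasi-random standard-normal draws
#' `d`), and the logs of the averages are summed.  With all \eqn{\sigma = 0}
#' this reduces exactly to [loglik_fixed()].  Averaged probabilities below
#' `1e-300` are floored and counted in attribute `n_clamped`.
#'
#' @param params a [bivop_params()] (sigmas may be positive).
#' @param data a [as_bivop_data()] object.
#' @param spec a [bivop_spec()].
#' @param draws a [halton_draws()] set covering every (crash, random
#'   coefficient); its dimensions must match `data` and `spec`.
#' @return The simulated log-likelihood with attribute `n_clamped`.
#' @export
simulated_loglik <- function(params, data, spec, draws) {
  if (!inherits(data, "bivop_data")) stop_spec("data must be a bivop_data")
  if (!inherits(draws, "bivop_draws"))
    stop_rpbivop("draws must be a bivop_draws set", "rpbivop_config_error")
  qt <- n_random_total(spec)
  if (draws$n_crashes != data$n || draws$n_random != qt)
    stop_rpbivop(sprintf(
      "draw set is %d x %d but data/spec require %d x %d",
      draws$n_crashes, draws$n_random, data$n, qt), "rpbivop_config_error")
  r1 <- spec$rear$random; r2 <- spec$front$random
  eta1 <- drop(data$X_rear %*% params$beta_rear)
  eta2 <- drop(data$X_front %*% params$beta_front)
  res <- .sml_loglik_cpp(
    data$y_rear, data$y_front, eta1, eta2,
    data$X_rear[, r1, drop = FALSE], data$X_front[, r2, drop = FALSE],
    params$sigma_rear[r1], params$sigma_front[r2],
    draws$draws, draws$R,
    params$cut_rear, params$cut_front, params$rho, 1e-300)
  ll <- res$loglik
  attr(ll, "n_clamped") <- as.integer(res$clamped)
  ll
}
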