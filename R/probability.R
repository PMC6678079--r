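#' Standard bivariate normal cumulative distribution function
#'
#' \eqn{\Phi_2(a, b; \rho) = P(Z_1 \le a, Z_2 \le b)} for standard normal
#' margins with correlation \eqn{\rho}.  Vectorized over `a` and `b`
#' (recycled); arguments may be infinite.  Uses Gauss-Legendre quadrature of
#' the Drezner-Wesolowsky single integral (Genz's node schedule), absolute
#' accuracy well below 1e-8 across \eqn{|\rho| < 1}.
#'
#' @param a,b numeric vectors of upper limits (may be `-Inf`/`Inf`).
#' @param rho scalar correlation, strictly inside (-1, 1).
#' @return numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0)        # 0.25
#' pbvnorm(0, 0, 0.244)    # 1/4 + asin(0.244) / (2 * pi)
#' @export
pbvnorm <- function(a, b, rho) {
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1)
    stop_domain("rho must be a single correlation in (-1, 1)")
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  .pbvnorm_cpp(a, b, rho)
}

#' Joint rectangle probability of an outcome pair
#'
#' Probability that the rear driver's outcome is `k` and the front driver's
#' is `l`, given the equations' linear indices: the four-term \eqn{\Phi_2}
#' combination over the threshold rectangle, with boundary thresholds
#' \eqn{\mu_0 = -\infty} and \eqn{\mu_K = +\infty}.
#'
#' @param k,l integer outcome levels (1-based).
#' @param eta_rear,eta_front linear indices \eqn{\beta' x} of the two
#'   equations; vectorized together with `k`, `l`.
#' @param params a [bivop_params()] (its thresholds and `rho` are used).
#' @return numeric vector of joint probabilities.
#' @export
rectangle_prob <- function(k, l, eta_rear, eta_front, params) {
  if (!inherits(params, "bivop_params"))
    stop_spec("params must be a bivop_params")
  K1 <- length(params$cut_rear) + 1L
  K2 <- length(params$cut_front) + 1L
  k <- as.integer(k); l <- as.integer(l)
  if (any(is.na(k)) || any(k < 1L) || any(k > K1))
    stop_domain(sprintf("k must be in 1..%d", K1))
  if (any(is.na(l)) || any(l < 1L) || any(l > K2))
    stop_domain(sprintf("l must be in 1..%d", K2))
  n <- max(length(k), length(l), length(eta_rear), length(eta_front))
  .rect_prob_cpp(rep_len(k, n), rep_len(l, n),
                 rep_len(as.numeric(eta_rear), n),
                 rep_len(as.numeric(eta_front), n),
                 params$cut_rear, params$cut_front, params$rho)
}

#' Joint outcome probability table for one crash
#'
#' Computes both linear indices from a [crash_record()] and fills the
#' \eqn{K \times L} table of joint outcome probabilities.  Rows marginalize
#' to the rear equation's univariate ordered probit probabilities and
#' columns to the front equation's.
#'
#' @param record a [crash_record()] (observed outcomes, if any, are ignored).
#' @param params a [bivop_params()].
#' @param spec a [bivop_spec()].
#' @return A `K x L` matrix of probabilities (rear level in rows, front level
#'   in columns) summing to 1.
#' @export
joint_outcome_probs <- function(record, params, spec) {
  if (!inherits(record, "crash_record"))
    stop_spec("record must be a crash_record")
  eta1 <- record_eta(record$x_rear, params$beta_rear, spec$rear)
  eta2 <- record_eta(record$x_front, params$beta_front, spec$front)
  K <- spec$K_rear; L <- spec$K_front
  kk <- rep(seq_len(K), times = L)
  ll <- rep(seq_len(L), each = K)
  p <- rectangle_prob(kk, ll, eta1, eta2, params)
  matrix(p, nrow = K, ncol = L,
         dimnames = list(rear = paste0("L", seq_len(K)),
                         front = paste0("L", seq_len(L))))
}

# Vectorized cell probabilities of observed outcomes under fixed parameters.
cell_probs_fixed <- function(params, data) {
  eta1 <- drop(data$X_rear %*% params$beta_rear)
  eta2 <- drop(data$X_front %*% params$beta_front)
  .rect_prob_cpp(data$y_rear, data$y_front, eta1, eta2,
                 params$cut_rear, params$cut_front, params$rho)
}

#' Fixed-parameter bivariate ordered probit log-likelihood
#'
#' Sum of log joint rectangle probabilities of the observed outcome pairs.
#' All random-coefficient standard deviations must be zero.  Cell
#' probabilities below `1e-300` are floored before taking logs; the number of
#' floored cells is returned as attribute `n_clamped` (with a warning) rather
#' than silently returning `-Inf`.
#'
#' @param params a [bivop_params()] with all `sigma` zero.
#' @param data a [as_bivop_data()] object.
#' @param spec a [bivop_spec()].
#' @return The log-likelihood (scalar) with attribute `n_clamped`.
#' @export
loglik_fixed <- function(params, data, spec) {
  if (!inherits(data, "bivop_data")) stop_spec("data must be a bivop_data")
  if (data$n < 1L) stop_usage("empty data")
  if (any(params$sigma_rear != 0) || any(params$sigma_front != 0))
    stop_usage("loglik_fixed requires all sigma = 0; use simulated_loglik")
  p <- cell_probs_fixed(params, data)
  clamped <- sum(p < 1e-300)
  if (clamped > 0)
    warning(sprintf("%d cell probabilities floored at 1e-300", clamped))
  ll <- sum(log(pmax(p, 1e-300)))
  attr(ll, "n_clamped") <- clamped
  ll
}

#' Share of a random coefficient's distribution above and below zero
#'
#' For a normally distributed coefficient with the given mean and standard
#' deviation, the population shares with a positive and a negative effect:
#' \eqn{100\,\Phi(\mu/\sigma)} above zero, the complement below.  A
#' degenerate coefficient (`sd = 0`) is wholly on the side of its mean.
#'
#' @param mean coefficient mean.
#' @param sd coefficient standard deviation, `>= 0`.
#' @return Named numeric vector `c(above, below)` in percent, summing to 100.
#' @examples
#' percent_observations(-0.3182, 0.1657)  # c(2.74, 97.26) approximately
#' @export
percent_observations <- function(mean, sd) {
  if (length(mean) != 1L || length(sd) != 1L)
    stop_usage("mean and sd must be scalars")
  if (!is.finite(sd) || sd < 0) stop_domain("sd must be nonnegative")
  above <- if (sd > 0) 100 * pnorm(mean / sd)
           else if (mean > 0) 100 else if (mean < 0) 0 else 50
  c(above = above, below = 100 - above)
}

#' z statistic and two-sided normal p-value
#'
#' @param coef estimate.
#' @param se standard error, `> 0`.
#' @return Named numeric vector `c(z, p)`.
#' @examples
#' z_and_p(0.2440, 0.0143)  # z = 17.06
#' @export
z_and_p <- function(coef, se) {
  if (!is.finite(se) || se <= 0) stop_domain("se must be positive")
  z <- coef / se
  c(z = z, p = 2 * pnorm(-abs(z)))
}
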