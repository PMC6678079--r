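# Shared builders for small test models and datasets.

# Two-dummy model, one random coefficient per equation.
toy_spec <- function(K = 4L) {
  bivop_spec(
    rear = bivop_equation(c("male", "age_le24"), random = "male"),
    front = bivop_equation("male", random = "male"),
    n_categories = c(K, K))
}

toy_truth <- function(spec = toy_spec(), rho = 0.25,
                      sigma_rear = 0.36, sigma_front = 0.53) {
  bivop_params(spec,
               beta_rear = c(-0.79, -0.38, -0.49),
               beta_front = c(-0.20, -0.44),
               sigma_rear = c(male = sigma_rear),
               sigma_front = c(male = sigma_front),
               cut_rear = c(0, 0.509, 1.3173),
               cut_front = c(0, 0.6191, 1.4814),
               rho = rho)
}

toy_scheme <- function() {
  covariate_scheme(c("male", "age_le24"), c(0.47, 0.29),
                   c("driver", "driver"))
}

toy_data <- function(n, truth = toy_truth(), spec = toy_spec(), seed = 11L) {
  cov <- generate_covariates(n, toy_scheme(), seed = seed)
  simulate_outcomes(cov, truth, spec, seed = seed + 1L)$data
}

# Independent univariate ordered-probit log-likelihood (direct pnorm sums).
uv_loglik <- function(y, eta, cuts) {
  cu <- c(-Inf, cuts, Inf)
  sum(log(pnorm(cu[y + 1L] - eta) - pnorm(cu[y] - eta)))
}

# Rectangle probability by adaptive quadrature of the conditional-normal
# representation: P(aL<X<=aU, bL<Y<=bU) =
#   int_{aL}^{aU} phi(x) [Phi((bU-rho x)/s) - Phi((bL-rho x)/s)] dx,
# s = sqrt(1-rho^2).  Independent of the implementation's angle integral.
rect_quad <- function(aL, aU, bL, bU, rho) {
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) {
    dnorm(x) * (pnorm((bU - rho * x) / s) - pnorm((bL - rho * x) / s))
  }, aL, aU, rel.tol = 1e-12, abs.tol = 1e-12)$value
}
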