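test_that("intercept-only ordered probit reproduces cumulative proportions", {
  # rear-column margins of the published joint table
  t1 <- table1_fixture()
  df <- expand_count_table(t1$counts)
  spec <- bivop_spec(rear = bivop_equation(), front = bivop_equation())
  d <- as_bivop_data(df, spec)
  uv <- fit_univariate_op(d, "rear", spec)
  cum <- cumsum(t1$rear_totals) / t1$n
  fitted_cum <- pnorm(uv$cuts - uv$beta[["(Intercept)"]])
  expect_equal(unname(fitted_cum), unname(cum[1:3]), tolerance = 1e-6)
  uvf <- fit_univariate_op(d, "front", spec)
  cumf <- cumsum(t1$front_totals) / t1$n
  expect_equal(unname(pnorm(uvf$cuts - uvf$beta[["(Intercept)"]])),
               unname(cumf[1:3]), tolerance = 1e-6)
})

test_that("univariate ordered probit recovers simulated coefficients", {
  spec <- toy_spec()
  truth <- toy_truth(spec, rho = 0, sigma_rear = 0, sigma_front = 0)
  d <- toy_data(20000, truth, spec, seed = 31)
  uv <- fit_univariate_op(d, "rear", spec)
  expect_true(all(abs(uv$beta - truth$beta_rear) < 3 * uv$se_beta))
  expect_true(all(abs(uv$cuts[-1] - truth$cut_rear[-1]) < 3 * uv$se_cuts))
})

test_that("degenerate designs are rejected with informative errors", {
  spec <- toy_spec()
  d <- toy_data(800, seed = 3)
  stopifnot(all(tabulate(d$y_rear, 4) > 0))
  # a covariate identically zero is collinear with nothing
  df <- d$df
  df$male__rear <- 0
  expect_error(fit_univariate_op(as_bivop_data(df, spec), "rear", spec),
               regexp = "male", class = "rpbivop_data_error")
  # an empty outcome category is named
  df2 <- d$df[d$df$outcome_rear != 4L, ]
  expect_error(fit_univariate_op(as_bivop_data(df2, spec), "rear", spec),
               regexp = "L4", class = "rpbivop_data_error")
})

test_that("simulated likelihood collapses to the fixed likelihood at sigma 0", {
  spec <- toy_spec()
  d <- toy_data(400, seed = 21)
  dr <- halton_draws(d$n, 2, 37, seed = 4)
  pr0 <- bivop_params(spec, beta_rear = c(-0.7, -0.3, -0.5),
                      beta_front = c(-0.25, -0.4),
                      sigma_rear = c(male = 0), sigma_front = c(male = 0),
                      cut_rear = c(0, 0.5, 1.3), cut_front = c(0, 0.6, 1.5),
                      rho = 0.3)
  prf <- bivop_params(spec, pr0$beta_rear, pr0$beta_front,
                      cut_rear = pr0$cut_rear, cut_front = pr0$cut_front,
                      rho = 0.3)
  expect_equal(as.numeric(simulated_loglik(pr0, d, spec, dr)),
               as.numeric(loglik_fixed(prf, d, spec)), tolerance = 1e-12)
})

test_that("simulated likelihood is invariant to draw order within a crash", {
  spec <- toy_spec()
  d <- toy_data(60, seed = 8)
  dr <- halton_draws(d$n, 2, 16, seed = 9)
  pr <- toy_truth(spec)
  ll <- as.numeric(simulated_loglik(pr, d, spec, dr))
  perm <- dr
  set.seed(1)
  for (i in 1:60) perm$draws[i, , ] <- perm$draws[i, , sample(16)]
  expect_equal(as.numeric(simulated_loglik(pr, d, spec, perm)), ll,
               tolerance = 1e-12)
})

test_that("simulated likelihood matches Gauss-Hermite quadrature on a toy", {
  # one random coefficient (rear male), two records
  spec <- bivop_spec(rear = bivop_equation("male", random = "male"),
                     front = bivop_equation("male"))
  df <- data.frame(outcome_rear = c(2L, 1L), outcome_front = c(3L, 1L),
                   male__rear = c(1, 1), male__front = c(0, 1))
  d <- as_bivop_data(df, spec)
  pr <- bivop_params(spec, beta_rear = c(-0.5, -0.4), beta_front = c(-0.2, -0.45),
                     sigma_rear = c(male = 0.6),
                     cut_rear = c(0, 0.5, 1.3), cut_front = c(0, 0.6, 1.5),
                     rho = 0.244)
  gh <- pracma::gaussHermite(64)
  cu1 <- c(-Inf, pr$cut_rear, Inf); cu2 <- c(-Inf, pr$cut_front, Inf)
  ll_gh <- 0
  for (i in 1:2) {
    eta2 <- drop(d$X_front[i, ] %*% pr$beta_front)
    k <- d$y_rear[i]; l <- d$y_front[i]
    cell <- function(g) {
      eta1 <- drop(d$X_rear[i, ] %*% pr$beta_rear) + g * d$df$male__rear[i]
      rectangle_prob(k, l, eta1, eta2, pr)
    }
    vals <- vapply(sqrt(2) * 0.6 * gh$x, cell, numeric(1))
    ll_gh <- ll_gh + log(sum(gh$w * vals) / sqrt(pi))
  }
  dr <- halton_draws(2, 1, 2000, seed = 12)
  ll_sml <- as.numeric(simulated_loglik(pr, d, spec, dr))
  expect_equal(ll_sml, ll_gh, tolerance = 1e-3)
})

test_that("simulated likelihood rejects mismatched draw sets", {
  spec <- toy_spec()
  d <- toy_data(50, seed = 14)
  dr <- halton_draws(49, 2, 10, seed = 1)
  expect_error(simulated_loglik(toy_truth(spec), d, spec, dr),
               class = "rpbivop_config_error")
})

test_that("standard_errors is exact for quadratic log-likelihoods", {
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  f <- function(th) -0.5 * drop(t(th) %*% A %*% th)
  se <- standard_errors(f, c(0, 0))
  expect_equal(se, sqrt(diag(solve(A))), tolerance = 1e-5)
  # doubling the curvature scales standard errors by 1/sqrt(2)
  f2 <- function(th) 2 * f(th)
  expect_equal(standard_errors(f2, c(0, 0)), se / sqrt(2), tolerance = 1e-5)
  # a maximum is required: a convex objective fails loudly
  expect_error(standard_errors(function(th) 0.5 * sum(th^2), c(0, 0)),
               regexp = "eigenvalue", class = "rpbivop_hessian_error")
})

test_that("fixed-parameter bivariate fit recovers truth and its likelihood", {
  spec <- bivop_spec(rear = bivop_equation("male"),
                     front = bivop_equation("male"))
  truth <- bivop_params(spec, beta_rear = c(-0.79, -0.38),
                        beta_front = c(-0.20, -0.44),
                        cut_rear = c(0, 0.509, 1.3173),
                        cut_front = c(0, 0.6191, 1.4814), rho = 0.3)
  cov <- generate_covariates(4000, covariate_scheme("male", 0.47, "driver"),
                             seed = 41)
  d <- simulate_outcomes(cov, truth, spec, seed = 42)$data
  fit <- fit_rpbop(d, spec, list(seed = 2))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$rho - 0.3), 3 * fit$se$rho)
  expect_true(all(abs(fit$params$beta_rear - truth$beta_rear) <
                    3 * fit$se$beta_rear))
  expect_true(all(abs(fit$params$beta_front - truth$beta_front) <
                    3 * fit$se$beta_front))
  expect_equal(fit$loglik, as.numeric(loglik_fixed(fit$params, d, spec)),
               tolerance = 1e-9)
  # rho is reported on the natural scale and inside (-1, 1)
  expect_lt(abs(fit$params$rho), 1)
})

test_that("more draws do not reduce the simulated log-likelihood", {
  spec <- toy_spec()
  d <- toy_data(200, seed = 17)
  pr <- toy_truth(spec)
  lls <- vapply(c(250L, 500L, 1000L, 2000L), function(R) {
    as.numeric(simulated_loglik(pr, d, spec, halton_draws(d$n, 2, R,
                                                          seed = 6)))
  }, numeric(1))
  # the log of a draw average is downward-biased (Jensen); the bias shrinks
  # as the draw count grows
  expect_true(all(diff(lls) > -0.1))
})

test_that("estimates concentrate as the sample grows", {
  spec <- bivop_spec(rear = bivop_equation("male"),
                     front = bivop_equation("male"))
  truth <- bivop_params(spec, beta_rear = c(-0.79, -0.38),
                        beta_front = c(-0.20, -0.44),
                        cut_rear = c(0, 0.509, 1.3173),
                        cut_front = c(0, 0.6191, 1.4814), rho = 0.25)
  scheme <- covariate_scheme("male", 0.47, "driver")
  bias_at <- function(n, reps) {
    errs <- vapply(seq_len(reps), function(r) {
      cov <- generate_covariates(n, scheme, seed = 300 + r)
      d <- simulate_outcomes(cov, truth, spec, seed = 400 + r)$data
      fit <- fit_rpbop(d, spec, list(seed = 2, se = FALSE))
      mean(abs(c(fit$params$beta_rear - truth$beta_rear,
                 fit$params$beta_front - truth$beta_front,
                 fit$params$rho - 0.25)))
    }, numeric(1))
    mean(errs)
  }
  expect_gt(bias_at(1000, 10), bias_at(10000, 10))
})
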