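intercept_only_spec <- function(K = 4L)
  bivop_spec(rear = bivop_equation(), front = bivop_equation(),
             n_categories = c(K, K))

random_params <- function(spec) {
  cuts <- function() c(0, sort(runif(2, 0.2, 2)))
  bivop_params(spec, beta_rear = rnorm(1), beta_front = rnorm(1),
               cut_rear = cuts(), cut_front = cuts(),
               rho = runif(1, -0.95, 0.95))
}

test_that("joint outcome table partitions the plane for random parameters", {
  spec <- intercept_only_spec()
  set.seed(7)
  for (i in 1:250) {
    pr <- random_params(spec)
    eta <- rnorm(2, 0, 2)
    p <- rectangle_prob(rep(1:4, 4), rep(1:4, each = 4), eta[1], eta[2], pr)
    expect_true(all(p >= 0) && all(p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("rectangle probabilities factorize at rho = 0", {
  spec <- intercept_only_spec()
  pr <- bivop_params(spec, 0.3, -0.1, cut_rear = c(0, 0.6, 1.5),
                     cut_front = c(0, 0.5, 1.3), rho = 0)
  cu1 <- c(-Inf, pr$cut_rear, Inf); cu2 <- c(-Inf, pr$cut_front, Inf)
  for (k in 1:4) for (l in 1:4) {
    want <- (pnorm(cu1[k + 1] - 0.25) - pnorm(cu1[k] - 0.25)) *
            (pnorm(cu2[l + 1] + 0.4) - pnorm(cu2[l] + 0.4))
    expect_equal(rectangle_prob(k, l, 0.25, -0.4, pr), want,
                 tolerance = 1e-14)
  }
})

test_that("rectangle probability matches Monte-Carlo latent-pair integration", {
  spec <- intercept_only_spec()
  pr <- bivop_params(spec, 0, 0, cut_rear = c(0, 0.6, 1.5),
                     cut_front = c(0, 0.5, 1.3), rho = 0.244)
  eta1 <- 0.3; eta2 <- -0.1
  n <- 1e6
  set.seed(99)
  z1 <- rnorm(n); z2 <- 0.244 * z1 + sqrt(1 - 0.244^2) * rnorm(n)
  y1 <- 1L + findInterval(eta1 + z1, pr$cut_rear)
  y2 <- 1L + findInterval(eta2 + z2, pr$cut_front)
  for (cell in list(c(2L, 3L), c(1L, 1L), c(4L, 2L))) {
    p <- rectangle_prob(cell[1], cell[2], eta1, eta2, pr)
    phat <- mean(y1 == cell[1] & y2 == cell[2])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 3 * se + 1e-12)
  }
})

test_that("rectangle probability grows when an upper threshold is raised", {
  spec <- intercept_only_spec()
  base <- c(0, 0.6, 1.5)
  p0 <- rectangle_prob(2, 2, 0.1, -0.2,
                       bivop_params(spec, 0, 0, cut_rear = base,
                                    cut_front = base, rho = 0.3))
  p1 <- rectangle_prob(2, 2, 0.1, -0.2,
                       bivop_params(spec, 0, 0, cut_rear = c(0, 0.9, 1.5),
                                    cut_front = base, rho = 0.3))
  expect_gt(p1, p0)
})

test_that("rectangle_prob validates outcome levels", {
  pr <- random_params(intercept_only_spec())
  expect_error(rectangle_prob(0, 1, 0, 0, pr), class = "rpbivop_domain_error")
  expect_error(rectangle_prob(1, 5, 0, 0, pr), class = "rpbivop_domain_error")
})

test_that("joint_outcome_probs marginalizes to the univariate ordered probits", {
  spec <- toy_spec()
  pr <- toy_truth(spec)
  rec <- crash_record(x_rear = c(male = 1, age_le24 = 0),
                      x_front = c(male = 0))
  tab <- joint_outcome_probs(rec, pr, spec)
  expect_equal(sum(tab), 1, tolerance = 1e-10)
  eta1 <- pr$beta_rear[["(Intercept)"]] + pr$beta_rear[["male"]]
  eta2 <- pr$beta_front[["(Intercept)"]]
  cu1 <- c(-Inf, pr$cut_rear, Inf); cu2 <- c(-Inf, pr$cut_front, Inf)
  expect_equal(unname(rowSums(tab)),
               pnorm(cu1[-1] - eta1) - pnorm(cu1[-5] - eta1),
               tolerance = 1e-9)
  expect_equal(unname(colSums(tab)),
               pnorm(cu2[-1] - eta2) - pnorm(cu2[-5] - eta2),
               tolerance = 1e-9)
})

test_that("zero covariates, unit-spaced thresholds and rho 0 give cell 0.25", {
  spec <- bivop_spec(rear = bivop_equation(constant = FALSE),
                     front = bivop_equation(constant = FALSE))
  pr <- bivop_params(spec, numeric(0), numeric(0),
                     cut_rear = c(0, 1, 2), cut_front = c(0, 1, 2), rho = 0)
  tab <- joint_outcome_probs(crash_record(), pr, spec)
  expect_equal(tab[1, 1], 0.25, tolerance = 1e-14)
})

test_that("loglik_fixed decomposes, matches single records and quadrature", {
  spec <- toy_spec()
  d <- toy_data(500, toy_truth(spec, sigma_rear = 0, sigma_front = 0), spec)
  pr0 <- bivop_params(spec, beta_rear = c(-0.7, -0.3, -0.5),
                      beta_front = c(-0.25, -0.4),
                      cut_rear = c(0, 0.5, 1.3), cut_front = c(0, 0.6, 1.5),
                      rho = 0)
  # independence decomposition
  ll <- loglik_fixed(pr0, d, spec)
  ll1 <- uv_loglik(d$y_rear, drop(d$X_rear %*% pr0$beta_rear), pr0$cut_rear)
  ll2 <- uv_loglik(d$y_front, drop(d$X_front %*% pr0$beta_front),
                   pr0$cut_front)
  expect_equal(as.numeric(ll), ll1 + ll2, tolerance = 1e-8)
  # single record = log rectangle probability
  d1 <- as_bivop_data(d$df[3, ], spec)
  pr <- bivop_params(spec, pr0$beta_rear, pr0$beta_front,
                     cut_rear = pr0$cut_rear, cut_front = pr0$cut_front,
                     rho = 0.244)
  eta1 <- drop(d1$X_rear %*% pr$beta_rear)
  eta2 <- drop(d1$X_front %*% pr$beta_front)
  expect_equal(as.numeric(loglik_fixed(pr, d1, spec)),
               log(rectangle_prob(d1$y_rear, d1$y_front, eta1, eta2, pr)),
               tolerance = 1e-12)
  expect_error(loglik_fixed(pr, structure(list(n = 0L),
                                          class = "bivop_data"), spec),
               class = "rpbivop_usage_error")
})

test_that("loglik_fixed agrees with a 2-D quadrature oracle on a toy set", {
  spec <- toy_spec()
  df <- data.frame(outcome_rear = c(1L, 2L, 4L), outcome_front = c(2L, 1L, 3L),
                   male__rear = c(1, 0, 1), male__front = c(0, 1, 1),
                   age_le24__rear = c(0, 1, 0))
  d <- as_bivop_data(df, spec)
  pr <- bivop_params(spec, beta_rear = c(-0.6, -0.35, -0.5),
                     beta_front = c(-0.2, -0.45),
                     cut_rear = c(0, 0.51, 1.32), cut_front = c(0, 0.62, 1.48),
                     rho = 0.244)
  eta1 <- drop(d$X_rear %*% pr$beta_rear)
  eta2 <- drop(d$X_front %*% pr$beta_front)
  cu1 <- c(-Inf, pr$cut_rear, Inf); cu2 <- c(-Inf, pr$cut_front, Inf)
  want <- sum(vapply(1:3, function(i) {
    k <- d$y_rear[i]; l <- d$y_front[i]
    log(rect_quad(cu1[k] - eta1[i], cu1[k + 1] - eta1[i],
                  cu2[l] - eta2[i], cu2[l + 1] - eta2[i], pr$rho))
  }, numeric(1)))
  expect_equal(as.numeric(loglik_fixed(pr, d, spec)), want,
               tolerance = 1e-7)
})

test_that("vanishing cell probabilities are floored and counted", {
  spec <- bivop_spec(rear = bivop_equation(), front = bivop_equation())
  df <- data.frame(outcome_rear = 4L, outcome_front = 4L)
  d <- as_bivop_data(df, spec)
  pr <- bivop_params(spec, beta_rear = -40, beta_front = -40,
                     cut_rear = c(0, 1, 2), cut_front = c(0, 1, 2), rho = 0.2)
  expect_warning(ll <- loglik_fixed(pr, d, spec), "floored")
  expect_true(is.finite(as.numeric(ll)))
  expect_identical(attr(ll, "n_clamped"), 1L)
})

test_that("percent_observations reproduces published splits and edge cases", {
  # printed random-coefficient rows: mean, sd -> percent above/below zero
  expect_equal(unname(percent_observations(-0.3182, 0.1657)),
               c(2.74, 97.26), tolerance = 0.005)
  expect_equal(unname(percent_observations(0, 1)), c(50, 50))
  expect_equal(unname(percent_observations(0.5, 0)), c(100, 0))
  expect_equal(unname(percent_observations(-0.5, 0)), c(0, 100))
  expect_equal(unname(percent_observations(0, 0)), c(50, 50))
  pc <- percent_observations(1.234, 5.678)
  expect_identical(unname(sum(pc)), 100)
  expect_error(percent_observations(1, -0.1), class = "rpbivop_domain_error")
})

test_that("z_and_p reproduces published z values", {
  expect_equal(z_and_p(0.2440, 0.0143)[["z"]], 17.06, tolerance = 0.005)
  expect_equal(z_and_p(-0.3182, 0.0269)[["z"]], -11.8, tolerance = 0.05)
  expect_equal(unname(z_and_p(0, 1)), c(0, 1))
  zp <- z_and_p(1.96, 1)
  expect_equal(zp[["p"]], 0.05, tolerance = 1e-3)
  expect_error(z_and_p(1, 0), class = "rpbivop_domain_error")
})
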