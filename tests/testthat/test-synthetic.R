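test_that("covariate generation honours prevalences, scopes and groups", {
  sch <- covariate_scheme(
    name = c("a", "b", "g1", "g2"),
    prevalence = c(0.3, 0, 0.2, 0.5),
    scope = c("driver", "shared", "shared", "shared"),
    group = c(NA, NA, "g", "g"))
  cov <- generate_covariates(50000, sch, seed = 77)
  # binomial concentration
  expect_lt(abs(mean(cov$a__rear) - 0.3), 0.01)
  expect_lt(abs(mean(cov$a__front) - 0.3), 0.01)
  # zero prevalence stays identically zero; shared column is single
  expect_true(all(cov$b == 0))
  expect_false("b__rear" %in% names(cov))
  # mutually exclusive group never double-fires and hits its rates
  expect_true(all(cov$g1 + cov$g2 <= 1))
  expect_lt(abs(mean(cov$g1) - 0.2), 0.01)
  expect_lt(abs(mean(cov$g2) - 0.5), 0.01)
  # rear and front copies differ for driver scope (independent draws)
  expect_gt(mean(cov$a__rear != cov$a__front), 0.2)
})

test_that("group prevalences summing beyond one are rejected", {
  expect_error(covariate_scheme(c("x", "y"), c(0.7, 0.6), c("shared", "shared"),
                                c("g", "g")),
               class = "rpbivop_schema_error")
})

test_that("simulation is deterministic and reproducible from its manifest", {
  spec <- toy_spec()
  cov <- generate_covariates(500, toy_scheme(), seed = 5)
  s1 <- simulate_outcomes(cov, toy_truth(spec), spec, seed = 9)
  s2 <- simulate_outcomes(cov, toy_truth(spec), spec, seed = 9)
  expect_identical(s1$data$df, s2$data$df)
  m <- s1$manifest
  expect_identical(m$n, 500L)
  s3 <- simulate_outcomes(cov, m$params, m$spec, seed = m$seed)
  expect_identical(s3$data$df, s1$data$df)
})

test_that("sigma = 0 reproduces the fixed-parameter generator exactly", {
  spec <- toy_spec()
  cov <- generate_covariates(400, toy_scheme(), seed = 15)
  with_rand <- simulate_outcomes(cov, toy_truth(spec, sigma_rear = 0,
                                                sigma_front = 0),
                                 spec, seed = 3)
  fixed_spec <- bivop_spec(rear = bivop_equation(c("male", "age_le24")),
                           front = bivop_equation("male"))
  tr <- toy_truth(spec)
  fixed_truth <- bivop_params(fixed_spec, tr$beta_rear, tr$beta_front,
                              cut_rear = tr$cut_rear, cut_front = tr$cut_front,
                              rho = tr$rho)
  no_rand <- simulate_outcomes(cov, fixed_truth, fixed_spec, seed = 3)
  expect_identical(with_rand$data$df$outcome_rear,
                   no_rand$data$df$outcome_rear)
  expect_identical(with_rand$data$df$outcome_front,
                   no_rand$data$df$outcome_front)
})

test_that("outcome concordance increases with the error correlation", {
  spec <- bivop_spec(rear = bivop_equation(), front = bivop_equation())
  mk <- function(rho) bivop_params(spec, 0, 0, cut_rear = c(0, 0.5, 1.3),
                                   cut_front = c(0, 0.6, 1.5), rho = rho)
  cov <- data.frame(row.names = seq_len(20000))
  hi <- simulate_outcomes(cov, mk(0.99), spec, seed = 2)$data
  lo <- simulate_outcomes(cov, mk(0), spec, seed = 2)$data
  tau_hi <- cor(hi$y_rear, hi$y_front, method = "kendall")
  tau_lo <- cor(lo$y_rear, lo$y_front, method = "kendall")
  expect_gt(tau_hi, tau_lo + 0.2)
})

test_that("empirical cell frequencies match the model probabilities", {
  spec <- toy_spec()
  truth <- toy_truth(spec, sigma_rear = 0, sigma_front = 0)
  cov <- generate_covariates(100000, toy_scheme(), seed = 55)
  d <- simulate_outcomes(cov, truth, spec, seed = 56)$data
  # stratify on one covariate profile and compare with the joint table
  sel <- d$df$male__rear == 1 & d$df$male__front == 0 &
    d$df$age_le24__rear == 0
  rec <- crash_record(x_rear = c(male = 1, age_le24 = 0),
                      x_front = c(male = 0))
  tab <- joint_outcome_probs(rec, truth, spec)
  n <- sum(sel)
  for (k in 1:4) for (l in 1:4) {
    phat <- mean(d$y_rear[sel] == k & d$y_front[sel] == l)
    se <- sqrt(tab[k, l] * (1 - tab[k, l]) / n)
    expect_lt(abs(phat - tab[k, l]), 3 * se + 1e-9)
  }
})

test_that("published-table fixtures carry the printed counts and estimates", {
  t1 <- table1_fixture()
  expect_identical(t1$n, 15159)
  expect_identical(unname(t1$rear_totals), c(12217, 1372, 1128, 442))
  expect_identical(unname(t1$front_totals), c(10093, 2531, 1873, 662))
  expect_identical(t1$counts[1, 1], 8723)
  tr <- table3_truth_fixture()
  expect_identical(tr$rho, 0.2440)
  expect_identical(tr$beta_front[["age_le24"]], -0.3182)
  expect_identical(tr$sigma_front[["age_le24"]], 0.1657)
  expect_identical(tr$sigma_rear[["(Intercept)"]], 0.2067)
  expect_true(all(diff(tr$cut_rear) > 0) && tr$cut_rear[1] == 0)
  expect_true(all(diff(tr$cut_front) > 0) && tr$cut_front[1] == 0)
})

test_that("fixture-driven simulation reproduces the sample's qualitative shape", {
  sim <- simulate_crashes(30000, seed = 19)
  d <- sim$data
  # monotone severity margins for both drivers
  expect_true(all(diff(tabulate(d$y_rear, 4)) < 0))
  expect_true(all(diff(tabulate(d$y_front, 4)) < 0))
  # struck (front) drivers are injured more often than striking (rear) ones
  inj_front <- mean(d$y_front > 1)
  inj_rear <- mean(d$y_rear > 1)
  expect_gt(inj_front, inj_rear)
})
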