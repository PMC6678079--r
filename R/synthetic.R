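#' Covariate scheme for synthetic crash data
#'
#' Describes the dummy covariates of a GES-like paired crash table: each
#' covariate has a prevalence (Bernoulli rate), a scope — `"shared"`
#' (identical for the two drivers of a crash: light, region, season, hour,
#' roadway) or `"driver"` (drawn independently per driver: age, sex, airbag,
#' belt, model year) — and optionally a group label marking mutually
#' exclusive dummies (e.g. model-year bins) drawn from one categorical.
#'
#' @param name character vector of covariate names.
#' @param prevalence numeric vector in `[0, 1]`.
#' @param scope character vector, `"shared"` or `"driver"`.
#' @param group optional character vector; `NA` for ungrouped dummies.
#'   Grouped dummies must share a scope and their prevalences sum to <= 1
#'   (the remainder is the implicit reference level).
#' @return A data frame of class `covariate_scheme`.
#' @export
covariate_scheme <- function(name, prevalence, scope, group = NA) {
  df <- data.frame(name = as.character(name),
                   prevalence = as.numeric(prevalence),
                   scope = as.character(scope),
                   group = as.character(group),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop_schema("duplicate covariate names")
  if (any(!df$scope %in% c("shared", "driver")))
    stop_schema("scope must be 'shared' or 'driver'")
  if (any(df$prevalence < 0 | df$prevalence > 1))
    stop_schema("prevalences must lie in [0, 1]")
  for (g in unique(stats::na.omit(df$group))) {
    rows <- df[!is.na(df$group) & df$group == g, ]
    if (sum(rows$prevalence) > 1 + 1e-12)
      stop_schema(sprintf("group '%s' prevalences sum to %.3f > 1",
                          g, sum(rows$prevalence)))
    if (length(unique(rows$scope)) != 1L)
      stop_schema(sprintf("group '%s' mixes scopes", g))
  }
  class(df) <- c("covariate_scheme", "data.frame")
  df
}

#' Generate dummy covariates for synthetic crashes
#'
#' Draws each ungrouped dummy as Bernoulli(prevalence) and each mutually
#' exclusive group from a single categorical (remaining mass on the implicit
#' reference).  Shared covariates produce one column used by both drivers;
#' driver-scoped covariates produce independent `<name>__rear` and
#' `<name>__front` columns.  Deterministic given the seed.
#'
#' @param n number of crashes.
#' @param scheme a [covariate_scheme()].
#' @param seed integer seed.
#' @return A data frame with `n` rows.
#' @export
generate_covariates <- function(n, scheme, seed = 1L) {
  if (!inherits(scheme, "covariate_scheme"))
    stop_schema("scheme must be a covariate_scheme")
  n <- as.integer(n)
  if (n < 1L) stop_usage("n must be >= 1")
  with_seed(seed, {
    out <- list()
    draw_block <- function(rows) {
      # returns an n x nrow(rows) 0/1 matrix honouring group exclusivity
      m <- matrix(0L, n, nrow(rows))
      colnames(m) <- rows$name
      done <- logical(nrow(rows))
      for (g in unique(rows$group)) {
        sel <- if (is.na(g)) logical(nrow(rows)) else
          (!is.na(rows$group) & rows$group == g)
        if (!any(sel)) next
        pr <- rows$prevalence[sel]
        lev <- sample.int(length(pr) + 1L, n, replace = TRUE,
                          prob = c(pr, 1 - sum(pr)))
        for (j in seq_along(which(sel)))
          m[, which(sel)[j]] <- as.integer(lev == j)
        done[sel] <- TRUE
      }
      for (j in which(!done))
        m[, j] <- rbinom(n, 1L, rows$prevalence[j])
      m
    }
    # draw in scheme order, one block per group (a group is consumed when
    # its first member is reached); driver scope draws twice (rear, front)
    handled <- logical(nrow(scheme))
    i <- 1L
    while (i <= nrow(scheme)) {
      if (handled[i]) { i <- i + 1L; next }
      g <- scheme$group[i]
      sel <- if (is.na(g)) i else which(!is.na(scheme$group) &
                                          scheme$group == g)
      rows <- scheme[sel, ]
      if (rows$scope[1L] == "shared") {
        m <- draw_block(rows)
        for (j in seq_len(ncol(m))) out[[colnames(m)[j]]] <- m[, j]
      } else {
        mr <- draw_block(rows)
        mf <- draw_block(rows)
        for (j in seq_len(ncol(mr))) {
          out[[paste0(colnames(mr)[j], "__rear")]] <- mr[, j]
          out[[paste0(colnames(mf)[j], "__front")]] <- mf[, j]
        }
      }
      handled[sel] <- TRUE
      i <- i + 1L
    }
    as.data.frame(out, check.names = FALSE)
  })
}

#' Simulate paired ordinal outcomes from the latent bivariate probit
#'
#' Per crash: draws the two latent errors from a standard bivariate normal
#' with correlation `rho` (Cholesky form), adds normal random-coefficient
#' deviations (`sd > 0` only) to the linear indices, and censors each latent
#' propensity into its ordinal level via the thresholds (half-open intervals
#' \eqn{\mu_{c-1} < y^* \le \mu_c}).  Errors are drawn before coefficient
#' deviations, so setting every `sigma` to zero reproduces the
#' fixed-parameter generator exactly under the same seed.
#'
#' @param covariates data frame from [generate_covariates()] (or any table
#'   resolvable against `spec`).
#' @param params a [bivop_params()]; the ground truth.
#' @param spec a [bivop_spec()].
#' @param seed integer seed.
#' @return A list: `data` (a [as_bivop_data()] object whose `df` contains the
#'   outcome and covariate columns) and `manifest` (class `truth_manifest`:
#'   `params`, `spec`, `n`, `seed` — sufficient to regenerate the outcomes).
#' @export
simulate_outcomes <- function(covariates, params, spec, seed = 1L) {
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  if (n < 1L) stop_usage("no crashes to simulate")
  Xr <- design_matrix(covariates, spec$rear, "rear")
  Xf <- design_matrix(covariates, spec$front, "front")
  eta1 <- drop(Xr %*% params$beta_rear)
  eta2 <- drop(Xf %*% params$beta_front)
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    e1 <- z1
    e2 <- params$rho * z1 + sqrt(1 - params$rho^2) * z2
    add_gamma <- function(eta, X, sigma) {
      for (q in which(sigma > 0))
        eta <- eta + X[, q] * rnorm(n, 0, sigma[[q]])
      eta
    }
    eta1 <- add_gamma(eta1, Xr, params$sigma_rear)
    eta2 <- add_gamma(eta2, Xf, params$sigma_front)
    censor <- function(ystar, cuts)
      1L + rowSums(outer(ystar, cuts, `>`))
    y1 <- censor(eta1 + e1, params$cut_rear)
    y2 <- censor(eta2 + e2, params$cut_front)
    df <- cbind(data.frame(crash_id = seq_len(n),
                           outcome_rear = y1, outcome_front = y2),
                covariates)
    list(data = as_bivop_data(df, spec),
         manifest = structure(list(params = params, spec = spec,
                                   n = n, seed = as.integer(seed)),
                              class = "truth_manifest"))
  })
}

#' One-call synthetic GES-like dataset
#'
#' Generates covariates from a scheme and paired outcomes from a ground
#' truth, defaulting to the published-model fixtures
#' ([table3_truth_fixture()], [table3_spec()], [table2_scheme()]).
#'
#' @param n number of crashes.
#' @param seed integer seed (covariates use `seed`, outcomes `seed + 1`).
#' @param params,spec,scheme ground truth, model specification and covariate
#'   scheme.
#' @return As [simulate_outcomes()].
#' @export
simulate_crashes <- function(n, seed = 1L,
                             params = table3_truth_fixture(),
                             spec = table3_spec(),
                             scheme = table2_scheme()) {
  cov <- generate_covariates(n, scheme, seed = seed)
  simulate_outcomes(cov, params, spec, seed = seed + 1L)
}
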