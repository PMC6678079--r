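# ---- unconstrained reparameterization -------------------------------------
#
# The optimizer works on an unconstrained vector theta:
#   beta (both equations)  - unchanged
#   log sigma              - one entry per random coefficient
#   threshold deltas       - free interior thresholds as cumulative exp()
#                            increments above the identification cutoff
#   atanh(rho)
# so that sigma > 0, thresholds strictly increase and |rho| < 1 by
# construction.  Reported estimates and standard errors are mapped back to
# the natural scale (delta method).

cuts_to_delta <- function(cuts, constant) {
  if (constant) log(diff(c(0, cuts[-1L])))
  else c(cuts[[1L]], log(diff(cuts)))
}

delta_to_cuts <- function(delta, constant) {
  delta <- pmin(delta, 50)  # guard exp overflow during wild line searches
  if (constant) c(0, cumsum(pmax(exp(delta), 1e-12)))
  else {
    if (length(delta) == 1L) delta
    else c(delta[[1L]],
           delta[[1L]] + cumsum(pmax(exp(delta[-1L]), 1e-12)))
  }
}

theta_layout <- function(spec) {
  p1 <- n_coef(spec$rear); p2 <- n_coef(spec$front)
  q1 <- sum(spec$rear$random); q2 <- sum(spec$front$random)
  d1 <- spec$K_rear - 1L - as.integer(spec$rear$constant)
  d2 <- spec$K_front - 1L - as.integer(spec$front$constant)
  sizes <- c(beta1 = p1, beta2 = p2, ls1 = q1, ls2 = q2,
             d1 = d1, d2 = d2, z = 1L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  idx <- Map(function(s, e) if (e >= s) seq.int(s, e) else integer(0),
             starts, ends)
  names(idx) <- names(sizes)
  c(idx, list(p = sum(sizes)))
}

pack_theta <- function(params, spec) {
  lay <- theta_layout(spec)
  th <- numeric(lay$p)
  th[lay$beta1] <- params$beta_rear
  th[lay$beta2] <- params$beta_front
  th[lay$ls1] <- log(pmax(params$sigma_rear[spec$rear$random], 1e-8))
  th[lay$ls2] <- log(pmax(params$sigma_front[spec$front$random], 1e-8))
  th[lay$d1] <- cuts_to_delta(params$cut_rear, spec$rear$constant)
  th[lay$d2] <- cuts_to_delta(params$cut_front, spec$front$constant)
  th[lay$z] <- atanh(params$rho)
  th
}

unpack_theta <- function(theta, spec) {
  lay <- theta_layout(spec)
  s1 <- stats::setNames(numeric(n_coef(spec$rear)), spec$rear$coef_names)
  s2 <- stats::setNames(numeric(n_coef(spec$front)), spec$front$coef_names)
  s1[spec$rear$random] <- exp(pmin(theta[lay$ls1], 50))
  s2[spec$front$random] <- exp(pmin(theta[lay$ls2], 50))
  bivop_params(spec,
               beta_rear = theta[lay$beta1], beta_front = theta[lay$beta2],
               sigma_rear = s1, sigma_front = s2,
               cut_rear = delta_to_cuts(theta[lay$d1], spec$rear$constant),
               cut_front = delta_to_cuts(theta[lay$d2], spec$front$constant),
               rho = tanh(theta[lay$z]))
}

# Jacobian d(natural)/d(theta) for the delta method; natural order equals
# theta order with (sigma, thresholds, rho) mapped to their own scales.
theta_jacobian <- function(theta, spec) {
  lay <- theta_layout(spec)
  J <- diag(lay$p)
  for (ix in list(lay$ls1, lay$ls2))
    for (i in ix) J[i, i] <- exp(pmin(theta[i], 50))
  cut_block <- function(ix, constant) {
    m <- length(ix)
    if (m == 0L) return()
    e <- exp(pmin(theta[ix], 50))
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (!constant && b == 1L) J[ix[a], ix[b]] <<- 1
      else J[ix[a], ix[b]] <<- if (b <= a && (constant || b > 1L)) e[b] else 0
    }
  }
  cut_block(lay$d1, spec$rear$constant)
  cut_block(lay$d2, spec$front$constant)
  J[lay$z, lay$z] <- 1 - tanh(theta[lay$z])^2
  J
}

# ---- numerical derivatives -------------------------------------------------

num_grad <- function(f, x, step = 1e-5 * pmax(1, abs(x))) {
  p <- length(x)
  g <- numeric(p)
  for (i in seq_len(p)) {
    e <- numeric(p); e[i] <- step[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * step[i])
  }
  g
}

# One-sided gradient (p + 1 evaluations): used inside line searches where
# speed matters more than the last digits; convergence is always certified
# with the central version.
num_grad_fwd <- function(f, x, step = 1e-6 * pmax(1, abs(x))) {
  p <- length(x)
  f0 <- f(x)
  g <- numeric(p)
  for (i in seq_len(p)) {
    e <- numeric(p); e[i] <- step[i]
    g[i] <- (f(x + e) - f0) / step[i]
  }
  g
}

num_hessian <- function(f, x, step = 1e-4 * pmax(1, abs(x))) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- f(x)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    e <- numeric(p); e[i] <- step[i]
    fp[i] <- f(x + e); fm[i] <- f(x - e)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / step[i]^2
  }
  if (p > 1L) {
    for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
      ei <- numeric(p); ei[i] <- step[i]
      ej <- numeric(p); ej[j] <- step[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * step[i] * step[j])
    }
  }
  (H + t(H)) / 2
}

#' Standard errors from the inverse numerical Hessian of a log-likelihood
#'
#' Central-difference Hessian (step `1e-4 * max(1, |theta|)` per coordinate)
#' of the log-likelihood at an interior optimum; standard errors are the
#' square roots of the diagonal of the inverse of the negative Hessian.
#' Fails with a diagnostic naming the offending eigenvalue when the negative
#' Hessian is not positive definite.
#'
#' @param loglik_fn function of the parameter vector returning the
#'   log-likelihood (to be maximized).
#' @param theta_hat parameter vector at the optimum.
#' @return numeric vector of standard errors.
#' @export
standard_errors <- function(loglik_fn, theta_hat) {
  V <- fisher_vcov(loglik_fn, theta_hat)
  sqrt(diag(V))
}

fisher_vcov <- function(loglik_fn, theta_hat) {
  H <- num_hessian(loglik_fn, theta_hat)
  A <- -(H + t(H)) / 2
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_rpbivop(sprintf(
      "negative Hessian is not positive definite (offending eigenvalue %g)",
      min(ev)), "rpbivop_hessian_error")
  solve(A)
}

# ---- univariate ordered probit (starting values) ---------------------------

#' Univariate ordered probit fit for one equation
#'
#' Maximum-likelihood ordered probit for the rear or front driver's equation
#' alone, in this package's parameterization (estimated constant, first
#' interior threshold fixed at 0).  Fitted through [MASS::polr()]
#' (`method = "probit"`) and remapped; intercept-only models use the exact
#' closed form (thresholds are normal quantiles of the empirical cumulative
#' proportions).  Used as starting values for [fit_rpbop()].
#'
#' @param data a [as_bivop_data()] object.
#' @param equation `"rear"` or `"front"`.
#' @param spec a [bivop_spec()].
#' @return An object of class `bivop_uvfit`: `beta`, `cuts`, `se_beta`,
#'   `se_cuts`, `vcov` (over `c(beta, free cuts)`), `loglik`, `n`, `K`.
#' @export
fit_univariate_op <- function(data, equation = c("rear", "front"), spec) {
  equation <- match.arg(equation)
  if (!inherits(data, "bivop_data")) stop_spec("data must be a bivop_data")
  eq <- spec[[equation]]
  K <- if (equation == "rear") spec$K_rear else spec$K_front
  y <- if (equation == "rear") data$y_rear else data$y_front
  X <- if (equation == "rear") data$X_rear else data$X_front
  Xc <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  tab <- tabulate(y, K)
  if (any(tab == 0L))
    stop_data(sprintf("no observations in outcome category L%d (%s equation)",
                      which(tab == 0L)[[1L]], equation))
  if (ncol(X) > 0L) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
      stop_data(paste0("non-identified coefficient(s) in ", equation,
                       " equation: ", paste(bad, collapse = ", ")))
    }
  }
  n <- length(y)
  if (ncol(Xc) == 0L) {
    # saturated intercept-only model: Phi(zeta_c) = cumulative proportions
    cum <- cumsum(tab) / n
    zeta <- qnorm(cum[seq_len(K - 1L)])
    if (eq$constant) {
      beta <- stats::setNames(-zeta[[1L]], "(Intercept)")
      cuts <- c(0, zeta[-1L] - zeta[[1L]])
    } else {
      beta <- stats::setNames(numeric(0), character(0))
      cuts <- zeta
    }
    ll <- sum(tab * log(diff(c(0, cum))))
    Vn <- NULL
  } else {
    dfp <- data.frame(.y = factor(y, levels = seq_len(K), ordered = TRUE),
                      Xc, check.names = FALSE)
    fml <- stats::as.formula(paste(
      ".y ~", paste(sprintf("`%s`", colnames(Xc)), collapse = " + ")))
    pf <- MASS::polr(fml, data = dfp, method = "probit", Hess = TRUE)
    cf <- pf$coefficients
    zeta <- pf$zeta
    Vp <- stats::vcov(pf)  # order: coefficients, then zetas
    p <- length(cf)
    if (eq$constant) {
      beta <- stats::setNames(c(-zeta[[1L]], cf), eq$coef_names)
      cuts <- c(0, zeta[-1L] - zeta[[1L]])
      # linear map (beta0, beta, free cuts) <- (cf, zeta)
      Tm <- matrix(0, p + K - 1L, p + K - 1L)
      Tm[1L, p + 1L] <- -1
      if (p > 0L) Tm[seq.int(2L, p + 1L), seq_len(p)] <- diag(p)
      if (K > 2L) for (m in seq_len(K - 2L)) {
        Tm[p + 1L + m, p + 1L + m] <- 1
        Tm[p + 1L + m, p + 1L] <- -1
      }
    } else {
      beta <- stats::setNames(cf, eq$coef_names)
      cuts <- zeta
      Tm <- diag(p + K - 1L)
    }
    Vn <- Tm %*% Vp %*% t(Tm)
    ll <- as.numeric(stats::logLik(pf))
  }
  se_all <- if (is.null(Vn)) rep(NA_real_, length(beta) + K - 1L -
                                   as.integer(eq$constant))
            else sqrt(pmax(diag(Vn), 0))
  nb <- length(beta)
  structure(list(equation = equation, K = K, n = n,
                 beta = beta, cuts = cuts,
                 se_beta = if (nb) se_all[seq_len(nb)] else numeric(0),
                 se_cuts = if (length(se_all) > nb)
                             se_all[seq.int(nb + 1L, length(se_all))]
                           else numeric(0),
                 vcov = Vn, loglik = ll),
            class = "bivop_uvfit")
}

# ---- main fitter -----------------------------------------------------------

default_fit_config <- function(config = list()) {
  cfg <- list(R = 200L, seed = 1L, max_iter = 500L, tol = 1e-5,
              se = TRUE, warm_start_draws = 50L, sd_alpha = 0.05,
              sigma_floor = 1e-3, verbose = FALSE)
  cfg[names(config)] <- config
  cfg
}

#' Fit a random-parameters bivariate ordered probit model
#'
#' Maximizes the simulated log-likelihood over the coefficient means, the
#' random-coefficient standard deviations (log scale), the free thresholds
#' (cumulative-exponential scale) and the error correlation (atanh scale)
#' with BFGS and finite-difference gradients.  Starting values come from two
#' separately fitted univariate ordered probits ([fit_univariate_op()]);
#' sigmas start at 0.1 and rho at 0.  With random coefficients present the
#' optimizer first converges on a coarse Halton draw set
#' (`warm_start_draws`), then polishes on the full `R` draws; reported
#' results always use the full set.  Standard errors come from the inverse
#' numerical Hessian of the total simulated log-likelihood, delta-mapped to
#' the natural scale.  Convergence requires the max-norm of the
#' per-crash-mean gradient to fall below `tol`; non-convergence is reported
#' in the returned object, never thrown.
#'
#' @param data a [as_bivop_data()] object.
#' @param spec a [bivop_spec()].
#' @param config list of settings: `R` (draws, default 200), `seed` (draw
#'   scramble seed, default 1), `max_iter` (500), `tol` (1e-5), `se`
#'   (compute standard errors, default TRUE), `warm_start_draws` (coarse
#'   first-stage draw count, 0 to disable, default 50), `sd_alpha`
#'   (significance level for [prune_random_params()], default 0.05).
#' @return An object of class `bivop_fit`.
#' @export
fit_rpbop <- function(data, spec, config = list()) {
  cfg <- default_fit_config(config)
  if (!inherits(data, "bivop_data")) stop_spec("data must be a bivop_data")
  n <- data$n
  qt <- n_random_total(spec)
  uv_rear <- fit_univariate_op(data, "rear", spec)
  uv_front <- fit_univariate_op(data, "front", spec)
  s1 <- stats::setNames(ifelse(spec$rear$random, 0.1, 0),
                        spec$rear$coef_names)
  s2 <- stats::setNames(ifelse(spec$front$random, 0.1, 0),
                        spec$front$coef_names)
  start <- bivop_params(spec, uv_rear$beta, uv_front$beta, s1, s2,
                        uv_rear$cuts, uv_front$cuts, rho = 0)
  theta <- pack_theta(start, spec)

  make_negll <- function(draws) {
    force(draws)
    function(th) {
      p <- unpack_theta(th, spec)
      ll <- if (qt > 0L) as.numeric(simulated_loglik(p, data, spec, draws))
            else sum(log(pmax(cell_probs_fixed(p, data), 1e-300)))
      -ll / n
    }
  }
  draws_full <- if (qt > 0L) halton_draws(n, qt, cfg$R, cfg$seed) else
    structure(list(draws = array(numeric(0), c(n, 0L, 1L)), R = 1L,
                   n_crashes = n, n_random = 0L, primes = integer(0),
                   seed = cfg$seed, drop = 50L), class = "bivop_draws")
  negll <- make_negll(draws_full)

  n_iter <- 0L; n_eval <- 0L
  msg <- character(0)
  ok <- TRUE
  run <- function(th0, fn, maxit, central = FALSE) {
    gr <- if (central) function(x) num_grad(fn, x)
          else function(x) num_grad_fwd(fn, x)
    # stop when the expected further gain (~ grad^2 / 2 curvature) is below
    # the gradient tolerance being certified
    reltol <- min(1e-9, max(1e-13, 0.5 * cfg$tol^2))
    opt <- nlminb(th0, fn, gradient = gr,
                  control = list(iter.max = maxit, eval.max = 10L * maxit,
                                 rel.tol = reltol))
    n_iter <<- n_iter + opt$iterations
    n_eval <<- n_eval + unname(opt$evaluations[[1L]])
    opt
  }
  res <- tryCatch({
    if (qt > 0L && cfg$warm_start_draws > 0L &&
        cfg$warm_start_draws < cfg$R) {
      draws_w <- halton_draws(n, qt, cfg$warm_start_draws, cfg$seed)
      theta <- run(theta, make_negll(draws_w), cfg$max_iter)$par
    }
    g <- NULL
    for (attempt in 1:3) {
      opt <- run(theta, negll, cfg$max_iter, central = attempt > 1L)
      theta <- opt$par
      g <- num_grad(negll, theta)
      if (max(abs(g)) < cfg$tol) break
    }
    list(theta = theta, grad = g)
  }, error = function(e) {
    ok <<- FALSE
    msg <<- c(msg, conditionMessage(e))
    NULL
  })
  if (!ok) {
    return(structure(list(params = start, spec = spec, config = cfg,
                          converged = FALSE, message = msg, n = n,
                          n_iter = n_iter, loglik = NA_real_),
                     class = "bivop_fit"))
  }
  theta <- res$theta
  gmax <- max(abs(res$grad))
  converged <- gmax < cfg$tol
  if (!converged)
    msg <- c(msg, sprintf("gradient max-norm %.3g above tol %.3g",
                          gmax, cfg$tol))
  params <- unpack_theta(theta, spec)
  ll <- -n * negll(theta)
  clamp_count <- if (qt > 0L)
    attr(simulated_loglik(params, data, spec, draws_full), "n_clamped")
  else sum(cell_probs_fixed(params, data) < 1e-300)

  se_nat <- rep(NA_real_, length(theta))
  vcov_trans <- NULL
  if (isTRUE(cfg$se)) {
    # A random standard deviation driven to (numerical) zero sits on the
    # boundary of the parameter space: its log-sigma coordinate has no
    # curvature and no meaningful standard error.  Such coordinates are
    # profiled out of the Hessian; the remaining block is inverted as usual.
    lay <- theta_layout(spec)
    ls_idx <- c(lay$ls1, lay$ls2)
    collapsed <- ls_idx[exp(pmin(theta[ls_idx], 50)) < cfg$sigma_floor]
    keep <- setdiff(seq_along(theta), collapsed)
    tot_ll <- function(th) -n * negll(th)
    se_res <- tryCatch({
      H <- num_hessian(tot_ll, theta)
      A <- -(H + t(H)) / 2
      Ak <- A[keep, keep, drop = FALSE]
      ev <- eigen(Ak, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0)
        stop_rpbivop(sprintf(
          "negative Hessian is not positive definite (offending eigenvalue %g)",
          min(ev)), "rpbivop_hessian_error")
      V <- matrix(NA_real_, length(theta), length(theta))
      V[keep, keep] <- solve(Ak)
      J <- theta_jacobian(theta, spec)
      se <- rep(NA_real_, length(theta))
      for (i in keep)
        se[[i]] <- sqrt(max(drop(J[i, keep, drop = FALSE] %*%
                                   V[keep, keep] %*% J[i, keep]), 0))
      list(se = se, V = V)
    }, error = function(e) {
      msg <<- c(msg, paste("standard errors unavailable:",
                           conditionMessage(e)))
      NULL
    })
    if (!is.null(se_res)) { se_nat <- se_res$se; vcov_trans <- se_res$V }
  }
  build_fit(params, spec, cfg, se_nat, theta, vcov_trans, ll, clamp_count,
            converged, msg, n, n_iter, n_eval,
            list(rear = uv_rear, front = uv_front))
}

# Assemble the reporting structure from the packed natural-scale SEs.
build_fit <- function(params, spec, cfg, se_nat, theta, vcov_trans, ll,
                      clamp_count, converged, msg, n, n_iter, n_eval,
                      uv_start) {
  lay <- theta_layout(spec)
  nmr <- spec$rear$coef_names; nmf <- spec$front$coef_names
  se <- list(
    beta_rear = stats::setNames(se_nat[lay$beta1], nmr),
    beta_front = stats::setNames(se_nat[lay$beta2], nmf),
    sigma_rear = stats::setNames(rep(NA_real_, length(nmr)), nmr),
    sigma_front = stats::setNames(rep(NA_real_, length(nmf)), nmf),
    cut_rear = c(if (spec$rear$constant) NA_real_, se_nat[lay$d1]),
    cut_front = c(if (spec$front$constant) NA_real_, se_nat[lay$d2]),
    rho = se_nat[lay$z])
  se$sigma_rear[spec$rear$random] <- se_nat[lay$ls1]
  se$sigma_front[spec$front$random] <- se_nat[lay$ls2]
  zp <- function(est, s) {
    z <- est / s
    list(z = z, p = 2 * pnorm(-abs(z)))
  }
  z <- p <- list()
  for (blk in c("beta_rear", "beta_front", "sigma_rear", "sigma_front",
                "cut_rear", "cut_front", "rho")) {
    est <- switch(blk, rho = params$rho, params[[blk]])
    r <- zp(est, se[[blk]])
    z[[blk]] <- r$z; p[[blk]] <- r$p
  }
  pct <- function(eqn, beta, sigma, random) {
    out <- matrix(NA_real_, length(beta), 2,
                  dimnames = list(names(beta), c("above", "below")))
    for (i in which(random))
      out[i, ] <- percent_observations(beta[[i]], sigma[[i]])
    out
  }
  percent_obs <- list(
    rear = pct("rear", params$beta_rear, params$sigma_rear,
               spec$rear$random),
    front = pct("front", params$beta_front, params$sigma_front,
                spec$front$random))
  structure(list(params = params, se = se, z = z, p = p,
                 percent_obs = percent_obs, loglik = as.numeric(ll),
                 converged = converged, n = n, n_iter = n_iter,
                 n_eval = n_eval, clamp_count = clamp_count,
                 draw_config = list(R = cfg$R, seed = cfg$seed,
                                    warm_start_draws = cfg$warm_start_draws),
                 spec = spec, config = cfg, theta = theta,
                 vcov_trans = vcov_trans, message = msg,
                 uv_start = uv_start),
            class = "bivop_fit")
}

#' @export
print.bivop_fit <- function(x, ...) {
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}

#' Fix random coefficients whose standard deviations are not significant
#'
#' Iteratively refits the model, at each step converting the random
#' coefficient with the least significant standard deviation (two-sided
#' p-value above `sd_alpha`, default 5%) into a fixed coefficient, until all
#' remaining standard deviations are significant.  A fit whose standard
#' deviations are all already significant is returned unchanged.
#'
#' @param fit a converged [fit_rpbop()] result.
#' @param data the data the fit used.
#' @param spec model specification (defaults to the fit's).
#' @param config fit configuration (defaults to the fit's).
#' @return The final refitted `bivop_fit`.
#' @export
prune_random_params <- function(fit, data, spec = fit$spec,
                                config = fit$config) {
  if (!inherits(fit, "bivop_fit")) stop_spec("fit must be a bivop_fit")
  if (!isTRUE(fit$converged))
    stop_usage("prune_random_params requires a converged fit")
  alpha <- default_fit_config(config)$sd_alpha
  current <- fit
  repeat {
    sp <- current$spec
    rows <- list()
    floor_ <- default_fit_config(config)$sigma_floor
    for (eqn in c("rear", "front")) {
      rnd <- which(sp[[eqn]]$random)
      for (i in rnd) {
        pv <- current$p[[paste0("sigma_", eqn)]][[i]]
        sg <- current$params[[paste0("sigma_", eqn)]][[i]]
        # an SD collapsed to the zero boundary is non-significant by fiat
        if (is.na(pv) && sg < floor_) pv <- 1
        rows[[length(rows) + 1L]] <-
          list(eq = eqn, name = sp[[eqn]]$coef_names[[i]], p = pv)
      }
    }
    if (!length(rows)) break
    pv <- vapply(rows, `[[`, numeric(1), "p")
    if (anyNA(pv))
      stop_usage("fit lacks standard errors for sigma; rerun with se = TRUE")
    if (all(pv <= alpha)) break
    worst <- rows[[which.max(pv)]]
    sp <- set_fixed(sp, worst$eq, worst$name)
    current <- fit_rpbop(data, sp, config)
    if (!isTRUE(current$converged)) break
  }
  current
}
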