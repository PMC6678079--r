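#' Define one equation of a bivariate ordered probit model
#'
#' Each driver's injury-severity equation is an ordered probit with a latent
#' propensity \eqn{y^* = \beta' x + \varepsilon} censored into `n_categories`
#' ordered levels by interior thresholds.  Coefficients named in `random`
#' receive an independent normal random deviation (mean 0, estimated standard
#' deviation) that varies across crashes.
#'
#' @param covariates character vector of covariate (dummy) names entering the
#'   linear index, in order.  May be empty for an intercept-only equation.
#' @param random character vector naming the coefficients treated as random:
#'   a subset of `covariates`, optionally including `"(Intercept)"`.
#' @param constant logical; include an estimated constant?  When `TRUE` the
#'   first interior threshold is fixed at 0 for identification.
#' @return A list describing the equation (used inside [bivop_spec()]).
#' @export
bivop_equation <- function(covariates = character(), random = character(),
                           constant = TRUE) {
  covariates <- as.character(covariates)
  if (anyDuplicated(covariates))
    stop_spec("duplicate covariate names within an equation")
  nm <- c(if (constant) "(Intercept)", covariates)
  random <- as.character(random)
  bad <- setdiff(random, nm)
  if (length(bad))
    stop_spec(paste0("random coefficients not in equation: ",
                     paste(bad, collapse = ", ")))
  list(covariates = covariates,
       constant = isTRUE(constant),
       coef_names = nm,
       random = stats::setNames(nm %in% random, nm))
}

#' Model specification for a bivariate ordered probit
#'
#' Binds the two equations (rear striking driver is equation 1, front struck
#' driver is equation 2) and the outcome category counts.
#'
#' @param rear,front equation definitions from [bivop_equation()].
#' @param n_categories integer vector of length 2: number of ordered outcome
#'   levels for the rear and front equation (default `c(4, 4)`, the regrouped
#'   KABCO scale L1--L4).
#' @return An object of class `bivop_spec`.
#' @examples
#' spec <- bivop_spec(
#'   rear  = bivop_equation(c("male", "age_le24"), random = "male"),
#'   front = bivop_equation("male", random = "male"))
#' @export
bivop_spec <- function(rear = bivop_equation(), front = bivop_equation(),
                       n_categories = c(4L, 4L)) {
  n_categories <- as.integer(n_categories)
  if (length(n_categories) != 2L || any(n_categories < 2L))
    stop_spec("n_categories must be two integers >= 2")
  out <- list(rear = rear, front = front,
              K_rear = n_categories[[1L]], K_front = n_categories[[2L]])
  class(out) <- "bivop_spec"
  out
}

eq_of <- function(spec, equation = c("rear", "front")) {
  equation <- match.arg(equation)
  spec[[equation]]
}

n_coef <- function(eq) length(eq$coef_names)

n_random_total <- function(spec) {
  sum(spec$rear$random) + sum(spec$front$random)
}

#' @export
print.bivop_spec <- function(x, ...) {
  fmt <- function(eq, K) {
    rnd <- names(eq$random)[eq$random]
    cat("  ", K, " categories; coefficients: ",
        paste(eq$coef_names, collapse = ", "), "\n", sep = "")
    if (length(rnd))
      cat("   random: ", paste(rnd, collapse = ", "), "\n", sep = "")
  }
  cat("Bivariate ordered probit specification\n")
  cat(" rear equation (j = 1):\n");  fmt(x$rear, x$K_rear)
  cat(" front equation (j = 2):\n"); fmt(x$front, x$K_front)
  invisible(x)
}

# Flip a named coefficient's random flag off; used by the pruning rule.
set_fixed <- function(spec, equation, coef_name) {
  eq <- spec[[equation]]
  if (!coef_name %in% names(eq$random))
    stop_spec(paste0("unknown coefficient '", coef_name, "'"))
  eq$random[[coef_name]] <- FALSE
  spec[[equation]] <- eq
  spec
}

#' Parameter set for a bivariate ordered probit model
#'
#' Collects the coefficient means, random-coefficient standard deviations,
#' interior thresholds and the cross-equation error correlation.  With an
#' estimated constant the first interior threshold is fixed at 0; with four
#' outcome levels each equation then carries two free thresholds (reported as
#' \eqn{\mu_1, \mu_2}).
#'
#' @param spec a [bivop_spec()].
#' @param beta_rear,beta_front numeric coefficient means, ordered as
#'   `(constant, covariates...)` per the spec.
#' @param sigma_rear,sigma_front standard deviations of the random
#'   coefficients.  Either a full-length vector (zero where fixed) or a named
#'   vector over the random coefficients only; defaults to all-fixed.
#' @param cut_rear,cut_front interior thresholds, length `K - 1`, strictly
#'   increasing; first entry must be 0 when the equation has a constant.
#' @param rho latent error correlation, in (-1, 1).
#' @return An object of class `bivop_params`.
#' @export
bivop_params <- function(spec, beta_rear, beta_front,
                         sigma_rear = NULL, sigma_front = NULL,
                         cut_rear, cut_front, rho = 0) {
  if (!inherits(spec, "bivop_spec")) stop_spec("spec must be a bivop_spec")
  norm_beta <- function(beta, eq, which) {
    beta <- as.numeric(beta)
    if (length(beta) != n_coef(eq))
      stop_spec(sprintf("beta_%s has length %d, expected %d",
                        which, length(beta), n_coef(eq)))
    stats::setNames(beta, eq$coef_names)
  }
  norm_sigma <- function(sigma, eq, which) {
    full <- stats::setNames(numeric(n_coef(eq)), eq$coef_names)
    if (is.null(sigma)) return(full)
    if (!is.null(names(sigma)) && length(sigma) != n_coef(eq)) {
      bad <- setdiff(names(sigma), eq$coef_names)
      if (length(bad))
        stop_spec(paste0("sigma_", which, " names unknown: ",
                         paste(bad, collapse = ", ")))
      full[names(sigma)] <- as.numeric(sigma)
    } else {
      if (length(sigma) != n_coef(eq))
        stop_spec(sprintf("sigma_%s has length %d, expected %d",
                          which, length(sigma), n_coef(eq)))
      full[] <- as.numeric(sigma)
    }
    if (any(full < 0)) stop_spec("sigma entries must be nonnegative")
    if (any(full[!eq$random] != 0))
      stop_spec(paste0("sigma_", which,
                       " nonzero for a coefficient not flagged random"))
    full
  }
  norm_cuts <- function(cuts, eq, K, which) {
    cuts <- as.numeric(cuts)
    if (length(cuts) != K - 1L)
      stop_spec(sprintf("cut_%s has length %d, expected %d",
                        which, length(cuts), K - 1L))
    if (any(diff(cuts) <= 0))
      stop_spec(paste0("cut_", which, " must be strictly increasing"))
    if (eq$constant && cuts[[1L]] != 0)
      stop_spec(paste0("cut_", which,
                       "[1] must be 0 when a constant is estimated"))
    cuts
  }
  rho <- as.numeric(rho)
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1)
    stop_domain("rho must be a single value in (-1, 1)")
  out <- list(beta_rear = norm_beta(beta_rear, spec$rear, "rear"),
              beta_front = norm_beta(beta_front, spec$front, "front"),
              sigma_rear = norm_sigma(sigma_rear, spec$rear, "rear"),
              sigma_front = norm_sigma(sigma_front, spec$front, "front"),
              cut_rear = norm_cuts(cut_rear, spec$rear, spec$K_rear, "rear"),
              cut_front = norm_cuts(cut_front, spec$front, spec$K_front,
                                    "front"),
              rho = rho)
  class(out) <- "bivop_params"
  out
}

#' @export
print.bivop_params <- function(x, digits = 4, ...) {
  cat("Bivariate ordered probit parameters\n")
  pr <- function(lbl, b, s) {
    cat(" ", lbl, ":\n", sep = "")
    tab <- cbind(mean = round(b, digits), sd = round(s, digits))
    print(tab)
  }
  pr("rear (j = 1)", x$beta_rear, x$sigma_rear)
  cat("  thresholds:", paste(round(x$cut_rear, digits), collapse = ", "), "\n")
  pr("front (j = 2)", x$beta_front, x$sigma_front)
  cat("  thresholds:", paste(round(x$cut_front, digits), collapse = ", "), "\n")
  cat("  rho:", round(x$rho, digits), "\n")
  invisible(x)
}
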