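# Column-resolution convention for paired crash tables: a covariate `v` of
# the rear equation is looked up as `v__rear`, falling back to `v` (shared
# within the crash); the front equation uses `v__front` then `v`.
resolve_column <- function(df, name, equation) {
  suffixed <- paste0(name, "__", equation)
  if (suffixed %in% names(df)) return(suffixed)
  if (name %in% names(df)) return(name)
  NA_character_
}

# Build one equation's design matrix (constant column first when present).
design_matrix <- function(df, eq, equation) {
  n <- nrow(df)
  cols <- lapply(eq$covariates, function(v) {
    cn <- resolve_column(df, v, equation)
    if (is.na(cn))
      stop_schema(paste0("missing covariate column for '", v, "' (",
                         equation, " equation): expected '", v, "__",
                         equation, "' or '", v, "'"))
    as.numeric(df[[cn]])
  })
  X <- do.call(cbind, c(list(if (eq$constant) rep(1, n)), cols))
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0L)
  colnames(X) <- eq$coef_names
  X
}

#' Assemble paired-crash data for model fitting
#'
#' Validates a one-row-per-crash data frame against a model specification and
#' precomputes the per-equation design matrices.  Outcome columns are
#' `outcome_rear` and `outcome_front`, coded as integer levels `1..K`
#' (L1 = no injury through L4 = incapacitating or fatal for the default
#' four-level regrouped KABCO scale).  Covariates follow the
#' `<name>__rear` / `<name>__front` / `<name>` (crash-shared) convention and
#' must be 0/1 dummies.
#'
#' @param df a data frame, one row per crash.
#' @param spec a [bivop_spec()].
#' @return An object of class `bivop_data`: list with elements `y_rear`,
#'   `y_front`, `X_rear`, `X_front`, `df`, `n`.
#' @export
as_bivop_data <- function(df, spec) {
  if (!inherits(spec, "bivop_spec")) stop_spec("spec must be a bivop_spec")
  df <- as.data.frame(df)
  for (oc in c("outcome_rear", "outcome_front"))
    if (!oc %in% names(df))
      stop_schema(paste0("missing outcome column '", oc, "'"))
  if (nrow(df) < 1L) stop_usage("no crash records")
  yr <- as.integer(df$outcome_rear)
  yf <- as.integer(df$outcome_front)
  if (anyNA(yr) || any(yr < 1L) || any(yr > spec$K_rear))
    stop_schema(sprintf("outcome_rear must be integers in 1..%d", spec$K_rear))
  if (anyNA(yf) || any(yf < 1L) || any(yf > spec$K_front))
    stop_schema(sprintf("outcome_front must be integers in 1..%d",
                        spec$K_front))
  Xr <- design_matrix(df, spec$rear, "rear")
  Xf <- design_matrix(df, spec$front, "front")
  for (X in list(Xr, Xf)) {
    covs <- X[, colnames(X) != "(Intercept)", drop = FALSE]
    if (length(covs) && !all(covs %in% c(0, 1)))
      stop_schema("covariate columns must be 0/1 dummies")
  }
  out <- list(y_rear = yr, y_front = yf, X_rear = Xr, X_front = Xf,
              df = df, n = nrow(df))
  class(out) <- "bivop_data"
  out
}

#' @export
print.bivop_data <- function(x, ...) {
  cat("Paired crash data:", x$n, "crashes\n")
  cat(" rear outcome counts: ",
      paste(tabulate(x$y_rear), collapse = " "), "\n")
  cat(" front outcome counts:",
      paste(tabulate(x$y_front), collapse = " "), "\n")
  invisible(x)
}

#' A single crash record
#'
#' Convenience constructor for one crash: the two drivers' covariate vectors
#' (named as in the model specification, without the constant) and optional
#' observed outcome levels.
#'
#' @param x_rear,x_front named numeric vectors of covariate values.
#' @param outcome_rear,outcome_front optional integer outcome levels.
#' @return An object of class `crash_record`.
#' @export
crash_record <- function(x_rear = numeric(), x_front = numeric(),
                         outcome_rear = NA_integer_,
                         outcome_front = NA_integer_) {
  structure(list(x_rear = x_rear, x_front = x_front,
                 outcome_rear = as.integer(outcome_rear),
                 outcome_front = as.integer(outcome_front)),
            class = "crash_record")
}

# Linear index of one equation for a single record.
record_eta <- function(rec_x, beta, eq) {
  eta <- if (eq$constant) beta[["(Intercept)"]] else 0
  for (v in eq$covariates) {
    if (!v %in% names(rec_x))
      stop_spec(paste0("record lacks covariate '", v, "'"))
    eta <- eta + beta[[v]] * rec_x[[v]]
  }
  eta
}
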