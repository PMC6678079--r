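#' Regroup KABCO injury codes into four ordered levels
#'
#' Police-reported KABCO codes collapse to the four-level scale used for
#' modelling: O (no injury) to L1, C (possible injury) to L2, B
#' (non-incapacitating evident injury) to L3, and A (incapacitating) or K
#' (fatal) to L4.  Codes outside `{O, C, B, A, K}` — e.g. "injured, severity
#' unknown" — are rejected with the offending row identifiers, mirroring
#' their exclusion from analysis datasets.
#'
#' @param code character vector of KABCO codes.
#' @param row_id optional identifiers used in error messages (defaults to
#'   positions).
#' @return An ordered factor with levels `L1 < L2 < L3 < L4`.
#' @examples
#' regroup_kabco(c("O", "C", "B", "A", "K"))
#' @export
regroup_kabco <- function(code, row_id = seq_along(code)) {
  map <- c(O = "L1", C = "L2", B = "L3", A = "L4", K = "L4")
  code <- as.character(code)
  bad <- !code %in% names(map)
  if (any(bad))
    stop_schema(paste0("unknown KABCO code(s) at row(s) ",
                       paste(head(row_id[bad], 10L), collapse = ", "),
                       ": ", paste(unique(code[bad]), collapse = ", ")))
  factor(unname(map[code]), levels = c("L1", "L2", "L3", "L4"),
         ordered = TRUE)
}

#' Dummy-code a categorical column against a reference level
#'
#' Emits one 0/1 column per non-reference level (e.g. spring/summer/autumn
#' dummies with winter as the implicit all-zero reference).  When `levels`
#' is supplied (e.g. the levels seen at fit time), values outside it are an
#' error.
#'
#' @param column vector of categorical values.
#' @param reference_level the level coded as all-zeros.
#' @param levels optional complete level set; defaults to the observed one.
#' @return A data frame of 0/1 integer columns named by level.
#' @export
dummy_encode <- function(column, reference_level, levels = NULL) {
  column <- as.character(column)
  obs <- unique(column)
  if (is.null(levels)) {
    levels <- sort(obs)
    if (length(levels) < 2L)
      stop_schema("need at least 2 observed levels to dummy-code")
  } else {
    unseen <- setdiff(obs, levels)
    if (length(unseen))
      stop_schema(paste0("level(s) not in the declared set: ",
                         paste(unseen, collapse = ", ")))
  }
  if (!reference_level %in% levels)
    stop_schema(paste0("reference level '", reference_level,
                       "' not among levels"))
  keep <- setdiff(levels, reference_level)
  out <- lapply(keep, function(l) as.integer(column == l))
  names(out) <- keep
  as.data.frame(out, check.names = FALSE)
}

#' Read a paired-crash CSV
#'
#' Reads a one-row-per-crash table (see [write_crash_csv()] for the column
#' convention), validates it against the model specification, drops
#' malformed rows — outcome outside `1..K`, non-0/1 dummy, missing value —
#' with a per-reason message, and returns the kept records in file order.
#'
#' @param path CSV path.
#' @param spec a [bivop_spec()].
#' @param quiet suppress the kept/dropped message.
#' @return A [as_bivop_data()] object with attribute `drop_log` (data frame
#'   of reasons and counts).
#' @export
read_crash_csv <- function(path, spec, quiet = FALSE) {
  if (!file.exists(path)) stop_schema(paste0("no such file: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (oc in c("outcome_rear", "outcome_front"))
    if (!oc %in% names(df)) stop_schema(paste0("missing column '", oc, "'"))
  used <- character(0)
  for (eqn in c("rear", "front"))
    for (v in spec[[eqn]]$covariates) {
      cn <- resolve_column(df, v, eqn)
      if (is.na(cn))
        stop_schema(paste0("missing covariate column for '", v, "' (",
                           eqn, " equation)"))
      used <- union(used, cn)
    }
  n0 <- nrow(df)
  reasons <- character(0)
  flag <- function(bad, why) {
    if (any(bad)) reasons <<- c(reasons, stats::setNames(sum(bad), why))
    bad
  }
  suppressWarnings({
    yr <- as.numeric(df$outcome_rear)
    yf <- as.numeric(df$outcome_front)
  })
  bad <- flag(is.na(yr) | yr != round(yr) | yr < 1 | yr > spec$K_rear,
              "outcome_rear out of range")
  bad <- bad | flag(is.na(yf) | yf != round(yf) | yf < 1 | yf > spec$K_front,
                    "outcome_front out of range")
  for (cn in used) {
    suppressWarnings(v <- as.numeric(df[[cn]]))
    bad <- bad | flag(is.na(v) | !(v %in% c(0, 1)),
                      paste0("non-binary or missing '", cn, "'"))
    df[[cn]] <- v
  }
  df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0L) stop_schema("no valid rows after validation")
  drop_log <- data.frame(reason = names(reasons),
                         n = as.integer(reasons), row.names = NULL)
  if (!quiet)
    message(sprintf("read %d rows: kept %d, dropped %d%s", n0, nrow(df),
                    n0 - nrow(df),
                    if (nrow(drop_log))
                      paste0(" (", paste(drop_log$reason, drop_log$n,
                                         sep = ": ", collapse = "; "), ")")
                    else ""))
  out <- as_bivop_data(df, spec)
  attr(out, "drop_log") <- drop_log
  out
}

#' Write a paired-crash table as CSV
#'
#' One row per crash; outcome columns `outcome_rear` / `outcome_front`
#' (integer levels `1..K`), driver-specific covariates suffixed `__rear` /
#' `__front`, crash-shared covariates unsuffixed.
#'
#' @param data a [as_bivop_data()] object or the list returned by
#'   [simulate_outcomes()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_crash_csv <- function(data, path) {
  if (is.list(data) && !inherits(data, "bivop_data") &&
      inherits(data$data, "bivop_data")) data <- data$data
  if (!inherits(data, "bivop_data")) stop_spec("data must be a bivop_data")
  write.csv(data$df, path, row.names = FALSE)
  invisible(path)
}

#' Write a truth manifest as JSON
#'
#' Serializes the ground-truth parameters, model structure, size and seed of
#' a synthetic dataset; together with the covariate scheme this regenerates
#' the dataset bit-exactly.
#'
#' @param manifest a `truth_manifest` from [simulate_outcomes()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (!inherits(manifest, "truth_manifest"))
    stop_spec("manifest must be a truth_manifest")
  sp <- manifest$spec
  obj <- list(
    n = manifest$n, seed = manifest$seed,
    n_categories = c(sp$K_rear, sp$K_front),
    rear = list(covariates = sp$rear$covariates,
                constant = sp$rear$constant,
                random = names(sp$rear$random)[sp$rear$random]),
    front = list(covariates = sp$front$covariates,
                 constant = sp$front$constant,
                 random = names(sp$front$random)[sp$front$random]),
    params = list(beta_rear = as.list(manifest$params$beta_rear),
                  beta_front = as.list(manifest$params$beta_front),
                  sigma_rear = as.list(manifest$params$sigma_rear),
                  sigma_front = as.list(manifest$params$sigma_front),
                  cut_rear = manifest$params$cut_rear,
                  cut_front = manifest$params$cut_front,
                  rho = manifest$params$rho))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a YAML model configuration
#'
#' Expected structure:
#' \preformatted{
#' n_categories: [4, 4]
#' rear:
#'   covariates: [male, age_le24]
#'   random: [male]
#'   constant: true
#' front:
#'   covariates: [male]
#'   random: []
#' }
#'
#' @param path YAML file path.
#' @return A [bivop_spec()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("no such file: ", path))
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) stop_schema(paste0("bad YAML: ",
                                                       conditionMessage(e))))
  for (eqn in c("rear", "front"))
    if (!is.list(y[[eqn]]))
      stop_schema(paste0("model config lacks '", eqn, "' block"))
  mk <- function(b) tryCatch(
    bivop_equation(covariates = unlist(b$covariates) %||% character(0),
                   random = unlist(b$random) %||% character(0),
                   constant = b$constant %||% TRUE),
    error = function(e) stop_schema(conditionMessage(e)))
  tryCatch(
    bivop_spec(rear = mk(y$rear), front = mk(y$front),
               n_categories = unlist(y$n_categories) %||% c(4L, 4L)),
    error = function(e) stop_schema(conditionMessage(e)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
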