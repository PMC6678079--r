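significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.01) "***" else if (p < 0.05) "**" else if (p < 0.10) "*" else ""
}

# Flatten a fit into report rows; front block first (the reporting
# convention), rear second, each with its thresholds; rho and the final
# log-likelihood close the table.
report_rows <- function(fit) {
  out <- list()
  add <- function(block, label, est, se, z, p, above = NA, below = NA) {
    out[[length(out) + 1L]] <<- data.frame(
      block = block, label = label, estimate = est, se = se, z = z, p = p,
      stars = significance_stars(p), pct_above = above, pct_below = below,
      stringsAsFactors = FALSE)
  }
  for (eqn in c("front", "rear")) {
    blk <- paste0("Driver in the ", eqn, " vehicle")
    sp <- fit$spec[[eqn]]
    beta <- fit$params[[paste0("beta_", eqn)]]
    sigma <- fit$params[[paste0("sigma_", eqn)]]
    seb <- fit$se[[paste0("beta_", eqn)]]
    ses <- fit$se[[paste0("sigma_", eqn)]]
    zb <- fit$z[[paste0("beta_", eqn)]]; pb <- fit$p[[paste0("beta_", eqn)]]
    zs <- fit$z[[paste0("sigma_", eqn)]]; ps <- fit$p[[paste0("sigma_", eqn)]]
    pct <- fit$percent_obs[[eqn]]
    for (i in seq_along(beta)) {
      nm <- names(beta)[[i]]
      lbl <- if (nm == "(Intercept)") "Constant" else nm
      if (sp$random[[i]]) {
        add(blk, lbl, beta[[i]], seb[[i]], zb[[i]], pb[[i]],
            pct[i, "above"], pct[i, "below"])
        add(blk, "  Standard deviation", sigma[[i]], ses[[i]], zs[[i]],
            ps[[i]])
      } else {
        add(blk, lbl, beta[[i]], seb[[i]], zb[[i]], pb[[i]])
      }
    }
    cuts <- fit$params[[paste0("cut_", eqn)]]
    sec <- fit$se[[paste0("cut_", eqn)]]
    zc <- fit$z[[paste0("cut_", eqn)]]; pc <- fit$p[[paste0("cut_", eqn)]]
    free <- if (sp$constant) seq_along(cuts)[-1L] else seq_along(cuts)
    for (m in seq_along(free)) {
      i <- free[[m]]
      add(blk, paste0("mu", m), cuts[[i]], sec[[i]], zc[[i]], pc[[i]])
    }
  }
  add("Model", "rho (correlation parameter)", fit$params$rho, fit$se$rho,
      fit$z$rho, fit$p$rho)
  do.call(rbind, out)
}

fmt_num <- function(x, d) ifelse(is.na(x), "-", sprintf(paste0("%.", d, "f"), x))
fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.2f%%", x))

#' Render a fitted model as a report table
#'
#' Produces the standard estimates table: per-equation blocks (front first)
#' with coefficient, significance stars (\code{***}/\code{**}/\code{*} at
#' the 1/5/10% levels), standard error, z value and — for random
#' coefficients only — the percent of observations above and below zero;
#' then thresholds, the error correlation and the final log-likelihood.
#' Coefficients and standard errors print with 4 decimals, z values and
#' percents with 2.  A non-converged fit renders a diagnostics block.
#'
#' @param fit a [fit_rpbop()] result.
#' @param format `"text"` (aligned table), `"tsv"` (tab-separated), or
#'   `"json"` (full-precision structured string).
#' @return A character vector of lines (`text`, `tsv`) or a JSON string.
#' @export
render_report <- function(fit, format = c("text", "tsv", "json")) {
  format <- match.arg(format)
  diag_lines <- character(0)
  if (!isTRUE(fit$converged))
    diag_lines <- c("NOT CONVERGED",
                    paste0("  ", unlist(fit$message)),
                    sprintf("  iterations: %s", fit$n_iter %||% NA))
  if (is.null(fit$se)) {
    if (format == "json")
      return(as.character(jsonlite::toJSON(
        list(converged = FALSE, message = unlist(fit$message)),
        auto_unbox = TRUE, digits = NA)))
    return(diag_lines)
  }
  rows <- report_rows(fit)
  if (format == "json") {
    obj <- list(converged = isTRUE(fit$converged),
                n = fit$n, loglik = fit$loglik,
                draws = fit$draw_config,
                rows = rows)
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA, dataframe = "rows")))
  }
  est <- paste0(fmt_num(rows$estimate, 4L),
                ifelse(rows$stars == "", "", paste0(" ", rows$stars)))
  body <- data.frame(Variable = rows$label, Coefficient = est,
                     `Standard Error` = fmt_num(rows$se, 4L),
                     `Z Value` = fmt_num(rows$z, 2L),
                     `Above 0` = fmt_pct(rows$pct_above),
                     `Below 0` = fmt_pct(rows$pct_below),
                     check.names = FALSE, stringsAsFactors = FALSE)
  footer <- c(sprintf("Final log-likelihood\t%.4f", fit$loglik),
              sprintf("Number of crashes\t%d", fit$n))
  if (format == "tsv") {
    lines <- c(paste(names(body), collapse = "\t"),
               vapply(seq_len(nrow(body)), function(i) {
                 paste(c(rows$block[[i]], unlist(body[i, ])), collapse = "\t")
               }, character(1)))
    lines[[1L]] <- paste("Block", lines[[1L]], sep = "\t")
    return(c(diag_lines, lines, footer))
  }
  widths <- pmax(nchar(names(body)),
                 apply(body, 2L, function(col) max(nchar(col))))
  pad <- function(v, w) formatC(v, width = w + 2L)
  hdr <- paste(mapply(pad, names(body), widths), collapse = "")
  lines <- c(diag_lines, hdr)
  last_block <- ""
  for (i in seq_len(nrow(body))) {
    if (rows$block[[i]] != last_block) {
      last_block <- rows$block[[i]]
      lines <- c(lines, paste0("-- ", last_block, " --"))
    }
    lines <- c(lines,
               paste(mapply(pad, unlist(body[i, ]), widths), collapse = ""))
  }
  c(lines, footer,
    "Note: ***, **, * mean significance at the 1%, 5%, 10% level")
}

#' Serialize a fit to JSON
#'
#' Full-precision JSON artifact with the estimates, standard errors, model
#' structure and diagnostics; [read_fit_json()] reconstructs a reportable
#' fit object from it.
#'
#' @param fit a [fit_rpbop()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  sp <- fit$spec
  obj <- list(
    n = fit$n, loglik = fit$loglik, converged = isTRUE(fit$converged),
    message = unlist(fit$message), n_iter = fit$n_iter,
    clamp_count = fit$clamp_count, draw_config = fit$draw_config,
    spec = list(n_categories = c(sp$K_rear, sp$K_front),
                rear = list(covariates = sp$rear$covariates,
                            constant = sp$rear$constant,
                            random = names(sp$rear$random)[sp$rear$random]),
                front = list(covariates = sp$front$covariates,
                             constant = sp$front$constant,
                             random = names(sp$front$random)[sp$front$random])),
    params = list(beta_rear = as.list(fit$params$beta_rear),
                  beta_front = as.list(fit$params$beta_front),
                  sigma_rear = as.list(fit$params$sigma_rear),
                  sigma_front = as.list(fit$params$sigma_front),
                  cut_rear = fit$params$cut_rear,
                  cut_front = fit$params$cut_front,
                  rho = fit$params$rho),
    se = lapply(fit$se, function(v) if (length(v) > 1L) as.list(v) else v),
    z = lapply(fit$z, function(v) if (length(v) > 1L) as.list(v) else v),
    p = lapply(fit$p, function(v) if (length(v) > 1L) as.list(v) else v))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Rebuild a reportable fit from its JSON artifact
#'
#' @param path path written by [write_fit_json()].
#' @return A `bivop_fit`-classed list sufficient for [render_report()].
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop_schema(paste0("no such file: ", path))
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- bivop_spec(
    rear = bivop_equation(o$spec$rear$covariates %||% character(0),
                          o$spec$rear$random %||% character(0),
                          o$spec$rear$constant),
    front = bivop_equation(o$spec$front$covariates %||% character(0),
                           o$spec$front$random %||% character(0),
                           o$spec$front$constant),
    n_categories = o$spec$n_categories)
  params <- bivop_params(spec,
                         beta_rear = unlist(o$params$beta_rear),
                         beta_front = unlist(o$params$beta_front),
                         sigma_rear = unlist(o$params$sigma_rear),
                         sigma_front = unlist(o$params$sigma_front),
                         cut_rear = o$params$cut_rear,
                         cut_front = o$params$cut_front,
                         rho = o$params$rho)
  num_vec <- function(v) {
    if (is.list(v)) {
      out <- vapply(v, function(x)
        if (is.null(x) || !length(x)) NA_real_ else as.numeric(x),
        numeric(1))
    } else {
      out <- suppressWarnings(as.numeric(v))
      names(out) <- names(v)
    }
    out
  }
  relist <- function(b) lapply(b, num_vec)
  fit <- list(params = params, spec = spec, se = relist(o$se),
              z = relist(o$z), p = relist(o$p),
              loglik = o$loglik, converged = o$converged, n = o$n,
              n_iter = o$n_iter, clamp_count = o$clamp_count,
              draw_config = o$draw_config, message = o$message)
  fit$percent_obs <- lapply(c(rear = "rear", front = "front"), function(eqn) {
    sp <- spec[[eqn]]
    beta <- params[[paste0("beta_", eqn)]]
    sigma <- params[[paste0("sigma_", eqn)]]
    out <- matrix(NA_real_, length(beta), 2,
                  dimnames = list(names(beta), c("above", "below")))
    for (i in which(sp$random)) out[i, ] <- percent_observations(beta[[i]],
                                                                 sigma[[i]])
    out
  })
  class(fit) <- "bivop_fit"
  fit
}
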