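#' Fit and compare the three missing-data models on one dataset
#'
#' The headline sensitivity workflow as one call: fit GEE (MCAR), the
#' linear mixed model (MAR) and the shared-parameter model (XMAR) --
#' optionally also the competing-risks SPM -- with a shared specification,
#' compute the marginalized declines over the horizon, and assemble a
#' comparison table with effect attenuation relative to the SPM reference,
#' AIC/BIC (undefined for GEE) and the SPM loading-factor hazard ratios.
#'
#' @param data a \code{\link{panel_data}} object.
#' @param spec an \code{\link{spm_spec}}.
#' @param horizon contrast horizon in years (default 20).
#' @param corr GEE working correlation (default exchangeable).
#' @param Q quadrature order for the SPM fit.
#' @param baseline baseline hazard family for the SPM.
#' @param include_competing also fit the two-cause SPM (requires a
#'   two-status dataset).
#' @param control passed to the fitters.
#' @return an object of class \code{"spm_comparison"}: list with
#'   \code{table} (one row per model: declines, additional decline with CI
#'   and p, attenuation vs the SPM reference, AIC, BIC), \code{loadings}
#'   (per-cause HR per SD rows), \code{fits} (the fitted objects),
#'   \code{horizon}.
#' @export
compare_models <- function(data, spec, horizon = 20,
                           corr = "exchangeable", Q = 9L,
                           baseline = "piecewise",
                           include_competing = FALSE, control = list()) {
  fits <- list()
  fits$SPM <- fit_spm(data, spec, Q = Q, baseline = baseline,
                      control = control)
  fits$GLMM <- fit_lmm(data, spec, control = control)
  fits$GEE <- try(fit_gee(data, spec, corr = corr, control = control),
                  silent = TRUE)
  if (inherits(fits$GEE, "try-error")) fits$GEE <- NULL
  if (include_competing)
    fits$`SPM-competing` <- fit_spm(data, spec, causes = 2L, Q = Q,
                                    baseline = baseline, control = control)

  assumption <- c(SPM = "XMAR", GLMM = "MAR", GEE = "MCAR",
                  `SPM-competing` = "XMAR, competing risks")
  ref_add <- NULL
  rows <- lapply(names(fits), function(m) {
    f <- fits[[m]]
    dc <- marginalized_decline(f, horizon = horizon)
    add <- dc[dc$contrast == "additional", ]
    wo <- dc[dc$contrast == "without", ]
    wi <- dc[dc$contrast == "with", ]
    if (m == "SPM") ref_add <<- add$estimate
    data.frame(
      model = m, assumption = assumption[[m]],
      decline_without = wo$estimate, without_lo = wo$lower,
      without_hi = wo$upper, without_p = wo$p,
      decline_with = wi$estimate, with_lo = wi$lower, with_hi = wi$upper,
      with_p = wi$p,
      additional = add$estimate, additional_lo = add$lower,
      additional_hi = add$upper, additional_p = add$p,
      attenuation_pct = if (m == "SPM") NA_real_ else
        attenuation(ref_add, add$estimate),
      AIC = f$AIC, BIC = f$BIC,
      converged = isTRUE(f$converged))
  })
  tab <- do.call(rbind, rows)

  loadings <- NULL
  for (m in intersect(c("SPM", "SPM-competing"), names(fits))) {
    f <- fits[[m]]
    for (k in seq_along(f$causes)) for (e in seq_len(f$d)) {
      h <- loading_hr_per_sd(f, cause = k, effect = e)
      loadings <- rbind(loadings, data.frame(
        model = m, cause = k,
        effect = c("intercept", "slope")[e],
        hr = h$hr, lower = h$lower, upper = h$upper,
        direction = h$direction))
    }
  }
  structure(list(table = tab, loadings = loadings, fits = fits,
                 horizon = horizon),
            class = "spm_comparison")
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "f"))
}

#' Render a model-comparison table
#'
#' @param x an \code{\link{compare_models}} result.
#' @param format \code{"text"} (aligned, NA printed as a dash),
#'   \code{"delimited"} (CSV; parses back to identical values) or
#'   \code{"markdown"}.
#' @return character vector of output lines (invisibly printed for
#'   \code{"text"}).
#' @export
render_report <- function(x, format = c("text", "delimited", "markdown")) {
  format <- match.arg(format)
  tab <- x$table
  if (format == "delimited") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
    return(out)
  }
  disp <- data.frame(
    model = sprintf("%s (%s)", tab$model, tab$assumption),
    `decline without` = sprintf("%s (%s, %s)", fmt_num(tab$decline_without),
                                fmt_num(tab$without_lo),
                                fmt_num(tab$without_hi)),
    `decline with` = sprintf("%s (%s, %s)", fmt_num(tab$decline_with),
                             fmt_num(tab$with_lo), fmt_num(tab$with_hi)),
    additional = sprintf("%s (%s, %s) p=%s", fmt_num(tab$additional),
                         fmt_num(tab$additional_lo),
                         fmt_num(tab$additional_hi),
                         fmt_num(tab$additional_p)),
    attenuation = ifelse(is.na(tab$attenuation_pct), "-ref-",
                         sprintf("%d%%", round(tab$attenuation_pct))),
    AIC = fmt_num(tab$AIC, 1), BIC = fmt_num(tab$BIC, 1),
    check.names = FALSE)
  disp$attenuation[tab$model == "SPM"] <- "-ref-"
  disp[is.na(disp)] <- "–"
  disp[] <- lapply(disp, function(col) ifelse(is.na(col), "–", col))
  if (format == "markdown") {
    hdr <- paste0("| ", paste(names(disp), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(disp)), collapse = "|"), "|")
    body <- apply(disp, 1, function(rw)
      paste0("| ", paste(rw, collapse = " | "), " |"))
    return(c(hdr, sep, body))
  }
  out <- utils::capture.output(print(disp, row.names = FALSE))
  if (!is.null(x$loadings)) {
    out <- c(out, "", "Loading factors (hazard ratio per SD of random effect):",
             utils::capture.output(print(
               transform(x$loadings, hr = fmt_num(hr),
                         lower = fmt_num(lower), upper = fmt_num(upper)),
               row.names = FALSE)))
  }
  out
}

#' @export
print.spm_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (%g-year marginalized declines)\n\n",
              x$horizon))
  cat(render_report(x, "text"), sep = "\n")
  invisible(x)
}
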