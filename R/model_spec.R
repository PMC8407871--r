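#' Model specification for the longitudinal and event sub-models
#'
#' Declares, by covariate name, the fixed-effect design of the longitudinal
#' sub-model (intercept, time, exposure, exposure-by-time interaction,
#' adjustors), the random-effect design (intercept only, or intercept +
#' slope), the event sub-model's covariate set (baseline covariates only;
#' may differ from the longitudinal set), and which random effects carry
#' loading factors into the log-hazard.
#'
#' @param exposure name of the binary exposure covariate whose interaction
#'   with time is the effect of interest.
#' @param adjustors character vector of adjustor covariate names (main
#'   effects).
#' @param random random-effect design: \code{"intercept+slope"} (default)
#'   or \code{"intercept"}.
#' @param hazard_covariates covariate names entering the event sub-model's
#'   linear predictor; default \code{c(exposure, adjustors)}.
#' @param loadings which random effects are shared with the event
#'   sub-model: subset of \code{c("intercept", "slope")}; default all
#'   random effects in the design.
#' @param time_interactions adjustors that additionally interact with time
#'   (their mean effect is averaged out by
#'   \code{\link{marginalized_decline}}).
#' @return an object of class \code{"spm_spec"}.
#' @export
spm_spec <- function(exposure, adjustors = character(),
                     random = c("intercept+slope", "intercept"),
                     hazard_covariates = NULL,
                     loadings = NULL,
                     time_interactions = character()) {
  random <- match.arg(random)
  re <- if (random == "intercept") "intercept" else c("intercept", "slope")
  loadings <- loadings %||% re
  if (!all(loadings %in% re))
    stop_config("loading set must be a subset of the random-effect design")
  if (!all(time_interactions %in% adjustors))
    stop_config("time_interactions must be a subset of adjustors")
  structure(list(
    exposure = exposure,
    adjustors = adjustors,
    random = random,
    re_dim = length(re),
    hazard_covariates = hazard_covariates %||% c(exposure, adjustors),
    loadings = loadings,
    time_interactions = time_interactions
  ), class = "spm_spec")
}

#' @export
print.spm_spec <- function(x, ...) {
  cat("Joint-model specification\n")
  cat("  longitudinal: y ~ time +", x$exposure, "+", x$exposure,
      "x time", if (length(x$adjustors))
        paste("+", paste(x$adjustors, collapse = " + ")), "\n")
  cat("  random effects:", x$random, "\n")
  cat("  hazard covariates:", paste(x$hazard_covariates, collapse = ", "), "\n")
  cat("  loadings on:", paste(x$loadings, collapse = ", "), "\n")
  invisible(x)
}

#' Build design matrices for both sub-models
#'
#' Expands a \code{\link{panel_data}} dataset and an \code{\link{spm_spec}}
#' into the numeric designs the likelihoods consume: the long-format
#' fixed-effect matrix X (one row per visit: intercept, time, exposure,
#' exposure-by-time, adjustors, optional adjustor-by-time columns), the
#' random-effect covariate (time), and the per-subject baseline hazard
#' design X*.  Column ordering is fixed by the spec, so parameter indexing
#' is stable across datasets.
#'
#' @param data a \code{\link{panel_data}} object.
#' @param spec an \code{\link{spm_spec}}.
#' @return list with elements \code{X} (n_obs x p), \code{y}, \code{t}
#'   (visit times), \code{subj} (integer subject index per row), \code{Xs}
#'   (N x q hazard design), \code{ids}, \code{beta_names},
#'   \code{alpha_names}, \code{d} (random-effect dimension),
#'   \code{etime}, \code{status} (N x causes matrix), \code{n_causes}.
#' @export
build_designs <- function(data, spec) {
  stopifnot(inherits(data, "panel_data"), inherits(spec, "spm_spec"))
  used <- unique(c(spec$exposure, spec$adjustors, spec$hazard_covariates))
  unknown <- setdiff(used, data$covariate_names)
  if (length(unknown))
    stop_config("unknown covariate(s) in specification: %s",
                paste(unknown, collapse = ", "))

  ids <- data$events$id
  subj <- match(data$visits$id, ids)
  t <- data$visits$time
  base <- data$baseline
  row_cov <- function(nm) base[[nm]][subj]

  X <- cbind(1, t, row_cov(spec$exposure), t * row_cov(spec$exposure))
  beta_names <- c("(Intercept)", "time", spec$exposure,
                  paste0(spec$exposure, ":time"))
  for (a in spec$adjustors) {
    X <- cbind(X, row_cov(a))
    beta_names <- c(beta_names, a)
  }
  for (a in spec$time_interactions) {
    X <- cbind(X, t * row_cov(a))
    beta_names <- c(beta_names, paste0(a, ":time"))
  }
  colnames(X) <- beta_names

  Xs <- as.matrix(base[, spec$hazard_covariates, drop = FALSE])
  storage.mode(Xs) <- "double"

  status_cols <- grep("^status", names(data$events), value = TRUE)
  status <- as.matrix(data$events[, status_cols, drop = FALSE])

  list(X = X, y = data$visits$y, t = t, subj = subj,
       Xs = Xs, ids = ids,
       beta_names = beta_names, alpha_names = spec$hazard_covariates,
       d = spec$re_dim,
       etime = data$events$time, status = status,
       n_causes = data$n_causes)
}

# Per-subject sufficient statistics of the longitudinal design that the
# closed-form Gaussian marginal and the quadrature machinery reuse.
design_stats <- function(ds) {
  N <- length(ds$ids)
  f <- factor(ds$subj, levels = seq_len(N))
  n_i <- as.numeric(tabulate(f, nbins = N))
  # rowsum drops absent factor levels; subjects without visits get 0.
  sum_by <- function(v) {
    out <- numeric(N)
    s <- rowsum(v, f, reorder = TRUE)
    out[as.integer(rownames(s))] <- s
    out
  }
  list(N = N, f = f, n_i = n_i,
       St = sum_by(ds$t), Stt = sum_by(ds$t^2),
       sum_by = sum_by)
}
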