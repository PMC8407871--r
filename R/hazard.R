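#' Parametric baseline hazard
#'
#' Baseline hazard families for the proportional-hazards event sub-model:
#' piecewise-constant (exponential pieces; last interval open-ended),
#' Weibull (\eqn{h_0(t) = \lambda \gamma t^{\gamma-1}}, so
#' \eqn{H_0(t) = \lambda t^\gamma}) and exponential (Weibull with shape 1).
#' All keep the cumulative hazard in closed form, which keeps the joint
#' likelihood closed-form per quadrature node.
#'
#' @param family \code{"piecewise"}, \code{"weibull"} or
#'   \code{"exponential"}.
#' @param cuts for piecewise: strictly increasing interior cut points
#'   (years); the first interval starts at 0 and the last is open-ended.
#' @param rates for piecewise: positive hazard rate per interval
#'   (length \code{length(cuts) + 1}); for weibull/exponential: the rate
#'   \eqn{\lambda}.
#' @param shape Weibull shape \eqn{\gamma} (ignored otherwise).
#' @return an object of class \code{"baseline_hazard"}.
#' @examples
#' bh <- baseline_hazard("piecewise", cuts = 5, rates = c(0.1, 0.2))
#' cumulative_hazard(bh, 10)  # 0.5 + 1.0 = 1.5
#' @export
baseline_hazard <- function(family = c("piecewise", "weibull", "exponential"),
                            cuts = NULL, rates, shape = 1) {
  family <- match.arg(family)
  if (family == "piecewise") {
    cuts <- as.numeric(cuts %||% numeric())
    if (length(cuts) && (any(diff(cuts) <= 0) || any(cuts <= 0)))
      stop_config("piecewise cut points must be positive and strictly increasing")
    if (length(rates) != length(cuts) + 1L)
      stop_config("need one rate per interval (%d)", length(cuts) + 1L)
  } else {
    if (length(rates) != 1L) stop_config("%s family takes a single rate", family)
    if (family == "exponential") shape <- 1
  }
  if (any(rates <= 0) || shape <= 0)
    stop_config("rates and shape must be positive")
  structure(list(family = family, cuts = cuts, rates = as.numeric(rates),
                 shape = as.numeric(shape)),
            class = "baseline_hazard")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  if (x$family == "piecewise") {
    lo <- c(0, x$cuts)
    hi <- c(x$cuts, Inf)
    cat("Piecewise-constant baseline hazard:\n")
    print(data.frame(from = lo, to = hi, rate = x$rates), row.names = FALSE)
  } else {
    cat(sprintf("%s baseline hazard: rate %.4g, shape %.4g\n",
                x$family, x$rates, x$shape))
  }
  invisible(x)
}

#' Cumulative baseline hazard
#'
#' \eqn{H_0(t) = \int_0^t h_0(u)\,du}, exact closed form per family.
#' @param baseline a \code{\link{baseline_hazard}}.
#' @param t non-negative time(s), years.
#' @return numeric vector of \eqn{H_0(t)}.
#' @export
cumulative_hazard <- function(baseline, t) {
  if (any(t < 0)) stop_config("negative time in cumulative_hazard")
  if (baseline$family == "piecewise") {
    lo <- c(0, baseline$cuts)
    hi <- c(baseline$cuts, Inf)
    H <- numeric(length(t))
    for (m in seq_along(baseline$rates)) {
      dur <- pmin(t, hi[m]) - lo[m]
      H <- H + baseline$rates[m] * pmax(dur, 0)
    }
    H
  } else {
    baseline$rates * t^baseline$shape
  }
}

# log h0(t); t > 0 required for weibull with shape != 1
log_base_hazard <- function(baseline, t) {
  if (baseline$family == "piecewise") {
    idx <- findInterval(t, baseline$cuts) + 1L
    log(baseline$rates[idx])
  } else {
    log(baseline$rates) + log(baseline$shape) +
      (baseline$shape - 1) * log(pmax(t, .Machine$double.xmin))
  }
}

#' Event-time log-likelihood contribution
#'
#' Contribution of one (or a vector of) subject(s) under the parametric
#' proportional-hazards sub-model with hazard
#' \eqn{h(t) = h_0(t) e^{\eta}}:
#' \deqn{\delta\,[\log h_0(T) + \eta] - H_0(T)\,e^{\eta}.}
#' The linear predictor \eqn{\eta} carries both the covariate term and any
#' loading term \eqn{\rho \cdot b} supplied by the joint model.
#'
#' @param baseline a \code{\link{baseline_hazard}}.
#' @param eta linear predictor(s).
#' @param time event/censoring time(s) \eqn{T \ge 0}.
#' @param status 0 (censored) / 1 (event).
#' @return numeric vector of log-likelihood contributions.
#' @export
event_loglik <- function(baseline, eta, time, status) {
  status * (log_base_hazard(baseline, time) + eta) -
    cumulative_hazard(baseline, time) * exp(eta)
}

#' Sample an event time by inverse-transform
#'
#' Solves \eqn{S(t \mid \eta) = u}, i.e. \eqn{H_0(t) e^{\eta} = -\log u},
#' in closed form per family (interval walk for the piecewise family).
#' Used by the cohort simulator.
#'
#' @param baseline a \code{\link{baseline_hazard}}.
#' @param eta linear predictor(s).
#' @param u uniform(0,1) draw(s).
#' @return event time(s), years; \code{Inf} where the hazard never
#'   accumulates the required mass (caller applies administrative
#'   censoring).
#' @export
sample_event_time <- function(baseline, eta, u) {
  if (any(u <= 0 | u >= 1)) stop_config("u must lie strictly in (0, 1)")
  target <- -log(u) * exp(-eta)   # solve H0(t) = target
  if (baseline$family == "piecewise") {
    lo <- c(0, baseline$cuts)
    hi <- c(baseline$cuts, Inf)
    Hlo <- cumulative_hazard(baseline, c(0, baseline$cuts))
    out <- rep(Inf, length(target))
    idx <- findInterval(target, Hlo)       # interval containing the target
    ok <- idx >= 1
    out[ok] <- lo[idx[ok]] +
      (target[ok] - Hlo[idx[ok]]) / baseline$rates[idx[ok]]
    out
  } else {
    (target / baseline$rates)^(1 / baseline$shape)
  }
}

# quantile-based default cut points for the piecewise family
default_cuts <- function(times, status, n_intervals = 5L) {
  et <- times[status == 1]
  if (!length(et)) et <- times
  qs <- stats::quantile(et, probs = seq_len(n_intervals - 1L) / n_intervals,
                        names = FALSE, type = 7)
  qs <- unique(qs[qs > 0])
  sort(qs)
}

#' Fit a parametric proportional-hazards model
#'
#' Maximum-likelihood fit of the event sub-model alone (no random
#' effects): covariate log-hazard ratios \eqn{\alpha} plus the baseline
#' hazard parameters.  Used to initialize the joint fit and as the
#' separate (MAR) event model.
#'
#' @param data a \code{\link{panel_data}} object.
#' @param spec an \code{\link{spm_spec}} (supplies the hazard covariate
#'   set).
#' @param cause which cause to fit (1 or 2).
#' @param baseline baseline family, see \code{\link{baseline_hazard}}.
#' @param n_intervals number of piecewise intervals (cut points at
#'   quantiles of the observed event times).
#' @param control list; \code{maxit} (default 500), \code{reltol}.
#' @return an object of classes \code{"ph_fit"}, \code{"spm_fitresult"}.
#' @export
fit_ph <- function(data, spec, cause = 1L,
                   baseline = c("piecewise", "weibull", "exponential"),
                   n_intervals = 5L, control = list()) {
  baseline <- match.arg(baseline)
  ds <- build_designs(data, spec)
  status <- ds$status[, cause]
  if (sum(status) == 0)
    stop("no events observed for cause ", cause, call. = FALSE)
  # optimize with centered covariates: removes the near-flat ridge between
  # covariate effects and the baseline level; the baseline is de-centered
  # on output so reported parameters are on the natural scale
  ctr <- colMeans(ds$Xs)
  Xs <- sweep(ds$Xs, 2, ctr)
  Tt <- ds$etime

  cuts <- if (baseline == "piecewise")
    default_cuts(Tt, status, n_intervals) else NULL
  n_base <- switch(baseline, piecewise = length(cuts) + 1L,
                   weibull = 2L, exponential = 1L)
  q <- ncol(Xs)

  make_bh <- function(th) {
    switch(baseline,
      piecewise = baseline_hazard("piecewise", cuts, exp(th)),
      weibull = baseline_hazard("weibull", rates = exp(th[1]),
                                shape = exp(th[2])),
      exponential = baseline_hazard("exponential", rates = exp(th)))
  }
  negll <- function(theta) {
    alpha <- theta[seq_len(q)]
    bh <- make_bh(theta[q + seq_len(n_base)])
    -sum(event_loglik(bh, drop(Xs %*% alpha), Tt, status))
  }

  # crude rate start: events per unit exposure time
  rate0 <- sum(status) / sum(Tt)
  th0 <- c(rep(0, q),
           switch(baseline, piecewise = rep(log(rate0), n_base),
                  weibull = c(log(rate0), 0), exponential = log(rate0)))
  ctrl <- list(maxit = control$maxit %||% 500,
               reltol = control$reltol %||% 1e-10)
  opt <- stats::optim(th0, negll, method = "BFGS", control = ctrl)
  hess <- stats::optimHess(opt$par, negll)
  vcv <- try(solve(hess), silent = TRUE)
  se_ok <- !inherits(vcv, "try-error") && all(diag(vcv) > 0)
  if (!se_ok) vcv <- matrix(NA_real_, length(th0), length(th0))

  alpha <- unname(opt$par[seq_len(q)])
  names(alpha) <- ds$alpha_names
  bh <- make_bh(opt$par[q + seq_len(n_base)])
  # de-center: H0(t) e^{a'x} = H0c(t) e^{a'(x - ctr)}
  shift <- sum(alpha * ctr)
  bh$rates <- bh$rates * exp(-shift)
  p <- length(th0)
  ll <- -opt$value
  ic <- information_criteria(ll, p, length(ds$ids))
  theta_names <- c(paste0("alpha.", ds$alpha_names),
                   paste0("logbase", seq_len(n_base)))
  structure(list(
    coefficients = alpha, baseline = bh, cause = cause, xs_center = ctr,
    theta = stats::setNames(unname(opt$par), theta_names),
    vcov_theta = vcv, se_ok = se_ok,
    logLik = ll, AIC = ic[["AIC"]], BIC = ic[["BIC"]], np = p,
    n_subjects = length(ds$ids), n_obs = sum(status),
    converged = opt$convergence == 0, iterations = opt$counts[["function"]],
    spec = spec, model = "PH"),
    class = c("ph_fit", "spm_fitresult"))
}
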