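# covariance of the fixed-effect block, in natural (beta) coordinates
beta_vcov <- function(fit) {
  if (inherits(fit, "gee_fit")) return(fit$vcov_theta)
  pos <- if (is.null(fit$map)) fit$beta_idx else
    match(fit$map$idx$beta, fit$map$free)
  fit$vcov_theta[pos, pos, drop = FALSE]
}

#' Empirical-Bayes random-effect predictions
#'
#' The mode of each subject's conditional (posterior) distribution of the
#' random effects given its observed outcomes -- and, for a
#' shared-parameter fit, its event record -- at the estimated parameters.
#' Subjects carrying no information return the prior mode 0.  For the LMM
#' the posterior is Gaussian, so mode and mean coincide.
#'
#' @param fit an \code{"spm_fit"} or \code{"lmm_fit"} object.
#' @param data dataset to predict for; defaults to the fitting data.
#' @return data.frame with columns \code{id}, \code{b.intercept} and (for
#'   an intercept+slope design) \code{b.slope}.
#' @export
empirical_bayes <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, c("spm_fit", "lmm_fit")))
  pc <- spm_precompute(data, fit$spec)
  if (inherits(fit, "spm_fit")) {
    params <- spm_params(fit$coefficients, fit$sigma, fit$tau,
                         causes = fit$causes)
    det_res <- spm_loglik_vec(params, pc, gh_rule(fit$Q, fit$d),
                              details = TRUE)
    bhat <- det_res$bhat
  } else {
    d <- pc$ds$d
    r <- pc$ds$y - drop(pc$ds$X %*% fit$coefficients)
    post <- lmm_posterior(pc$st, r, pc$ds$t, fit$sigma, fit$tau, d)
    bhat <- if (d == 2L) cbind(post$m1, post$m2) else cbind(post$m1)
  }
  out <- data.frame(id = pc$ds$ids, b.intercept = bhat[, 1])
  if (ncol(bhat) == 2L) out$b.slope <- bhat[, 2]
  out
}

# fixed-effect design row(s) for one subject at arbitrary times
design_at <- function(spec, baseline_row, times) {
  X <- cbind(1, times, baseline_row[[spec$exposure]],
             times * baseline_row[[spec$exposure]])
  for (a in spec$adjustors) X <- cbind(X, baseline_row[[a]])
  for (a in spec$time_interactions) X <- cbind(X, times * baseline_row[[a]])
  X
}

#' Predicted subject trajectories
#'
#' \eqn{\hat y_i(t) = X_i(t)\hat\beta + Z_i(t)\hat b_i}: the subject-level
#' predicted outcome trajectory combining the fixed-effect profile with
#' the empirical-Bayes random effects (population-level prediction when
#' \code{b} is zero).
#'
#' @param fit an \code{"spm_fit"}, \code{"lmm_fit"} or \code{"gee_fit"}
#'   object (GEE predicts at population level only).
#' @param times numeric vector of prediction times (years); \code{NULL}
#'   (default) predicts at each subject's observed visit times and
#'   includes the observed outcome in the result.
#' @param data dataset; defaults to the fitting data.
#' @param level \code{"subject"} (empirical-Bayes, default) or
#'   \code{"population"} (\eqn{b = 0}).
#' @return long data.frame: \code{id}, \code{time}, \code{observed} (NA
#'   off-visit), \code{predicted}, \code{model}.
#' @export
predict_trajectory <- function(fit, times = NULL, data = fit$data,
                               level = c("subject", "population")) {
  level <- match.arg(level)
  spec <- fit$spec
  if (inherits(fit, "gee_fit")) level <- "population"
  eb <- if (level == "subject") empirical_bayes(fit, data) else NULL
  ids <- data$events$id
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    row <- data$baseline[i, , drop = FALSE]
    if (is.null(times)) {
      vi <- data$visits[data$visits$id == ids[i], , drop = FALSE]
      tt <- vi$time; obs <- vi$y
    } else {
      tt <- times; obs <- NA_real_
    }
    if (!length(tt)) next
    Xi <- design_at(spec, row, tt)
    pred <- drop(Xi %*% fit$coefficients)
    if (!is.null(eb)) {
      pred <- pred + eb$b.intercept[i] +
        if (!is.null(eb$b.slope)) tt * eb$b.slope[i] else 0
    }
    out[[i]] <- data.frame(id = ids[i], time = tt, observed = obs,
                           predicted = pred)
  }
  res <- do.call(rbind, out)
  res$model <- fit$model
  rownames(res) <- NULL
  res
}

#' @export
predict.spm_fitresult <- function(object, times = NULL, data = object$data,
                                  level = c("subject", "population"), ...) {
  predict_trajectory(object, times = times, data = data,
                     level = match.arg(level))
}

#' Marginalized decline contrast over a horizon
#'
#' The estimated absolute outcome change over \code{horizon} years at each
#' exposure level, marginalized over the empirical adjustor distribution
#' (adjustor-by-time effects, when present, are averaged at the observed
#' adjustor means), plus the additional decline attributable to exposure:
#' \deqn{\Delta(a) = h\,(\beta_t + a\,\beta_{x\times t} + \sum_j \bar w_j
#'   \beta_{w_j \times t}).}
#' Standard errors and Wald CIs/p-values are exact delta-method results
#' (the contrast is linear in \eqn{\beta}).
#'
#' @param fit a fitted model with time and exposure-by-time terms.
#' @param horizon years (default 20).
#' @param exposure_levels two exposure values to contrast (default 0, 1).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class \code{"decline_contrast"}: data.frame with
#'   rows \code{without}, \code{with}, \code{additional}; columns
#'   \code{estimate}, \code{se}, \code{lower}, \code{upper}, \code{p}.
#' @export
marginalized_decline <- function(fit, horizon = 20,
                                 exposure_levels = c(0, 1),
                                 conf_level = 0.95) {
  spec <- fit$spec
  bn <- names(fit$coefficients)
  int_name <- paste0(spec$exposure, ":time")
  if (!all(c("time", int_name) %in% bn))
    stop_config("fit lacks time and %s terms", int_name)
  Vb <- beta_vcov(fit)
  adj_mean <- vapply(spec$time_interactions,
                     function(a) mean(fit$data$baseline[[a]]), numeric(1))

  gvec <- function(a) {
    g <- stats::setNames(numeric(length(bn)), bn)
    g["time"] <- horizon
    g[int_name] <- horizon * a
    for (j in seq_along(adj_mean))
      g[paste0(names(adj_mean)[j], ":time")] <- horizon * adj_mean[j]
    g
  }
  rows <- list(without = gvec(exposure_levels[1]),
               with = gvec(exposure_levels[2]))
  rows$additional <- rows$with - rows$without
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- do.call(rbind, lapply(rows, function(g) {
    est <- sum(g * fit$coefficients)
    se <- sqrt(drop(t(g) %*% Vb %*% g))
    data.frame(estimate = est, se = se,
               lower = est - z * se, upper = est + z * se,
               p = 2 * stats::pnorm(-abs(est / se)))
  }))
  out <- cbind(contrast = rownames(out), out)
  rownames(out) <- NULL
  structure(out, class = c("decline_contrast", "data.frame"),
            horizon = horizon)
}

#' Loading-factor hazard ratio per random-effect SD
#'
#' Expresses a loading factor on the interpretable scale the event
#' sub-model implies: the hazard ratio associated with a one-SD difference
#' in the shared random effect, \eqn{HR = \exp(|\rho_e|\,sd_e)} with
#' \eqn{sd_e} the estimated random-effect SD from the same fit.  The sign
#' convention is reported explicitly: a negative loading means a *lower*
#' random effect (e.g. lower latent baseline cognition, or steeper latent
#' decline) increases the hazard, and the HR is reported "per SD lower".
#' The CI is a delta-method Wald interval on the log-HR scale.
#'
#' @param fit a converged \code{"spm_fit"}.
#' @param cause event cause index (default 1).
#' @param effect random-effect index: 1 = intercept, 2 = slope.
#' @param conf_level confidence level (default 0.95).
#' @return list with \code{hr}, \code{lower}, \code{upper},
#'   \code{direction} (\code{"per SD lower"}/\code{"per SD higher"}),
#'   \code{rho}, \code{sd}, \code{se_loghr}.
#' @export
loading_hr_per_sd <- function(fit, cause = 1L, effect = 1L,
                              conf_level = 0.95) {
  stopifnot(inherits(fit, "spm_fit"))
  rho <- fit$causes[[cause]]$rho[effect]
  sd_e <- sqrt(fit$tau[effect, effect])
  if (sd_e < 1e-6) {
    warning("random-effect SD is essentially zero; HR degenerate at 1")
    return(list(hr = 1, lower = 1, upper = 1, direction = "degenerate",
                rho = rho, sd = sd_e, se_loghr = NA_real_))
  }
  s <- if (rho < 0) -1 else 1
  f <- function(th_free) {
    theta <- fit$theta
    theta[fit$free] <- th_free
    pp <- fit$to_params(theta)
    s * pp$causes[[cause]]$rho[effect] * sqrt(pp$tau[effect, effect])
  }
  loghr <- f(fit$theta[fit$free])
  se <- if (fit$se_ok) {
    g <- numeric_grad(f, fit$theta[fit$free])
    sqrt(drop(t(g) %*% fit$vcov_theta %*% g))
  } else NA_real_
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(loghr),
       lower = exp(loghr - z * se), upper = exp(loghr + z * se),
       direction = if (s < 0) "per SD lower" else "per SD higher",
       rho = rho, sd = sd_e, se_loghr = se)
}

#' Percent effect attenuation relative to a reference estimate
#'
#' \eqn{100\,(ref - comp)/ref}: positive when the comparator estimate is
#' closer to zero than the reference, i.e. the effect is attenuated under
#' the comparator's (weaker) missingness assumption.  The unrounded value
#' is returned; reports round to the nearest integer percent.
#'
#' @param reference reference point estimate (non-zero).
#' @param comparator comparator point estimate.
#' @return percent attenuation (unrounded); \code{NA} when the reference
#'   is zero.
#' @examples
#' attenuation(-0.134, -0.111)  # ~17.2
#' @export
attenuation <- function(reference, comparator) {
  if (!length(reference) || is.na(reference) || reference == 0)
    return(NA_real_)
  100 * (reference - comparator) / reference
}
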