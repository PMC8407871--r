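# Shared S3 methods for fitted model objects ("spm_fitresult").

#' @export
print.spm_fitresult <- function(x, ...) {
  cat(sprintf("%s fit: %d subjects, %d observations\n",
              x$model, x$n_subjects, x$n_obs))
  if (!isTRUE(x$converged)) cat("  ** not converged **\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 5))
  if (!is.null(x$sigma))
    cat(sprintf("Residual SD: %.4f\n", x$sigma))
  if (!is.null(x$tau)) {
    cat("Random-effect SDs:",
        paste(round(sqrt(diag(x$tau)), 4), collapse = ", "))
    if (nrow(x$tau) == 2L)
      cat(sprintf("  (corr %.3f)",
                  x$tau[1, 2] / sqrt(x$tau[1, 1] * x$tau[2, 2])))
    cat("\n")
  }
  if (!is.na(x$logLik))
    cat(sprintf("logLik %.2f  AIC %.1f  BIC %.1f  (p = %d, N = %d)\n",
                x$logLik, x$AIC, x$BIC, x$np, x$n_subjects))
  invisible(x)
}

#' @export
summary.spm_fitresult <- function(object, ...) {
  est <- object$coefficients
  Vb <- beta_vcov(object)
  se <- sqrt(diag(Vb))
  zv <- est / se
  tab <- data.frame(estimate = est, se = se, z = zv,
                    p = 2 * stats::pnorm(-abs(zv)))
  out <- list(fit = object, coef_table = tab)
  if (inherits(object, "spm_fit")) {
    out$loadings <- do.call(rbind, lapply(seq_along(object$causes),
      function(k) do.call(rbind, lapply(seq_len(object$d), function(e) {
        h <- loading_hr_per_sd(object, cause = k, effect = e)
        data.frame(cause = k, effect = c("intercept", "slope")[e],
                   rho = h$rho, hr_per_sd = h$hr, lower = h$lower,
                   upper = h$upper, direction = h$direction)
      }))))
  }
  class(out) <- "summary.spm_fitresult"
  out
}

#' @export
print.summary.spm_fitresult <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  print(round(x$coef_table, 5))
  if (!is.null(x$loadings)) {
    cat("\nLoading factors:\n")
    print(x$loadings, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.spm_fitresult <- function(object, ...) object$coefficients

#' @export
vcov.spm_fitresult <- function(object, ...) beta_vcov(object)

#' @export
logLik.spm_fitresult <- function(object, ...) {
  structure(object$logLik, df = object$np, nobs = object$n_subjects,
            class = "logLik")
}

#' @export
nobs.spm_fitresult <- function(object, ...) object$n_subjects

#' Residuals of a fitted longitudinal model
#'
#' \code{type = "marginal"}: observed minus the fixed-effect prediction
#' \eqn{y - X\hat\beta}; \code{type = "conditional"}: also subtracts the
#' empirical-Bayes random-effect contribution.
#' @param object a fitted model.
#' @param type \code{"conditional"} (default for mixed fits) or
#'   \code{"marginal"}.
#' @param ... unused.
#' @return numeric vector, one element per observed visit.
#' @export
residuals.spm_fitresult <- function(object,
                                    type = c("conditional", "marginal"),
                                    ...) {
  type <- match.arg(type)
  if (inherits(object, "gee_fit")) type <- "marginal"
  pr <- predict_trajectory(object, data = object$data,
                           level = if (type == "conditional") "subject"
                                   else "population")
  pr$observed - pr$predicted
}

#' Observed-versus-predicted plot
#'
#' Scatter of observed outcomes against subject-level (empirical-Bayes)
#' predictions at the observed visit times, with the identity line; the
#' Pearson correlation is shown in the title.
#' @param x a fitted model.
#' @param ... passed to \code{plot}.
#' @export
plot.spm_fitresult <- function(x, ...) {
  pr <- predict_trajectory(x, data = x$data)
  r <- stats::cor(pr$observed, pr$predicted, use = "complete.obs")
  plot(pr$predicted, pr$observed,
       xlab = "predicted", ylab = "observed",
       main = sprintf("%s: observed vs predicted (r = %.3f)", x$model, r),
       ...)
  graphics::abline(0, 1, lty = 2)
  invisible(pr)
}

#' Simulate outcome vectors from a fitted mixed/joint model
#'
#' Draws new random effects and residual errors at the estimated
#' parameters and returns simulated outcome values on the observed visit
#' grid (parametric-bootstrap responses).
#' @param object an \code{"spm_fit"} or \code{"lmm_fit"}.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with \code{id}, \code{time} and one column per
#'   simulation.
#' @export
simulate.spm_fitresult <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ds <- build_designs(object$data, object$spec)
  N <- length(ds$ids)
  mu <- drop(ds$X %*% object$coefficients)
  out <- data.frame(id = ds$ids[ds$subj], time = ds$t)
  L <- t(chol(object$tau))
  d <- nrow(object$tau)
  for (s in seq_len(nsim)) {
    b <- matrix(stats::rnorm(N * d), N, d) %*% t(L)
    zb <- b[ds$subj, 1] + if (d == 2L) ds$t * b[ds$subj, 2] else 0
    out[[paste0("sim_", s)]] <-
      mu + zb + stats::rnorm(length(mu), 0, object$sigma)
  }
  out
}
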