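#' Akaike and Bayesian information criteria
#'
#' \eqn{AIC = -2\ell + 2p}; \eqn{BIC = -2\ell + p \log N}.  Following
#' mixed-model convention, \eqn{N} is the number of *subjects* (independent
#' units), not the number of observations.
#'
#' @param loglik maximized log-likelihood.
#' @param p number of free parameters (must be \eqn{\ge 0}).
#' @param N number of subjects (\eqn{\ge 1}).
#' @return named numeric vector \code{c(AIC = , BIC = )}.
#' @export
information_criteria <- function(loglik, p, N) {
  stopifnot(p >= 0, N >= 1)
  c(AIC = -2 * loglik + 2 * p, BIC = -2 * loglik + p * log(N))
}

# ---- closed-form Gaussian marginal & random-effect posterior -------------
#
# For subject i with design (X_i, Z_i), Z_i = (1) or (1, t), the marginal
# outcome distribution is N(X_i beta, Z_i tau Z_i' + sigma^2 I).  Using
# A = sigma^2 tau^{-1} + Z_i'Z_i:
#   log|Sigma| = 2(n_i - d) log sigma + log|tau| + log|A|
#   r'Sigma^{-1} r = (r'r - u'A^{-1}u)/sigma^2,  u = Z_i'r
# and the random-effect posterior given the outcomes is
#   b | y ~ N(A^{-1}u, sigma^2 A^{-1}).
# Everything is computed componentwise across subjects (d <= 2).
lmm_posterior <- function(st, r, t, sigma, tau, d) {
  sigma2 <- sigma^2
  Sr <- st$sum_by(r)
  Srr <- st$sum_by(r^2)
  if (d == 2L) {
    Str <- st$sum_by(t * r)
    dtau <- tau[1, 1] * tau[2, 2] - tau[1, 2]^2
    W11 <- tau[2, 2] / dtau; W22 <- tau[1, 1] / dtau
    W12 <- -tau[1, 2] / dtau
    A11 <- sigma2 * W11 + st$n_i
    A12 <- sigma2 * W12 + st$St
    A22 <- sigma2 * W22 + st$Stt
    detA <- A11 * A22 - A12^2
    m1 <- (A22 * Sr - A12 * Str) / detA
    m2 <- (A11 * Str - A12 * Sr) / detA
    quad <- (Srr - (m1 * Sr + m2 * Str)) / sigma2
    logdetSigma <- 2 * (st$n_i - 2) * log(sigma) + log(dtau) + log(detA)
    logp <- -0.5 * st$n_i * log(2 * pi) - 0.5 * logdetSigma - 0.5 * quad
    list(logp = logp, m1 = m1, m2 = m2,
         V11 = sigma2 * A22 / detA, V12 = -sigma2 * A12 / detA,
         V22 = sigma2 * A11 / detA)
  } else {
    A <- sigma2 / tau[1, 1] + st$n_i
    m1 <- Sr / A
    quad <- (Srr - m1 * Sr) / sigma2
    logdetSigma <- 2 * (st$n_i - 1) * log(sigma) + log(tau[1, 1]) + log(A)
    logp <- -0.5 * st$n_i * log(2 * pi) - 0.5 * logdetSigma - 0.5 * quad
    list(logp = logp, m1 = m1, m2 = NULL,
         V11 = sigma2 / A, V12 = NULL, V22 = NULL)
  }
}

#' Marginal log-density of one subject's outcome vector
#'
#' The log of the multivariate-normal density of a subject's outcomes under
#' the linear mixed sub-model: mean \eqn{X_i\beta}, covariance
#' \eqn{Z_i \tau Z_i' + \sigma^2 I}.  Reference (non-vectorized)
#' implementation used for oracle checks; the fitters use an algebraically
#' identical closed form.
#'
#' @param beta fixed-effect vector.
#' @param sigma residual SD.
#' @param tau random-effect covariance (1x1 or 2x2).
#' @param y outcome vector of the subject.
#' @param X fixed-effect design rows of the subject.
#' @param t visit times of the subject (random-effect covariate).
#' @return scalar log-density (0 for a subject with no visits).
#' @export
lmm_subject_loglik <- function(beta, sigma, tau, y, X, t) {
  n <- length(y)
  if (n == 0L) return(0)
  Z <- if (nrow(as.matrix(tau)) == 2L) cbind(1, t) else matrix(1, n, 1)
  S <- Z %*% tau %*% t(Z) + sigma^2 * diag(n)
  r <- y - drop(X %*% beta)
  ch <- chol(S)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, r, transpose = TRUE)^2)
}

#' Fit the linear mixed comparator model (MAR) by maximum likelihood
#'
#' Gaussian linear mixed model with random intercept (+ slope), estimated
#' by full maximum likelihood (not REML) so its log-likelihood, AIC and
#' BIC are directly comparable with the joint shared-parameter fit.
#' Standard errors come from the numerically differentiated observed
#' information.  Optimization is unconstrained: \eqn{\log\sigma} and the
#' Cholesky factor of \eqn{\tau}; a variance estimate on the boundary is
#' reported as near-zero with a warning flag rather than an error.
#'
#' @param data a \code{\link{panel_data}} object.
#' @param spec an \code{\link{spm_spec}}.
#' @param control list; \code{maxit} (default 500), \code{reltol}
#'   (default 1e-10).
#' @return an object of classes \code{"lmm_fit"}, \code{"spm_fitresult"}
#'   with components \code{coefficients} (beta), \code{sigma}, \code{tau},
#'   \code{theta}, \code{vcov_theta}, \code{logLik}, \code{AIC},
#'   \code{BIC}, convergence diagnostics.
#' @export
fit_lmm <- function(data, spec, control = list()) {
  ds <- build_designs(data, spec)
  st <- design_stats(ds)
  d <- ds$d
  if (st$N < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (d == 2L && !any(st$n_i >= 2))
    stop(paste("random slope is not identifiable: no subject has 2+ visits;",
               "use random = 'intercept'"), call. = FALSE)
  p <- ncol(ds$X)

  negll <- function(theta) {
    beta <- theta[seq_len(p)]
    sigma <- exp(theta[p + 1L])
    L <- theta_to_chol(theta[p + 1L + seq_len(chol_npar(d))], d)
    tau <- L %*% t(L)
    r <- ds$y - drop(ds$X %*% beta)
    v <- suppressWarnings(
      -sum(lmm_posterior(st, r, ds$t, sigma, tau, d)$logp))
    if (!is.finite(v)) 1e10 else v
  }

  beta0 <- stats::coef(stats::lm.fit(ds$X, ds$y))
  beta0[is.na(beta0)] <- 0
  res0 <- ds$y - drop(ds$X %*% beta0)
  s0 <- max(stats::sd(res0), 1e-3)   # floor: perfect-fit start stays finite
  L0 <- if (d == 2L) diag(c(0.7 * s0, 0.05)) else
    matrix(0.7 * s0, 1, 1)
  th0 <- c(beta0, log(0.7 * s0), chol_to_theta(L0))
  ctrl <- list(maxit = control$maxit %||% 500,
               reltol = control$reltol %||% 1e-10)
  opt <- stats::optim(th0, negll, method = "BFGS", control = ctrl)
  hess <- stats::optimHess(opt$par, negll)
  vcv <- try(solve(hess), silent = TRUE)
  se_ok <- !inherits(vcv, "try-error") && all(diag(vcv) > 0)
  if (!se_ok) vcv <- matrix(NA_real_, length(th0), length(th0))

  beta <- stats::setNames(unname(opt$par[seq_len(p)]), ds$beta_names)
  sigma <- unname(exp(opt$par[p + 1L]))
  L <- theta_to_chol(opt$par[p + 1L + seq_len(chol_npar(d))], d)
  tau <- L %*% t(L)
  dimnames(tau) <- list(c("intercept", "slope")[seq_len(d)],
                        c("intercept", "slope")[seq_len(d)])
  np <- length(th0)
  ll <- -opt$value
  ic <- information_criteria(ll, np, st$N)
  theta_names <- c(ds$beta_names, "log.sigma",
                   paste0("tau.chol", seq_len(chol_npar(d))))
  grad <- numeric_grad(negll, opt$par)
  structure(list(
    coefficients = beta, sigma = sigma, tau = tau,
    theta = stats::setNames(unname(opt$par), theta_names),
    beta_idx = seq_len(p),
    vcov_theta = vcv, se_ok = se_ok,
    logLik = ll, AIC = ic[["AIC"]], BIC = ic[["BIC"]], np = np,
    n_subjects = st$N, n_obs = length(ds$y),
    converged = opt$convergence == 0,
    iterations = opt$counts[["function"]],
    gradient_norm = sqrt(sum(grad^2)),
    boundary = any(diag(tau) < 1e-8),
    spec = spec, data = data, model = "LMM"),
    class = c("lmm_fit", "spm_fitresult"))
}

# central-difference gradient
numeric_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h * max(1, abs(x[k]))
    (f(x + e) - f(x - e)) / (2 * e[k])
  }, numeric(1))
}
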