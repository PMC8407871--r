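#' Shared-parameter model parameter set
#'
#' Bundles the full joint-model parameter vector: longitudinal fixed
#' effects \code{beta}, residual SD \code{sigma}, random-effect covariance
#' \code{tau}, and per event cause the covariate log-hazard ratios
#' \code{alpha}, the \code{\link{baseline_hazard}}, and the loading-factor
#' vector \code{rho} (one entry per shared random effect; units log-hazard
#' per random-effect unit).
#'
#' @param beta named fixed-effect vector.
#' @param sigma residual SD (> 0).
#' @param tau random-effect covariance matrix (1x1 or 2x2, PSD).
#' @param causes list with one element per cause, each a list with
#'   components \code{alpha}, \code{baseline}, \code{rho}; for a single
#'   cause the components may be given directly via \code{...}.
#' @param ... single-cause shorthand: \code{alpha}, \code{baseline},
#'   \code{rho}.
#' @return an object of class \code{"spm_params"}.
#' @export
spm_params <- function(beta, sigma, tau, causes = NULL, ...) {
  if (is.null(causes)) causes <- list(list(...))
  tau <- as.matrix(tau)
  stopifnot(sigma > 0, nrow(tau) == ncol(tau))
  if (min(eigen(tau, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop_config("tau must be positive semi-definite")
  d <- nrow(tau)
  for (k in seq_along(causes)) {
    ck <- causes[[k]]
    stopifnot(inherits(ck$baseline, "baseline_hazard"))
    if (length(ck$rho) != d)
      stop_config("cause %d: rho must have one entry per random effect", k)
  }
  structure(list(beta = beta, sigma = sigma, tau = tau, causes = causes,
                 d = d), class = "spm_params")
}

# ---- internal precomputation ---------------------------------------------

spm_precompute <- function(data, spec, params_causes = NULL) {
  ds <- build_designs(data, spec)
  st <- design_stats(ds)
  list(ds = ds, st = st)
}

# event quantities for a cause at given baseline parameters; the
# cumulative-hazard multiplier is kept on the log scale so the survival
# penalty -exp(le + rho.b) is never truncated away under extreme
# parameter values (truncation would unbound the likelihood).
cause_terms <- function(bh, alpha, Xs, etime, status) {
  eta_cov <- drop(Xs %*% alpha)
  H <- cumulative_hazard(bh, etime)
  lh <- log_base_hazard(bh, etime)
  list(delta = status, le = log(H) + eta_cov,
       const = status * (lh + eta_cov))
}

# ---- conditional log-likelihood (reference, per subject) -----------------

#' Conditional joint log-likelihood of one subject given random effects
#'
#' \eqn{\sum_j \log N(y_{ij};\, X_{ij}\beta + Z_{ij}b,\ \sigma^2)} plus,
#' per cause, the event contribution
#' \eqn{\delta[\log h_0(T) + \eta] - H_0(T)e^{\eta}} with
#' \eqn{\eta = X^*\alpha + \rho \cdot b}.  With zero visits the
#' longitudinal product is empty and contributes 0.  The conditional
#' independence of the two sub-models given \eqn{b} is the model's
#' partly-ignorable (XMAR) assumption.
#'
#' @param params an \code{\link{spm_params}} object.
#' @param subject list with \code{y}, \code{X} (matrix), \code{t},
#'   \code{Xs} (hazard covariate vector), \code{etime}, \code{status}
#'   (vector, one entry per cause).
#' @param b random-effect value (length \code{params$d}).
#' @return scalar log-likelihood.
#' @export
subject_conditional_loglik <- function(params, subject, b) {
  d <- params$d
  ll <- 0
  n <- length(subject$y)
  if (n > 0) {
    Zb <- if (d == 2L) b[1] + subject$t * b[2] else rep(b[1], n)
    mu <- drop(subject$X %*% params$beta) + Zb
    ll <- sum(stats::dnorm(subject$y, mu, params$sigma, log = TRUE))
  }
  for (k in seq_along(params$causes)) {
    ck <- params$causes[[k]]
    eta <- sum(subject$Xs * ck$alpha) + sum(ck$rho * b)
    ll <- ll + event_loglik(ck$baseline, eta, subject$etime,
                            subject$status[k])
  }
  ll
}

#' Marginal log-likelihood of one subject (adaptive quadrature)
#'
#' \eqn{\log \int \exp\{\ell_i(b)\}\, N(b; 0, \tau)\, db}, approximated by
#' Gauss-Hermite quadrature recentered and rescaled at the subject's
#' conditional posterior mode (adaptive quadrature), log-sum-exp
#' stabilized.  If mode finding fails the rule falls back to non-adaptive
#' centering at the prior mode with a warning.
#'
#' @param params an \code{\link{spm_params}} object.
#' @param subject subject bundle, see
#'   \code{\link{subject_conditional_loglik}}.
#' @param rule a \code{\link{gh_rule}} of matching dimension.
#' @return scalar log marginal likelihood.
#' @export
subject_marginal_loglik <- function(params, subject, rule) {
  d <- params$d
  stopifnot(rule$d == d)
  logpost <- function(b)
    subject_conditional_loglik(params, subject, b) +
      mvn_logdens(b, params$tau)
  opt <- try(stats::optim(rep(0, d), function(b) -logpost(b),
                          method = "BFGS"), silent = TRUE)
  if (inherits(opt, "try-error") || !all(is.finite(opt$par))) {
    warning("mode finding failed; using non-adaptive rule centered at 0")
    bhat <- rep(0, d)
    Sig <- params$tau
  } else {
    bhat <- opt$par
    H <- stats::optimHess(bhat, function(b) -logpost(b))
    Sig <- try(solve(H), silent = TRUE)
    if (inherits(Sig, "try-error") || any(diag(Sig) <= 0)) Sig <- params$tau
  }
  Cl <- t(chol(Sig))
  K <- nrow(rule$z)
  vals <- numeric(K)
  for (k in seq_len(K)) {
    b <- bhat + sqrt(2) * drop(Cl %*% rule$z[k, ])
    vals[k] <- rule$logw[k] + sum(rule$z[k, ]^2) + logpost(b)
  }
  mx <- max(vals)
  mx + log(sum(exp(vals - mx))) + d / 2 * log(2) + sum(log(diag(Cl)))
}

mvn_logdens <- function(b, tau) {
  d <- length(b)
  ch <- chol(tau)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, b, transpose = TRUE)^2)
}

# ---- vectorized marginal log-likelihood ----------------------------------
#
# Exploits the Gaussian conjugacy of the longitudinal sub-model:
#   L_i = p(y_i) * \int exp{ E_i(b) } N(b; m_i, V_i) db,
# where p(y_i) is the closed-form LMM marginal, (m_i, V_i) the Gaussian
# random-effect posterior given the outcomes alone, and
#   E_i(b) = sum_k [ delta_ik rho_k.b - H_k(T_i) e^{X*alpha_k} e^{rho_k.b} ]
# the event part (its b-free constants are pulled out).  The remaining
# low-dimensional integral is evaluated by Gauss-Hermite quadrature
# recentered at the mode of the full conditional posterior (a few damped
# Newton steps from m_i; the objective is strictly concave in b).
spm_loglik_vec <- function(params, pc, rule, details = FALSE) {
  ds <- pc$ds; st <- pc$st
  d <- params$d
  sigma <- params$sigma; tau <- params$tau
  r <- ds$y - drop(ds$X %*% params$beta)
  post <- lmm_posterior(st, r, ds$t, sigma, tau, d)
  N <- st$N

  nc <- length(params$causes)
  delta <- vector("list", nc); ee <- vector("list", nc)
  rho <- vector("list", nc)
  const <- numeric(N)
  for (k in seq_len(nc)) {
    ck <- params$causes[[k]]
    tm <- cause_terms(ck$baseline, ck$alpha, ds$Xs, ds$etime, ds$status[, k])
    delta[[k]] <- tm$delta; ee[[k]] <- tm$le
    const <- const + tm$const
    rho[[k]] <- ck$rho
  }

  # mode-search weights exp(le + eta), capped for search robustness only
  wfun <- function(le, eta) exp(pmin(le + eta, 27.6))  # cap ~ 1e12
  # exact survival penalty exp(le + eta), capped at e^700 (still ~1e304)
  pen <- function(le, eta) exp(pmin(le + eta, 700))

  if (d == 2L) {
    dV <- post$V11 * post$V22 - post$V12^2
    Vi11 <- post$V22 / dV; Vi22 <- post$V11 / dV; Vi12 <- -post$V12 / dV
    b1 <- post$m1; b2 <- post$m2
    for (it in 1:8) {
      g1 <- -(Vi11 * (b1 - post$m1) + Vi12 * (b2 - post$m2))
      g2 <- -(Vi12 * (b1 - post$m1) + Vi22 * (b2 - post$m2))
      h11 <- Vi11; h12 <- Vi12; h22 <- Vi22
      for (k in seq_len(nc)) {
        w <- wfun(ee[[k]], rho[[k]][1] * b1 + rho[[k]][2] * b2)
        g1 <- g1 + (delta[[k]] - w) * rho[[k]][1]
        g2 <- g2 + (delta[[k]] - w) * rho[[k]][2]
        h11 <- h11 + w * rho[[k]][1]^2
        h12 <- h12 + w * rho[[k]][1] * rho[[k]][2]
        h22 <- h22 + w * rho[[k]][2]^2
      }
      dt <- h11 * h22 - h12^2
      db1 <- (h22 * g1 - h12 * g2) / dt
      db2 <- (h11 * g2 - h12 * g1) / dt
      s <- pmin(1, 2 / pmax(abs(db1), abs(db2), 1e-12))  # damping
      b1 <- b1 + s * db1; b2 <- b2 + s * db2
    }
    # curvature at the mode -> adaptive scale
    h11 <- Vi11; h12 <- Vi12; h22 <- Vi22
    for (k in seq_len(nc)) {
      w <- wfun(ee[[k]], rho[[k]][1] * b1 + rho[[k]][2] * b2)
      h11 <- h11 + w * rho[[k]][1]^2
      h12 <- h12 + w * rho[[k]][1] * rho[[k]][2]
      h22 <- h22 + w * rho[[k]][2]^2
    }
    dt <- h11 * h22 - h12^2
    ch <- chol2_vec(h22 / dt, -h12 / dt, h11 / dt)
    bad <- !is.finite(b1 + b2 + dt) | dt <= 0
    if (any(bad)) {      # non-adaptive fallback centered at the posterior
      b1[bad] <- post$m1[bad]; b2[bad] <- post$m2[bad]
      ch$c11[bad] <- sqrt(post$V11[bad])
      ch$c21[bad] <- post$V12[bad] / ch$c11[bad]
      ch$c22[bad] <- sqrt(pmax(post$V22[bad] - ch$c21[bad]^2, 1e-12))
    }

    K <- nrow(rule$z)
    M <- matrix(0, N, K)
    s2 <- sqrt(2)
    for (k in seq_len(K)) {
      z1 <- rule$z[k, 1]; z2 <- rule$z[k, 2]
      bb1 <- b1 + s2 * ch$c11 * z1
      bb2 <- b2 + s2 * (ch$c21 * z1 + ch$c22 * z2)
      E <- 0
      for (j in seq_len(nc)) {
        eta <- rho[[j]][1] * bb1 + rho[[j]][2] * bb2
        E <- E + delta[[j]] * eta - pen(ee[[j]], eta)
      }
      q1 <- bb1 - post$m1; q2 <- bb2 - post$m2
      qf <- Vi11 * q1^2 + 2 * Vi12 * q1 * q2 + Vi22 * q2^2
      M[, k] <- rule$logw[k] + z1^2 + z2^2 + E -
        log(2 * pi) - 0.5 * log(dV) - 0.5 * qf
    }
    logI <- logsumexp_rows(M) + log(2) + log(ch$c11) + log(ch$c22)
    bhat <- cbind(b1, b2)
  } else {
    Vi <- 1 / post$V11
    b1 <- post$m1
    for (it in 1:8) {
      g <- -Vi * (b1 - post$m1)
      h <- Vi
      for (k in seq_len(nc)) {
        w <- wfun(ee[[k]], rho[[k]][1] * b1)
        g <- g + (delta[[k]] - w) * rho[[k]][1]
        h <- h + w * rho[[k]][1]^2
      }
      db <- g / h
      b1 <- b1 + pmin(1, 2 / pmax(abs(db), 1e-12)) * db
    }
    h <- Vi
    for (k in seq_len(nc))
      h <- h + wfun(ee[[k]], rho[[k]][1] * b1) * rho[[k]][1]^2
    cc <- sqrt(1 / h)
    bad <- !is.finite(b1 + cc)
    if (any(bad)) { b1[bad] <- post$m1[bad]; cc[bad] <- sqrt(post$V11[bad]) }

    K <- nrow(rule$z)
    M <- matrix(0, N, K)
    for (k in seq_len(K)) {
      z1 <- rule$z[k, 1]
      bb1 <- b1 + sqrt(2) * cc * z1
      E <- 0
      for (j in seq_len(nc)) {
        eta <- rho[[j]][1] * bb1
        E <- E + delta[[j]] * eta - pen(ee[[j]], eta)
      }
      qf <- Vi * (bb1 - post$m1)^2
      M[, k] <- rule$logw[k] + z1^2 + E -
        0.5 * log(2 * pi) - 0.5 * log(post$V11) - 0.5 * qf
    }
    logI <- logsumexp_rows(M) + 0.5 * log(2) + log(cc)
    bhat <- cbind(b1)
  }

  by_subject <- post$logp + const + logI
  if (details)
    list(loglik = sum(by_subject), by_subject = by_subject, bhat = bhat,
         post = post)
  else sum(by_subject)
}

#' Joint marginal log-likelihood of a dataset
#'
#' Sum over subjects of the marginal (random effects integrated out) joint
#' log-likelihood under a shared-parameter model; order-invariant in the
#' subjects.
#'
#' @param params an \code{\link{spm_params}} object (causes must match the
#'   dataset's).
#' @param data a \code{\link{panel_data}} object.
#' @param spec an \code{\link{spm_spec}}.
#' @param rule a \code{\link{gh_rule}}; default order 9.
#' @return scalar log-likelihood with attribute \code{"by_subject"}.
#' @export
spm_loglik <- function(params, data, spec, rule = gh_rule(9L, params$d)) {
  pc <- spm_precompute(data, spec)
  res <- spm_loglik_vec(params, pc, rule, details = TRUE)
  structure(res$loglik, by_subject = res$by_subject)
}

# ---- fitting -------------------------------------------------------------

spm_parmap <- function(p, d, q, n_base, nc, fix_rho = NULL) {
  idx <- list(beta = seq_len(p), lsig = p + 1L,
              tau = p + 1L + seq_len(chol_npar(d)))
  pos <- p + 1L + chol_npar(d)
  idx$causes <- vector("list", nc)
  for (k in seq_len(nc)) {
    a <- pos + seq_len(q); pos <- pos + q
    b <- pos + seq_len(n_base[k]); pos <- pos + n_base[k]
    r <- pos + seq_len(d); pos <- pos + d
    idx$causes[[k]] <- list(alpha = a, base = b, rho = r)
  }
  npar <- pos
  fixed <- rep(NA_real_, npar)
  if (!is.null(fix_rho)) {
    if (isTRUE(fix_rho)) fix_rho <- rep(0, d * nc)
    stopifnot(length(fix_rho) == d * nc)
    j <- 1L
    for (k in seq_len(nc)) for (e in seq_len(d)) {
      fixed[idx$causes[[k]]$rho[e]] <- fix_rho[j]
      j <- j + 1L
    }
  }
  list(idx = idx, npar = npar, fixed = fixed, free = which(is.na(fixed)))
}

# theta holds the baseline level in centered-covariate form (see fit_ph);
# xs_center de-centers the rates so returned params are on the natural scale
spm_theta_to_params <- function(theta, map, d, baseline, cuts, beta_names,
                                alpha_names, xs_center) {
  idx <- map$idx
  beta <- stats::setNames(unname(theta[idx$beta]), beta_names)
  sigma <- unname(exp(theta[idx$lsig]))
  L <- theta_to_chol(theta[idx$tau], d)
  tau <- L %*% t(L)
  causes <- lapply(seq_along(idx$causes), function(k) {
    ik <- idx$causes[[k]]
    alpha <- stats::setNames(unname(theta[ik$alpha]), alpha_names)
    dec <- exp(-sum(alpha * xs_center))
    bh <- switch(baseline,
      piecewise = baseline_hazard("piecewise", cuts[[k]],
                                  exp(theta[ik$base]) * dec),
      weibull = baseline_hazard("weibull",
                                rates = exp(theta[ik$base][1]) * dec,
                                shape = exp(theta[ik$base][2])),
      exponential = baseline_hazard("exponential",
                                    rates = exp(theta[ik$base]) * dec))
    list(alpha = alpha, baseline = bh, rho = unname(theta[ik$rho]))
  })
  spm_params(beta, sigma, tau, causes)
}

#' Fit a shared-parameter joint model
#'
#' Maximum-likelihood fit of the conventional shared-parameter model: the
#' Gaussian linear mixed longitudinal sub-model and one or two
#' cause-specific parametric proportional-hazards event sub-models,
#' coupled through loading factors \eqn{\rho} on the shared random
#' effects.  The marginal likelihood integrates the random effects out by
#' adaptive Gauss-Hermite quadrature.  Estimation is two-stage: the
#' separate LMM (\code{\link{fit_lmm}}) and PH (\code{\link{fit_ph}}) fits
#' initialize the joint quasi-Newton maximization with \eqn{\rho = 0}
#' starts; up to three deterministic restarts with perturbed loadings are
#' attempted on non-convergence.  Standard errors come from the
#' numerically differentiated observed information; if the Hessian is not
#' positive definite the fit is returned with SEs flagged unreliable.
#'
#' @param data a \code{\link{panel_data}} object.
#' @param spec an \code{\link{spm_spec}}.
#' @param causes 1 (single informative cause) or 2 (competing causes,
#'   e.g. dementia and death; requires a two-status dataset).
#' @param baseline baseline hazard family: \code{"piecewise"} (default;
#'   cut points at quantiles of each cause's observed event times),
#'   \code{"weibull"}, or \code{"exponential"}.
#' @param n_intervals piecewise interval count (default 5).
#' @param Q quadrature order per random-effect dimension (default 9).
#' @param fix_rho \code{NULL} (all loadings free), \code{TRUE} (all fixed
#'   at 0, the MAR-constrained joint model), or a numeric vector of length
#'   \code{d * causes} with \code{NA} for free entries.
#' @param control list; \code{maxit} (default 500), \code{reltol}
#'   (default 1e-10), \code{hessian} (default TRUE).
#' @return an object of classes \code{"spm_fit"}, \code{"spm_fitresult"};
#'   see \code{\link{fit_lmm}} for the common fields.  Additional fields:
#'   \code{causes} (per-cause \code{alpha}, \code{baseline}, \code{rho}),
#'   \code{eb} (per-subject empirical-Bayes modes), \code{loading_hr}
#'   (per-cause hazard ratios per random-effect SD).
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_config(n = 300, seed = 1))
#' spec <- spm_spec("atrophy", adjustors = "age")
#' fit <- fit_spm(sim$data, spec, Q = 5)
#' summary(fit)
#' }
#' @export
fit_spm <- function(data, spec, causes = 1L,
                    baseline = c("piecewise", "weibull", "exponential"),
                    n_intervals = 5L, Q = 9L, fix_rho = NULL,
                    control = list()) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(data, "panel_data"))
  if (causes == 2L && data$n_causes < 2L)
    stop_config("competing-risks fit requires a second status column")
  pc <- spm_precompute(data, spec)
  ds <- pc$ds
  d <- ds$d
  p <- ncol(ds$X); q <- ncol(ds$Xs)
  N <- length(ds$ids)
  rule <- gh_rule(Q, d)

  cuts <- vector("list", causes)
  n_base <- integer(causes)
  for (k in seq_len(causes)) {
    if (sum(ds$status[, k]) == 0)
      stop("no events observed for cause ", k, call. = FALSE)
    cuts[[k]] <- if (baseline == "piecewise")
      default_cuts(ds$etime, ds$status[, k], n_intervals) else NULL
    n_base[k] <- switch(baseline, piecewise = length(cuts[[k]]) + 1L,
                        weibull = 2L, exponential = 1L)
  }
  map <- spm_parmap(p, d, q, n_base, causes, fix_rho)

  xs_center <- colMeans(ds$Xs)
  to_params <- function(theta)
    spm_theta_to_params(theta, map, d, baseline, cuts, ds$beta_names,
                        ds$alpha_names, xs_center)

  # --- two-stage initialization
  lmm0 <- fit_lmm(data, spec, control = control)
  theta0 <- numeric(map$npar)
  theta0[map$idx$beta] <- lmm0$coefficients
  theta0[map$idx$lsig] <- log(lmm0$sigma)
  theta0[map$idx$tau] <- chol_to_theta(t(chol(lmm0$tau)))
  for (k in seq_len(causes)) {
    ph0 <- try(fit_ph(data, spec, cause = k, baseline = baseline,
                      n_intervals = n_intervals, control = control),
               silent = TRUE)
    ik <- map$idx$causes[[k]]
    if (!inherits(ph0, "try-error")) {
      theta0[ik$alpha] <- ph0$coefficients
      theta0[ik$base] <- ph0$theta[q + seq_len(n_base[k])]
    } else {
      theta0[ik$base] <- log(sum(ds$status[, k]) / sum(ds$etime))
    }
    theta0[ik$rho] <- 0
  }
  theta0[!is.na(map$fixed)] <- map$fixed[!is.na(map$fixed)]

  negll_free <- function(th_free) {
    theta <- theta0
    theta[map$free] <- th_free
    v <- try(suppressWarnings(-spm_loglik_vec(to_params(theta), pc, rule)),
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }

  ctrl <- list(maxit = control$maxit %||% 500,
               reltol = control$reltol %||% 1e-10)
  rho_free_pos <- which(map$free %in%
                          unlist(lapply(map$idx$causes, `[[`, "rho")))
  start_free <- theta0[map$free]
  jitters <- c(0, 0.3, -0.3, 0.6)  # deterministic restart offsets for rho
  best <- NULL
  for (j in jitters) {
    sf <- start_free
    sf[rho_free_pos] <- sf[rho_free_pos] + j
    opt <- stats::optim(sf, negll_free, method = "BFGS", control = ctrl)
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
    if (best$convergence == 0) break
  }
  # polish from the best point with a fresh quasi-Newton state
  opt <- stats::optim(best$par, negll_free, method = "BFGS", control = ctrl)
  if (opt$value > best$value) opt <- best
  theta <- theta0
  theta[map$free] <- opt$par

  grad <- numeric_grad(negll_free, opt$par)
  gnorm <- sqrt(sum(grad^2))
  converged <- opt$convergence == 0 &&
    gnorm < max(1e-4 * abs(opt$value), 1)

  do_hess <- control$hessian %||% TRUE
  se_ok <- FALSE
  vcv <- matrix(NA_real_, length(map$free), length(map$free))
  if (do_hess) {
    hess <- stats::optimHess(opt$par, negll_free)
    vtry <- try(solve(hess), silent = TRUE)
    if (!inherits(vtry, "try-error") && all(diag(vtry) > 0)) {
      vcv <- (vtry + t(vtry)) / 2
      se_ok <- TRUE
    }
  }

  params <- to_params(theta)
  det_res <- spm_loglik_vec(params, pc, rule, details = TRUE)
  ll <- det_res$loglik
  np <- length(map$free)
  ic <- information_criteria(ll, np, N)

  theta_names <- character(map$npar)
  theta_names[map$idx$beta] <- ds$beta_names
  theta_names[map$idx$lsig] <- "log.sigma"
  theta_names[map$idx$tau] <- paste0("tau.chol", seq_len(chol_npar(d)))
  re_names <- c("intercept", "slope")[seq_len(d)]
  for (k in seq_len(causes)) {
    ik <- map$idx$causes[[k]]
    theta_names[ik$alpha] <- paste0("alpha", k, ".", ds$alpha_names)
    theta_names[ik$base] <- paste0("logbase", k, ".", seq_len(n_base[k]))
    theta_names[ik$rho] <- paste0("rho", k, ".", re_names)
  }
  dimnames(vcv) <- list(theta_names[map$free], theta_names[map$free])
  eb <- data.frame(id = ds$ids, b.intercept = det_res$bhat[, 1])
  if (d == 2L) eb$b.slope <- det_res$bhat[, 2]

  fit <- structure(list(
    coefficients = params$beta, sigma = params$sigma, tau = params$tau,
    causes = params$causes, d = d,
    theta = stats::setNames(theta, theta_names),
    free = map$free, map = map,
    beta_idx = map$idx$beta,
    vcov_theta = vcv, se_ok = se_ok,
    logLik = ll, AIC = ic[["AIC"]], BIC = ic[["BIC"]], np = np,
    n_subjects = N, n_obs = length(ds$y),
    converged = converged, iterations = opt$counts[["function"]],
    gradient_norm = gnorm,
    eb = eb, Q = Q, baseline_family = baseline, cuts = cuts,
    to_params = to_params,
    spec = spec, data = data, model = "SPM"),
    class = c("spm_fit", "spm_fitresult"))
  fit$loading_hr <- try(lapply(seq_len(causes), function(k)
    lapply(seq_len(d), function(e)
      loading_hr_per_sd(fit, cause = k, effect = e))), silent = TRUE)
  fit
}

#' Fit a competing-risks shared-parameter model
#'
#' Convenience wrapper: \code{fit_spm(..., causes = 2)}.  Both
#' cause-specific hazards (e.g. dementia and death) share the same random
#' effects \eqn{b_i}, each with its own covariate effects, baseline hazard
#' and loading factors.
#'
#' @inheritParams fit_spm
#' @param ... passed to \code{\link{fit_spm}}.
#' @return an \code{"spm_fit"} object with two cause components.
#' @export
fit_spm_competing <- function(data, spec, ...) {
  fit_spm(data, spec, causes = 2L, ...)
}
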