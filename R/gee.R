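#' Fit the GEE comparator model (MCAR)
#'
#' Gaussian identity-link generalized estimating equations with a
#' selectable working correlation (independent, exchangeable, AR1,
#' unstructured) and robust sandwich standard errors.  Consistent for the
#' marginal mean only under MCAR dropout, which is what makes it the
#' strongest-assumption comparator in the missing-data sensitivity
#' workflow.  Correlation and scale parameters are moment estimators from
#' Pearson residuals, iterated with the mean coefficients to convergence.
#' AR1 and unstructured correlations are indexed by scheduled wave number
#' (visits are matched to the nearest wave), so they require a declared
#' wave schedule.
#'
#' @param data a \code{\link{panel_data}} object.
#' @param spec an \code{\link{spm_spec}}.
#' @param corr working correlation family.
#' @param waves wave schedule for AR1/unstructured; defaults to the
#'   schedule stored on the dataset.
#' @param control list; \code{maxit} (default 100), \code{tol}
#'   (default 1e-10 on the coefficient change).
#' @return an object of classes \code{"gee_fit"}, \code{"spm_fitresult"}.
#'   No log-likelihood, AIC or BIC are defined (quasi-likelihood method);
#'   \code{vcov_theta} holds the sandwich covariance of the coefficients.
#' @export
fit_gee <- function(data, spec,
                    corr = c("exchangeable", "independent", "ar1",
                             "unstructured"),
                    waves = NULL, control = list()) {
  corr <- match.arg(corr)
  ds <- build_designs(data, spec)
  p <- ncol(ds$X)
  N <- length(ds$ids)
  maxit <- control$maxit %||% 100
  tol <- control$tol %||% 1e-10

  wave_idx <- NULL
  if (corr %in% c("ar1", "unstructured")) {
    waves <- waves %||% data$waves
    if (is.null(waves))
      stop_config("%s working correlation requires a declared wave schedule",
                  corr)
    wave_idx <- vapply(ds$t, function(tt) which.min(abs(waves - tt)),
                       integer(1))
  }
  rows <- split(seq_along(ds$y), ds$subj)

  beta <- stats::coef(stats::lm.fit(ds$X, ds$y))
  phi <- 1
  alpha_c <- 0            # exchangeable / AR1 correlation parameter
  Runs <- NULL            # unstructured wave-by-wave correlation

  corr_matrix <- function(idx) {
    n <- length(idx)
    switch(corr,
      independent = diag(n),
      exchangeable = {
        R <- matrix(alpha_c, n, n); diag(R) <- 1; R
      },
      ar1 = {
        w <- wave_idx[idx]
        alpha_c^abs(outer(w, w, "-"))
      },
      unstructured = {
        w <- wave_idx[idx]
        R <- Runs[w, w, drop = FALSE]; diag(R) <- 1; R
      })
  }

  for (it in seq_len(maxit)) {
    e <- (ds$y - drop(ds$X %*% beta))
    phi <- sum(e^2) / (length(e) - p)
    ep <- e / sqrt(phi)
    if (corr == "exchangeable") {
      num <- 0; den <- 0
      for (ii in rows) {
        n <- length(ii)
        if (n > 1) {
          s <- sum(ep[ii])
          num <- num + (s^2 - sum(ep[ii]^2)) / 2
          den <- den + n * (n - 1) / 2
        }
      }
      alpha_c <- num / max(den - p, 1)
    } else if (corr == "ar1") {
      num <- 0; den <- 0
      for (ii in rows) {
        w <- wave_idx[ii]
        if (length(ii) > 1) {
          lag1 <- which(diff(w) == 1)
          num <- num + sum(ep[ii][lag1] * ep[ii][lag1 + 1])
          den <- den + length(lag1)
        }
      }
      alpha_c <- num / max(den - p, 1)
    } else if (corr == "unstructured") {
      W <- length(waves)
      S <- matrix(0, W, W); C <- matrix(0, W, W)
      for (ii in rows) {
        w <- wave_idx[ii]
        S[w, w] <- S[w, w] + tcrossprod(ep[ii])
        C[w, w] <- C[w, w] + 1
      }
      Runs <- S / pmax(C, 1)
      diag(Runs) <- 1
    }

    A <- matrix(0, p, p); u <- numeric(p)
    for (ii in rows) {
      Xi <- ds$X[ii, , drop = FALSE]
      Ri <- corr_matrix(ii)
      Wi <- solve(Ri) / phi
      A <- A + crossprod(Xi, Wi %*% Xi)
      u <- u + crossprod(Xi, Wi %*% ds$y[ii])
    }
    beta_new <- drop(solve(A, u))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  converged <- it < maxit || max(abs(beta_new - beta)) < tol

  # robust sandwich covariance
  e <- ds$y - drop(ds$X %*% beta)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (ii in rows) {
    Xi <- ds$X[ii, , drop = FALSE]
    Wi <- solve(corr_matrix(ii)) / phi
    g <- crossprod(Xi, Wi %*% e[ii])
    A <- A + crossprod(Xi, Wi %*% Xi)
    B <- B + tcrossprod(g)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(ds$beta_names, ds$beta_names)

  structure(list(
    coefficients = stats::setNames(beta, ds$beta_names),
    theta = stats::setNames(beta, ds$beta_names),
    beta_idx = seq_len(p),
    vcov_theta = V, se_ok = TRUE,
    corr = corr, corr_par = if (corr %in% c("exchangeable", "ar1"))
      alpha_c else Runs,
    scale = phi,
    logLik = NA_real_, AIC = NA_real_, BIC = NA_real_, np = p,
    n_subjects = N, n_obs = length(ds$y),
    converged = converged, iterations = it,
    spec = spec, data = data, model = "GEE"),
    class = c("gee_fit", "spm_fitresult"))
}
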