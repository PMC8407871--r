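#' Ground-truth parameters for the synthetic cohort generator
#'
#' Default true parameters calibrated to the margins of a large
#' community-based cognitive-aging cohort: binary exposure (brain atrophy)
#' prevalence 34%; age 62.84 (SD 4.48) years; standardized cognitive
#' z-score with baseline mean -0.23 and SD 0.98; a 20-year mean decline of
#' -0.951 without exposure and an additional -0.134 with exposure; and a
#' dementia-like censoring event whose hazard rises with lower latent
#' baseline cognition and steeper latent decline (negative loadings).
#' The random-slope SD (0.15) is set so the default slope loading
#' reproduces a hazard ratio of about 1.08 per SD of latent decline.
#' All entries are configurable.
#'
#' @param beta named fixed-effect vector (intercept, time, exposure,
#'   exposure:time, age).
#' @param sigma residual SD.
#' @param tau 2x2 random-effect covariance.
#' @param alpha list (one element per cause) of named log-HR vectors for
#'   \code{atrophy} and \code{age}.
#' @param baseline list of \code{\link{baseline_hazard}} objects, one per
#'   cause (default Weibull).
#' @param rho list of loading vectors (length 2), one per cause.
#' @param exposure_prevalence Bernoulli prevalence of the exposure.
#' @param age_mean,age_sd adjustor (age) distribution.
#' @return an object of class \code{"spm_truth"}.
#' @export
true_params <- function(
    beta = c("(Intercept)" = 1.4091, time = -0.04755,
             atrophy = -0.20, "atrophy:time" = -0.0067, age = -0.025),
    sigma = 0.40,
    tau = matrix(c(0.88^2, 0.25 * 0.88 * 0.15,
                   0.25 * 0.88 * 0.15, 0.15^2), 2, 2),
    alpha = list(c(atrophy = log(1.5), age = 0.05)),
    baseline = list(baseline_hazard("weibull",
                                    rates = 0.0045 / exp(0.05 * 62.84),
                                    shape = 1.4)),
    rho = list(c(-0.9, -0.5)),
    exposure_prevalence = 0.34,
    age_mean = 62.84, age_sd = 4.48) {
  stopifnot(length(alpha) == length(baseline),
            length(alpha) == length(rho))
  structure(list(beta = beta, sigma = sigma, tau = as.matrix(tau),
                 alpha = alpha, baseline = baseline, rho = rho,
                 exposure_prevalence = exposure_prevalence,
                 age_mean = age_mean, age_sd = age_sd,
                 n_causes = length(alpha)),
            class = "spm_truth")
}

#' Add a competing death cause to a truth object
#'
#' Appends a second cause-specific hazard (death) with its own covariate
#' effects, Weibull baseline and (weaker) negative loadings, for
#' simulating competing-risks cohorts.
#'
#' @param truth an \code{\link{true_params}} object with one cause.
#' @param alpha named log-HR vector for the death hazard.
#' @param baseline a \code{\link{baseline_hazard}} for death.
#' @param rho loading vector for death.
#' @return the truth object with two causes.
#' @export
with_death_cause <- function(
    truth = true_params(),
    alpha = c(atrophy = 0.10, age = 0.07),
    baseline = baseline_hazard("weibull", rates = 5.5e-5, shape = 1.3),
    rho = c(-0.3, -0.1)) {
  truth$alpha <- c(truth$alpha, list(alpha))
  truth$baseline <- c(truth$baseline, list(baseline))
  truth$rho <- c(truth$rho, list(rho))
  truth$n_causes <- 2L
  truth
}

#' Generator settings for the synthetic cohort
#'
#' @param n cohort size.
#' @param waves scheduled visit times (years); the index visit is wave 0.
#' @param jitter uniform jitter half-width (years) applied to post-baseline
#'   waves.
#' @param horizon administrative censoring time (years); must be at least
#'   the last wave.
#' @param mechanism dropout mechanism: \code{"xmar"} (event-driven
#'   deletion; default), \code{"xmar-competing"} (dementia + death),
#'   \code{"mcar"}, \code{"mar"}, or \code{"none"}.
#' @param mcar_prob per-wave independent deletion probability (the MCAR
#'   mechanism, and an optional intermittent overlay under XMAR).
#' @param mar_coefs named vector of dropout-logit coefficients for the MAR
#'   mechanism: \code{intercept}, \code{prev_y} (previous observed
#'   outcome), \code{exposure}.
#' @param seed integer master seed; all randomness derives from it.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n = 1840L, waves = c(0, 6, 15, 18, 20),
                       jitter = 0.5, horizon = 21,
                       mechanism = c("xmar", "xmar-competing", "mcar",
                                     "mar", "none"),
                       mcar_prob = 0.13,
                       mar_coefs = c(intercept = -2, prev_y = -0.5,
                                     exposure = 0.3),
                       seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(n >= 1, horizon >= max(waves), mcar_prob >= 0, mcar_prob <= 1,
            jitter >= 0)
  structure(list(n = as.integer(n), waves = waves, jitter = jitter,
                 horizon = horizon, mechanism = mechanism,
                 mcar_prob = mcar_prob, mar_coefs = mar_coefs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic longitudinal cohort with informative dropout
#'
#' Draws baseline covariates, subject random effects
#' \eqn{b_i \sim MVN(0,\tau)}, outcomes at jittered scheduled waves from
#' the longitudinal sub-model, and event times per cause by
#' inverse-transform sampling of the proportional-hazards sub-model with
#' \eqn{\eta = X^*\alpha + \rho\cdot b}; then applies the configured
#' missingness mechanism.  Deterministic given the seed.  The full
#' (pre-deletion) cohort, true random effects and uncensored event times
#' are retained as ground truth.
#'
#' Under \code{"xmar"}/\code{"xmar-competing"} the emitted event table
#' records the (possibly censored) event and visits after it are deleted.
#' Under \code{"none"}, \code{"mcar"} and \code{"mar"} the latent event
#' process does not truncate follow-up and the event table is censored at
#' the administrative horizon (true event times remain in the truth
#' component).
#'
#' @param config a \code{\link{sim_config}}.
#' @param truth a \code{\link{true_params}} object (a death cause is added
#'   automatically for \code{"xmar-competing"}).
#' @return list of class \code{"sim_cohort"}: \code{data} (a
#'   \code{\link{panel_data}}), \code{truth} (list with \code{subjects}:
#'   id, atrophy, age, b0, b1, true event/censoring info; and
#'   \code{full_visits}: the complete outcome matrix before deletion),
#'   \code{config}, \code{params}.
#' @export
simulate_cohort <- function(config = sim_config(), truth = true_params()) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "spm_truth"))
  if (config$mechanism == "xmar-competing" && truth$n_causes < 2L)
    truth <- with_death_cause(truth)
  set.seed(config$seed)
  n <- config$n
  W <- length(config$waves)

  atrophy <- stats::rbinom(n, 1, truth$exposure_prevalence)
  age <- stats::rnorm(n, truth$age_mean, truth$age_sd)
  b <- matrix(stats::rnorm(n * 2), n, 2) %*% chol(truth$tau)

  tmat <- matrix(rep(config$waves, each = n), n, W)
  if (config$jitter > 0 && W > 1)
    tmat[, -1] <- tmat[, -1] +
      matrix(stats::runif(n * (W - 1), -config$jitter, config$jitter),
             n, W - 1)

  beta <- truth$beta
  ymat <- matrix(0, n, W)
  for (w in seq_len(W)) {
    tt <- tmat[, w]
    mu <- beta[["(Intercept)"]] + beta[["time"]] * tt +
      beta[["atrophy"]] * atrophy + beta[["atrophy:time"]] * atrophy * tt +
      beta[["age"]] * age +
      b[, 1] + b[, 2] * tt
    ymat[, w] <- mu + stats::rnorm(n, 0, truth$sigma)
  }

  Xs <- cbind(atrophy = atrophy, age = age)
  tstar <- matrix(Inf, n, truth$n_causes)
  for (k in seq_len(truth$n_causes)) {
    eta <- drop(Xs[, names(truth$alpha[[k]]), drop = FALSE] %*%
                  truth$alpha[[k]]) + drop(b %*% truth$rho[[k]])
    tstar[, k] <- sample_event_time(truth$baseline[[k]], eta,
                                    stats::runif(n))
  }

  full <- list(
    ids = seq_len(n),
    baseline = data.frame(id = seq_len(n), atrophy = atrophy, age = age),
    tmat = tmat, ymat = ymat, tstar = tstar,
    b = b, n_causes = truth$n_causes)

  data <- apply_missingness(full, config)
  truth_subj <- data.frame(id = seq_len(n), atrophy = atrophy, age = age,
                           b0 = b[, 1], b1 = b[, 2])
  for (k in seq_len(truth$n_causes))
    truth_subj[[paste0("tstar", k)]] <- tstar[, k]
  full_visits <- data.frame(
    id = rep(seq_len(n), W),
    wave = rep(seq_len(W), each = n),
    time = as.vector(tmat), y = as.vector(ymat))
  full_visits <- full_visits[order(full_visits$id, full_visits$time), ]
  rownames(full_visits) <- NULL

  structure(list(data = data,
                 truth = list(subjects = truth_subj,
                              full_visits = full_visits, full = full),
                 config = config, params = truth),
            class = "sim_cohort")
}

#' Apply a missingness mechanism to a full cohort
#'
#' Converts the complete simulated cohort into the observed
#' \code{\link{panel_data}} under the configured mechanism:
#' \itemize{
#'   \item \strong{MCAR}: each post-baseline visit independently deleted
#'     with probability \code{mcar_prob};
#'   \item \strong{MAR}: monotone dropout, with per-wave dropout
#'     probability a logistic function of observed covariates and the
#'     previous observed outcome;
#'   \item \strong{XMAR}: deletion induced solely by the event process
#'     (which depends on the random effects), i.e. all visits after the
#'     event/censoring time are removed, plus the optional MCAR overlay.
#' }
#' The baseline visit is never deleted.  Deletion is deterministic given
#' the visit-level random draws, so re-applying the mechanism to the
#' retained full cohort reproduces the same dataset.
#'
#' @param full the \code{full} component of a \code{\link{simulate_cohort}}
#'   result (complete outcome matrix, event times, random effects).
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{panel_data}} object.
#' @export
apply_missingness <- function(full, config) {
  n <- length(full$ids)
  W <- ncol(full$tmat)
  mech <- config$mechanism
  xmar <- mech %in% c("xmar", "xmar-competing")

  # observed event record
  if (xmar) {
    t1 <- do.call(pmin, c(lapply(seq_len(ncol(full$tstar)),
                                 function(k) full$tstar[, k]),
                          list(config$horizon)))
    etime <- t1
    status <- matrix(0L, n, full$n_causes)
    for (k in seq_len(full$n_causes))
      status[, k] <- as.integer(full$tstar[, k] <= etime + 1e-12 &
                                  full$tstar[, k] < config$horizon)
    # ties across causes: first cause wins
    if (full$n_causes == 2L)
      status[status[, 1] == 1L, 2] <- 0L
  } else {
    etime <- rep(config$horizon, n)
    status <- matrix(0L, n, if (mech == "none") full$n_causes else 1L)
  }

  keep <- matrix(TRUE, n, W)
  # derive deletion draws from the master seed, independent of earlier use
  set.seed(config$seed + 1000003L)
  if (xmar) {
    keep <- full$tmat <= etime + 1e-12
    if (config$mcar_prob > 0 && W > 1)
      keep[, -1] <- keep[, -1] &
        matrix(stats::runif(n * (W - 1)) > config$mcar_prob, n, W - 1)
  } else if (mech == "mcar") {
    if (config$mcar_prob > 0 && W > 1)
      keep[, -1] <- matrix(stats::runif(n * (W - 1)) > config$mcar_prob,
                           n, W - 1)
  } else if (mech == "mar") {
    cf <- config$mar_coefs
    u <- matrix(stats::runif(n * W), n, W)
    dropped <- rep(FALSE, n)
    for (w in 2:W) {
      lp <- cf[["intercept"]] + cf[["prev_y"]] * full$ymat[, w - 1] +
        cf[["exposure"]] * full$baseline$atrophy
      dropped <- dropped | (u[, w] < stats::plogis(lp))
      keep[, w] <- keep[, w - 1] & !dropped
    }
  }
  keep[, 1] <- TRUE

  visits <- data.frame(id = rep(full$ids, W),
                       time = as.vector(full$tmat),
                       y = as.vector(full$ymat))[as.vector(keep), ]
  events <- data.frame(id = full$ids, time = etime,
                       status = status[, 1])
  if (ncol(status) == 2L) events$status2 <- status[, 2]
  panel_data(visits, full$baseline, events, waves = config$waves)
}

#' Replicate simulation study across fitters
#'
#' Runs \code{R} independent replicates of the simulate-then-fit workflow
#' (replicate seeds derived deterministically from the master seed) and
#' collects, per replicate and fitter, the exposure-by-time estimate, its
#' SE and Wald CI coverage of the truth, SPM loading estimates, BIC of the
#' SPM versus the zero-loading-constrained joint model, and
#' observed-versus-predicted Pearson correlations among event-dropout
#' subjects.  Fitter failures are recorded, not fatal.
#'
#' @param config a \code{\link{sim_config}} (its seed is the master seed).
#' @param truth a \code{\link{true_params}}.
#' @param R number of replicates.
#' @param fitters subset of \code{c("gee", "lmm", "spm")}.
#' @param spec model specification; default
#'   \code{spm_spec("atrophy", adjustors = "age")}.
#' @param Q quadrature order for the SPM fits (default 5; the fit default
#'   of 9 is used for final analyses).
#' @param conf_level Wald coverage level.
#' @return an object of class \code{"replicate_study"}: list with
#'   \code{reps} (one row per replicate), \code{summary} (bias, empirical
#'   SE, coverage per fitter), \code{truth_value} (true
#'   exposure-by-time coefficient), \code{truth}.
#' @export
replicate_study <- function(config, truth = true_params(), R = 20L,
                            fitters = c("gee", "lmm", "spm"),
                            spec = spm_spec("atrophy", adjustors = "age"),
                            Q = 5L, conf_level = 0.95) {
  stopifnot(R >= 1)
  int_name <- paste0(spec$exposure, ":time")
  truth_value <- truth$beta[[int_name]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- vector("list", R)

  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_cohort(cfg, truth)
    rec <- list(rep = r, seed = cfg$seed)
    lmm <- NULL; spm <- NULL

    grab <- function(fit) {
      est <- fit$coefficients[[int_name]]
      se <- sqrt(beta_vcov(fit)[int_name, int_name])
      list(est = est, se = se,
           cover = as.integer(abs(est - truth_value) <= z * se))
    }
    if ("gee" %in% fitters) {
      g <- try(fit_gee(sim$data, spec), silent = TRUE)
      if (!inherits(g, "try-error")) {
        gg <- grab(g)
        rec$gee_est <- gg$est; rec$gee_se <- gg$se; rec$gee_cover <- gg$cover
      }
    }
    if ("lmm" %in% fitters || "spm" %in% fitters) {
      lmm <- try(fit_lmm(sim$data, spec), silent = TRUE)
      if (!inherits(lmm, "try-error")) {
        ll <- grab(lmm)
        rec$lmm_est <- ll$est; rec$lmm_se <- ll$se; rec$lmm_cover <- ll$cover
      } else lmm <- NULL
    }
    if ("spm" %in% fitters) {
      spm <- try(fit_spm(sim$data, spec, Q = Q), silent = TRUE)
      if (!inherits(spm, "try-error")) {
        ss <- grab(spm)
        rec$spm_est <- ss$est; rec$spm_se <- ss$se; rec$spm_cover <- ss$cover
        rec$rho0 <- spm$causes[[1]]$rho[1]
        rec$rho1 <- spm$causes[[1]]$rho[2]
        rec$spm_bic <- spm$BIC
        # BIC of the rho = 0 constrained joint model via exact
        # separability: its likelihood is the product of the separate fits
        ph <- try(fit_ph(sim$data, spec, baseline = "piecewise"),
                  silent = TRUE)
        if (!is.null(lmm) && !inherits(ph, "try-error"))
          rec$constrained_bic <- information_criteria(
            lmm$logLik + ph$logLik, lmm$np + ph$np,
            n_subjects(sim$data))[["BIC"]]
        # observed-vs-predicted correlation among event-dropout subjects
        if (!is.null(lmm)) {
          drop_ids <- sim$data$events$id[sim$data$events$status == 1]
          ps <- predict_trajectory(spm, data = sim$data)
          pl <- predict_trajectory(lmm, data = sim$data)
          sel <- ps$id %in% drop_ids & !is.na(ps$observed)
          if (sum(sel) > 3) {
            rec$cor_spm <- stats::cor(ps$observed[sel], ps$predicted[sel])
            rec$cor_lmm <- stats::cor(pl$observed[sel], pl$predicted[sel])
          }
        }
      }
    }
    rows[[r]] <- rec
  }

  all_names <- unique(unlist(lapply(rows, names)))
  reps <- do.call(rbind, lapply(rows, function(rc) {
    rc[setdiff(all_names, names(rc))] <- NA
    as.data.frame(rc[all_names])
  }))

  summ <- do.call(rbind, lapply(intersect(c("gee", "lmm", "spm"), fitters),
                                function(f) {
    est <- reps[[paste0(f, "_est")]]
    if (is.null(est)) return(NULL)
    data.frame(fitter = f,
               mean_est = mean(est, na.rm = TRUE),
               bias = mean(est, na.rm = TRUE) - truth_value,
               emp_se = stats::sd(est, na.rm = TRUE),
               mean_se = mean(reps[[paste0(f, "_se")]], na.rm = TRUE),
               coverage = mean(reps[[paste0(f, "_cover")]], na.rm = TRUE),
               n_ok = sum(!is.na(est)))
  }))
  structure(list(reps = reps, summary = summ, truth_value = truth_value,
                 truth = truth, config = config),
            class = "replicate_study")
}

#' @export
print.replicate_study <- function(x, ...) {
  cat(sprintf("Replicate study: %d replicate(s); true exposure-by-time = %.4g\n",
              nrow(x$reps), x$truth_value))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
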