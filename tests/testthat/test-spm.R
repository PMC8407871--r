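make_params <- function(sim) truth_params(sim)

test_that("quadrature rule integrates the Gaussian measure exactly", {
  for (d in 1:2) for (Q in c(5, 9, 15)) {
    r <- gh_rule(Q, d)
    expect_equal(sum(exp(r$logw)) / pi^(d / 2), 1, tolerance = 1e-10)
  }
})

test_that("conditional log-likelihood decouples and matches hand values", {
  beta <- c("(Intercept)" = 0.2, time = -0.05, atrophy = -0.1,
            "atrophy:time" = -0.01, age = -0.02)
  tau <- matrix(c(0.6, 0.05, 0.05, 0.02), 2)
  bh <- baseline_hazard("exponential", rates = 0.05)
  p <- spm_params(beta, 0.5, tau,
                  alpha = c(atrophy = 0.3, age = 0.01), baseline = bh,
                  rho = c(-0.7, -0.3))
  subj <- list(y = 0.4, X = matrix(c(1, 2, 1, 2, 60), 1), t = 2,
               Xs = c(atrophy = 1, age = 60), etime = 8, status = 1)
  b <- c(0.3, -0.1)
  # hand computation
  mu <- sum(subj$X[1, ] * beta) + b[1] + 2 * b[2]
  eta <- 0.3 + 0.6 + (-0.7) * 0.3 + (-0.3) * (-0.1)
  hand <- dnorm(0.4, mu, 0.5, log = TRUE) +
    (log(0.05) + eta) - 0.05 * 8 * exp(eta)
  expect_equal(subject_conditional_loglik(p, subj, b), hand,
               tolerance = 1e-12)

  # no causes: pure Gaussian part
  p0 <- spm_params(beta, 0.5, tau, causes = list())
  expect_equal(subject_conditional_loglik(p0, subj, b),
               dnorm(0.4, mu, 0.5, log = TRUE), tolerance = 1e-12)

  # zero visits: event part only
  subj0 <- list(y = numeric(), X = matrix(0, 0, 5), t = numeric(),
                Xs = c(atrophy = 0, age = 55), etime = 5, status = 0)
  eta0 <- 0.01 * 55 + sum(p$causes[[1]]$rho * b)
  expect_equal(subject_conditional_loglik(p, subj0, b),
               -0.05 * 5 * exp(eta0), tolerance = 1e-12)
})

test_that("vectorized marginal equals the per-subject reference", {
  sim <- simulate_cohort(sim_config(n = 40, seed = 101))
  spec <- default_spec()
  params <- make_params(sim)
  rule <- gh_rule(9, 2)
  ll <- spm_loglik(params, sim$data, spec, rule)
  ds <- build_designs(sim$data, spec)
  ref <- vapply(seq_len(40), function(i)
    subject_marginal_loglik(params, subject_bundle(ds, i), rule),
    numeric(1))
  expect_equal(unname(attr(ll, "by_subject")), ref, tolerance = 1e-9)
  expect_equal(as.numeric(ll), sum(ref), tolerance = 1e-9)
})

test_that("zero coupling factorizes into longitudinal x event marginals", {
  sim <- simulate_cohort(sim_config(n = 30, seed = 103))
  spec <- default_spec()
  params <- make_params(sim)
  params$causes[[1]]$rho <- c(0, 0)
  rule <- gh_rule(15, 2)
  ll <- attr(spm_loglik(params, sim$data, spec, rule), "by_subject")
  ds <- build_designs(sim$data, spec)
  for (i in seq_len(30)) {
    s <- subject_bundle(ds, i)
    lng <- lmm_subject_loglik(params$beta, params$sigma, params$tau,
                              s$y, s$X, s$t)
    ev <- event_loglik(params$causes[[1]]$baseline,
                       sum(s$Xs * params$causes[[1]]$alpha),
                       s$etime, s$status[1])
    expect_equal(ll[i], lng + ev, tolerance = 1e-8)
  }
})

test_that("vanishing random-effect variance collapses to b = 0", {
  sim <- simulate_cohort(sim_config(n = 15, seed = 105))
  spec <- default_spec()
  params <- make_params(sim)
  params$tau <- diag(1e-10, 2)
  ll <- attr(spm_loglik(params, sim$data, spec, gh_rule(9, 2)),
             "by_subject")
  ds <- build_designs(sim$data, spec)
  for (i in seq_len(15)) {
    s <- subject_bundle(ds, i)
    expect_equal(ll[i], subject_conditional_loglik(params, s, c(0, 0)),
                 tolerance = 1e-6)
  }
})

test_that("log-likelihood is additive over subjects", {
  sim <- simulate_cohort(sim_config(n = 25, seed = 107))
  spec <- default_spec()
  params <- make_params(sim)
  d <- sim$data
  ll1 <- as.numeric(spm_loglik(params, d, spec))
  # dataset concatenated with itself
  shift <- function(df) transform(df, id = id + 1000)
  d2 <- panel_data(rbind(d$visits, shift(d$visits)),
                   rbind(d$baseline, shift(d$baseline)),
                   rbind(d$events, shift(d$events)), waves = d$waves)
  ll2 <- as.numeric(spm_loglik(params, d2, spec))
  expect_equal(ll2, 2 * ll1, tolerance = 1e-9)

  # single-subject dataset equals that subject's marginal
  one <- panel_data(d$visits[d$visits$id == 3, ],
                    d$baseline[d$baseline$id %in% c(3, 4), ],
                    d$events[d$events$id %in% c(3, 4), ], waves = d$waves)
  lls <- attr(spm_loglik(params, one, spec), "by_subject")
  ds <- build_designs(d, spec)
  expect_equal(unname(lls[1]),
               subject_marginal_loglik(params, subject_bundle(ds, 3),
                                       gh_rule(9, 2)),
               tolerance = 1e-9)
})

test_that("marginal matches dense-grid integration on a small fixture", {
  sim <- simulate_cohort(sim_config(n = 5, seed = 109))
  spec <- default_spec()
  params <- make_params(sim)
  ds <- build_designs(sim$data, spec)
  ll <- attr(spm_loglik(params, sim$data, spec, gh_rule(15, 2)),
             "by_subject")
  # 2-d trapezoid grid over +/- 6 prior SDs
  s1 <- sqrt(params$tau[1, 1]); s2 <- sqrt(params$tau[2, 2])
  g1 <- seq(-6 * s1, 6 * s1, length.out = 401)
  g2 <- seq(-6 * s2, 6 * s2, length.out = 401)
  h1 <- diff(g1)[1]; h2 <- diff(g2)[1]
  for (i in 1:5) {
    s <- subject_bundle(ds, i)
    M <- outer(g1, g2, Vectorize(function(a, b)
      subject_conditional_loglik(params, s, c(a, b)) +
        spmjoint:::mvn_logdens(c(a, b), params$tau)))
    grid_ll <- log(sum(exp(M)) * h1 * h2)
    expect_equal(ll[i], grid_ll, tolerance = 5e-5)
  }
})

test_that("outcome-unit rescaling is an exact reparameterization", {
  sim <- simulate_cohort(sim_config(n = 30, seed = 111))
  spec <- default_spec()
  params <- make_params(sim)
  cc <- 2.5
  ll <- as.numeric(spm_loglik(params, sim$data, spec))
  d2 <- sim$data
  d2$visits$y <- d2$visits$y * cc
  p2 <- params
  p2$beta <- params$beta * cc
  p2$sigma <- params$sigma * cc
  p2$tau <- params$tau * cc^2
  p2$causes[[1]]$rho <- params$causes[[1]]$rho / cc
  ll2 <- as.numeric(spm_loglik(p2, d2, spec))
  # Jacobian of y -> c y: each observation contributes -log(c)
  expect_equal(ll2, ll - nrow(d2$visits) * log(cc), tolerance = 1e-8)
})

test_that("quadrature order is converged by Q = 9 (adaptive centering)", {
  sim <- simulate_cohort(sim_config(n = 40, seed = 113))
  spec <- default_spec()
  params <- make_params(sim)
  l9 <- attr(spm_loglik(params, sim$data, spec, gh_rule(9, 2)),
             "by_subject")
  l13 <- attr(spm_loglik(params, sim$data, spec, gh_rule(13, 2)),
              "by_subject")
  expect_lt(max(abs(l9 - l13)), 1e-4)
})

test_that("a second cause with vanishing hazard reduces to one cause", {
  sim <- simulate_cohort(sim_config(n = 25, seed = 115,
                                    mechanism = "xmar-competing"))
  spec <- default_spec()
  tp <- sim$params
  p1 <- spm_params(tp$beta, tp$sigma, tp$tau, causes = list(
    list(alpha = tp$alpha[[1]], baseline = tp$baseline[[1]],
         rho = tp$rho[[1]])))
  null_cause <- list(alpha = c(atrophy = 0, age = 0),
                     baseline = baseline_hazard("exponential",
                                                rates = 1e-300),
                     rho = c(0, 0))
  p2 <- spm_params(tp$beta, tp$sigma, tp$tau,
                   causes = list(p1$causes[[1]], null_cause))
  # evaluate both on the same dataset (second status column all zero so
  # the null cause contributes only its vanishing survival penalty)
  d <- sim$data
  d$events$status2 <- 0L
  ll1 <- attr(spm_loglik(p1, d, spec), "by_subject")
  ll2 <- attr(spm_loglik(p2, d, spec), "by_subject")
  expect_equal(ll2, ll1, tolerance = 1e-10)
})

test_that("competing-risks fit recovers distinct cause-specific loadings", {
  sim <- simulate_cohort(sim_config(n = 800, seed = 117,
                                    mechanism = "xmar-competing"))
  fit <- fit_spm_competing(sim$data, default_spec(), Q = 5)
  expect_equal(length(fit$causes), 2L)
  tp <- sim$params
  for (k in 1:2) {
    rho_hat <- fit$causes[[k]]$rho[1]
    se <- sqrt(diag(fit$vcov_theta))[paste0("rho", k, ".intercept")]
    expect_lt(abs(rho_hat - tp$rho[[k]][1]), 3 * se)
  }
})

test_that("competing fit without a second status column is an error", {
  sim <- simulate_cohort(sim_config(n = 20, seed = 119))
  expect_error(fit_spm(sim$data, default_spec(), causes = 2),
               "second status")
})
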