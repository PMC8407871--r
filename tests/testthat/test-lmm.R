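test_that("near-noise-free common-line data gives the degenerate fit", {
  # y = 2 + 3 t for every subject (plus 1e-3 noise so the degenerate
  # maximum is unique): fixed line recovered, variances collapse
  set.seed(1)
  n <- 12
  visits <- do.call(rbind, lapply(1:n, function(i)
    data.frame(id = i, time = c(0, 2, 5),
               y = 2 + 3 * c(0, 2, 5) + rnorm(3, 0, 1e-3))))
  d <- panel_data(visits,
                  data.frame(id = 1:n, atrophy = rep(0:1, n / 2)),
                  data.frame(id = 1:n, time = 6, status = 0))
  fit <- fit_lmm(d, spm_spec("atrophy"))
  expect_equal(fit$coefficients[["(Intercept)"]], 2, tolerance = 1e-2)
  expect_equal(fit$coefficients[["time"]], 3, tolerance = 1e-2)
  expect_lt(fit$sigma, 0.01)
  expect_lt(max(diag(fit$tau)), 1e-3)
})

test_that("subject log-density matches a directly computed bivariate normal", {
  beta <- c(1, -0.5)
  X <- cbind(1, c(0, 4)); t <- c(0, 4); y <- c(0.8, -1.4)
  sigma <- 0.6
  tau <- matrix(c(0.5, 0.1, 0.1, 0.04), 2)
  Z <- cbind(1, t)
  S <- Z %*% tau %*% t(Z) + sigma^2 * diag(2)
  r <- y - drop(X %*% beta)
  ref <- -log(2 * pi) - 0.5 * log(det(S)) -
    0.5 * drop(t(r) %*% solve(S) %*% r)
  expect_equal(lmm_subject_loglik(beta, sigma, tau, y, X, t), ref,
               tolerance = 1e-12)
  # single observation, tau = 0, residual 0 -> standard normal at 0
  expect_equal(lmm_subject_loglik(c(0), 1, matrix(1e-300, 1, 1),
                                  0, matrix(1, 1, 1), 0),
               log(1 / sqrt(2 * pi)), tolerance = 1e-6)
})

test_that("fitted optimum dominates a brute-force grid (3 subjects)", {
  visits <- data.frame(id = rep(1:3, each = 2),
                       time = rep(c(0, 3), 3),
                       y = c(0.2, 1.1, -0.4, 0.9, 0.1, 1.6))
  d <- panel_data(visits, data.frame(id = 1:3, x = c(0, 1, 0)),
                  data.frame(id = 1:3, time = 4, status = 0))
  sp <- spm_spec("x", random = "intercept")
  fit <- fit_lmm(d, sp)
  ds <- build_designs(d, sp)
  grid <- expand.grid(b0 = seq(-1, 1, by = 0.05),
                      b1 = seq(0, 0.8, by = 0.05),
                      ls = seq(-2, 0.5, by = 0.1),
                      lt = seq(-3, 0.5, by = 0.25))
  gll <- function(b0, b1, ls, lt) {
    beta <- c(b0, b1, 0, 0)
    sum(vapply(1:3, function(i) {
      rows <- ds$subj == i
      lmm_subject_loglik(beta, exp(ls), matrix(exp(2 * lt), 1, 1),
                         ds$y[rows], ds$X[rows, , drop = FALSE],
                         ds$t[rows])
    }, numeric(1)))
  }
  # grid restricted to zero exposure effects; refit with those fixed is
  # bounded above by the free optimum
  vals <- mapply(gll, grid$b0, grid$b1, grid$ls, grid$lt)
  expect_gte(fit$logLik, max(vals) - 1e-6)
})

test_that("sum of subject log-densities equals the maximized objective", {
  d <- balanced_panel(17, n = 60)
  sp <- default_spec()
  fit <- fit_lmm(d, sp)
  ds <- build_designs(d, sp)
  total <- sum(vapply(seq_len(n_subjects(d)), function(i) {
    rows <- ds$subj == i
    lmm_subject_loglik(fit$coefficients, fit$sigma, fit$tau,
                       ds$y[rows], ds$X[rows, , drop = FALSE], ds$t[rows])
  }, numeric(1)))
  expect_equal(total, fit$logLik, tolerance = 1e-8)
})

test_that("maximum-likelihood fit agrees with lme4 (independent oracle)", {
  library(lme4)
  d <- balanced_panel(23, n = 200)
  sp <- default_spec()
  fit <- fit_lmm(d, sp)
  long <- merge(d$visits, d$baseline, by = "id")
  m <- lmer(y ~ time * atrophy + age + (1 + time | id), data = long,
            REML = FALSE,
            control = lmerControl(check.conv.singular = "ignore",
                                  check.conv.grad = "ignore"))
  expect_equal(unname(fit$logLik), unname(as.numeric(logLik(m))),
               tolerance = 1e-5)
  fe <- fixef(m)
  expect_equal(unname(fit$coefficients["time"]), unname(fe["time"]),
               tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["atrophy:time"]),
               unname(fe["time:atrophy"]), tolerance = 1e-4)
  expect_equal(fit$sigma, sigma(m), tolerance = 1e-3)
})

test_that("parameters are recovered from complete data (no dropout)", {
  truth <- true_params(rho = list(c(0, 0)))
  sim <- simulate_cohort(sim_config(n = 500, mechanism = "none", seed = 41),
                         truth)
  fit <- fit_lmm(sim$data, default_spec())
  Vb <- vcov(fit)
  for (nm in c("time", "atrophy:time")) {
    se <- sqrt(Vb[nm, nm])
    expect_lt(abs(fit$coefficients[[nm]] - truth$beta[[nm]]), 3 * se)
  }
  expect_equal(fit$sigma, truth$sigma, tolerance = 0.05)
  expect_equal(sqrt(fit$tau[1, 1]), sqrt(truth$tau[1, 1]), tolerance = 0.1)
})

test_that("loglik is invariant to subject order", {
  d <- random_panel(29, n = 10)
  d$events$status <- 0L
  sp <- default_spec()
  f1 <- fit_lmm(d, sp)
  perm <- c(4, 2, 9, 1, 10, 3, 8, 5, 7, 6)
  d2 <- panel_data(d$visits, d$baseline[perm, ], d$events[perm, ],
                   waves = d$waves)
  f2 <- fit_lmm(d2, sp)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("slope with all-singleton subjects is an estimation error", {
  visits <- data.frame(id = 1:5, time = 1, y = rnorm(5))
  d <- panel_data(visits, data.frame(id = 1:5, atrophy = c(0, 1, 0, 1, 0),
                                     age = 60),
                  data.frame(id = 1:5, time = 2, status = 0))
  expect_error(fit_lmm(d, default_spec()), "intercept")
})

test_that("information criteria follow their closed forms", {
  ic <- information_criteria(-100, 5, 50)
  expect_equal(ic[["AIC"]], 210)
  expect_equal(ic[["BIC"]], 200 + 5 * log(50))
  ic0 <- information_criteria(-10, 0, 7)
  expect_equal(ic0[["AIC"]], 20)
  expect_equal(ic0[["BIC"]], 20)
  ic1 <- information_criteria(-3, 1, exp(2))
  expect_equal(ic1[["BIC"]] - ic1[["AIC"]], 0)
})
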