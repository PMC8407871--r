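test_that("cumulative hazard has the exact closed form per family", {
  bh <- baseline_hazard("piecewise", cuts = 5, rates = c(0.1, 0.2))
  expect_equal(cumulative_hazard(bh, 10), 1.5)
  expect_equal(exp(-cumulative_hazard(bh, 10)), exp(-1.5))
  expect_equal(cumulative_hazard(bh, 0), 0)
  expect_equal(cumulative_hazard(baseline_hazard("weibull", rates = 0.3,
                                                 shape = 2), 0), 0)
  expect_error(cumulative_hazard(bh, -1), "negative")

  # Weibull with shape 1 reduces to exponential on a grid
  w <- baseline_hazard("weibull", rates = 0.17, shape = 1)
  e <- baseline_hazard("exponential", rates = 0.17)
  tg <- seq(0, 30, by = 0.25)
  expect_equal(cumulative_hazard(w, tg), cumulative_hazard(e, tg))
})

test_that("event log-likelihood matches hand computation", {
  bh <- baseline_hazard("piecewise", cuts = 5, rates = c(0.1, 0.2))
  # censored: -H0(T) e^eta
  expect_equal(event_loglik(bh, 0, 10, 0), -1.5)
  # event under a constant rate: log(lambda) + eta - lambda T e^eta
  e <- baseline_hazard("exponential", rates = 0.1)
  expect_equal(event_loglik(e, 0.3, 2, 1),
               log(0.1) + 0.3 - 0.2 * exp(0.3))
})

test_that("survival is a proper distribution (density integrates to 1)", {
  bh <- baseline_hazard("piecewise", cuts = c(3, 8), rates = c(0.05, 0.1, 0.2))
  eta <- 0.4
  dens <- function(t) {
    vapply(t, function(tt)
      exp(event_loglik(bh, eta, tt, 1)), numeric(1))
  }
  total <- stats::integrate(dens, 0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("inverse-transform sampling solves S(t|eta) = u exactly", {
  e <- baseline_hazard("exponential", rates = 0.1)
  expect_equal(sample_event_time(e, 0, exp(-1)), 10)
  # u -> 1- gives t -> 0+
  expect_lt(sample_event_time(e, 0, 1 - 1e-12), 1e-9)
  expect_error(sample_event_time(e, 0, 0), "strictly")

  # piecewise inversion and cumulative_hazard are mutual inverses
  bh <- baseline_hazard("piecewise", cuts = c(2, 7, 12),
                        rates = c(0.02, 0.08, 0.15, 0.3))
  set.seed(9)
  u <- runif(200); eta <- rnorm(200, 0, 0.8)
  tt <- sample_event_time(bh, eta, u)
  expect_equal(cumulative_hazard(bh, tt) * exp(eta), -log(u),
               tolerance = 1e-10)
})

test_that("sampled event times follow the analytic survival (DKW band)", {
  bh <- baseline_hazard("weibull", rates = 0.02, shape = 1.4)
  set.seed(21)
  n <- 1e5
  tt <- sample_event_time(bh, 0.2, runif(n))
  eps <- sqrt(log(2 / 0.05) / (2 * n))        # 95% DKW band half-width
  tg <- seq(0.5, 40, by = 0.5)
  S_emp <- vapply(tg, function(g) mean(tt > g), numeric(1))
  S_true <- exp(-cumulative_hazard(bh, tg) * exp(0.2))
  expect_lt(max(abs(S_emp - S_true)), eps)
})

test_that("fit_ph recovers the grid-search optimum on a small fixture", {
  # 6 subjects, single covariate, all events, exponential baseline
  d <- panel_data(
    visits = data.frame(id = 1:6, time = 0, y = 0),
    baseline = data.frame(id = 1:6, x = c(0, 0, 0, 1, 1, 1)),
    events = data.frame(id = 1:6, time = c(4, 7, 12, 1.5, 3, 5),
                        status = 1))
  sp <- spm_spec("x", random = "intercept", hazard_covariates = "x")
  fit <- fit_ph(d, sp, baseline = "exponential")
  # dense grid oracle over (alpha, log lambda)
  grid <- expand.grid(a = seq(-0.5, 2.5, by = 0.01),
                      ll = seq(-4, 0, by = 0.01))
  ll_at <- function(a, ll) {
    bh <- baseline_hazard("exponential", rates = exp(ll))
    sum(event_loglik(bh, a * c(0, 0, 0, 1, 1, 1), d$events$time, 1))
  }
  vals <- mapply(ll_at, grid$a, grid$ll)
  best <- grid[which.max(vals), ]
  expect_equal(unname(fit$coefficients["x"]), best$a, tolerance = 0.02)
  expect_gte(fit$logLik, max(vals))
  # closed form for exponential regression with all events:
  # alpha-hat solves group rates; here exp(alpha) = rate1/rate0
  rate0 <- 3 / sum(c(4, 7, 12)); rate1 <- 3 / sum(c(1.5, 3, 5))
  expect_equal(unname(fit$coefficients["x"]), log(rate1 / rate0),
               tolerance = 1e-4)
})

test_that("fit_ph finds no effect when there is none (recovery)", {
  sim <- simulate_cohort(sim_config(n = 2000, seed = 31),
                         true_params(alpha = list(c(atrophy = 0, age = 0)),
                                     rho = list(c(0, 0))))
  fit <- fit_ph(sim$data, default_spec(), baseline = "piecewise")
  se <- sqrt(diag(fit$vcov_theta))[1]
  expect_lt(abs(fit$coefficients[["atrophy"]]), 3 * se)
})

test_that("duplicating the cohort preserves estimates and scales SEs by sqrt(2)", {
  d <- random_panel(13, n = 40)
  d$events$status <- 1L                     # ensure events
  d2 <- d
  d2$visits <- rbind(d$visits, transform(d$visits, id = id + 100))
  d2$baseline <- rbind(d$baseline, transform(d$baseline, id = id + 100))
  d2$events <- rbind(d$events, transform(d$events, id = id + 100))
  sp <- default_spec()
  f1 <- fit_ph(d, sp, baseline = "exponential")
  f2 <- fit_ph(d2, sp, baseline = "exponential")
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-4)
  expect_equal(sqrt(diag(f1$vcov_theta)) / sqrt(diag(f2$vcov_theta)),
               rep(sqrt(2), length(f1$theta)), tolerance = 0.02)
})

test_that("zero events is an estimation error", {
  d <- tiny_panel()
  d$events$status <- 0L
  expect_error(fit_ph(d, default_spec()), "no events")
})
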