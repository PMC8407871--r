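test_that("empirical-Bayes modes: prior mode for empty subjects, grid argmax otherwise", {
  sim <- simulate_cohort(sim_config(n = 40, seed = 201))
  spec <- default_spec()
  fit <- fit_spm(sim$data, spec, Q = 5)
  eb <- empirical_bayes(fit)
  expect_equal(nrow(eb), 40)

  # subjects with visits: EB mode matches a dense 2-d grid argmax of the
  # conditional log-posterior (tolerance: grid spacing)
  ds <- build_designs(sim$data, spec)
  params <- spm_params(fit$coefficients, fit$sigma, fit$tau,
                       causes = fit$causes)
  g1 <- seq(-2.5, 2.5, by = 0.02)
  g2 <- seq(-0.5, 0.5, by = 0.005)
  for (i in c(1, 7, 19, 33)) {
    s <- subject_bundle(ds, i)
    lp <- outer(g1, g2, Vectorize(function(a, b)
      subject_conditional_loglik(params, s, c(a, b)) +
        spmjoint:::mvn_logdens(c(a, b), params$tau)))
    best <- which(lp == max(lp), arr.ind = TRUE)[1, ]
    expect_lt(abs(eb$b.intercept[i] - g1[best[1]]), 0.03)
    expect_lt(abs(eb$b.slope[i] - g2[best[2]]), 0.0075)
  }
})

test_that("a subject with no visits and no event information sits at the prior mode", {
  d <- tiny_panel()
  # subject 4: no visits, censored immediately (no information)
  d2 <- panel_data(d$visits,
                   rbind(d$baseline, data.frame(id = 4, atrophy = 0, age = 60)),
                   rbind(d$events, data.frame(id = 4, time = 1e-4, status = 0)),
                   waves = d$waves)
  fit <- fit_lmm(d2, default_spec())
  eb <- empirical_bayes(fit)
  expect_equal(eb$b.intercept[eb$id == 4], 0, tolerance = 1e-10)
  expect_equal(eb$b.slope[eb$id == 4], 0, tolerance = 1e-10)
})

test_that("shrinkage: scaling tau down never grows the EB modes", {
  sim <- simulate_cohort(sim_config(n = 25, seed = 203))
  fit <- fit_lmm(sim$data, default_spec())
  norms <- sapply(c(1, 0.3, 0.05, 1e-6), function(s) {
    f <- fit; f$tau <- fit$tau * s
    eb <- empirical_bayes(f)
    mean(sqrt(eb$b.intercept^2 + eb$b.slope^2))
  })
  expect_true(all(diff(norms) < 1e-8))
  expect_lt(norms[4], 1e-3)   # tau -> 0 forces all modes to ~0
})

test_that("trajectory predictions are linear and reduce to the population mean", {
  sim <- simulate_cohort(sim_config(n = 20, seed = 205))
  fit <- fit_lmm(sim$data, default_spec())
  tt <- c(0, 5, 10, 20)
  pop <- predict_trajectory(fit, times = tt, level = "population")
  # population prediction equals X(t) beta for each subject profile
  for (i in c(3, 11)) {
    rows <- pop[pop$id == i, ]
    base <- sim$data$baseline[i, ]
    mu <- fit$coefficients[["(Intercept)"]] +
      fit$coefficients[["time"]] * tt +
      fit$coefficients[["atrophy"]] * base$atrophy +
      fit$coefficients[["atrophy:time"]] * tt * base$atrophy +
      fit$coefficients[["age"]] * base$age
    expect_equal(rows$predicted, mu, tolerance = 1e-10)
  }
  # subject-level adds b: difference is exactly b0 + b1 t
  sub <- predict_trajectory(fit, times = tt, level = "subject")
  eb <- empirical_bayes(fit)
  dfr <- sub$predicted - pop$predicted
  expect_equal(dfr[sub$id == 3],
               eb$b.intercept[3] + tt * eb$b.slope[3], tolerance = 1e-10)
})

test_that("marginalized decline reproduces the closed form", {
  # synthetic fit object with known coefficients (no adjustor-by-time terms)
  sim <- simulate_cohort(sim_config(n = 20, seed = 207))
  fit <- fit_lmm(sim$data, default_spec())
  fit$coefficients[] <- c(0.1, -0.046, -0.2, -0.0067, -0.01)
  dc <- marginalized_decline(fit, horizon = 20)
  expect_equal(dc$estimate[dc$contrast == "without"], -0.92)
  expect_equal(dc$estimate[dc$contrast == "with"], -1.054)
  expect_equal(dc$estimate[dc$contrast == "additional"], -0.134)
  # additivity: additional = horizon x interaction coefficient, exactly
  expect_equal(dc$estimate[dc$contrast == "additional"],
               20 * fit$coefficients[["atrophy:time"]])
  expect_equal(dc$estimate[dc$contrast == "with"] -
                 dc$estimate[dc$contrast == "without"],
               dc$estimate[dc$contrast == "additional"])
  # zero horizon: all zeros
  dc0 <- marginalized_decline(fit, horizon = 0)
  expect_equal(dc0$estimate, c(0, 0, 0))
  # missing interaction term is a configuration error
  f2 <- fit; names(f2$coefficients)[4] <- "other"
  expect_error(marginalized_decline(f2), "atrophy:time")
})

test_that("adjustor-by-time effects are averaged over the empirical distribution", {
  sim <- simulate_cohort(sim_config(n = 60, seed = 209))
  sp <- spm_spec("atrophy", adjustors = "age", time_interactions = "age")
  fit <- fit_lmm(sim$data, sp)
  dc <- marginalized_decline(fit, horizon = 20)
  expected_wo <- 20 * (fit$coefficients[["time"]] +
                         mean(sim$data$baseline$age) *
                           fit$coefficients[["age:time"]])
  expect_equal(dc$estimate[dc$contrast == "without"], expected_wo,
               tolerance = 1e-10)
})

test_that("delta-method SE agrees with a parametric bootstrap (GEE, 500 draws)", {
  spec <- default_spec()
  cfg <- sim_config(n = 200, mechanism = "none", seed = 211)
  fit0 <- fit_gee(simulate_cohort(cfg)$data, spec)
  se_delta <- marginalized_decline(fit0, 20)$se[3]
  boots <- vapply(1:500, function(r) {
    cfg$seed <- 211 + r
    f <- fit_gee(simulate_cohort(cfg)$data, spec)
    marginalized_decline(f, 20)$estimate[3]
  }, numeric(1))
  expect_equal(se_delta, sd(boots), tolerance = 0.12)
})

test_that("loading hazard ratios per SD have the stated closed form", {
  sim <- simulate_cohort(sim_config(n = 250, seed = 213))
  fit <- fit_spm(sim$data, default_spec(), Q = 5)
  h <- loading_hr_per_sd(fit, cause = 1, effect = 1)
  rho <- fit$causes[[1]]$rho[1]
  expect_equal(h$hr, exp(abs(rho) * sqrt(fit$tau[1, 1])), tolerance = 1e-10)
  expect_equal(h$direction,
               if (rho < 0) "per SD lower" else "per SD higher")
  expect_true(h$lower < h$hr && h$hr < h$upper)

  # all-zero loadings give HR exactly 1
  fit0 <- fit_spm(sim$data, default_spec(), Q = 5, fix_rho = TRUE)
  h0 <- loading_hr_per_sd(fit0, cause = 1, effect = 1)
  expect_equal(h0$hr, 1)
})

test_that("attenuation arithmetic and conventions", {
  expect_equal(round(attenuation(-0.134, -0.111)), 17)
  expect_equal(round(attenuation(-0.134, -0.081)), 40)
  expect_equal(attenuation(0.5, 0.5), 0)
  expect_true(is.na(attenuation(0, 0.1)))
})
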