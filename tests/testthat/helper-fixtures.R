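# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files.

# Minimal hand-built dataset: 3 subjects, hand-checkable.
tiny_panel <- function() {
  visits <- data.frame(
    id = c(1, 1, 1, 2, 2, 3),
    time = c(0, 6, 20, 0, 6, 0),
    y = c(0.1, -0.2, -0.9, 0.5, 0.4, -1.0))
  baseline <- data.frame(id = 1:3, atrophy = c(0, 1, 1),
                         age = c(60, 65, 70))
  events <- data.frame(id = 1:3, time = c(25, 10, 4),
                       status = c(0, 1, 0))
  panel_data(visits, baseline, events, waves = c(0, 6, 15, 18, 20))
}

default_spec <- function(...) spm_spec("atrophy", adjustors = "age", ...)

# Random valid dataset for property-style round-trip checks.
random_panel <- function(seed, n = 8, causes = 1) {
  set.seed(seed)
  waves <- c(0, 3, 7, 12)
  rows <- list(); ev <- list()
  for (i in seq_len(n)) {
    nv <- sample(0:4, 1)
    tt <- sort(sample(waves, nv)) + c(0, stats::runif(max(nv - 1, 0), 0, 0.4))
    tt <- unique(round(tt, 3))
    etime <- max(tt, 0) + stats::rexp(1, 0.2) + 0.01
    st <- stats::rbinom(1, 1, 0.5)
    rows[[i]] <- if (length(tt))
      data.frame(id = i, time = tt, y = round(stats::rnorm(length(tt)), 4))
    else NULL
    e <- data.frame(id = i, time = round(etime, 3), status = st)
    if (causes == 2) {
      e$status2 <- ifelse(st == 1, 0, stats::rbinom(1, 1, 0.5))
    }
    ev[[i]] <- e
  }
  visits <- do.call(rbind, rows)
  baseline <- data.frame(id = seq_len(n),
                         atrophy = stats::rbinom(n, 1, 0.4),
                         age = round(stats::rnorm(n, 62, 4), 2))
  panel_data(visits, baseline, do.call(rbind, ev), waves = waves)
}

# Complete balanced dataset with no dropout (for MCAR-concordance checks).
balanced_panel <- function(seed, n = 150) {
  cfg <- sim_config(n = n, mechanism = "none", jitter = 0, seed = seed)
  simulate_cohort(cfg)$data
}

# Subject bundle for the per-subject likelihood API.
subject_bundle <- function(ds, i) {
  rows <- which(ds$subj == i)
  list(y = ds$y[rows], X = ds$X[rows, , drop = FALSE], t = ds$t[rows],
       Xs = ds$Xs[i, ], etime = ds$etime[i],
       status = unname(ds$status[i, ]))
}

# spm_params at the generator truth for a given simulated cohort.
truth_params <- function(sim) {
  tp <- sim$params
  spm_params(tp$beta, tp$sigma, tp$tau,
             causes = lapply(seq_len(tp$n_causes), function(k)
               list(alpha = tp$alpha[[k]], baseline = tp$baseline[[k]],
                    rho = tp$rho[[k]])))
}
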