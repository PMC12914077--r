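test_that("identical configurations give bit-identical registries", {
  cfg <- sim_config(n_areas = 12, lattice_dims = c(3, 4), n_patients = 500,
                    seed = 99)
  r1 <- simulate_registry(cfg)
  r2 <- simulate_registry(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$field, r2$field)
  expect_identical(r1$aggregates, r2$aggregates)
})

test_that("degenerate marginal puts every record in that category", {
  m <- default_marginals()
  m$ecog <- c(good = 1, poor = 0, not_stated = 0)
  cfg <- sim_config(n_areas = 4, lattice_dims = c(2, 2), n_patients = 300,
                    covariate_marginals = m, seed = 5)
  rec <- generate_population(cfg)
  expect_true(all(rec$ecog == "good"))
})

test_that("covariate marginals are validated", {
  m <- default_marginals()
  m$age_group <- c(le60 = 0.4, gt60 = 0.7)
  expect_error(sim_config(covariate_marginals = m), "summing to 1")
  expect_error(sim_config(tau_u2 = -1), "non-negative")
  expect_error(sim_config(n_areas = 6, lattice_dims = c(2, 2)),
               "rows \\* cols")
})

test_that("sampled covariate composition matches the configured marginals", {
  cfg <- sim_config(n_areas = 10, lattice_dims = c(2, 5), n_patients = 6704,
                    seed = 21)
  rec <- generate_population(cfg)
  p <- 5154 / 6704 # configured share of age > 60
  se <- sqrt(p * (1 - p) / 6704)
  expect_lt(abs(mean(rec$age_group == "gt60") - p), 3 * se)
})

test_that("null effects with mu = 0 give a death rate near one half", {
  eff <- default_true_effects()
  eff$beta[] <- 0
  eff$gamma[] <- 0
  eff$delta1 <- 0
  eff$delta2 <- 0
  cfg <- sim_config(n_areas = 9, lattice_dims = c(3, 3), n_patients = 10000,
                    true_effects = eff, mu = 0, tau_u2 = 0, tau_v2 = 0,
                    seed = 31)
  reg <- simulate_registry(cfg)
  expect_lt(abs(mean(reg$records$outcome) - 0.5), 3 * 0.5 / sqrt(10000))
})

test_that("with null effects the rate calibrates to plogis(mu) at large n", {
  eff <- default_true_effects()
  eff$beta[] <- 0
  eff$gamma[] <- 0
  eff$delta1 <- 0
  eff$delta2 <- 0
  target <- 0.0425
  cfg <- sim_config(n_areas = 9, lattice_dims = c(3, 3), n_patients = 50000,
                    true_effects = eff, mu = stats::qlogis(target),
                    tau_u2 = 0, tau_v2 = 0, seed = 13)
  reg <- simulate_registry(cfg)
  se <- sqrt(target * (1 - target) / 50000)
  expect_lt(abs(mean(reg$records$outcome) - target), 3 * se)
})

test_that("stage IV effect is recovered as a crude log-OR", {
  eff <- default_true_effects()
  eff$beta[] <- 0
  eff$beta["stage_IV"] <- log(3.19)
  eff$gamma[] <- 0
  eff$delta1 <- 0
  eff$delta2 <- 0
  cfg <- sim_config(n_areas = 4, lattice_dims = c(2, 2), n_patients = 60000,
                    true_effects = eff, mu = stats::qlogis(0.05),
                    tau_u2 = 0, tau_v2 = 0, seed = 8)
  reg <- simulate_registry(cfg)
  rec <- reg$records
  tab <- table(rec$stage == "IV", rec$outcome)
  crude <- log(tab["TRUE", "1"] * tab["FALSE", "0"] /
                 (tab["TRUE", "0"] * tab["FALSE", "1"]))
  # binomial sampling error on the log-OR
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(crude - log(3.19)), 3 * se)
})

test_that("spatial field centers and respects zero variances", {
  lat <- generate_lattice(3, 3)
  f <- simulate_spatial_field(lat$adjacency, 0, 0, seed = 4)
  expect_identical(f$u, rep(0, 9))
  expect_identical(f$v, rep(0, 9))
  f <- simulate_spatial_field(lat$adjacency, 0.5, 0.2, seed = 4)
  expect_equal(mean(f$u), 0, tolerance = 1e-13)
  expect_equal(mean(f$v), 0, tolerance = 1e-13)
})

test_that("simulate_outcomes demands covariates for occupied areas", {
  cfg <- sim_config(n_areas = 4, lattice_dims = c(2, 2), n_patients = 50,
                    seed = 2)
  reg <- simulate_registry(cfg)
  ac <- reg$area_covariates[-1, ]
  expect_error(
    simulate_outcomes(reg$records, ac, reg$field, cfg),
    "missing area covariates"
  )
})

test_that("aggregation preserves totals and empty cells carry zeros", {
  reg <- desk_registry(seed = 3, n_patients = 400, J = 12, dims = c(3, 4))
  agg <- reg$aggregates
  expect_equal(sum(agg$deaths), sum(reg$records$outcome))
  expect_equal(sum(agg$n), nrow(reg$records))
  expect_equal(nrow(agg), 12 * 3)
  # force an empty cell and re-aggregate
  rec <- reg$records[reg$records$area_id != 5, ]
  agg2 <- aggregate_counts(rec, 12, 3)
  expect_true(all(agg2$n[agg2$area_id == 5] == 0))
  expect_true(all(agg2$deaths[agg2$area_id == 5] == 0))
})

test_that("per-stratum counts re-sum to the cell totals", {
  reg <- desk_registry(seed = 6, n_patients = 600, J = 6, dims = c(2, 3))
  sd <- estimate_f(reg$records, 6, 3)
  agg <- reg$aggregates
  jt <- (agg$area_id - 1) * 3 + agg$period
  # f rows times N recover integer stratum counts summing to N_jt
  for (r in which(agg$n > 0)) {
    counts <- sd$f[jt[r], ] * sd$N[jt[r]]
    expect_equal(sum(counts), agg$n[r])
    expect_equal(counts, round(counts), tolerance = 1e-9)
  }
  expect_equal(sd$N[jt], agg$n, ignore_attr = TRUE)
})

test_that("registry CSV and config YAML round-trip", {
  reg <- desk_registry(seed = 14, n_patients = 120, J = 4, dims = c(2, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_registry_csv(reg$records, f)
  back <- read_registry_csv(f)
  expect_equal(back$outcome, reg$records$outcome)
  expect_equal(as.character(back$stage), as.character(reg$records$stage))

  cfgf <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(reg$config, cfgf)
  cfg2 <- read_sim_config(cfgf)
  expect_equal(cfg2$covariate_marginals, reg$config$covariate_marginals)
  expect_equal(cfg2$true_effects$beta, reg$config$true_effects$beta)
  expect_identical(simulate_registry(cfg2)$records, reg$records)
})
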