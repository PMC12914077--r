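test_that("crude rates reproduce the published cohort values", {
  expect_equal(crude_rate(285, 6704), 4.25)
  expect_equal(crude_rate(0, 100), 0)
  expect_equal(crude_rate(67, 660), 10.15)
  expect_error(crude_rate(5, 0), "positive")
  expect_error(crude_rate(7, 5), "deaths")
})

test_that("Wilson interval reproduces the published CI and boundary case", {
  expect_equal(wilson_ci(285, 6704), c(lower = 3.79, upper = 4.76))
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
})

test_that("Wilson interval matches root-finding on the score equation", {
  # score-equation oracle: bounds p where (phat - p)^2 = z^2 p(1-p)/n
  z <- stats::qnorm(0.975)
  score <- function(p, x, n) (x / n - p)^2 - z^2 * p * (1 - p) / n
  for (case in list(c(50, 100), c(5, 40), c(285, 6704))) {
    x <- case[1]; n <- case[2]
    lo <- stats::uniroot(score, c(1e-12, x / n), x = x, n = n, tol = 1e-12)$root
    hi <- stats::uniroot(score, c(x / n, 1 - 1e-12), x = x, n = n, tol = 1e-12)$root
    expect_equal(unname(wilson_ci(x, n)), round(100 * c(lo, hi), 2))
  }
})

test_that("Wilson interval contains the point estimate and narrows with n", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(10:5000, 1)
    x <- stats::rbinom(1, n, stats::runif(1))
    ci <- wilson_ci(x, n)
    rate <- crude_rate(x, n)
    expect_lte(ci[["lower"]], rate)
    expect_gte(ci[["upper"]], rate)
    wider <- wilson_ci(round(x / 2), ceiling(n / 2))
    expect_gte(diff(wider) + 1e-9, diff(ci))
  }
})

test_that("descriptive tables match brute-force tabulation", {
  reg <- desk_registry(seed = 201, n_patients = 800, J = 4, dims = c(2, 2))
  tab <- descriptive_table(reg$records)
  for (v in unique(tab$variable)) {
    sub <- tab[tab$variable == v, ]
    expect_equal(sum(sub$n), 800)
    expect_lt(abs(sum(sub$pct) - 100), 0.05) # rounding slack
    for (i in seq_len(nrow(sub))) {
      expect_equal(sub$n[i], sum(reg$records[[v]] == sub$category[i]))
    }
  }
  out <- descriptive_table(reg$records, by_outcome = TRUE)
  expect_equal(sum(out$survivors + out$deaths),
               6 * 800) # six covariates, each partitioning the cohort
  one <- out[out$variable == "ecog" & out$category == "poor", ]
  sub <- reg$records[reg$records$ecog == "poor", ]
  expect_equal(one$deaths, sum(sub$outcome))
  expect_equal(one$deaths_pct, crude_rate(sum(sub$outcome), nrow(sub)))
})

test_that("single-category variables report 100 percent", {
  rec <- data.frame(g = factor(rep("only", 25)))
  tab <- descriptive_table(rec, variables = "g")
  expect_equal(tab$pct, 100)
})

test_that("AOR table flags significance by the credible interval", {
  reg <- desk_registry(seed = 203, n_patients = 150, J = 4, dims = c(2, 2))
  dat <- hrr_data_from_registry(reg, "joint")
  nm <- spathrr:::hrr_param_names(dat)
  row <- numeric(length(nm)); names(row) <- nm
  row[c("tau_u2", "tau_v2")] <- 1
  s0 <- fake_samples(row, dat, n = 300)
  tab <- aor_table(s0)
  expect_true(all(tab$aor == 1))
  expect_false(any(tab$significant))
  row["stage_IV"] <- log(3.19)
  s1 <- fake_samples(row, dat, n = 300)
  tab1 <- aor_table(s1)
  r <- tab1[tab1$parameter == "stage_IV", ]
  expect_equal(r$aor, 3.19, tolerance = 1e-12)
  expect_equal(r$lower, 3.19, tolerance = 1e-12)
  expect_true(r$significant)
})

test_that("SRR surface is 1 under a null model and responds to u", {
  reg <- desk_registry(seed = 207, n_patients = 1500, J = 6, dims = c(2, 3))
  dat <- hrr_data_from_registry(reg, "joint")
  nm <- spathrr:::hrr_param_names(dat)
  row <- numeric(length(nm)); names(row) <- nm
  row["mu"] <- -3; row[c("tau_u2", "tau_v2")] <- 1
  null_fit <- fake_samples(row, dat, n = 200)
  surf <- srr_surface(null_fit)
  occ <- surf[surf$n > 0, ]
  expect_true(all(abs(occ$srr_mean - 1) < 1e-10))
  # doubling one area's structured effect raises its SRR
  row2 <- row
  row2["u[3]"] <- 0.4
  s_half <- srr_surface(fake_samples(row2, dat, n = 200))
  row2["u[3]"] <- 0.8
  s_full <- srr_surface(fake_samples(row2, dat, n = 200))
  for (t in 1:3) {
    a3h <- s_half[s_half$area_id == 3 & s_half$period == t, "srr_mean"]
    a3f <- s_full[s_full$area_id == 3 & s_full$period == t, "srr_mean"]
    expect_gt(a3f, a3h)
  }
})

test_that("SRR surface is equivariant under area relabeling", {
  reg <- desk_registry(seed = 209, n_patients = 900, J = 4, dims = c(2, 2))
  dat <- hrr_data_from_registry(reg, "joint")
  nm <- spathrr:::hrr_param_names(dat)
  row <- numeric(length(nm)); names(row) <- nm
  row["mu"] <- -3; row[c("tau_u2", "tau_v2")] <- 1
  row[sprintf("u[%d]", 1:4)] <- c(0.5, -0.2, 0, -0.3)
  base <- srr_surface(fake_samples(row, dat, n = 150))
  # swap areas 1 and 2 everywhere in the inputs
  perm <- c(2L, 1L, 3L, 4L)
  reg2 <- reg
  reg2$records$area_id <- perm[reg$records$area_id]
  reg2$area_covariates <- reg$area_covariates
  reg2$aggregates <- aggregate_counts(reg2$records, 4, 3)
  dat2 <- hrr_data_from_registry(reg2, "joint")
  row2 <- row
  row2[sprintf("u[%d]", 1:4)] <- row[sprintf("u[%d]", perm)]
  swapped <- srr_surface(fake_samples(row2, dat2, n = 150))
  for (t in 1:3) {
    expect_equal(
      swapped[swapped$area_id == 2 & swapped$period == t, "srr_mean"],
      base[base$area_id == 1 & base$period == t, "srr_mean"],
      tolerance = 1e-12
    )
  }
})

test_that("structured-variance fraction edge cases", {
  reg <- desk_registry(seed = 211, n_patients = 150, J = 4, dims = c(2, 2))
  dat <- hrr_data_from_registry(reg, "joint")
  nm <- spathrr:::hrr_param_names(dat)
  row <- numeric(length(nm)); names(row) <- nm
  row[c("tau_u2", "tau_v2")] <- 1
  row[sprintf("u[%d]", 1:4)] <- c(0.4, -0.4, 0.2, -0.2)
  only_u <- fake_samples(row, dat, n = 150)
  expect_equal(spatial_variance_fraction(only_u)$mean_pct, 100)
  row2 <- row
  row2[sprintf("u[%d]", 1:4)] <- 0
  row2[sprintf("v[%d]", 1:4)] <- c(0.1, -0.1, 0.2, -0.2)
  only_v <- fake_samples(row2, dat, n = 150)
  expect_equal(spatial_variance_fraction(only_v)$mean_pct, 0)
  row3 <- row2
  row3[sprintf("v[%d]", 1:4)] <- 0
  expect_error(spatial_variance_fraction(fake_samples(row3, dat, n = 150)),
               "zero")
})

test_that("generator fields reproduce a tuned structured share", {
  # tune tau_u2 : tau_v2 so the marginal structured share is 0.8 on the
  # 4 x 5 lattice (mean diagonal of the Laplacian pseudo-inverse = 0.249)
  lat <- generate_lattice(4, 5)
  g <- mean(diag(laplacian_pinv(lat$adjacency)))
  tau_u2 <- 0.4
  tau_v2 <- tau_u2 * g * (1 - 0.8) / 0.8
  set.seed(808)
  shares <- replicate(20, {
    f <- simulate_spatial_field(lat$adjacency, tau_u2, tau_v2)
    stats::var(f$u) / (stats::var(f$u) + stats::var(f$v))
  })
  expect_lt(abs(mean(shares) - 0.8), 0.1)
  expect_true(all(abs(shares - 0.8) < 0.25)) # single fields fluctuate more
})

test_that("choropleth export writes one valid file per period and round-trips", {
  reg <- desk_registry(seed = 213, n_patients = 700, J = 6, dims = c(2, 3))
  set.seed(213)
  dat <- hrr_data_from_registry(reg, "joint")
  fit <- run_mcmc(dat, sampler_config(600, 300, n_chains = 1, seed = 2))
  surf <- srr_surface(fit, max_draws = 200)
  dir <- withr::local_tempdir()
  files <- choropleth_export(surf, reg$lattice$polygons, dir = dir)
  expect_length(files, 3L)
  back <- read_geojson(files[2])
  expect_equal(nrow(back$properties), 6L)
  sl <- surf[surf$period == 2, ]
  expect_equal(back$properties$srr_mean, sl$srr_mean[order(sl$area_id)],
               tolerance = 1e-9)
  expect_error(choropleth_export(surf, reg$lattice$polygons[1:3]),
               "no polygon")
})

test_that("published summary counts load and rates reproduce", {
  counts <- vlcr_summary_counts()
  tot <- counts[counts$variable == "total", ]
  expect_equal(tot$survivors + tot$deaths, 6704)
  expect_equal(crude_rate(tot$deaths, tot$survivors + tot$deaths), 4.25)
})
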