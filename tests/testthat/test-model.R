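# Shared small fixture: 6-area registry with joint-protocol data.
model_fixture <- function(seed = 29, n = 400) {
  reg <- desk_registry(seed = seed, n_patients = n, J = 6, dims = c(2, 3))
  list(reg = reg, dat = hrr_data_from_registry(reg, "joint"))
}

random_params <- function(J, seed = 1) {
  set.seed(seed)
  p <- hrr_params(
    mu = stats::rnorm(1, -3, 0.5), beta = stats::rnorm(9, 0, 0.3),
    gamma = stats::rnorm(5, 0, 0.2), delta1 = stats::rnorm(1, 0, 0.1),
    delta2 = stats::rnorm(1, 0, 0.1), u = stats::rnorm(J, 0, 0.3),
    v = stats::rnorm(J, 0, 0.1), tau_u2 = 0.4, tau_v2 = 0.02
  )
  p$u <- p$u - mean(p$u)
  p
}

test_that("individual log-likelihood: null parameters give n * log(1/2)", {
  fx <- model_fixture()
  null_p <- hrr_params(mu = 0, beta = rep(0, 9), gamma = rep(0, 5),
                       u = rep(0, 6), v = rep(0, 6))
  expect_equal(individual_loglik(null_p, fx$dat),
               nrow(fx$reg$records) * log(0.5))
})

test_that("individual log-likelihood matches a per-record enumeration oracle", {
  fx <- model_fixture(seed = 7, n = 10)
  params <- random_params(6, seed = 2)
  rec <- fx$reg$records
  X <- stratum_design()
  Z <- area_design(fx$reg$area_covariates)
  k <- stratum_index(rec)
  ll <- 0
  for (i in seq_len(nrow(rec))) {
    j <- rec$area_id[i]
    ct <- rec$period[i] - 2
    eta <- params$mu + sum(X[k[i] + 1, ] * params$beta) +
      sum(Z[j, ] * params$gamma) + params$u[j] + params$v[j] +
      params$delta1 * ct + params$delta2 * ct^2
    p <- stats::plogis(eta)
    ll <- ll + ifelse(rec$outcome[i] == 1, log(p), log(1 - p))
  }
  expect_equal(individual_loglik(params, fx$dat), ll, tolerance = 1e-12)
})

test_that("Binomial aggregate cell with N = 1 reduces to a Bernoulli record", {
  lev <- covariate_levels()
  rec <- data.frame(
    patient_id = 1L, area_id = 1L, period = 2L,
    age_group = factor("gt60", levels = lev$age_group),
    mdm = factor("no", levels = lev$mdm),
    scs = factor("yes", levels = lev$scs),
    stage = factor("III", levels = lev$stage),
    comorbidity = factor("yes", levels = lev$comorbidity),
    ecog = factor("poor", levels = lev$ecog),
    outcome = 1L
  )
  lat <- generate_lattice(1, 2)
  ac <- flat_area_covariates(2)
  agg <- aggregate_counts(rec, 2, 3)
  sd <- estimate_f(rec, 2, 3)
  d_ind <- hrr_data(records = rec, area_covariates = ac,
                    adjacency = lat$adjacency)
  d_agg <- hrr_data(aggregates = agg, strata = sd, area_covariates = ac,
                    adjacency = lat$adjacency)
  params <- random_params(2, seed = 3)
  expect_equal(aggregate_loglik(params, d_agg, "binomial"),
               individual_loglik(params, d_ind), tolerance = 1e-12)
})

test_that("Poisson and Binomial aggregate likelihoods agree for rare outcomes", {
  fx <- model_fixture(seed = 41, n = 800)
  params <- random_params(6, seed = 4)
  params$mu <- -4.5 # keeps every cell risk well under 5%
  risks <- spathrr:::aggregate_risks(params, fx$dat)
  expect_true(all(risks < 0.05))
  lb <- aggregate_loglik(params, fx$dat, "binomial")
  lp <- aggregate_loglik(params, fx$dat, "poisson")
  expect_lt(abs(lb - lp) / abs(lb), 0.03)
})

test_that("joint log-likelihood is exactly additive and permutation-invariant", {
  fx <- model_fixture(seed = 53, n = 300)
  params <- random_params(6, seed = 5)
  expect_identical(
    joint_loglik(params, fx$dat),
    individual_loglik(params, fx$dat) + aggregate_loglik(params, fx$dat)
  )
  reg <- fx$reg
  perm <- sample(nrow(reg$records))
  reg2 <- reg
  reg2$records <- reg$records[perm, ]
  dat2 <- hrr_data_from_registry(reg2, "joint")
  expect_equal(joint_loglik(params, dat2), joint_loglik(params, fx$dat),
               tolerance = 1e-12)
})

test_that("joint log-likelihood with one empty part equals the other part", {
  reg <- desk_registry(seed = 61, n_patients = 200, J = 4, dims = c(2, 2))
  params <- random_params(4, seed = 6)
  d_ind <- hrr_data_from_registry(reg, "individual_only")
  d_agg <- hrr_data_from_registry(reg, "aggregate_only")
  expect_identical(joint_loglik(params, d_ind),
                   individual_loglik(params, d_ind))
  expect_identical(joint_loglik(params, d_agg),
                   aggregate_loglik(params, d_agg))
  expect_identical(aggregate_loglik(params, d_ind), 0)
  expect_identical(individual_loglik(params, d_agg), 0)
})

test_that("ecological consistency: constant covariates make the aggregate model binomial-exact", {
  lev <- covariate_levels()
  n <- 40
  rec <- data.frame(
    patient_id = seq_len(n), area_id = rep(1:2, each = n / 2), period = 1L,
    age_group = factor("gt60", levels = lev$age_group),
    mdm = factor("yes", levels = lev$mdm),
    scs = factor("no", levels = lev$scs),
    stage = factor("IV", levels = lev$stage),
    comorbidity = factor("no", levels = lev$comorbidity),
    ecog = factor("good", levels = lev$ecog),
    outcome = rep(c(0L, 1L), n / 2)
  )
  lat <- generate_lattice(1, 2)
  ac <- flat_area_covariates(2)
  agg <- aggregate_counts(rec, 2, 3)
  sd <- estimate_f(rec, 2, 3)
  d_ind <- hrr_data(records = rec, area_covariates = ac,
                    adjacency = lat$adjacency)
  d_agg <- hrr_data(aggregates = agg, strata = sd, area_covariates = ac,
                    adjacency = lat$adjacency)
  params <- random_params(2, seed = 7)
  lc <- sum(lchoose(agg$n[agg$n > 0], agg$deaths[agg$n > 0]))
  expect_equal(aggregate_loglik(params, d_agg, "binomial"),
               individual_loglik(params, d_ind) + lc, tolerance = 1e-12)
})

test_that("log-prior responds quadratically to coefficient changes", {
  lat <- generate_lattice(2, 3)
  pr <- prior_spec()
  p1 <- hrr_params(beta = c(0.5, rep(0, 8)), u = rep(0, 6), v = rep(0, 6))
  p2 <- p1
  p2$beta[1] <- 1.0
  d <- log_prior(p1, pr, lat$adjacency) - log_prior(p2, pr, lat$adjacency)
  expect_equal(d, 0.725 * (1.0^2 - 0.5^2) / 2, tolerance = 1e-12)
})

test_that("log-prior ICAR term matches the dense Laplacian quadratic form", {
  set.seed(77)
  adj <- generate_lattice(2, 3)$adjacency
  pr <- prior_spec()
  u <- stats::rnorm(6)
  u <- u - mean(u)
  base <- hrr_params(u = rep(0, 6), v = rep(0, 6), tau_u2 = 0.6)
  with_u <- base
  with_u$u <- u
  got <- log_prior(with_u, pr, adj) - log_prior(base, pr, adj)
  want <- -0.5 * as.numeric(t(u) %*% graph_laplacian(adj) %*% u) / 0.6
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("prior precision from the odds-ratio range", {
  expect_equal(round(prior_precision_from_or_range(0.1, 10, 0.95), 3), 0.725)
  expect_equal(prior_precision_from_or_range(exp(-stats::qnorm(0.975)),
                                             exp(stats::qnorm(0.975)), 0.95),
               1.0, tolerance = 1e-12)
  # independent numeric inversion: find precision whose implied interval is (0.5, 2)
  oracle <- stats::uniroot(function(prec) {
    stats::qnorm(0.975, sd = 1 / sqrt(prec)) - log(2)
  }, c(0.01, 100), tol = 1e-12)$root
  expect_equal(prior_precision_from_or_range(0.5, 2, 0.95), oracle,
               tolerance = 1e-8)
  expect_error(prior_precision_from_or_range(0.2, 10), "symmetric")
})

test_that("overdispersion check calibrates under the null and detects inflation", {
  set.seed(88)
  ncells <- 150
  n <- rep(60, ncells)
  p <- rep(0.05, ncells)
  m <- n * p
  # null: counts drawn from the fitted Poisson model
  agg_null <- data.frame(area_id = 1, period = 1, n = n,
                         deaths = stats::rpois(ncells, m))
  res <- overdispersion_statistic(agg_null, p, family = "poisson", B = 500)
  expect_false(res$flag)
  expect_lt(abs(res$ratio - 1), 0.5)
  # negative-binomial counts with variance twice the mean
  agg_nb <- data.frame(area_id = 1, period = 1, n = n,
                       deaths = stats::rnbinom(ncells, size = m, mu = m))
  res2 <- overdispersion_statistic(agg_nb, p, family = "poisson", B = 500)
  expect_true(res2$flag)
  expect_gt(res2$ratio, 1.3)
  # single occupied cell: zero residual degrees of freedom
  one <- data.frame(area_id = 1, period = 1, n = 50, deaths = 2)
  expect_error(overdispersion_statistic(one, 0.04), "zero df")
})

test_that("hrr_data validates indices and outcome coding", {
  reg <- desk_registry(seed = 91, n_patients = 100, J = 4, dims = c(2, 2))
  rec <- reg$records
  rec$outcome[1] <- 2L
  expect_error(
    hrr_data(records = rec, area_covariates = reg$area_covariates,
             adjacency = reg$lattice$adjacency),
    "binary"
  )
  rec <- reg$records
  rec$area_id[1] <- 9L
  expect_error(
    hrr_data(records = rec, area_covariates = reg$area_covariates,
             adjacency = reg$lattice$adjacency),
    "index mismatch"
  )
  agg <- reg$aggregates
  agg$deaths[1] <- agg$n[1] + 1L
  expect_error(
    hrr_data(aggregates = agg, strata = estimate_f(reg$records, 4, 3),
             area_covariates = reg$area_covariates,
             adjacency = reg$lattice$adjacency),
    "exceed"
  )
})
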