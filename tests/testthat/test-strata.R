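test_that("default schema yields 192 strata; degenerate schema yields 1", {
  defn <- strata_definition()
  expect_equal(defn$K, 192L)
  expect_equal(unname(defn$counts), c(2L, 2L, 2L, 4L, 2L, 3L))
  one <- strata_definition(list(a = "x", b = "y"))
  expect_equal(one$K, 1L)
  expect_equal(nrow(enumerate_strata(one)), 1L)
})

test_that("stratum index round-trips through the enumeration for all k", {
  defn <- strata_definition()
  strata <- enumerate_strata(defn)
  expect_equal(strata$stratum, 0:191)
  k_back <- stratum_index(strata, defn)
  expect_identical(k_back, 0:191)
  # lexicographic: first covariate most significant, last varies fastest
  expect_equal(as.character(strata$ecog[1:3]), c("good", "poor", "not_stated"))
  expect_equal(as.character(strata$age_group[c(1, 97)]), c("le60", "gt60"))
})

test_that("estimate_f reproduces hand-computed tables", {
  defn <- strata_definition()
  lev <- covariate_levels()
  base <- data.frame(
    area_id = 1L, period = 1L,
    age_group = factor("gt60", levels = lev$age_group),
    mdm = factor("yes", levels = lev$mdm),
    scs = factor("no", levels = lev$scs),
    stage = factor("IV", levels = lev$stage),
    comorbidity = factor("no", levels = lev$comorbidity),
    ecog = factor("good", levels = lev$ecog)
  )
  rec <- base[rep(1, 4), ]
  # all records in a single stratum
  sd1 <- estimate_f(rec, 1, 1, defn)
  expect_equal(sum(sd1$f[1, ] == 1), 1L)
  expect_equal(sum(sd1$f[1, ]), 1)
  # two strata with counts 3 and 1
  rec$stage[4] <- "I"
  sd2 <- estimate_f(rec, 1, 1, defn)
  ks <- stratum_index(rec, defn)
  expect_equal(sd2$f[1, ks[1] + 1], 0.75)
  expect_equal(sd2$f[1, ks[4] + 1], 0.25)
})

test_that("estimate_f matches a brute-force counting oracle", {
  reg <- desk_registry(seed = 17, n_patients = 500, J = 6, dims = c(2, 3))
  defn <- strata_definition()
  sd <- estimate_f(reg$records, 6, 3, defn)
  strata <- enumerate_strata(defn)
  rec <- reg$records
  for (probe in list(c(2, 1), c(5, 3), c(1, 2))) {
    sub <- rec[rec$area_id == probe[1] & rec$period == probe[2], ]
    jt <- (probe[1] - 1) * 3 + probe[2]
    expect_equal(sd$N[jt], nrow(sub))
    for (k in sample(0:191, 10)) {
      row <- strata[k + 1, ]
      n_k <- sum(
        sub$age_group == row$age_group & sub$mdm == row$mdm &
          sub$scs == row$scs & sub$stage == row$stage &
          sub$comorbidity == row$comorbidity & sub$ecog == row$ecog
      )
      expect_equal(sd$f[jt, k + 1] * max(sd$N[jt], 1), n_k)
    }
  }
})

test_that("strata_long serializes every cell with normalized rows", {
  reg <- desk_registry(seed = 23, n_patients = 300, J = 4, dims = c(2, 2))
  sd <- estimate_f(reg$records, 4, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  long <- strata_long(sd, file = f)
  expect_equal(nrow(long), 4 * 3 * 192)
  sums <- tapply(long$f, list(long$area_id, long$period), sum)
  occupied <- tapply(long$N, list(long$area_id, long$period), max) > 0
  expect_true(all(abs(sums[occupied] - 1) < 1e-12))
  back <- utils::read.csv(f)
  expect_equal(back$f, long$f)
})

test_that("marginal risk: identity and convex-combination examples", {
  defn <- strata_definition()
  params <- hrr_params(mu = -2, beta = stats::rnorm(9, 0, 0.3),
                       gamma = numeric(0), delta1 = 0.1, delta2 = -0.05)
  # single stratum: equals the individual risk of that stratum
  f <- rep(0, 192)
  f[41] <- 1
  X <- stratum_design(defn)
  eta40 <- params$mu + sum(X[41, ] * params$beta) + 0.3 + 0.1 +
    params$delta1 * (-1) + params$delta2 * 1
  expect_equal(
    marginal_risk(params, f, u_j = 0.3, v_j = 0.1, period = 1, defn = defn),
    stats::plogis(eta40)
  )
  # two equal-weight strata with risks 0.2 and 0.4 average to 0.3
  defn2 <- strata_definition(list(x = c("a", "b")))
  p2 <- hrr_params(mu = stats::qlogis(0.2),
                   beta = stats::qlogis(0.4) - stats::qlogis(0.2))
  expect_equal(
    marginal_risk(p2, c(0.5, 0.5), period = 2, n_periods = 3, defn = defn2),
    0.3
  )
  expect_error(marginal_risk(p2, c(0.6, 0.5), defn = defn2), "sum to 1")
})

test_that("marginal risk bounds: min and max stratum risks bracket p_jt", {
  set.seed(45)
  defn <- strata_definition()
  X <- stratum_design(defn)
  for (rep in 1:10) {
    params <- hrr_params(mu = stats::rnorm(1, -3, 1),
                         beta = stats::rnorm(9, 0, 0.5),
                         delta1 = stats::rnorm(1, 0, 0.2),
                         delta2 = stats::rnorm(1, 0, 0.2))
    u_j <- stats::rnorm(1, 0, 0.4)
    t <- sample(1:3, 1)
    w <- stats::rgamma(192, 0.5) ; f <- w / sum(w)
    p <- marginal_risk(params, f, u_j = u_j, period = t, defn = defn)
    eta <- params$mu + as.numeric(X %*% params$beta) + u_j +
      params$delta1 * (t - 2) + params$delta2 * (t - 2)^2
    risks <- stats::plogis(eta)
    expect_gte(p, min(risks) - 1e-12)
    expect_lte(p, max(risks) + 1e-12)
  }
})
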