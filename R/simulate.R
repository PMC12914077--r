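#' Default covariate marginals of the synthetic registry
#'
#' Category probabilities matching the published composition of the
#' Victorian lung-cancer SACT cohort (n = 6704): exact count fractions for
#' age group, MDM presentation, supportive-care screening, comorbidity and
#' ECOG status; the clinical-stage marginal is renormalized over stages
#' I-IV (the strata schema carries four stage categories).
#'
#' @return named list of probability vectors, each summing to 1.
#' @export
default_marginals <- function() {
  list(
    age_group = c(le60 = 1550, gt60 = 5154) / 6704,
    mdm = c(no = 2257, yes = 4447) / 6704,
    scs = c(no = 3726, yes = 2978) / 6704,
    stage = c(I = 199, II = 471, III = 1401, IV = 3766) / 5837,
    comorbidity = c(no = 3184, yes = 3520) / 6704,
    ecog = c(good = 4174, poor = 660, not_stated = 1870) / 6704
  )
}

#' Default true effect sizes of the generator
#'
#' Log odds-ratio coefficients used as the data-generating truth: the
#' individual-level effects are the adjusted odds ratios of the published
#' multivariable analysis (age > 60 = 1.06, MDM = 0.66, supportive-care
#' screening = 0.53, stage II/III/IV = 1.15/1.28/3.19, comorbidity = 1.12,
#' poor ECOG = 3.09); the ECOG not-stated coefficient ln(2.22) is the crude
#' contrast of that group against good ECOG; area-level coefficients are
#' modest socioeconomic-gradient and remoteness effects on the same scale.
#'
#' @return list with `beta` (named, ordered as [stratum_design()] columns),
#'   `gamma` (named, ordered as [area_design()] columns), `delta1`, `delta2`.
#' @export
default_true_effects <- function() {
  list(
    beta = c(
      age_group_gt60 = log(1.06),
      mdm_yes = log(0.66),
      scs_yes = log(0.53),
      stage_II = log(1.15),
      stage_III = log(1.28),
      stage_IV = log(3.19),
      comorbidity_yes = log(1.12),
      ecog_poor = log(3.09),
      ecog_not_stated = log(2.22)
    ),
    gamma = c(
      seifa_q2 = -0.15,
      seifa_q3 = -0.25,
      seifa_q4 = -0.47,
      remoteness_accessible = 0.10,
      remoteness_moderately_accessible = 0.15
    ),
    delta1 = -0.12,
    delta2 = 0.05
  )
}

#' Simulation configuration for the synthetic registry
#'
#' Defines the study conditions the generator emulates: 79 areas observed
#' over 3 periods, 6704 patients, the published covariate composition, and
#' effect sizes equal to the published adjusted odds ratios. The intercept
#' default (-3.955) is calibrated so the expected overall early-mortality
#' rate is 4.25% under the default effects; `tau_u2 = 0.4` and
#' `tau_v2 = 0.015` put roughly 88% of the spatial variation into the
#' structured (ICAR) component on the default map.
#'
#' @param n_areas number of areas (default 79).
#' @param lattice_dims optional `c(rows, cols)` for the toy map; when given,
#'   `rows * cols` must equal `n_areas`. Default `NULL` chooses a near-square
#'   grid truncated to `n_areas` cells.
#' @param n_periods number of time periods (default 3).
#' @param n_patients cohort size (default 6704).
#' @param covariate_marginals named list of per-covariate category
#'   probabilities (each summing to 1 within 1e-9).
#' @param true_effects list as [default_true_effects()].
#' @param mu intercept on the log-odds scale.
#' @param tau_u2 ICAR marginal variance scale (>= 0).
#' @param tau_v2 unstructured effect variance (>= 0).
#' @param period_probs allocation probabilities over periods (default equal).
#' @param area_probs optional allocation probabilities over areas (default
#'   equal; patients are allocated multinomially).
#' @param seed integer RNG seed or `NULL`.
#' @return object of class `hrr_sim_config`.
#' @export
sim_config <- function(n_areas = 79L, lattice_dims = NULL, n_periods = 3L,
                       n_patients = 6704L,
                       covariate_marginals = default_marginals(),
                       true_effects = default_true_effects(),
                       mu = -3.955, tau_u2 = 0.4, tau_v2 = 0.015,
                       period_probs = NULL, area_probs = NULL, seed = NULL) {
  n_areas <- as.integer(n_areas)
  n_periods <- as.integer(n_periods)
  n_patients <- as.integer(n_patients)
  if (n_areas < 1L || n_periods < 1L || n_patients < 1L) {
    stop("n_areas, n_periods and n_patients must be positive")
  }
  if (is.null(lattice_dims)) {
    rows <- max(1L, floor(sqrt(n_areas)))
    cols <- as.integer(ceiling(n_areas / rows))
    lattice_dims <- c(rows, cols)
  } else {
    lattice_dims <- as.integer(lattice_dims)
    if (prod(lattice_dims) != n_areas) {
      stop("when lattice_dims is given, rows * cols must equal n_areas")
    }
  }
  for (nm in names(covariate_marginals)) {
    p <- covariate_marginals[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("marginal '%s' must be probabilities summing to 1 (tol 1e-9)", nm))
    }
  }
  if (tau_u2 < 0 || tau_v2 < 0) stop("variances must be non-negative")
  if (is.null(period_probs)) period_probs <- rep(1 / n_periods, n_periods)
  if (length(period_probs) != n_periods || abs(sum(period_probs) - 1) > 1e-9) {
    stop("period_probs must be n_periods probabilities summing to 1")
  }
  if (!is.null(area_probs) &&
      (length(area_probs) != n_areas || abs(sum(area_probs) - 1) > 1e-9)) {
    stop("area_probs must be n_areas probabilities summing to 1")
  }
  structure(
    list(
      n_areas = n_areas, lattice_dims = lattice_dims, n_periods = n_periods,
      n_patients = n_patients, covariate_marginals = covariate_marginals,
      true_effects = true_effects, mu = mu, tau_u2 = tau_u2, tau_v2 = tau_v2,
      period_probs = period_probs, area_probs = area_probs,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "hrr_sim_config"
  )
}

#' Read / write a simulation configuration as YAML
#'
#' The file maps 1:1 onto the [sim_config()] fields.
#'
#' @param config an `hrr_sim_config`.
#' @param file path.
#' @export
write_sim_config <- function(config, file) {
  stopifnot(inherits(config, "hrr_sim_config"))
  x <- unclass(config)
  x$covariate_marginals <- lapply(x$covariate_marginals, as.list)
  x$true_effects$beta <- as.list(x$true_effects$beta)
  x$true_effects$gamma <- as.list(x$true_effects$gamma)
  yaml::write_yaml(x, file, precision = 15L)
  invisible(file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  x <- yaml::read_yaml(file)
  x$covariate_marginals <- lapply(x$covariate_marginals, unlist)
  x$true_effects$beta <- unlist(x$true_effects$beta)
  x$true_effects$gamma <- unlist(x$true_effects$gamma)
  do.call(sim_config, x)
}

#' Generate the synthetic patient population (outcomes unset)
#'
#' Covariates are drawn independently from the configured marginals;
#' patients are allocated to areas and periods multinomially (equal
#' probabilities unless configured otherwise). Identical configurations,
#' including the seed, give bit-identical output.
#'
#' @param config an [sim_config()].
#' @param use_config_seed set the RNG from `config$seed` (default `TRUE`;
#'   orchestration code that seeds once upstream passes `FALSE`).
#' @return data frame with `patient_id`, `area_id`, `period`, one column per
#'   covariate, and `outcome` (all `NA` until [simulate_outcomes()]).
#' @export
generate_population <- function(config, use_config_seed = TRUE) {
  stopifnot(inherits(config, "hrr_sim_config"))
  if (use_config_seed && !is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  area_probs <- config$area_probs
  if (is.null(area_probs)) area_probs <- rep(1 / config$n_areas, config$n_areas)
  rec <- data.frame(
    patient_id = seq_len(n),
    area_id = sample.int(config$n_areas, n, replace = TRUE, prob = area_probs),
    period = sample.int(config$n_periods, n, replace = TRUE,
                        prob = config$period_probs)
  )
  for (nm in names(config$covariate_marginals)) {
    p <- config$covariate_marginals[[nm]]
    rec[[nm]] <- factor(
      names(p)[sample.int(length(p), n, replace = TRUE, prob = p)],
      levels = names(p)
    )
  }
  rec$outcome <- NA_integer_
  rec
}

#' Generate area-level covariates
#'
#' Assigns each area a socioeconomic (IRSAD-style) quartile uniformly at
#' random and a remoteness class with the published cohort proportions
#' (highly accessible 89%, accessible 8%, moderately accessible 3%).
#' Assignments are spatially unstructured by design.
#'
#' @param config an [sim_config()].
#' @param use_config_seed see [generate_population()].
#' @return data frame with `area_id`, `seifa` (factor q1-q4, q1 = most
#'   disadvantaged), `remoteness`.
#' @export
generate_area_covariates <- function(config, use_config_seed = TRUE) {
  stopifnot(inherits(config, "hrr_sim_config"))
  if (use_config_seed && !is.null(config$seed)) set.seed(config$seed)
  J <- config$n_areas
  data.frame(
    area_id = seq_len(J),
    seifa = factor(sample(c("q1", "q2", "q3", "q4"), J, replace = TRUE),
                   levels = c("q1", "q2", "q3", "q4")),
    remoteness = factor(
      sample(c("highly_accessible", "accessible", "moderately_accessible"),
             J, replace = TRUE, prob = c(5965, 545, 194) / 6704),
      levels = c("highly_accessible", "accessible", "moderately_accessible")
    )
  )
}

#' Area-level design matrix
#'
#' Treatment coding with references "most disadvantaged quartile" (q1) and
#' "highly accessible"; columns ordered as the `gamma` defaults.
#'
#' @param area_covariates data frame from [generate_area_covariates()] (or
#'   equivalent), ordered/indexed by `area_id`.
#' @return a `J x 5` 0/1 matrix.
#' @export
area_design <- function(area_covariates) {
  a <- area_covariates[order(area_covariates$area_id), , drop = FALSE]
  cbind(
    seifa_q2 = as.numeric(a$seifa == "q2"),
    seifa_q3 = as.numeric(a$seifa == "q3"),
    seifa_q4 = as.numeric(a$seifa == "q4"),
    remoteness_accessible = as.numeric(a$remoteness == "accessible"),
    remoteness_moderately_accessible =
      as.numeric(a$remoteness == "moderately_accessible")
  )
}

#' Simulate the structured and unstructured spatial fields
#'
#' `u` is a zero-centered ICAR draw (see [simulate_icar()]); `v` is an
#' i.i.d. zero-mean normal field, centered after drawing.
#'
#' @param adj an [adjacency] object.
#' @param tau_u2,tau_v2 non-negative variance scales.
#' @param seed optional seed.
#' @return list with `u` and `v`.
#' @export
simulate_spatial_field <- function(adj, tau_u2, tau_v2, seed = NULL) {
  if (tau_u2 < 0 || tau_v2 < 0) stop("variances must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  u <- simulate_icar(adj, tau_u2)
  v <- stats::rnorm(adj$n_areas, 0, sqrt(tau_v2))
  if (tau_v2 > 0) v <- v - mean(v)
  list(u = u, v = v)
}

#' Simulate binary early-mortality outcomes
#'
#' Bernoulli outcomes from the full data-generating model:
#' \deqn{\mathrm{logit}(p_{ijt}) = \mu + \beta^\top x_{ijt} + \gamma^\top z_j
#'   + u_j + v_j + \delta_1 c(t) + \delta_2 c(t)^2,}
#' with `c(t)` the centered period index (t - 2 for three periods).
#'
#' @param records population from [generate_population()].
#' @param area_covariates data frame covering every occupied area.
#' @param field list with `u`, `v` of length `n_areas`.
#' @param config an [sim_config()].
#' @return `records` with the `outcome` column filled in.
#' @export
simulate_outcomes <- function(records, area_covariates, field, config) {
  stopifnot(inherits(config, "hrr_sim_config"))
  J <- config$n_areas
  if (length(field$u) != J || length(field$v) != J) {
    stop("field vectors must have length n_areas")
  }
  occupied <- sort(unique(records$area_id))
  missing <- setdiff(occupied, area_covariates$area_id)
  if (length(missing)) {
    stop(sprintf("missing area covariates for occupied area(s): %s",
                 paste(missing, collapse = ", ")))
  }
  defn <- strata_definition(lapply(config$covariate_marginals, names))
  X <- stratum_design(defn)
  k <- stratum_index(records, defn)
  Z <- area_design(area_covariates)
  eff <- config$true_effects
  beta <- eff$beta
  gamma <- if (is.null(eff$gamma)) numeric(ncol(Z)) else eff$gamma
  if (length(beta) != ncol(X)) stop("true_effects$beta length mismatch")
  ct <- records$period - (config$n_periods + 1) / 2
  eta <- config$mu + as.numeric(X %*% beta)[k + 1L] +
    as.numeric(Z %*% gamma)[records$area_id] +
    field$u[records$area_id] + field$v[records$area_id] +
    eff$delta1 * ct + eff$delta2 * ct^2
  records$outcome <- stats::rbinom(nrow(records), 1L, stats::plogis(eta))
  records
}

#' Aggregate outcomes to area-period counts
#'
#' @param records data frame with outcomes set.
#' @param n_areas,n_periods grid dimensions (defaults: observed maxima).
#' @return data frame over the full area x period grid with columns
#'   `area_id`, `period`, `n` (at risk) and `deaths`; empty cells carry
#'   zeros. Row order matches the `f` rows of [estimate_f()].
#' @export
aggregate_counts <- function(records, n_areas = max(records$area_id),
                             n_periods = max(records$period)) {
  if (anyNA(records$outcome)) stop("outcomes must be set before aggregation")
  if (!all(records$outcome %in% c(0L, 1L))) stop("outcomes must be binary")
  grid <- data.frame(
    area_id = rep(seq_len(n_areas), each = n_periods),
    period = rep(seq_len(n_periods), times = n_areas)
  )
  jt <- (records$area_id - 1L) * n_periods + records$period
  grid$n <- as.integer(tabulate(jt, nbins = n_areas * n_periods))
  deaths <- integer(n_areas * n_periods)
  sums <- rowsum(as.integer(records$outcome), jt)
  deaths[as.integer(rownames(sums))] <- as.integer(sums[, 1L])
  grid$deaths <- deaths
  grid
}

#' Simulate a complete synthetic registry
#'
#' One-call orchestration: toy lattice, area covariates, spatial fields,
#' population, outcomes and aggregates. The configuration seed is set once
#' at the start, so the whole bundle is reproducible.
#'
#' @param config an [sim_config()].
#' @return object of class `hrr_registry`: list with `config`, `lattice`,
#'   `area_covariates`, `field`, `records`, `aggregates`.
#' @export
simulate_registry <- function(config = sim_config()) {
  stopifnot(inherits(config, "hrr_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  lattice <- generate_lattice(config$lattice_dims[1L], config$lattice_dims[2L],
                              config$n_areas)
  area_cov <- generate_area_covariates(config, use_config_seed = FALSE)
  field <- simulate_spatial_field(lattice$adjacency, config$tau_u2,
                                  config$tau_v2)
  records <- generate_population(config, use_config_seed = FALSE)
  records <- simulate_outcomes(records, area_cov, field, config)
  structure(
    list(
      config = config, lattice = lattice, area_covariates = area_cov,
      field = field, records = records,
      aggregates = aggregate_counts(records, config$n_areas, config$n_periods)
    ),
    class = "hrr_registry"
  )
}

#' @export
print.hrr_registry <- function(x, ...) {
  cat(sprintf(
    "Synthetic registry: %d patients, %d areas x %d periods, %d deaths (%.2f%%)\n",
    nrow(x$records), x$config$n_areas, x$config$n_periods,
    sum(x$records$outcome), 100 * mean(x$records$outcome)
  ))
  invisible(x)
}

#' Write the registry records as CSV
#'
#' Fixed header: `patient_id, area_id, period, age_group, mdm, scs, stage,
#' comorbidity, ecog, outcome` (the default covariate schema).
#'
#' @param records records data frame.
#' @param file output path.
#' @export
write_registry_csv <- function(records, file) {
  cols <- c("patient_id", "area_id", "period", "age_group", "mdm", "scs",
            "stage", "comorbidity", "ecog", "outcome")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop(sprintf("records lack column(s): %s", paste(missing, collapse = ", ")))
  }
  utils::write.csv(records[, cols], file, row.names = FALSE)
  invisible(file)
}

#' Read registry records written by [write_registry_csv()]
#'
#' @param file CSV path.
#' @return records data frame with factor covariates in the default schema.
#' @export
read_registry_csv <- function(file) {
  rec <- utils::read.csv(file, stringsAsFactors = FALSE)
  lev <- covariate_levels()
  for (nm in names(lev)) rec[[nm]] <- factor(rec[[nm]], levels = lev[[nm]])
  rec
}
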