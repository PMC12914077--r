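#' Model parameter set
#'
#' Bundles every parameter of the spatiotemporal HRR model: intercept `mu`
#' (log-odds), individual-level log-OR vector `beta`, area-level vector
#' `gamma`, structured (`u`) and unstructured (`v`) area effects, linear and
#' quadratic temporal coefficients on the centered period index, and the
#' variance hyperparameters.
#'
#' @param mu intercept.
#' @param beta,gamma numeric coefficient vectors (possibly length 0).
#' @param delta1,delta2 temporal coefficients.
#' @param u,v numeric vectors of length J.
#' @param tau_u2,tau_v2 positive variances.
#' @return object of class `hrr_params`.
#' @export
hrr_params <- function(mu = 0, beta = numeric(0), gamma = numeric(0),
                       delta1 = 0, delta2 = 0, u = numeric(0), v = numeric(0),
                       tau_u2 = 1, tau_v2 = 1) {
  if (tau_u2 <= 0 || tau_v2 <= 0) stop("variance hyperparameters must be positive")
  if (length(u) != length(v)) stop("u and v must have equal length")
  structure(
    list(mu = mu, beta = beta, gamma = gamma, delta1 = delta1,
         delta2 = delta2, u = u, v = v, tau_u2 = tau_u2, tau_v2 = tau_v2),
    class = "hrr_params"
  )
}

#' Prior specification
#'
#' Non-intercept regression coefficients get zero-mean normal priors with
#' precision 0.725, the value implied by a 95% prior belief that an odds
#' ratio lies in (0.1, 10) (see [prior_precision_from_or_range()]); the
#' intercept gets an improper flat prior; the ICAR and unstructured
#' precisions `1/tau^2` get Gamma(shape, rate) hyperpriors (disease-mapping
#' default Gamma(0.5, 0.0005)).
#'
#' @param coef_precision normal prior precision for beta, gamma, delta.
#' @param tau_shape,tau_rate gamma hyperprior on the random-effect precisions.
#' @return object of class `hrr_prior`.
#' @export
prior_spec <- function(coef_precision = 0.725, tau_shape = 0.5,
                       tau_rate = 0.0005) {
  if (coef_precision <= 0 || tau_shape <= 0 || tau_rate <= 0) {
    stop("prior precisions and gamma hyperparameters must be positive")
  }
  structure(
    list(coef_precision = coef_precision, tau_shape = tau_shape,
         tau_rate = tau_rate),
    class = "hrr_prior"
  )
}

#' Normal prior precision implied by an odds-ratio range
#'
#' Solves for the precision of a zero-mean normal prior on a log odds ratio
#' such that the stated probability mass lies between `or_low` and
#' `or_high`: precision = (z / ln or_high)^2 with z the standard-normal
#' quantile at (1 + level) / 2. The range must be symmetric on the log
#' scale (`or_low * or_high = 1`).
#'
#' @param or_low,or_high odds-ratio interval endpoints.
#' @param level probability mass inside the interval (default 0.95).
#' @return scalar precision; `(0.1, 10, 0.95)` gives 0.725 to 3 decimals.
#' @export
prior_precision_from_or_range <- function(or_low, or_high, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (or_low <= 0 || or_high <= or_low) stop("need 0 < or_low < or_high")
  if (abs(or_low * or_high - 1) > 1e-8) {
    stop("odds-ratio range must be symmetric on the log scale (or_low * or_high = 1)")
  }
  (stats::qnorm((1 + level) / 2) / log(or_high))^2
}

# Centered period index c(t) = t - (T + 1) / 2.
center_period <- function(period, n_periods) period - (n_periods + 1) / 2

#' Assemble model data for the joint HRR likelihood
#'
#' Collapses individual records to (area, period, stratum) cells, aligns the
#' aggregate counts with the within-area covariate distribution, and builds
#' the stratum- and area-level design matrices. Either data level may be
#' empty (`NULL`): the joint likelihood then reduces to the other part.
#'
#' @param records individual records with outcomes, or `NULL`.
#' @param aggregates area-period count table (`area_id`, `period`, `n`,
#'   `deaths`) as from [aggregate_counts()], or `NULL`.
#' @param strata a `strata_distribution` from [estimate_f()]; required when
#'   `aggregates` is given.
#' @param area_covariates area covariate table covering all areas.
#' @param adjacency an [adjacency] object (defines J).
#' @param n_periods number of periods.
#' @param defn a [strata_definition()].
#' @return object of class `hrr_data`.
#' @export
hrr_data <- function(records = NULL, aggregates = NULL, strata = NULL,
                     area_covariates, adjacency, n_periods = 3L,
                     defn = strata_definition()) {
  stopifnot(inherits(adjacency, "adjacency"))
  J <- adjacency$n_areas
  n_periods <- as.integer(n_periods)
  X <- stratum_design(defn)
  Z <- area_design(area_covariates)
  if (nrow(Z) != J) stop("area_covariates must cover exactly the J areas")

  cells <- NULL
  if (!is.null(records) && nrow(records) > 0) {
    if (anyNA(records$outcome)) stop("individual records must carry outcomes")
    if (!all(records$outcome %in% c(0L, 1L))) stop("outcomes must be binary")
    if (any(records$area_id < 1L | records$area_id > J)) {
      stop("record area_id out of range: index mismatch with adjacency")
    }
    if (any(records$period < 1L | records$period > n_periods)) {
      stop("record period out of range")
    }
    k <- stratum_index(records, defn)
    jt <- (records$area_id - 1L) * n_periods + records$period
    key <- (jt - 1L) * defn$K + k
    agg_y <- rowsum(as.numeric(records$outcome), key)
    agg_n <- rowsum(rep(1, nrow(records)), key)
    ukey <- as.integer(rownames(agg_y))
    cells <- data.frame(
      jt = ukey %/% defn$K + 1L,
      k = ukey %% defn$K,
      y = as.numeric(agg_y[, 1L]),
      n = as.numeric(agg_n[, 1L])
    )
  }

  agg <- NULL
  if (!is.null(aggregates) && nrow(aggregates) > 0) {
    if (is.null(strata)) stop("aggregate data require a strata distribution")
    stopifnot(inherits(strata, "strata_distribution"))
    if (strata$n_areas != J || strata$n_periods != n_periods) {
      stop("strata distribution dimensions do not match: index mismatch")
    }
    if (any(aggregates$deaths > aggregates$n)) stop("deaths exceed at-risk count")
    if (any(aggregates$area_id < 1L | aggregates$area_id > J)) {
      stop("aggregate area_id out of range: index mismatch with adjacency")
    }
    keep <- aggregates$n > 0
    a <- aggregates[keep, , drop = FALSE]
    jt <- (a$area_id - 1L) * n_periods + a$period
    if (any(abs(rowSums(strata$f[jt, , drop = FALSE]) - 1) > 1e-9)) {
      stop("strata distribution has unnormalized rows for occupied cells")
    }
    agg <- list(jt = jt, y = a$deaths, n = a$n,
                lchoose = lchoose(a$n, a$deaths),
                f = strata$f[jt, , drop = FALSE])
  }

  structure(
    list(
      cells = cells, agg = agg, X = X, Z = Z, adjacency = adjacency,
      n_periods = n_periods, defn = defn, J = J,
      area_factors = area_covariates,
      ct = center_period(seq_len(n_periods), n_periods)
    ),
    class = "hrr_data"
  )
}

#' Convenience constructor from a synthetic registry
#'
#' `protocol = "joint"` feeds every record to the individual likelihood and
#' the same records, aggregated, to the aggregate likelihood (the published
#' analysis protocol). `protocol = "disjoint"` randomly splits the cohort:
#' `individual_fraction` of patients enter the individual likelihood, the
#' complement only through aggregate counts and the strata table (the
#' classic HRR configuration combining a survey with census margins; the two
#' likelihood parts then use disjoint patients and posterior uncertainty is
#' calibrated). `"individual_only"` and `"aggregate_only"` drop one part.
#'
#' @param registry an `hrr_registry` from [simulate_registry()].
#' @param protocol data-use protocol, see Details.
#' @param individual_fraction fraction for the disjoint split (default 0.5).
#' @return an [hrr_data()] object.
#' @export
hrr_data_from_registry <- function(registry,
                                   protocol = c("joint", "disjoint",
                                                "individual_only",
                                                "aggregate_only"),
                                   individual_fraction = 0.5) {
  stopifnot(inherits(registry, "hrr_registry"))
  protocol <- match.arg(protocol)
  cfg <- registry$config
  rec <- registry$records
  build <- function(ind, agg_rec) {
    aggregates <- NULL
    strata <- NULL
    if (!is.null(agg_rec)) {
      aggregates <- aggregate_counts(agg_rec, cfg$n_areas, cfg$n_periods)
      strata <- estimate_f(agg_rec, cfg$n_areas, cfg$n_periods)
    }
    hrr_data(records = ind, aggregates = aggregates, strata = strata,
             area_covariates = registry$area_covariates,
             adjacency = registry$lattice$adjacency,
             n_periods = cfg$n_periods)
  }
  switch(protocol,
    joint = build(rec, rec),
    individual_only = build(rec, NULL),
    aggregate_only = build(NULL, rec),
    disjoint = {
      idx <- sample.int(nrow(rec), size = round(individual_fraction * nrow(rec)))
      build(rec[idx, , drop = FALSE], rec[-idx, , drop = FALSE])
    }
  )
}

# Linear predictor pieces shared by the likelihood functions:
# a[jt] = mu + (Z gamma)_j + u_j + v_j + delta1 c(t) + delta2 c(t)^2 over the
# full area-major (j, t) grid, and b[k] = (X beta)_k over strata.
eta_components <- function(params, data) {
  J <- data$J
  TT <- data$n_periods
  zg <- if (length(params$gamma)) as.numeric(data$Z %*% params$gamma) else numeric(J)
  u <- if (length(params$u)) params$u else numeric(J)
  v <- if (length(params$v)) params$v else numeric(J)
  area_part <- params$mu + zg + u + v
  time_part <- params$delta1 * data$ct + params$delta2 * data$ct^2
  a <- rep(area_part, each = TT) + rep(time_part, times = J)
  b <- if (length(params$beta)) as.numeric(data$X %*% params$beta) else numeric(nrow(data$X))
  list(a = a, b = b)
}

#' Individual-level Bernoulli log-likelihood
#'
#' Sum of Bernoulli log-probabilities over the individual records (computed
#' on the collapsed (area, period, stratum) cells, which is exact because
#' records within a cell share the same risk).
#'
#' @param params an [hrr_params()].
#' @param data an [hrr_data()].
#' @return scalar log-likelihood (0 when there are no individual records).
#' @export
individual_loglik <- function(params, data) {
  stopifnot(inherits(data, "hrr_data"))
  if (is.null(data$cells)) return(0)
  e <- eta_components(params, data)
  eta <- e$a[data$cells$jt] + e$b[data$cells$k + 1L]
  # log p = -log(1 + exp(-eta)), log(1 - p) = -eta + log p
  logp <- -log1p(exp(-eta))
  sum(data$cells$y * logp + (data$cells$n - data$cells$y) * (logp - eta))
}

# Area-period marginal risks p_jt for the aggregate cells.
aggregate_risks <- function(params, data) {
  e <- eta_components(params, data)
  P <- stats::plogis(outer(e$a[data$agg$jt], e$b, "+"))
  rowSums(data$agg$f * P)
}

#' Aggregate-level log-likelihood (Binomial or Poisson)
#'
#' The aggregate outcome model: deaths in each occupied (area, period) cell
#' follow `Binomial(N_jt, p_jt)` (or, optionally, `Poisson(N_jt p_jt)`)
#' with `p_jt` the marginal risk obtained by integrating the individual
#' model over the within-area covariate distribution `f_jtk`. Both families
#' include their normalizing constants, so their values are comparable; for
#' rare outcomes the two agree closely.
#'
#' @inheritParams individual_loglik
#' @param family `"binomial"` or `"poisson"`.
#' @return scalar log-likelihood (0 when there are no aggregate data).
#' @export
aggregate_loglik <- function(params, data, family = c("binomial", "poisson")) {
  stopifnot(inherits(data, "hrr_data"))
  family <- match.arg(family)
  if (is.null(data$agg)) return(0)
  p <- pmin(pmax(aggregate_risks(params, data), 1e-12), 1 - 1e-12)
  y <- data$agg$y
  n <- data$agg$n
  if (family == "binomial") {
    sum(data$agg$lchoose + y * log(p) + (n - y) * log1p(-p))
  } else {
    lam <- n * p
    sum(y * log(lam) - lam - lgamma(y + 1))
  }
}

#' Joint HRR log-likelihood
#'
#' The full likelihood of the hierarchical related regression model is the
#' product of the individual-level and aggregate-level likelihoods; on the
#' log scale, their sum.
#'
#' @inheritParams aggregate_loglik
#' @export
joint_loglik <- function(params, data, family = c("binomial", "poisson")) {
  individual_loglik(params, data) + aggregate_loglik(params, data, family)
}

#' Joint log-prior density
#'
#' Normal log-densities (precision `coef_precision`) for beta, gamma and the
#' two temporal coefficients; the intrinsic CAR term for `u` (its quadratic
#' form plus the rank-deficiency-aware power of `tau_u2`; graph-dependent
#' constants dropped); i.i.d. normal for `v`; gamma log-densities for the
#' two precisions. The flat intercept prior contributes 0.
#'
#' @param params an [hrr_params()].
#' @param prior an [prior_spec()].
#' @param adj an [adjacency] object.
#' @return scalar log-density (up to constants not involving parameters).
#' @export
log_prior <- function(params, prior = prior_spec(), adj) {
  stopifnot(inherits(prior, "hrr_prior"), inherits(adj, "adjacency"))
  coefs <- c(params$beta, params$gamma, params$delta1, params$delta2)
  lp <- sum(stats::dnorm(coefs, 0, 1 / sqrt(prior$coef_precision), log = TRUE))
  if (length(params$u)) {
    rank <- icar_rank(adj)
    lp <- lp - rank / 2 * log(2 * pi * params$tau_u2) -
      icar_pairwise_ss(params$u, adj) / (2 * params$tau_u2)
  }
  if (length(params$v)) {
    lp <- lp + sum(stats::dnorm(params$v, 0, sqrt(params$tau_v2), log = TRUE))
  }
  lp + stats::dgamma(1 / params$tau_u2, prior$tau_shape, prior$tau_rate, log = TRUE) +
    stats::dgamma(1 / params$tau_v2, prior$tau_shape, prior$tau_rate, log = TRUE)
}

# Rank of the ICAR precision: connected areas minus number of non-singleton
# components (isolated areas are pinned at zero and carry no prior mass).
icar_rank <- function(adj) {
  active <- adj$counts > 0
  if (!any(active)) return(0L)
  length(which(active)) - length(unique(adj$components[active]))
}

#' Overdispersion check for the aggregate counts
#'
#' Pearson X^2 over residual degrees of freedom for the fitted family, with
#' a parametric-bootstrap p-value: `B` replicate count vectors are simulated
#' from the fitted model and the observed ratio is compared against the
#' replicate distribution. The flag is raised when the ratio is
#' significantly above 1 (p < 0.05), indicating the Poisson/Binomial mean
#' structure understates the variance.
#'
#' @param aggregates area-period count table (`n`, `deaths`).
#' @param fitted_p fitted per-cell risks (same length as `aggregates` rows).
#' @param family `"poisson"` or `"binomial"`.
#' @param B number of bootstrap replicates (default 1000).
#' @return list with `ratio`, `df`, `p_value`, `flag`.
#' @export
overdispersion_statistic <- function(aggregates, fitted_p,
                                     family = c("poisson", "binomial"),
                                     B = 1000L) {
  family <- match.arg(family)
  keep <- aggregates$n > 0
  y <- aggregates$deaths[keep]
  n <- aggregates$n[keep]
  p <- fitted_p[keep]
  df <- length(y) - 1L
  if (df <= 0L) stop("overdispersion check needs more than one occupied cell (zero df)")
  m <- n * p
  vfun <- if (family == "poisson") m else m * (1 - p)
  pearson <- function(yy) sum((yy - m)^2 / vfun)
  ratio <- pearson(y) / df
  reps <- vapply(seq_len(B), function(b) {
    yy <- if (family == "poisson") stats::rpois(length(m), m) else stats::rbinom(length(m), n, p)
    pearson(yy) / df
  }, numeric(1))
  p_value <- (1 + sum(reps >= ratio)) / (B + 1)
  list(ratio = ratio, df = df, p_value = p_value, flag = p_value < 0.05)
}
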