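#' Sampler configuration
#'
#' Defaults follow the documented full protocol (100,000 iterations with the
#' first 50,000 discarded as burn-in, two chains); examples and tests use a
#' desk-scale profile such as `sampler_config(10000, 5000)`.
#'
#' @param n_iterations total iterations per chain.
#' @param burn_in iterations discarded (must be `< n_iterations`).
#' @param n_chains number of chains (>= 2 needed for the BGR diagnostic).
#' @param thin thinning interval.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param target_accept Robbins-Monro target acceptance for scalar updates.
#' @param adapt_interval adaptation window length (burn-in only).
#' @return object of class `hrr_sampler_config`.
#' @export
sampler_config <- function(n_iterations = 100000L, burn_in = 50000L,
                           n_chains = 2L, thin = 1L, seed = 1L,
                           target_accept = 0.44, adapt_interval = 50L) {
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  if (n_chains < 1L) stop("need at least one chain")
  if (thin < 1L) stop("thin must be a positive integer")
  structure(
    list(n_iterations = n_iterations, burn_in = burn_in,
         n_chains = as.integer(n_chains), thin = as.integer(thin),
         seed = as.integer(seed), target_accept = target_accept,
         adapt_interval = as.integer(adapt_interval)),
    class = "hrr_sampler_config"
  )
}

# Flatten an hrr_data object into the arrays the C++ sampler consumes.
pack_model_data <- function(data, family = "binomial") {
  stopifnot(inherits(data, "hrr_data"))
  J <- data$J
  TT <- data$n_periods
  K <- data$defn$K
  adj <- data$adjacency

  if (!is.null(data$cells)) {
    cells <- data$cells # already area-major (sorted by jt, stratum)
    c_r <- cells$jt - 1L
    c_k <- cells$k
    c_y <- cells$y
    c_n <- cells$n
    area_of_cell <- (cells$jt - 1L) %/% TT
    cellA <- cumsum(c(0L, tabulate(area_of_cell + 1L, nbins = J)))
  } else {
    c_r <- c_k <- integer(0)
    c_y <- c_n <- numeric(0)
    cellA <- integer(J + 1L)
  }

  if (!is.null(data$agg)) {
    ag_r <- data$agg$jt - 1L
    ag_y <- data$agg$y
    ag_n <- data$agg$n
    ag_const <- if (family == "binomial") data$agg$lchoose else -lgamma(data$agg$y + 1)
    area_of_agg <- ag_r %/% TT
    aggA <- cumsum(c(0L, tabulate(area_of_agg + 1L, nbins = J)))
    fs_start <- 0L
    fs_k <- integer(0)
    fs_v <- numeric(0)
    for (i in seq_along(ag_r)) {
      nz <- which(data$agg$f[i, ] > 0)
      fs_k <- c(fs_k, nz - 1L)
      fs_v <- c(fs_v, data$agg$f[i, nz])
      fs_start <- c(fs_start, length(fs_k))
    }
  } else {
    ag_r <- integer(0)
    ag_y <- ag_n <- ag_const <- numeric(0)
    aggA <- integer(J + 1L)
    fs_start <- 0L
    fs_k <- integer(0)
    fs_v <- numeric(0)
  }

  ct <- data$ct
  le <- lap_eig(adj)
  list(
    J = J, T = TT, K = K, P = ncol(data$X), Q = ncol(data$Z),
    trans = translation_moves(data),
    c_r = as.integer(c_r), c_k = as.integer(c_k),
    c_y = as.numeric(c_y), c_n = as.numeric(c_n),
    cellA = as.integer(cellA),
    ag_r = as.integer(ag_r), ag_y = as.numeric(ag_y),
    ag_n = as.numeric(ag_n), ag_const = as.numeric(ag_const),
    aggA = as.integer(aggA),
    fs_start = as.integer(fs_start), fs_k = as.integer(fs_k),
    fs_v = as.numeric(fs_v),
    X = as.numeric(data$X), Z = as.numeric(data$Z),
    ct = as.numeric(ct), ct2 = as.numeric(ct^2),
    nbr_start = as.integer(cumsum(c(0L, adj$counts))),
    nbr_id = as.integer(unlist(adj$neighbors, use.names = FALSE) - 1L),
    comp = as.integer(adj$components - 1L),
    ncount = as.numeric(adj$counts),
    icar_rank = as.numeric(icar_rank(adj)),
    lap_eigval = le$values,
    lap_eigvec = as.numeric(le$vectors)
  )
}

# Spectral decomposition of the graph Laplacian, used by the sampler's
# blocked update of the variance partition between the structured and
# unstructured fields (eigenvalues below numerical zero are clamped to 0).
lap_eig <- function(adj) {
  e <- eigen(graph_laplacian(adj), symmetric = TRUE)
  e$values[e$values < max(e$values, 1) * 1e-9] <- 0
  e
}

# Reference-translation moves: joint Metropolis directions that shift the
# intercept against a dummy block (or the quadratic time term), changing the
# linear predictor only where the block is at its reference level.  These are
# ordinary symmetric MH kernels on the joint posterior; they decorrelate the
# intercept from weakly-observed reference categories (e.g. stage I).
translation_moves <- function(data) {
  TT <- data$n_periods
  st <- enumerate_strata(data$defn)
  Xnm <- colnames(data$X)
  Znm <- colnames(data$Z)
  moves <- list()
  for (nm in data$defn$names) {
    lev <- data$defn$levels[[nm]]
    if (length(lev) < 2L) next
    dec <- which(Xnm %in% paste(nm, lev[-1L], sep = "_")) - 1L
    if (!length(dec)) next
    items <- st$stratum[st[[nm]] == lev[1L]]
    moves[[length(moves) + 1L]] <- list(
      name = paste0("shift_", nm), side = 0L, items = as.integer(items),
      beta_dec = as.integer(dec), gamma_dec = integer(0), d2_scale = 0
    )
  }
  af <- data$area_factors
  for (nm in setdiff(names(af), "area_id")) {
    col <- af[[nm]]
    if (!is.factor(col)) next
    dec <- which(startsWith(Znm, paste0(nm, "_"))) - 1L
    if (!length(dec)) next
    ref_areas <- which(as.integer(col[order(af$area_id)]) == 1L)
    if (!length(ref_areas)) next
    rows <- as.integer(outer(seq_len(TT) - 1L, (ref_areas - 1L) * TT, "+"))
    moves[[length(moves) + 1L]] <- list(
      name = paste0("shift_", nm), side = 1L, items = sort(rows),
      beta_dec = integer(0), gamma_dec = as.integer(dec), d2_scale = 0
    )
  }
  ct2 <- data$ct^2
  nzv <- unique(ct2[ct2 != 0])
  zrows <- which(ct2 == 0)
  if (length(nzv) == 1L && length(zrows)) {
    rows <- as.integer(outer(zrows - 1L, (seq_len(data$J) - 1L) * TT, "+"))
    moves[[length(moves) + 1L]] <- list(
      name = "shift_delta2", side = 1L, items = sort(rows),
      beta_dec = integer(0), gamma_dec = integer(0), d2_scale = nzv
    )
  }
  moves
}

hrr_param_names <- function(data) {
  J <- data$J
  beta_nm <- colnames(data$X)
  gamma_nm <- colnames(data$Z)
  c("mu", beta_nm, gamma_nm, "delta1", "delta2",
    sprintf("u[%d]", seq_len(J)), sprintf("v[%d]", seq_len(J)),
    "tau_u2", "tau_v2")
}

# Storage layout of the C++ draws: mu, beta, gamma, delta1, delta2, u, v,
# taus -- whereas the MH acceptance vector is ordered mu, gamma, delta1,
# delta2, beta, u, v (the sampler's sweep order).
mh_accept_names <- function(data) {
  c("mu", colnames(data$Z), "delta1", "delta2", colnames(data$X),
    vapply(translation_moves(data), `[[`, character(1), "name"),
    sprintf("u[%d]", seq_len(data$J)), sprintf("v[%d]", seq_len(data$J)))
}

default_inits <- function(data, prior, chain) {
  P <- ncol(data$X)
  Q <- ncol(data$Z)
  J <- data$J
  n_fixed <- 1L + P + Q + 2L
  fixed <- numeric(n_fixed)
  if (chain > 1L) {
    # over-dispersed start: +/- one prior sd on the fixed effects
    sd0 <- 1 / sqrt(prior$coef_precision)
    fixed <- rep_len(c(sd0, -sd0), n_fixed)
  }
  # The spatial fields start at small random values rather than exactly
  # zero: a u that starts identically zero makes the first conjugate draw
  # of the ICAR precision explode (the pairwise sum of squares is 0),
  # which freezes the structured field for the rest of the chain.
  u0 <- center_by_component(stats::rnorm(J, 0, 0.1),
                            data$adjacency$components)
  u0[data$adjacency$counts == 0] <- 0
  v0 <- stats::rnorm(J, 0, 0.1)
  c(fixed, u0, v0, 1, 1)
}

#' Run the Metropolis-within-Gibbs sampler for the joint HRR model
#'
#' Scalar adaptive random-walk Metropolis updates for the intercept,
#' individual- and area-level coefficients and the two temporal terms;
#' single-site updates for each structured effect `u_j` (with its ICAR full
#' conditional as the prior part) and each unstructured effect `v_j`;
#' conjugate Gibbs draws for the two precision parameters. After every
#' sweep, `u` is re-centered within each connected component and the global
#' mean is absorbed into the flat intercept. Proposal scales adapt during
#' burn-in only (Robbins-Monro towards 0.44 acceptance) and are frozen
#' afterwards. Runs are deterministic given the configuration seed.
#'
#' @param data an [hrr_data()] object.
#' @param sampler an [sampler_config()].
#' @param prior an [prior_spec()].
#' @param family aggregate likelihood family, `"binomial"` or `"poisson"`.
#' @param inits optional list of per-chain initial parameter vectors.
#' @return object of class `hrr_samples`: per-chain draw matrices (post
#'   burn-in, thinned; columns named), per-chain deviance vectors, MH
#'   acceptance rates, and the inputs needed by downstream summaries.
#' @export
run_mcmc <- function(data, sampler = sampler_config(), prior = prior_spec(),
                     family = c("binomial", "poisson"), inits = NULL) {
  stopifnot(inherits(data, "hrr_data"), inherits(sampler, "hrr_sampler_config"))
  family <- match.arg(family)
  packed <- pack_model_data(data, family)
  fam_code <- if (family == "binomial") 0L else 1L
  nm <- hrr_param_names(data)
  chains <- vector("list", sampler$n_chains)
  deviance <- vector("list", sampler$n_chains)
  acceptance <- vector("list", sampler$n_chains)
  for (ch in seq_len(sampler$n_chains)) {
    set.seed(sampler$seed + ch - 1L)
    init <- if (is.null(inits)) default_inits(data, prior, ch) else inits[[ch]]
    if (length(init) != length(nm)) stop("initial value vector has wrong length")
    res <- cpp_run_chain(packed, unclass(prior), unclass(sampler), init, fam_code)
    colnames(res$draws) <- nm
    chains[[ch]] <- res$draws
    deviance[[ch]] <- as.numeric(res$deviance)
    acc <- as.numeric(res$acceptance)
    names(acc) <- mh_accept_names(data)
    acceptance[[ch]] <- acc
  }
  structure(
    list(chains = chains, deviance = deviance, acceptance = acceptance,
         param_names = nm, data = data, family = family, prior = prior,
         sampler = sampler),
    class = "hrr_samples"
  )
}

#' @export
print.hrr_samples <- function(x, ...) {
  cat(sprintf(
    "HRR posterior samples: %d chain(s) x %d draws, %d parameters (%s aggregate likelihood)\n",
    length(x$chains), nrow(x$chains[[1L]]), length(x$param_names), x$family
  ))
  invisible(x)
}

# Pooled draw matrix across chains.
pooled_draws <- function(samples, pars = NULL) {
  stopifnot(inherits(samples, "hrr_samples"))
  d <- do.call(rbind, samples$chains)
  if (!is.null(pars)) d <- d[, pars, drop = FALSE]
  d
}

#' Posterior summaries
#'
#' Means, standard deviations and equal-tailed credible intervals from the
#' pooled post-burn-in draws. With `or_scale = TRUE` the draws are
#' exponentiated before summarizing (odds-ratio scale).
#'
#' @param samples an `hrr_samples` object (or a draw matrix with named
#'   columns).
#' @param level credible level (default 0.95).
#' @param pars optional character vector of parameters.
#' @param or_scale summarize `exp(draws)` instead of the draws.
#' @return data frame with columns `parameter`, `mean`, `sd`, `median`,
#'   `lower`, `upper`.
#' @export
posterior_summary <- function(samples, level = 0.95, pars = NULL,
                              or_scale = FALSE) {
  d <- if (inherits(samples, "hrr_samples")) pooled_draws(samples, pars)
       else as.matrix(samples)
  if (!is.null(pars) && !inherits(samples, "hrr_samples")) {
    d <- d[, pars, drop = FALSE]
  }
  if (nrow(d) < 100L) stop("need at least 100 retained draws to summarize")
  if (or_scale) d <- exp(d)
  alpha <- (1 - level) / 2
  qs <- t(apply(d, 2L, stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
                names = FALSE))
  data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2L, stats::sd),
    median = qs[, 2L],
    lower = qs[, 1L],
    upper = qs[, 3L],
    row.names = NULL
  )
}

#' Adaptive scalar random-walk Metropolis sampler
#'
#' General-purpose single-parameter sampler used for reference checks
#' (e.g. conjugate toy posteriors): normal random-walk proposals whose
#' scale adapts during burn-in by Robbins-Monro towards a target
#' acceptance rate, frozen afterwards.
#'
#' @param logpost function of a scalar returning the log posterior density
#'   (up to a constant).
#' @param init starting value.
#' @param n_iterations,burn_in chain length and discarded prefix.
#' @param target_accept,adapt_interval adaptation settings.
#' @param init_step initial proposal standard deviation.
#' @return list with `draws` (post burn-in), `acceptance`, `step`.
#' @export
rw_metropolis <- function(logpost, init = 0, n_iterations = 10000L,
                          burn_in = n_iterations %/% 2L, target_accept = 0.44,
                          adapt_interval = 50L, init_step = 1) {
  theta <- init
  lp <- logpost(theta)
  if (!is.finite(lp)) stop("log posterior not finite at the initial value")
  lstep <- log(init_step)
  draws <- numeric(n_iterations - burn_in)
  acc_win <- 0L
  acc_tot <- 0L
  win <- 0L
  for (iter in seq_len(n_iterations)) {
    prop <- theta + exp(lstep) * stats::rnorm(1)
    lp_new <- logpost(prop)
    if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp) {
      theta <- prop
      lp <- lp_new
      acc_win <- acc_win + 1L
      if (iter > burn_in) acc_tot <- acc_tot + 1L
    }
    if (iter <= burn_in && iter %% adapt_interval == 0L) {
      win <- win + 1L
      lstep <- lstep + (acc_win / adapt_interval - target_accept) / sqrt(win)
      acc_win <- 0L
    } else if (iter %% adapt_interval == 0L) {
      acc_win <- 0L
    }
    if (iter > burn_in) draws[iter - burn_in] <- theta
  }
  list(draws = draws, acceptance = acc_tot / (n_iterations - burn_in),
       step = exp(lstep))
}
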