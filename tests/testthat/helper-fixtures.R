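# Shared fixtures and independent oracles used across the test files.

# Minimal area-covariate table (all reference levels).
flat_area_covariates <- function(J) {
  data.frame(
    area_id = seq_len(J),
    seifa = factor(rep("q1", J), levels = c("q1", "q2", "q3", "q4")),
    remoteness = factor(rep("highly_accessible", J),
                        levels = c("highly_accessible", "accessible",
                                   "moderately_accessible"))
  )
}

# Random symmetric adjacency on J nodes with edge probability p.
random_adjacency <- function(J, p = 0.5) {
  W <- matrix(0L, J, J)
  if (J > 1) {
    for (i in seq_len(J - 1)) {
      for (j in seq((i + 1), J)) {
        if (stats::runif(1) < p) W[i, j] <- W[j, i] <- 1L
      }
    }
  }
  adjacency(apply(W, 1L, function(r) which(r == 1L), simplify = FALSE))
}

# Dense-matrix oracle for the ICAR conditional: condition the Gaussian with
# precision Q = L / tau on all coordinates but i (standard GMRF identity,
# computed from the precision matrix rather than neighbor lists).
icar_conditional_oracle <- function(u, i, adj, tau_u2) {
  Qm <- graph_laplacian(adj) / tau_u2
  list(mean = -(Qm[i, -i, drop = FALSE] %*% u[-i])[1L] / Qm[i, i],
       variance = 1 / Qm[i, i])
}

# Quadratic-form oracle for the unnormalized ICAR log-density.
icar_logdensity_oracle <- function(u, adj, tau_u2) {
  L <- graph_laplacian(adj)
  -0.5 * as.numeric(t(u) %*% L %*% u) / tau_u2
}

# Laplacian pseudo-inverse (dense eigenvalue route).
laplacian_pinv <- function(adj) {
  L <- graph_laplacian(adj)
  e <- eigen(L, symmetric = TRUE)
  pos <- e$values > max(e$values, 1) * 1e-9
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

# Small simulated registry shared by several tests.
desk_registry <- function(seed = 11, n_patients = 2000, J = 20,
                          dims = c(4, 5)) {
  simulate_registry(sim_config(
    n_areas = J, lattice_dims = dims, n_patients = n_patients, seed = seed
  ))
}

# Hand-rolled hrr_samples object with externally supplied draws, for
# reporting functions that only need draw matrices plus model data.
fake_samples <- function(draw_row, data, n = 200, jitter = 0,
                         family = "binomial") {
  nm <- spathrr:::hrr_param_names(data)
  stopifnot(length(draw_row) == length(nm))
  ch <- matrix(rep(draw_row, each = n), nrow = n,
               dimnames = list(NULL, nm))
  if (jitter > 0) {
    jt <- matrix(stats::rnorm(length(ch), 0, jitter), nrow = n)
    ch <- ch + jt
  }
  structure(
    list(chains = list(ch), deviance = list(rep(0, n)),
         acceptance = list(numeric(0)), param_names = nm, data = data,
         family = family, prior = prior_spec(), sampler = NULL),
    class = "hrr_samples"
  )
}

# Parameter vector (draw layout) from an hrr_params object.
params_to_row <- function(params, data) {
  c(params$mu, params$beta, params$gamma, params$delta1, params$delta2,
    params$u, params$v, params$tau_u2, params$tau_v2)
}
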