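#' Full conditional of one ICAR effect
#'
#' Under the Besag intrinsic CAR prior, the full conditional of \eqn{u_i}
#' given the remaining effects is normal with mean the average of the
#' neighboring values and variance \eqn{\tau_u^2 / n_i}, where \eqn{n_i} is
#' the neighbor count.
#'
#' @param u numeric vector of spatial effects.
#' @param i area index.
#' @param adj an [adjacency] object.
#' @param tau_u2 conditional variance scale (> 0).
#' @return list with `mean` and `variance`.
#' @export
icar_conditional <- function(u, i, adj, tau_u2) {
  stopifnot(inherits(adj, "adjacency"), length(u) == adj$n_areas)
  if (tau_u2 <= 0) stop("tau_u2 must be positive")
  ni <- adj$counts[i]
  if (ni < 1L) {
    stop(sprintf(
      "area %d is isolated; the ICAR conditional is undefined (use the isolated-area rule u = 0)", i
    ))
  }
  list(mean = mean(u[adj$neighbors[[i]]]), variance = tau_u2 / ni)
}

#' Unnormalized ICAR log-density
#'
#' Pairwise-difference form of the Besag intrinsic CAR prior:
#' \deqn{-\frac{1}{2\tau_u^2} \sum_{i<j:\ w_{ij}=1} (u_i - u_j)^2,}
#' equal to \eqn{-u^\top L u / (2\tau_u^2)} with \eqn{L} the graph Laplacian.
#' The value is invariant to adding a constant within a connected component
#' and is maximal (zero) for constant fields.
#'
#' @inheritParams icar_conditional
#' @return scalar log-density up to an additive constant.
#' @export
icar_logdensity_unnorm <- function(u, adj, tau_u2) {
  if (tau_u2 <= 0) stop("tau_u2 must be positive")
  -icar_pairwise_ss(u, adj) / (2 * tau_u2)
}

# Sum of squared differences over adjacent pairs, each pair counted once.
icar_pairwise_ss <- function(u, adj) {
  stopifnot(inherits(adj, "adjacency"), length(u) == adj$n_areas)
  s <- 0
  for (i in seq_len(adj$n_areas)) {
    nb <- adj$neighbors[[i]]
    nb <- nb[nb > i]
    if (length(nb)) s <- s + sum((u[i] - u[nb])^2)
  }
  s
}

#' Simulate a zero-centered ICAR field
#'
#' Draws \eqn{u \sim N(0, \tau_u^2 L^{+})} where \eqn{L^{+}} is the
#' Moore-Penrose pseudo-inverse of the graph Laplacian, via the spectral
#' decomposition of \eqn{L}: independent normal coordinates on the
#' eigenvectors with positive eigenvalue \eqn{\lambda} have variance
#' \eqn{\tau_u^2/\lambda}. Null-space eigenvectors (one per connected
#' component) are excluded, so the draw sums to zero within every component;
#' isolated areas get \eqn{u_j = 0}. Component means are subtracted once more
#' so centering is exact in floating point.
#'
#' @param adj an [adjacency] object.
#' @param tau_u2 marginal variance scale (>= 0); 0 returns the zero field.
#' @return numeric vector of length `adj$n_areas`.
#' @export
simulate_icar <- function(adj, tau_u2) {
  stopifnot(inherits(adj, "adjacency"))
  if (tau_u2 < 0) stop("tau_u2 must be non-negative")
  J <- adj$n_areas
  if (tau_u2 == 0) return(numeric(J))
  L <- graph_laplacian(adj)
  e <- eigen(L, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  if (!any(pos)) return(numeric(J)) # edgeless graph
  coefs <- stats::rnorm(sum(pos), 0, sqrt(tau_u2 / e$values[pos]))
  u <- as.numeric(e$vectors[, pos, drop = FALSE] %*% coefs)
  center_by_component(u, adj$components)
}

# Exact per-component centering (components of size 1 end at exactly 0).
center_by_component <- function(u, components) {
  for (cpt in unique(components)) {
    idx <- components == cpt
    u[idx] <- u[idx] - mean(u[idx])
  }
  u
}
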