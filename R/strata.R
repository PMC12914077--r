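#' Individual covariate schema of the early-mortality model
#'
#' Default covariate set and category levels: age group (<= 60 / > 60 years),
#' multidisciplinary-meeting presentation, supportive-care screening,
#' clinical stage at diagnosis (I-IV), comorbidity, and ECOG performance
#' status (good / poor / not stated). The first level of each covariate is
#' the reference category of the design encoding.
#'
#' @return named list of character level vectors.
#' @export
covariate_levels <- function() {
  list(
    age_group = c("le60", "gt60"),
    mdm = c("no", "yes"),
    scs = c("no", "yes"),
    stage = c("I", "II", "III", "IV"),
    comorbidity = c("no", "yes"),
    ecog = c("good", "poor", "not_stated")
  )
}

#' Define the covariate strata
#'
#' A stratum is one combination of individual-level covariate categories;
#' with the default schema there are 2 x 2 x 2 x 4 x 2 x 3 = 192 strata.
#'
#' @param levels named list of character level vectors (default
#'   [covariate_levels()]).
#' @return object of class `strata_definition` with elements `names`,
#'   `levels`, `counts`, `K`.
#' @export
strata_definition <- function(levels = covariate_levels()) {
  counts <- vapply(levels, length, integer(1))
  if (any(counts < 1L)) stop("every covariate needs at least one category")
  structure(
    list(names = names(levels), levels = levels, counts = counts,
         K = prod(counts)),
    class = "strata_definition"
  )
}

#' Enumerate the strata in lexicographic order
#'
#' Strata are indexed `0 .. K-1` lexicographically with the first covariate
#' most significant (the last covariate varies fastest). The mapping between
#' stratum indices and covariate tuples is a bijection; see
#' [stratum_index()] for the inverse direction.
#'
#' @param defn a [strata_definition()].
#' @return data frame with column `stratum` (0-based index) and one factor
#'   column per covariate.
#' @export
enumerate_strata <- function(defn = strata_definition()) {
  stopifnot(inherits(defn, "strata_definition"))
  grid <- expand.grid(rev(defn$levels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(defn$levels)), drop = FALSE]
  out <- cbind(stratum = seq_len(nrow(grid)) - 1L, grid)
  for (nm in defn$names) out[[nm]] <- factor(out[[nm]], levels = defn$levels[[nm]])
  out
}

#' Map covariate tuples to stratum indices
#'
#' @param covariates data frame carrying the covariate columns named in
#'   `defn` (character or factor, values among the declared levels).
#' @param defn a [strata_definition()].
#' @return integer vector of 0-based stratum indices.
#' @export
stratum_index <- function(covariates, defn = strata_definition()) {
  stopifnot(inherits(defn, "strata_definition"))
  k <- integer(nrow(covariates))
  for (nm in defn$names) {
    if (is.null(covariates[[nm]])) stop(sprintf("missing covariate column '%s'", nm))
    li <- match(as.character(covariates[[nm]]), defn$levels[[nm]]) - 1L
    if (anyNA(li)) stop(sprintf("undeclared level in covariate '%s'", nm))
    k <- k * length(defn$levels[[nm]]) + li
  }
  k
}

#' Individual-level design matrix per stratum
#'
#' Treatment (reference-category) coding of the covariate tuple of every
#' stratum: one indicator column per non-reference level, named
#' `<covariate>_<level>`. Row `k + 1` encodes stratum `k`.
#'
#' @param defn a [strata_definition()].
#' @return a `K x P` 0/1 matrix.
#' @export
stratum_design <- function(defn = strata_definition()) {
  strata <- enumerate_strata(defn)
  cols <- list()
  for (nm in defn$names) {
    lev <- defn$levels[[nm]]
    for (l in lev[-1L]) {
      cols[[paste(nm, l, sep = "_")]] <- as.numeric(strata[[nm]] == l)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- NULL
  X
}

#' Estimate the within-area joint covariate distribution f_jtk
#'
#' Empirical per (area, period) probability table over the covariate strata:
#' `f[jt, k] = #(records in area j, period t with stratum k) / N_jt`. Cells
#' with no records have `N_jt = 0` and an all-zero (undefined) `f` row;
#' they contribute no aggregate likelihood terms downstream.
#'
#' @param records data frame with `area_id`, `period` and the covariate
#'   columns of `defn`.
#' @param n_areas,n_periods grid dimensions (areas indexed `1..n_areas`,
#'   periods `1..n_periods`).
#' @param defn a [strata_definition()].
#' @return object of class `strata_distribution`: list with `f` (a
#'   `(n_areas * n_periods) x K` matrix, rows in area-major order), `N`
#'   (at-risk counts), `n_areas`, `n_periods`, `defn`. Row `jt` of `f`
#'   corresponds to `area j = (jt - 1) %/% n_periods + 1`,
#'   `period t = (jt - 1) %% n_periods + 1`.
#' @export
estimate_f <- function(records, n_areas, n_periods, defn = strata_definition()) {
  k <- stratum_index(records, defn)
  jt <- (records$area_id - 1L) * n_periods + records$period
  if (any(records$area_id < 1L | records$area_id > n_areas)) {
    stop("area_id out of range")
  }
  if (any(records$period < 1L | records$period > n_periods)) {
    stop("period out of range")
  }
  JT <- n_areas * n_periods
  counts <- matrix(0, JT, defn$K)
  idx <- cbind(jt, k + 1L)
  for (r in seq_len(nrow(idx))) {
    counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1
  }
  N <- rowSums(counts)
  f <- counts
  nz <- N > 0
  f[nz, ] <- f[nz, , drop = FALSE] / N[nz]
  structure(
    list(f = f, N = N, n_areas = n_areas, n_periods = n_periods, defn = defn),
    class = "strata_distribution"
  )
}

#' Long-format serialization of a strata distribution
#'
#' @param sd a `strata_distribution` from [estimate_f()].
#' @param file optional CSV path; when given the table is also written out.
#' @return data frame with columns `area_id`, `period`, `stratum`, `f`, `N`
#'   (rows with `N = 0` are kept, with `f = 0`).
#' @export
strata_long <- function(sd, file = NULL) {
  stopifnot(inherits(sd, "strata_distribution"))
  JT <- sd$n_areas * sd$n_periods
  area <- rep((seq_len(JT) - 1L) %/% sd$n_periods + 1L, each = sd$defn$K)
  period <- rep((seq_len(JT) - 1L) %% sd$n_periods + 1L, each = sd$defn$K)
  out <- data.frame(
    area_id = area,
    period = period,
    stratum = rep(seq_len(sd$defn$K) - 1L, times = JT),
    f = as.vector(t(sd$f)),
    N = rep(sd$N, each = sd$defn$K)
  )
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Marginalize individual risk over the within-area covariate distribution
#'
#' The area-period average risk is the exact convex combination
#' \eqn{p_{jt} = \sum_k f_{jtk}\, p_{jtk}} of the stratum-level risks
#' \eqn{p_{jtk} = \mathrm{logit}^{-1}(\mu + X_k\beta + \gamma^\top z_j + u_j
#' + v_j + \delta_1 c(t) + \delta_2 c(t)^2)}, with `c(t)` the centered
#' period index. This marginalization is the ecological-bias correction at
#' the heart of the hierarchical related regression model.
#'
#' @param params an [hrr_params()] parameter set.
#' @param f_jt numeric vector of stratum probabilities (length K, sums to 1
#'   within 1e-9).
#' @param z_j numeric area-level design row (length matching
#'   `params$gamma`; may be length 0).
#' @param u_j,v_j structured and unstructured area effects (scalars).
#' @param period 1-based period index.
#' @param n_periods number of periods (default 3).
#' @param defn a [strata_definition()] (used for the stratum design).
#' @return scalar risk in `[min_k p_jtk, max_k p_jtk]`.
#' @export
marginal_risk <- function(params, f_jt, z_j = numeric(0), u_j = 0, v_j = 0,
                          period = 1L, n_periods = 3L,
                          defn = strata_definition()) {
  if (abs(sum(f_jt) - 1) > 1e-9) stop("stratum probabilities must sum to 1")
  if (any(f_jt < 0)) stop("stratum probabilities must be non-negative")
  X <- stratum_design(defn)
  if (length(f_jt) != nrow(X)) stop("f has the wrong number of strata")
  ct <- period - (n_periods + 1) / 2
  eta <- params$mu + as.numeric(X %*% params$beta) +
    sum(z_j * params$gamma) + u_j + v_j +
    params$delta1 * ct + params$delta2 * ct^2
  sum(f_jt * stats::plogis(eta))
}
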