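#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Standard between/within variance decomposition for `m >= 2` chains of
#' equal length `n`:
#' \deqn{\hat R = \sqrt{\frac{(n-1)W/n + B/n}{W}},}
#' with `W` the mean within-chain variance and `B/n` the variance of the
#' chain means. Identical chains give exactly 1; values near 1 indicate
#' convergence (the automated flag threshold used elsewhere in the package
#' is 1.1).
#'
#' @param chains a numeric matrix (iterations x chains) or a list of
#'   equal-length numeric vectors.
#' @return scalar PSRF.
#' @export
bgr_statistic <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2L) stop("the BGR statistic needs at least two chains")
  if (n < 10L) stop("chains are too short (need length >= 10)")
  W <- mean(apply(chains, 2L, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  if (W == 0) {
    return(if (B_over_n == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Batch-means Monte Carlo standard error
#'
#' The chain is split into `n_batches` consecutive batches (default 50, the
#' BUGS convention); the Monte Carlo standard error of the posterior mean is
#' the standard deviation of the batch means divided by the square root of
#' the number of batches. The pass rule compares the MC error to the
#' posterior standard deviation: a ratio below 5% indicates the chain is
#' long enough for stable estimates.
#'
#' @param chain numeric vector of length >= 400.
#' @param n_batches number of batches.
#' @return list with `mc_se`, `ratio` (MC error / posterior sd; `NA` for a
#'   degenerate chain), `pass` (`FALSE` when degenerate or ratio >= 0.05).
#' @export
mc_error <- function(chain, n_batches = 50L) {
  n <- length(chain)
  if (n < 400L) stop("chain too short for batch-means MC error (need >= 400)")
  bs <- n %/% n_batches
  chain_t <- chain[seq_len(bs * n_batches)]
  bm <- colMeans(matrix(chain_t, nrow = bs))
  mc_se <- stats::sd(bm) / sqrt(n_batches)
  post_sd <- stats::sd(chain)
  if (post_sd == 0) {
    return(list(mc_se = mc_se, ratio = NA_real_, pass = FALSE))
  }
  ratio <- mc_se / post_sd
  list(mc_se = mc_se, ratio = ratio, pass = is.finite(ratio) && ratio < 0.05)
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{\bar D} the posterior mean deviance,
#' \eqn{p_D = \bar D - D(\bar\theta)} the effective number of parameters,
#' and \eqn{D(\theta) = -2 \log L(\theta)}. For fitted HRR models the
#' deviance uses the same joint likelihood (and aggregate family) as the
#' fit; the generic method accepts a draw matrix plus a log-likelihood
#' function.
#'
#' @param object an `hrr_samples` fit, or a draw matrix (rows = draws).
#' @param ... passed to methods.
#' @return list with `Dbar`, `D_at_mean`, `pD`, `DIC`, and
#'   `n_nonfinite` (count of non-finite deviance draws, excluded from
#'   `Dbar`).
#' @export
dic <- function(object, ...) UseMethod("dic")

#' @rdname dic
#' @param loglik function mapping a parameter vector (a draw row) to a
#'   scalar log-likelihood.
#' @export
dic.default <- function(object, loglik, ...) {
  draws <- as.matrix(object)
  dev <- apply(draws, 1L, function(th) -2 * loglik(th))
  finite <- is.finite(dev)
  Dbar <- mean(dev[finite])
  D_at_mean <- -2 * loglik(colMeans(draws[finite, , drop = FALSE]))
  pD <- Dbar - D_at_mean
  list(Dbar = Dbar, D_at_mean = D_at_mean, pD = pD, DIC = Dbar + pD,
       n_nonfinite = sum(!finite))
}

#' @rdname dic
#' @export
dic.hrr_samples <- function(object, ...) {
  dev <- unlist(object$deviance, use.names = FALSE)
  finite <- is.finite(dev)
  Dbar <- mean(dev[finite])
  pm <- colMeans(pooled_draws(object))
  D_at_mean <- -2 * joint_loglik(unpack_params(pm, object$data), object$data,
                                 object$family)
  pD <- Dbar - D_at_mean
  list(Dbar = Dbar, D_at_mean = D_at_mean, pD = pD, DIC = Dbar + pD,
       n_nonfinite = sum(!finite))
}

# Rebuild an hrr_params object from a named draw / posterior-mean vector.
unpack_params <- function(x, data) {
  P <- ncol(data$X)
  Q <- ncol(data$Z)
  J <- data$J
  hrr_params(
    mu = x[["mu"]],
    beta = unname(x[1L + seq_len(P)]),
    gamma = unname(x[1L + P + seq_len(Q)]),
    delta1 = x[["delta1"]],
    delta2 = x[["delta2"]],
    u = unname(x[3L + P + Q + seq_len(J)]),
    v = unname(x[3L + P + Q + J + seq_len(J)]),
    tau_u2 = x[["tau_u2"]],
    tau_v2 = x[["tau_v2"]]
  )
}

#' Forward model selection by the 5-point DIC rule
#'
#' Fits every single-variable model, starts from the variable with the
#' lowest DIC, then tries the remaining variables in order of their
#' single-variable DIC, retaining an addition only when it lowers the DIC
#' of the current model by at least `threshold` points (default 5).
#'
#' @param variables character vector of candidate variable names.
#' @param fit_dic function mapping a character vector of variables to the
#'   DIC of the corresponding model fit.
#' @param threshold required DIC reduction (default 5; the boundary is
#'   closed: a reduction of exactly 5 retains the variable).
#' @return list with `selected` (character vector) and `trace` (data frame
#'   with columns `step`, `candidate`, `dic`, `delta`, `action`).
#' @export
select_model <- function(variables, fit_dic, threshold = 5) {
  if (length(variables) == 0L) stop("empty candidate set")
  singles <- vapply(variables, function(v) fit_dic(v), numeric(1))
  ord <- order(singles)
  first <- variables[ord[1L]]
  selected <- first
  dic_cur <- singles[ord[1L]]
  trace <- data.frame(
    step = 1L, candidate = first, dic = dic_cur, delta = NA_real_,
    action = "start", stringsAsFactors = FALSE
  )
  step <- 1L
  for (v in variables[ord[-1L]]) {
    step <- step + 1L
    dic_new <- fit_dic(c(selected, v))
    delta <- dic_new - dic_cur
    retain <- delta <= -threshold
    trace <- rbind(trace, data.frame(
      step = step, candidate = v, dic = dic_new, delta = delta,
      action = if (retain) "retained" else "rejected",
      stringsAsFactors = FALSE
    ))
    if (retain) {
      selected <- c(selected, v)
      dic_cur <- dic_new
    }
  }
  list(selected = selected, trace = trace)
}

#' Convergence and fit diagnostics for an HRR fit
#'
#' Per-parameter BGR statistics (requires >= 2 chains), batch-means MC
#' errors with the 5% pass rule, and the DIC decomposition. The automated
#' BGR flag uses the conventional 1.1 threshold.
#'
#' @param samples an `hrr_samples` fit.
#' @param pars parameters to cover (default: all fixed effects plus the
#'   variance parameters).
#' @return object of class `hrr_diagnostics` with elements `table` (one row
#'   per parameter: `bgr`, `mc_se`, `mc_ratio`, `bgr_ok`, `mc_ok`), `dic`,
#'   and `all_ok`.
#' @export
diagnostics_report <- function(samples, pars = NULL) {
  stopifnot(inherits(samples, "hrr_samples"))
  if (is.null(pars)) {
    J <- samples$data$J
    pars <- setdiff(samples$param_names,
                    c(sprintf("u[%d]", seq_len(J)), sprintf("v[%d]", seq_len(J))))
  }
  rows <- lapply(pars, function(p) {
    per_chain <- lapply(samples$chains, function(ch) ch[, p])
    bgr <- if (length(per_chain) >= 2L) bgr_statistic(per_chain) else NA_real_
    me <- mc_error(unlist(per_chain, use.names = FALSE))
    data.frame(
      parameter = p, bgr = bgr, mc_se = me$mc_se, mc_ratio = me$ratio,
      bgr_ok = is.na(bgr) | bgr < 1.1, mc_ok = me$pass,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  d <- dic(samples)
  structure(
    list(table = tab, dic = d,
         all_ok = all(tab$bgr_ok, na.rm = TRUE) && all(tab$mc_ok)),
    class = "hrr_diagnostics"
  )
}

#' @export
print.hrr_diagnostics <- function(x, ...) {
  cat("HRR convergence diagnostics\n")
  print(x$table, digits = 4)
  cat(sprintf("DIC = %.2f (Dbar = %.2f, pD = %.2f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  cat(if (x$all_ok) "All monitored parameters pass.\n" else
        "Some parameters fail the convergence gates.\n")
  invisible(x)
}

#' Serialize a diagnostics report to JSON
#'
#' @param report an `hrr_diagnostics` object.
#' @param file output path.
#' @export
write_diagnostics_json <- function(report, file) {
  stopifnot(inherits(report, "hrr_diagnostics"))
  jsonlite::write_json(
    list(parameters = report$table, dic = report$dic, all_ok = report$all_ok),
    file,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(file)
}
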