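#' Crude percentage rate
#'
#' @param deaths,n event and at-risk counts (`0 <= deaths <= n`, `n > 0`).
#' @return `100 * deaths / n`, rounded to 2 decimals.
#' @examples
#' crude_rate(285, 6704) # 4.25
#' @export
crude_rate <- function(deaths, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(deaths < 0 | deaths > n)) stop("need 0 <= deaths <= n")
  round(100 * deaths / n, 2)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval; always contains the point estimate and its
#' width shrinks with n at fixed proportion. Bounds are returned as
#' percentages rounded to 2 decimals.
#'
#' @inheritParams crude_rate
#' @param level confidence level in (0, 1).
#' @return named numeric vector `c(lower, upper)` in percent.
#' @examples
#' wilson_ci(285, 6704) # (3.79, 4.76)
#' @export
wilson_ci <- function(deaths, n, level = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (deaths < 0 || deaths > n) stop("need 0 <= deaths <= n")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  p <- deaths / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  round(100 * c(lower = centre - half, upper = centre + half), 2)
}

#' Descriptive frequency table
#'
#' Counts and percentages per category for each requested variable; with
#' `by_outcome = TRUE` the table is split by the binary outcome with row
#' percentages (survivors/deaths layout).
#'
#' @param records records data frame.
#' @param variables character vector of column names (default: the
#'   covariate schema columns present in `records`).
#' @param by_outcome split counts by `outcome` with row percentages.
#' @return data frame; percentages rounded to 2 decimals.
#' @export
descriptive_table <- function(records, variables = NULL, by_outcome = FALSE) {
  if (is.null(variables)) {
    variables <- intersect(names(covariate_levels()), names(records))
  }
  out <- lapply(variables, function(v) {
    f <- records[[v]]
    if (is.null(f)) stop(sprintf("no column '%s' in records", v))
    f <- as.factor(f)
    if (by_outcome) {
      if (anyNA(records$outcome)) stop("outcomes must be set")
      alive <- tapply(records$outcome == 0L, f, sum, default = 0L)
      dead <- tapply(records$outcome == 1L, f, sum, default = 0L)
      tot <- alive + dead
      data.frame(
        variable = v, category = levels(f),
        survivors = as.integer(alive),
        survivors_pct = round(100 * alive / pmax(tot, 1L), 2),
        deaths = as.integer(dead),
        deaths_pct = round(100 * dead / pmax(tot, 1L), 2),
        row.names = NULL
      )
    } else {
      n <- as.integer(table(f))
      data.frame(
        variable = v, category = levels(f), n = n,
        pct = round(100 * n / length(f), 2),
        row.names = NULL
      )
    }
  })
  do.call(rbind, out)
}

#' Adjusted odds-ratio table from posterior samples
#'
#' Exponentiated posterior summaries of the requested log-odds-ratio
#' coefficients with equal-tailed credible intervals; a coefficient is
#' flagged significant when its credible interval excludes the null odds
#' ratio of 1.
#'
#' @param samples an `hrr_samples` fit.
#' @param pars coefficients to summarize (default: the individual- and
#'   area-level coefficients).
#' @param level credible level.
#' @return data frame with columns `parameter`, `aor`, `lower`, `upper`,
#'   `significant`.
#' @export
aor_table <- function(samples, pars = NULL, level = 0.95) {
  stopifnot(inherits(samples, "hrr_samples"))
  if (is.null(pars)) pars <- c(colnames(samples$data$X), colnames(samples$data$Z))
  s <- posterior_summary(samples, level = level, pars = pars, or_scale = TRUE)
  data.frame(
    parameter = s$parameter,
    aor = s$mean,
    lower = s$lower,
    upper = s$upper,
    significant = s$lower > 1 | s$upper < 1,
    row.names = NULL
  )
}

#' Standardized relative risk surface
#'
#' For each posterior draw, area-period risks are standardized to the
#' pooled covariate distribution (the at-risk-weighted average of the
#' within-area stratum distributions), and divided by the pooled average
#' standardized risk of that draw:
#' \deqn{SRR_{jt} = p_{jt}(\bar f) / \bar p, \qquad
#'   \bar p = \textstyle\sum_{jt} N_{jt} p_{jt}(\bar f) / \sum_{jt} N_{jt}.}
#' Differences between areas therefore reflect area and period effects, not
#' covariate composition. Summaries (posterior mean, credible interval,
#' exceedance probability P(SRR > 1)) are reported per occupied cell;
#' cells without data are flagged with `NA`.
#'
#' @param samples an `hrr_samples` fit whose data carry aggregate cells.
#' @param level credible level.
#' @param max_draws cap on the number of pooled draws used (default 2000;
#'   draws are subsampled deterministically by thinning).
#' @return object of class `srr_surface`: data frame with `area_id`,
#'   `period`, `n`, `srr_mean`, `srr_lower`, `srr_upper`, `exceedance`.
#' @export
srr_surface <- function(samples, level = 0.95, max_draws = 2000L) {
  stopifnot(inherits(samples, "hrr_samples"))
  data <- samples$data
  if (is.null(data$agg)) stop("SRR surface needs aggregate data cells")
  draws <- pooled_draws(samples)
  if (nrow(draws) > max_draws) {
    draws <- draws[seq.int(1L, nrow(draws), length.out = max_draws), , drop = FALSE]
  }
  J <- data$J
  TT <- data$n_periods
  f_bar <- as.numeric(colSums(data$agg$f * data$agg$n) / sum(data$agg$n))
  jt <- data$agg$jt
  w <- data$agg$n / sum(data$agg$n)
  ndr <- nrow(draws)
  srr <- matrix(NA_real_, ndr, length(jt))
  for (i in seq_len(ndr)) {
    params <- unpack_params(draws[i, ], data)
    e <- eta_components(params, data)
    p_jt <- as.numeric(stats::plogis(outer(e$a[jt], e$b, "+")) %*% f_bar)
    srr[i, ] <- p_jt / sum(w * p_jt)
  }
  alpha <- (1 - level) / 2
  qs <- apply(srr, 2L, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  occupied <- data.frame(
    area_id = (jt - 1L) %/% TT + 1L,
    period = (jt - 1L) %% TT + 1L,
    n = data$agg$n,
    srr_mean = colMeans(srr),
    srr_lower = qs[1L, ],
    srr_upper = qs[2L, ],
    exceedance = colMeans(srr > 1)
  )
  grid <- expand.grid(period = seq_len(TT), area_id = seq_len(J))[, 2:1]
  out <- merge(grid, occupied, by = c("area_id", "period"), all.x = TRUE, sort = TRUE)
  out$n[is.na(out$n)] <- 0L
  out <- out[order(out$area_id, out$period), ]
  rownames(out) <- NULL
  class(out) <- c("srr_surface", "data.frame")
  out
}

#' Structured share of the spatial variation
#'
#' Per posterior draw, the empirical-variance partition
#' `var(u) / (var(u) + var(v))` between the structured (ICAR) and
#' unstructured spatial effects; the posterior mean is reported as a
#' percentage together with an equal-tailed credible interval.
#'
#' @param samples an `hrr_samples` fit.
#' @param level credible level.
#' @return list with `mean_pct`, `lower_pct`, `upper_pct`, `draws`
#'   (per-draw fractions in `[0, 1]`).
#' @export
spatial_variance_fraction <- function(samples, level = 0.95) {
  stopifnot(inherits(samples, "hrr_samples"))
  J <- samples$data$J
  d <- pooled_draws(samples)
  U <- d[, sprintf("u[%d]", seq_len(J)), drop = FALSE]
  V <- d[, sprintf("v[%d]", seq_len(J)), drop = FALSE]
  var_u <- apply(U, 1L, stats::var)
  var_v <- apply(V, 1L, stats::var)
  tot <- var_u + var_v
  if (all(tot == 0)) stop("both spatial variance components are zero")
  frac <- ifelse(tot > 0, var_u / tot, NA_real_)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(frac, probs = c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(mean_pct = 100 * mean(frac, na.rm = TRUE),
       lower_pct = 100 * qs[1L], upper_pct = 100 * qs[2L], draws = frac)
}

#' Export an SRR surface as per-period choropleth GeoJSON
#'
#' One GeoJSON FeatureCollection per period, with the SRR posterior mean,
#' credible bounds and exceedance probability attached as feature
#' properties.
#'
#' @param surface an [srr_surface()] result.
#' @param polygons list of polygon rings indexed by area id.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (files are `<prefix>_period<t>.geojson`).
#' @return character vector of written file paths.
#' @export
choropleth_export <- function(surface, polygons, dir = ".", prefix = "srr") {
  stopifnot(inherits(surface, "srr_surface"))
  ids <- sort(unique(surface$area_id))
  if (length(polygons) < max(ids)) {
    missing <- ids[ids > length(polygons)]
    stop(sprintf("no polygon for area id(s): %s", paste(missing, collapse = ", ")))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (t in sort(unique(surface$period))) {
    sl <- surface[surface$period == t, , drop = FALSE]
    sl <- sl[order(sl$area_id), , drop = FALSE]
    props <- data.frame(
      period = t,
      srr_mean = sl$srr_mean, srr_lower = sl$srr_lower,
      srr_upper = sl$srr_upper, exceedance = sl$exceedance
    )
    path <- file.path(dir, sprintf("%s_period%d.geojson", prefix, t))
    write_geojson(polygons[sl$area_id], path, properties = props)
    files <- c(files, path)
  }
  files
}

#' Published cohort summary counts
#'
#' Survivor/death counts by patient characteristics for the Victorian
#' lung-cancer SACT cohort (6704 patients, 2011-2022), as published in
#' aggregate form; shipped as a plain-text fixture and used for the
#' descriptive-rate computations.
#'
#' @return data frame with columns `variable`, `category`, `survivors`,
#'   `deaths`.
#' @export
vlcr_summary_counts <- function() {
  path <- system.file("extdata", "vlcr_summary_counts.csv", package = "spathrr",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published cohort composition
#'
#' Frequencies of demographic and clinical characteristics for the same
#' cohort (the published baseline table). Note that the published baseline
#' and outcome tables disagree slightly on the age split; both are shipped
#' as printed.
#'
#' @return data frame with columns `variable`, `category`, `n`.
#' @export
vlcr_cohort_composition <- function() {
  path <- system.file("extdata", "vlcr_cohort_composition.csv",
                      package = "spathrr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
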