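#' Growth-model parameters
#'
#' Bundles the coefficients of the log-linear mixed-effects tumor-growth
#' model.  Defaults are the median estimates pooled across a cohort of
#' NSCLC PDX drug-response experiments; they describe a control tumor of
#' about 170 mm\eqn{^3} at baseline growing ~8% per day, a treatment that
#' slows daily log-growth by 0.02, and moderate mouse-to-mouse spread.
#'
#' `tau01` is interpreted as the intercept–slope *correlation* by
#' default.  A covariance interpretation is available via
#' `tau01_type = "covariance"`, but is validated against
#' `tau0 * tau1`: the default value 0.034 exceeds that product, so it is
#' only internally consistent as a correlation.
#'
#' @param beta_int Fixed intercept: log baseline tumor volume (log mm^3).
#' @param beta_day Control growth rate of log-volume per day (1/day).
#' @param beta_effect Treated-minus-control difference in daily
#'   log-growth (1/day); negative values denote growth inhibition.
#' @param gamma Treatment main effect on log baseline volume.  Zero under
#'   randomization at baseline.
#' @param sigma Residual SD of log-volume (within-mouse measurement
#'   noise).  Must be non-negative.
#' @param tau0 SD of the mouse-level random intercept.
#' @param tau1 SD of the mouse-level random slope (1/day).  This is the
#'   "inter-mouse variation" that limits the precision of a single
#'   mouse's growth rate.
#' @param tau01 Association between random intercept and slope; a
#'   correlation in \[-1, 1\] (default) or a covariance, per `tau01_type`.
#' @param tau01_type Either `"correlation"` or `"covariance"`.
#'
#' @return An object of class `pdx_params`: a named list of the validated
#'   parameters plus `re_cov`, the implied 2x2 random-effects covariance
#'   matrix.
#' @examples
#' p <- pdx_params()                       # cohort medians
#' p2 <- pdx_params(beta_effect = -0.044)  # a large effect
#' @export
pdx_params <- function(beta_int = 5.135, beta_day = 0.076,
                       beta_effect = -0.02, gamma = 0,
                       sigma = 0.155, tau0 = 0.28, tau1 = 0.009,
                       tau01 = 0.034,
                       tau01_type = c("correlation", "covariance")) {
  tau01_type <- match.arg(tau01_type)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  beta_int <- num1(beta_int, "beta_int")
  beta_day <- num1(beta_day, "beta_day")
  beta_effect <- num1(beta_effect, "beta_effect")
  gamma <- num1(gamma, "gamma")
  sigma <- num1(sigma, "sigma")
  tau0 <- num1(tau0, "tau0")
  tau1 <- num1(tau1, "tau1")
  tau01 <- num1(tau01, "tau01")
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (tau0 < 0) stop("'tau0' must be >= 0", call. = FALSE)
  if (tau1 < 0) stop("'tau1' must be >= 0", call. = FALSE)

  if (tau01_type == "correlation") {
    if (abs(tau01) > 1)
      stop("intercept-slope correlation 'tau01' must lie in [-1, 1]",
           call. = FALSE)
    cov01 <- tau01 * tau0 * tau1
  } else {
    cov01 <- tau01
    if (tau0 > 0 && tau1 > 0 && abs(cov01) > tau0 * tau1 + 1e-12)
      stop("covariance 'tau01' exceeds tau0 * tau1; the random-effects ",
           "covariance matrix is not positive semidefinite", call. = FALSE)
    if ((tau0 == 0 || tau1 == 0) && cov01 != 0)
      stop("covariance 'tau01' must be 0 when tau0 or tau1 is 0",
           call. = FALSE)
  }
  re_cov <- matrix(c(tau0^2, cov01, cov01, tau1^2), 2, 2,
                   dimnames = list(c("intercept", "slope"),
                                   c("intercept", "slope")))

  structure(list(beta_int = beta_int, beta_day = beta_day,
                 beta_effect = beta_effect, gamma = gamma,
                 sigma = sigma, tau0 = tau0, tau1 = tau1,
                 tau01 = tau01, tau01_type = tau01_type,
                 re_cov = re_cov),
            class = "pdx_params")
}

#' @export
print.pdx_params <- function(x, ...) {
  cat("PDX log-linear growth model parameters\n")
  cat(sprintf("  fixed effects : beta_int = %.4g, beta_day = %.4g, beta_effect = %.4g, gamma = %.4g\n",
              x$beta_int, x$beta_day, x$beta_effect, x$gamma))
  cat(sprintf("  variance comp.: sigma = %.4g, tau0 = %.4g, tau1 = %.4g, tau01 = %.4g (%s)\n",
              x$sigma, x$tau0, x$tau1, x$tau01, x$tau01_type))
  cat(sprintf("  weekly growth ratio exp(7 * beta_effect) = %.3f\n",
              effect_to_weekly_ratio(x$beta_effect)))
  invisible(x)
}

#' Measurement design for a two-arm PDX experiment
#'
#' @param days Measurement days: strictly increasing non-negative
#'   integers, at least two of them (the growth slope must be
#'   identifiable per mouse).  Defaults to the twice-weekly, 4-week
#'   schedule `make_schedule(4, 2)`.
#' @param n_per_group Mice per arm (>= 1).  `n_per_group = 1` is the
#'   1x1x1 design.
#' @param alpha Two-sided type-I error level in (0, 1).
#'
#' @return An object of class `pdx_design`.
#' @examples
#' pdx_design()                          # 1x1x1, twice weekly, 4 weeks
#' pdx_design(make_schedule(8, 3), n_per_group = 3, alpha = 0.2)
#' @export
pdx_design <- function(days = make_schedule(4, 2), n_per_group = 1,
                       alpha = 0.05) {
  if (!is.numeric(days) || length(days) < 2L)
    stop("'days' must contain at least 2 measurement days", call. = FALSE)
  days <- as.numeric(days)
  if (any(!is.finite(days)) || any(days < 0))
    stop("'days' must be finite and non-negative", call. = FALSE)
  if (any(diff(days) <= 0))
    stop("'days' must be strictly increasing", call. = FALSE)
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 1 || n_per_group != round(n_per_group))
    stop("'n_per_group' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  structure(list(days = days, n_per_group = as.integer(n_per_group),
                 alpha = alpha),
            class = "pdx_design")
}

#' @export
print.pdx_design <- function(x, ...) {
  cat(sprintf("PDX design: %d mice/arm, alpha = %g, %d measurement days\n",
              x$n_per_group, x$alpha, length(x$days)))
  cat("  days:", paste(x$days, collapse = ", "), "\n")
  invisible(x)
}

#' Build a tumor-measurement schedule
#'
#' Tiles a within-week day pattern over a number of weeks.  Twice-weekly
#' measurement uses offsets {0, 4} within each week (e.g. Monday and
#' Friday), so 4 weeks gives days 0, 4, 7, 11, 14, 18, 21, 25.
#' Three-times-weekly uses offsets {0, 2, 4} (Mon/Wed/Fri); the offsets
#' can be overridden.
#'
#' @param weeks Number of weeks of follow-up (>= 1).
#' @param per_week Measurements per week: 2 or 3 (ignored when `offsets`
#'   is supplied).
#' @param offsets Optional custom within-week offsets in \[0, 7).
#' @return Integer vector of measurement days starting at 0.
#' @examples
#' make_schedule(4, 2)   # 0 4 7 11 14 18 21 25
#' make_schedule(2, 3)   # 0 2 4 7 9 11
#' @export
make_schedule <- function(weeks, per_week = 2, offsets = NULL) {
  if (!is.numeric(weeks) || length(weeks) != 1L || weeks < 1 ||
      weeks != round(weeks))
    stop("'weeks' must be an integer >= 1", call. = FALSE)
  if (is.null(offsets)) {
    if (!per_week %in% c(2, 3))
      stop("unsupported measurement frequency: 'per_week' must be 2 or 3 ",
           "(or supply 'offsets')", call. = FALSE)
    offsets <- if (per_week == 2) c(0, 4) else c(0, 2, 4)
  } else {
    if (any(offsets < 0 | offsets >= 7) || any(diff(sort(offsets)) == 0))
      stop("'offsets' must be distinct values in [0, 7)", call. = FALSE)
    offsets <- sort(offsets)
  }
  as.integer(rep(7 * (seq_len(weeks) - 1), each = length(offsets)) + offsets)
}

#' Weekly growth ratio implied by a treatment effect
#'
#' Converts the treatment effect on daily log-growth into the
#' multiplicative factor applied to the control arm's weekly growth:
#' `exp(7 * beta_effect)`.  A large inhibitory effect of -0.044/day means
#' treated tumors grow at 0.73 times the control's weekly rate.
#'
#' @param beta_effect Difference in daily log-growth (1/day); vectorized.
#' @return Dimensionless ratio(s); 1 means no effect.
#' @examples
#' effect_to_weekly_ratio(c(-0.044, -0.02, -0.010))  # 0.73 0.87 0.93
#' @export
effect_to_weekly_ratio <- function(beta_effect) {
  exp(7 * beta_effect)
}

## Frozen effect-size / variation categories (cohort quartiles of the
## fitted per-experiment coefficients; hard-coded so grids are
## reproducible without the original data).
.effect_levels <- c(small = -0.010, medium = -0.02, large = -0.044)
.tau1_levels <- c(small = 0.005, average = 0.009, large = 0.013)

#' Cohort-quartile effect-size and variation categories
#'
#' The labelled values of the treatment effect (`beta_effect`) and
#' inter-mouse variation (`tau1`) used by the standard condition grids:
#' effect small/medium/large = -0.010 / -0.02 / -0.044 (upper quartile,
#' median, lower quartile of fitted effects) and tau1
#' small/average/large = 0.005 / 0.009 / 0.013.
#'
#' @return Named list with numeric vectors `effect` and `tau1`.
#' @export
condition_levels <- function() {
  list(effect = .effect_levels, tau1 = .tau1_levels)
}

#' Standard condition grids for power exploration
#'
#' Builds the grids of (parameters, design) conditions used to map power
#' as a function of one design feature at a time, or of their
#' combinations:
#' \describe{
#'   \item{`"effect"`}{20 evenly spaced `beta_effect` values on
#'     \[-0.08, 0.019\] with `tau1 = 0.005`, 4 weeks twice weekly.}
#'   \item{`"variation"`}{20 evenly spaced `tau1` values on
#'     \[0.0001, 0.02\] with `beta_effect = -0.02`, 4 weeks twice weekly.}
#'   \item{`"schedule"`}{weeks 1–8 crossed with 2 and 3 measurements per
#'     week, at the median effect and small variation.}
#'   \item{`"combination"`}{\{small, medium, large effect\} x
#'     \{small, average tau1\} x \{4, 8 weeks\} x \{2, 3 per week\} x
#'     \{alpha .05, .2\}: the 48-cell grid of the standard power and
#'     sample-size tables.}
#' }
#' All other coefficients are held at the values in `params`.
#'
#' @param feature Which feature varies (see above).
#' @param params Baseline [pdx_params()]; non-varying coefficients are
#'   taken from it.
#' @param alpha Significance level(s) for the single-feature grids
#'   (the combination grid always uses .05 and .2).
#' @return A data frame of class `pdx_grid` with columns `label`,
#'   `beta_effect`, `tau1`, `weeks`, `per_week`, `alpha`.
#' @examples
#' nrow(make_condition_grid("combination"))  # 48
#' head(make_condition_grid("effect"))
#' @export
make_condition_grid <- function(feature = c("effect", "variation",
                                            "schedule", "combination"),
                                params = pdx_params(),
                                alpha = c(0.05, 0.2)) {
  feature <- match.arg(feature)
  ef <- .effect_levels
  tl <- .tau1_levels
  g <- switch(feature,
    effect = expand.grid(
      beta_effect = seq(-0.08, 0.019, length.out = 20),
      tau1 = tl[["small"]], weeks = 4, per_week = 2, alpha = alpha,
      KEEP.OUT.ATTRS = FALSE),
    variation = expand.grid(
      beta_effect = params$beta_effect,
      tau1 = seq(0.0001, 0.02, length.out = 20),
      weeks = 4, per_week = 2, alpha = alpha, KEEP.OUT.ATTRS = FALSE),
    schedule = expand.grid(
      beta_effect = params$beta_effect, tau1 = tl[["small"]],
      weeks = 1:8, per_week = c(2, 3), alpha = alpha,
      KEEP.OUT.ATTRS = FALSE),
    combination = expand.grid(
      beta_effect = ef, tau1 = tl[c("small", "average")],
      weeks = c(4, 8), per_week = c(2, 3), alpha = c(0.05, 0.2),
      KEEP.OUT.ATTRS = FALSE)
  )
  g$label <- switch(feature,
    effect = sprintf("effect_%.4f_a%g", g$beta_effect, g$alpha),
    variation = sprintf("tau1_%.4f_a%g", g$tau1, g$alpha),
    schedule = sprintf("wk%d_x%d_a%g", g$weeks, g$per_week, g$alpha),
    combination = sprintf(
      "%s-effect_%s-tau1_%dwk_%dx_a%g",
      names(ef)[match(g$beta_effect, ef)],
      names(tl)[match(g$tau1, tl)],
      g$weeks, g$per_week, g$alpha))
  g <- g[, c("label", "beta_effect", "tau1", "weeks", "per_week", "alpha")]
  attr(g, "params") <- params
  attr(g, "feature") <- feature
  class(g) <- c("pdx_grid", "data.frame")
  g
}

#' Read model parameters and design from a config file
#'
#' Reads a YAML or JSON file with (optionally nested under `params` and
#' `design`) the fields of [pdx_params()] and [pdx_design()].  Missing
#' fields take the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `params` (`pdx_params`) and `design`
#'   (`pdx_design`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pf <- names(formals(pdx_params))
  df <- c("days", "n_per_group", "alpha")
  ppart <- if (!is.null(cfg$params)) cfg$params else cfg[names(cfg) %in% pf]
  dpart <- if (!is.null(cfg$design)) cfg$design else cfg[names(cfg) %in% df]
  bad <- setdiff(names(ppart), pf)
  if (length(bad)) stop("unknown parameter field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(dpart), df)
  if (length(bad)) stop("unknown design field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  list(params = do.call(pdx_params, ppart),
       design = do.call(pdx_design, dpart))
}
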