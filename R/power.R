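#' Per-mouse slope variance and schedule information
#'
#' `schedule_sxx()` returns \eqn{S_{xx} = \sum_j (d_j - \bar d)^2}, the
#' spread of the measurement days, which governs how precisely a single
#' mouse's growth slope is estimated.  `slope_variance()` returns the
#' variance of a per-mouse ordinary-least-squares growth slope,
#' \eqn{v = \tau_1^2 + \sigma^2 / S_{xx}}: biological spread between
#' mice plus measurement noise filtered through the schedule.
#'
#' @param days Numeric vector of measurement days (>= 2 distinct).
#' @param params A [pdx_params()] object.
#' @return A single numeric value.
#' @examples
#' schedule_sxx(make_schedule(4, 2))   # 522
#' slope_variance(pdx_params(), make_schedule(4, 2))
#' @export
schedule_sxx <- function(days) {
  if (length(unique(days)) < 2L)
    stop("degenerate schedule: need >= 2 distinct days", call. = FALSE)
  sum((days - mean(days))^2)
}

#' @rdname schedule_sxx
#' @export
slope_variance <- function(params, days) {
  stopifnot(inherits(params, "pdx_params"))
  params$tau1^2 + params$sigma^2 / schedule_sxx(days)
}

#' Closed-form power for the two-group slope-difference test
#'
#' Power of the two-sided test of the treatment effect on daily
#' log-growth, treating the variance components as known.  With `n`
#' mice per arm measured on a common schedule, the estimated
#' treated-minus-control slope difference has standard error
#' \eqn{SE = \sqrt{2 (\tau_1^2 + \sigma^2/S_{xx}) / n}}, and
#' \deqn{power = \Phi(|\beta_{eff}|/SE - z_{1-\alpha/2}) +
#'               \Phi(-|\beta_{eff}|/SE - z_{1-\alpha/2}).}
#' Both rejection tails are counted, so power equals \eqn{\alpha}
#' exactly when `beta_effect = 0`.
#'
#' The intercept variance `tau0` and the intercept–slope association do
#' not enter: they cancel from the slope contrast in a balanced design.
#'
#' @param params A [pdx_params()] object.
#' @param design A [pdx_design()] object (days, mice per arm, alpha).
#' @return A `pdx_power` object with `power`, `method = "analytic"` and
#'   the echoed inputs.
#' @examples
#' # the 1x1x1 design, large effect, small inter-mouse variation
#' analytic_power(pdx_params(beta_effect = -0.044, tau1 = 0.005),
#'                pdx_design(make_schedule(4, 2)))
#' @export
analytic_power <- function(params, design) {
  stopifnot(inherits(params, "pdx_params"), inherits(design, "pdx_design"))
  se <- sqrt(2 * slope_variance(params, design$days) / design$n_per_group)
  za <- qnorm(1 - design$alpha / 2)
  ncp <- abs(params$beta_effect) / se
  pow <- pnorm(ncp - za) + pnorm(-ncp - za)
  structure(list(power = pow, method = "analytic",
                 params = params, design = design),
            class = "pdx_power")
}

#' Monte-Carlo power by simulate-fit-test
#'
#' Repeats the cycle simulate an experiment, fit the growth model, test
#' the treatment effect, and reports the rejection fraction.
#'
#' Two test variants are available.  `test = "known"` (default) forms a
#' Wald z statistic from the fitted `beta_effect` and the *generating*
#' slope-difference standard error \eqn{\sqrt{2 v / n}} — the same
#' known-variance footing as [analytic_power()], and the only test that
#' can account for inter-mouse slope variation when there is one mouse
#' per arm (with n = 1, `tau1` cannot be estimated from the data).
#' `test = "estimated"` uses each fit's own model-based test
#' ([test_effect()]: the exact slope t for balanced replicated designs,
#' the residual t for the 1x1x1 linear model); it shows what an analysis
#' of the realized data alone would conclude, and for the 1x1x1 design
#' it is anticonservative whenever `tau1 > 0`.
#'
#' @param params A [pdx_params()] object.
#' @param design A [pdx_design()] object.
#' @param n_sims Number of replicate experiments (>= 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @param test `"known"` or `"estimated"`; see Details.
#' @param include_gamma Passed to [fit_growth_model()].
#' @return A `pdx_power` object with `power`, `method = "simulation"`,
#'   `n_sims`, `seed`, the Monte-Carlo standard error `mc_stderr`, and
#'   `n_nonconverged`, the count of replicates whose mixed-model fit
#'   needed a simplified covariance structure (they are kept, not
#'   dropped).
#' @examples
#' p <- pdx_params(beta_effect = -0.044, tau1 = 0.005)
#' simulate_power(p, pdx_design(), n_sims = 200, seed = 1)
#' @export
simulate_power <- function(params, design, n_sims = 10000, seed = NULL,
                           test = c("known", "estimated"),
                           include_gamma = TRUE) {
  stopifnot(inherits(params, "pdx_params"), inherits(design, "pdx_design"))
  test <- match.arg(test)
  if (n_sims < 100) stop("'n_sims' must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  se_known <- sqrt(2 * slope_variance(params, design$days) /
                     design$n_per_group)
  za <- qnorm(1 - design$alpha / 2)
  n_reject <- 0L
  n_nonconverged <- 0L
  template <- NULL   # reusable lmer structure for fast refits

  for (s in seq_len(n_sims)) {
    tr <- simulate_experiment(params, design)
    if (design$n_per_group == 1L) {
      fit <- fit_growth_model(tr, include_gamma = include_gamma)
    } else if (test == "known") {
      ## only the point estimate is needed: reuse the lmer structure
      res <- .fast_mixed_fit(tr, template, include_gamma)
      fit <- res$fit
      template <- res$template
      if (!is.na(fit$fallback)) n_nonconverged <- n_nonconverged + 1L
    } else {
      fit <- fit_growth_model(tr, include_gamma = include_gamma)
      if (!is.na(fit$fallback)) n_nonconverged <- n_nonconverged + 1L
    }
    rej <- if (test == "known") {
      abs(fit$beta_effect) / se_known > za
    } else {
      test_effect(fit, design$alpha)$reject
    }
    if (rej) n_reject <- n_reject + 1L
  }

  pow <- n_reject / n_sims
  structure(list(power = pow, method = "simulation",
                 n_sims = as.integer(n_sims), seed = seed,
                 mc_stderr = sqrt(pow * (1 - pow) / n_sims),
                 n_nonconverged = n_nonconverged, test = test,
                 params = params, design = design),
            class = "pdx_power")
}

## Refit the full-covariance lmer template on new responses; fall back to
## the general fitting path (with its covariance ladder) if that fails.
.fast_mixed_fit <- function(tr, template, include_gamma) {
  if (!is.null(template)) {
    cand <- suppressMessages(suppressWarnings(tryCatch(
      lme4::refit(template, tr$log_volume), error = function(e) NULL)))
    if (!is.null(cand) && .lmer_converged(cand)) {
      est <- lme4::fixef(cand)
      se <- sqrt(diag(as.matrix(vcov(cand))))
      z <- est[["day:treated"]] / se[["day:treated"]]
      fit <- structure(list(
        beta_effect = est[["day:treated"]],
        se_beta_effect = se[["day:treated"]],
        statistic = z, p_value = 2 * pnorm(-abs(z)),
        model_kind = "mixed", fallback = NA_character_,
        singular = lme4::isSingular(cand)), class = "pdx_fit")
      return(list(fit = fit, template = template))
    }
  }
  fit <- fit_growth_model(tr, include_gamma = include_gamma)
  tmpl <- if (is.na(fit$fallback)) fit$fit else template
  list(fit = fit, template = tmpl)
}

#' Smallest group size reaching a target power
#'
#' Inverts the closed-form power calculation: the starting point is
#' \eqn{n_0 = \lceil 2 (z_{1-\alpha/2} + z_{power})^2 v /
#' \beta_{eff}^2 \rceil} with \eqn{v} the per-mouse slope variance, then
#' the integer is refined against [analytic_power()] (the second
#' rejection tail can move the boundary by one).
#'
#' @param params A [pdx_params()] object; `beta_effect` must be nonzero.
#' @param design A [pdx_design()] object supplying the schedule and
#'   alpha; its `n_per_group` is ignored.
#' @param target_power Target power in (0, 1); default 0.80.
#' @return A `pdx_samplesize` object with `n_per_group`, `target_power`
#'   and `achieved_power` (analytic power at the returned n).
#' @examples
#' # medium effect, average variation, 4 weeks twice weekly
#' required_sample_size(pdx_params(), pdx_design())   # 5 mice per arm
#' @export
required_sample_size <- function(params, design, target_power = 0.80) {
  stopifnot(inherits(params, "pdx_params"), inherits(design, "pdx_design"))
  if (params$beta_effect == 0)
    stop("beta_effect = 0: no finite sample size reaches the target power",
         call. = FALSE)
  if (target_power <= 0 || target_power >= 1)
    stop("'target_power' must lie in (0, 1)", call. = FALSE)
  v <- slope_variance(params, design$days)
  n <- ceiling(2 * (qnorm(1 - design$alpha / 2) + qnorm(target_power))^2 *
                 v / params$beta_effect^2)
  n <- max(1, n)
  pow_at <- function(n) {
    analytic_power(params, pdx_design(design$days, n, design$alpha))$power
  }
  while (n > 1 && pow_at(n - 1) >= target_power) n <- n - 1
  while (pow_at(n) < target_power) n <- n + 1
  structure(list(n_per_group = as.integer(n), target_power = target_power,
                 achieved_power = pow_at(n),
                 params = params, design = design),
            class = "pdx_samplesize")
}

#' Retrospective 1x1x1 power for completed experiments
#'
#' Given per-experiment fitted coefficients (one row per experiment,
#' columns named after [pdx_params()] fields — at least `beta_effect`,
#' `tau1` and `sigma`), computes the closed-form power each experiment
#' would have had as a 1x1x1 study, at each requested alpha level.
#' Experiments with `beta_effect = 0` have power equal to alpha and are
#' flagged `no_effect`.
#'
#' @param coeffs Data frame of per-experiment coefficient estimates.
#' @param days Measurement days shared by the experiments, or a
#'   data-frame column name giving per-experiment day counts is not
#'   supported — supply one schedule per call.
#' @param alphas Numeric vector of significance levels.
#' @return A `pdx_retro` object: data frame with one row per experiment
#'   and one `power_a<alpha>` column per alpha, plus a `no_effect` flag;
#'   its `summary` attribute holds the median power and the fraction of
#'   experiments with power >= 0.8 per alpha.
#' @examples
#' co <- data.frame(beta_effect = c(-0.044, -0.02, 0),
#'                  tau1 = c(0.005, 0.009, 0.009), sigma = 0.155)
#' retrospective_power(co, make_schedule(4, 2))
#' @export
retrospective_power <- function(coeffs, days = make_schedule(4, 2),
                                alphas = c(0.05, 0.2)) {
  coeffs <- as.data.frame(coeffs)
  need <- c("beta_effect", "tau1", "sigma")
  miss <- setdiff(need, names(coeffs))
  if (length(miss))
    stop("missing coefficient column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- coeffs
  out$no_effect <- coeffs$beta_effect == 0
  for (a in alphas) {
    out[[sprintf("power_a%g", a)]] <- vapply(seq_len(nrow(coeffs)),
      function(i) {
        p <- pdx_params(beta_effect = coeffs$beta_effect[i],
                        tau1 = coeffs$tau1[i], sigma = coeffs$sigma[i])
        analytic_power(p, pdx_design(days, 1L, a))$power
      }, numeric(1))
  }
  summ <- do.call(rbind, lapply(alphas, function(a) {
    pw <- out[[sprintf("power_a%g", a)]]
    data.frame(alpha = a, median_power = median(pw),
               frac_powered = mean(pw >= 0.8))
  }))
  structure(out, summary = summ, days = days,
            class = c("pdx_retro", "data.frame"))
}

#' @export
print.pdx_power <- function(x, ...) {
  cat(sprintf("Power: %.4f  [%s]\n", x$power, x$method))
  if (x$method == "simulation") {
    cat(sprintf("  n_sims = %d, MC stderr = %.4f, test SE = %s%s\n",
                x$n_sims, x$mc_stderr, x$test,
                if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
    if (x$n_nonconverged > 0)
      cat(sprintf("  %d replicate(s) used a simplified covariance structure\n",
                  x$n_nonconverged))
  }
  cat(sprintf("  beta_effect = %g, tau1 = %g, sigma = %g; %d mice/arm, %d days, alpha = %g\n",
              x$params$beta_effect, x$params$tau1, x$params$sigma,
              x$design$n_per_group, length(x$design$days), x$design$alpha))
  invisible(x)
}

#' @export
print.pdx_samplesize <- function(x, ...) {
  cat(sprintf("Required sample size: %d mice per group\n", x$n_per_group))
  cat(sprintf("  target power %.2f, achieved %.4f (analytic), alpha = %g\n",
              x$target_power, x$achieved_power, x$design$alpha))
  invisible(x)
}

#' @export
print.pdx_retro <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Retrospective 1x1x1 power for %d experiment(s)\n", nrow(x)))
  if (any(x$no_effect))
    cat(sprintf("  %d experiment(s) with no treatment effect (power = alpha)\n",
                sum(x$no_effect)))
  for (i in seq_len(nrow(s)))
    cat(sprintf("  alpha = %g: median power %.3f, %.0f%% of experiments >= 80%% power\n",
                s$alpha[i], s$median_power[i], 100 * s$frac_powered[i]))
  invisible(x)
}
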