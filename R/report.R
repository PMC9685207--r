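#' Evaluate power over a condition grid
#'
#' Computes analytic power (and optionally Monte-Carlo power and the
#' required sample size for 80% power) for every row of a condition
#' grid from [make_condition_grid()].
#'
#' @param grid A `pdx_grid` data frame.
#' @param params Baseline [pdx_params()]; each row overrides
#'   `beta_effect` and `tau1`.
#' @param n_per_group Mice per arm used for the power columns.
#' @param n_sims If non-NULL, also run [simulate_power()] with this many
#'   replicates per cell.
#' @param seed Seed for the simulation arm; cell `i` uses `seed + i` so
#'   cells are independent but reproducible.
#' @param sample_size Also compute `n_required` for 80% power?
#' @return The grid with columns `n_per_group`, `power_analytic` and,
#'   when requested, `power_sim`, `mc_stderr`, `n_required`.
#' @examples
#' g <- make_condition_grid("combination")
#' head(grid_power(g))
#' @export
grid_power <- function(grid, params = pdx_params(), n_per_group = 1,
                       n_sims = NULL, seed = 1, sample_size = FALSE) {
  stopifnot(inherits(grid, "pdx_grid") || is.data.frame(grid))
  out <- as.data.frame(grid)
  out$n_per_group <- as.integer(n_per_group)
  cell <- function(i) {
    p <- pdx_params(beta_int = params$beta_int, beta_day = params$beta_day,
                    beta_effect = out$beta_effect[i], gamma = params$gamma,
                    sigma = params$sigma, tau0 = params$tau0,
                    tau1 = out$tau1[i], tau01 = params$tau01,
                    tau01_type = params$tau01_type)
    d <- pdx_design(make_schedule(out$weeks[i], out$per_week[i]),
                    n_per_group, out$alpha[i])
    list(p = p, d = d)
  }
  out$power_analytic <- vapply(seq_len(nrow(out)), function(i) {
    cd <- cell(i); analytic_power(cd$p, cd$d)$power
  }, numeric(1))
  if (!is.null(n_sims)) {
    sim <- lapply(seq_len(nrow(out)), function(i) {
      cd <- cell(i)
      simulate_power(cd$p, cd$d, n_sims = n_sims, seed = seed + i)
    })
    out$power_sim <- vapply(sim, `[[`, numeric(1), "power")
    out$mc_stderr <- vapply(sim, `[[`, numeric(1), "mc_stderr")
  }
  if (sample_size) {
    out$n_required <- vapply(seq_len(nrow(out)), function(i) {
      cd <- cell(i)
      required_sample_size(cd$p, cd$d)$n_per_group
    }, integer(1))
  }
  out
}

#' Standard 48-cell power table for the 1x1x1 design
#'
#' Analytic (and optionally simulated) power for every combination of
#' effect size (small/medium/large), inter-mouse variation
#' (small/average), follow-up duration (4/8 weeks), measurement
#' frequency (2/3 per week) and alpha (.05/.2), with one mouse per arm.
#' Cells with power >= 0.80 are flagged `powered`.
#'
#' @inheritParams grid_power
#' @param out Optional CSV path; written with [utils::write.csv()].
#' @return Data frame with 48 rows.
#' @examples
#' tab <- run_power_table()
#' subset(tab, powered)[, c("label", "power_analytic")]
#' @export
run_power_table <- function(params = pdx_params(), n_sims = NULL,
                            seed = 1, out = NULL) {
  g <- make_condition_grid("combination", params = params)
  res <- grid_power(g, params = params, n_per_group = 1,
                    n_sims = n_sims, seed = seed)
  res$powered <- res$power_analytic >= 0.80
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}

#' Standard 48-cell required-sample-size table
#'
#' Mice per group needed to reach 80% power, for the same condition
#' grid as [run_power_table()].
#'
#' @inheritParams run_power_table
#' @return Data frame with 48 rows and column `n_required`.
#' @examples
#' tab <- run_samplesize_table()
#' range(tab$n_required)
#' @export
run_samplesize_table <- function(params = pdx_params(), out = NULL) {
  g <- make_condition_grid("combination", params = params)
  res <- grid_power(g, params = params, n_per_group = 1,
                    sample_size = TRUE)
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  res
}

#' Power curves over effect size, variation and follow-up schedule
#'
#' Three curve families for the 1x1x1 design at alpha .05 and .2, all
#' other coefficients at their defaults: (a) treatment effect swept over
#' \[-0.08, 0.019\]; (b) inter-mouse variation swept over
#' \[0.0001, 0.02\]; (c) follow-up duration 1–8 weeks at 2 and 3
#' measurements per week.
#'
#' @inheritParams run_power_table
#' @param out Optional directory; one CSV per curve family is written
#'   there (`power_curve_effect.csv` etc.).
#' @return Named list of data frames (`effect`, `variation`,
#'   `schedule`) of class `pdx_power_curves`.
#' @examples
#' cv <- run_power_curves()
#' lapply(cv, head, 3)
#' @export
run_power_curves <- function(params = pdx_params(), n_sims = NULL,
                             seed = 1, out = NULL) {
  fams <- c("effect", "variation", "schedule")
  res <- lapply(fams, function(f) {
    g <- make_condition_grid(f, params = params)
    grid_power(g, params = params, n_per_group = 1,
               n_sims = n_sims, seed = seed)
  })
  names(res) <- fams
  if (!is.null(out)) {
    if (!dir.exists(out)) dir.create(out, recursive = TRUE)
    for (f in fams)
      write.csv(res[[f]], file.path(out, sprintf("power_curve_%s.csv", f)),
                row.names = FALSE)
  }
  structure(res, class = "pdx_power_curves")
}

#' @export
print.pdx_power_curves <- function(x, ...) {
  cat("PDX power curves:\n")
  for (nm in names(x))
    cat(sprintf("  $%s: %d conditions\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Plot power curves
#'
#' Base-graphics panels of the three curve families from
#' [run_power_curves()], one line per alpha level (and per measurement
#' frequency for the schedule panel), with the 80% power threshold
#' marked.
#'
#' @param x A `pdx_power_curves` object.
#' @param which Which families to draw.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.pdx_power_curves <- function(x, which = names(x), ...) {
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (nm in which) {
    df <- x[[nm]]
    xvar <- switch(nm, effect = "beta_effect", variation = "tau1",
                   schedule = "weeks")
    if (nm == "schedule") {
      ka <- interaction(df$per_week, df$alpha)
      wide <- tapply(df$power_analytic, list(df$weeks, ka), mean)
      graphics::matplot(sort(unique(df$weeks)), wide, type = "b",
                        pch = 19, lty = 1, xlab = "weeks of follow-up",
                        ylab = "power", ylim = c(0, 1),
                        main = "duration x frequency", ...)
      graphics::legend("bottomright", legend = colnames(wide),
                       col = seq_len(ncol(wide)), lty = 1, pch = 19,
                       title = "per-week.alpha", cex = 0.8, bty = "n")
    } else {
      wide <- tapply(df$power_analytic, list(df[[xvar]], df$alpha), mean)
      graphics::matplot(sort(unique(df[[xvar]])), wide, type = "l",
                        lty = 1, xlab = xvar, ylab = "power",
                        ylim = c(0, 1), main = nm, ...)
      graphics::legend("bottomright", legend = colnames(wide),
                       col = seq_len(ncol(wide)), lty = 1,
                       title = "alpha", cex = 0.8, bty = "n")
    }
    graphics::abline(h = 0.8, lty = 3)
  }
  invisible(x)
}
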