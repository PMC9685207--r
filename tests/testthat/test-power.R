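test_that("analytic power has the exact null level and known limits", {
  for (a in c(0.05, 0.2, 0.5)) {
    p0 <- pdx_params(beta_effect = 0)
    expect_equal(analytic_power(p0, pdx_design(days_4wk_2x, 1, a))$power, a)
  }
  # vanishing variation and a long schedule drive power to 1
  p <- pdx_params(beta_effect = -0.005, tau1 = 1e-6)
  long <- pdx_design(make_schedule(50, 3))
  expect_gt(analytic_power(p, long)$power, 0.999)
  expect_error(schedule_sxx(c(3, 3)), "degenerate")
})

test_that("analytic power is monotone in effect, n, schedule and noise", {
  d <- pdx_design(days_4wk_2x)
  pw <- function(params, design = d) analytic_power(params, design)$power
  effs <- c(-0.005, -0.01, -0.02, -0.044, -0.08)
  p_eff <- vapply(effs, function(b) pw(pdx_params(beta_effect = b)),
                  numeric(1))
  expect_true(all(diff(p_eff) > 0))

  ns <- c(1, 2, 5, 10)
  p_n <- vapply(ns, function(n)
    pw(medians, pdx_design(days_4wk_2x, n)), numeric(1))
  expect_true(all(diff(p_n) > 0))

  p_wk <- vapply(1:8, function(w)
    pw(medians, pdx_design(make_schedule(w, 2))), numeric(1))
  expect_true(all(diff(p_wk) > 0))

  taus <- c(0.001, 0.005, 0.009, 0.013, 0.02)
  p_tau <- vapply(taus, function(t) pw(pdx_params(tau1 = t)), numeric(1))
  expect_true(all(diff(p_tau) < 0))

  sig <- c(0.05, 0.155, 0.4)
  p_sig <- vapply(sig, function(s) pw(pdx_params(sigma = s)), numeric(1))
  expect_true(all(diff(p_sig) < 0))

  expect_lt(pw(medians, pdx_design(days_4wk_2x, 1, 0.05)),
            pw(medians, pdx_design(days_4wk_2x, 1, 0.2)))
  # tau0 and the intercept-slope association do not move slope power
  expect_equal(pw(pdx_params(tau0 = 0.8, tau01 = 0.9)), pw(medians))
})

test_that("Monte-Carlo power agrees with the closed form", {
  p <- pdx_params(beta_effect = -0.044, tau1 = 0.005)
  d <- pdx_design(days_4wk_2x)
  an <- analytic_power(p, d)$power
  sim <- simulate_power(p, d, n_sims = 2000, seed = 31)
  expect_lt(abs(sim$power - an), 3 * max(sim$mc_stderr, 1e-3))
  # reproducible given the seed
  sim2 <- simulate_power(p, d, n_sims = 2000, seed = 31)
  expect_identical(sim$power, sim2$power)
  expect_error(simulate_power(p, d, n_sims = 50), "n_sims")
})

test_that("simulated power orders effect sizes correctly", {
  d <- pdx_design(days_4wk_2x)
  pows <- vapply(c(-0.010, -0.02, -0.044), function(b) {
    simulate_power(pdx_params(beta_effect = b), d,
                   n_sims = 1500, seed = 37)$power
  }, numeric(1))
  expect_true(all(diff(pows) > 0.05))
})

test_that("the naive 1x1x1 t-test over-rejects when mice truly vary", {
  # with one mouse per arm the residual t-test cannot see tau1; its
  # rejection rate under the null exceeds alpha, which is why the
  # known-variance test is the default
  p0 <- pdx_params(beta_effect = 0)       # tau1 = 0.009
  d <- pdx_design(days_4wk_2x, 1, 0.05)
  naive <- simulate_power(p0, d, n_sims = 1500, seed = 41,
                          test = "estimated")
  expect_gt(naive$power, 0.10)
  known <- simulate_power(p0, d, n_sims = 1500, seed = 43, test = "known")
  expect_lt(abs(known$power - 0.05), 3 * sqrt(0.05 * 0.95 / 1500))
})

test_that("sample-size inversion brackets the target power", {
  cases <- expand.grid(beta = c(-0.010, -0.02, -0.044),
                       tau1 = c(0.005, 0.009),
                       alpha = c(0.05, 0.2))
  for (i in seq_len(nrow(cases))) {
    p <- pdx_params(beta_effect = cases$beta[i], tau1 = cases$tau1[i])
    d <- pdx_design(days_4wk_2x, alpha = cases$alpha[i])
    ss <- required_sample_size(p, d)
    expect_gte(ss$achieved_power, 0.80)
    if (ss$n_per_group > 1) {
      below <- analytic_power(
        p, pdx_design(days_4wk_2x, ss$n_per_group - 1, cases$alpha[i]))
      expect_lt(below$power, 0.80)
    }
  }
  expect_error(required_sample_size(pdx_params(beta_effect = 0),
                                    pdx_design(days_4wk_2x)),
               "no finite")
})

test_that("required sample size shrinks with effect and grows with tau1", {
  d <- pdx_design(days_4wk_2x)
  n_by_eff <- vapply(c(-0.010, -0.02, -0.044), function(b)
    required_sample_size(pdx_params(beta_effect = b), d)$n_per_group,
    integer(1))
  expect_true(all(diff(n_by_eff) <= 0))
  n_by_tau <- vapply(c(0.005, 0.009, 0.013), function(t)
    required_sample_size(pdx_params(tau1 = t), d)$n_per_group, integer(1))
  expect_true(all(diff(n_by_tau) >= 0))
})

test_that("retrospective power is analytic power applied row-wise", {
  co <- data.frame(beta_effect = c(-0.02, -0.044, 0),
                   tau1 = c(0.009, 0.005, 0.009),
                   sigma = c(0.155, 0.155, 0.155))
  r <- retrospective_power(co, days_4wk_2x, alphas = c(0.05, 0.2))
  # row 1 is the medium/average cell at n = 1
  expect_equal(r$power_a0.05[1],
               analytic_power(medians, pdx_design(days_4wk_2x))$power)
  # null rows are flagged and sit exactly at alpha
  expect_true(r$no_effect[3])
  expect_equal(r$power_a0.05[3], 0.05)
  expect_equal(r$power_a0.2[3], 0.2)
  s <- attr(r, "summary")
  expect_equal(nrow(s), 2)
  expect_equal(s$median_power[s$alpha == 0.05], median(r$power_a0.05))
  expect_error(retrospective_power(co[, 1:2], days_4wk_2x), "missing")
})
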