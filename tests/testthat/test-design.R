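test_that("make_schedule tiles the weekly measurement pattern", {
  expect_equal(make_schedule(4, 2), c(0, 4, 7, 11, 14, 18, 21, 25))
  expect_equal(make_schedule(1, 2), c(0, 4))
  expect_equal(make_schedule(2, 3), c(0, 2, 4, 7, 9, 11))
  expect_error(make_schedule(4, 4), "unsupported")
  expect_error(make_schedule(0, 2), "integer >= 1")

  for (w in 1:6) for (k in 2:3) {
    s <- make_schedule(w, k)
    expect_length(s, w * k)
    expect_identical(s[1], 0L)
    expect_true(all(diff(s) > 0))
    if (w > 1)            # consecutive weekly tiles are 7 days apart
      expect_equal(s[(k + 1):(w * k)] - s[1:((w - 1) * k)],
                   rep(7L, (w - 1) * k))
  }
  expect_equal(make_schedule(2, 2, offsets = c(0, 3)), c(0, 3, 7, 10))
  expect_error(make_schedule(2, 2, offsets = c(0, 8)), "offsets")
})

test_that("weekly growth ratio is exp(7 * effect), monotone, 1 at zero", {
  expect_equal(effect_to_weekly_ratio(0), 1)
  expect_equal(round(effect_to_weekly_ratio(-0.044), 2), 0.73)
  expect_equal(round(effect_to_weekly_ratio(-0.010), 2), 0.93)
  b <- seq(-0.08, 0.02, by = 0.005)
  expect_true(all(diff(effect_to_weekly_ratio(b)) > 0))
})

test_that("parameter validation enforces a coherent random-effects model", {
  p <- pdx_params()
  expect_equal(p$beta_int, 5.135)
  expect_equal(p$tau1, 0.009)
  # default association is a correlation; its implied covariance is tiny
  expect_equal(p$re_cov[1, 2], 0.034 * 0.28 * 0.009)
  ev <- eigen(p$re_cov, symmetric = TRUE)$values
  expect_true(all(ev >= -1e-12))

  expect_error(pdx_params(sigma = -1), "sigma")
  expect_error(pdx_params(tau1 = -0.1), "tau1")
  expect_error(pdx_params(tau01 = 1.5), "correlation")
  # 0.034 read as a covariance exceeds tau0 * tau1: must be rejected
  expect_error(pdx_params(tau01 = 0.034, tau01_type = "covariance"),
               "positive semidefinite")
  expect_silent(pdx_params(tau01 = 0.002, tau01_type = "covariance"))
})

test_that("design validation catches degenerate schedules", {
  expect_error(pdx_design(days = 5), "at least 2")
  expect_error(pdx_design(days = c(0, 5, 5)), "strictly increasing")
  expect_error(pdx_design(days = c(0, 5), alpha = 1.2), "alpha")
  expect_error(pdx_design(days = c(0, 5), n_per_group = 0), "n_per_group")
  d <- pdx_design(make_schedule(8, 3), n_per_group = 4, alpha = 0.2)
  expect_s3_class(d, "pdx_design")
  expect_length(d$days, 24)
})

test_that("condition grids reproduce the published design cardinalities", {
  ga <- make_condition_grid("effect")
  expect_equal(nrow(ga), 40)               # 20 effects x 2 alphas
  expect_equal(min(ga$beta_effect), -0.08)
  expect_equal(max(ga$beta_effect), 0.019)
  expect_equal(unique(ga$tau1), 0.005)

  gb <- make_condition_grid("variation")
  expect_equal(nrow(gb), 40)
  expect_equal(range(gb$tau1), c(0.0001, 0.02))
  expect_equal(unique(gb$beta_effect), -0.02)

  gc <- make_condition_grid("schedule")
  expect_equal(nrow(gc), 32)               # 8 weeks x 2 freq x 2 alphas
  expect_setequal(unique(gc$weeks), 1:8)

  gd <- make_condition_grid("combination")
  expect_equal(nrow(gd), 48)
  expect_equal(anyDuplicated(gd$label), 0)
  expect_setequal(unique(gd$beta_effect), c(-0.010, -0.02, -0.044))
  expect_setequal(unique(gd$tau1), c(0.005, 0.009))

  expect_error(make_condition_grid("frequency"), "arg")
})

test_that("config files round-trip through YAML and JSON", {
  cfg <- list(params = list(beta_effect = -0.044, tau1 = 0.005),
              design = list(days = c(0, 4, 7, 11), n_per_group = 3,
                            alpha = 0.2))
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  got <- read_config(fy)
  expect_equal(got$params$beta_effect, -0.044)
  expect_equal(got$params$beta_int, 5.135)   # default retained
  expect_equal(got$design$n_per_group, 3L)
  expect_equal(got$design$alpha, 0.2)

  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE, digits = NA)
  gotj <- read_config(fj)
  expect_equal(gotj$params$beta_effect, -0.044)
  expect_equal(gotj$design$days, c(0, 4, 7, 11))

  bad <- list(params = list(beta_wrong = 1))
  yaml::write_yaml(bad, fy)
  expect_error(read_config(fy), "unknown parameter")
})
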