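# Shared fixtures: cohort-median parameters, the standard twice-weekly
# 4-week schedule, and the published 48-cell power / sample-size tables
# used by the reproduction tests.

medians <- pdx_params()           # beta_effect -0.02, tau1 0.009, etc.
days_4wk_2x <- make_schedule(4, 2)

# per-mouse OLS slopes, one per mouse (closed-form simple regression)
per_mouse_slopes <- function(tr) {
  vapply(split(tr, tr$mouse_id, drop = TRUE), function(d) {
    dx <- d$day - mean(d$day)
    sum(dx * d$log_volume) / sum(dx^2)
  }, numeric(1))
}

# Published 48-cell tables.  Cells are keyed by effect category
# (small/medium/large), tau1 category (average/small), duration (weeks),
# frequency (per week) and alpha.  `power` is the published power table,
# `n_req` the published required sample sizes.
published_cells <- local({
  base <- expand.grid(
    effect = c("small", "medium", "large"),
    alpha = c(0.05, 0.2),
    tau1 = c("average", "small"),
    per_week = c(2, 3),
    weeks = c(4, 8),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$power <- c(
    # 4 wk, twice weekly: average tau1 (a=.05 then .2), small tau1
    0.09, 0.25, 0.82, 0.25, 0.50, 0.94,
    0.12, 0.38, 0.96, 0.32, 0.65, 0.99,
    # 4 wk, three times weekly
    0.10, 0.28, 0.86, 0.27, 0.54, 0.96,
    0.15, 0.46, 0.99, 0.35, 0.72, 1.00,
    # 8 wk, twice weekly
    0.12, 0.35, 0.94, 0.30, 0.62, 0.99,
    0.23, 0.71, 1.00, 0.48, 0.89, 1.00,
    # 8 wk, three times weekly
    0.12, 0.36, 0.95, 0.31, 0.62, 0.99,
    0.24, 0.74, 1.00, 0.49, 0.91, 1.00)
  base$n_req <- c(
    21, 5, 1, 12, 3, 1,   13, 3, 1, 7, 2, 1,
    18, 5, 1, 11, 3, 1,   10, 3, 1, 6, 2, 1,
    14, 4, 1, 8, 2, 1,     6, 2, 1, 4, 1, 1,
    14, 4, 1, 8, 2, 1,     5, 2, 1, 3, 1, 1)
  base
})

cell_params <- function(effect, tau1) {
  lv <- condition_levels()
  pdx_params(beta_effect = lv$effect[[effect]], tau1 = lv$tau1[[tau1]])
}
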