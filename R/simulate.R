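#' Simulate a two-arm PDX growth experiment
#'
#' Draws longitudinal log-tumor-volume trajectories under the log-linear
#' mixed-effects growth model.  For each mouse a random intercept and
#' slope are drawn from a bivariate normal with SDs `tau0`, `tau1` and
#' the configured association; measurements then follow
#' `log_volume = (beta_int + gamma*T + b0) + (beta_day + beta_effect*T + b1)*day + eps`,
#' with i.i.d. Gaussian residuals of SD `sigma`.  Mice are independent;
#' data are complete and balanced on the design's schedule.
#'
#' Simulation happens directly on the log scale, where the model is
#' linear; [write_trajectories()] can exponentiate on export.
#'
#' @param params A [pdx_params()] object.
#' @param design A [pdx_design()] object.
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return A data frame of class `pdx_trajectories` with columns
#'   `mouse_id` (factor), `group` (`"control"`/`"treated"`), `day`,
#'   `log_volume`, one row per mouse per scheduled day, and attributes
#'   `params`, `design`, `seed`.
#' @examples
#' tr <- simulate_experiment(pdx_params(), pdx_design(n_per_group = 3),
#'                           seed = 42)
#' head(tr)
#' @export
simulate_experiment <- function(params, design, seed = NULL) {
  stopifnot(inherits(params, "pdx_params"), inherits(design, "pdx_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_per_group
  days <- design$days
  n_mice <- 2L * n
  trt <- rep(c(0L, 1L), each = n)

  ## correlated (b0, b1) via Cholesky of the 2x2 covariance
  re <- .draw_random_effects(n_mice, params$re_cov)

  id <- rep(seq_len(n_mice), each = length(days))
  d <- rep(days, times = n_mice)
  ti <- trt[id]
  mu <- (params$beta_int + params$gamma * ti + re[id, 1L]) +
        (params$beta_day + params$beta_effect * ti + re[id, 2L]) * d
  y <- mu + rnorm(length(d), 0, params$sigma)

  out <- data.frame(
    mouse_id = factor(sprintf("m%02d", id), levels = sprintf("m%02d", seq_len(n_mice))),
    group = factor(ifelse(ti == 1L, "treated", "control"),
                   levels = c("control", "treated")),
    day = d,
    log_volume = y)
  attr(out, "params") <- params
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  class(out) <- c("pdx_trajectories", "data.frame")
  out
}

## n draws of (b0, b1); handles singular covariances (tau0 or tau1 = 0).
.draw_random_effects <- function(n, re_cov) {
  z <- matrix(rnorm(2L * n), n, 2L)
  L <- tryCatch(t(chol(re_cov)), error = function(e) NULL)
  if (is.null(L)) {            # PSD but singular: use eigen square root
    e <- eigen(re_cov, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2L)
  }
  z %*% t(L)
}

#' Write / read trajectory CSV files
#'
#' `write_trajectories()` writes a tidy UTF-8 CSV with header
#' `mouse_id,group,day,log_volume` (or `volume_mm3` when
#' `scale = "volume"`, in which case log-volumes are exponentiated).
#' `read_trajectories()` reads either dialect back; raw volumes are
#' log-transformed and must be strictly positive.  Duplicate
#' (mouse, day) rows and missing columns are rejected.
#'
#' @param trajectories A `pdx_trajectories` data frame (or any data frame
#'   with the same columns).
#' @param path File path.
#' @param scale Write `log_volume` (default) or raw `volume_mm3`.
#' @return `write_trajectories()` returns `path` invisibly;
#'   `read_trajectories()` returns a `pdx_trajectories` data frame.
#' @examples
#' tr <- simulate_experiment(pdx_params(), pdx_design(n_per_group = 2), 1)
#' f <- tempfile(fileext = ".csv")
#' write_trajectories(tr, f)
#' tr2 <- read_trajectories(f)
#' all.equal(tr$log_volume, tr2$log_volume)
#' @export
write_trajectories <- function(trajectories, path,
                               scale = c("log", "volume")) {
  scale <- match.arg(scale)
  df <- as.data.frame(trajectories)[, c("mouse_id", "group", "day",
                                        "log_volume")]
  if (scale == "volume") {
    df$volume_mm3 <- exp(df$log_volume)
    df$log_volume <- NULL
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mouse_id", "group", "day")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("log_volume" %in% names(df)) {
    y <- df$log_volume
  } else if ("volume_mm3" %in% names(df)) {
    if (any(!is.finite(df$volume_mm3) | df$volume_mm3 <= 0))
      stop("volumes must be strictly positive for the log transform",
           call. = FALSE)
    y <- log(df$volume_mm3)
  } else {
    stop("need a 'log_volume' or 'volume_mm3' column", call. = FALSE)
  }
  if (anyDuplicated(df[, c("mouse_id", "day")]))
    stop("duplicate (mouse_id, day) rows", call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite log-volumes", call. = FALSE)
  out <- data.frame(
    mouse_id = factor(df$mouse_id),
    group = factor(df$group, levels = c("control", "treated")),
    day = as.numeric(df$day),
    log_volume = as.numeric(y))
  if (anyNA(out$group))
    stop("'group' must be 'control' or 'treated'", call. = FALSE)
  class(out) <- c("pdx_trajectories", "data.frame")
  out
}

#' @export
print.pdx_trajectories <- function(x, ...) {
  n_mice <- length(unique(x$mouse_id))
  cat(sprintf("PDX trajectories: %d mice (%d control, %d treated), %d days, %d records\n",
              n_mice,
              length(unique(x$mouse_id[x$group == "control"])),
              length(unique(x$mouse_id[x$group == "treated"])),
              length(unique(x$day)), nrow(x)))
  print(head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("  ... (", nrow(x) - 4L, " more rows)\n", sep = "")
  invisible(x)
}
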