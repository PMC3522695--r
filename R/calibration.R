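# Four-step calibration of the population model against tumor-volume
# time series: (1) control fixes T and K*; (2) as-bcl-2 fixes K' with T
# held; (3) anti-CD-20 fixes K''g with T and K* held; (4) the combination
# arm is predicted with no free parameters.

ARM_LEVELS <- c("control", "as_bcl2", "anti_cd20", "combination")

#' Tumor-volume time series for one treatment arm
#'
#' Long-format measurements for one arm: per-animal rows and/or a
#' group-mean row set (`animal_id = "mean"`) with the standard error of
#' the mean across animals. Rows are sorted by animal and day so that
#' downstream results are invariant to input row order.
#'
#' @param group Arm label, one of `"control"`, `"as_bcl2"`,
#'   `"anti_cd20"`, `"combination"`.
#' @param data A data frame with columns `animal_id` (character; `"mean"`
#'   for group means), `day` (days since first measurement), `volume`
#'   (tumor volume, mm^3, or nondimensional after normalisation) and
#'   optionally `sem` (same units, `NA` where unavailable).
#' @param normalized Whether volumes are already divided by their day-0
#'   value.
#' @return An object of class `tumor_series`.
#' @export
tumor_series <- function(group, data, normalized = FALSE) {
  group <- match.arg(group, ARM_LEVELS)
  need <- c("animal_id", "day", "volume")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("`data` must have columns animal_id, day, volume", call. = FALSE)
  if (!"sem" %in% names(data)) data$sem <- NA_real_
  data <- data[c("animal_id", "day", "volume", "sem")]
  data$animal_id <- as.character(data$animal_id)
  if (any(!is.finite(data$day)) || any(data$day < 0))
    stop("`day` must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(data$volume)) || any(data$volume <= 0))
    stop("volumes must be finite and positive", call. = FALSE)
  data <- data[order(data$animal_id, data$day), , drop = FALSE]
  rownames(data) <- NULL
  for (id in unique(data$animal_id)) {
    d <- data$day[data$animal_id == id]
    if (anyDuplicated(d))
      stop("duplicate day for animal '", id, "'", call. = FALSE)
    if (!0 %in% d)
      stop("animal '", id, "' has no day-0 measurement", call. = FALSE)
  }
  structure(list(group = group, data = data, normalized = normalized),
            class = "tumor_series")
}

#' @export
print.tumor_series <- function(x, ...) {
  ids <- unique(x$data$animal_id)
  cat(sprintf("Tumor series '%s': %d series (%s), %d rows, days %g-%g%s\n",
              x$group, length(ids),
              paste(utils::head(ids, 6), collapse = ", "),
              nrow(x$data), min(x$data$day), max(x$data$day),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalise a series by its initial volume
#'
#' Divides each animal's (and the mean series') volumes by its own day-0
#' volume, giving the nondimensional population \eqn{N^* = N/N(0)} the
#' model works in; SEMs are scaled by the same factor. Refuses to run
#' twice.
#'
#' @param x A [tumor_series].
#' @return The normalised [tumor_series]; every series has value exactly
#'   1 at day 0.
#' @export
normalize_series <- function(x) {
  stopifnot(inherits(x, "tumor_series"))
  if (x$normalized)
    stop("series is already normalized", call. = FALSE)
  d <- x$data
  for (id in unique(d$animal_id)) {
    sel <- d$animal_id == id
    v0 <- d$volume[sel & d$day == 0]
    d$volume[sel] <- d$volume[sel] / v0
    d$sem[sel] <- d$sem[sel] / v0
  }
  tumor_series(x$group, d, normalized = TRUE)
}

#' Fit configuration
#'
#' @param window `"full"` (all measurement days) or `"early"` (days 0-7);
#'   both parameter sets are meaningful because single-dose treatment
#'   effects concentrate in the first week.
#' @param bounds Named list: `T` gives the search range of the e-folding
#'   time in days, `k` the range of all dimensionless rate ratios.
#' @param weighting `"sem"` weights squared log-residuals by
#'   `(value/sem)^2` (the delta-method weight of a log-scale residual)
#'   when every SEM is available, `"none"` uses unit weights.
#' @param grid_T,grid_k Number of coarse grid points per axis searched
#'   before local refinement.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(window = c("full", "early"),
                       bounds = list(T = c(1, 30), k = c(0, 10)),
                       weighting = c("sem", "none"),
                       grid_T = 30, grid_k = 101) {
  window <- match.arg(window)
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(bounds$T), length(bounds$T) == 2, bounds$T[1] > 0,
            is.numeric(bounds$k), length(bounds$k) == 2, bounds$k[1] >= 0)
  structure(list(window = window, bounds = bounds, weighting = weighting,
                 grid_T = grid_T, grid_k = grid_k),
            class = "fit_config")
}

# group-mean rows if present, else the single animal's rows
series_for_fit <- function(x) {
  stopifnot(inherits(x, "tumor_series"))
  if (!x$normalized)
    stop("series must be normalized before fitting", call. = FALSE)
  d <- x$data
  if ("mean" %in% d$animal_id) return(d[d$animal_id == "mean", , drop = FALSE])
  ids <- unique(d$animal_id)
  if (length(ids) == 1L) return(d)
  stop("multiple animals present but no 'mean' series; fit group means",
       call. = FALSE)
}

apply_window <- function(d, window) {
  if (window == "early") d <- d[d$day <= 7, , drop = FALSE]
  d
}

# weighted least squares on log N*; weight (N*/sem)^2 is the log-scale
# delta-method weight 1/Var(log N*)
fit_weights <- function(d, weighting) {
  if (weighting == "sem" && all(is.finite(d$sem)) && all(d$sem > 0))
    (d$volume / d$sem)^2
  else
    rep(1, nrow(d))
}

log_loss <- function(model_vals, d, w) {
  sum(w * (log(pmax(model_vals, 1e-12)) - log(d$volume))^2)
}

new_fit_result <- function(step, fitted, fixed, window_days, loss, traj) {
  structure(list(step = step, fitted = fitted, fixed = fixed,
                 window = window_days, loss = loss, trajectory = traj),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Calibration step %d  (window %g-%g days)\n",
              x$step, x$window[1], x$window[2]))
  if (length(x$fitted)) {
    cat("  fitted:",
        paste(sprintf("%s = %.6g", names(x$fitted), unlist(x$fitted)),
              collapse = ", "), "\n")
  } else cat("  fitted: none (pure prediction)\n")
  if (length(x$fixed))
    cat("  fixed: ",
        paste(sprintf("%s = %.6g", names(x$fixed), unlist(x$fixed)),
              collapse = ", "), "\n")
  cat(sprintf("  loss: %.6g\n", x$loss))
  invisible(x)
}

#' Step 1: fit T and K* on the control arm
#'
#' With no antibody (\eqn{K'' = 0}) and \eqn{N^*(0) = 1}, finds the
#' e-folding time `T` and the death/birth ratio `K*` minimising the
#' weighted least-squares objective on log-transformed normalised
#' volumes. A coarse grid over the bounds is searched first (ties broken
#' toward the lexicographically smallest parameter vector), then refined
#' with box-constrained quasi-Newton iterations.
#'
#' @param control Normalised [tumor_series] for the control arm.
#' @param cfg A [fit_config].
#' @return A `fit_result` with `fitted$T_days` and `fitted$k_star`.
#' @export
fit_step1 <- function(control, cfg = fit_config()) {
  d <- apply_window(series_for_fit(control), cfg$window)
  if (nrow(d) < 3)
    stop("step 1 needs at least 3 time points in the window ",
         "(2 free parameters)", call. = FALSE)
  w <- fit_weights(d, cfg$weighting)
  obj <- function(par) {
    p <- model_params(par[1], par[2])
    log_loss(logistic_solution(p, d$day / par[1])$n_star, d, w)
  }
  lo <- c(cfg$bounds$T[1], cfg$bounds$k[1])
  hi <- c(cfg$bounds$T[2], cfg$bounds$k[2])
  grid <- expand.grid(
    k = seq(lo[2], hi[2], length.out = cfg$grid_k),
    T = seq(lo[1], hi[1], length.out = cfg$grid_T)
  )[, c("T", "k")]
  gl <- apply(grid, 1, obj)
  best <- order(gl, grid$T, grid$k)[1]
  start <- as.numeric(grid[best, ])
  opt <- stats::optim(start, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(factr = 1e2, maxit = 500))
  par <- if (opt$value <= gl[best]) opt$par else start
  loss <- min(opt$value, gl[best])
  p <- model_params(par[1], par[2])
  new_fit_result(1L,
                 fitted = list(T_days = par[1], k_star = par[2]),
                 fixed = list(k_kill = 0, g = 1, n0 = 1),
                 window_days = range(d$day), loss = loss,
                 traj = logistic_solution(p, d$day / par[1]))
}

# one-parameter grid + golden-section refinement, deterministic
fit_one_param <- function(obj, bounds, grid_n) {
  ks <- seq(bounds[1], bounds[2], length.out = grid_n)
  gl <- vapply(ks, obj, numeric(1))
  best <- which.min(gl)
  step <- diff(bounds) / (grid_n - 1)
  lo <- max(bounds[1], ks[best] - step)
  hi <- min(bounds[2], ks[best] + step)
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
  if (opt$objective <= gl[best]) list(par = opt$minimum, loss = opt$objective)
  else list(par = ks[best], loss = gl[best])
}

#' Step 2: fit K' on the as-bcl-2 arm
#'
#' The antisense oligonucleotide is modelled as changing only the
#' death/birth ratio, written \eqn{K'}. `T` is held at the step-1 value.
#'
#' @param asbcl2 Normalised [tumor_series] for the as-bcl-2 arm.
#' @param T_days E-folding time fixed from step 1.
#' @param cfg A [fit_config].
#' @return A `fit_result` with `fitted$k_prime`.
#' @export
fit_step2 <- function(asbcl2, T_days, cfg = fit_config()) {
  d <- apply_window(series_for_fit(asbcl2), cfg$window)
  if (nrow(d) < 2)
    stop("step 2 needs at least 2 time points in the window", call. = FALSE)
  w <- fit_weights(d, cfg$weighting)
  obj <- function(k) {
    log_loss(logistic_solution(model_params(T_days, k),
                               d$day / T_days)$n_star, d, w)
  }
  fit <- fit_one_param(obj, cfg$bounds$k, cfg$grid_k * 2 - 1)
  p <- model_params(T_days, fit$par)
  new_fit_result(2L,
                 fitted = list(k_prime = fit$par),
                 fixed = list(T_days = T_days, k_kill = 0, g = 1, n0 = 1),
                 window_days = range(d$day), loss = fit$loss,
                 traj = logistic_solution(p, d$day / T_days))
}

#' Step 3: fit K''g on the anti-CD-20 arm
#'
#' The antibody adds the direct-kill term; `T` and `K*` are held at
#' their step-1 values and the product \eqn{K''g} is the single free
#' parameter (at the reference dose \eqn{g = 1}, so the product is
#' \eqn{K''} itself).
#'
#' @param rituximab Normalised [tumor_series] for the anti-CD-20 arm.
#' @param T_days,k_star Parameters fixed from step 1.
#' @param cfg A [fit_config].
#' @return A `fit_result` with `fitted$k_killg`.
#' @export
fit_step3 <- function(rituximab, T_days, k_star, cfg = fit_config()) {
  d <- apply_window(series_for_fit(rituximab), cfg$window)
  if (nrow(d) < 2)
    stop("step 3 needs at least 2 time points in the window", call. = FALSE)
  w <- fit_weights(d, cfg$weighting)
  obj <- function(kg) {
    p <- model_params(T_days, k_star, k_kill = kg, g = 1)
    log_loss(logistic_solution(p, d$day / T_days)$n_star, d, w)
  }
  fit <- fit_one_param(obj, cfg$bounds$k, cfg$grid_k * 2 - 1)
  p <- model_params(T_days, k_star, k_kill = fit$par, g = 1)
  new_fit_result(3L,
                 fitted = list(k_killg = fit$par),
                 fixed = list(T_days = T_days, k_star = k_star, g = 1, n0 = 1),
                 window_days = range(d$day), loss = fit$loss,
                 traj = logistic_solution(p, d$day / T_days))
}

#' Step 4: predict the combination arm
#'
#' Builds the combination-therapy trajectory from the parameters fitted
#' on the single-agent arms, with no free parameters: death/birth ratio
#' \eqn{K'} (as-bcl-2 present) and kill term \eqn{K''g} (antibody
#' present) act together. Two modes:
#' \itemize{
#'   \item single regime: \eqn{(K', K''g)} throughout;
#'   \item two-phase: an early regime up to `switch_day`, then the
#'     `late` parameter set continuing from the carried-over population
#'     (single-dose drugs wane; the early window and the post-day-7
#'     regrowth need not share effective parameters).
#' }
#'
#' @param T_days E-folding time (step 1).
#' @param k_prime Death/birth ratio under as-bcl-2 (step 2).
#' @param k_killg Kill/death ratio times dose factor (step 3).
#' @param days Measurement days at which to evaluate the prediction.
#' @param switch_day Day of the regime switch (two-phase mode only).
#' @param late Named list `list(k_prime=, k_killg=)` for the post-switch
#'   regime; `NULL` gives the single-regime mode.
#' @return A [trajectory] evaluated at `days`.
#' @export
predict_combination <- function(T_days, k_prime, k_killg, days,
                                switch_day = 7, late = NULL) {
  t_star <- days / T_days
  early <- model_params(T_days, k_prime, k_kill = k_killg, g = 1)
  if (is.null(late)) {
    sched <- regime_schedule(early)
  } else {
    plate <- model_params(T_days, late$k_prime, k_kill = late$k_killg, g = 1)
    sched <- regime_schedule(list(early, plate),
                             start = c(0, switch_day / T_days))
  }
  simulate_regimes(sched, t_star)
}

#' Run the full four-step calibration
#'
#' Executes steps 1-4 in order on a four-arm dataset, threading the
#' fixed parameters through, and evaluates the no-free-parameter
#' combination prediction against the combination arm.
#'
#' @param dataset Named list of [tumor_series] (names
#'   `control`, `as_bcl2`, `anti_cd20`, `combination`), or a cohort from
#'   [generate_cohort]. Unnormalised series are normalised first.
#' @param cfg A [fit_config].
#' @param predict_mode `"single"` or `"two_phase"`; in two-phase mode the
#'   early window (days 0-7) parameter set drives the first phase and the
#'   full-window set the regrowth phase after `switch_day`.
#' @param switch_day Regime switch day for two-phase prediction.
#' @return An object of class `fit_set`: `$steps` (four `fit_result`s),
#'   `$params` (the threaded parameter values), `$prediction`, and the
#'   observed combination series.
#' @export
fit_all <- function(dataset, cfg = fit_config(),
                    predict_mode = c("single", "two_phase"),
                    switch_day = 7) {
  predict_mode <- match.arg(predict_mode)
  if (inherits(dataset, "tumor_cohort")) dataset <- dataset$series
  missing_arms <- setdiff(ARM_LEVELS, names(dataset))
  if (length(missing_arms))
    stop("dataset is missing arm(s): ", paste(missing_arms, collapse = ", "),
         call. = FALSE)
  dataset <- lapply(dataset[ARM_LEVELS], function(s) {
    if (s$normalized) s else normalize_series(s)
  })

  s1 <- fit_step1(dataset$control, cfg)
  T_days <- s1$fitted$T_days
  k_star <- s1$fitted$k_star
  s2 <- fit_step2(dataset$as_bcl2, T_days, cfg)
  s3 <- fit_step3(dataset$anti_cd20, T_days, k_star, cfg)

  dcomb <- series_for_fit(dataset$combination)
  if (predict_mode == "single") {
    pred <- predict_combination(T_days, s2$fitted$k_prime, s3$fitted$k_killg,
                                dcomb$day)
  } else {
    cfg_e <- cfg; cfg_e$window <- "early"
    cfg_f <- cfg; cfg_f$window <- "full"
    s2e <- fit_step2(dataset$as_bcl2, T_days, cfg_e)
    s3e <- fit_step3(dataset$anti_cd20, T_days, k_star, cfg_e)
    s2f <- fit_step2(dataset$as_bcl2, T_days, cfg_f)
    s3f <- fit_step3(dataset$anti_cd20, T_days, k_star, cfg_f)
    pred <- predict_combination(
      T_days, s2e$fitted$k_prime, s3e$fitted$k_killg, dcomb$day,
      switch_day = switch_day,
      late = list(k_prime = s2f$fitted$k_prime, k_killg = s3f$fitted$k_killg))
  }
  w4 <- fit_weights(dcomb, cfg$weighting)
  s4 <- new_fit_result(4L, fitted = list(),
                       fixed = list(T_days = T_days, k_prime = s2$fitted$k_prime,
                                    k_killg = s3$fitted$k_killg, n0 = 1),
                       window_days = range(dcomb$day),
                       loss = log_loss(pred$n_star, dcomb, w4),
                       traj = pred)

  structure(list(
    steps = list(step1 = s1, step2 = s2, step3 = s3, step4 = s4),
    params = list(T_days = T_days, k_star = k_star,
                  k_prime = s2$fitted$k_prime, k_killg = s3$fitted$k_killg),
    prediction = pred,
    observed_combination = dcomb,
    config = cfg, predict_mode = predict_mode, switch_day = switch_day
  ), class = "fit_set")
}

#' @export
print.fit_set <- function(x, ...) {
  cat("Four-step calibration\n")
  p <- x$params
  cat(sprintf("  T = %.4g days, K* = %.4g, K' = %.4g, K''g = %.4g\n",
              p$T_days, p$k_star, p$k_prime, p$k_killg))
  cat(sprintf("  combination prediction (%s mode): loss %.4g on %d days\n",
              x$predict_mode, x$steps$step4$loss,
              length(x$prediction$t_star)))
  invisible(x)
}
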