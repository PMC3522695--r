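# Synthetic tumor-volume cohorts with the statistical structure the
# calibration assumes: model-driven trajectories per arm, per-animal
# initial-volume variation, sparse measurement days, multiplicative
# lognormal measurement noise. Also the noiseless reference fixtures
# built from the DoHH2 xenograft parameter sets.

V0_DEFAULT <- c(control = 158, as_bcl2 = 114, anti_cd20 = 125,
                combination = 109)

#' Reference DoHH2 xenograft parameter sets
#'
#' The fitted nondimensional parameters for the four treatment arms of
#' the DoHH2 SCID-mouse xenograft experiments (single-dose as-bcl-2 at
#' 200 ug/g, rituximab at 5 ug/g, so g = 1): e-folding time T = 7 days
#' throughout; `"early"` gives the parameter set matching the first week
#' only (K* = 0.11, K' = 0.15, K''g = 3.5), `"full"` the whole-window
#' set (K* = 0.11, K' = 0.09, K''g = 2).
#'
#' @param window `"early"` or `"full"`.
#' @return Named list of [model_params], one per arm.
#' @seealso [arm_params_table] for the same values in the tabular form
#'   [lifetime_table] consumes; [dohh2_lifetimes] for the published
#'   rounded lifetimes.
#' @export
dohh2_params <- function(window = c("early", "full")) {
  window <- match.arg(window)
  k_prime <- if (window == "early") 0.15 else 0.09
  k_killg <- if (window == "early") 3.5 else 2
  list(
    control = model_params(7, 0.11),
    as_bcl2 = model_params(7, k_prime),
    anti_cd20 = model_params(7, 0.11, k_kill = k_killg, g = 1),
    combination = model_params(7, k_prime, k_kill = k_killg, g = 1)
  )
}

#' Arm parameters as a table
#'
#' Flattens a per-arm parameter list into the `(arm, k_ratio, k_killg)`
#' data frame [lifetime_table] consumes.
#'
#' @param params Named list of [model_params], e.g. from [dohh2_params].
#' @return A data frame with one row per arm.
#' @export
arm_params_table <- function(params) {
  data.frame(
    arm = names(params),
    k_ratio = vapply(params, `[[`, numeric(1), "k_star"),
    k_killg = vapply(params, function(p) p$k_kill * p$g, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Published rounded lifetimes for the DoHH2 arms
#'
#' The rounded maximum cell lifetimes (days) reported for the reference
#' experiments, usable as the `reference` argument of [lifetime_table].
#' Note the full-window anti-CD-20 entry: the lifetime formula gives
#' 7/(0.11 x 4) = 15.9 days, rounding to 16, while the reference table
#' prints 15; [lifetime_table] flags this rather than forcing agreement.
#'
#' @param window `"early"` or `"full"`.
#' @return Named numeric vector of lifetimes per arm.
#' @export
dohh2_lifetimes <- function(window = c("early", "full")) {
  window <- match.arg(window)
  if (window == "early")
    c(control = 32, as_bcl2 = 23, anti_cd20 = 12, combination = 8)
  else
    c(control = 32, as_bcl2 = 39, anti_cd20 = 15, combination = 19)
}

#' Specification of a synthetic cohort
#'
#' Describes a four-arm mouse cohort the way the reference experiments
#' were run: a handful of animals per arm, volumes followed over about
#' three weeks on a sparse day grid, per-animal initial volumes around
#' the arm means, multiplicative measurement noise on every volume.
#'
#' @param arm_params Named list of true per-arm [model_params] (or
#'   [regime_schedule]s for two-phase truths); defaults to the
#'   full-window DoHH2 set.
#' @param n_animals Animals per arm.
#' @param days Measurement days; must include day 0.
#' @param v0_mean Named vector of mean initial volumes per arm, mm^3.
#' @param v0_cv Lognormal coefficient of variation of per-animal initial
#'   volumes.
#' @param noise_cv Lognormal CV of multiplicative measurement noise,
#'   independent across animals and days.
#' @param k_jitter_cv Optional lognormal CV of per-animal jitter on the
#'   death/birth ratio (between-animal biological variability; 0 = off).
#' @param seed Integer seed; mandatory, the single source of randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(arm_params = dohh2_params("full"), n_animals = 5,
                        days = c(0, 5, 7, 11, 15, 19, 23),
                        v0_mean = V0_DEFAULT, v0_cv = 0.15, noise_cv = 0.10,
                        k_jitter_cv = 0, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("`seed` is mandatory and must be a single integer", call. = FALSE)
  if (!0 %in% days) stop("`days` must include day 0", call. = FALSE)
  if (n_animals < 1) stop("`n_animals` must be >= 1", call. = FALSE)
  if (v0_cv < 0 || noise_cv < 0 || k_jitter_cv < 0)
    stop("CVs must be non-negative", call. = FALSE)
  if (!all(ARM_LEVELS %in% names(arm_params)))
    stop("`arm_params` must name all four arms", call. = FALSE)
  if (!all(ARM_LEVELS %in% names(v0_mean)))
    stop("`v0_mean` must name all four arms", call. = FALSE)
  structure(list(arm_params = arm_params[ARM_LEVELS],
                 n_animals = as.integer(n_animals), days = sort(days),
                 v0_mean = v0_mean[ARM_LEVELS], v0_cv = v0_cv,
                 noise_cv = noise_cv, k_jitter_cv = k_jitter_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# mean-1 lognormal multipliers with coefficient of variation cv
ln_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

arm_n_star <- function(p, days) {
  if (inherits(p, "regime_schedule"))
    simulate_regimes(p, days / p$T_days)$n_star
  else
    logistic_solution(p, days / p$T_days)$n_star
}

#' Generate a synthetic tumor-volume cohort
#'
#' Draws per-animal initial volumes, evaluates each arm's true model
#' trajectory on the measurement days, applies multiplicative lognormal
#' measurement noise, and appends group-mean rows with the standard error
#' of the mean across animals. Deterministic given the spec's seed; the
#' ambient RNG state is left untouched.
#'
#' @param spec A [cohort_spec].
#' @return An object of class `tumor_cohort`: `$series` is a named list
#'   of unnormalised [tumor_series], `$spec` the generating spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  nd <- length(spec$days)
  series <- lapply(ARM_LEVELS, function(arm) {
    p <- spec$arm_params[[arm]]
    rows <- lapply(seq_len(spec$n_animals), function(a) {
      v0 <- spec$v0_mean[[arm]] * ln_mult(1, spec$v0_cv)
      pa <- p
      if (spec$k_jitter_cv > 0 && !inherits(p, "regime_schedule"))
        pa <- model_params(p$T_days, p$k_star * ln_mult(1, spec$k_jitter_cv),
                           p$k_kill, p$g, p$n0)
      vol <- v0 * arm_n_star(pa, spec$days) * ln_mult(nd, spec$noise_cv)
      data.frame(animal_id = sprintf("m%d", a), day = spec$days,
                 volume = vol, sem = NA_real_, stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    mv <- tapply(d$volume, d$day, mean)
    ms <- if (spec$n_animals > 1)
      tapply(d$volume, d$day, stats::sd) / sqrt(spec$n_animals)
    else rep(NA_real_, nd)
    mrow <- data.frame(animal_id = "mean",
                       day = as.numeric(names(mv)),
                       volume = as.numeric(mv), sem = as.numeric(ms),
                       stringsAsFactors = FALSE)
    tumor_series(arm, rbind(d, mrow))
  })
  names(series) <- ARM_LEVELS
  structure(list(series = series, spec = spec), class = "tumor_cohort")
}

#' @export
print.tumor_cohort <- function(x, ...) {
  cat(sprintf("Synthetic tumor cohort: 4 arms x %d animals, days %s (seed %d)\n",
              x$spec$n_animals, paste(x$spec$days, collapse = ","),
              x$spec$seed))
  invisible(x)
}

#' Noiseless reference fixture
#'
#' Group-mean dataset generated exactly from the DoHH2 parameter set of
#' the chosen window on the default day grid: per-arm mean volumes are
#' the printed initial means times the closed-form model trajectory, with
#' no noise and no SEM. Suitable for round-trip parameter-recovery
#' checks.
#'
#' @param window `"early"` or `"full"` parameter set (see [dohh2_params]).
#' @param days Measurement days.
#' @return A `tumor_cohort` of mean-only series.
#' @export
dohh2_fixture <- function(window = c("early", "full"),
                          days = c(0, 5, 7, 11, 15, 19, 23)) {
  window <- match.arg(window)
  params <- dohh2_params(window)
  series <- lapply(ARM_LEVELS, function(arm) {
    p <- params[[arm]]
    tumor_series(arm, data.frame(
      animal_id = "mean", day = days,
      volume = V0_DEFAULT[[arm]] * arm_n_star(p, days),
      sem = NA_real_, stringsAsFactors = FALSE))
  })
  names(series) <- ARM_LEVELS
  spec <- cohort_spec(arm_params = params, n_animals = 1L, days = days,
                      v0_cv = 0, noise_cv = 0, seed = 0L)
  structure(list(series = series, spec = spec, window = window),
            class = "tumor_cohort")
}
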