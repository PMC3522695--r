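# Nondimensional logistic-type model of malignant B-cell population dynamics.
#
# dN*/dt* = N* - K*.(1 + N* + K''g).N*
#
# with N* = N/N(0), t* = t/T, T = 1/K_b the e-folding time of untreated
# growth. K* (K' under as-bcl-2) is the death/birth rate ratio, K'' the
# kill/death rate ratio of anti-CD-20, g the dose factor (g = 1 at the
# reference dose of 5 ug rituximab per g body mass).

#' Nondimensional model parameters for one treatment regime
#'
#' Bundles the parameters of the nondimensional B-cell population model:
#' the birth-rate time scale, the death/birth ratio, the antibody
#' kill/death ratio and the dose factor. The crowding enhancement of the
#' death rate, \eqn{f = 1 + N^*}, is structural and carries no parameter.
#'
#' @param T_days Characteristic e-folding time \eqn{T = 1/K_b} in days;
#'   the time for e-fold growth of the untreated population.
#' @param k_star Dimensionless death/birth rate ratio \eqn{K^* = K_d/K_b}
#'   (written \eqn{K'} for arms receiving as-bcl-2).
#' @param k_kill Dimensionless kill/death rate ratio \eqn{K''} of the
#'   anti-CD-20 antibody; 0 for arms without antibody.
#' @param g Dimensionless dose factor, normalised so that \eqn{g = 1} at
#'   5 micrograms antibody per gram body mass.
#' @param n0 Initial nondimensional population \eqn{N^*(0)}; 1 by
#'   construction when populations are normalised by their initial value.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(T_days = 7, k_star = 0.11)
#' growth_rate(1, p)
#' @export
model_params <- function(T_days, k_star, k_kill = 0, g = 1, n0 = 1) {
  for (nm in c("T_days", "k_star", "k_kill", "g", "n0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (T_days <= 0) stop("`T_days` must be positive", call. = FALSE)
  if (k_star < 0) stop("`k_star` must be non-negative", call. = FALSE)
  if (k_kill < 0) stop("`k_kill` must be non-negative", call. = FALSE)
  if (g < 0) stop("`g` must be non-negative", call. = FALSE)
  if (n0 <= 0) stop("`n0` must be positive", call. = FALSE)
  structure(
    list(T_days = T_days, k_star = k_star, k_kill = k_kill, g = g, n0 = n0),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Nondimensional growth model parameters\n")
  cat(sprintf("  T = %g days (e-folding time),  K* = %g,  K''g = %g,  N*(0) = %g\n",
              x$T_days, x$k_star, x$k_kill * x$g, x$n0))
  invisible(x)
}

# net linear rate r and self-limitation coefficient A of the logistic form
# dN*/dt* = r N* - A N*^2, with r = 1 - K*(1 + K''g), A = K*
logistic_coefs <- function(p) {
  list(r = 1 - p$k_star * (1 + p$k_kill * p$g), a = p$k_star)
}

#' Population growth rate dN*/dt*
#'
#' Right-hand side of the nondimensional model: birth at unit rate minus
#' death enhanced by crowding and antibody kill,
#' \eqn{dN^*/dt^* = N^* - K^* (1 + N^* + K''g) N^*}.
#'
#' @param n_star Nondimensional population \eqn{N^* \ge 0} (vectorised).
#' @param p A [model_params] object.
#' @return The rate \eqn{dN^*/dt^*}, same length as `n_star`.
#' @export
growth_rate <- function(n_star, p) {
  stopifnot(inherits(p, "model_params"))
  if (!is.numeric(n_star) || any(!is.finite(n_star)))
    stop("`n_star` must be finite numeric", call. = FALSE)
  if (any(n_star < 0))
    stop("`n_star` must be non-negative: populations cannot be negative",
         call. = FALSE)
  n_star - p$k_star * (1 + n_star + p$k_kill * p$g) * n_star
}

#' Closed-form solution of the constant-parameter model
#'
#' For fixed parameters the model is the logistic equation
#' \eqn{dN^*/dt^* = r N^* - A N^{*2}} with \eqn{r = 1 - K^*(1 + K''g)}
#' and \eqn{A = K^*}, whose exact solution is
#' \deqn{N^*(t^*) = \frac{r n_0}{A n_0 + (r - A n_0) e^{-r t^*}}}
#' (and \eqn{n_0/(1 + A n_0 t^*)} in the degenerate case \eqn{r = 0}).
#'
#' @param p A [model_params] object, constant over the grid.
#' @param t_star Nondimensional time points (non-negative, increasing).
#' @param n0 Starting population; defaults to `p$n0`.
#' @return A [trajectory] object.
#' @export
logistic_solution <- function(p, t_star, n0 = p$n0) {
  stopifnot(inherits(p, "model_params"))
  check_time_grid(t_star)
  if (!is.numeric(n0) || length(n0) != 1L || n0 < 0)
    stop("`n0` must be a single non-negative number", call. = FALSE)
  cf <- logistic_coefs(p)
  vals <- logistic_values(cf$r, cf$a, n0, t_star)
  trajectory(t_star, vals, p$T_days)
}

logistic_values <- function(r, a, n0, t_star) {
  if (n0 == 0) return(rep(0, length(t_star)))
  if (abs(r) < 1e-14) {
    vals <- n0 / (1 + a * n0 * t_star)
  } else {
    denom <- a * n0 + (r - a * n0) * exp(-r * t_star)
    vals <- r * n0 / denom
    vals[!is.finite(vals)] <- 0  # exp overflow in strongly decaying regimes
  }
  pmax(vals, 0)
}

#' Numerical solution by adaptive Runge-Kutta
#'
#' Integrates [growth_rate] with `deSolve::ode` (Dormand-Prince 4(5),
#' relative tolerance 1e-8, absolute 1e-10 by default). Used as an
#' independent cross-check of [logistic_solution]; piecewise simulation
#' prefers the closed form inside constant regimes.
#'
#' @inheritParams logistic_solution
#' @param rtol,atol Integration tolerances.
#' @return A [trajectory] object.
#' @export
ode_solution <- function(p, t_star, n0 = p$n0, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "model_params"))
  check_time_grid(t_star)
  deriv <- function(t, y, parms) list(growth_rate(max(y, 0), p))
  out <- deSolve::ode(y = c(n = n0), times = t_star, func = deriv,
                      parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  trajectory(t_star, pmax(out[, "n"], 0), p$T_days)
}

#' Steady state of the constant-parameter model
#'
#' Nontrivial fixed point of the model,
#' \eqn{\max(0,\; 1/K^* - 1 - K''g)}: the crowding-limited plateau of the
#' tumor, driven to extinction when the kill term exceeds the net growth
#' margin.
#'
#' @param p A [model_params] object with `k_star > 0`.
#' @return The non-negative steady-state population.
#' @export
steady_state <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$k_star <= 0)
    stop("no finite steady state: k_star = 0 gives unbounded growth",
         call. = FALSE)
  max(0, 1 / p$k_star - 1 - p$k_kill * p$g)
}

#' Piecewise-constant treatment schedule
#'
#' An ordered sequence of model-parameter regimes with nondimensional
#' switch times. All regimes must share the same `T_days`: the time
#' nondimensionalisation is fixed once per analysis. Used, e.g., to
#' restart the combination-therapy prediction with late-phase parameters
#' at day 7.
#'
#' @param params A [model_params] object or list of them, one per regime.
#' @param start Nondimensional start times, strictly increasing, first 0.
#' @param span Total nondimensional time span covered by the schedule;
#'   defaults to `Inf` (open-ended).
#' @return An object of class `regime_schedule`.
#' @export
regime_schedule <- function(params, start = 0, span = Inf) {
  if (inherits(params, "model_params")) params <- list(params)
  if (!length(params) || !all(vapply(params, inherits, TRUE, "model_params")))
    stop("`params` must be model_params objects", call. = FALSE)
  if (length(start) != length(params))
    stop("`start` must give one start time per regime", call. = FALSE)
  if (start[1] != 0) stop("first regime must start at t* = 0", call. = FALSE)
  if (any(diff(start) <= 0))
    stop("regime start times must be strictly increasing", call. = FALSE)
  if (span <= start[length(start)])
    stop("`span` must exceed the last switch time", call. = FALSE)
  T_all <- vapply(params, `[[`, numeric(1), "T_days")
  if (length(unique(T_all)) != 1L)
    stop("all regimes must share the same `T_days`", call. = FALSE)
  structure(list(params = params, start = start, span = span,
                 T_days = T_all[1]),
            class = "regime_schedule")
}

#' @export
print.regime_schedule <- function(x, ...) {
  cat(sprintf("Treatment schedule: %d regime(s), T = %g days\n",
              length(x$params), x$T_days))
  for (i in seq_along(x$params)) {
    p <- x$params[[i]]
    cat(sprintf("  t* >= %-6g K* = %g, K''g = %g\n",
                x$start[i], p$k_star, p$k_kill * p$g))
  }
  invisible(x)
}

#' Simulate a treatment schedule
#'
#' Solves the model over a piecewise-constant schedule, carrying the
#' population value across each switch (the state is continuous; only
#' parameters change). Within each regime the closed-form logistic
#' solution is used by default; `method = "numeric"` integrates
#' regime-by-regime with [ode_solution] instead.
#'
#' @param s A [regime_schedule] (or a single [model_params], treated as a
#'   one-regime schedule).
#' @param t_star Nondimensional evaluation grid, increasing, within the
#'   schedule span.
#' @param method `"analytic"` (closed form per regime) or `"numeric"`.
#' @return A [trajectory] object.
#' @export
simulate_regimes <- function(s, t_star, method = c("analytic", "numeric")) {
  if (inherits(s, "model_params")) s <- regime_schedule(s)
  stopifnot(inherits(s, "regime_schedule"))
  method <- match.arg(method)
  check_time_grid(t_star)
  if (max(t_star) > s$span)
    stop("`t_star` exceeds the schedule span", call. = FALSE)

  nreg <- length(s$params)
  # carried-over state at each regime start
  n_at <- numeric(nreg)
  n_at[1] <- s$params[[1]]$n0
  solve_one <- function(p, n0, tt) {
    if (method == "analytic") logistic_solution(p, tt, n0)$n_star
    else ode_solution(p, tt, n0)$n_star
  }
  if (nreg > 1) {
    for (i in seq_len(nreg - 1)) {
      dt <- s$start[i + 1] - s$start[i]
      n_at[i + 1] <- solve_one(s$params[[i]], n_at[i], c(0, dt))[2]
    }
  }
  reg <- findInterval(t_star, s$start)
  vals <- numeric(length(t_star))
  for (i in unique(reg)) {
    idx <- reg == i
    vals[idx] <- solve_one(s$params[[i]], n_at[i], t_star[idx] - s$start[i])
  }
  trajectory(t_star, vals, s$T_days)
}

#' Nondimensional population trajectory
#'
#' @param t_star Nondimensional time grid, strictly increasing.
#' @param n_star Population values \eqn{N^*(t^*) \ge 0}.
#' @param T_days The e-folding time attached for conversion to days,
#'   \eqn{t = t^* T}.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(t_star, n_star, T_days) {
  check_time_grid(t_star)
  if (length(n_star) != length(t_star))
    stop("`t_star` and `n_star` must have equal length", call. = FALSE)
  if (any(n_star < 0)) stop("`n_star` must be non-negative", call. = FALSE)
  structure(list(t_star = t_star, n_star = n_star, T_days = T_days),
            class = "trajectory")
}

check_time_grid <- function(t_star) {
  if (!is.numeric(t_star) || !length(t_star) || any(!is.finite(t_star)))
    stop("time grid must be finite numeric", call. = FALSE)
  if (any(t_star < 0)) stop("time grid must be non-negative", call. = FALSE)
  if (length(t_star) > 1 && any(diff(t_star) <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  invisible(t_star)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d points, t* in [%g, %g] (%g to %g days)\n",
              length(x$t_star), min(x$t_star), max(x$t_star),
              min(x$t_star) * x$T_days, max(x$t_star) * x$T_days))
  cat(sprintf("  N* from %.4g to %.4g\n",
              x$n_star[1], x$n_star[length(x$n_star)]))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t_star = x$t_star, t_days = x$t_star * x$T_days,
             n_star = x$n_star)
}

#' Write a trajectory to CSV
#'
#' Columns `t_star,t_days,n_star`, '.' decimal separator, UTF-8. Optional
#' leading `#` comment lines carry provenance (seed, configuration hash).
#'
#' @param x A [trajectory].
#' @param path Output file path.
#' @param comments Character vector written as `# `-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "trajectory"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
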