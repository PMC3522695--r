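# Derived efficacy metrics: death-rate enhancement factor E, characteristic
# malignant-cell lifetimes L and L(0), the per-arm lifetime table and the
# multiplicative-synergy comparison of lifetime ratios.

# half-up rounding (base round() rounds half to even, which would not
# reproduce conventional table rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Death-rate enhancement factor E
#'
#' Total multiplier on the death/birth ratio in the loss term:
#' \eqn{E = 1 + N^* + K''g}, combining baseline death, crowding
#' (hypoxia/starvation at tumor scale) and antibody kill. Along a growing
#' trajectory its minimum is at \eqn{t = 0}, so
#' \eqn{E(0) = 2 + K''g} when \eqn{N^*(0) = 1}.
#'
#' @param n_star Nondimensional population (vectorised).
#' @param k_killg Kill/death ratio times dose factor.
#' @return \eqn{E}, same length as `n_star`.
#' @export
enhancement_factor <- function(n_star, k_killg) {
  if (any(n_star < 0) || any(k_killg < 0))
    stop("`n_star` and `k_killg` must be non-negative", call. = FALSE)
  1 + n_star + k_killg
}

#' Characteristic malignant-cell lifetime
#'
#' \eqn{L = T / (K E)}: the inverse effective death rate in days, where
#' `K` is the death/birth ratio of the arm (K* or K') and `E` the
#' enhancement factor. Its maximum over a growing trajectory, \eqn{L(0)},
#' uses \eqn{E(0)}.
#'
#' @param T_days E-folding time in days.
#' @param k_ratio Death/birth ratio (K* or K').
#' @param E Enhancement factor.
#' @return Lifetime in days, unrounded.
#' @export
cell_lifetime <- function(T_days, k_ratio, E) {
  if (T_days <= 0) stop("`T_days` must be positive", call. = FALSE)
  if (any(k_ratio * E <= 0))
    stop("`k_ratio * E` must be positive (zero effective death rate ",
         "gives an unbounded lifetime)", call. = FALSE)
  T_days / (k_ratio * E)
}

#' Per-arm cell-lifetime table
#'
#' Builds the maximum-lifetime table \eqn{L(0) = T/(K (2 + K''g))} for
#' the four arms, plus the isolated-cell lifetime \eqn{T/K^*} (no
#' crowding, no antibody). Raw values are kept alongside the
#' conventionally rounded ones: per-arm lifetimes to the nearest whole
#' day, the isolated lifetime floored. An optional `reference` vector of
#' published lifetimes is compared against, with disagreement flagged
#' rather than forced.
#'
#' @param T_days E-folding time in days.
#' @param arm_params Data frame with columns `arm` (the four arm labels),
#'   `k_ratio` and `k_killg`. See [dohh2_params] / [arm_params_table] for
#'   the reference sets.
#' @param window Label recorded in the report: `"early"` (parameters from
#'   days 0-7) or `"full"`.
#' @param reference Optional named numeric vector of published rounded
#'   lifetimes per arm for comparison.
#' @return An object of class `lifetime_report` with elements `$table`,
#'   `$isolated_days`, `$ratios` (see [synergy_ratios]) and `$window`.
#' @export
lifetime_table <- function(T_days, arm_params, window = c("early", "full"),
                           reference = NULL) {
  window <- match.arg(window)
  need <- c("arm", "k_ratio", "k_killg")
  if (!is.data.frame(arm_params) || !all(need %in% names(arm_params)))
    stop("`arm_params` needs columns arm, k_ratio, k_killg", call. = FALSE)
  missing_arms <- setdiff(ARM_LEVELS, arm_params$arm)
  if (length(missing_arms))
    stop("missing arm(s): ", paste(missing_arms, collapse = ", "),
         call. = FALSE)
  ap <- arm_params[match(ARM_LEVELS, arm_params$arm), ]
  E0 <- enhancement_factor(1, ap$k_killg)
  L0 <- cell_lifetime(T_days, ap$k_ratio, E0)
  tab <- data.frame(
    arm = ap$arm, k_ratio = ap$k_ratio, k_killg = ap$k_killg, E0 = E0,
    L0_days_raw = L0, L0_days_rounded = round_half_up(L0),
    stringsAsFactors = FALSE
  )
  if (!is.null(reference)) {
    tab$reference_days <- as.numeric(reference[tab$arm])
    tab$flag <- ifelse(
      is.na(tab$reference_days) | tab$reference_days == tab$L0_days_rounded,
      "", sprintf("computed %d, reference table prints %g",
                  as.integer(tab$L0_days_rounded), tab$reference_days))
  }
  k_ctrl <- ap$k_ratio[ap$arm == "control"]
  rep <- structure(list(
    table = tab,
    isolated_days = floor(T_days / k_ctrl),
    isolated_days_raw = T_days / k_ctrl,
    T_days = T_days, window = window
  ), class = "lifetime_report")
  rep$ratios <- synergy_ratios(rep)
  rep
}

#' Lifetime ratios and the multiplicative-synergy comparison
#'
#' Ratios of the control lifetime to each single-agent lifetime, their
#' product, and the control/combination ratio. If the combination acted
#' as the independent product of the single agents, the product of the
#' single-agent ratios would equal the combination ratio; the report
#' carries both and their absolute gap. Ratios are computed from the
#' rounded integer lifetimes and reported to one decimal; the product is
#' the product of the two rounded ratios, again to one decimal.
#'
#' @param report A `lifetime_report` from [lifetime_table].
#' @return A list with `control_vs_as_bcl2`, `control_vs_anti_cd20`,
#'   `product`, `control_vs_combination` and `synergy_gap`.
#' @export
synergy_ratios <- function(report) {
  stopifnot(inherits(report, "lifetime_report"))
  L <- stats::setNames(report$table$L0_days_rounded, report$table$arm)
  if (any(L <= 0)) stop("zero rounded lifetime in report", call. = FALSE)
  r_as <- round_half_up(L["control"] / L["as_bcl2"], 1)
  r_anti <- round_half_up(L["control"] / L["anti_cd20"], 1)
  r_comb <- round_half_up(L["control"] / L["combination"], 1)
  prod <- round_half_up(r_as * r_anti, 1)
  list(control_vs_as_bcl2 = unname(r_as),
       control_vs_anti_cd20 = unname(r_anti),
       product = unname(prod),
       control_vs_combination = unname(r_comb),
       synergy_gap = unname(abs(prod - r_comb)))
}

#' @export
print.lifetime_report <- function(x, ...) {
  cat(sprintf("Cell lifetimes (window: %s, T = %g days)\n", x$window, x$T_days))
  cat(sprintf("  isolated cell: %d days (raw %.2f)\n",
              as.integer(x$isolated_days), x$isolated_days_raw))
  print(x$table, row.names = FALSE, digits = 4)
  r <- x$ratios
  cat(sprintf("  control/as-bcl-2 = %.1f, control/anti-CD-20 = %.1f\n",
              r$control_vs_as_bcl2, r$control_vs_anti_cd20))
  cat(sprintf("  product = %.1f vs control/combination = %.1f (gap %.1f)\n",
              r$product, r$control_vs_combination, r$synergy_gap))
  invisible(x)
}

#' Write a lifetime report
#'
#' CSV with columns `arm,K_ratio,K_killg,E0,L0_days_raw,L0_days_rounded`
#' followed by `#`-prefixed key-value lines with the isolated lifetime
#' and the synergy ratios.
#'
#' @param x A `lifetime_report`.
#' @param path Output file path.
#' @param comments Extra `# `-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_lifetime_report <- function(x, path, comments = character()) {
  stopifnot(inherits(x, "lifetime_report"))
  out <- x$table[c("arm", "k_ratio", "k_killg", "E0",
                   "L0_days_raw", "L0_days_rounded")]
  names(out) <- c("arm", "K_ratio", "K_killg", "E0",
                  "L0_days_raw", "L0_days_rounded")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  kv <- c(sprintf("window = %s", x$window),
          sprintf("T_days = %g", x$T_days),
          sprintf("isolated_days = %d", as.integer(x$isolated_days)),
          sprintf("%s = %g", names(x$ratios), unlist(x$ratios)))
  if (!is.null(x$table$flag) && any(nzchar(x$table$flag)))
    kv <- c(kv, sprintf("flag_%s = %s",
                        x$table$arm[nzchar(x$table$flag)],
                        x$table$flag[nzchar(x$table$flag)]))
  writeLines(paste0("# ", kv), con)
  invisible(path)
}
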