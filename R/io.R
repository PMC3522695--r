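# File I/O and run configuration: the long-format tumor-volume CSV
# schema, YAML run configuration with strict key validation, and the
# plain-text run report.

COHORT_COLS <- c("group", "animal_id", "day", "volume_mm3", "sem_mm3")

#' Write a cohort to the long-format CSV schema
#'
#' Columns `group,animal_id,day,volume_mm3,sem_mm3` (SEM empty on
#' per-animal rows), one row per measurement, `#`-prefixed provenance
#' comments at the top.
#'
#' @param cohort A `tumor_cohort` or named list of [tumor_series].
#' @param path Output file path.
#' @param comments Character vector of `# `-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_tumor_data <- function(cohort, path, comments = character()) {
  df <- cohort_to_df(cohort)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Flatten a cohort to a long data frame
#'
#' @param cohort A `tumor_cohort` or named list of [tumor_series].
#' @return Data frame with the CSV schema columns.
#' @export
cohort_to_df <- function(cohort) {
  if (inherits(cohort, "tumor_cohort")) cohort <- cohort$series
  if (inherits(cohort, "tumor_series")) cohort <- list(cohort)
  rows <- lapply(cohort, function(s) {
    data.frame(group = s$group, animal_id = s$data$animal_id,
               day = s$data$day, volume_mm3 = s$data$volume,
               sem_mm3 = s$data$sem, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

schema_error <- function(msg, rows = NULL) {
  if (!is.null(rows))
    msg <- paste0(msg, " (row ", paste(rows, collapse = ", "), ")")
  stop(errorCondition(msg, class = c("schema_error", "error")))
}

#' Read tumor-volume data from CSV
#'
#' Reads and validates the long-format schema
#' (`group,animal_id,day,volume_mm3,sem_mm3`); schema violations are
#' reported with the offending data row numbers. `#` lines are ignored.
#'
#' @param path CSV file path.
#' @return Named list of unnormalised [tumor_series], one per group
#'   present.
#' @export
read_tumor_data <- function(path) {
  if (!file.exists(path)) schema_error(paste0("file not found: ", path))
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLS[1:4], names(df))
  if (length(missing_cols))
    schema_error(paste0("missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  if (!"sem_mm3" %in% names(df)) df$sem_mm3 <- NA_real_
  bad <- which(!df$group %in% ARM_LEVELS)
  if (length(bad))
    schema_error(paste0("unknown group value(s): ",
                        paste(unique(df$group[bad]), collapse = ", ")), bad)
  bad <- which(!is.finite(df$day) | df$day < 0)
  if (length(bad)) schema_error("invalid day", bad)
  bad <- which(!is.finite(df$volume_mm3) | df$volume_mm3 <= 0)
  if (length(bad)) schema_error("non-positive or missing volume", bad)
  out <- lapply(split(df, df$group), function(g) {
    tryCatch(
      tumor_series(g$group[1], data.frame(
        animal_id = g$animal_id, day = g$day, volume = g$volume_mm3,
        sem = suppressWarnings(as.numeric(g$sem_mm3)),
        stringsAsFactors = FALSE)),
      error = function(e) schema_error(paste0("group '", g$group[1], "': ",
                                              conditionMessage(e))))
  })
  out[intersect(ARM_LEVELS, names(out))]
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("config_error", "error")))
}

#' Default run configuration
#'
#' The full configuration tree driving the command-line pipeline:
#' `fit.*` (window, bounds, weighting), `predict.*` (mode, switch day),
#' `simulate.*` (model parameters and grid for trajectory export),
#' `generate.*` (cohort spec fields), `paths.*` (input file, output
#' directory), `report.window` and the global `seed`.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    fit = list(window = "full", bounds = list(T = c(1, 30), k = c(0, 10)),
               weighting = "sem"),
    predict = list(mode = "single", switch_day = 7),
    simulate = list(T_days = NULL, k_star = NULL, k_kill = 0, g = 1,
                    span_days = 23, step_days = 0.5),
    generate = list(n_animals = 5, days = c(0, 5, 7, 11, 15, 19, 23),
                    v0_cv = 0.15, noise_cv = 0.10, k_jitter_cv = 0,
                    noiseless = FALSE, window = "full"),
    report = list(window = "early"),
    paths = list(input = NULL, out_dir = "."),
    seed = 1L
  )
}

merge_config <- function(base, override, path = character()) {
  unknown <- setdiff(names(override), names(base))
  if (length(unknown))
    config_error(paste0("unknown config key(s): ",
                        paste(paste(c(path, unknown[1]), collapse = "."),
                              collapse = ", ")))
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration
#'
#' Loads a YAML configuration file, overlays explicit overrides, and
#' validates every key against [default_run_config]; unknown keys are
#' rejected.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Nested list overlaid after the file.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      config_error(paste0("config file not found: ", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}

# polynomial rolling hash (mod 2^31 - 1) of the canonical config text,
# for output provenance
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_comments <- function(cfg) {
  c(sprintf("lymphodyn %s", as.character(utils::packageVersion("lymphodyn"))),
    sprintf("config_hash = %s", config_hash(cfg)),
    sprintf("seed = %d", as.integer(cfg$seed)))
}

#' Write the calibration run report
#'
#' Key-value text document with every fitted and fixed parameter, the
#' window and loss of each step, the prediction mode and the provenance
#' (package version, configuration hash, seed).
#'
#' @param fit A `fit_set` from [fit_all].
#' @param path Output file path.
#' @param cfg Run configuration used (for provenance lines).
#' @return `path`, invisibly.
#' @export
write_run_report <- function(fit, path, cfg = default_run_config()) {
  stopifnot(inherits(fit, "fit_set"))
  lines <- paste0("# ", provenance_comments(cfg))
  for (s in fit$steps) {
    pre <- sprintf("step%d.", s$step)
    lines <- c(lines,
               sprintf("%swindow_days = %g:%g", pre, s$window[1], s$window[2]),
               sprintf("%sloss = %.12g", pre, s$loss))
    if (length(s$fitted))
      lines <- c(lines, sprintf("%sfitted.%s = %.12g", pre,
                                names(s$fitted), unlist(s$fitted)))
    if (length(s$fixed))
      lines <- c(lines, sprintf("%sfixed.%s = %.12g", pre,
                                names(s$fixed), unlist(s$fixed)))
  }
  lines <- c(lines,
             sprintf("predict.mode = %s", fit$predict_mode),
             sprintf("predict.switch_day = %g", fit$switch_day))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
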