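#' Read a trial table from CSV
#'
#' Expected schema: `subject`, `condition`, `task` (reactive|proactive),
#' `trial_type` (go|stop), `ssd` (seconds or empty), `cue` (go-probability
#' fraction or empty), `response` (0/1), `rt` (seconds or empty).
#' Violations (a response without an RT, an RT without a response, unknown
#' task labels) raise a parse error listing the offending rows. RT values
#' above 10 trigger a units warning (task deadlines are well under a
#' second, so values that large look like milliseconds); no silent
#' conversion is applied.
#'
#' @param path CSV file path.
#' @return A trial-table tibble.
#' @export
read_trials <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject = readr::col_character(),
                           condition = readr::col_character(),
                           task = readr::col_character(),
                           trial_type = readr::col_character(),
                           ssd = readr::col_double(),
                           cue = readr::col_double(),
                           response = readr::col_integer(),
                           rt = readr::col_double()))
  validate_trials(tab)
  tab
}

validate_trials <- function(tab) {
  need <- c("subject", "condition", "task", "trial_type", "ssd", "cue",
            "response", "rt")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    rlang::abort(paste("missing columns:",
                       paste(missing_cols, collapse = ", ")),
                 class = "raceddm_parse")
  }
  bad <- which((tab$response == 1L & is.na(tab$rt)) |
                 (tab$response == 0L & !is.na(tab$rt)))
  if (length(bad)) {
    rlang::abort(paste0("response/rt mismatch (response=1 requires rt, ",
                        "response=0 forbids it) at rows: ",
                        paste(utils::head(bad, 10), collapse = ", ")),
                 class = "raceddm_parse")
  }
  if (!all(tab$task %in% c("reactive", "proactive"))) {
    rlang::abort("task must be 'reactive' or 'proactive'",
                 class = "raceddm_parse")
  }
  bad_cue <- which(tab$task == "reactive" & !is.na(tab$cue))
  if (length(bad_cue)) {
    rlang::abort("reactive rows must have empty cue",
                 class = "raceddm_parse")
  }
  if (any(tab$rt > 10, na.rm = TRUE)) {
    rlang::warn(paste("rt values exceed 10 s - these look like",
                      "milliseconds; expected seconds (no conversion",
                      "applied)"))
  }
  invisible(tab)
}

#' Write a trial table to CSV
#'
#' Floats are written with 17 significant digits so a write/read round
#' trip is bit-exact.
#'
#' @param trials Trial-table tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials
  for (col in c("ssd", "cue", "rt")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' The file embeds the seed and a hash of the fitting configuration, so
#' every artifact records what is needed to regenerate it.
#'
#' @param fit A `race_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "race_fit"))
  payload <- list(
    model = fit$model, modulation = fit$modulation, task = fit$task,
    params = fit$params, free = fit$free,
    chi2 = fit$cost, k = fit$k, n = fit$n, aic = fit$aic, bic = fit$bic,
    converged = fit$converged,
    seed = fit$config$seed,
    config = fit$config[setdiff(names(fit$config), "bounds")],
    bounds = fit$config$bounds,
    config_hash = rlang::hash(fit$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized fit back as a list
#'
#' @param path JSON path written by [write_fit()].
#' @return A list mirroring the serialized fields, with `params` as a
#'   tibble.
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$params <- tibble::as_tibble(x$params)
  x
}

#' Read a fitting configuration from YAML
#'
#' Recognised keys match the arguments of [fit_config()]; unknown keys
#' raise a named-key error.
#'
#' @param path YAML file path.
#' @return A `fit_config`.
#' @export
read_fit_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(fit_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    rlang::abort(paste("unknown fit configuration keys:",
                       paste(unknown, collapse = ", ")),
                 class = "raceddm_config")
  }
  if (!is.null(y$bounds)) y$bounds <- lapply(y$bounds, as.numeric)
  do.call(fit_config, y)
}

#' Read a parameter table from YAML
#'
#' Either a flat mapping of parameter names to values (one condition) or a
#' `conditions:` list of such mappings with `condition` (and `cue`)
#' entries.
#'
#' @param path YAML file path.
#' @return A `process_params` or a per-condition tibble.
#' @export
read_params_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$conditions)) {
    return(dplyr::bind_rows(lapply(y$conditions, tibble::as_tibble)))
  }
  as_process_params(y)
}
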