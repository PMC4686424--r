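#' Specification of a synthetic multi-subject cohort
#'
#' Fixture machinery for recovery studies and end-to-end pipeline runs:
#' subjects' parameters are drawn around a known truth with Gaussian
#' between-subject dispersion, truncated to the parameter search boxes
#' (out-of-box draws are redrawn; after 1000 attempts the value is clamped
#' to the box edge). The truth record travels with the generated data.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param design A [task_design()].
#' @param model Generator model (`"dpm"`, `"independent"`,
#'   `"interactive"`).
#' @param params Truth parameters: a [process_params()] or a per-condition
#'   table as for [simulate_task()].
#' @param between_subject_sd Named numeric vector of per-parameter
#'   dispersions (same units as the parameter); parameters not named get
#'   dispersion 0.
#' @param seed Integer seed; the cohort is byte-reproducible given the
#'   spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, design, model = "dpm", params,
                        between_subject_sd = numeric(), seed = 1L) {
  if (n_subjects < 1L) rlang::abort("`n_subjects` must be >= 1")
  if (length(between_subject_sd) &&
      (is.null(names(between_subject_sd)) ||
         any(between_subject_sd < 0))) {
    rlang::abort("`between_subject_sd` must be a named vector of non-negative dispersions")
  }
  structure(list(n_subjects = as.integer(n_subjects), design = design,
                 model = model, params = params,
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_subject_params <- function(truth_tbl, sds, bounds) {
  out <- truth_tbl
  for (pn in names(sds)) {
    if (!pn %in% names(out) || sds[[pn]] <= 0) next
    box <- bounds[[pn]] %||% c(-Inf, Inf)
    # one shared deviation per subject, preserving condition contrasts
    base <- out[[pn]][1]
    dev <- NA_real_
    for (try in seq_len(1000L)) {
      cand <- stats::rnorm(1, 0, sds[[pn]])
      if (all(out[[pn]] + cand >= box[1] & out[[pn]] + cand <= box[2])) {
        dev <- cand
        break
      }
    }
    if (is.na(dev)) {
      shifted <- pmin(pmax(out[[pn]], box[1]), box[2])
      out[[pn]] <- shifted
    } else {
      out[[pn]] <- out[[pn]] + dev
    }
  }
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `raceddm_cohort` with elements `trials` (one
#'   tibble, all subjects), `subject_params` (per-subject truth), and
#'   `spec`.
#' @examples
#' d <- task_design("reactive", n_go = 20, n_stop_per_ssd = 2)
#' sp <- cohort_spec(3, d, "dpm", preset_params("dpm"),
#'                   between_subject_sd = c(v_e = 0.1), seed = 7)
#' generate_cohort(sp)$subject_params
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  truth_tbl <- params_table(spec$params, spec$design)
  bounds <- param_bounds()
  withr::with_seed(spec$seed, {
    subs <- lapply(seq_len(spec$n_subjects), function(s) {
      ptbl <- draw_subject_params(truth_tbl, spec$between_subject_sd,
                                  bounds)
      cfg <- sim_config(deadline = spec$design$deadline,
                        seed = spec$seed + 7919L * s)
      tab <- simulate_task(spec$model, spec$design, ptbl, cfg,
                           subject = sprintf("s%03d", s))
      ptbl$subject <- sprintf("s%03d", s)
      list(trials = tab, params = ptbl)
    })
    structure(list(trials = dplyr::bind_rows(lapply(subs, `[[`,
                                                    "trials")),
                   subject_params = dplyr::bind_rows(lapply(subs, `[[`,
                                                            "params")),
                   spec = spec),
              class = "raceddm_cohort")
  })
}

#' @export
print.raceddm_cohort <- function(x, ...) {
  cat("<raceddm_cohort>", x$spec$n_subjects, "subjects,",
      nrow(x$trials), "trials,", x$spec$design$task, "design\n")
  invisible(x)
}

#' Parameter-recovery harness
#'
#' Generates (or takes) a synthetic cohort, pools its trials, fits the
#' requested model with the full protocol, and reports truth versus
#' estimate for every parameter, with bias and relative error. Fit
#' failures are recorded in the report rather than raised.
#'
#' @param spec A [cohort_spec()] or an existing `raceddm_cohort`.
#' @param model,modulation Model to fit, as in [fit_race_model()].
#' @param config A [fit_config()].
#' @return A list of class `recovery_report`: `report` (tibble with
#'   columns `condition`, `parameter`, `truth`, `estimate`, `bias`,
#'   `rel_error`), `fit`, `cohort`, `ok`.
#' @export
recovery_harness <- function(spec, model = "dpm", modulation = "none",
                             config = fit_config()) {
  cohort <- if (inherits(spec, "raceddm_cohort")) spec
            else generate_cohort(spec)
  design <- cohort$spec$design
  fit <- tryCatch(
    fit_race_model(cohort$trials, model, modulation, design, config),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(report = NULL, fit = NULL, cohort = cohort,
                          ok = FALSE, error = conditionMessage(fit)),
                     class = "recovery_report"))
  }
  truth_tbl <- params_table(cohort$spec$params, design)
  est_tbl <- fit$params
  pars <- intersect(c("a", "tr", "v_e", "v_b", "xb", "sso"),
                    names(truth_tbl))
  rows <- list()
  for (ci in seq_len(nrow(truth_tbl))) {
    cond <- truth_tbl$condition[ci]
    ei <- if (cond %in% est_tbl$condition) {
      which(est_tbl$condition == cond)[1]
    } else {
      min(ci, nrow(est_tbl))
    }
    for (pn in pars) {
      tv <- truth_tbl[[pn]][ci]
      if (is.na(tv)) next
      ev <- if (pn %in% names(est_tbl)) est_tbl[[pn]][ei] else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        condition = cond, parameter = pn, truth = tv, estimate = ev,
        bias = ev - tv,
        rel_error = if (tv != 0) abs(ev - tv) / abs(tv) else abs(ev))
    }
  }
  structure(list(report = dplyr::bind_rows(rows), fit = fit,
                 cohort = cohort, ok = TRUE),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", if (x$ok) "ok" else paste("failed:", x$error),
      "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
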