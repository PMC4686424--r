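#' Diffusion/race parameters for one condition
#'
#' Bundles the parameters of the gain-modulated execution process and (for
#' stop-trial models) the braking process. All times are in seconds and
#' evidence is in arbitrary units, so drift rates are evidence/s.
#'
#' @param a Boundary height (> 0). Distance the execution process must
#'   travel from 0 to trigger a response.
#' @param tr Onset delay in seconds (>= 0). Lumps pre- and post-decision
#'   delays; accumulation starts at `t = tr`.
#' @param v_e Execution drift rate (evidence/s).
#' @param v_b Braking drift rate magnitude (evidence/s, >= 0). Applied
#'   negatively by the dependent process model and positively by the
#'   independent and interactive race models. `NA` for go-only simulation.
#' @param xb Dynamic gain coefficient (1/s, >= 0). The execution process is
#'   multiplied by `cosh(xb * (t - tr))`, a hyperbolic urgency signal that
#'   equals 1 at onset and accelerates accumulation toward the deadline.
#'   `xb = 0` disables the gain.
#' @param sigma Diffusion constant (evidence/sqrt(s), > 0). Defaults to the
#'   conventional scaling constant 0.1.
#' @param sso Stop-signal onset delay in seconds (>= 0); the registration
#'   lag between stop-cue presentation and braking onset. Used only by the
#'   interactive race model.
#'
#' @return A list of class `process_params`.
#' @examples
#' process_params(a = 0.534, tr = 0.174, v_e = 1.266, v_b = 0.990, xb = 0.878)
#' @export
process_params <- function(a, tr, v_e, v_b = NA_real_, xb = 0,
                           sigma = 0.1, sso = NA_real_) {
  p <- list(a = as.numeric(a), tr = as.numeric(tr), v_e = as.numeric(v_e),
            v_b = as.numeric(v_b), xb = as.numeric(xb),
            sigma = as.numeric(sigma), sso = as.numeric(sso))
  validate_process_params(p)
  structure(p, class = "process_params")
}

validate_process_params <- function(p) {
  stopifnot(is.numeric(p$a), is.numeric(p$tr), is.numeric(p$v_e))
  chk <- c(a = p$a, tr = p$tr, v_e = p$v_e, xb = p$xb, sigma = p$sigma)
  if (any(!is.finite(chk))) {
    rlang::abort("process parameters a, tr, v_e, xb, sigma must be finite")
  }
  if (p$a <= 0) rlang::abort("boundary height `a` must be > 0")
  if (p$sigma <= 0) rlang::abort("diffusion constant `sigma` must be > 0")
  if (p$tr < 0) rlang::abort("onset delay `tr` must be >= 0")
  if (p$xb < 0) rlang::abort("gain coefficient `xb` must be >= 0")
  if (!is.na(p$v_b) && p$v_b < 0) {
    rlang::abort("braking drift `v_b` is stored as a magnitude (>= 0)")
  }
  if (!is.na(p$sso) && p$sso < 0) rlang::abort("`sso` must be >= 0")
  invisible(p)
}

#' @export
print.process_params <- function(x, ...) {
  cat("<process_params>\n")
  vals <- unlist(x)
  print(vals[!is.na(vals) | names(vals) %in% c("v_b", "sso")])
  invisible(x)
}

#' Coerce a one-row data frame or named list to `process_params`
#'
#' @param x Named list, `process_params`, or one-row data frame with columns
#'   among a, tr, v_e, v_b, xb, sigma, sso.
#' @return A `process_params` object.
#' @export
as_process_params <- function(x) {
  if (inherits(x, "process_params")) return(x)
  x <- as.list(x)
  process_params(
    a = x$a, tr = x$tr, v_e = x$v_e,
    v_b = if (is.null(x$v_b)) NA_real_ else x$v_b,
    xb = if (is.null(x$xb)) 0 else x$xb,
    sigma = if (is.null(x$sigma)) 0.1 else x$sigma,
    sso = if (is.null(x$sso)) NA_real_ else x$sso
  )
}

#' Simulation configuration
#'
#' @param dt Integration step in seconds (0 < dt <= 0.005; default 1 ms).
#' @param deadline Trial time limit in seconds (end of the trial window).
#' @param n_trials Trials per condition.
#' @param seed Integer seed for the counter-based per-trial noise streams.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, deadline = 0.650, n_trials = 1000L,
                       seed = 1L) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.005) {
    rlang::abort("`dt` must be in (0, 0.005] seconds")
  }
  if (deadline <= 0) rlang::abort("`deadline` must be > 0")
  if (n_trials < 0) rlang::abort("`n_trials` must be >= 0")
  structure(list(dt = dt, deadline = deadline,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "sim_config")
}

#' Representative best-fit parameter sets
#'
#' Ready-made parameter sets for each model and task, taken from published
#' best-fit estimates for the reactive stop-signal and proactive
#' go-probability tasks. These serve as defaults for simulation examples and
#' as ground truth in recovery studies.
#'
#' @param model One of `"dpm"`, `"independent"`, `"interactive"` (reactive
#'   task, single condition) or one of `"drift"`, `"onset"`, `"drift_onset"`,
#'   `"bound"` (modulation models).
#' @param task `"reactive"` or `"proactive"`.
#'
#' @return For single-condition models, a `process_params` object. For
#'   modulation models, a tibble with one row per condition (column
#'   `condition` plus parameter columns), suitable for [simulate_task()].
#' @examples
#' preset_params("dpm")
#' preset_params("drift", task = "proactive")
#' @export
preset_params <- function(model = c("dpm", "independent", "interactive",
                                    "drift", "onset", "drift_onset",
                                    "bound"),
                          task = c("reactive", "proactive")) {
  model <- match.arg(model)
  task <- match.arg(task)
  if (model %in% c("dpm", "independent", "interactive")) {
    return(switch(model,
      dpm = process_params(a = 0.534, tr = 0.174, v_e = 1.266,
                           v_b = 0.990, xb = 0.878),
      independent = process_params(a = 0.250, tr = 0.338, v_e = 1.127,
                                   v_b = 1.269, xb = 1.52),
      interactive = process_params(a = 0.445, tr = 0.220, v_e = 1.195,
                                   v_b = 3.023, xb = 1.474, sso = 0.197)
    ))
  }
  if (task == "reactive") {
    tbl <- switch(model,
      drift = tibble::tibble(
        condition = c("baseline", "caution"),
        a = 0.536, tr = 0.178, v_e = c(1.289, 1.243), v_b = 0.984,
        xb = 0.877),
      onset = tibble::tibble(
        condition = c("baseline", "caution"),
        a = 0.531, tr = c(0.171, 0.180), v_e = 1.236, v_b = 0.960,
        xb = 0.893),
      drift_onset = tibble::tibble(
        condition = c("baseline", "caution"),
        a = 0.538, tr = c(0.173, 0.178), v_e = c(1.269, 1.247), v_b = 0.989,
        xb = 0.858),
      bound = tibble::tibble(
        condition = c("baseline", "caution"),
        a = c(0.525, 0.551), tr = 0.178, v_e = 1.268, v_b = 0.984,
        xb = 0.878)
    )
  } else {
    cues <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
    lab <- proactive_cue_labels(cues)
    tbl <- switch(model,
      drift = tibble::tibble(
        condition = lab, cue = cues, a = 0.487, tr = 0.292,
        v_e = c(1.411, 1.562, 1.683, 1.761, 1.880, 1.925), xb = 1.563),
      onset = tibble::tibble(
        condition = lab, cue = cues, a = 0.628,
        tr = c(0.182, 0.161, 0.134, 0.117, 0.084, 0.076), v_e = 1.42,
        xb = 0.641),
      drift_onset = tibble::tibble(
        condition = lab, cue = cues, a = 0.06,
        tr = c(0.515, 0.506, 0.492, 0.479, 0.451, 0.463),
        v_e = c(0.831, 0.970, 0.968, 0.979, 0.932, 1.079), xb = 1.468),
      bound = tibble::tibble(
        condition = lab, cue = cues,
        a = c(0.379, 0.344, 0.305, 0.281, 0.246, 0.236), tr = 0.272,
        v_e = 0.914, xb = 0.913)
    )
    tbl$v_b <- NA_real_
  }
  tbl$sigma <- 0.1
  tbl
}

proactive_cue_labels <- function(cues) sprintf("p%02.0f", 100 * cues)
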