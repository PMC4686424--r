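#' Cumulative-sum BOLD proxy for one trajectory
#'
#' The model-predicted BOLD magnitude of a trial is the cumulative sum of
#' the execution process over the trial, `sum(theta_e * dt)` — a single
#' area-under-the-curve number that jointly reflects the
#' distance-to-threshold and time-to-threshold of the decision. For
#' responded trials the path (and hence the sum) ends at the boundary
#' crossing; for sub-threshold trials it ends at the deadline. No
#' hemodynamic convolution is applied.
#'
#' @param trajectory Data frame with a `theta_e` column (e.g. from
#'   [integrate_execution()]).
#' @param dt Integration step the trajectory was simulated at (seconds).
#' @return Area in evidence-seconds (trapezoid rule, with the implicit 0
#'   at process onset).
#' @export
trial_auc <- function(trajectory, dt) {
  if (!nrow(trajectory)) return(0)
  th <- trajectory$theta_e
  dt * (sum(th) - th[length(th)] / 2)
}

#' Model-predicted BOLD magnitudes in the proactive task
#'
#' Simulates `n` proactive trials per go-probability cue at the supplied
#' per-cue parameters, splits them by outcome ("go" when the execution
#' process reached threshold, "no-go" otherwise), and averages the
#' per-trial cumulative-sum areas. Two pooled bins mirror the imaging
#' contrasts: go trials from the lower cues (<= 60%) and no-go trials from
#' the higher cues (>= 40%).
#'
#' @param params Per-cue parameter table (columns `cue`, `a`, `tr`, `v_e`,
#'   `xb`, ...), e.g. `preset_params("drift", task = "proactive")`.
#' @param design A proactive [task_design()].
#' @param n Trials per cue (default 100).
#' @param seed RNG seed.
#' @param dt Integration step in seconds.
#' @param pooled Append the two pooled-bin rows.
#' @return A tibble with columns `bin`, `cue`, `outcome`, `mean_auc`,
#'   `n_trials`. Per-cue rows have `bin = "cue"`; pooled rows have
#'   `bin = "go_low"` / `"nogo_high"` and `cue = NA`. Cue-outcome cells
#'   with no trials are absent, not zero.
#' @examples
#' predict_bold(preset_params("drift", task = "proactive"),
#'              task_design("proactive"), n = 200, seed = 1)
#' @export
predict_bold <- function(params, design = task_design("proactive"),
                         n = 100L, seed = 1L, dt = 0.001,
                         pooled = TRUE) {
  stopifnot(design$task == "proactive")
  ptbl <- tibble::as_tibble(params)
  if (!"cue" %in% names(ptbl)) {
    rlang::abort("`params` needs a `cue` column for the proactive design")
  }
  cfg <- sim_config(dt = dt, deadline = design$deadline, seed = seed)
  trials <- purrr::map_dfr(seq_len(nrow(ptbl)), function(ci) {
    prow <- as_process_params(ptbl[ci, setdiff(names(ptbl),
                                               c("condition", "cue"))])
    sim <- simulate_go_trials(prow, n, cfg, stream = (ci - 1) * 10^7)
    sim$cue <- ptbl$cue[ci]
    sim
  })
  trials$outcome <- ifelse(trials$response == 1L, "go", "no-go")
  per_cue <- dplyr::summarise(
    dplyr::group_by(trials, .data$cue, .data$outcome),
    mean_auc = mean(.data$auc), n_trials = dplyr::n(), .groups = "drop")
  per_cue$bin <- "cue"
  out <- per_cue
  if (pooled) {
    go_low <- trials[trials$outcome == "go" & trials$cue <= 0.6, ]
    nogo_high <- trials[trials$outcome == "no-go" & trials$cue >= 0.4, ]
    pool <- list()
    if (nrow(go_low)) {
      pool[[1]] <- tibble::tibble(bin = "go_low", cue = NA_real_,
                                  outcome = "go",
                                  mean_auc = mean(go_low$auc),
                                  n_trials = nrow(go_low))
    }
    if (nrow(nogo_high)) {
      pool[[length(pool) + 1]] <- tibble::tibble(
        bin = "nogo_high", cue = NA_real_, outcome = "no-go",
        mean_auc = mean(nogo_high$auc), n_trials = nrow(nogo_high))
    }
    out <- dplyr::bind_rows(out, pool)
  }
  dplyr::select(out, "bin", "cue", "outcome", "mean_auc", "n_trials")
}
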