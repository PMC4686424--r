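#' Task design for a reactive or proactive experiment
#'
#' Trial-structure constants. The reactive design is a stop-signal task with
#' five stop-signal delays (SSDs) between 200 and 400 ms, a 650 ms trial
#' window, and 50% stop trials. The proactive design cues the go-trial
#' probability (0-100% in six steps), uses a single late 450 ms SSD, and a
#' 555 ms trial window. In both, a response aimed at the target intersects
#' it 500 ms after trial onset.
#'
#' Default per-subject trial counts mirror the experiments: reactive, 100 go
#' trials and 20 stop trials per SSD; proactive, 40 trials per cue
#' (10 blocks of 24 trials with each cue sampled 4 times per block).
#'
#' @param task `"reactive"` or `"proactive"`.
#' @param ssds Stop-signal delays in seconds.
#' @param deadline Trial window in seconds.
#' @param cues Go-probability cues (fractions in \[0, 1\]; proactive only).
#' @param stop_fraction Fraction of stop trials (reactive only).
#' @param target_time Target response time in seconds.
#' @param n_go,n_stop_per_ssd,n_per_cue Default trial counts per condition.
#' @return A list of class `task_design`.
#' @examples
#' task_design("reactive")
#' task_design("proactive")
#' @export
task_design <- function(task = c("reactive", "proactive"),
                        ssds = NULL, deadline = NULL, cues = NULL,
                        stop_fraction = 0.5, target_time = 0.5,
                        n_go = 100L, n_stop_per_ssd = 20L,
                        n_per_cue = 40L) {
  task <- match.arg(task)
  if (is.null(ssds)) {
    ssds <- if (task == "reactive") c(0.200, 0.250, 0.300, 0.350, 0.400)
            else 0.450
  }
  if (is.null(deadline)) deadline <- if (task == "reactive") 0.650 else 0.555
  if (is.null(cues)) {
    cues <- if (task == "proactive") c(0, 0.2, 0.4, 0.6, 0.8, 1) else numeric()
  }
  if (any(ssds >= deadline)) {
    rlang::abort("all stop-signal delays must fall before the deadline")
  }
  if (length(cues) && (any(cues < 0) || any(cues > 1))) {
    rlang::abort("cues are go-probability fractions in [0, 1]")
  }
  structure(list(task = task, ssds = ssds, deadline = deadline,
                 cues = cues, stop_fraction = stop_fraction,
                 target_time = target_time, n_go = as.integer(n_go),
                 n_stop_per_ssd = as.integer(n_stop_per_ssd),
                 n_per_cue = as.integer(n_per_cue)),
            class = "task_design")
}

#' Contextual-modulation specification
#'
#' Declares which model generates trials and which parameters are free to
#' vary across conditions when fitting contextual modulation: the drift
#' rate (`"drift"`), onset delay (`"onset"`), both (`"drift_onset"`), or
#' boundary height (`"bound"`). `"none"` fits a single shared parameter
#' set.
#'
#' @param model `"dpm"`, `"independent"`, or `"interactive"`.
#' @param modulation One of `"none"`, `"drift"`, `"onset"`,
#'   `"drift_onset"`, `"bound"`.
#' @param conditions Character vector of condition labels.
#' @return A list of class `modulation_spec`.
#' @export
modulation_spec <- function(model = c("dpm", "independent", "interactive"),
                            modulation = c("none", "drift", "onset",
                                           "drift_onset", "bound"),
                            conditions = "pooled") {
  model <- match.arg(model)
  modulation <- match.arg(modulation)
  structure(list(model = model, modulation = modulation,
                 conditions = as.character(conditions),
                 free_params = modulation_free_params(modulation)),
            class = "modulation_spec")
}

modulation_free_params <- function(modulation) {
  switch(modulation,
         none = character(),
         drift = "v_e",
         onset = "tr",
         drift_onset = c("v_e", "tr"),
         bound = "a")
}

model_code <- function(model) {
  switch(model, go = 0L, dpm = 1L, independent = 2L, interactive = 3L,
         rlang::abort(paste0("unknown model '", model, "'")))
}

#' Simulate go trials
#'
#' A response and RT are recorded iff the gain-scaled execution process
#' reaches the boundary `a` before the end of the trial window. The
#' returned `auc` column is the cumulative sum of the execution state times
#' `dt` over the path (the BOLD proxy).
#'
#' @param params A [process_params()] object (or coercible).
#' @param n Number of trials.
#' @param cfg A [sim_config()].
#' @param stream Substream offset (distinct cells of a design use distinct
#'   offsets so their noise never overlaps).
#' @return A tibble with columns `response` (0/1), `rt` (s, `NA` when no
#'   response), `auc`.
#' @export
simulate_go_trials <- function(params, n, cfg = sim_config(), stream = 0) {
  simulate_trials_impl("go", params, NA_real_, n, cfg, stream)
}

#' Simulate stop trials under one of the three race models
#'
#' * `"dpm"` (dependent process model): at `t = SSD` a braking process is
#'   initiated at the current state of the execution process and drifts
#'   toward 0 with rate `-v_b` (no gain); the trial is stopped if it
#'   reaches 0 before the execution process reaches `a`.
#' * `"independent"`: a braking accumulator starts from 0 at `t = SSD`
#'   with drift `+v_b` and races to the same boundary `a`; the stop wins if
#'   it crosses first.
#' * `"interactive"`: from `t = SSD + sso` onward, a positively
#'   accumulating braking signal is subtracted from the execution signal;
#'   a response requires the net signal to reach `a` before the deadline.
#'
#' In every model a response made before the braking process is active
#' stands.
#'
#' @inheritParams simulate_go_trials
#' @param ssd Stop-signal delay in seconds (>= 0).
#' @param model `"dpm"`, `"independent"`, or `"interactive"`.
#' @return A tibble with columns `response`, `rt`, `auc`.
#' @export
simulate_stop_trials <- function(params, ssd, n, cfg = sim_config(),
                                 model = c("dpm", "independent",
                                           "interactive"),
                                 stream = 0) {
  model <- match.arg(model)
  if (!is.finite(ssd) || ssd < 0) rlang::abort("`ssd` must be >= 0")
  params <- as_process_params(params)
  if (is.na(params$v_b)) {
    rlang::abort("stop-trial simulation requires a braking drift `v_b`")
  }
  if (model == "interactive" && is.na(params$sso)) {
    rlang::abort("the interactive race model requires `sso`")
  }
  simulate_trials_impl(model, params, ssd, n, cfg, stream)
}

simulate_trials_impl <- function(model, params, ssd, n, cfg, stream) {
  params <- as_process_params(params)
  out <- cpp_simulate(model_code(model), as.integer(n), params$a,
                      params$tr, params$v_e,
                      if (is.na(params$v_b)) 0 else params$v_b,
                      params$xb, params$sigma,
                      if (is.na(params$sso)) 0 else params$sso,
                      if (is.na(ssd)) 0 else ssd,
                      cfg$dt, cfg$deadline, as.double(cfg$seed),
                      as.double(stream))
  tibble::tibble(response = as.integer(!is.na(out$rt)), rt = out$rt,
                 auc = out$auc)
}

#' Simulate a full experimental dataset
#'
#' Batches the trial generators across conditions, SSDs (reactive) or cues
#' (proactive), producing a trial table in the on-disk CSV schema. In the
#' proactive task only the execution process runs: a "no-go" outcome is any
#' trial on which it fails to reach the boundary by the deadline, so the
#' late single SSD is not modelled as a reactive braking event.
#'
#' @param model `"dpm"`, `"independent"`, or `"interactive"` (ignored for
#'   proactive designs, which use the execution process only).
#' @param design A [task_design()].
#' @param params Either a single [process_params()] (one condition) or a
#'   data frame with one row per condition: column `condition` (and `cue`
#'   for proactive designs) plus parameter columns.
#' @param cfg A [sim_config()]; `cfg$seed` makes the table reproducible.
#' @param n_go,n_stop_per_ssd,n_per_cue Optional overrides of the design's
#'   per-condition trial counts.
#' @param subject Subject identifier stored in the table.
#' @return A tibble with columns `subject`, `condition`, `task`,
#'   `trial_type`, `ssd`, `cue`, `response`, `rt`.
#' @examples
#' d <- task_design("reactive", n_go = 20, n_stop_per_ssd = 4)
#' simulate_task("dpm", d, preset_params("dpm"), sim_config(seed = 1))
#' @export
simulate_task <- function(model, design, params, cfg = NULL,
                          n_go = NULL, n_stop_per_ssd = NULL,
                          n_per_cue = NULL, subject = "sim") {
  stopifnot(inherits(design, "task_design"))
  if (is.null(cfg)) cfg <- sim_config(deadline = design$deadline)
  cfg$deadline <- design$deadline
  ptbl <- params_table(params, design)
  n_go <- n_go %||% design$n_go
  n_stop_per_ssd <- n_stop_per_ssd %||% design$n_stop_per_ssd
  n_per_cue <- n_per_cue %||% design$n_per_cue

  cells <- list()
  stream <- 0
  stream_step <- 10^7  # cells can hold up to 1e7 trials without overlap
  for (ci in seq_len(nrow(ptbl))) {
    prow <- as_process_params(ptbl[ci, setdiff(names(ptbl),
                                               c("condition", "cue"))])
    cond <- ptbl$condition[ci]
    if (design$task == "reactive") {
      go <- simulate_go_trials(prow, n_go, cfg, stream = stream)
      stream <- stream + stream_step
      cells[[length(cells) + 1L]] <- dplyr::mutate(
        go, subject = subject, condition = cond, task = "reactive",
        trial_type = "go", ssd = NA_real_, cue = NA_real_)
      for (ssd in design$ssds) {
        st <- simulate_stop_trials(prow, ssd, n_stop_per_ssd, cfg,
                                   model = model, stream = stream)
        stream <- stream + stream_step
        cells[[length(cells) + 1L]] <- dplyr::mutate(
          st, subject = subject, condition = cond, task = "reactive",
          trial_type = "stop", ssd = ssd, cue = NA_real_)
      }
    } else {
      cue <- if ("cue" %in% names(ptbl)) ptbl$cue[ci] else NA_real_
      go <- simulate_go_trials(prow, n_per_cue, cfg, stream = stream)
      stream <- stream + stream_step
      cells[[length(cells) + 1L]] <- dplyr::mutate(
        go, subject = subject, condition = cond, task = "proactive",
        trial_type = "go", ssd = NA_real_, cue = cue)
    }
  }
  if (!length(cells)) {
    return(empty_trial_table())
  }
  dplyr::select(dplyr::bind_rows(cells), "subject", "condition", "task",
                "trial_type", "ssd", "cue", "response", "rt")
}

params_table <- function(params, design) {
  if (inherits(params, "process_params")) {
    tbl <- tibble::as_tibble(unclass(params)[!vapply(params, is.null,
                                                     TRUE)])
    tbl$condition <- "pooled"
    if (design$task == "proactive" && length(design$cues) == 1L) {
      tbl$cue <- design$cues
    }
    return(tbl)
  }
  tbl <- tibble::as_tibble(params)
  if (!"condition" %in% names(tbl)) {
    rlang::abort("multi-condition `params` need a `condition` column")
  }
  if (design$task == "proactive" && !"cue" %in% names(tbl)) {
    if (nrow(tbl) != length(design$cues)) {
      rlang::abort("proactive `params` need a `cue` column or one row per design cue")
    }
    tbl$cue <- design$cues
  }
  tbl
}

empty_trial_table <- function() {
  tibble::tibble(subject = character(), condition = character(),
                 task = character(), trial_type = character(),
                 ssd = numeric(), cue = numeric(), response = integer(),
                 rt = numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
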