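#' RT quantiles
#'
#' Linear-interpolation (type 7) quantiles of a response-time vector at the
#' standard probabilities used by the fitting cost. The same definition is
#' applied to observed and simulated RTs so the cost is internally
#' coherent.
#'
#' @param rts Numeric vector of response times in seconds.
#' @param probs Quantile levels; default `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @return Named non-decreasing numeric vector.
#' @export
rt_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  rts <- rts[!is.na(rts)]
  if (!length(rts)) {
    rlang::abort("no response times to summarise", class = "raceddm_empty")
  }
  stats::quantile(rts, probs = probs, type = 7, names = TRUE)
}

#' Summarise a trial table into the fitting observables
#'
#' Reactive designs yield, per condition: the go-trial response probability
#' `p_go`, the per-SSD stop accuracy (probability of withholding), RT
#' quantiles of correct (go-trial) responses, and RT quantiles of error
#' (stop-trial) responses collapsed across SSDs (error responses are rare
#' at early SSDs). Proactive designs yield the response probability per
#' go-probability cue and RT quantiles pooled over high (> 50%) and low
#' (< 50%) cues, together with the pooled response probabilities `p_high`
#' and `p_low` that multiply the quantile cost terms.
#'
#' Cells with no observations are reported as absent (`NULL` quantile
#' entries, zero probabilities), not invented.
#'
#' @param trials A trial table as returned by [simulate_task()] or
#'   [read_trials()].
#' @param design The [task_design()] the table was generated under.
#' @return An object of class `behavior_summary`: a list with elements
#'   `task` and `stats` (a tibble with one row per condition, list-columns
#'   for the quantile vectors).
#' @export
summarize_trials <- function(trials, design) {
  stopifnot(inherits(design, "task_design"))
  if (design$task == "reactive") {
    stats <- summarize_reactive(trials, design)
  } else {
    stats <- summarize_proactive(trials, design)
  }
  structure(list(task = design$task, stats = stats),
            class = "behavior_summary")
}

summarize_reactive <- function(trials, design) {
  conds <- unique(trials$condition)
  rows <- lapply(conds, function(cond) {
    tt <- trials[trials$condition == cond, ]
    go <- tt[tt$trial_type == "go", ]
    st <- tt[tt$trial_type == "stop", ]
    p_go <- if (nrow(go)) mean(go$response) else NA_real_
    go_rts <- go$rt[go$response == 1L]
    q_correct <- if (length(go_rts)) rt_quantiles(go_rts) else NULL
    p_stop <- vapply(design$ssds, function(s) {
      sel <- st$ssd == s
      if (!any(sel)) NA_real_ else mean(st$response[sel] == 0L)
    }, numeric(1))
    names(p_stop) <- format(design$ssds)
    err_rts <- st$rt[st$response == 1L]
    q_error <- if (length(err_rts)) rt_quantiles(err_rts) else NULL
    p_err <- if (nrow(st)) mean(st$response) else 0
    tibble::tibble(condition = cond, p_go = p_go,
                   p_corr = ifelse(is.na(p_go), 0, p_go),
                   p_err = p_err,
                   p_stop = list(p_stop), q_correct = list(q_correct),
                   q_error = list(q_error),
                   n_go = nrow(go), n_stop = nrow(st))
  })
  dplyr::bind_rows(rows)
}

summarize_proactive <- function(trials, design) {
  # proactive "conditions" are the six cues, summarised jointly into one
  # observable vector (the condition column labels cue cells)
  if (!"cue" %in% names(trials) || all(is.na(trials$cue))) {
    rlang::abort("proactive trial tables need a `cue` column")
  }
  rows <- lapply("pooled", function(cond) {
    tt <- trials
    p_resp <- vapply(design$cues, function(cu) {
      sel <- abs(tt$cue - cu) < 1e-9
      if (!any(sel)) NA_real_ else mean(tt$response[sel])
    }, numeric(1))
    names(p_resp) <- format(design$cues)
    hi <- tt$rt[tt$response == 1L & tt$cue > 0.5]
    lo <- tt$rt[tt$response == 1L & tt$cue < 0.5]
    q_hi <- if (length(hi)) rt_quantiles(hi) else NULL
    q_lo <- if (length(lo)) rt_quantiles(lo) else NULL
    p_high <- if (any(tt$cue > 0.5)) mean(tt$response[tt$cue > 0.5]) else 0
    p_low <- if (any(tt$cue < 0.5)) mean(tt$response[tt$cue < 0.5]) else 0
    tibble::tibble(condition = cond, p_resp = list(p_resp),
                   p_high = p_high, p_low = p_low,
                   q_hi = list(q_hi), q_lo = list(q_lo), n = nrow(tt))
  })
  dplyr::bind_rows(rows)
}

# average a summary across conditions: the fitting target of the flat
# (all-parameters-free) optimisation stage
average_summary <- function(obs) {
  s <- obs$stats
  avg_vec <- function(col) {
    xs <- s[[col]][!vapply(s[[col]], is.null, TRUE)]
    if (!length(xs)) return(NULL)
    Reduce(`+`, xs) / length(xs)
  }
  if (obs$task == "reactive") {
    stats <- tibble::tibble(
      condition = "average",
      p_go = mean(s$p_go, na.rm = TRUE),
      p_corr = mean(s$p_corr), p_err = mean(s$p_err),
      p_stop = list(avg_vec("p_stop")),
      q_correct = list(avg_vec("q_correct")),
      q_error = list(avg_vec("q_error")),
      n_go = sum(s$n_go), n_stop = sum(s$n_stop))
  } else {
    # single pooled response probability and averaged hi/lo quantiles
    q_avg <- NULL
    qs <- c(s$q_hi[!vapply(s$q_hi, is.null, TRUE)],
            s$q_lo[!vapply(s$q_lo, is.null, TRUE)])
    if (length(qs)) q_avg <- Reduce(`+`, qs) / length(qs)
    p_all <- mean(unlist(s$p_resp), na.rm = TRUE)
    stats <- tibble::tibble(
      condition = "average", p_resp = list(c(mean = p_all)),
      p_high = mean(s$p_high), p_low = mean(s$p_low),
      q_hi = list(q_avg), q_lo = list(NULL), n = sum(s$n))
  }
  structure(list(task = obs$task, stats = stats),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary> task:", x$task, "\n")
  print(x$stats)
  invisible(x)
}

#' Tidy a behavioural summary
#'
#' @param x A `behavior_summary`.
#' @param ... Unused.
#' @return A long tibble with columns `condition`, `statistic`, `level`,
#'   `value`.
#' @export
tidy.behavior_summary <- function(x, ...) {
  s <- x$stats
  out <- list()
  for (i in seq_len(nrow(s))) {
    cond <- s$condition[i]
    scal <- s[i, vapply(s, is.numeric, TRUE)]
    out[[length(out) + 1L]] <- tibble::tibble(
      condition = cond, statistic = names(scal), level = NA_character_,
      value = unname(unlist(scal[1, ])))
    for (col in names(s)[vapply(s, is.list, TRUE)]) {
      v <- s[[col]][[i]]
      if (is.null(v)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        condition = cond, statistic = col,
        level = if (is.null(names(v))) as.character(seq_along(v)) else names(v),
        value = as.numeric(v))
    }
  }
  dplyr::bind_rows(out)
}

#' Logistic point of subjective equality
#'
#' Fits a logistic regression of a binary outcome (stopping, or deciding
#' not to go) on a stimulus level `x` — the stop-signal delay in seconds
#' for reactive stop curves, the go-trial probability for proactive no-go
#' curves. On the linear-predictor scale `y = lambda * x + lambda0`, the
#' point of subjective equality is the level at which the curve crosses
#' 50%: `PSE = -lambda0 / lambda`.
#'
#' Proportion-level data are fit with binomial weights via `n`. Perfect
#' separation is flagged and handled by refitting with half-count
#' smoothing of the proportions.
#'
#' @param x Stimulus levels.
#' @param y Binary outcomes (0/1) or proportions in \[0, 1\].
#' @param n Optional trial counts per level when `y` holds proportions.
#' @return An object of class `logistic_fit` with elements `lambda`
#'   (slope), `lambda0` (intercept), `pse`, and `separation`.
#' @examples
#' ssd <- seq(0.2, 0.4, by = 0.05)
#' p_stop <- c(0.95, 0.8, 0.5, 0.25, 0.1)
#' logistic_pse(ssd, p_stop, n = rep(20, 5))
#' @export
logistic_pse <- function(x, y, n = NULL) {
  if (length(unique(x[!is.na(y)])) < 2L) {
    rlang::abort("need >= 2 distinct stimulus levels",
                 class = "raceddm_degenerate")
  }
  if (length(unique(stats::na.omit(y))) < 2L && is.null(n)) {
    rlang::abort("constant outcomes: PSE undefined",
                 class = "raceddm_degenerate")
  }
  if (is.null(n)) n <- rep(1, length(y))
  succ <- y * n
  fail <- n - succ
  if (all(succ == 0) || all(fail == 0)) {
    rlang::abort("constant outcomes: PSE undefined",
                 class = "raceddm_degenerate")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(cbind(succ, fail) ~ x, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
            grepl("did not converge", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!separation && max(abs(stats::coef(fit))) > 1e3) separation <- TRUE
  if (separation) {
    # half-count smoothing pulls the proportions off 0/1 so the penalised
    # fit has a finite slope
    fit <- stats::glm(cbind(succ + 0.5, fail + 0.5) ~ x,
                      family = stats::quasibinomial())
    rlang::warn("perfect separation: PSE from smoothed fit")
  }
  co <- stats::coef(fit)
  lambda0 <- unname(co[1])
  lambda <- unname(co[2])
  if (!is.finite(lambda) || abs(lambda) < 1e-12) {
    rlang::abort("slope is zero: PSE undefined",
                 class = "raceddm_degenerate")
  }
  structure(list(lambda = lambda, lambda0 = lambda0,
                 pse = -lambda0 / lambda, separation = separation,
                 model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> slope:", signif(x$lambda, 4),
      " intercept:", signif(x$lambda0, 4),
      " PSE:", signif(x$pse, 4), "\n")
  invisible(x)
}

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda0", "lambda", "pse"),
                 estimate = c(x$lambda0, x$lambda, x$pse))
}

#' Mean go RT with the low-probability cues collapsed
#'
#' Reporting convenience for proactive tables: mean RT of responses per
#' cue, with the sparse 0/20/40% cues collapsed into a single cell. Not
#' part of the fitting cost.
#'
#' @param trials Proactive trial table.
#' @param collapse_low Collapse cues below 50% into one `"low"` cell.
#' @return A tibble with columns `cue`, `mean_rt`, `n`.
#' @export
mean_go_rt <- function(trials, collapse_low = TRUE) {
  resp <- trials[trials$response == 1L & !is.na(trials$rt), ]
  grp <- if (collapse_low) ifelse(resp$cue < 0.5, "low", format(resp$cue))
         else format(resp$cue)
  resp$cue_group <- grp
  dplyr::summarise(dplyr::group_by(resp, .data$cue_group),
                   mean_rt = mean(.data$rt), n = dplyr::n(),
                   .groups = "drop")
}
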