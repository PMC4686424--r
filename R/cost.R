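#' Weighted chi-square cost for the reactive task
#'
#' Sum over conditions of the weighted squared errors between observed and
#' model-predicted observables: the go response probability, the stop
#' accuracy at each SSD, and the correct/error RT quantile vectors. The
#' quantile terms are multiplied by the observed response probabilities on
#' correct (`p_corr`) and error (`p_err`) trials so that sparsely observed
#' distributions contribute proportionally less.
#'
#' Quantile terms where either side has no responses are skipped; the
#' probability terms still penalise the mismatch.
#'
#' @param obs,pred `behavior_summary` objects for a reactive design, with
#'   matching conditions.
#' @param w A [weight_set()].
#' @return Non-negative scalar cost (the chi-square of the fit tables).
#' @export
cost_reactive <- function(obs, pred, w = weight_set()) {
  stopifnot(obs$task == "reactive", pred$task == "reactive")
  so <- obs$stats
  sp <- pred$stats
  if (!identical(so$condition, sp$condition)) {
    sp <- sp[match(so$condition, sp$condition), ]
    if (anyNA(sp$condition)) {
      rlang::abort("obs and pred conditions do not align",
                   class = "raceddm_structure")
    }
  }
  total <- 0
  for (j in seq_len(nrow(so))) {
    total <- total + na_term(w$w_g * (so$p_go[j] - sp$p_go[j])^2)
    ps_o <- so$p_stop[[j]]
    ps_p <- sp$p_stop[[j]]
    if (length(ps_o) != length(ps_p) || length(ps_o) != length(w$w_d)) {
      rlang::abort("stop-curve lengths do not align",
                   class = "raceddm_structure")
    }
    total <- total + sum(na_term(w$w_d * (ps_o - ps_p)^2))
    total <- total + quantile_term(so$q_correct[[j]], sp$q_correct[[j]],
                                   w$w_c, so$p_corr[j])
    total <- total + quantile_term(so$q_error[[j]], sp$q_error[[j]],
                                   w$w_e, so$p_err[j])
  }
  total
}

#' Weighted chi-square cost for the proactive task
#'
#' Squared errors in the response probability at each go-probability cue,
#' plus the pooled high-cue and low-cue RT-quantile errors multiplied by
#' the observed response probabilities `p_high` and `p_low`.
#'
#' @inheritParams cost_reactive
#' @return Non-negative scalar cost.
#' @export
cost_proactive <- function(obs, pred, w = weight_set()) {
  stopifnot(obs$task == "proactive", pred$task == "proactive")
  so <- obs$stats
  sp <- pred$stats
  if (nrow(so) != nrow(sp)) {
    rlang::abort("obs and pred conditions do not align",
                 class = "raceddm_structure")
  }
  total <- 0
  for (j in seq_len(nrow(so))) {
    po <- so$p_resp[[j]]
    pp <- sp$p_resp[[j]]
    if (length(po) != length(pp)) {
      rlang::abort("cue-curve lengths do not align",
                   class = "raceddm_structure")
    }
    wp <- if (length(w$w_p) == length(po)) w$w_p else rep(1, length(po))
    total <- total + sum(na_term(wp * (po - pp)^2))
    total <- total + quantile_term(so$q_hi[[j]], sp$q_hi[[j]], w$w_h,
                                   so$p_high[j])
    total <- total + quantile_term(so$q_lo[[j]], sp$q_lo[[j]], w$w_l,
                                   so$p_low[j])
  }
  total
}

# degenerate inputs (cells with no trials) produce NA observables; such
# terms are skipped rather than propagated
na_term <- function(x) {
  x[!is.finite(x)] <- 0
  x
}

# Weighted residual vector of a fit: the cost equals sum(residuals^2)
# when every term is present. Used by the least-squares refinement; the
# layout is fixed by the observed summary, and entries the prediction
# cannot supply (no simulated responses where the data have them) are
# filled with a fixed penalty so the refinement is pushed back toward
# response-producing parameters.
summary_residuals <- function(obs, pred, w, penalty = 0.3) {
  so <- obs$stats
  sp <- pred$stats
  qres <- function(qo, qp, wq, pm) {
    if (is.null(qo) || !is.finite(pm) || pm <= 0) return(numeric(0))
    if (is.null(qp)) return(sqrt(pm * wq) * rep(penalty, length(qo)))
    sqrt(pm * wq) * (qo - qp)
  }
  out <- numeric(0)
  for (j in seq_len(nrow(so))) {
    if (obs$task == "reactive") {
      out <- c(out,
               sqrt(w$w_g) * (so$p_go[j] - sp$p_go[j]),
               sqrt(w$w_d) * (so$p_stop[[j]] - sp$p_stop[[j]]),
               qres(so$q_correct[[j]], sp$q_correct[[j]], w$w_c,
                    so$p_corr[j]),
               qres(so$q_error[[j]], sp$q_error[[j]], w$w_e,
                    so$p_err[j]))
    } else {
      po <- so$p_resp[[j]]
      wp <- if (length(w$w_p) == length(po)) w$w_p else rep(1, length(po))
      out <- c(out,
               sqrt(wp) * (po - sp$p_resp[[j]]),
               qres(so$q_hi[[j]], sp$q_hi[[j]], w$w_h, so$p_high[j]),
               qres(so$q_lo[[j]], sp$q_lo[[j]], w$w_l, so$p_low[j]))
    }
  }
  na_term(out)
}

quantile_term <- function(qo, qp, w, p_mult) {
  if (is.null(qo) || is.null(qp) || p_mult <= 0) return(0)
  if (length(qo) != length(qp) || length(qo) != length(w)) {
    rlang::abort("quantile vector lengths do not align",
                 class = "raceddm_structure")
  }
  p_mult * sum(na_term(w * (qo - qp)^2))
}

#' Information criteria for a weighted-SSE fit
#'
#' Maps the chi-square (weighted sum of squared errors) to AIC and BIC
#' under the Gaussian-SSE convention:
#' `AIC = n log(cost / n) + 2 k` and `BIC = n log(cost / n) + k log(n)`,
#' where `n` is the number of fitted data points and `k` the number of
#' free parameters. Comparisons are only meaningful within this
#' convention.
#'
#' @param cost Chi-square (>= 0).
#' @param k Number of free parameters.
#' @param n Number of fitted data points.
#' @return Named list with `aic` and `bic` (`-Inf` at cost = 0).
#' @export
information_criteria <- function(cost, k, n) {
  if (cost < 0) rlang::abort("cost must be >= 0")
  if (n <= k) rlang::warn("n <= k: information criteria are unreliable")
  if (cost == 0) {
    return(list(aic = -Inf, bic = -Inf))
  }
  base <- n * log(cost / n)
  list(aic = base + 2 * k, bic = base + k * log(n))
}
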