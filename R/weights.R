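#' Maritz-Jarrett standard error of a sample quantile
#'
#' Beta-weighted (bootstrap-free) estimate of the sampling standard error
#' of the q-th sample quantile. With sorted observations `x_(1..n)` and
#' `m = floor(q n + 0.5)`, the order-statistic weights
#' `W_i = P((i-1)/n < B <= i/n)` with `B ~ Beta(m, n - m + 1)` give the
#' first two moments `C_k = sum W_i x_(i)^k`, and the SE is
#' `sqrt(C_2 - C_1^2)`.
#'
#' @param x Numeric sample (n >= 5).
#' @param q Quantile level in (0, 1).
#' @return Standard error on the scale of `x`.
#' @export
maritz_jarrett_se <- function(x, q = 0.5) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 5L) {
    rlang::abort("need at least 5 observations",
                 class = "raceddm_insufficient")
  }
  if (q <= 0 || q >= 1) rlang::abort("`q` must be in (0, 1)")
  m <- max(1L, min(n, floor(q * n + 0.5)))
  i <- seq_len(n)
  w <- stats::pbeta(i / n, m, n - m + 1) -
    stats::pbeta((i - 1) / n, m, n - m + 1)
  c1 <- sum(w * x)
  c2 <- sum(w * x^2)
  sqrt(max(c2 - c1^2, 0))
}

#' Quantile weights for the fitting cost
#'
#' One weight per RT quantile, computed as the median of the five
#' Maritz-Jarrett standard errors divided by each quantile's own SE.
#' Quantiles estimated more variably than typical get weights below 1,
#' more stable ones above 1, and the weights are invariant to rescaling
#' the RTs.
#'
#' @param rts Response times (n >= 10), ignored when `se` is given.
#' @param probs Quantile levels.
#' @param se Optional precomputed vector of quantile standard errors.
#' @param cap Maximum weight, applied when an SE is (numerically) zero.
#' @return Numeric weight vector, one entry per quantile level.
#' @export
quantile_weights <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             se = NULL, cap = 10) {
  if (is.null(se)) {
    rts <- rts[!is.na(rts)]
    if (length(rts) < 10L) {
      rlang::abort("need at least 10 observations",
                   class = "raceddm_insufficient")
    }
    se <- vapply(probs, function(q) maritz_jarrett_se(rts, q), numeric(1))
  }
  ref <- stats::median(se)
  if (ref <= 0) return(rep(1, length(se)))
  w <- ref / se
  w[!is.finite(w) | w > cap] <- cap
  w
}

#' Accuracy weights from between-subject variability
#'
#' One weight per condition for the response-probability cost terms: the
#' standard deviation of each condition's probability across subjects,
#' with each condition weighted by `mean(SDs) / SD_condition`.
#'
#' @param prob_matrix Numeric matrix, subjects in rows, conditions in
#'   columns (>= 2 subjects).
#' @param cap Maximum weight (applied at zero SDs).
#' @return Named numeric weight vector (one per column).
#' @export
accuracy_weights <- function(prob_matrix, cap = 10) {
  prob_matrix <- as.matrix(prob_matrix)
  if (nrow(prob_matrix) < 2L) {
    rlang::abort("need at least 2 subjects",
                 class = "raceddm_insufficient")
  }
  sds <- apply(prob_matrix, 2, stats::sd)
  ref <- mean(sds)
  if (ref <= 0) return(stats::setNames(rep(1, ncol(prob_matrix)),
                                       colnames(prob_matrix)))
  w <- ref / sds
  w[!is.finite(w) | w > cap] <- cap
  w
}

#' Weight set for the fitting cost
#'
#' Container for the weights entering [cost_reactive()] /
#' [cost_proactive()]. Defaults are unit weights; use
#' [weights_from_summary()] or [weights_from_cohort()] to derive
#' data-driven weights.
#'
#' @param w_g Go-probability weight (reactive).
#' @param w_d Per-SSD stop-accuracy weights (reactive).
#' @param w_c,w_e Correct/error RT-quantile weight vectors (reactive).
#' @param w_p Per-cue response-probability weights (proactive).
#' @param w_h,w_l High/low RT-quantile weight vectors (proactive).
#' @return A list of class `weight_set`.
#' @export
weight_set <- function(w_g = 1, w_d = rep(1, 5), w_c = rep(1, 5),
                       w_e = rep(1, 5), w_p = rep(1, 6),
                       w_h = rep(1, 5), w_l = rep(1, 5)) {
  w <- list(w_g = w_g, w_d = w_d, w_c = w_c, w_e = w_e, w_p = w_p,
            w_h = w_h, w_l = w_l)
  if (any(unlist(w) <= 0)) rlang::abort("all weights must be > 0")
  structure(w, class = "weight_set")
}

#' Data-driven quantile weights from a trial table
#'
#' Builds a [weight_set()] whose RT-quantile weights come from
#' Maritz-Jarrett standard errors of the observed RTs. Accuracy weights
#' stay at 1 unless a multi-subject cohort is available (see
#' [weights_from_cohort()]).
#'
#' @param trials Trial table.
#' @param design Matching [task_design()].
#' @return A `weight_set`.
#' @export
weights_from_summary <- function(trials, design) {
  w <- weight_set(w_d = rep(1, length(design$ssds)),
                  w_p = rep(1, max(length(design$cues), 1L)))
  if (design$task == "reactive") {
    go_rts <- trials$rt[trials$trial_type == "go" & trials$response == 1L]
    err_rts <- trials$rt[trials$trial_type == "stop" &
                           trials$response == 1L]
    if (length(go_rts) >= 10L) w$w_c <- quantile_weights(go_rts)
    if (length(err_rts) >= 10L) w$w_e <- quantile_weights(err_rts)
  } else {
    hi <- trials$rt[trials$response == 1L & trials$cue > 0.5]
    lo <- trials$rt[trials$response == 1L & trials$cue < 0.5]
    if (length(hi) >= 10L) w$w_h <- quantile_weights(hi)
    if (length(lo) >= 10L) w$w_l <- quantile_weights(lo)
  }
  w
}

#' Full weight set from a multi-subject cohort
#'
#' Quantile weights from the pooled RTs (Maritz-Jarrett) and accuracy
#' weights from the across-subject standard deviations of each condition's
#' response probability.
#'
#' @param cohort A cohort object from [generate_cohort()], or a trial
#'   table with a `subject` column.
#' @param design Matching [task_design()].
#' @return A `weight_set`.
#' @export
weights_from_cohort <- function(cohort, design) {
  trials <- if (inherits(cohort, "raceddm_cohort")) cohort$trials else cohort
  w <- weights_from_summary(trials, design)
  subs <- unique(trials$subject)
  if (length(subs) < 2L) return(w)
  if (design$task == "reactive") {
    acc <- t(vapply(subs, function(s) {
      tt <- trials[trials$subject == s & trials$trial_type == "stop", ]
      vapply(design$ssds, function(d) {
        sel <- tt$ssd == d
        if (!any(sel)) NA_real_ else mean(tt$response[sel] == 0L)
      }, numeric(1))
    }, numeric(length(design$ssds))))
    if (!anyNA(acc)) w$w_d <- unname(accuracy_weights(acc))
    pg <- vapply(subs, function(s) {
      tt <- trials[trials$subject == s & trials$trial_type == "go", ]
      mean(tt$response)
    }, numeric(1))
    sd_ref <- mean(apply(acc, 2, stats::sd))
    if (is.finite(sd_ref) && stats::sd(pg) > 0) {
      w$w_g <- min(sd_ref / stats::sd(pg), 10)
    }
  } else {
    acc <- t(vapply(subs, function(s) {
      tt <- trials[trials$subject == s, ]
      vapply(design$cues, function(cu) {
        sel <- abs(tt$cue - cu) < 1e-9
        if (!any(sel)) NA_real_ else mean(tt$response[sel])
      }, numeric(1))
    }, numeric(length(design$cues))))
    if (!anyNA(acc)) w$w_p <- unname(accuracy_weights(acc))
  }
  w
}
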