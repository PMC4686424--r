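# Fast prediction path used inside cost evaluations.
#
# Cost evaluations simulate the same design cells thousands of times with
# identical noise (common random numbers). The per-trial normal increments
# are therefore generated once per (cell, n) and cached as matrices; each
# evaluation replays the dynamics over the cached noise in C++ and the
# summary statistics are computed directly from the rt vectors, skipping
# trial-table construction. The same noise is reused across conditions,
# which removes Monte-Carlo noise from between-condition contrasts.

noise_cache <- function() new.env(parent = emptyenv())

cached_noise <- function(cache, n, nsteps, seed, stream, substream) {
  key <- paste(n, nsteps, seed, stream, substream, sep = "|")
  m <- cache[[key]]
  if (is.null(m)) {
    m <- cpp_noise_matrix(as.integer(n), as.integer(nsteps),
                          as.double(seed), as.double(stream),
                          as.integer(substream))
    cache[[key]] <- m
  }
  m
}

fast_trials <- function(model, p, ssd, n, cfg, stream, cache,
                        antithetic = TRUE) {
  nsteps <- as.integer(ceiling(cfg$deadline / cfg$dt)) + 1L
  ncol_need <- if (antithetic) ceiling(n / 2) else n
  ze <- cached_noise(cache, ncol_need, nsteps, cfg$seed, stream, 0L)
  zb <- if (model == "go") matrix(0, 0, 0) else
    cached_noise(cache, ncol_need, nsteps, cfg$seed, stream, 1L)
  v_b <- p$v_b %||% NA_real_
  sso <- p$sso %||% NA_real_
  cpp_simulate_cached(model_code(model), p$a, p$tr, p$v_e,
                      if (is.na(v_b)) 0 else v_b, p$xb, p$sigma,
                      if (is.na(sso)) 0 else sso,
                      if (is.na(ssd)) 0 else ssd,
                      cfg$dt, cfg$deadline, ze, zb,
                      as.integer(n), as.integer(antithetic))
}

# one reactive condition -> one summary row (list fields)
reactive_row_cached <- function(model, p, design, n_go, n_stop, cfg,
                                cache) {
  go <- fast_trials("go", p, NA, n_go, cfg, stream = 0, cache = cache)
  go_rts <- go$rt[!is.na(go$rt)]
  p_go <- length(go_rts) / n_go
  q_correct <- if (length(go_rts) >= 1L) rt_quantiles(go_rts) else NULL
  p_stop <- numeric(length(design$ssds))
  err_rts <- numeric()
  for (si in seq_along(design$ssds)) {
    st <- fast_trials(model, p, design$ssds[si], n_stop, cfg,
                      stream = si * 10^7, cache = cache)
    resp <- !is.na(st$rt)
    p_stop[si] <- 1 - mean(resp)
    err_rts <- c(err_rts, st$rt[resp])
  }
  names(p_stop) <- format(design$ssds)
  q_error <- if (length(err_rts) >= 1L) rt_quantiles(err_rts) else NULL
  p_err <- length(err_rts) / (n_stop * length(design$ssds))
  list(p_go = p_go, p_corr = p_go, p_err = p_err, p_stop = p_stop,
       q_correct = q_correct, q_error = q_error)
}

predict_reactive_cached <- function(model, ptbl, design, n_go, n_stop,
                                    cfg, cache) {
  rows <- lapply(seq_len(nrow(ptbl)), function(ci) {
    p <- as.list(ptbl[ci, ])
    r <- reactive_row_cached(model, p, design, n_go, n_stop, cfg, cache)
    tibble::tibble(condition = ptbl$condition[ci], p_go = r$p_go,
                   p_corr = r$p_corr, p_err = r$p_err,
                   p_stop = list(r$p_stop),
                   q_correct = list(r$q_correct),
                   q_error = list(r$q_error),
                   n_go = n_go, n_stop = n_stop * length(design$ssds))
  })
  structure(list(task = "reactive", stats = dplyr::bind_rows(rows)),
            class = "behavior_summary")
}

predict_proactive_cached <- function(ptbl, design, n_per_cue, cfg,
                                     cache) {
  p_resp <- numeric(nrow(ptbl))
  hi <- numeric()
  lo <- numeric()
  for (ci in seq_len(nrow(ptbl))) {
    p <- as.list(ptbl[ci, ])
    sim <- fast_trials("go", p, NA, n_per_cue, cfg,
                       stream = (ci - 1) * 10^7, cache = cache)
    rts <- sim$rt[!is.na(sim$rt)]
    p_resp[ci] <- length(rts) / n_per_cue
    if (ptbl$cue[ci] > 0.5) hi <- c(hi, rts)
    if (ptbl$cue[ci] < 0.5) lo <- c(lo, rts)
  }
  names(p_resp) <- format(ptbl$cue)
  hi_cells <- ptbl$cue > 0.5
  lo_cells <- ptbl$cue < 0.5
  p_high <- if (any(hi_cells)) mean(p_resp[hi_cells]) else 0
  p_low <- if (any(lo_cells)) mean(p_resp[lo_cells]) else 0
  stats <- tibble::tibble(
    condition = "pooled", p_resp = list(p_resp),
    p_high = p_high, p_low = p_low,
    q_hi = list(if (length(hi)) rt_quantiles(hi) else NULL),
    q_lo = list(if (length(lo)) rt_quantiles(lo) else NULL),
    n = n_per_cue * nrow(ptbl))
  structure(list(task = "proactive", stats = stats),
            class = "behavior_summary")
}

# flat-stage prediction against the condition-averaged observables
predict_flat_cached <- function(model, design, p, n_sim, cfg, cache) {
  if (design$task == "reactive") {
    n_go <- as.integer(ceiling(n_sim / 2))
    n_stop <- as.integer(ceiling(n_sim / (2 * length(design$ssds))))
    r <- reactive_row_cached(model, unclass(p), design, n_go, n_stop,
                             cfg, cache)
    stats <- tibble::tibble(condition = "average", p_go = r$p_go,
                            p_corr = r$p_corr, p_err = r$p_err,
                            p_stop = list(r$p_stop),
                            q_correct = list(r$q_correct),
                            q_error = list(r$q_error),
                            n_go = n_go,
                            n_stop = n_stop * length(design$ssds))
    return(structure(list(task = "reactive", stats = stats),
                     class = "behavior_summary"))
  }
  sim <- fast_trials("go", unclass(p), NA, as.integer(n_sim), cfg,
                     stream = 0, cache = cache)
  rts <- sim$rt[!is.na(sim$rt)]
  pr <- length(rts) / n_sim
  stats <- tibble::tibble(
    condition = "average", p_resp = list(c(mean = pr)), p_high = pr,
    p_low = 0, q_hi = list(if (length(rts)) rt_quantiles(rts) else NULL),
    q_lo = list(NULL), n = as.integer(n_sim))
  structure(list(task = "proactive", stats = stats),
            class = "behavior_summary")
}
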