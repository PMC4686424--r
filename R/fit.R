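#' Fitting configuration
#'
#' Controls the two-stage optimization protocol: a stochastic basin-hopping
#' search for the global error basin (iterated at most `basin_max_iter`
#' times or until `basin_fail_limit` consecutive failures to improve the
#' global best), each hop polished by a short Nelder-Mead run, followed by
#' a full Nelder-Mead simplex descent into the basin. The whole protocol is
#' run `n_restarts` times from scratch and the result with the lowest AIC
#' is kept.
#'
#' Predicted summaries inside the cost are computed from fixed-seed
#' simulation with `n_sim_per_eval` trials per condition using common
#' random numbers across evaluations, which makes the cost surface
#' deterministic and locally smooth for the simplex stage.
#'
#' The basin-hopping search runs at a cheaper simulation resolution
#' (`n_sim_search` trials per condition); the final simplex polish and all
#' reported costs use the full `n_sim_per_eval`. The search is initialised
#' at the best of `n_screen` Latin-hypercube points.
#'
#' @param n_sim_per_eval Simulated trials per condition per cost
#'   evaluation at the polish/reporting stage.
#' @param n_sim_search Simulated trials per condition during the
#'   basin-hopping search stage.
#' @param n_screen Latin-hypercube points screened to initialise the
#'   search.
#' @param n_multistart Screen points carried into full simplex descents
#'   before basin hopping; all resulting candidates are re-ranked at full
#'   resolution.
#' @param multistart_maxit Simplex iterations per multistart descent.
#' @param nm_restarts Consecutive fresh-simplex Nelder-Mead runs in the
#'   final polish (restarting the simplex escapes premature collapse).
#' @param basin_max_iter Maximum basin-hopping iterations.
#' @param basin_fail_limit Consecutive failed hops (improvement below
#'   `tol`) before the basin stage halts.
#' @param basin_step_frac Hop size as a fraction of each parameter's box.
#' @param basin_temp Metropolis temperature for accepting uphill hops.
#' @param basin_local_maxit Nelder-Mead iterations polishing each hop.
#' @param simplex_maxit Iterations of the final simplex stage.
#' @param n_restarts Full protocol restarts (>= 3 recommended).
#' @param dt Integration step used inside full-resolution cost
#'   evaluations (seconds). Match the step the data were generated or
#'   recorded at to avoid discretization bias in the polish stage.
#' @param dt_search Coarser integration step for the search stages
#'   (default: same as `dt`).
#' @param seed Master seed: drives the optimizer's randomness and the
#'   common-random-number streams of the simulated predictions.
#' @param bounds Named list of `c(lower, upper)` parameter boxes; see
#'   [param_bounds()].
#' @param profile_grid Run the (tr, xb) profile-grid candidate stage
#'   (disable only for quick exploratory fits).
#' @param tol Minimum improvement counting as a successful hop.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_sim_per_eval = 10000L, n_sim_search = 4000L,
                       n_screen = 100L, n_multistart = 8L,
                       multistart_maxit = 150L,
                       basin_max_iter = 100L,
                       basin_fail_limit = 40L, basin_step_frac = 0.1,
                       basin_temp = 1.0, basin_local_maxit = 100L,
                       simplex_maxit = 500L, nm_restarts = 2L,
                       n_restarts = 3L,
                       dt = 0.001, dt_search = NULL, seed = 1L,
                       profile_grid = TRUE,
                       bounds = param_bounds(), tol = 1e-6) {
  structure(list(n_sim_per_eval = as.integer(n_sim_per_eval),
                 n_sim_search = as.integer(n_sim_search),
                 n_screen = as.integer(n_screen),
                 n_multistart = as.integer(n_multistart),
                 multistart_maxit = as.integer(multistart_maxit),
                 nm_restarts = as.integer(nm_restarts),
                 basin_max_iter = as.integer(basin_max_iter),
                 basin_fail_limit = as.integer(basin_fail_limit),
                 basin_step_frac = basin_step_frac,
                 basin_temp = basin_temp,
                 basin_local_maxit = as.integer(basin_local_maxit),
                 simplex_maxit = as.integer(simplex_maxit),
                 n_restarts = as.integer(n_restarts), dt = dt,
                 dt_search = dt_search %||% dt,
                 profile_grid = isTRUE(profile_grid),
                 seed = as.integer(seed), bounds = bounds, tol = tol),
            class = "fit_config")
}

#' Parameter search boxes
#'
#' Default bounds envelope typical best-fit values for both tasks with
#' headroom. Units: `a` evidence, `tr`/`sso` seconds, drifts evidence/s,
#' `xb` 1/s.
#' @return Named list of `c(lower, upper)` pairs.
#' @export
param_bounds <- function() {
  list(a = c(0.05, 1.5), tr = c(0.001, 0.5), v_e = c(0.01, 5),
       v_b = c(0.01, 5), xb = c(0, 5), sso = c(0, 0.3))
}

free_param_names <- function(model, task) {
  if (task == "proactive") return(c("a", "tr", "v_e", "xb"))
  base <- c("a", "tr", "v_e", "v_b", "xb")
  if (model == "interactive") c(base, "sso") else base
}

bounds_for <- function(names, bounds) {
  lo <- vapply(names, function(p) bounds[[p]][1], numeric(1))
  hi <- vapply(names, function(p) bounds[[p]][2], numeric(1))
  list(lower = lo, upper = hi)
}

params_from_vector <- function(theta, constants = list()) {
  p <- utils::modifyList(
    list(a = NA_real_, tr = NA_real_, v_e = NA_real_, v_b = NA_real_,
         xb = 0, sigma = 0.1, sso = NA_real_),
    constants)
  for (nm in names(theta)) p[[nm]] <- unname(theta[nm])
  process_params(p$a, p$tr, p$v_e, p$v_b, p$xb, p$sigma, p$sso)
}

# ---- optimizers --------------------------------------------------------

box_penalised <- function(fn, lower, upper) {
  function(x) {
    viol <- pmax(lower - x, 0) + pmax(x - upper, 0)
    if (any(viol > 0)) return(1e6 * (1 + sum(viol^2)))
    fn(x)
  }
}

nm_minimize <- function(fn, x0, lower, upper, maxit) {
  fnb <- box_penalised(fn, lower, upper)
  if (length(x0) == 1L) {
    res <- stats::optimize(fnb, lower = lower, upper = upper,
                           tol = 1e-4)
    return(list(par = stats::setNames(res$minimum, names(x0)),
                value = res$objective))
  }
  # parameter-scaled simplex: step sizes proportional to each box
  res <- stats::optim(x0, fnb, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = (upper - lower) / 4,
                                     reltol = 1e-9))
  list(par = res$par, value = res$value)
}

basin_hop <- function(fn, x0, lower, upper, config) {
  step <- config$basin_step_frac * (upper - lower)
  cur <- nm_minimize(fn, x0, lower, upper, config$basin_local_maxit)
  best <- cur
  fails <- 0L
  iters <- 0L
  for (it in seq_len(config$basin_max_iter)) {
    iters <- it
    cand0 <- cur$par + stats::runif(length(x0), -1, 1) * step
    cand0 <- pmin(pmax(cand0, lower), upper)
    cand <- nm_minimize(fn, cand0, lower, upper,
                        config$basin_local_maxit)
    if (cand$value < best$value - config$tol) {
      best <- cand
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
    accept <- cand$value <= cur$value ||
      stats::runif(1) < exp((cur$value - cand$value) / config$basin_temp)
    if (accept) cur <- cand
    if (fails >= config$basin_fail_limit) break
  }
  c(best, list(iterations = iters, fails = fails))
}

random_start <- function(lower, upper) {
  stats::setNames(lower + stats::runif(length(lower)) * (upper - lower),
                  names(lower))
}

# Latin-hypercube sample on [0,1]^k: one stratified draw per row and
# dimension, strata in random order
lhs_sample <- function(n, k) {
  vapply(seq_len(k), function(j) (sample(n) - stats::runif(n)) / n,
         numeric(n))
}

# Moment-based starting point for given onset delay and gain: the
# remaining execution parameters are solved from the observed RT
# quantiles — the median decision time T = q50 - tr fixes
# a = v T cosh(xb T) once v is set from the quantile spread via the
# inverse-Gaussian sd sigma sqrt(T) / v (deflated by the gain, which
# compresses the late tail).
moment_start <- function(q, tr, xb, free, bounds, sigma = 0.1) {
  q10 <- unname(q[1]); q50 <- unname(q[3]); q90 <- unname(q[5])
  sd_obs <- max((q90 - q10) / 2.563, 1e-3)
  T_med <- q50 - tr
  if (T_med <= 0.02) return(NULL)
  gain <- cosh(xb * T_med)
  v <- sigma * sqrt(T_med) / (sd_obs * sqrt(gain))
  a <- v * T_med * gain
  th <- c(a = a, tr = tr, v_e = v, v_b = 1.0, xb = xb, sso = 0.1)[free]
  lo <- vapply(free, function(p) bounds[[p]][1], numeric(1))
  hi <- vapply(free, function(p) bounds[[p]][2], numeric(1))
  pmin(pmax(th, lo), hi)
}

quantile_anchor <- function(avg_obs) {
  s <- avg_obs$stats
  if (avg_obs$task == "reactive") s$q_correct[[1]] else s$q_hi[[1]]
}

# ---- predicted summaries ----------------------------------------------

eval_counts <- function(design, config) {
  if (design$task == "reactive") {
    list(n_go = as.integer(ceiling(config$n_sim_per_eval / 2)),
         n_stop = as.integer(ceiling(
           config$n_sim_per_eval / (2 * length(design$ssds)))))
  } else {
    list(n_per_cue = config$n_sim_per_eval)
  }
}

predict_summary <- function(model, design, ptbl, config) {
  cfg <- sim_config(dt = config$dt, deadline = design$deadline,
                    seed = config$seed)
  nc <- eval_counts(design, config)
  tab <- if (design$task == "reactive") {
    simulate_task(model, design, ptbl, cfg, n_go = nc$n_go,
                  n_stop_per_ssd = nc$n_stop)
  } else {
    simulate_task(model, design, ptbl, cfg, n_per_cue = nc$n_per_cue)
  }
  summarize_trials(tab, design)
}

# ---- cost wiring -------------------------------------------------------

cost_for_task <- function(task) {
  if (task == "reactive") cost_reactive else cost_proactive
}

count_data_points <- function(obs) {
  s <- obs$stats
  n <- 0L
  for (j in seq_len(nrow(s))) {
    if (obs$task == "reactive") {
      n <- n + 1L + length(s$p_stop[[j]]) +
        length(s$q_correct[[j]]) + length(s$q_error[[j]])
    } else {
      n <- n + length(s$p_resp[[j]]) + length(s$q_hi[[j]]) +
        length(s$q_lo[[j]])
    }
  }
  n
}

subset_summary <- function(obs, cond) {
  structure(list(task = obs$task,
                 stats = obs$stats[obs$stats$condition == cond, ]),
            class = "behavior_summary")
}

# ---- stage 1: flat fit -------------------------------------------------

#' Flat (all-parameters-free) fit to condition-averaged data
#'
#' First stage of the fitting protocol: every model parameter is free and
#' optimized against the condition-averaged observables (cost without the
#' summation over conditions) by basin hopping followed by a Nelder-Mead
#' polish.
#'
#' @param trials Trial table.
#' @param model `"dpm"`, `"independent"`, or `"interactive"` (proactive
#'   designs use the execution process only).
#' @param design A [task_design()].
#' @param config A [fit_config()]. The caller controls the random start
#'   via the R RNG; use [fit_race_model()] for the seeded full protocol.
#' @param weights Optional [weight_set()]; defaults to
#'   [weights_from_summary()].
#' @return List with `params` (a `process_params`), `cost`, `converged`,
#'   and a `trace` tibble.
#' @export
fit_flat <- function(trials, model, design, config = fit_config(),
                     weights = NULL) {
  obs <- summarize_trials(trials, design)
  w <- weights %||% weights_from_summary(trials, design)
  avg_obs <- average_summary(obs)
  free <- free_param_names(model, design$task)
  bx <- bounds_for(free, config$bounds)
  costf <- cost_for_task(design$task)
  cfg_search <- sim_config(dt = config$dt_search,
                           deadline = design$deadline,
                           seed = config$seed)
  cfg_final <- sim_config(dt = config$dt, deadline = design$deadline,
                          seed = config$seed)
  cache <- noise_cache()
  n_eval <- 0L
  make_fn <- function(n_sim, cfg_sim) {
    function(theta) {
      n_eval <<- n_eval + 1L
      p <- try(params_from_vector(stats::setNames(theta, free)),
               silent = TRUE)
      if (inherits(p, "try-error")) return(1e6)
      pred <- predict_flat_cached(model, design, p, n_sim, cfg_sim,
                                  cache)
      costf(avg_obs, pred, w)
    }
  }
  fn_search <- make_fn(config$n_sim_search, cfg_search)
  fn_final <- make_fn(config$n_sim_per_eval, cfg_final)

  # stratified screen at cheap resolution
  pts <- t(t(lhs_sample(config$n_screen, length(free))) *
             (bx$upper - bx$lower) + bx$lower)
  vals <- apply(pts, 1, fn_search)
  ord <- order(vals)

  # simplex descents from the best screen points: the cost surface has
  # several locally good basins, so a set of candidates is carried
  # forward and disambiguated at full resolution
  n_ms <- min(config$n_multistart, config$n_screen)
  starts <- lapply(ord[seq_len(n_ms)],
                   function(i) stats::setNames(pts[i, ], free))
  cands <- lapply(starts, function(x0) {
    nm_minimize(fn_search, x0, bx$lower, bx$upper,
                config$multistart_maxit)
  })
  cvals <- vapply(cands, `[[`, numeric(1), "value")

  # basin hopping around the best candidate (cheap resolution)
  bh <- basin_hop(fn_search, cands[[which.min(cvals)]]$par, bx$lower,
                  bx$upper, config)
  cands[[length(cands) + 1L]] <- bh

  # rank every candidate at full resolution; the top two basins are each
  # refined by Levenberg-Marquardt on the weighted residual vector (the
  # surface is smooth under common random numbers, so the least-squares
  # step digs much deeper than the simplex), then the winner gets a
  # final simplex + LM polish
  make_res_fn <- function(n_sim) {
    function(theta) {
      p <- try(params_from_vector(stats::setNames(theta, free)),
               silent = TRUE)
      if (inherits(p, "try-error")) return(rep(1e3, 16))
      pred <- predict_flat_cached(model, design, p, n_sim, cfg_final,
                                  cache)
      summary_residuals(avg_obs, pred, w)
    }
  }
  # finite-difference steps must exceed the Monte-Carlo granularity of
  # the probability observables (1/n steps), so the intermediate stage
  # uses ~1% secant steps and the full-resolution stage ~0.3%
  lm_step <- function(x0, n_sim, maxiter, eps) {
    lm <- try(suppressWarnings(minpack.lm::nls.lm(
      par = x0, lower = bx$lower, upper = bx$upper,
      fn = make_res_fn(n_sim),
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           epsfcn = eps))),
      silent = TRUE)
    if (inherits(lm, "try-error")) return(x0)
    stats::coef(lm)
  }
  lm_refine <- function(x0) {
    par <- lm_step(x0, config$n_sim_per_eval, 40L, 1e-5)
    list(par = par, value = fn_final(par))
  }

  # the search-resolution descents stall well above the basin floors
  # (their Monte-Carlo floor hides the between-basin differences), so
  # every candidate first gets a short least-squares slide at an
  # intermediate resolution before the basins are ranked at full
  # resolution
  n_mid <- max(config$n_sim_search,
               as.integer(ceiling(config$n_sim_per_eval / 5)))
  cands <- lapply(cands, function(cc) {
    list(par = lm_step(cc$par, n_mid, 10L, 1e-4), value = cc$value)
  })

  # (tr, xb) profile: those two parameters trade off against the rest
  # along a stiff curved valley that descent methods traverse poorly,
  # so they are scanned on a deterministic grid and the remaining,
  # well-conditioned parameters are fitted by least squares at each
  # grid point from moment-based starts
  grid_cands <- list()
  q_anchor <- if (isTRUE(config$profile_grid)) quantile_anchor(avg_obs)
              else NULL
  if (!is.null(q_anchor)) {
    sub <- setdiff(free, c("tr", "xb"))
    lo_s <- vapply(sub, function(p) config$bounds[[p]][1], numeric(1))
    hi_s <- vapply(sub, function(p) config$bounds[[p]][2], numeric(1))
    res_mid <- make_res_fn(config$n_sim_search)
    for (trv in unname(q_anchor[1]) * seq(0.2, 0.65, by = 0.15)) {
      for (xbv in c(0, 0.6, 1.1, 1.6, 2.2, 3)) {
        x00 <- moment_start(q_anchor, trv, xbv, free, config$bounds)
        if (is.null(x00)) next
        # deadline truncation makes the spread-based drift estimate an
        # upper bound, so each grid point is also tried at reduced
        # evidence scales (a and v_e shrunk together preserve the mean
        # crossing time)
        for (scl in c(1.6, 1, 0.5)) {
          x0 <- x00
          x0["a"] <- max(x0["a"] * scl, config$bounds$a[1])
          x0["v_e"] <- max(x0["v_e"] * scl, config$bounds$v_e[1])
          sub_fn <- function(th_sub) {
            th <- x0
            th[sub] <- th_sub
            res_mid(th)
          }
          lmr <- try(suppressWarnings(minpack.lm::nls.lm(
            par = x0[sub], lower = lo_s, upper = hi_s, fn = sub_fn,
            control = minpack.lm::nls.lm.control(maxiter = 8,
                                                 epsfcn = 1e-4))),
            silent = TRUE)
          th <- x0
          if (!inherits(lmr, "try-error")) th[sub] <- stats::coef(lmr)
          # the on-grid solution keeps its (tr, xb) anchor, preserving
          # candidate diversity for the conditional-stage probe
          cands[[length(cands) + 1L]] <- list(par = th,
                                              value = NA_real_)
          grid_cands[[length(grid_cands) + 1L]] <- th
        }
      }
    }
  }
  # drop near-duplicate candidates before any full-resolution work
  sig <- vapply(cands, function(cc) paste(signif(cc$par, 3),
                                          collapse = "|"), character(1))
  keep <- !duplicated(sig)
  cands <- cands[keep]
  grid_cands <- grid_cands[!duplicated(vapply(grid_cands, function(p) {
    paste(signif(p, 3), collapse = "|")
  }, character(1)))]
  fvals <- vapply(cands, function(cc) fn_final(cc$par), numeric(1))
  top <- order(fvals)[seq_len(min(2L, length(cands)))]
  polished <- lapply(top, function(i) lm_refine(cands[[i]]$par))
  pvals <- vapply(polished, `[[`, numeric(1), "value")
  best <- polished[[which.min(pvals)]]
  for (r in seq_len(config$nm_restarts)) {
    cand <- nm_minimize(fn_final, best$par, bx$lower, bx$upper,
                        config$simplex_maxit)
    if (cand$value <= best$value) best <- cand
  }
  fin <- lm_refine(best$par)
  if (fin$value <= best$value) best <- fin
  trace <- tibble::tibble(
    stage = c("screen", "multistart", "basin", "simplex"),
    cost = c(min(vals), min(cvals), bh$value, best$value),
    evals = c(config$n_screen, NA_integer_, NA_integer_, n_eval))

  # keep a diversified shortlist of flat solutions: the averaged
  # observables often cannot tell compensating parameter sets apart, and
  # the conditional stage can probe which shortlisted set explains the
  # full condition structure (see fit_conditional)
  ord_f <- order(fvals)
  shortlist <- list(best$par)
  for (i in ord_f) {
    cc <- cands[[i]]$par
    if (!is.finite(fvals[i]) || fvals[i] > 0.01) next
    distinct <- all(vapply(shortlist, function(sp) {
      any(abs(cc - sp) / pmax(abs(sp), 0.05) > 0.08)
    }, logical(1)))
    if (distinct) shortlist[[length(shortlist) + 1L]] <- cc
    if (length(shortlist) >= 12L) break
  }

  list(params = params_from_vector(stats::setNames(best$par, free)),
       cost = best$value, free = free, weights = w, obs = obs,
       converged = is.finite(best$value) && best$value < 1e5,
       candidates = lapply(c(shortlist, grid_cands), function(p) {
         params_from_vector(stats::setNames(p, free))
       }),
       trace = trace, n_eval = n_eval)
}

# ---- stage 2: conditional fit -----------------------------------------

#' Conditional fit: free parameters per condition
#'
#' Second stage of the protocol. All parameters are held at the flat-stage
#' estimates except the modulated parameter(s), which are (a) re-seeded by
#' a short basin-hopping search individually per condition (so the joint
#' simplex does not start from identical values across conditions) and
#' (b) jointly polished by a final Nelder-Mead simplex on the full
#' multi-condition cost.
#'
#' @param trials Trial table with a `condition` column (reactive) or `cue`
#'   column (proactive).
#' @param model Generator model, as in [fit_flat()].
#' @param modulation `"none"`, `"drift"`, `"onset"`, `"drift_onset"`, or
#'   `"bound"`.
#' @param design A [task_design()].
#' @param flat Result of [fit_flat()].
#' @param config A [fit_config()].
#' @return A `race_fit` object.
#' @export
fit_conditional <- function(trials, model, modulation, design, flat,
                            config = fit_config()) {
  free <- modulation_free_params(modulation)
  obs <- flat$obs
  w <- flat$weights
  costf <- cost_for_task(design$task)

  if (!length(free)) {
    return(build_race_fit(trials, model, modulation, design, flat,
                          config, cond_params = NULL))
  }

  conds <- if (design$task == "reactive") obs$stats$condition
           else proactive_cue_labels(design$cues)
  make_ptbl_for <- function(fv) {
    if (design$task == "reactive") {
      function(mat) {
        tbl <- tibble::as_tibble(fv[c("a", "tr", "v_e", "v_b", "xb",
                                      "sigma", "sso")])
        tbl <- tbl[rep(1, length(conds)), ]
        tbl$condition <- conds
        for (k in seq_along(free)) tbl[[free[k]]] <- mat[, k]
        tbl
      }
    } else {
      function(mat) {
        tbl <- tibble::as_tibble(fv[c("a", "tr", "v_e", "xb", "sigma")])
        tbl <- tbl[rep(1, length(conds)), ]
        tbl$condition <- conds
        tbl$cue <- design$cues
        tbl$v_b <- NA_real_
        for (k in seq_along(free)) tbl[[free[k]]] <- mat[, k]
        tbl
      }
    }
  }
  bx <- bounds_for(free, config$bounds)

  cfg_sim <- sim_config(dt = config$dt, deadline = design$deadline,
                        seed = config$seed)
  cache <- noise_cache()
  pred_joint <- function(ptbl, n_sim) {
    if (design$task == "reactive") {
      predict_reactive_cached(
        model, ptbl, design,
        n_go = as.integer(ceiling(n_sim / 2)),
        n_stop = as.integer(ceiling(n_sim / (2 * length(design$ssds)))),
        cfg = cfg_sim, cache = cache)
    } else {
      predict_proactive_cached(ptbl, design, as.integer(n_sim), cfg_sim,
                               cache)
    }
  }

  seed_mat <- function(fv) {
    start <- vapply(free, function(p) fv[[p]], numeric(1))
    matrix(rep(start, each = length(conds)), nrow = length(conds),
           dimnames = list(conds, free))
  }
  quick_reseed <- function(pf, mat, n_sim = NULL) {
    for (ci in seq_along(conds)) {
      fn_c <- condition_cost_fn(trials, model, design, obs, w, config,
                                pf, mat, ci, free, cfg_sim, cache,
                                n_sim = n_sim)
      r <- nm_minimize(fn_c, stats::setNames(mat[ci, ], free),
                       bx$lower, bx$upper, 25L)
      mat[ci, ] <- r$par
    }
    mat
  }

  # the condition-averaged observables of the flat stage often cannot
  # distinguish compensating constant-parameter sets, but the full
  # condition structure can: probe every shortlisted flat solution by a
  # quick per-condition re-seed and one full-cost evaluation, and carry
  # the one that explains the conditions best
  flat_list <- flat$candidates %||% list(flat$params)
  if (length(flat_list) > 1L) {
    # two passes: a cheap screen of every candidate, then a
    # full-resolution probe of the leaders
    probe_at <- function(cand, n_sim) {
      fv <- unclass(cand)
      pf <- make_ptbl_for(fv)
      m <- quick_reseed(pf, seed_mat(fv), n_sim = n_sim)
      costf(obs, pred_joint(pf(m), n_sim), w)
    }
    n_cheap <- max(config$n_sim_search,
                   as.integer(ceiling(config$n_sim_per_eval / 5)))
    cheap <- vapply(flat_list, probe_at, numeric(1), n_sim = n_cheap)
    lead <- order(cheap)[seq_len(min(8L, length(flat_list)))]
    flat_list <- flat_list[lead]
    probe <- vapply(flat_list, probe_at, numeric(1),
                    n_sim = config$n_sim_per_eval)

    if (isTRUE(getOption("raceddm.debug"))) {
      for (i in seq_along(flat_list)) {
        fv <- unclass(flat_list[[i]])
        message(sprintf(
          "probe %2d: a=%.3f tr=%.3f v=%.3f xb=%.3f -> %.4g",
          i, fv$a, fv$tr, fv$v_e, fv$xb, probe[i]))
      }
    }
    flat$params <- flat_list[[which.min(probe)]]
  }
  flat_vals <- unclass(flat$params)
  ptbl_for <- make_ptbl_for(flat_vals)

  # per-condition re-seeding: short basin hop on that condition's own
  # cost terms, everything else fixed
  seed_cfg <- config
  seed_cfg$basin_max_iter <- max(10L, config$basin_max_iter %/% 4L)
  seed_cfg$basin_fail_limit <- max(5L, config$basin_fail_limit %/% 4L)
  mat <- seed_mat(flat_vals)
  for (ci in seq_along(conds)) {
    fn_c <- condition_cost_fn(trials, model, design, obs, w, config,
                              ptbl_for, mat, ci, free, cfg_sim, cache)
    bh <- basin_hop(fn_c, stats::setNames(mat[ci, ], free), bx$lower,
                    bx$upper, seed_cfg)
    mat[ci, ] <- bh$par
  }

  # joint simplex on the full multi-condition cost, full resolution
  n_eval <- 0L
  fn_joint <- function(theta) {
    n_eval <<- n_eval + 1L
    m <- matrix(theta, nrow = length(conds), byrow = FALSE)
    pred <- pred_joint(ptbl_for(m), config$n_sim_per_eval)
    costf(obs, pred, w)
  }
  lower_j <- rep(bx$lower, each = length(conds))
  upper_j <- rep(bx$upper, each = length(conds))
  res <- list(par = as.numeric(mat), value = fn_joint(as.numeric(mat)))
  for (r in seq_len(config$nm_restarts)) {
    cand <- nm_minimize(fn_joint, res$par, lower_j, upper_j,
                        config$simplex_maxit)
    if (cand$value <= res$value) res <- cand
  }
  res_fn <- function(theta) {
    m <- matrix(theta, nrow = length(conds), byrow = FALSE)
    pred <- pred_joint(ptbl_for(m), config$n_sim_per_eval)
    summary_residuals(obs, pred, w)
  }
  lm <- try(suppressWarnings(minpack.lm::nls.lm(
    par = res$par, lower = lower_j, upper = upper_j, fn = res_fn,
    control = minpack.lm::nls.lm.control(maxiter = 30, epsfcn = 1e-5))),
    silent = TRUE)
  if (!inherits(lm, "try-error")) {
    lm_par <- stats::coef(lm)
    lm_val <- fn_joint(lm_par)
    if (lm_val <= res$value) res <- list(par = lm_par, value = lm_val)
  }
  mat_fin <- matrix(res$par, nrow = length(conds),
                    dimnames = list(conds, free))
  build_race_fit(trials, model, modulation, design, flat, config,
                 cond_params = ptbl_for(mat_fin), cond_cost = res$value,
                 n_eval = n_eval)
}

condition_cost_fn <- function(trials, model, design, obs, w, config,
                              ptbl_for, mat, ci, free, cfg_sim, cache,
                              n_sim = NULL) {
  costf <- cost_for_task(design$task)
  n_sim <- n_sim %||% config$n_sim_search
  if (design$task == "reactive") {
    cond <- obs$stats$condition[ci]
    obs_c <- subset_summary(obs, cond)
    n_go <- as.integer(ceiling(n_sim / 2))
    n_stop <- as.integer(ceiling(n_sim / (2 * length(design$ssds))))
    function(theta) {
      m <- mat
      m[ci, ] <- theta
      ptbl <- ptbl_for(m)
      pred <- predict_reactive_cached(model,
                                      ptbl[ptbl$condition == cond, ],
                                      design, n_go, n_stop, cfg_sim,
                                      cache)
      pred$stats$condition <- cond
      costf(obs_c, pred, w)
    }
  } else {
    # per-cue re-seeding target: this cue's response probability plus its
    # own RT quantiles when observed responses allow them
    cue <- design$cues[ci]
    sel <- abs(trials$cue - cue) < 1e-9
    p_obs <- mean(trials$response[sel])
    rts <- trials$rt[sel & trials$response == 1L]
    q_obs <- if (length(rts) >= 5L) rt_quantiles(rts) else NULL
    function(theta) {
      m <- mat
      m[ci, ] <- theta
      prow <- as.list(ptbl_for(m)[ci, ])
      sim <- fast_trials("go", prow, NA, as.integer(n_sim), cfg_sim,
                         stream = (ci - 1) * 10^7, cache = cache)
      sim_rts <- sim$rt[!is.na(sim$rt)]
      cost <- (p_obs - length(sim_rts) / n_sim)^2
      if (!is.null(q_obs) && length(sim_rts) >= 5L) {
        cost <- cost + p_obs * sum((q_obs - rt_quantiles(sim_rts))^2)
      }
      cost
    }
  }
}

build_race_fit <- function(trials, model, modulation, design, flat,
                           config, cond_params = NULL, cond_cost = NULL,
                           n_eval = NA_integer_) {
  obs <- flat$obs
  w <- flat$weights
  costf <- cost_for_task(design$task)
  if (is.null(cond_params)) {
    # shared parameters across all conditions
    conds <- if (design$task == "reactive") obs$stats$condition
             else proactive_cue_labels(design$cues)
    fv <- unclass(flat$params)
    ptbl <- tibble::as_tibble(fv[c("a", "tr", "v_e", "v_b", "xb", "sigma",
                                   "sso")])
    ptbl <- ptbl[rep(1, length(conds)), ]
    ptbl$condition <- conds
    if (design$task == "proactive") ptbl$cue <- design$cues
    k <- length(flat$free)
    free <- character()
  } else {
    ptbl <- cond_params
    free <- modulation_free_params(modulation)
    k <- length(free) * nrow(ptbl)
  }
  pred <- predict_summary(model, design, ptbl, config)
  cost <- costf(obs, pred, w)
  n <- count_data_points(obs)
  ic <- information_criteria(cost, k, n)
  structure(list(model = model, modulation = modulation,
                 task = design$task, design = design,
                 params = ptbl, free = free, flat_params = flat$params,
                 cost = cost, k = k, n = n, aic = ic$aic, bic = ic$bic,
                 weights = w, obs = obs, pred = pred,
                 trace = flat$trace, config = config,
                 n_eval = n_eval, converged = flat$converged),
            class = "race_fit")
}

# ---- full protocol -----------------------------------------------------

#' Fit a race-diffusion model to a trial table
#'
#' Runs the complete hierarchical protocol: (1) flat fit of all parameters
#' to the condition-averaged data by basin hopping plus simplex; (2)
#' conditional fit in which only the modulated parameter(s) vary across
#' conditions, re-seeded per condition and jointly polished by a final
#' simplex. The whole protocol is restarted `config$n_restarts` times and
#' the run with the lowest AIC is returned (ties broken by lower cost,
#' then earlier run).
#'
#' @inheritParams fit_conditional
#' @param modulation Which parameter(s) vary across conditions;
#'   `"none"` fits one shared parameter set.
#' @param config A [fit_config()]; `config$seed` makes the whole fit
#'   reproducible.
#' @param keep_restarts Keep all restart results in `$restarts`.
#' @return A `race_fit` object.
#' @export
fit_race_model <- function(trials, model = c("dpm", "independent",
                                             "interactive"),
                           modulation = c("none", "drift", "onset",
                                          "drift_onset", "bound"),
                           design, config = fit_config(),
                           keep_restarts = FALSE) {
  model <- match.arg(model)
  modulation <- match.arg(modulation)
  runs <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    runs[[r]] <- withr::with_seed(config$seed + 1000L * r, {
      flat <- fit_flat(trials, model, design, config)
      fit <- fit_conditional(trials, model, modulation, design, flat,
                             config)
      fit$restart <- r
      fit
    })
  }
  best <- best_of_n(runs)
  if (keep_restarts) best$restarts <- runs
  best
}

#' Select the best of several fits by AIC
#'
#' @param results List of `race_fit` objects (>= 1).
#' @return The fit with the lowest AIC; ties are broken by lower cost,
#'   then by earlier position in the list.
#' @export
best_of_n <- function(results) {
  if (!length(results)) rlang::abort("no fit results supplied")
  aics <- vapply(results, function(f) f$aic, numeric(1))
  costs <- vapply(results, function(f) f$cost, numeric(1))
  ord <- order(aics, costs, seq_along(results))
  results[[ord[1L]]]
}

#' Model-comparison table
#'
#' @param ... `race_fit` objects (or a single list of them).
#' @return A tibble with columns `model`, `modulation`, `chi2`, `k`, `n`,
#'   `aic`, `bic`, sorted by AIC.
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "race_fit")) {
    fits <- fits[[1L]]
  }
  tbl <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(model = f$model, modulation = f$modulation,
                   chi2 = f$cost, k = f$k, n = f$n, aic = f$aic,
                   bic = f$bic)
  }))
  dplyr::arrange(tbl, .data$aic)
}

# ---- methods -----------------------------------------------------------

#' @export
print.race_fit <- function(x, ...) {
  cat("<race_fit>", x$model,
      if (x$modulation != "none") paste0("(", x$modulation,
                                         " modulation)"), "\n")
  cat(sprintf("  chi2 = %.5g  k = %d  n = %d  AIC = %.2f  BIC = %.2f\n",
              x$cost, x$k, x$n, x$aic, x$bic))
  print(x$params)
  invisible(x)
}

#' Tidy a fitted race model
#'
#' @param x A `race_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `condition`, `parameter`,
#'   `estimate`, `free`.
#' @export
tidy.race_fit <- function(x, ...) {
  pars <- intersect(c("a", "tr", "v_e", "v_b", "xb", "sigma", "sso"),
                    names(x$params))
  out <- tidyr::pivot_longer(x$params[, c("condition", pars)],
                             cols = dplyr::all_of(pars),
                             names_to = "parameter",
                             values_to = "estimate")
  out$free <- out$parameter %in% x$free |
    (x$modulation == "none" & out$parameter %in%
       free_param_names(x$model, x$task))
  out[!is.na(out$estimate), ]
}

#' One-row fit summary
#'
#' @param x A `race_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `modulation`, `chi2`, `k`, `n`,
#'   `aic`, `bic`, `converged`.
#' @export
glance.race_fit <- function(x, ...) {
  tibble::tibble(model = x$model, modulation = x$modulation,
                 chi2 = x$cost, k = x$k, n = x$n, aic = x$aic,
                 bic = x$bic, converged = x$converged)
}
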