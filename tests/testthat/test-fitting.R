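test_that("best_of_n selects by AIC with documented tie-breaks", {
  mk <- function(aic, cost, id) {
    structure(list(aic = aic, cost = cost, id = id), class = "race_fit")
  }
  single <- mk(-5, 1, "a")
  expect_identical(best_of_n(list(single))$id, "a")

  three <- list(mk(-10, 1, "a"), mk(-12, 1, "b"), mk(-11, 1, "c"))
  expect_identical(best_of_n(three)$id, "b")

  # AIC tie: lower cost wins; full tie: earlier run wins
  tie <- list(mk(-10, 2, "a"), mk(-10, 1, "b"), mk(-10, 1, "c"))
  expect_identical(best_of_n(tie)$id, "b")
  expect_error(best_of_n(list()))
})

test_that("the full fitting protocol is deterministic under a seed", {
  d <- reactive_design_small()
  tab <- simulate_task("dpm", d, dpm_truth(), sim_config(seed = 71))
  f1 <- fit_race_model(tab, "dpm", "none", d, tiny_fit_config(seed = 7))
  f2 <- fit_race_model(tab, "dpm", "none", d, tiny_fit_config(seed = 7))
  expect_equal(f1$params, f2$params, tolerance = 1e-12)
  expect_equal(f1$cost, f2$cost, tolerance = 1e-12)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-12)
})

test_that("flat fit lands at or below the cost of the generating truth", {
  d <- task_design("reactive", n_go = 2000, n_stop_per_ssd = 400)
  tab <- simulate_task("dpm", d, dpm_truth(), sim_config(seed = 72))
  cfg <- fit_config(n_sim_per_eval = 4000L, n_sim_search = 1500L,
                    n_screen = 20L, n_multistart = 3L,
                    multistart_maxit = 60L, basin_max_iter = 8L,
                    basin_fail_limit = 4L, basin_local_maxit = 25L,
                    simplex_maxit = 80L, nm_restarts = 1L,
                    dt = 0.0025, seed = 8, profile_grid = FALSE)
  flat <- withr::with_seed(8, fit_flat(tab, "dpm", d, cfg))
  expect_true(flat$converged)

  # evaluate the cost at the generating parameters with the same
  # common random numbers: the optimizer should not be meaningfully
  # worse than the truth evaluation plus its Monte-Carlo jitter
  obs <- summarize_trials(tab, d)
  avg <- raceddm:::average_summary(obs)
  cache <- raceddm:::noise_cache()
  cfg_sim <- sim_config(dt = cfg$dt, deadline = d$deadline,
                        seed = cfg$seed)
  pred <- raceddm:::predict_flat_cached("dpm", d, dpm_truth(),
                                        cfg$n_sim_per_eval, cfg_sim,
                                        cache)
  truth_cost <- cost_reactive(avg, pred, flat$weights)
  expect_lt(flat$cost, truth_cost * 2 + 1e-3)
})

test_that("degenerate near-empty data yield a flagged fit, not a crash", {
  d <- task_design("reactive", n_go = 2, n_stop_per_ssd = 0)
  tab <- simulate_task("dpm", d, dpm_truth(), sim_config(seed = 73))
  expect_lt(nrow(tab), 3)
  fit <- fit_race_model(tab, "dpm", "none", d, tiny_fit_config(seed = 9))
  expect_s3_class(fit, "race_fit")
  expect_true(is.finite(fit$cost))
})

test_that("conditional fit with no free parameters returns the flat fit", {
  d <- reactive_design_small()
  tab <- simulate_task("dpm", d, dpm_truth(), sim_config(seed = 74))
  cfg <- tiny_fit_config(seed = 11)
  flat <- withr::with_seed(11, fit_flat(tab, "dpm", d, cfg))
  fit <- fit_conditional(tab, "dpm", "none", d, flat, cfg)
  expect_equal(nrow(fit$params), 1)
  expect_equal(fit$params$a[1], flat$params$a)
  expect_equal(fit$k, 5)
  expect_equal(fit$n, 16)
})

test_that("fit objects expose tidy/glance/compare interfaces", {
  d <- reactive_design_small()
  tab <- simulate_task("dpm", d, dpm_truth(), sim_config(seed = 75))
  fit <- fit_race_model(tab, "dpm", "none", d, tiny_fit_config(seed = 2))
  td <- tidy(fit)
  expect_true(all(c("condition", "parameter", "estimate", "free") %in%
                    names(td)))
  expect_true(all(c("a", "tr", "v_e", "v_b", "xb") %in% td$parameter))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$chi2, fit$cost)
  cmp <- compare_fits(fit, fit)
  expect_equal(nrow(cmp), 2)
  expect_true(all(diff(cmp$aic) >= 0))
  ic <- information_criteria(fit$cost, fit$k, fit$n)
  expect_equal(fit$aic, ic$aic)
})

test_that("weight sets stay positive and respect the validation rules", {
  expect_error(weight_set(w_g = 0))
  d <- reactive_design_small()
  tab <- simulate_task("dpm", d, dpm_truth(), sim_config(seed = 76))
  w <- weights_from_summary(tab, task_design("reactive"))
  expect_true(all(unlist(w) > 0))

  sp <- cohort_spec(4, d, "dpm", dpm_truth(),
                    between_subject_sd = c(v_e = 0.15), seed = 77)
  wc <- weights_from_cohort(generate_cohort(sp), task_design("reactive"))
  expect_length(wc$w_d, 5)
  expect_true(all(unlist(wc) > 0))
})
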