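test_that("zero dispersion gives every subject the truth parameters", {
  d <- reactive_design_small()
  sp <- cohort_spec(4, d, "dpm", dpm_truth(),
                    between_subject_sd = c(v_e = 0), seed = 61)
  coh <- generate_cohort(sp)
  expect_equal(length(unique(coh$subject_params$v_e)), 1L)
  expect_equal(unique(coh$subject_params$v_e), 1.266)
  expect_equal(dplyr::n_distinct(coh$trials$subject), 4L)
})

test_that("cohorts are byte-identical under the same seed", {
  d <- reactive_design_small()
  sp <- cohort_spec(3, d, "dpm", dpm_truth(),
                    between_subject_sd = c(v_e = 0.1, tr = 0.02),
                    seed = 62)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$subject_params, c2$subject_params)
  # dispersion actually disperses
  expect_gt(stats::sd(c1$subject_params$v_e), 0)
})

test_that("generated tables satisfy the trial-table invariants", {
  d <- proactive_design_small()
  sp <- cohort_spec(3, d, "dpm", preset_params("drift", "proactive"),
                    between_subject_sd = c(v_e = 0.1), seed = 63)
  coh <- generate_cohort(sp)
  t <- coh$trials
  expect_true(all((t$response == 1L) == !is.na(t$rt)))
  expect_true(all(is.na(t$ssd)))
  expect_true(all(t$cue %in% d$cues))
  expect_true(all(t$rt[!is.na(t$rt)] <= d$deadline + 1e-9))
  # draws are truncated to the parameter boxes
  expect_true(all(coh$subject_params$v_e > 0))
})

test_that("subject-wise PSEs correlate across tasks when drift is shared", {
  # subjects share a single execution drift across the reactive and
  # proactive tasks; faster subjects respond more and stop later in
  # both, so their stop-curve and no-go-curve PSEs co-vary
  set.seed(64)
  n_sub <- 15
  v_es <- rnorm(n_sub, 1.266, 0.12)
  rd <- task_design("reactive", n_go = 50, n_stop_per_ssd = 40)
  pd <- task_design("proactive", n_per_cue = 60)
  pro_truth <- preset_params("drift", task = "proactive")
  pse_stop <- pse_nogo <- numeric(n_sub)
  for (s in seq_len(n_sub)) {
    pr <- dpm_truth()
    pr$v_e <- v_es[s]
    rt_tab <- simulate_task("dpm", rd, pr, sim_config(seed = 640 + s))
    st <- summarize_trials(rt_tab, rd)$stats
    pse_stop[s] <- logistic_pse(rd$ssds, unname(st$p_stop[[1]]),
                                n = rep(rd$n_stop_per_ssd, 5))$pse
    pp <- pro_truth
    pp$v_e <- pp$v_e + (v_es[s] - 1.266)
    pp_tab <- simulate_task("dpm", pd, pp,
                            sim_config(deadline = pd$deadline,
                                       seed = 6400 + s))
    ps <- summarize_trials(pp_tab, pd)$stats
    pse_nogo[s] <- logistic_pse(pd$cues, 1 - unname(ps$p_resp[[1]]),
                                n = rep(pd$n_per_cue, 6))$pse
  }
  expect_gt(stats::cor(pse_stop, pse_nogo), 0)
})

test_that("recovery harness reports truth vs estimate per parameter", {
  d <- reactive_design_small()
  sp <- cohort_spec(2, d, "dpm", dpm_truth(),
                    between_subject_sd = c(v_e = 0), seed = 65)
  rep <- recovery_harness(sp, "dpm", "none", tiny_fit_config(seed = 5))
  expect_true(rep$ok)
  expect_setequal(unique(rep$report$parameter),
                  c("a", "tr", "v_e", "v_b", "xb"))
  expect_true(all(is.finite(rep$report$rel_error)))
  expect_equal(rep$report$truth[rep$report$parameter == "a"], 0.534)
})
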