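test_that("trial AUC matches closed-form areas on noise-free paths", {
  expect_equal(trial_auc(tibble::tibble(theta_e = numeric()), 0.001), 0)

  # responded trial: triangle area a^2 / (2 v_e) = 0.125
  p <- noise_free(a = 0.5, tr = 0, v_e = 1.0)
  traj <- integrate_execution(p, sim_config(deadline = 1, seed = 1))
  expect_equal(trial_auc(traj, 0.001), 0.125, tolerance = 0.01)

  # sub-threshold trial: 0.5 * v_e * T^2 over a 0.4 s window
  p2 <- noise_free(a = 5, tr = 0, v_e = 0.5)
  traj2 <- integrate_execution(p2, sim_config(deadline = 0.4, seed = 1))
  expect_equal(trial_auc(traj2, 0.001), 0.04, tolerance = 0.01)
})

test_that("AUC is stable under step refinement", {
  p <- noise_free(a = 0.5, tr = 0.1, v_e = 1.2, xb = 1.0)
  a1 <- trial_auc(integrate_execution(p, sim_config(dt = 0.002,
                                                    deadline = 1,
                                                    seed = 1)), 0.002)
  a2 <- trial_auc(integrate_execution(p, sim_config(dt = 0.0005,
                                                    deadline = 1,
                                                    seed = 1)), 0.0005)
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("simulated go-trial AUC matches the trajectory integral", {
  p <- process_params(a = 0.5, tr = 0.1, v_e = 1.2, xb = 0.8,
                      sigma = 0.1)
  cfg <- sim_config(deadline = 0.65, seed = 13)
  s <- simulate_go_trials(p, 1, cfg, stream = 0)
  traj <- integrate_execution(p, cfg, stream = 0)
  expect_equal(s$auc, trial_auc(traj, cfg$dt), tolerance = 0.01)
})

test_that("predict_bold returns per-cue and pooled bins with counts", {
  pred <- predict_bold(preset_params("drift", task = "proactive"),
                       task_design("proactive"), n = 300, seed = 3)
  expect_true(all(c("go_low", "nogo_high") %in% pred$bin))
  percue <- pred[pred$bin == "cue", ]
  expect_true(all(percue$n_trials > 0))
  expect_true(all(percue$mean_auc > 0))
  # pooled bins respect the cue windows
  expect_equal(sum(percue$n_trials), 6 * 300)

  # a parameter set that always responds has no no-go rows
  fastp <- tibble::tibble(condition = "p100", cue = 1, a = 0.2,
                          tr = 0.05, v_e = 4, xb = 0, v_b = NA_real_,
                          sigma = 0.01)
  pred2 <- predict_bold(fastp, task_design("proactive", cues = 1),
                        n = 200, seed = 4)
  expect_false(any(pred2$outcome == "no-go"))
})
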