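test_that("noise-free go trial responds at tr + a/v_e", {
  p <- noise_free(a = 0.534, tr = 0.174, v_e = 1.266)
  s <- simulate_go_trials(p, 5, sim_config(deadline = 0.65, seed = 1))
  expect_true(all(s$response == 1L))
  expect_equal(s$rt, rep(0.174 + 0.534 / 1.266, 5), tolerance = 3e-3)
})

test_that("go response probability limits behave", {
  fast <- process_params(a = 0.2, tr = 0.05, v_e = 4, sigma = 0.01)
  s <- simulate_go_trials(fast, 500, sim_config(deadline = 0.65,
                                                seed = 2))
  expect_equal(mean(s$response), 1)

  still <- noise_free(a = 0.5, tr = 0.05, v_e = 0)
  s2 <- simulate_go_trials(still, 100, sim_config(deadline = 0.65,
                                                  seed = 3))
  expect_equal(mean(s2$response), 0)
})

test_that("DPM braking inherits the execution state and can stop", {
  # noise-free: braking starts at theta_e(SSD) and with a huge braking
  # drift reaches 0 (almost) instantly, while the execution process
  # still needs ~0.3 s to reach the boundary
  p <- noise_free(a = 0.534, tr = 0.174, v_e = 1.266, v_b = 50)
  s <- simulate_stop_trials(p, ssd = 0.30, n = 5,
                            sim_config(deadline = 0.65, seed = 4),
                            model = "dpm")
  expect_true(all(s$response == 0L))

  # a response made before the SSD stands
  s2 <- simulate_stop_trials(p, ssd = 0.63, n = 5,
                             sim_config(deadline = 0.65, seed = 4),
                             model = "dpm")
  expect_true(all(s2$response == 1L))
  expect_true(all(s2$rt < 0.63))
})

test_that("stop trials with SSD at or past the deadline equal go trials", {
  p <- dpm_truth()
  cfg <- sim_config(deadline = 0.65, seed = 5)
  go <- simulate_go_trials(p, 2000, cfg)
  st <- simulate_stop_trials(p, ssd = 0.65, n = 2000, cfg, model = "dpm")
  # identical noise substreams make this an exact identity
  expect_identical(go$rt, st$rt)

  pint <- preset_params("interactive")
  pint$sso <- 10
  it <- simulate_stop_trials(pint, ssd = 0.3, n = 1000, cfg,
                             model = "interactive")
  go2 <- simulate_go_trials(pint, 1000, cfg)
  expect_identical(go2$rt, it$rt)
})

test_that("independent race: zero braking drift never stops (noise-free)", {
  p <- noise_free(a = 0.3, tr = 0.1, v_e = 1.0, v_b = 0)
  s <- simulate_stop_trials(p, ssd = 0.15, n = 5,
                            sim_config(deadline = 0.65, seed = 6),
                            model = "independent")
  expect_true(all(s$response == 1L))
})

test_that("independent race outcome follows the closed-form crossing race", {
  # noise-free: stop wins iff ssd + a/v_b < tr + a/v_e
  cfg <- sim_config(deadline = 0.65, seed = 7)
  win <- noise_free(a = 0.3, tr = 0.1, v_e = 1.0, v_b = 3)   # 0.25 < 0.4
  s1 <- simulate_stop_trials(win, ssd = 0.15, n = 3, cfg,
                             model = "independent")
  expect_true(all(s1$response == 0L))

  lose <- noise_free(a = 0.3, tr = 0.1, v_e = 1.0, v_b = 0.7) # 0.58 > 0.4
  s2 <- simulate_stop_trials(lose, ssd = 0.15, n = 3, cfg,
                             model = "independent")
  expect_true(all(s2$response == 1L))
})

test_that("interactive race suppression and pre-emption behave", {
  # braking far stronger than execution: response prevented whenever the
  # execution process is still below the boundary at ss_tr
  p <- noise_free(a = 0.445, tr = 0.22, v_e = 1.195, v_b = 50,
                  sso = 0.05)
  s <- simulate_stop_trials(p, ssd = 0.2, n = 5,
                            sim_config(deadline = 0.65, seed = 8),
                            model = "interactive")
  expect_true(all(s$response == 0L))

  # execution reaching the boundary before ss_tr responds regardless
  p2 <- noise_free(a = 0.2, tr = 0.05, v_e = 2, v_b = 50, sso = 0.25)
  s2 <- simulate_stop_trials(p2, ssd = 0.3, n = 5,
                             sim_config(deadline = 0.65, seed = 8),
                             model = "interactive")
  expect_true(all(s2$response == 1L))
  expect_true(all(s2$rt < 0.3 + 0.25))
  expect_error(simulate_stop_trials(noise_free(0.4, 0.2, 1, v_b = 1),
                                    0.3, 5, model = "interactive"))
})

test_that("P(stop) is non-increasing in SSD for all three models", {
  cfg <- sim_config(deadline = 0.65, seed = 9)
  ssds <- seq(0.2, 0.4, by = 0.05)
  for (model in c("dpm", "independent", "interactive")) {
    p <- preset_params(model)
    pstop <- vapply(ssds, function(d) {
      mean(simulate_stop_trials(p, d, 4000, cfg,
                                model = model)$response == 0L)
    }, numeric(1))
    expect_true(all(diff(pstop) <= 0.02),
                info = paste(model, paste(round(pstop, 3),
                                          collapse = " ")))
  }
})

test_that("simulate_task is reproducible and honors trial counts", {
  d <- reactive_design_small()
  p <- dpm_truth()
  t1 <- simulate_task("dpm", d, p, sim_config(seed = 10))
  t2 <- simulate_task("dpm", d, p, sim_config(seed = 10))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 40 + 5 * 8)
  expect_true(all(t1$trial_type[!is.na(t1$ssd)] == "stop"))

  t0 <- simulate_task("dpm", d, p, sim_config(seed = 10), n_go = 0,
                      n_stop_per_ssd = 0)
  expect_equal(nrow(t0), 0)
})

test_that("drift modulation makes response probability and speed monotone", {
  d <- task_design("proactive", n_per_cue = 2000)
  ptbl <- preset_params("drift", task = "proactive")
  tab <- simulate_task("dpm", d, ptbl, sim_config(seed = 11))
  byc <- dplyr::summarise(dplyr::group_by(tab, cue),
                          p = mean(response),
                          mrt = mean(rt, na.rm = TRUE))
  byc <- dplyr::arrange(byc, cue)
  expect_true(all(diff(byc$p) > 0))
  expect_true(all(diff(byc$mrt) < 0))
})
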