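test_that("dynamic gain is 1 at onset, 1 under zero gain, and hyperbolic", {
  expect_equal(dynamic_gain(0, 0.878), 1)
  expect_equal(dynamic_gain(0.4, 0), 1)
  expect_equal(dynamic_gain(0.5, 0.878), cosh(0.439))
  expect_error(dynamic_gain(-0.1, 1))
  expect_error(dynamic_gain(0.1, -1))
})

test_that("gain is non-decreasing in time for positive gain", {
  for (xb in c(0, 0.5, 0.878, 2, 5)) {
    g <- dynamic_gain(seq(0, 0.6, by = 0.01), xb)
    expect_true(all(diff(g) >= 0))
    expect_true(all(g >= 1))
  }
})

test_that("noise-free execution path crosses at tr + a/v_e", {
  p <- noise_free(a = 0.5, tr = 0.1, v_e = 1.0)
  traj <- integrate_execution(p, sim_config(deadline = 1, seed = 1))
  expect_equal(max(traj$time), 0.6, tolerance = 2e-3)
  expect_equal(first_passage(traj, 0.5), 0.6, tolerance = 2e-3)
})

test_that("zero drift, zero noise never crosses and stays flat", {
  p <- noise_free(a = 0.5, tr = 0.0, v_e = 0)
  traj <- integrate_execution(p, sim_config(deadline = 0.5, seed = 1))
  expect_equal(nrow(traj), 500)
  expect_true(all(abs(traj$theta_e) < 1e-6))
  expect_true(is.na(first_passage(traj, 0.5)))
})

test_that("first_passage finds the earliest weak crossing", {
  flat <- tibble::tibble(time = seq(0.001, 1, by = 0.001), theta_e = 0)
  expect_true(is.na(first_passage(flat, 0.5)))

  ramp <- tibble::tibble(time = seq(0.001, 1, by = 0.001),
                         theta_e = seq(0.001, 1, by = 0.001))
  expect_equal(first_passage(ramp, 0.5), 0.5)

  # path that crosses the lower boundary before the upper one:
  # brute-force scan oracle picks the earlier crossing
  set.seed(42)
  for (i in 1:10) {
    x <- cumsum(rnorm(400, mean = sample(c(-0.01, 0.01), 1), sd = 0.05))
    tr <- tibble::tibble(time = seq_along(x) / 1000, theta_e = x)
    up <- first_passage(tr, 0.5, "up")
    dn <- first_passage(tr, -0.5, "down")
    oracle_up <- which(x >= 0.5)
    oracle_dn <- which(x <= -0.5)
    expect_equal(up, if (length(oracle_up)) oracle_up[1] / 1000
                     else NA_real_)
    expect_equal(dn, if (length(oracle_dn)) oracle_dn[1] / 1000
                     else NA_real_)
  }
})

test_that("first-passage moments match inverse-Gaussian closed forms", {
  # with no gain and an effectively unbounded window, the first-passage
  # time is inverse-Gaussian: mean a/v, variance a sigma^2 / v^3
  p <- process_params(a = 0.5, tr = 0, v_e = 1.0, xb = 0, sigma = 0.1)
  n <- 20000
  s <- simulate_go_trials(p, n, sim_config(deadline = 2.5, seed = 7))
  expect_gt(mean(s$response), 0.9999)
  m <- mean(s$rt)
  v <- stats::var(s$rt)
  se_m <- sqrt(v / n)
  expect_lt(abs(m - 0.5), 3 * se_m)
  se_v <- v * sqrt(2 / (n - 1)) * 2  # generous SE for the variance
  expect_lt(abs(v - 0.005), 3 * se_v)
})

test_that("halving the step size leaves the mean RT within MC error", {
  p <- process_params(a = 0.5, tr = 0.1, v_e = 1.0, xb = 0.8,
                      sigma = 0.1)
  n <- 30000
  s1 <- simulate_go_trials(p, n, sim_config(dt = 0.001, deadline = 2,
                                            seed = 8))
  s2 <- simulate_go_trials(p, n, sim_config(dt = 0.0005, deadline = 2,
                                            seed = 9))
  m1 <- mean(s1$rt, na.rm = TRUE)
  m2 <- mean(s2$rt, na.rm = TRUE)
  se_diff <- sqrt(stats::var(s1$rt, na.rm = TRUE) / sum(s1$response) +
                    stats::var(s2$rt, na.rm = TRUE) / sum(s2$response))
  expect_lt(abs(m1 - m2), 3 * se_diff)
})

test_that("every trial is either a response in (tr, deadline] or none", {
  cfg <- sim_config(deadline = 0.65, seed = 3)
  set.seed(12)
  for (i in 1:5) {
    p <- process_params(a = runif(1, 0.2, 0.8), tr = runif(1, 0.05, 0.3),
                        v_e = runif(1, 0.5, 2), v_b = runif(1, 0.5, 2),
                        xb = runif(1, 0, 2))
    s <- simulate_stop_trials(p, ssd = 0.3, n = 500, cfg, model = "dpm")
    resp <- s$response == 1L
    expect_true(all(is.na(s$rt[!resp])))
    expect_true(all(s$rt[resp] > p$tr & s$rt[resp] <= 0.65 + 1e-9))
  }
})

test_that("invalid construction arguments are rejected", {
  expect_error(process_params(a = -1, tr = 0.1, v_e = 1))
  expect_error(process_params(a = 0.5, tr = -0.1, v_e = 1))
  expect_error(process_params(a = 0.5, tr = 0.1, v_e = 1, sigma = 0))
  expect_error(process_params(a = 0.5, tr = 0.1, v_e = 1, xb = -2))
  expect_error(sim_config(dt = 0))
  expect_error(sim_config(dt = 0.01))
})
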