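test_that("Maritz-Jarrett SE matches a bootstrap oracle at the median", {
  set.seed(31)
  x <- rnorm(200)
  boot <- replicate(4000, stats::median(sample(x, replace = TRUE)))
  expect_equal(maritz_jarrett_se(x, 0.5), stats::sd(boot),
               tolerance = 0.15)
})

test_that("Maritz-Jarrett SE degenerate and equivariance properties", {
  expect_equal(maritz_jarrett_se(rep(0.4, 50), 0.3), 0)
  set.seed(32)
  x <- rlnorm(80)
  for (q in c(0.1, 0.5, 0.9)) {
    expect_equal(maritz_jarrett_se(3.7 * x, q),
                 3.7 * maritz_jarrett_se(x, q), tolerance = 1e-10)
  }
  expect_error(maritz_jarrett_se(1:4, 0.5),
               class = "raceddm_insufficient")
})

test_that("quantile weights are median-SE ratios", {
  expect_equal(quantile_weights(se = c(2, 1, 1, 1, 2)),
               c(0.5, 1, 1, 1, 0.5))
  expect_equal(quantile_weights(se = rep(0.3, 5)), rep(1, 5))
  set.seed(33)
  x <- rlnorm(500, -1, 0.3)
  expect_equal(quantile_weights(x), quantile_weights(2.5 * x),
               tolerance = 1e-8)
  expect_error(quantile_weights(1:5), class = "raceddm_insufficient")
})

test_that("accuracy weights are mean-SD ratios and permute with columns", {
  m <- cbind(a = c(0, 1), b = c(0, 1), c = c(0, 4))
  expect_equal(unname(accuracy_weights(m)), c(2, 2, 0.5))
  expect_equal(unname(accuracy_weights(cbind(c(0, 1), c(0, 1)))),
               c(1, 1))
  perm <- accuracy_weights(m[, c(3, 1, 2)])
  expect_equal(unname(perm), c(0.5, 2, 2))
  expect_error(accuracy_weights(matrix(1, 1, 3)),
               class = "raceddm_insufficient")
})

test_that("reactive cost is zero at identity and matches hand arithmetic", {
  d <- task_design("reactive")
  tab <- simulate_task("dpm", reactive_design_small(), dpm_truth(),
                       sim_config(seed = 41))
  tab_b <- dplyr::mutate(tab, condition = "baseline")
  tab_c <- dplyr::mutate(tab, condition = "caution")
  obs <- summarize_trials(dplyr::bind_rows(tab_b, tab_c), d)
  expect_equal(cost_reactive(obs, obs), 0)

  # single discrepancy in P_g of 0.02 with unit weight: 0.0004 per
  # context
  pred <- obs
  pred$stats$p_go <- pred$stats$p_go - 0.02
  expect_equal(cost_reactive(obs, pred), 2 * 0.02^2, tolerance = 1e-12)

  w2 <- weight_set(w_g = 2, w_d = rep(2, 5), w_c = rep(2, 5),
                   w_e = rep(2, 5))
  expect_equal(cost_reactive(obs, pred, w2),
               2 * cost_reactive(obs, pred), tolerance = 1e-12)
})

test_that("proactive cost identities and multiplier structure hold", {
  d <- task_design("proactive")
  tab <- simulate_task("dpm", proactive_design_small(),
                       preset_params("drift", "proactive"),
                       sim_config(seed = 42))
  obs <- summarize_trials(tab, d)
  expect_equal(cost_proactive(obs, obs), 0)

  pred <- obs
  pr <- pred$stats$p_resp[[1]]
  pr[3] <- pr[3] - 0.1
  pred$stats$p_resp[[1]] <- pr
  expect_equal(cost_proactive(obs, pred), 0.01, tolerance = 1e-12)

  # with no observed responses the quantile terms vanish and only the
  # probability terms remain
  obs0 <- obs
  obs0$stats$p_high <- 0
  obs0$stats$p_low <- 0
  pred2 <- obs
  pred2$stats$q_hi[[1]] <- obs$stats$q_hi[[1]] + 0.05
  expect_equal(cost_proactive(obs0, pred2),
               0)
})

test_that("cost raises structural errors on misaligned summaries", {
  d <- task_design("reactive")
  tab <- simulate_task("dpm", reactive_design_small(), dpm_truth(),
                       sim_config(seed = 43))
  obs <- summarize_trials(tab, d)
  pred <- obs
  pred$stats$condition <- "other"
  expect_error(cost_reactive(obs, pred), class = "raceddm_structure")
})

test_that("information criteria follow the Gaussian-SSE convention", {
  ic0 <- information_criteria(0.5, 0, 16)
  expect_equal(ic0$aic, ic0$bic)
  expect_equal(ic0$aic, 16 * log(0.5 / 16))

  ic <- information_criteria(0.0028, 5, 16)
  expect_equal(ic$aic, 16 * log(0.0028 / 16) + 10, tolerance = 1e-9)
  expect_equal(ic$aic, -128.4, tolerance = 0.05)
  expect_equal(ic$bic, 16 * log(0.0028 / 16) + 5 * log(16),
               tolerance = 1e-9)

  # ordering between two fits is invariant to a common n
  a1 <- information_criteria(0.002, 5, 16)$aic
  a2 <- information_criteria(0.004, 2, 16)$aic
  b1 <- information_criteria(0.002, 5, 32)$aic
  b2 <- information_criteria(0.004, 2, 32)$aic
  expect_equal(sign(a1 - a2), sign(b1 - b2))

  expect_equal(information_criteria(0, 5, 16)$aic, -Inf)
})
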