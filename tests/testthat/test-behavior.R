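test_that("rt_quantiles matches an independent interpolation oracle", {
  expect_equal(unname(rt_quantiles(rep(0.5, 12))), rep(0.5, 5))

  # brute-force type-7 oracle: h = (n-1)p + 1, linear interpolation
  oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  x <- seq(0.1, 1.0, by = 0.1)
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(unname(rt_quantiles(x)), oracle(x, probs))

  set.seed(5)
  y <- rlnorm(37, -1, 0.4)
  expect_equal(unname(rt_quantiles(y)), oracle(y, probs))
  expect_true(all(diff(rt_quantiles(y)) >= 0))
  expect_error(rt_quantiles(numeric()), class = "raceddm_empty")
})

test_that("reactive summary equals a hand computation on a small table", {
  d <- task_design("reactive")
  tab <- tibble::tibble(
    subject = "s1", condition = "pooled", task = "reactive",
    trial_type = c(rep("go", 10), rep("stop", 10)),
    ssd = c(rep(NA, 10), rep(d$ssds, each = 2)),
    cue = NA_real_,
    response = c(rep(1L, 8), 0L, 0L,
                 rep(0L, 8), 1L, 1L),
    rt = c(seq(0.45, 0.59, by = 0.02), NA, NA,
           rep(NA, 8), 0.52, 0.58))
  s <- summarize_trials(tab, d)$stats
  expect_equal(s$p_go, 0.8)
  expect_equal(s$p_corr, 0.8)
  expect_equal(s$p_err, 0.2)
  # last SSD cell holds both stop-trial responses
  expect_equal(unname(s$p_stop[[1]]), c(1, 1, 1, 1, 0))
  expect_equal(unname(s$q_correct[[1]]),
               unname(stats::quantile(seq(0.45, 0.59, by = 0.02),
                                      c(.1, .3, .5, .7, .9))))
  expect_equal(unname(s$q_error[[1]]),
               unname(stats::quantile(c(0.52, 0.58),
                                      c(.1, .3, .5, .7, .9))))
})

test_that("summary handles absent cells and is row-order invariant", {
  d <- task_design("reactive")
  tab <- simulate_task("dpm", reactive_design_small(), dpm_truth(),
                       sim_config(seed = 21))
  s1 <- summarize_trials(tab, d)
  s2 <- summarize_trials(tab[sample(nrow(tab)), ], d)
  expect_equal(s1$stats, s2$stats)

  # no stop-trial responses -> error quantiles absent, p_err = 0
  tab2 <- tab
  tab2$response[tab2$trial_type == "stop"] <- 0L
  tab2$rt[tab2$trial_type == "stop"] <- NA_real_
  s3 <- summarize_trials(tab2, d)$stats
  expect_null(s3$q_error[[1]])
  expect_equal(s3$p_err, 0)

  tab3 <- tab
  tab3$response[tab3$trial_type == "go"] <- 1L
  tab3$rt[tab3$trial_type == "go" & is.na(tab3$rt)] <- 0.6
  expect_equal(summarize_trials(tab3, d)$stats$p_go, 1)
})

test_that("proactive pooling sends each response to exactly one side", {
  d <- proactive_design_small()
  tab <- simulate_task("dpm", d, preset_params("drift", "proactive"),
                       sim_config(seed = 22))
  s <- summarize_trials(tab, d)$stats
  n_hi <- sum(tab$response == 1 & tab$cue > 0.5)
  n_lo <- sum(tab$response == 1 & tab$cue < 0.5)
  expect_equal(n_hi + n_lo, sum(tab$response))
  expect_length(s$p_resp[[1]], 6)
  expect_true(all(!is.na(s$p_resp[[1]])))
})

test_that("logistic PSE is -lambda0/lambda and recovers a known curve", {
  # arithmetic identity on a constructed fit
  fit <- logistic_pse(c(0, 0.25, 0.5, 0.75, 1),
                      c(0.88, 0.73, 0.5, 0.27, 0.12),
                      n = rep(1000, 5))
  expect_equal(fit$pse, -fit$lambda0 / fit$lambda)
  expect_equal(fit$pse, 0.5, tolerance = 0.02)

  # generator-truth recovery: lambda = 10, lambda0 = -3 -> PSE = 0.3
  set.seed(9)
  x <- runif(2000)
  y <- rbinom(2000, 1, plogis(10 * x - 3))
  fit2 <- logistic_pse(x, y)
  expect_lt(abs(fit2$pse - 0.3), 0.02)

  expect_error(logistic_pse(c(0, 1), c(1, 1), n = c(5, 5)),
               class = "raceddm_degenerate")
  expect_error(logistic_pse(c(0.2, 0.2), c(0, 1)),
               class = "raceddm_degenerate")
})

test_that("perfect separation is flagged and still yields a PSE", {
  x <- seq(0.2, 0.4, by = 0.05)
  y <- c(1, 1, 1, 0, 0)
  expect_warning(fit <- logistic_pse(x, y, n = rep(20, 5)),
                 "separation")
  expect_true(fit$separation)
  expect_true(is.finite(fit$pse))
  expect_gt(fit$pse, 0.3)
  expect_lt(fit$pse, 0.4)
})

test_that("PSE recovery error is small across synthetic cohorts", {
  set.seed(77)
  errs <- replicate(100, {
    pse_true <- runif(1, 0.3, 0.7)
    slope <- runif(1, 8, 14)
    x <- seq(0, 1, length.out = 8)
    y <- rbinom(8, 60, plogis(slope * (x - pse_true))) / 60
    fit <- logistic_pse(x, y, n = rep(60, 8))
    abs(fit$pse - pse_true)
  })
  expect_lt(median(errs), 0.02)
})
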