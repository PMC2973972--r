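test_that("1.5 x IQR outlier rule flags only the extreme response time", {
  rts <- c(790, 795, 800, 805, 810, 2000)
  # linear-interpolation quantiles: Q25 = 796.25, Q75 = 808.75, IQR = 12.5
  # fences 777.5 / 827.5 -> only 2000 flagged
  expect_identical(flag_outliers(rts), c(rep(FALSE, 5), TRUE))
  expect_false(any(flag_outliers(rep(800, 10))))
  expect_identical(flag_outliers(numeric(0)), logical(0))
  expect_warning(out <- flag_outliers(c(800, 900)), "fewer than 4")
  expect_false(any(out))
})

test_that("outlier rule is idempotent on the retained set", {
  withr::with_seed(3, {
    for (i in 1:20) {
      rts <- c(rnorm(40, 800, 40), runif(3, 1200, 2200))
      f1 <- flag_outliers(rts)
      f2 <- flag_outliers(rts[!f1])
      expect_lte(sum(f2), sum(f1))
    }
  })
})

test_that("rt_summary computes per-level means, CIs and accuracies", {
  sq <- build_trial_sequence(small_cfg, seed = 4, max_modulator_cor = Inf)
  ses <- simulate_session(sq, rigid_subject, seed = 5)
  s <- rt_summary(ses)
  red <- s$levels[s$levels$level == "red", ]
  expect_equal(red$mean_rt, 800)        # all RTs exactly 800
  expect_equal(red$ci_lo, red$ci_hi)    # zero-width CI
  expect_equal(red$accuracy, 0.5)       # deterministic alternation
  expect_true(all(s$levels$ci_lo <= s$levels$mean_rt &
                    s$levels$mean_rt <= s$levels$ci_hi))
  expect_true(all(s$levels$accuracy >= 0 & s$levels$accuracy <= 1,
                  na.rm = TRUE))
})

test_that("integration-method SSRT reproduces the worked example", {
  # p(respond) = 2/4; 5th fastest of 10 Go RTs = 780; mean SSD = 537.5
  expect_equal(ssrt_integration(ssrt_example), 242.5)
  # degenerate response rates are rejected
  ex <- ssrt_example
  ex$n_respond <- 4
  expect_error(ssrt_integration(ex), "fails")
  ex$n_respond <- 0
  expect_error(ssrt_integration(ex), "succeeds")
  ex <- ssrt_example
  ex$go_rts <- ex$go_rts[1:5]
  expect_error(ssrt_integration(ex), "at least 10")
})

test_that("SSRT estimator recovers the generative SSRT", {
  # many Stop trials per session; median error over seeds small
  cfg <- task_config(levels = data.frame(label = c("green", "red"),
                                         n_go = c(24L, 1200L),
                                         n_stop = c(0L, 600L)),
                     rest_blocks = data.frame(position = numeric(0),
                                              duration = numeric(0)))
  sq <- build_trial_sequence(cfg, seed = 30, max_modulator_cor = Inf)
  errs <- vapply(1:25, function(s) {
    ses <- simulate_session(sq, subject_params(ssrt_mu = 260,
                                               ssrt_sigma = 20), seed = s)
    ssrt_integration(ses) - 260
  }, 0)
  expect_lt(abs(stats::median(errs)), 15)
})

test_that("ZRFT follows its defining formula and inhibition points are sane", {
  # (830 - 400 - 326) / 60
  z <- (830 - 400 - 326) / 60
  expect_equal(z, 1.7333, tolerance = 1e-4)
  sessions <- lapply(1:12, function(s) {
    sq <- build_trial_sequence(published_cfg, seed = s, max_modulator_cor = Inf)
    simulate_session(sq, subject_params(), seed = s + 600)
  })
  inh <- inhibition_function(sessions)
  expect_true(all(inh$points$p_stop_success >= 0 &
                    inh$points$p_stop_success <= 1))
  # within a session ZRFT decreases as SSD grows
  one <- inhibition_function(sessions[[1]])
  ord <- order(one$points$ssd)
  expect_true(all(diff(one$points$zrft[ord]) < 0))
})

test_that("pooled Weibull fit is monotone increasing and close to the points", {
  sessions <- lapply(1:24, function(s) {
    sq <- build_trial_sequence(published_cfg, seed = s, max_modulator_cor = Inf)
    subj <- sample_subject(default_population()$means,
                           default_population()$sds, seed = s + 50)
    simulate_session(sq, subj, seed = s + 700)
  })
  inh <- inhibition_function(sessions)
  expect_false(is.null(inh$weibull))
  zs <- seq(min(inh$points$zrft), max(inh$points$zrft), length.out = 50)
  w <- weibull_inhibition(inh$weibull, zs)
  expect_true(all(diff(w) >= -1e-9))
  expect_gte(inh$weibull["r2"], 0.9)
})

test_that("step inhibition function arises from a noiseless race", {
  sq <- build_trial_sequence(small_cfg, seed = 12, max_modulator_cor = Inf)
  ses <- simulate_session(sq, rigid_subject, seed = 13)
  st <- ses$trials[ses$trials$trial_type == "stop", ]
  # success iff ssd + 250 <= 800
  expect_true(all((st$ssd <= 550) == (st$outcome == "StopSuccess")))
})

test_that("linear contrast matches hand computations and edge cases", {
  # two subjects with contrast scores 10 and 30: F = 2 * 20^2 / 200 = 4
  # (weights -3,-1,1,3 so a lone fourth-level mean of m gives score 3 m)
  m <- rbind(c(0, 0, 0, 10 / 3), c(0, 0, 0, 10))
  res <- linear_contrast(m)
  expect_equal(res$F, 4)
  expect_equal(res$df, c(1, 1))
  flat <- matrix(5, nrow = 6, ncol = 4)
  expect_equal(linear_contrast(flat)$F, 0)
  shifted <- matrix(rep(c(1, 2, 3, 4), each = 3), nrow = 3)
  expect_warning(res2 <- linear_contrast(shifted), "zero variance")
  expect_identical(res2$F, Inf)
})

test_that("linear contrast rejects at about its nominal rate under the null", {
  rej <- withr::with_seed(99, {
    vapply(1:1000, function(i) {
      m <- matrix(rnorm(24 * 4), 24, 4)
      linear_contrast(m)$p < 0.05
    }, logical(1))
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("paired t matches the hand-computed example and guards degeneracy", {
  res <- paired_t(c(1, 2, 3, 4), c(2, 2, 4, 6))
  # differences 1, 0, 1, 2: mean 1, sd 0.8165, t = 1 / (0.8165 / 2)
  expect_equal(res$t, 2.449, tolerance = 1e-3)
  expect_equal(res$df, 3)
  ref <- stats::t.test(c(2, 2, 4, 6), c(1, 2, 3, 4), paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero-variance")
})
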