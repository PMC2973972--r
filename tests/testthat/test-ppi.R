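make_bold <- function(seed, regions, cfg = published_cfg, subj = subject_params(),
                      n_scans = 616) {
  sq <- build_trial_sequence(cfg, seed = seed, max_modulator_cor = Inf)
  ses <- simulate_session(sq, subj, seed = seed + 1)
  synthesize_bold(ses, regions, n_scans = n_scans, seed = seed + 2,
                  seed_region = if (any(vapply(regions, function(r)
                    r$coupling_seed != 0 || r$coupling_delta != 0,
                    logical(1)))) regions[[1]]$name else NULL)
}

test_that("eigenvariate of identical voxels is the standardized series", {
  withr::with_seed(1, s <- cumsum(rnorm(100)))
  X <- rbind(s, s, s, s)
  e <- extract_eigenvariate(X)
  expect_equal(stats::cor(e, s), 1, tolerance = 1e-10)
  expect_equal(stats::sd(e), 1)
  expect_error(extract_eigenvariate(matrix(0, 3, 10)), "all-zero")
})

test_that("eigenvariate sign convention is deterministic for balanced +/- voxels", {
  withr::with_seed(2, s <- rnorm(80))
  X <- rbind(s, -s, s, -s)
  e1 <- extract_eigenvariate(X)
  e2 <- extract_eigenvariate(X)
  expect_identical(e1, e2)
  # aligns with the first voxel when the mean series vanishes
  expect_gt(stats::cor(e1, s), 0)
})

test_that("eigenvariate denoises many noisy copies of a common series", {
  withr::with_seed(3, {
    s <- as.numeric(scale(cumsum(rnorm(200))))
    X <- t(vapply(1:50, function(i) s + rnorm(200, 0, 0.5), numeric(200)))
  })
  e <- extract_eigenvariate(X)
  expect_gte(abs(stats::cor(e, s)), 0.95)
})

test_that("deconvolution inverts the HRF convolution on noiseless data", {
  # band-limited neural signal: slow sinusoids well below the scan Nyquist
  grid <- stopsig:::micro_grid(1.6, 100)
  t <- (seq_len(grid$n_micro) - 1) * grid$dt
  x_true <- 1 + 0.6 * sin(2 * pi * t / 40) + 0.3 * cos(2 * pi * t / 23)
  y <- stopsig:::sample_at_scans(
    stopsig:::convolve_causal(x_true, canonical_hrf(grid$dt)), grid)
  x_hat <- deconvolve(y, tr = 1.6, lambda = 1e-2)
  keep <- t > 30 & t < max(t) - 10  # away from onset/offset transients
  expect_gte(stats::cor(x_hat[keep], x_true[keep]), 0.99)
  # reconvolving the estimate reproduces the data
  y_hat <- stopsig:::sample_at_scans(
    stopsig:::convolve_causal(as.numeric(x_hat), canonical_hrf(grid$dt)), grid)
  expect_gte(stats::cor(y_hat, y), 0.999)
})

test_that("deconvolution limiting behaviour: zero data and heavy smoothing", {
  y0 <- numeric(60)
  expect_true(all(abs(deconvolve(y0, lambda = 1)) < 1e-8))
  withr::with_seed(5, y <- rnorm(60))
  x <- deconvolve(y, lambda = 1e7)
  expect_lt(stats::sd(x[-(1:16)]) / (stats::sd(y) + 1e-12), 0.05)
})

test_that("GCV picks a workable lambda for clean data end to end", {
  grid <- stopsig:::micro_grid(1.6, 80)
  t <- (seq_len(grid$n_micro) - 1) * grid$dt
  x_true <- 1 + 0.5 * sin(2 * pi * t / 32)
  y <- stopsig:::sample_at_scans(
    stopsig:::convolve_causal(x_true, canonical_hrf(grid$dt)), grid)
  x <- deconvolve(y, tr = 1.6, lambda = "gcv")
  expect_lte(attr(x, "lambda"), 1e4)
  keep <- t > 30 & t < max(t) - 10
  expect_gte(stats::cor(x[keep], x_true[keep]), 0.9)
})

test_that("psych vector is balanced and interaction collapses for unit neural", {
  regions <- list(region_spec("seed", amp_stop_success = 1,
                              amp_stop_failure = 0.3))
  b <- make_bold(40, regions, n_scans = 616)
  ses <- b$session
  neural <- rep(1, 616 * 16)
  reg <- ppi_regressors(neural, ses)
  st <- table(ses$trials$outcome)
  # microtime psych sums to the outcome imbalance (0 when balanced)
  expect_equal(sum(reg[, "ppi"] - reg[, "psych"]), 0, tolerance = 1e-9)
  ses2 <- ses
  ses2$trials$outcome[ses2$trials$trial_type == "stop"] <- "Go"
  ses2$trials$trial_type <- "go"
  expect_error(ppi_regressors(neural, ses2), "no Stop trials")
})

test_that("PPI regressor correlations stay moderate on generated designs", {
  op <- deconv_operator(1.6, 616, 100)
  mx <- vapply(1:10, function(s) {
    b <- make_bold(50 + 7 * s,
                   list(region_spec("seed", amp_stop_success = 1,
                                    amp_stop_failure = 0.3, amp_go = 0.5,
                                    noise_sd = 1, ar1_rho = 0.3)))
    y <- b$signal[1, ] - mean(b$signal[1, ])
    reg <- ppi_regressors(deconvolve(y, operator = op), b$session)
    max(abs(stats::cor(reg)[upper.tri(diag(3))]))
  }, 0)
  expect_true(all(mx < 0.7))
})

test_that("PPI estimates are invariant to seed rescaling up to scale", {
  regions <- list(region_spec("seed", amp_stop_success = 1,
                              amp_stop_failure = 0.3, noise_sd = 0.5),
                  region_spec("sink", coupling_seed = 0.2,
                              coupling_delta = 0.8, noise_sd = 0.5))
  b <- make_bold(60, regions)
  op <- deconv_operator(1.6, 616, 100)
  r1 <- ppi_analysis(b, "seed", "sink", operator = op)$sink
  b2 <- b
  b2$signal["seed", ] <- 5 * b2$signal["seed", ]
  op5 <- deconv_operator(1.6, 616, 100)
  r2 <- ppi_analysis(b2, "seed", "sink", operator = op5)$sink
  expect_equal(r1$coef$t, r2$coef$t, tolerance = 1e-6)
  # a 5x larger seed series scales the interaction regressor by 5, so its
  # coefficient shrinks by 5
  expect_equal(r1$coef$estimate[3] / r2$coef$estimate[3], 5,
               tolerance = 1e-6)
})

test_that("collinear PPI regressors are rejected", {
  reg <- cbind(physio = rep(1, 50), psych = rep(1, 50), ppi = rep(1, 50))
  expect_error(fit_ppi(rnorm(50), reg), "collinear")
})
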