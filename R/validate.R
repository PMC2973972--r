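#' Simulation-based validation metrics
#'
#' Each function in this family recomputes one family of quality metrics
#' from scratch by running the simulator and the corresponding analysis,
#' and returns the measured quantities. They back the package's acceptance
#' checks and can be rerun with any seed.
#'
#' @name validate
#' @keywords internal
NULL

#' Design identities of the published configuration
#'
#' Regenerates a trial sequence under the default configuration and counts
#' what the task description prints: per-level trial counts, probability
#' labels, the scheduled duration and the staircase geometry.
#'
#' @param seed integer seed for the sequence draw.
#' @return Named list of measured quantities.
#' @export
validate_design <- function(seed = 1) {
  cfg <- task_config()
  sq <- build_trial_sequence(cfg, seed = seed)
  tr <- sq$trials
  counts <- table(factor(tr$level, levels = cfg$levels$label),
                  factor(tr$trial_type, levels = c("go", "stop")))
  list(n_trials = nrow(tr),
       n_stop_total = sum(tr$trial_type == "stop"),
       n_go_baseline = sum(tr$level == "green"),
       n_go_experimental = sum(tr$trial_type == "go" & tr$p_stop > 0),
       pct_yellow = implied_stop_probability(counts["yellow", "go"],
                                             counts["yellow", "stop"]),
       pct_amber = implied_stop_probability(counts["amber", "go"],
                                            counts["amber", "stop"]),
       pct_orange = implied_stop_probability(counts["orange", "go"],
                                             counts["orange", "stop"]),
       pct_red = implied_stop_probability(counts["red", "go"],
                                          counts["red", "stop"]),
       duration_s = scheduled_duration(cfg),
       ssd_init_ms = cfg$ssd_init,
       ssd_init_before_target_ms = cfg$target_rt - cfg$ssd_init)
}

#' Staircase convergence to balanced stopping
#'
#' Simulates sessions under the default task and subject parameters and
#' measures per-level stop-success fractions; the 1-up-1-down rule should
#' balance successes and failures.
#'
#' @param n_seeds number of simulated sessions.
#' @param seed master seed.
#' @return List with the per-level median success fractions and their range.
#' @export
validate_staircase <- function(n_seeds = 100, seed = 1) {
  cfg <- task_config()
  fracs <- vapply(seq_len(n_seeds), function(s) {
    sq <- build_trial_sequence(cfg, seed = derive_seed(seed, 21, s))
    ses <- simulate_session(sq, subject_params(),
                            seed = derive_seed(seed, 22, s))
    st <- ses$trials[ses$trials$trial_type == "stop", ]
    tapply(st$outcome == "StopSuccess",
           factor(st$level, levels = cfg$levels$label[cfg$levels$p_stop > 0]),
           mean)
  }, numeric(4))
  med <- apply(fracs, 1, stats::median)
  list(median_by_level = med, min_median = min(med), max_median = max(med),
       overall_mean = mean(fracs))
}

#' SSRT recovery by the integration method
#'
#' Long stationary sessions (600 Stop trials at one level) are simulated
#' at a known generative SSRT and re-estimated; the worked fixture value
#' is also recomputed.
#'
#' @param n_seeds number of simulated sessions.
#' @param n_stop Stop trials per session.
#' @param ssrt_mu generative mean SSRT (ms).
#' @param seed master seed.
#' @return List with the median signed error, the generative value, the
#'   median estimate and the worked-example SSRT.
#' @export
validate_ssrt <- function(n_seeds = 100, n_stop = 600, ssrt_mu = 260,
                          seed = 1) {
  cfg <- task_config(levels = data.frame(label = c("green", "red"),
                                         n_go = c(24L, 2L * n_stop),
                                         n_stop = c(0L, n_stop)),
                     rest_blocks = data.frame(position = numeric(0),
                                              duration = numeric(0)))
  sq <- build_trial_sequence(cfg, seed = derive_seed(seed, 31, 1),
                             max_modulator_cor = Inf)
  subj <- subject_params(ssrt_mu = ssrt_mu, ssrt_sigma = 20)
  est <- vapply(seq_len(n_seeds), function(s)
    ssrt_integration(simulate_session(sq, subj,
                                      seed = derive_seed(seed, 32, s))),
    0)
  worked <- ssrt_integration(list(go_rts = seq(700, 880, by = 20),
                                  n_stop = 4, n_respond = 2,
                                  ssds = c(500, 525, 550, 575)))
  list(median_error_ms = stats::median(est) - ssrt_mu,
       median_estimate_ms = stats::median(est), true_ssrt_ms = ssrt_mu,
       worked_example_ms = worked)
}

#' Race-model signatures in simulated cohorts
#'
#' Measures the selection effect (StopFailure responses faster than
#' experimental Go responses), the monotonicity of the pooled inhibition
#' function in SSD, and the fit quality of the cumulative Weibull on a
#' pooled cohort.
#'
#' @param n_sessions sessions for the StopFailure-vs-Go check.
#' @param cohort_n subjects in the pooled inhibition cohort.
#' @param seed master seed.
#' @return List with the fraction of sessions showing the selection
#'   effect, the maximum increase of success probability across SSD bins,
#'   and the Weibull R-squared.
#' @export
validate_race <- function(n_sessions = 100, cohort_n = 24, seed = 1) {
  cfg <- task_config()
  pop <- default_population()
  seqs <- lapply(seq_len(min(cohort_n, n_sessions)), function(s)
    build_trial_sequence(cfg, seed = derive_seed(seed, 41, s)))
  sessions <- lapply(seq_len(n_sessions), function(s) {
    subj <- sample_subject(pop$means, pop$sds,
                           seed = derive_seed(seed, 42, s))
    simulate_session(seqs[[(s - 1) %% length(seqs) + 1]], subj,
                     seed = derive_seed(seed, 43, s))
  })
  sel <- vapply(sessions, function(ses) {
    tr <- ses$trials
    sf <- tr$outcome == "StopFailure"
    go <- tr$trial_type == "go" & tr$p_stop > 0
    mean(tr$rt[sf], na.rm = TRUE) < mean(tr$rt[go], na.rm = TRUE)
  }, logical(1))
  all_st <- do.call(rbind, lapply(sessions, function(x)
    x$trials[x$trials$trial_type == "stop", c("ssd", "outcome")]))
  br <- unique(stats::quantile(all_st$ssd, 0:6 / 6))
  bins <- cut(all_st$ssd, breaks = br, include.lowest = TRUE)
  p_bin <- tapply(all_st$outcome == "StopSuccess", bins, mean)
  inh <- inhibition_function(sessions[seq_len(cohort_n)])
  list(frac_stopfail_faster = mean(sel),
       max_inhibition_increase = max(diff(p_bin)),
       weibull_r2 = unname(inh$weibull["r2"]))
}

#' GLM parameter recovery and null calibration
#'
#' Simulates noisy BOLD data with planted StopSuccess/StopFailure
#' amplitudes and a stop-signal probability slope, and measures 95 percent
#' confidence-interval coverage for the contrast and the slope; also
#' measures the type-I error of the linear contrast and the
#' repeated-measures ANOVA on pure-noise cohorts.
#'
#' @param n_sims noisy GLM simulations.
#' @param n_null null replicates for the calibration rates.
#' @param seed master seed.
#' @return List with the two coverages and the two type-I rates.
#' @export
validate_glm <- function(n_sims = 500, n_null = 500, seed = 1) {
  region <- list(region_spec("r", amp_stop_success = 1,
                             amp_stop_failure = 0.3, amp_go = 0.5,
                             slope_pstop = 2, noise_sd = 1, ar1_rho = 0.3))
  true_contrast <- 0.7
  true_slope <- 2
  n_designs <- 5
  base <- lapply(seq_len(n_designs), function(s) {
    sq <- build_trial_sequence(task_config(),
                               seed = derive_seed(seed, 51, s))
    ses <- simulate_session(sq, subject_params(),
                            seed = derive_seed(seed, 52, s))
    list(ses = ses, des = build_design_matrix(ses))
  })
  cover <- vapply(seq_len(n_sims), function(s) {
    b <- base[[(s - 1) %% n_designs + 1]]
    bd <- synthesize_bold(b$ses, region, seed = derive_seed(seed, 53, s))
    fit <- fit_glm(bd$signal, b$des)
    ct <- glm_contrast(fit, c(stop_success = 1, stop_failure = -1))
    sl <- glm_contrast(fit, c(go_pstop_mod = 1))
    tq <- stats::qt(0.975, fit$dof)
    c(abs(ct$estimate - true_contrast) <= tq * ct$se,
      abs(sl$estimate - true_slope) <= tq * sl$se)
  }, logical(2))
  nulls <- withr::with_seed(derive_seed(seed, 54, 1), {
    vapply(seq_len(n_null), function(i) {
      m <- matrix(stats::rnorm(24 * 4), 24, 4)
      v <- array(stats::rnorm(24 * 4 * 2), c(24, 4, 2))
      an <- rm_anova_2way(v)
      c(linear_contrast(m)$p < 0.05,
        an$p[an$effect == "A"] < 0.05)
    }, logical(2))
  })
  list(coverage_contrast = mean(cover[1, ]),
       coverage_slope = mean(cover[2, ]),
       type1_linear_contrast = mean(nulls[1, ]),
       type1_rm_anova = mean(nulls[2, ]))
}

#' PPI sign recovery and null calibration
#'
#' Simulates 24-subject cohorts with a planted negative (M1-like) and
#' positive (SMC-like) coupling change, runs the full seed-to-sink PPI
#' chain, and measures how often the group-level sign is recovered; null
#' cohorts (no coupling change) measure the group-level false-positive
#' rate at alpha = 0.05.
#'
#' @param n_cohorts planted-effect cohorts.
#' @param n_null null cohorts.
#' @param cohort_n subjects per cohort.
#' @param seed master seed.
#' @return List with the two sign-recovery rates, the null rejection rate
#'   and the mean group-t statistics.
#' @export
validate_ppi <- function(n_cohorts = 100, n_null = 60, cohort_n = 24,
                         seed = 1) {
  cfg <- pipeline_config(n_subjects = cohort_n)
  null_regions <- cfg$regions
  null_regions$m1$coupling_delta <- 0
  null_regions$smc$coupling_delta <- 0
  op <- deconv_operator(cfg$tr, cfg$n_scans, cfg$lambda)
  seqs <- lapply(seq_len(cohort_n), function(s)
    build_trial_sequence(cfg$task, seed = derive_seed(seed, 61, s)))

  run_cohort <- function(regions, cseed) {
    est <- vapply(seq_len(cohort_n), function(s) {
      subj <- sample_subject(cfg$population$means, cfg$population$sds,
                             seed = derive_seed(cseed, 62, s))
      ses <- simulate_session(seqs[[s]], subj,
                              seed = derive_seed(cseed, 63, s))
      b <- synthesize_bold(ses, regions, tr = cfg$tr,
                           n_scans = cfg$n_scans,
                           seed = derive_seed(cseed, 64, s),
                           seed_region = cfg$seed_region)
      pr <- ppi_analysis(b, cfg$seed_region, c("m1", "smc"), operator = op)
      c(pr$m1$coef$estimate[3], pr$smc$coef$estimate[3])
    }, numeric(2))
    c(group_t(est[1, ])$t, group_t(est[2, ])$t)
  }

  planted <- vapply(seq_len(n_cohorts), function(cs)
    run_cohort(cfg$regions, derive_seed(seed, 65, cs)), numeric(2))
  nulls <- vapply(seq_len(n_null), function(cs)
    run_cohort(null_regions, derive_seed(seed, 66, cs)), numeric(2))
  tcrit <- stats::qt(0.975, cohort_n - 1)
  list(m1_negative_rate = mean(planted[1, ] < 0),
       smc_positive_rate = mean(planted[2, ] > 0),
       null_rejection_rate = mean(abs(nulls) > tcrit),
       mean_t_m1 = mean(planted[1, ]), mean_t_smc = mean(planted[2, ]))
}
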