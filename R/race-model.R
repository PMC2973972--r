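#' Generative behavioural parameters for one subject
#'
#' Parameterises the independent horse-race model that generates per-trial
#' behaviour. The Go process finishing time is ex-Gaussian,
#' \code{go_mu + slow_slope * p_stop + Normal(0, go_sigma) + Exp(go_tau)},
#' so cued stop-signal probability slows responding linearly (proactive
#' inhibition). The Stop process latency (SSRT) is
#' \code{Normal(ssrt_mu, ssrt_sigma)}; stopping succeeds when the stop
#' process, launched at the stop-signal onset time, beats the Go process.
#' With probability \code{p_trigger_fail} the Stop process is never
#' triggered and the trial is a StopFailure regardless of timing.
#'
#' @param go_mu Gaussian mean of the Go finishing time at p_stop = 0 (ms).
#' @param go_sigma Gaussian SD of the Go finishing time (ms).
#' @param go_tau exponential component of the Go finishing time (ms).
#' @param slow_slope proactive slowing, ms per unit stop-signal probability.
#' @param ssrt_mu mean stop-signal reaction time (ms).
#' @param ssrt_sigma SD of the stop-signal reaction time (ms).
#' @param p_trigger_fail probability the stop process fails to launch.
#' @return An object of class \code{subject_params}.
#' @examples
#' subject_params(go_mu = 780, slow_slope = 90)
#' @export
subject_params <- function(go_mu = 780, go_sigma = 40, go_tau = 30,
                           slow_slope = 90, ssrt_mu = 260, ssrt_sigma = 30,
                           p_trigger_fail = 0) {
  p <- list(go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
            slow_slope = slow_slope, ssrt_mu = ssrt_mu,
            ssrt_sigma = ssrt_sigma, p_trigger_fail = p_trigger_fail)
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

validate_subject_params <- function(p) {
  stopifnot(p$go_sigma >= 0, p$go_tau >= 0, p$ssrt_sigma >= 0,
            p$slow_slope >= 0,
            p$p_trigger_fail >= 0, p$p_trigger_fail <= 1)
  invisible(p)
}

# invariant ranges used when truncating population draws
subject_param_ranges <- function() {
  list(go_mu = c(0, Inf), go_sigma = c(0, Inf), go_tau = c(0, Inf),
       slow_slope = c(0, Inf), ssrt_mu = c(0, Inf), ssrt_sigma = c(0, Inf),
       p_trigger_fail = c(0, 1))
}

#' Draw one subject from a population
#'
#' Each parameter is drawn from a normal distribution with the given
#' population mean and SD, truncated (by resampling) to the parameter's
#' valid range. Deterministic per seed.
#'
#' @param population_means a \code{subject_params} of population means.
#' @param population_sds a \code{subject_params}-shaped list of population
#'   SDs (all >= 0); zero SD returns the mean exactly.
#' @param seed integer seed.
#' @return A \code{subject_params}.
#' @export
sample_subject <- function(population_means, population_sds, seed) {
  stopifnot(inherits(population_means, "subject_params"))
  rng <- subject_param_ranges()
  withr::with_seed(seed, {
    out <- lapply(names(rng), function(nm) {
      mu <- population_means[[nm]]
      sd <- population_sds[[nm]]
      stopifnot(sd >= 0)
      if (sd == 0) return(mu)
      for (i in 1:1000) {
        x <- stats::rnorm(1, mu, sd)
        if (x >= rng[[nm]][1] && x <= rng[[nm]][2]) return(x)
      }
      min(max(mu, rng[[nm]][1]), rng[[nm]][2])
    })
    names(out) <- names(rng)
    do.call(subject_params, out)
  })
}

#' Default population for simulated cohorts
#'
#' Population means and between-subject SDs used for 24-subject cohort
#' simulations. Means are chosen so that simulated sessions resemble the
#' task's human benchmarks qualitatively: baseline Go responses near the
#' 800 ms target, tens of ms of proactive slowing across cue levels, and an
#' SSRT in the 250-300 ms range.
#'
#' @return A list with elements \code{means} and \code{sds}.
#' @export
default_population <- function() {
  list(means = subject_params(go_mu = 780, go_sigma = 40, go_tau = 30,
                              slow_slope = 90, ssrt_mu = 260, ssrt_sigma = 30,
                              p_trigger_fail = 0),
       sds = list(go_mu = 20, go_sigma = 5, go_tau = 5, slow_slope = 20,
                  ssrt_mu = 20, ssrt_sigma = 5, p_trigger_fail = 0))
}

#' Simulate one session of task behaviour
#'
#' Runs the independent horse race over a trial sequence. Go trials record
#' the Go finishing time as the response time. On Stop trials the SSD is
#' taken from that level's staircase; the trial is a StopSuccess when the
#' stop process is triggered and \code{ssd + ssrt <= t_go}, otherwise a
#' StopFailure recording the Go finishing time as the response. The
#' staircase for the trial's level is updated after every Stop trial.
#'
#' @param sequence a \code{trial_sequence}.
#' @param subject a \code{subject_params}.
#' @param seed integer seed; behaviour is reproducible per
#'   (sequence, subject, seed).
#' @return An object of class \code{session_data}: list with \code{trials}
#'   (the sequence's trials plus \code{rt} ms, \code{ssd} ms and
#'   \code{outcome} in Go/StopSuccess/StopFailure), \code{subject},
#'   \code{staircases} (final per-level states) and \code{seed}.
#' @examples
#' seq1 <- build_trial_sequence(task_config(), seed = 1)
#' ses <- simulate_session(seq1, subject_params(), seed = 2)
#' table(ses$trials$outcome)
#' @export
simulate_session <- function(sequence, subject, seed) {
  stopifnot(inherits(sequence, "trial_sequence"),
            inherits(subject, "subject_params"))
  cfg <- sequence$config
  tr <- sequence$trials
  n <- nrow(tr)
  withr::with_seed(seed, {
    t_go <- subject$go_mu + subject$slow_slope * tr$p_stop +
      stats::rnorm(n, 0, subject$go_sigma) +
      (if (subject$go_tau > 0) stats::rexp(n, 1 / subject$go_tau) else 0)
    t_ssrt <- stats::rnorm(n, subject$ssrt_mu, subject$ssrt_sigma)
    trig_fail <- stats::runif(n) < subject$p_trigger_fail

    rt <- t_go
    ssd <- rep(NA_real_, n)
    outcome <- rep("Go", n)
    stair <- list()
    stop_idx <- which(tr$trial_type == "stop")
    for (i in stop_idx) {
      lvl <- tr$level[i]
      if (is.null(stair[[lvl]]))
        stair[[lvl]] <- staircase_init(lvl, cfg$ssd_init, cfg$staircase_step,
                                       cfg$ssd_bounds)
      ssd[i] <- stair[[lvl]]$ssd
      success <- !trig_fail[i] && (ssd[i] + t_ssrt[i] <= t_go[i])
      outcome[i] <- if (success) "StopSuccess" else "StopFailure"
      if (success) rt[i] <- NA_real_
      stair[[lvl]] <- next_ssd(stair[[lvl]], success)
    }
    trials <- tr
    trials$rt <- rt
    trials$ssd <- ssd
    trials$outcome <- outcome
    structure(list(sequence = sequence, trials = trials, subject = subject,
                   staircases = stair, seed = seed),
              class = "session_data")
  })
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("session_data: %d trials, seed %s\n", nrow(x$trials),
              format(x$seed)))
  print(table(x$trials$outcome))
  invisible(x)
}

#' Write one subject's behaviour table
#'
#' @param session a \code{session_data}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_behavior <- function(session, path) {
  stopifnot(inherits(session, "session_data"))
  tr <- session$trials
  out <- data.frame(index = tr$index, level = tr$level,
                    trial_type = tr$trial_type, ssd = tr$ssd, rt = tr$rt,
                    outcome = tr$outcome)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
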