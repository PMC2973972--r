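#' Default synthetic region set
#'
#' Four regions with planted effects spanning the phenomena the analysis
#' chain must recover: a striatum-like seed more active on StopSuccess than
#' StopFailure trials and parametrically modulated by stop-signal
#' probability; an M1-like sink whose coupling with the seed weakens during
#' successful stopping (negative PPI); an SMC-like sink whose coupling
#' strengthens (positive PPI); and a region driven only by trial-wise
#' response time.
#'
#' @param noise_sd marginal AR(1) noise SD shared by all regions.
#' @param ar1_rho lag-1 noise autocorrelation.
#' @return Named list of \code{region_spec}s.
#' @export
default_regions <- function(noise_sd = 1, ar1_rho = 0.3) {
  list(
    putamen = region_spec("putamen", amp_stop_success = 1,
                          amp_stop_failure = 0.3, amp_go = 0.5,
                          slope_pstop = 2, amp_sd = 0.3,
                          noise_sd = noise_sd, ar1_rho = ar1_rho,
                          n_voxels = 32),
    m1 = region_spec("m1", amp_stop_failure = 0.3, amp_go = 0.4,
                     coupling_seed = 0.2, coupling_delta = -0.8,
                     noise_sd = noise_sd, ar1_rho = ar1_rho),
    smc = region_spec("smc", amp_stop_success = 0.4, amp_go = 0.3,
                      coupling_seed = 0.2, coupling_delta = 0.8,
                      noise_sd = noise_sd, ar1_rho = ar1_rho),
    rt_region = region_spec("rt_region", amp_go = 0.4, slope_rt = 10,
                            noise_sd = noise_sd, ar1_rho = ar1_rho)
  )
}

#' Pipeline configuration
#'
#' Assembles the full study configuration: task design, behavioural
#' population, synthetic region set, scanner timing and PPI settings.
#' Defaults describe a 24-subject cohort under the published task.
#'
#' @param n_subjects cohort size.
#' @param task a \code{task_config}.
#' @param population list with \code{means} (\code{subject_params}) and
#'   \code{sds}.
#' @param regions named list of \code{region_spec}s.
#' @param seed_region name of the PPI seed region.
#' @param sink_regions names of the PPI sink regions.
#' @param tr repetition time (s).
#' @param n_scans usable scans per session.
#' @param lambda deconvolution regularization for the PPI stage.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_subjects = 24, task = task_config(),
                            population = default_population(),
                            regions = default_regions(),
                            seed_region = "putamen",
                            sink_regions = c("m1", "smc"),
                            tr = 1.6, n_scans = 616, lambda = 100) {
  structure(list(n_subjects = n_subjects, task = task,
                 population = population, regions = regions,
                 seed_region = seed_region, sink_regions = sink_regions,
                 tr = tr, n_scans = n_scans, lambda = lambda),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys (all optional): \code{n_subjects},
#' \code{tr}, \code{n_scans}, \code{lambda}, \code{seed_region},
#' \code{sink_regions}, \code{task} (fields of \code{\link{task_config}},
#' with \code{levels} as a list of label/n_go/n_stop records),
#' \code{population} (\code{means}/\code{sds} with
#' \code{\link{subject_params}} fields) and \code{regions} (list of
#' \code{\link{region_spec}} records).
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_subjects", "tr", "n_scans", "lambda", "seed_region",
              "sink_regions"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$task)) {
    ta <- y$task
    if (!is.null(ta$levels))
      ta$levels <- do.call(rbind, lapply(ta$levels, as.data.frame))
    if (!is.null(ta$rest_blocks))
      ta$rest_blocks <- do.call(rbind, lapply(ta$rest_blocks, as.data.frame))
    args$task <- do.call(task_config, ta)
  }
  if (!is.null(y$population)) {
    pop <- default_population()
    if (!is.null(y$population$means))
      pop$means <- do.call(subject_params,
                           utils::modifyList(unclass(pop$means),
                                             y$population$means))
    if (!is.null(y$population$sds))
      pop$sds <- utils::modifyList(pop$sds, y$population$sds)
    args$population <- pop
  }
  if (!is.null(y$regions))
    args$regions <- lapply(y$regions, function(r) do.call(region_spec, r))
  do.call(pipeline_config, args)
}

#' Derive a stage seed from the master seed
#'
#' Counter-based splitting: each (stage, unit) pair maps to its own
#' 31-bit seed, so stages and subjects can be rerun independently while
#' the whole run stays reproducible from one master seed.
#'
#' @param master integer master seed.
#' @param stage stage index (1-based).
#' @param unit within-stage unit (e.g. subject index), 0 for stage-level.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage, unit = 0) {
  m <- 2147483647
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(stage) * 9973) %% m
  x <- (x * 48271 + as.numeric(unit) * 7919 + 1) %% m
  as.integer(x + (x == 0))
}

#' Simulate a behavioural cohort
#'
#' Draws \code{n_subjects} parameter sets from the population and simulates
#' one session each, with per-subject pseudorandomised trial sequences.
#'
#' @param config a \code{pipeline_config}.
#' @param seed master seed.
#' @return List of \code{session_data}, one per subject.
#' @export
simulate_cohort <- function(config = pipeline_config(), seed = 1) {
  lapply(seq_len(config$n_subjects), function(s) {
    sq <- build_trial_sequence(config$task, seed = derive_seed(seed, 1, s))
    subj <- sample_subject(config$population$means, config$population$sds,
                           seed = derive_seed(seed, 2, s))
    simulate_session(sq, subj, seed = derive_seed(seed, 3, s))
  })
}

#' Run the full pipeline
#'
#' Executes design, behavioural simulation, behavioural analysis, BOLD
#' synthesis, GLM and PPI for one synthetic cohort, writing TSV outputs and
#' a JSON run manifest into \code{out_dir}.
#'
#' @param config a \code{pipeline_config}, or a YAML path accepted by
#'   \code{\link{read_pipeline_config}}.
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = "stopsig_run", quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- character(0)
  paths <- character(0)
  t0 <- Sys.time()

  run_stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed (seed ", seed, "): ",
           conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    out
  }

  # 1. design + 2. simulate behaviour
  sessions <- run_stage("design", function() simulate_cohort(config, seed))
  run_stage("simulate", function() {
    for (s in seq_along(sessions)) {
      p1 <- file.path(out_dir, sprintf("events_sub%02d.tsv", s))
      p2 <- file.path(out_dir, sprintf("behavior_sub%02d.tsv", s))
      write_events(sessions[[s]]$sequence, p1)
      write_behavior(sessions[[s]], p2)
      paths <<- c(paths, p1, p2)
    }
    say("simulate: %d subjects, %d trials each", length(sessions),
        nrow(sessions[[1]]$trials))
  })

  # 3. behavioural analysis
  behav <- run_stage("behavior", function() {
    sums <- lapply(sessions, rt_summary)
    rows <- do.call(rbind, lapply(seq_along(sums), function(s)
      cbind(subject = s, sums[[s]]$levels)))
    ssrt <- vapply(sums, `[[`, 0, "ssrt")
    p <- file.path(out_dir, "behavior_summary.tsv")
    utils::write.table(rows, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
    inhib <- inhibition_function(sessions)
    p2 <- file.path(out_dir, "inhibition.tsv")
    utils::write.table(inhib$points, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p2)
    say("behavior: mean SSRT %.0f ms, Weibull R2 %.3f", mean(ssrt),
        if (!is.null(inhib$weibull)) inhib$weibull["r2"] else NA)
    list(summaries = sums, ssrt = ssrt, inhibition = inhib)
  })

  # 4. BOLD synthesis
  bolds <- run_stage("bold_synth", function() {
    out <- lapply(seq_along(sessions), function(s)
      synthesize_bold(sessions[[s]], config$regions, tr = config$tr,
                      n_scans = config$n_scans,
                      seed = derive_seed(seed, 4, s),
                      seed_region = config$seed_region))
    p <- file.path(out_dir, "bold_sub01.tsv")
    write_bold(out[[1]], p)
    paths <<- c(paths, p, sub("\\.tsv$", ".json", p))
    say("bold_synth: %d regions x %d scans per subject",
        length(config$regions), config$n_scans)
    out
  })

  # 5. GLM
  glm_res <- run_stage("glm", function() {
    per <- lapply(seq_along(bolds), function(s) {
      des <- build_design_matrix(sessions[[s]], tr = config$tr,
                                 n_scans = config$n_scans)
      fit <- fit_glm(bolds[[s]]$signal, des)
      glm_contrast(fit, c(stop_success = 1, stop_failure = -1))
    })
    est <- sapply(per, function(d) d$estimate)  # regions x subjects
    rownames(est) <- per[[1]]$region
    grp <- apply(est, 1, function(v) unlist(group_t(v)))
    tab <- data.frame(region = colnames(grp), t(grp), row.names = NULL)
    p <- file.path(out_dir, "glm_group.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
    say("glm: StopSuccess>StopFailure group t (seed region) = %.2f",
        tab$t[tab$region == config$seed_region])
    list(per_subject = per, group = tab)
  })

  # 6. PPI
  ppi_res <- run_stage("ppi", function() {
    op <- deconv_operator(config$tr, config$n_scans, config$lambda)
    per <- lapply(bolds, function(b)
      ppi_analysis(b, config$seed_region, config$sink_regions,
                   operator = op))
    tab <- do.call(rbind, lapply(config$sink_regions, function(rn) {
      est <- vapply(per, function(x)
        x[[rn]]$coef$estimate[x[[rn]]$coef$term == "ppi"], 0)
      g <- group_t(est)
      data.frame(sink = rn, mean_ppi = g$mean, t = g$t, df = g$df, p = g$p)
    }))
    p <- file.path(out_dir, "ppi_group.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
    say("ppi: %s", paste(sprintf("%s t=%.2f", tab$sink, tab$t),
                         collapse = ", "))
    list(per_subject = per, group = tab)
  })

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_yaml(config), cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    master_seed = seed,
    stage_seeds = list(design = derive_seed(seed, 1, 1),
                       subjects = derive_seed(seed, 2, 1),
                       behavior = derive_seed(seed, 3, 1),
                       bold = derive_seed(seed, 4, 1)),
    package_version = as.character(utils::packageVersion("stopsig")),
    stages = stages,
    outputs = c(paths, cfg_path),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stopifnot(all(file.exists(manifest$outputs)))
  invisible(list(manifest = manifest, sessions = sessions, behavior = behav,
                 glm = glm_res, ppi = ppi_res))
}

config_to_yaml <- function(config) {
  list(n_subjects = config$n_subjects, tr = config$tr,
       n_scans = config$n_scans, lambda = config$lambda,
       seed_region = config$seed_region,
       sink_regions = config$sink_regions,
       task = list(levels = config$task$levels,
                   target_rt = config$task$target_rt,
                   ssd_init = config$task$ssd_init),
       population = list(means = unclass(config$population$means),
                         sds = config$population$sds),
       regions = lapply(config$regions, unclass))
}

#' Write the small hand-checkable fixtures used in the unit tests
#'
#' Produces (1) the worked SSRT example: ten Go response times and four
#' Stop trials whose integration-method SSRT is 242.5 ms; (2) a
#' deterministic staircase trace; (3) a small noiseless BOLD round-trip
#' set (events plus region signals).
#'
#' @param out_dir output directory.
#' @return Character vector of written paths, invisibly.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  # worked SSRT example
  ssrt_fix <- data.frame(
    kind = c(rep("go", 10), rep("stop", 4)),
    rt = c(seq(700, 880, by = 20), rep(NA, 4)),
    ssd = c(rep(NA, 10), c(500, 525, 550, 575)),
    responded = c(rep(NA, 10), c(TRUE, TRUE, FALSE, FALSE)))
  p <- file.path(out_dir, "ssrt_worked_example.tsv")
  utils::write.table(ssrt_fix, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)

  # deterministic staircase trace: alternating fail/success from 550
  st <- staircase_init("demo")
  for (succ in c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
    st <- next_ssd(st, succ)
  p <- file.path(out_dir, "staircase_trace.tsv")
  utils::write.table(cbind(trial = seq_len(nrow(st$history)), st$history),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  # noiseless BOLD round-trip set
  cfg <- task_config()
  sq <- build_trial_sequence(cfg, seed = 101)
  ses <- simulate_session(sq, subject_params(), seed = 102)
  regions <- list(region_spec("act", amp_stop_success = 1,
                              amp_stop_failure = 0.3, amp_go = 0.5,
                              slope_pstop = 2))
  bold <- synthesize_bold(ses, regions, seed = 103)
  p1 <- file.path(out_dir, "roundtrip_events.tsv")
  p2 <- file.path(out_dir, "roundtrip_bold.tsv")
  write_events(sq, p1)
  write_bold(bold, p2)
  paths <- c(paths, p1, p2, sub("\\.tsv$", ".json", p2))
  invisible(paths)
}

#' Read an SSRT worked-example fixture
#'
#' @param path TSV written by \code{\link{generate_fixtures}}.
#' @return A list usable by \code{\link{ssrt_integration}}.
#' @export
read_ssrt_fixture <- function(path) {
  d <- utils::read.delim(path)
  go <- d$kind == "go"
  list(go_rts = d$rt[go], n_stop = sum(!go),
       n_respond = sum(d$responded[!go]), ssds = d$ssd[!go])
}
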