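#' Region specification for the BOLD forward model
#'
#' Ground-truth effect sizes for one synthetic region: event amplitudes per
#' trial outcome, slopes for the standardized (mean-centred) parametric
#' modulators, condition-dependent coupling onto the seed region's neural
#' signal, and the AR(1) noise model.
#'
#' @param name region name.
#' @param amp_stop_success,amp_stop_failure,amp_go event amplitudes (signal
#'   units) for StopSuccess, StopFailure and experimental Go trials.
#' @param slope_pstop,slope_rt amplitudes per unit of the centred
#'   stop-signal probability (fraction) and centred response time (s)
#'   modulators on experimental Go trials.
#' @param coupling_seed baseline gain of the seed region's neural signal
#'   onto this region.
#' @param coupling_delta gain change with Stop trial context (+1 during
#'   StopSuccess trials, -1 during StopFailure trials); a positive value
#'   means stronger coupling during successful stopping.
#' @param amp_sd SD of a per-trial Gaussian fluctuation added to every
#'   event amplitude of the region. Trial-to-trial neural variability in a
#'   seed region is what condition-dependent coupling transmits to its
#'   sinks over and above the mean task responses, so a PPI is only
#'   identifiable beyond the task model when the seed's \code{amp_sd} is
#'   positive.
#' @param noise_sd marginal SD of the additive AR(1) noise (per voxel when
#'   \code{n_voxels > 1}).
#' @param ar1_rho lag-1 autocorrelation of the noise (|rho| < 1).
#' @param n_voxels number of voxels synthesized for the region; above 1 the
#'   voxels share the region's clean signal and receive independent noise,
#'   the region series is their mean, and the voxel matrix is kept so that
#'   eigenvariate summaries can be tested (used for seed regions).
#' @return An object of class \code{region_spec}.
#' @export
region_spec <- function(name, amp_stop_success = 0, amp_stop_failure = 0,
                        amp_go = 0, slope_pstop = 0, slope_rt = 0,
                        coupling_seed = 0, coupling_delta = 0,
                        amp_sd = 0, noise_sd = 0, ar1_rho = 0,
                        n_voxels = 1) {
  stopifnot(amp_sd >= 0, noise_sd >= 0, abs(ar1_rho) < 1, n_voxels >= 1)
  structure(list(name = name, amp_stop_success = amp_stop_success,
                 amp_stop_failure = amp_stop_failure, amp_go = amp_go,
                 slope_pstop = slope_pstop, slope_rt = slope_rt,
                 coupling_seed = coupling_seed,
                 coupling_delta = coupling_delta,
                 amp_sd = amp_sd, noise_sd = noise_sd, ar1_rho = ar1_rho,
                 n_voxels = as.integer(n_voxels)),
            class = "region_spec")
}

# Shared event structure for the forward model and the GLM design matrix.
# Impulses are response-locked: at onset + rt for responded trials and at
# onset + target RT for StopSuccess trials. Modulators are centred over the
# non-outlier experimental Go events. Outlier Go trials form their own
# impulse set; baseline Go trials are left implicit.
session_events <- function(session, outlier_flags = NULL) {
  stopifnot(inherits(session, "session_data"))
  tr <- session$trials
  cfg <- session$sequence$config
  if (is.null(outlier_flags)) outlier_flags <- session_outlier_flags(tr)
  stopifnot(length(outlier_flags) == nrow(tr))
  target_s <- cfg$target_rt / 1000
  pitch_s <- (cfg$bar_travel_total + cfg$iti) / 1000

  ss <- tr$outcome == "StopSuccess"
  sf <- tr$outcome == "StopFailure"
  go_exp <- tr$trial_type == "go" & tr$p_stop > 0 & !outlier_flags & !is.na(tr$rt)
  go_out <- tr$trial_type == "go" & tr$p_stop > 0 & outlier_flags & !is.na(tr$rt)

  list(stop_success = list(onsets = tr$onset[ss] + target_s),
       stop_failure = list(onsets = tr$onset[sf] + tr$rt[sf] / 1000),
       go_exp = list(onsets = tr$onset[go_exp] + tr$rt[go_exp] / 1000,
                     rt_c = tr$rt[go_exp] / 1000 - mean(tr$rt[go_exp]) / 1000,
                     p_c = tr$p_stop[go_exp] - mean(tr$p_stop[go_exp])),
       go_outlier = list(onsets = tr$onset[go_out] + tr$rt[go_out] / 1000),
       rest = session$sequence$rests,
       stop_spans = data.frame(onset = tr$onset[ss | sf],
                               duration = rep(pitch_s, sum(ss | sf)),
                               context = ifelse(ss[ss | sf], 1, -1)))
}

# microtime context signal: +1 over StopSuccess trials, -1 over StopFailure
context_micro <- function(events, grid) {
  sp <- events$stop_spans
  pos <- sp[sp$context > 0, , drop = FALSE]
  neg <- sp[sp$context < 0, , drop = FALSE]
  micro_boxcar(pos$onset, pos$duration, grid) -
    micro_boxcar(neg$onset, neg$duration, grid)
}

# microtime neural impulse train for one region's own (non-coupling)
# events; amp_sd > 0 adds iid per-trial amplitude fluctuations (drawn from
# the current RNG stream, so callers control reproducibility)
region_neural_micro <- function(region, events, grid) {
  amp_sd <- region$amp_sd %||% 0
  fluct <- function(k) if (amp_sd > 0) stats::rnorm(k, 0, amp_sd) else 0
  n_ss <- length(events$stop_success$onsets)
  n_sf <- length(events$stop_failure$onsets)
  n_out <- length(events$go_outlier$onsets)
  x <- micro_impulses(events$stop_success$onsets,
                      rep(region$amp_stop_success, n_ss) + fluct(n_ss), grid)
  x <- x + micro_impulses(events$stop_failure$onsets,
                          rep(region$amp_stop_failure, n_sf) + fluct(n_sf),
                          grid)
  amp_go <- region$amp_go + region$slope_pstop * events$go_exp$p_c +
    region$slope_rt * events$go_exp$rt_c + fluct(length(events$go_exp$onsets))
  x <- x + micro_impulses(events$go_exp$onsets, amp_go, grid)
  x + micro_impulses(events$go_outlier$onsets,
                     rep(region$amp_go, n_out) + fluct(n_out), grid)
}

#' Synthesize a region-by-scan BOLD dataset with planted effects
#'
#' Forward model mirroring the event-related GLM: per region, a neural
#' impulse train (response-locked events scaled by the region's amplitudes
#' and modulator slopes) plus condition-dependent coupling terms
#' \code{(coupling_seed + context * coupling_delta) * seed_neural}, where
#' context is +1 during StopSuccess trials and -1 during StopFailure
#' trials, is convolved with the canonical HRF at microtime resolution,
#' sampled at the scan times, and overlaid with AR(1) Gaussian noise.
#'
#' @param session a \code{session_data} (carries the trial sequence).
#' @param regions list of \code{region_spec}s.
#' @param tr repetition time in seconds.
#' @param n_scans number of scans; events beyond the scan window are
#'   silently outside the model.
#' @param seed integer seed for the noise.
#' @param seed_region name of the region whose neural signal drives the
#'   coupling terms; required when any \code{coupling_seed} or
#'   \code{coupling_delta} is non-zero.
#' @param outlier_flags optional logical per-trial outlier flags; default
#'   recomputes the per-level 1.5 x IQR rule.
#' @return An object of class \code{bold_dataset}: \code{signal} (region x
#'   scan matrix), \code{voxels} (named list of voxel x scan matrices for
#'   regions with \code{n_voxels > 1}), \code{tr}, \code{n_scans},
#'   \code{regions} (ground truth), \code{session}, \code{seed_region},
#'   \code{seed}.
#' @export
synthesize_bold <- function(session, regions, tr = 1.6, n_scans = 616,
                            seed = 1, seed_region = NULL,
                            outlier_flags = NULL) {
  stopifnot(inherits(session, "session_data"), length(regions) >= 1)
  names(regions) <- vapply(regions, `[[`, "", "name")
  has_coupling <- any(vapply(regions, function(r)
    r$coupling_seed != 0 || r$coupling_delta != 0, logical(1)))
  if (has_coupling) {
    if (is.null(seed_region)) stop("coupling requires a seed_region")
    if (!seed_region %in% names(regions))
      stop("unknown seed region '", seed_region, "'")
  }
  grid <- micro_grid(tr, n_scans)
  hrf <- canonical_hrf(grid$dt)
  events <- session_events(session, outlier_flags)
  ctx <- if (has_coupling) context_micro(events, grid) else NULL

  signal <- matrix(0, nrow = length(regions), ncol = n_scans,
                   dimnames = list(names(regions), NULL))
  voxels <- list()
  withr::with_seed(seed, {
    # one neural realisation per region, so the seed's own signal and the
    # coupling terms it drives share identical per-trial fluctuations
    neural_all <- lapply(regions, region_neural_micro, events = events,
                         grid = grid)
    seed_neural <- if (has_coupling) neural_all[[seed_region]] else NULL
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      neural <- neural_all[[i]]
      if (has_coupling && names(regions)[i] != seed_region &&
          (r$coupling_seed != 0 || r$coupling_delta != 0))
        neural <- neural + (r$coupling_seed + ctx * r$coupling_delta) *
          seed_neural
      y <- sample_at_scans(convolve_causal(neural, hrf), grid)
      nv <- r$n_voxels %||% 1L
      if (nv > 1) {
        vox <- matrix(rep(y, each = nv), nv, n_scans)
        if (r$noise_sd > 0)
          vox <- vox + t(ar1_noise_matrix(n_scans, nv, r$ar1_rho,
                                          r$noise_sd))
        voxels[[r$name]] <- vox
        signal[i, ] <- colMeans(vox)
      } else {
        if (r$noise_sd > 0)
          y <- y + ar1_noise(n_scans, r$ar1_rho, r$noise_sd)
        signal[i, ] <- y
      }
    }
  })
  structure(list(signal = signal, voxels = voxels, tr = tr,
                 n_scans = n_scans, regions = regions, session = session,
                 seed_region = seed_region, seed = seed),
            class = "bold_dataset")
}

# AR(1) noise with marginal SD `sd`; stationary initialisation, one column
# per series
ar1_noise_matrix <- function(n, k, rho, sd) {
  e <- matrix(stats::rnorm(n * k, 0, sd * sqrt(1 - rho^2)), n, k)
  if (rho == 0) return(e)
  init <- stats::rnorm(k, 0, sd)
  x <- stats::filter(e, rho, method = "recursive", init = matrix(init, 1))
  matrix(as.numeric(x), n, k)
}

ar1_noise <- function(n, rho, sd) ar1_noise_matrix(n, 1L, rho, sd)[, 1]

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("bold_dataset: %d regions x %d scans, TR %g s\n",
              nrow(x$signal), x$n_scans, x$tr))
  cat("regions:", paste(rownames(x$signal), collapse = ", "), "\n")
  invisible(x)
}

#' Tile a region into noisy voxel copies
#'
#' Expands one region's series into \code{n_voxels} copies with independent
#' Gaussian noise, for testing voxel-level summaries such as the first
#' eigenvariate.
#'
#' @param dataset a \code{bold_dataset}.
#' @param region region name.
#' @param n_voxels number of voxel copies.
#' @param noise_sd SD of the independent noise added per voxel.
#' @param seed integer seed.
#' @return A voxel x scan matrix.
#' @export
tile_region_voxels <- function(dataset, region, n_voxels = 32, noise_sd = 0.5,
                               seed = 1) {
  stopifnot(inherits(dataset, "bold_dataset"),
            region %in% rownames(dataset$signal))
  base <- dataset$signal[region, ]
  withr::with_seed(seed, {
    t(vapply(seq_len(n_voxels),
             function(i) base + stats::rnorm(length(base), 0, noise_sd),
             numeric(length(base))))
  })
}

#' Write / read a BOLD dataset as TSV + JSON sidecar
#'
#' @param dataset a \code{bold_dataset}.
#' @param path output TSV path (regions x scans); a \code{.json} sidecar
#'   with tr, region names and ground truth is written next to it.
#' @return \code{path}, invisibly.
#' @export
write_bold <- function(dataset, path) {
  stopifnot(inherits(dataset, "bold_dataset"))
  df <- as.data.frame(dataset$signal)
  df <- cbind(region = rownames(dataset$signal), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(tr = dataset$tr, n_scans = dataset$n_scans,
               seed_region = dataset$seed_region,
               regions = lapply(dataset$regions, unclass))
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
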