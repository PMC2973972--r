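#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak at 6 s, undershoot peak
#' at 16 s, unit dispersions, undershoot ratio 1/6), sampled at \code{dt}
#' over 32 s and scaled to unit peak.
#'
#' @param dt sampling interval in seconds (0 < dt <= 1.6).
#' @param duration kernel length in seconds.
#' @return Numeric kernel of length \code{duration / dt}.
#' @examples
#' h <- canonical_hrf(0.1)
#' h[1]  # 0 at t = 0
#' @export
canonical_hrf <- function(dt, duration = 32) {
  stopifnot(dt > 0, dt <= 1.6)
  t <- seq(0, duration - dt, by = dt)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# --- microtime machinery shared by the forward model and the GLM ----------
# Events are represented as unit-area impulses on a fine grid (dt = tr /
# oversample), convolved with the canonical HRF and sampled at scan onsets.

micro_grid <- function(tr, n_scans, oversample = 16L) {
  dt <- tr / oversample
  list(dt = dt, oversample = as.integer(oversample),
       n_micro = as.integer(n_scans) * as.integer(oversample),
       n_scans = as.integer(n_scans))
}

# place amplitude-weighted impulses at event onsets on the microtime grid;
# onsets beyond the scan window are dropped
micro_impulses <- function(onsets, amplitudes, grid) {
  x <- numeric(grid$n_micro)
  idx <- floor(onsets / grid$dt) + 1L
  keep <- idx >= 1L & idx <= grid$n_micro
  for (j in which(keep)) x[idx[j]] <- x[idx[j]] + amplitudes[j]
  x
}

# boxcar of unit height over [onset, onset + duration)
micro_boxcar <- function(onsets, durations, grid) {
  x <- numeric(grid$n_micro)
  for (j in seq_along(onsets)) {
    a <- floor(onsets[j] / grid$dt) + 1L
    b <- min(ceiling((onsets[j] + durations[j]) / grid$dt), grid$n_micro)
    if (a <= grid$n_micro && b >= a) x[a:b] <- 1
  }
  x
}

# causal convolution with a kernel, truncated to the input length; FFT on a
# power-of-two grid with the kernel transform cached per (n, kernel length)
.fft_cache <- new.env(parent = emptyenv())

convolve_causal <- function(x, kernel) {
  n <- length(x)
  m <- length(kernel)
  L <- 2^ceiling(log2(n + m - 1))
  key <- paste0(L, "_", m, "_", signif(sum(kernel), 12))
  fk <- .fft_cache[[key]]
  if (is.null(fk)) {
    fk <- stats::fft(c(kernel, numeric(L - m)))
    .fft_cache[[key]] <- fk
  }
  fx <- stats::fft(c(x, numeric(L - n)))
  y <- Re(stats::fft(fx * fk, inverse = TRUE)) / L
  y[seq_len(n)]
}

# sample a microtime series at scan onsets
sample_at_scans <- function(x, grid) {
  x[seq(1L, grid$n_micro, by = grid$oversample)]
}

# full event -> scan-resolution regressor
event_regressor <- function(onsets, amplitudes, tr, n_scans,
                            oversample = 16L, hrf = NULL) {
  grid <- micro_grid(tr, n_scans, oversample)
  if (is.null(hrf)) hrf <- canonical_hrf(grid$dt)
  sample_at_scans(convolve_causal(micro_impulses(onsets, amplitudes, grid),
                                  hrf), grid)
}
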