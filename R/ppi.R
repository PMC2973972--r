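#' First eigenvariate of a voxel set
#'
#' Scan-wise projection on the first left singular vector of the voxel x
#' scan matrix, scaled to unit variance and sign-aligned to correlate
#' positively with the mean voxel series (falling back to the first voxel
#' when the mean series is degenerate).
#'
#' @param voxel_matrix numeric voxel x scan matrix.
#' @return Numeric series of length n_scans (unit variance).
#' @export
extract_eigenvariate <- function(voxel_matrix) {
  X <- as.matrix(voxel_matrix)
  stopifnot(nrow(X) >= 1)
  if (all(X == 0)) stop("all-zero voxel matrix; eigenvariate undefined")
  sv <- svd(X, nu = 0, nv = 1)
  e <- as.numeric(sv$v[, 1])
  if (stats::sd(e) == 0) stop("degenerate eigenvariate (constant series)")
  e <- e / stats::sd(e)
  ref <- colMeans(X)
  if (stats::sd(ref) == 0 || abs(stats::cor(e, ref)) < 1e-12) ref <- X[1, ]
  if (stats::sd(ref) > 0 && stats::cor(e, ref) < 0) e <- -e
  e
}

# Sparse convolution operator mapping a microtime neural series to
# scan-sampled BOLD, plus a first-difference smoother; Cholesky-factorised
# once so many series can be deconvolved at a fixed lambda.
deconv_operator <- function(tr, n_scans, lambda, oversample = 16L) {
  stopifnot(lambda >= 0)
  grid <- micro_grid(tr, n_scans, oversample)
  hrf <- canonical_hrf(grid$dt)
  lk <- length(hrf)
  scan_idx <- seq(1L, grid$n_micro, by = grid$oversample)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (s in seq_along(scan_idx)) {
    tidx <- scan_idx[s]
    j <- seq.int(max(1L, tidx - lk + 1L), tidx)
    rows <- c(rows, rep.int(s, length(j)))
    cols <- c(cols, j)
    vals <- c(vals, hrf[tidx - j + 1L])
  }
  H <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(grid$n_scans, grid$n_micro))
  n <- grid$n_micro
  D <- Matrix::sparseMatrix(i = rep(seq_len(n - 1L), 2),
                            j = c(seq_len(n - 1L), seq.int(2L, n)),
                            x = c(rep(-1, n - 1L), rep(1, n - 1L)),
                            dims = c(n - 1L, n))
  M <- Matrix::crossprod(H) + lambda * Matrix::crossprod(D) +
    Matrix::Diagonal(n, 1e-10)
  list(H = H, chol = Matrix::Cholesky(Matrix::forceSymmetric(M)),
       grid = grid, lambda = lambda)
}

deconv_apply <- function(op, y) {
  y <- as.matrix(y)
  as.matrix(Matrix::solve(op$chol, as.matrix(Matrix::crossprod(op$H, y))))
}

#' Hemodynamic deconvolution by generalized ridge regression
#'
#' Recovers a microtime neural series x from a scan-resolution BOLD series
#' y by minimising ||H x - y||^2 + lambda ||D x||^2, where H convolves with
#' the canonical HRF at microtime resolution (tr / 16) and D is a
#' first-difference smoother. This generalized-ridge solution approximates
#' the Bayesian shrinkage of empirical-Bayes deconvolution with a
#' smoothness prior; \code{lambda} can be fixed or selected by generalized
#' cross-validation.
#'
#' @param series numeric BOLD series (length n_scans).
#' @param tr repetition time (s).
#' @param lambda regularization weight (>= 0), or \code{"gcv"} to select it
#'   by generalized cross-validation over a log-spaced grid.
#' @param oversample microtime bins per TR.
#' @param operator optional precomputed \code{deconv_operator}, reused
#'   across calls with the same (tr, n_scans, lambda).
#' @return Numeric microtime neural series (length n_scans * oversample)
#'   with attribute \code{lambda}.
#' @export
deconvolve <- function(series, tr = 1.6, lambda = "gcv", oversample = 16L,
                       operator = NULL) {
  n_scans <- length(series)
  if (!is.null(operator)) {
    x <- deconv_apply(operator, series)[, 1]
    attr(x, "lambda") <- operator$lambda
    return(x)
  }
  if (identical(lambda, "gcv"))
    lambda <- select_lambda_gcv(series, tr, oversample)
  op <- deconv_operator(tr, n_scans, lambda, oversample)
  x <- deconv_apply(op, series)[, 1]
  attr(x, "lambda") <- lambda
  x
}

# GCV with a Hutchinson trace estimator (fixed probe RNG so the selection
# is deterministic for a given series)
select_lambda_gcv <- function(series, tr, oversample = 16L,
                              grid = 10^seq(-2, 4),
                              n_probe = 4L) {
  n <- length(series)
  probes <- withr::with_seed(20260101, {
    matrix(sample(c(-1, 1), n * n_probe, replace = TRUE), n, n_probe)
  })
  scores <- vapply(grid, function(lam) {
    op <- deconv_operator(tr, n, lam, oversample)
    x <- deconv_apply(op, series)[, 1]
    rss <- sum((as.numeric(op$H %*% x) - series)^2)
    hp <- deconv_apply(op, probes)
    tr_a <- mean(colSums(probes * as.matrix(op$H %*% hp)))
    n * rss / (n - min(tr_a, n - 1))^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Build PPI regressors
#'
#' The psychological vector codes StopSuccess events as +1 and StopFailure
#' events as -1 impulses at microtime, placed at the same response-locked
#' times as the event model (target response time for StopSuccess, the
#' recorded response for StopFailure); the interaction is its elementwise
#' product with the (deconvolved) neural seed series. All three vectors are
#' convolved with the canonical HRF and resampled to scan resolution.
#'
#' @param neural microtime neural series (from \code{\link{deconvolve}}).
#' @param session a \code{session_data} providing Stop trial onsets and
#'   outcomes.
#' @param tr repetition time (s).
#' @param center_psych subtract the mean of the non-zero psychological
#'   codes (for designs with unbalanced Stop outcomes); default keeps the
#'   plain +1/-1 coding, appropriate under staircase-balanced outcomes.
#' @return A scan x 3 matrix with columns \code{physio}, \code{psych},
#'   \code{ppi}.
#' @export
ppi_regressors <- function(neural, session, tr = 1.6, center_psych = FALSE) {
  stopifnot(inherits(session, "session_data"))
  ev <- session_events(session)
  on_ss <- ev$stop_success$onsets
  on_sf <- ev$stop_failure$onsets
  if (length(on_ss) + length(on_sf) == 0) stop("no Stop trials; PPI undefined")
  n_micro <- length(neural)
  oversample <- 16L
  n_scans <- n_micro %/% oversample
  grid <- micro_grid(tr, n_scans, oversample)
  stopifnot(grid$n_micro == n_micro)
  code <- c(rep(1, length(on_ss)), rep(-1, length(on_sf)))
  if (center_psych) code <- code - mean(code)
  psych <- micro_impulses(c(on_ss, on_sf), code, grid)
  hrf <- canonical_hrf(grid$dt)
  out <- cbind(
    physio = sample_at_scans(convolve_causal(as.numeric(neural), hrf), grid),
    psych = sample_at_scans(convolve_causal(psych, hrf), grid),
    ppi = sample_at_scans(convolve_causal(psych * as.numeric(neural), hrf),
                          grid))
  out
}

#' Fit the PPI model at one sink region
#'
#' AR(1)-prewhitened regression of the sink series on the physiological,
#' psychological and interaction regressors (plus optional nuisance
#' columns and an intercept). The PPI sign is positive/negative when the
#' interaction coefficient is significant at \code{alpha}, otherwise null.
#'
#' @param sink numeric BOLD series of the sink region.
#' @param regressors scan x 3 matrix from \code{\link{ppi_regressors}}.
#' @param nuisance optional scan x k numeric matrix.
#' @param alpha significance level for the sign call.
#' @return An object of class \code{ppi_result}: data.frame \code{coef}
#'   (term, estimate, se, t, p), \code{sign}, \code{rho}, \code{dof}.
#' @export
fit_ppi <- function(sink, regressors, nuisance = NULL, alpha = 0.05) {
  stopifnot(ncol(regressors) == 3, length(sink) == nrow(regressors))
  X <- cbind(regressors, nuisance, intercept = 1)
  sv <- svd(scale(X[, seq_len(3)], center = FALSE), nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e8)
    stop("PPI regressors are collinear (condition number > 1e8)")
  fit <- fit_glm(matrix(sink, nrow = 1), X)
  idx <- seq_len(3)
  est <- fit$betas[1, idx]
  se <- sqrt(fit$sigma2[1] * diag(fit$xtx_inv)[idx])
  t <- est / se
  p <- 2 * stats::pt(-abs(t), fit$dof)
  sign <- if (p[3] < alpha) if (est[3] > 0) "positive" else "negative"
  else "null"
  structure(list(coef = data.frame(term = c("physio", "psych", "ppi"),
                                   estimate = est, se = se, t = t, p = p,
                                   row.names = NULL),
                 sign = sign, rho = fit$rho, dof = fit$dof),
            class = "ppi_result")
}

#' @export
print.ppi_result <- function(x, ...) {
  print(x$coef, row.names = FALSE)
  cat(sprintf("PPI sign: %s (AR1 rho %.3f, dof %d)\n", x$sign, x$rho, x$dof))
  invisible(x)
}

#' Seed-to-sink PPI analysis on a synthetic dataset
#'
#' Convenience wrapper implementing the full seed-to-sink chain: the seed
#' series is the first eigenvariate of the seed's voxel set when the
#' dataset carries one (otherwise the region series), mean-centred and
#' deconvolved; the PPI regressors are built from the dataset's session;
#' and each sink is fit with the session's task model (conditions of no
#' interest, the summed Stop regressor, modulators and the
#' discrete-cosine drift basis) as nuisance columns, so that
#' condition-dependent coupling is tested over and above the sink's own
#' event responses. The Stop regressors enter as their sum because the
#' psychological vector already spans their difference.
#'
#' @param dataset a \code{bold_dataset}.
#' @param seed_region seed region name.
#' @param sink_regions character vector of sink region names.
#' @param lambda deconvolution regularization (number or \code{"gcv"}).
#' @param operator optional precomputed \code{deconv_operator}.
#' @param alpha significance level for sign calls.
#' @param task_nuisance include the task model as nuisance regressors.
#' @return Named list of \code{ppi_result}s, one per sink.
#' @export
ppi_analysis <- function(dataset, seed_region, sink_regions,
                         lambda = 100, operator = NULL, alpha = 0.05,
                         task_nuisance = TRUE) {
  stopifnot(inherits(dataset, "bold_dataset"),
            seed_region %in% rownames(dataset$signal),
            all(sink_regions %in% rownames(dataset$signal)))
  seed_series <- if (seed_region %in% names(dataset$voxels))
    extract_eigenvariate(dataset$voxels[[seed_region]])
  else dataset$signal[seed_region, ]
  seed_series <- seed_series - mean(seed_series)
  neural <- deconvolve(seed_series, tr = dataset$tr, lambda = lambda,
                       operator = operator)
  reg <- ppi_regressors(neural, dataset$session, tr = dataset$tr)
  nuis <- NULL
  if (task_nuisance) {
    des <- build_design_matrix(dataset$session, tr = dataset$tr,
                               n_scans = dataset$n_scans)
    keep <- setdiff(des$names,
                    c("stop_success", "stop_failure", "intercept"))
    nuis <- cbind(stop_all = des$X[, "stop_success"] +
                    des$X[, "stop_failure"],
                  des$X[, keep, drop = FALSE])
  }
  # one whitened fit for all sinks (shared design; rho pooled over sinks)
  X <- cbind(reg, nuis, intercept = 1)
  sv <- svd(scale(X[, seq_len(3)], center = FALSE), nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e8)
    stop("PPI regressors are collinear (condition number > 1e8)")
  Y <- dataset$signal[sink_regions, , drop = FALSE]
  fit <- fit_glm(Y, X)
  idx <- seq_len(3)
  se_base <- sqrt(diag(fit$xtx_inv)[idx])
  out <- lapply(seq_along(sink_regions), function(i) {
    est <- fit$betas[i, idx]
    se <- sqrt(fit$sigma2[i]) * se_base
    t <- est / se
    p <- 2 * stats::pt(-abs(t), fit$dof)
    sign <- if (p[3] < alpha) if (est[3] > 0) "positive" else "negative"
    else "null"
    structure(list(coef = data.frame(term = c("physio", "psych", "ppi"),
                                     estimate = unname(est),
                                     se = unname(se), t = unname(t),
                                     p = unname(p), row.names = NULL),
                   sign = sign, rho = fit$rho, dof = fit$dof),
              class = "ppi_result")
  })
  names(out) <- sink_regions
  out
}
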