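#' Build the first-level design matrix
#'
#' Event regressors for StopSuccess, StopFailure and experimental Go trials
#' (response-locked impulses convolved with the canonical HRF), two
#' mean-centred parametric modulators on the experimental Go events
#' (response time in seconds and stop-signal probability as a fraction),
#' a rest-block boxcar and an outlier-trial impulse regressor (conditions
#' of no interest), a discrete-cosine high-pass basis with the configured
#' cutoff, an intercept, and optional nuisance columns. Baseline Go trials
#' are not modelled and form the implicit baseline.
#'
#' @param session a \code{session_data}.
#' @param tr repetition time (s).
#' @param n_scans number of scans.
#' @param highpass high-pass cutoff period in seconds (cosines with longer
#'   periods are included); \code{Inf} disables the basis.
#' @param nuisance optional numeric matrix of extra columns (scans x k).
#' @param outlier_flags optional per-trial logical flags; default applies
#'   the per-level 1.5 x IQR rule.
#' @return An object of class \code{design_matrix}: \code{X} (scan x
#'   regressor), \code{names}, \code{frame_times}, \code{n_dct},
#'   \code{modulator_cor} (correlation between the two modulator columns).
#' @export
build_design_matrix <- function(session, tr = 1.6, n_scans = 616,
                                highpass = 128, nuisance = NULL,
                                outlier_flags = NULL) {
  stopifnot(inherits(session, "session_data"), tr > 0, n_scans > 1)
  grid <- micro_grid(tr, n_scans)
  hrf <- canonical_hrf(grid$dt)
  ev <- session_events(session, outlier_flags)
  reg <- function(onsets, amp = rep(1, length(onsets)))
    sample_at_scans(convolve_causal(micro_impulses(onsets, amp, grid), hrf),
                    grid)
  cols <- list(
    stop_success = reg(ev$stop_success$onsets),
    stop_failure = reg(ev$stop_failure$onsets),
    go_exp       = reg(ev$go_exp$onsets),
    go_rt_mod    = reg(ev$go_exp$onsets, ev$go_exp$rt_c),
    go_pstop_mod = reg(ev$go_exp$onsets, ev$go_exp$p_c)
  )
  if (length(ev$go_outlier$onsets) > 0)
    cols$outlier <- reg(ev$go_outlier$onsets)
  if (nrow(ev$rest) > 0)
    cols$rest <- sample_at_scans(
      convolve_causal(micro_boxcar(ev$rest$onset, ev$rest$duration, grid),
                      hrf), grid)
  # no-interest events may fall entirely beyond the scan window; drop their
  # empty columns rather than failing the rank check
  for (nm in intersect(c("outlier", "rest"), names(cols)))
    if (all(cols[[nm]] == 0)) cols[[nm]] <- NULL
  X <- do.call(cbind, cols)
  nm <- names(cols)
  dct <- dct_basis(n_scans, tr, highpass)
  if (ncol(dct) > 0) {
    X <- cbind(X, dct)
    nm <- c(nm, paste0("dct", seq_len(ncol(dct))))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    X <- cbind(X, nuisance)
    nm <- c(nm, paste0("nuisance", seq_len(ncol(nuisance))))
  }
  X <- cbind(X, intercept = 1)
  nm <- c(nm, "intercept")
  colnames(X) <- nm
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- nm[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, names = nm,
                 frame_times = (seq_len(n_scans) - 1) * tr,
                 n_dct = ncol(dct),
                 modulator_cor = stats::cor(cols$go_rt_mod,
                                            cols$go_pstop_mod)),
            class = "design_matrix")
}

# discrete cosine high-pass basis: cosines with period > cutoff seconds,
# excluding the constant term
dct_basis <- function(n_scans, tr, cutoff) {
  if (!is.finite(cutoff)) return(matrix(0, n_scans, 0))
  n_fun <- max(floor(2 * n_scans * tr / cutoff), 0)
  if (n_fun == 0) return(matrix(0, n_scans, 0))
  t <- seq_len(n_scans) - 1
  sapply(seq_len(n_fun), function(k)
    sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * k / (2 * n_scans)))
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d scans x %d regressors (%d DCT)\n",
              nrow(x$X), ncol(x$X), x$n_dct))
  cat("modulator correlation:", signif(x$modulator_cor, 3), "\n")
  invisible(x)
}

#' Write a design matrix as TSV
#' @param design a \code{design_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_design_matrix <- function(design, path) {
  utils::write.table(as.data.frame(design$X), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit the first-level GLM with AR(1) prewhitening
#'
#' Two-pass fit: ordinary least squares, estimation of the AR(1)
#' coefficient from the lag-1 autocorrelation of the residuals (pooled over
#' regions), quasi-differencing of data and design by the estimated
#' coefficient, and a refit on the whitened model.
#'
#' @param Y region x scan matrix (or a single series).
#' @param design a \code{design_matrix} or a plain numeric matrix.
#' @param rho optional fixed AR(1) coefficient; default estimates it.
#' @return An object of class \code{glm_fit}: \code{betas} (region x
#'   regressor), \code{sigma2}, \code{rho}, \code{dof}, \code{xtx_inv},
#'   \code{names}, and \code{resid} (whitened residuals, region x scan).
#' @export
fit_glm <- function(Y, design, rho = NULL) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  nm <- colnames(X)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  n <- ncol(Y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (n <= p) stop("more regressors than scans")
  Yt <- t(Y)
  if (is.null(rho)) {
    res0 <- stats::lm.fit(X, Yt)$residuals
    res0 <- as.matrix(res0)
    num <- sum(res0[-1, , drop = FALSE] * res0[-n, , drop = FALSE])
    den <- sum(res0^2)
    rho <- if (den > 0) num / den else 0
    rho <- max(min(rho, 0.99), -0.99)
  }
  W <- function(M) {
    M <- as.matrix(M)
    rbind(sqrt(1 - rho^2) * M[1, , drop = FALSE],
          M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE])
  }
  Xw <- W(X); Yw <- W(Yt)
  fit <- stats::lm.fit(Xw, Yw)
  betas <- t(as.matrix(fit$coefficients))
  colnames(betas) <- nm
  rownames(betas) <- rownames(Y)
  resid <- t(as.matrix(fit$residuals))
  dof <- n - p
  sigma2 <- rowSums(resid^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(Xw)))
  structure(list(betas = betas, sigma2 = sigma2, rho = rho, dof = dof,
                 xtx_inv = xtx_inv, names = nm, resid = resid),
            class = "glm_fit")
}

#' Linear contrast of GLM parameter estimates
#'
#' @param fit a \code{glm_fit}.
#' @param weights numeric contrast vector, either full length or a named
#'   vector over a subset of regressors (others zero).
#' @return A data.frame with one row per region: estimate, se, t, p.
#' @export
glm_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  w <- contrast_vector(fit$names, weights)
  if (all(w == 0)) stop("contrast weights are all zero")
  est <- as.numeric(fit$betas %*% w)
  se <- sqrt(fit$sigma2 * as.numeric(t(w) %*% fit$xtx_inv %*% w))
  t <- est / se
  data.frame(region = rownames(fit$betas) %||% seq_along(est),
             estimate = est, se = se, t = t,
             p = 2 * stats::pt(-abs(t), fit$dof))
}

contrast_vector <- function(names, weights) {
  if (!is.null(names(weights))) {
    stopifnot(all(names(weights) %in% names))
    w <- stats::setNames(numeric(length(names)), names)
    w[names(weights)] <- weights
    as.numeric(w)
  } else {
    stopifnot(length(weights) == length(names))
    as.numeric(weights)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Second-level one-sample t-test
#'
#' Random-effects test of per-subject contrast estimates against zero.
#'
#' @param estimates numeric vector, one contrast estimate per subject.
#' @return List with \code{t}, \code{df}, two-sided \code{p}, \code{mean}.
#' @export
group_t <- function(estimates) {
  n <- length(estimates)
  stopifnot(n >= 2)
  s <- stats::sd(estimates)
  if (s == 0) stop("zero variance across subjects; t undefined")
  t <- mean(estimates) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       mean = mean(estimates))
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA for a subjects x factor A x factor B array (here
#' stop-signal probability x response-time bin). Each effect is tested
#' against its own subject-by-effect interaction. Sphericity for factor A
#' and the A x B interaction is handled by the Greenhouse-Geisser epsilon
#' applied to numerator and denominator degrees of freedom; a two-level
#' factor needs no correction.
#'
#' @param values numeric array subjects x a x b, complete (no NA).
#' @return A data.frame with one row per effect (A, B, AB): F, df1, df2,
#'   epsilon, df1_gg, df2_gg, p (GG-corrected where epsilon < 1).
#' @export
rm_anova_2way <- function(values) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  if (any(is.na(values))) stop("missing cells; complete design required")
  n <- dim(values)[1]; a <- dim(values)[2]; b <- dim(values)[3]
  stopifnot(n >= 2, a >= 2, b >= 2)
  g <- mean(values)
  m_i <- apply(values, 1, mean)
  m_j <- apply(values, 2, mean)
  m_k <- apply(values, 3, mean)
  m_ij <- apply(values, c(1, 2), mean)
  m_ik <- apply(values, c(1, 3), mean)
  m_jk <- apply(values, c(2, 3), mean)

  ss_a <- n * b * sum((m_j - g)^2)
  ss_as <- b * sum((m_ij - outer(m_i, m_j, "+") + g)^2)
  ss_b <- n * a * sum((m_k - g)^2)
  ss_bs <- a * sum((m_ik - outer(m_i, m_k, "+") + g)^2)
  ss_ab <- n * sum((m_jk - outer(m_j, m_k, "+") + g)^2)
  resid <- values
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    resid[i, j, k] <- values[i, j, k] - m_ij[i, j] - m_ik[i, k] -
      m_jk[j, k] + m_i[i] + m_j[j] + m_k[k] - g
  ss_abs <- sum(resid^2)

  eff <- function(name, ss, df1, ss_err, df2, eps) {
    f <- if (ss_err > 0) (ss / df1) / (ss_err / df2) else 0
    data.frame(effect = name, F = f, df1 = df1, df2 = df2, epsilon = eps,
               df1_gg = df1 * eps, df2_gg = df2 * eps,
               p = stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE))
  }
  # GG epsilon for A from the covariance of the subject x A means; for the
  # interaction from the covariance of the interaction-contrast space
  eps_a <- if (a > 2) gg_epsilon(m_ij) else 1
  cells <- matrix(aperm(values, c(1, 2, 3)), nrow = n)  # subjects x (a*b)
  eps_ab <- if (a > 2 || b > 2) gg_epsilon_contrast(cells, a, b) else 1
  rbind(eff("A", ss_a, a - 1, ss_as, (a - 1) * (n - 1), eps_a),
        eff("B", ss_b, b - 1, ss_bs, (b - 1) * (n - 1),
            if (b > 2) gg_epsilon(m_ik) else 1),
        eff("AB", ss_ab, (a - 1) * (b - 1), ss_abs,
            (a - 1) * (b - 1) * (n - 1), eps_ab))
}

# Greenhouse-Geisser epsilon from a subjects x levels matrix
gg_epsilon <- function(M) {
  k <- ncol(M)
  S <- stats::cov(M)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))  # orthonormal contrasts
  E <- t(C) %*% S %*% C
  lam <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  min(max(eps, 1 / (k - 1)), 1)
}

# GG epsilon on the interaction contrast space of an a x b within design
gg_epsilon_contrast <- function(cells, a, b) {
  Ca <- qr.Q(qr(stats::contr.helmert(a)))
  Cb <- qr.Q(qr(stats::contr.helmert(b)))
  # `cells` columns are ordered with factor A fastest (column j + a*(k-1)),
  # so the interaction contrasts are kron(Cb, Ca)
  C <- kronecker(Cb, Ca)
  S <- stats::cov(cells)
  E <- t(C) %*% S %*% C
  d <- (a - 1) * (b - 1)
  lam <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  eps <- sum(lam)^2 / (d * sum(lam^2))
  min(max(eps, 1 / d), 1)
}

#' Per-subject ROI cell means for the probability x RT-bin analysis
#'
#' Classifies a subject's experimental Go trials by stop-signal probability
#' level and a within-level median split on response time (fast/slow), and
#' returns the mean of a per-trial statistic per cell.
#'
#' @param session a \code{session_data}.
#' @param stat numeric per-trial values aligned with the session's trials
#'   (e.g. a trial-wise activation estimate); default uses response time.
#' @return A levels x 2 matrix (rows = p_stop levels, columns fast/slow).
#' @export
pstop_rtbin_cells <- function(session, stat = NULL) {
  tr <- session$trials
  flags <- session_outlier_flags(tr)
  go <- tr$trial_type == "go" & tr$p_stop > 0 & !flags & !is.na(tr$rt)
  if (is.null(stat)) stat <- tr$rt
  lv <- sort(unique(tr$p_stop[go]))
  out <- matrix(NA_real_, length(lv), 2,
                dimnames = list(paste0(round(100 * lv), "%"),
                                c("fast", "slow")))
  for (i in seq_along(lv)) {
    sel <- which(go & tr$p_stop == lv[i])
    med <- stats::median(tr$rt[sel])
    fast <- sel[tr$rt[sel] <= med]
    slow <- sel[tr$rt[sel] > med]
    out[i, 1] <- mean(stat[fast])
    out[i, 2] <- mean(stat[slow])
  }
  out
}
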