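#' Flag response-time outliers by the 1.5 x IQR rule
#'
#' A response time is an outlier when it lies more than 1.5 times the
#' interquartile range below the 25th or above the 75th percentile of its
#' stop-signal probability level's RT distribution. Quantiles use linear
#' interpolation between order statistics (the default sample-quantile
#' convention).
#'
#' @param rts numeric response times (ms) of one level; NAs are never
#'   flagged.
#' @return Logical vector of the same length, TRUE where flagged.
#' @examples
#' flag_outliers(c(790, 795, 800, 805, 810, 2000))
#' @export
flag_outliers <- function(rts) {
  ok <- !is.na(rts)
  flags <- rep(FALSE, length(rts))
  if (sum(ok) == 0) return(flags)
  if (sum(ok) < 4) {
    warning("fewer than 4 response times; no outliers flagged")
    return(flags)
  }
  q <- stats::quantile(rts[ok], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  flags[ok] <- rts[ok] < q[1] - 1.5 * iqr | rts[ok] > q[2] + 1.5 * iqr
  flags
}

# add per-level outlier flags for Go trials (Stop trials never flagged)
session_outlier_flags <- function(trials) {
  flags <- rep(FALSE, nrow(trials))
  for (lvl in unique(trials$level)) {
    sel <- trials$level == lvl & trials$trial_type == "go"
    if (any(sel)) flags[sel] <- suppressWarnings(flag_outliers(trials$rt[sel]))
  }
  flags
}

#' Per-level behavioural summary of one session
#'
#' Mean Go response time with a t-based 95 percent confidence interval and
#' Stop accuracy, per stop-signal probability level, after excluding
#' outlying Go response times. Also reports the pooled-session SSRT (see
#' \code{\link{ssrt_integration}}) and the mean StopFailure response time.
#'
#' @param session a \code{session_data}.
#' @param conf confidence level for the RT interval.
#' @return A list of class \code{behavioral_summary} with a per-level
#'   data.frame \code{levels} (columns level, p_stop, n_go, mean_rt,
#'   ci_lo, ci_hi, n_stop, accuracy), plus \code{ssrt},
#'   \code{mean_stopfail_rt} and \code{n_outliers}.
#' @export
rt_summary <- function(session, conf = 0.95) {
  stopifnot(inherits(session, "session_data"))
  tr <- session$trials
  flags <- session_outlier_flags(tr)
  lv <- session$sequence$config$levels
  rows <- lapply(seq_len(nrow(lv)), function(i) {
    lvl <- lv$label[i]
    go <- tr$trial_type == "go" & tr$level == lvl & !flags & !is.na(tr$rt)
    st <- tr$trial_type == "stop" & tr$level == lvl
    n_go <- sum(go)
    if (n_go == 0 && sum(st) == 0) return(NULL)
    m <- if (n_go > 0) mean(tr$rt[go]) else NA_real_
    half <- if (n_go > 1 && stats::sd(tr$rt[go]) > 0)
      stats::qt(1 - (1 - conf) / 2, n_go - 1) * stats::sd(tr$rt[go]) / sqrt(n_go)
    else 0
    acc <- if (sum(st) > 0) mean(tr$outcome[st] == "StopSuccess") else NA_real_
    data.frame(level = lvl, p_stop = lv$p_stop[i], n_go = n_go, mean_rt = m,
               ci_lo = m - half, ci_hi = m + half, n_stop = sum(st),
               accuracy = acc)
  })
  sf <- tr$outcome == "StopFailure" & !is.na(tr$rt)
  ssrt <- tryCatch(ssrt_integration(session), error = function(e) NA_real_)
  structure(list(levels = do.call(rbind, rows),
                 ssrt = ssrt,
                 mean_stopfail_rt = if (any(sf)) mean(tr$rt[sf]) else NA_real_,
                 n_outliers = sum(flags)),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  print(x$levels, row.names = FALSE)
  cat(sprintf("SSRT %.1f ms | StopFailure RT %.1f ms | %d RT outliers\n",
              x$ssrt, x$mean_stopfail_rt, x$n_outliers))
  invisible(x)
}

#' SSRT by the integration method
#'
#' Pools all stop-signal probability levels above zero. The response rate on
#' Stop trials, p(respond), indexes the Go RT distribution: the SSRT is the
#' ceiling(p * n)-th fastest Go response time (outliers excluded) minus the
#' mean stop-signal onset time over all Stop trials.
#'
#' @param session a \code{session_data}, or a list with elements
#'   \code{go_rts} (numeric, Go RTs at levels with p_stop > 0, outliers
#'   already excluded), \code{n_stop}, \code{n_respond} and \code{ssds}.
#' @return SSRT in ms.
#' @examples
#' ssrt_integration(list(go_rts = seq(700, 880, by = 20), n_stop = 4,
#'                       n_respond = 2, ssds = c(500, 525, 550, 575)))
#' @export
ssrt_integration <- function(session) {
  if (inherits(session, "session_data")) {
    tr <- session$trials
    flags <- session_outlier_flags(tr)
    go <- tr$trial_type == "go" & tr$p_stop > 0 & !flags & !is.na(tr$rt)
    st <- tr$trial_type == "stop"
    x <- list(go_rts = tr$rt[go], n_stop = sum(st),
              n_respond = sum(tr$outcome[st] == "StopFailure"),
              ssds = tr$ssd[st])
  } else x <- session
  if (x$n_stop < 1) stop("no Stop trials; SSRT undefined")
  if (length(x$go_rts) < 10)
    stop("need at least 10 Go response times at levels with p_stop > 0")
  p_respond <- x$n_respond / x$n_stop
  if (p_respond <= 0 || p_respond >= 1)
    stop("p(respond) = ", p_respond,
         "; the integration method is undefined when stopping always ",
         if (p_respond <= 0) "succeeds" else "fails")
  srt <- sort(x$go_rts)
  k <- ceiling(p_respond * length(srt))
  srt[k] - mean(x$ssds)
}

#' ZRFT-normalised inhibition function with cumulative Weibull fit
#'
#' Bins Stop trials by stop-signal onset time and computes, per bin, the
#' proportion of successfully stopped responses and the Z-transformed
#' relative finishing time ZRFT = (mean Go RT - SSD - SSRT) / SD(Go RT)
#' (Go statistics over levels with p_stop > 0, outliers excluded; positive
#' ZRFT = early stop-signal onset). Sessions may be pooled; each session
#' contributes points normalised by its own Go statistics and SSRT. A
#' cumulative Weibull
#' \deqn{W(z) = \gamma - (\gamma - \delta) \exp(-((z - z_0)/\alpha)^\beta)}
#' is fit to the pooled (zrft, success) points by bounded least squares,
#' with the shift z0 fixed at the smallest observed ZRFT so the curve is
#' defined over the whole data range.
#'
#' @param sessions a \code{session_data} or list of them.
#' @param n_bins number of SSD bins per session (quantile-spaced; bins with
#'   identical SSD collapse).
#' @return A list of class \code{inhibition_function}: \code{points}
#'   (data.frame ssd, zrft, p_stop_success, n per bin) and \code{weibull}
#'   (named vector alpha, beta, gamma, delta, z0, r2), NULL when fewer than
#'   3 distinct bins.
#' @export
inhibition_function <- function(sessions, n_bins = 6) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  pts <- lapply(sessions, function(ses) {
    tr <- ses$trials
    flags <- session_outlier_flags(tr)
    go <- tr$trial_type == "go" & tr$p_stop > 0 & !flags & !is.na(tr$rt)
    st <- which(tr$trial_type == "stop")
    if (length(st) == 0 || sum(go) < 2) return(NULL)
    mu <- mean(tr$rt[go]); sdev <- stats::sd(tr$rt[go])
    ssrt <- tryCatch(ssrt_integration(ses), error = function(e) return(NULL))
    if (is.null(ssrt) || sdev == 0) return(NULL)
    ssd <- tr$ssd[st]
    succ <- tr$outcome[st] == "StopSuccess"
    br <- unique(stats::quantile(ssd, probs = seq(0, 1, length.out = n_bins + 1),
                                 type = 7, names = FALSE))
    bin <- if (length(br) > 2)
      cut(ssd, breaks = br, include.lowest = TRUE) else factor(rep(1, length(ssd)))
    centers <- tapply(ssd, bin, mean)
    data.frame(ssd = as.numeric(centers),
               zrft = (mu - as.numeric(centers) - ssrt) / sdev,
               p_stop_success = as.numeric(tapply(succ, bin, mean)),
               n = as.numeric(tapply(succ, bin, length)))
  })
  points <- do.call(rbind, pts)
  points <- points[!is.na(points$ssd), , drop = FALSE]
  out <- list(points = points, weibull = NULL, group_points = NULL)
  if (!is.null(points) && length(unique(round(points$zrft, 6))) >= 3) {
    # the Weibull is fit to the group-mean inhibition function: pooled
    # session points aggregated into ZRFT bins (weighted by trial count)
    gp <- if (length(sessions) > 1) {
      br <- unique(stats::quantile(points$zrft,
                                   probs = seq(0, 1, length.out = 11),
                                   type = 7, names = FALSE))
      bin <- cut(points$zrft, breaks = br, include.lowest = TRUE)
      agg <- data.frame(
        zrft = as.numeric(tapply(points$zrft * points$n, bin, sum) /
                            tapply(points$n, bin, sum)),
        p_stop_success = as.numeric(
          tapply(points$p_stop_success * points$n, bin, sum) /
            tapply(points$n, bin, sum)),
        n = as.numeric(tapply(points$n, bin, sum)))
      agg[!is.na(agg$zrft), , drop = FALSE]
    } else points
    out$group_points <- gp
    if (length(unique(round(gp$zrft, 6))) >= 3)
      out$weibull <- fit_weibull_inhibition(gp$zrft, gp$p_stop_success,
                                            gp$n)
  }
  structure(out, class = "inhibition_function")
}

# Bounded least-squares fit of the cumulative Weibull on shifted ZRFT.
fit_weibull_inhibition <- function(z, p, w = rep(1, length(p))) {
  z0 <- min(z)
  sse <- function(par) {
    pred <- par[3] - (par[3] - par[4]) * exp(-(pmax(z - z0, 0) / par[1])^par[2])
    sum(w * (p - pred)^2)
  }
  fit <- stats::optim(c(alpha = 1, beta = 2, gamma = 1, delta = 0), sse,
                      method = "L-BFGS-B",
                      lower = c(1e-3, 1e-3, 0.5, 0),
                      upper = c(50, 20, 1, 0.5))
  par <- fit$par
  sst <- sum(w * (p - stats::weighted.mean(p, w))^2)
  r2 <- if (sst > 0) 1 - fit$value / sst else NA_real_
  c(par, z0 = z0, r2 = r2)
}

#' Evaluate a fitted inhibition-function Weibull
#'
#' @param weibull named vector from \code{\link{inhibition_function}}.
#' @param z ZRFT values.
#' @return Predicted stop-success proportions.
#' @export
weibull_inhibition <- function(weibull, z) {
  weibull["gamma"] - (weibull["gamma"] - weibull["delta"]) *
    exp(-(pmax(z - weibull["z0"], 0) / weibull["alpha"])^weibull["beta"])
}

#' Linear-contrast test across ordered levels
#'
#' Per-subject contrast scores s_i = sum_j w_j m_ij with centred linear
#' weights; the test statistic is F(1, n-1) = n * mean(s)^2 / var(s), the
#' square of the one-sample t on the scores.
#'
#' @param level_means numeric matrix, subjects x ordered levels.
#' @param weights contrast weights; default centred linear weights for the
#'   number of columns (e.g. -3,-1,1,3 for four levels).
#' @return List with \code{F}, \code{df} = c(1, n-1) and two-sided \code{p}.
#' @export
linear_contrast <- function(level_means, weights = NULL) {
  level_means <- as.matrix(level_means)
  n <- nrow(level_means); k <- ncol(level_means)
  stopifnot(n >= 2, k >= 2)
  if (is.null(weights)) weights <- 2 * (seq_len(k) - (k + 1) / 2)
  stopifnot(length(weights) == k)
  s <- as.numeric(level_means %*% weights)
  v <- stats::var(s)
  if (v == 0) {
    if (mean(s) == 0) return(list(F = 0, df = c(1, n - 1), p = 1))
    warning("zero variance of contrast scores with non-zero mean")
    return(list(F = Inf, df = c(1, n - 1), p = 0))
  }
  f <- n * mean(s)^2 / v
  list(F = f, df = c(1, n - 1), p = stats::pf(f, 1, n - 1, lower.tail = FALSE))
}

#' Paired t-test on per-subject values
#'
#' @param x,y equal-length numeric vectors of per-subject values.
#' @return List with \code{t}, \code{df} and two-sided \code{p}.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- y - x
  if (stats::sd(d) == 0)
    stop("zero-variance differences; paired t undefined")
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}
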