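#' Task configuration for the stop-signal anticipation task
#'
#' Builds the parameter set that defines one session of the stop-signal
#' anticipation task: the cued stop-signal probability levels with their
#' per-level Go and Stop trial counts, the block structure, trial timing,
#' rest blocks, and the staircase settings used to adapt the stop-signal
#' onset time (SSD).
#'
#' The default configuration reproduces the published task: five probability
#' levels (0/17/20/25/33 percent), 234 baseline Go trials, 180 experimental
#' Go trials, 60 Stop trials, blocks of 12-15 trials, a 1000 ms intertrial
#' interval, a bar that reaches the target line in 800 ms and completes its
#' travel in 1000 ms (so the trial pitch is 2 s), and two 24 s rest blocks at
#' one third and two thirds of the task.
#'
#' @param levels data.frame with columns \code{label}, \code{n_go},
#'   \code{n_stop}. Stop-signal probabilities are implied by the counts.
#' @param block_size_range integer length-2, minimum and maximum trials per
#'   block.
#' @param target_rt Target response time in ms (bar reaches the target line).
#' @param bar_travel_total Total bar travel time in ms; together with
#'   \code{iti} this sets the trial pitch.
#' @param iti Intertrial interval in ms.
#' @param rest_blocks data.frame with columns \code{position} (fraction of
#'   total trials after which the rest is inserted) and \code{duration}
#'   (seconds). Use a zero-row data.frame for no rest blocks.
#' @param staircase_step Staircase step size in ms.
#' @param ssd_init Initial stop-signal onset time in ms, shared by all
#'   levels.
#' @param ssd_bounds length-2 numeric, allowed SSD range in ms.
#' @return An object of class \code{task_config}.
#' @examples
#' cfg <- task_config()
#' scheduled_duration(cfg)  # 996 s
#' @export
task_config <- function(levels = NULL,
                        block_size_range = c(12L, 15L),
                        target_rt = 800,
                        bar_travel_total = 1000,
                        iti = 1000,
                        rest_blocks = data.frame(position = c(1 / 3, 2 / 3),
                                                 duration = c(24, 24)),
                        staircase_step = 25,
                        ssd_init = 550,
                        ssd_bounds = c(50, 775)) {
  if (is.null(levels)) {
    levels <- data.frame(
      label  = c("green", "yellow", "amber", "orange", "red"),
      n_go   = c(234L, 30L, 48L, 54L, 48L),
      n_stop = c(0L, 6L, 12L, 18L, 24L)
    )
  }
  stopifnot(is.data.frame(levels),
            all(c("label", "n_go", "n_stop") %in% names(levels)))
  if (any(levels$n_go < 0) || any(levels$n_stop < 0))
    stop("trial counts must be non-negative")
  # an explicit p_stop column is honoured (and later validated against the
  # counts); otherwise probabilities are implied by the counts
  if (is.null(levels$p_stop))
    levels$p_stop <- ifelse(levels$n_go + levels$n_stop > 0,
                            levels$n_stop / (levels$n_go + levels$n_stop), 0)
  if (any(levels$p_stop >= 1))
    stop("stop-signal probability must be < 1 for every level (level ",
         levels$label[which(levels$p_stop >= 1)[1]], ")")
  if (length(block_size_range) != 2 || block_size_range[1] < 1 ||
      block_size_range[1] > block_size_range[2])
    stop("block_size_range must be (min, max) with 1 <= min <= max")
  if (staircase_step <= 0) stop("staircase_step must be > 0")
  if (ssd_init < ssd_bounds[1] || ssd_init > ssd_bounds[2])
    stop("ssd_init must lie within ssd_bounds")
  if (nrow(rest_blocks) > 0)
    stopifnot(all(rest_blocks$position > 0 & rest_blocks$position < 1),
              all(rest_blocks$duration >= 0))
  structure(list(levels = levels,
                 block_size_range = as.integer(block_size_range),
                 target_rt = target_rt,
                 bar_travel_total = bar_travel_total,
                 iti = iti,
                 rest_blocks = rest_blocks,
                 staircase_step = staircase_step,
                 ssd_init = ssd_init,
                 ssd_bounds = ssd_bounds),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Stop-signal anticipation task configuration\n")
  lv <- x$levels
  lv$p_pct <- round(100 * lv$p_stop)
  print(lv, row.names = FALSE)
  cat(sprintf("blocks %d-%d trials | pitch %g ms | target RT %g ms\n",
              x$block_size_range[1], x$block_size_range[2],
              x$bar_travel_total + x$iti, x$target_rt))
  cat(sprintf("SSD init %g ms, step %g ms, bounds [%g, %g] ms\n",
              x$ssd_init, x$staircase_step, x$ssd_bounds[1], x$ssd_bounds[2]))
  invisible(x)
}

#' Stop-signal probability implied by trial counts
#'
#' The probability label shown to participants is the per-level Stop trial
#' fraction, rounded to the nearest integer percent.
#'
#' @param n_go number of Go trials at the level.
#' @param n_stop number of Stop trials at the level.
#' @return Integer percent, \code{100 * n_stop / (n_go + n_stop)} rounded.
#' @examples
#' implied_stop_probability(30, 6)   # 17
#' implied_stop_probability(54, 18)  # 25
#' @export
implied_stop_probability <- function(n_go, n_stop) {
  if (n_go < 0 || n_stop < 0) stop("counts must be non-negative")
  if (n_go + n_stop == 0) stop("n_go + n_stop must be > 0")
  as.integer(round(100 * n_stop / (n_go + n_stop)))
}

#' Scheduled session duration
#'
#' Total scheduled duration in seconds: every trial occupies the bar travel
#' time plus the intertrial interval, and each rest block adds its duration.
#'
#' @param config a \code{task_config}.
#' @return Duration in seconds.
#' @export
scheduled_duration <- function(config) {
  stopifnot(inherits(config, "task_config"))
  n <- sum(config$levels$n_go) + sum(config$levels$n_stop)
  rest <- if (nrow(config$rest_blocks) > 0) sum(config$rest_blocks$duration) else 0
  n * (config$bar_travel_total + config$iti) / 1000 + rest
}

# Partition `total` into `k` integer parts within [lo, hi], uniformly over the
# slack units. Assumes feasibility.
partition_blocks <- function(total, k, lo, hi) {
  extra <- total - k * lo
  slack <- rep(seq_len(k), each = hi - lo)
  picked <- sample(slack, extra)
  lo + tabulate(picked, nbins = k)
}

# Arrange the trials of one experimental block so that the block opens with a
# Go trial and never shows more than two consecutive Stop trials.
arrange_block <- function(types, levels_id, max_tries = 2000L) {
  n <- length(types)
  for (i in seq_len(max_tries)) {
    ord <- sample.int(n)
    ty <- types[ord]
    if (ty[1] == "stop") next
    r <- rle(ty)
    if (any(r$values == "stop" & r$lengths > 2)) next
    return(list(types = ty, levels_id = levels_id[ord]))
  }
  stop("could not arrange block under the Stop-trial spacing constraints")
}

#' Build a pseudorandomised trial sequence
#'
#' Generates one session of the stop-signal anticipation task: baseline
#' blocks (0 percent level, Go only) alternate with experimental blocks
#' (levels with stop-signal probability > 0), block sizes are drawn uniformly
#' within the configured range, Stop trials are pseudorandomly interspersed
#' (each experimental block opens with a Go trial and never contains more
#' than two consecutive Stop trials), and rest blocks are inserted after the
#' blocks closest to the configured positions. Onsets advance by the trial
#' pitch, plus the rest duration where a rest intervenes.
#'
#' Candidate sequences are screened on the correlation structure of the
#' eventual GLM regressors: a draw is rejected and redrawn (deterministically
#' from the seed) if the HRF-convolved condition regressors and the centred
#' stop-signal probability modulator correlate too strongly.
#'
#' @param config a \code{task_config}.
#' @param seed integer seed; the sequence is reproducible per (config, seed).
#' @param max_modulator_cor screen threshold for the absolute correlation
#'   between the stop-signal probability modulator and each convolved
#'   condition regressor; set to \code{Inf} to disable the screen.
#' @param max_attempts redraw budget for the screen.
#' @return An object of class \code{trial_sequence}: a list with the
#'   \code{config}, the \code{seed}, and \code{trials}, a data.frame with
#'   columns \code{index}, \code{block_id}, \code{block_type},
#'   \code{trial_type}, \code{level}, \code{p_stop}, \code{onset} (s).
#' @examples
#' seq1 <- build_trial_sequence(task_config(), seed = 7)
#' table(seq1$trials$trial_type)
#' @export
build_trial_sequence <- function(config, seed,
                                 max_modulator_cor = 0.4,
                                 max_attempts = 25L) {
  stopifnot(inherits(config, "task_config"))
  lv <- config$levels
  # counts must be consistent with the implied probability of each level
  for (i in seq_len(nrow(lv))) {
    p <- lv$p_stop[i]
    if (p > 0) {
      expected_go <- lv$n_stop[i] * (1 - p) / p
      if (abs(expected_go - lv$n_go[i]) > 0.5)
        stop("level ", lv$label[i], ": n_go = ", lv$n_go[i],
             " inconsistent with n_stop = ", lv$n_stop[i],
             " at p_stop = ", signif(p, 3))
    }
  }
  for (attempt in seq_len(max_attempts)) {
    sub_seed <- (as.integer(seed) + 104729L * (attempt - 1L)) %% .Machine$integer.max
    seqn <- withr::with_seed(sub_seed, draw_trial_sequence(config))
    seqn$seed <- seed
    if (!is.finite(max_modulator_cor)) return(seqn)
    if (max(modulator_condition_cor(seqn)) < max_modulator_cor) return(seqn)
  }
  warning("no sequence passed the regressor-correlation screen in ",
          max_attempts, " attempts; returning the last draw")
  seqn
}

# One unscreened draw; assumes the RNG is already seeded.
draw_trial_sequence <- function(config) {
  lv <- config$levels
  lo <- config$block_size_range[1]
  hi <- config$block_size_range[2]
  base_idx <- which(lv$p_stop == 0)
  exp_idx <- which(lv$p_stop > 0)
  n_base <- sum(lv$n_go[base_idx])
  n_exp <- sum(lv$n_go[exp_idx]) + sum(lv$n_stop[exp_idx])

  feas <- function(N) {
    if (N == 0 || ceiling(N / hi) > floor(N / lo)) return(integer(0))
    seq.int(ceiling(N / hi), floor(N / lo))
  }
  kb_all <- feas(n_base); ke_all <- feas(n_exp)
  if (n_base > 0 && length(kb_all) == 0 || n_exp > 0 && length(ke_all) == 0)
    stop("trial totals cannot be partitioned into blocks of ", lo, "-", hi)

  if (n_base == 0 || n_exp == 0) {
    k <- if (n_base > 0) sample(rep(kb_all, 2), 1) else sample(rep(ke_all, 2), 1)
    sizes <- partition_blocks(max(n_base, n_exp), k, lo, hi)
    block_type <- rep(if (n_base > 0) "baseline" else "experimental", k)
  } else {
    # alternate baseline/experimental blocks; the more numerous type (by at
    # most one block) opens the session
    pairs <- expand.grid(kb = kb_all, ke = ke_all)
    strict <- pairs[abs(pairs$kb - pairs$ke) <= 1, , drop = FALSE]
    if (nrow(strict) > 0) {
      # strict alternation; the more numerous type opens the session
      pick <- strict[sample.int(nrow(strict), 1), ]
      k <- pick$kb + pick$ke
      first <- if (pick$kb >= pick$ke) "baseline" else "experimental"
      second <- setdiff(c("baseline", "experimental"), first)
      block_type <- character(k)
      block_type[seq(1, k, by = 2)] <- first
      block_type[seq(2, k, by = 2)] <- second
    } else {
      # counts too asymmetric for strict alternation: spread the rarer
      # block type evenly among the other
      pick <- pairs[sample.int(nrow(pairs), 1), ]
      k <- pick$kb + pick$ke
      rare <- if (pick$kb < pick$ke) "baseline" else "experimental"
      n_rare <- min(pick$kb, pick$ke)
      block_type <- rep(setdiff(c("baseline", "experimental"), rare), k)
      at <- unique(round(seq(1, k, length.out = n_rare + 2)))[2:(n_rare + 1)]
      block_type[at] <- rare
    }
    sizes_b <- partition_blocks(n_base, pick$kb, lo, hi)
    sizes_e <- partition_blocks(n_exp, pick$ke, lo, hi)
    sizes <- integer(k)
    sizes[block_type == "baseline"] <- sizes_b
    sizes[block_type == "experimental"] <- sizes_e
  }

  # experimental trial pool: per-level Go and Stop labels; redraw the pool
  # split if a block happens to receive too many Stop trials for the
  # spacing constraints
  pool_type0 <- c(rep("go", sum(lv$n_go[exp_idx])), rep("stop", sum(lv$n_stop[exp_idx])))
  pool_lvl0 <- c(rep(exp_idx, lv$n_go[exp_idx]), rep(exp_idx, lv$n_stop[exp_idx]))
  for (try in 1:100) {
    ord <- sample.int(length(pool_type0))
    pool_type <- pool_type0[ord]; pool_lvl <- pool_lvl0[ord]
    trial_type <- character(0); level_id <- integer(0); block_id <- integer(0)
    pos <- 1L
    ok <- TRUE
    for (b in seq_len(length(sizes))) {
      nb <- sizes[b]
      if (block_type[b] == "baseline") {
        bi <- sample(rep(base_idx, n_base), nb)  # level mix if several baselines
        trial_type <- c(trial_type, rep("go", nb))
        level_id <- c(level_id, bi)
      } else {
        sel <- seq.int(pos, pos + nb - 1L)
        arr <- tryCatch(arrange_block(pool_type[sel], pool_lvl[sel]),
                        error = function(e) NULL)
        if (is.null(arr)) { ok <- FALSE; break }
        trial_type <- c(trial_type, arr$types)
        level_id <- c(level_id, arr$levels_id)
        pos <- pos + nb
      }
      block_id <- c(block_id, rep(b, nb))
    }
    if (ok) break
  }
  if (!ok) stop("could not arrange the Stop trials under the spacing constraints")

  n_total <- length(trial_type)
  pitch <- (config$bar_travel_total + config$iti) / 1000
  onset <- (seq_len(n_total) - 1L) * pitch
  # rest blocks after the block boundary nearest each configured position
  rest_after <- integer(0)
  if (nrow(config$rest_blocks) > 0 && n_total > 0) {
    cum <- cumsum(sizes)
    for (r in seq_len(nrow(config$rest_blocks))) {
      targ <- config$rest_blocks$position[r] * n_total
      after <- cum[which.min(abs(cum - targ))]
      rest_after[r] <- after
      if (after < n_total)
        onset[(after + 1L):n_total] <- onset[(after + 1L):n_total] +
          config$rest_blocks$duration[r]
    }
  }
  rests <- if (length(rest_after) > 0)
    data.frame(onset = onset[rest_after] + pitch,
               duration = config$rest_blocks$duration)
  else data.frame(onset = numeric(0), duration = numeric(0))

  trials <- data.frame(index = seq_len(n_total),
                       block_id = block_id,
                       block_type = block_type[block_id],
                       trial_type = trial_type,
                       level = lv$label[level_id],
                       p_stop = lv$p_stop[level_id],
                       onset = onset)
  structure(list(config = config, trials = trials, rests = rests,
                 seed = NA_integer_),
            class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("trial_sequence: %d trials, %d blocks, seed %s\n",
              nrow(x$trials), max(x$trials$block_id), format(x$seed)))
  print(table(level = x$trials$level, type = x$trials$trial_type))
  invisible(x)
}

# Correlation screen used by build_trial_sequence: HRF-convolved stop and
# experimental-Go condition regressors against the centred p_stop modulator.
modulator_condition_cor <- function(sequence, tr = 1.6) {
  tr_df <- sequence$trials
  dur <- scheduled_duration(sequence$config)
  n_scans <- ceiling(dur / tr)
  go <- tr_df[tr_df$trial_type == "go" & tr_df$p_stop > 0, ]
  st <- tr_df[tr_df$trial_type == "stop", ]
  if (nrow(go) < 2 || nrow(st) < 1) return(0)
  r_go <- event_regressor(go$onset, rep(1, nrow(go)), tr, n_scans)
  r_st <- event_regressor(st$onset, rep(1, nrow(st)), tr, n_scans)
  pmod <- go$p_stop - mean(go$p_stop)
  r_pm <- event_regressor(go$onset, pmod, tr, n_scans)
  abs(c(stats::cor(r_pm, r_go), stats::cor(r_pm, r_st)))
}

#' Write / read an events table
#'
#' Serialises a trial sequence as a tab-separated events table (one row per
#' trial, \code{onset} and \code{duration} in seconds, dot decimal
#' separator), the layout used for task-fMRI event files.
#'
#' @param sequence a \code{trial_sequence}.
#' @param path output file path.
#' @return \code{write_events} returns \code{path} invisibly;
#'   \code{read_events} returns the events data.frame.
#' @export
write_events <- function(sequence, path) {
  stopifnot(inherits(sequence, "trial_sequence"))
  tr <- sequence$trials
  ev <- data.frame(onset = tr$onset,
                   duration = sequence$config$bar_travel_total / 1000,
                   trial_type = tr$trial_type,
                   level = tr$level,
                   p_stop = tr$p_stop,
                   block_id = tr$block_id)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
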