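#' Per-level 1-up-1-down staircase on the stop-signal onset time
#'
#' Each stop-signal probability level tracks its own stop-signal onset time
#' (SSD). After a successful Stop trial the SSD moves one step towards the
#' target response time (stopping gets harder); after a failed Stop trial it
#' moves one step away. The walk is clamped to the configured bounds, so the
#' SSD always equals \code{ssd_init + k * step} for some integer k within
#' bounds. With a stationary race this rule converges on the SSD at which
#' stopping succeeds about half the time.
#'
#' @param level cue level identifier (label or index).
#' @param ssd_init initial SSD in ms.
#' @param step step size in ms (> 0).
#' @param bounds length-2 numeric, allowed SSD range in ms.
#' @return An object of class \code{staircase_state} with fields
#'   \code{level}, \code{ssd}, \code{step}, \code{bounds} and a
#'   \code{history} data.frame of (ssd, outcome) pairs.
#' @examples
#' st <- staircase_init("red")
#' st <- next_ssd(st, stop_success = TRUE)   # 550 -> 575
#' st <- next_ssd(st, stop_success = FALSE)  # 575 -> 550
#' @export
staircase_init <- function(level, ssd_init = 550, step = 25,
                           bounds = c(50, 775)) {
  stopifnot(step > 0, length(bounds) == 2, bounds[1] <= bounds[2],
            ssd_init >= bounds[1], ssd_init <= bounds[2])
  structure(list(level = level, ssd = ssd_init, step = step, bounds = bounds,
                 history = data.frame(ssd = numeric(0), success = logical(0))),
            class = "staircase_state")
}

#' @param state a \code{staircase_state}.
#' @param stop_success logical, outcome of the Stop trial just run at
#'   \code{state$ssd}.
#' @rdname staircase_init
#' @export
next_ssd <- function(state, stop_success) {
  stopifnot(inherits(state, "staircase_state"), is.logical(stop_success),
            length(stop_success) == 1, !is.na(stop_success))
  state$history <- rbind(state$history,
                         data.frame(ssd = state$ssd, success = stop_success))
  delta <- if (stop_success) state$step else -state$step
  state$ssd <- min(max(state$ssd + delta, state$bounds[1]), state$bounds[2])
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("staircase [%s]: ssd = %g ms (step %g, bounds [%g, %g], %d trials)\n",
              format(x$level), x$ssd, x$step, x$bounds[1], x$bounds[2],
              nrow(x$history)))
  invisible(x)
}

#' Export staircase trajectories
#'
#' Writes the per-level SSD trajectories of a simulated session as a
#' tab-separated table (trial order within level, level, ssd, outcome).
#'
#' @param session a \code{session_data} object from
#'   \code{\link{simulate_session}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_staircase <- function(session, path) {
  stopifnot(inherits(session, "session_data"))
  st <- session$trials[session$trials$trial_type == "stop", ]
  out <- data.frame(index = st$index, level = st$level, ssd = st$ssd,
                    outcome = st$outcome)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
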