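#' Infusion dose schedules
#'
#' A dose schedule is a list of non-overlapping infusion windows. During a
#' window the forcing function `vM(t)` equals the window's rate
#' (concentration per week); outside every window it is 0. Window
#' membership uses the half-open convention `[start, start + duration)` so
#' adjacent windows never double-count a boundary instant.
#'
#' @param starts numeric vector of window start times (weeks, sorted or
#'   sortable, non-negative).
#' @param duration infusion duration (weeks, > 0), shared by all windows.
#' @param rate infusion rate during a window (concentration per week).
#' @return An object of class `dose_schedule`: a list with `starts`,
#'   `duration` and `rate`.
#' @seealso [infliximab_schedule()], [infusion_rate()]
#' @export
dose_schedule <- function(starts, duration, rate) {
  starts <- sort(as.numeric(starts))
  if (length(starts) == 0) stop("schedule needs at least one window",
                                call. = FALSE)
  if (any(starts < 0)) stop("window start times must be >= 0", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (!is.numeric(rate) || rate < 0)
    stop("rate must be >= 0", call. = FALSE)
  if (length(starts) > 1) {
    gap <- min(diff(starts))
    if (duration >= gap)
      stop("infusion duration (", duration,
           ") must be shorter than the smallest inter-dose gap (", gap, ")",
           call. = FALSE)
  }
  structure(list(starts = starts, duration = duration, rate = rate),
            class = "dose_schedule")
}

#' Infliximab-style induction/maintenance schedule
#'
#' Generates the standard biologic dosing pattern: induction infusions at
#' weeks 0, 2, 4 and 8, followed by maintenance infusions every 8 weeks, up
#' to the treatment horizon. For a 50-week horizon the window start times
#' are 0, 2, 4, 8, 16, 24, 32, 40 and 48 weeks.
#'
#' The infusion itself is short: by default 1 day (1/7 week) at a rate such
#' that `rate * duration` equals the total dose per infusion. Neither the
#' infusion length nor the dose magnitude is a property of the regimen name;
#' both are knobs.
#'
#' @param horizon treatment horizon (weeks, > 0).
#' @param dose_total total drug amount delivered per infusion
#'   (concentration units); the window rate is `dose_total / duration`.
#' @param duration infusion duration (weeks); default 1/7 (one day).
#' @param induction_times induction window starts (weeks).
#' @param maintenance_interval spacing of maintenance windows after the
#'   last induction dose (weeks).
#' @return A [dose_schedule()].
#' @export
#' @examples
#' s <- infliximab_schedule(horizon = 50)
#' s$starts  # 0 2 4 8 16 24 32 40 48
infliximab_schedule <- function(horizon, dose_total = 2, duration = 1 / 7,
                                induction_times = c(0, 2, 4, 8),
                                maintenance_interval = 8) {
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be > 0", call. = FALSE)
  starts <- induction_times
  last <- max(induction_times)
  repeat {
    nxt <- last + maintenance_interval
    if (nxt > horizon) break
    starts <- c(starts, nxt)
    last <- nxt
  }
  starts <- starts[starts <= horizon]
  dose_schedule(starts, duration = duration, rate = dose_total / duration)
}

#' Infusion forcing function vM(t)
#'
#' Evaluates the piecewise-constant infusion rate at time(s) `t`: the
#' schedule's rate if `t` falls inside an infusion window
#' `[start, start + duration)`, else 0.
#'
#' @param t time or vector of times (weeks, >= 0).
#' @param schedule a [dose_schedule()].
#' @return numeric vector of infusion rates (concentration per week).
#' @export
infusion_rate <- function(t, schedule) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  for (s in schedule$starts)
    out[t >= s & t < s + schedule$duration] <- schedule$rate
  out
}

# All discontinuity times of vM(t) within [0, horizon]; the integrator is
# restarted at each so the piecewise-constant forcing is never smoothed.
schedule_breakpoints <- function(schedule, horizon) {
  b <- sort(unique(c(schedule$starts, schedule$starts + schedule$duration)))
  b[b > 0 & b < horizon]
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat("Dose schedule:", length(x$starts), "infusion windows\n")
  cat("  starts (weeks):", paste(x$starts, collapse = ", "), "\n")
  cat(sprintf("  duration %.4g weeks at rate %.4g per week (dose %.4g per window)\n",
              x$duration, x$rate, x$rate * x$duration))
  invisible(x)
}
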