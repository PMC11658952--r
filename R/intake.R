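#' Energy-intake schedules
#'
#' Prescribed energy intake as a function of time. Three kinds are
#' supported: `constant` (one level throughout), `step` (two levels with a
#' single switch, the form used to describe very-low-energy programmes where
#' food reintroduction raises intake from week 10), and `piecewise`
#' (arbitrary levels over half-open weekly intervals, used internally by the
#' synthetic-cohort generator to add compliance drift).
#'
#' Time is handled in days internally; week `k` spans days
#' `[7(k-1), 7k)`. Switches use the half-open convention: the new level
#' applies from the switch day onwards.
#'
#' @param level,level1,level2 intake levels, kcal/d (>= 0).
#' @param switch_week week at which a step schedule switches from `level1`
#'   to `level2` (> 0); the switch takes effect at day `7 * switch_week`.
#' @param levels numeric vector of intake levels for a piecewise schedule.
#' @param switch_weeks strictly increasing week indices, one fewer than
#'   `levels`; level `i+1` applies from day `7 * switch_weeks[i]`.
#' @return An object of class `eb_intake`.
#' @examples
#' constant_intake(800)
#' step_intake(800, 1200, switch_week = 10)  # the VLED default
#' piecewise_intake(c(800, 1000, 1400), c(8, 10))
#' @name intake_schedule
NULL

new_intake <- function(kind, levels, switch_weeks) {
  if (!is.numeric(levels) || any(!is.finite(levels)) || any(levels < 0)) {
    stop("intake levels must be >= 0 kcal/d", call. = FALSE)
  }
  if (length(switch_weeks)) {
    if (any(switch_weeks <= 0) || is.unsorted(switch_weeks, strictly = TRUE)) {
      stop("switch weeks must be positive and strictly increasing",
           call. = FALSE)
    }
  }
  if (length(levels) != length(switch_weeks) + 1) {
    stop("need exactly one more level than switch week", call. = FALSE)
  }
  structure(list(kind = kind, levels = as.numeric(levels),
                 switch_weeks = as.numeric(switch_weeks)),
            class = "eb_intake")
}

#' @rdname intake_schedule
#' @export
constant_intake <- function(level) {
  new_intake("constant", level, numeric(0))
}

#' @rdname intake_schedule
#' @export
step_intake <- function(level1 = 800, level2 = 1200, switch_week = 10) {
  new_intake("step", c(level1, level2), switch_week)
}

#' @rdname intake_schedule
#' @export
piecewise_intake <- function(levels, switch_weeks) {
  new_intake("piecewise", levels, switch_weeks)
}

#' @export
print.eb_intake <- function(x, ...) {
  if (x$kind == "constant") {
    cat(sprintf("Intake schedule: constant %g kcal/d\n", x$levels))
  } else {
    bounds <- c(0, x$switch_weeks, Inf)
    cat(sprintf("Intake schedule (%s):\n", x$kind))
    for (i in seq_along(x$levels)) {
      cat(sprintf("  weeks [%g, %g): %g kcal/d\n",
                  bounds[i], bounds[i + 1], x$levels[i]))
    }
  }
  invisible(x)
}

#' Energy intake at a given time
#'
#' @param t time since the start of the intervention, days (>= 0).
#'   Vectorised.
#' @param schedule an intake schedule; see [intake_schedule].
#' @return Intake in kcal/d at each `t`.
#' @examples
#' ll <- step_intake()
#' ei_at(c(35, 77), ll)   # 800 in week 5, 1200 in week 11
#' @export
ei_at <- function(t, schedule) {
  stopifnot(inherits(schedule, "eb_intake"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("t must be >= 0 days", call. = FALSE)
  }
  switch_days <- schedule$switch_weeks * 7
  idx <- findInterval(t, switch_days) + 1L  # half-open: switch day -> new level
  schedule$levels[idx]
}

# Days (within [0, t_end]) at which the schedule is discontinuous; the ODE
# integration is restarted at each.
intake_break_days <- function(schedule, t_end) {
  d <- schedule$switch_weeks * 7
  d[d > 0 & d < t_end]
}
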